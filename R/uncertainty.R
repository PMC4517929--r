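## Correlated Monte Carlo parameter sampling and the scenario-analysis
## driver. Parameters sharing a correlation family are comonotone: one
## uniform quantile per family per draw is mapped through each member's
## moment-matched marginal (normal, lognormal, beta, or gamma).

#' Monte Carlo draw plan
#'
#' Pre-computes the shared uniform quantiles: one per correlation family per
#' draw, so parameters tagged to the same family have rank correlation 1
#' while families are mutually independent. The same seed always yields the
#' identical draw sequence.
#'
#' @param n_draws number of Monte Carlo draws (4,000 for full runs; small
#'   values for tests).
#' @param seed integer seed.
#' @param sd_scaling multiplies every spec's SD (0.5 / 1 / 2 in scenario
#'   analyses).
#' @param specs distribution specs (defaults to the bundle's at sampling
#'   time; only needed here to fix the family set).
#' @return a `draw_plan` with the quantile matrix.
#' @export
draw_plan <- function(n_draws = 50, seed = 1L, sd_scaling = 1,
                      specs = default_dist_specs(default_disease_table()$name)) {
  if (n_draws < 1) stop("draw_plan: n_draws must be >= 1")
  fams <- unique(vapply(specs, `[[`, character(1), "correlation_family"))
  set.seed(seed)
  q <- matrix(stats::runif(n_draws * length(fams)), nrow = n_draws,
              dimnames = list(NULL, fams))
  structure(list(n_draws = n_draws, seed = seed, sd_scaling = sd_scaling,
                 quantiles = q, families = fams),
            class = "draw_plan")
}

## quantile of a moment-matched marginal with mean m > 0 and sd s
q_marginal <- function(u, family, m, s) {
  if (all(s == 0)) return(rep_len(m, max(length(u), length(m))))
  switch(family,
    normal = stats::qnorm(u, m, s),
    lognormal = {
      s2 <- log(1 + (s / m)^2)
      stats::qlnorm(u, log(m) - s2 / 2, sqrt(s2))
    },
    beta = {
      v <- s^2
      v <- pmin(v, 0.95 * m * (1 - m))   # keep the (mean, sd) pair feasible
      a <- m * (m * (1 - m) / v - 1)
      stats::qbeta(u, a, (1 - m) / m * a)
    },
    gamma = stats::qgamma(u, shape = (m / s)^2, rate = m / s^2),
    stop(sprintf("q_marginal: unknown distribution family '%s'", family))
  )
}

## perturbation factor with mean 1 for a relative-SD spec
q_factor <- function(u, family, rel_sd) q_marginal(u, family, 1, rel_sd)

#' Draw a perturbed input bundle and tax schedule
#'
#' Applies one Monte Carlo draw of every uncertain parameter: disease rates
#' (one +/-5% factor per disease, correlated across strata and across the
#' rate set), trends (+/-0.5 percentage points), morbidity and costs
#' (+/-10%, lognormal), initiation and cessation (+/-20%, beta, one quantile
#' per family), smoking relative risks (lognormal factor on the excess risk),
#' the tax increase (+/-1 percentage point), elasticities (+/-20%, one
#' quantile across the four age bands), the minority elasticity scalar
#' (normal, SD 0.10 absolute), and the law cost (gamma). Draws from every
#' family have mean equal to the point estimate.
#'
#' @param bundle input bundle (point estimates).
#' @param plan a [draw_plan()].
#' @param i draw index in `1..n_draws`.
#' @param schedule a [tax_schedule()] to perturb alongside the bundle.
#' @return list with elements `bundle`, `schedule`, `law_cost`.
#' @export
sample_parameters <- function(bundle, plan, i, schedule = tax_schedule()) {
  if (i < 1 || i > plan$n_draws) stop("sample_parameters: draw index out of range")
  u <- plan$quantiles[i, ]
  sc <- plan$sd_scaling
  specs <- bundle$dist_specs
  gq <- function(name) {
    sp <- specs[[name]]
    if (is.null(sp)) stop(sprintf("sample_parameters: no spec named '%s'", name))
    u[[sp$correlation_family]]
  }
  fac <- function(name) {
    sp <- specs[[name]]
    q_factor(u[[sp$correlation_family]], sp$family, sp$sd * sc)
  }

  b <- bundle
  ## morbidity and costs
  b$pyld <- b$pyld * fac("pyld")
  b$costs$baseline <- b$costs$baseline * fac("baseline_cost")
  cost_f <- fac("disease_costs")

  ## smoking initiation / cessation: per-cell beta marginals, shared quantile
  ui <- gq("initiation"); uc <- gq("cessation")
  b$smoking$initiation_at_20[] <- q_marginal(
    ui, "beta", bundle$smoking$initiation_at_20,
    specs$initiation$sd * sc * bundle$smoking$initiation_at_20)
  b$smoking$cessation[] <- q_marginal(
    uc, "beta", as.vector(bundle$smoking$cessation),
    specs$cessation$sd * sc * as.vector(bundle$smoking$cessation))

  ## per-disease rate sets, trends, disability, relative risks
  for (k in seq_along(b$diseases)) {
    d <- b$diseases[[k]]
    rf <- fac(paste0("rates_", d$name))
    d$incidence <- pmin(d$incidence * rf, 1)
    d$case_fatality <- pmin(d$case_fatality * rf, 1)
    d$remission <- pmin(d$remission * rf, 1)
    d$prevalence <- pmin(d$prevalence * rf, 1)
    apc_spec <- specs[[paste0("apc_", d$name)]]
    apc_shift <- stats::qnorm(u[[apc_spec$correlation_family]], 0, apc_spec$sd * sc)
    d$apc_incidence <- d$apc_incidence + apc_shift
    d$apc_case_fatality <- d$apc_case_fatality + apc_shift
    d$disability_rate <- d$disability_rate * fac(paste0("dr_", d$name))
    rr_f <- fac(paste0("rr_", d$name))
    d$rr_current <- pmax(1 + (d$rr_current - 1) * rr_f, 0)
    d$cost_first_year <- d$cost_first_year * cost_f
    d$cost_prevalent <- d$cost_prevalent * cost_f
    d$cost_last6mo <- d$cost_last6mo * cost_f
    b$diseases[[k]] <- d
  }

  ## keep all-cause mortality coherent with the perturbed disease deaths
  if (!is.null(bundle$residual_mortality)) {
    dd <- blank_surface(b$strata)
    for (d in b$diseases) dd <- dd + d$prevalence * d$case_fatality
    b$mortality <- pmin(bundle$residual_mortality + dd, 0.95)
  }

  ## intervention parameters
  s <- schedule
  s$annual_increase <- q_marginal(gq("tax_increase"), "normal",
                                  schedule$annual_increase,
                                  specs$tax_increase$sd * sc)
  e_f <- fac("elasticity")
  s$elasticities$elasticity <- schedule$elasticities$elasticity * e_f
  s$ethnic_scalar <- max(0, q_marginal(gq("ethnic_scalar"), "normal",
                                       schedule$ethnic_scalar,
                                       specs$ethnic_scalar$sd * sc))
  law <- q_marginal(gq("law_cost"), "gamma", bundle$costs$law_cost,
                    max(bundle$costs$law_cost_sd * sc, 1e-12))
  list(bundle = b, schedule = s, law_cost = law)
}

#' Compare the tax intervention against business as usual
#'
#' Runs the full pipeline once at point estimates (or for a supplied
#' perturbed draw): BAU and tax smoking projections, PIF surface, the two
#' life tables, and the incremental summary.
#'
#' @param bundle input bundle.
#' @param schedule a [tax_schedule()].
#' @param config an [mslt_config()].
#' @param law_cost one-off law cost (defaults to the bundle's).
#' @param horizon simulated years (default: full cohort lifetime).
#' @return list with `incremental`, `res_bau`, `res_int`, `traj_bau`,
#'   `traj_int`, `pif`.
#' @export
mslt_compare <- function(bundle, schedule = tax_schedule(),
                         config = mslt_config(), law_cost = NULL,
                         horizon = NULL) {
  traj_bau <- project_bau(bundle, horizon)
  traj_int <- apply_tax_effect(traj_bau, schedule, bundle)
  pif <- pif_surface(bundle, traj_bau, traj_int)
  res_bau <- run_mslt(bundle, traj_bau, NULL, config)
  res_int <- run_mslt(bundle, traj_int, pif, config)
  if (is.null(law_cost)) law_cost <- bundle$costs$law_cost
  inc <- incremental_results(res_int, res_bau, law_cost = law_cost)
  list(incremental = inc, res_bau = res_bau, res_int = res_int,
       traj_bau = traj_bau, traj_int = traj_int, pif = pif)
}

#' Monte Carlo uncertainty analysis
#'
#' Repeats the tax-vs-BAU comparison over perturbed parameter draws and
#' summarizes the outputs with means, medians, and 2.5/97.5-percentile
#' uncertainty intervals.
#'
#' @param bundle input bundle.
#' @param plan a [draw_plan()] (needs `n_draws >= 2` for intervals).
#' @param schedule a [tax_schedule()].
#' @param config an [mslt_config()].
#' @param horizon simulated years.
#' @return an `mslt_uncertainty` list: per-draw outputs (`draws`) and the
#'   `summary` table.
#' @export
run_uncertainty <- function(bundle, plan, schedule = tax_schedule(),
                            config = mslt_config(), horizon = NULL) {
  if (plan$n_draws < 2) stop("run_uncertainty: need n_draws >= 2 for intervals")
  strata <- bundle$strata
  min_cols <- strata_cols(strata, ethnicity = strata$ethnicities[2])
  rows <- vector("list", plan$n_draws)
  for (i in seq_len(plan$n_draws)) {
    dr <- sample_parameters(bundle, plan, i, schedule)
    cmp <- mslt_compare(dr$bundle, dr$schedule, config,
                        law_cost = dr$law_cost, horizon = horizon)
    tot <- cmp$incremental$total
    rows[[i]] <- data.frame(
      draw = i,
      d_qalys = tot$d_qalys,
      d_qalys_minority = sum(cmp$incremental$by_stratum$d_qalys[min_cols]),
      net_cost_nzd = tot$net_cost_nzd,
      net_savings_usd = tot$net_savings_usd)
  }
  draws <- do.call(rbind, rows)
  outs <- setdiff(names(draws), "draw")
  summ <- do.call(rbind, lapply(outs, function(v) {
    x <- draws[[v]]
    data.frame(output = v, mean = mean(x), median = stats::median(x),
               lo95 = stats::quantile(x, 0.025, names = FALSE),
               hi95 = stats::quantile(x, 0.975, names = FALSE),
               ui_width = diff(stats::quantile(x, c(0.025, 0.975),
                                               names = FALSE)))
  }))
  structure(list(draws = draws, summary = summ, plan = plan),
            class = "mslt_uncertainty")
}

#' Scenario specification
#'
#' Each switch maps to exactly one documented mutation of the run
#' configuration: the annual tax rate, the last tax year, extending rate
#' trends beyond their cap indefinitely, removing the minority elasticity
#' uplift, and the life-year variant (all morbidity and the discount rate
#' set to zero).
#'
#' @param name scenario label.
#' @param tax_rate annual tax increase.
#' @param end_year last tax year.
#' @param extend_trends if TRUE, trends run indefinitely.
#' @param ethnic_scalar_off if TRUE, minority elasticity equals majority.
#' @param zero_morbidity_zero_discount if TRUE, outputs are life-years.
#' @param discount_rate discount rate.
#' @return a `scenario_spec` list.
#' @export
scenario_spec <- function(name, tax_rate = 0.10, end_year = 2031,
                          extend_trends = FALSE, ethnic_scalar_off = FALSE,
                          zero_morbidity_zero_discount = FALSE,
                          discount_rate = 0) {
  structure(list(name = name, tax_rate = tax_rate, end_year = end_year,
                 extend_trends = extend_trends,
                 ethnic_scalar_off = ethnic_scalar_off,
                 zero_morbidity_zero_discount = zero_morbidity_zero_discount,
                 discount_rate = discount_rate),
            class = "scenario_spec")
}

#' Run a set of scenario analyses
#'
#' Executes the tax-vs-BAU comparison once per scenario at point estimates
#' and tabulates incremental QALYs (or life-years), net cost, and ratios
#' against the first (base) scenario.
#'
#' @param bundle input bundle.
#' @param specs list of [scenario_spec()]s; the first is the base.
#' @param horizon simulated years.
#' @return data frame, one row per scenario.
#' @export
run_scenarios <- function(bundle, specs, horizon = NULL) {
  known <- names(scenario_spec("x"))
  rows <- lapply(specs, function(sp) {
    if (!inherits(sp, "scenario_spec")) stop("run_scenarios: specs must be scenario_spec objects")
    if (!all(names(sp) %in% known)) {
      stop("run_scenarios: unknown switch: ",
           paste(setdiff(names(sp), known), collapse = ", "))
    }
    b <- bundle
    if (sp$extend_trends) b$trends$cap_year <- Inf
    sched <- tax_schedule(end_year = sp$end_year,
                          annual_increase = sp$tax_rate,
                          ethnic_scalar = if (sp$ethnic_scalar_off) 0 else
                            bundle$elasticities$ethnic_scalar)
    cfg <- mslt_config(discount_rate =
                         if (sp$zero_morbidity_zero_discount) 0 else sp$discount_rate,
                       zero_morbidity = sp$zero_morbidity_zero_discount)
    cmp <- mslt_compare(b, sched, cfg, horizon = horizon)
    tot <- cmp$incremental$total
    min_cols <- strata_cols(b$strata, ethnicity = b$strata$ethnicities[2])
    data.frame(
      scenario = sp$name,
      outcome = if (sp$zero_morbidity_zero_discount) "life_years" else "qalys",
      gain = if (sp$zero_morbidity_zero_discount) tot$d_person_years else tot$d_qalys,
      gain_minority = sum(cmp$incremental$by_stratum$d_qalys[min_cols]),
      net_cost_nzd = tot$net_cost_nzd,
      row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out$gain_ratio_vs_base <- out$gain / out$gain[1]
  out
}
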