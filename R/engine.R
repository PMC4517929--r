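## Core cohort simulator: a main life table plus one parallel life table per
## disease. Annual cycles; each disease table has susceptible / case
## occupancies with incidence inflow and case-fatality and remission
## outflows (remitted cases rejoin the susceptible pool). Total mortality each cycle is residual ("rest") mortality plus
## the disease-specific deaths, so the all-cause trend emerges as the
## death-weighted sum of modelled-disease trends and the long-run residual
## trend. Person-years use the half-cycle correction.

#' Engine run settings
#'
#' @param discount_rate annual discount rate applied by the summary
#'   functions (0 for the main analysis, 0.03 as a variant). Streams are
#'   stored undiscounted; discounting uses the end-of-year convention.
#' @param zero_morbidity if TRUE the utility weight is 1 everywhere, so
#'   accumulated "QALYs" are plain life-years.
#' @return an `mslt_config` list.
#' @export
mslt_config <- function(discount_rate = 0, zero_morbidity = FALSE) {
  structure(list(discount_rate = discount_rate,
                 zero_morbidity = zero_morbidity),
            class = "mslt_config")
}

## end-of-year discount factors for years 1..n
discount_factors <- function(n, rate) (1 + rate)^-(seq_len(n))

#' Run the multistate life table for one scenario
#'
#' Simulates the closed baseline-year cohort to extinction (terminal
#' absorption at age 110). Each annual cycle: (1) rates are trend-adjusted;
#' (2) each disease's incidence is scaled by `1 - PIF`; (3) the disease
#' tables advance (incidence inflow; case-fatality and remission outflows);
#' (4) total mortality is residual mortality plus disease-specific deaths;
#' (5) person-years, QALYs, and costs accrue.
#'
#' @param bundle input bundle.
#' @param trajectory smoking trajectory for the scenario (its horizon sets
#'   the simulated years).
#' @param pif optional PIF surface from [pif_surface()] (omit for the
#'   reference scenario the PIFs were computed against).
#' @param config an [mslt_config()].
#' @param equity if TRUE, minority strata are simulated with the majority's
#'   background (residual) mortality and background morbidity while keeping
#'   minority smoking and disease parameters — the equity analysis.
#' @return an `mslt_results` object holding `cohort x stratum x year` arrays
#'   of person-years, QALYs, costs, deaths, and per-disease deaths, plus the
#'   start-of-year alive counts.
#' @export
run_mslt <- function(bundle, trajectory, pif = NULL,
                     config = mslt_config(), equity = FALSE) {
  strata <- bundle$strata
  nA <- n_ages(strata); nS <- n_strata(strata)
  years <- trajectory$years
  nT <- length(years)
  base_year <- bundle$base_year
  sex_col <- match(strata$sex_of[strata$ids], strata$sexes)
  nD <- length(bundle$diseases)
  dis_names <- names(bundle$diseases)

  ## residual mortality from the all-cause surface and baseline disease deaths
  dis_deaths0 <- blank_surface(strata)
  for (d in bundle$diseases) {
    dis_deaths0 <- dis_deaths0 + d$prevalence * d$case_fatality
  }
  residual <- bundle$mortality - dis_deaths0
  if (any(residual < -1e-12)) {
    bad <- which(residual < -1e-12, arr.ind = TRUE)[1, ]
    stop(sprintf(paste0("run_mslt: modelled-disease deaths exceed all-cause ",
                        "mortality at age %s, stratum %s"),
                 strata$ages[bad[1]], strata$ids[bad[2]]))
  }
  residual[residual < 0] <- 0

  ## background morbidity net of the modelled diseases' share
  dr_prev0 <- blank_surface(strata)
  for (d in bundle$diseases) {
    dr_prev0 <- dr_prev0 + d$disability_rate[, sex_col] * d$prevalence
  }
  pyld_other <- bundle$pyld - dr_prev0
  if (any(pyld_other < -1e-9)) {
    stop("run_mslt: disease morbidity exceeds total morbidity (pyld_other < 0)")
  }
  pyld_other[pyld_other < 0] <- 0

  if (equity) {
    cp <- counterpart_cols(strata, strata$ethnicities[1])
    min_cols <- strata_cols(strata, ethnicity = strata$ethnicities[2])
    residual[, min_cols] <- residual[, cp[min_cols]]
    pyld_other[, min_cols] <- pyld_other[, cp[min_cols]]
  }

  eth_apc <- bundle$trends$residual_apc[strata$eth_of[strata$ids]]
  cap_year <- bundle$trends$cap_year

  ## per-disease trend factors for every simulated year: [year, disease]
  tf_inc <- vapply(bundle$diseases, function(d)
    trend_factor(d$apc_incidence, years, base_year, cap_year), numeric(nT))
  tf_cfr <- vapply(bundle$diseases, function(d)
    trend_factor(d$apc_case_fatality, years, base_year, cap_year), numeric(nT))
  tf_rem <- vapply(bundle$diseases, function(d)
    trend_factor(d$apc_remission, years, base_year, cap_year), numeric(nT))
  dim(tf_inc) <- dim(tf_cfr) <- dim(tf_rem) <- c(nT, nD)

  ## rate and state arrays stacked over diseases: [age, stratum, disease]
  stack <- function(get) {
    a <- array(0, dim = c(nA, nS, nD))
    for (k in seq_len(nD)) a[, , k] <- get(bundle$diseases[[k]])
    a
  }
  INC <- stack(function(d) d$incidence)
  CFR <- stack(function(d) d$case_fatality)
  REM <- stack(function(d) d$remission)
  DRR <- stack(function(d) d$disability_rate[, sex_col])
  ## disease occupancy as a proportion of the living cohort cell
  P <- stack(function(d) d$prevalence)
  cf1 <- vapply(bundle$diseases, `[[`, numeric(1), "cost_first_year")
  cfp <- vapply(bundle$diseases, `[[`, numeric(1), "cost_prevalent")
  cf6 <- vapply(bundle$diseases, `[[`, numeric(1), "cost_last6mo")

  residual <- unname(residual); pyld_other <- unname(pyld_other)
  baseline_cost <- unname(bundle$costs$baseline)

  alive <- array(0, dim = c(nA, nS, nT + 1L),
                 dimnames = list(cohort_age0 = strata$ages,
                                 stratum = strata$ids, year = NULL))
  alive[, , 1] <- bundle$population
  py <- qal <- cst <- dth <- array(0, dim = c(nA, nS, nT))
  ddth <- array(0, dim = c(nA, nS, nT, nD),
                dimnames = list(NULL, NULL, NULL, disease = dis_names))

  for (t in seq_len(nT)) {
    rt <- t:nA                          # age rows of the active cohorts
    n <- length(rt)                     # cohort rows 1..n (age = cohort+t-1)
    nc <- n * nS
    a_now <- alive[seq_len(n), , t, drop = FALSE]
    dim(a_now) <- c(n, nS)

    q_rest <- residual[rt, , drop = FALSE] *
      rep(trend_factor(eth_apc, years[t], base_year, cap_year), each = n)

    ## disease tables, all diseases at once: occupancy is the prevalent
    ## proportion of the living cohort cell, advanced by the illness-death
    ## flows p' = p + i (1 - p) - (f + r) p, with remission returning to the
    ## susceptible pool. Occupancy arrays are cohort-indexed (rows 1..n
    ## travel with their cohort); rate surfaces are gathered at the cohorts'
    ## current ages (rows rt).
    Pd <- P[seq_len(n), , , drop = FALSE]
    i_t <- INC[rt, , , drop = FALSE] * rep(tf_inc[t, ], each = nc)
    if (!is.null(pif)) {
      pif_t <- pif[seq_len(n), , t, , drop = FALSE]
      dim(pif_t) <- c(n, nS, nD)
      i_t <- i_t * (1 - pif_t)
    }
    i_t[i_t < 0] <- 0; i_t[i_t > 1] <- 1
    f_t <- CFR[rt, , , drop = FALSE] * rep(tf_cfr[t, ], each = nc)
    f_t[f_t > 1] <- 1
    r_t <- REM[rt, , , drop = FALSE] * rep(tf_rem[t, ], each = nc)
    r_t[r_t > 1] <- 1

    new_frac <- (1 - Pd) * i_t          # incident proportion this year
    die_frac <- Pd * f_t                # dying-of-disease proportion
    rem_frac <- Pd * r_t

    collapse <- function(a) {           # sum over the disease dimension
      dim(a) <- c(nc, nD)
      m <- rowSums(a)
      dim(m) <- c(n, nS); m
    }
    mort_sum <- collapse(die_frac)
    dr_sum <- collapse(DRR[rt, , , drop = FALSE] * Pd)
    cost_sum <- collapse(new_frac * rep(cf1, each = nc) +
                         Pd * rep(cfp, each = nc) +
                         die_frac * rep(cf6, each = nc))
    ddth[seq_len(n), , t, ] <- die_frac * as.vector(a_now)

    P[seq_len(n), , ] <- Pd + new_frac - die_frac - rem_frac

    q_tot <- q_rest + mort_sum
    q_tot[q_tot > 1] <- 1
    q_tot[n, ] <- 1                     # terminal absorption at age 110
    deaths <- a_now * q_tot
    a_next <- a_now - deaths
    person_years <- (a_now + a_next) / 2

    w <- if (config$zero_morbidity) {
      1
    } else {
      1 - (pyld_other[rt, , drop = FALSE] + dr_sum)
    }
    if (any(w < -1e-9)) {
      stop("run_mslt: utility weight below 0 — inconsistent morbidity inputs")
    }
    w[w < 0] <- 0

    alive[seq_len(n), , t + 1L] <- a_next
    dth[seq_len(n), , t] <- deaths
    py[seq_len(n), , t] <- person_years
    qal[seq_len(n), , t] <- person_years * w
    cst[seq_len(n), , t] <- a_now * baseline_cost[rt, , drop = FALSE] +
      a_now * cost_sum
  }

  structure(list(alive = alive, deaths = dth, disease_deaths = ddth,
                 person_years = py, qalys = qal, costs = cst,
                 years = years, strata = strata, config = config,
                 scenario = trajectory$scenario, equity = equity,
                 bundle_tag = bundle$tag),
            class = "mslt_results")
}

#' @export
print.mslt_results <- function(x, ...) {
  cat("<mslt_results> scenario:", x$scenario,
      if (x$equity) "(equity backgrounds)" else "", "\n")
  cat("  years", x$years[1], "-", x$years[length(x$years)],
      "| person-years", format(round(sum(x$person_years)), big.mark = ","),
      "| QALYs", format(round(sum(x$qalys)), big.mark = ","), "\n")
  invisible(x)
}

#' Totals per stratum from a life-table run
#'
#' @param results an `mslt_results`.
#' @param discount_rate overrides the rate in the run's config if given.
#' @return data frame with stratum, person_years, qalys, costs, deaths.
#' @export
results_totals <- function(results, discount_rate = NULL) {
  rate <- if (is.null(discount_rate)) results$config$discount_rate else discount_rate
  df <- discount_factors(length(results$years), rate)
  tot <- function(a) as.vector(apply(sweep(a, 3, df, `*`), 2, sum))
  data.frame(stratum = results$strata$ids,
             person_years = tot(results$person_years),
             qalys = tot(results$qalys),
             costs = tot(results$costs),
             deaths = as.vector(apply(results$deaths, 2, sum)),
             row.names = NULL)
}

#' Per-year aggregate streams from a life-table run
#'
#' @inheritParams results_totals
#' @return data frame with year and undiscounted person_years, qalys, costs.
#' @export
annual_streams <- function(results) {
  data.frame(year = results$years,
             person_years = apply(results$person_years, 3, sum),
             qalys = apply(results$qalys, 3, sum),
             costs = apply(results$costs, 3, sum))
}

#' Incremental results of an intervention against a comparator
#'
#' QALY gains, gross cost difference, the one-off law cost, and net cost
#' (negative net cost = net savings), per stratum and in total, in both the
#' model currency (NZ$) and US$ at purchasing power parity.
#'
#' @param intervention,bau `mslt_results` for the two scenarios (same strata
#'   and horizon).
#' @param law_cost one-off intervention cost charged to the intervention
#'   scenario in the base year.
#' @param discount_rate discount rate for the comparison (defaults to the
#'   intervention run's config).
#' @param ppp purchasing-power-parity factor; US$ values are NZ$ divided by
#'   this (default 1.486, which reproduces the NZ$-to-US$ magnitudes of the
#'   source costing even though a "multiply" reading of the same factor
#'   would not — see the package vignette).
#' @return an `mslt_incremental` list with `by_stratum` and `total`.
#' @export
incremental_results <- function(intervention, bau, law_cost = 0,
                                discount_rate = NULL, ppp = 1.486) {
  if (!identical(intervention$years, bau$years)) {
    stop("incremental_results: runs have different horizons")
  }
  rate <- if (is.null(discount_rate)) intervention$config$discount_rate else discount_rate
  ti <- results_totals(intervention, rate)
  tb <- results_totals(bau, rate)
  law_disc <- law_cost * discount_factors(1, rate)
  by_stratum <- data.frame(
    stratum = ti$stratum,
    d_qalys = ti$qalys - tb$qalys,
    d_person_years = ti$person_years - tb$person_years,
    d_costs = ti$costs - tb$costs,
    row.names = NULL)
  d_cost_tot <- sum(by_stratum$d_costs)
  net_cost <- d_cost_tot + law_disc
  total <- list(
    d_qalys = sum(by_stratum$d_qalys),
    d_person_years = sum(by_stratum$d_person_years),
    d_costs = d_cost_tot,
    law_cost = law_disc,
    net_cost_nzd = net_cost,
    net_savings_nzd = -net_cost,
    net_cost_usd = net_cost / ppp,
    net_savings_usd = -net_cost / ppp)
  structure(list(by_stratum = by_stratum, total = total,
                 discount_rate = rate, ppp = ppp),
            class = "mslt_incremental")
}

#' @export
print.mslt_incremental <- function(x, ...) {
  cat("<mslt_incremental> discount", x$discount_rate * 100, "%\n")
  cat(sprintf("  QALYs gained: %.1f | net savings: NZ$%.0f (US$%.0f)\n",
              x$total$d_qalys, x$total$net_savings_nzd,
              x$total$net_savings_usd))
  invisible(x)
}

#' Equity analysis: minority results on majority backgrounds
#'
#' Re-runs the life table with the minority strata given the majority's
#' residual mortality and background morbidity (smoking and disease
#' parameters stay minority-specific), so that health gains for the minority
#' are not devalued by its worse background rates.
#'
#' @inheritParams run_mslt
#' @return an `mslt_results` from the equity run.
#' @export
equity_recompute <- function(bundle, trajectory, pif = NULL,
                             config = mslt_config()) {
  run_mslt(bundle, trajectory, pif = pif, config = config, equity = TRUE)
}

#' All-cause mortality rates by current age from a run
#'
#' @param results an `mslt_results`.
#' @param year calendar year to extract.
#' @param combine_sexes if TRUE, deaths and person-years are pooled over
#'   sexes within each ethnicity.
#' @return data frame with age, group (stratum or ethnicity), deaths,
#'   person_years, rate (deaths per person-year).
#' @export
mortality_rates <- function(results, year, combine_sexes = FALSE) {
  t <- match(year, results$years)
  if (is.na(t)) stop("mortality_rates: year outside the simulated horizon")
  strata <- results$strata
  nA <- n_ages(strata)
  act <- seq_len(max(nA - t + 1L, 1L))
  ages_now <- strata$ages[act] + (t - 1L)
  d <- results$deaths[act, , t, drop = FALSE]; dim(d) <- c(length(act), n_strata(strata))
  p <- results$person_years[act, , t, drop = FALSE]; dim(p) <- dim(d)
  if (combine_sexes) {
    groups <- strata$ethnicities
    d2 <- sapply(groups, function(e) rowSums(d[, strata_cols(strata, ethnicity = e), drop = FALSE]))
    p2 <- sapply(groups, function(e) rowSums(p[, strata_cols(strata, ethnicity = e), drop = FALSE]))
  } else {
    groups <- strata$ids
    d2 <- d; p2 <- p
  }
  out <- data.frame(
    age = rep(ages_now, times = length(groups)),
    group = rep(groups, each = length(act)),
    deaths = as.vector(d2), person_years = as.vector(p2), row.names = NULL)
  out$rate <- ifelse(out$person_years > 0, out$deaths / out$person_years, NA_real_)
  out
}

#' Table-2-style summary of incremental gains by sex, baseline age group, and ethnicity
#'
#' @param intervention,bau `mslt_results` for the two scenarios.
#' @param bundle the input bundle (for per-capita denominators).
#' @param breaks baseline-age group boundaries.
#' @param discount_rate discount rate.
#' @return data frame of QALY gains and cost savings per group, with
#'   per-1,000-capita rates.
#' @export
incremental_by_group <- function(intervention, bau, bundle,
                                 breaks = c(0, 15, 25, 45, 65, 111),
                                 discount_rate = 0) {
  strata <- intervention$strata
  df <- discount_factors(length(intervention$years), discount_rate)
  dq <- sweep(intervention$qalys - bau$qalys, 3, df, `*`)
  dc <- sweep(intervention$costs - bau$costs, 3, df, `*`)
  dq2 <- apply(dq, c(1, 2), sum)   # cohort x stratum
  dc2 <- apply(dc, c(1, 2), sum)
  grp <- cut(strata$ages, breaks = breaks, right = FALSE)
  rows <- list()
  for (g in levels(grp)) {
    sel <- which(grp == g)
    for (j in seq_along(strata$ids)) {
      id <- strata$ids[j]
      popg <- sum(bundle$population[sel, j])
      rows[[length(rows) + 1L]] <- data.frame(
        sex = strata$sex_of[[id]], ethnicity = strata$eth_of[[id]],
        age_group = g, population = popg,
        qalys = sum(dq2[sel, j]), cost_savings = -sum(dc2[sel, j]),
        qalys_per_1000 = 1000 * sum(dq2[sel, j]) / max(popg, 1e-12),
        row.names = NULL)
    }
  }
  do.call(rbind, rows)
}

#' Internal validation: model mortality against input-implied mortality
#'
#' Intended for runs with all trends set to zero: compares, per disease and
#' age group, the model's disease-specific mortality rate in a given year
#' with the rate implied directly by the inputs (prevalence x case
#' fatality), and flags cells whose relative difference exceeds the
#' tolerance. Diseases with no deaths in a group are excluded.
#'
#' @param results an `mslt_results` (run with zeroed trends for the check to
#'   be meaningful).
#' @param bundle the input bundle the run used.
#' @param year calendar year at which to compare (default: 10 years in).
#' @param breaks age-group boundaries.
#' @param tolerance relative-difference threshold for flagging.
#' @return data frame with disease, age_group, model_rate, input_rate,
#'   rel_diff, flag.
#' @export
validate_internal <- function(results, bundle, year = NULL,
                              breaks = c(30, 45, 65, 85, 111),
                              tolerance = 0.10) {
  strata <- results$strata
  nA <- n_ages(strata)
  if (is.null(year)) year <- results$years[1] + 10L
  t <- match(year, results$years)
  act <- seq_len(nA - t + 1L)
  ages_now <- strata$ages[act] + (t - 1L)
  grp <- cut(ages_now, breaks = breaks, right = FALSE)
  ## compare annual risks: deaths over the population alive at the start of
  ## the year, matching the occupancy x case-fatality reading of the inputs
  at_risk <- results$alive[act, , t, drop = FALSE]
  dim(at_risk) <- c(length(act), n_strata(strata))
  age_idx <- match(ages_now, strata$ages)
  rows <- list()
  for (k in seq_along(bundle$diseases)) {
    d <- bundle$diseases[[k]]
    dd <- results$disease_deaths[act, , t, k, drop = FALSE]
    dim(dd) <- dim(at_risk)
    implied <- d$prevalence[age_idx, , drop = FALSE] *
      d$case_fatality[age_idx, , drop = FALSE]
    for (g in levels(grp)) {
      sel <- which(grp == g)
      if (!length(sel)) next
      model_rate <- sum(dd[sel, ]) / max(sum(at_risk[sel, ]), 1e-300)
      input_rate <- sum(implied[sel, ] * at_risk[sel, ]) /
        max(sum(at_risk[sel, ]), 1e-300)
      if (input_rate <= 0 && model_rate <= 0) next   # empty disease-group
      rel <- abs(model_rate - input_rate) / max(input_rate, 1e-300)
      rows[[length(rows) + 1L]] <- data.frame(
        disease = d$name, age_group = g, model_rate = model_rate,
        input_rate = input_rate, rel_diff = rel,
        flag = rel > tolerance, row.names = NULL)
    }
  }
  if (!length(rows)) return(data.frame())
  do.call(rbind, rows)
}

## zero out every trend in a bundle (validation runs)
zero_trends <- function(bundle) {
  bundle$trends$residual_apc[] <- 0
  for (k in seq_along(bundle$diseases)) {
    bundle$diseases[[k]]$apc_incidence <- 0
    bundle$diseases[[k]]$apc_case_fatality <- 0
    bundle$diseases[[k]]$apc_remission <- 0
  }
  bundle
}
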