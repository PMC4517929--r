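## Synthetic input generator: a fully self-consistent toy population with the
## statistical structure of a two-ethnicity high-income country, so the whole
## pipeline is testable without external data. Disease prevalence is derived
## from incidence / case fatality / remission by forward cohort simulation,
## so epidemiological coherence holds by construction.

#' Default definitions for the 16 tobacco-related diseases
#'
#' Coronary heart disease, stroke, COPD, lower respiratory tract infection,
#' and twelve cancers; smoking is protective (RR < 1) for the last three
#' (endometrial cancer, melanoma, thyroid cancer). Parameters are plausible
#' magnitudes for a high-income country, not estimates for any real one.
#'
#' @return data frame, one row per disease, with flags, incidence-curve and
#'   case-fatality parameters, relative risks, ex-smoker decay rates, excess
#'   costs, and annual-percent-change trends.
#' @export
default_disease_table <- function() {
  d <- function(name, cancer, protective, female_only, rr0, gamma, onset,
                peak_inc, cfr0, remission, dr, cf_first, cf_prev, cf_last,
                apc_inc, apc_cfr, apc_rem) {
    data.frame(name = name, is_cancer = cancer, is_protective = protective,
               female_only = female_only, rr0 = rr0, gamma = gamma,
               onset = onset, peak_inc = peak_inc, cfr0 = cfr0,
               remission = remission, dr = dr, cost_first_year = cf_first,
               cost_prevalent = cf_prev, cost_last6mo = cf_last,
               apc_incidence = apc_inc, apc_case_fatality = apc_cfr,
               apc_remission = apc_rem)
  }
  fast <- log(2) / 3    # cardiovascular excess risk halves every 3 years
  slow <- log(2) / 10   # cancers / respiratory halve every 10 years
  rbind(
    d("chd",        FALSE, FALSE, FALSE, 2.2, fast, 40, 0.020, 0.050, 0,    0.08, 15000, 2500, 25000, -0.020, -0.020, 0),
    d("stroke",     FALSE, FALSE, FALSE, 2.0, fast, 50, 0.012, 0.060, 0,    0.15, 18000, 4000, 25000, -0.020, -0.020, 0),
    d("copd",       FALSE, FALSE, FALSE, 8.0, slow, 45, 0.006, 0.050, 0,    0.20,  8000, 3000, 20000, -0.010, -0.010, 0),
    d("lrti",       FALSE, FALSE, FALSE, 2.0, slow,  0, 0.030, 0.005, NA,   0.02,  4000,    0,  8000,  0.000, -0.010, 0),
    d("lung_cancer",     TRUE, FALSE, FALSE, 12.0, slow, 50, 0.0040, 0.300, 0.10, 0.15, 30000, 4000, 35000, -0.005, -0.015, 0.005),
    d("oesophageal_cancer", TRUE, FALSE, FALSE, 3.0, slow, 55, 0.0006, 0.300, 0.08, 0.15, 30000, 4000, 35000, -0.003, -0.010, 0.005),
    d("stomach_cancer",  TRUE, FALSE, FALSE, 2.0, slow, 55, 0.0007, 0.250, 0.10, 0.12, 28000, 3500, 32000, -0.010, -0.010, 0.005),
    d("liver_cancer",    TRUE, FALSE, FALSE, 2.5, slow, 55, 0.0004, 0.350, 0.06, 0.15, 30000, 4000, 35000,  0.005, -0.010, 0.005),
    d("head_neck_cancer", TRUE, FALSE, FALSE, 4.0, slow, 50, 0.0008, 0.150, 0.14, 0.12, 26000, 3000, 30000, -0.005, -0.010, 0.005),
    d("pancreatic_cancer", TRUE, FALSE, FALSE, 2.0, slow, 55, 0.0005, 0.400, 0.04, 0.15, 30000, 4000, 35000,  0.000, -0.005, 0.002),
    d("cervical_cancer", TRUE, FALSE, TRUE, 1.8, slow, 35, 0.0004, 0.100, 0.16, 0.10, 24000, 2500, 28000, -0.010, -0.015, 0.005),
    d("bladder_cancer",  TRUE, FALSE, FALSE, 2.5, slow, 55, 0.0007, 0.120, 0.14, 0.10, 24000, 2500, 28000, -0.005, -0.010, 0.005),
    d("kidney_cancer",   TRUE, FALSE, FALSE, 1.8, slow, 50, 0.0005, 0.150, 0.12, 0.10, 26000, 3000, 30000,  0.000, -0.010, 0.005),
    d("endometrial_cancer", TRUE, TRUE, TRUE, 0.70, slow, 50, 0.0006, 0.080, 0.16, 0.08, 24000, 2500, 26000,  0.005, -0.010, 0.005),
    d("melanoma",        TRUE, TRUE, FALSE, 0.85, slow, 40, 0.0010, 0.060, 0.18, 0.05, 20000, 2000, 24000,  0.010, -0.015, 0.005),
    d("thyroid_cancer",  TRUE, TRUE, FALSE, 0.75, slow, 35, 0.0004, 0.040, 0.18, 0.05, 20000, 2000, 24000,  0.010, -0.015, 0.005)
  )
}

#' Generator settings
#'
#' @param total_population baseline cohort size (persons). The default is a
#'   1/100 scale of a 4.4-million population, keeping runs fast while leaving
#'   all per-capita outputs unchanged.
#' @param minority_share share of the total population in the minority
#'   ethnicity (default 0.15).
#' @param base_year first simulated calendar year.
#' @param prevalence_ratio minority / majority current-smoker prevalence
#'   ratio at adult ages (default 33/14, the high-smoking-minority pattern).
#' @param mortality_ratio minority / majority all-cause mortality ratio.
#' @param majority_adult_prevalence peak majority current-smoker prevalence.
#' @param mortality_rr_current all-cause mortality RR, current vs never
#'   smokers, used for differential survival in the smoking projection.
#' @param diseases disease definition table ([default_disease_table()]).
#' @param law_cost_full cost of the enabling law at full (4.4 M) population
#'   scale, NZ$ (default 3.54 million); scaled by the population scale.
#' @param law_cost_sd_full SD of the law cost at full scale (gamma).
#' @param jitter relative magnitude of the seed-dependent noise applied to
#'   generated curves (0 disables).
#' @return a `generator_config` list.
#' @export
generator_config <- function(total_population = 44000,
                             minority_share = 0.15,
                             base_year = 2011,
                             prevalence_ratio = 33 / 14,
                             mortality_ratio = 2.0,
                             majority_adult_prevalence = 0.16,
                             mortality_rr_current = 2.0,
                             diseases = default_disease_table(),
                             law_cost_full = 3.54e6,
                             law_cost_sd_full = 1.05e6,
                             jitter = 0.05) {
  structure(list(total_population = total_population,
                 minority_share = minority_share,
                 base_year = base_year,
                 prevalence_ratio = prevalence_ratio,
                 mortality_ratio = mortality_ratio,
                 majority_adult_prevalence = majority_adult_prevalence,
                 mortality_rr_current = mortality_rr_current,
                 diseases = diseases,
                 law_cost_full = law_cost_full,
                 law_cost_sd_full = law_cost_sd_full,
                 jitter = jitter),
            class = "generator_config")
}

## prevalence implied by forward-simulating the case fraction of the living
## population through the incidence -> case flow, with case fatality and
## remission as outflows: p' = p + i (1 - p) - (f + r) p. With constant
## rates and no remission this converges to the classic i / (i + f)
## steady state.
stationary_prevalence <- function(incidence, case_fatality, remission) {
  n <- length(incidence)
  prev <- numeric(n)
  p <- 0
  for (a in seq_len(n)) {
    prev[a] <- p
    p <- p + incidence[a] * (1 - p) - (case_fatality[a] + remission[a]) * p
    if (p < 0) p <- 0
  }
  prev
}

#' Check epidemiological coherence of a disease definition
#'
#' Forward-simulates a cohort through the disease's incidence, case-fatality
#' and remission rates over the full age range and reports, per stratum, the
#' maximum absolute difference between the supplied prevalence surface and
#' the implied one. The generator must achieve residuals below 0.005.
#'
#' @param disease a disease definition from a bundle (list with `incidence`,
#'   `prevalence`, `case_fatality`, `remission` surfaces).
#' @param mortality all-cause mortality surface on the same age grid (used
#'   only to verify the grids align; the disease flow itself excludes
#'   background mortality, which removes cases and non-cases alike).
#' @return data frame with columns `stratum` and `max_residual`.
#' @export
check_coherence <- function(disease, mortality) {
  surfs <- list(disease$incidence, disease$prevalence,
                disease$case_fatality, disease$remission, mortality)
  dims <- vapply(surfs, nrow, integer(1))
  if (length(unique(dims)) != 1) {
    stop("check_coherence: surfaces are defined on different age grids")
  }
  ids <- colnames(disease$incidence)
  res <- vapply(seq_along(ids), function(j) {
    implied <- stationary_prevalence(disease$incidence[, j],
                                     disease$case_fatality[, j],
                                     disease$remission[, j])
    max(abs(implied - disease$prevalence[, j]))
  }, numeric(1))
  data.frame(stratum = ids, max_residual = res, row.names = NULL)
}

#' Generate a self-consistent synthetic input bundle
#'
#' Builds the full model input set: a stratified baseline population, 16
#' disease definitions with coherent incidence / prevalence / case-fatality /
#' remission surfaces, smoking-state distributions with a high-prevalence
#' minority, initiation and cessation rates, cost and morbidity surfaces
#' rising with age, trends, and Monte Carlo distribution specifications.
#' Identical `(config, seed)` yields a bit-identical bundle.
#'
#' @param config a [generator_config()].
#' @param seed integer seed for the generator's random curve jitter.
#' @return an object of class `mslt_bundle`.
#' @export
generate_bundle <- function(config = generator_config(), seed = 1L) {
  validate_generator_config(config)
  set.seed(seed)
  strata <- stratum_set()
  nA <- n_ages(strata); nS <- n_strata(strata)
  ages <- strata$ages
  jit <- function(n = 1) exp(stats::rnorm(n, 0, config$jitter))

  ## ---- population ---------------------------------------------------------
  shape <- (1 - pmin(ages, 105) / 110)^1.2
  pop <- blank_surface(strata)
  for (j in seq_len(nS)) {
    eth <- strata$eth_of[[strata$ids[j]]]
    w <- shape * jit(nA)^0.4
    if (eth == strata$ethnicities[2]) w <- w * exp(-ages / 90)  # younger minority
    pop[, j] <- w
  }
  min_cols <- strata_cols(strata, ethnicity = strata$ethnicities[2])
  maj_cols <- strata_cols(strata, ethnicity = strata$ethnicities[1])
  tgt_min <- config$total_population * config$minority_share
  tgt_maj <- config$total_population - tgt_min
  pop[, min_cols] <- pop[, min_cols] * tgt_min / sum(pop[, min_cols])
  pop[, maj_cols] <- pop[, maj_cols] * tgt_maj / sum(pop[, maj_cols])

  ## ---- diseases -----------------------------------------------------------
  tab <- config$diseases
  sex_col <- match(strata$sex_of[strata$ids], strata$sexes)
  eth_min <- strata$eth_of[strata$ids] == strata$ethnicities[2]
  diseases <- vector("list", nrow(tab))
  names(diseases) <- tab$name
  for (k in seq_len(nrow(tab))) {
    p <- tab[k, ]
    inc <- blank_surface(strata); cfr <- blank_surface(strata)
    rem <- blank_surface(strata)
    for (j in seq_len(nS)) {
      sx <- strata$sex_of[[strata$ids[j]]]
      curve <- p$peak_inc * stats::plogis((ages - p$onset) / 8) * jit(1)
      if (p$female_only && sx == strata$sexes[1]) curve <- curve * 0
      if (eth_min[j] && !p$is_protective) curve <- curve * 1.4  # higher minority burden
      inc[, j] <- pmin(curve, 1)
      cfr[, j] <- pmin(p$cfr0 * (0.4 + 0.6 * stats::plogis((ages - 65) / 12)) * jit(1), 0.95)
    }
    if (p$name == "lrti") {
      inc[] <- pmin(0.01 + 0.05 * stats::plogis((ages - 70) / 10), 1) *
        rep(jit(nS), each = nA)
      rem[] <- 1 - cfr           # acute: survivors fully remit within the year
    } else if (p$is_cancer) {
      rem[] <- pmin(p$remission, 1 - cfr)
    }
    prev <- blank_surface(strata)
    for (j in seq_len(nS)) {
      prev[, j] <- stationary_prevalence(inc[, j], cfr[, j], rem[, j])
    }
    rr <- matrix(0, nA, 2, dimnames = list(age = ages, sex = strata$sexes))
    for (s in 1:2) {
      sex_fac <- if (s == 1) 1.05 else 0.95
      rr[, s] <- 1 + (p$rr0 - 1) * sex_fac * exp(-pmax(0, ages - 40) / 80)
    }
    rr[rr < 0] <- 0
    dr <- matrix(p$dr * (0.8 + 0.4 * stats::plogis((ages - 60) / 20)), nA, 2,
                 dimnames = list(age = ages, sex = strata$sexes))
    diseases[[k]] <- list(
      name = p$name, is_cancer = p$is_cancer, is_protective = p$is_protective,
      female_only = p$female_only,
      incidence = inc, prevalence = prev, case_fatality = cfr, remission = rem,
      rr_current = rr, gamma = p$gamma, disability_rate = dr,
      cost_first_year = p$cost_first_year * jit(1),
      cost_prevalent = p$cost_prevalent * jit(1),
      cost_last6mo = p$cost_last6mo * jit(1),
      apc_incidence = p$apc_incidence, apc_case_fatality = p$apc_case_fatality,
      apc_remission = p$apc_remission
    )
  }

  ## ---- mortality: residual Gompertz + modelled-disease deaths -------------
  residual <- blank_surface(strata)
  for (j in seq_len(nS)) {
    q <- 2e-4 + 0.004 * exp(-ages / 2) + 1e-4 * exp(0.082 * ages) * jit(1)
    if (eth_min[j]) q <- q * config$mortality_ratio
    residual[, j] <- pmin(q, 0.6)
  }
  disease_deaths <- blank_surface(strata)
  for (d in diseases) disease_deaths <- disease_deaths + d$prevalence * d$case_fatality
  mortality <- pmin(residual + disease_deaths, 0.95)

  ## ---- morbidity (pYLD) and costs -----------------------------------------
  pyld_base <- blank_surface(strata)
  for (j in seq_len(nS)) {
    pyld_base[, j] <- (0.02 + 0.18 * (ages / 110)^2) * jit(1) *
      (if (eth_min[j]) 1.15 else 1)
  }
  dr_prev0 <- blank_surface(strata)
  for (d in diseases) dr_prev0 <- dr_prev0 + d$disability_rate[, sex_col] * d$prevalence
  pyld_total <- pmin(pyld_base + dr_prev0, 0.95)

  baseline_cost <- blank_surface(strata)
  for (j in seq_len(nS)) {
    baseline_cost[, j] <- (1500 + 13000 * (ages / 110)^3) * jit(1)
  }
  pop_scale <- config$total_population / 4.4e6
  law_cost <- config$law_cost_full * pop_scale
  law_cost_sd <- config$law_cost_sd_full * pop_scale

  ## ---- smoking ------------------------------------------------------------
  states <- smoking_states(); nK <- length(states)
  i_nev <- match("never", states); i_cur <- match("current", states)
  i_for <- match("former", states)
  ex_idx <- match(sprintf("ex%02d", 0:(EX_BINS - 1L)), states)
  initial <- array(0, dim = c(nA, nS, nK),
                   dimnames = list(age = ages, stratum = strata$ids, state = states))
  uptake <- stats::plogis((ages - 19) / 2)          # ramp over ages 15-25
  taper <- 1 - 0.55 * stats::plogis((ages - 60) / 10)
  ex_w <- exp(-(0:(EX_BINS - 1L)) / 8); ex_w <- ex_w / sum(ex_w) * 0.5
  for (j in seq_len(nS)) {
    cur <- config$majority_adult_prevalence * uptake * taper
    if (eth_min[j]) cur <- cur * config$prevalence_ratio
    cur <- pmin(cur, 0.85)
    ex_tot <- 0.30 * stats::plogis((ages - 45) / 12) * (if (eth_min[j]) 1.2 else 1)
    ex_tot <- pmin(ex_tot, 1 - cur - 0.02)
    initial[, j, i_cur] <- cur
    for (b in seq_len(EX_BINS)) initial[, j, ex_idx[b]] <- ex_tot * ex_w[b]
    initial[, j, i_for] <- ex_tot * 0.5
    initial[, j, i_nev] <- 1 - cur - ex_tot
  }

  cess <- matrix(0, 3, nS, dimnames = list(band = c("20-34", "35-54", "55+"),
                                           stratum = strata$ids))
  # annual net cessation probabilities by sex x ethnicity x age band
  cess_tab <- list(
    "male.majority"   = c(0.0414, 0.0384, 0.0722),
    "female.majority" = c(0.0554, 0.0431, 0.0714),
    "male.minority"   = c(0.0393, 0.0369, 0.0769),
    "female.minority" = c(0.0451, 0.0472, 0.0699))
  for (id in strata$ids) cess[, id] <- cess_tab[[id]]
  init_at_20 <- stats::setNames(numeric(nS), strata$ids)
  init_apc <- stats::setNames(numeric(nS), strata$ids)
  init_tab <- list("male.majority" = c(0.18, 0.0339),
                   "female.majority" = c(0.16, 0.0276),
                   "male.minority" = c(0.36, 0.0288),
                   "female.minority" = c(0.33, 0.0322))
  for (id in strata$ids) {
    init_at_20[id] <- init_tab[[id]][1]
    init_apc[id] <- init_tab[[id]][2]
  }

  bundle <- structure(list(
    strata = strata,
    base_year = config$base_year,
    population = pop,
    mortality = mortality,
    residual_mortality = residual,
    pyld = pyld_total,
    diseases = diseases,
    costs = list(baseline = baseline_cost, law_cost = law_cost,
                 law_cost_sd = law_cost_sd),
    smoking = list(initial = initial, cessation = cess,
                   initiation_at_20 = init_at_20, initiation_apc = init_apc,
                   mortality_rr_current = config$mortality_rr_current,
                   gamma_allcause = log(2) / 3),
    trends = list(residual_apc = stats::setNames(c(-0.0175, -0.0225),
                                                 strata$ethnicities),
                  cap_year = 2026),
    elasticities = list(bands = default_elasticities(), ethnic_scalar = 0.20),
    dist_specs = default_dist_specs(names(diseases)),
    seed = seed,
    config = config,
    tag = sprintf("msltax-bundle-seed%d-n%d-m%0.3f", seed,
                  round(config$total_population), config$minority_share)
  ), class = "mslt_bundle")
  bundle
}

validate_generator_config <- function(config) {
  bad <- character(0)
  if (is.null(config$diseases) || nrow(config$diseases) < 1) {
    bad <- c(bad, "diseases: need at least one disease definition")
  }
  if (is.null(config$minority_share) || config$minority_share <= 0 ||
      config$minority_share >= 1) {
    bad <- c(bad, "minority_share: must be in (0, 1)")
  }
  if (is.null(config$total_population) || config$total_population <= 0) {
    bad <- c(bad, "total_population: must be positive")
  }
  if (length(bad)) {
    stop("invalid generator config:\n  ", paste(bad, collapse = "\n  "))
  }
  invisible(config)
}

#' @export
print.mslt_bundle <- function(x, ...) {
  cat("<mslt_bundle> seed", x$seed, "base year", x$base_year, "\n")
  cat("  population:", format(round(sum(x$population)), big.mark = ","),
      "in", n_strata(x$strata), "strata x", n_ages(x$strata), "ages\n")
  cat("  diseases:", length(x$diseases),
      sprintf("(%d protective)", sum(vapply(x$diseases, `[[`, logical(1),
                                            "is_protective"))), "\n")
  invisible(x)
}

## Monte Carlo distribution specifications (see uncertainty module).
## relative = TRUE: sd is a fraction of the point estimate.
default_dist_specs <- function(disease_names) {
  specs <- list(
    list(name = "pyld", family = "lognormal", sd = 0.10, relative = TRUE,
         correlation_family = "pyld"),
    list(name = "baseline_cost", family = "lognormal", sd = 0.10,
         relative = TRUE, correlation_family = "costs"),
    list(name = "disease_costs", family = "lognormal", sd = 0.10,
         relative = TRUE, correlation_family = "costs"),
    list(name = "initiation", family = "beta", sd = 0.20, relative = TRUE,
         correlation_family = "initiation"),
    list(name = "cessation", family = "beta", sd = 0.20, relative = TRUE,
         correlation_family = "cessation"),
    list(name = "tax_increase", family = "normal", sd = 0.01,
         relative = FALSE, correlation_family = "tax_increase"),
    list(name = "elasticity", family = "normal", sd = 0.20, relative = TRUE,
         correlation_family = "elasticity"),
    list(name = "ethnic_scalar", family = "normal", sd = 0.10,
         relative = FALSE, correlation_family = "ethnic_scalar"),
    list(name = "law_cost", family = "gamma", sd = NA, relative = FALSE,
         correlation_family = "law_cost")
  )
  for (d in disease_names) {
    specs <- c(specs, list(
      list(name = paste0("rates_", d), family = "normal", sd = 0.05,
           relative = TRUE, correlation_family = paste0("rates_", d)),
      list(name = paste0("apc_", d), family = "normal", sd = 0.005,
           relative = FALSE, correlation_family = paste0("apc_", d)),
      list(name = paste0("dr_", d), family = "normal", sd = 0.10,
           relative = TRUE, correlation_family = paste0("dr_", d)),
      list(name = paste0("rr_", d), family = "lognormal", sd = 0.10,
           relative = TRUE, correlation_family = paste0("rr_", d))
    ))
  }
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}
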