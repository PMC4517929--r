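#' Relative risk of an ex-smoker by time since quitting
#'
#' Excess relative risk decays exponentially toward the never-smoker risk and
#' is extinguished entirely 20 years after quitting:
#' `rr(t) = 1 + (rr_current - 1) * exp(-gamma * t)` for `t < 20`, and exactly 1
#' for `t >= 20`. The same formula applies symmetrically to protective
#' exposures (`rr_current < 1`), whose deficit likewise decays toward 1.
#'
#' @param rr_current relative risk for current versus never smokers (>= 0);
#'   may be a vector or matrix.
#' @param years_since_quit non-negative years since quitting (scalar or
#'   vector; recycled against `rr_current`).
#' @param gamma exponential decay rate per year.
#' @return relative risk(s), same shape as the broadcast of the inputs.
#' @export
rr_ex_smoker <- function(rr_current, years_since_quit, gamma) {
  if (any(rr_current < 0)) stop("rr_ex_smoker: rr_current must be >= 0")
  if (any(years_since_quit < 0)) stop("rr_ex_smoker: years_since_quit must be >= 0")
  rr <- 1 + (rr_current - 1) * exp(-gamma * years_since_quit)
  cut <- rep_len(years_since_quit >= 20, length(rr))
  rr[cut] <- 1
  rr
}

#' Apply an annual proportional trend to a rate, capped at a trend horizon
#'
#' Rates move by a constant annual proportional change (APC) from the base
#' year until `cap_year`, after which they are held flat (set
#' `cap_year = Inf` to extend the trend indefinitely).
#'
#' @param rate rate (scalar, vector, or surface matrix) at `base_year`.
#' @param apc signed annual proportional change (e.g. -0.0225 for a 2.25%/yr
#'   decline). `1 + apc` must be positive.
#' @param year calendar year the trended rate is wanted for (`>= base_year`).
#' @param base_year calendar year the input rate refers to.
#' @param cap_year last year the trend runs; flat thereafter.
#' @return trended rate, same shape as `rate`.
#' @export
apply_trend <- function(rate, apc, year, base_year = 2011, cap_year = 2026) {
  if (any(1 + apc <= 0)) stop("apply_trend: 1 + apc must be positive")
  if (any(year < base_year)) stop("apply_trend: year must be >= base_year")
  rate * (1 + apc)^(pmin(year, cap_year) - base_year)
}

## trend factor alone (used by the engine each cycle)
trend_factor <- function(apc, year, base_year, cap_year) {
  (1 + apc)^(pmin(year, cap_year) - base_year)
}

#' Population impact fraction from two exposure distributions
#'
#' `PIF = 1 - sum(p_int * rr) / sum(p_bau * rr)`, summed over smoking states
#' (never, current, each years-since-quit bin, and long-quit ex-smokers).
#' Applied to disease incidence as `incidence_int = incidence_bau * (1 - PIF)`.
#' For a protective exposure (RR < 1) a prevalence reduction yields a negative
#' PIF, i.e. an incidence increase.
#'
#' @param p_bau,p_int numeric vectors of state prevalences under the baseline
#'   and counterfactual scenarios (same length and state order; each should
#'   sum to 1 over states).
#' @param rr relative risk per state (never-smoker state has RR 1).
#' @return the population impact fraction (dimensionless, `<= 1`).
#' @export
population_impact_fraction <- function(p_bau, p_int, rr) {
  if (length(p_bau) != length(rr) || length(p_int) != length(rr)) {
    stop("population_impact_fraction: p_bau, p_int and rr must be the same length")
  }
  denom <- sum(p_bau * rr)
  if (denom <= 0) stop("population_impact_fraction: corrupted input, sum(p_bau * rr) <= 0")
  1 - sum(p_int * rr) / denom
}

## ---- smoking-state RR machinery -------------------------------------------
##
## With the exponential decay above, the exposure-weighted mean RR over the
## smoking states collapses to
##    sum_s p_s rr_s = 1 + (rr_current - 1) * E,
## where E = p_current + sum_tau p_ex(tau) exp(-gamma tau) is a disease-free
## "effective exposure" that depends on the disease only through its decay
## rate gamma. The engine exploits this: E is computed once per trajectory for
## each distinct gamma, and per-disease PIFs follow by broadcasting rr_current.

## weights over the smoking states for a given gamma
state_rr_weights <- function(gamma) {
  states <- smoking_states()
  w <- stats::setNames(numeric(length(states)), states)
  w["current"] <- 1
  w[sprintf("ex%02d", 0:19)] <- exp(-gamma * (0:19))
  w  # never and former have weight 0
}

## effective exposure E for each (cohort, stratum, year) of a trajectory,
## for one or several decay rates at once (one aperm, one matmul)
effective_exposure <- function(traj, gamma) {
  W <- vapply(gamma, state_rr_weights, numeric(length(smoking_states())))
  d <- traj$dist  # [cohort, stratum, state, year]
  dm <- dim(d)
  m <- aperm(d, c(1, 2, 4, 3))
  dim(m) <- c(dm[1] * dm[2] * dm[4], dm[3])  # rows: cohort x stratum x year
  e <- m %*% W
  lapply(stats::setNames(seq_along(gamma), as.character(gamma)), function(g) {
    out <- e[, g]
    dim(out) <- dm[c(1, 2, 4)]
    out
  })
}

#' Population impact fraction surface between two smoking trajectories
#'
#' Computes, for every disease in the bundle, the PIF linking the
#' counterfactual trajectory to the baseline one for each cohort (age in the
#' base year), stratum, and simulated year, using the disease's current-smoker
#' RR by sex and age and its ex-smoker decay rate.
#'
#' @param bundle an input bundle from [generate_bundle()] or [read_bundle()].
#' @param traj_bau,traj_int smoking trajectories from [project_bau()] /
#'   [apply_tax_effect()] / [scenario_prevalence()], on identical strata and
#'   horizons.
#' @return a `cohort x stratum x year x disease` PIF array (zero for
#'   cohort-years past the age cap).
#' @export
pif_surface <- function(bundle, traj_bau, traj_int) {
  if (!identical(dim(traj_bau$dist), dim(traj_int$dist))) {
    stop("pif_surface: trajectories have mismatched dimensions")
  }
  strata <- bundle$strata
  gammas <- unique(vapply(bundle$diseases, function(d) d$gamma, numeric(1)))
  E_bau <- effective_exposure(traj_bau, gammas)
  E_int <- effective_exposure(traj_int, gammas)

  nA <- n_ages(strata); nS <- n_strata(strata)
  horizon <- dim(traj_bau$dist)[4]
  sex_col <- match(strata$sex_of[strata$ids], strata$sexes)
  nD <- length(bundle$diseases)

  ## age index of cohort i at year t is i + t - 1; pad out-of-range with nA + 1
  idx <- outer(seq_len(nA), seq_len(horizon) - 1L, `+`)
  idx[idx > nA] <- nA + 1L               # reads the padding slot below

  pif <- array(0, dim = c(nA, nS, horizon, nD),
               dimnames = list(NULL, stratum = strata$ids, NULL,
                               disease = names(bundle$diseases)))
  for (k in seq_len(nD)) {
    dis <- bundle$diseases[[k]]
    eb <- E_bau[[as.character(dis$gamma)]]
    ei <- E_int[[as.character(dis$gamma)]]
    for (j in seq_len(nS)) {
      rr_pad <- c(dis$rr_current[, sex_col[j]], 1)
      rr_al <- rr_pad[idx]               # [cohort, year] current-age RR
      num <- 1 + (rr_al - 1) * ei[, j, ]
      den <- 1 + (rr_al - 1) * eb[, j, ]
      pif[, j, , k] <- 1 - num / den
    }
  }
  pif
}
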