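## Smoking-state projection: closed 2011 cohort, annual cycles.
##
## States: never, current, ex-smoker by single years since quitting (bins
## 0..19), and "former" (quit >= 20 years ago, carrying no excess risk).
## Distributions are fractions of the *surviving* members of each
## cohort-stratum cell; differential mortality by smoking state re-weights
## the composition each year and the fractions renormalise to 1.

EX_BINS <- 20L

#' Smoking state labels used throughout the package
#'
#' @return character vector: `never`, `current`, `ex00`..`ex19` (years since
#'   quitting), `former` (quit 20+ years ago, no excess risk).
#' @export
smoking_states <- function() {
  c("never", "current", sprintf("ex%02d", 0:(EX_BINS - 1L)), "former")
}

## all-cause mortality RR by smoking state (current vs never = rr_current,
## ex-smokers decay toward 1, never/former = 1)
state_mortality_rr <- function(rr_current, gamma) {
  states <- smoking_states()
  rr <- stats::setNames(rep(1, length(states)), states)
  rr["current"] <- rr_current
  rr[sprintf("ex%02d", 0:(EX_BINS - 1L))] <-
    rr_ex_smoker(rr_current, 0:(EX_BINS - 1L), gamma)
  rr
}

#' Tax schedule for annual excise increases
#'
#' @param start_year,end_year calendar years of the first and last annual tax
#'   rise (inclusive).
#' @param annual_increase proportional tax increase per rise (default 0.10).
#' @param elasticities data frame with columns `age_lo`, `age_hi`,
#'   `elasticity` giving the prevalence price elasticity per age band
#'   (elasticities must be `<= 0`). The default bands are 15-20: -0.38,
#'   21-24: -0.29, 25-34: -0.19, 35+: -0.10.
#' @param ethnic_scalar proportional uplift of the elasticity magnitude for
#'   the minority ethnicity (default 0.20, i.e. +20%).
#' @return object of class `tax_schedule`.
#' @export
tax_schedule <- function(start_year = 2011, end_year = 2031,
                         annual_increase = 0.10,
                         elasticities = default_elasticities(),
                         ethnic_scalar = 0.20) {
  if (end_year < start_year) stop("tax_schedule: end_year before start_year")
  if (any(elasticities$elasticity > 0)) {
    stop("tax_schedule: elasticities must be <= 0")
  }
  if (ethnic_scalar < 0) stop("tax_schedule: ethnic_scalar must be >= 0")
  structure(list(start_year = start_year, end_year = end_year,
                 annual_increase = annual_increase,
                 elasticities = elasticities,
                 ethnic_scalar = ethnic_scalar),
            class = "tax_schedule")
}

#' Default prevalence price elasticities by age band
#'
#' @return data frame with the four age bands and their elasticities
#'   (15-20: -0.38, 21-24: -0.29, 25-34: -0.19, 35+: -0.10).
#' @export
default_elasticities <- function() {
  data.frame(
    age_lo = c(15L, 21L, 25L, 35L),
    age_hi = c(20L, 24L, 34L, 110L),
    elasticity = c(-0.38, -0.29, -0.19, -0.10)
  )
}

## elasticity by single age (0 below the youngest band)
elasticity_by_age <- function(ages, elasticities) {
  e <- numeric(length(ages))
  for (k in seq_len(nrow(elasticities))) {
    in_band <- ages >= elasticities$age_lo[k] & ages <= elasticities$age_hi[k]
    e[in_band] <- elasticities$elasticity[k]
  }
  e
}

## cessation probability by single age from the three banded rates
cessation_by_age <- function(ages, cess) {
  # cess: numeric length 3, bands 20-34 / 35-54 / 55+
  out <- numeric(length(ages))
  out[ages >= 20 & ages <= 34] <- cess[1]
  out[ages >= 35 & ages <= 54] <- cess[2]
  out[ages >= 55] <- cess[3]
  out
}

## ---- core annual projection ------------------------------------------------

## One scenario projection. `tax` is NULL or a tax_schedule; `scenario` one of
## "bau", "no_cessation_ongoing_initiation", "complete_cessation_2011".
simulate_smoking <- function(bundle, horizon = NULL, tax = NULL,
                             scenario = "bau") {
  strata <- bundle$strata
  nA <- n_ages(strata); nS <- n_strata(strata)
  states <- smoking_states(); nK <- length(states)
  if (is.null(horizon)) horizon <- nA
  base_year <- bundle$base_year
  years <- base_year + seq_len(horizon) - 1L

  smo <- bundle$smoking
  cess <- smo$cessation                    # 3 bands x nS
  init0 <- smo$initiation_at_20            # nS
  init_apc <- smo$initiation_apc           # nS
  if (scenario == "no_cessation_ongoing_initiation") cess[] <- 0
  if (scenario == "complete_cessation_2011") { init0[] <- 0 }

  rr_state <- state_mortality_rr(smo$mortality_rr_current, smo$gamma_allcause)
  i_cur <- match("current", states); i_nev <- match("never", states)
  i_ex0 <- match("ex00", states); i_for <- match("former", states)
  ex_idx <- match(sprintf("ex%02d", 0:(EX_BINS - 1L)), states)

  # per-age cessation probabilities, one column per stratum
  cess_age <- vapply(seq_len(nS), function(j) cessation_by_age(strata$ages, cess[, j]),
                     numeric(nA))

  # elasticity by age x stratum (minority scaled up)
  if (!is.null(tax)) {
    e_age <- elasticity_by_age(strata$ages, tax$elasticities)
    minority <- strata$ethnicities[2]
    e_mat <- vapply(seq_len(nS), function(j) {
      if (strata$eth_of[[strata$ids[j]]] == minority) e_age * (1 + tax$ethnic_scalar) else e_age
    }, numeric(nA))
  }

  # residual-trend factors for the mortality used in differential survival
  eth_apc <- bundle$trends$residual_apc[strata$eth_of[strata$ids]]
  cap_year <- bundle$trends$cap_year

  dist <- array(0, dim = c(nA, nS, nK, horizon),
                dimnames = list(cohort_age0 = strata$ages, stratum = strata$ids,
                                state = states, year = years))
  mort_pad <- rbind(unname(bundle$mortality), rep(1, nS))  # age cap padding
  cess_pad <- rbind(cess_age, rep(0, nS))
  if (!is.null(tax)) e_pad <- rbind(e_mat, rep(0, nS))

  P <- bundle$smoking$initial              # [age, stratum, state] at base year
  if (scenario == "complete_cessation_2011") {
    P[, , i_ex0] <- P[, , i_ex0] + P[, , i_cur]
    P[, , i_cur] <- 0
  }
  if (!is.null(tax) && base_year >= tax$start_year && base_year <= tax$end_year) {
    P <- apply_tax_year(P, e_mat, tax$annual_increase, i_cur, i_ex0)
  }
  dist[, , , 1] <- P

  ## persistent working matrix: rows are (cohort, stratum) cells, cols states
  M <- matrix(P, ncol = nK)
  for (t in seq_len(horizon - 1L)) {
    year_next <- years[t + 1L]
    age_rows <- pmin(seq_len(nA) + t, nA + 1L)   # current age of each cohort

    ## 1. survival re-weighting under status-specific mortality
    q_all <- mort_pad[age_rows, , drop = FALSE] *
      rep(trend_factor(eth_apc, year_next, base_year, cap_year), each = nA)
    rbar <- as.vector(M %*% rr_state)
    rbar[rbar < 1e-300] <- 1e-300
    qv <- as.vector(q_all) / rbar          # per-cell scaling of state mortality
    surv <- 1 - outer(qv, rr_state)        # [cell, state] survival
    surv[surv < 0] <- 0
    M <- M * surv
    tot <- rowSums(M)
    tot[tot <= 0] <- 1
    M <- M / tot

    ## 2. ex-bin advance (one bin per simulated year)
    M[, i_for] <- M[, i_for] + M[, ex_idx[EX_BINS]]
    M[, ex_idx[2:EX_BINS]] <- M[, ex_idx[1:(EX_BINS - 1L)]]
    M[, ex_idx[1L]] <- 0

    ## 3. net cessation into ex-bin 0
    c_age <- as.vector(cess_pad[age_rows, , drop = FALSE])
    quit <- M[, i_cur] * c_age
    M[, i_cur] <- M[, i_cur] - quit
    M[, ex_idx[1L]] <- M[, ex_idx[1L]] + quit

    ## 4. initiation for the cohort reaching age 20 this year
    a20 <- 20L - t                          # cohort age0 whose age is 20 now
    if (a20 >= 1L && a20 <= 19L) {          # under 20 at baseline only
      rows <- a20 + 1L + (seq_len(nS) - 1L) * nA   # cell rows of that cohort
      rate <- init0 * (1 - init_apc)^(year_next - base_year)
      if (any(rate < 0 | rate > 1)) {
        stop("simulate_smoking: initiation rate outside [0, 1] after trend")
      }
      start <- M[cbind(rows, i_nev)] * rate
      M[cbind(rows, i_nev)] <- M[cbind(rows, i_nev)] - start
      M[cbind(rows, i_cur)] <- M[cbind(rows, i_cur)] + start
    }

    ## 5. tax-year prevalence shock (intervention only); elasticities are
    ## indexed by current age, so realign them to the cohort rows first
    if (!is.null(tax) && year_next >= tax$start_year && year_next <= tax$end_year) {
      e_now <- as.vector(e_pad[age_rows, , drop = FALSE])
      fac <- 1 + e_now * tax$annual_increase
      if (any(fac < 0)) {
        stop("tax effect: elasticity x increase implies negative prevalence")
      }
      cur <- M[, i_cur]
      displaced <- cur * (1 - fac)
      M[, i_cur] <- cur - displaced
      M[, i_ex0] <- M[, i_ex0] + displaced
    }

    dist[, , , t + 1L] <- M
  }

  structure(list(dist = dist, years = years, strata = strata,
                 scenario = scenario, schedule = tax,
                 bundle_tag = bundle$tag),
            class = "smoking_trajectory")
}

## multiply current prevalence by (1 + elasticity * increase) for ages 15+,
## displaced smokers enter ex-bin 0. P is [age0-as-current-age?, stratum, state]:
## rows are cohorts, but the elasticity matrix is passed already aligned to the
## *current age* of each row by the caller.
apply_tax_year <- function(P, e_mat, increase, i_cur, i_ex0) {
  fac <- 1 + e_mat * increase              # [age, stratum]
  if (any(fac < 0)) {
    stop("tax effect: elasticity x increase implies negative prevalence")
  }
  cur <- P[, , i_cur]
  displaced <- cur * (1 - fac)
  P[, , i_cur] <- cur - displaced
  P[, , i_ex0] <- P[, , i_ex0] + displaced
  P
}

#' Project business-as-usual smoking-state distributions
#'
#' Advances the baseline-year smoking-state distribution of the closed cohort
#' one year at a time: cohort members reaching age 20 initiate at a
#' geometrically declining rate, current smokers quit at banded net cessation
#' rates into the newest ex-bin, ex-bins advance by one year since quitting,
#' and the within-cell composition is re-weighted by survival under
#' status-specific all-cause mortality before renormalising to 1.
#'
#' @param bundle input bundle carrying the initial distribution, initiation
#'   and cessation rates, and mortality.
#' @param horizon number of simulated years (default: until the youngest
#'   cohort passes the age cap).
#' @return a `smoking_trajectory`: a `cohort x stratum x state x year` array
#'   of fractions plus metadata. Rows index the cohort by its age in the base
#'   year; the current age in simulated year `t` is `age0 + t - 1`.
#' @export
project_bau <- function(bundle, horizon = NULL) {
  simulate_smoking(bundle, horizon = horizon, tax = NULL, scenario = "bau")
}

#' Apply a tax schedule to a business-as-usual projection
#'
#' Re-simulates the projection with the tax-year prevalence shock: in each
#' year with a tax rise, current-smoker prevalence in each elasticity age
#' band is multiplied by `1 + elasticity * annual_increase` (a 10% rise with
#' elasticity -0.38 is a 3.8% relative reduction) and displaced smokers enter
#' the newest ex-bin. The minority elasticity is the majority value scaled by
#' `1 + ethnic_scalar`. The shock applies in tax years only; in other years
#' the modified state simply carries forward under the usual dynamics.
#'
#' @param traj a BAU trajectory from [project_bau()].
#' @param schedule a [tax_schedule()].
#' @param bundle the same input bundle the BAU trajectory was built from.
#' @return intervention `smoking_trajectory` on the same horizon.
#' @export
apply_tax_effect <- function(traj, schedule, bundle) {
  if (!inherits(schedule, "tax_schedule")) stop("apply_tax_effect: need a tax_schedule")
  if (!identical(traj$bundle_tag, bundle$tag)) {
    stop("apply_tax_effect: trajectory was built from a different bundle")
  }
  if (schedule$start_year < traj$years[1] ||
      schedule$end_year > traj$years[length(traj$years)]) {
    stop("apply_tax_effect: schedule years outside the simulation horizon")
  }
  simulate_smoking(bundle, horizon = length(traj$years), tax = schedule,
                   scenario = traj$scenario)
}

#' Counterfactual smoking scenarios spanning the tobacco-control envelope
#'
#' `"no_cessation_ongoing_initiation"`: cessation forced to zero from the
#' base year while initiation continues for cohort members under 20 at
#' baseline (prevalence rises until the youngest cohort passes age 20, then
#' declines through differential mortality only).
#' `"complete_cessation_2011"`: every current smoker moves to the newest
#' ex-bin in the base year and initiation is switched off.
#'
#' @param kind scenario label (above).
#' @param bundle input bundle.
#' @param horizon simulated years.
#' @return a `smoking_trajectory`.
#' @export
scenario_prevalence <- function(kind = c("no_cessation_ongoing_initiation",
                                         "complete_cessation_2011"),
                                bundle, horizon = NULL) {
  kind <- match.arg(kind)
  simulate_smoking(bundle, horizon = horizon, tax = NULL, scenario = kind)
}

#' Convert a smoking trajectory to a long data frame
#'
#' @param traj a `smoking_trajectory`.
#' @param states optional subset of state labels.
#' @return data frame with sex, age (current age), ethnicity, year, state,
#'   fraction.
#' @export
trajectory_to_long <- function(traj, states = NULL) {
  strata <- traj$strata
  dm <- dim(traj$dist)
  keep <- if (is.null(states)) smoking_states() else states
  rows <- list()
  for (t in seq_along(traj$years)) {
    act <- seq_len(dm[1] - t + 1L)
    ages_now <- strata$ages[act] + (t - 1L)
    for (s in keep) {
      k <- match(s, smoking_states())
      sl <- traj$dist[act, , k, t, drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        sex = rep(strata$sex_of[strata$ids], each = length(act)),
        age = rep(ages_now, times = dm[2]),
        ethnicity = rep(strata$eth_of[strata$ids], each = length(act)),
        year = traj$years[t], state = s,
        fraction = as.vector(sl), row.names = NULL)
    }
  }
  do.call(rbind, rows)
}

#' Current-smoker prevalence from a trajectory
#'
#' Population-weighted current-smoker prevalence per stratum-year (or
#' aggregated over strata), weighting cohort cells by baseline population.
#'
#' @param traj a `smoking_trajectory`.
#' @param bundle the input bundle (for baseline population weights).
#' @param ages optional restriction to current ages within this range.
#' @return data frame with year, stratum, prevalence.
#' @export
current_prevalence <- function(traj, bundle, ages = c(0, 110)) {
  strata <- traj$strata
  i_cur <- match("current", smoking_states())
  nA <- n_ages(strata)
  out <- expand.grid(year = traj$years, stratum = strata$ids,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$prevalence <- NA_real_
  for (t in seq_along(traj$years)) {
    act <- seq_len(nA - t + 1L)
    ages_now <- strata$ages[act] + (t - 1L)
    sel <- act[ages_now >= ages[1] & ages_now <= ages[2]]
    w <- bundle$population[sel, , drop = FALSE]
    p <- traj$dist[sel, , i_cur, t]
    prev <- colSums(w * p) / pmax(colSums(w), 1e-300)
    out$prevalence[out$year == traj$years[t]] <- prev
  }
  out
}
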