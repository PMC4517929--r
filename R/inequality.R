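## Age-standardized mortality and ethnic inequality metrics: standardized
## rates (WHO World Standard weights), standardized rate differences (SRD),
## rate ratios (SRR), and percentage changes between scenarios.

#' WHO World Standard Population weights
#'
#' The 2000-2025 WHO World Standard age distribution in 5-year bands
#' (85+ pooled), as percentages summing to 100.
#'
#' @return data frame with `age_lo`, `age_hi`, `weight`.
#' @export
who_standard_weights <- function() {
  data.frame(
    age_lo = c(seq(0, 85, by = 5)),
    age_hi = c(seq(4, 84, by = 5), 110),
    weight = c(8.86, 8.69, 8.60, 8.47, 8.22, 7.93, 7.61, 7.15, 6.59,
               6.04, 5.37, 4.55, 3.72, 2.96, 2.21, 1.52, 0.91, 0.63)
  )
}

#' Age-standardize a mortality rate schedule
#'
#' Computes `sum(w_a * rate_a) * 100000` with weights renormalized to sum to
#' 1 over the ages supplied (so any contiguous band — 45-64, 65-84, 85+, all
#' 45+ — can be standardized with the same standard population).
#'
#' @param rates deaths per person-year, one value per entry of `ages`.
#' @param ages single-year ages the rates refer to. May be omitted when
#'   `weights` is a numeric vector aligned with `rates`.
#' @param weights either the data frame from [who_standard_weights()] (the
#'   default) or a numeric weight per rate.
#' @param band optional `c(lo, hi)` age band; `ages` must cover every single
#'   year of it.
#' @return the age-standardized rate per 100,000 person-years.
#' @export
standardize <- function(rates, ages = NULL, weights = who_standard_weights(),
                        band = NULL) {
  if (is.numeric(weights)) {
    if (length(weights) != length(rates)) {
      stop("standardize: numeric weights must align with rates")
    }
    w <- weights
  } else {
    if (is.null(ages)) stop("standardize: ages needed with banded weights")
    if (!is.null(band)) {
      keep <- ages >= band[1] & ages <= band[2]
      if (!all(band[1]:band[2] %in% ages[keep])) {
        stop("standardize: rates do not cover every age in the band")
      }
      ages <- ages[keep]; rates <- rates[keep]
    }
    bi <- findInterval(ages, weights$age_lo)
    if (any(bi < 1) || any(ages > max(weights$age_hi))) {
      stop("standardize: ages outside the standard population's range")
    }
    # spread each band's weight evenly over its single years present
    w <- weights$weight[bi] / tabulate(bi, nbins = nrow(weights))[bi]
  }
  if (any(!is.finite(rates))) stop("standardize: non-finite rates")
  w <- w / sum(w)
  sum(w * rates) * 1e5
}

#' Inequality summary for a pair of standardized rates
#'
#' @param std_a standardized rate for the disadvantaged group (per 100,000).
#' @param std_b standardized rate for the reference group.
#' @return an `inequality_summary` list: `rate_a`, `rate_b`,
#'   `srd = rate_a - rate_b`, `srr = rate_a / rate_b`, and
#'   `excess_srr = srr - 1`.
#' @export
inequality_summary <- function(std_a, std_b) {
  if (std_b <= 0) stop("inequality_summary: reference rate must be positive")
  structure(list(rate_a = std_a, rate_b = std_b,
                 srd = std_a - std_b, srr = std_a / std_b,
                 excess_srr = std_a / std_b - 1),
            class = "inequality_summary")
}

#' @export
print.inequality_summary <- function(x, ...) {
  cat(sprintf("rates %.1f vs %.1f per 100,000 | SRD %.1f | SRR %.3f\n",
              x$rate_a, x$rate_b, x$srd, x$srr))
  invisible(x)
}

#' Percentage changes in inequality between two scenarios
#'
#' Signed percentage changes (negative = decrease under the comparison
#' scenario) in each group's rate, in the SRD, and in the excess SRR
#' (`SRR - 1`), computed on unrounded values.
#'
#' @param bau,intervention `inequality_summary` objects for the two
#'   scenarios.
#' @return data frame with one row of percentage changes.
#' @export
inequality_change <- function(bau, intervention) {
  pc <- function(a, b) if (b == 0 && a == b) 0 else 100 * (a - b) / b
  data.frame(
    pct_change_rate_a = pc(intervention$rate_a, bau$rate_a),
    pct_change_rate_b = pc(intervention$rate_b, bau$rate_b),
    pct_change_srd = pc(intervention$srd, bau$srd),
    pct_change_excess_srr = pc(intervention$excess_srr, bau$excess_srr))
}

#' Table-3-shaped inequality report from two life-table runs
#'
#' Standardized mortality rates in a given year for minority and majority,
#' by sex and for sexes combined, over the age bands 45-64, 65-84, 85+, and
#' all 45+, with SRD, SRR, and percentage changes between the scenarios.
#'
#' @param res_bau,res_int `mslt_results` for comparator and intervention.
#' @param year calendar year of the comparison (e.g. 30 years after
#'   baseline).
#' @param bands list of `c(lo, hi)` age bands.
#' @return data frame, one row per sex-group x band.
#' @export
inequality_report <- function(res_bau, res_int, year,
                              bands = list(c(45, 64), c(65, 84), c(85, 110),
                                           c(45, 110))) {
  strata <- res_bau$strata
  sex_groups <- c(as.list(strata$sexes), list(strata$sexes))
  names(sex_groups) <- c(strata$sexes, "combined")
  rows <- list()
  for (gname in names(sex_groups)) {
    sexes <- sex_groups[[gname]]
    for (band in bands) {
      s <- lapply(list(res_bau, res_int), function(res) {
        rts <- lapply(strata$ethnicities, function(eth) {
          cols <- unlist(lapply(sexes, function(sx)
            strata_cols(strata, sex = sx, ethnicity = eth)))
          group_rates(res, year, cols, band)
        })
        inequality_summary(
          standardize(rts[[2]]$rate, rts[[2]]$age, band = band),
          standardize(rts[[1]]$rate, rts[[1]]$age, band = band))
      })
      chg <- inequality_change(s[[1]], s[[2]])
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(group = gname, band = sprintf("%d-%d", band[1], band[2]),
                   rate_minority_bau = s[[1]]$rate_a,
                   rate_majority_bau = s[[1]]$rate_b,
                   srd_bau = s[[1]]$srd, srr_bau = s[[1]]$srr,
                   rate_minority_int = s[[2]]$rate_a,
                   rate_majority_int = s[[2]]$rate_b,
                   srd_int = s[[2]]$srd, srr_int = s[[2]]$srr),
        chg)
    }
  }
  do.call(rbind, rows)
}

## pooled mortality rates by single age for a set of stratum columns
group_rates <- function(results, year, cols, band) {
  t <- match(year, results$years)
  if (is.na(t)) stop("group_rates: year outside horizon")
  strata <- results$strata
  nA <- n_ages(strata)
  act <- seq_len(nA - t + 1L)
  ages_now <- strata$ages[act] + (t - 1L)
  keep <- which(ages_now >= band[1] & ages_now <= band[2])
  d <- results$deaths[act, cols, t, drop = FALSE]
  p <- results$person_years[act, cols, t, drop = FALSE]
  dim(d) <- c(length(act), length(cols)); dim(p) <- dim(d)
  data.frame(age = ages_now[keep],
             rate = rowSums(d[keep, , drop = FALSE]) /
               pmax(rowSums(p[keep, , drop = FALSE]), 1e-300))
}
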