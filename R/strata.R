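#' Stratum set for a two-sex, two-ethnicity population
#'
#' The model population is stratified by sex and ethnicity, with single-year
#' ages 0 to 110. All internal surfaces are stored as `n_age x n_stratum`
#' matrices whose columns follow the stratum order returned here.
#'
#' @param sexes character vector of sex labels (length 2).
#' @param ethnicities character vector of ethnicity labels, majority first.
#' @param ages integer ages covered by every surface.
#' @return An object of class `stratum_set`: a list with the labels, the
#'   stratum id vector (`"<sex>.<ethnicity>"`), and lookup vectors `sex_of`
#'   and `eth_of` mapping stratum id to sex / ethnicity.
#' @export
stratum_set <- function(sexes = c("male", "female"),
                        ethnicities = c("majority", "minority"),
                        ages = 0:110) {
  if (length(ethnicities) < 2) {
    stop("stratum_set: need at least two ethnicity labels (majority, minority)")
  }
  grid <- expand.grid(ethnicity = ethnicities, sex = sexes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ids <- paste(grid$sex, grid$ethnicity, sep = ".")
  structure(list(
    sexes = sexes,
    ethnicities = ethnicities,
    ages = as.integer(ages),
    ids = ids,
    sex_of = stats::setNames(grid$sex, ids),
    eth_of = stats::setNames(grid$ethnicity, ids)
  ), class = "stratum_set")
}

#' @export
print.stratum_set <- function(x, ...) {
  cat("<stratum_set> ", length(x$ids), " strata, ages ",
      min(x$ages), "-", max(x$ages), "\n", sep = "")
  cat("  ", paste(x$ids, collapse = ", "), "\n", sep = "")
  invisible(x)
}

n_ages <- function(strata) length(strata$ages)
n_strata <- function(strata) length(strata$ids)

## Empty age x stratum surface
blank_surface <- function(strata, value = 0) {
  matrix(value, nrow = n_ages(strata), ncol = n_strata(strata),
         dimnames = list(age = strata$ages, stratum = strata$ids))
}

## Build an age x stratum surface from per-stratum age functions or vectors.
## `f` is either a function(age, sex, ethnicity) or a numeric vector over ages.
surface_from <- function(strata, f) {
  out <- blank_surface(strata)
  for (j in seq_along(strata$ids)) {
    id <- strata$ids[j]
    if (is.function(f)) {
      out[, j] <- f(strata$ages, strata$sex_of[[id]], strata$eth_of[[id]])
    } else {
      out[, j] <- f
    }
  }
  out
}

#' Convert a surface matrix to a long data frame
#'
#' @param m an `age x stratum` matrix with dimnames as built by the package.
#' @param strata the `stratum_set` the matrix is defined on.
#' @param value_name name of the value column.
#' @return data frame with columns sex, age, ethnicity, `value_name`.
#' @export
surface_to_long <- function(m, strata, value_name = "value") {
  df <- data.frame(
    sex = rep(strata$sex_of[strata$ids], each = n_ages(strata)),
    age = rep(strata$ages, times = n_strata(strata)),
    ethnicity = rep(strata$eth_of[strata$ids], each = n_ages(strata)),
    value = as.vector(m),
    row.names = NULL
  )
  names(df)[names(df) == "value"] <- value_name
  df
}

#' Rebuild a surface matrix from a long data frame
#'
#' Inverse of [surface_to_long()]. Every (sex, age, ethnicity) cell of the
#' stratum set must be present exactly once.
#'
#' @inheritParams surface_to_long
#' @param df long data frame with columns sex, age, ethnicity and a value.
#' @export
surface_from_long <- function(df, strata, value_name = "value") {
  m <- blank_surface(strata, NA_real_)
  id <- paste(df$sex, df$ethnicity, sep = ".")
  j <- match(id, strata$ids)
  i <- match(df$age, strata$ages)
  if (anyNA(j) || anyNA(i)) {
    stop("surface_from_long: rows outside the stratum set's sex/age/ethnicity grid")
  }
  m[cbind(i, j)] <- df[[value_name]]
  if (anyNA(m)) stop("surface_from_long: missing cells for some (age, stratum)")
  m
}

## columns of a surface belonging to one ethnicity / sex
strata_cols <- function(strata, sex = NULL, ethnicity = NULL) {
  keep <- rep(TRUE, n_strata(strata))
  if (!is.null(sex)) keep <- keep & strata$sex_of[strata$ids] == sex
  if (!is.null(ethnicity)) keep <- keep & strata$eth_of[strata$ids] == ethnicity
  which(keep)
}

## map each stratum column to the column for the same sex in another ethnicity
counterpart_cols <- function(strata, ethnicity) {
  vapply(strata$ids, function(id) {
    strata_cols(strata, sex = strata$sex_of[[id]], ethnicity = ethnicity)
  }, integer(1))
}

stopifnot_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("%s must lie in [0, 1] and be finite", what))
  }
  invisible(x)
}
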