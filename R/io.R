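## Bundle and results I/O: a bundle directory is a set of long-format
## delimited tables (columns sex, age, ethnicity[, ...], value) plus a JSON
## manifest naming diseases, flags, scalar parameters, distribution specs,
## and the generator seed. Every table carries a provenance header line.

provenance_header <- function(bundle_tag, seed = NA) {
  sprintf("# msltax %s | tag %s | seed %s",
          as.character(utils::packageVersion("msltax")), bundle_tag, seed)
}

write_table <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(df, con, row.names = FALSE)
}

read_table <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Write an input bundle to a directory of delimited tables
#'
#' @param bundle an `mslt_bundle`.
#' @param dir output directory (created; must not already contain a
#'   manifest).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  if (file.exists(file.path(dir, "manifest.json"))) {
    stop("write_bundle: directory already holds a bundle; refusing to overwrite")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  strata <- bundle$strata
  hdr <- provenance_header(bundle$tag, bundle$seed)

  for (nm in c("population", "mortality", "residual_mortality", "pyld")) {
    write_table(surface_to_long(bundle[[nm]], strata),
                file.path(dir, paste0(nm, ".csv")), hdr)
  }
  write_table(surface_to_long(bundle$costs$baseline, strata),
              file.path(dir, "baseline_cost.csv"), hdr)

  ## disease rate surfaces in one long table
  rate_rows <- lapply(bundle$diseases, function(d) {
    df <- surface_to_long(d$incidence, strata, "incidence")
    df$prevalence <- as.vector(d$prevalence)
    df$case_fatality <- as.vector(d$case_fatality)
    df$remission <- as.vector(d$remission)
    cbind(disease = d$name, df)
  })
  write_table(do.call(rbind, rate_rows), file.path(dir, "disease_rates.csv"), hdr)

  ## RR and disability by disease x sex x age
  rr_rows <- lapply(bundle$diseases, function(d) {
    data.frame(disease = d$name,
               sex = rep(strata$sexes, each = n_ages(strata)),
               age = rep(strata$ages, 2),
               rr_current = as.vector(d$rr_current),
               disability_rate = as.vector(d$disability_rate))
  })
  write_table(do.call(rbind, rr_rows), file.path(dir, "disease_rr.csv"), hdr)

  ## initial smoking-state distribution
  sm <- bundle$smoking$initial
  smdf <- data.frame(
    sex = rep(strata$sex_of[strata$ids], each = n_ages(strata)),
    age = rep(strata$ages, times = n_strata(strata)),
    ethnicity = rep(strata$eth_of[strata$ids], each = n_ages(strata)),
    state = rep(smoking_states(), each = n_ages(strata) * n_strata(strata)),
    fraction = as.vector(sm))
  write_table(smdf, file.path(dir, "smoking_initial.csv"), hdr)

  manifest <- list(
    package = "msltax",
    version = as.character(utils::packageVersion("msltax")),
    tag = bundle$tag,
    seed = bundle$seed,
    base_year = bundle$base_year,
    sexes = strata$sexes,
    ethnicities = strata$ethnicities,
    ages = range(strata$ages),
    diseases = lapply(bundle$diseases, function(d) d[c(
      "name", "is_cancer", "is_protective", "female_only", "gamma",
      "cost_first_year", "cost_prevalent", "cost_last6mo",
      "apc_incidence", "apc_case_fatality", "apc_remission")]),
    smoking = list(
      cessation = as.list(as.data.frame(bundle$smoking$cessation)),
      cessation_bands = rownames(bundle$smoking$cessation),
      initiation_at_20 = as.list(bundle$smoking$initiation_at_20),
      initiation_apc = as.list(bundle$smoking$initiation_apc),
      mortality_rr_current = bundle$smoking$mortality_rr_current,
      gamma_allcause = bundle$smoking$gamma_allcause),
    trends = list(residual_apc = as.list(bundle$trends$residual_apc),
                  cap_year = bundle$trends$cap_year),
    elasticities = list(bands = bundle$elasticities$bands,
                        ethnic_scalar = bundle$elasticities$ethnic_scalar),
    costs = list(law_cost = bundle$costs$law_cost,
                 law_cost_sd = bundle$costs$law_cost_sd),
    dist_specs = bundle$dist_specs)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read an input bundle written by [write_bundle()]
#'
#' @param dir bundle directory.
#' @return an `mslt_bundle`.
#' @export
read_bundle <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  strata <- stratum_set(sexes = man$sexes, ethnicities = man$ethnicities,
                        ages = man$ages[1]:man$ages[2])
  surf <- function(nm, value_name = "value") {
    surface_from_long(read_table(file.path(dir, paste0(nm, ".csv"))), strata,
                      value_name)
  }
  rates <- read_table(file.path(dir, "disease_rates.csv"))
  rrdf <- read_table(file.path(dir, "disease_rr.csv"))
  dlist <- if (is.data.frame(man$diseases)) {
    split(man$diseases, seq_len(nrow(man$diseases)))
  } else man$diseases
  diseases <- lapply(dlist, function(m) {
    sub <- rates[rates$disease == m$name, ]
    rsub <- rrdf[rrdf$disease == m$name, ]
    rr <- matrix(rsub$rr_current[order(match(rsub$sex, strata$sexes), rsub$age)],
                 n_ages(strata), 2,
                 dimnames = list(age = strata$ages, sex = strata$sexes))
    dr <- matrix(rsub$disability_rate[order(match(rsub$sex, strata$sexes), rsub$age)],
                 n_ages(strata), 2,
                 dimnames = list(age = strata$ages, sex = strata$sexes))
    list(name = m$name, is_cancer = m$is_cancer,
         is_protective = m$is_protective, female_only = m$female_only,
         incidence = surface_from_long(sub, strata, "incidence"),
         prevalence = surface_from_long(sub, strata, "prevalence"),
         case_fatality = surface_from_long(sub, strata, "case_fatality"),
         remission = surface_from_long(sub, strata, "remission"),
         rr_current = rr, gamma = m$gamma, disability_rate = dr,
         cost_first_year = m$cost_first_year,
         cost_prevalent = m$cost_prevalent, cost_last6mo = m$cost_last6mo,
         apc_incidence = m$apc_incidence,
         apc_case_fatality = m$apc_case_fatality,
         apc_remission = m$apc_remission)
  })
  names(diseases) <- vapply(diseases, `[[`, character(1), "name")

  smdf <- read_table(file.path(dir, "smoking_initial.csv"))
  states <- smoking_states()
  initial <- array(0, dim = c(n_ages(strata), n_strata(strata), length(states)),
                   dimnames = list(age = strata$ages, stratum = strata$ids,
                                   state = states))
  id <- paste(smdf$sex, smdf$ethnicity, sep = ".")
  initial[cbind(match(smdf$age, strata$ages), match(id, strata$ids),
                match(smdf$state, states))] <- smdf$fraction

  cess <- do.call(cbind, man$smoking$cessation)[, strata$ids, drop = FALSE]
  rownames(cess) <- man$smoking$cessation_bands

  specs <- man$dist_specs
  structure(list(
    strata = strata,
    base_year = man$base_year,
    population = surf("population"),
    mortality = surf("mortality"),
    residual_mortality = surf("residual_mortality"),
    pyld = surf("pyld"),
    diseases = diseases,
    costs = list(baseline = surface_from_long(
                   read_table(file.path(dir, "baseline_cost.csv")), strata),
                 law_cost = man$costs$law_cost,
                 law_cost_sd = man$costs$law_cost_sd),
    smoking = list(initial = initial, cessation = cess,
                   initiation_at_20 = unlist(man$smoking$initiation_at_20)[strata$ids],
                   initiation_apc = unlist(man$smoking$initiation_apc)[strata$ids],
                   mortality_rr_current = man$smoking$mortality_rr_current,
                   gamma_allcause = man$smoking$gamma_allcause),
    trends = list(residual_apc = unlist(man$trends$residual_apc)[strata$ethnicities],
                  cap_year = man$trends$cap_year),
    elasticities = list(bands = as.data.frame(man$elasticities$bands),
                        ethnic_scalar = man$elasticities$ethnic_scalar),
    dist_specs = specs,
    seed = man$seed,
    config = NULL,
    tag = man$tag
  ), class = "mslt_bundle")
}

#' Write life-table results as long-format tables plus a JSON summary
#'
#' @param cmp result of [mslt_compare()].
#' @param bundle the input bundle of the comparison.
#' @param dir output directory (created fresh; refuses to overwrite).
#' @return `dir`, invisibly.
#' @export
write_results <- function(cmp, bundle, dir) {
  if (file.exists(file.path(dir, "summary.json"))) {
    stop("write_results: directory already holds results; refusing to overwrite")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- provenance_header(bundle$tag, bundle$seed)
  for (nm in c("res_bau", "res_int")) {
    res <- cmp[[nm]]
    st <- annual_streams(res)
    write_table(st, file.path(dir, paste0(nm, "_streams.csv")), hdr)
    write_table(results_totals(res), file.path(dir, paste0(nm, "_totals.csv")), hdr)
  }
  by_group <- incremental_by_group(cmp$res_int, cmp$res_bau, bundle)
  write_table(by_group, file.path(dir, "incremental_by_group.csv"), hdr)
  jsonlite::write_json(
    list(tag = bundle$tag, seed = bundle$seed,
         total = cmp$incremental$total,
         by_stratum = cmp$incremental$by_stratum,
         by_group = by_group),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
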