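## Shared fixtures: the default synthetic bundle is expensive enough to build
## once per test run and reuse read-only.
.fixtures <- new.env()

default_bundle <- function() {
  if (is.null(.fixtures$bundle)) {
    .fixtures$bundle <- generate_bundle(generator_config(), seed = 1)
  }
  .fixtures$bundle
}

default_bau <- function() {
  if (is.null(.fixtures$bau)) .fixtures$bau <- project_bau(default_bundle())
  .fixtures$bau
}

default_tax_traj <- function() {
  if (is.null(.fixtures$tax)) {
    .fixtures$tax <- apply_tax_effect(default_bau(), tax_schedule(),
                                      default_bundle())
  }
  .fixtures$tax
}

default_compare <- function() {
  if (is.null(.fixtures$cmp)) .fixtures$cmp <- mslt_compare(default_bundle())
  .fixtures$cmp
}

## a bundle stripped to a single inert disease: handy for closed-form checks
inert_disease_bundle <- function(mortality_value = 0, pyld_value = 0,
                                 baseline_cost = 0) {
  b <- generate_bundle(generator_config(), seed = 3)
  d <- b$diseases[[1]]
  for (s in c("incidence", "prevalence", "case_fatality", "remission")) {
    d[[s]][] <- 0
  }
  d$disability_rate[] <- 0
  b$diseases <- list(chd = d)
  b$dist_specs <- msltax:::default_dist_specs("chd")
  b$mortality[] <- mortality_value
  b$residual_mortality[] <- mortality_value
  b$pyld[] <- pyld_value
  b$costs$baseline[] <- baseline_cost
  b$trends$residual_apc[] <- 0        # keep closed-form oracles exact
  b
}
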