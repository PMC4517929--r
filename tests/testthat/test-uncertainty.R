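test_that("marginal draws of every family have mean equal to the point estimate", {
  set.seed(1)
  u <- stats::runif(10000)
  for (fam in c("normal", "lognormal", "gamma")) {
    x <- msltax:::q_marginal(u, fam, 2.5, 0.25)
    expect_equal(mean(x), 2.5, tolerance = 0.01)
  }
  xb <- msltax:::q_marginal(u, "beta", 0.04, 0.2 * 0.04)
  expect_equal(mean(xb), 0.04, tolerance = 0.01)
  expect_true(all(xb >= 0 & xb <= 1))
  expect_error(msltax:::q_marginal(u, "cauchy", 1, 1), "unknown")
})

test_that("zero SD makes every draw equal the point estimate", {
  b <- default_bundle()
  plan <- draw_plan(5, seed = 2, sd_scaling = 0)
  for (i in 1:3) {
    dr <- sample_parameters(b, plan, i)
    expect_equal(dr$bundle$pyld, b$pyld, tolerance = 1e-12)
    expect_equal(dr$bundle$diseases$chd$incidence, b$diseases$chd$incidence,
                 tolerance = 1e-12)
    expect_equal(dr$schedule$annual_increase, 0.10, tolerance = 1e-12)
  }
})

test_that("parameters sharing a correlation family are comonotone", {
  b <- default_bundle()
  plan <- draw_plan(40, seed = 5)
  cess <- t(vapply(seq_len(40), function(i)
    as.vector(sample_parameters(b, plan, i)$bundle$smoking$cessation),
    numeric(12)))
  ## all 12 sex x age x ethnicity cessation cells move in lockstep
  rk <- apply(cess, 2, rank)
  for (j in 2:12) expect_equal(rk[, j], rk[, 1])
  ## elasticities share one quantile across the four age bands
  els <- t(vapply(seq_len(40), function(i)
    sample_parameters(b, plan, i)$schedule$elasticities$elasticity,
    numeric(4)))
  rk2 <- apply(-els, 2, rank)   # elasticities are negative
  for (j in 2:4) expect_equal(rk2[, j], rk2[, 1])
  ## independent families are not comonotone
  pylds <- vapply(seq_len(40), function(i)
    sample_parameters(b, plan, i)$bundle$pyld[50, 1], numeric(1))
  expect_false(all(rank(pylds) == rk[, 1]))
})

test_that("draw plans are reproducible and draw means are centred", {
  p1 <- draw_plan(30, seed = 11)
  p2 <- draw_plan(30, seed = 11)
  expect_identical(p1$quantiles, p2$quantiles)
  b <- default_bundle()
  laws <- vapply(seq_len(30), function(i)
    sample_parameters(b, p1, i)$law_cost, numeric(1))
  expect_equal(mean(laws), b$costs$law_cost, tolerance = 0.15)
  expect_true(all(laws > 0))   # gamma law cost cannot go negative
})

test_that("uncertainty runs are reproducible and need at least two draws", {
  b <- default_bundle()
  expect_error(run_uncertainty(b, draw_plan(1, seed = 3)), "n_draws")
  u1 <- run_uncertainty(b, draw_plan(8, seed = 3), horizon = 60)
  u2 <- run_uncertainty(b, draw_plan(8, seed = 3), horizon = 60)
  expect_identical(u1$draws, u2$draws)
  expect_true(all(c("mean", "lo95", "hi95") %in% names(u1$summary)))
})

test_that("degenerate SDs collapse the uncertainty interval to zero width", {
  b <- default_bundle()
  u <- run_uncertainty(b, draw_plan(4, seed = 9, sd_scaling = 0),
                       horizon = 60)
  expect_equal(max(u$summary$ui_width), 0, tolerance = 1e-6)
})

test_that("scenario driver: dose response, switches, and life-year variant", {
  b <- default_bundle()
  specs <- list(
    scenario_spec("base"),
    scenario_spec("tax20", tax_rate = 0.20),
    scenario_spec("no_scalar", ethnic_scalar_off = TRUE),
    scenario_spec("life_years", zero_morbidity_zero_discount = TRUE))
  tab <- run_scenarios(b, specs, horizon = 90)
  expect_equal(tab$gain_ratio_vs_base[1], 1)
  ## a 20% tax gains more than a 10% tax
  expect_gt(tab$gain[tab$scenario == "tax20"],
            tab$gain[tab$scenario == "base"])
  ## removing the minority elasticity uplift strictly reduces minority gains
  expect_lt(tab$gain_minority[tab$scenario == "no_scalar"],
            tab$gain_minority[tab$scenario == "base"])
  ## the life-year variant reports pure survival gains: positive and of the
  ## same order as the QALY gain, but not the same quantity
  ly <- tab$gain[tab$scenario == "life_years"]
  expect_gt(ly, 0)
  expect_false(isTRUE(all.equal(ly, tab$gain[tab$scenario == "base"])))
  expect_equal(ly, tab$gain[tab$scenario == "base"], tolerance = 0.5)
  expect_equal(tab$outcome[tab$scenario == "life_years"], "life_years")
})

test_that("the base scenario row equals a direct comparison run", {
  b <- default_bundle()
  tab <- run_scenarios(b, list(scenario_spec("base")), horizon = 70)
  cmp <- mslt_compare(b, horizon = 70)
  expect_equal(tab$gain, cmp$incremental$total$d_qalys, tolerance = 1e-9)
  expect_equal(tab$net_cost_nzd, cmp$incremental$total$net_cost_nzd,
               tolerance = 1e-9)
})

test_that("unknown scenario switches and bad draw indices are rejected", {
  b <- default_bundle()
  sp <- scenario_spec("x")
  sp$bogus <- TRUE
  expect_error(run_scenarios(b, list(sp), horizon = 20), "unknown switch")
  expect_error(sample_parameters(b, draw_plan(5, seed = 1), 9), "out of range")
})
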