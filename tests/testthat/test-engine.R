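test_that("no mortality and no incidence leave the population constant", {
  b <- inert_disease_bundle(mortality_value = 0)
  traj <- project_bau(b, horizon = 30)
  res <- run_mslt(b, traj)
  n0 <- sum(b$population)
  ## only the cohorts aging past 110 leave; below that everything persists
  for (t in 1:29) {
    act <- seq_len(111 - t)
    expect_equal(sum(res$alive[act, , t + 1]), sum(b$population[act, ]),
                 tolerance = 1e-9)
  }
  expect_equal(sum(res$qalys), sum(res$person_years))   # pyld = 0
})

test_that("population conservation: alive(t+1) = alive(t) - deaths(t)", {
  res <- default_compare()$res_bau
  for (t in c(1, 10, 50, 90)) {
    expect_equal(res$alive[, , t + 1], res$alive[, , t] - res$deaths[, , t],
                 tolerance = 1e-9)
  }
  expect_true(all(res$deaths >= 0))
})

test_that("constant all-cause risk reproduces geometric survival and half-cycle person-years", {
  q <- 0.1
  b <- inert_disease_bundle(mortality_value = q)
  traj <- project_bau(b, horizon = 20)
  res <- run_mslt(b, traj)
  cohort <- 31; j <- 1
  N <- b$population[cohort, j]
  for (t in 1:19) {
    expect_equal(res$alive[cohort, j, t + 1], N * (1 - q)^t, tolerance = 1e-9)
    expect_equal(res$person_years[cohort, j, t],
                 (N * (1 - q)^(t - 1) + N * (1 - q)^t) / 2, tolerance = 1e-9)
  }
})

test_that("disease deaths equal occupancy times case fatality", {
  b <- default_bundle()
  res <- default_compare()$res_bau
  ## year 1: occupancy is exactly the input prevalence
  t <- 1
  for (k in c(1, 5, 12)) {
    d <- b$diseases[[k]]
    expected <- b$population * d$prevalence * d$case_fatality
    expect_equal(res$disease_deaths[, , t, k], unname(expected),
                 tolerance = 1e-9)
  }
})

test_that("discounting follows the end-year annuity closed form", {
  f <- msltax:::discount_factors(25, 0.03)
  expect_equal(sum(f), (1 - 1.03^-25) / 0.03, tolerance = 1e-12)
  expect_equal(msltax:::discount_factors(5, 0), rep(1, 5))
})

test_that("higher discount rates shrink the incremental QALY gain more than proportionally", {
  cmp <- default_compare()
  inc0 <- incremental_results(cmp$res_int, cmp$res_bau, discount_rate = 0)
  inc3 <- incremental_results(cmp$res_int, cmp$res_bau, discount_rate = 0.03)
  inc6 <- incremental_results(cmp$res_int, cmp$res_bau, discount_rate = 0.06)
  expect_gt(inc0$total$d_qalys, inc3$total$d_qalys)
  expect_gt(inc3$total$d_qalys, inc6$total$d_qalys)
  ## gains peak decades out, so 3% discounting cuts far more than a constant
  ## stream would lose over the same horizon
  n <- length(cmp$res_bau$years)
  flat_ratio <- sum(msltax:::discount_factors(n, 0.03)) / n
  expect_lt(inc3$total$d_qalys / inc0$total$d_qalys, flat_ratio)
})

test_that("null intervention yields zero QALY difference and the law cost", {
  b <- default_bundle()
  bau <- default_bau()
  el0 <- default_elasticities(); el0$elasticity <- rep(0, 4)
  tj <- apply_tax_effect(bau, tax_schedule(elasticities = el0,
                                           ethnic_scalar = 0), b)
  pif <- pif_surface(b, bau, tj)
  r1 <- run_mslt(b, bau); r2 <- run_mslt(b, tj, pif)
  inc <- incremental_results(r2, r1, law_cost = 1234)
  expect_equal(inc$total$d_qalys, 0, tolerance = 1e-12)
  expect_equal(inc$total$net_cost_nzd, 1234, tolerance = 1e-9)
})

test_that("US$ conversion divides by the PPP factor", {
  cmp <- default_compare()
  inc <- cmp$incremental
  expect_equal(inc$total$net_savings_usd,
               inc$total$net_savings_nzd / 1.486, tolerance = 1e-12)
  ## the printed-magnitude direction check: NZ$3,770M -> ~US$2,537M
  expect_equal(3770 / 1.486, 2537, tolerance = 0.001)
})

test_that("zero excess costs reduce total cost to alive x baseline", {
  b <- inert_disease_bundle(mortality_value = 0.02, baseline_cost = 1000)
  traj <- project_bau(b, horizon = 10)
  res <- run_mslt(b, traj)
  for (t in c(1, 5, 10)) {
    act <- seq_len(111 - t + 1)
    expect_equal(sum(res$costs[act, , t]), sum(res$alive[act, , t] * 1000),
                 tolerance = 1e-9)
  }
})

test_that("negative residual mortality raises a coherence error naming the stratum", {
  b <- default_bundle()
  b$mortality[50, 2] <- 0   # all-cause below modelled-disease deaths
  traj <- project_bau(b, horizon = 5)
  expect_error(run_mslt(b, traj), "male.minority")
})

test_that("mismatched horizons are rejected in incremental comparisons", {
  b <- default_bundle()
  r1 <- run_mslt(b, project_bau(b, horizon = 10))
  r2 <- run_mslt(b, project_bau(b, horizon = 12))
  expect_error(incremental_results(r1, r2), "horizons")
})

test_that("equity recomputation: identical backgrounds change nothing, better ones help", {
  b <- default_bundle()
  bau <- default_bau()
  ## force identical backgrounds across ethnicities
  b_eq <- b
  strata <- b$strata
  cp <- msltax:::counterpart_cols(strata, strata$ethnicities[1])
  min_cols <- msltax:::strata_cols(strata, ethnicity = strata$ethnicities[2])
  dd0 <- Reduce(`+`, lapply(b$diseases, function(d) d$prevalence * d$case_fatality))
  b_eq$mortality[, min_cols] <- (b$mortality - dd0)[, cp[min_cols]] +
    dd0[, min_cols]
  b_eq$pyld[, min_cols] <- local({
    drp <- Reduce(`+`, lapply(b$diseases, function(d)
      d$disability_rate[, match(strata$sex_of[strata$ids], strata$sexes)] *
        d$prevalence))
    ((b$pyld - drp)[, cp[min_cols]] + drp[, min_cols])
  })
  traj_eq <- project_bau(b_eq)
  r_std <- run_mslt(b_eq, traj_eq)
  r_eq <- equity_recompute(b_eq, traj_eq)
  expect_equal(r_eq$qalys, r_std$qalys, tolerance = 1e-12)

  ## with the real (worse) minority backgrounds, equity QALY gains are larger
  cmp <- default_compare()
  std_gain <- sum((cmp$res_int$qalys - cmp$res_bau$qalys)[, min_cols, ])
  eq_int <- equity_recompute(b, cmp$traj_int, cmp$pif)
  eq_bau <- equity_recompute(b, cmp$traj_bau)
  eq_gain <- sum((eq_int$qalys - eq_bau$qalys)[, min_cols, ])
  expect_gt(eq_gain, std_gain)
})

test_that("internal validation passes on zero-trend runs and catches faults", {
  b <- msltax:::zero_trends(default_bundle())
  traj <- project_bau(b, horizon = 15)
  res <- run_mslt(b, traj)
  v <- validate_internal(res, b, tolerance = 0.10)
  expect_true(nrow(v) > 0)
  expect_false(any(v$flag))
  ## corrupt one disease's case fatality by +50% in the inputs only
  b_bad <- b
  b_bad$diseases$chd$case_fatality <- b_bad$diseases$chd$case_fatality * 1.5
  v_bad <- validate_internal(res, b_bad, tolerance = 0.10)
  expect_true(any(v_bad$flag[v_bad$disease == "chd"]))
  ## an empty disease is excluded from the table
  b_e <- b
  b_e$diseases$chd$incidence[] <- 0
  b_e$diseases$chd$prevalence[] <- 0
  b_e$diseases$chd$case_fatality[] <- 0
  traj_e <- project_bau(b_e, horizon = 15)
  res_e <- run_mslt(b_e, traj_e)
  v_e <- validate_internal(res_e, b_e)
  expect_false("chd" %in% v_e$disease)
})

test_that("Table-2-style group breakdown reconciles with the totals", {
  cmp <- default_compare()
  b <- default_bundle()
  bg <- incremental_by_group(cmp$res_int, cmp$res_bau, b)
  expect_equal(sum(bg$qalys), cmp$incremental$total$d_qalys, tolerance = 1e-9)
  expect_equal(sum(bg$population), sum(b$population), tolerance = 1e-9)
  rep <- mslt_report(cmp, b)
  expect_gt(rep$per_capita_ratio, 1)   # larger per-capita gains for minority
})
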