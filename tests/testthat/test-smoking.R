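icur <- match("current", smoking_states())
inev <- match("never", smoking_states())
iex0 <- match("ex00", smoking_states())

test_that("state fractions sum to one in every stratum-year", {
  traj <- default_bau()
  nA <- length(traj$strata$ages)
  for (t in c(1, 2, 25, 60, 100)) {
    act <- seq_len(nA - t + 1L)
    sums <- apply(traj$dist[act, , , t, drop = FALSE], c(1, 2), sum)
    expect_equal(max(abs(sums - 1)), 0, tolerance = 1e-12)
  }
})

test_that("no flows and equal mortality leave the distribution constant", {
  b <- default_bundle()
  b$smoking$cessation[] <- 0
  b$smoking$initiation_at_20[] <- 0
  b$smoking$mortality_rr_current <- 1
  ## park everyone in never/current so ex-bin aging cannot move mass
  b$smoking$initial[, , ] <- 0
  b$smoking$initial[, , inev] <- 0.8
  b$smoking$initial[, , icur] <- 0.2
  traj <- project_bau(b, horizon = 30)
  for (t in 2:30) {
    act <- seq_len(111 - t + 1L)
    expect_equal(traj$dist[act, , icur, t],
                 traj$dist[act, , icur, 1][seq_along(act), ],
                 tolerance = 1e-12)
  }
})

test_that("constant cessation with no initiation decays current geometrically", {
  b <- default_bundle()
  c0 <- 0.05
  b$smoking$cessation[] <- c0
  b$smoking$initiation_at_20[] <- 0
  b$smoking$mortality_rr_current <- 1
  traj <- project_bau(b, horizon = 15)
  cohort <- 31            # age 30 at baseline: inside the 20-34 band throughout
  p0 <- traj$dist[cohort, , icur, 1]
  for (t in 1:14) {
    expect_equal(traj$dist[cohort, , icur, t + 1], p0 * (1 - c0)^t,
                 tolerance = 1e-10)
  }
})

test_that("differential mortality alone strictly reduces the current fraction", {
  b <- default_bundle()
  b$smoking$cessation[] <- 0
  b$smoking$initiation_at_20[] <- 0
  b$smoking$mortality_rr_current <- 2
  b$smoking$initial[, , ] <- 0
  b$smoking$initial[, , inev] <- 0.7
  b$smoking$initial[, , icur] <- 0.3
  traj <- project_bau(b, horizon = 40)
  cohort <- 41
  cur <- traj$dist[cohort, 1, icur, 1:40]
  expect_true(all(diff(cur) < 0))
})

test_that("a 10% rise reduces band prevalence by elasticity x increase", {
  b <- default_bundle()
  bau <- default_bau()
  tj <- apply_tax_effect(bau, tax_schedule(start_year = 2011, end_year = 2011),
                         b)
  maj <- which(b$strata$ids == "male.majority")
  for (band in list(c(15, 20, -0.38), c(21, 24, -0.29), c(25, 34, -0.19),
                    c(35, 110, -0.10))) {
    rows <- which(b$strata$ages >= band[1] & b$strata$ages <= band[2])
    red <- 1 - tj$dist[rows, maj, icur, 1] / bau$dist[rows, maj, icur, 1]
    expect_equal(unname(red), rep(-band[3] * 0.10, length(rows)),
                 tolerance = 1e-12)
  }
  ## minority band scaled by +20%: -0.38 * 1.2 * 0.10 = 4.56% reduction
  mino <- which(b$strata$ids == "male.minority")
  rows <- which(b$strata$ages >= 15 & b$strata$ages <= 20)
  red <- 1 - tj$dist[rows, mino, icur, 1] / bau$dist[rows, mino, icur, 1]
  expect_equal(unname(red), rep(0.0456, length(rows)), tolerance = 1e-12)
})

test_that("zero elasticity reproduces the BAU trajectory exactly", {
  b <- default_bundle()
  bau <- default_bau()
  el0 <- default_elasticities(); el0$elasticity <- rep(0, 4)
  tj <- apply_tax_effect(bau, tax_schedule(elasticities = el0,
                                           ethnic_scalar = 0), b)
  expect_identical(tj$dist, bau$dist)
})

test_that("tax-year prevalence reduction is linear in elasticity x increase", {
  b <- default_bundle()
  bau <- default_bau()
  maj <- 1; row <- 18   # age 17 at baseline -> in the youngest band
  reds <- vapply(c(0.05, 0.10, 0.20), function(inc) {
    tj <- apply_tax_effect(bau, tax_schedule(end_year = 2011,
                                             annual_increase = inc), b)
    1 - tj$dist[row, maj, icur, 1] / bau$dist[row, maj, icur, 1]
  }, numeric(1))
  expect_equal(reds / c(0.05, 0.10, 0.20), rep(0.38, 3), tolerance = 1e-10)
})

test_that("intervention current prevalence never exceeds BAU materially", {
  bau <- default_bau(); tj <- default_tax_traj()
  expect_lt(max(tj$dist[, , icur, ] - bau$dist[, , icur, ]), 1e-6)
})

test_that("complete cessation empties the current state for all years", {
  b <- default_bundle()
  tj <- scenario_prevalence("complete_cessation_2011", b, horizon = 60)
  expect_true(all(tj$dist[, , icur, ] == 0))
  ## 2012 ex-bin mass equals 2011 current+new-quit mass under ex-state survival:
  ## one-step bookkeeping oracle for a single cohort cell
  bau <- default_bau()
  cohort <- 41; j <- 1
  p2011 <- bau$dist[cohort, j, , 1]
  moved <- p2011
  moved[iex0] <- moved[iex0] + moved[icur]
  moved[icur] <- 0
  eth <- b$strata$eth_of[[b$strata$ids[j]]]
  q <- b$mortality[cohort + 1, j] *          # age 41 in 2012, trended
    (1 + b$trends$residual_apc[[eth]])
  rrs <- msltax:::state_mortality_rr(b$smoking$mortality_rr_current,
                                     b$smoking$gamma_allcause)
  surv <- pmax(1 - q * rrs / sum(moved * rrs), 0)
  expected <- moved * surv / sum(moved * surv)
  ## after the survival step the quit-year bin advances by one
  expect_equal(unname(tj$dist[cohort, j, iex0 + 1, 2]),
               unname(expected[iex0]), tolerance = 1e-12)
})

test_that("scenario A raises prevalence while initiation lasts, then declines", {
  b <- default_bundle()
  bau <- default_bau()
  tjA <- scenario_prevalence("no_cessation_ongoing_initiation", b)
  prA <- current_prevalence(tjA, b)
  tot <- stats::aggregate(prevalence ~ year, prA, mean)
  ## higher than BAU throughout
  prB <- stats::aggregate(prevalence ~ year, current_prevalence(bau, b), mean)
  expect_true(all(tot$prevalence >= prB$prevalence - 1e-12))
  ## declines once the youngest cohort has passed initiation age
  late <- tot$prevalence[tot$year >= 2032 & tot$year <= 2080]
  expect_true(all(diff(late) < 0))
  expect_error(scenario_prevalence("nonsense", b), "arg")
})

test_that("ex-smoker bins advance by exactly one year since quitting", {
  b <- default_bundle()
  b$smoking$cessation[] <- 0
  b$smoking$initiation_at_20[] <- 0
  b$smoking$mortality_rr_current <- 1
  b$smoking$initial[, , ] <- 0
  b$smoking$initial[, , inev] <- 0.9
  b$smoking$initial[, , iex0] <- 0.1     # everyone else quit this year
  traj <- project_bau(b, horizon = 25)
  cohort <- 31; j <- 2
  for (t in 1:19) {
    expect_equal(traj$dist[cohort, j, iex0 + t, t + 1], 0.1, tolerance = 1e-12)
  }
  ## after 20 years the mass sits in the no-excess-risk former pool
  ifor <- match("former", smoking_states())
  expect_equal(traj$dist[cohort, j, ifor, 22], 0.1, tolerance = 1e-12)
})
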