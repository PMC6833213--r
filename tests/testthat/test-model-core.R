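# Oxygen balance primitives: cumulative integration, the two maintenance
# parameterizations, and the forward OUR model.

test_that("cumulativeOUR implements the right-endpoint rectangle rule", {
  expect_equal(cumulativeOUR(0:3, c(2, 2, 2, 2)), c(0, 2, 4, 6))
  expect_equal(cumulativeOUR(c(0, 1), c(0, 0)), c(0, 0))
  # hand sum: 2 * 0.5, then + 4 * 1.0
  expect_equal(cumulativeOUR(c(0, 0.5, 1.5), c(1, 2, 4)), c(0, 1, 5))
  expect_error(cumulativeOUR(c(0, 1, 1), c(1, 1, 1)),
               class = "coursense_invalid_input")
  expect_error(cumulativeOUR(c(0, 1), c(1, 1, 1)),
               class = "coursense_invalid_input")
})

test_that("cumulativeOUR is non-decreasing for non-negative signals and exact for grid-aligned steps", {
  set.seed(7)
  for (i in 1:20) {
    tt <- cumsum(runif(15, 0.05, 1))
    our <- runif(15, 0, 3)
    expect_true(all(diff(cumulativeOUR(tt, our)) >= 0))
  }
  # piecewise-constant integrand aligned to the grid: rectangle rule is exact
  tt <- c(0, 1, 2, 5, 7)
  rate <- c(0, 3, 3, 0.5, 2)   # rate over (t[m-1], t[m]] is rate[m]
  expect_equal(cumulativeOUR(tt, rate), c(0, 3, 6, 7.5, 11.5))
})

test_that("betaOfTime is clamped before activation and linear after", {
  expect_identical(betaOfTime(0.01, 10, 10), 0)
  expect_identical(betaOfTime(0.01, 10, 5), 0)
  expect_equal(betaOfTime(0.01, 10, 15), 0.05)
  # continuity at the activation boundary
  expect_lt(betaOfTime(0.01, 10, 10 + 1e-9), 1e-10)
  # never negative, also for negative slopes
  expect_true(all(betaOfTime(-0.01, 10, seq(0, 30)) >= 0))
})

test_that("betaOfBiomass switches at xSpecific and evaluates the polynomial above it", {
  yeast <- yeastMaintenanceModel()
  expect_equal(betaOfBiomass(yeast, xSpecific(yeast)), 0)
  expect_lt(betaOfBiomass(yeast, xSpecific(yeast) + 1e-9), 1e-10)
  expect_identical(betaOfBiomass(yeast, 0), 0)
  ecoli <- ecoliMaintenanceModel()
  # direct polynomial evaluation at X = 30 g/l
  expect_equal(betaOfBiomass(ecoli, 30), 0.0186297, tolerance = 1e-6)
  expect_error(betaOfBiomass(ecoli, -1), class = "coursense_invalid_input")
  expect_true(all(betaOfBiomass(ecoli, seq(0, 60, by = 0.5)) >= 0))
})

test_that("forwardOUR composes growth and maintenance terms", {
  ecoli <- ecoliMaintenanceModel()
  expect_equal(forwardOUR(2, ecoli, 0, x = 1, xPrime = 1), 2)
  expect_equal(forwardOUR(2, ecoli, 0, x = 1, xPrime = 0), 0)
  # above threshold: alpha X' + beta(X) X with beta(30) = 0.0186297
  expect_equal(forwardOUR(1, ecoli, 0, x = 30, xPrime = 0.5),
               0.5 + 0.0186297 * 30, tolerance = 1e-6)
  expect_error(forwardOUR(1, ecoli, c(0, 1), x = 30, xPrime = 0.5),
               class = "coursense_invalid_input")
})

test_that("integrating the forward model recovers the analytic balance at first order", {
  # independent check: alpha (X - X0) + trapezoid quadrature of beta(X) X on
  # a 100x finer grid, vs the package's right-rule cOUR of the forward OUR
  ecoli <- ecoliMaintenanceModel()
  alpha <- 1.01
  x0 <- 15
  mu <- 0.1
  xFun <- function(t) x0 * exp(mu * t)
  err <- vapply(c(0.1, 0.01), function(dt) {
    tt <- seq(0, 8, by = dt)
    x <- xFun(tt)
    our <- forwardOUR(alpha, ecoli, tt, x, mu * x)
    courEnd <- cumulativeOUR(tt, our)[length(tt)]
    tFine <- seq(0, 8, by = dt / 100)
    bx <- betaOfBiomass(ecoli, xFun(tFine)) * xFun(tFine)
    maint <- sum((bx[-1] + bx[-length(bx)]) / 2 * diff(tFine))
    abs(courEnd - (alpha * (x[length(x)] - x0) + maint))
  }, numeric(1))
  expect_lt(err[2], 0.05)
  # first-order convergence: a 10x finer grid shrinks the error ~10x
  expect_gt(err[1] / err[2], 5)
  expect_lt(err[1] / err[2], 20)
})

test_that("ourSeries validates its grid and round-trips cour <-> our", {
  s <- ourSeries(0:3, our = c(2, 2, 2, 2))
  expect_equal(courValues(s), c(0, 2, 4, 6))
  s2 <- ourSeries(0:3, cour = c(0, 2, 4, 6))
  expect_equal(ourValues(s2)[-1], c(2, 2, 2))
  expect_equal(cumulativeOUR(sampleTimes(s2), ourValues(s2)), courValues(s2))
  expect_error(ourSeries(c(0, 0, 1), our = c(1, 1, 1)))
  expect_error(ourSeries(0:1, cour = c(1, 2)))   # cour must start at 0
})

test_that("courAtTimes interpolates exactly at grid points and rejects extrapolation", {
  s <- ourSeries(c(0, 1, 2, 4), our = c(0, 1, 2, 3))
  expect_equal(courAtTimes(s, c(1, 2, 4)), courValues(s)[-1])
  expect_equal(courAtTimes(s, 3), (courValues(s)[3] + courValues(s)[4]) / 2)
  expect_error(courAtTimes(s, 5), class = "coursense_invalid_input")
})
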