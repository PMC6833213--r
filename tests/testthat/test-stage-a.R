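# Offline stoichiometry identification: weights, criterion, closed-form
# solve, activation-time search, maintenance regression and threshold.

test_that("uncertaintyWeight matches the Monod-form variance limits", {
  expect_equal(uncertaintyWeight(c(0.5, 2, 7), kExp = 1), c(1, 1, 1))
  expect_equal(uncertaintyWeight(2, kExp = 0), 0.25)
  expect_equal(uncertaintyWeight(5, kExp = 0.4), 0.424)
  expect_error(uncertaintyWeight(0, kExp = 0.5), class = "coursense_invalid_input")
  # weight interpolates linearly (hence continuously/monotonically) in kExp
  x <- 3
  k <- seq(0, 1, by = 0.1)
  w <- vapply(k, function(kk) uncertaintyWeight(x, kk), numeric(1))
  expect_equal(w, (1 - k) / x^2 + k)
})

test_that("entropyCriterion is zero at a perfect fit and quadratic in the residuals", {
  set.seed(11)
  inst <- randomStageAInstance()
  ds <- inst$dataset
  x <- biomassValues(ds)
  r <- coursense:::maintenanceRegressor(sampleTimes(ds), x, inst$tI)
  pred <- 1.2 * (x - initialBiomass(ds)) + 0.01 * r
  expect_equal(entropyCriterion(ds, pred, 1.2, 0.01, inst$tI, 0.4)$sValue, 0)
  resid <- runif(length(x), -0.5, 0.5)
  s1 <- entropyCriterion(ds, pred + resid, 1.2, 0.01, inst$tI, 1)$sValue
  s2 <- entropyCriterion(ds, pred + 2 * resid, 1.2, 0.01, inst$tI, 1)$sValue
  expect_equal(s2, 4 * s1)
  expect_lte(s1, 0)
  expect_error(entropyCriterion(ds, pred[-1], 1.2, 0.01, inst$tI, 0.4),
               class = "coursense_invalid_input")
})

test_that("entropyCriterion reproduces the 3-sample hand computation", {
  ds <- offlineDataset(c(1, 2, 3), c(1, 2, 4), x0 = 1)
  # predictions at alpha = 2: 0, 2, 6; residuals 0, 0.1, 0.3
  out <- entropyCriterion(ds, c(0, 2.1, 6.3), alpha = 2, k1 = 0, tI = 3, kExp = 1)
  expect_equal(out$sValue, -0.10)
})

test_that("solveStoichiometry reduces to the one-parameter ratio without post-activation samples", {
  ds <- offlineDataset(1:5, c(0.5, 1, 2, 4, 8), x0 = 0.25)
  cour <- 1.5 * (biomassValues(ds) - 0.25)
  fit <- solveStoichiometry(ds, cour, tI = 5, kExp = 0.4)
  expect_equal(fit$alpha, 1.5)
  expect_identical(fit$k1, 0)
  expect_identical(fit$nPost, 0L)
})

test_that("solveStoichiometry recovers generating parameters exactly on noise-free two-phase data", {
  cfg <- simulationConfig(betaMode = "time", alphaTrue = 1.01, k1True = 4e-3,
                          tITrue = 10)
  ex <- simulateStageAExperiment(cfg)
  ds <- ex@offlineDataset
  cour <- courAtTimes(ex@observedOurSeries, sampleTimes(ds))
  fit <- solveStoichiometry(ds, cour, tI = 10, kExp = 0.4)
  expect_lt(relDiff(fit$alpha, 1.01), 1e-9)
  expect_lt(relDiff(fit$k1, 4e-3), 1e-9)
})

test_that("closed-form solve agrees with brute-force criterion maximization", {
  set.seed(123)
  for (i in 1:8) {
    inst <- randomStageAInstance()
    fit <- solveStoichiometry(inst$dataset, inst$cour, inst$tI, inst$kExp)
    sFun <- function(a, k)
      entropyCriterion(inst$dataset, inst$cour, a, k, inst$tI, inst$kExp)$sValue
    oracle <- gridRefineOracle(sFun)
    expect_lt(relDiff(fit$alpha, oracle["alpha"]), 1e-4)
    expect_lt(relDiff(fit$k1, oracle["k1"]), 1e-4)
  }
})

test_that("collinear growth and maintenance regressors raise a degenerate-fit error", {
  # two post-activation samples engineered so that the maintenance regressor
  # is exactly twice the growth regressor at both samples
  t2 <- (9 + sqrt(57)) / 6
  ds <- offlineDataset(c(2, t2), c(2, 3), x0 = 1)
  r <- coursense:::maintenanceRegressor(c(2, t2), c(2, 3), tI = 1)
  expect_equal(r / (c(2, 3) - 1), rep(r[1], 2) / 1)   # proportional columns
  cour <- 1.3 * (c(2, 3) - 1) + 0.01 * r
  expect_error(solveStoichiometry(ds, cour, tI = 1, kExp = 1),
               class = "coursense_degenerate_fit")
})

test_that("kExp limits reproduce the independent least-squares solutions", {
  set.seed(5)
  inst <- randomStageAInstance()
  ds <- inst$dataset
  g <- biomassValues(ds) - initialBiomass(ds)
  r <- coursense:::maintenanceRegressor(sampleTimes(ds), biomassValues(ds), inst$tI)
  fit1 <- solveStoichiometry(ds, inst$cour, inst$tI, kExp = 1)
  ols <- coef(lm(inst$cour ~ 0 + g + r))
  expect_lt(relDiff(fit1$alpha, ols[["g"]]), 1e-10)
  expect_lt(relDiff(fit1$k1, ols[["r"]]), 1e-10)
  fit0 <- solveStoichiometry(ds, inst$cour, inst$tI, kExp = 0)
  wls <- coef(lm(inst$cour ~ 0 + g + r, weights = 1 / biomassValues(ds)^2))
  expect_lt(relDiff(fit0$alpha, wls[["g"]]), 1e-10)
  expect_lt(relDiff(fit0$k1, wls[["r"]]), 1e-10)
  # solutions move continuously between the two limits
  ks <- seq(0, 1, by = 0.05)
  alphas <- vapply(ks, function(k)
    solveStoichiometry(ds, inst$cour, inst$tI, k)$alpha, numeric(1))
  expect_true(all(abs(diff(alphas)) < 0.1 * max(abs(alphas))))
})

test_that("findInductionTime recovers the true activation time on synthetic data", {
  cfg <- simulationConfig(betaMode = "time", k1True = 4e-3, tITrue = 12,
                          inductionTime = 12, tEnd = 20)
  ex <- simulateStageAExperiment(cfg)
  ds <- ex@offlineDataset
  cour <- courAtTimes(ex@observedOurSeries, sampleTimes(ds))
  search <- findInductionTime(ds, cour, kExp = 0.4)
  expect_equal(search$tI, 12)
  expect_lt(relDiff(search$alpha, 1.01), 1e-9)
  expect_lt(relDiff(search$k1, 4e-3), 1e-9)
  expect_false(is.unsorted(search$trace$candidate_t_i))
})

test_that("single-phase data yields the earliest flat candidate and flags unidentifiable maintenance", {
  ds <- offlineDataset(1:6, 0.3 * exp(0.4 * (1:6)), x0 = 0.3)
  cour <- 1.2 * (biomassValues(ds) - 0.3)
  # perfect single-phase fit: S = 0 (to rounding) at every candidate, so the
  # flat region resolves to its earliest member
  search <- findInductionTime(ds, cour, kExp = 0.4)
  expect_equal(search$tI, 2)
  expect_equal(search$alpha, 1.2)
  expect_lt(abs(search$k1), 1e-10)
  # when no sample follows the chosen activation time, maintenance is
  # unidentifiable and the search says so
  search2 <- findInductionTime(ds, cour, kExp = 0.4, candidates = 6)
  expect_match(search2$flags, "unidentifiable", all = FALSE)
})

test_that("fitMaintenancePolynomial recovers exact generating polynomials", {
  x <- seq(7, 30, by = 1.7)
  lineFit <- fitMaintenancePolynomial(
    data.frame(x = x, beta = 2.3851e-3 * x - 1.5014e-2), degree = 1)
  expect_equal(lineFit@kBeta1, 2.3851e-3)
  expect_equal(lineFit@kBeta0, -1.5014e-2)
  expect_identical(lineFit@kBeta2, 0)
  parab <- fitMaintenancePolynomial(
    data.frame(x = x, beta = 2e-4 * x^2 - 3e-3 * x + 0.05), degree = 2)
  expect_equal(parab@kBeta2, 2e-4)
  expect_equal(parab@kBeta1, -3e-3)
  expect_equal(parab@kBeta0, 0.05)
  expect_error(fitMaintenancePolynomial(data.frame(x = c(1, 2), beta = c(1, 2)),
                                        degree = 2),
               class = "coursense_invalid_input")
})

test_that("degree-1 maintenance fit matches the closed-form simple regression", {
  set.seed(21)
  df <- data.frame(x = c(8, 15, 24), beta = c(0.004, 0.02, 0.041) + rnorm(3, 0, 1e-3))
  fit <- fitMaintenancePolynomial(df, degree = 1)
  slope <- sum((df$x - mean(df$x)) * (df$beta - mean(df$beta))) /
    sum((df$x - mean(df$x))^2)
  expect_equal(fit@kBeta1, slope)
  expect_equal(fit@kBeta0, mean(df$beta) - slope * mean(df$x))
})

test_that("computeXSpecific solves the published threshold cases", {
  yeast <- computeXSpecific(maintenanceModel(0, 2.3851e-3, -1.5014e-2,
                                             xSpecific = 1, degree = 1))
  expect_equal(signif(as.numeric(yeast), 3), 6.29)
  expect_false(attr(yeast, "stationaryFallback"))
  ecoli <- computeXSpecific(maintenanceModel(7.2e-5, -2.9625e-3, 4.27047e-2,
                                             xSpecific = 1, degree = 2))
  expect_equal(signif(as.numeric(ecoli), 3), 20.6)
  expect_true(attr(ecoli, "stationaryFallback"))
  unit <- computeXSpecific(maintenanceModel(0, 1, -10, xSpecific = 1, degree = 1))
  expect_equal(as.numeric(unit), 10)
  expect_error(computeXSpecific(maintenanceModel(0, 0, 1, xSpecific = 1, degree = 1)),
               class = "coursense_invalid_model")
  expect_error(computeXSpecific(maintenanceModel(0, 1, 10, xSpecific = 1, degree = 1)),
               class = "coursense_invalid_model")
  # a quadratic with real roots takes the larger one
  twoRoots <- computeXSpecific(maintenanceModel(1, -3, 2, xSpecific = 1, degree = 2))
  expect_equal(as.numeric(twoRoots), 2)
})

test_that("fitStrain recovers the generating strain end-to-end and pools replicates idempotently", {
  cfg <- simulationConfig(betaMode = "time", alphaTrue = 1.01, k1True = 4e-3,
                          tITrue = 10)
  ex <- simulateStageAExperiment(cfg)
  single <- fitStrain(ex, kExp = 0.4)
  p <- single@strainParameters
  expect_lt(relDiff(p@alpha, 1.01), 1e-6)
  expect_lt(relDiff(p@k1, 4e-3), 1e-6)
  expect_equal(p@tI, 10)
  # beta(t) over post-activation samples is linear in X only approximately;
  # pooling three identical replicates must not move any coefficient
  triple <- fitStrain(list(ex, ex, ex), kExp = 0.4)
  q <- triple@strainParameters
  expect_equal(q@alpha, p@alpha)
  expect_equal(q@k1, p@k1)
  expect_equal(q@maintenance@kBeta1, p@maintenance@kBeta1)
  expect_equal(q@maintenance@kBeta0, p@maintenance@kBeta0)
  expect_equal(q@maintenance@xSpecific, p@maintenance@xSpecific)
})

test_that("a known induction time bypasses the activation-time search", {
  cfg <- simulationConfig(betaMode = "time", k1True = 4e-3, tITrue = 10)
  ex <- simulateStageAExperiment(cfg)
  ds <- ex@offlineDataset
  ds@inductionTime <- 10
  fit <- fitStrain(list(offline = ds, our = ex@observedOurSeries), kExp = 0.4)
  expect_identical(nrow(fit@criterionTrace), 0L)
  expect_equal(fit@strainParameters@tI, 10)
  expect_lt(relDiff(fit@strainParameters@alpha, 1.01), 1e-6)
})
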