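# Synthetic fed-batch generator: growth law, forward balance, sampling and
# observation noise.

test_that("pre-induction growth matches the exponential closed form", {
  cfg <- simulationConfig(muMax = 0.3, decelRate = 0, x0 = 0.2, tEnd = 5,
                          inductionTime = 4.999, maintenanceTrue = zeroMaintenance())
  ex <- simulateCulture(cfg)
  xEnd <- ex@truth$x[nrow(ex@truth)]
  expect_lt(abs(xEnd - 0.2 * exp(0.3 * 5)) / (0.2 * exp(0.3 * 5)), 1e-3)
})

test_that("with zero maintenance the oxygen balance telescopes exactly", {
  cfg <- simulationConfig(maintenanceTrue = zeroMaintenance())
  ex <- simulateCulture(cfg)
  expect_equal(ex@truth$cour, cfg$alphaTrue * (ex@truth$x - cfg$x0))
  # the Stage B identity: cOUR/alpha + x0 reproduces X on the grid
  expect_equal(ex@truth$cour / cfg$alphaTrue + cfg$x0, ex@truth$x)
})

test_that("the truth trajectory satisfies the forward balance on its grid", {
  cfg <- simulationConfig()
  ex <- simulateCulture(cfg)
  with(ex@truth, expect_equal(
    our, forwardOUR(cfg$alphaTrue, cfg$maintenanceTrue, time_h, x, x_prime)))
})

test_that("the default culture crosses X_specific before the end", {
  ex <- simulateCulture(simulationConfig())
  xs <- xSpecific(ecoliMaintenanceModel())
  expect_gt(max(ex@truth$x), xs)
  expect_lt(min(ex@truth$x), xs)
})

test_that("sampleOffline picks hourly samples and handles ragged ends", {
  cfg <- simulationConfig(tEnd = 8, inductionTime = 4)
  truth <- simulateCulture(cfg)@truth
  ds <- sampleOffline(truth, 1, x0 = 0.2)
  expect_equal(sampleTimes(ds), 1:8)
  truth85 <- simulateCulture(simulationConfig(tEnd = 8.5, inductionTime = 4))@truth
  ds85 <- sampleOffline(truth85, 1, x0 = 0.2)
  expect_equal(max(sampleTimes(ds85)), 8)
  expect_error(sampleOffline(truth, 9, x0 = 0.2), class = "coursense_invalid_input")
  # sampling at the online interval reproduces the truth grid (minus t0)
  dense <- sampleOffline(truth, cfg$onlineInterval, x0 = 0.2)
  expect_equal(biomassValues(dense), truth$x[-1])
})

test_that("addNoise is a no-op at zero CV and reproducible under a seed", {
  cfg0 <- simulationConfig(ourNoiseCv = 0, dcwNoiseCv = 0)
  ex0 <- simulateCulture(cfg0)
  noisy0 <- addNoise(ex0)
  expect_identical(courValues(noisy0@observedOurSeries),
                   courValues(ex0@observedOurSeries))
  expect_identical(biomassValues(noisy0@offlineDataset),
                   biomassValues(ex0@offlineDataset))
  ex <- simulateCulture(simulationConfig())
  a <- addNoise(ex, seed = 17)
  b <- addNoise(ex, seed = 17)
  expect_identical(courValues(a@observedOurSeries), courValues(b@observedOurSeries))
  expect_identical(biomassValues(a@offlineDataset), biomassValues(b@offlineDataset))
  expect_identical(a@truth, ex@truth)   # truth untouched
})

test_that("empirical DCW noise matches the configured coefficient of variation", {
  # 10^4 offline samples of a flat trajectory, 5% multiplicative noise
  n <- 10000L
  truth <- data.frame(time_h = seq(0, 100, length.out = n + 1),
                      x = rep(10, n + 1), x_prime = 0, our = 0, cour = 0)
  series <- ourSeries(truth$time_h, our = truth$our)
  ds <- offlineDataset(truth$time_h[-1], truth$x[-1], x0 = 10)
  cfg <- simulationConfig(dcwNoiseCv = 0.05, ourNoiseCv = 0)
  ex <- new("SyntheticExperiment", truth = truth, observedOurSeries = series,
            offlineDataset = ds, config = cfg)
  noisy <- addNoise(ex, seed = 42)
  cv <- sd(biomassValues(noisy@offlineDataset) / 10 - 1)
  expect_gt(cv, 0.045)
  expect_lt(cv, 0.055)
})

test_that("noise is unbiased: replicate means converge to the truth", {
  cfg <- simulationConfig(betaMode = "time", ourNoiseCv = 0.05, dcwNoiseCv = 0)
  ex <- simulateStageAExperiment(cfg)
  m <- length(ex@observedOurSeries@cour)
  truthEnd <- ex@observedOurSeries@cour[m]
  reps <- vapply(seq_len(1000), function(s)
    addNoise(ex, seed = s)@observedOurSeries@cour[m], numeric(1))
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - truthEnd), 3 * se)
})

test_that("Monod-form noise reproduces the requested variance structure", {
  kExp <- 0.4
  cfg <- simulationConfig(betaMode = "time", ourNoiseCv = 0.05, dcwNoiseCv = 0)
  ex <- simulateStageAExperiment(cfg)
  idx <- c(3L, 20L)   # early (small X) and late (large X) sample
  xAt <- ex@truth$x[idx - 1L]
  reps <- vapply(seq_len(400), function(s) {
    noisyCour <- addNoise(ex, kExpForVariance = kExp, seed = s)@observedOurSeries@cour
    noisyCour[idx] - ex@observedOurSeries@cour[idx]
  }, numeric(2))
  empirical <- apply(reps, 1, var)
  expected <- 0.05^2 * xAt^2 / (1 - kExp + kExp * xAt^2)
  expect_equal(empirical / expected, c(1, 1), tolerance = 0.25)
})

test_that("configuration invariants are enforced", {
  expect_error(simulationConfig(tEnd = 5, inductionTime = 6),
               class = "coursense_invalid_input")
  expect_error(simulationConfig(muMax = -0.1), class = "coursense_invalid_input")
  expect_error(simulationConfig(onlineInterval = 0), class = "coursense_invalid_input")
})
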