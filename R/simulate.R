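## Synthetic fed-batch cultures: two-phase growth (constant specific growth
## rate mu up to induction, exponentially decelerating mu afterwards), OUR
## from the forward Luedeking-Piret balance, cOUR by the package's own
## right-endpoint integration, and multiplicative Gaussian observation noise
## on cOUR and offline DCW.  Everything Stage A/B assume is reproducible here
## without any external data.

#' Configuration of a synthetic fed-batch culture
#'
#' Defaults emulate a recombinant E. coli fed-batch: growth yield
#' `alphaTrue = 1.01` g O2/g DCW with the quadratic E. coli-type maintenance
#' polynomial, `muMax = 0.35` 1/h up to induction at 10 h, post-induction
#' deceleration `decelRate = 0.15` 1/h (the culture then crosses
#' X_specific and approaches ~40 g/l by 20 h), inoculation at
#' `x0 = 0.2` g/l, 1-min online grid, hourly offline sampling, 2%
#' multiplicative cOUR noise and 5% DCW noise.
#'
#' @param alphaTrue growth oxygen yield, g O2/g DCW.
#' @param betaMode `"biomass"` (polynomial beta(X), for Stage B round trips)
#'   or `"time"` (time-linear beta(t) = k1 (t - tI), the form Stage A
#'   identifies).
#' @param maintenanceTrue a [MaintenanceModel-class] (used when
#'   `betaMode = "biomass"`).
#' @param k1True,tITrue slope and activation time of beta(t) (used when
#'   `betaMode = "time"`); `tITrue` defaults to `inductionTime`.
#' @param muMax pre-induction specific growth rate, 1/h.
#' @param decelRate post-induction exponential decay rate of mu, 1/h.
#' @param x0 initial biomass, g/l.
#' @param tEnd culture duration, h.
#' @param inductionTime induction time, h.
#' @param ourNoiseCv multiplicative coefficient of variation on observed cOUR.
#' @param dcwNoiseCv multiplicative coefficient of variation on offline DCW.
#' @param offlineInterval offline sampling interval, h.
#' @param onlineInterval online grid interval, h.
#' @param seed integer seed for the observation noise.
#' @return a validated configuration list.
#' @export
simulationConfig <- function(alphaTrue = 1.01,
                             betaMode = c("biomass", "time"),
                             maintenanceTrue = ecoliMaintenanceModel(),
                             k1True = 4e-3,
                             tITrue = inductionTime,
                             muMax = 0.35,
                             decelRate = 0.15,
                             x0 = 0.2,
                             tEnd = 20,
                             inductionTime = 10,
                             ourNoiseCv = 0.02,
                             dcwNoiseCv = 0.05,
                             offlineInterval = 1,
                             onlineInterval = 1 / 60,
                             seed = 1L) {
  betaMode <- match.arg(betaMode)
  config <- list(alphaTrue = alphaTrue, betaMode = betaMode,
                 maintenanceTrue = maintenanceTrue, k1True = k1True,
                 tITrue = tITrue, muMax = muMax, decelRate = decelRate,
                 x0 = x0, tEnd = tEnd, inductionTime = inductionTime,
                 ourNoiseCv = ourNoiseCv, dcwNoiseCv = dcwNoiseCv,
                 offlineInterval = offlineInterval,
                 onlineInterval = onlineInterval, seed = as.integer(seed))
  for (f in c("muMax", "decelRate", "ourNoiseCv", "dcwNoiseCv"))
    if (config[[f]] < 0) stopInvalidInput("%s must be non-negative", f)
  for (f in c("offlineInterval", "onlineInterval", "x0", "alphaTrue"))
    if (config[[f]] <= 0) stopInvalidInput("%s must be positive", f)
  if (!(config$tEnd > config$inductionTime && config$inductionTime > 0))
    stopInvalidInput("need tEnd > inductionTime > 0")
  config
}

## Closed-form log-growth integral M(t) = int_0^t mu(s) ds for the two-phase
## growth law; exact, so the truth trajectory carries no integration error.
logGrowthIntegral <- function(t, muMax, decelRate, tI) {
  pre <- muMax * pmin(t, tI)
  s <- pmax(t - tI, 0)
  post <- if (decelRate > 0) muMax * (1 - exp(-decelRate * s)) / decelRate
          else muMax * s
  pre + post
}

growthRate <- function(t, muMax, decelRate, tI) {
  ifelse(t < tI, muMax, muMax * exp(-decelRate * (t - tI)))
}

#' Simulate a noise-free fed-batch culture
#'
#' Evaluates the two-phase growth law in closed form on the online grid
#' (X(t) = x0 exp(M(t)) with M the exact integral of mu), derives OUR from
#' the forward oxygen balance with the configured maintenance
#' parameterisation, and integrates cOUR with [cumulativeOUR()].  The growth
#' term uses the interval-mean rate `diff(X)/diff(t)` (what an
#' interval-averaging gas analyzer reports), so the growth part of cOUR
#' telescopes to `alpha * (X - X0)` exactly on the grid; the only remaining
#' discretization error is the first-order maintenance quadrature.  The
#' returned experiment carries noise-free observables; add observation noise
#' with [addNoise()].
#'
#' @param config a [simulationConfig()] list.
#' @return a [SyntheticExperiment-class].
#' @export
simulateCulture <- function(config) {
  times <- seq(0, config$tEnd, by = config$onlineInterval)
  x <- config$x0 * exp(logGrowthIntegral(times, config$muMax,
                                         config$decelRate,
                                         config$inductionTime))
  ## interval-mean growth rate (as an interval-averaging gas analyzer sees
  ## it): right-rule integration of alpha * xPrime then telescopes to
  ## alpha * (X - X0) exactly, the discrete oxygen balance the estimator
  ## assumes
  xPrime <- c(growthRate(0, config$muMax, config$decelRate,
                         config$inductionTime) * config$x0,
              diff(x) / diff(times))
  our <- if (config$betaMode == "biomass")
    forwardOUR(config$alphaTrue, config$maintenanceTrue, times, x, xPrime)
  else
    config$alphaTrue * xPrime +
      betaOfTime(config$k1True, config$tITrue, times) * x
  cour <- cumulativeOUR(times, our)
  truth <- data.frame(time_h = times, x = x, x_prime = xPrime,
                      our = our, cour = cour)
  new("SyntheticExperiment", truth = truth,
      observedOurSeries = ourSeries(times, our = our, cour = cour),
      offlineDataset = sampleOffline(truth, config$offlineInterval, config$x0,
                                     inductionTime = NA_real_,
                                     label = "synthetic"),
      config = config)
}

#' Pick offline samples from a truth trajectory
#'
#' Samples the truth biomass at multiples of the offline interval (nearest
#' grid point; the sample at t = 0 is represented by `x0`, not duplicated).
#'
#' @param truth truth data.frame from [simulateCulture()] (columns `time_h`,
#'   `x`).
#' @param offlineInterval sampling interval, h.
#' @param x0 initial biomass, g/l.
#' @param inductionTime optional known induction time, h.
#' @param label experiment label.
#' @return an [OfflineDataset-class].
#' @export
sampleOffline <- function(truth, offlineInterval, x0,
                          inductionTime = NA_real_, label = "synthetic") {
  tEnd <- truth$time_h[nrow(truth)]
  if (offlineInterval > tEnd)
    stopInvalidInput("offline interval (%.4g h) exceeds culture duration (%.4g h)",
                     offlineInterval, tEnd)
  wanted <- seq(offlineInterval, tEnd + 1e-9, by = offlineInterval)
  wanted <- wanted[wanted <= tEnd + 1e-9]
  idx <- vapply(wanted, function(w) which.min(abs(truth$time_h - w)), integer(1))
  idx <- unique(idx)
  offlineDataset(sampleTimes = truth$time_h[idx], biomass = truth$x[idx],
                 x0 = x0, inductionTime = inductionTime, label = label)
}

#' Add observation noise to a synthetic experiment
#'
#' Applies independent multiplicative Gaussian noise to the observed cOUR
#' signal and to the offline DCW values; the truth trajectory is untouched
#' and the result is reproducible for a given seed.  When `kExpForVariance`
#' is supplied the cOUR noise standard deviation instead follows the
#' Monod-form uncertainty model,
#' `sd_m = ourNoiseCv * sqrt(X_m^2 / (1 - kExp + kExp X_m^2))`, matching the
#' variance structure the Stage A weights assume.
#'
#' @param experiment a [SyntheticExperiment-class].
#' @param kExpForVariance optional weight coefficient in \[0, 1\] selecting
#'   Monod-form cOUR noise; `NULL` (default) selects constant-CV
#'   multiplicative noise.
#' @param seed integer seed; defaults to the experiment's configured seed.
#' @return a [SyntheticExperiment-class] with noisy observables.
#' @export
addNoise <- function(experiment, kExpForVariance = NULL,
                     seed = experiment@config$seed) {
  config <- experiment@config
  set.seed(seed)
  series <- experiment@observedOurSeries
  cour <- series@cour
  n <- length(cour)

  if (config$ourNoiseCv > 0 && n > 1L) {
    z <- stats::rnorm(n - 1L)
    sd <- if (is.null(kExpForVariance)) {
      config$ourNoiseCv * cour[-1L]
    } else {
      xAt <- stats::approx(experiment@truth$time_h, experiment@truth$x,
                           xout = series@times[-1L], rule = 2)$y
      config$ourNoiseCv * sqrt(xAt^2 /
        (1 - kExpForVariance + kExpForVariance * xAt^2))
    }
    cour[-1L] <- cour[-1L] + sd * z
  }
  series <- ourSeries(series@times, cour = cour)

  ds <- experiment@offlineDataset
  dcw <- ds@biomass
  if (config$dcwNoiseCv > 0)
    dcw <- dcw * (1 + config$dcwNoiseCv * stats::rnorm(length(dcw)))
  ds@biomass <- dcw
  validObject(ds)

  new("SyntheticExperiment", truth = experiment@truth,
      observedOurSeries = series, offlineDataset = ds, config = config)
}

#' Simulate an offline-grid-consistent Stage A experiment
#'
#' Generates observations exactly on the offline sample grid with the
#' time-linear maintenance parameterisation and the same discretization the
#' offline identification uses: `cOUR_m = alpha (X_m - X0) + k1 R_m` with the
#' discrete post-activation maintenance sum R_m.  Because generator and
#' estimator share the discretization, Stage A recovers `(alphaTrue, k1True,
#' tITrue)` from the noise-free output to machine precision — the
#' parameter-recovery reference case.  (The dense-grid [simulateCulture()]
#' carries an O(offline interval) discretization mismatch in the maintenance
#' term and is the harder, realistic case.)
#'
#' @param config a [simulationConfig()] list (its `betaMode` is ignored; the
#'   time-linear form is always used here).
#' @return a [SyntheticExperiment-class] whose OUR series lives on the
#'   offline grid (prepended with the inoculation point).
#' @export
simulateStageAExperiment <- function(config) {
  tI <- config$tITrue
  sampleTimes <- seq(config$offlineInterval, config$tEnd + 1e-9,
                     by = config$offlineInterval)
  sampleTimes <- sampleTimes[sampleTimes <= config$tEnd + 1e-9]
  x <- config$x0 * exp(logGrowthIntegral(sampleTimes, config$muMax,
                                         config$decelRate,
                                         config$inductionTime))
  r <- maintenanceRegressor(sampleTimes, x, tI)
  cour <- config$alphaTrue * (x - config$x0) + config$k1True * r
  series <- ourSeries(c(0, sampleTimes), cour = c(0, cour))
  xPrime <- growthRate(sampleTimes, config$muMax, config$decelRate,
                       config$inductionTime) * x
  truth <- data.frame(time_h = sampleTimes, x = x, x_prime = xPrime,
                      our = series@our[-1L], cour = cour)
  new("SyntheticExperiment", truth = truth, observedOurSeries = series,
      offlineDataset = offlineDataset(sampleTimes, x, config$x0,
                                      inductionTime = NA_real_,
                                      label = "synthetic-stage-a"),
      config = config)
}
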