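## Stage B: online recursive biomass estimation from the cOUR stream alone.
##
## Below the strain's specific biomass threshold the estimator is the
## growth-only affine map X_m = cOUR_m / alpha + X0.  Once the estimate
## crosses X_specific the maintenance oxygen is accrued with the
## previous-point rule, sum beta(X_l) X_l dt, and subtracted from cOUR
## before dividing by alpha.  The regime switch is latched: no reverting
## below the threshold (avoids chattering near X_specific).

#' Initialize the online biomass estimator
#'
#' @param params a [StrainParameters-class].
#' @param x0 initial biomass at inoculation, g/l (convert optical density
#'   with [odToDcw()] first if needed).
#' @param t0 inoculation time, h (default 0).
#' @return an [EstimatorState-class].
#' @export
initializeEstimator <- function(params, x0, t0 = 0) {
  if (length(x0) != 1L || !is.finite(x0) || x0 <= 0)
    stopInvalidInput("x0 must be a single positive biomass concentration")
  new("EstimatorState", xCurrent = as.numeric(x0), maintenanceIntegral = 0,
      tLast = as.numeric(t0), x0 = as.numeric(x0),
      aboveSpecific = x0 > params@maintenance@xSpecific)
}

#' One recursive update of the biomass estimate
#'
#' Consumes the next cOUR observation.  In the growth regime the estimate is
#' `cOUR_m / alpha + X0`; in the maintenance regime the maintenance integral
#' is first advanced with the previous estimate over the elapsed interval
#' (each point's prediction is computed once, never revisited) and then
#' subtracted from cOUR.  A slightly decreasing cOUR stream (sensor glitch
#' beyond -1e-6 g/l) triggers a data-quality warning but the value is used
#' as-is; negative estimates are floored at 0 with a warning.
#'
#' @param state an [EstimatorState-class].
#' @param cour cumulative oxygen uptake observation, g O2/l.
#' @param t observation time, h; must exceed the state's last time.
#' @param params a [StrainParameters-class].
#' @return list with the advanced `state` and the estimate `x` (g/l).
#' @export
updateEstimate <- function(state, cour, t, params) {
  if (t <= state@tLast)
    stopInvalidInput("non-monotone time: t = %.6g h after t = %.6g h", t, state@tLast)
  lastCour <- attr(state, "lastCour")
  if (!is.null(lastCour) && cour < lastCour - 1e-6)
    warnDataQuality("decreasing cOUR stream at t = %.4g h (%.6g -> %.6g g/l); using value as-is",
                    t, lastCour, cour)

  if (state@aboveSpecific) {
    dt <- t - state@tLast
    state@maintenanceIntegral <- state@maintenanceIntegral +
      betaOfBiomass(params@maintenance, state@xCurrent) * state@xCurrent * dt
    x <- (cour - state@maintenanceIntegral) / params@alpha + state@x0
  } else {
    x <- cour / params@alpha + state@x0
  }
  if (x < 0) {
    warnDataQuality("negative biomass estimate (%.4g g/l) at t = %.4g h floored at 0", x, t)
    x <- 0
  }
  if (!state@aboveSpecific && x > params@maintenance@xSpecific)
    state@aboveSpecific <- TRUE   # latched: no switching back
  state@xCurrent <- x
  state@tLast <- t
  attr(state, "lastCour") <- cour
  list(state = state, x = x)
}

#' Estimate a full biomass trajectory from a cOUR stream
#'
#' Folds [updateEstimate()] over an [OURSeries-class] (its first point, at
#' inoculation, is reported as `x0`).  Deterministic: identical inputs give
#' bit-identical trajectories.
#'
#' @param params a [StrainParameters-class].
#' @param series an [OURSeries-class] carrying the online cOUR signal.
#' @param x0 initial biomass, g/l.
#' @param t0 inoculation time, h; defaults to the series' first time point.
#' @return a [BiomassTrajectory-class].
#' @export
estimateTrajectory <- function(params, series, x0, t0 = NULL) {
  tt <- series@times
  cour <- series@cour
  if (is.null(t0)) t0 <- tt[1L]
  state <- initializeEstimator(params, x0, t0)
  n <- length(tt)
  x <- numeric(n)
  reg <- character(n)
  x[1L] <- state@xCurrent
  reg[1L] <- if (state@aboveSpecific) "maintenance" else "growth"
  for (m in seq_len(n)[-1L]) {
    reg[m] <- if (state@aboveSpecific) "maintenance" else "growth"
    upd <- updateEstimate(state, cour[m], tt[m], params)
    state <- upd$state
    x[m] <- upd$x
  }
  new("BiomassTrajectory", times = tt, xEstimates = x, regime = reg)
}
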