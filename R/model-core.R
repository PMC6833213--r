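## Luedeking-Piret oxygen balance: OUR(t) = alpha * X'(t) + beta * X(t).
## This file holds the discretized cumulative form and the two
## parameterizations of the maintenance coefficient beta (time-linear for
## offline identification, polynomial-in-biomass for online estimation).

#' Cumulative oxygen uptake by right-endpoint rectangle integration
#'
#' Integrates an OUR signal into cOUR on its own grid using the rectangle rule
#' with the integrand evaluated at the right endpoint of each subinterval:
#' `c[1] = 0`, `c[m] = c[m-1] + our[m] * (t[m] - t[m-1])`.  This is exactly
#' the discretization used by the offline identification and online
#' estimation equations, so the three stages stay mutually consistent.
#'
#' @param times hours, strictly increasing.
#' @param our OUR values, g O2/l/h, same length as `times`.
#' @return cOUR vector, g O2/l, same length; starts at 0 and is
#'   non-decreasing whenever `our >= 0`.
#' @examples
#' cumulativeOUR(0:3, c(2, 2, 2, 2))   # 0 2 4 6
#' @export
cumulativeOUR <- function(times, our) {
  times <- as.numeric(times); our <- as.numeric(our)
  if (length(times) != length(our))
    stopInvalidInput("times (%d) and our (%d) must have equal length",
                     length(times), length(our))
  if (length(times) < 1L)
    stopInvalidInput("at least one time point is required")
  if (length(times) >= 2L && any(diff(times) <= 0))
    stopInvalidInput("times must be strictly increasing")
  if (length(times) == 1L) return(0)
  c(0, cumsum(our[-1L] * diff(times)))
}

#' Time-linear maintenance coefficient
#'
#' The maintenance coefficient during offline identification,
#' beta(t) = k1 * (t - tI), clamped at zero: before the activation time tI
#' (induction, or the inferred time at which maintenance consumption becomes
#' appreciable) maintenance is negligible and beta is 0.
#'
#' @param k1 slope of beta(t).
#' @param tI activation time, h.
#' @param t time(s), h; vectorized.
#' @return `max(0, k1 * (t - tI))`, elementwise.
#' @examples
#' betaOfTime(0.01, tI = 10, t = c(5, 10, 15))   # 0 0 0.05
#' @export
betaOfTime <- function(k1, tI, t) {
  pmax(0, k1 * (t - tI))
}

#' Biomass-parameterised maintenance coefficient
#'
#' Evaluates beta(X) = kBeta2 X^2 + kBeta1 X + kBeta0 above the strain's
#' specific biomass threshold; below (or at) `xSpecific` maintenance is
#' negligible and the coefficient is 0.  Negative polynomial values are
#' clamped at zero so maintenance never credits oxygen back.
#'
#' @param model a [MaintenanceModel-class].
#' @param x biomass concentration(s), g/l, non-negative; vectorized.
#' @return maintenance coefficient(s), same length as `x`.
#' @examples
#' ec <- maintenanceModel(7.2e-5, -2.9625e-3, 4.27047e-2, degree = 2)
#' betaOfBiomass(ec, 30)
#' @export
betaOfBiomass <- function(model, x) {
  x <- as.numeric(x)
  if (any(x < 0, na.rm = TRUE))
    stopInvalidInput("biomass must be non-negative")
  val <- model@kBeta2 * x^2 + model@kBeta1 * x + model@kBeta0
  out <- pmax(0, val)
  if (!is.na(model@xSpecific)) out[x <= model@xSpecific] <- 0
  out
}

#' Forward Luedeking-Piret OUR model
#'
#' Computes OUR(t) = alpha * X'(t) + beta(X(t)) * X(t) along a trajectory,
#' with the maintenance term switched on only above the strain's specific
#' biomass threshold (handled inside [betaOfBiomass()]).  Used by the
#' synthetic-data generator and as the consistency check between the two
#' stages.
#'
#' @param alpha growth oxygen yield, g O2/g DCW.
#' @param model a [MaintenanceModel-class].
#' @param times hours (only used for validation of lengths).
#' @param x biomass trajectory, g/l, non-negative.
#' @param xPrime biomass derivative, g/l/h.
#' @return OUR vector, g O2/l/h.
#' @export
forwardOUR <- function(alpha, model, times, x, xPrime) {
  n <- length(times)
  if (length(x) != n || length(xPrime) != n)
    stopInvalidInput("times, x and xPrime must have equal length")
  alpha * xPrime + betaOfBiomass(model, x) * x
}

#' Interpolate a cOUR signal at arbitrary times
#'
#' Linear interpolation of the cumulative oxygen uptake of an
#' [OURSeries-class] at the requested times (exact at grid points); used to
#' align the online cOUR signal with offline sample times.
#'
#' @param series an [OURSeries-class].
#' @param at times, h, within the span of the series.
#' @return cOUR values at `at`, g O2/l.
#' @export
courAtTimes <- function(series, at) {
  tt <- series@times
  if (any(at < tt[1L] - 1e-9) || any(at > tt[length(tt)] + 1e-9))
    stopInvalidInput("requested times [%.4g, %.4g] outside series span [%.4g, %.4g]",
                     min(at), max(at), tt[1L], tt[length(tt)])
  stats::approx(tt, series@cour, xout = at, rule = 2)$y
}

#' Convert optical density to dry cell weight
#'
#' @param od optical density, o.u.
#' @param factor conversion factor, g/l per o.u. (default 0.4).
#' @return DCW, g/l.
#' @export
odToDcw <- function(od, factor = 0.4) {
  if (factor <= 0) stopInvalidInput("OD conversion factor must be positive")
  od * factor
}
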