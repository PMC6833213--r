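#' @import methods
NULL

## ---------------------------------------------------------------------------
## OURSeries
## ---------------------------------------------------------------------------

#' Sampled oxygen uptake rate signal with its running integral
#'
#' An `OURSeries` holds an oxygen uptake rate (OUR) signal sampled on a
#' strictly increasing time grid starting at inoculation (t0), together with
#' the cumulative oxygen uptake (cOUR) obtained by right-endpoint
#' rectangle integration of OUR over each subinterval.  cOUR is the sole
#' online driver signal of the biomass estimator.
#'
#' @slot times hours since inoculation, strictly increasing; the first entry
#'   is t0.
#' @slot our oxygen uptake rate at each time, g O2 / l / h.
#' @slot cour cumulative oxygen uptake at each time, g O2 / l; `cour[1] == 0`.
#'
#' @seealso [OURSeries()], [cumulativeOUR()]
#' @export
setClass("OURSeries",
  representation(times = "numeric", our = "numeric", cour = "numeric"))

setValidity("OURSeries", function(object) {
  msgs <- character()
  n <- length(object@times)
  if (n < 2L)
    msgs <- c(msgs, "an OURSeries needs at least 2 time points")
  if (length(object@our) != n || length(object@cour) != n)
    msgs <- c(msgs, "times, our and cour must have equal length")
  if (anyNA(object@times) || any(!is.finite(object@times)))
    msgs <- c(msgs, "times must be finite")
  else if (n >= 2L && any(diff(object@times) <= 0))
    msgs <- c(msgs, "times must be strictly increasing")
  if (length(object@cour) >= 1L && is.finite(object@cour[1L]) &&
      abs(object@cour[1L]) > 1e-12)
    msgs <- c(msgs, "cour must start at 0 (cOUR is re-based at inoculation)")
  if (length(msgs)) msgs else TRUE
})

#' Construct an OURSeries
#'
#' Builds the series either from an OUR signal (cOUR is then derived with
#' [cumulativeOUR()]) or from an observed cOUR signal (OUR is then recovered
#' as the per-interval mean rate, so that re-integration reproduces the given
#' cOUR exactly).
#'
#' @param times hours since inoculation, strictly increasing; first entry is
#'   inoculation time t0 (conventionally 0).
#' @param our oxygen uptake rate, g O2/l/h; omit if `cour` is given.
#' @param cour cumulative oxygen uptake, g O2/l, starting at 0; omit if `our`
#'   is given.
#' @return an [OURSeries-class] object.
#' @examples
#' ourSeries(times = 0:3, our = c(2, 2, 2, 2))
#' @export
ourSeries <- function(times, our = NULL, cour = NULL) {
  times <- as.numeric(times)
  if (is.null(our) && is.null(cour))
    stopInvalidInput("one of 'our' or 'cour' must be supplied")
  if (is.null(cour)) {
    cour <- cumulativeOUR(times, as.numeric(our))
  } else {
    cour <- as.numeric(cour)
    if (length(cour) != length(times))
      stopInvalidInput("times and cour must have equal length")
    if (is.null(our)) {
      dt <- diff(times)
      if (any(dt <= 0))
        stopInvalidInput("times must be strictly increasing")
      our <- c(0, diff(cour) / dt)
    }
  }
  new("OURSeries", times = times, our = as.numeric(our), cour = cour)
}

setMethod("show", "OURSeries", function(object) {
  n <- length(object@times)
  cat(sprintf("OURSeries: %d points, t = [%.3g, %.3g] h, cOUR(end) = %.4g g O2/l\n",
              n, object@times[1L], object@times[n], object@cour[n]))
})

## ---------------------------------------------------------------------------
## OfflineDataset
## ---------------------------------------------------------------------------

#' Sparse offline biomass observations for one cultivation
#'
#' Timed dry-cell-weight (DCW) samples for a single fed-batch experiment,
#' together with the initial biomass concentration at inoculation and, when
#' known (recombinant E. coli runs: IPTG injection), the induction time.
#' Optical-density readings are converted upstream with [odToDcw()].
#'
#' @slot sampleTimes hours since inoculation, strictly increasing.
#' @slot biomass DCW in g/l at each sample time.
#' @slot x0 initial biomass concentration at inoculation, g/l.
#' @slot inductionTime induction time in hours, or `NA_real_` when unknown
#'   (yeast runs; the activation time is then inferred in Stage A).
#' @slot label free-text experiment identifier.
#' @export
setClass("OfflineDataset",
  representation(sampleTimes = "numeric", biomass = "numeric", x0 = "numeric",
                 inductionTime = "numeric", label = "character"))

setValidity("OfflineDataset", function(object) {
  msgs <- character()
  n <- length(object@sampleTimes)
  if (n < 2L)
    msgs <- c(msgs, "at least 2 offline samples are required")
  if (length(object@biomass) != n)
    msgs <- c(msgs, "sampleTimes and biomass must have equal length")
  if (n >= 2L && any(diff(object@sampleTimes) <= 0))
    msgs <- c(msgs, "sampleTimes must be strictly increasing")
  if (any(object@biomass < 0, na.rm = TRUE))
    msgs <- c(msgs, "biomass must be non-negative")
  if (length(object@x0) != 1L || !is.finite(object@x0) || object@x0 <= 0)
    msgs <- c(msgs, "x0 must be a single positive number")
  if (length(object@inductionTime) != 1L)
    msgs <- c(msgs, "inductionTime must be a single number (NA if unknown)")
  if (length(msgs)) msgs else TRUE
})

#' Construct an OfflineDataset
#'
#' @param sampleTimes hours since inoculation, strictly increasing.
#' @param biomass DCW g/l at each sample time.
#' @param x0 initial biomass at inoculation, g/l (> 0).
#' @param inductionTime induction time in hours; `NA` (default) when unknown.
#' @param label experiment identifier.
#' @return an [OfflineDataset-class] object.
#' @export
offlineDataset <- function(sampleTimes, biomass, x0,
                           inductionTime = NA_real_, label = "experiment") {
  new("OfflineDataset", sampleTimes = as.numeric(sampleTimes),
      biomass = as.numeric(biomass), x0 = as.numeric(x0),
      inductionTime = as.numeric(inductionTime), label = as.character(label))
}

setMethod("show", "OfflineDataset", function(object) {
  cat(sprintf("OfflineDataset '%s': %d samples over [%.3g, %.3g] h, X0 = %.3g g/l",
              object@label, length(object@sampleTimes),
              object@sampleTimes[1L], max(object@sampleTimes), object@x0))
  if (is.finite(object@inductionTime))
    cat(sprintf(", induction at %.3g h", object@inductionTime))
  cat("\n")
})

## ---------------------------------------------------------------------------
## MaintenanceModel
## ---------------------------------------------------------------------------

#' Polynomial maintenance coefficient beta(X)
#'
#' The oxygen-for-maintenance coefficient expressed as a polynomial in
#' biomass concentration, beta(X) = kBeta2 X^2 + kBeta1 X + kBeta0, applied
#' only above the strain-specific threshold `xSpecific` (below it maintenance
#' consumption is negligible and beta is taken as 0).  Degree 1 models
#' (yeast-like strains) have `kBeta2 == 0`.
#'
#' @slot kBeta2,kBeta1,kBeta0 polynomial coefficients (units 1/h per matching
#'   power of g/l).
#' @slot xSpecific biomass threshold, g/l, above which maintenance applies.
#' @slot degree 1 or 2.
#' @slot stationaryFallback TRUE when `xSpecific` was taken at the parabola's
#'   stationary point because the quadratic has no real root.
#' @seealso [maintenanceModel()], [betaOfBiomass()], [computeXSpecific()]
#' @export
setClass("MaintenanceModel",
  representation(kBeta2 = "numeric", kBeta1 = "numeric", kBeta0 = "numeric",
                 xSpecific = "numeric", degree = "integer",
                 stationaryFallback = "logical"))

setValidity("MaintenanceModel", function(object) {
  msgs <- character()
  for (s in c("kBeta2", "kBeta1", "kBeta0", "xSpecific"))
    if (length(slot(object, s)) != 1L)
      msgs <- c(msgs, sprintf("%s must be a single number", s))
  if (!object@degree %in% c(1L, 2L))
    msgs <- c(msgs, "degree must be 1 or 2")
  if (object@degree == 1L && isTRUE(object@kBeta2 != 0))
    msgs <- c(msgs, "degree 1 requires kBeta2 == 0")
  if (is.finite(object@xSpecific) && object@xSpecific <= 0)
    msgs <- c(msgs, "xSpecific must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Construct a MaintenanceModel
#'
#' @param kBeta2,kBeta1,kBeta0 polynomial coefficients of beta(X).
#' @param xSpecific activation threshold, g/l; if `NULL` it is computed from
#'   the coefficients with [computeXSpecific()].
#' @param degree polynomial degree, 1 or 2.
#' @return a [MaintenanceModel-class] object.
#' @examples
#' # S. cerevisiae-type linear model
#' maintenanceModel(kBeta1 = 2.3851e-3, kBeta0 = -1.5014e-2, degree = 1)
#' @export
maintenanceModel <- function(kBeta2 = 0, kBeta1 = 0, kBeta0 = 0,
                             xSpecific = NULL, degree = if (kBeta2 != 0) 2L else 1L) {
  degree <- as.integer(degree)
  obj <- new("MaintenanceModel", kBeta2 = as.numeric(kBeta2),
             kBeta1 = as.numeric(kBeta1), kBeta0 = as.numeric(kBeta0),
             xSpecific = NA_real_, degree = degree,
             stationaryFallback = FALSE)
  if (is.null(xSpecific)) {
    xs <- computeXSpecific(obj)
    obj@xSpecific <- as.numeric(xs)
    obj@stationaryFallback <- isTRUE(attr(xs, "stationaryFallback"))
  } else {
    obj@xSpecific <- as.numeric(xSpecific)
  }
  validObject(obj)
  obj
}

setMethod("show", "MaintenanceModel", function(object) {
  cat(sprintf("MaintenanceModel (degree %d): beta(X) = %.6g X^2 + %.6g X + %.6g\n",
              object@degree, object@kBeta2, object@kBeta1, object@kBeta0))
  cat(sprintf("  X_specific = %.4g g/l%s\n", object@xSpecific,
              if (object@stationaryFallback) " (stationary-point fallback)" else ""))
})

## ---------------------------------------------------------------------------
## StrainParameters
## ---------------------------------------------------------------------------

#' Strain stoichiometric parameter set
#'
#' Everything the online estimator needs for one cell strain: the specific
#' oxygen consumption yield for growth (alpha, g O2 per g DCW), the
#' time-linear maintenance slope k1 with its activation time tI (used during
#' offline identification), the uncertainty weight coefficient kExp, and the
#' biomass-parameterised maintenance polynomial.
#'
#' @slot alpha growth oxygen yield, g O2 / g DCW (> 0).
#' @slot k1 slope of the time-linear maintenance coefficient beta(t), 1/h^2
#'   scale.
#' @slot tI maintenance activation (induction) time used in Stage A, h.
#' @slot kExp weight coefficient in \[0, 1\]; 1 recovers ordinary least
#'   squares, 0 recovers variance proportional to X^2.
#' @slot maintenance a [MaintenanceModel-class].
#' @slot strainLabel free text.
#' @export
setClass("StrainParameters",
  representation(alpha = "numeric", k1 = "numeric", tI = "numeric",
                 kExp = "numeric", maintenance = "MaintenanceModel",
                 strainLabel = "character"))

setValidity("StrainParameters", function(object) {
  msgs <- character()
  if (length(object@alpha) != 1L || !is.finite(object@alpha) || object@alpha <= 0)
    msgs <- c(msgs, "alpha must be a single positive number")
  if (length(object@kExp) != 1L || is.na(object@kExp) ||
      object@kExp < 0 || object@kExp > 1)
    msgs <- c(msgs, "kExp must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Construct a StrainParameters object
#'
#' @param alpha growth oxygen yield, g O2 / g DCW.
#' @param maintenance a [MaintenanceModel-class].
#' @param k1 time-linear maintenance slope (Stage A bookkeeping).
#' @param tI activation time used during Stage A, h.
#' @param kExp uncertainty weight coefficient in \[0, 1\].
#' @param strainLabel free text.
#' @return a [StrainParameters-class] object.
#' @export
strainParameters <- function(alpha, maintenance, k1 = 0, tI = NA_real_,
                             kExp = 0.4, strainLabel = "strain") {
  new("StrainParameters", alpha = as.numeric(alpha), k1 = as.numeric(k1),
      tI = as.numeric(tI), kExp = as.numeric(kExp), maintenance = maintenance,
      strainLabel = as.character(strainLabel))
}

setMethod("show", "StrainParameters", function(object) {
  cat(sprintf("StrainParameters '%s': alpha = %.4g g O2/g DCW, k1 = %.4g, tI = %.4g h, kExp = %.3g\n",
              object@strainLabel, object@alpha, object@k1, object@tI, object@kExp))
  show(object@maintenance)
})

## ---------------------------------------------------------------------------
## EstimatorState & BiomassTrajectory
## ---------------------------------------------------------------------------

#' Running state of the online biomass estimator
#'
#' @slot xCurrent latest biomass estimate, g/l.
#' @slot maintenanceIntegral accumulated maintenance oxygen,
#'   sum of beta(X_l) X_l dt, g O2/l; non-decreasing.
#' @slot tLast time of last update, h.
#' @slot x0 initial biomass, g/l.
#' @slot aboveSpecific latched TRUE once the estimate exceeded X_specific.
#' @seealso [initializeEstimator()], [updateEstimate()]
#' @export
setClass("EstimatorState",
  representation(xCurrent = "numeric", maintenanceIntegral = "numeric",
                 tLast = "numeric", x0 = "numeric", aboveSpecific = "logical"))

setValidity("EstimatorState", function(object) {
  msgs <- character()
  if (object@x0 <= 0) msgs <- c(msgs, "x0 must be positive")
  if (object@maintenanceIntegral < 0)
    msgs <- c(msgs, "maintenanceIntegral must be non-negative")
  if (object@xCurrent < 0) msgs <- c(msgs, "xCurrent must be non-negative")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "EstimatorState", function(object) {
  cat(sprintf("EstimatorState: X = %.4g g/l at t = %.4g h, maintenance integral = %.4g g O2/l, %s\n",
              object@xCurrent, object@tLast, object@maintenanceIntegral,
              if (object@aboveSpecific) "maintenance regime" else "growth regime"))
})

#' Estimated biomass trajectory
#'
#' @slot times hours.
#' @slot xEstimates biomass estimates, g/l.
#' @slot regime per-point regime flag, `"growth"` (growth-only estimator) or
#'   `"maintenance"` (maintenance-corrected estimator); switches at most once,
#'   and never back.
#' @export
setClass("BiomassTrajectory",
  representation(times = "numeric", xEstimates = "numeric", regime = "character"))

setValidity("BiomassTrajectory", function(object) {
  msgs <- character()
  n <- length(object@times)
  if (length(object@xEstimates) != n || length(object@regime) != n)
    msgs <- c(msgs, "times, xEstimates and regime must have equal length")
  if (!all(object@regime %in% c("growth", "maintenance")))
    msgs <- c(msgs, "regime entries must be 'growth' or 'maintenance'")
  if (any(object@regime[-1] == "growth" & object@regime[-n] == "maintenance"))
    msgs <- c(msgs, "regime must not switch back from maintenance to growth")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "BiomassTrajectory", function(object) {
  n <- length(object@times)
  cat(sprintf("BiomassTrajectory: %d points, X = %.3g -> %.4g g/l, %d in maintenance regime\n",
              n, object@xEstimates[1L], object@xEstimates[n],
              sum(object@regime == "maintenance")))
})

## ---------------------------------------------------------------------------
## SyntheticExperiment & StageAFit
## ---------------------------------------------------------------------------

#' Simulated fed-batch experiment
#'
#' Ground-truth trajectory on the online grid plus the observables handed to
#' Stage A/B: a (possibly noisy) [OURSeries-class] and a (possibly noisy)
#' [OfflineDataset-class].
#'
#' @slot truth data.frame with columns `time_h`, `x`, `x_prime`, `our`,
#'   `cour` — the noise-free trajectory.
#' @slot observedOurSeries [OURSeries-class] on the online grid.
#' @slot offlineDataset [OfflineDataset-class] on the offline grid.
#' @slot config the generating configuration (list).
#' @export
setClass("SyntheticExperiment",
  representation(truth = "data.frame", observedOurSeries = "OURSeries",
                 offlineDataset = "OfflineDataset", config = "list"))

setMethod("show", "SyntheticExperiment", function(object) {
  n <- nrow(object@truth)
  cat(sprintf("SyntheticExperiment: %d truth points to t = %.3g h, X(end) = %.4g g/l\n",
              n, object@truth$time_h[n], object@truth$x[n]))
  show(object@observedOurSeries)
  show(object@offlineDataset)
})

#' Stage A fit report
#'
#' @slot strainParameters the fitted [StrainParameters-class].
#' @slot perExperiment list (one entry per experiment) with the
#'   per-experiment solution, Gram weight, residuals and flags.
#' @slot betaSamples data.frame (`x`, `beta`, `experiment`) of the pooled
#'   (biomass, maintenance) pairs behind the beta(X) regression.
#' @slot criterionTrace data.frame (`experiment`, `candidate_t_i`,
#'   `s_value`) from the activation-time search.
#' @slot flags character vector of fit diagnostics.
#' @export
setClass("StageAFit",
  representation(strainParameters = "StrainParameters", perExperiment = "list",
                 betaSamples = "data.frame", criterionTrace = "data.frame",
                 flags = "character"))

setMethod("show", "StageAFit", function(object) {
  cat(sprintf("StageAFit over %d experiment(s)\n", length(object@perExperiment)))
  show(object@strainParameters)
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = "; "), "\n")
})
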