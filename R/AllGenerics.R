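#' Accessors for coursense objects
#'
#' Small accessor family: `sampleTimes()` returns the time grid of a series,
#' dataset or trajectory; `ourValues()`/`courValues()` the OUR and cumulative
#' OUR signals; `biomassValues()` the offline DCW observations;
#' `biomassEstimates()` and `regime()` the online estimates and their
#' per-point regime; `initialBiomass()`, `inductionTime()`, `alphaYield()`,
#' `maintenance()` and `xSpecific()` the corresponding parameters.
#'
#' @param object a coursense S4 object.
#' @return the requested slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sampleTimes", function(object) standardGeneric("sampleTimes"))
#' @rdname accessors
#' @export
setGeneric("ourValues", function(object) standardGeneric("ourValues"))
#' @rdname accessors
#' @export
setGeneric("courValues", function(object) standardGeneric("courValues"))
#' @rdname accessors
#' @export
setGeneric("biomassValues", function(object) standardGeneric("biomassValues"))
#' @rdname accessors
#' @export
setGeneric("biomassEstimates", function(object) standardGeneric("biomassEstimates"))
#' @rdname accessors
#' @export
setGeneric("regime", function(object) standardGeneric("regime"))
#' @rdname accessors
#' @export
setGeneric("initialBiomass", function(object) standardGeneric("initialBiomass"))
#' @rdname accessors
#' @export
setGeneric("inductionTime", function(object) standardGeneric("inductionTime"))
#' @rdname accessors
#' @export
setGeneric("alphaYield", function(object) standardGeneric("alphaYield"))
#' @rdname accessors
#' @export
setGeneric("maintenance", function(object) standardGeneric("maintenance"))
#' @rdname accessors
#' @export
setGeneric("xSpecific", function(object) standardGeneric("xSpecific"))

#' @rdname accessors
setMethod("sampleTimes", "OURSeries", function(object) object@times)
#' @rdname accessors
setMethod("sampleTimes", "OfflineDataset", function(object) object@sampleTimes)
#' @rdname accessors
setMethod("sampleTimes", "BiomassTrajectory", function(object) object@times)
#' @rdname accessors
setMethod("ourValues", "OURSeries", function(object) object@our)
#' @rdname accessors
setMethod("courValues", "OURSeries", function(object) object@cour)
#' @rdname accessors
setMethod("biomassValues", "OfflineDataset", function(object) object@biomass)
#' @rdname accessors
setMethod("biomassEstimates", "BiomassTrajectory", function(object) object@xEstimates)
#' @rdname accessors
setMethod("regime", "BiomassTrajectory", function(object) object@regime)
#' @rdname accessors
setMethod("initialBiomass", "OfflineDataset", function(object) object@x0)
#' @rdname accessors
setMethod("inductionTime", "OfflineDataset", function(object) object@inductionTime)
#' @rdname accessors
setMethod("alphaYield", "StrainParameters", function(object) object@alpha)
#' @rdname accessors
setMethod("maintenance", "StrainParameters", function(object) object@maintenance)
#' @rdname accessors
setMethod("xSpecific", "MaintenanceModel", function(object) object@xSpecific)
#' @rdname accessors
setMethod("xSpecific", "StrainParameters", function(object) object@maintenance@xSpecific)
#' @rdname accessors
setMethod("inductionTime", "StrainParameters", function(object) object@tI)
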