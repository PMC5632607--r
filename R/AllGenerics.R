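#' Accessors for gridded and fitted objects
#'
#' Small accessor family used across the package instead of direct slot
#' access: `gridLayout()` returns the [RasterLayout], `gridValues()` the
#' value matrix of a raster-like object, `validMask()` its validity mask,
#' `speciesName()` the species tag, `layerNames()` the environmental layer
#' names of a stack or fitted model.
#'
#' @param x an object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("gridLayout", function(x) standardGeneric("gridLayout"))
#' @rdname accessors
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))
#' @rdname accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))
#' @rdname accessors
#' @export
setGeneric("speciesName", function(x) standardGeneric("speciesName"))
#' @rdname accessors
#' @export
setGeneric("layerNames", function(x) standardGeneric("layerNames"))

#' @rdname accessors
#' @export
setMethod("gridLayout", "EnvStack", function(x) x@layout)
#' @rdname accessors
#' @export
setMethod("gridLayout", "SuitabilityModel", function(x) x@layout)
#' @rdname accessors
#' @export
setMethod("gridLayout", "BinaryModel", function(x) x@layout)
#' @rdname accessors
#' @export
setMethod("gridLayout", "LandCover", function(x) x@layout)
#' @rdname accessors
#' @export
setMethod("gridLayout", "VirtualSpecies", function(x) x@layout)
#' @rdname accessors
#' @export
setMethod("gridLayout", "RichnessModel", function(x) x@layout)

#' @rdname accessors
#' @export
setMethod("gridValues", "SuitabilityModel", function(x) x@grid)
#' @rdname accessors
#' @export
setMethod("gridValues", "BinaryModel", function(x) x@grid)
#' @rdname accessors
#' @export
setMethod("gridValues", "LandCover", function(x) x@classGrid)
#' @rdname accessors
#' @export
setMethod("gridValues", "RichnessModel", function(x) x@grid)
#' @rdname accessors
#' @export
setMethod("gridValues", "VirtualSpecies", function(x) x@truth)

#' @rdname accessors
#' @export
setMethod("validMask", "EnvStack", function(x) x@validMask)
#' @rdname accessors
#' @export
setMethod("validMask", "SuitabilityModel", function(x) x@validMask)
#' @rdname accessors
#' @export
setMethod("validMask", "BinaryModel", function(x) !is.na(x@grid))

#' @rdname accessors
#' @export
setMethod("speciesName", "OccurrenceSet", function(x) x@species)
#' @rdname accessors
#' @export
setMethod("speciesName", "SuitabilityModel", function(x) x@species)
#' @rdname accessors
#' @export
setMethod("speciesName", "BinaryModel", function(x) x@species)
#' @rdname accessors
#' @export
setMethod("speciesName", "VirtualSpecies", function(x) x@species)

#' @rdname accessors
#' @export
setMethod("layerNames", "EnvStack", function(x) x@layerNames)
#' @rdname accessors
#' @export
setMethod("layerNames", "EnfaModel", function(x) x@layerNames)

#' Extract one layer of an environmental stack as a matrix
#' @param x an [EnvStack]; @param layer layer name or index.
#' @export
envLayer <- function(x, layer) {
  if (is.character(layer)) layer <- match(layer, x@layerNames)
  if (is.na(layer)) stop("unknown layer", call. = FALSE)
  matrix(x@values[, , layer], x@layout@nRows, x@layout@nCols)
}

#' Occurrence points as a matrix
#' @param x an [OccurrenceSet].
#' @export
occPoints <- function(x) x@points

#' Number of occurrence points
#' @param x an [OccurrenceSet].
#' @export
setMethod("length", "OccurrenceSet", function(x) nrow(x@points))

setMethod("show", "RasterLayout", function(object) {
  cat(sprintf("RasterLayout: %d x %d cells, cell size %g, origin (%g, %g)\n",
              object@nRows, object@nCols, object@cellSize,
              object@originX, object@originY))
})

setMethod("show", "EnvStack", function(object) {
  cat(sprintf("EnvStack: %d layers [%s%s] on %d x %d grid (%d valid cells)\n",
              length(object@layerNames),
              paste(utils::head(object@layerNames, 4), collapse = ", "),
              if (length(object@layerNames) > 4) ", ..." else "",
              object@layout@nRows, object@layout@nCols, sum(object@validMask)))
})

setMethod("show", "OccurrenceSet", function(object) {
  cat(sprintf("OccurrenceSet: %d %s points for '%s'\n",
              nrow(object@points), object@source, object@species))
})

setMethod("show", "SuitabilityModel", function(object) {
  cat(sprintf("SuitabilityModel (%s, %s) for '%s': %d valid cells\n",
              object@engine, object@scale, object@species, sum(object@validMask)))
})

setMethod("show", "BinaryModel", function(object) {
  cat(sprintf("%s for '%s': %d presence cells (threshold %g, rule %s)\n",
              object@kind, object@species, sum(object@grid == 1L, na.rm = TRUE),
              object@thresholdUsed, object@thresholdRule))
})

setMethod("show", "EnfaModel", function(object) {
  cat(sprintf("EnfaModel: %d layers, %d presence cells\n  M = %.3f, T = %.3f, retained factors: %s\n",
              length(object@layerNames), object@nPresence,
              object@globalMarginality, object@globalTolerance,
              paste(object@retained, collapse = ", ")))
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat(sprintf("ConfusionMatrix: TP=%d FP=%d FN=%d TN=%d (kappa %.3f, sens %.3f, spec %.3f)\n",
              object@TP, object@FP, object@FN, object@TN,
              kappaStat(object), sensitivity(object), specificity(object)))
})

setMethod("show", "ThresholdReport", function(object) {
  cat(sprintf("ThresholdReport for '%s' (%s): %d candidates, kappa threshold %s, ROC threshold %s, AUC %.3f\n",
              object@species, object@engine, nrow(object@curve),
              format(object@kappaThreshold), format(object@rocThreshold), object@auc))
})

setMethod("show", "RichnessModel", function(object) {
  cat(sprintf("RichnessModel: %d species, richness 0-%d, %d classes\n",
              object@nSpecies, max(object@grid, na.rm = TRUE),
              length(object@classBreaks)))
})

setMethod("show", "ValidationReport", function(object) {
  cat(sprintf("ValidationReport: %d species\n", nrow(object@table)))
  print(object@table, digits = 4)
  cat(sprintf("site success:   mean %.1f, sd %.1f\nbuffer success: mean %.1f, sd %.1f\n",
              object@summary$siteMean, object@summary$siteSd,
              object@summary$bufferMean, object@summary$bufferSd))
})

#' Validation report table and summary
#' @param x a [ValidationReport].
#' @export
validationTable <- function(x) x@table

#' @rdname validationTable
#' @export
validationSummary <- function(x) x@summary
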