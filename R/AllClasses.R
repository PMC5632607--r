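#' @import methods
NULL

#' Raster layout (grid georeferencing)
#'
#' Shared georeferencing for all gridded objects: grid dimensions, map
#' coordinates of the top-left corner, and a single square cell size.
#' Cell \code{(r, c)} covers the half-open square
#' \eqn{[x_0 + (c-1)s, x_0 + cs) \times (y_0 - rs, y_0 - (r-1)s]} with row 1
#' at the top; a point maps to the cell containing it and points exactly on
#' the right/bottom edge of the grid are clipped inward.
#'
#' @slot nRows,nCols positive integers.
#' @slot originX,originY map coordinates of the top-left corner.
#' @slot cellSize positive cell size in map units (square cells).
#' @export
setClass("RasterLayout",
  representation(nRows = "integer", nCols = "integer",
                 originX = "numeric", originY = "numeric",
                 cellSize = "numeric"),
  validity = function(object) {
    if (object@nRows < 1L || object@nCols < 1L) return("grid dimensions must be positive")
    if (!is.finite(object@cellSize) || object@cellSize <= 0) return("cellSize must be > 0")
    if (!is.finite(object@originX) || !is.finite(object@originY)) return("origin must be finite")
    TRUE
  })

#' @param nRows,nCols,originX,originY,cellSize see slots.
#' @rdname RasterLayout-class
#' @export
RasterLayout <- function(nRows, nCols, originX = 0, originY = nRows * cellSize,
                         cellSize = 1) {
  new("RasterLayout", nRows = assertCount(nRows, "nRows"),
      nCols = assertCount(nCols, "nCols"),
      originX = as.numeric(originX), originY = as.numeric(originY),
      cellSize = assertNumber(cellSize, "cellSize", min = 0, strictMin = TRUE))
}

#' Aligned multi-layer environmental raster stack
#'
#' Holds one real-valued grid per environmental layer (e.g. bioclimatic and
#' topographic variables), all sharing a single [RasterLayout], plus a
#' validity mask. Every valid cell carries a finite value in every layer;
#' invalid cells are represented in memory by the mask (values there are
#' \code{NA}), and by a declared nodata value on disk.
#'
#' @slot layout a [RasterLayout].
#' @slot layerNames character vector, one name per layer.
#' @slot values numeric array \code{nRows x nCols x nLayers}.
#' @slot validMask logical matrix \code{nRows x nCols}.
#' @export
setClass("EnvStack",
  representation(layout = "RasterLayout", layerNames = "character",
                 values = "array", validMask = "matrix"),
  validity = function(object) {
    d <- dim(object@values)
    if (length(d) != 3L) return("values must be a 3-d array")
    if (d[1] != object@layout@nRows || d[2] != object@layout@nCols)
      return("values dimensions disagree with layout")
    if (d[3] != length(object@layerNames)) return("one name per layer required")
    if (anyDuplicated(object@layerNames)) return("layer names must be unique")
    if (!identical(dim(object@validMask), d[1:2])) return("validMask dimensions disagree")
    if (!any(object@validMask)) return("at least one valid cell required")
    for (k in seq_len(d[3]))
      if (!all(is.finite(object@values[, , k][object@validMask])))
        return(sprintf("layer '%s' has non-finite values on valid cells", object@layerNames[k]))
    TRUE
  })

#' @param values array or list of matrices; @param layerNames,layout,validMask see slots.
#' @rdname EnvStack-class
#' @export
EnvStack <- function(values, layerNames, layout, validMask = NULL) {
  if (is.list(values)) {
    dims <- unique(lapply(values, dim))
    if (length(dims) != 1L)
      stop("all layers must share identical dimensions", call. = FALSE)
    values <- array(unlist(values, use.names = FALSE),
                    dim = c(dims[[1]], length(values)))
  }
  if (is.null(validMask))
    validMask <- apply(is.finite(values), c(1, 2), all)
  for (k in seq_len(dim(values)[3])) {
    lay <- values[, , k]; lay[!validMask] <- NA_real_; values[, , k] <- lay
  }
  new("EnvStack", values = values, layerNames = as.character(layerNames),
      layout = layout, validMask = validMask)
}

#' Species occurrence points
#'
#' A set of occurrence points for one species from one source (museum
#' records, field survey records, or generated pseudoabsences). Duplicate
#' coordinates are permitted; collapsing them to distinct cells is an
#' explicit operation performed by the consumers that need it.
#'
#' @slot species species name.
#' @slot points two-column numeric matrix of x/y map coordinates.
#' @slot source one of \code{"museum"}, \code{"field"}, \code{"pseudoabsence"}.
#' @slot siteId optional per-point site identifier (length 0 or \code{nrow(points)}).
#' @export
setClass("OccurrenceSet",
  representation(species = "character", points = "matrix",
                 source = "character", siteId = "character"),
  validity = function(object) {
    if (length(object@species) != 1L) return("species must be a single string")
    if (ncol(object@points) != 2L) return("points must have two columns (x, y)")
    if (!object@source %in% c("museum", "field", "pseudoabsence"))
      return("source must be museum, field or pseudoabsence")
    if (length(object@siteId) && length(object@siteId) != nrow(object@points))
      return("siteId must be empty or one id per point")
    TRUE
  })

#' @param species,points,source,siteId see slots.
#' @rdname OccurrenceSet-class
#' @export
OccurrenceSet <- function(species, points, source = "museum", siteId = character()) {
  points <- matrix(as.numeric(points), ncol = 2,
                   dimnames = list(NULL, c("x", "y")))
  new("OccurrenceSet", species = species, points = points,
      source = source, siteId = as.character(siteId))
}

#' Continuous or ordinal habitat-suitability raster
#'
#' Output of a suitability engine for one species: continuous scores in
#' 0--100, or ordinal integer scores 1--10 (the narrow-scale convention used
#' by some rule-based engines), aligned to the [EnvStack] it was fitted on.
#'
#' @slot species,engine character; engine is one of \code{enfa},
#'   \code{envelope}, \code{mahalanobis}, \code{external}.
#' @slot grid numeric score matrix (\code{NA} on invalid cells).
#' @slot scale \code{"continuous_0_100"} or \code{"ordinal_1_10"}.
#' @slot validMask logical matrix.
#' @slot layout a [RasterLayout].
#' @export
setClass("SuitabilityModel",
  representation(species = "character", engine = "character", grid = "matrix",
                 scale = "character", validMask = "matrix", layout = "RasterLayout"),
  validity = function(object) {
    if (!object@engine %in% c("enfa", "envelope", "mahalanobis", "external"))
      return("unknown engine tag")
    if (!object@scale %in% c("continuous_0_100", "ordinal_1_10"))
      return("unknown scale tag")
    if (!identical(dim(object@grid), c(object@layout@nRows, object@layout@nCols)))
      return("grid dimensions disagree with layout")
    v <- object@grid[object@validMask]
    if (!all(is.finite(v))) return("non-finite scores on valid cells")
    if (object@scale == "continuous_0_100" && (any(v < 0) || any(v > 100)))
      return("continuous scores must lie in [0, 100]")
    if (object@scale == "ordinal_1_10" &&
        (any(v != round(v)) || any(v < 1) || any(v > 10)))
      return("ordinal scores must be integers in [1, 10]")
    TRUE
  })

SuitabilityModel <- function(species, engine, grid, scale, validMask, layout) {
  grid[!validMask] <- NA_real_
  new("SuitabilityModel", species = species, engine = engine, grid = grid,
      scale = scale, validMask = validMask, layout = layout)
}

#' Binary presence/absence distribution model
#'
#' A thresholded suitability model: a potential distribution model
#' (\code{kind = "PDM"}) or its habitat-masked reduction, the actual
#' distribution model (\code{kind = "ADM"}). Cells hold 1 (presence),
#' 0 (absence) or \code{NA} (invalid). An ADM's presence cells are a subset
#' of its parent PDM's presence cells.
#'
#' @slot species character.
#' @slot kind \code{"PDM"} or \code{"ADM"}.
#' @slot grid integer matrix in \{0, 1, NA\}.
#' @slot thresholdUsed the score cutoff that produced the model.
#' @slot thresholdRule \code{"kappa"}, \code{"roc"} or \code{"external"}.
#' @slot layout a [RasterLayout].
#' @slot metadata free-form list (e.g. habitat classes and subcell rule for ADMs).
#' @export
setClass("BinaryModel",
  representation(species = "character", kind = "character", grid = "matrix",
                 thresholdUsed = "numeric", thresholdRule = "character",
                 layout = "RasterLayout", metadata = "list"),
  validity = function(object) {
    if (!object@kind %in% c("PDM", "ADM")) return("kind must be PDM or ADM")
    if (!object@thresholdRule %in% c("kappa", "roc", "external"))
      return("thresholdRule must be kappa, roc or external")
    if (!identical(dim(object@grid), c(object@layout@nRows, object@layout@nCols)))
      return("grid dimensions disagree with layout")
    v <- object@grid[!is.na(object@grid)]
    if (!all(v %in% c(0L, 1L))) return("grid values must be 0, 1 or NA")
    TRUE
  })

BinaryModel <- function(species, kind, grid, thresholdUsed, thresholdRule,
                        layout, metadata = list()) {
  storage.mode(grid) <- "integer"
  new("BinaryModel", species = species, kind = kind, grid = grid,
      thresholdUsed = as.numeric(thresholdUsed), thresholdRule = thresholdRule,
      layout = layout, metadata = metadata)
}

#' Categorical land-cover raster
#'
#' Integer class raster at a resolution equal to or finer than the model
#' grid; the land-cover cell size must divide the model cell size exactly
#' (integer subcell ratio, e.g. 250 m land cover under a 1 km model grid).
#'
#' @slot classGrid integer matrix (\code{NA} invalid).
#' @slot legend named character vector mapping class code to class name.
#' @slot layout the (fine) [RasterLayout].
#' @export
setClass("LandCover",
  representation(classGrid = "matrix", legend = "character", layout = "RasterLayout"),
  validity = function(object) {
    if (!identical(dim(object@classGrid), c(object@layout@nRows, object@layout@nCols)))
      return("classGrid dimensions disagree with layout")
    codes <- unique(object@classGrid[!is.na(object@classGrid)])
    if (length(codes) && !all(as.character(codes) %in% names(object@legend)))
      return("classGrid contains codes missing from the legend")
    TRUE
  })

LandCover <- function(classGrid, legend, layout) {
  storage.mode(classGrid) <- "integer"
  new("LandCover", classGrid = classGrid, legend = legend, layout = layout)
}

#' Species to suitable land-cover class associations
#'
#' @slot table named list: species name -> integer vector of suitable
#'   land-cover class codes.
#' @export
setClass("HabitatTable", representation(table = "list"),
  validity = function(object) {
    if (is.null(names(object@table)) || any(!nzchar(names(object@table))))
      return("every entry must be named by species")
    TRUE
  })

#' @param table named list of integer class-code vectors.
#' @param legend optional land-cover legend; if given, every referenced code
#'   must exist in it.
#' @rdname HabitatTable-class
#' @export
HabitatTable <- function(table, legend = NULL) {
  table <- lapply(table, function(x) as.integer(x))
  if (!is.null(legend)) {
    bad <- setdiff(as.character(unlist(table)), names(legend))
    if (length(bad))
      stop("habitat table references unknown land-cover codes: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  new("HabitatTable", table = table)
}

#' Virtual species with a planted Gaussian niche
#'
#' Truth object for synthetic experiments. Suitability on valid cells is
#' \eqn{\exp(-\frac12 \sum_i ((z_i - c_i)/w_i)^2)} in standardized
#' environmental space, so the planted centre offset and widths give known
#' marginality and tolerance for recovery tests.
#'
#' @slot species character.
#' @slot nicheCenter,nicheWidth numeric, one entry per environmental layer.
#' @slot truth suitability matrix in \[0, 1\].
#' @slot suitableClasses integer land-cover codes the species occupies.
#' @slot layout a [RasterLayout].
#' @export
setClass("VirtualSpecies",
  representation(species = "character", nicheCenter = "numeric",
                 nicheWidth = "numeric", truth = "matrix",
                 suitableClasses = "integer", layout = "RasterLayout"),
  validity = function(object) {
    if (length(object@nicheCenter) != length(object@nicheWidth))
      return("nicheCenter and nicheWidth lengths differ")
    if (any(object@nicheWidth <= 0)) return("niche widths must be positive")
    v <- object@truth[!is.na(object@truth)]
    if (!length(v) || max(v) <= 0) return("truth suitability must be positive somewhere")
    if (any(v < 0) || any(v > 1)) return("truth suitability must lie in [0, 1]")
    TRUE
  })

#' Fitted Ecological Niche Factor Analysis model
#'
#' @slot layerNames environmental layer names.
#' @slot marginalityVector per-layer mean of the standardized presence sample.
#' @slot globalMarginality \eqn{M = \lVert m \rVert / 1.96}.
#' @slot factors orthonormal axes as columns; column 1 is the marginality axis,
#'   remaining columns are specialization axes ordered by decreasing eigenvalue.
#' @slot eigenvalues global/presence variance ratio per factor.
#' @slot globalTolerance \eqn{T = 1/\sqrt{\sum_k \lambda_k / V}}.
#' @slot retained indices of the retained factors (always includes 1).
#' @slot presenceScores presence-cell scores on all factors (rows = cells).
#' @slot factorMedians per-factor median of the presence scores.
#' @slot globalMean,globalSd per-layer standardization used at fit time.
#' @slot nPresence number of distinct presence cells.
#' @export
setClass("EnfaModel",
  representation(layerNames = "character", marginalityVector = "numeric",
                 globalMarginality = "numeric", factors = "matrix",
                 eigenvalues = "numeric", globalTolerance = "numeric",
                 retained = "integer", presenceScores = "matrix",
                 factorMedians = "numeric", globalMean = "numeric",
                 globalSd = "numeric", nPresence = "integer"),
  validity = function(object) {
    V <- length(object@layerNames)
    if (!identical(dim(object@factors), c(V, V))) return("factors must be V x V")
    if (length(object@eigenvalues) != V) return("one eigenvalue per factor required")
    if (object@globalMarginality < 0) return("M must be >= 0")
    if (object@globalTolerance <= 0) return("T must be > 0")
    G <- crossprod(object@factors)
    if (max(abs(G - diag(V))) > 1e-6) return("factor axes must be orthonormal")
    ls <- object@eigenvalues[-1]
    if (length(ls) > 1 && any(diff(ls) > 1e-8))
      return("specialization eigenvalues must be non-increasing")
    TRUE
  })

#' Confusion matrix for binary prediction against test points
#'
#' Integer TP/FP/FN/TN counts. Derived statistics (sensitivity, specificity,
#' omission and commission error, overall accuracy, Cohen's kappa) are
#' available through accessor functions.
#'
#' @slot TP,FP,FN,TN non-negative integer counts.
#' @export
setClass("ConfusionMatrix",
  representation(TP = "integer", FP = "integer", FN = "integer", TN = "integer"),
  validity = function(object) {
    n <- object@TP + object@FP + object@FN + object@TN
    if (any(c(object@TP, object@FP, object@FN, object@TN) < 0))
      return("counts must be non-negative")
    if (n <= 0) return("at least one observation required")
    TRUE
  })

#' @param TP,FP,FN,TN counts.
#' @rdname ConfusionMatrix-class
#' @export
ConfusionMatrix <- function(TP, FP, FN, TN) {
  new("ConfusionMatrix", TP = as.integer(TP), FP = as.integer(FP),
      FN = as.integer(FN), TN = as.integer(TN))
}

#' Threshold sweep report for one species x engine
#'
#' Per-candidate-threshold confusion-matrix metrics, the two selected
#' thresholds (maximum-kappa and ROC closest-to-(0,1)) and the trapezoid AUC
#' over the swept ROC points plus the degenerate endpoints (0,0) and (1,1).
#'
#' @slot species,engine character.
#' @slot curve data.frame with one row per candidate threshold
#'   (columns threshold, TP, FP, FN, TN, kappa, sensitivity, specificity).
#' @slot kappaThreshold,rocThreshold selected thresholds (NA when degenerate).
#' @slot auc area under the ROC curve in \[0, 1\].
#' @export
setClass("ThresholdReport",
  representation(species = "character", engine = "character",
                 curve = "data.frame", kappaThreshold = "numeric",
                 rocThreshold = "numeric", auc = "numeric"),
  validity = function(object) {
    if (!nrow(object@curve)) return("empty threshold curve")
    if (is.na(object@auc) || object@auc < -1e-12 || object@auc > 1 + 1e-12)
      return("auc must lie in [0, 1]")
    for (s in c("kappaThreshold", "rocThreshold")) {
      v <- slot(object, s)
      if (!is.na(v) && !v %in% object@curve$threshold)
        return(sprintf("%s must be a member of the candidate set", s))
    }
    TRUE
  })

#' Stacked species-richness raster
#'
#' Cellwise sum of binary ADM presence indicators, with ordered richness
#' class intervals partitioning \[1, nSpecies\].
#'
#' @slot grid non-negative integer richness matrix (\code{NA} invalid).
#' @slot nSpecies number of stacked models.
#' @slot classBreaks list of \code{c(lo, hi)} integer intervals.
#' @slot layout a [RasterLayout].
#' @export
setClass("RichnessModel",
  representation(grid = "matrix", nSpecies = "integer",
                 classBreaks = "list", layout = "RasterLayout"),
  validity = function(object) {
    v <- object@grid[!is.na(object@grid)]
    if (any(v < 0) || any(v > object@nSpecies))
      return("richness must lie in [0, nSpecies]")
    b <- do.call(rbind, object@classBreaks)
    if (b[1, 1] != 1L || b[nrow(b), 2] != object@nSpecies ||
        (nrow(b) > 1 && any(b[-1, 1] != b[-nrow(b), 2] + 1L)))
      return("classBreaks must partition [1, nSpecies]")
    TRUE
  })

#' Per-species field-validation report
#'
#' One row per species with the site-based (distinct 1-cell field presences)
#' and buffer-based (cells within a radius of any field point) validation
#' counts and success percentages, plus a mean / population-sd summary.
#'
#' @slot table data.frame, one row per species.
#' @slot summary list with the mean and population sd of both success columns.
#' @export
setClass("ValidationReport",
  representation(table = "data.frame", summary = "list"))
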