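# Auxiliary suitability engines: percentile envelope and Mahalanobis
# distance (deterministic stand-ins for other presence-only algorithms in
# multi-engine workflows), plus an adapter for externally produced rasters.

#' Percentile-envelope suitability
#'
#' For each layer i, \eqn{score_i(x) = 2\min(F_i(x), 1 - F_i(x))} where
#' \eqn{F_i} is the mid-distribution empirical CDF of the presence sample on
#' that layer (\eqn{F(x) = (\#\{p < x\} + \frac12\#\{p = x\})/n}, the
#' percentile convention under which the sample median sits at 0.5); the
#' cell score is \eqn{100 \min_i score_i(x)}. Cells at the presence median
#' of every layer score 100; cells outside the presence range on any layer
#' score 0.
#'
#' @param stack an [EnvStack].
#' @param occ presence [OccurrenceSet] (>= 5 distinct presence cells).
#' @param species species tag for the output.
#' @return a continuous 0--100 [SuitabilityModel] with engine \code{"envelope"}.
#' @export
envelopePredict <- function(stack, occ, species = occ@species) {
  cells <- presenceCellIndex(stack, occ, minCells = 5L)
  V <- length(stack@layerNames)
  grid <- matrix(NA_real_, stack@layout@nRows, stack@layout@nCols)
  sc <- rep(1, sum(stack@validMask))
  for (k in seq_len(V)) {
    lay <- envLayer(stack, k)
    pv <- sort(lay[cells])
    x <- lay[stack@validMask]
    midF <- (findInterval(x, pv, left.open = TRUE) + findInterval(x, pv)) /
      (2 * length(pv))
    sc <- pmin(sc, 2 * pmin(midF, 1 - midF))
  }
  grid[stack@validMask] <- 100 * pmax(sc, 0)
  SuitabilityModel(species, "envelope", grid, "continuous_0_100",
                   stack@validMask, stack@layout)
}

#' Mahalanobis-distance suitability
#'
#' Squared Mahalanobis distance of each valid cell to the presence centroid
#' under the (ridge-regularized when near singular) presence covariance,
#' rank-normalized over valid cells:
#' \eqn{score = 100 (1 - rank(d^2)/n_{cells})} with ties sharing the lowest
#' rank. Rank normalization is used instead of a chi-square transform to
#' avoid distributional assumptions.
#'
#' @param stack an [EnvStack].
#' @param occ presence [OccurrenceSet] (>= V + 2 distinct presence cells).
#' @param species species tag for the output.
#' @param ridge diagonal ridge used when the presence covariance is singular.
#' @return a continuous 0--100 [SuitabilityModel], engine \code{"mahalanobis"}.
#' @export
mahalanobisPredict <- function(stack, occ, species = occ@species, ridge = 1e-6) {
  V <- length(stack@layerNames)
  cells <- presenceCellIndex(stack, occ, minCells = V + 2L)
  Z <- sapply(seq_len(V), function(k) stack@values[, , k][stack@validMask])
  Zp <- sapply(seq_len(V), function(k) envLayer(stack, k)[cells])
  S <- regularizeCov(stats::cov(Zp), ridge)
  d2 <- stats::mahalanobis(Z, colMeans(Zp), S)
  n <- nrow(Z)
  score <- 100 * (1 - rank(d2, ties.method = "min") / n)
  grid <- matrix(NA_real_, stack@layout@nRows, stack@layout@nCols)
  grid[stack@validMask] <- score
  SuitabilityModel(species, "mahalanobis", grid, "continuous_0_100",
                   stack@validMask, stack@layout)
}

# Matrix index (row, col pairs) of distinct valid presence cells; errors
# below `minCells`.
presenceCellIndex <- function(stack, occ, minCells) {
  cells <- distinctCells(stack@layout, occ)
  cells <- cells[stack@validMask[cells], , drop = FALSE]
  if (nrow(cells) < minCells)
    stop("engine requires at least ", minCells,
         " distinct presence cells on valid ground; got ", nrow(cells),
         call. = FALSE)
  cells
}

#' Ingest an externally produced suitability raster
#'
#' Adapter for suitability surfaces computed outside the package (e.g.
#' rule-based or maximum-entropy engines). The raster must be aligned to the
#' environmental grid; continuous rasters are clipped to \[0, 100\], ordinal
#' rasters must hold integers 1--10.
#'
#' @param path ASCII-grid path.
#' @param stack the [EnvStack] defining the target grid.
#' @param scale \code{"continuous_0_100"} or \code{"ordinal_1_10"}.
#' @param species species tag.
#' @return a [SuitabilityModel] with engine \code{"external"}.
#' @export
ingestExternal <- function(path, stack, scale = "continuous_0_100",
                           species = "species") {
  g <- readAsciiGrid(path)
  if (!sameLayout(g$layout, stack@layout))
    stop("external raster ", path, " is not aligned with the environmental grid",
         call. = FALSE)
  vals <- g$values
  mask <- stack@validMask & !is.na(vals)
  if (scale == "continuous_0_100") {
    vals <- pmin(pmax(vals, 0), 100)
  } else if (scale == "ordinal_1_10") {
    v <- vals[mask]
    if (any(v != round(v)) || any(v < 1) || any(v > 10))
      stop("ordinal raster must hold integers in [1, 10]", call. = FALSE)
  } else stop("unknown scale tag: ", scale, call. = FALSE)
  SuitabilityModel(species, "external", vals, scale, mask, stack@layout)
}
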