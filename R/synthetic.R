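# Synthetic-landscape generators. Every stochastic generator takes an
# explicit seed and restores the caller's RNG state, so runs are reproducible
# and independent of ambient RNG usage.

#' Generate a spatially autocorrelated, collinear environmental stack
#'
#' Each layer is a seeded random mixture of a few latent smoothed noise
#' fields plus independent smoothed noise, then standardized to global mean
#' 0 and sd 1 over valid cells. Smoothing is an isotropic Gaussian kernel of
#' sd `autocorrRange` cells (0 = white noise). The shared latent fields make
#' the layers strongly pairwise correlated, mimicking the few underlying
#' climate gradients behind collinear bioclimatic variables.
#'
#' @param seed integer RNG seed.
#' @param nLayers number of layers (>= 2).
#' @param nRows,nCols grid dimensions.
#' @param autocorrRange Gaussian smoothing sd in cells (>= 0; 0 = white noise).
#' @param cellSize,originX,originY georeferencing of the output grid.
#' @param nLatent number of shared latent fields (default 3).
#' @param noiseSd sd of the layer-specific noise relative to the unit-scale
#'   latent mixture (default 0.3; larger = less collinear layers).
#' @param layerNames optional layer names (default \code{env01, env02, ...}).
#' @return an [EnvStack].
#' @export
genEnvStack <- function(seed, nLayers = 6, nRows = 100, nCols = 100,
                        autocorrRange = 6, cellSize = 1, originX = 0,
                        originY = nRows * cellSize, nLatent = 3,
                        noiseSd = 0.3, layerNames = NULL) {
  nLayers <- assertCount(nLayers, "nLayers", min = 2L)
  nRows <- assertCount(nRows, "nRows"); nCols <- assertCount(nCols, "nCols")
  nLatent <- assertCount(nLatent, "nLatent")
  assertNumber(autocorrRange, "autocorrRange", min = 0)
  if (is.null(layerNames)) layerNames <- sprintf("env%02d", seq_len(nLayers))
  withSeed(seed, {
    field <- function()
      as.vector(smoothField(matrix(stats::rnorm(nRows * nCols), nRows, nCols),
                            autocorrRange))
    latent <- sapply(seq_len(nLatent), function(i) field())
    loadings <- matrix(stats::rnorm(nLatent * nLayers), nLatent, nLayers)
    mixed <- latent %*% loadings +
      noiseSd * sapply(seq_len(nLayers), function(i) field())
    vals <- array(0, dim = c(nRows, nCols, nLayers))
    for (k in seq_len(nLayers)) {
      v <- mixed[, k]
      vals[, , k] <- matrix((v - mean(v)) / popSd(v), nRows, nCols)
    }
    EnvStack(vals, layerNames,
             RasterLayout(nRows, nCols, originX, originY, cellSize))
  })
}

#' Plant a virtual species with a Gaussian niche
#'
#' The niche centre has Euclidean norm `1.96 * marginalityTarget` in
#' standardized environmental space, so the ENFA global-marginality
#' estimator targets `marginalityTarget`. Its direction is drawn toward the
#' environment of a seeded random landscape cell (screening a handful of
#' candidate cells for niche support), so the planted optimum lies on the
#' environmentally realised manifold rather than in empty multivariate
#' space — as a real species' optimum does. Niche widths are solved per
#' layer (by root finding on the landscape's value distribution) so that the
#' suitability-weighted sd of each layer is approximately `toleranceTarget`.
#' Truth suitability on valid cells is
#' \eqn{\exp(-\frac12\sum_i ((z_i - c_i)/w_i)^2)}.
#'
#' @param stack an [EnvStack] (standardized layers).
#' @param seed integer RNG seed.
#' @param marginalityTarget planted global marginality (>= 0).
#' @param toleranceTarget planted niche width (> 0) on the standardized scale.
#' @param species species name.
#' @param suitableClasses land-cover class codes the species occupies.
#' @param nCandidates candidate cells screened for the niche direction.
#' @return a [VirtualSpecies]; errors if the niche is degenerate
#'   (fewer than 50 cells with suitability above 0.5).
#' @export
genVirtualSpecies <- function(stack, seed, marginalityTarget = 1,
                              toleranceTarget = 0.5, species = "virtual_sp",
                              suitableClasses = 1L, nCandidates = 50L) {
  assertNumber(marginalityTarget, "marginalityTarget", min = 0)
  assertNumber(toleranceTarget, "toleranceTarget", min = 0, strictMin = TRUE)
  V <- length(stack@layerNames)
  Z <- sapply(seq_len(V), function(k) stack@values[, , k][stack@validMask])
  center <- withSeed(seed, {
    if (marginalityTarget == 0) rep(0, V) else {
      tgt <- 1.96 * marginalityTarget
      nrm <- sqrt(rowSums(Z^2))
      cand <- which(nrm >= tgt)
      if (!length(cand))
        cand <- order(nrm, decreasing = TRUE)[seq_len(min(10L, nrow(Z)))]
      cand <- cand[sample.int(length(cand), min(nCandidates, length(cand)))]
      # crude support screen at fixed width before the per-layer width solve
      w0sq <- toleranceTarget^2 / max(1 - toleranceTarget^2, 0.25)
      best <- NULL; bestCount <- -1L
      for (ci in cand) {
        ctr <- tgt * Z[ci, ] / nrm[ci]
        cnt <- sum(rowSums(sweep(Z, 2, ctr)^2) < 2 * log(2) * w0sq)
        if (cnt > bestCount) { bestCount <- cnt; best <- ctr }
        if (cnt >= 100L) break
      }
      best
    }
  })
  widths <- vapply(seq_len(V), function(i)
    solveNicheWidth(Z[, i], center[i], toleranceTarget), numeric(1))
  d2 <- rowSums(sweep(sweep(Z, 2, center), 2, widths, "/")^2)
  suit <- exp(-0.5 * d2)
  truth <- matrix(NA_real_, stack@layout@nRows, stack@layout@nCols)
  truth[stack@validMask] <- suit
  if (sum(suit > 0.5) < 50L)
    stop("degenerate niche: fewer than 50 cells with suitability > 0.5",
         call. = FALSE)
  new("VirtualSpecies", species = species, nicheCenter = center,
      nicheWidth = widths, truth = truth,
      suitableClasses = as.integer(suitableClasses), layout = stack@layout)
}

# Width w such that the 1-d suitability-weighted sd of layer values z around
# centre ci is `target`; the weighted sd is monotone increasing in w and
# bounded by the layer's global sd, so unattainable targets clamp to the
# bracket ends.
solveNicheWidth <- function(z, ci, target) {
  f <- function(w) {
    wts <- exp(-0.5 * ((z - ci) / w)^2)
    s <- sum(wts)
    if (s < 1e-12) return(-target)  # no support: treat weighted sd as 0
    mu <- sum(wts * z) / s
    sqrt(sum(wts * (z - mu)^2) / s) - target
  }
  lo <- 1e-3; hi <- 200
  if (f(hi) < 0) return(hi)
  if (f(lo) >= 0) return(lo)
  stats::uniroot(f, c(lo, hi), tol = 1e-5)$root
}

#' Sample museum-style occurrence records from a virtual species
#'
#' Cells are drawn with probability proportional to
#' \code{truth^gamma} (`gamma >= 1` concentrates sampling in good habitat,
#' mimicking detection concentrated where the species is common), optionally
#' biased toward seeded hotspot clusters to mimic uneven museum collecting
#' effort. The point is placed uniformly within the drawn cell.
#'
#' @param vs a [VirtualSpecies].
#' @param n number of records (>= 1).
#' @param seed integer RNG seed.
#' @param clustering hotspot bias strength (0 = unbiased).
#' @param gamma sampling sharpness exponent (default 2).
#' @param replace sample cells with replacement (duplicate records allowed,
#'   as in museum data). With \code{replace = FALSE}, `n` may not exceed the
#'   number of cells with nonzero suitability.
#' @param nHotspots number of hotspot centres used when \code{clustering > 0}.
#' @param source source tag for the output set.
#' @return an [OccurrenceSet].
#' @export
sampleOccurrences <- function(vs, n, seed, clustering = 0, gamma = 2,
                              replace = TRUE, nHotspots = 5,
                              source = "museum") {
  n <- assertCount(n, "n")
  assertNumber(clustering, "clustering", min = 0)
  ok <- which(!is.na(vs@truth) & vs@truth > 0)
  p <- vs@truth[ok]^gamma
  if (!replace && n > length(ok))
    stop("cannot draw ", n, " distinct cells: only ", length(ok),
         " cells have nonzero suitability", call. = FALSE)
  withSeed(seed, {
    if (clustering > 0) {
      hot <- sample(seq_along(ok), min(nHotspots, length(ok)), prob = p)
      hr <- (ok[hot] - 1) %% nrow(vs@truth) + 1
      hc <- (ok[hot] - 1) %/% nrow(vs@truth) + 1
      r <- (ok - 1) %% nrow(vs@truth) + 1
      cc <- (ok - 1) %/% nrow(vs@truth) + 1
      sdc <- max(dim(vs@truth)) / 10
      bias <- rowSums(sapply(seq_along(hot), function(j)
        exp(-((r - hr[j])^2 + (cc - hc[j])^2) / (2 * sdc^2))))
      p <- p * (1 + clustering * bias)
    }
    drawn <- ok[sample.int(length(ok), n, replace = replace, prob = p)]
    rows <- (drawn - 1) %% nrow(vs@truth) + 1
    cols <- (drawn - 1) %/% nrow(vs@truth) + 1
    s <- vs@layout@cellSize
    x <- vs@layout@originX + (cols - 1 + stats::runif(n)) * s
    y <- vs@layout@originY - (rows - 1 + stats::runif(n)) * s
    OccurrenceSet(vs@species, cbind(x, y), source)
  })
}

#' Generate a patchy categorical land-cover raster
#'
#' A seeded smooth random field at `subcellRatio` times finer resolution
#' than the model grid, cut at equal-area quantiles into `nClasses`
#' contiguous-patch classes.
#'
#' @param stack the model-resolution [EnvStack] the land cover nests under.
#' @param seed integer RNG seed.
#' @param nClasses number of classes (>= 2).
#' @param patchScale patch size scale in model cells.
#' @param subcellRatio integer subcell ratio (fine cells per model cell side).
#' @return a [LandCover] at the fine resolution.
#' @export
genLandCover <- function(stack, seed, nClasses = 4, patchScale = 8,
                         subcellRatio = 4) {
  nClasses <- assertCount(nClasses, "nClasses", min = 2L)
  subcellRatio <- assertCount(subcellRatio, "subcellRatio", min = 1L)
  assertNumber(patchScale, "patchScale", min = 0)
  nr <- stack@layout@nRows * subcellRatio
  nc <- stack@layout@nCols * subcellRatio
  field <- withSeed(seed,
    smoothField(matrix(stats::rnorm(nr * nc), nr, nc),
                patchScale * subcellRatio))
  fineValid <- stack@validMask[rep(seq_len(stack@layout@nRows), each = subcellRatio),
                               rep(seq_len(stack@layout@nCols), each = subcellRatio)]
  qs <- stats::quantile(field[fineValid], probs = seq(0, 1, length.out = nClasses + 1))
  qs[1] <- -Inf; qs[nClasses + 1] <- Inf
  classes <- matrix(findInterval(field, qs, rightmost.closed = TRUE), nr, nc)
  classes[!fineValid] <- NA_integer_
  baseNames <- c("tropical_dry_forest", "temperate_forest", "agriculture",
                 "secondary_scrub", "urban", "water")
  nm <- if (nClasses <= length(baseNames)) baseNames[seq_len(nClasses)]
        else sprintf("class%02d", seq_len(nClasses))
  LandCover(classes, stats::setNames(nm, as.character(seq_len(nClasses))),
            RasterLayout(nr, nc, stack@layout@originX, stack@layout@originY,
                         stack@layout@cellSize / subcellRatio))
}

#' Dominant land-cover class of each model cell
#'
#' The modal class among the subcells of each model-resolution cell, ties
#' broken by the lowest class code; \code{NA} where every subcell is invalid.
#'
#' @param lc a [LandCover]; @param layout the model-resolution [RasterLayout].
#' @return integer matrix at model resolution.
#' @export
dominantLandCover <- function(lc, layout) {
  k <- subcellRatioOf(lc, layout)
  codes <- sort(as.integer(names(lc@legend)))
  nCell <- layout@nRows * layout@nCols
  cg <- lc@classGrid
  crow <- (row(cg) - 1L) %/% k + 1L
  ccol <- (col(cg) - 1L) %/% k + 1L
  cid <- (ccol - 1L) * layout@nRows + crow
  cls <- match(cg, codes)
  okf <- !is.na(cls)
  counts <- matrix(tabulate(cid[okf] + (cls[okf] - 1L) * nCell,
                            nbins = nCell * length(codes)), nrow = nCell)
  out <- codes[max.col(counts, ties.method = "first")]
  out[rowSums(counts) == 0L] <- NA_integer_
  matrix(out, layout@nRows, layout@nCols)
}

# Integer subcell ratio of a land cover under a model layout; errors when the
# grids are misaligned or the ratio is not an exact integer.
subcellRatioOf <- function(lc, layout) {
  k <- layout@cellSize / lc@layout@cellSize
  if (abs(k - round(k)) > 1e-9 || round(k) < 1)
    stop("land-cover cell size must divide the model cell size exactly",
         call. = FALSE)
  k <- as.integer(round(k))
  if (lc@layout@nRows != layout@nRows * k || lc@layout@nCols != layout@nCols * k ||
      abs(lc@layout@originX - layout@originX) > 1e-9 ||
      abs(lc@layout@originY - layout@originY) > 1e-9)
    stop("land cover is not aligned with the model grid", call. = FALSE)
  k
}

#' Simulate a stratified point-count field survey
#'
#' Sites are placed by stratified random sampling only in model cells whose
#' dominant land-cover class is among the species' suitable classes (the
#' survey is restricted to the species' habitat, as in point-count surveys
#' confined to one vegetation formation). Each site holds up to
#' `pointsPerSite` count points at least `minPointSpacing` apart inside a
#' square site extent; a species detection at a point is a Bernoulli draw
#' with probability `detectionProb` times the truth suitability of the
#' point's cell, and a point contributes at most one occurrence (presence,
#' not abundance).
#'
#' @param vs a [VirtualSpecies].
#' @param lc a [LandCover] nested under the species' grid.
#' @param nSites number of survey sites (>= 1).
#' @param pointsPerSite maximum count points per site (default 30).
#' @param minPointSpacing minimum distance between points in map units
#'   (default 0.2 map units, the 200 m analog under 1-km cells).
#' @param detectionProb per-point detection probability scaling (in (0, 1]).
#' @param seed integer RNG seed.
#' @param siteExtent side length of the square site extent (default twice the
#'   cell size).
#' @return an [OccurrenceSet] with \code{source = "field"} and per-point site ids.
#' @export
simulateFieldSurvey <- function(vs, lc, nSites = 46, pointsPerSite = 30,
                                minPointSpacing = 0.2, detectionProb = 0.8,
                                seed = 1,
                                siteExtent = 2 * vs@layout@cellSize) {
  nSites <- assertCount(nSites, "nSites")
  pointsPerSite <- assertCount(pointsPerSite, "pointsPerSite")
  assertNumber(detectionProb, "detectionProb", min = 0, max = 1, strictMin = TRUE)
  dom <- dominantLandCover(lc, vs@layout)
  eligible <- which(!is.na(dom) & matrix(dom %in% vs@suitableClasses, nrow(dom)) &
                    !is.na(vs@truth))
  if (length(eligible) < nSites)
    stop("stratification error: only ", length(eligible),
         " cells have suitable dominant land cover for ", nSites, " sites",
         call. = FALSE)
  lay <- vs@layout
  xmin <- lay@originX; xmax <- lay@originX + lay@nCols * lay@cellSize
  ymin <- lay@originY - lay@nRows * lay@cellSize; ymax <- lay@originY
  withSeed(seed, {
    sites <- sample(eligible, nSites)
    pts <- NULL; ids <- character()
    for (si in seq_len(nSites)) {
      r <- (sites[si] - 1) %% lay@nRows + 1
      cc <- (sites[si] - 1) %/% lay@nRows + 1
      ctr <- cellCenters(lay, cbind(r, cc))
      lox <- max(xmin, ctr[1] - siteExtent / 2)
      hix <- min(xmax, ctr[1] + siteExtent / 2)
      loy <- max(ymin, ctr[2] - siteExtent / 2)
      hiy <- min(ymax, ctr[2] + siteExtent / 2)
      acc <- matrix(numeric(0), ncol = 2)
      attempts <- 0L
      while (nrow(acc) < pointsPerSite && attempts < 200L * pointsPerSite) {
        cand <- c(stats::runif(1, lox, hix), stats::runif(1, loy, hiy))
        if (!nrow(acc) ||
            min((acc[, 1] - cand[1])^2 + (acc[, 2] - cand[2])^2) >=
              minPointSpacing^2)
          acc <- rbind(acc, cand)
        attempts <- attempts + 1L
      }
      if (nrow(acc)) {
        cells <- pointsToCells(lay, acc)
        suit <- vs@truth[cbind(cells[, 1], cells[, 2])]
        suit[is.na(suit)] <- 0
        det <- stats::runif(nrow(acc)) < detectionProb * suit
        if (any(det)) {
          pts <- rbind(pts, acc[det, , drop = FALSE])
          ids <- c(ids, rep(sprintf("site_%03d", si), sum(det)))
        }
      }
    }
    if (is.null(pts)) pts <- matrix(numeric(0), ncol = 2)
    OccurrenceSet(vs@species, pts, "field", siteId = ids)
  })
}

#' Rectangular synthetic ecoregions covering a grid
#'
#' Quadrant rectangles (for \code{nRegions = 4}) or equal-width vertical
#' strips otherwise; a deterministic stand-in for ecoregion polygons.
#'
#' @param layout a [RasterLayout]; @param nRegions number of regions.
#' @return region list in the [readEcoregions()] format.
#' @export
genEcoregions <- function(layout, nRegions = 4) {
  xmin <- layout@originX; xmax <- layout@originX + layout@nCols * layout@cellSize
  ymin <- layout@originY - layout@nRows * layout@cellSize; ymax <- layout@originY
  rect <- function(x0, x1, y0, y1)
    matrix(c(x0, y0, x1, y0, x1, y1, x0, y1, x0, y0), ncol = 2, byrow = TRUE)
  if (nRegions == 4L) {
    xm <- (xmin + xmax) / 2; ym <- (ymin + ymax) / 2
    boxes <- list(rect(xmin, xm, ym, ymax), rect(xm, xmax, ym, ymax),
                  rect(xmin, xm, ymin, ym), rect(xm, xmax, ymin, ym))
  } else {
    xs <- seq(xmin, xmax, length.out = nRegions + 1)
    boxes <- lapply(seq_len(nRegions), function(i)
      rect(xs[i], xs[i + 1], ymin, ymax))
  }
  lapply(seq_along(boxes), function(i)
    list(name = sprintf("ecoregion_%d", i), rings = list(boxes[[i]])))
}
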