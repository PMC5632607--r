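# Stacked-ADM species richness and ecoregion cross-tabulation.

defaultRichnessBreaks <- function(n) {
  if (n >= 9L) list(c(1L, 4L), c(5L, 8L), c(9L, n))
  else if (n >= 5L) list(c(1L, 4L), c(5L, n))
  else list(c(1L, n))
}

#' Stack binary models into a species-richness raster
#'
#' Cellwise sum of presence indicators over the supplied ADMs (the order of
#' the list is immaterial). All models must share one grid; a cell is valid
#' when it is valid in every model.
#'
#' @param adms list of [BinaryModel]s on a common grid.
#' @param classBreaks list of \code{c(lo, hi)} intervals partitioning
#'   \[1, nSpecies\]; default \{1-4, 5-8, 9-n\} (truncated for small stacks).
#' @return a [RichnessModel].
#' @export
stackRichness <- function(adms, classBreaks = NULL) {
  if (!length(adms)) stop("no models supplied", call. = FALSE)
  lay <- adms[[1]]@layout
  for (m in adms)
    if (!sameLayout(lay, m@layout))
      stop("model for '", m@species, "' is not aligned with the stack grid",
           call. = FALSE)
  n <- length(adms)
  rich <- matrix(0L, lay@nRows, lay@nCols)
  valid <- matrix(TRUE, lay@nRows, lay@nCols)
  for (m in adms) {
    valid <- valid & !is.na(m@grid)
    g <- m@grid; g[is.na(g)] <- 0L
    rich <- rich + g
  }
  rich[!valid] <- NA_integer_
  if (is.null(classBreaks)) classBreaks <- defaultRichnessBreaks(n)
  new("RichnessModel", grid = rich, nSpecies = as.integer(n),
      classBreaks = lapply(classBreaks, as.integer), layout = lay)
}

# Even-odd point-in-region test: a point is inside when it falls in an odd
# number of the region's rings (outer rings and holes alternate).
pointsInRegion <- function(region, pts) {
  inside <- rep(FALSE, nrow(pts))
  for (ring in region$rings)
    inside <- xor(inside, mgcv::in.out(ring, pts))
  inside
}

#' Cross-tabulate richness classes with ecoregion polygons
#'
#' For every richness class, the percentage of its cells whose centres fall
#' in each region (cells on a boundary go to the first containing region in
#' file order) plus an "outside" remainder; percentages sum to 100 per
#' class. Classes with no cells are reported as all-zero rows and flagged.
#'
#' @param rm a [RichnessModel].
#' @param regions region list as returned by [readEcoregions()].
#' @return data.frame with columns \code{class}, \code{cells}, one
#'   percentage column per region, and \code{outside}; the
#'   \code{"emptyClasses"} attribute lists classes with zero cells.
#' @export
richnessByRegion <- function(rm, regions) {
  regionNames <- vapply(regions, function(r) r$name, "")
  cells <- which(!is.na(rm@grid) & rm@grid >= 1L)
  rows <- (cells - 1L) %% nrow(rm@grid) + 1L
  cols <- (cells - 1L) %/% nrow(rm@grid) + 1L
  ctr <- cellCenters(rm@layout, cbind(rows, cols))
  regIdx <- rep(NA_integer_, length(cells))
  for (i in seq_along(regions)) {
    ok <- tryCatch(pointsInRegion(regions[[i]], ctr),
                   error = function(e) NULL)
    if (is.null(ok)) { warning("degenerate polygon '", regionNames[i], "' skipped")
                       next }
    regIdx[is.na(regIdx) & ok] <- i
  }
  rich <- rm@grid[cells]
  lab <- vapply(rm@classBreaks, function(b)
    if (b[1] == b[2]) as.character(b[1]) else paste0(b[1], "-", b[2]), "")
  out <- data.frame(class = lab,
                    cells = 0L,
                    matrix(0, length(lab), length(regionNames),
                           dimnames = list(NULL, make.names(regionNames))),
                    outside = 0, check.names = FALSE)
  empty <- character()
  for (ci in seq_along(rm@classBreaks)) {
    b <- rm@classBreaks[[ci]]
    sel <- rich >= b[1] & rich <= b[2]
    nsel <- sum(sel)
    out$cells[ci] <- nsel
    if (!nsel) { empty <- c(empty, lab[ci]); next }
    counts <- tabulate(regIdx[sel], nbins = length(regionNames))
    out[ci, 2 + seq_along(regionNames)] <- 100 * counts / nsel
    out$outside[ci] <- 100 * sum(is.na(regIdx[sel])) / nsel
  }
  attr(out, "emptyClasses") <- empty
  out
}

#' Write a richness raster and its region cross-tab
#' @param rm a [RichnessModel]; @param regions region list;
#' @param rasterPath,csvPath output paths.
#' @export
writeRichness <- function(rm, regions, rasterPath, csvPath) {
  writeAsciiGrid(rm@grid, rm@layout, rasterPath)
  utils::write.csv(richnessByRegion(rm, regions), csvPath, row.names = FALSE)
  invisible(rasterPath)
}
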