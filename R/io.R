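# File I/O. Rasters travel as ESRI ASCII grids (.asc): a plain-text header
# (ncols, nrows, xllcorner, yllcorner, cellsize, NODATA_value) followed by
# rows of values, top row first. Values are written with 17 significant
# digits so a write -> read round trip is bit-identical.

#' Read / write a single raster layer (ESRI ASCII grid)
#'
#' @param path file path.
#' @return for the reader, a list with \code{values} (numeric matrix, top row
#'   first, \code{NA} at nodata cells) and \code{layout} (a [RasterLayout]).
#' @export
readAsciiGrid <- function(path) {
  if (!file.exists(path)) stop("cannot read raster: ", path, call. = FALSE)
  con <- file(path, "r"); on.exit(close(con))
  hdr <- character(); val <- list()
  for (i in 1:6) {
    ln <- strsplit(trimws(readLines(con, 1L)), "[[:space:]]+")[[1]]
    hdr[tolower(ln[1])] <- ln[2]
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  if (!all(need %in% names(hdr)))
    stop("malformed ASCII grid header in ", path, call. = FALSE)
  nc <- as.integer(hdr["ncols"]); nr <- as.integer(hdr["nrows"])
  cs <- as.numeric(hdr["cellsize"]); nodata <- as.numeric(hdr["nodata_value"])
  vals <- scan(con, what = numeric(), n = nr * nc, quiet = TRUE)
  if (length(vals) != nr * nc) stop("truncated raster body in ", path, call. = FALSE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  layout <- RasterLayout(nr, nc, originX = as.numeric(hdr["xllcorner"]),
                         originY = as.numeric(hdr["yllcorner"]) + nr * cs,
                         cellSize = cs)
  list(values = m, layout = layout)
}

#' @param values numeric matrix (top row first); \code{NA} written as nodata.
#' @param layout a [RasterLayout].
#' @param nodata nodata sentinel written to disk.
#' @rdname readAsciiGrid
#' @export
writeAsciiGrid <- function(values, layout, path, nodata = -9999) {
  stopifnot(identical(dim(values), c(layout@nRows, layout@nCols)))
  values[is.na(values)] <- nodata
  hdr <- sprintf("ncols %d\nnrows %d\nxllcorner %.17g\nyllcorner %.17g\ncellsize %.17g\nNODATA_value %.17g",
                 layout@nCols, layout@nRows, layout@originX,
                 layout@originY - layout@nRows * layout@cellSize,
                 layout@cellSize, nodata)
  body <- apply(values, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read aligned raster layers into an environmental stack
#'
#' Layers on mismatched grids are rejected with an error naming the
#' offending layer, never resampled silently. The validity mask is the
#' intersection of per-layer finiteness.
#'
#' @param paths character vector of ASCII-grid paths.
#' @param layerNames optional names (default: file base names).
#' @return an [EnvStack].
#' @export
readEnvStack <- function(paths, layerNames = NULL) {
  if (length(paths) < 1L) stop("at least one layer required", call. = FALSE)
  if (is.null(layerNames))
    layerNames <- sub("\\.[^.]*$", "", basename(paths))
  first <- readAsciiGrid(paths[1])
  layers <- vector("list", length(paths)); layers[[1]] <- first$values
  for (i in seq_along(paths)[-1]) {
    g <- readAsciiGrid(paths[i])
    if (!sameLayout(first$layout, g$layout))
      stop("layer '", layerNames[i], "' (", paths[i],
           ") is not aligned with '", layerNames[1], "'", call. = FALSE)
    layers[[i]] <- g$values
  }
  EnvStack(layers, layerNames, first$layout)
}

#' Write an environmental stack, one ASCII grid per layer
#' @param stack an [EnvStack]; @param dir output directory.
#' @return invisibly, the written paths.
#' @export
writeEnvStack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(stack@layerNames, ".asc"))
  for (k in seq_along(paths))
    writeAsciiGrid(envLayer(stack, k), stack@layout, paths[k])
  invisible(paths)
}

#' Read occurrence points from CSV
#'
#' The CSV must have columns \code{species,x,y,source} (optionally
#' \code{site_id}). Rows are filtered to the requested species and source;
#' an empty result is a warning, not an error.
#'
#' @param path CSV path.
#' @param species species to keep.
#' @param source source tag to keep (\code{"museum"} or \code{"field"}).
#' @return an [OccurrenceSet].
#' @export
readOccurrences <- function(path, species, source = "museum") {
  if (!file.exists(path)) stop("cannot read occurrences: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "x", "y", "source")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("occurrence CSV lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  df <- df[df$species == species & df$source == source, , drop = FALSE]
  message(nrow(df), " ", source, " record(s) read for '", species, "'")
  if (!nrow(df)) warning("no occurrences for '", species, "' (", source, ")",
                         call. = FALSE)
  OccurrenceSet(species, cbind(df$x, df$y), source,
                if ("site_id" %in% names(df)) as.character(df$site_id) else character())
}

#' Write one or more occurrence sets to a CSV
#' @param occs an [OccurrenceSet] or list of them; @param path CSV path.
#' @export
writeOccurrences <- function(occs, path) {
  if (methods::is(occs, "OccurrenceSet")) occs <- list(occs)
  rows <- lapply(occs, function(o)
    data.frame(species = o@species,
               x = o@points[, 1], y = o@points[, 2], source = o@source,
               site_id = if (length(o@siteId)) o@siteId else NA_character_))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read / write a categorical land-cover raster
#'
#' The class raster travels as an integer ASCII grid plus a legend CSV
#' (columns \code{code,name}) next to it.
#'
#' @param path raster path; the legend is read from/written to
#'   \code{<path minus extension>_legend.csv} unless \code{legendPath} is given.
#' @param legendPath optional explicit legend path.
#' @export
readLandCover <- function(path, legendPath = NULL) {
  g <- readAsciiGrid(path)
  if (is.null(legendPath))
    legendPath <- paste0(sub("\\.[^.]*$", "", path), "_legend.csv")
  leg <- utils::read.csv(legendPath, stringsAsFactors = FALSE)
  legend <- stats::setNames(as.character(leg$name), as.character(leg$code))
  LandCover(g$values, legend, g$layout)
}

#' @param lc a [LandCover].
#' @rdname readLandCover
#' @export
writeLandCover <- function(lc, path, legendPath = NULL) {
  writeAsciiGrid(lc@classGrid, lc@layout, path)
  if (is.null(legendPath))
    legendPath <- paste0(sub("\\.[^.]*$", "", path), "_legend.csv")
  utils::write.csv(data.frame(code = names(lc@legend), name = unname(lc@legend)),
                   legendPath, row.names = FALSE)
  invisible(path)
}

#' Read a habitat-association table from CSV
#'
#' CSV columns \code{species,class_code}, one row per association.
#'
#' @param path CSV path.
#' @param legend optional land-cover legend used to validate class codes.
#' @return a [HabitatTable].
#' @export
readHabitatTable <- function(path, legend = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("species", "class_code") %in% names(df)))
    stop("habitat CSV needs columns species, class_code", call. = FALSE)
  HabitatTable(split(as.integer(df$class_code), df$species), legend = legend)
}

#' @param habitat a [HabitatTable].
#' @rdname readHabitatTable
#' @export
writeHabitatTable <- function(habitat, path) {
  df <- do.call(rbind, lapply(names(habitat@table), function(sp)
    data.frame(species = sp, class_code = habitat@table[[sp]])))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read ecoregion polygons from GeoJSON
#'
#' Supports FeatureCollections of Polygon and MultiPolygon geometries. Rings
#' beyond the first in a polygon are holes (even-odd rule at point-in-polygon
#' time). Region names come from a \code{name} property when present.
#'
#' @param path GeoJSON path.
#' @return list of regions, each a list with \code{name} and \code{rings}
#'   (list of two-column coordinate matrices).
#' @export
readEcoregions <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features else list(gj)
  ringMat <- function(r) {
    m <- do.call(rbind, lapply(r, function(p) c(p[[1]], p[[2]])))
    matrix(as.numeric(m), ncol = 2)
  }
  out <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    geom <- f$geometry
    rings <- switch(geom$type,
      Polygon = lapply(geom$coordinates, ringMat),
      MultiPolygon = unlist(lapply(geom$coordinates,
                                   function(poly) lapply(poly, ringMat)),
                            recursive = FALSE),
      stop("unsupported geometry type: ", geom$type, call. = FALSE))
    nm <- f$properties$name
    out[[i]] <- list(name = if (is.null(nm)) paste0("region_", i) else nm,
                     rings = rings)
  }
  out
}

#' Write rectangular ecoregions to GeoJSON
#' @param regions list as returned by [readEcoregions()]; @param path output path.
#' @export
writeEcoregions <- function(regions, path) {
  feats <- lapply(regions, function(r) {
    coords <- lapply(r$rings, function(m)
      lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2])))
    list(type = "Feature", properties = list(name = r$name),
         geometry = list(type = "Polygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read a suitability raster
#'
#' The raster body is an ASCII grid; species, engine and scale tags travel
#' in a JSON sidecar \code{<path>.json}.
#'
#' @param model a [SuitabilityModel]; @param path raster path.
#' @export
writeSuitability <- function(model, path) {
  writeAsciiGrid(model@grid, model@layout, path)
  jsonlite::write_json(list(species = model@species, engine = model@engine,
                            scale = model@scale),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeSuitability
#' @export
readSuitability <- function(path) {
  g <- readAsciiGrid(path)
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  SuitabilityModel(meta$species, meta$engine, g$values, meta$scale,
                   !is.na(g$values), g$layout)
}

#' Write / read a binary PDM or ADM raster
#'
#' Threshold metadata (kind, threshold, rule, extra metadata such as the
#' habitat classes behind an ADM) travels in a JSON sidecar.
#'
#' @param model a [BinaryModel]; @param path raster path.
#' @export
writeBinaryModel <- function(model, path) {
  writeAsciiGrid(model@grid, model@layout, path)
  jsonlite::write_json(list(species = model@species, kind = model@kind,
                            threshold = model@thresholdUsed,
                            rule = model@thresholdRule,
                            metadata = model@metadata),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeBinaryModel
#' @export
readBinaryModel <- function(path) {
  g <- readAsciiGrid(path)
  meta <- jsonlite::fromJSON(paste0(path, ".json"), simplifyVector = TRUE)
  BinaryModel(meta$species, meta$kind, g$values, meta$threshold, meta$rule,
              g$layout, metadata = as.list(meta$metadata))
}

#' Serialize a fitted ENFA model to JSON (and back)
#'
#' Stores vectors, factor axes, eigenvalues, presence medians and the
#' standardization constants needed for reproducible re-scoring.
#'
#' @param model an [EnfaModel]; @param path JSON path.
#' @export
writeEnfaModel <- function(model, path) {
  jsonlite::write_json(
    list(layerNames = model@layerNames,
         marginalityVector = model@marginalityVector,
         globalMarginality = model@globalMarginality,
         factors = model@factors, eigenvalues = model@eigenvalues,
         globalTolerance = model@globalTolerance,
         retained = model@retained,
         presenceScores = model@presenceScores,
         factorMedians = model@factorMedians,
         globalMean = model@globalMean, globalSd = model@globalSd,
         nPresence = model@nPresence),
    path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname writeEnfaModel
#' @export
readEnfaModel <- function(path) {
  j <- jsonlite::fromJSON(path)
  new("EnfaModel", layerNames = j$layerNames,
      marginalityVector = j$marginalityVector,
      globalMarginality = j$globalMarginality,
      factors = matrix(j$factors, ncol = length(j$layerNames)),
      eigenvalues = j$eigenvalues, globalTolerance = j$globalTolerance,
      retained = as.integer(j$retained),
      presenceScores = matrix(j$presenceScores, ncol = length(j$layerNames)),
      factorMedians = j$factorMedians, globalMean = j$globalMean,
      globalSd = j$globalSd, nPresence = as.integer(j$nPresence))
}
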