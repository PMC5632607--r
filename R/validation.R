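# Field validation of ADMs: site-based and buffer-based prediction success,
# and the museum-vs-field proportionality correlation.

#' Site-based prediction success
#'
#' The distinct model cells containing at least one field point form the
#' sampled presence-cell set (duplicate points within one cell collapse,
#' mirroring field counts expressed per 1 x 1 km cell). A cell is a true
#' presence when the ADM predicts presence there; success is
#' \eqn{100 \cdot true / total}.
#'
#' @param adm a [BinaryModel].
#' @param field a field [OccurrenceSet].
#' @return list with \code{species}, \code{totalPresenceCells},
#'   \code{truePresences}, \code{falseAbsences}, \code{successPct}
#'   (NA, flagged \code{empty = TRUE}, when there are no field points).
#' @export
siteSuccess <- function(adm, field) {
  cells <- distinctCells(adm@layout, field)
  total <- nrow(cells)
  if (!total) {
    warning("no field points for '", field@species, "': empty report row")
    return(list(species = field@species, totalPresenceCells = 0L,
                truePresences = 0L, falseAbsences = 0L,
                successPct = NA_real_, empty = TRUE))
  }
  pred <- adm@grid[cells]
  true <- sum(pred == 1L, na.rm = TRUE)
  list(species = field@species, totalPresenceCells = total,
       truePresences = true, falseAbsences = total - true,
       successPct = 100 * true / total, empty = FALSE)
}

#' Buffer-based prediction success
#'
#' Builds the union of disks of the given radius around the field points
#' (overlapping buffers aggregate into single areas); the buffer cell set is
#' the valid cells whose centres lie inside the union, and success is the
#' percentage of those cells where the ADM predicts presence. Membership is
#' by cell-centre inclusion, consistent with pixel-count evaluation.
#'
#' @param adm a [BinaryModel].
#' @param field a field [OccurrenceSet].
#' @param radius buffer radius in map units (> 0; default one cell size,
#'   the 1-km analog).
#' @return list with \code{species}, \code{totalBufferCells},
#'   \code{trueBufferCells}, \code{falseBufferCells}, \code{successPct}.
#' @export
bufferSuccess <- function(adm, field, radius = adm@layout@cellSize) {
  assertNumber(radius, "radius", min = 0, strictMin = TRUE)
  valid <- which(!is.na(adm@grid))
  rows <- (valid - 1L) %% nrow(adm@grid) + 1L
  cols <- (valid - 1L) %/% nrow(adm@grid) + 1L
  ctr <- cellCenters(adm@layout, cbind(rows, cols))
  inBuf <- rep(FALSE, length(valid))
  for (i in seq_len(nrow(field@points))) {
    p <- field@points[i, ]
    inBuf <- inBuf | ((ctr[, 1] - p[1])^2 + (ctr[, 2] - p[2])^2 <= radius^2)
  }
  total <- sum(inBuf)
  if (!total) {
    warning("buffers cover no valid cells for '", field@species,
            "': empty report row")
    return(list(species = field@species, totalBufferCells = 0L,
                trueBufferCells = 0L, falseBufferCells = 0L,
                successPct = NA_real_, empty = TRUE))
  }
  true <- sum(adm@grid[valid[inBuf]] == 1L)
  list(species = field@species, totalBufferCells = total,
       trueBufferCells = true, falseBufferCells = total - true,
       successPct = 100 * true / total, empty = FALSE)
}

#' Museum-vs-field proportionality correlation
#'
#' Pearson correlation between per-species museum record counts and field
#' occurrence counts, with the two-sided p-value from the t-transform with
#' n - 2 degrees of freedom. A strong positive correlation indicates field
#' occurrences were recorded close to proportionally to the historical
#' sampling of the species pool.
#'
#' @param museumCounts,fieldCounts per-species integer vectors (same length,
#'   >= 3 species).
#' @return list with \code{r}, \code{p.value}, \code{n}; when either vector
#'   has zero variance, \code{r} is NA and \code{degenerate} is TRUE.
#' @export
proportionalityTest <- function(museumCounts, fieldCounts) {
  if (length(museumCounts) != length(fieldCounts))
    stop("count vectors must have the same length", call. = FALSE)
  if (length(museumCounts) < 3L)
    stop("at least 3 species required", call. = FALSE)
  if (stats::sd(museumCounts) == 0 || stats::sd(fieldCounts) == 0) {
    warning("zero variance in a count vector: correlation undefined")
    return(list(r = NA_real_, p.value = NA_real_, n = length(museumCounts),
                degenerate = TRUE))
  }
  ct <- stats::cor.test(museumCounts, fieldCounts, method = "pearson")
  list(r = unname(ct$estimate), p.value = ct$p.value,
       n = length(museumCounts), degenerate = FALSE)
}

#' Validate a batch of ADMs against field occurrence sets
#'
#' Runs [siteSuccess()] and [bufferSuccess()] for every species and
#' assembles a [ValidationReport]: one row per species plus the mean and
#' population (n-denominator) standard deviation of both success columns,
#' computed over species with at least one field presence cell.
#'
#' @param adms list of [BinaryModel]s (named by species or tagged).
#' @param fieldSets list of field [OccurrenceSet]s, matched to `adms` by
#'   species name.
#' @param radius buffer radius passed to [bufferSuccess()].
#' @return a [ValidationReport].
#' @export
batchValidate <- function(adms, fieldSets, radius = NULL) {
  if (!length(adms)) stop("at least one species required", call. = FALSE)
  fieldBySpecies <- stats::setNames(fieldSets,
                                    vapply(fieldSets, function(f) f@species, ""))
  rows <- lapply(adms, function(adm) {
    fld <- fieldBySpecies[[adm@species]]
    if (is.null(fld)) stop("no field set for species '", adm@species, "'",
                           call. = FALSE)
    s <- siteSuccess(adm, fld)
    b <- bufferSuccess(adm, fld,
                       radius = if (is.null(radius)) adm@layout@cellSize else radius)
    data.frame(species = adm@species,
               sitePresenceCells = s$totalPresenceCells,
               siteTrue = s$truePresences, siteFalse = s$falseAbsences,
               siteSuccessPct = s$successPct,
               bufferCells = b$totalBufferCells,
               bufferTrue = b$trueBufferCells, bufferFalse = b$falseBufferCells,
               bufferSuccessPct = b$successPct)
  })
  tab <- do.call(rbind, rows)
  ok <- tab$sitePresenceCells > 0
  new("ValidationReport", table = tab,
      summary = list(siteMean = mean(tab$siteSuccessPct[ok]),
                     siteSd = popSd(tab$siteSuccessPct[ok]),
                     bufferMean = mean(tab$bufferSuccessPct[ok]),
                     bufferSd = popSd(tab$bufferSuccessPct[ok]),
                     nSpecies = sum(ok)))
}

#' Write a validation report to CSV (rows) and JSON (summary)
#' @param report a [ValidationReport]; @param csvPath,jsonPath output paths.
#' @export
writeValidationReport <- function(report, csvPath, jsonPath = NULL) {
  utils::write.csv(report@table, csvPath, row.names = FALSE)
  if (!is.null(jsonPath))
    jsonlite::write_json(report@summary, jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(csvPath)
}
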