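# PDM -> ADM reduction by subcell land-cover masking.

#' Reduce a potential distribution model to an actual distribution model
#'
#' A PDM presence cell stays presence iff the fraction of its land-cover
#' subcells whose class is suitable for the species reaches
#' `suitableFraction` (default 0.5, majority-suitable; the subcell rule is
#' exposed because overlay conventions differ). All other cells become
#' absence. The land-cover raster must nest exactly under the model grid
#' (integer subcell ratio, shared origin).
#'
#' @param pdm a [BinaryModel] of kind \code{"PDM"}.
#' @param lc a [LandCover].
#' @param habitat a [HabitatTable]; the species must be present in it.
#' @param species species to look up (default: the PDM's species).
#' @param suitableFraction required suitable-subcell fraction in (0, 1].
#' @return a [BinaryModel] of kind \code{"ADM"} with the parent threshold
#'   metadata retained; its presence cells are a subset of the PDM's.
#' @export
reduceToAdm <- function(pdm, lc, habitat, species = pdm@species,
                        suitableFraction = 0.5) {
  assertNumber(suitableFraction, "suitableFraction", min = 0, max = 1,
               strictMin = TRUE)
  if (!species %in% names(habitat@table))
    stop("species '", species, "' not found in the habitat table", call. = FALSE)
  classes <- habitat@table[[species]]
  k <- subcellRatioOf(lc, pdm@layout)
  frac <- suitableSubcellFraction(lc, pdm@layout, classes, k)
  grid <- pdm@grid
  keep <- !is.na(grid) & grid == 1L & frac >= suitableFraction
  grid[!is.na(grid)] <- 0L
  grid[keep] <- 1L
  adm <- BinaryModel(species, "ADM", grid, pdm@thresholdUsed,
                     pdm@thresholdRule, pdm@layout,
                     metadata = c(pdm@metadata,
                                  list(suitableFraction = suitableFraction,
                                       habitatClasses = classes,
                                       parentKind = "PDM")))
  stopifnot(all(adm@grid[!is.na(adm@grid)] <= pdm@grid[!is.na(adm@grid)]))
  adm
}

# Per model cell, the fraction of its k x k subcells whose class is in
# `classes` (NA subcells count as unsuitable).
suitableSubcellFraction <- function(lc, layout, classes, k) {
  suit <- matrix(as.numeric(!is.na(lc@classGrid) & lc@classGrid %in% classes),
                 nrow(lc@classGrid), ncol(lc@classGrid))
  crow <- (row(suit) - 1L) %/% k + 1L
  ccol <- (col(suit) - 1L) %/% k + 1L
  cid <- (ccol - 1L) * layout@nRows + crow
  counts <- tabulate(cid[suit > 0], nbins = layout@nRows * layout@nCols)
  matrix(counts / k^2, layout@nRows, layout@nCols)
}

#' Presence-cell count and valid-area fraction of a binary model
#'
#' @param model a [BinaryModel].
#' @return list with \code{presenceCells}, \code{validCells} and
#'   \code{fraction} (presence / valid; 0 when the model has no valid cells).
#' @export
areaSummary <- function(model) {
  valid <- sum(!is.na(model@grid))
  pres <- sum(model@grid == 1L, na.rm = TRUE)
  list(presenceCells = pres, validCells = valid,
       fraction = if (valid) pres / valid else 0)
}
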