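# Grid geometry: point <-> cell mapping and layout comparison.

#' Map points to grid cells
#'
#' A point maps to the cell whose half-open square contains it; points
#' exactly on the right or bottom edge of the grid are clipped inward so the
#' bounding box is fully covered. Points outside the bounding box map to
#' \code{NA}.
#'
#' @param layout a [RasterLayout].
#' @param xy two-column matrix of map coordinates.
#' @return integer matrix with columns \code{row}, \code{col} (1-based,
#'   row 1 at the top).
#' @export
pointsToCells <- function(layout, xy) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  s <- layout@cellSize
  col <- floor((xy[, 1] - layout@originX) / s) + 1L
  row <- floor((layout@originY - xy[, 2]) / s) + 1L
  # clip points sitting exactly on the max edge inward
  col[xy[, 1] == layout@originX + layout@nCols * s] <- layout@nCols
  row[xy[, 2] == layout@originY - layout@nRows * s] <- layout@nRows
  out <- col < 1L | col > layout@nCols | row < 1L | row > layout@nRows
  col[out] <- NA_integer_; row[out] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Cell centres in map coordinates
#' @param layout a [RasterLayout].
#' @param cells integer matrix with columns row, col.
#' @return two-column matrix of x/y centre coordinates.
#' @export
cellCenters <- function(layout, cells) {
  cells <- matrix(as.integer(cells), ncol = 2)
  cbind(x = layout@originX + (cells[, 2] - 0.5) * layout@cellSize,
        y = layout@originY - (cells[, 1] - 0.5) * layout@cellSize)
}

#' Do two layouts describe the same grid?
#' @param a,b [RasterLayout] objects.
#' @param tol numeric tolerance on origin and cell size.
#' @export
sameLayout <- function(a, b, tol = 1e-9) {
  a@nRows == b@nRows && a@nCols == b@nCols &&
    abs(a@originX - b@originX) <= tol && abs(a@originY - b@originY) <= tol &&
    abs(a@cellSize - b@cellSize) <= tol
}

#' Clip an occurrence set to a grid's bounding box
#'
#' The declared clip step: points outside the layout's bounding box are
#' dropped (with a message giving the count), so that downstream operations
#' may assume every point maps to a cell.
#'
#' @param occ an [OccurrenceSet]; @param layout a [RasterLayout].
#' @export
clipToGrid <- function(occ, layout) {
  cells <- pointsToCells(layout, occ@points)
  keep <- !is.na(cells[, 1])
  if (!all(keep))
    message(sum(!keep), " point(s) outside the grid dropped for '",
            occ@species, "'")
  OccurrenceSet(occ@species, occ@points[keep, , drop = FALSE], occ@source,
                if (length(occ@siteId)) occ@siteId[keep] else character())
}

# Distinct presence cells of an occurrence set (duplicates collapsed).
distinctCells <- function(layout, occ) {
  cells <- pointsToCells(layout, occ@points)
  cells <- cells[!is.na(cells[, 1]), , drop = FALSE]
  unique(cells)
}
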