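# Bundled study count tables for the twelve endemic dry-forest bird species
# of western Mexico: per-species museum record and field occurrence-cell
# counts, and the cross-tabulation of field occurrences against
# actual-distribution-model predictions (site and buffer evaluations).

#' Bundled per-species occurrence counts
#'
#' Museum record counts (records with distinct locations) and field
#' occurrence-site counts (distinct 1 x 1 km cells) for the twelve endemic
#' bird species of the western Mexican tropical dry forest.
#'
#' @return data.frame with columns \code{species}, \code{museum}, \code{field}.
#' @export
occurrenceCountTable <- function() {
  utils::read.csv(system.file("extdata", "bird_occurrence_counts.csv",
                              package = "admodel"), stringsAsFactors = FALSE)
}

#' Bundled field-validation cross-tabulation counts
#'
#' Per-species true-presence / false-absence cell counts from validating
#' habitat-masked distribution models against field occurrence data, under
#' the site evaluation (distinct 1-km presence cells) and the area
#' evaluation (cells within aggregated 1-km buffers around field sites).
#'
#' @return data.frame with columns \code{species}, \code{site_total},
#'   \code{site_true}, \code{site_false}, \code{buffer_total},
#'   \code{buffer_true}, \code{buffer_false}.
#' @export
fieldValidationTable <- function() {
  utils::read.csv(system.file("extdata", "field_validation_counts.csv",
                              package = "admodel"), stringsAsFactors = FALSE)
}

#' Success rates and summary from a validation count table
#'
#' Recomputes the site and buffer success percentages
#' (\eqn{100 \cdot true / total}) from raw counts and summarises each column
#' with its mean and population standard deviation.
#'
#' @param counts data.frame in the [fieldValidationTable()] layout.
#' @return list with \code{table} (counts plus \code{site_success_pct} and
#'   \code{buffer_success_pct}) and \code{summary}.
#' @export
successRateSummary <- function(counts = fieldValidationTable()) {
  counts$site_success_pct <- 100 * counts$site_true / counts$site_total
  counts$buffer_success_pct <- 100 * counts$buffer_true / counts$buffer_total
  list(table = counts,
       summary = list(siteMean = mean(counts$site_success_pct),
                      siteSd = popSd(counts$site_success_pct),
                      bufferMean = mean(counts$buffer_success_pct),
                      bufferSd = popSd(counts$buffer_success_pct)))
}
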