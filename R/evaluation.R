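# Model evaluation: pseudoabsence sampling, confusion-matrix metrics,
# interval metric curves with ROC/AUC, dual threshold selection,
# binarization, and the Wilcoxon signed-rank comparison of threshold sets.

#' Confusion-matrix statistics
#'
#' Derived statistics of a [ConfusionMatrix]: sensitivity
#' \eqn{TP/(TP+FN)}, specificity \eqn{TN/(TN+FP)}, omission error
#' \eqn{FN/(TP+FN)}, commission error \eqn{FP/(FP+TN)}, overall accuracy
#' \eqn{(TP+TN)/N}, and Cohen's kappa
#' \eqn{(P_o - P_e)/(1 - P_e)} with
#' \eqn{P_e = [(TP+FP)(TP+FN) + (FN+TN)(FP+TN)]/N^2}. Statistics whose
#' denominator is zero are \code{NaN}.
#'
#' @param cm a [ConfusionMatrix].
#' @name confusion-metrics
NULL

#' @rdname confusion-metrics
#' @export
sensitivity <- function(cm) cm@TP / (cm@TP + cm@FN)
#' @rdname confusion-metrics
#' @export
specificity <- function(cm) cm@TN / (cm@TN + cm@FP)
#' @rdname confusion-metrics
#' @export
omissionError <- function(cm) cm@FN / (cm@TP + cm@FN)
#' @rdname confusion-metrics
#' @export
commissionError <- function(cm) cm@FP / (cm@FP + cm@TN)
#' @rdname confusion-metrics
#' @export
overallAccuracy <- function(cm) (cm@TP + cm@TN) / (cm@TP + cm@FP + cm@FN + cm@TN)
#' @rdname confusion-metrics
#' @export
kappaStat <- function(cm) {
  N <- cm@TP + cm@FP + cm@FN + cm@TN
  po <- (cm@TP + cm@TN) / N
  pe <- ((cm@TP + cm@FP) * (cm@TP + cm@FN) +
         (cm@FN + cm@TN) * (cm@FP + cm@TN)) / N^2
  (po - pe) / (1 - pe)
}

#' Seeded 75/25 train/test split of an occurrence set
#'
#' Records are shuffled with a fixed seed and split by point (not by cell),
#' the convention used when a presence-only engine reserves a fraction of
#' the records for external accuracy assessment.
#'
#' @param occ an [OccurrenceSet].
#' @param trainFraction fraction of records used for training (default 0.75).
#' @param seed integer RNG seed.
#' @return list with elements \code{train} and \code{test}.
#' @export
trainTestSplit <- function(occ, trainFraction = 0.75, seed = 1) {
  assertNumber(trainFraction, "trainFraction", min = 0, max = 1, strictMin = TRUE)
  n <- nrow(occ@points)
  withSeed(seed, {
    idx <- sample.int(n)
    nTrain <- max(1L, floor(trainFraction * n))
    take <- function(i) OccurrenceSet(occ@species,
                                      occ@points[i, , drop = FALSE], occ@source,
                                      if (length(occ@siteId)) occ@siteId[i] else character())
    list(train = take(idx[seq_len(nTrain)]),
         test = take(idx[-seq_len(nTrain)]))
  })
}

#' Sample pseudoabsence points from another engine's absence area
#'
#' Draws `n` distinct cells uniformly without replacement from the absence
#' cells of a binary model (typically produced by a different engine than
#' the one under test, so the evaluation is not circular), excluding cells
#' that contain any of the `exclusion` points, and places one point at each
#' drawn cell's centre.
#'
#' @param absenceModel a [BinaryModel] supplying the absence area.
#' @param n number of pseudoabsences.
#' @param seed integer RNG seed.
#' @param exclusion optional [OccurrenceSet] (or list of them) whose cells
#'   are excluded from sampling.
#' @param engineUnderTest optional engine tag of the model being evaluated;
#'   a warning is issued when it matches the absence model's engine recorded
#'   in its metadata.
#' @return an [OccurrenceSet] with \code{source = "pseudoabsence"}.
#' @export
samplePseudoabsences <- function(absenceModel, n, seed, exclusion = NULL,
                                 engineUnderTest = NULL) {
  n <- assertCount(n, "n")
  if (!is.null(engineUnderTest) &&
      identical(engineUnderTest, absenceModel@metadata$engine))
    warning("pseudoabsences drawn from the same engine as the model under test")
  absent <- !is.na(absenceModel@grid) & absenceModel@grid == 0L
  if (!is.null(exclusion)) {
    if (methods::is(exclusion, "OccurrenceSet")) exclusion <- list(exclusion)
    for (occ in exclusion) {
      cells <- pointsToCells(absenceModel@layout, occ@points)
      cells <- cells[!is.na(cells[, 1]), , drop = FALSE]
      absent[cells] <- FALSE
    }
  }
  eligible <- which(absent)
  if (length(eligible) < n)
    stop("pseudoabsence sampling error: need ", n, " absence cells, only ",
         length(eligible), " eligible (deficit ", n - length(eligible), ")",
         call. = FALSE)
  withSeed(seed, {
    drawn <- eligible[sample.int(length(eligible), n)]
    rows <- (drawn - 1L) %% nrow(absenceModel@grid) + 1L
    cols <- (drawn - 1L) %/% nrow(absenceModel@grid) + 1L
    OccurrenceSet(absenceModel@species, cellCenters(absenceModel@layout,
                                                    cbind(rows, cols)),
                  "pseudoabsence")
  })
}

# Suitability scores at a point set's cells; points on invalid cells are
# dropped with a message giving the count.
scoresAtPoints <- function(model, occ) {
  cells <- pointsToCells(model@layout, occ@points)
  sc <- rep(NA_real_, nrow(cells))
  inGrid <- !is.na(cells[, 1])
  sc[inGrid] <- model@grid[cells[inGrid, , drop = FALSE]]
  dropped <- sum(is.na(sc))
  if (dropped)
    message(dropped, " point(s) on invalid cells dropped from evaluation")
  sc[!is.na(sc)]
}

#' Confusion matrix of a suitability model at one threshold
#'
#' Predicted presence iff score >= t (the interval \[t, max\] convention of
#' interval-wise accuracy scans). TP/FN come from the presence points,
#' FP/TN from the pseudoabsence points; points on invalid cells are dropped
#' with a logged count.
#'
#' @param model a [SuitabilityModel].
#' @param t threshold.
#' @param presences,pseudoabsences [OccurrenceSet]s of test points.
#' @return a [ConfusionMatrix].
#' @export
evaluateAtThreshold <- function(model, t, presences, pseudoabsences) {
  sp <- scoresAtPoints(model, presences)
  sa <- scoresAtPoints(model, pseudoabsences)
  ConfusionMatrix(TP = sum(sp >= t), FN = sum(sp < t),
                  FP = sum(sa >= t), TN = sum(sa < t))
}

defaultThresholds <- function(scale)
  if (scale == "ordinal_1_10") 1:10 else c(3, 20, 40, 60, 70, 80, 90)

#' Metric curve over candidate thresholds, with AUC and selected thresholds
#'
#' Sweeps the candidate thresholds (ascending; defaults: 3, 20, 40, 60, 70,
#' 80, 90 for continuous models, 1..10 for ordinal models, matching an
#' interval-scan from wide to narrow prediction intervals), computing the
#' confusion matrix, kappa, sensitivity and specificity at each. The AUC is
#' the trapezoid area over the swept ROC points plus the degenerate
#' endpoints (0,0) and (1,1). The maximum-kappa and ROC closest-to-(0,1)
#' thresholds are selected from the sweep (NA when degenerate).
#'
#' @param model a [SuitabilityModel].
#' @param presences,pseudoabsences test point sets.
#' @param thresholds ascending candidate thresholds (NULL = scale default).
#' @return a [ThresholdReport].
#' @export
metricCurve <- function(model, presences, pseudoabsences, thresholds = NULL) {
  if (is.null(thresholds)) thresholds <- defaultThresholds(model@scale)
  if (!length(thresholds)) stop("empty threshold list", call. = FALSE)
  if (is.unsorted(thresholds)) stop("thresholds must be ascending", call. = FALSE)
  rows <- lapply(thresholds, function(t) {
    cm <- evaluateAtThreshold(model, t, presences, pseudoabsences)
    data.frame(threshold = t, TP = cm@TP, FP = cm@FP, FN = cm@FN, TN = cm@TN,
               kappa = kappaStat(cm), sensitivity = sensitivity(cm),
               specificity = specificity(cm))
  })
  curve <- do.call(rbind, rows)
  auc <- trapezoidAuc(curve$sensitivity, 1 - curve$specificity)
  rep <- new("ThresholdReport", species = model@species, engine = model@engine,
             curve = curve, kappaThreshold = NA_real_, rocThreshold = NA_real_,
             auc = auc)
  rep@kappaThreshold <- tryCatch(selectKappaThreshold(rep),
                                 error = function(e) NA_real_)
  rep@rocThreshold <- tryCatch(selectRocThreshold(rep),
                               error = function(e) NA_real_)
  rep
}

trapezoidAuc <- function(tpr, fpr) {
  ok <- is.finite(tpr) & is.finite(fpr)
  pts <- unique(rbind(c(0, 0), cbind(fpr[ok], tpr[ok]), c(1, 1)))
  pts <- pts[order(pts[, 1], pts[, 2]), , drop = FALSE]
  sum(diff(pts[, 1]) * (utils::head(pts[, 2], -1) + utils::tail(pts[, 2], -1)) / 2)
}

#' Select the maximum-kappa threshold from a sweep
#'
#' The candidate threshold with maximal kappa; ties go to the lowest
#' threshold. Errors when kappa is undefined at every candidate.
#'
#' @param report a [ThresholdReport].
#' @export
selectKappaThreshold <- function(report) {
  k <- report@curve$kappa
  if (all(!is.finite(k)))
    stop("kappa undefined at every candidate threshold", call. = FALSE)
  report@curve$threshold[which.max(ifelse(is.finite(k), k, -Inf))]
}

#' Select the ROC closest-to-(0,1) threshold from a sweep
#'
#' The candidate minimizing the Euclidean distance
#' \eqn{\sqrt{(1-sens)^2 + (1-spec)^2}} to the perfect-classification corner
#' (the operational form of "sensitivity maximized, 1-specificity
#' minimized"); ties go to the lowest threshold.
#'
#' @param report a [ThresholdReport].
#' @param rule \code{"distance"} (default) or \code{"youden"} (maximize
#'   sensitivity + specificity - 1).
#' @export
selectRocThreshold <- function(report, rule = c("distance", "youden")) {
  rule <- match.arg(rule)
  sens <- report@curve$sensitivity; spec <- report@curve$specificity
  crit <- if (rule == "distance") sqrt((1 - sens)^2 + (1 - spec)^2)
          else -(sens + spec - 1)
  if (all(!is.finite(crit)))
    stop("ROC criterion undefined at every candidate threshold", call. = FALSE)
  report@curve$threshold[which.min(ifelse(is.finite(crit), crit, Inf))]
}

#' Binarize a suitability model into a presence/absence PDM
#'
#' Presence iff score >= t; invalid cells preserved as \code{NA}.
#'
#' @param model a [SuitabilityModel].
#' @param t threshold on the model's own scale.
#' @param rule threshold rule tag recorded on the output
#'   (\code{"kappa"}, \code{"roc"} or \code{"external"}).
#' @return a [BinaryModel] of kind \code{"PDM"}.
#' @export
binarize <- function(model, t, rule = "external") {
  grid <- matrix(NA_integer_, model@layout@nRows, model@layout@nCols)
  grid[model@validMask] <- as.integer(model@grid[model@validMask] >= t)
  BinaryModel(model@species, "PDM", grid, t, rule, model@layout,
              metadata = list(engine = model@engine))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped; absolute differences are ranked with
#' midranks for ties; \eqn{W = \min(W^+, W^-)}. The two-sided p-value is
#' exact (full enumeration of the \eqn{2^n} sign assignments, correct under
#' ties) for n <= `exactMax`, and a normal approximation with tie
#' correction and continuity correction otherwise. When every difference is
#' zero the result is flagged degenerate with p = 1.
#'
#' @param a numeric vector: first sample, or the differences if `b` is NULL.
#' @param b optional second sample (paired with `a`).
#' @param exactMax largest n for exact enumeration (default 20).
#' @return list with \code{statistic} (W), \code{Wplus}, \code{Wminus},
#'   \code{p.value}, \code{n} (pairs after zero removal), \code{method},
#'   \code{degenerate}.
#' @export
wilcoxonSignedRank <- function(a, b = NULL, exactMax = 20L) {
  d <- if (is.null(b)) as.numeric(a) else as.numeric(a) - as.numeric(b)
  d <- d[!is.na(d)]
  if (!length(d)) stop("no pairs supplied", call. = FALSE)
  d <- d[d != 0]
  if (!length(d))
    return(list(statistic = 0, Wplus = 0, Wminus = 0, p.value = 1,
                n = 0L, method = "degenerate", degenerate = TRUE))
  r <- rank(abs(d))
  Wplus <- sum(r[d > 0]); Wminus <- sum(r[d < 0])
  W <- min(Wplus, Wminus)
  n <- length(d)
  tot <- n * (n + 1) / 2
  if (n <= exactMax) {
    sums <- 0
    for (ri in r) sums <- c(sums, sums + ri)
    p <- mean(pmin(sums, tot - sums) <= W + 1e-9)
    method <- "exact enumeration"
  } else {
    ties <- table(r)
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48)
    z <- (W + 0.5 - tot / 2) / sigma
    p <- min(1, 2 * stats::pnorm(z))
    method <- "normal approximation with tie correction"
  }
  list(statistic = W, Wplus = Wplus, Wminus = Wminus, p.value = p,
       n = n, method = method, degenerate = FALSE)
}
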