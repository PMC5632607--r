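test_that("confusion-matrix statistics match their definitions", {
  cm <- ConfusionMatrix(TP = 40, FP = 10, FN = 10, TN = 40)
  expect_equal(kappaStat(cm), 0.6)
  expect_equal(sensitivity(cm), 0.8)
  expect_equal(specificity(cm), 0.8)
  expect_equal(overallAccuracy(cm), 0.8)
  expect_equal(omissionError(cm), 0.2)
  expect_equal(commissionError(cm), 0.2)
  # kappa = 1 iff no errors with both classes present
  expect_equal(kappaStat(ConfusionMatrix(12, 0, 0, 30)), 1)
  # proportional rows (prediction independent of truth) -> kappa = 0
  expect_equal(kappaStat(ConfusionMatrix(6, 3, 4, 2)), 0)
  # random matrices stay within [-1, 1] and match the oracle formula
  set.seed(99)
  for (i in 1:25) {
    v <- rpois(4, 12) + c(1, 0, 0, 1)
    cm <- ConfusionMatrix(v[1], v[2], v[3], v[4])
    expect_equal(kappaStat(cm), oracleKappa(v[1], v[2], v[3], v[4]))
    expect_gte(kappaStat(cm), -1); expect_lte(kappaStat(cm), 1)
  }
  expect_error(ConfusionMatrix(0, 0, 0, 0), "at least one")
})

test_that("threshold evaluation counts points on either side of the cutoff", {
  sc <- matrix(c(10, 30, 50, 70, 90, NA), 2, 3)
  model <- suitModel(sc)
  lay <- gridLayout(model)
  pres <- occAtCells(lay, rbind(c(1, 2), c(2, 2), c(1, 3)))   # scores 50, 70, 90
  abs_ <- occAtCells(lay, rbind(c(1, 1), c(2, 1)))            # scores 10, 30
  cm <- evaluateAtThreshold(model, 60, pres, abs_)
  expect_equal(c(cm@TP, cm@FN, cm@FP, cm@TN), c(2L, 1L, 0L, 2L))
  cm0 <- evaluateAtThreshold(model, 0, pres, abs_)
  expect_equal(c(cm0@FN, cm0@TN), c(0L, 0L))
  cmHi <- evaluateAtThreshold(model, 101, pres, abs_)
  expect_equal(c(cmHi@TP, cmHi@FP), c(0L, 0L))
  # a point on the invalid cell is dropped with a message
  presBad <- occAtCells(lay, rbind(c(1, 2), c(2, 3)))
  expect_message(cmDrop <- evaluateAtThreshold(model, 60, presBad, abs_),
                 "1 point")
  expect_equal(cmDrop@TP + cmDrop@FN, 1L)
})

test_that("AUC is 1 for perfect separation, 0.5 for uninformative scores", {
  sc <- matrix(seq(5, 100, length.out = 20), 4, 5)
  model <- suitModel(sc)
  lay <- gridLayout(model)
  hi <- which(sc > 60, arr.ind = TRUE); lo <- which(sc < 40, arr.ind = TRUE)
  rep1 <- metricCurve(model, occAtCells(lay, hi), occAtCells(lay, lo))
  expect_equal(rep1@auc, 1)
  flat <- suitModel(matrix(50, 4, 5))
  rep2 <- metricCurve(flat, occAtCells(lay, hi), occAtCells(lay, lo))
  expect_equal(rep2@auc, 0.5)
  expect_error(metricCurve(model, occAtCells(lay, hi), occAtCells(lay, lo),
                           thresholds = numeric()), "empty threshold")
})

test_that("swept AUC with per-point candidate scores equals the Mann-Whitney oracle", {
  set.seed(7)
  for (i in 1:5) {
    sc <- matrix(sample(0:100, 30, replace = TRUE), 5, 6)
    model <- suitModel(sc)
    lay <- gridLayout(model)
    all <- which(!is.na(sc), arr.ind = TRUE)
    pi <- sample(nrow(all), 8)
    ai <- sample(setdiff(seq_len(nrow(all)), pi), 8)
    pres <- occAtCells(lay, all[pi, ]); abs_ <- occAtCells(lay, all[ai, ])
    cand <- sort(unique(c(sc[all[pi, ]], sc[all[ai, ]])))
    rep <- metricCurve(model, pres, abs_, thresholds = cand)
    expect_equal(rep@auc, oracleAucMW(sc[all[pi, ]], sc[all[ai, ]]),
                 tolerance = 1e-12)
  }
})

makeReport <- function(thresholds, kappa, sens, spec) {
  methods::new("ThresholdReport", species = "sp", engine = "external",
               curve = data.frame(threshold = thresholds, TP = 1L, FP = 1L,
                                  FN = 1L, TN = 1L, kappa = kappa,
                                  sensitivity = sens, specificity = spec),
               kappaThreshold = NA_real_, rocThreshold = NA_real_, auc = 0.5)
}

test_that("kappa threshold selection takes the argmax with low-threshold ties", {
  rep <- makeReport(c(20, 60, 80), c(0.3, 0.7, 0.5), rep(1, 3), rep(1, 3))
  expect_equal(selectKappaThreshold(rep), 60)
  tie <- makeReport(c(20, 60, 80), c(0.3, 0.7, 0.7), rep(1, 3), rep(1, 3))
  expect_equal(selectKappaThreshold(tie), 60)
  und <- makeReport(c(20, 60), c(NaN, NaN), c(1, 1), c(1, 1))
  expect_error(selectKappaThreshold(und), "undefined")
})

test_that("ROC threshold selection minimizes distance to (0,1)", {
  rep <- makeReport(c(20, 60, 80), rep(0.5, 3),
                    sens = c(1.0, 0.8, 0.5), spec = c(0.6, 0.9, 1.0))
  expect_equal(selectRocThreshold(rep), 60)   # distance 0.224 beats 0.4 and 0.5
  perfect <- makeReport(c(20, 60), rep(0.5, 2), c(0.7, 1), c(0.9, 1))
  expect_equal(selectRocThreshold(perfect), 60)
  # Youden alternative is exposed
  expect_equal(selectRocThreshold(rep, rule = "youden"), 60)
})

test_that("selections equal exhaustive scans and ignore duplicated candidates", {
  set.seed(31)
  for (i in 1:10) {
    k <- runif(5); sens <- runif(5); spec <- runif(5)
    thr <- c(3, 20, 40, 60, 80)
    rep <- makeReport(thr, k, sens, spec)
    expect_equal(selectKappaThreshold(rep), thr[which.max(k)])
    d <- sqrt((1 - sens)^2 + (1 - spec)^2)
    expect_equal(selectRocThreshold(rep), thr[which.min(d)])
    dup <- makeReport(c(thr, thr), c(k, k), c(sens, sens), c(spec, spec))
    expect_equal(selectKappaThreshold(dup), selectKappaThreshold(rep))
    expect_equal(selectRocThreshold(dup), selectRocThreshold(rep))
  }
})

test_that("binarization nests presence sets as the threshold rises", {
  stack <- genEnvStack(43, nLayers = 3, nRows = 15, nCols = 15)
  occ <- occAtCells(gridLayout(stack),
                    which(envLayer(stack, 1) > 0.4, arr.ind = TRUE))
  suit <- envelopePredict(stack, occ)
  expect_equal(sum(gridValues(binarize(suit, 0))), sum(validMask(stack)))
  expect_equal(sum(gridValues(binarize(suit, 100.01))), 0)
  prev <- NULL
  for (t in c(3, 20, 40, 60, 80, 90)) {
    cur <- gridValues(binarize(suit, t)) == 1L
    if (!is.null(prev)) expect_true(all(prev[cur]))  # cur subset of prev
    prev <- cur
  }
})

test_that("pseudoabsences are distinct uniform draws from eligible absence cells", {
  grid <- matrix(0L, 8, 8)
  am <- binModel(grid)
  pa <- samplePseudoabsences(am, 10, seed = 5)
  cells <- pointsToCells(gridLayout(am), occPoints(pa))
  expect_equal(nrow(unique(cells)), 10L)
  expect_equal(pa@source, "pseudoabsence")
  # all-presence model cannot supply pseudoabsences
  expect_error(samplePseudoabsences(binModel(matrix(1L, 4, 4)), 3, seed = 1),
               "deficit")
  # excluded cells are never drawn
  excl <- occAtCells(gridLayout(am), cbind(1:8, 1))
  pa2 <- samplePseudoabsences(am, 20, seed = 6, exclusion = excl)
  expect_false(any(pointsToCells(gridLayout(am), occPoints(pa2))[, 2] == 1))
  # uniformity over absence cells across repeated draws
  tallies <- numeric(64)
  for (s in 1:150) {
    d <- samplePseudoabsences(am, 20, seed = s)
    cl <- pointsToCells(gridLayout(am), occPoints(d))
    tallies <- tallies + tabulate((cl[, 2] - 1L) * 8L + cl[, 1], nbins = 64)
  }
  expect_gt(chisq.test(tallies)$p.value, 0.01)
  # same-engine warning
  amTag <- binModel(grid); amTag@metadata$engine <- "enfa"
  expect_warning(samplePseudoabsences(amTag, 3, seed = 2,
                                      engineUnderTest = "enfa"),
                 "same engine")
})

test_that("train/test split is a seeded 75/25 partition of the records", {
  occ <- OccurrenceSet("sp", cbind(runif(40), runif(40)))
  sp <- trainTestSplit(occ, seed = 11)
  expect_equal(length(sp$train), 30)
  expect_equal(length(sp$test), 10)
  both <- rbind(occPoints(sp$train), occPoints(sp$test))
  expect_equal(nrow(unique(both)), 40)
  sp2 <- trainTestSplit(occ, seed = 11)
  expect_identical(occPoints(sp$train), occPoints(sp2$train))
})

test_that("Wilcoxon signed-rank statistic and exact p behave as defined", {
  w <- wilcoxonSignedRank(c(1, 2, 3, 4, 5, -6))
  expect_equal(w$Wplus, 15); expect_equal(w$Wminus, 6)
  expect_equal(w$statistic, 6)
  # most extreme assignment: all positive, n = 5 -> p = 2/2^5
  w5 <- wilcoxonSignedRank(c(2, 4, 1, 7, 3))
  expect_equal(w5$p.value, 0.0625)
  # agreement with the stats oracle when there are no ties
  d <- c(3.2, -1.1, 0.7, 2.5, -4.4, 1.9, -0.2, 5.1, 2.2, -3.3)
  ours <- wilcoxonSignedRank(d)
  ref <- wilcox.test(d, exact = TRUE, correct = FALSE)
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
  # full-enumeration oracle with ties, n = 12
  dt <- c(1, 1, -2, 3, 3, 3, -4, 5, 5, -1, 2, 2)
  expect_equal(wilcoxonSignedRank(dt)$p.value, oracleWilcoxonExact(dt),
               tolerance = 1e-12)
  # zero differences are dropped before ranking
  expect_equal(wilcoxonSignedRank(c(0, 0, dt))$n, 12L)
  # all-zero input is flagged degenerate with p = 1
  w0 <- wilcoxonSignedRank(rep(0, 4))
  expect_true(w0$degenerate); expect_equal(w0$p.value, 1)
  # large-sample branch: close to the exact distribution (tie-free case)
  set.seed(3); dbig <- rnorm(30) + 0.4
  approx <- wilcoxonSignedRank(dbig)
  expect_equal(approx$method, "normal approximation with tie correction")
  ref2 <- wilcox.test(dbig, exact = TRUE, correct = FALSE)
  expect_lt(abs(approx$p.value - ref2$p.value), 0.02)
})
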