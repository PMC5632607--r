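test_that("species equal to the global pool has zero marginality and unit tolerance", {
  stack <- genEnvStack(2, nLayers = 3, nRows = 12, nCols = 12)
  fit <- suppressMessages(enfaFit(stack, occEverywhere(stack)))
  expect_lt(sqrt(sum(fit@marginalityVector^2)), 1e-9)
  expect_equal(fit@globalMarginality, 0, tolerance = 1e-9)
  expect_equal(fit@eigenvalues, rep(1, 3), tolerance = 1e-6)
  expect_equal(fit@globalTolerance, 1, tolerance = 1e-6)
})

test_that("marginality matches hand-computed means on a two-layer toy", {
  stack <- handStack(10)
  l1 <- envLayer(stack, 1)
  cells <- which(l1 > 1, arr.ind = TRUE)
  fit <- enfaFit(stack, occAtCells(gridLayout(stack), cells))
  # brute-force: standardized presence means per layer
  exp1 <- mean(l1[cells]); exp2 <- mean(envLayer(stack, 2)[cells])
  expect_equal(unname(fit@marginalityVector[1]), exp1, tolerance = 1e-12)
  expect_equal(unname(fit@marginalityVector[2]), exp2, tolerance = 1e-12)
  expect_gt(fit@marginalityVector[1], 0)
  expect_lt(abs(fit@marginalityVector[2]), 0.2)
  expect_equal(fit@globalMarginality, sqrt(exp1^2 + exp2^2) / 1.96,
               tolerance = 1e-12)
  # factor axes orthonormal, eigenvalues non-negative and ordered
  expect_equal(crossprod(fit@factors), diag(2), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(fit@eigenvalues >= -1e-8))
})

test_that("marginality index is invariant to layer order and sign flips", {
  stack <- genEnvStack(13, nLayers = 4, nRows = 20, nCols = 20)
  cells <- which(envLayer(stack, 2) > 0.8, arr.ind = TRUE)
  occ <- occAtCells(gridLayout(stack), cells)
  fit <- enfaFit(stack, occ)

  perm <- c(3, 1, 4, 2)
  permStack <- EnvStack(lapply(perm, function(k) envLayer(stack, k)),
                        layerNames(stack)[perm], gridLayout(stack))
  fitPerm <- enfaFit(permStack, occ)
  expect_equal(fitPerm@globalMarginality, fit@globalMarginality, tolerance = 1e-9)
  expect_equal(fitPerm@globalTolerance, fit@globalTolerance, tolerance = 1e-9)

  flip <- lapply(1:4, function(k) if (k == 2) -envLayer(stack, k)
                 else envLayer(stack, k))
  flipStack <- EnvStack(flip, layerNames(stack), gridLayout(stack))
  fitFlip <- enfaFit(flipStack, occ)
  expect_equal(fitFlip@globalMarginality, fit@globalMarginality, tolerance = 1e-9)
  expect_equal(sort(fitFlip@eigenvalues), sort(fit@eigenvalues), tolerance = 1e-7)
})

test_that("too few distinct presence cells is a fit error", {
  stack <- genEnvStack(4, nLayers = 4, nRows = 10, nCols = 10)
  occ <- occAtCells(gridLayout(stack), cbind(1:3, 1:3))
  expect_error(enfaFit(stack, occ), "distinct presence cells")
  # duplicates collapse to distinct cells
  occDup <- occAtCells(gridLayout(stack), cbind(c(1, 1, 1, 1), c(1, 1, 1, 1)))
  expect_error(enfaFit(stack, occDup), "got 1")
})

test_that("suitability scoring equals the brute-force count oracle exactly", {
  stack <- genEnvStack(17, nLayers = 3, nRows = 15, nCols = 15)
  cells <- which(envLayer(stack, 1) + envLayer(stack, 2) > 0.9, arr.ind = TRUE)
  fit <- enfaFit(stack, occAtCells(gridLayout(stack), cells))
  suit <- enfaSuitability(fit, stack)
  expect_equal(gridValues(suit)[validMask(stack)], oracleEnfaSuit(fit, stack),
               tolerance = 1e-12)
  expect_true(all(gridValues(suit)[validMask(stack)] >= 0))
  expect_true(all(gridValues(suit)[validMask(stack)] <= 100))
  expect_error(enfaSuitability(fit, genEnvStack(1, nLayers = 2, nRows = 15,
                                                nCols = 15)),
               "different layer set")
})

test_that("median-count scoring rule behaves at its extremes", {
  # hand-built one-factor model: presences score -1, 0, 2; median 0
  model <- methods::new("EnfaModel", layerNames = "a",
                        marginalityVector = 0.3, globalMarginality = 0.3 / 1.96,
                        factors = matrix(1, 1, 1), eigenvalues = 1.2,
                        globalTolerance = 1 / sqrt(1.2), retained = 1L,
                        presenceScores = matrix(c(-1, 0, 2), 3, 1),
                        factorMedians = 0, globalMean = 0, globalSd = 1,
                        nPresence = 3L)
  stack <- EnvStack(list(matrix(c(-1, 0, 2), 1, 3)), "a", RasterLayout(1, 3))
  hs <- gridValues(enfaSuitability(model, stack))
  # at the presence median every presence is as-or-more extreme -> 100
  expect_equal(hs[1, 2], 100)
  # as extreme as the most extreme presence -> only that one counts -> 100/N
  expect_equal(hs[1, 3], 100 / 3)
  # intermediate deviation 1: two of three presences at least as extreme
  expect_equal(hs[1, 1], 200 / 3)
})

test_that("variable importance ranks the shifted layer first", {
  stack <- handStack(12)
  l1 <- envLayer(stack, 1)
  cells <- which(l1 > 1, arr.ind = TRUE)
  fit <- enfaFit(stack, occAtCells(gridLayout(stack), cells))
  vi <- variableImportance(fit)
  expect_equal(vi$layer[vi$marginalityRank == 1], "gradX")
  # loadings are unit-norm per factor
  expect_equal(colSums(fit@factors^2), c(marginality = 1, spec01 = 1),
               tolerance = 1e-9)
  # zero-marginality model has all-zero marginality scores
  stack2 <- genEnvStack(2, nLayers = 3, nRows = 10, nCols = 10)
  fit0 <- suppressMessages(enfaFit(stack2, occEverywhere(stack2)))
  expect_equal(variableImportance(fit0)$marginality, rep(0, 3),
               tolerance = 1e-9)
})

test_that("ENFA models serialize to JSON and re-score identically", {
  stack <- genEnvStack(19, nLayers = 3, nRows = 12, nCols = 12)
  cells <- which(envLayer(stack, 1) > 0.5, arr.ind = TRUE)
  fit <- enfaFit(stack, occAtCells(gridLayout(stack), cells))
  p <- withr::local_tempfile(fileext = ".json")
  writeEnfaModel(fit, p)
  back <- readEnfaModel(p)
  expect_equal(back@eigenvalues, fit@eigenvalues)
  expect_equal(back@factors, fit@factors, ignore_attr = TRUE)
  expect_equal(gridValues(enfaSuitability(back, stack)),
               gridValues(enfaSuitability(fit, stack)))
})
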