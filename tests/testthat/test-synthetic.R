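test_that("generated layers are exactly standardized and seed-deterministic", {
  s1 <- genEnvStack(11, nLayers = 4, nRows = 30, nCols = 25)
  s2 <- genEnvStack(11, nLayers = 4, nRows = 30, nCols = 25)
  s3 <- genEnvStack(12, nLayers = 4, nRows = 30, nCols = 25)
  expect_identical(s1@values, s2@values)
  expect_false(identical(s1@values, s3@values))
  for (k in 1:4) {
    v <- envLayer(s1, k)
    expect_lt(abs(mean(v)), 1e-9)
    expect_lt(abs(sqrt(mean((v - mean(v))^2)) - 1), 1e-9)
  }
  expect_error(genEnvStack(1, nRows = 0), "nRows")
})

test_that("autocorrelation range controls lag-1 spatial correlation", {
  lag1 <- function(stack) {
    mean(sapply(seq_along(layerNames(stack)), function(k) {
      v <- envLayer(stack, k)
      cor(as.vector(v[, -1]), as.vector(v[, -ncol(v)]))
    }))
  }
  white <- genEnvStack(21, nLayers = 3, nRows = 100, nCols = 100,
                       autocorrRange = 0)
  smooth <- genEnvStack(21, nLayers = 3, nRows = 100, nCols = 100,
                        autocorrRange = 5)
  expect_lt(abs(lag1(white)), 0.05)
  expect_gt(lag1(smooth), 0.5)
})

test_that("latent mixing produces collinear layers", {
  stack <- genEnvStack(31, nLayers = 6, nRows = 60, nCols = 60)
  Z <- sapply(1:6, function(k) as.vector(envLayer(stack, k)))
  cm <- abs(cor(Z)[upper.tri(diag(6))])
  expect_gt(median(cm), 0.3)
})

test_that("virtual species plants the requested niche geometry", {
  stack <- genEnvStack(41, nLayers = 6, nRows = 60, nCols = 60)
  # zero marginality -> centre at the environmental centroid
  vs0 <- genVirtualSpecies(stack, 1, marginalityTarget = 0, toleranceTarget = 0.7)
  expect_identical(vs0@nicheCenter, rep(0, 6))
  # norm of the centre is 1.96 * target
  vs <- genVirtualSpecies(stack, 2, marginalityTarget = 1.5, toleranceTarget = 0.6)
  expect_equal(sqrt(sum(vs@nicheCenter^2)), 2.94, tolerance = 1e-9)
  # truth follows the Gaussian-kernel definition on valid cells
  Z <- sapply(1:6, function(k) envLayer(stack, k)[validMask(stack)])
  d2 <- rowSums(sweep(sweep(Z, 2, vs@nicheCenter), 2, vs@nicheWidth, "/")^2)
  expect_equal(gridValues(vs)[validMask(stack)], exp(-0.5 * d2))
  # seeded determinism
  expect_identical(gridValues(genVirtualSpecies(stack, 2, 1.5, 0.6)),
                   gridValues(vs))
  # absurdly narrow niches are rejected as degenerate
  expect_error(genVirtualSpecies(stack, 3, marginalityTarget = 3,
                                 toleranceTarget = 0.05),
               "degenerate niche")
})

test_that("occurrence sampling is uniform under flat truth and seed-stable", {
  lay <- RasterLayout(12, 12)
  vs <- uniformVS(lay)
  occ <- sampleOccurrences(vs, 10000, seed = 5)
  cells <- pointsToCells(lay, occPoints(occ))
  tab <- tabulate((cells[, 2] - 1L) * 12L + cells[, 1], nbins = 144)
  expect_gt(chisq.test(tab)$p.value, 0.01)

  o1 <- sampleOccurrences(vs, 50, seed = 9, clustering = 0)
  o2 <- sampleOccurrences(vs, 50, seed = 9, clustering = 0)
  expect_identical(occPoints(o1), occPoints(o2))
  expect_error(sampleOccurrences(vs, 0, seed = 1), "`n`")
  expect_error(sampleOccurrences(vs, 145, seed = 1, replace = FALSE),
               "nonzero suitability")
  # sampling concentrates where truth is high when gamma sharpens
  stack <- genEnvStack(51, nLayers = 3, nRows = 40, nCols = 40)
  vsp <- genVirtualSpecies(stack, 6, marginalityTarget = 1, toleranceTarget = 0.6)
  oc <- sampleOccurrences(vsp, 300, seed = 7)
  cl <- pointsToCells(lay <- gridLayout(stack), occPoints(oc))
  expect_gt(mean(gridValues(vsp)[cl]), mean(gridValues(vsp), na.rm = TRUE))
})

test_that("land cover partitions the valid area into patchy classes", {
  stack <- genEnvStack(61, nLayers = 2, nRows = 30, nCols = 30)
  lc <- genLandCover(stack, 3, nClasses = 4, patchScale = 6, subcellRatio = 4)
  expect_equal(dim(gridValues(lc)), c(120L, 120L))
  expect_equal(gridLayout(lc)@cellSize, 0.25)
  areas <- table(gridValues(lc))
  expect_equal(sum(areas), 120L * 120L)             # classes partition the area
  expect_equal(sort(as.integer(names(areas))), 1:4)
  # large-scale two-class cover yields two big contiguous blobs: the count of
  # same-class neighbours dominates
  lc2 <- genLandCover(stack, 4, nClasses = 2, patchScale = 15, subcellRatio = 1)
  g <- gridValues(lc2)
  agree <- mean(g[, -1] == g[, -ncol(g)])
  expect_gt(agree, 0.95)
  expect_identical(gridValues(genLandCover(stack, 3, 4, 6, 4)), gridValues(lc))
})

test_that("dominant class matches a subcell-count oracle with low-code ties", {
  stack <- genEnvStack(71, nLayers = 2, nRows = 10, nCols = 10)
  lc <- genLandCover(stack, 8, nClasses = 3, patchScale = 1, subcellRatio = 3)
  dom <- dominantLandCover(lc, gridLayout(stack))
  cg <- gridValues(lc)
  for (r in 1:10) for (cc in 1:10) {
    sub <- cg[((r - 1) * 3 + 1):(r * 3), ((cc - 1) * 3 + 1):(cc * 3)]
    counts <- sapply(1:3, function(cl) sum(sub == cl, na.rm = TRUE))
    expect_identical(dom[r, cc], which(counts == max(counts))[1])
  }
  # deterministic tie-break: 2x2 blocks split between classes 2 and 1
  tie <- matrix(c(2L, 1L, 1L, 2L), 2, 2)
  lcTie <- admodel:::LandCover(tie, c("1" = "a", "2" = "b"),
                               RasterLayout(2, 2, cellSize = 0.5))
  expect_identical(dominantLandCover(lcTie, RasterLayout(1, 1))[1, 1], 1L)
})

test_that("field survey respects stratification, spacing and detection model", {
  lay <- RasterLayout(20, 20)
  vs <- uniformVS(lay)
  # land cover: left half class 1 (suitable), right half class 2
  cg <- matrix(2L, 40, 40); cg[, 1:20] <- 1L
  lc <- admodel:::LandCover(cg, c("1" = "in", "2" = "out"),
                            RasterLayout(40, 40, originY = 20, cellSize = 0.5))
  svy <- simulateFieldSurvey(vs, lc, nSites = 8, pointsPerSite = 5,
                             minPointSpacing = 0.1, detectionProb = 1, seed = 3)
  # truth = 1 and detection 1 -> every point detected; all sites in class 1 half
  expect_equal(length(svy), 40)
  expect_true(all(occPoints(svy)[, 1] <= 11))  # site extent reaches 1 cell out
  expect_equal(length(unique(svy@siteId)), 8)

  # spacing larger than the site extent diagonal -> at most one point per site
  svy1 <- simulateFieldSurvey(vs, lc, nSites = 5, pointsPerSite = 5,
                              minPointSpacing = 4, detectionProb = 1, seed = 4,
                              siteExtent = 2)
  expect_true(all(table(svy1@siteId) <= 1))

  # detection is Bernoulli(p x truth): detected fraction within 3 binomial sd
  svy2 <- simulateFieldSurvey(vs, lc, nSites = 20, pointsPerSite = 30,
                              minPointSpacing = 0.05, detectionProb = 0.5,
                              seed = 5)
  nPts <- 20 * 30
  expect_lt(abs(length(svy2) - 0.5 * nPts), 3 * sqrt(nPts * 0.25))

  # too few eligible cells
  vs2 <- uniformVS(lay); vs2@suitableClasses <- 3L
  expect_error(simulateFieldSurvey(vs2, lc, nSites = 3, seed = 1),
               "stratification")
})
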