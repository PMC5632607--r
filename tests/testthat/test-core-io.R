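test_that("ASCII grid round trip is bit-identical, mask and layout included", {
  lay <- RasterLayout(7, 5, originX = -3.25, originY = 12.5, cellSize = 0.75)
  set.seed(42)
  vals <- matrix(rnorm(35) * 1e3, 7, 5)
  vals[c(3, 11, 30)] <- NA
  p <- withr::local_tempfile(fileext = ".asc")
  writeAsciiGrid(vals, lay, p)
  g <- readAsciiGrid(p)
  expect_identical(g$values, vals)
  expect_true(sameLayout(g$layout, lay))
})

test_that("environmental stacks reject misaligned layers and round-trip", {
  stack <- genEnvStack(3, nLayers = 3, nRows = 12, nCols = 9)
  dir <- withr::local_tempdir()
  paths <- writeEnvStack(stack, dir)
  back <- readEnvStack(paths)
  expect_identical(back@values, stack@values)
  expect_identical(back@validMask, stack@validMask)
  expect_identical(layerNames(back), layerNames(stack))

  # same dims, different cell size -> alignment error naming the layer
  bad <- file.path(dir, "badlayer.asc")
  writeAsciiGrid(envLayer(stack, 1), RasterLayout(12, 9, cellSize = 2), bad)
  expect_error(readEnvStack(c(paths[1], bad)), "badlayer")
  expect_error(readEnvStack("no/such/file.asc"), "no/such/file")
})

test_that("stack validity enforces shared dims and finite valid cells", {
  expect_error(EnvStack(list(matrix(1, 2, 2), matrix(1, 3, 3)),
                        c("a", "b"), RasterLayout(2, 2)))
  m <- matrix(NA_real_, 2, 2)
  expect_error(EnvStack(list(m), "a", RasterLayout(2, 2)),
               "at least one valid cell")
})

test_that("occurrence CSV reading filters by species/source and validates schema", {
  counts <- occurrenceCountTable()
  rows <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i)
    rbind(data.frame(species = counts$species[i],
                     x = runif(counts$museum[i]), y = runif(counts$museum[i]),
                     source = "museum"),
          data.frame(species = counts$species[i],
                     x = runif(counts$field[i]), y = runif(counts$field[i]),
                     source = "field"))))
  p <- withr::local_tempfile(fileext = ".csv")
  write.csv(rows, p, row.names = FALSE)
  occ <- suppressMessages(readOccurrences(p, "Cacicus melanicterus", "museum"))
  expect_equal(length(occ), 135)
  fld <- suppressMessages(readOccurrences(p, "Polioptila nigriceps", "field"))
  expect_equal(length(fld), 12)

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("species,x,y,source", empty)
  expect_warning(o0 <- suppressMessages(readOccurrences(empty, "x")), "no occurrences")
  expect_equal(length(o0), 0)

  noy <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,x,source", "a,1,museum"), noy)
  expect_error(readOccurrences(noy, "a"), "lacks column")
})

test_that("points map to half-open cells with max-edge clipping", {
  lay <- RasterLayout(4, 4, originX = 0, originY = 4, cellSize = 1)
  pts <- rbind(c(0, 4),        # top-left corner -> cell (1,1)
               c(0.999, 3.001),# still cell (1,1)
               c(1, 3),        # on interior edges -> cell (2,2) by half-open rule
               c(4, 0),        # bottom-right grid corner -> clipped to (4,4)
               c(2.5, 4),      # top edge -> row 1
               c(-0.01, 2), c(2, 4.5))  # outside
  cells <- pointsToCells(lay, pts)
  expect_equal(cells[1, ], c(row = 1L, col = 1L))
  expect_equal(cells[2, ], c(row = 1L, col = 1L))
  expect_equal(cells[3, ], c(row = 2L, col = 2L))
  expect_equal(cells[4, ], c(row = 4L, col = 4L))
  expect_equal(cells[5, ], c(row = 1L, col = 3L))
  expect_true(all(is.na(cells[6:7, ])))
  # centres map back to their own cells
  ctr <- cellCenters(lay, cbind(2, 3))
  expect_equal(pointsToCells(lay, ctr), cbind(row = 2L, col = 3L))
})

test_that("clipping drops outside points with a message", {
  lay <- RasterLayout(3, 3)
  occ <- OccurrenceSet("sp", rbind(c(0.5, 0.5), c(5, 5)))
  expect_message(cl <- clipToGrid(occ, lay), "1 point")
  expect_equal(length(cl), 1)
})

test_that("land cover, habitat table and ecoregions round-trip", {
  stack <- genEnvStack(5, nLayers = 2, nRows = 8, nCols = 8)
  lc <- genLandCover(stack, 9, nClasses = 3, patchScale = 2, subcellRatio = 2)
  p <- withr::local_tempfile(fileext = ".asc")
  writeLandCover(lc, p)
  back <- readLandCover(p)
  expect_identical(gridValues(back), gridValues(lc))
  expect_identical(back@legend, lc@legend)

  hp <- withr::local_tempfile(fileext = ".csv")
  writeHabitatTable(HabitatTable(list(a = c(1L, 2L), b = 3L)), hp)
  hab <- readHabitatTable(hp, legend = lc@legend)
  expect_equal(hab@table$a, c(1L, 2L))
  expect_error(readHabitatTable(hp, legend = lc@legend[1:2]),
               "unknown land-cover codes")

  gp <- withr::local_tempfile(fileext = ".geojson")
  regions <- genEcoregions(gridLayout(stack), 4)
  writeEcoregions(regions, gp)
  back2 <- readEcoregions(gp)
  expect_equal(length(back2), 4)
  expect_equal(back2[[2]]$name, regions[[2]]$name)
  expect_equal(back2[[3]]$rings[[1]], regions[[3]]$rings[[1]])
})

test_that("suitability and binary model files round-trip with metadata", {
  stack <- genEnvStack(6, nLayers = 2, nRows = 6, nCols = 6)
  occ <- occEverywhere(stack)
  suit <- envelopePredict(stack, occ)
  p <- withr::local_tempfile(fileext = ".asc")
  writeSuitability(suit, p)
  back <- readSuitability(p)
  expect_identical(gridValues(back), gridValues(suit))
  expect_equal(back@engine, "envelope")

  pdm <- binarize(suit, 40, "kappa")
  bp <- withr::local_tempfile(fileext = ".asc")
  writeBinaryModel(pdm, bp)
  bb <- readBinaryModel(bp)
  expect_identical(gridValues(bb), gridValues(pdm))
  expect_equal(bb@thresholdUsed, 40)
  expect_equal(bb@thresholdRule, "kappa")
})
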