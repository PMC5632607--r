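# Shared fixtures and independent brute-force oracles. Oracles are written
# as direct, loop-based computations so they stay independent of the
# package's vectorised implementations.

# Small deterministic two-layer stack with orthogonal gradients, layers
# standardized to population mean 0 / sd 1.
handStack <- function(n = 10) {
  std <- function(m) (m - mean(m)) / sqrt(mean((m - mean(m))^2))
  l1 <- std(matrix(rep(seq_len(n), each = n), n, n, byrow = FALSE) +
              0.13 * sin(seq_len(n * n)))       # column gradient + wiggle
  l2 <- std(matrix(rep(seq_len(n), times = n), n, n) +
              0.11 * cos(seq_len(n * n)))       # row gradient + wiggle
  EnvStack(list(l1, l2), c("gradX", "gradY"), RasterLayout(n, n))
}

# Occurrence set with one point at each given cell's centre.
occAtCells <- function(layout, cells, species = "sp", source = "museum") {
  OccurrenceSet(species, cellCenters(layout, cells), source)
}

# Occurrences at every valid cell centre of a stack.
occEverywhere <- function(stack, species = "sp") {
  idx <- which(validMask(stack))
  lay <- gridLayout(stack)
  r <- (idx - 1) %% lay@nRows + 1
  cc <- (idx - 1) %/% lay@nRows + 1
  occAtCells(lay, cbind(r, cc), species)
}

# VirtualSpecies with flat truth = 1 on every cell.
uniformVS <- function(layout, species = "flat") {
  methods::new("VirtualSpecies", species = species,
               nicheCenter = c(0, 0), nicheWidth = c(1, 1),
               truth = matrix(1, layout@nRows, layout@nCols),
               suitableClasses = 1L, layout = layout)
}

# Hand-built binary model from a 0/1/NA matrix.
binModel <- function(grid, layout = RasterLayout(nrow(grid), ncol(grid)),
                     species = "sp", kind = "PDM", threshold = 50,
                     rule = "external") {
  admodel:::BinaryModel(species, kind, grid, threshold, rule, layout)
}

# Hand-built continuous suitability model from a score matrix.
suitModel <- function(grid, layout = RasterLayout(nrow(grid), ncol(grid)),
                      species = "sp", engine = "external") {
  admodel:::SuitabilityModel(species, engine, grid, "continuous_0_100",
                             !is.na(grid), layout)
}

## ---- independent oracles -------------------------------------------------

# Confusion-matrix statistics computed directly from the 2x2 table.
oracleKappa <- function(tp, fp, fn, tn) {
  n <- tp + fp + fn + tn
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  (po - pe) / (1 - pe)
}

# Mann-Whitney AUC: probability a random presence outscores a random
# pseudoabsence, ties counted 1/2.
oracleAucMW <- function(presScores, absScores) {
  tot <- 0
  for (p in presScores) for (a in absScores)
    tot <- tot + (p > a) + 0.5 * (p == a)
  tot / (length(presScores) * length(absScores))
}

# Brute-force ENFA suitability: O(cells x presences x factors) counting of
# as-or-more-extreme presence deviations (deviations rounded at 1e-9, the
# scoring rule's tie convention).
oracleEnfaSuit <- function(model, stack) {
  V <- length(layerNames(model))
  msk <- validMask(stack)
  Z <- sapply(seq_len(V), function(k) envLayer(stack, k)[msk])
  Z <- sweep(sweep(Z, 2, model@globalMean), 2, model@globalSd, "/")
  scores <- Z %*% model@factors
  w <- abs(model@eigenvalues[model@retained])
  out <- numeric(nrow(Z))
  for (x in seq_len(nrow(Z))) {
    acc <- 0
    for (j in seq_along(model@retained)) {
      k <- model@retained[j]
      devX <- round(abs(scores[x, k] - model@factorMedians[k]), 9)
      cnt <- 0L
      for (p in seq_len(model@nPresence))
        if (round(abs(model@presenceScores[p, k] - model@factorMedians[k]), 9)
            >= devX)
          cnt <- cnt + 1L
      acc <- acc + w[j] * cnt / model@nPresence
    }
    out[x] <- 100 * acc / sum(w)
  }
  out
}

# Brute-force percentile-envelope score per valid cell.
oracleEnvelope <- function(stack, presCells) {
  V <- length(layerNames(stack))
  msk <- validMask(stack)
  idx <- which(msk)
  out <- numeric(length(idx))
  for (ii in seq_along(idx)) {
    sc <- Inf
    for (k in seq_len(V)) {
      lay <- envLayer(stack, k)
      pv <- lay[presCells]
      v <- lay[idx[ii]]
      f <- (sum(pv < v) + 0.5 * sum(pv == v)) / length(pv)  # mid-CDF
      sc <- min(sc, 2 * min(f, 1 - f))
    }
    out[ii] <- 100 * max(sc, 0)
  }
  out
}

# Ray-casting point-in-polygon with even-odd rule over a region's rings.
oraclePointInRegion <- function(region, x, y) {
  inside <- FALSE
  for (ring in region$rings) {
    n <- nrow(ring)
    j <- n
    for (i in seq_len(n)) {
      xi <- ring[i, 1]; yi <- ring[i, 2]
      xj <- ring[j, 1]; yj <- ring[j, 2]
      if ((yi > y) != (yj > y) &&
          x < (xj - xi) * (y - yi) / (yj - yi) + xi)
        inside <- !inside
      j <- i
    }
  }
  inside
}

# Exact two-sided Wilcoxon signed-rank p by full 2^n enumeration (midranks).
oracleWilcoxonExact <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  n <- length(d)
  W <- min(sum(r[d > 0]), sum(r[d < 0]))
  tot <- sum(r)
  hits <- 0L
  for (mask in 0:(2^n - 1)) {
    wp <- sum(r[bitwAnd(bitwShiftR(mask, seq_len(n) - 1L), 1L) == 1L])
    if (min(wp, tot - wp) <= W + 1e-9) hits <- hits + 1L
  }
  hits / 2^n
}

# Subcell suitable fraction per model cell by explicit loops.
oracleSubcellFraction <- function(lc, layout, classes) {
  k <- layout@cellSize / gridLayout(lc)@cellSize
  out <- matrix(0, layout@nRows, layout@nCols)
  cg <- gridValues(lc)
  for (r in seq_len(layout@nRows)) for (cc in seq_len(layout@nCols)) {
    sub <- cg[((r - 1) * k + 1):(r * k), ((cc - 1) * k + 1):(cc * k)]
    out[r, cc] <- sum(!is.na(sub) & sub %in% classes) / k^2
  }
  out
}
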