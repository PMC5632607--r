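# Ecological Niche Factor Analysis: marginality, specialization
# eigen-analysis, global Marginality and Tolerance indices, suitability
# scoring and variable importance.

#' Fit an ENFA model
#'
#' Contrasts the species' environmental space (the distinct presence cells;
#' duplicate records in a cell carry no extra environmental information and
#' are collapsed) against the global environmental space (all valid cells).
#' Layers are standardized to global mean 0, sd 1 at fit time. The
#' marginality vector is the per-layer mean of the standardized presence
#' sample; the global marginality index is \eqn{M = \lVert m\rVert / 1.96}
#' (the ENFA convention, so \eqn{M \approx 1} means a two-sd shift). The
#' first factor is the marginality axis \eqn{u_1 = m/\lVert m\rVert};
#' specialization axes solve the symmetric whitened form of the generalized
#' eigenproblem on (global covariance, presence covariance) restricted to
#' the orthocomplement of \eqn{u_1}, so the factor axes are exactly
#' orthonormal and the eigenvalues are global/presence variance ratios. The
#' global tolerance is \eqn{T = 1/\sqrt{\bar\lambda}} over all V factors.
#'
#' @param stack an [EnvStack].
#' @param occ an [OccurrenceSet] of presences; at least V + 2 distinct
#'   presence cells are required (V = number of layers).
#' @param ridge ridge added to the presence covariance diagonal when it is
#'   near singular (collinear layers are expected); applied with a warning.
#' @param retainFraction retained factors are the smallest prefix (always
#'   including the marginality axis) whose summed absolute eigenvalues reach
#'   this fraction of the total (default 0.8).
#' @return an [EnfaModel].
#' @export
enfaFit <- function(stack, occ, ridge = 1e-6, retainFraction = 0.8) {
  V <- length(stack@layerNames)
  cells <- distinctCells(stack@layout, occ)
  valid <- stack@validMask[cells]
  cells <- cells[valid, , drop = FALSE]
  if (nrow(cells) < V + 2L)
    stop("ENFA fit requires at least V + 2 = ", V + 2L,
         " distinct presence cells on valid ground; got ", nrow(cells),
         call. = FALSE)

  Zall <- sapply(seq_len(V), function(k) stack@values[, , k][stack@validMask])
  gMean <- colMeans(Zall)
  gSd <- apply(Zall, 2, popSd)  # population sd: idempotent on standardized stacks
  if (any(gSd <= 0)) stop("constant environmental layer", call. = FALSE)
  Zall <- sweep(sweep(Zall, 2, gMean), 2, gSd, "/")

  cellIdx <- match((cells[, 2] - 1L) * stack@layout@nRows + cells[, 1],
                   which(stack@validMask))
  Zp <- Zall[cellIdx, , drop = FALSE]

  m <- colMeans(Zp)
  normM <- sqrt(sum(m^2))
  M <- normM / 1.96
  Sg <- stats::cov(Zall)
  Sp <- stats::cov(Zp)
  Sp <- regularizeCov(Sp, ridge)

  if (normM > 1e-12) {
    u1 <- m / normM
  } else {
    message("zero marginality: substituting the first presence principal axis")
    u1 <- eigen(Sp, symmetric = TRUE)$vectors[, 1]
  }

  # orthonormal basis of the subspace orthogonal to u1
  B <- qr.Q(qr(cbind(u1, diag(V))))[, 2:V, drop = FALSE]
  SpB <- symm(t(B) %*% Sp %*% B)
  SgB <- symm(t(B) %*% Sg %*% B)
  ep <- eigen(SpB, symmetric = TRUE)
  if (min(ep$values) <= 0) {
    SpB <- SpB + diag(ridge, V - 1L)
    ep <- eigen(SpB, symmetric = TRUE)
    warning("near-singular presence covariance: ridge regularization applied")
  }
  W <- ep$vectors %*% diag(1 / sqrt(ep$values), V - 1L) %*% t(ep$vectors)
  es <- eigen(symm(W %*% SgB %*% W), symmetric = TRUE)
  specLambda <- pmax(es$values, 0)
  ord <- order(specLambda, decreasing = TRUE)
  axes <- B %*% es$vectors[, ord, drop = FALSE]
  lambda1 <- as.numeric((t(u1) %*% Sg %*% u1) / (t(u1) %*% Sp %*% u1))

  factors <- cbind(u1, axes)
  colnames(factors) <- c("marginality", sprintf("spec%02d", seq_len(V - 1L)))
  rownames(factors) <- stack@layerNames
  eigenvalues <- c(lambda1, specLambda[ord])
  tol <- 1 / sqrt(mean(eigenvalues))

  total <- sum(abs(eigenvalues))
  retained <- seq_len(which(cumsum(abs(eigenvalues)) >= retainFraction * total - 1e-12)[1])

  scores <- Zp %*% factors
  new("EnfaModel", layerNames = stack@layerNames, marginalityVector = m,
      globalMarginality = M, factors = factors, eigenvalues = eigenvalues,
      globalTolerance = tol, retained = as.integer(retained),
      presenceScores = scores, factorMedians = apply(scores, 2, stats::median),
      globalMean = gMean, globalSd = gSd, nPresence = nrow(Zp))
}

symm <- function(x) (x + t(x)) / 2

regularizeCov <- function(S, ridge) {
  ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
  if (!ok || rcond(S) < 1e-10) {
    warning("near-singular presence covariance: ridge regularization applied")
    S <- S + diag(ridge, nrow(S))
  }
  S
}

#' Score habitat suitability from a fitted ENFA model
#'
#' Median-count ("as-or-more-extreme") scoring: for each valid cell x and
#' retained factor k, \eqn{HS_k(x)} is the fraction of presence cells whose
#' factor-k score deviates from the presence median at least as much (in
#' absolute value, both sides pooled) as x's does; the cell score is the
#' eigenvalue-weighted average \eqn{100\,\sum_k |\lambda_k| HS_k / \sum_k
#' |\lambda_k|} over the retained factors, the marginality axis included.
#' A cell at the presence median on every factor scores 100.
#'
#' @param model a fitted [EnfaModel].
#' @param stack the [EnvStack] the model was fitted on (same layers).
#' @param species species tag recorded on the output.
#' @return a continuous 0--100 [SuitabilityModel] with engine \code{"enfa"}.
#' @export
enfaSuitability <- function(model, stack, species = "species") {
  if (!identical(model@layerNames, stack@layerNames))
    stop("model was fitted on a different layer set", call. = FALSE)
  V <- length(model@layerNames)
  Z <- sapply(seq_len(V), function(k) stack@values[, , k][stack@validMask])
  Z <- sweep(sweep(Z, 2, model@globalMean), 2, model@globalSd, "/")
  w <- abs(model@eigenvalues[model@retained])
  N <- model@nPresence
  hs <- numeric(nrow(Z))
  for (j in seq_along(model@retained)) {
    k <- model@retained[j]
    # deviations rounded at 1e-9 (standardized-score units) so tie handling
    # is stable under serialization round trips and reordered arithmetic
    devP <- sort(round(abs(model@presenceScores[, k] - model@factorMedians[k]), 9))
    devX <- round(abs(as.vector(Z %*% model@factors[, k]) - model@factorMedians[k]), 9)
    cnt <- N - findInterval(devX, devP, left.open = TRUE)  # presences >= devX
    hs <- hs + w[j] * cnt / N
  }
  hs <- 100 * hs / sum(w)
  grid <- matrix(NA_real_, stack@layout@nRows, stack@layout@nCols)
  grid[stack@validMask] <- pmin(pmax(hs, 0), 100)
  SuitabilityModel(species, "enfa", grid, "continuous_0_100",
                   stack@validMask, stack@layout)
}

#' Per-layer marginality and specialization importance scores
#'
#' The marginality score of a layer is the absolute value of its entry in
#' the marginality vector; the specialization score is
#' \eqn{\sum_k |\lambda_k| |loading_{k,i}|} over the non-marginality factors.
#'
#' @param model a fitted [EnfaModel].
#' @return data.frame with columns layer, marginality, specialization and
#'   the two rank columns (1 = most important).
#' @export
variableImportance <- function(model) {
  marg <- abs(model@marginalityVector)
  V <- length(model@layerNames)
  specAxes <- seq_len(V)[-1]
  spec <- as.vector(abs(model@factors[, specAxes, drop = FALSE]) %*%
                      abs(model@eigenvalues[specAxes]))
  data.frame(layer = model@layerNames, marginality = marg,
             specialization = spec,
             marginalityRank = rank(-marg, ties.method = "min"),
             specializationRank = rank(-spec, ties.method = "min"),
             row.names = NULL)
}
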