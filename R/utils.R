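# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

assertCount <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min)
    stop(sprintf("`%s` must be a single integer >= %s", name, min), call. = FALSE)
  as.integer(x)
}

assertNumber <- function(x, name, min = -Inf, max = Inf, strictMin = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (strictMin && x <= min) || (!strictMin && x < min) || x > max)
    stop(sprintf("`%s` must be a single number in [%s, %s]%s", name, min, max,
                 if (strictMin) " (exclusive lower bound)" else ""),
         call. = FALSE)
  as.numeric(x)
}

# Row-stochastic Gaussian band matrix; smoothField(M, sigma) = G_r M t(G_c).
# Kernel truncated at 3*sigma and renormalised near the edges, so the smoothed
# field has no wrap-around artefacts.
gaussBand <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  idx <- seq_len(n)
  W <- exp(-outer(idx, idx, "-")^2 / (2 * sigma^2))
  W[abs(outer(idx, idx, "-")) > ceiling(3 * sigma)] <- 0
  W / rowSums(W)
}

smoothField <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  gaussBand(nrow(mat), sigma) %*% mat %*% t(gaussBand(ncol(mat), sigma))
}

# Population (n-denominator) standard deviation.
popSd <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}
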