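#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx convolve cor dist fft kruskal.test ks.test
#'   median pnorm rnorm runif sd setNames var wilcox.test
#' @importFrom utils head tail
#' @importFrom mclust Mclust mclustBIC
NULL

# Run expr with a local RNG state seeded at `seed`; the caller's RNG
# stream is untouched.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

#' Derive a child seed from a master seed and a tag
#'
#' Every stochastic stage of the pipeline draws its own seed
#' deterministically from the master seed and a stage tag, so that
#' re-running one stage cannot perturb another.
#'
#' @param master integer master seed.
#' @param tag character tag naming the consumer.
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(master, tag) {
  stopifnot(is.numeric(master), length(master) == 1, is.character(tag))
  m <- 2147483647  # 2^31 - 1 (prime)
  h <- as.numeric(master) %% m
  for (k in utf8ToInt(tag)) h <- (h * 69069 + k) %% m
  as.integer(h %% (m - 2) + 1)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# Two-sided Wilcoxon rank-sum tests of each column of `X` (n1 x n_bins)
# against a common pooled sample `pool`, using the normal approximation
# with tie correction and no continuity correction.  The pooled null
# sample is shared across bins, so it is sorted once and per-column
# ranks are obtained by binary search; columns containing ties are
# recomputed exactly from the combined rank table.
ranksum_cols <- function(X, pool) {
  X <- as.matrix(X)
  n1 <- nrow(X)
  nb <- ncol(X)
  n2 <- length(pool)
  if (n1 < 2L) stopf("rank-sum test needs at least 2 observations per bin, got %d", n1)
  if (n2 < 1L) stopf("empty baseline pool")
  N <- n1 + n2
  sp <- sort(pool)
  cnt_le <- matrix(findInterval(X, sp), n1, nb)
  cnt_lt <- matrix(findInterval(X, sp, left.open = TRUE), n1, nb)
  eq <- cnt_le - cnt_lt
  # within-column midranks of X itself
  rX <- apply(X, 2L, rank)
  if (is.null(dim(rX))) rX <- matrix(rX, n1, nb)
  mid <- cnt_lt + eq / 2 + rX
  W <- colSums(mid)
  # tie-correction term sum(t^3 - t); the pool contribution is shared
  tpool <- table(pool)
  tie <- rep(sum(tpool^3 - tpool), nb)
  needs_exact <- which(colSums(eq) > 0 | apply(X, 2L, anyDuplicated) > 0)
  for (j in needs_exact) {
    tt <- table(c(X[, j], pool))
    tie[j] <- sum(tt^3 - tt)
  }
  mu <- n1 * (N + 1) / 2
  sig2 <- n1 * n2 / 12 * ((N + 1) - tie / (N * (N - 1)))
  z <- ifelse(sig2 > 0, (W - mu) / sqrt(sig2), 0)
  p <- 2 * pnorm(-abs(z))
  list(statistic = W, z = z, p = p)
}

# Pearson correlation that returns NA (with a reason attribute) rather
# than erroring on degenerate inputs.
safe_cor <- function(x, y) {
  if (length(x) != length(y)) stopf("length mismatch in correlation")
  if (sd(x) == 0 || sd(y) == 0) {
    out <- NA_real_
    attr(out, "reason") <- "zero-variance input"
    return(out)
  }
  cor(x, y)
}

cosine <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stopf("cosine similarity undefined for zero-norm vector")
  sum(a * b) / (na * nb)
}

# log2-spaced band centers
log2_bands <- function(n_bands, lo_hz, hi_hz) {
  stopifnot(n_bands >= 2, lo_hz > 0, lo_hz < hi_hz)
  2^seq(log2(lo_hz), log2(hi_hz), length.out = n_bands)
}

bands_per_octave <- function(band_centers_hz) {
  l <- log2(band_centers_hz)
  d <- diff(l)
  if (any(abs(d - d[1]) > 1e-8 * abs(d[1]))) {
    stopf("band axis is not uniform in log2(Hz)")
  }
  1 / d[1]
}
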