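test_that("fast MTF equals the direct double-sum DFT on small matrices", {
  set.seed(21)
  delays <- seq(0, 150, 10)            # 16 delays
  ba <- tiny_bands(16, 200, 6400)
  for (i in 1:3) {
    W <- matrix(rnorm(16 * 16), 16, 16)
    m <- mtf(W, delays, ba)
    ref <- dft2_direct(W)
    expect_lt(max(abs(m$magnitude_full - ref)), 1e-10)
  }
})

test_that("MTF conventions: symmetry, Parseval, zero map, planted peak", {
  delays <- seq(0, 400, 10)
  ba <- tiny_bands(32, 180, 7000)
  W <- make_gabor_strf(gabor_strf_params(1000, 200, 4, 0.5, bandwidth_oct = 1.5,
                                         duration_ms = 300), delays, ba)
  m <- mtf(W, delays, ba)
  # point symmetry of the raw magnitude for real inputs
  M <- m$magnitude_full
  nd <- nrow(M); nb <- ncol(M)
  flip <- function(i, n) c(1, rev(seq_len(n - 1) + 1))[i]
  for (i in c(2, 5, 17)) for (j in c(2, 9)) {
    expect_equal(M[i, j], M[flip(i, nd), flip(j, nb)], tolerance = 1e-12)
  }
  # Parseval with the documented (unnormalized) convention
  expect_equal(sum(M^2), nd * nb * sum(W^2), tolerance = 1e-10)
  # planted (4 Hz, 0.5 c/o) lands within one bin, symmetric in sign
  ix <- which(m$magnitude == max(m$magnitude), arr.ind = TRUE)[1, ]
  dt <- diff(sort(unique(m$omega_t_hz)))[1]
  ds <- diff(m$omega_s_cpo)[1]
  expect_lte(abs(abs(m$omega_t_hz[ix[1]]) - 4), dt + 1e-9)
  expect_lte(abs(m$omega_s_cpo[ix[2]] - 0.5), ds + 1e-9)
  expect_true(all(m$omega_s_cpo >= 0))
  # zero STRF maps to zero MTF
  expect_true(all(mtf(matrix(0, 41, 32), delays, ba)$magnitude == 0))
})

test_that("modulation marginals are unit-norm and peak at planted rates", {
  delays <- seq(0, 400, 10)
  ba <- tiny_bands(32, 180, 7000)
  W <- make_gabor_strf(gabor_strf_params(1000, 200, 4, 0.5, bandwidth_oct = 1.5,
                                         duration_ms = 300), delays, ba)
  mm <- modulation_marginals(mtf(W, delays, ba))
  expect_equal(sum(mm$temporal^2), 1, tolerance = 1e-12)
  expect_equal(sum(mm$spectral^2), 1, tolerance = 1e-12)
  expect_lte(abs(as.numeric(names(mm$temporal)[which.max(mm$temporal)]) - 4), 2.5)
  expect_lte(abs(as.numeric(names(mm$spectral)[which.max(mm$spectral)]) - 0.5), 0.2)
  z <- modulation_marginals(mtf(matrix(0, 10, 8), seq(0, 90, 10), tiny_bands(8)))
  expect_true(is.na(z))
  expect_match(attr(z, "reason"), "zero")
})

test_that("tuning summary finds best frequency with documented conventions", {
  delays <- seq(0, 400, 10)
  ba <- tiny_bands(32, 180, 7000)
  W <- make_gabor_strf(gabor_strf_params(1000, 150, 2, 0.3), delays, ba)
  ts <- tuning_summary(W, ba)
  bf_band <- which.min(abs(ba - 1000))
  expect_lte(abs(which.min(abs(ba - ts$best_frequency_hz)) - bf_band), 1)
  expect_false(ts$inhibitory_dominant)
  expect_equal(sum(ts$spectral^2), 1, tolerance = 1e-12)
  expect_equal(sum(ts$temporal^2), 1, tolerance = 1e-12)
  # purely inhibitory STRF: flagged, BF from |weights|
  tneg <- tuning_summary(-abs(W), ba)
  expect_true(tneg$inhibitory_dominant)
  expect_equal(tneg$best_frequency_hz, ts$best_frequency_hz)
  # tie across two bands resolves to the lower frequency
  Wt <- matrix(0, 5, 4)
  Wt[2, 2] <- 1; Wt[2, 4] <- 1
  expect_equal(tuning_summary(Wt, tiny_bands(4))$best_frequency_hz,
               tiny_bands(4)[2])
  z <- tuning_summary(matrix(0, 5, 4), tiny_bands(4))
  expect_true(is.na(z))
})

test_that("ensemble MTF averages element-wise on a shared grid", {
  delays <- seq(0, 200, 10)
  ba <- tiny_bands(16, 200, 6400)
  m1 <- mtf(make_gabor_strf(gabor_strf_params(500, 80, 2, 0.2), delays, ba), delays, ba)
  m2 <- mtf(make_gabor_strf(gabor_strf_params(2000, 120, 8, 0.6), delays, ba), delays, ba)
  expect_equal(ensemble_mtf(list(m1))$magnitude, m1$magnitude)
  expect_equal(ensemble_mtf(list(m1, m1))$magnitude, m1$magnitude)
  # a two-peak population keeps both peaks
  em <- ensemble_mtf(list(m1, m2))
  pk <- function(m) which(m$magnitude == max(m$magnitude), arr.ind = TRUE)[1, ]
  p1 <- pk(m1); p2 <- pk(m2)
  med <- median(em$magnitude)
  expect_gt(em$magnitude[p1[1], p1[2]], 3 * med)
  expect_gt(em$magnitude[p2[1], p2[2]], 3 * med)
  short <- mtf(make_gabor_strf(gabor_strf_params(500, 80), seq(0, 100, 10), ba),
               seq(0, 100, 10), ba)
  expect_error(ensemble_mtf(list(m1, short)), "grids differ")
})

test_that("cosine permutation test separates planted differences only", {
  set.seed(22)
  A <- matrix(rnorm(10 * 16, sd = 0.05), 10, 16)
  A <- sweep(A, 2, c(rep(1, 8), rep(0, 8)), "+")
  # copied group: observed similarity 1, large p
  same <- cosine_perm_test(A, A, n_perm = 500, seed = 3)
  expect_equal(same$observed, 1)
  expect_gte(same$p, 0.5)
  # orthogonal means with low noise: minimal attainable p
  B <- matrix(rnorm(10 * 16, sd = 0.05), 10, 16)
  B <- sweep(B, 2, c(rep(0, 8), rep(1, 8)), "+")
  diffr <- cosine_perm_test(A, B, n_perm = 500, seed = 3)
  expect_lte(diffr$p, 1 / 501 + 1e-9)
  # deterministic under seed
  expect_identical(cosine_perm_test(A, B, 200, seed = 9),
                   cosine_perm_test(A, B, 200, seed = 9))
  expect_error(cosine_perm_test(A[1, , drop = FALSE], B), ">= 2")
})

test_that("best-frequency Kruskal-Wallis behaves at both extremes", {
  set.seed(23)
  # one group two octaves up: decisive rejection
  g <- rep(c("a", "b"), each = 30)
  v <- c(2^rnorm(30, 9), 2^rnorm(30, 11))
  expect_lt(kruskal_bf(v, g)$p, 0.001)
  # identical single-value groups: H = 0
  expect_equal(kruskal_bf(c(5, 5), c("a", "b"))$H, 0)
  expect_error(kruskal_bf(c(1, 2), factor(c("a", "a"), levels = c("a", "b"))),
               "empty|2 groups")
})
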