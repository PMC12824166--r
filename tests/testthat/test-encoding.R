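test_that("cochlear front-end is tonotopic, silent on silence, flat on noise", {
  fs <- 16000
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  tone <- 0.5 * sin(2 * pi * 1000 * t)
  sp <- cochlear_spectrogram(tone, fs, n_bands = 32)
  prof <- rowMeans(sp$values[, 20:180])
  expect_equal(which.max(prof), which.min(abs(sp$band_centers_hz - 1000)))
  # silence maps to all-zero frames
  sp0 <- cochlear_spectrogram(numeric(fs), fs, n_bands = 16)
  expect_true(all(sp0$values == 0))
  # white noise: compressed band energies within 6 dB of flat
  set.seed(13)
  wn <- rnorm(10 * fs)
  wn <- 0.9 * wn / max(abs(wn))
  spn <- cochlear_spectrogram(wn, fs, n_bands = 32)
  e <- 20 * log10(rowMeans(spn$values))
  expect_lte(max(e) - min(e), 6)
  expect_error(cochlear_spectrogram(c(0.1, NaN), fs), "NaN")
  expect_error(cochlear_spectrogram(c(0.1, 1.5), fs), "clipped")
})

test_that("lagged design matrix lays out history correctly", {
  ba <- tiny_bands(3, 200, 800)
  S <- matrix(seq_len(3 * 6), 3, 6)
  sp <- spectrogram(S, ba, 100)
  # L = 0: the design is the transposed stimulus
  D0 <- build_lagged_design(sp, 0)
  expect_equal(unclass(D0)[, ], t(S), ignore_attr = TRUE)
  # column count = n_bands x n_lags
  D <- build_lagged_design(sp, seq(0, 30, 10))
  expect_equal(ncol(D), 3 * 4)
  # impulse at frame k appears on a moving diagonal across lag blocks
  I <- matrix(0, 1, 10); I[1, 4] <- 1
  Di <- build_lagged_design(spectrogram(I, 440, 100), seq(0, 30, 10))
  for (l in 0:3) expect_equal(which(Di[, l + 1] == 1), 4 + l)
  # zero padding before stimulus start
  expect_true(all(Di[1:3, 2:4] == 0))
  expect_error(build_lagged_design(sp, c(0, 15)), "multiple")
})

test_that("NRC with vanishing tolerance matches explicit least squares", {
  set.seed(14)
  ba <- tiny_bands(3, 200, 800)
  vals <- matrix(abs(rnorm(3 * 200)), 3, 200)
  sp <- spectrogram(vals, ba, 100)
  y <- simulate_highgamma(matrix(rnorm(15), 5, 3), sp, 15, seed = 9)$block$traces[1, ]
  D <- build_lagged_design(sp, seq(0, 40, 10))
  m <- fit_nrc(D, y, tolerance_grid = 1e-12, cv_folds = 2, seed = 3)
  est <- m$split$est
  Dc <- scale(D[est, ], scale = FALSE)
  yc <- y[est] - mean(y[est])
  w_ols <- solve(crossprod(Dc), crossprod(Dc, yc))
  rel_err <- max(abs(as.vector(t(m$weights)) - w_ols)) / max(abs(w_ols))
  expect_lt(rel_err, 1e-6)
})

test_that("noiseless synthetic responses are fully identifiable", {
  stim <- tiny_stimulus(seed = 15, n_sentences = 3, n_repeats = 2, n_bands = 8)
  ba <- stim$spec$band_centers_hz
  W <- make_gabor_strf(gabor_strf_params(800, 80, 3, 0.4), seq(0, 200, 10), ba)
  y <- simulate_highgamma(W, stim, snr_db = Inf, seed = 1)$block$traces[1, ]
  D <- build_lagged_design(stim, seq(0, 200, 10))
  m <- fit_nrc(D, y, seed = 5, groups = stim_groups(stim))
  expect_gte(cosine_sim(m$weights, W), 0.99)
  expect_gte(m$test_r, 0.99)
  # prediction on the same stimulus is essentially perfect
  pr <- predict(m, stim$spec, response = y)
  expect_gte(pr$r, 0.999)
})

test_that("regularization is monotone in retained rank and weight norm", {
  stim <- tiny_stimulus(seed = 16, n_sentences = 2, n_repeats = 2, n_bands = 8)
  y <- simulate_highgamma(matrix(rnorm(8 * 8), 8, 8), stim, 5, seed = 2)$block$traces[1, ]
  D <- build_lagged_design(stim, seq(0, 70, 10))
  tols <- c(0.5, 0.1, 0.01, 0.001, 1e-6)
  fits <- lapply(tols, function(tl) fit_nrc(D, y, tolerance_grid = tl,
                                            cv_folds = 2, seed = 4))
  norms <- vapply(fits, function(m) sqrt(sum(m$weights^2)), numeric(1))
  expect_true(all(diff(norms) >= -1e-10))   # norm grows as tolerance shrinks
})

test_that("held-out frames never influence estimation", {
  stim <- tiny_stimulus(seed = 17, n_sentences = 3, n_repeats = 2, n_bands = 6)
  y <- simulate_highgamma(matrix(rnorm(5 * 6), 5, 6), stim, 10, seed = 3)$block$traces[1, ]
  D <- build_lagged_design(stim, seq(0, 40, 10))
  g <- stim_groups(stim)
  m1 <- fit_nrc(D, y, seed = 6, groups = g)
  y_poisoned <- y
  y_poisoned[m1$split$test] <- 1e6 * rnorm(length(m1$split$test))
  m2 <- fit_nrc(D, y_poisoned, seed = 6, groups = g)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$tolerance, m2$tolerance)
})

test_that("degenerate fits are rejected with clear errors", {
  stim <- tiny_stimulus(seed = 18, n_sentences = 2, n_repeats = 2, n_bands = 4)
  D <- build_lagged_design(stim, seq(0, 30, 10))
  expect_error(fit_nrc(D, rep(1, nrow(D))), "constant")
  expect_error(fit_nrc(D, rnorm(nrow(D)), tolerance_grid = numeric(0)), "empty")
  # zero-weight model reports an undefined prediction r with a reason
  m <- fit_nrc(D, rnorm(nrow(D)), tolerance_grid = 0.5, cv_folds = 2, seed = 1)
  m$weights[] <- 0
  pr <- predict(m, stim$spec, response = rnorm(ncol(stim$spec$values)))
  expect_true(is.na(pr$r))
  expect_match(attr(pr$r, "reason"), "zero")
})

test_that("semantic design assigns word vectors to frames", {
  E <- synth_embeddings(5, 8, seed = 19)
  words <- data.frame(word_type = c(2, 4), onset_s = c(0.1, 0.3),
                      offset_s = c(0.3, 0.5))
  M <- semantic_design(words, E, n_frames = 60, frame_rate = 100)
  expect_equal(dim(M), c(8, 60))
  expect_equal(M[, 15], unname(E["2", ]))
  expect_equal(M[, 1], rep(0, 8))          # silence frame
  expect_equal(M[, 55], rep(0, 8))
  # abutting words: each frame carries exactly one vector
  expect_equal(M[, 30], unname(E["2", ]))
  expect_equal(M[, 31], unname(E["4", ]))
  expect_error(semantic_design(data.frame(word_type = 99, onset_s = 0,
                                          offset_s = 0.1), E, 60), "99")
  ow <- data.frame(word_type = c(1, 2), onset_s = c(0, 0.05), offset_s = c(0.1, 0.2))
  expect_error(semantic_design(ow, E, 60), "overlap")
})

test_that("model-class comparison reports direction and p by latency group", {
  set.seed(20)
  res <- data.frame(strf_r = c(rnorm(20, 0.8, 0.05), rnorm(10, 0.2, 0.05)),
                    semantic_r = c(rnorm(20, 0.2, 0.05), rnorm(10, 0.2, 0.05)),
                    latency_ms = c(rep(100, 20), rep(400, 10)))
  out <- compare_models(res)
  short <- out[out$latency_group == "short", ]
  expect_equal(short$direction, "strf")
  expect_lt(short$p, 0.01)
  # identical r vectors: no effect
  same <- data.frame(strf_r = rnorm(20, 0.5, 0.1), latency_ms = rep(100, 20))
  same$semantic_r <- same$strf_r
  outs <- suppressWarnings(compare_models(same))
  expect_gt(outs$p[1], 0.05)
  expect_warning(compare_models(same), "empty")
})
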