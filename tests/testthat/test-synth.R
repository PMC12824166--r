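test_that("Gabor STRF generator honors its analytic structure", {
  ba <- tiny_bands(32, 180, 7000)
  delays <- seq(0, 400, by = 10)
  # zero modulation, phase 0: an all-positive blob at (peak delay, BF)
  p0 <- gabor_strf_params(1000, 200, temporal_mod_hz = 0, spectral_mod_cpo = 0,
                          duration_ms = 200)
  W0 <- make_gabor_strf(p0, delays, ba)
  expect_true(all(W0 >= 0))
  pk <- which(W0 == max(W0), arr.ind = TRUE)
  expect_equal(delays[pk[1]], 200)
  expect_equal(ba[pk[2]], ba[which.min(abs(ba - 1000))])
  # zero amplitude: all-zero matrix
  pz <- gabor_strf_params(1000, 200, amplitude = 0)
  expect_true(all(make_gabor_strf(pz, delays, ba) == 0))
  # unit L2 norm scaled by amplitude
  pa <- gabor_strf_params(800, 150, 4, 0.5, amplitude = 2.5)
  expect_equal(sqrt(sum(make_gabor_strf(pa, delays, ba)^2)), 2.5)
  # planted (4 Hz, 0.5 c/o): |2D FFT| argmax within one bin of truth
  pg <- gabor_strf_params(1000, 200, 4, 0.5, bandwidth_oct = 1.5,
                          duration_ms = 300)
  Wg <- make_gabor_strf(pg, delays, ba)
  M <- Mod(fft(Wg))
  nd <- nrow(Wg); nb <- ncol(Wg)
  ft <- speechenc:::dft_freqs(nd, 1000 / 10)
  fs <- speechenc:::dft_freqs(nb, speechenc:::bands_per_octave(ba))
  ix <- which(M == max(M), arr.ind = TRUE)[1, ]
  expect_lte(abs(abs(ft[ix[1]]) - 4), 1000 / 10 / nd + 1e-9)
  expect_lte(abs(abs(fs[ix[2]]) - 0.5), speechenc:::bands_per_octave(ba) / nb + 1e-9)
})

test_that("Gabor generator rejects modulation rates beyond the axis Nyquist", {
  ba <- tiny_bands(8, 250, 4000)   # 1.75 bands/octave
  delays <- seq(0, 200, by = 20)   # 50 Hz sampling over delays
  expect_error(make_gabor_strf(gabor_strf_params(1000, 100, temporal_mod_hz = 30),
                               delays, ba), "Nyquist")
  expect_error(make_gabor_strf(gabor_strf_params(1000, 100, spectral_mod_cpo = 2),
                               delays, ba), "Nyquist")
})

test_that("synthetic spectrogram obeys the presentation protocol", {
  cfg <- synth_config(seed = 3, n_sentences = 10, sentence_dur_s = 3,
                      gap_s = 1, n_repeats = 1, n_bands = 16)
  stim <- synth_spectrogram(cfg)
  # 10 presentations x (3 s + 1 s) x 100 frames/s
  expect_equal(ncol(stim$spec$values), 4000)
  # silent gaps are exactly zero
  fr <- cfg$frame_rate_hz
  in_sentence <- rep(FALSE, 4000)
  for (k in seq_len(nrow(stim$events))) {
    in_sentence[(stim$events$onset_s[k] * fr + 1):(stim$events$offset_s[k] * fr)] <- TRUE
  }
  expect_true(all(colSums(stim$spec$values[, !in_sentence, drop = FALSE]) == 0))
  expect_true(all(colSums(stim$spec$values[, in_sentence, drop = FALSE]) > 0))
  # event and word times are exact frame multiples
  expect_true(all(abs(stim$events$onset_s * fr - round(stim$events$onset_s * fr)) < 1e-9))
  expect_true(all(abs(stim$words$onset_s * fr - round(stim$words$onset_s * fr)) < 1e-9))
  # words lie inside their presentation and do not overlap
  for (k in unique(stim$words$presentation)) {
    w <- stim$words[stim$words$presentation == k, ]
    ev <- stim$events[k, ]
    expect_true(all(w$onset_s >= ev$onset_s & w$offset_s <= ev$offset_s))
    expect_true(all(diff(w$onset_s) >= 0))
    if (nrow(w) > 1) expect_true(all(w$onset_s[-1] >= w$offset_s[-nrow(w)] - 1e-12))
  }
  # repeated presentations of a sentence share identical content
  cfg2 <- synth_config(seed = 3, n_sentences = 3, sentence_dur_s = 1,
                       gap_s = 1, n_repeats = 3, n_bands = 8)
  st2 <- synth_spectrogram(cfg2)
  reps <- which(st2$events$sentence == st2$events$sentence[1])
  seg <- function(k) {
    i0 <- st2$events$onset_s[k] * 100 + 1
    st2$spec$values[, i0:(i0 + 99)]
  }
  expect_identical(seg(reps[1]), seg(reps[2]))
})

test_that("generators are bit-identical under a fixed seed", {
  cfg <- synth_config(seed = 42, n_sentences = 2, sentence_dur_s = 1,
                      gap_s = 0.5, n_repeats = 2, n_bands = 8)
  expect_identical(synth_spectrogram(cfg)$spec$values,
                   synth_spectrogram(cfg)$spec$values)
  expect_identical(synth_embeddings(20, 16, seed = 7),
                   synth_embeddings(20, 16, seed = 7))
  e1 <- synth_electrodes_preset(seed = 9)
  expect_identical(e1, synth_electrodes_preset(seed = 9))
})

test_that("simulated high-gamma is the planted convolution plus scaled noise", {
  stim <- tiny_stimulus(seed = 5, n_sentences = 2, n_repeats = 1, n_bands = 6)
  ba <- stim$spec$band_centers_hz
  W <- matrix(rnorm(5 * 6), 5, 6)
  sim <- simulate_highgamma(W, stim, snr_db = Inf, seed = 1)
  # independent oracle: direct double-loop causal convolution
  S <- stim$spec$values
  nf <- ncol(S)
  ref <- numeric(nf)
  for (tt in seq_len(nf)) {
    for (d in seq_len(min(5, tt))) {
      ref[tt] <- ref[tt] + sum(W[d, ] * S[, tt - d + 1])
    }
  }
  expect_equal(sim$block$traces[1, ], ref, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(sim$noise, rep(0, nf))
  # zero STRF: pure noise trace of the stated variance is impossible to
  # scale from a zero signal, so request a pure-noise electrode instead
  simz <- simulate_highgamma(matrix(0, 5, 6), stim, snr_db = -Inf, seed = 2)
  expect_equal(simz$signal, rep(0, nf))
  expect_gt(sd(simz$noise), 0.9)
  # realized SNR within 5% of request on a long stimulus
  stim60 <- tiny_stimulus(seed = 6, n_sentences = 8, n_repeats = 2,
                          n_bands = 16, sentence_dur_s = 2.75)
  Wb <- make_gabor_strf(gabor_strf_params(1000, 120, 4, 0.5),
                        seq(0, 400, 10), stim60$spec$band_centers_hz)
  s2 <- simulate_highgamma(Wb, stim60, snr_db = 10, seed = 3)
  snr_realized <- var(s2$signal) / var(s2$noise)
  expect_lt(abs(snr_realized - 10) / 10, 0.05)
})

test_that("simulated trials respect the planted latency and baseline", {
  tmpl <- rep(2, 200)
  tt <- simulate_trials(tmpl, planted_latency_ms = 50, n_repeats = 4,
                        trial_noise_sd = 0, seed = 1)
  expect_equal(dim(tt$values), c(1, 4, 500 + 200, 1))
  # zero noise: all trials identical
  expect_identical(tt$values[1, 1, , 1], tt$values[1, 2, , 1])
  # zeros through baseline + latency, then the template
  expect_true(all(tt$values[1, 1, 1:550, 1] == 0))
  expect_true(all(tt$values[1, 1, 551:700, 1] == 2))
  # zero latency departs at the first post-onset bin
  t0 <- simulate_trials(tmpl, 0, 2, trial_noise_sd = 0, seed = 1)
  expect_equal(t0$values[1, 1, 501, 1], 2)
  expect_equal(t0$values[1, 1, 500, 1], 0)
  expect_error(simulate_trials(tmpl, 50, n_repeats = 1), "n_repeats")
})

test_that("electrode simulator plants balanced, labeled clusters", {
  tab <- synth_electrodes(rbind(c(-50, 20, 10), c(-40, 0, 40), c(-55, -5, 25)),
                          spread_mm = 2, n_per_center = 30, seed = 4)
  expect_equal(nrow(tab), 90)
  expect_equal(unname(table(tab$region)), rep(30L, 3), ignore_attr = TRUE)
  expect_true(all(tab$hemisphere == "L"))
  expect_true(all(tab$x < 0))
  expect_error(synth_electrodes(rbind(c(0, 0, 0)), spread_mm = 0), "spread_mm")
})

test_that("synthetic embeddings are unit-norm and near-orthogonal in expectation", {
  E <- synth_embeddings(100, 64, seed = 8)
  expect_equal(sqrt(rowSums(E^2)), rep(1, 100), ignore_attr = TRUE)
  # Monte-Carlo mean cosine over many random pairs is ~ 0
  set.seed(1)
  idx <- matrix(sample.int(100, 2000, replace = TRUE), ncol = 2)
  idx <- idx[idx[, 1] != idx[, 2], ]
  cs <- rowSums(E[idx[, 1], ] * E[idx[, 2], ])
  expect_lt(abs(mean(cs)), 0.02)
})
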