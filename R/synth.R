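#' Synthetic study configuration
#'
#' Bundles the stimulus-protocol constants used by the synthetic-data
#' generators: a repeated-sentence listening protocol (by default ten
#' unique sentences, each presented ten times, separated by one-second
#' silent gaps) with a log-spaced auditory band axis.
#'
#' @param seed integer seed; all generator output is bit-identical for a
#'   fixed config.
#' @param n_sentences number of unique sentences.
#' @param sentence_dur_s duration of each sentence in seconds.
#' @param gap_s silent gap between presentations in seconds (> 0).
#' @param n_repeats presentations per unique sentence (>= 1; trial-level
#'   analyses require >= 2).
#' @param frame_rate_hz spectrogram frame rate (frames/s).
#' @param n_bands,band_lo_hz,band_hi_hz band axis: `n_bands` centers
#'   log2-spaced from `band_lo_hz` to `band_hi_hz`.
#' @param snr_db signal-to-noise ratio (10*log10 variance ratio) for
#'   simulated responses.
#' @param planted_latency_ms onset latency planted in simulated trials.
#' @param embedding_dim dimension of synthetic word-embedding vectors.
#' @param n_word_types vocabulary size for the synthetic word stream.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(seed,
                         n_sentences = 10L,
                         sentence_dur_s = 3,
                         gap_s = 1,
                         n_repeats = 10L,
                         frame_rate_hz = 100,
                         n_bands = 64L,
                         band_lo_hz = 180,
                         band_hi_hz = 7000,
                         snr_db = 10,
                         planted_latency_ms = 80,
                         embedding_dim = 50L,
                         n_word_types = 200L) {
  stopifnot(length(seed) == 1, is.finite(seed))
  if (gap_s <= 0) stopf("gap_s must be > 0 (got %g)", gap_s)
  if (band_lo_hz >= band_hi_hz) stopf("band_lo_hz must be < band_hi_hz")
  if (n_repeats < 1) stopf("n_repeats must be >= 1")
  if (n_sentences < 1) stopf("n_sentences must be >= 1")
  if (sentence_dur_s <= 0) stopf("sentence_dur_s must be > 0")
  if (embedding_dim < 2) stopf("embedding_dim must be >= 2")
  cfg <- list(seed = as.integer(seed), n_sentences = as.integer(n_sentences),
              sentence_dur_s = sentence_dur_s, gap_s = gap_s,
              n_repeats = as.integer(n_repeats), frame_rate_hz = frame_rate_hz,
              n_bands = as.integer(n_bands), band_lo_hz = band_lo_hz,
              band_hi_hz = band_hi_hz, snr_db = snr_db,
              planted_latency_ms = planted_latency_ms,
              embedding_dim = as.integer(embedding_dim),
              n_word_types = as.integer(n_word_types))
  structure(cfg, class = "synth_config")
}

#' Spectrogram container
#'
#' @param values bands x frames matrix of non-negative, power-like values.
#' @param band_centers_hz monotone band centers, uniform in log2(Hz).
#' @param frame_rate_hz frame rate in frames/s.
#' @return An object of class `spectrogram`.
#' @export
spectrogram <- function(values, band_centers_hz, frame_rate_hz) {
  values <- as.matrix(values)
  if (nrow(values) != length(band_centers_hz)) {
    stopf("values has %d rows but %d band centers", nrow(values), length(band_centers_hz))
  }
  if (any(values < 0)) stopf("spectrogram values must be non-negative")
  bands_per_octave(band_centers_hz)  # validates log2 uniformity
  structure(list(values = values, band_centers_hz = band_centers_hz,
                 frame_rate_hz = frame_rate_hz),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %d bands (%.0f-%.0f Hz, log2-spaced) x %d frames @ %g Hz\n",
              nrow(x$values), min(x$band_centers_hz), max(x$band_centers_hz),
              ncol(x$values), x$frame_rate_hz))
  invisible(x)
}

#' Gabor parameterization of a ground-truth STRF
#'
#' A separable Gabor over time lag and log-frequency whose modulation
#' coordinates (temporal modulation in Hz, spectral modulation in
#' cycles/octave) are known analytically, so modulation-domain analyses
#' can be tested against planted truth.
#'
#' @param best_freq_hz center of the spectral envelope (Hz).
#' @param peak_delay_ms center of the temporal envelope (ms).
#' @param temporal_mod_hz temporal modulation rate (Hz).
#' @param spectral_mod_cpo spectral modulation rate (cycles/octave).
#' @param bandwidth_oct SD of the Gaussian spectral envelope (octaves).
#' @param duration_ms full width of the Hann temporal envelope (ms).
#' @param amplitude overall scale; the weight matrix has L2 norm equal
#'   to `amplitude`.
#' @param phase phase (radians) of the temporal carrier.
#' @return An object of class `gabor_strf_params`.
#' @export
gabor_strf_params <- function(best_freq_hz, peak_delay_ms,
                              temporal_mod_hz = 0, spectral_mod_cpo = 0,
                              bandwidth_oct = 1, duration_ms = 150,
                              amplitude = 1, phase = 0) {
  structure(list(best_freq_hz = best_freq_hz, peak_delay_ms = peak_delay_ms,
                 temporal_mod_hz = temporal_mod_hz,
                 spectral_mod_cpo = spectral_mod_cpo,
                 bandwidth_oct = bandwidth_oct, duration_ms = duration_ms,
                 amplitude = amplitude, phase = phase),
            class = "gabor_strf_params")
}

#' Generate a Gabor spectrotemporal receptive field
#'
#' Temporal sinusoid at `temporal_mod_hz` under a Hann window centered
#' at `peak_delay_ms`, times a spectral sinusoid at `spectral_mod_cpo`
#' under a Gaussian in log2-frequency centered at `best_freq_hz`.
#' The matrix is L2-normalized and scaled by `amplitude`.
#'
#' @param params a [gabor_strf_params()] object.
#' @param delay_axis_ms monotone increasing delay axis (ms), uniform.
#' @param band_axis_hz monotone band centers, uniform in log2(Hz).
#' @return delays x bands weight matrix.
#' @export
make_gabor_strf <- function(params, delay_axis_ms, band_axis_hz) {
  stopifnot(inherits(params, "gabor_strf_params"))
  if (is.unsorted(delay_axis_ms, strictly = TRUE) ||
      is.unsorted(band_axis_hz, strictly = TRUE)) {
    stopf("axes must be strictly increasing")
  }
  dd <- diff(delay_axis_ms)
  if (any(abs(dd - dd[1]) > 1e-9)) stopf("delay axis must be uniform")
  bpo <- bands_per_octave(band_axis_hz)
  fs_t <- 1000 / dd[1]                    # temporal sampling rate over delays, Hz
  if (params$temporal_mod_hz >= fs_t / 2) {
    stopf("temporal_mod_hz (%g) at or above delay-axis Nyquist (%g Hz)",
          params$temporal_mod_hz, fs_t / 2)
  }
  if (params$spectral_mod_cpo >= bpo / 2) {
    stopf("spectral_mod_cpo (%g) at or above band-axis Nyquist (%g c/o)",
          params$spectral_mod_cpo, bpo / 2)
  }
  td <- delay_axis_ms - params$peak_delay_ms
  hann <- ifelse(abs(td) <= params$duration_ms / 2,
                 0.5 * (1 + cos(2 * pi * td / params$duration_ms)), 0)
  wt <- hann * cos(2 * pi * params$temporal_mod_hz * td / 1000 + params$phase)
  l <- log2(band_axis_hz) - log2(params$best_freq_hz)
  genv <- exp(-l^2 / (2 * params$bandwidth_oct^2))
  ws <- genv * cos(2 * pi * params$spectral_mod_cpo * l)
  W <- outer(wt, ws)
  nrm <- sqrt(sum(W^2))
  if (nrm > 0) W <- W / nrm
  W * params$amplitude
}

# content of one unique sentence: ripple-textured noise spectrogram plus
# a word tiling; all draws come from the current RNG stream
synth_one_sentence <- function(cfg, band_axis, n_ripples = 8) {
  nf <- round(cfg$sentence_dur_s * cfg$frame_rate_hz)
  nb <- cfg$n_bands
  l <- log2(band_axis) - log2(band_axis[1])          # octaves above bottom band
  t <- (seq_len(nf) - 1) / cfg$frame_rate_hz
  bpo <- bands_per_octave(band_axis)
  ripple <- matrix(0, nb, nf)
  for (r in seq_len(n_ripples)) {
    wt <- runif(1, 1, min(12, cfg$frame_rate_hz / 2 * 0.8))
    ws <- runif(1, 0.1, min(1.5, bpo / 2 * 0.8))
    ph <- runif(1, 0, 2 * pi)
    sgn <- sample(c(-1, 1), 1)
    ripple <- ripple + outer(ws * l, sgn * wt * t, function(a, b) cos(2 * pi * (a + b) + ph))
  }
  ripple <- ripple / n_ripples
  # heavy-tailed (chi-square) texture: keeps the bulk of the lagged
  # autocorrelation spectrum well above the silence-gating common mode
  tex <- matrix(rnorm(nb * nf), nb, nf)^2 + 0.05
  vals <- exp(1.2 * ripple) * tex
  # word tiling: 2-6 words, 200-600 ms, frame-aligned, from sentence start
  n_words <- sample(2:6, 1)
  fr <- cfg$frame_rate_hz
  starts <- integer(0); ends <- integer(0)
  cur <- 0L
  for (w in seq_len(n_words)) {
    dur <- round(runif(1, 0.2, 0.6) * fr)
    if (cur + dur > nf) break
    starts <- c(starts, cur); ends <- c(ends, cur + dur)
    cur <- cur + dur
  }
  words <- data.frame(word_type = sample.int(cfg$n_word_types, length(starts), replace = TRUE),
                      onset_s = starts / fr, offset_s = ends / fr)
  list(values = vals, words = words)
}

#' Synthesize a repeated-sentence stimulus spectrogram
#'
#' Generates `n_sentences` unique ripple-textured noise sentences, then
#' lays out `n_sentences * n_repeats` presentations in seeded random
#' order, each preceded by a silent gap of `gap_s` seconds (exactly-zero
#' frames).  Each unique sentence is tiled with 2-6 non-overlapping
#' words carrying word-type ids; all event times are exact frame
#' multiples.
#'
#' @param cfg a [synth_config()].
#' @return A list of class `synth_stimulus` with elements `spec`
#'   ([spectrogram()]), `events` (one row per presentation: sentence,
#'   onset_s, offset_s), `words` (word annotations at absolute times),
#'   `sentences` (per-unique-sentence content), and `config`.
#' @export
synth_spectrogram <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(child_seed(cfg$seed, "spectrogram"), {
    band_axis <- log2_bands(cfg$n_bands, cfg$band_lo_hz, cfg$band_hi_hz)
    fr <- cfg$frame_rate_hz
    sent_f <- round(cfg$sentence_dur_s * fr)
    gap_f <- round(cfg$gap_s * fr)
    if (sent_f < 1) stopf("sentence duration too short for frame rate")
    uniq <- lapply(seq_len(cfg$n_sentences), function(s) synth_one_sentence(cfg, band_axis))
    order_seq <- sample(rep(seq_len(cfg$n_sentences), cfg$n_repeats))
    n_pres <- length(order_seq)
    total_f <- n_pres * (gap_f + sent_f)
    vals <- matrix(0, cfg$n_bands, total_f)
    events <- data.frame(presentation = seq_len(n_pres), sentence = order_seq,
                         onset_s = NA_real_, offset_s = NA_real_)
    words_list <- vector("list", n_pres)
    pos <- 0L
    for (k in seq_len(n_pres)) {
      pos <- pos + gap_f
      s <- order_seq[k]
      vals[, (pos + 1):(pos + sent_f)] <- uniq[[s]]$values
      events$onset_s[k] <- pos / fr
      events$offset_s[k] <- (pos + sent_f) / fr
      wk <- uniq[[s]]$words
      if (nrow(wk)) {
        wk <- data.frame(presentation = k, sentence = s,
                         word_type = wk$word_type,
                         onset_s = wk$onset_s + pos / fr,
                         offset_s = wk$offset_s + pos / fr)
        words_list[[k]] <- wk
      }
      pos <- pos + sent_f
    }
    words <- do.call(rbind, words_list)
    rownames(words) <- NULL
    structure(list(spec = spectrogram(vals, band_axis, fr),
                   events = events, words = words,
                   sentences = uniq, config = cfg),
              class = "synth_stimulus")
  })
}

#' Simulate a high-gamma trace from a planted STRF
#'
#' The noiseless trace is the causal convolution of the stimulus with
#' the STRF summed over bands; white Gaussian noise is added so that
#' the realized signal/noise variance ratio matches `snr_db`.
#'
#' @param strf_truth delays x bands weight matrix; delay spacing is one
#'   stimulus frame.
#' @param stim a [spectrogram()] (or `synth_stimulus`).
#' @param snr_db requested SNR in dB; `Inf` for a noiseless trace;
#'   `-Inf` flags a pure-noise electrode (unit-variance noise only).
#' @param seed integer seed for the noise.
#' @return List with `block` (a [neural_block()] with one electrode at
#'   the stimulus frame rate, stage `"highgamma"`), `signal`, and
#'   `noise` components.
#' @export
simulate_highgamma <- function(strf_truth, stim, snr_db = 10, seed = 1) {
  if (inherits(stim, "synth_stimulus")) stim <- stim$spec
  stopifnot(inherits(stim, "spectrogram"))
  W <- as.matrix(strf_truth)
  if (ncol(W) != nrow(stim$values)) {
    stopf("STRF has %d bands but stimulus has %d", ncol(W), nrow(stim$values))
  }
  S <- stim$values
  nf <- ncol(S)
  nd <- nrow(W)
  sig <- rep(0, nf)
  for (d in seq_len(nd)) {
    contrib <- as.vector(W[d, , drop = FALSE] %*% S)
    if (d == 1) sig <- sig + contrib
    else sig[d:nf] <- sig[d:nf] + contrib[seq_len(nf - d + 1)]
  }
  noise <- with_seed(seed, {
    if (is.infinite(snr_db) && snr_db > 0) {
      rep(0, nf)
    } else if (is.infinite(snr_db) && snr_db < 0) {
      rnorm(nf)  # pure-noise electrode
    } else {
      rnorm(nf, sd = sd(sig) * 10^(-snr_db / 20))
    }
  })
  if (is.infinite(snr_db) && snr_db < 0) sig <- rep(0, nf)
  trace <- sig + noise
  blk <- neural_block(matrix(trace, 1), stim$frame_rate_hz,
                      stage = "highgamma", ids = "sim1")
  list(block = blk, signal = sig, noise = noise, snr_db = snr_db)
}

#' Trial tensor container
#'
#' Sentence-aligned trial stacks: `sentences x repeats x time x
#' electrodes`, with a shared onset index and a pre-onset baseline span.
#'
#' @param values 4-d array (sentences x repeats x time x electrodes).
#' @param rate_hz frame rate of the time axis.
#' @param baseline_ms pre-onset baseline span in ms (>= one frame).
#' @return An object of class `trial_tensor`; the onset is at frame
#'   `baseline_frames + 1`.
#' @export
trial_tensor <- function(values, rate_hz, baseline_ms = 500) {
  stopifnot(length(dim(values)) == 4)
  bf <- round(baseline_ms * rate_hz / 1000)
  if (bf < 1) stopf("baseline span must cover at least one frame")
  if (bf >= dim(values)[3]) stopf("baseline span exceeds the time axis")
  structure(list(values = values, rate_hz = rate_hz,
                 baseline_ms = baseline_ms, baseline_frames = bf),
            class = "trial_tensor")
}

#' @export
print.trial_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<trial_tensor> %d sentences x %d repeats x %d frames x %d electrodes @ %g Hz (baseline %g ms)\n",
              d[1], d[2], d[3], d[4], x$rate_hz, x$baseline_ms))
  invisible(x)
}

#' Simulate sentence-aligned trials with a planted onset latency
#'
#' Each trial is baseline noise until `planted_latency_ms` after the
#' onset index, then the template response (shifted by the latency)
#' plus i.i.d. Gaussian trial noise.  A 500-ms pre-onset baseline
#' segment is included in every trial.
#'
#' @param template_response post-onset response template sampled at
#'   `rate_hz`, starting at stimulus onset.
#' @param planted_latency_ms planted latency (>= 0) in ms.
#' @param n_repeats number of repeats (>= 2).
#' @param trial_noise_sd SD of the additive trial noise.
#' @param seed integer seed.
#' @param rate_hz frame rate, default 1000 (1-ms bins).
#' @param baseline_ms baseline span before onset, default 500.
#' @return A [trial_tensor()] with one sentence and one electrode.
#' @export
simulate_trials <- function(template_response, planted_latency_ms, n_repeats,
                            trial_noise_sd = 0.1, seed = 1,
                            rate_hz = 1000, baseline_ms = 500) {
  if (n_repeats < 2) stopf("n_repeats must be >= 2 (got %d)", n_repeats)
  if (planted_latency_ms < 0) stopf("planted_latency_ms must be >= 0")
  nf_base <- round(baseline_ms * rate_hz / 1000)
  npost <- length(template_response)
  shift <- round(planted_latency_ms * rate_hz / 1000)
  ntime <- nf_base + npost
  mean_trace <- rep(0, ntime)
  if (shift < npost) {
    mean_trace[(nf_base + shift + 1):ntime] <- template_response[seq_len(npost - shift)]
  }
  vals <- with_seed(seed, {
    arr <- array(0, dim = c(1, n_repeats, ntime, 1))
    for (r in seq_len(n_repeats)) {
      arr[1, r, , 1] <- mean_trace + rnorm(ntime, sd = trial_noise_sd)
    }
    arr
  })
  tt <- trial_tensor(vals, rate_hz, baseline_ms)
  tt$planted_latency_ms <- planted_latency_ms
  tt
}

#' Simulate electrode coordinates around planted spatial clusters
#'
#' @param centers k x 3 matrix of cluster centers (x, y, z in mm,
#'   MNI-like; negative x = left hemisphere).
#' @param spread_mm isotropic Gaussian SD around each center (> 0).
#' @param n_per_center electrodes per center (scalar or length k).
#' @param hemispheres hemisphere label per center (`"L"`/`"R"`); by
#'   default from the sign of the center's x (positive x = right).
#' @param regions region name per center; default `region1..k`.
#' @param seed integer seed.
#' @return A data.frame (`electrode_table`): id, hemisphere, x, y, z,
#'   region.
#' @export
synth_electrodes <- function(centers, spread_mm = 2, n_per_center = 30,
                             hemispheres = NULL, regions = NULL, seed = 1) {
  centers <- as.matrix(centers)
  if (ncol(centers) != 3) stopf("centers must be k x 3")
  if (spread_mm <= 0) stopf("spread_mm must be > 0")
  k <- nrow(centers)
  n_per_center <- rep_len(n_per_center, k)
  if (is.null(hemispheres)) hemispheres <- ifelse(centers[, 1] > 0, "R", "L")
  if (is.null(regions)) regions <- paste0("region", seq_len(k))
  with_seed(seed, {
    rows <- lapply(seq_len(k), function(i) {
      n <- n_per_center[i]
      xyz <- matrix(rnorm(n * 3, sd = spread_mm), n, 3)
      xyz <- sweep(xyz, 2, centers[i, ], "+")
      if (hemispheres[i] == "R") xyz[, 1] <- abs(xyz[, 1])
      if (hemispheres[i] == "L") xyz[, 1] <- -abs(xyz[, 1])
      data.frame(hemisphere = hemispheres[i], x = unname(xyz[, 1]),
                 y = unname(xyz[, 2]), z = unname(xyz[, 3]),
                 region = regions[i], row.names = NULL)
    })
    out <- do.call(rbind, rows)
    out <- cbind(id = sprintf("e%03d", seq_len(nrow(out))), out)
    class(out) <- c("electrode_table", "data.frame")
    out
  })
}

#' Default preset: three well-separated left-hemisphere clusters
#'
#' Centers emulating inferior frontal gyrus, middle precentral gyrus
#' and ventral sensorimotor cortex at >= 5x the within-cluster spread.
#'
#' @param seed integer seed.
#' @param n_per_center electrodes per cluster.
#' @param spread_mm within-cluster SD in mm.
#' @return An `electrode_table` data.frame.
#' @export
synth_electrodes_preset <- function(seed = 1, n_per_center = 30, spread_mm = 2) {
  centers <- rbind(IFG = c(-50, 25, 5),
                   mPreCG = c(-45, 0, 40),
                   vSMC = c(-58, -8, 22))
  synth_electrodes(centers, spread_mm = spread_mm, n_per_center = n_per_center,
                   regions = rownames(centers), seed = seed)
}

#' Synthetic word embeddings
#'
#' I.i.d. Gaussian vectors normalized to unit L2 norm, one per word
#' type; a pluggable stand-in for an external embedding table.
#'
#' @param n_word_types vocabulary size.
#' @param embedding_dim vector dimension (>= 2).
#' @param seed integer seed.
#' @return n_word_types x embedding_dim matrix with rownames = type id.
#' @export
synth_embeddings <- function(n_word_types = 200, embedding_dim = 50, seed = 1) {
  if (embedding_dim < 2) stopf("embedding_dim must be >= 2")
  with_seed(seed, {
    E <- matrix(rnorm(n_word_types * embedding_dim), n_word_types)
    E <- E / sqrt(rowSums(E^2))
    rownames(E) <- as.character(seq_len(n_word_types))
    E
  })
}
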