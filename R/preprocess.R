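#' Neural block container
#'
#' Continuous multi-electrode traces with a sample rate and a
#' processing-stage tag.
#'
#' @param traces electrodes x samples matrix.
#' @param sample_rate_hz sampling rate (> 0).
#' @param stage one of `"raw"`, `"referenced"`, `"highgamma"`,
#'   `"zscored"`.
#' @param ids electrode ids (default `e1..n`).
#' @return An object of class `neural_block`.
#' @export
neural_block <- function(traces, sample_rate_hz, stage = "raw", ids = NULL) {
  traces <- as.matrix(traces)
  if (sample_rate_hz <= 0) stopf("sample_rate_hz must be > 0")
  stage <- match.arg(stage, c("raw", "referenced", "highgamma", "zscored"))
  if (is.null(ids)) ids <- paste0("e", seq_len(nrow(traces)))
  if (length(ids) != nrow(traces)) stopf("ids length != number of electrodes")
  rownames(traces) <- ids
  structure(list(traces = traces, sample_rate_hz = sample_rate_hz,
                 stage = stage, ids = ids),
            class = "neural_block")
}

#' @export
print.neural_block <- function(x, ...) {
  cat(sprintf("<neural_block> %d electrodes x %d samples @ %g Hz [stage: %s]\n",
              nrow(x$traces), ncol(x$traces), x$sample_rate_hz, x$stage))
  invisible(x)
}

#' Common average reference
#'
#' Subtracts the instantaneous across-electrode mean from every
#' electrode, so the across-electrode mean of the output is zero at
#' every sample.
#'
#' @param block a raw [neural_block()] with >= 2 electrodes.
#' @return A `neural_block` at stage `"referenced"`.
#' @export
common_average_reference <- function(block) {
  stopifnot(inherits(block, "neural_block"))
  if (block$stage != "raw") stopf("common_average_reference expects stage 'raw', got '%s'", block$stage)
  if (nrow(block$traces) < 2) stopf("common average reference undefined for a single electrode")
  ref <- colMeans(block$traces)
  out <- block
  out$traces <- sweep(block$traces, 2, ref)
  out$stage <- "referenced"
  out
}

# FFT-based analytic signal; returns the analytic amplitude (envelope)
analytic_amplitude <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(fft(x) * h, inverse = TRUE) / n)
}

# zero-phase Butterworth band-pass (forward-backward)
bandpass_zerophase <- function(x, band, fs, order = 4) {
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  signal::filtfilt(bf, x)
}

# anti-alias low-pass then sample at the exact output grid; preserves
# total duration to within one output sample
resample_env <- function(x, fs_in, fs_out, lowpass = TRUE) {
  if (fs_out >= fs_in) stopf("resample_env only downsamples")
  n <- length(x)
  if (lowpass) {
    bf <- signal::butter(4, (0.8 * fs_out / 2) / (fs_in / 2), type = "low")
    x <- signal::filtfilt(bf, x)
  }
  t_in <- (seq_len(n) - 1) / fs_in
  n_out <- floor(n / fs_in * fs_out)
  t_out <- (seq_len(n_out) - 1) / fs_out
  approx(t_in, x, xout = t_out, rule = 2)$y
}

#' High-gamma analytic amplitude via the Hilbert transform
#'
#' Per electrode: zero-phase 4th-order Butterworth band-pass over the
#' high-gamma band, analytic amplitude of the analytic signal,
#' anti-alias filtering and resampling to `out_rate`.  The output is
#' non-negative and carries an `edge_ms` attribute flagging filter
#' transients at the block edges.
#'
#' @param block a `neural_block` at stage `"raw"` or `"referenced"`.
#' @param band band edges in Hz, default `c(70, 150)`.
#' @param out_rate output rate, default 100 Hz.
#' @return A `neural_block` at stage `"highgamma"`.
#' @export
hilbert_highgamma <- function(block, band = c(70, 150), out_rate = 100) {
  stopifnot(inherits(block, "neural_block"))
  if (!block$stage %in% c("raw", "referenced")) {
    stopf("hilbert_highgamma expects stage raw/referenced, got '%s'", block$stage)
  }
  fs <- block$sample_rate_hz
  if (fs < 2 * band[2]) stopf("sample rate %g below Nyquist for band edge %g Hz", fs, band[2])
  env <- t(apply(block$traces, 1, function(x) {
    resample_env(analytic_amplitude(bandpass_zerophase(x, band, fs)), fs, out_rate)
  }))
  out <- neural_block(pmax(env, 0), out_rate, stage = "highgamma", ids = block$ids)
  attr(out, "edge_ms") <- 250
  attr(out, "band_hz") <- band
  out
}

#' High-gamma amplitude via Morlet wavelet decomposition
#'
#' Amplitude is the mean magnitude of a complex Morlet wavelet bank
#' (log-spaced centers across the high-gamma band, fixed cycle count),
#' resampled to `out_rate` (default 1000 Hz for 1-ms latency analysis).
#'
#' @param block a `neural_block` at stage `"raw"` or `"referenced"`.
#' @param band band edges in Hz, default `c(70, 150)`.
#' @param out_rate output rate, default 1000 Hz.
#' @param n_wavelets number of log-spaced centers, default 8.
#' @param n_cycles wavelet width in cycles, default 7.
#' @return A `neural_block` at stage `"highgamma"`.
#' @export
morlet_highgamma <- function(block, band = c(70, 150), out_rate = 1000,
                             n_wavelets = 8, n_cycles = 7) {
  stopifnot(inherits(block, "neural_block"))
  if (!block$stage %in% c("raw", "referenced")) {
    stopf("morlet_highgamma expects stage raw/referenced, got '%s'", block$stage)
  }
  fs <- block$sample_rate_hz
  if (fs < 2 * band[2]) stopf("sample rate %g below Nyquist for band edge %g Hz", fs, band[2])
  n <- ncol(block$traces)
  centers <- 2^seq(log2(band[1]), log2(band[2]), length.out = n_wavelets)
  freqs <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2 - 1), -1)) * fs / n
  env <- t(apply(block$traces, 1, function(x) {
    X <- fft(x)
    acc <- numeric(n)
    for (f0 in centers) {
      sigma_t <- n_cycles / (2 * pi * f0)
      # analytic Morlet: one-sided Gaussian in frequency around f0
      H <- 2 * exp(-2 * pi^2 * sigma_t^2 * (freqs - f0)^2)
      H[freqs < 0] <- 0
      acc <- acc + Mod(fft(X * H, inverse = TRUE) / n)
    }
    acc <- acc / length(centers)
    if (out_rate < fs) resample_env(acc, fs, out_rate) else acc
  }))
  out <- neural_block(pmax(env, 0), min(out_rate, fs),
                      stage = "highgamma", ids = block$ids)
  attr(out, "edge_ms") <- 250
  attr(out, "band_hz") <- band
  out
}

#' Z-score each electrode over the entire block
#'
#' Subtracts the full-block mean and divides by the full-block SD per
#' electrode (silences included).
#'
#' @param block a `neural_block`.
#' @return A `neural_block` at stage `"zscored"`.
#' @export
zscore_block <- function(block) {
  stopifnot(inherits(block, "neural_block"))
  mu <- rowMeans(block$traces)
  sdv <- apply(block$traces, 1, sd)
  bad <- which(sdv == 0)
  if (length(bad)) {
    stopf("zero-variance electrode(s): %s", paste(block$ids[bad], collapse = ", "))
  }
  out <- block
  out$traces <- (block$traces - mu) / sdv
  out$stage <- "zscored"
  out
}

#' Reject electrodes with excessive noise
#'
#' Simple robust rule: an electrode is rejected if its full-block SD
#' exceeds `factor` times the median SD across electrodes.
#'
#' @param block a `neural_block`.
#' @param factor rejection multiplier, default 5.
#' @return The block without rejected electrodes; rejected ids are in
#'   `attr(, "rejected")`.
#' @export
reject_noisy_electrodes <- function(block, factor = 5) {
  stopifnot(inherits(block, "neural_block"))
  sdv <- apply(block$traces, 1, sd)
  keep <- sdv <= factor * median(sdv)
  out <- block
  out$traces <- block$traces[keep, , drop = FALSE]
  out$ids <- block$ids[keep]
  attr(out, "rejected") <- block$ids[!keep]
  out
}
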