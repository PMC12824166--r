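# Shared fixtures built in code.

# small log2-spaced band axis
tiny_bands <- function(n = 8, lo = 200, hi = 3200) {
  2^seq(log2(lo), log2(hi), length.out = n)
}

# compact repeated-sentence stimulus for encoding tests
tiny_stimulus <- function(seed = 1, n_sentences = 4, n_repeats = 2,
                          n_bands = 16, sentence_dur_s = 2, gap_s = 1) {
  cfg <- synth_config(seed = seed, n_sentences = n_sentences,
                      sentence_dur_s = sentence_dur_s, gap_s = gap_s,
                      n_repeats = n_repeats, n_bands = n_bands)
  synth_spectrogram(cfg)
}

# presentation-group vector for a synthetic stimulus (frames -> group id)
stim_groups <- function(stim) {
  cfg <- stim$config
  per <- round((cfg$sentence_dur_s + cfg$gap_s) * cfg$frame_rate_hz)
  rep(stim$events$presentation, each = per)
}

cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# evaluate expr under a local seed without touching the session RNG
with_seed_test <- function(seed, expr) speechenc:::with_seed(seed, expr)

# amplitude-modulated high-gamma carrier with a known slow envelope
am_carrier <- function(fs = 3052, dur_s = 8, f_carrier = 110, f_env = 2,
                       depth = 0.5) {
  t <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  env <- 1 + depth * cos(2 * pi * f_env * t)
  list(t = t, env = env, x = env * cos(2 * pi * f_carrier * t), fs = fs)
}

# direct double-sum 2D DFT magnitude (independent oracle for mtf())
dft2_direct <- function(W) {
  nd <- nrow(W); nb <- ncol(W)
  out <- matrix(0, nd, nb)
  for (k in 0:(nd - 1)) for (l in 0:(nb - 1)) {
    acc <- 0 + 0i
    for (a in 0:(nd - 1)) for (b in 0:(nb - 1)) {
      acc <- acc + W[a + 1, b + 1] * exp(-2i * pi * (k * a / nd + l * b / nb))
    }
    out[k + 1, l + 1] <- Mod(acc)
  }
  out
}
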