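#' Detect speech-onset response latency at 1-ms resolution
#'
#' For every 1-ms post-onset bin, the repeats' values are compared
#' against the pooled 500-ms pre-onset baseline by an (uncorrected)
#' two-sided Wilcoxon rank-sum test; the onset latency is the start of
#' the first run of at least `run_len` consecutive bins with
#' `p < alpha`.  The consecutive-bin requirement is the multiplicity
#' control.  Latency 0 ms means the first post-onset bin.
#'
#' @param tensor a [trial_tensor()] at 1000 frames/s with a 500-ms
#'   baseline.
#' @param sentence sentence index.
#' @param electrode electrode index, default 1.
#' @param alpha per-bin level, default 0.05.
#' @param run_len required run of consecutive significant bins,
#'   default 15.
#' @return Latency in ms, or `NA_real_` if no qualifying run exists.
#' @export
detect_onset <- function(tensor, sentence = 1, electrode = 1,
                         alpha = 0.05, run_len = 15) {
  stopifnot(inherits(tensor, "trial_tensor"))
  if (tensor$rate_hz != 1000) {
    stopf("detect_onset requires a 1000 frames/s tensor (got %g)", tensor$rate_hz)
  }
  if (tensor$baseline_ms != 500) {
    stopf("detect_onset requires a 500-ms baseline (got %g)", tensor$baseline_ms)
  }
  d <- dim(tensor$values)
  if (d[2] < 2) stopf("detect_onset needs >= 2 repeats")
  bf <- tensor$baseline_frames
  x <- tensor$values[sentence, , , electrode]
  baseline <- as.vector(x[, seq_len(bf)])
  post <- x[, (bf + 1):d[3], drop = FALSE]
  p <- ranksum_cols(post, baseline)$p
  sig <- p < alpha
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  hit <- which(r$values & r$lengths >= run_len)
  if (!length(hit)) return(NA_real_)
  (starts[hit[1]] - 1) * 1000 / tensor$rate_hz
}

#' Electrode speech-onset latency
#'
#' The shortest per-sentence onset latency is the electrode's speech
#' onset latency.
#'
#' @param per_sentence_ms numeric vector of per-sentence latencies (ms;
#'   `NA` = no onset detected for that sentence).
#' @return List of class `onset_latency`: `latency_ms` (min over
#'   detected sentences, `NA` if none) and `per_sentence_ms`.
#' @export
electrode_latency <- function(per_sentence_ms) {
  if (length(per_sentence_ms) == 0) stopf("no sentences analyzed")
  present <- per_sentence_ms[!is.na(per_sentence_ms)]
  structure(list(latency_ms = if (length(present)) min(present) else NA_real_,
                 per_sentence_ms = per_sentence_ms),
            class = "onset_latency")
}

#' Compare two onset-latency distributions under increasing cutoffs
#'
#' At each temporal cutoff the latencies of each group at or below the
#' cutoff are compared by a two-sample Kolmogorov-Smirnov test;
#' p-values are Bonferroni-corrected over `n_comparisons` (by default
#' the number of cutoffs; multiply externally for multiple group
#' pairs).
#'
#' @param group_a,group_b latencies in ms (NA dropped).
#' @param cutoffs_ms cutoffs in ms, default `seq(80, 720, by = 40)`.
#' @param n_comparisons Bonferroni factor, default `length(cutoffs_ms)`.
#' @return data.frame: cutoff_ms, n_a, n_b, ks_stat, p, p_bonf.
#'   Cutoffs at which either truncated group is empty are skipped with
#'   a warning.
#' @export
compare_latency_distributions <- function(group_a, group_b,
                                          cutoffs_ms = seq(80, 720, by = 40),
                                          n_comparisons = length(cutoffs_ms)) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (!length(group_a) || !length(group_b)) stopf("empty latency group")
  rows <- lapply(cutoffs_ms, function(cc) {
    a <- group_a[group_a <= cc]
    b <- group_b[group_b <= cc]
    if (!length(a) || !length(b)) {
      warnf("cutoff %g ms skipped: empty truncated group", cc)
      return(NULL)
    }
    kt <- suppressWarnings(ks.test(a, b))
    data.frame(cutoff_ms = cc, n_a = length(a), n_b = length(b),
               ks_stat = unname(kt$statistic), p = kt$p.value,
               p_bonf = min(1, kt$p.value * n_comparisons))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(cutoff_ms = numeric(0), n_a = integer(0),
                                      n_b = integer(0), ks_stat = numeric(0),
                                      p = numeric(0), p_bonf = numeric(0))
  out
}
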