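#' Align a neural block into a sentence x repeat trial tensor
#'
#' Cuts a window around every presentation onset and stacks the
#' segments as `sentences x repeats x time x electrodes`, with a shared
#' onset index and a pre-onset baseline span.
#'
#' @param block a [neural_block()] (typically z-scored high-gamma).
#' @param events data.frame with columns `sentence` and `onset_s`, one
#'   row per presentation; every sentence must occur equally often.
#' @param window `c(start, end)` in seconds relative to onset;
#'   `-window[1]` must cover `baseline_ms`.
#' @param baseline_ms baseline span before onset, default 500.
#' @return A [trial_tensor()].
#' @export
align_trials <- function(block, events, window = c(-0.5, 3), baseline_ms = 500) {
  stopifnot(inherits(block, "neural_block"))
  if (!all(c("sentence", "onset_s") %in% names(events))) {
    stopf("events needs columns 'sentence' and 'onset_s'")
  }
  if (-window[1] * 1000 < baseline_ms) {
    stopf("window start %.3f s does not cover the %g ms baseline", window[1], baseline_ms)
  }
  fs <- block$sample_rate_hz
  n <- ncol(block$traces)
  i0 <- round(events$onset_s * fs) + round(window[1] * fs) + 1
  i1 <- round(events$onset_s * fs) + round(window[2] * fs)
  bad <- which(i0 < 1 | i1 > n)
  if (length(bad)) {
    stopf("window out of block range for presentation(s): %s",
          paste(bad, collapse = ", "))
  }
  sent_ids <- sort(unique(events$sentence))
  reps <- table(events$sentence)
  if (length(unique(reps)) != 1) stopf("unequal repeat counts across sentences")
  n_rep <- as.integer(reps[1])
  ntime <- i1[1] - i0[1] + 1
  n_el <- nrow(block$traces)
  vals <- array(NA_real_, c(length(sent_ids), n_rep, ntime, n_el))
  for (si in seq_along(sent_ids)) {
    idx <- which(events$sentence == sent_ids[si])
    idx <- idx[order(events$onset_s[idx])]
    for (r in seq_along(idx)) {
      vals[si, r, , ] <- t(block$traces[, i0[idx[r]]:i1[idx[r]], drop = FALSE])
    }
  }
  tt <- trial_tensor(vals, fs, baseline_ms)
  tt$sentence_ids <- sent_ids
  tt$electrode_ids <- block$ids
  tt
}

#' Per-bin rank-sum test of evoked activity against baseline
#'
#' For each post-onset time bin, the repeats' values at that bin are
#' compared against the pooled baseline values of that sentence (all
#' repeats x all baseline bins) by a two-sided Wilcoxon rank-sum test;
#' p-values are Bonferroni-corrected for the number of post-onset bins.
#'
#' @param tensor a [trial_tensor()].
#' @param sentence sentence index.
#' @param electrode electrode index, default 1.
#' @param alpha significance level for the corrected mask, default 0.05.
#' @return An object of class `evoked_response`: `mean_trace` (over
#'   repeats, full window), `p` and `p_bonf` per post-onset bin,
#'   logical `mask`, and `magnitude` (mean z over significant bins;
#'   `NA` if none).
#' @export
per_bin_test <- function(tensor, sentence, electrode = 1, alpha = 0.05) {
  stopifnot(inherits(tensor, "trial_tensor"))
  d <- dim(tensor$values)
  if (d[2] < 2) stopf("per_bin_test needs >= 2 repeats, got %d", d[2])
  bf <- tensor$baseline_frames
  x <- tensor$values[sentence, , , electrode]     # repeats x time
  baseline <- as.vector(x[, seq_len(bf)])
  post <- x[, (bf + 1):d[3], drop = FALSE]
  res <- ranksum_cols(post, baseline)
  n_bins <- ncol(post)
  p_bonf <- pmin(1, res$p * n_bins)
  mask <- p_bonf < alpha
  mag <- if (any(mask)) mean(colMeans(post)[mask]) else NA_real_
  structure(list(mean_trace = colMeans(x), p = res$p, p_bonf = p_bonf,
                 mask = mask, magnitude = mag, n_bins = n_bins,
                 rate_hz = tensor$rate_hz, alpha = alpha),
            class = "evoked_response")
}

#' Is an electrode speech-responsive?
#'
#' TRUE iff any post-onset bin of any sentence is significant after
#' correcting over the full per-electrode family (bins within sentence
#' via [per_bin_test()], then a further Bonferroni factor over the
#' number of sentences), which controls the electrode-level family-wise
#' error at `alpha`.
#'
#' @param evoked_list list of [per_bin_test()] results, one per
#'   sentence, for one electrode.
#' @param alpha family-wise level, default 0.05.
#' @param correct_sentences apply the across-sentence Bonferroni factor
#'   (default TRUE).
#' @return Logical flag with attribute `magnitude` (mean significant-bin
#'   amplitude averaged over sentences with significant bins, `NA` if
#'   none).
#' @export
is_responsive <- function(evoked_list, alpha = 0.05, correct_sentences = TRUE) {
  if (length(evoked_list) == 0) stopf("empty evoked set")
  k <- if (correct_sentences) length(evoked_list) else 1
  hits <- vapply(evoked_list, function(e) any(e$p_bonf * k < alpha), logical(1))
  mags <- vapply(evoked_list, function(e) e$magnitude, numeric(1))
  out <- any(hits)
  attr(out, "magnitude") <- if (any(!is.na(mags))) mean(mags, na.rm = TRUE) else NA_real_
  out
}

#' Responsivity flags and magnitudes for every electrode
#'
#' Convenience wrapper running [per_bin_test()] over all sentences and
#' electrodes of a tensor and summarizing with [is_responsive()].
#'
#' @inheritParams per_bin_test
#' @param tensor a [trial_tensor()].
#' @return data.frame: electrode, responsive, magnitude.
#' @export
responsivity_flags <- function(tensor, alpha = 0.05) {
  d <- dim(tensor$values)
  ids <- tensor$electrode_ids
  if (is.null(ids)) ids <- paste0("e", seq_len(d[4]))
  out <- lapply(seq_len(d[4]), function(el) {
    ev <- lapply(seq_len(d[1]), function(s) per_bin_test(tensor, s, el, alpha))
    fl <- is_responsive(ev, alpha)
    data.frame(electrode = ids[el], responsive = as.logical(fl),
               magnitude = attr(fl, "magnitude"))
  })
  do.call(rbind, out)
}

#' Summarize responsiveness by region
#'
#' Per region (x hemisphere when given): number of electrodes,
#' proportion responsive, mean response magnitude and SEM.  Response
#' magnitudes are compared between regions pairwise by two-sided
#' Wilcoxon rank-sum tests, Bonferroni-corrected over pairs;
#' hemispheres are compared within region without correction.
#'
#' @param flags logical vector of responsivity flags.
#' @param magnitudes response magnitudes (NA allowed).
#' @param regions region label per electrode.
#' @param hemispheres optional hemisphere label per electrode.
#' @return List with `table` (per-region summary), `pairwise`
#'   (region-pair rank-sum results, NULL with a single region), and
#'   `hemisphere` (per-region L/R comparison, if hemispheres given).
#' @export
region_summary <- function(flags, magnitudes, regions, hemispheres = NULL) {
  stopifnot(length(flags) == length(magnitudes), length(flags) == length(regions))
  keep <- !is.na(regions)
  regs <- sort(unique(regions[keep]))
  empty <- setdiff(unique(regions), regs)
  if (length(empty)) warnf("omitting empty region(s): %s", paste(empty, collapse = ", "))
  one <- function(idx) {
    m <- magnitudes[idx]
    m <- m[!is.na(m)]
    data.frame(n = length(idx), prop_responsive = mean(flags[idx]),
               mean_magnitude = if (length(m)) mean(m) else NA_real_,
               sem_magnitude = if (length(m) > 1) sd(m) / sqrt(length(m)) else NA_real_)
  }
  if (is.null(hemispheres)) {
    tab <- do.call(rbind, lapply(regs, function(r) cbind(region = r, one(which(regions == r)))))
  } else {
    rows <- list()
    for (r in regs) for (h in sort(unique(hemispheres[regions == r]))) {
      idx <- which(regions == r & hemispheres == h)
      if (length(idx)) rows[[length(rows) + 1]] <- cbind(region = r, hemisphere = h, one(idx))
    }
    tab <- do.call(rbind, rows)
  }
  pairwise <- NULL
  if (length(regs) >= 2) {
    prs <- utils::combn(regs, 2)
    n_pairs <- ncol(prs)
    pairwise <- do.call(rbind, lapply(seq_len(n_pairs), function(j) {
      a <- magnitudes[regions == prs[1, j]]
      b <- magnitudes[regions == prs[2, j]]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      p <- if (length(a) && length(b)) {
        suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
      } else NA_real_
      data.frame(region_a = prs[1, j], region_b = prs[2, j],
                 p = p, p_bonf = pmin(1, p * n_pairs))
    }))
  }
  hemi <- NULL
  if (!is.null(hemispheres)) {
    hemi <- do.call(rbind, lapply(regs, function(r) {
      a <- magnitudes[regions == r & hemispheres == "L"]
      b <- magnitudes[regions == r & hemispheres == "R"]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      p <- if (length(a) && length(b)) {
        suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
      } else NA_real_
      data.frame(region = r, p = p)
    }))
  }
  list(table = tab, pairwise = pairwise, hemisphere = hemi)
}
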