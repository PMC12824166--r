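#' Modulation transfer function of an STRF
#'
#' The MTF is the magnitude of the two-dimensional discrete Fourier
#' transform of the STRF weight matrix.  Axes are temporal modulation
#' in Hz (from the delay spacing; signed, upward vs downward sweeps)
#' and spectral modulation in cycles/octave (from the band spacing;
#' folded to non-negative values; the discarded half-plane is redundant
#' by the conjugate symmetry of real matrices).  The transform is
#' unnormalized, so `sum(MTF^2) = n_delays * n_bands * sum(STRF^2)`
#' (Parseval).
#'
#' @param strf a `strf_model`, or a delays x bands matrix (then supply
#'   `delays_ms` and `band_centers_hz`).
#' @param delays_ms,band_centers_hz axes for plain-matrix input;
#'   delays uniform in ms, bands uniform in log2(Hz).
#' @return An object of class `mtf_result`: `magnitude` (signed
#'   temporal x non-negative spectral grid), `omega_t_hz`,
#'   `omega_s_cpo`, and `magnitude_full` (the raw unfolded transform
#'   magnitude).
#' @export
mtf <- function(strf, delays_ms = NULL, band_centers_hz = NULL) {
  if (inherits(strf, "strf_model")) {
    W <- strf$weights
    delays_ms <- strf$delays_ms
    band_centers_hz <- strf$feature_axis
  } else {
    W <- as.matrix(strf)
    if (is.null(delays_ms) || is.null(band_centers_hz)) {
      stopf("delays_ms and band_centers_hz required for matrix input")
    }
  }
  dd <- diff(delays_ms)
  if (any(abs(dd - dd[1]) > 1e-9)) stopf("delay axis must be uniform")
  bpo <- bands_per_octave(band_centers_hz)
  nd <- nrow(W); nb <- ncol(W)
  M_full <- Mod(fft(W))
  # grid frequencies in DFT order
  ft <- dft_freqs(nd, 1000 / dd[1])       # Hz
  fsrate_s <- bpo                          # samples per octave
  fsp <- dft_freqs(nb, fsrate_s)          # cycles/octave
  # rows: shift to ascending signed omega_t; cols: keep omega_s >= 0
  row_ord <- order(ft)
  col_keep <- which(fsp >= 0)
  col_ord <- col_keep[order(fsp[col_keep])]
  structure(list(magnitude = M_full[row_ord, col_ord, drop = FALSE],
                 omega_t_hz = ft[row_ord], omega_s_cpo = fsp[col_ord],
                 magnitude_full = M_full),
            class = "mtf_result")
}

# DFT bin frequencies for n samples at rate `rate` (per unit)
dft_freqs <- function(n, rate) {
  k <- seq_len(n) - 1
  k[k > n / 2] <- k[k > n / 2] - n
  k * rate / n
}

#' Temporal and spectral modulation tuning marginals
#'
#' The temporal modulation tuning vector sums MTF magnitude over
#' spectral modulation at each absolute temporal modulation rate; the
#' spectral vector sums over (signed) temporal modulation at each
#' spectral rate.  Both are normalized to unit L2 norm.
#'
#' @param m an [mtf()] result.
#' @return List with `temporal` (named by |omega_t| in Hz) and
#'   `spectral` (named by omega_s in c/o), or `NA` with a `reason`
#'   attribute when the MTF is identically zero.
#' @export
modulation_marginals <- function(m) {
  stopifnot(inherits(m, "mtf_result"))
  if (all(m$magnitude == 0)) {
    out <- NA
    attr(out, "reason") <- "zero MTF: normalization undefined"
    return(out)
  }
  at <- abs(m$omega_t_hz)
  lv <- sort(unique(at))
  temporal <- vapply(lv, function(f) sum(m$magnitude[at == f, ]), numeric(1))
  spectral <- colSums(m$magnitude)
  temporal <- temporal / sqrt(sum(temporal^2))
  spectral <- spectral / sqrt(sum(spectral^2))
  names(temporal) <- signif(lv, 6)
  names(spectral) <- signif(m$omega_s_cpo, 6)
  list(temporal = temporal, spectral = spectral)
}

#' Scalar and vector tuning descriptors of an STRF
#'
#' Spectral tuning is the per-band L2 norm of the weights across
#' delays, temporal tuning the per-delay L2 norm across bands (both
#' unit-normalized).  The best frequency is the band center at the
#' argmax of the spectral tuning vector restricted to bands where the
#' excitatory (positive) part of the STRF dominates; ties resolve to
#' the lower frequency.  If no band is excitatory-dominant the STRF is
#' flagged `inhibitory_dominant` and the argmax is taken over
#' `|weights|`.
#'
#' @param strf a `strf_model` or delays x bands matrix (then supply
#'   `band_centers_hz`).
#' @param band_centers_hz band axis for matrix input.
#' @return List of class `tuning_summary`: `best_frequency_hz`,
#'   `spectral`, `temporal`, `inhibitory_dominant`; or `NA` with a
#'   `reason` attribute for an all-zero STRF.
#' @export
tuning_summary <- function(strf, band_centers_hz = NULL) {
  if (inherits(strf, "strf_model")) {
    W <- strf$weights
    band_centers_hz <- strf$feature_axis
  } else {
    W <- as.matrix(strf)
    if (is.null(band_centers_hz)) stopf("band_centers_hz required for matrix input")
  }
  if (all(W == 0)) {
    out <- NA
    attr(out, "reason") <- "all-zero STRF"
    return(out)
  }
  spectral <- sqrt(colSums(W^2))
  temporal <- sqrt(rowSums(W^2))
  pos_dom <- colSums(pmax(W, 0)) >= colSums(pmax(-W, 0))
  inhib <- !any(pos_dom)
  cand <- if (inhib) spectral else ifelse(pos_dom, spectral, -Inf)
  bf_idx <- which(cand == max(cand))[1]          # tie -> lower band
  structure(list(best_frequency_hz = band_centers_hz[bf_idx],
                 spectral = spectral / sqrt(sum(spectral^2)),
                 temporal = temporal / sqrt(sum(temporal^2)),
                 inhibitory_dominant = inhib),
            class = "tuning_summary")
}

#' Ensemble (mean) modulation transfer function
#'
#' @param mtfs list of [mtf()] results on identical grids.
#' @return An `mtf_result` whose magnitude is the element-wise mean.
#' @export
ensemble_mtf <- function(mtfs) {
  stopifnot(length(mtfs) >= 1)
  ref <- mtfs[[1]]
  for (m in mtfs) {
    if (!isTRUE(all.equal(m$omega_t_hz, ref$omega_t_hz)) ||
        !isTRUE(all.equal(m$omega_s_cpo, ref$omega_s_cpo))) {
      stopf("MTF grids differ; cannot average")
    }
  }
  avg <- Reduce(`+`, lapply(mtfs, `[[`, "magnitude")) / length(mtfs)
  out <- ref
  out$magnitude <- avg
  out$magnitude_full <- NULL
  out
}

#' Cosine-similarity permutation test on group-mean tuning vectors
#'
#' The statistic is the cosine similarity between the two group-mean
#' vectors; the null distribution recomputes it under random
#' relabelings of group membership.  One-sided toward low similarity
#' (dissimilar means), with the add-one permutation p-value
#' `p = (1 + #(null <= observed)) / (1 + n_perm)`.
#'
#' @param group_a,group_b members x dim matrices of tuning vectors.
#' @param n_perm number of permutations, default 1000.
#' @param seed integer seed.
#' @return List: `observed` cosine similarity, `p`, `n_perm`.
#' @export
cosine_perm_test <- function(group_a, group_b, n_perm = 1000, seed = 1) {
  A <- as.matrix(group_a); B <- as.matrix(group_b)
  if (ncol(A) != ncol(B)) stopf("vector lengths differ between groups")
  if (nrow(A) < 2 || nrow(B) < 2) stopf("each group needs >= 2 members")
  obs <- cosine(colMeans(A), colMeans(B))
  X <- rbind(A, B)
  n <- nrow(X); na <- nrow(A); nb <- nrow(B)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      ia <- sample.int(n, na)
      ma <- colMeans(X[ia, , drop = FALSE])
      mb <- colMeans(X[-ia, , drop = FALSE])
      cosine(ma, mb)
    }, numeric(1))
  })
  p <- (1 + sum(null <= obs)) / (1 + n_perm)
  list(observed = obs, p = p, n_perm = n_perm)
}

#' Kruskal-Wallis test of best frequency across regions
#'
#' @param values best-frequency values (Hz).
#' @param groups region label per value.
#' @return List: `H` statistic, `p`, `df`.
#' @export
kruskal_bf <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stopf("need >= 2 groups")
  cnt <- table(groups)
  if (any(cnt == 0)) {
    stopf("empty group(s): %s", paste(names(cnt)[cnt == 0], collapse = ", "))
  }
  if (length(unique(values)) == 1) {
    # all observations tied: no evidence of any group difference
    return(list(H = 0, p = 1, df = nlevels(groups) - 1))
  }
  kt <- kruskal.test(values, groups)
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter))
}
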