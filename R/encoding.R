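#' Cochlear-style auditory spectrogram of a waveform
#'
#' A gammatone filterbank front-end: log2-spaced bands, half-wave
#' rectification, low-pass envelope extraction, cube-root compression,
#' and framing at `frame_rate`.
#'
#' @param wave numeric waveform in `[-1, 1]`.
#' @param sample_rate sampling rate in Hz (>= 16 kHz for the default
#'   band range).
#' @param n_bands,band_lo_hz,band_hi_hz band axis (log2-spaced).
#' @param frame_rate output frame rate, default 100 Hz.
#' @return A [spectrogram()].
#' @export
cochlear_spectrogram <- function(wave, sample_rate, n_bands = 64,
                                 band_lo_hz = 180, band_hi_hz = 7000,
                                 frame_rate = 100) {
  if (any(!is.finite(wave))) stopf("waveform contains NaN/Inf samples")
  if (max(abs(wave)) > 1) stopf("waveform exceeds [-1, 1]: clipped or unscaled audio")
  if (sample_rate < 2 * band_hi_hz) {
    stopf("sample rate %g too low for top band %g Hz", sample_rate, band_hi_hz)
  }
  centers <- log2_bands(n_bands, band_lo_hz, band_hi_hz)
  fs <- sample_rate
  L <- round(0.05 * fs)                       # 50-ms FIR gammatone kernels
  tt <- (seq_len(L) - 1) / fs
  lp <- signal::butter(4, 30 / (fs / 2), type = "low")
  n_frames <- floor(length(wave) / fs * frame_rate)
  spf <- fs / frame_rate
  vals <- matrix(0, n_bands, n_frames)
  for (b in seq_len(n_bands)) {
    f <- centers[b]
    erb <- 24.7 * (4.37 * f / 1000 + 1)
    g <- tt^3 * exp(-2 * pi * 1.019 * erb * tt) * cos(2 * pi * f * tt)
    g <- g / sqrt(sum(g^2))
    y <- signal::fftfilt(g, wave)
    y <- pmax(y, 0)                            # half-wave rectification
    y <- pmax(signal::filtfilt(lp, y), 0)^(1 / 3)
    idx <- pmin(length(y), round(seq_len(n_frames) * spf))
    idx0 <- c(0, idx[-n_frames])
    vals[b, ] <- vapply(seq_len(n_frames),
                        function(i) mean(y[(idx0[i] + 1):idx[i]]), numeric(1))
  }
  spectrogram(vals, centers, frame_rate)
}

#' Build a lagged (time-delayed) design matrix
#'
#' Row `t` concatenates the stimulus at delays `0, 10, ..., 400` ms
#' (feature blocks ordered by lag), with zeros padded before the
#' stimulus start.
#'
#' @param stim a [spectrogram()], `synth_stimulus`, or plain
#'   features x frames matrix (then `frame_rate` must be supplied or
#'   attached as an attribute).
#' @param delays_ms delay axis in ms; each must be a multiple of the
#'   frame period.
#' @param frame_rate frame rate for plain-matrix input.
#' @return frames x (lags * features) matrix with attributes
#'   `delays_ms`, `n_features`, `feature_axis`, `frame_rate`.
#' @export
build_lagged_design <- function(stim, delays_ms = seq(0, 400, by = 10),
                                frame_rate = NULL) {
  if (inherits(stim, "synth_stimulus")) stim <- stim$spec
  if (inherits(stim, "spectrogram")) {
    S <- stim$values
    frame_rate <- stim$frame_rate_hz
    feature_axis <- stim$band_centers_hz
  } else {
    S <- as.matrix(stim)
    if (is.null(frame_rate)) frame_rate <- attr(stim, "frame_rate")
    if (is.null(frame_rate)) stopf("frame_rate needed for plain-matrix input")
    feature_axis <- seq_len(nrow(S))
  }
  period <- 1000 / frame_rate
  lags <- delays_ms / period
  if (any(abs(lags - round(lags)) > 1e-8)) {
    stopf("delays must be multiples of the frame period (%g ms)", period)
  }
  lags <- as.integer(round(lags))
  nf <- ncol(S)
  nfeat <- nrow(S)
  D <- matrix(0, nf, nfeat * length(lags))
  St <- t(S)
  for (l in seq_along(lags)) {
    sh <- lags[l]
    cols <- ((l - 1) * nfeat + 1):(l * nfeat)
    if (sh == 0) D[, cols] <- St
    else D[(sh + 1):nf, cols] <- St[seq_len(nf - sh), , drop = FALSE]
  }
  structure(D, delays_ms = delays_ms, n_features = nfeat,
            feature_axis = feature_axis, frame_rate = frame_rate)
}

# contiguous 90/10 split at group (sentence) boundaries, seeded
nrc_split <- function(nf, test_frac, seed, groups = NULL) {
  if (is.null(groups)) groups <- seq_len(nf)
  stopifnot(length(groups) == nf)
  runs <- rle(as.vector(groups))
  sizes <- runs$lengths
  n_units <- length(sizes)
  target <- max(1, round(test_frac * nf))
  start_unit <- with_seed(seed, sample.int(n_units, 1))
  u <- start_unit
  got <- 0L
  while (got < target && u <= n_units) {
    got <- got + sizes[u]
    u <- u + 1L
  }
  offs <- cumsum(c(0L, sizes))
  test_idx <- (offs[start_unit] + 1):offs[u - 1]
  list(est = setdiff(seq_len(nf), test_idx), test = test_idx)
}

# eigen-truncated normalized reverse correlation solve
nrc_solve <- function(eig, XtY, tol) {
  d <- eig$values
  keep <- which(d > tol * max(d) & d > 0)
  V <- eig$vectors[, keep, drop = FALSE]
  V %*% ((crossprod(V, XtY)) / d[keep])
}

#' Fit encoding models by normalized reverse correlation
#'
#' Weights are the pseudo-inverse of the stimulus autocorrelation
#' applied to the stimulus-response cross-correlation, with the
#' autocorrelation eigen-spectrum truncated at eigenvalues below
#' `tolerance * max(eigenvalue)`.  The tolerance is chosen to maximize
#' mean cross-validated prediction correlation within the estimation
#' set (contiguous-block folds); the final model is refit on the full
#' estimation set and evaluated on the held-out test block (by default
#' a contiguous, seeded 10% of frames at group boundaries).
#'
#' @param design lagged design matrix from [build_lagged_design()].
#' @param response numeric response vector (one electrode) or frames x
#'   electrodes matrix; multi-electrode fits share the (expensive)
#'   design-side computations.
#' @param tolerance_grid candidate tolerances, default
#'   `c(0.5, 0.1, 0.05, 0.01, 0.005, 0.001)`.
#' @param cv_folds number of contiguous CV folds, default 5.
#' @param test_frac held-out fraction, default 0.1.
#' @param seed seed for the split.
#' @param groups optional group id per frame (e.g. presentation index)
#'   so the split respects sentence boundaries.
#' @return For a vector response an object of class `strf_model`
#'   (weights as lags x features matrix, `delays_ms`, `feature_axis`,
#'   `tolerance`, `cv_table`, `test_r`, `split`); for a matrix
#'   response a list of such models (class `strf_model_list`).
#' @export
fit_nrc <- function(design, response,
                    tolerance_grid = c(0.5, 0.1, 0.05, 0.01, 0.005, 0.001),
                    cv_folds = 5, test_frac = 0.1, seed = 1, groups = NULL) {
  if (length(tolerance_grid) == 0) stopf("empty tolerance grid")
  tolerance_grid <- sort(tolerance_grid, decreasing = TRUE)
  Y <- as.matrix(response)
  nf <- nrow(design)
  if (nrow(Y) != nf) stopf("response length %d != design frames %d", nrow(Y), nf)
  csd <- apply(Y, 2, sd)
  if (any(csd == 0)) stopf("constant response (electrode %s)",
                           paste(which(csd == 0), collapse = ", "))
  p <- ncol(design)
  if (nf < 2 * p) warnf("only %d frames for %d parameters; regularization will dominate", nf, p)
  sp <- nrc_split(nf, test_frac, seed, groups)
  est <- sp$est; tst <- sp$test
  folds <- split(est, cut(seq_along(est), cv_folds, labels = FALSE))
  # per-fold cross-products and sums; training-set quantities by
  # subtraction, centered (auto/cross-covariance form) so the stimulus
  # DC mode does not dominate the eigen-spectrum
  XtX_f <- lapply(folds, function(ix) crossprod(design[ix, , drop = FALSE]))
  XtY_f <- lapply(folds, function(ix) crossprod(design[ix, , drop = FALSE],
                                                Y[ix, , drop = FALSE]))
  sx_f <- lapply(folds, function(ix) colSums(design[ix, , drop = FALSE]))
  sy_f <- lapply(folds, function(ix) colSums(Y[ix, , drop = FALSE]))
  n_f <- vapply(folds, length, integer(1))
  XtX_est <- Reduce(`+`, XtX_f)
  XtY_est <- Reduce(`+`, XtY_f)
  sx_est <- Reduce(`+`, sx_f)
  sy_est <- Reduce(`+`, sy_f)
  n_est <- sum(n_f)
  centered <- function(XtX, XtY, sx, sy, n) {
    list(XtX = XtX - outer(sx, sx) / n,
         XtY = XtY - outer(sx, sy) / n,
         mx = sx / n, my = sy / n)
  }
  n_tol <- length(tolerance_grid)
  n_el <- ncol(Y)
  cv_r <- array(NA_real_, c(cv_folds, n_tol, n_el))
  for (f in seq_len(cv_folds)) {
    tr <- centered(XtX_est - XtX_f[[f]], XtY_est - XtY_f[[f]],
                   sx_est - sx_f[[f]], sy_est - sy_f[[f]], n_est - n_f[f])
    eig <- eigen(tr$XtX, symmetric = TRUE)
    D_f <- sweep(design[folds[[f]], , drop = FALSE], 2, tr$mx)
    Y_f <- Y[folds[[f]], , drop = FALSE]
    for (ti in seq_len(n_tol)) {
      W <- nrc_solve(eig, tr$XtY, tolerance_grid[ti])
      P <- D_f %*% W
      for (e in seq_len(n_el)) cv_r[f, ti, e] <- safe_cor(P[, e], Y_f[, e])
    }
  }
  ce <- centered(XtX_est, XtY_est, sx_est, sy_est, n_est)
  eig_est <- eigen(ce$XtX, symmetric = TRUE)
  D_tst <- sweep(design[tst, , drop = FALSE], 2, ce$mx)
  delays <- attr(design, "delays_ms")
  nfeat <- attr(design, "n_features")
  models <- vector("list", n_el)
  for (e in seq_len(n_el)) {
    mean_r <- colMeans(matrix(cv_r[, , e], nrow = cv_folds), na.rm = TRUE)
    best <- which.max(mean_r)   # ties resolve to the larger tolerance
    w <- nrc_solve(eig_est, ce$XtY[, e, drop = FALSE], tolerance_grid[best])
    test_r <- safe_cor(as.vector(D_tst %*% w), Y[tst, e])
    models[[e]] <- structure(
      list(weights = matrix(w, nrow = length(delays), byrow = TRUE),
           delays_ms = delays, feature_axis = attr(design, "feature_axis"),
           frame_rate = attr(design, "frame_rate"),
           tolerance = tolerance_grid[best],
           intercept = ce$my[e] - sum(ce$mx * w),
           cv_table = data.frame(tolerance = tolerance_grid, mean_cv_r = mean_r),
           test_r = test_r, split = sp),
      class = "strf_model")
  }
  if (n_el == 1) models[[1]] else structure(models, class = "strf_model_list", split = sp)
}

#' @export
print.strf_model <- function(x, ...) {
  cat(sprintf("<strf_model> %d delays x %d features; tolerance %g; test r = %.3f\n",
              nrow(x$weights), ncol(x$weights), x$tolerance, x$test_r))
  invisible(x)
}

#' Predict a response from a fitted encoding model
#'
#' The prediction is the lagged design of the stimulus times the model
#' weights (equivalently, convolving the spectrogram with the STRF);
#' the correlation excludes the zero-padded startup frames.
#'
#' @param object a `strf_model`.
#' @param stim stimulus ([spectrogram()] or feature matrix) with axes
#'   compatible with the model.
#' @param response optional observed response for computing Pearson r.
#' @param ... unused.
#' @return List with `prediction` and `r` (`NA` with a `reason`
#'   attribute when undefined, e.g. zero weights).
#' @export
predict.strf_model <- function(object, stim, response = NULL, ...) {
  D <- build_lagged_design(stim, object$delays_ms,
                           frame_rate = object$frame_rate)
  if (attr(D, "n_features") != ncol(object$weights)) {
    stopf("stimulus has %d features but model expects %d",
          attr(D, "n_features"), ncol(object$weights))
  }
  b0 <- if (is.null(object$intercept)) 0 else object$intercept
  pred <- as.vector(D %*% as.vector(t(object$weights))) + b0
  r <- NULL
  if (!is.null(response)) {
    if (length(response) != length(pred)) stopf("response length mismatch")
    pad <- max(object$delays_ms) * attr(D, "frame_rate") / 1000
    keep <- (pad + 1):length(pred)
    if (all(object$weights == 0)) {
      r <- NA_real_
      attr(r, "reason") <- "zero weights: prediction is constant"
    } else {
      r <- safe_cor(pred[keep], response[keep])
    }
  }
  list(prediction = pred, r = r)
}

#' Frame-level semantic (word-embedding) stimulus representation
#'
#' Each 10-ms frame falling inside a word carries that word's embedding
#' vector; frames outside words are zero vectors.
#'
#' @param words data.frame with `word_type`, `onset_s`, `offset_s`
#'   (non-overlapping).
#' @param embeddings word-type x dim matrix with rownames = type id
#'   (see [synth_embeddings()]).
#' @param n_frames total number of frames to produce.
#' @param frame_rate frame rate, default 100 Hz.
#' @return dim x frames matrix with a `frame_rate` attribute, suitable
#'   for [build_lagged_design()].
#' @export
semantic_design <- function(words, embeddings, n_frames, frame_rate = 100) {
  wt <- as.character(words$word_type)
  missing <- setdiff(unique(wt), rownames(embeddings))
  if (length(missing)) {
    stopf("word type(s) missing from embedding table: %s",
          paste(missing, collapse = ", "))
  }
  o <- order(words$onset_s)
  if (any(words$onset_s[o][-1] < words$offset_s[o][-length(o)] - 1e-9)) {
    stopf("overlapping word annotations")
  }
  dim_e <- ncol(embeddings)
  M <- matrix(0, dim_e, n_frames)
  for (i in seq_len(nrow(words))) {
    i0 <- round(words$onset_s[i] * frame_rate) + 1
    i1 <- round(words$offset_s[i] * frame_rate)
    if (i1 < i0 || i0 > n_frames) next
    M[, i0:min(i1, n_frames)] <- embeddings[wt[i], ]
  }
  attr(M, "frame_rate") <- frame_rate
  M
}

#' Compare STRF and semantic model predictions by latency group
#'
#' Electrodes are partitioned at the latency cutoff; within each group
#' (and within each region if a `region` column is present) the two
#' models' held-out prediction correlations are compared by a
#' two-sided Wilcoxon rank-sum test, and the winning direction is
#' reported.
#'
#' @param results data.frame with columns `strf_r`, `semantic_r`,
#'   `latency_ms`, and optionally `region`.
#' @param cutoff_ms latency cutoff, default 200.
#' @return data.frame: region (or `"all"`), latency_group, n, p,
#'   direction.  Empty groups are skipped with a warning.
#' @export
compare_models <- function(results, cutoff_ms = 200) {
  stopifnot(all(c("strf_r", "semantic_r", "latency_ms") %in% names(results)))
  regions <- if ("region" %in% names(results)) {
    c("all", sort(unique(results$region)))
  } else "all"
  rows <- list()
  for (rg in regions) {
    sub <- if (rg == "all") results else results[results$region == rg, ]
    for (grp in c("short", "long")) {
      idx <- if (grp == "short") which(sub$latency_ms < cutoff_ms)
             else which(sub$latency_ms >= cutoff_ms)
      if (!length(idx)) {
        warnf("group '%s' empty in region '%s'; skipped", grp, rg)
        next
      }
      a <- sub$strf_r[idx]; b <- sub$semantic_r[idx]
      p <- if (length(idx) >= 2) {
        suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
      } else NA_real_
      dir <- if (median(a, na.rm = TRUE) > median(b, na.rm = TRUE)) "strf" else "semantic"
      rows[[length(rows) + 1]] <- data.frame(region = rg, latency_group = grp,
                                             n = length(idx), p = p,
                                             direction = dir)
    }
  }
  do.call(rbind, rows)
}
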