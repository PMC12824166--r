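#' Project electrode coordinates to the left hemisphere
#'
#' Right-hemisphere rows get a negative x coordinate (MNI sign flip);
#' left-hemisphere rows are unchanged.  Idempotent.
#'
#' @param table an electrode table (data.frame with `hemisphere` in
#'   `{"L","R"}` and coordinate columns `x`, `y`, `z`).
#' @return The table with projected x coordinates.
#' @export
project_to_left <- function(table) {
  if (!all(c("hemisphere", "x") %in% names(table))) {
    stopf("electrode table needs 'hemisphere' and 'x' columns")
  }
  if (any(is.na(table$hemisphere))) stopf("missing hemisphere label(s)")
  r <- table$hemisphere == "R"
  table$x[r] <- -abs(table$x[r])
  table
}

#' Fit Gaussian mixtures over a range of cluster numbers
#'
#' Full-covariance Gaussian mixture models are fit for each k in
#' `k_range`; the number of clusters is selected by the Bayesian
#' information criterion, and the mean silhouette width is reported for
#' k >= 2 (silhouette is undefined at k = 1).  The agreement flag
#' records whether the BIC choice coincides with the silhouette choice.
#'
#' Fitting uses model-based hierarchical initialization, which is
#' deterministic for fixed data, so the solution is identical for
#' identical `(data, seed)`; `n_restarts` is accepted for interface
#' stability.
#'
#' @param coords n x d coordinate matrix (d = 3 for MNI-like space).
#' @param k_range candidate cluster numbers, default `1:8`.
#' @param n_restarts accepted for interface compatibility.
#' @param seed integer seed.
#' @return An object of class `cluster_solution`: `table` (k, bic,
#'   silhouette), `selected_k` (BIC optimum), `silhouette_k`,
#'   `agreement`, `assignments`, `means`, `covariances`.
#' @export
fit_gmm_range <- function(coords, k_range = 1:8, n_restarts = 10, seed = 1) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n <= max(k_range)) stopf("need more points (%d) than max k (%d)", n, max(k_range))
  dd <- dist(coords)
  fits <- with_seed(seed, {
    lapply(k_range, function(k) {
      fit <- tryCatch(
        suppressWarnings(Mclust(coords, G = k, modelNames = "VVV",
                                verbose = FALSE)),
        error = function(e) NULL)
      if (is.null(fit) || is.null(fit$classification)) {
        # degenerate covariance: retry with a regularizing conjugate prior
        fit <- tryCatch(
          suppressWarnings(Mclust(coords, G = k, modelNames = "VVV",
                                  prior = mclust::priorControl(),
                                  verbose = FALSE)),
          error = function(e) NULL)
      }
      if (is.null(fit)) return(NULL)
      sil <- if (k >= 2 && length(unique(fit$classification)) == k) {
        mean(cluster::silhouette(fit$classification, dd)[, 3])
      } else NA_real_
      list(k = k, bic = as.numeric(fit$bic), silhouette = sil, fit = fit)
    })
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stopf("all mixture fits failed")
  if (any(!ok)) warnf("mixture fit failed for k = %s",
                      paste(k_range[!ok], collapse = ", "))
  fits <- fits[ok]
  tab <- data.frame(k = vapply(fits, `[[`, numeric(1), "k"),
                    bic = vapply(fits, `[[`, numeric(1), "bic"),
                    silhouette = vapply(fits, `[[`, numeric(1), "silhouette"))
  selected_k <- tab$k[which.max(tab$bic)]          # mclust BIC: larger is better
  sil_ok <- !is.na(tab$silhouette)
  silhouette_k <- if (any(sil_ok)) tab$k[sil_ok][which.max(tab$silhouette[sil_ok])] else NA_integer_
  agreement <- if (selected_k >= 2 && !is.na(silhouette_k)) {
    selected_k == silhouette_k
  } else NA
  best <- fits[[which.max(tab$bic)]]$fit
  structure(list(table = tab, selected_k = selected_k,
                 silhouette_k = silhouette_k, agreement = agreement,
                 assignments = as.integer(best$classification),
                 means = t(best$parameters$mean),
                 covariances = best$parameters$variance$sigma),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("<cluster_solution> selected k = %d (BIC); silhouette k = %s; agreement: %s\n",
              x$selected_k, x$silhouette_k, x$agreement))
  print(x$table, row.names = FALSE)
  invisible(x)
}
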