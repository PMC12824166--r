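#' Pipeline run configuration
#'
#' Collects every stage parameter of the end-to-end analysis together
#' with a master seed; each stochastic stage draws its own child seed
#' from the master via [child_seed()], so the whole run is
#' deterministic under the master seed.
#'
#' @param seed master integer seed.
#' @param synth named list of overrides for [synth_config()].
#' @param n_per_center,spread_mm electrode-map preset parameters.
#' @param delays_ms encoding-model delay axis.
#' @param tolerance_grid NRC tolerance grid.
#' @param cv_folds,test_frac cross-validation folds and held-out
#'   fraction.
#' @param k_range cluster numbers searched.
#' @param latency_cutoffs_ms KS-comparison cutoffs.
#' @param latency_window_s alignment window for the 1-ms latency
#'   analysis.
#' @param resp_window_s alignment window for responsivity.
#' @param n_perm permutations for tuning-vector tests.
#' @param alpha significance level.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1,
                       synth = list(),
                       n_per_center = 6, spread_mm = 2,
                       delays_ms = seq(0, 300, by = 10),
                       tolerance_grid = c(0.5, 0.1, 0.05, 0.01, 0.005, 0.001),
                       cv_folds = 5, test_frac = 0.1,
                       k_range = 1:6,
                       latency_cutoffs_ms = seq(80, 720, by = 40),
                       latency_window_s = c(-0.5, 1),
                       resp_window_s = NULL,
                       n_perm = 1000, alpha = 0.05) {
  cfg <- list(seed = as.integer(seed), synth = synth,
              n_per_center = n_per_center, spread_mm = spread_mm,
              delays_ms = delays_ms, tolerance_grid = tolerance_grid,
              cv_folds = cv_folds, test_frac = test_frac, k_range = k_range,
              latency_cutoffs_ms = latency_cutoffs_ms,
              latency_window_s = latency_window_s,
              resp_window_s = resp_window_s, n_perm = n_perm, alpha = alpha)
  structure(cfg, class = "run_config")
}

#' Bundled synthetic demo preset
#'
#' A small repeated-sentence protocol (4 unique sentences x 10
#' repeats, 2-s sentences with 1-s gaps, 24 bands) that exercises every
#' pipeline stage in a few minutes on one CPU.
#'
#' @param seed master seed.
#' @return A [run_config()].
#' @export
demo_config <- function(seed = 1) {
  run_config(seed = seed,
             synth = list(n_sentences = 4L, sentence_dur_s = 2, gap_s = 1,
                          n_repeats = 10L, n_bands = 24L, snr_db = 10,
                          embedding_dim = 16L, n_word_types = 50L))
}

# canonical (key-sorted) form for hashing
canonical <- function(x) {
  if (is.list(x)) {
    if (!is.null(names(x))) x <- x[order(names(x))]
    lapply(x, canonical)
  } else x
}

#' Stable hash of a run configuration
#'
#' MD5 of the canonical (key-sorted) JSON serialization; invariant
#' under key reordering.
#'
#' @param cfg a [run_config()].
#' @return Character MD5 hash.
#' @export
config_hash <- function(cfg) {
  j <- jsonlite::toJSON(canonical(unclass(cfg)), auto_unbox = TRUE, digits = NA)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(j, tf)
  unname(tools::md5sum(tf))
}

write_json_det <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
}

pipeline_synth_cfg <- function(cfg) {
  args <- cfg$synth
  args$seed <- child_seed(cfg$seed, "synth")
  do.call(synth_config, args)
}

# --- individual stages -----------------------------------------------------

stage_simulate <- function(cfg) {
  scfg <- pipeline_synth_cfg(cfg)
  stim <- synth_spectrogram(scfg)
  electrodes <- synth_electrodes_preset(seed = child_seed(cfg$seed, "electrodes"),
                                        n_per_center = cfg$n_per_center,
                                        spread_mm = cfg$spread_mm)
  n_el <- nrow(electrodes)
  band_axis <- stim$spec$band_centers_hz
  truth <- with_seed(child_seed(cfg$seed, "truth"), {
    lapply(seq_len(n_el), function(i) {
      gabor_strf_params(
        best_freq_hz = 2^runif(1, log2(band_axis[3]), log2(band_axis[length(band_axis) - 2])),
        peak_delay_ms = runif(1, 60, 140),
        temporal_mod_hz = runif(1, 2, 8),
        spectral_mod_cpo = runif(1, 0.2, 1),
        bandwidth_oct = runif(1, 0.6, 1.4),
        duration_ms = runif(1, 100, 180))
    })
  })
  delay_axis <- cfg$delays_ms
  strfs <- lapply(truth, make_gabor_strf, delay_axis_ms = delay_axis,
                  band_axis_hz = band_axis)
  # noisy high-gamma envelope per electrode at the stimulus frame rate
  env <- t(vapply(seq_len(n_el), function(i) {
    simulate_highgamma(strfs[[i]], stim$spec, snr_db = scfg$snr_db,
                       seed = child_seed(cfg$seed, paste0("hg", i)))$block$traces[1, ]
  }, numeric(ncol(stim$spec$values))))
  # carrier-modulated raw voltage at 1000 Hz (per-electrode carrier
  # frequency and phase, so common-average referencing is benign)
  raw_rate <- 1000
  nf <- ncol(env)
  t_env <- (seq_len(nf) - 1) / stim$spec$frame_rate_hz
  n_raw <- round(nf / stim$spec$frame_rate_hz * raw_rate)
  t_raw <- (seq_len(n_raw) - 1) / raw_rate
  raw <- with_seed(child_seed(cfg$seed, "raw"), {
    t(vapply(seq_len(n_el), function(i) {
      amp <- approx(t_env, pmax(env[i, ], 0) + 0.2, xout = t_raw, rule = 2)$y
      fc <- runif(1, 90, 130)
      ph <- runif(1, 0, 2 * pi)
      amp * cos(2 * pi * fc * t_raw + ph) + 0.05 * rnorm(n_raw)
    }, numeric(n_raw)))
  })
  list(stim = stim, electrodes = electrodes, truth_params = truth,
       truth_strfs = strfs, envelopes = env,
       raw = neural_block(raw, raw_rate, stage = "raw", ids = electrodes$id),
       scfg = scfg)
}

stage_preprocess <- function(cfg, sim) {
  ref <- common_average_reference(sim$raw)
  hg100 <- zscore_block(hilbert_highgamma(ref, out_rate = 100))
  hg1000 <- zscore_block(morlet_highgamma(ref, out_rate = 1000))
  list(hg100 = hg100, hg1000 = hg1000)
}

stage_responsivity <- function(cfg, sim, pre) {
  dur <- sim$scfg$sentence_dur_s
  win <- if (is.null(cfg$resp_window_s)) c(-0.5, dur) else cfg$resp_window_s
  tens <- align_trials(pre$hg100, sim$stim$events, window = win)
  flags <- responsivity_flags(tens, alpha = cfg$alpha)
  flags$region <- sim$electrodes$region
  flags$hemisphere <- sim$electrodes$hemisphere
  summ <- region_summary(flags$responsive, flags$magnitude, flags$region,
                         flags$hemisphere)
  list(flags = flags, summary = summ)
}

stage_latency <- function(cfg, sim, pre) {
  dur <- sim$scfg$sentence_dur_s
  win <- c(cfg$latency_window_s[1], min(cfg$latency_window_s[2], dur))
  tens <- align_trials(pre$hg1000, sim$stim$events, window = win)
  d <- dim(tens$values)
  lat <- do.call(rbind, lapply(seq_len(d[4]), function(el) {
    per_sent <- vapply(seq_len(d[1]), function(s) {
      detect_onset(tens, s, el, alpha = cfg$alpha)
    }, numeric(1))
    data.frame(electrode = sim$electrodes$id[el],
               region = sim$electrodes$region[el],
               hemisphere = sim$electrodes$hemisphere[el],
               latency_ms = electrode_latency(per_sent)$latency_ms)
  }))
  regs <- sort(unique(lat$region))
  prs <- utils::combn(regs, 2)
  ks <- lapply(seq_len(ncol(prs)), function(j) {
    a <- lat$latency_ms[lat$region == prs[1, j]]
    b <- lat$latency_ms[lat$region == prs[2, j]]
    if (all(is.na(a)) || all(is.na(b))) return(NULL)
    tab <- compare_latency_distributions(
      a, b, cutoffs_ms = cfg$latency_cutoffs_ms,
      n_comparisons = length(cfg$latency_cutoffs_ms) * ncol(prs))
    cbind(region_a = prs[1, j], region_b = prs[2, j], tab)
  })
  list(latencies = lat, ks = do.call(rbind, ks))
}

stage_clustering <- function(cfg, sim, resp) {
  keep <- which(resp$flags$responsive)
  coords <- as.matrix(project_to_left(sim$electrodes)[keep, c("x", "y", "z")])
  if (nrow(coords) <= max(cfg$k_range)) {
    warnf("too few responsive electrodes (%d) for clustering; using all electrodes",
          nrow(coords))
    keep <- seq_len(nrow(sim$electrodes))
    coords <- as.matrix(project_to_left(sim$electrodes)[, c("x", "y", "z")])
  }
  sol <- fit_gmm_range(coords, k_range = cfg$k_range,
                       seed = child_seed(cfg$seed, "gmm"))
  list(solution = sol, electrode_idx = keep)
}

stage_encoding <- function(cfg, sim, pre, lat) {
  stim <- sim$stim
  fr <- stim$spec$frame_rate_hz
  nf <- min(ncol(stim$spec$values), ncol(pre$hg100$traces))
  spec_t <- stim$spec
  spec_t$values <- spec_t$values[, seq_len(nf), drop = FALSE]
  design <- build_lagged_design(spec_t, cfg$delays_ms)
  groups <- rep(stim$events$presentation,
                each = round((stim$events$offset_s[1] - stim$events$onset_s[1] +
                              sim$scfg$gap_s) * fr))[seq_len(nf)]
  Y <- t(pre$hg100$traces[, seq_len(nf), drop = FALSE])
  strf_fits <- fit_nrc(design, Y, tolerance_grid = cfg$tolerance_grid,
                       cv_folds = cfg$cv_folds, test_frac = cfg$test_frac,
                       seed = child_seed(cfg$seed, "split"), groups = groups)
  emb <- synth_embeddings(sim$scfg$n_word_types, sim$scfg$embedding_dim,
                          seed = child_seed(cfg$seed, "embeddings"))
  sem <- semantic_design(stim$words, emb, n_frames = nf, frame_rate = fr)
  sem_design <- build_lagged_design(sem, cfg$delays_ms, frame_rate = fr)
  sem_fits <- fit_nrc(sem_design, Y, tolerance_grid = cfg$tolerance_grid,
                      cv_folds = cfg$cv_folds, test_frac = cfg$test_frac,
                      seed = child_seed(cfg$seed, "split"), groups = groups)
  results <- data.frame(
    electrode = sim$electrodes$id, region = sim$electrodes$region,
    latency_ms = lat$latencies$latency_ms,
    strf_r = vapply(strf_fits, `[[`, numeric(1), "test_r"),
    semantic_r = vapply(sem_fits, `[[`, numeric(1), "test_r"),
    tolerance = vapply(strf_fits, `[[`, numeric(1), "tolerance"))
  comparison <- tryCatch(compare_models(results), warning = function(w) {
    suppressWarnings(compare_models(results))
  })
  list(strf_fits = strf_fits, sem_fits = sem_fits, results = results,
       comparison = comparison)
}

stage_tuning <- function(cfg, sim, enc) {
  mtfs <- lapply(enc$strf_fits, mtf)
  marg <- lapply(mtfs, modulation_marginals)
  summ <- lapply(enc$strf_fits, tuning_summary)
  regions <- sim$electrodes$region
  tab <- data.frame(
    electrode = sim$electrodes$id, region = regions,
    best_frequency_hz = vapply(summ, function(s) {
      if (inherits(s, "tuning_summary")) s$best_frequency_hz else NA_real_
    }, numeric(1)),
    inhibitory_dominant = vapply(summ, function(s) {
      if (inherits(s, "tuning_summary")) s$inhibitory_dominant else NA
    }, logical(1)))
  regs <- sort(unique(regions))
  ens <- lapply(setNames(regs, regs), function(r) ensemble_mtf(mtfs[regions == r]))
  ok <- vapply(marg, is.list, logical(1))
  tests <- list()
  if (length(regs) >= 2) {
    prs <- utils::combn(regs, 2)
    for (j in seq_len(ncol(prs))) {
      ia <- which(regions == prs[1, j] & ok)
      ib <- which(regions == prs[2, j] & ok)
      if (length(ia) < 2 || length(ib) < 2) next
      for (which_v in c("temporal", "spectral")) {
        A <- do.call(rbind, lapply(marg[ia], `[[`, which_v))
        B <- do.call(rbind, lapply(marg[ib], `[[`, which_v))
        pt <- cosine_perm_test(A, B, n_perm = cfg$n_perm,
                               seed = child_seed(cfg$seed, paste0("perm", j, which_v)))
        tests[[paste(prs[1, j], prs[2, j], which_v, sep = "_")]] <-
          list(observed_cosine = pt$observed, p = pt$p)
      }
    }
    kb <- kruskal_bf(tab$best_frequency_hz[!is.na(tab$best_frequency_hz)],
                     tab$region[!is.na(tab$best_frequency_hz)])
    tests$best_frequency_kruskal <- kb
  }
  list(table = tab, ensembles = ens, tests = tests)
}

# --- orchestration ---------------------------------------------------------

stage_cached <- function(name, cfg, out_dir, cache, log, compute) {
  cache_dir <- file.path(out_dir, "cache")
  path <- file.path(cache_dir, sprintf("%s-%s.rds", name, config_hash(cfg)))
  if (cache && file.exists(path)) {
    res <- tryCatch(readRDS(path), error = function(e) NULL)
    if (!is.null(res)) {
      log(sprintf("stage %s: loaded from cache", name))
      return(res)
    }
    warnf("corrupt cache for stage %s; recomputing", name)
  }
  log(sprintf("stage %s: computing", name))
  res <- tryCatch(compute(), error = function(e) {
    stopf("stage %s failed: %s", name, conditionMessage(e))
  })
  if (cache) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    saveRDS(res, path)
  }
  res
}

#' Run the full analysis pipeline on synthetic data
#'
#' Orchestrates simulate, preprocess, responsivity, latency,
#' clustering, encoding and tuning in order, writing CSV/JSON tables,
#' a ground-truth container and a log to `out_dir`.  Deterministic
#' under the master seed: two runs from the same config produce
#' byte-identical tables.  Stage outputs are cached keyed by the
#' config hash; corrupt caches are recomputed with a warning.
#'
#' @param cfg a [run_config()] (e.g. [demo_config()]).
#' @param out_dir output directory (created if needed).
#' @param cache reuse cached stage outputs, default TRUE.
#' @param stop_after last stage to run: one of `"simulate"`,
#'   `"preprocess"`, `"responsivity"`, `"latency"`, `"clustering"`,
#'   `"encoding"`, `"tuning"` (default: the full pipeline).
#' @return Invisibly, a list with the completed stage results.
#' @export
run_pipeline <- function(cfg, out_dir, cache = TRUE, stop_after = "tuning") {
  stopifnot(inherits(cfg, "run_config"))
  ord <- c(simulate = 1, preprocess = 2, responsivity = 3, latency = 4,
           clustering = 5, encoding = 6, tuning = 7)
  stop_after <- match.arg(stop_after, names(ord))
  lvl <- ord[[stop_after]]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  log <- function(msg) log_lines <<- c(log_lines, msg)
  hash <- config_hash(cfg)
  log(sprintf("run_pipeline: config hash %s, master seed %d", hash, cfg$seed))
  done <- list()

  sim <- stage_cached("simulate", cfg, out_dir, cache, log, function() stage_simulate(cfg))
  container_write(
    c(setNames(sim$truth_strfs, paste0("strf_", sim$electrodes$id)),
      list(envelopes = sim$envelopes)),
    file.path(out_dir, "ground_truth.rds"),
    meta = list(config = canonical(unclass(cfg)),
                regions = as.character(sim$electrodes$region)))
  done$sim <- sim
  if (lvl >= 2) {
    pre <- stage_cached("preprocess", cfg, out_dir, cache, log, function() stage_preprocess(cfg, sim))
    done$pre <- pre
  }
  if (lvl >= 3) {
    resp <- stage_cached("responsivity", cfg, out_dir, cache, log, function() stage_responsivity(cfg, sim, pre))
    data.table::fwrite(resp$flags, file.path(out_dir, "responsivity.csv"))
    data.table::fwrite(resp$summary$table, file.path(out_dir, "region_summary.csv"))
    done$responsivity <- resp
  }
  if (lvl >= 4) {
    lat <- stage_cached("latency", cfg, out_dir, cache, log, function() stage_latency(cfg, sim, pre))
    data.table::fwrite(lat$latencies, file.path(out_dir, "latencies.csv"))
    if (!is.null(lat$ks)) write_json_det(lat$ks, file.path(out_dir, "latency_ks.json"))
    done$latency <- lat
  }
  if (lvl >= 5) {
    clus <- stage_cached("clustering", cfg, out_dir, cache, log,
                         function() suppressWarnings(stage_clustering(cfg, sim, resp)))
    write_json_det(list(selected_k = clus$solution$selected_k,
                        silhouette_k = clus$solution$silhouette_k,
                        agreement = clus$solution$agreement,
                        table = clus$solution$table),
                   file.path(out_dir, "clusters.json"))
    data.table::fwrite(data.frame(electrode = sim$electrodes$id[clus$electrode_idx],
                                  cluster = clus$solution$assignments),
                       file.path(out_dir, "cluster_assignments.csv"))
    done$clustering <- clus
  }
  if (lvl >= 6) {
    enc <- stage_cached("encoding", cfg, out_dir, cache, log,
                        function() suppressWarnings(stage_encoding(cfg, sim, pre, lat)))
    data.table::fwrite(enc$results, file.path(out_dir, "encoding.csv"))
    data.table::fwrite(enc$comparison, file.path(out_dir, "model_comparison.csv"))
    done$encoding <- enc
  }
  if (lvl >= 7) {
    tun <- stage_cached("tuning", cfg, out_dir, cache, log, function() stage_tuning(cfg, sim, enc))
    data.table::fwrite(tun$table, file.path(out_dir, "tuning.csv"))
    write_json_det(tun$tests, file.path(out_dir, "tuning_tests.json"))
    done$tuning <- tun
  }

  manifest <- list(config = canonical(unclass(cfg)), config_hash = hash,
                   package_version = as.character(utils::packageVersion("speechenc")),
                   last_stage = stop_after,
                   outputs = sort(setdiff(list.files(out_dir), c("cache", "log.txt", "manifest.json"))))
  write_json_det(manifest, file.path(out_dir, "manifest.json"))
  log(sprintf("run_pipeline: done (through %s)", stop_after))
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  invisible(done)
}
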