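#' Pipeline configuration
#'
#' Bundles every stage parameter with its published default: 2-35 Hz EEG
#' bandpass, 200/2 uV artifact bounds, 64 Hz analysis rate, 0.1 Hz
#' highpass / 32 Hz lowpass for the phase path, `[0.01, 20]` Hz respiration
#' bandpass, 4 s Bartlett segments, 2 s PLV windows, 500 surrogate pairs at
#' 90% confidence on the 4-32 Hz (1 Hz) grid, `[4,32]` @ 0.25 Hz EEG and
#' `[0.0625,16]` @ 0.0625 Hz respiration feature grids, and 10-fold CV.
#' The configuration serializes with the results, so a run is reproducible
#' from its output directory alone.
#'
#' @param synthetic a [synthetic_config()] describing the cohort to simulate,
#'   or `NULL` when reading sessions from disk.
#' @param input_paths character vector of EDF/BDF session files (used when
#'   `synthetic` is `NULL`; condition/subject come from the sidecars).
#' @param n_subjects number of simulated subjects.
#' @param stages character vector of stages to run, a subset of
#'   `c("preprocess", "spectral", "respiration", "synchrony", "classify")`
#'   (simulation always runs). Disabling `"preprocess"` makes every analysis
#'   stage fail fast with a named dependency error.
#' @param use_ica run ocular ICA cleanup in the spectral preprocessing path.
#' @param eeg_bandpass,artifact_upper,artifact_lower,analysis_fs,phase_highpass,phase_lowpass,resp_bandpass
#'   preprocessing parameters (Hz, uV).
#' @param psd_segment_sec Bartlett segment length in seconds.
#' @param plv_win_sec PLV window length in seconds.
#' @param n_surrogate_pairs,surrogate_confidence surrogate-threshold settings.
#' @param phase_freqs phase-estimation grid in Hz.
#' @param eeg_feature_grid,resp_feature_grid `c(fmin, fmax, df)` in Hz.
#' @param feature_channels EEG channels used for classification features
#'   (default: all available; fewer keeps the feature dimension tractable).
#' @param feature_stride take every k-th time sample of the S-transform maps
#'   as a feature vector (1 = every sample as published; larger strides keep
#'   desk-scale runs tractable).
#' @param resp_transition transition width (Hz) of the respiration bandpass;
#'   the default matches the published filter-length scale at 256 Hz.
#' @param folds,kcca_kappa,kcca_max_lag,kcca_max_n,svm_sigma_grid,svm_cost_grid
#'   classifier settings ([train_eval_svm()], [kcca_dependency()]).
#' @param svm_fold_gap cross-validation embargo in pre-downsampling sample
#'   positions (scaled by the selected KCCA factor before use).
#' @param svm_sigma_rel when `svm_sigma_grid` is `NULL`, the RBF width grid is
#'   `svm_sigma_rel` times the median pairwise feature distance.
#' @param seed master seed; per-stage seeds derive from it via [derive_seed()].
#' @param out_dir optional output directory for CSV/JSON result files.
#' @return object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            input_paths = NULL,
                            n_subjects = 4,
                            stages = c("preprocess", "spectral", "respiration",
                                       "synchrony", "classify"),
                            use_ica = TRUE,
                            eeg_bandpass = c(2, 35),
                            artifact_upper = 200, artifact_lower = 2,
                            analysis_fs = 64,
                            phase_highpass = 0.1, phase_lowpass = 32,
                            resp_bandpass = c(0.01, 20),
                            resp_transition = 0.25,
                            psd_segment_sec = 4,
                            plv_win_sec = 2,
                            n_surrogate_pairs = 500,
                            surrogate_confidence = 0.9,
                            phase_freqs = seq(4, 32, by = 1),
                            eeg_feature_grid = c(4, 32, 0.25),
                            resp_feature_grid = c(0.0625, 16, 0.0625),
                            feature_channels = NULL,
                            feature_stride = 1L,
                            folds = 10,
                            kcca_kappa = 0.02, kcca_max_lag = 10, kcca_max_n = 500,
                            svm_sigma_grid = NULL, svm_sigma_rel = 2^(-4:4),
                            svm_cost_grid = 2^(-2:6), svm_fold_gap = 0L,
                            seed = 1L, out_dir = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  src <- if (!is.null(x$synthetic)) sprintf("synthetic (%d subjects)", x$n_subjects)
         else sprintf("%d files", length(x$input_paths))
  cat(sprintf("<pipeline_config> input=%s | stages: %s | seed=%d\n",
              src, paste(x$stages, collapse = ", "), x$seed))
  invisible(x)
}

# Spectral-path preprocessing for one EEG recording: bandpass, artifact mask,
# optional ocular ICA, downsample, transient discard. Returns recording + mask.
preprocess_eeg_spectral <- function(eeg, cfg) {
  bp <- design_fir("bandpass", cfg$eeg_bandpass, eeg$fs)
  filt <- fir_filter(eeg, bp)
  mask <- amplitude_artifact_mask(filt, upper = cfg$artifact_upper,
                                  lower = cfg$artifact_lower)
  if (cfg$use_ica)
    filt <- remove_ocular_ica(filt, seed = derive_seed(cfg$seed, "ica"))
  fac <- as.integer(round(eeg$fs / cfg$analysis_fs))
  ds <- downsample(filt, cfg$analysis_fs, alias_tol = 0.05)
  mask <- downsample_mask(mask, fac)
  n_tr <- ceiling(bp$taps / fac)
  out <- discard_transient(ds, n_tr)
  mask$keep <- mask$keep[, -(seq_len(n_tr)), drop = FALSE]
  list(rec = out, mask = mask)
}

# Phase-path preprocessing: 0.1 Hz highpass + 32 Hz lowpass, downsample, trim.
preprocess_eeg_phase <- function(eeg, cfg) {
  hp <- design_fir("highpass", cfg$phase_highpass, eeg$fs)
  lp <- design_fir("lowpass", cfg$phase_lowpass, eeg$fs,
                   transition = min(2, eeg$fs / 2 - cfg$phase_lowpass))
  filt <- fir_filter(fir_filter(eeg, hp), lp)
  fac <- as.integer(round(eeg$fs / cfg$analysis_fs))
  ds <- downsample(filt, cfg$analysis_fs, alias_tol = 0.05)
  discard_transient(ds, ceiling(max(hp$taps, lp$taps) / fac))
}

preprocess_resp <- function(resp, cfg) {
  bp <- design_fir("bandpass", cfg$resp_bandpass, resp$fs,
                   transition = cfg$resp_transition)
  filt <- fir_filter(resp, bp)
  ds <- downsample(filt, cfg$analysis_fs, alias_tol = 0.05)
  discard_transient(ds, ceiling(bp$taps / round(resp$fs / cfg$analysis_fs)))
}

st_grid <- function(g) seq_fgrid(g[1], g[2], g[3])

# Session-level classification features for one modality.
session_features <- function(recs, grid, fs, channels = NULL, stride = 1L) {
  maps_by_session <- lapply(recs, function(rec) {
    chs <- channels %||% rec$channel_labels
    idx <- match(chs, rec$channel_labels)
    plan <- st_plan(ncol(rec$samples), rec$fs, grid)
    maps <- lapply(idx, function(i) stransform(rec$samples[i, ], rec$fs, plan = plan))
    names(maps) <- chs
    f <- extract_features(maps, labels = rep(rec$condition, ncol(rec$samples)))
    if (stride > 1L) {
      keep <- seq(1L, nrow(f$x), by = as.integer(stride))
      f$x <- f$x[keep, , drop = FALSE]
      f$labels <- f$labels[keep]
    }
    f
  })
  maps_by_session
}

concat_features <- function(fsets) {
  x <- do.call(rbind, lapply(fsets, function(f) f$x))
  labels <- unlist(lapply(fsets, function(f) f$labels))
  out <- fsets[[1]]
  out$x <- x
  out$labels <- labels
  out
}

# Downsample-by-KCCA then classify one subject's labeled feature sequence.
classify_features <- function(features, cfg, seed) {
  sel <- tryCatch(
    suppressWarnings(select_downsampling_factor(
      features, max_lag = cfg$kcca_max_lag, kappa = cfg$kcca_kappa,
      max_n = cfg$kcca_max_n)),
    error = function(e) NULL)
  L <- if (is.null(sel)) 1L else sel$L
  feats <- apply_downsampling(features, L)
  sigma_grid <- cfg$svm_sigma_grid
  if (is.null(sigma_grid))
    sigma_grid <- cfg$svm_sigma_rel * median_pairwise_dist(feats$x)
  rep_ <- train_eval_svm(feats, folds = cfg$folds,
                         sigma_grid = sigma_grid,
                         cost_grid = cfg$svm_cost_grid,
                         fold_gap = ceiling(cfg$svm_fold_gap / max(L, 1)),
                         seed = seed)
  rep_$L_ds <- L
  rep_
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) a cohort of labeled EEG + respiration sessions, then
#' runs the enabled stages: band-by-region Bartlett power with the two-way
#' within-subject ANOVA per band; respiration Stockwell contrast; PLV
#' synchrony counting against a surrogate threshold; and per-subject
#' EEG-only / respiration-only / joint RBF-SVM classification. Stage failures
#' are caught and reported per stage; stages whose inputs were disabled fail
#' fast with a named dependency error.
#'
#' @param config a [pipeline_config()].
#' @return object of class `"pipeline_result"`: per-stage outputs, per-stage
#'   `status`, the `config` and a config hash. If `config$out_dir` is set,
#'   CSV/JSON result files are written there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  status <- list()
  res <- list(config = cfg)

  # --- input sessions -------------------------------------------------------
  if (!is.null(cfg$synthetic)) {
    sessions <- generate_cohort(cfg$synthetic, cfg$n_subjects)
  } else {
    if (is.null(cfg$input_paths)) stop("neither synthetic config nor input paths given")
    sessions <- lapply(cfg$input_paths, read_session)
    names(sessions) <- vapply(sessions, function(s)
      paste(s$eeg$subject_id, s$eeg$condition, sep = "_"), "")
  }
  status$simulate <- "ok"

  # --- preprocessing --------------------------------------------------------
  if (!("preprocess" %in% cfg$stages)) {
    downstream <- intersect(cfg$stages,
                            c("spectral", "respiration", "synchrony", "classify"))
    for (s in downstream)
      status[[s]] <- sprintf("dependency error: stage '%s' requires 'preprocess'", s)
    return(pipeline_bundle(res, status, failed = length(downstream) > 0))
  }
  pre <- tryCatch({
    lapply(sessions, function(s) {
      spec <- preprocess_eeg_spectral(s$eeg, cfg)
      list(spectral = spec$rec, mask = spec$mask,
           phase = preprocess_eeg_phase(s$eeg, cfg),
           resp = preprocess_resp(s$resp, cfg),
           subject = s$eeg$subject_id, condition = s$eeg$condition)
    })
  }, error = function(e) e)
  if (inherits(pre, "error")) {
    status$preprocess <- conditionMessage(pre)
    return(pipeline_bundle(res, status, failed = TRUE))
  }
  status$preprocess <- "ok"

  # --- spectral stage -------------------------------------------------------
  if ("spectral" %in% cfg$stages) {
    out <- tryCatch({
      N <- round(cfg$psd_segment_sec * cfg$analysis_fs)
      rows <- lapply(pre, function(p) {
        psd <- bartlett_psd(p$spectral, N, mask = p$mask)
        band_region_power(psd, biosemi32_regions(),
                          subject_id = p$subject, condition = p$condition)
      })
      tab <- do.call(rbind, rows)
      list(power_table = tab, anova = band_power_anova(tab))
    }, error = function(e) e)
    if (inherits(out, "error")) status$spectral <- conditionMessage(out)
    else { res$spectral <- out; status$spectral <- "ok" }
  }

  # --- respiration stage ----------------------------------------------------
  if ("respiration" %in% cfg$stages) {
    out <- tryCatch({
      grid <- st_grid(cfg$resp_feature_grid)
      maps <- lapply(pre, function(p) list(
        subject = p$subject, condition = p$condition,
        map = stransform(p$resp$samples[1, ], p$resp$fs,
                         grid[1], grid[length(grid)], grid[2] - grid[1])))
      respiration_tfa_contrast(maps)
    }, error = function(e) e)
    if (inherits(out, "error")) status$respiration <- conditionMessage(out)
    else { res$respiration <- out; status$respiration <- "ok" }
  }

  # --- synchrony stage ------------------------------------------------------
  if ("synchrony" %in% cfg$stages) {
    out <- tryCatch({
      ref_ch <- "Cz"
      ctl <- Filter(function(p) p$condition == "control", pre)
      ref <- unlist(lapply(ctl, function(p) {
        i <- match(ref_ch, p$phase$channel_labels)
        if (is.na(i)) i <- 1L
        p$phase$samples[i, ]
      }))
      ref <- ref[seq_len(min(length(ref), 900 * cfg$analysis_fs))]
      thr <- surrogate_threshold(ref, fs = cfg$analysis_fs,
                                 n_pairs = cfg$n_surrogate_pairs,
                                 confidence = cfg$surrogate_confidence,
                                 freqs = cfg$phase_freqs,
                                 win_sec = cfg$plv_win_sec,
                                 seed = derive_seed(cfg$seed, "synchrony"))
      plvs <- do.call(rbind, lapply(pre, function(p)
        pair_plv_summaries(p$phase, freqs = cfg$phase_freqs,
                           win_sec = cfg$plv_win_sec,
                           exceed_at = thr$threshold)))
      list(threshold = thr, pair_plv = plvs,
           counts = count_synchronous_pairs(plvs, thr))
    }, error = function(e) e)
    if (inherits(out, "error")) status$synchrony <- conditionMessage(out)
    else { res$synchrony <- out; status$synchrony <- "ok" }
  }

  # --- classification stage -------------------------------------------------
  if ("classify" %in% cfg$stages) {
    out <- tryCatch({
      eeg_grid <- st_grid(cfg$eeg_feature_grid)
      resp_grid <- st_grid(cfg$resp_feature_grid)
      subjects <- unique(vapply(pre, function(p) p$subject, ""))
      reports <- list()
      for (s in subjects) {
        ps <- Filter(function(p) p$subject == s, pre)
        # the two modality paths discard different filter transients; align
        # each session's recordings on their common tail
        ps <- lapply(ps, function(p) {
          m <- min(ncol(p$phase$samples), ncol(p$resp$samples))
          p$phase <- with_samples(p$phase, p$phase$samples[, ncol(p$phase$samples) - m + seq_len(m), drop = FALSE])
          p$resp <- with_samples(p$resp, p$resp$samples[, ncol(p$resp$samples) - m + seq_len(m), drop = FALSE])
          p
        })
        feeg <- concat_features(session_features(
          lapply(ps, function(p) p$phase), eeg_grid, cfg$analysis_fs,
          channels = cfg$feature_channels, stride = cfg$feature_stride))
        fresp <- concat_features(session_features(
          lapply(ps, function(p) p$resp), resp_grid, cfg$analysis_fs,
          stride = cfg$feature_stride))
        fjoint <- build_joint_features(feeg, fresp)
        seed_s <- derive_seed(cfg$seed, "classify",
                              extra = match(s, subjects))
        reports[[s]] <- list(
          eeg = classify_features(feeg, cfg, seed_s),
          resp = classify_features(fresp, cfg, seed_s),
          joint = classify_features(fjoint, cfg, seed_s))
      }
      acc <- t(vapply(reports, function(r)
        c(eeg = r$eeg$accuracy, resp = r$resp$accuracy, joint = r$joint$accuracy),
        numeric(3)))
      list(reports = reports, accuracy = acc, mean_accuracy = colMeans(acc))
    }, error = function(e) e)
    if (inherits(out, "error")) status$classify <- conditionMessage(out)
    else { res$classify <- out; status$classify <- "ok" }
  }

  bundle <- pipeline_bundle(res, status)
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(bundle, cfg$out_dir)
  bundle
}

pipeline_bundle <- function(res, status, failed = FALSE) {
  res$status <- status
  res$failed <- failed || any(vapply(status, function(s) s != "ok", logical(1)))
  class(res) <- "pipeline_result"
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  for (s in names(x$status)) cat(sprintf("  %-12s %s\n", s, x$status[[s]]))
  if (!is.null(x$classify))
    cat("  mean CV accuracy:",
        paste(sprintf("%s=%.3f", names(x$classify$mean_accuracy),
                      x$classify$mean_accuracy), collapse = " "), "\n")
  invisible(x)
}

write_pipeline_outputs <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  if (!is.null(bundle$spectral)) {
    w(bundle$spectral$power_table, "band_region_power.csv")
    an <- do.call(rbind, lapply(names(bundle$spectral$anova), function(b) {
      d <- as.data.frame(bundle$spectral$anova[[b]])
      d$band <- b
      d$lambda <- attr(bundle$spectral$anova[[b]], "lambda")
      d
    }))
    jsonlite::write_json(an, file.path(out_dir, "spectral_anova.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(bundle$respiration)) {
    w(bundle$respiration$spectra, "respiration_spectra.csv")
    jsonlite::write_json(as.data.frame(bundle$respiration$anova),
                         file.path(out_dir, "respiration_anova.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(bundle$synchrony)) {
    w(bundle$synchrony$counts, "synchrony_counts.csv")
    thr <- bundle$synchrony$threshold
    jsonlite::write_json(thr[c("threshold", "confidence", "n_pairs", "seed", "method")],
                         file.path(out_dir, "surrogate_threshold.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(bundle$classify)) {
    acc <- as.data.frame(bundle$classify$accuracy)
    acc$subject <- rownames(acc)
    w(acc, "classifier_accuracy.csv")
  }
  st <- c(bundle$status, list(seed = bundle$config$seed))
  jsonlite::write_json(st, file.path(out_dir, "run_status.json"), auto_unbox = TRUE)
  invisible(out_dir)
}
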