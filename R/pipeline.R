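# End-to-end orchestration: preprocess each recording, build the per-beat
# feature table, fit the cohort PCA basis and BP-reference splines, assemble
# the calibrated regression dataset, run the nested cross-validated models
# and the SHAP importance analysis.

#' Preprocess one recording
#'
#' Filters both signals, segments and normalizes PPG beats, fits the
#' 4-Gaussian decomposition with sequential seeding, applies the fit-loss
#' quality gate, detects QRS complexes and computes per-beat PAT.
#'
#' @param rec a recording (see [generate_cohort()]).
#' @param config a `ppgbp_config`.
#' @return list: `beats`, `fits`, `fiducials`, `qrs`, `pat`, `ecg_filt`.
#' @export
process_recording <- function(rec, config = default_config()) {
  pp <- config$preprocessing
  ppg_f <- filter_ppg(rec$ppg$x, rec$ppg$fs, band = pp$ppg_band)
  beats <- segment_beats(ppg_f, rec$ppg$fs, beat_len = pp$beat_len,
                         sg_order = pp$sg_order, sg_window = pp$sg_window,
                         template_n = pp$sqi_template_beats)
  fits <- fit_beats(beats, max_iter = config$gauss$max_iter,
                    ftol = config$gauss$ftol,
                    sigma_floor = config$gauss$sigma_floor)
  for (k in seq_along(fits)) {
    beats$sqi[k] <- gate_quality(fits[[k]], beats$sqi[k],
                                 gate = config$gauss$loss_gate)
  }
  fids <- lapply(seq_len(nrow(beats$zeta)), function(k) {
    detect_fiducials(beats$zeta[k, ], beats$vpg[k, ], beats$apg[k, ],
                     prominence = config$fiducials$prominence,
                     notch_window = config$fiducials$notch_window,
                     e_margin = config$fiducials$e_margin)
  })
  ecg_f <- filter_ecg(rec$ecg$x, rec$ecg$fs,
                      mains_hz = pp$mains_hz, highpass_hz = pp$ecg_highpass)
  qrs <- detect_qrs(ecg_f, rec$ecg$fs)
  pat <- compute_pat(qrs, beats, range = pp$pat_range)
  list(beats = beats, fits = fits, fiducials = fids, qrs = qrs, pat = pat,
       ecg_filt = ecg_f)
}

#' Per-beat PPG feature table
#'
#' Evaluates the morphology, APG and Gaussian feature blocks (and, given a
#' basis, the PCA projections) for every beat of a processed recording.
#'
#' @param proc output of [process_recording()].
#' @param height_cm participant height.
#' @param basis optional `ppgbp_pca_basis`.
#' @param config a `ppgbp_config`.
#' @return data.frame with `onset_time`, `sqi` and 52 (or 61 with PCA)
#'   feature columns.
#' @export
beat_feature_table <- function(proc, height_cm, basis = NULL,
                               config = default_config()) {
  beats <- proc$beats
  rows <- lapply(seq_len(nrow(beats$zeta)), function(k) {
    z <- beats$zeta[k, ]; v <- beats$vpg[k, ]; a <- beats$apg[k, ]
    out <- c(
      morphology_features(z, v, proc$fiducials[[k]], height_cm,
                          nha_harmonics = config$features$nha_harmonics),
      apg_features(proc$fiducials[[k]], z),
      gaussian_features(proc$fits[[k]])
    )
    if (!is.null(basis)) out <- c(out, pca_features(z, v, a, basis))
    out
  })
  df <- as.data.frame(do.call(rbind, rows))
  cbind(data.frame(onset_time = beats$onset_time, sqi = beats$sqi), df)
}

#' Names of the dataset's feature blocks
#'
#' @return list with `ppg` (61 names), `ecg` (10), `demo` (6).
#' @export
feature_names <- function() {
  list(
    ppg = c("n_amp", "ri", "delta_t", "ct", "t_sys", "t_dia", "t_ratio",
            "stt", "svri", "a1", "a2", "ipa", "width25", "width50",
            "pi_idx", "nha", "ihar", "skewness", "kurtosis",
            "sys_mu", "sys_sigma", "dia_mu", "dia_sigma",
            "b_a", "c_a", "d_a", "e_a", "agi", "slope_bc", "slope_bd",
            "ppg_ai",
            paste0("a_g", 1:4), paste0("mu_g", 1:4), paste0("sigma_g", 1:4),
            "gauss_ai", "gauss_ri", "gauss_rtt", "gauss_ai_r", "gauss_ri_r",
            "gauss_lvet", "gauss_sys_dias", "gauss_a4_a1",
            "gauss_sigma4_a1",
            paste0("ppg_pca", 1:3), paste0("vpg_pca", 1:3),
            paste0("apg_pca", 1:3)),
    ecg = c("hjorth_mobility", "hjorth_complexity", "fractal_dimension",
            "shannon_entropy", "approx_entropy", "sample_entropy",
            "mse_2", "mse_4", "mse_6", "mse_8"),
    demo = c("age", "sex", "height", "weight", "bmi", "bp_cal")
  )
}

#' Assemble the calibrated regression dataset for a cohort
#'
#' Runs preprocessing and feature extraction for every recording, fits the
#' pooled PCA basis and the per-channel BP-reference splines (penalty
#' selected by cohort leave-one-out error), windows the features around the
#' reference grid (40-s windows at the cuff rate; 15-s windows at the
#' augmentation rate), conditions and calibrates the streams, attaches
#' demographics and stacks all participants.
#'
#' @param cohort list of recordings.
#' @param config a `ppgbp_config`.
#' @param augment build augmented rows at the `dataset$f_aug` grid.
#' @param verbose emit one progress line per stage.
#' @return Object of class `ppgbp_dataset`: `X` (features), `y`
#'   (dsbp/dmap/ddbp), `participant_id`, `t`, `augmented`, `feature_names`
#'   (dynamic), `ecg_features`, `demo_names`, `baselines`, `pca_basis`,
#'   `spline_p`.
#' @export
assemble_dataset <- function(cohort, config = default_config(),
                             augment = TRUE, verbose = FALSE) {
  validate_config(config)
  say <- function(...) if (verbose) message(sprintf(...))
  ds_cfg <- config$dataset
  say("preprocessing %d recordings", length(cohort))
  procs <- lapply(cohort, process_recording, config = config)
  say("fitting PCA basis")
  basis <- fit_pca_basis(lapply(procs, `[[`, "beats"),
                         sqi_threshold = config$features$sqi_min,
                         n_comp = config$features$pca_n)
  say("selecting spline penalties")
  channels <- c("sbp", "map", "dbp")
  p_sel <- lapply(channels, function(ch) {
    series <- lapply(cohort, function(r) {
      data.frame(t = r$cuff$t, y = r$cuff[[ch]])
    })
    select_p(series, grid = config$bp_reference$p_grid,
             time_scale = config$bp_reference$time_scale)$p
  })
  names(p_sel) <- channels
  fn <- feature_names()
  ecg_opts <- list(m = config$ecg_features$sampen_m,
                   r_frac = config$ecg_features$sampen_r,
                   mse_scales = config$ecg_features$mse_scales,
                   k_max = config$ecg_features$higuchi_kmax,
                   n_bins = config$ecg_features$entropy_bins)
  all_rows <- list()
  baselines <- list()
  for (i in seq_along(cohort)) {
    rec <- cohort[[i]]; proc <- procs[[i]]
    say("building windows for %s", rec$participant_id)
    splines <- lapply(channels, function(ch) {
      fit_smoothing_spline(rec$cuff$t, rec$cuff[[ch]], p_sel[[ch]],
                           time_scale = config$bp_reference$time_scale)
    })
    names(splines) <- channels
    beat_df <- beat_feature_table(proc, rec$demographics$height, basis,
                                  config)
    grid <- resample_spline(splines$sbp, config$bp_reference$f_bp)$t
    make_rows <- function(times, w) {
      wf <- window_features(beat_df, proc$pat, proc$ecg_filt, rec$ecg$fs,
                            proc$qrs, times, window_s = w,
                            sqi_min = ds_cfg$sqi_min, ecg_opts = ecg_opts)
      for (ch in channels) wf[[ch]] <- predict(splines[[ch]], wf$t)
      wf
    }
    rows <- make_rows(grid, ds_cfg$window_s)
    rows$augmented <- FALSE
    if (augment) {
      aug_t <- resample_spline(splines$sbp, ds_cfg$f_aug)$t
      aug_t <- aug_t[!vapply(aug_t, function(x) any(abs(grid - x) < 1e-6),
                             logical(1))]
      if (length(aug_t)) {
        arows <- make_rows(aug_t, ds_cfg$window_aug_s)
        arows$augmented <- TRUE
        rows <- rbind(rows, arows)
      }
    }
    rows <- rows[order(rows$t), ]
    dyn_cols <- c(fn$ppg, "pat", fn$ecg)
    rows <- condition_feature_streams(rows, dyn_cols,
                                      mad_k = ds_cfg$outlier_mad,
                                      mad_window = ds_cfg$outlier_window)
    cal <- calibrate(rows, rest_window = c(0, config$cohort$rest_s),
                     feature_cols = dyn_cols)
    r <- cal$rows
    demo <- rec$demographics
    r$participant_id <- rec$participant_id
    r$age <- demo$age; r$sex <- demo$sex; r$height <- demo$height
    r$weight <- demo$weight; r$bmi <- demo$bmi
    r$bp_cal <- cal$baseline_bp[["sbp"]]
    all_rows[[i]] <- r
    baselines[[rec$participant_id]] <- cal[c("baseline_features",
                                             "baseline_bp")]
  }
  big <- do.call(rbind, all_rows)
  dyn_cols <- c(fn$ppg, "pat", fn$ecg)
  # keep features observed for every participant; impute any residual gaps
  keep <- dyn_cols[vapply(dyn_cols, function(cl) {
    all(tapply(big[[cl]], big$participant_id,
               function(v) any(is.finite(v))))
  }, logical(1))]
  dropped <- setdiff(dyn_cols, keep)
  if (length(dropped)) {
    say("dropping features missing for some participant: %s",
        paste(dropped, collapse = ", "))
  }
  structure(list(
    X = big[c(keep, fn$demo)],
    y = big[c("dsbp", "dmap", "ddbp")],
    participant_id = big$participant_id,
    t = big$t,
    augmented = big$augmented,
    feature_names = keep,
    ecg_features = intersect(fn$ecg, keep),
    demo_names = fn$demo,
    baselines = baselines,
    pca_basis = basis,
    spline_p = p_sel
  ), class = "ppgbp_dataset")
}

#' Drop collinear dynamic features from a dataset
#'
#' Applies [remove_collinear()] to the unaugmented rows' dynamic features
#' (demographics are exempt) and restricts the dataset to the survivors.
#'
#' @param dataset a `ppgbp_dataset`.
#' @param threshold VIF threshold.
#' @return list: `dataset` (reduced), `report` (`ppgbp_collinearity`).
#' @export
reduce_collinearity <- function(dataset, threshold = 10) {
  Xd <- dataset$X[!dataset$augmented, dataset$feature_names, drop = FALSE]
  ok <- vapply(Xd, function(v) all(is.finite(v)) && sd(v) > 0, logical(1))
  rep <- remove_collinear(Xd[, ok, drop = FALSE], threshold = threshold)
  surv <- names(rep$X_reduced)
  dataset$feature_names <- intersect(dataset$feature_names, surv)
  dataset$ecg_features <- intersect(dataset$ecg_features, surv)
  dataset$X <- dataset$X[c(dataset$feature_names, dataset$demo_names)]
  list(dataset = dataset, report = rep)
}

#' Run the full analysis pipeline
#'
#' Generates (or accepts) a cohort, assembles the calibrated dataset,
#' removes collinear features, evaluates the requested models in nested
#' LOSOCV, compares them against the zero-change baseline and computes the
#' SHAP ranking report. All artifacts are written as CSV under `out_dir`.
#'
#' @param config a `ppgbp_config`.
#' @param out_dir output directory (`NULL` for no files).
#' @param cohort optional pre-generated cohort.
#' @param models model kinds to run.
#' @param verbose progress lines.
#' @return list: `dataset`, `collinearity`, `cv` (per model), `baseline`,
#'   `comparison`, `ranking` (per model).
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         cohort = NULL, models = c("lasso_ols", "rf"),
                         verbose = TRUE) {
  validate_config(config)
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.null(cohort)) {
    say("generating cohort of %d participants", config$cohort$n_participants)
    cohort <- generate_cohort(config$cohort$n_participants,
                              seed = config$cohort$seed, config = config)
  }
  ds <- assemble_dataset(cohort, config, verbose = verbose)
  red <- reduce_collinearity(ds, threshold = config$dataset$vif_threshold)
  ds <- red$dataset
  say("collinearity: kappa %.1f -> %.1f, %d features removed, %d kept",
      red$report$kappa_before, red$report$kappa_after,
      length(red$report$removed), length(ds$feature_names))
  est <- config$estimation
  cv <- list(); ranking <- list()
  for (mk in models) {
    say("nested LOSOCV: %s / %s / %s", mk, est$feature_set, est$channel)
    cv[[mk]] <- nested_losocv(ds, model_kind = mk, channel = est$channel,
                              feature_set = est$feature_set,
                              n_trees = est$n_trees, seed = est$seed)
    say("computing SHAP attributions: %s", mk)
    ranking[[mk]] <- .pipeline_ranking(cv[[mk]], ds, config)
  }
  base <- baseline_reference(ds, channel = est$channel)
  metric_list <- c(
    lapply(cv, function(x) setNames(x$metrics$rmse, x$metrics$participant)),
    list(baseline = setNames(base$rmse, base$participant))
  )
  comparison <- compare_models(metric_list)
  out <- list(dataset = ds, collinearity = red$report, cv = cv,
              baseline = base, comparison = comparison, ranking = ranking)
  if (!is.null(out_dir)) .write_run(out, config, out_dir)
  out
}

# per-fold SHAP on a sample of the fold's training rows
.pipeline_ranking <- function(cv, dataset, config) {
  imp <- config$importance
  cols <- cv$columns
  attr_list <- lapply(cv$folds, function(f) {
    idx_tr <- which(dataset$participant_id %in% f$train_participants)
    set.seed(config$estimation$seed %% .Machine$integer.max)
    bg_idx <- sample(idx_tr, min(imp$background_n, length(idx_tr)))
    ex_idx <- sample(idx_tr, min(imp$explain_n, length(idx_tr)))
    Xb <- dataset$X[bg_idx, cols, drop = FALSE]
    Xe <- dataset$X[ex_idx, cols, drop = FALSE]
    if (inherits(f$model, "ppgbp_rf")) {
      shap_tree(f$model, Xb, Xe)
    } else {
      shap_linear(f$model, Xb, Xe,
                  max_exact = imp$kernel_max_exact,
                  n_samples = imp$kernel_n_samples,
                  seed = config$estimation$seed)
    }
  })
  ranking_coefficient(attr_list)
}

.write_run <- function(out, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_config(config, file.path(out_dir, "config.yaml"))
  ds <- out$dataset
  flat <- cbind(data.frame(participant_id = ds$participant_id, t = ds$t,
                           augmented = ds$augmented), ds$X, ds$y)
  write.csv(flat, file.path(out_dir, "dataset.csv"), row.names = FALSE)
  for (mk in names(out$cv)) {
    write.csv(out$cv[[mk]]$metrics,
              file.path(out_dir, paste0("metrics_", mk, ".csv")),
              row.names = FALSE)
    write.csv(out$ranking[[mk]]$summary,
              file.path(out_dir, paste0("importance_", mk, ".csv")),
              row.names = FALSE)
  }
  write.csv(out$baseline, file.path(out_dir, "metrics_baseline.csv"),
            row.names = FALSE)
  write.csv(out$comparison, file.path(out_dir, "comparisons.csv"),
            row.names = FALSE)
  invisible(out_dir)
}
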