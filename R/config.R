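#' Default pipeline configuration
#'
#' Returns the full configuration for the end-to-end analysis. Every default
#' follows the study design the pipeline models: a 5-minute rest, a 10-minute
#' stepped vasoconstrictor infusion (0.2 mcg/kg/min increments each minute), a
#' 6-minute maximum-infusion plateau and an 8-minute washout; cuff inflations
#' once per minute; a 40-s feature window around each cuff reading with beat
#' quality gated at SQI > 0.8; a Gaussian-decomposition quality gate at a fit
#' RMSE of 0.03; augmentation at 1/15 Hz with 15-s windows; and collinearity
#' removal at VIF > 10.
#'
#' @param ... named overrides of top-level sections, each a named list merged
#'   over the defaults (unknown keys are an error).
#' @return A nested named list of class `ppgbp_config`.
#' @export
#' @examples
#' cfg <- default_config(cohort = list(n_participants = 4))
#' cfg$cohort$n_participants
default_config <- function(...) {
  cfg <- list(
    cohort = list(
      n_participants = 26L,
      seed = 1L,
      # protocol stage durations, seconds
      rest_s = 300, dose_s = 600, max_s = 360, washout_s = 480,
      infusion_step = 0.2,          # mcg/kg/min per minute, 10 increments
      # cohort-level response statistics
      peak_dsbp_median = 20,        # mmHg
      peak_dsbp_iqr = 8,            # mmHg
      outlier_fraction = 0.15,      # fraction exceeding 30 mmHg peak
      bradycardia_gain = 0.3,       # bpm drop per mmHg rise in SBP
      cuff_interval_s = 60,
      cuff_dropout_p = 0.1,
      cuff_noise_sd = 4,            # mmHg
      ppg_fs = 125, ecg_fs = 256,
      ppg_noise_sd = 0.02,          # additive, fraction of unit amplitude
      ecg_noise_sd = 0.02,
      ecg_mains_amp = 0.05,
      ecg_wander_amp = 0.1,
      artefact_rate_per_min = 0.2,  # expected motion-artefact bursts
      artefact_len_s = 3,
      conduction_delay_s = 0.25,    # R peak to pulse foot
      link_features = FALSE,        # inject known linear feature->dBP map
      link_coefs = NULL
    ),
    preprocessing = list(
      ppg_band = c(0.5, 10), filter_order = 8,
      ecg_highpass = 0.5, mains_hz = 50,
      beat_len = 100L,
      sg_order = 7L, sg_window = 11L,
      sqi_template_beats = 20L,
      pat_fiducial = "onset",       # onset | max_slope
      pat_range = c(0.05, 0.8)
    ),
    fiducials = list(
      prominence = 0.01,
      notch_window = 0.5,           # beat fraction after S searched for N
      e_margin = 0.1                # APG waves allowed until t_N + margin
    ),
    gauss = list(
      loss_gate = 0.03,
      max_iter = 200L, ftol = 1e-8,
      sigma_floor = 1e-4
    ),
    features = list(
      nha_harmonics = 10L,
      sqi_min = 0.8,
      pca_n = 3L
    ),
    ecg_features = list(
      sampen_m = 2L, sampen_r = 0.2, # r as fraction of window SD
      mse_scales = c(2L, 4L, 6L, 8L),
      higuchi_kmax = 17L,
      entropy_bins = 16L
    ),
    bp_reference = list(
      p_grid = 10^seq(-3, 8),
      f_bp = 1 / 60,
      time_scale = 60   # roughness integral in minutes (unit knot spacing)
    ),
    dataset = list(
      window_s = 40, sqi_min = 0.8,
      outlier_mad = 5, outlier_window = 10L,
      f_aug = 1 / 15, window_aug_s = 15,
      vif_threshold = 10
    ),
    estimation = list(
      n_lambda = 30L, lambda_min_ratio = 1e-4,
      n_trees = 300L,
      channel = "sbp",
      feature_set = "ppg+ecg",      # ppg | ecg | ppg+ecg | pat
      seed = 1L
    ),
    importance = list(
      background_n = 100L,
      explain_n = 50L,
      kernel_max_exact = 12L,
      kernel_n_samples = 2048L
    )
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) {
      stop("unknown configuration section(s): ", paste(bad, collapse = ", "))
    }
    for (sec in names(over)) {
      badkey <- setdiff(names(over[[sec]]), names(cfg[[sec]]))
      if (length(badkey)) {
        stop("unknown configuration key(s) in '", sec, "': ",
             paste(badkey, collapse = ", "))
      }
      cfg[[sec]][names(over[[sec]])] <- over[[sec]]
    }
  }
  structure(cfg, class = "ppgbp_config")
}

#' Validate a pipeline configuration
#'
#' Checks field types and value ranges, naming the offending field in the
#' error message.
#'
#' @param cfg a `ppgbp_config` list.
#' @return `cfg`, invisibly, if valid.
#' @export
validate_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!isTRUE(ok)) stop("invalid config field '", field, "': ", msg)
  }
  co <- cfg$cohort
  chk(co$n_participants >= 1, "cohort.n_participants", "must be >= 1")
  for (f in c("rest_s", "dose_s", "max_s", "washout_s")) {
    chk(co[[f]] > 0, paste0("cohort.", f), "stage duration must be positive")
  }
  chk(co$cuff_dropout_p >= 0 && co$cuff_dropout_p < 1,
      "cohort.cuff_dropout_p", "must be in [0, 1)")
  chk(co$cuff_noise_sd >= 0, "cohort.cuff_noise_sd", "must be >= 0")
  chk(co$ppg_fs >= 50, "cohort.ppg_fs", "PPG sampling rate must be >= 50 Hz")
  chk(co$ecg_fs >= 100, "cohort.ecg_fs", "ECG sampling rate must be >= 100 Hz")
  chk(cfg$gauss$loss_gate > 0, "gauss.loss_gate", "must be positive")
  chk(cfg$dataset$vif_threshold > 1, "dataset.vif_threshold", "must exceed 1")
  chk(cfg$dataset$window_s > 0, "dataset.window_s", "must be positive")
  chk(cfg$features$sqi_min >= 0 && cfg$features$sqi_min <= 1,
      "features.sqi_min", "must be in [0, 1]")
  chk(cfg$estimation$channel %in% c("sbp", "map", "dbp"),
      "estimation.channel", "must be one of sbp, map, dbp")
  chk(cfg$estimation$feature_set %in% c("ppg", "ecg", "ppg+ecg", "pat"),
      "estimation.feature_set", "must be one of ppg, ecg, ppg+ecg, pat")
  invisible(cfg)
}

#' Read / write a configuration file
#'
#' Configurations round-trip losslessly through YAML.
#'
#' @param path file path.
#' @param cfg a `ppgbp_config`.
#' @return `read_config` returns a validated `ppgbp_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(default_config, raw)
  validate_config(cfg)
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}
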