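# Shared fixtures, built lazily once per test run.
#
# The "small cohort" uses a shortened four-stage protocol and reduced
# sampling rates so the full pipeline stays fast while exercising every
# stage; generator noise/artefact settings are the defaults.

.fixtures <- new.env(parent = emptyenv())

small_config <- function(...) {
  default_config(
    cohort = list(n_participants = 4, seed = 11,
                  rest_s = 120, dose_s = 240, max_s = 120, washout_s = 120,
                  cuff_interval_s = 30, ppg_fs = 80, ecg_fs = 128),
    estimation = list(n_trees = 50L),
    importance = list(background_n = 20L, explain_n = 8L,
                      kernel_n_samples = 128L),
    ...
  )
}

small_cohort <- function() {
  if (is.null(.fixtures$cohort)) {
    cfg <- small_config()
    .fixtures$cohort <- generate_cohort(cfg$cohort$n_participants,
                                        seed = cfg$cohort$seed, config = cfg)
  }
  .fixtures$cohort
}

# assembled (pre-collinearity-reduction) dataset for the small cohort
small_dataset <- function() {
  if (is.null(.fixtures$dataset)) {
    .fixtures$dataset <- suppressWarnings(
      assemble_dataset(small_cohort(), small_config())
    )
  }
  .fixtures$dataset
}

# collinearity-reduced version
small_dataset_reduced <- function() {
  if (is.null(.fixtures$reduced)) {
    .fixtures$reduced <- reduce_collinearity(small_dataset())
  }
  .fixtures$reduced
}

# A normalized beat built directly from the stiffness-parameterised
# 4-Gaussian pulse model: amplitudes rescaled so max = 1. Returns the beat
# and its effective ground-truth parameters.
theta_beat <- function(s = 0.3, n = 100) {
  th <- stiffness_theta(s)
  u <- seq(0, 1, length.out = n)
  z <- gauss_sum(u, th)
  sc <- max(z)
  th_true <- th
  th_true[c(1, 4, 7, 10)] <- th[c(1, 4, 7, 10)] / sc
  list(zeta = z / sc, theta = th_true, u = u)
}

# normalized beat + Savitzky-Golay derivatives (as segment_beats produces)
beat_with_derivs <- function(zeta) {
  du <- 1 / (length(zeta) - 1)
  list(zeta = zeta,
       vpg = signal::sgolayfilt(zeta, p = 7, n = 11, m = 1, ts = du),
       apg = signal::sgolayfilt(zeta, p = 7, n = 11, m = 2, ts = du))
}

# simple textbook two-wave pulse: systolic lobe + distinct diastolic wave
textbook_beat <- function(n = 100) {
  u <- seq(0, 1, length.out = n)
  z <- exp(-(u - 0.25)^2 / (2 * 0.08^2)) + 0.45 * exp(-(u - 0.65)^2 / (2 * 0.09^2))
  (z - min(z)) / (max(z) - min(z))
}

# synthetic calibrated dataset with a known linear feature -> dBP map,
# shaped like a ppgbp_dataset (participant grouping + augmented rows)
make_linear_dataset <- function(n_parts = 6, rows_per = 40, M = 8,
                                noise_sd = 0.5, seed = 99) {
  set.seed(seed)
  pid <- rep(sprintf("S%02d", seq_len(n_parts)), each = rows_per)
  n <- length(pid)
  X <- as.data.frame(matrix(rnorm(n * M), n, M))
  names(X) <- paste0("f", seq_len(M))
  y <- 3 * X$f1 - 2 * X$f2 + rnorm(n, 0, noise_sd)
  demo <- data.frame(age = rep(round(runif(n_parts, 20, 45)), each = rows_per),
                     sex = rep(rbinom(n_parts, 1, 0.5), each = rows_per),
                     height = rep(rnorm(n_parts, 170, 8), each = rows_per),
                     weight = rep(rnorm(n_parts, 70, 10), each = rows_per),
                     bmi = rep(rnorm(n_parts, 23, 2), each = rows_per),
                     bp_cal = rep(rnorm(n_parts, 115, 8), each = rows_per))
  aug <- rep(c(FALSE, TRUE), length.out = rows_per)[
    rep(seq_len(rows_per), n_parts)]
  structure(list(
    X = cbind(X, demo),
    y = data.frame(dsbp = y, dmap = 0.85 * y, ddbp = 0.75 * y),
    participant_id = pid,
    t = rep(seq_len(rows_per) * 15, n_parts),
    augmented = aug,
    feature_names = names(X)[seq_len(M)],
    ecg_features = character(0),
    demo_names = names(demo)
  ), class = "ppgbp_dataset")
}
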