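# Synthetic cohort generator: emulates a stepped vasoconstrictor infusion
# protocol (rest -> dose ramp -> max infusion -> washout) with reflex
# bradycardia, stiffness-driven pulse morphology change, sparse noisy cuff
# readings and intermittent artefact bursts. Ground truth (beat onsets,
# per-beat Gaussian parameters, R-peak times, artefact masks) is always
# emitted so downstream stages can be oracle-tested.

# Pulse morphology endpoints of the stiffness ramp. Amplitude/centre/width of
# the four Gaussian components (incident wave, tidal wave, dicrotic wave,
# late re-reflections) at rest (s = 0) and at maximum vasoconstriction
# (s = 1). With rising stiffness the tidal wave grows (A2 up), reflections
# arrive earlier (mu2, mu3 down) and the dicrotic notch fills in.
.theta_rest <- c(A1 = 0.80, mu1 = 0.22, s1 = 0.075,
                 A2 = 0.28, mu2 = 0.42, s2 = 0.100,
                 A3 = 0.30, mu3 = 0.67, s3 = 0.075,
                 A4 = 0.14, mu4 = 0.85, s4 = 0.090)
.theta_max  <- c(A1 = 0.85, mu1 = 0.21, s1 = 0.080,
                 A2 = 0.78, mu2 = 0.38, s2 = 0.115,
                 A3 = 0.42, mu3 = 0.58, s3 = 0.110,
                 A4 = 0.20, mu4 = 0.80, s4 = 0.110)

#' Pulse-shape parameters as a function of arterial stiffness
#'
#' Linear interpolation between a rest-state and a maximum-vasoconstriction
#' 4-Gaussian parameter set. The tidal-wave amplitude is non-decreasing and
#' the tidal/dicrotic wave centres non-increasing in `s`.
#'
#' @param s stiffness in \[0, 1\] (values are clipped).
#' @return Named numeric vector of 12 parameters
#'   (A1, mu1, s1, ..., A4, mu4, s4).
#' @export
stiffness_theta <- function(s) {
  s <- pmin(pmax(s, 0), 1)
  if (length(s) == 1L) {
    return((1 - s) * .theta_rest + s * .theta_max)
  }
  t(vapply(s, function(si) (1 - si) * .theta_rest + si * .theta_max,
           numeric(12L)))
}

#' Evaluate the 4-Gaussian pulse model
#'
#' Sum of four Gaussian components at normalized times `u` for a length-12
#' parameter vector (A1, mu1, s1, ..., A4, mu4, s4).
#'
#' @param u normalized times.
#' @param theta length-12 parameter vector.
#' @return Numeric vector of the model pulse.
#' @export
gauss_sum <- function(u, theta) {
  out <- numeric(length(u))
  for (i in 0:3) {
    A <- theta[3 * i + 1]; mu <- theta[3 * i + 2]; sg <- theta[3 * i + 3]
    out <- out + A * exp(-(u - mu)^2 / (2 * sg^2))
  }
  out
}

#' Draw participant demographics
#'
#' @param n number of participants.
#' @return data.frame with participant_id, age (years), sex (0 female /
#'   1 male), height (cm), weight (kg) and bmi (kg/m^2, derived exactly as
#'   weight / (height/100)^2).
#' @keywords internal
draw_demographics <- function(n) {
  age <- round(runif(n, 20, 46))
  sex <- rbinom(n, 1, 0.5)
  height <- round(rnorm(n, 170, 9), 1)
  height <- pmin(pmax(height, 150), 200)
  bmi_target <- rnorm(n, 22.5, 3)
  bmi_target <- pmin(pmax(bmi_target, 17), 35)
  weight <- round(bmi_target * (height / 100)^2, 1)
  data.frame(
    participant_id = sprintf("P%03d", seq_len(n)),
    age = age, sex = sex, height = height, weight = weight,
    bmi = weight / (height / 100)^2,
    stringsAsFactors = FALSE
  )
}

#' Latent hemodynamics for one participant
#'
#' Builds 1-Hz latent SBP/MAP/DBP, heart-rate and stiffness series over the
#' four protocol stages. The pressor response is a first-order lag of the
#' normalised infusion-rate profile, scaled so the participant's peak change
#' in SBP equals `peak_dsbp`. Heart rate falls linearly with the rise in SBP
#' (reflex bradycardia) and stiffness is a clipped linear function of the SBP
#' change.
#'
#' @param peak_dsbp peak change in systolic pressure, mmHg.
#' @param cfg cohort section of [default_config()].
#' @param sbp0,dbp0,hr0 baseline systolic/diastolic pressure (mmHg) and heart
#'   rate (bpm).
#' @return data.frame at 1 Hz: t, stage, infusion_rate, sbp, map, dbp, hr,
#'   stiffness, dsbp.
#' @export
latent_hemodynamics <- function(peak_dsbp, cfg, sbp0 = 115, dbp0 = 70,
                                hr0 = 68) {
  dur <- cfg$rest_s + cfg$dose_s + cfg$max_s + cfg$washout_s
  t <- seq(0, dur - 1)
  stage <- cut(t,
               breaks = c(-Inf, cfg$rest_s, cfg$rest_s + cfg$dose_s,
                          cfg$rest_s + cfg$dose_s + cfg$max_s, Inf),
               labels = c("rest", "dose_increase", "max_infusion", "washout"))
  # stepped infusion: +step every minute for dose_s/60 increments, then flat
  n_inc <- floor(cfg$dose_s / 60)
  rate <- numeric(length(t))
  in_dose <- stage == "dose_increase"
  rate[in_dose] <- cfg$infusion_step *
    pmin(floor((t[in_dose] - cfg$rest_s) / 60) + 1, n_inc)
  rate[stage == "max_infusion"] <- cfg$infusion_step * n_inc
  # first-order pharmacodynamic lag of the normalised rate profile
  tau <- 120
  e <- numeric(length(t))
  r_norm <- rate / (cfg$infusion_step * n_inc)
  for (k in seq_along(t)[-1]) {
    e[k] <- e[k - 1] + (r_norm[k] - e[k - 1]) / tau
  }
  e <- e / max(e)
  dsbp <- peak_dsbp * e
  sbp <- sbp0 + dsbp
  dbp <- dbp0 + 0.75 * dsbp
  map <- dbp + (sbp - dbp) / 3
  hr <- hr0 - cfg$bradycardia_gain * dsbp
  stiffness <- pmin(pmax(dsbp / 40, 0), 1)
  data.frame(t = t, stage = stage, infusion_rate = rate,
             sbp = sbp, map = map, dbp = dbp, hr = hr,
             stiffness = stiffness, dsbp = dsbp)
}

# Linear interpolation lookup into a latent series at arbitrary times.
.latent_at <- function(latent, col, times) {
  approx(latent$t, latent[[col]], xout = times, rule = 2)$y
}

# Shared heartbeat schedule: beat (R-peak) times following the latent heart
# rate. The PPG and ECG synthesizers both use this so that the pulse foot
# trails each R peak by exactly the conduction delay.
.beat_schedule <- function(latent, start = 0.35, margin = 0.2) {
  dur <- max(latent$t) + 1
  b <- start
  times <- c(); periods <- c()
  while (b < dur - margin) {
    T_b <- 60 / .latent_at(latent, "hr", b)
    times <- c(times, b); periods <- c(periods, T_b)
    b <- b + T_b
  }
  list(t = times, period = periods)
}

#' Synthesize a PPG waveform from latent hemodynamics
#'
#' Each beat is a 4-Gaussian pulse whose parameters follow the instantaneous
#' stiffness via [stiffness_theta()]; beats are placed at the latent heart
#' rate by overlap-add. Optional additive white noise and motion-artefact
#' bursts (flagged in the returned ground truth) can be configured.
#'
#' @param latent data.frame from [latent_hemodynamics()].
#' @param fs sampling rate, Hz (>= 50).
#' @param seed integer seed for noise and artefact placement.
#' @param noise_sd additive white-noise SD (units of unit pulse amplitude).
#' @param amp_mod fractional respiratory amplitude modulation (0 disables).
#' @param artefact_rate expected artefact bursts per minute.
#' @param artefact_len_s burst length, seconds.
#' @param onset_delay_s delay of the first pulse foot after the nominal beat
#'   time (the pulse-arrival delay from the heart to the periphery).
#' @return list with `x` (samples), `fs`, `truth` (data.frame of per-beat
#'   onset time, period, stiffness and the 12 ground-truth pulse parameters)
#'   and `artefact` (logical per-sample mask).
#' @export
synthesize_ppg <- function(latent, fs, seed = 1L, noise_sd = 0,
                           amp_mod = 0, artefact_rate = 0,
                           artefact_len_s = 3, onset_delay_s = 0.25) {
  if (fs < 50) stop("PPG sampling rate must be >= 50 Hz")
  if (!all(is.finite(latent$hr)) || !all(is.finite(latent$stiffness))) {
    stop("latent hemodynamic series must be finite")
  }
  dur <- max(latent$t) + 1
  n <- floor(dur * fs)
  tt <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  # pulse feet trail the shared heartbeat schedule by the conduction delay
  sched <- .beat_schedule(latent)
  onsets <- sched$t + onset_delay_s
  periods <- sched$period
  stiff <- .latent_at(latent, "stiffness", onsets)
  nb <- length(onsets)
  thetas <- stiffness_theta(stiff)
  if (nb == 1L) thetas <- matrix(thetas, nrow = 1L)
  for (k in seq_len(nb)) {
    # evaluate from the first sample at or after the onset (the 1e-9 guard
    # keeps floating-point jitter from including a pre-onset sample) until
    # well past the beat, so the truncated tail is negligible
    i0 <- max(1L, floor(onsets[k] * fs + 1e-9) + 1L)
    i1 <- min(n, ceiling((onsets[k] + 1.5 * periods[k]) * fs))
    if (i1 < i0) next
    u <- (tt[i0:i1] - onsets[k]) / periods[k]
    x[i0:i1] <- x[i0:i1] + gauss_sum(u, thetas[k, ])
  }
  if (amp_mod > 0) {
    x <- x * (1 + amp_mod * sin(2 * pi * 0.25 * tt))
  }
  artefact <- rep(FALSE, n)
  set.seed(seed %% .Machine$integer.max)
  if (noise_sd > 0) x <- x + rnorm(n, sd = noise_sd)
  if (artefact_rate > 0) {
    n_art <- stats::rpois(1, artefact_rate * dur / 60)
    if (n_art > 0) {
      starts <- runif(n_art, 0, dur - artefact_len_s)
      for (s0 in starts) {
        idx <- which(tt >= s0 & tt < s0 + artefact_len_s)
        x[idx] <- x[idx] + rnorm(length(idx), sd = 0.8) +
          0.8 * sin(2 * pi * 1.7 * tt[idx])
        artefact[idx] <- TRUE
      }
    }
  }
  truth <- data.frame(onset_t = onsets, period = periods, stiffness = stiff)
  truth <- cbind(truth, as.data.frame(thetas))
  list(x = x, fs = fs, truth = truth, artefact = artefact)
}

#' Synthesize a single-lead ECG from latent hemodynamics
#'
#' A per-beat P-QRS-T template (sum of localised Gaussian waves in beat-phase
#' units) is placed at the latent heart rate, with configurable baseline
#' wander (< 0.5 Hz), mains interference and white noise. Ground-truth R-peak
#' times are returned alongside.
#'
#' @param latent data.frame from [latent_hemodynamics()].
#' @param fs sampling rate, Hz (>= 100).
#' @param seed integer seed for the noise.
#' @param noise_sd white-noise SD (units of R amplitude).
#' @param mains_amp amplitude of the mains interference sinusoid.
#' @param mains_hz mains frequency, Hz.
#' @param wander_amp amplitude of the baseline wander.
#' @return list with `x`, `fs`, `r_peaks` (seconds).
#' @export
synthesize_ecg <- function(latent, fs, seed = 1L, noise_sd = 0,
                           mains_amp = 0, mains_hz = 50, wander_amp = 0) {
  if (fs < 100) stop("ECG sampling rate must be >= 100 Hz")
  if (!all(is.finite(latent$hr))) stop("latent hemodynamic series must be finite")
  dur <- max(latent$t) + 1
  n <- floor(dur * fs)
  tt <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  # P-QRS-T waves: phase offset from R, amplitude, phase width
  waves <- cbind(off = c(-0.18, -0.025, 0, 0.03, 0.25),
                 amp = c(0.12, -0.15, 1.0, -0.25, 0.30),
                 sig = c(0.030, 0.008, 0.012, 0.010, 0.050))
  sched <- .beat_schedule(latent)
  r_peaks <- sched$t
  for (k in seq_along(r_peaks)) {
    b <- r_peaks[k]; T_b <- sched$period[k]
    i0 <- max(1L, floor((b - 0.3 * T_b) * fs) + 1L)
    i1 <- min(n, ceiling((b + 0.45 * T_b) * fs))
    phase <- (tt[i0:i1] - b) / T_b
    seg <- numeric(length(phase))
    for (w in seq_len(nrow(waves))) {
      seg <- seg + waves[w, "amp"] *
        exp(-(phase - waves[w, "off"])^2 / (2 * waves[w, "sig"]^2))
    }
    x[i0:i1] <- x[i0:i1] + seg
  }
  set.seed(seed %% .Machine$integer.max)
  if (wander_amp > 0) {
    ph <- runif(3, 0, 2 * pi)
    x <- x + wander_amp * (0.6 * sin(2 * pi * 0.18 * tt + ph[1]) +
                           0.3 * sin(2 * pi * 0.32 * tt + ph[2]) +
                           0.1 * sin(2 * pi * 0.45 * tt + ph[3]))
  }
  if (mains_amp > 0) x <- x + mains_amp * sin(2 * pi * mains_hz * tt)
  if (noise_sd > 0) x <- x + rnorm(n, sd = noise_sd)
  list(x = x, fs = fs, r_peaks = r_peaks)
}

#' Generate a synthetic cohort
#'
#' Draws per-participant demographics, a peak systolic response (cohort
#' median configurable, default 20 mmHg with an IQR of 8 mmHg and a
#' configurable fraction of >30 mmHg "outlier" responders), latent
#' hemodynamics over the four protocol stages, PPG and ECG waveforms and
#' sparse cuff readings (scheduled once per minute with Bernoulli dropout and
#' additive Gaussian noise).
#'
#' @param n_participants cohort size (>= 1).
#' @param seed master integer seed; the run is fully deterministic given it.
#' @param config a `ppgbp_config`; only the `cohort` section is used.
#' @return list of recordings. Each recording is a list with
#'   `participant_id`, `demographics` (one-row data.frame), `ppg`, `ecg`
#'   (as returned by the synthesizers), `cuff` (data.frame t/sbp/map/dbp),
#'   `latent`, and `peak_dsbp`.
#' @export
generate_cohort <- function(n_participants, seed = 1L,
                            config = default_config()) {
  validate_config(config)
  if (n_participants < 1) stop("invalid config field 'n_participants': must be >= 1")
  co <- config$cohort
  set.seed(seed %% .Machine$integer.max)
  demo <- draw_demographics(n_participants)
  # peak systolic response: bulk normal (median/IQR as configured) with a
  # designated outlier-responder fraction above 30 mmHg
  sd_bulk <- co$peak_dsbp_iqr / (2 * stats::qnorm(0.75))
  is_out <- runif(n_participants) < co$outlier_fraction
  peak <- rnorm(n_participants, co$peak_dsbp_median, sd_bulk)
  peak[peak < 5] <- 5
  peak[is_out] <- runif(sum(is_out), 31, 42)
  sbp0 <- rnorm(n_participants, 115, 8)
  dbp0 <- sbp0 - rnorm(n_participants, 45, 5)
  hr0 <- rnorm(n_participants, 68, 6)
  part_seeds <- sample.int(2^30, 3 * n_participants)
  cohort <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    latent <- latent_hemodynamics(peak[p], co, sbp0 = sbp0[p],
                                  dbp0 = dbp0[p], hr0 = hr0[p])
    if (isTRUE(co$link_features)) {
      latent <- .apply_feature_link(latent, co)
    }
    ppg <- synthesize_ppg(latent, co$ppg_fs, seed = part_seeds[3 * p - 2],
                          noise_sd = co$ppg_noise_sd, amp_mod = 0.05,
                          artefact_rate = co$artefact_rate_per_min,
                          artefact_len_s = co$artefact_len_s,
                          onset_delay_s = co$conduction_delay_s)
    ecg <- synthesize_ecg(latent, co$ecg_fs, seed = part_seeds[3 * p - 1],
                          noise_sd = co$ecg_noise_sd,
                          mains_amp = co$ecg_mains_amp,
                          wander_amp = co$ecg_wander_amp)
    cuff <- .sample_cuff(latent, co, part_seeds[3 * p])
    cohort[[p]] <- list(
      participant_id = demo$participant_id[p],
      demographics = demo[p, , drop = FALSE],
      ppg = ppg, ecg = ecg, cuff = cuff, latent = latent,
      peak_dsbp = peak[p]
    )
  }
  cohort
}

# Replace the protocol-driven pressure response with a known linear map from
# the stiffness-driven pulse parameters to dBP, used for model-recovery
# tests: dSBP(t) = sum_j c_j * (theta_j(s(t)) - theta_j(0)).
.apply_feature_link <- function(latent, co) {
  coefs <- co$link_coefs
  if (is.null(coefs)) coefs <- c(A2 = 40, mu3 = -120)
  th <- stiffness_theta(latent$stiffness)
  th0 <- stiffness_theta(0)
  dsbp <- numeric(nrow(latent))
  for (nm in names(coefs)) {
    dsbp <- dsbp + coefs[[nm]] * (th[, nm] - th0[[nm]])
  }
  base_sbp <- latent$sbp - latent$dsbp
  base_dbp <- latent$dbp - 0.75 * latent$dsbp
  latent$dsbp <- dsbp
  latent$sbp <- base_sbp + dsbp
  latent$dbp <- base_dbp + 0.75 * dsbp
  latent$map <- latent$dbp + (latent$sbp - latent$dbp) / 3
  latent
}

# Cuff schedule: one inflation per minute, Bernoulli dropout, additive
# Gaussian read noise.
.sample_cuff <- function(latent, co, seed) {
  set.seed(seed %% .Machine$integer.max)
  times <- seq(co$cuff_interval_s, max(latent$t), by = co$cuff_interval_s)
  keep <- runif(length(times)) >= co$cuff_dropout_p
  times <- times[keep]
  data.frame(
    t = times,
    sbp = .latent_at(latent, "sbp", times) + rnorm(length(times), 0, co$cuff_noise_sd),
    map = .latent_at(latent, "map", times) + rnorm(length(times), 0, co$cuff_noise_sd),
    dbp = .latent_at(latent, "dbp", times) + rnorm(length(times), 0, co$cuff_noise_sd)
  )
}

#' Write / read a cohort as plain-text CSV files
#'
#' One directory per participant holding two-column (t, value) signal CSVs,
#' cuff events and demographics, plus a cohort manifest listing participants
#' and paths.
#'
#' @param cohort list of recordings from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `write_cohort` returns the manifest path; `read_cohort` returns a
#'   cohort list (ground-truth fields are not persisted).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(participant_id = character(), path = character())
  for (rec in cohort) {
    pdir <- file.path(dir, rec$participant_id)
    dir.create(pdir, showWarnings = FALSE)
    ppg_t <- (seq_along(rec$ppg$x) - 1) / rec$ppg$fs
    write.csv(data.frame(t = ppg_t, value = rec$ppg$x),
              file.path(pdir, "ppg.csv"), row.names = FALSE)
    ecg_t <- (seq_along(rec$ecg$x) - 1) / rec$ecg$fs
    write.csv(data.frame(t = ecg_t, value = rec$ecg$x),
              file.path(pdir, "ecg.csv"), row.names = FALSE)
    write.csv(rec$cuff, file.path(pdir, "cuff.csv"), row.names = FALSE)
    write.csv(rec$demographics, file.path(pdir, "demographics.csv"),
              row.names = FALSE)
    manifest <- rbind(manifest,
                      data.frame(participant_id = rec$participant_id,
                                 path = rec$participant_id))
  }
  mpath <- file.path(dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)
  mpath
}

#' @rdname write_cohort
#' @param ppg_fs,ecg_fs sampling rates used to reconstruct the signal vectors
#'   from the (t, value) files; inferred from the time column when `NULL`.
#' @export
read_cohort <- function(dir, ppg_fs = NULL, ecg_fs = NULL) {
  manifest <- read.csv(file.path(dir, "manifest.csv"),
                       stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    pdir <- file.path(dir, manifest$path[i])
    ppg <- read.csv(file.path(pdir, "ppg.csv"))
    ecg <- read.csv(file.path(pdir, "ecg.csv"))
    fs_p <- if (is.null(ppg_fs)) 1 / median(diff(ppg$t)) else ppg_fs
    fs_e <- if (is.null(ecg_fs)) 1 / median(diff(ecg$t)) else ecg_fs
    list(
      participant_id = manifest$participant_id[i],
      demographics = read.csv(file.path(pdir, "demographics.csv"),
                              stringsAsFactors = FALSE),
      ppg = list(x = ppg$value, fs = fs_p),
      ecg = list(x = ecg$value, fs = fs_e),
      cuff = read.csv(file.path(pdir, "cuff.csv"))
    )
  })
}
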