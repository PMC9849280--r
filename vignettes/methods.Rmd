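---
title: "Estimating blood-pressure changes from pulse-wave morphology: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating blood-pressure changes from pulse-wave morphology: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppgbp)
```

# The problem

Cuff sphygmomanometers give blood pressure (BP) once a minute at best, and
miss inflations; continuous arterial lines are invasive. The
photoplethysmogram (PPG) — the optical pulse signal a pulse oximeter or
smartwatch records — and the single-lead ECG are continuous and cheap, and
their waveform morphology changes when vascular tone changes. `ppgbp`
implements a complete pipeline for estimating *changes* in systolic, mean
and diastolic pressure (ΔSBP/ΔMAP/ΔDBP) from those waveforms, built around
the physiological setting of a phenylephrine pressor challenge: a
vasoconstrictor infusion raises BP by roughly 20 mmHg over a four-stage
protocol (rest, stepped dose increase, maximum infusion, washout), arterial
stiffening makes the reflected pressure waves (the late-systolic tidal wave
and early-diastolic dicrotic wave) larger and earlier, and the baroreflex
slows the heart.

Because raw pressor-study recordings are not publicly distributable, the
package includes a first-class synthetic cohort generator that reproduces
the *statistical* structure of such a study: every downstream stage is
developed and tested against it, with full ground truth (beat onsets,
per-beat pulse parameters, R-peak times, artefact masks).

# The synthetic cohort

`generate_cohort()` draws, per participant: demographics (age, sex, height,
weight, BMI derived exactly); a peak systolic response sampled so the cohort
median is 20 mmHg with an interquartile range of 8 mmHg, plus a configurable
fraction (default 15%) of "outlier" responders above 30 mmHg — the shape of
responses reported for weight-based phenylephrine dosing; and latent 1-Hz
hemodynamics in which the pressure response is a first-order lag (time
constant 120 s) of the stepped infusion profile (0.2 mcg/kg/min increments
each minute for ten increments), heart rate falls at 0.3 bpm per mmHg of
systolic rise (the literature gives the direction of reflex bradycardia but
not the gain; 0.3 is a mid-range choice), and a dimensionless arterial
stiffness is the systolic rise clipped to [0, 1] at 40 mmHg.

Each PPG beat is a sum of four Gaussians — incident wave, tidal wave,
dicrotic wave, late re-reflections — whose parameters interpolate linearly
between a hand-tuned rest set and a maximum-vasoconstriction set
(`stiffness_theta()`). The two endpoint sets were tuned once so that the
rest pulse shows a clear dicrotic notch and the stiff pulse loses it while
its tidal wave grows and arrives earlier; they are fixed constants, not
fitting targets. The ECG is a per-beat P-QRS-T template of localized waves
sharing the same heartbeat schedule, with the pulse foot trailing each R
peak by a fixed conduction delay (default 250 ms), plus configurable
baseline wander, 50-Hz mains interference and white noise. Cuff readings
are scheduled once a minute with Bernoulli dropout (default 0.1, modelling
failed inflations) and Gaussian read noise (default SD 4 mmHg, inside the
±5 mmHg bias / 8 mmHg SD tolerance of oscillometric devices).

What the generator does **not** emulate — and what passing tests therefore
do not demonstrate — includes: biophysical pressure-flow coupling
(Windkessel or transmission-line dynamics), drug pharmacokinetics, motion
artefacts of ambulatory recordings beyond stylized bursts, beat-to-beat BP
variability, and any nonlinearity in the feature–BP link beyond what the
stiffness parameterisation induces. Results on this cohort validate the
*software* and the statistical machinery, not clinical performance.

# Signal conditioning

The PPG is band-passed 0.5–10 Hz with an 8th-order Butterworth response
(cascaded 4th-order high- and low-pass sections, numerically stable at
these very low normalized cut-offs); the ECG gets an 8th-order 0.5-Hz
high-pass and a 2nd-order 50-Hz notch. All filters are applied zero-phase,
which preserves fiducial timing — several features are time intervals. The
zero-phase application is realised in the frequency domain: the signal is
reflection-padded and its spectrum multiplied by the cascade's squared
magnitude response, the steady-state gain of forward-backward filtering.
This form is exactly symmetric under time reversal and exact at DC,
whereas recursive forward-backward implementations leak asymmetric edge
transients.

Pulse onsets are maxima of the PPG derivative (the systolic upslope) with
an adaptive amplitude threshold; detection is two-pass — a first pass
estimates the beat period, a second enforces a minimum spacing of 0.6
periods — because at high stiffness the diastolic upslope otherwise
produces doubled onsets. Each onset-to-onset beat is resampled to 100
samples by cubic splines and min-max normalized to exactly [0, 1]:
amplitude and duration are deliberately discarded, since pulse amplitude
responds to respiration and contact pressure independently of BP, and
duration is heart rate. First and second derivatives (VPG, APG) come from a
7th-order Savitzky–Golay filter, window 11 samples (the window length is a
package choice; only the order is canonical).

Beat quality (SQI) is the Pearson correlation of each normalized beat
against the running mean of the last 20 accepted beats, clipped to [0, 1];
a beat is "good" above 0.8. QRS detection is a standard Pan–Tompkins
implementation (band-pass, derivative, squaring, 150-ms integration,
adaptive signal/noise thresholds with search-back), and the ECG quality
index per 10-s block is the agreement fraction between Pan–Tompkins and an
independent fixed-threshold peak picker within ±50 ms, multiplied by an R-R
regularity factor max(0, 1 − 2.5·CV): on broadband noise both detectors
fire on random peaks and can agree by chance, but only a true rhythm has
near-constant inter-peak intervals within a block. Pulse arrival time
(PAT) is pulse foot minus nearest preceding R peak, gated to [0.05, 0.8] s.

# Pulse decomposition and features

Each normalized beat ζ(t) is fitted as the sum of four Gaussians with
amplitudes in [0, 1], widths floored at 1e-4 and centres constrained to a
monotone increasing sequence; the loss is the RMSE between beat and model.
The optimizer is bounded Levenberg–Marquardt least squares; the monotone
constraint is enforced by reparameterising centres as cumulative
non-negative increments, which keeps the objective smooth instead of
introducing constraint boundaries. The first beat starts from amplitudes
(0.9, 2/3, 0.5, 1/3), centres (0.2, 0.4, 0.6, 0.8) and equal widths — the
canonical width entry of 0.01 is read as a *variance* (σ = 0.1), since the
parameter triple is described as amplitude/mean/variance while the model
formula uses σ²; empirically both readings converge to identical optima on
clean pulses, so nothing downstream depends on this. Subsequent beats are
seeded from the previous converged fit; if a seeded fit exceeds the quality
gate the beat is refitted from the default seed and the better fit kept,
which both restarts the chain after artefacts and guarantees sequential
seeding never does worse than default seeding. A beat whose fit RMSE
exceeds 0.03 has its SQI set to 0 — the decomposition doubles as a quality
gate.

The feature library has exactly 77 named columns: 61 from the PPG (19 pulse
morphology, 4 VPG, 8 APG, 21 Gaussian-decomposition indices, 9 PCA
projections), 10 from the ECG, 6 demographics. Conventions worth noting:

* Timing features are in normalized beat fractions; systole/diastole split
  at the dicrotic notch. The systolic peak is the *first* turning point
  above the pulse midpoint (prominence ≥ 0.01 to ignore numerical ripple),
  not the global maximum — at high stiffness the tidal wave can overtop the
  incident peak. A vanished notch is inferred from the APG local maximum
  and flagged.
* The normalised harmonic area uses 10 harmonics of the beat fundamental
  (the count is open in the literature; 10 captures everything above the
  numerical noise floor of a 100-sample beat).
* `gauss_ri` is implemented as the printed convention area(g_s) −
  area(g_3), although the symmetric reading area(g_d) is arguably intended;
  the choice is isolated in one function.
* `gauss_lvet` approximates left-ventricular ejection time as the point
  where the systolic wave g_s decays below 1% of its maximum after its
  peak — an approximation, kept behind a single function.
* The VPG dispersion features use standard deviations (the prose
  convention) rather than variances (the table wording); the two are
  monotone-equivalent for importance ranking.
* Sex is encoded 0/1; the other demographics are continuous.

The PCA basis is fitted once on beats pooled across all participants
(SQI > 0.8, resampled to 100 samples, mean beat subtracted), as the study
design does. A leakage-safe per-fold variant was considered and rejected:
the basis is unsupervised — fitted without any BP labels — and refitting it
inside every inner cross-validation fold multiplies pipeline cost roughly
25-fold for a negligible leakage channel. Eigenvector signs are fixed by
making the largest-magnitude loading positive.

ECG features are computed on windows of the filtered waveform itself (not
on R-R series): Hjorth mobility and complexity, Higuchi fractal dimension
(k_max = 17), Shannon entropy over a 16-bin amplitude histogram, and the
sample-entropy family with m = 2 and tolerance r = 0.2 × window SD —
standard defaults in the heart-rate-variability literature, configurable.
Multiscale entropy coarse-grains by non-overlapping means at scales 2, 4,
6, 8, keeping r fixed in absolute terms from the original window. ApEn
counts self-matches; SampEn does not, and returns missing (never infinity)
when no template pair matches.

# The BP reference

Cuff readings are sparse and noisy, so the per-channel reference is a
natural cubic smoothing spline minimising p·Σ(yᵢ − f(tᵢ))² + ∫f″(t)²dt —
large p approaches interpolation, small p the least-squares line. The
implementation is the standard banded natural-spline formulation, written
in-package because the explicit p-weighting and its leave-one-out selection
are part of the method's contract (`stats::smooth.spline` hides the
equivalent weight behind internal rescaling; it serves as an independent
oracle in the tests). One penalty per channel is shared across the cohort,
selected by the participant-averaged leave-one-out RMSE over the log-spaced
grid 10⁻³…10⁸.

One unit choice matters: with knot times in seconds the roughness matrix
scales like 1/h³ with h = 60 s between readings, and the entire canonical
grid sits in the near-interpolating regime. The pipeline therefore
expresses the roughness integral in minutes (`time_scale = 60`), giving
unit knot spacing for the once-per-minute cuff schedule, under which the
grid spans the full linear-to-interpolating range. The penalty's
formulation leaves its time units open; the once-per-minute schedule makes
minutes the natural reading.

# Dataset assembly and calibration

Features are averaged over good-quality beats in a 40-s window centred on
each reference BP time; a window where more than half the beats are bad is
recorded missing, never imputed silently. ECG features are computed from
the window's samples when at least half the window is covered by
good-quality blocks. Windowed streams are then conditioned per participant:
values beyond 5 robust (MAD) deviations from a 10-row rolling median are
removed, a scalar random-walk Kalman smoother (noise variances estimated
from the stream's first differences) damps transients, and remaining gaps
are filled by nearest-neighbour imputation in time. Conditioning runs on
the windowed series, after windowing.

Hybrid calibration personalises the cohort model with one baseline per
person: every dynamic feature becomes its relative change from the
participant's rest-period mean, x = (f − f̂)/f̂, and the target is the BP
change from the rest-period mean. A participant with no rest-window rows
falls back to a one-minute window around the first reading. Demographics
(age, sex, height, weight, BMI) and the baseline BP value join as static
columns.

Augmentation adds training rows by evaluating the smoothing splines on a
1/15-Hz grid with 15-s feature windows (disjoint windows, preserving row
independence); augmented rows are flagged and used for training and
hyperparameter validation only — all reported metrics use the original
once-per-minute rows.

Collinearity is removed by iterated variance inflation factors on the
unaugmented dynamic features (demographics exempt, since they must survive
to the importance analysis): the feature with the largest VIF is removed
until all VIF ≤ 10, i.e. until no feature is 90%-predictable from the rest.
The condition number (singular-value ratio of the unit-variance design) is
reported before and after.

# Estimation and evaluation

Two model families: LASSO-selected OLS (the L1 penalty picks the support at
a given λ, ordinary least squares refitted on the support gives the
coefficients; an empty support degrades to predicting the training mean)
and a 300-tree random forest with squared-error splits, tuned over `mtry`.
Grids are data-driven: 30 log-spaced λ from the smallest
all-zeroing penalty down by 10⁻⁴, and mtry ∈ {⌈M/10⌉, ⌈M/3⌉, ⌈M/2⌉, M}.

Evaluation is nested leave-one-subject-out cross-validation: the outer loop
holds out each participant entirely; the inner loop — itself a LOSOCV over
the remaining participants — picks the hyperparameter minimising mean inner
RMSE, scoring inner held-out participants on unaugmented rows to mirror the
outer evaluation. Per-fold metrics are the Pearson correlation (missing for
folds with fewer than three evaluable rows or constant references, never
reported as zero), RMSE and MAE. The zero-change baseline (ΔBP ≡ 0
everywhere, the floor any model must beat) reports the RMS and mean
absolute reference change with an undefined correlation. Paired model
comparisons use the two-tailed Wilcoxon signed-rank test (exact
distribution up to n = 25) with Benjamini–Hochberg adjustment across the
family.

# Feature importance

Attributions are Shapley values with the interventional value function: the
worth of a feature coalition at a point is the mean model output over a
background sample with coalition features taken from the point and the rest
from the background row. For arbitrary models `shap_kernel()` enumerates
all coalitions exactly up to 12 features and otherwise solves the
Shapley-kernel-weighted regression on sampled coalitions with the two
boundary coalitions imposed as constraints. For forests `shap_tree()` is
exact and fast: per background row and tree, the coalitions reaching a
given leaf form a cube determined by the path features on which the
foreground and background diverge, so each leaf contributes in closed form
with factorial weights in the counts of foreground- and
background-constrained features (implemented in C++). Both satisfy local
accuracy — base value plus attributions equals the prediction — exactly,
and both are cross-checked in the tests against brute-force enumeration of
the defining sum.

Per cross-validation fold, features are ranked by mean absolute attribution
over a sample of training rows (background 100 rows, explained 50, both
seeded; ties get average ranks) and the rank is normalised to (M − rank)/
(M − 1) ∈ [0, 1]. Medians and ranges across folds summarise stability, and
Kendall's τ-b between channels' median coefficients quantifies whether
SBP/MAP/DBP agree on what matters.

# Numerical choices and degenerate inputs

* Optimizer tolerances: 1e-8 relative cost change, 200 iterations per beat;
  widths floored at 1e-4 to avoid singular components.
* Filters refuse sampling rates that make them unrealizable; flat signals
  yield empty annotations with zero quality rather than errors.
* A feature with a zero calibration baseline is dropped for that
  participant (the relative change is undefined); a feature missing for any
  participant is dropped cohort-wide with a log line.
* Ties in importance ranking take average ranks; eigenvector signs and all
  RNG seeds are fixed, so every pipeline artifact is reproducible
  bit-for-bit given the configuration.

# Problem sizes

The shipped tests exercise the full pipeline on a four-participant cohort
with a shortened protocol (2-min rest, 4-min ramp, 2 + 2 min plateau and
washout) at 80 Hz PPG / 128 Hz ECG, and the headline checks use 200
decomposed beats and >1000 pooled beats for PCA — sizes chosen so the whole
suite runs comfortably on one CPU while leaving every algorithmic path
identical to a full-scale run. The generator's statistical defaults (cohort
median response 20 mmHg, IQR 8 mmHg, cuff noise SD 4 mmHg, 10% dropout)
are the study conditions and are never tuned per run.

# Known limitations

* The stiffness-to-morphology map is a linear interpolation between two
  endpoint shapes: realistic in direction, simplistic in detail.
* The synthetic feature–BP relationship is essentially monotone in one
  latent variable, so model comparisons on synthetic cohorts say little
  about which family would win on clinical data.
* `gauss_lvet` and the notch-inference fallback are documented
  approximations.
* Kernel SHAP with sampled coalitions is exact only for additive models;
  for the forest the exact tree algorithm is used instead.
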