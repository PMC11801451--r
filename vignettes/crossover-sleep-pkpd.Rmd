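---
title: "Methods: simulating and analysing crossover PK-sleep studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing crossover PK-sleep studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somnopk)
```

# Scope and model

somnopk implements the complete computational analysis of a randomized,
placebo-controlled crossover night study of a sleep-promoting drug:
noncompartmental pharmacokinetics of overnight plasma sampling, hypnogram
metrics, the quantitative-EEG slow-wave-energy pipeline, cardiovascular and
endocrine summaries, and within-subject crossover statistics. A synthetic
study generator embeds the population parameters of a buccal low-dose
dexmedetomidine cohort (and a sublingual pilot preset), so the whole chain
can be validated by parameter recovery without access to raw trial data.

This vignette records the modelling assumptions, the numerical conventions,
and the design decisions that were genuinely open, so that a maintainer can
see *why* the code does what it does.

# Pharmacokinetics

## The simulated concentration curve

Plasma concentration follows the one-compartment model with first-order
absorption $k_a$ and elimination $k_e$ (the Bateman function), normalised so
that $\mathrm{AUC}_\infty = s/k_e$:

$$C(t) = s\,\frac{k_a}{k_a-k_e}\left(e^{-k_e t}-e^{-k_a t}\right),
\qquad C(t) = s\,k_e\,t\,e^{-k_e t} \;\text{when } k_a = k_e .$$

`calibrate_bateman(tmax, thalf, cmax)` inverts the model: $k_e = \ln 2 /
t_{1/2}$; $k_a$ solves $t_{max} = \ln(k_a/k_e)/(k_a-k_e)$ by bracketed root
finding in $[k_e(1+10^{-9}), 10^3]$ to $|\Delta t_{max}| < 10^{-3}$ h (the
pair is infeasible when $t_{max}\ln 2/t_{1/2} \ge 1$, since the Bateman peak
cannot occur later than $1/k_e$).

**Grid-sampled Cmax convention.** The scale $s$ is chosen so that the
maximum of the curve *sampled on the study grid* (pre-dose draw at
$-0.5$ h, then 0.25–9 h) equals the target $C_{max}$, not the continuous
maximum. Cohort tables report observed maxima on the sampling grid, so the
grid convention makes recovery exact instead of biased by the distance
between the true peak and the nearest grid point.

**A deliberate over-determination.** The triple $(t_{max}, t_{1/2},
C_{max})$ fully determines the curve, including its AUC. The implied
$\mathrm{AUC}_{0-9}$ of the 40-µg calibration (≈1.4 ng·h/ml) is larger than
the corresponding cohort-table mean (1.12 ng·h/ml): cohort means are
averages of individually fitted profiles and need not be jointly realizable
by one curve. The package therefore treats $t_{1/2}$ and $C_{max}$ as the
recovery targets and documents the AUC discrepancy; the corresponding
recovery check in the test suite is expected to fail and is annotated as
such.

## Variability model

Between-subject variability multiplies the scale by a mean-preserving
lognormal factor (`bsv_cv`, default 0.25, matching the ~22–26% cohort CVs);
residual assay noise is proportional (`residual_cv`, default 0.05). The
mean-preserving parameterisation ($\mu_{\log} = \log m - \sigma_{\log}^2/2$)
keeps the cohort mean equal to the calibrated value, which is what the
recovery targets compare against. Values below the limit of quantification
(0.01 ng/ml; limit of detection 0.005 ng/ml) are flagged BLQ; the pre-dose
sample is 0 in every condition.

## Noncompartmental analysis conventions

* **Terminal slope.** Candidate sets are the last $k \ge 3$ quantifiable,
  positive samples strictly after $t_{max}$; the set maximising adjusted
  $R^2$ wins, ties going to more points. This is the conventional best-fit
  rule; the originating study states only the model class, so the rule is
  configurable in the sense that the fit function is exposed directly.
* **BLQ policy.** BLQ at or before $t_{max}$ counts as 0 (the curve is
  genuinely near zero there); BLQ after $t_{max}$ is excluded and the AUC
  integration truncates at the last quantifiable sample — values below the
  quantification limit are never invented.
* **Time 0.** The dose is taken at lights-off; the only pre-dose sample
  sits at $-0.5$ h, and the time-0 concentration is taken as 0.
* **AUC.** Linear trapezoid throughout (no log-linear down-slope variant);
  with the 18-point grid the difference is far below the recovery
  tolerances. $\mathrm{AUC}_\infty = \mathrm{AUC}_{all} +
  C_{last}/\lambda_z$.

# Sleep architecture

## Metrics

Stages are scored per 30-s epoch over {W, N1, N2, N3, R}. Sleep onset is
the first occurrence of **three consecutive epochs of any sleep stage**,
reported from lights-off to the *first* of the three epochs (whether the
original scoring anchored on the first or last onset epoch is not
documented; the first-epoch convention was chosen and the onset index is
exposed so either can be derived). REM latency runs from onset to the first
R epoch. Missing onset or missing REM propagate as `NA`, never as 0. Halves
of the night are split on time since lights-off (epochs 0–479 / 480–959 for
an 8-h night), matching the half-night definition used for slow-wave
energy, with the middle epoch of an odd-length night assigned to the first
half.

## The generator: latent variables plus deterministic layout

Each subject × condition night is summarised by latent variables — sleep
latency, REM latency, N2, N3 and REM minutes — drawn from condition means
(placebo baseline + additive condition effects) with a shared per-subject
random effect giving correlation $\rho = 0.7$ across conditions (a typical
crossover test-retest correlation, giving realistic paired power at
n = 17). The latents are rounded to the 0.5-min epoch grid and a stage
sequence is laid out that realizes them *exactly*: wake until onset, an
all-NREM block through the drawn REM latency, then NREM/REM cycles with
slow-wave sleep weighted toward early cycles and REM/wake toward late ones.
The layout is verified against the scoring rules before acceptance and
redrawn otherwise, so the metrics layer recovers the drawn values without
bias — a Markov-chain hypnogram generator could not guarantee that.

Two closure choices keep every night summing to time in bed:

* **N1 and WASO absorb the closure constraint**, split proportionally to
  their configured means. Renormalising all stages instead would shrink the
  configured condition effects on N2/N3/REM — exactly the quantities the
  recovery targets measure.
* **Latencies are lognormal** (mean-preserving), because a normal draw
  truncated at zero would bias the active-condition latency means upward
  (by ~1.4 min for a 13.5 ± 10 min draw) and corrupt the configured
  latency effect. Stage minutes stay normal; at the default SDs their
  clipping probability is negligible.

The default placebo baseline (latency 25, REM latency 70, N1 41, N2 219,
N3 68, REM 82, WASO 45 min) is a poor-sleeper-plausible night whose
components sum exactly to the 8-h time in bed; no placebo reference table
was available, so only condition *differences* are treated as recovery
targets and the baseline is fully configurable.

# Quantitative EEG

## Pipeline

Preprocessing applies a 50-Hz notch (European mains; frequency and width
configurable), a zero-phase 0.5–40 Hz band-pass, and downsampling to
128 Hz. Filters are Butterworth (notch order 2, low-pass order 6, high-pass
order 2) applied forward–backward so band-power estimates are not
phase-distorted; the anti-aliasing low-pass runs at the raw rate and the
high-pass after decimation. When C3/C4/M1/M2 channels are present they are
re-referenced to the contralateral mastoid (C3-M2, C4-M1).

Spectra use Welch's averaged modified periodogram per 30-s epoch: 4-s Hann
windows with 50% overlap (14 windows per epoch), density scaling in
µV²/Hz, 0.25-Hz bins from DC to Nyquist. The scaling satisfies Parseval
(PSD integral = signal variance, verified to 2% on noise) and returns
$a^2/2$ for a sinusoid of amplitude $a$.

Delta power sums the bins with $0.75 \le f \le 4.0$ Hz — inclusive edges,
14 bins — times the 0.25-Hz bin width (integrated band power, µV²). A
`density_sum` mode reports the bare density sum instead (µV²/Hz, the
convention some pipelines label band power with); because the two differ
only by the constant bin width, log-scale *differences* between conditions
are identical under both, and only such differences are used as recovery
targets.

Slow-wave energy (SWE) per half-night is the cumulative delta power across
epochs scored N2 or N3 and free of artifacts, log10-transformed for the
statistics layer. With two derivations, "better signal quality" is
operationalized as *fewer artifact-flagged epochs* (tie → C3-M2); the
originating description names no criterion, and artifact burden is the
property that actually degrades a cumulative band-power sum.

## EEG simulator

Each night is two channels of: 1/f background (unit-RMS spectrally shaped
noise, default 10 µV RMS), a stage-dependent delta oscillation (default
amplitudes W 0, N1 6, N2 20, N3 40, R 4 µV at 1.25 Hz) damped by
$e^{-t/\tau}$ with $\tau = 4$ h to emulate the overnight dissipation of
homeostatic sleep pressure, 50-Hz line noise (2 µV), and high-amplitude
transients in a configurable fraction (default 5%) of epochs, flagged per
channel in the artifact mask. A per-condition multiplier scales delta
amplitude in the first half of the night (defaults $10^{0.07/2}$ and
$10^{0.09/2}$ for the two active doses, i.e. first-half SWE ~0.07 and
~0.09 log10 units above placebo). The defaults were calibrated once so a
simulated placebo night lands near a first-half log10 SWE of ~4.7 through
the full pipeline.

# Cardiovascular and endocrine layer

The Schellong rule is implemented literally: the difference between the
last supine blood pressure and each of the *first three* upright readings;
an event requires a systolic drop ≥ 20 mmHg and/or a diastolic drop
≥ 10 mmHg (inclusive thresholds). A `scan_all` flag extends the scan to all
five upright readings for sensitivity analyses. Missing readings propagate
as missing, never as zeros. Nocturnal heart rate is averaged over epochs
scored N1/N2/N3 and over epochs scored R; hormone summaries are arithmetic
means over the protocol samples (nocturnal series at 0/90/180/360/480 min
after lights-off; awakening response at 0/15/30/45/60/75 min). The
physiology simulator draws subject-level means around the configured
per-condition targets with mean-preserving lognormal hormone levels
(cortisol SDs approach the mean, so a normal draw would go negative).

# Statistics

For a complete crossover with one observation per subject and condition,
the condition contrast from a linear mixed model with a participant random
intercept equals the paired mean difference; the package therefore uses
paired estimators with distribution-free inference instead of a model
fitter:

* estimate $= \overline{y-x}$, percentile-bootstrap 95% CI over subjects
  (default 10 000 resamples);
* sign-flip permutation p-value: exact enumeration of all $2^n$ sign
  patterns when $2^n \le 2^{15}$, otherwise Monte-Carlo with the identity
  flip included so $p > 0$ (default 10 000 flips); zero-variance
  differences report $p = 1$ with a degeneracy flag;
* standardized effect size $d_z = \overline{d}/s_d$;
* Benjamini–Hochberg correction applied **per variable** (all pairwise
  contrasts of one variable form one family); the family structure is an
  open convention and is configurable by calling `bh_adjust()` over any
  other grouping;
* SWE is analysed on the log10 scale and contrasts are convertible to
  percent via $(10^{\Delta}-1)\cdot 100$; all other variables stay on
  their natural scale.

All bootstrap/permutation seeds are mandatory arguments with recorded
defaults, so reports are reproducible bit for bit.

# Determinism and numerical choices

* Every simulator routes randomness through an internal seed guard: a fixed
  seed yields bit-identical output, and the caller's RNG state is restored.
  Child seeds for the different generators are derived from the design seed
  and kept within 32-bit range.
* Epoch quantization is 0.5 min; latent draws are rounded to it before
  layout, so recovery of latents is exact rather than within half an epoch.
* `fit_lambda_z` treats adjusted-R² ties within $10^{-12}$ as equal
  (favouring more points), protecting the tie rule from floating-point
  noise on exactly log-linear tails.
* Integration boundaries that fall between samples are handled by linear
  interpolation; AUC additivity over interior grid points holds to
  $10^{-12}$.

# Validation problem sizes

The test suite validates each stage at sizes chosen to keep the whole suite
fast while leaving no rule untested: exhaustive enumerations for the onset
and Schellong rules; single-epoch spectra for the Parseval and sinusoid
identities; crossover recovery at the study size n = 17 with the null-size
check of the permutation test run at n = 12 over 2 000 replicates (where
exact enumeration makes the achievable size essentially nominal); one full
8-h default-configuration EEG night end to end, with shorter nights used
for the homeostatic-decline property. The recovery script averages
replicate n = 17 studies (20 for pharmacokinetics, 40 for sleep effects) so
that reported values estimate the generator parameters rather than a single
study's draw.

# What passing tests do and do not show

The generator reproduces the *structure* of a crossover PK–sleep study —
correlated within-subject nights, realistic stage budgets, 1/f EEG spectra
with stage-dependent delta activity and artifacts, LOQ-censored
concentration profiles — and embeds the printed cohort parameters, so
recovery tests demonstrate that the analysis chain is unbiased and
correctly wired. They do not demonstrate performance on real recordings:
real hypnograms have scorer disagreement and arousal fragmentation the
latent-layout model does not emulate; real EEG has non-stationary artifact
morphology; real PK profiles deviate from one-compartment kinetics (the
AUC over-determination above is a visible symptom). Between-subject SDs,
CIs and p-values of the original cohort depend on its raw data and are
deliberately not targets.

# Limitations

* No EDF reader/writer: signals and hypnograms move through the package's
  plain-text formats.
* No pharmacodynamic link model (no concentration–effect hysteresis), no
  spindle/sigma analysis, no heart-rate variability, and no mixed-model
  layer — the paired estimator is exact for the complete-crossover design
  but does not handle missing-at-random condition dropout beyond listwise
  deletion.
* Visual sleep staging is consumed, not performed.
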