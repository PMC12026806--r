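---
title: "Models and methods behind neurodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind neurodyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

neurodyn implements the quantitative chain of a two-region LFP study —
dorsal hippocampal CA1 and prelimbic medial prefrontal cortex recorded
around a drug injection — together with the behavioral and histological
analyses that accompany such experiments, and a synthetic-data generator
that makes the whole chain testable without raw recordings. This vignette
explains the models, the defaults, the numerical choices, and what the
synthetic tests do and do not establish.

## Preprocessing

Wideband signals are linearly detrended, notch-filtered at the 50 Hz mains
fundamental and its harmonics up to 200 Hz, and decimated to 1 kHz.

* **Detrending** is linear by default (`detrend_signal`). "Detrended" is
  ambiguous in common usage; least-squares linear detrending subsumes mean
  removal and is idempotent. A constant signal detrends to all zeros, which
  is valid output, not an error.
* **Notch filters** are biquad IIR notches with quality factor Q = 30,
  applied forward–backward. Zero-phase filtering matters because the
  directionality estimator downstream measures phase lags; any asymmetric
  group delay would bias it. The input is padded with odd (point-symmetric)
  reflections sized to several ring-down time constants (4·Q/f cycles) so
  the high-Q transient decays inside the padding. At Q = 30 the −3 dB notch
  width at 50 Hz is ±0.8 Hz: attenuation at the line exceeds 40 dB after
  the double pass while frequencies 3 Hz away lose less than 1 dB.
* **Decimation** applies an 8th-order Butterworth low-pass at 0.8 of the
  output Nyquist (forward–backward) before subsampling; factors above 13
  are decomposed into cascaded stages, the standard guard against
  narrow-transition IIR instability. Whether the original acquisition
  chain used an explicit anti-aliasing filter is not documented; we assume
  one, since decimation without it is not meaningful.
* **Channel screening** replaces by-eye spectrogram inspection with an
  explicit rule: a channel is flagged when its windowed broadband power
  exceeds a robust z-score of 5 (against the median and MAD over all
  channels and windows) in more than 20% of windows. The thresholds are
  arguments, not constants, because any quantitative translation of
  "visual inspection" is a convention.

## Spectral estimation

`multitaper_psd` averages Slepian-taper eigenspectra with time-half-bandwidth
NW = 5 and K = 9 tapers over 60 s windows without overlap, so the spectral
concentration half-width is NW/T ≈ 0.083 Hz. The DPSS tapers are computed
exactly from the symmetric tridiagonal formulation (Sturm-count bisection
for the K largest eigenvalues, inverse iteration with a pivoted tridiagonal
solve, Gram–Schmidt against close eigenpairs), in compiled code, and cached
per window length. PSDs are one-sided in power per Hz, so they integrate to
the signal variance — the Parseval check in the test suite.

Two normalizations follow the field's conventions:

* **1/f normalization** multiplies power by frequency and drops the f = 0
  bin, for which the operation is undefined. Multiplication is the simplest
  deterministic whitening; `method = "fit"` instead divides by a power law
  fitted over 1–100 Hz, for users who prefer removing the *estimated*
  background. The choice is visible in `norm_state` and the two methods are
  never mixed silently.
* **Band power** is the *mean* (not the sum) over bins inside the band, so
  bands of unequal width (delta spans 3 Hz, high gamma 48 Hz) remain
  comparable. Whether the original quantification averaged or summed is
  not documented; the mean is our convention and is stated here.
* **Decibels** appear only in `autoplot` methods. All quantification is in
  linear power.

Band limits are role-specific on purpose: power uses theta 8–12 Hz and low
gamma 30–48 Hz, coherence quantification uses low gamma 20–40 Hz, and
directionality uses theta 4–10 Hz. These are the conventions of the
respective analyses and are kept in separate `band_set()` roles rather than
unified, because unifying them would silently change results.

**Baseline z-scoring** (`zscore_to_baseline`) demeans by the baseline-window
mean and divides by the baseline sample standard deviation (denominator
n − 1). At least two baseline windows with nonzero variance are required;
fewer is an error, not a silent NaN. Quantification epochs default to
minutes 5–15 (baseline) and 50–60 (post-drug) of a one-hour pre-task
session; scaled-down sessions place the epochs proportionally and the plans
below state the sizes actually used.

## Phase–amplitude coupling

The Tort modulation index bins the instantaneous phase of a slow band into
N = 18 equal bins (the standard bin count; the original protocol does not
state one), averages the fast-band amplitude per bin, normalizes to a
distribution P and reports MI = (log N − H(P))/log N. MI is 0 for a uniform
P, 1 when all amplitude sits in one bin, and invariant to positive scaling
of the amplitude up to floating-point rounding in the bin sums.

Phase and amplitude come from zero-phase FIR band-passes (Hamming design,
order three cycles of the low cutoff) followed by the analytic signal; the
FIR is applied by FFT convolution with exact group-delay compensation,
since direct convolution at thousands of taps would dominate runtime.

Numerical edge cases:

* An **empty phase bin** (possible in short windows) triggers a documented
  fallback — a uniform epsilon mass is added and the result carries an
  `empty_bins` attribute — rather than a NaN.
* Grid cells whose **phase band would extend below 0.5 Hz** (centers 0, 1
  and 2 Hz at the default 4 Hz bandwidth) are masked as invalid: the
  band-pass is numerically undefined there even though such cells are
  commonly plotted. Amplitude cells crossing the Nyquist frequency are
  masked likewise.
* **ROIs**: quantification defaults are CA1 theta–high-gamma (5–10 /
  50–100 Hz), PL delta–high-gamma (2–6 / 75–100 Hz) and PL
  theta–high-frequency (4–10 / 150–200 Hz). The variant ranges that
  accompany the described sPCP phenotype (CA1 delta–high-frequency 2–5 /
  150–200 Hz; a wider PL delta–high-gamma 2–5 / 75–120 Hz) ship as a named
  preset (`pac_rois("results")`) rather than being merged — the two sets
  differ in the source material and we do not guess the intent.

Significance is assessed against circular time shifts of the amplitude
envelope (≥ 1 s), which preserve both spectra while destroying the
phase–amplitude alignment. Note that circular shifts only decouple
*stochastic* rhythms; a strictly periodic driver re-aligns at multiples of
its period, which is why the generator (and the test fixtures) use
narrowband noise rather than pure sinusoids as slow rhythms.

## Connectivity

**wPLI.** Both signals are band-passed with zero-phase Butterworth filters
of order 3 (the classic choice for this pipeline), and the index is
|mean I| / mean |I| with I the imaginary part of the analytic
cross-spectrum. Weighting by the imaginary part rejects zero-lag common
sources — the dominant nuisance with referenced intracranial electrodes.
The non-debiased estimator is the default (`debias = TRUE` switches to the
debiased squared form); the plain estimator is what "wPLI" without
qualification denotes.

**PSI.** Within each 60 s epoch, complex coherency is estimated from
Hanning-windowed, half-overlapping 1 s segments, and
PSI = Im Σ_f C̄(f)·C(f+δf) over the band with δf = 1 Hz. Positive values
mean the first argument leads; we pin the convention to CA1-first, so
positive PSI is dHPC → mPFC. The estimator is exactly antisymmetric under
argument swap (the test asserts bit-level negation). PSI is reported
un-normalized by default; dividing by the epoch-wise standard error
(`normalize = TRUE`) matches the other common convention and changes no
sign. Bands narrower than δf are an error.

**Surrogates** are circular time shifts of one channel (uniform ≥ 1 s),
which preserve autospectra and destroy cross-phase. The source protocol
invokes surrogate data without defining the construction; circular shifting
is the least-assumption choice for continuous recordings.

## Behavior and histology

Mobility is the variance of the instantaneous acceleration module
√(x²+y²+z²) in 1-minute bins, reported as a ratio to the baseline maximum;
the ratio is invariant to uniform accelerometer gain. The discrimination
index is (t_novel − t_familiar)/(t_novel + t_familiar) computed from
*total* durations per phase (whether the original analysis used totals or
per-visit means is not documented; totals are our convention). Zero total
exploration leaves the DI undefined and flagged — the animal-exclusion
convention — never silently 0.

Histology counts are aggregated per animal by pooling cells across
sections (100·Σcoexpress/Σmarker), which is more stable than averaging
section-wise percentages when per-section counts are small (single-digit
counts occur in the dentate gyrus); the mean-of-sections variant is
implemented and selectable, since published summary tables cannot
distinguish the two. Group rows are unweighted means ± SEM over animals;
the pooled "all" row equals the animal-count-weighted mean of the sex
means, exactly, before rounding — the identity that reconstructs published
pooled rows from their sex-stratified rows (reference values ship in
`coexpression_reference()`). Report rounding is to the nearest integer.
The between-sex comparison is a Welch t-test with Cohen's d; the original
summary does not name its test, and Welch is the safe default for small
unequal groups.

## Inference

`rm_anova` decomposes sums of squares for one within-subject factor
(epoch), an optional between-subject factor (treatment) and their
interaction, with subjects as units. With a two-level within factor the
within F equals the squared paired t exactly, and all F values are
invariant to affine transforms of the dependent variable — both asserted
in the tests, alongside equality with R's `aov()` Error-strata
decomposition as an independent oracle. Greenhouse–Geisser correction is
implemented for designs with more than two within levels but is off by
default (two-level designs dominate here and sphericity is moot for them).
Incomplete or unbalanced designs are rejected with the offending unit and
level named.

Two designs coexist deliberately: biomarkers use epoch (within) ×
treatment (between, sessions recorded on different days), while the
discrimination-index design treats the four treatment conditions as a
repeated factor. In the virtual experiment every animal experiences every
condition, so for the biomarker design the *session* (animal × treatment)
is the repeated-measures unit — the same structure as analyzing the two
treatment days as separate subjects.

The type-I calibration in the acceptance suite runs the 2×2 design on
pure noise 1000 times and checks the interaction rejection rate at
α = 0.05 lands within 0.05 ± 0.02.

## The synthetic generator

Each channel is the sum of: a 1/f^α Gaussian background (α = 1 by default,
synthesized by spectral shaping, so the log-log PSD slope is exactly
controllable); band-limited oscillations per power band (frequency-domain
narrowband noise with raised-cosine edges, unit RMS, scaled by amplitude);
planted couplings; a shared narrowband component (4–10 Hz) delayed by
20 ms in PL so CA1 leads; an optional zero-lag common source added
identically to both channels; and an accelerometer whose three axes share
a smoothed-rectified-Gaussian activity envelope independent of the LFP
noise.

Coupling multiplies a fast carrier by (1 + κ·cos φ)/(1 + κ), where φ is
the phase of the slow rhythm — the normalization keeps the mean carrier
amplitude κ-invariant, isolating coupling strength from power changes. If
a planted band oscillation covers the requested phase frequency it serves
as the driver (so, e.g., delta-band power and delta-coupled fast activity
share one rhythm); otherwise a dedicated slow narrowband component is
generated and added to the trace.

Condition effects are *power* gains on the band oscillations, ramped in by
a logistic (≈ 30 s) after the injection time to avoid step artifacts. The
default sPCP phenotype is delta ×2.0, theta ×0.6, low gamma ×0.6 plus
aberrant delta-coupled fast activity (κ = 0.5: delta→150–200 Hz in CA1,
delta→75–120 Hz in PL); the drug condition halves each deviation from 1
(delta ×1.5, theta and low gamma ×0.8, κ = 0.25). The activity envelope
gains 1.5 under sPCP + saline (sustained agitation) and 0.8 otherwise. The
source study reports directions and F statistics, not effect sizes, so
these magnitudes are package conventions, chosen once to make every
planted parameter comfortably recoverable at 600–900 s session lengths,
and not tuned thereafter. The same applies to the novel-object preference
probabilities behind the virtual behavior tables (healthy 0.70/0.75 for
STM/LTM, sPCP + saline 0.55/0.50, sPCP + drug 0.62/0.72 — impairment under
sPCP, partial STM and full LTM rescue by the drug).

Everything is a pure function of the configuration including its seed;
the experiment runner derives per-session seeds from a master seed with a
hash-style stream splitter, so enlarging a cohort never changes existing
animals' data.

**What the generator does not emulate:** spiking activity, volume
conduction geometry, electrode drift and movement artifacts, non-Gaussian
heavy-tailed noise, state transitions (sleep/wake), and any locomotion
trajectory structure. Passing tests therefore establish estimator
correctness and planted-effect recoverability under the stated noise
model — not robustness to everything real recordings contain.

## Problem sizes and runtime choices

The default test and acceptance workloads use: 600 s sessions at 1 kHz for
full-grid coupling recovery; 60–120 s constructions for the wPLI/PSI
contracts (100 seeded sessions for sign recovery); 900 s sessions, 20
seeds and 3 conditions for the condition-ordering study (with the
coupling quantification restricted to a coarsened grid over the target
ROI — same bands, fewer centers); and 1000 replicates for the type-I
calibration. These sizes were chosen so each planted effect is recovered
with wide margin while a full run stays in the minutes range on one CPU.

## Known limitations

* Narrow (1 Hz) Butterworth bands below ~2 Hz at 1 kHz sampling approach
  the numerical stability limit of order-3 IIR design; the wPLI
  spectrogram's default range starts at 2 Hz for this reason.
* The mixed-design ANOVA uses weighted-means sums of squares; with
  unbalanced between groups this is the sequential (not Type III)
  decomposition. Designs here are balanced by construction.
* The binary writer quantizes to int16 with a per-channel scale (peak =
  32000 counts), bounding round-trip error at peak/64000 per sample.
* `flag_noisy_channels` assumes at least one clean channel; if every
  channel is bad the pipeline aborts rather than guessing.
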