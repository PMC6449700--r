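---
title: "Methods: pre-stimulus physiology and reaction-time modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pre-stimulus physiology and reaction-time modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its methods: the models and
procedures it implements, the tunable parameters and why their defaults
are what they are, what the synthetic-data generator does and does not
emulate, and the numerical and design choices made where the design was
genuinely open. Everything quantitative stated here is computed by the
test suite or by `scripts/acceptance.R`; nothing is asserted beyond what
those runs check.

## The analysis problem

A driver supervising a partially automated vehicle receives a stream of
arrow stimuli; most indicate reliable operation, a minority signal an
automation failure that requires a button press. The scientific question
is whether the driver's physiological state *just before* a failure
signal predicts the latency of their response. The pipeline therefore
revolves around three pre-stimulus windows per failure trial, all
half-open `[onset − W, onset)`:

* 10 s of ECG, summarized as meanRR and RMSSD;
* 1 s of EEG, summarized as alpha-band power in dB;
* 3 s of gaze, summarized as log dispersion (lnX, lnY);

plus the reaction time itself, and a session clock shared by all streams.

**Time base.** All streams carry timestamps in seconds on one session
clock; alignment is plain timestamp arithmetic. This replaces the network
clock-synchronization layer a live lab setup would use, while keeping the
same contract (timestamped samples in, time-locked windows out).

**Half-open windows.** The sample exactly at stimulus onset belongs to
the stimulus, not to the pre-stimulus state, so windows exclude their
right edge. This prevents any stimulus-evoked activity from leaking into
"pre-stimulus" features. A window with no samples flags the trial invalid
rather than aborting the run.

**Missingness policy.** Every failure trial yields a feature-table row;
per-feature validity flags record what could not be computed (artifactual
epoch, too few beats, too few confident gaze samples, missed response).
Model fitting excludes incomplete rows listwise — the mixed models
tolerate the resulting imbalance — and trials with missed detections are
excluded from RT models by default (exclusion, not imputation, since the
missingness mechanism for misses is not ignorable and the package takes
no stance on it).

## ECG: wavelet R-peak detection and HRV

R peaks are detected on the full record (never per window, to avoid edge
artifacts from repeated decompositions) with a maximal overlap discrete
wavelet transform:

1. MODWT with the sym4 wavelet (least-asymmetric Daubechies, 8 taps),
   implemented in-package with circular boundary handling; its
   multiresolution analysis is exact (details + smooth reconstruct the
   input to ~1e−12, tested).
2. The detail levels whose octave pass-bands `[fs/2^(j+1), fs/2^j]` have
   midpoints in the QRS energy band (default 8–25 Hz) are summed and the
   result squared. The lower default edge sits at 8 Hz because the octave
   below (~4–8 Hz) admits T-wave energy: on synthetic records with
   30%-amplitude T-waves it produced systematic false detections ~250 ms
   after each R peak. The band is a parameter; correctness is always
   judged by ground-truth recovery, not by the constant.
3. Local maxima of the squared reconstruction above an adaptive threshold
   (0.3 × the 95th percentile of 2-s blocks) are accepted greedily,
   strongest first, under a 250-ms refractory period — slightly below any
   physiologically plausible RR interval.
4. Each candidate is refined to the raw-signal maximum within ±50 ms, so
   reported peak times land on the R wave and are invariant to positive
   rescaling of the waveform (tested).

The detector is sampling-rate agnostic (level selection adapts to `fs`);
the synthetic default is 250 Hz. On 5-min synthetic records with T-waves
at signal-to-noise ratio 10, sensitivity and positive predictive value
are ≥ 99% (acceptance run).

meanRR is the arithmetic mean of successive peak differences inside the
10-s window; RMSSD is the root mean square of successive differences of
those intervals; both in ms, both requiring at least 3 peaks (2
intervals), otherwise the trial is flagged. RMSSD is checked against a
deliberately naive explicit-loop oracle to machine precision.

## EEG: filtering, screening, alpha power

The continuous record is filtered before epoching, as in standard
continuous-EEG workflows: a 1-Hz high-pass with 2-Hz transition bandwidth
and a 40-Hz low-pass with 10-Hz transition bandwidth. Both are Hamming
windowed-sinc FIR designs with order `ceiling(3.3 · fs / transition)`
(the Hamming design rule), cutoffs at −6 dB. The high-pass is built by
spectral inversion of a unit-DC-gain low-pass, which pins its DC response
to exactly zero — a plain `fir1` high-pass normalized at Nyquist leaks
about −25 dB of DC with these parameters, which matters when the
transition band touches 0 Hz. Each symmetric filter is applied once and
its group delay compensated exactly (reflection padding at the edges), so
filtering is zero-phase and pre-stimulus timing cannot shift; this is
verified by checking that a synthetic alpha burst confined to
`[onset − 1, onset)` stays in its window after filtering.

Multichannel records can be re-referenced to the mastoid average
(sample-wise subtraction of the mean of two reference channels). Epochs
with any sample beyond ±100 µV are invalidated; channels whose
record-level SD lies beyond ±2 SD of the across-channel distribution are
flagged (flagged only — interpolation is out of scope, and the synthetic
data is single-channel "Pz" by default since only Pz alpha enters the
models). Ocular ICA cleanup is not implemented: it requires manual
component identification, and the generator produces no blinks; the
±100 µV rule is what protects the features from large artifacts.

Alpha power per epoch: least-squares linear detrend, Hamming window,
transform length `nfft` = next power of two at or above the epoch length,
one-sided PSD, floor at 1e−12 (configurable) before `10·log10`, value
read at the grid bin nearest 10 Hz. At 500 Hz and a 1-s epoch,
`nfft = 512` and the bin is 5000/512 = 9.765625 Hz — 9.76 to two
truncated decimals. That nfft is the unique power of two reproducing that
printed bin, which is why it is the default; it remains configurable.
The power floor only matters for degenerate (e.g. all-zero) epochs, where
it returns a finite −120 dB instead of −∞. Detrending makes the value
invariant (< 0.01 dB, tested) to any linear ramp, and dB linearity in log
amplitude (+6.02 dB per doubling) is tested directly.

## Gaze: confidence-filtered dispersion

Samples below confidence 0.8 (boundary inclusive: ≥ 0.8 is kept) are
discarded; the remaining x and y positions in the 3-s window give sample
standard deviations (n−1 denominator — the convention of the statistical
environments this analysis style comes from; configurable in principle
but deliberately not a tuning knob) and their natural logs. A trial needs
at least 10 retained samples (default) and strictly positive dispersion;
ln is per-axis, so a degenerate y axis does not destroy lnX. No
saccade/fixation parsing is attempted: dispersion is computed on raw
retained samples. lnY is computed and stored for completeness even though
only lnX enters the full model.

## Behavior: RT and the A statistic

A `U` press is attributed to the most recent arrow whose window
`(onset, next onset]` contains it; with arrows ~13 s apart and RTs below
3 s, the window choice is not delicate. RTs above 2,600 ms are winsorized
to exactly 2,600 ms (set equal, not discarded). Presses inside a reliable
arrow's window count as false alarms.

Sensitivity is the Zhang–Mueller *A*: the average of the areas under the
minimum-area and maximum-area *proper* ROC curves through the observed
(F, H) point. It needs no z-transforms and is defined at H, F ∈ {0, 1} —
the reason it is preferred over d′ here. The package carries two
independent routes: the closed-form piecewise expression, and a numeric
construction in which the minimum-area curve is the concave two-chord
curve (0,0)–(F,H)–(1,1) and the maximum-area curve is found by
optimizing, over the supergradient slope at (F,H), the area under
`min(1, H + s(x − F))` subject to the curve staying proper. The two agree
to better than 1e−6 over the full (H, F) grid (acceptance run), and A is
verified monotone in H and antitone in F. For H < F the point is
reflected: A(H,F) = 1 − A(F,H).

## The mixed-effects RT models

The model family is

```
RT ~ 1 + (PzAlpha + meanRR + RMSSD [+ lnX] + TimePeriod)^k
       + (1 | participant) + (1 | trial)
```

with k up to 3, crossed random intercepts for participant and for trial
position (1–10 within each period), fit with lme4.

Design choices, each genuinely open and decided as follows:

* **ML, not REML**, for every fit that feeds a likelihood-ratio test of
  fixed effects — REML likelihoods of models with different fixed effects
  are not comparable. REML remains available (`ml = FALSE`) for variance
  reporting.
* **Standardization before expansion.** Continuous predictors are
  z-scored before the interaction expansion; interaction coefficients are
  otherwise scale-dependent and incomparable across studies. The LRT is
  invariant to any affine predictor rescaling (tested), so this choice
  affects reporting, not inference.
* **TimePeriod as a centered numeric covariate** (1–5, centered at 3): a
  single slope per interaction, matching the one-coefficient-per-term
  reporting convention of the model family, rather than a 4-df factor.
* **Random intercepts only** by default. Random slopes exist as an option
  but are off: the reference model formulas contain intercept terms only,
  and the generator's ground-truth model is the intercept structure, so
  recovery is well-posed.
* **LRT degrees of freedom** = difference in fixed-effect parameter
  counts; the random structure is held fixed across compared models, so
  boundary problems for variance components never arise. Comparing a
  model with itself returns χ² = 0, p = 1. Misuse — REML fits,
  non-nested fixed effects, fits on different rows — is a hard error.
* **bobyqa optimizer**: lme4's default occasionally reports spurious
  gradient-check failures on small-variance fits; since the LRT machinery
  (correctly) refuses non-converged fits, the optimizer with clean
  convergence behavior is the right default.

Nakagawa R²: with `var_f` the variance of the fixed-effect linear
predictor over the fitted rows, marginal = var_f / (var_f + σ²_participant
+ σ²_trial + σ²_resid) and conditional adds the random-intercept variances
to the numerator. marginal ≤ conditional ≤ 1 always (tested).

`model_search()` reproduces the staged sequence: four single-predictor ×
period interactive models (each LRT'd against its additive null, df 1);
the full five-term order-3 model; the reduced four-term model with lnX
dropped, LRT'd against its additive null (df 10); and three follow-up
LRTs probing the alpha×HRV, alpha×period and HRV×period interactions.
Each follow-up compares the full reduced interactive model (15 fixed
parameters) against "additive plus that single two-way term" (6), giving
df 9 — the only comparison structure consistent with the reference
df values.

## The synthetic-data generator

The generator is first-class, tested code, and its documented feature→RT
map is exactly the model family the fitting stage assumes — that is what
makes parameter recovery well-posed.

**Event schedule.** Five 600-s periods per participant; 50 arrows per
period with inter-event intervals uniform on 13 ± 2 s *rescaled* to fit
the period — the arrow count is authoritative when count and spacing
conflict (600/13 ≈ 46, but trial bookkeeping — 10 unreliable trials per
period — is driven by counts). Exactly 20% of arrows are unreliable, at
randomized positions, with outcomes split 6/2/2 across
no-change / incorrect-change / correct-change. Arrow duration (150 ms) is
metadata; nothing is rendered.

**ECG.** RR intervals are the mean plus i.i.d. Gaussian deviations with
σ = RMSSD/√2, which makes the expected RMSSD equal the target exactly
(an AR(1) option was considered and rejected: a single time-domain HRV
metric does not constrain autocorrelation, and the i.i.d. construction
keeps the target analytic). Non-positive draws are resampled; a
configuration whose draws would be non-positive more than 1% of the time
is rejected as unphysiological. The waveform is baseline noise plus a
stereotyped biphasic QRS pulse (~80 ms Mexican-hat) at each cumulative RR
time and an optional T-wave hump (30% amplitude, +250 ms) — enough
morphology to stress a QRS detector, with ground-truth peak times
recorded. Within each trial's 10-s pre-window the RR statistics switch to
that trial's latent (meanRR, RMSSD), so the extracted features have
known per-trial truth.

**EEG.** 1/f-shaped background (spectral shaping of white noise,
exponent 1, RMS 10 µV) plus a 10-Hz sinusoid whose amplitude equals the
trial's latent value throughout the 1-s pre-window, with 0.2-s
raised-cosine ramps outside it. The monotonicity benchmark uses 100
trials with latent amplitudes spaced 1–12 µV against that background —
a range chosen to represent clearly separated attentional states; the
acceptance run checks Spearman rank correlation > 0.9 between latent
amplitude and measured dB.

**Gaze.** 120-fps Gaussian scatter about the screen center with
per-trial dispersion (log-normal multiplier on a 50/40 px baseline)
inside the 3-s pre-windows; a configured fraction of samples receives
confidence below 0.8 (uniform on [0, 0.8)), the rest uniform on [0.8, 1].

**Responses.** RT = intercept + β·(standardized latent features and
configured interactions) + participant intercept + trial intercept +
Gaussian residual, floored at 150 ms; misses at a configured rate; a
second press reports the outcome with configured accuracy; reliable
arrows draw false alarms at a configured rate. The ms-scale defaults
(intercept 900, SDs 100/30/150 ms) give realistic RT distributions and a
conditional-over-marginal R² pattern dominated by random effects, as in
real data of this kind.

**Two levels of simulation.** `simulate_session()` produces raw streams
and exercises the full signal path; `simulate_feature_table()` generates
the per-trial features directly from the latent model. The calibration
benchmarks (coefficient recovery, type-I error) run at the latent level:
they are statements about the estimator, and the canonical benchmark
config works on a standardized RT scale (intercept 0, SDs 0.6/0.2/0.75,
planted alpha×HRV coefficient 0.5, RT floor disabled — a 150-ms floor is
meaningless for a standardized response). Latent-level measurement noise
defaults to zero so that coefficient recovery is a test of the fitter,
not of errors-in-variables attenuation; the signal path carries real
measurement error and is validated separately by its own ground-truth
recovery tests.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: real QRS morphology variation, ectopic beats
and electrode motion artifacts; EEG blinks, saccade potentials and
non-stationary background (no ICA is therefore needed or implemented);
saccade dynamics in gaze (i.i.d. scatter only); RT distributions' right
skew (the latent model is Gaussian); and any dependence structure between
modalities beyond the planted linear couplings.

## Problem sizes and runtime choices

The study-scale benchmarks use 25 participants × 5 periods × 10 trials
(1,250 trials), the size this design family targets; coefficient recovery
averages 50 such replicates and the type-I benchmark uses 200 null
replicates, sizes at which the Monte-Carlo error of the checked
quantities is several times smaller than the acceptance bands. Unit tests
use 1-min ECG records and the acceptance run a 5-min record at SNR 10;
these are the smallest sizes at which the ≥ 99% sensitivity/PPV bands are
meaningful. The full signal-level pipeline is exercised end-to-end on
compact sessions (minutes of signal) because its correctness claims —
windowing, time-locking, determinism — do not depend on duration.

## Known limitations

* The MODWT uses circular boundary handling; within ~half a filter width
  of the record edges, detail coefficients mix the two record ends. The
  detector can occasionally place one spurious peak near a record edge;
  in windowed use (peaks taken from 10-s windows interior to the record)
  this is immaterial.
* The A statistic's numeric oracle optimizes a one-parameter family; it
  is an independent check of the closed form, not a general ROC fitter.
* `flag_bad_channels()` flags; it does not interpolate.
* The pipeline assumes one session clock. Ingesting native device
  formats with independent clocks (and their drift) is out of scope.
* Period-level accuracy aggregation is provided; repeated-measures ANOVA
  machinery for secondary tasks is not (standard tools exist elsewhere).
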