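---
title: "Motor-speech DDK analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motor-speech DDK analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddktools)
```

## The problem

Diadochokinesis (DDK) tests ask a speaker to repeat a syllable such as
"pa", "ta" or "ka" as fast as possible for about ten seconds.  Because
each repetition is a full motor-planning and articulation cycle, the
timing microstructure of these recordings — repetition rate, cycle
regularity, the proportion of time spent articulating versus pausing,
and the voice onset time (VOT) of each plosive — carries information
about motor-speech control.  In older adults, such measures are
candidate digital biomarkers of cognitive performance: the question is
not whether any single feature is "significant", but whether the
feature set as a whole improves the estimation of count-valued
cognitive test scores (episodic-memory errors, executive search
strategy, working-memory errors) beyond readily available demographic
and clinical covariates.

`ddktools` implements that full analysis: a synthetic-data generator
with exact timing ground truth, a preprocessing and feature-extraction
chain producing a 19-feature motor-speech profile per recording, and a
model-selection layer that fits count GLMs and asks the
improvement-in-fit question with AICc.

## Acoustic chain

### Preprocessing

Recordings arrive as mono WAV at anywhere from 8 to 48 kHz (consumer
hardware).  Screening excludes 8-kHz recordings outright, recordings
shorter than `min_duration` (default 2 s — a 10-s protocol recording
below that cannot contain a usable trial), and recordings whose
active-speech fraction after denoising is below 2% ("no utterance").
Everything admitted is resampled to one internal analysis rate of
16 kHz so frame/hop parameters are uniform, then denoised and
peak-normalized.

Noise reduction is spectral gating: a short-time spectrum (32-ms Hann
frames), a per-band noise floor tracked as the 20th percentile of
magnitude over a 1.5-s sliding window (so the gate follows
non-stationary backgrounds), and a soft sigmoid mask that attenuates
bins below floor + 6 dB by up to 20 dB.  The parameters were fixed
once from the synthetic test bench: the gate must strictly reduce
silent-span energy at 10 dB SNR while leaving the active span of a
clean recording correlated above 0.99 with its input.

### Onset detection

The onset strength envelope is the half-wave-rectified positive first
difference of the log-magnitude short-time spectrum, averaged across
bands (46-ms frames, 10-ms hop).  Two numerical details matter:

* envelope samples are stamped with the *end* time of their analysis
  window, because the flux peak produced by a broadband burst occurs
  at the frame that first includes it;
* near-empty bins are floored 80 dB below the recording maximum
  before the log, so spectral-leakage flutter in silent bands does
  not contribute flux, and trailing zero-padded frames are dropped
  because a window sliding off the end of a sustained sound smears it
  into a broadband artifact that mimics an onset.

Peaks are accepted above `threshold_rel` (default 1.5) times an
adaptive baseline (local median over 1 s plus 5% of the global
maximum) and kept greedily in descending strength under a 90-ms
minimum separation — above the fastest plausible human syllable rate
(~11/s).  Each accepted peak is then refined against the waveform:
within a window from 25 ms before to 10 ms after the coarse time, the
onset is placed at the first 5-ms energy sample after the preceding
energy minimum that crosses 15% of the local peak.  This removes the
sub-frame bias of the spectral time base; on the synthetic bench the
refined onsets sit within about 2 ms of truth, against the 10-ms hop.

### Segmentation and voice onset time

Speech/pause segmentation thresholds a 25-ms RMS envelope (5-ms hop)
with hysteresis between an enter level (35% of the log-domain range
between the 10th-percentile floor and the 95th-percentile speech
level) and an exit level (20%), then enforces a 30-ms minimum speech
and 25-ms minimum pause duration.  Because a centred RMS window makes
an ideal step cross any fixed threshold about half a window early,
each detected interval is shrunk by half the RMS frame per side.
Pauses are defined only *between* repetitions: leading and trailing
silence belongs to neither zone, so speech% + pause% is at most 100
of the file duration (both percentages use the full sample duration
as denominator).  A degenerate input with no dynamic range is
classified by crest factor: a sustained periodic sound (median RMS
above 0.35 of peak) becomes one full-span speech interval, broadband
noise becomes silence.

VOT is measured per repetition as voicing onset minus burst onset.
The burst is located by a 5-ms energy-rise criterion searching from
the interval start — and up to 150 ms *before* it, bounded by the
previous interval, because a long voicing gap can split one syllable
into a burst fragment and a vowel interval.  Voicing onset is the
first 30-ms analysis frame (5-ms step) whose normalized
autocorrelation peak in the 70–400 Hz fundamental band reaches 0.5,
with linear interpolation of the threshold crossing; the window is
centred, which cancels the systematic half-window delay of a
leading-edge convention.  VOTs above a 150-ms ceiling are treated as
segmentation errors and dropped (still counted as attempts).

### The 19 features

The feature panel groups into onset (count, rate), inter-onset
interval (mean, SD, inverse minimum, log-ratio decrement normalized
by IOI count, inverse-IOI mean and COV), syllable (articulation rate,
duration mean/COV, speech percent, speech-to-pause ratio), pause
(mean, COV, percent), voice onset (VOT mean, COV) and energy (onset
strength COV).  All COVs are sample SD divided by mean, and all SDs
use the n−1 denominator, matching common statistical software.  Two
conventions deserve emphasis because the field does not fix them:

* `decrement_on_ioi = log(IOI_last / IOI_first) / N_IOI` uses the
  natural log, the raw (untrimmed) first and last intervals, and is
  positive when the speaker slows;
* onset strengths are normalized per recording (maximum 1), not per
  cohort.

Features whose defining event set is empty (no pauses, no measurable
VOTs, fewer than two onsets) are explicit `NA`s, never zeros or
infinities, and models containing such a feature simply drop those
recordings.

## Synthetic data

### Audio

`synthesize_ddk_recording()` emits a repetition train in which each
syllable is a broadband noise burst followed by a voiced vowel — a
3-harmonic tone with a 10-ms raised-cosine attack, chosen because it
gives an unambiguous periodicity onset for VOT testing without full
formant synthesis.  The vowel starts exactly `vot` seconds after the
syllable onset, the field definition of VOT (voice onset minus speech
onset); the burst may overlap the vowel when `vot` is shorter than
the burst.  IOIs are Gaussian around a per-repetition mean that runs
linearly from `ioi_mean (1 − drift/2)` to `ioi_mean (1 + drift/2)`,
so the sign of the IOI-decrement feature is controllable.  SNR is
defined on the active-speech span only; a whole-file definition would
let the silence fraction distort it.  The manifest records every
onset, voice onset and zone boundary exactly, which is what makes the
timing-recovery bench (recall/precision at 50-ms tolerance, IOI and
VOT error bounds) possible.

Defaults — 4.5 syllables/s, 10-ms IOI jitter, 5% slowing drift,
120-ms syllables, 40-ms VOT, 120-Hz f0, 25-dB SNR — are typical
values for fast monosyllabic DDK in older adults and were fixed once;
they are deliberately ordinary rather than tuned to any cohort,
since no public recording-level statistics exist for this protocol.

### Cohort

`simulate_cohort()` draws per-participant speech parameters (rate,
jitter, drift, syllable duration, VOT, SNR, f0), derives the 19
features from them in closed form, and attaches demographic and
clinical covariates with the marginal distributions of a community
sample aged 50+: age Normal(66.9, 7.3) truncated at 50, 72% female,
a five-level education ordinal, a psychiatric-diagnosis flag (15%
healthy-cognition, 30% subjective-impairment), and HADS anxiety and
depression as overdispersed counts capped at 21.  Outcomes come from
the same families the analysis fits: executive strategy is
Poisson(exp η), episodic- and working-memory errors are negative
binomial with size `nb_dispersion` (default 1.2, matching the
overdispersion implied by score summaries of mean ≈ 4, SD ≈ 4.4).
The linear predictor adds the covariate block and any planted
per-SD `feature_effects`; every coefficient is stored with the
output, so the null world is verifiable by construction.

What the generator does *not* emulate: real spectro-temporal syllable
variety, articulatory slurring, room reverberation, codec artifacts,
or any group-level difference in speech features (the default world
is null; `group_feature_shift` plants one when a classification
simulation needs it, and applies at the feature level, not to the
synthesized audio).  Passing tests therefore demonstrate correctness
of the measurement and inference chain under controlled conditions,
not robustness to all field recordings.

One invariant is deliberately not enforced: real executive-strategy
scores have a minimum of one, but the simulated outcome is drawn as
pure Poisson because the selection operating characteristics are only
meaningful under the exact stated family; at the default mean of 7.7
a zero occurs with probability below 0.1%.

## Statistical layer

### Count GLMs and AICc

Executive function is fitted as Poisson, episodic and working memory
as negative binomial (log link throughout).  The NB fit alternates
weighted least squares at fixed dispersion with maximum-likelihood
dispersion updates until the log-likelihood is stable to 1e−10 —
the same alternation `MASS::glm.nb` performs, run on a prebuilt model
matrix so that thousands of subset fits stay fast; agreement with
`glm.nb` is enforced in the tests at 1e−6 on the log-likelihood.  The
dispersion parameter is counted in k for AICc, matching the
likelihood-based parameter count of the glm.nb/MuMIn toolchain.
AICc = AIC + 2k(k+1)/(n−k−1).

### Exhaustive selection

For each group × outcome × test combination, the null model (age,
sex, education as an ordinal numeric, psychiatric flag, HADS anxiety
and depression) is fitted first, then every feature subset containing
no forbidden pair, with no interaction terms.  Two design points keep
AICc values comparable: the complete-case set is computed once across
the outcome, the covariates and *all* candidate features and reused
for every subset (AICc comparisons require identical n), and subsets
are enumerated in canonical (sorted) order so results are invariant
to how the caller lists features.

A pair of features is forbidden when |r| exceeds 0.6 in all three DDK
tests — absolute correlation, because collinearity is sign-agnostic,
computed within the analysis group (configurable to pooled; with very
small groups the pipeline falls back to pooled automatically).  A
pair with an undefined correlation in any test stays selectable.

The improvement criterion is ΔAICc = AICc_null − AICc_best strictly
greater than 2.  The candidate set contains the models that beat the
null by more than 2 *and* sit within 2 of the best; appearance rates
are the fraction of candidate models containing each feature.
Nagelkerke pseudo-R² is reported against the intercept-only reference
(so the null covariate block itself has a nonzero R²_N), as a
percentage.

Two operating characteristics are worth knowing.  With a single
candidate feature the ΔAICc > 2 rule behaves like a likelihood-ratio
test at roughly the 4.5% level.  With a panel of p quasi-independent
features the per-run family-wise false-positive rate grows roughly
like 1 − 0.955^p — best-of-many selection is not a calibrated test,
which is why a null-world pipeline run shows a handful of
"significant" combinations out of 18 and why feature-level
conclusions should rest on appearance rates across candidate sets
rather than single best models.

### Group classification

The supplementary question — do speech features improve HC vs SCI
classification? — is answered with logistic models (covariates only
vs covariates plus all features, no forbidden-pair filtering,
collinear fits accepted) compared by paired ROC curves.  AUC is
Mann–Whitney concordance with half credit for ties; the comparison
uses the paired placement-value (DeLong) variance.  The calibration
simulation evaluates the test under its own assumptions —
prespecified score vectors — where its type-I rate is nominal.
Comparing *nested models refit on the same data* inherits in-sample
optimism and rejects more often as n grows; that caveat applies to
any apparent-fit ROC comparison of nested models, including the one
this pipeline reproduces, and no cross-validation is applied because
none is part of the reproduced analysis.

## Pipeline and problem sizes

`run_pipeline()` chains simulate → screen/denoise → extract →
assemble → select → classify, writes the 18-row selection report,
the long-format appearance-rate table, the 3-row ROC report, an
exclusion log and a config snapshot, and is byte-deterministic under
a fixed seed (every stage seed derives from the master).  The default
exhaustive stage analyses a fixed 10-feature panel spanning all six
quality groups (onset count, IOI mean, IOI SD, inverse minimum IOI,
IOI decrement, articulation rate, syllable-duration COV,
speech-to-pause ratio, pause mean, VOT mean) under the default cap of
2^10 fits; the full 19 features are available by raising `cap`.  A
data-driven choice of the panel was rejected because it would change
the inference.

The shipped validation uses a 200-participant cohort (≈570 recordings
after 7% missingness) for the end-to-end run, 36 grid cells for
timing recovery, 1000 replicates for the null-world ΔAICc rate and
ROC calibration, and 200 replicates for planted-effect power; these
sizes give Monte-Carlo error comfortably below the asserted bounds
while keeping a full run in minutes on one CPU.

## Known limitations

* The syllable/pause/VOT feature family re-implements published
  *definitions*; equivalence with the proprietary extraction used in
  the original cohort study cannot be validated, only behaviour
  against ground truth.
* The log-ratio direction of the IOI decrement and the per-recording
  normalization of onset strengths are documented conventions; a
  different implementation may flip the sign or scale.
* Education enters the null model as an ordinal numeric (dummy coding
  is a configuration away); reference levels change coefficients but
  not the ΔAICc question.
* The in-sample ROC comparison is optimistic for the full model, as
  discussed above.
* Synthetic audio is a timing model, not a phonetic one; performance
  on real recordings with reverberation, clipping or variable
  microphone distance is untested here.
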