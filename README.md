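# ddktools

Acoustic analysis of diadochokinetic (DDK) motor-speech tests with
count-model selection for cognitive scores.

DDK tests ask a speaker to repeat a syllable ("pa", "ta" or "ka") as
fast as possible for ~10 seconds.  The timing microstructure of the
recording — repetition rate, cycle-to-cycle variability, the split of
time between articulation and pauses, and the voice onset time (VOT)
of each plosive — is a candidate digital biomarker of cognition in
older adults.  `ddktools` is for researchers who want to run that
analysis end to end, and to validate every stage against ground
truth:

* **Synthesis** — DDK-like audio with exact event manifests
  (`synthesize_ddk_recording()`), and cohorts with covariates and
  count outcomes drawn from known GLMs (`simulate_cohort()`).
* **Preprocessing** — WAV I/O, screening (8-kHz exclusion, negligible
  length, no-utterance), non-stationary spectral-gating noise
  reduction, peak normalization (`screen_recording()`, `denoise()`,
  `normalize()`).
* **Feature extraction** — a 19-feature motor-speech profile per
  recording: onset count/rate; inter-onset-interval (IOI) mean, SD,
  inverse minimum, log-ratio decrement, inverse-IOI mean/COV;
  articulation rate, syllable duration mean/COV, speech percent,
  speech-to-pause ratio; pause mean/COV/percent; VOT mean/COV; onset
  strength COV (`extract_features()`).
* **Inference** — Poisson and negative-binomial GLMs of count-valued
  cognitive scores; exhaustive AICc-ranked subset selection over the
  features under a pairwise-correlation exclusion rule (|r| > 0.6 in
  all three DDK tests); Nagelkerke pseudo-R²; candidate-set feature
  appearance rates (`exhaustive_selection()`); paired DeLong ROC
  comparison of group classifiers with and without the speech
  features (`compare_group_classifiers()`).

## The statistical core

For each group × outcome × test combination the null model contains
the demographic/clinical block (age, sex, education, psychiatric
flag, HADS anxiety/depression).  Candidate models add every subset of
speech features that contains no forbidden pair, with no
interactions.  Writing `AICc = 2k − 2·logL + 2k(k+1)/(n−k−1)`, the
speech features are judged to improve estimation when

```
ΔAICc = AICc_null − AICc_best > 2,
```

and the *candidate set* comprises the models beating the null by more
than 2 while lying within 2 of the best; each feature's appearance
rate is the fraction of candidate models containing it.  Fit is
summarised by Nagelkerke's R²_N (percent) against the intercept-only
reference.

## Worked example

Synthesise a recording, extract its features, and test whether a
planted feature effect is recovered by model selection:

```r
library(ddktools)

syn <- synthesize_ddk_recording(syllable_train_spec(seed = 42,
                                                    snr_db = 25))
syn$manifest
#> <ddk_manifest> 43 onsets, IOI mean 0.219 s (sd 0.0114), 43 syllable / 42 pause zones

round(extract_features(syn$recording)[c("onset_rate", "ioi_mean",
                                        "ioi_sd", "vot_mean")], 4)
#> onset_rate   ioi_mean     ioi_sd   vot_mean
#>     4.3000     0.2193     0.0114     0.0414
```

The extracted IOI mean (0.2193 s) and jitter (0.0114 s) match the
manifest truth above, and the VOT estimate (41.4 ms) sits within
1.4 ms of the 40-ms generative value.

```r
sim <- simulate_cohort(cohort_spec(
  n_participants = 600, seed = 7,
  feature_effects = list(executive_strategy = c(ioi_sd = 0.3))))
d <- merge(sim$cohort, sim$features[sim$features$test == "pa", ],
           by = "participant_id")
sel <- exhaustive_selection(
  d[d$group == "HC", ], "executive_strategy",
  features = c("ioi_sd", "speech_to_pause_ratio", "vot_mean"),
  family = "poisson")
sel
#> <ddk_selection> outcome executive_strategy (poisson), n = 479, 8 models
#>   delta AICc (null - best) = 401.41  *significant (> 2)*
#>   R2_N null 13.8%, best 63.0% (delta 49.3%)
#>   best subset: ioi_sd
```

The planted IOI-jitter effect dominates: the best model contains
`ioi_sd`, ΔAICc far exceeds the threshold of 2, and `ioi_sd` appears
in 100% of the candidate models (`appearance_rates(sel)`), while the
two null features do not improve fit on their own.

A full study — simulate, synthesise and analyse ~570 recordings, run
all 18 group × outcome × test selections and the 3 per-test ROC
comparisons, and write CSV reports — is one call:

```r
res <- run_pipeline(pipeline_config(n_participants = 200, seed = 1,
                                    out_dir = "ddk_run"))
res$selection_report   # 18 rows: delta AICc, R2_N, best subset
res$roc_report         # 3 rows: AUC null vs full, DeLong p
```

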