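Package: ddktools
Title: Acoustic Analysis of Diadochokinetic Speech Tests with
    Count-Model Selection for Cognitive Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing rapid syllable-repetition
    (diadochokinetic, DDK) speech recordings as digital biomarkers of
    cognition in older adults.  Synthesises DDK-like audio with known
    timing ground truth, screens and denoises WAV recordings, detects
    syllable onsets and measures inter-onset intervals and voice onset
    times, segments speech and pause zones, and computes a 19-feature
    motor-speech profile per recording.  Fits Poisson and
    negative-binomial generalized linear models of count-valued
    cognitive scores, performs exhaustive AICc-ranked subset selection
    over the speech features under a pairwise-correlation exclusion
    constraint, reports Nagelkerke pseudo-R2 and candidate-set feature
    appearance rates, and compares paired ROC curves for group
    classification with and without the speech features.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    signal
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
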