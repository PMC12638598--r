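# Shared fixtures, computed lazily and cached per test file.

.fixtures <- new.env(parent = emptyenv())

# a standard synthetic train plus its denoised/normalized recording
std_train <- function(seed = 7, snr_db = 30, ...) {
  key <- paste("train", seed, snr_db, paste(deparse(list(...)),
                                            collapse = ""))
  if (!is.null(.fixtures[[key]])) return(.fixtures[[key]])
  syn <- synthesize_ddk_recording(
    syllable_train_spec(seed = seed, snr_db = snr_db, ...))
  dn <- normalize(denoise(normalize(syn$recording)))
  out <- list(recording = syn$recording, manifest = syn$manifest,
              clean = dn)
  .fixtures[[key]] <- out
  out
}

# simulated cohort merged with one test's features
sim_analysis_frame <- function(n, seed, test = "pa", ...) {
  sim <- simulate_cohort(cohort_spec(n_participants = n, seed = seed,
                                     ...))
  merge(sim$cohort,
        sim$features[sim$features$test == test, , drop = FALSE],
        by = "participant_id")
}

null_covs <- c("age", "sex", "education", "psychiatric",
               "hads_anxiety", "hads_depression")

# onset series with specified inter-onset intervals
onsets_from_iois <- function(iois, strengths = NULL, start = 0.5) {
  times <- start + c(0, cumsum(iois))
  if (is.null(strengths))
    strengths <- rep(1, length(times))
  structure(list(times = times, strengths = strengths),
            class = "ddk_onsets")
}

segments_manual <- function(speech, pause, total) {
  structure(list(speech_intervals = matrix(speech, ncol = 2,
                                           byrow = TRUE),
                 pause_intervals = matrix(pause, ncol = 2,
                                          byrow = TRUE),
                 total_duration = total),
            class = "ddk_segments")
}

vot_manual <- function(vots, n_attempted = length(vots)) {
  structure(list(vots = vots, n_attempted = n_attempted),
            class = "ddk_vot")
}
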