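test_that("synthesised trains honour the requested timing structure", {
  spec <- syllable_train_spec(seed = 2, ioi_sd = 0, ioi_drift = 0,
                              ioi_mean = 0.2, n_repetitions = 40)
  syn <- synthesize_ddk_recording(spec)
  expect_length(syn$recording$samples, round(10 * spec$sample_rate))
  iois <- diff(syn$manifest$onset_times)
  expect_equal(iois, rep(0.2, length(iois)), tolerance = 1e-12)
  expect_equal(syn$manifest$voice_onset_times,
               syn$manifest$onset_times + spec$vot)
  # syllable and pause zones tile the active span
  syl <- syn$manifest$syllable_intervals
  pau <- syn$manifest$pause_intervals
  expect_equal(pau[, 1], syl[-nrow(syl), 2])
  expect_equal(pau[, 2], syn$manifest$onset_times[-1])
})

test_that("empty, truncated and jitter-free cases behave as specified", {
  # zero repetitions: noise-only waveform, empty manifest
  syn0 <- synthesize_ddk_recording(
    syllable_train_spec(seed = 1, n_repetitions = 0))
  expect_length(syn0$manifest$onset_times, 0)
  expect_gt(stats::sd(syn0$recording$samples), 0)

  # repetitions that would overflow the file are truncated
  syn <- synthesize_ddk_recording(
    syllable_train_spec(seed = 1, duration = 2, n_repetitions = 50,
                        ioi_mean = 0.25, ioi_sd = 0))
  k <- length(syn$manifest$onset_times)
  expect_lt(k, 50)
  expect_lte(max(syn$manifest$syllable_intervals[, 2]), 2)
})

test_that("identical seeds give bit-identical audio and manifests", {
  a <- synthesize_ddk_recording(syllable_train_spec(seed = 1))
  b <- synthesize_ddk_recording(syllable_train_spec(seed = 1))
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$manifest, b$manifest)
  c <- synthesize_ddk_recording(syllable_train_spec(seed = 2))
  expect_false(identical(a$recording$samples, c$recording$samples))
})

test_that("IOI drift runs linearly from slow-start to slow-end", {
  spec <- syllable_train_spec(seed = 1, ioi_sd = 0, ioi_drift = 0.2,
                              ioi_mean = 0.25, n_repetitions = 35)
  syn <- synthesize_ddk_recording(spec)
  iois <- diff(syn$manifest$onset_times)
  expect_equal(iois[1], 0.25 * 0.9, tolerance = 1e-9)
  expect_equal(iois[length(iois)], 0.25 * 1.1, tolerance = 1e-9)
  expect_true(all(diff(iois) > 0))
})

test_that("invalid train specifications are rejected", {
  expect_error(syllable_train_spec(duration = 0), "duration")
  expect_error(syllable_train_spec(syllable_duration = 0.04,
                                   burst_duration = 0.02, vot = 0.03),
               "burst_duration")
  expect_error(syllable_train_spec(ioi_sd = -1), "ioi_sd")
})

test_that("wav and manifest files round-trip", {
  syn <- std_train()
  wav <- tempfile(fileext = ".wav")
  man <- tempfile(fileext = ".tsv")
  write_wav(syn$recording, wav)
  write_manifest(syn$manifest, man)
  rec2 <- read_wav(wav)
  expect_equal(rec2$sample_rate, syn$recording$sample_rate)
  expect_length(rec2$samples, length(syn$recording$samples))
  # 16-bit quantisation: peak-scaled error within ~2 LSB
  scale <- max(abs(syn$recording$samples))
  expect_lt(max(abs(rec2$samples * scale - syn$recording$samples)),
            scale * 1e-4)
  man2 <- read_manifest(man)
  expect_equal(man2$onset_times, syn$manifest$onset_times,
               tolerance = 1e-6)
  expect_equal(man2$syllable_intervals[, 2],
               syn$manifest$syllable_intervals[, 2], tolerance = 1e-6)
})

test_that("simulated outcome means match exp(eta) and the NB limit", {
  # outcome means track the linear predictor at n = 10,000
  sim <- simulate_cohort(cohort_spec(n_participants = 10000, seed = 9))
  for (o in c("episodic_memory", "executive_strategy",
              "working_memory")) {
    expect_lt(abs(mean(sim$cohort[[o]]) /
                    mean(exp(sim$truth$eta[[o]])) - 1), 0.02)
  }
  # huge NB size: variance/mean ratio approaches Poisson's 1
  # (flat linear predictor isolates the family's own dispersion)
  sim2 <- simulate_cohort(cohort_spec(
    n_participants = 10000, seed = 10, nb_dispersion = 1e6,
    null_coefficients = c(age = 0, sexM = 0, education = 0,
                          psychiatric = 0, hads_anxiety = 0,
                          hads_depression = 0)))
  y <- sim2$cohort$episodic_memory
  expect_lt(abs(stats::var(y) / mean(y) - 1), 0.05)
})

test_that("cohort simulation is seeded, marks missing recordings, and
           validates its coefficients", {
  a <- simulate_cohort(cohort_spec(n_participants = 50, seed = 4))
  b <- simulate_cohort(cohort_spec(n_participants = 50, seed = 4))
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$features, b$features)

  sim <- simulate_cohort(cohort_spec(n_participants = 1000, seed = 5,
                                     missing_recording_rate = 0.07))
  n_miss <- tapply(sim$params$missing, sim$params$test, sum)
  # binomial(1000, 0.07) central 95% interval
  expect_true(all(n_miss >= qbinom(0.025, 1000, 0.07) &
                    n_miss <= qbinom(0.975, 1000, 0.07)))

  expect_error(cohort_spec(null_coefficients = c(age = Inf, sexM = 0,
    education = 0, psychiatric = 0, hads_anxiety = 0,
    hads_depression = 0)), "age")
  expect_error(cohort_spec(
    feature_effects = list(executive_strategy = c(ioi_sd = NaN))),
    "ioi_sd")
  expect_error(cohort_spec(
    feature_effects = list(executive_strategy = c(not_a_feature = 1))),
    "not_a_feature")
})

test_that("null-world outcomes carry no feature signal", {
  sim <- simulate_cohort(cohort_spec(n_participants = 4000, seed = 6))
  # construction record: eta reproducible from the null block alone
  b <- sim$truth$spec$null_coefficients
  co <- sim$cohort
  eta <- log(7.7) + b[["age"]] * (co$age - 67) +
    b[["sexM"]] * (co$sex == "M") +
    b[["education"]] * (co$education - 3) +
    b[["psychiatric"]] * co$psychiatric +
    b[["hads_anxiety"]] * (co$hads_anxiety - 5) +
    b[["hads_depression"]] * (co$hads_depression - 3)
  expect_equal(unname(sim$truth$eta$executive_strategy), unname(eta),
               tolerance = 1e-12)
})
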