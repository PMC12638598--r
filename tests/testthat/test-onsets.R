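test_that("the onset strength envelope localises energy rises", {
  sr <- 16000
  # silence: flat envelope
  silent <- ddk_recording(numeric(3 * sr), sr)
  env <- onset_strength_envelope(silent)
  expect_true(all(env$values == 0))

  # constant tone: negligible flux after the initial attack
  t <- (0:(3 * sr - 1)) / sr
  x <- sin(2 * pi * 150 * t)
  x[t < 0.5] <- 0
  tone <- ddk_recording(x, sr)
  env <- onset_strength_envelope(tone)
  expect_lt(abs(env$times[which.max(env$values)] - 0.5), 0.025)
  late <- env$values[env$times > 0.7]
  expect_lt(max(late), 0.05 * max(env$values))

  # single noise burst at t = 1.0 s: global maximum within one hop
  x <- numeric(3 * sr)
  set.seed(1)
  x[(sr + 1):(sr + 240)] <- stats::rnorm(240)
  burst <- ddk_recording(x, sr)
  env <- onset_strength_envelope(burst)
  expect_lt(abs(env$times[which.max(env$values)] - 1.0), 0.011)

  expect_error(onset_strength_envelope(ddk_recording(numeric(100), sr)),
               "shorter")
})

test_that("peak picking recovers repetition counts and times", {
  # seven repetitions, the classic annotated-waveform structure
  syn7 <- std_train(seed = 12, n_repetitions = 7, ioi_mean = 0.25)
  on <- detect_onsets(onset_strength_envelope(syn7$clean),
                      refine = syn7$clean)
  expect_length(on$times, 7)
  expect_lt(max(abs(on$times - syn7$manifest$onset_times)), 0.010)

  # forty repetitions at ~4/s (kept inside the 10-s file)
  syn40 <- std_train(seed = 13, n_repetitions = 40, ioi_mean = 0.23,
                     ioi_sd = 0.005)
  on40 <- detect_onsets(onset_strength_envelope(syn40$clean),
                        refine = syn40$clean)
  expect_length(on40$times, 40)

  # strengths normalized to a per-recording max of 1
  expect_equal(max(on40$strengths), 1)
  expect_true(all(on40$strengths > 0 & on40$strengths <= 1))
})

test_that("minimum separation suppresses double detections", {
  sr <- 16000
  x <- numeric(2 * sr)
  set.seed(2)
  x[(sr + 1):(sr + 160)] <- stats::rnorm(160)          # t = 1.000
  x[(sr + 481):(sr + 640)] <- stats::rnorm(160)        # t = 1.030
  rec <- ddk_recording(x, sr)
  on <- detect_onsets(onset_strength_envelope(rec),
                      min_separation = 0.100)
  expect_length(on$times, 1)
})

test_that("empty envelopes yield empty onset series without error", {
  env <- onset_strength_envelope(ddk_recording(numeric(32000), 16000))
  on <- detect_onsets(env)
  expect_length(on$times, 0)
  feats <- onset_ioi_features(on, 2)
  expect_equal(unname(feats["onset_count"]), 0)
  expect_true(is.na(feats["ioi_mean"]))
})

test_that("onset/IOI feature formulas match hand-computed values", {
  # constant IOI series: 41 onsets spaced 0.2 s in 10 s
  on <- onsets_from_iois(rep(0.2, 40), start = 0.5)
  f <- onset_ioi_features(on, 10)
  expect_equal(unname(f["onset_count"]), 41)
  expect_equal(unname(f["onset_rate"]), 4.1)
  expect_equal(unname(f["ioi_mean"]), 0.2, tolerance = 1e-9)
  expect_equal(unname(f["ioi_sd"]), 0, tolerance = 1e-9)
  expect_equal(unname(f["inverse_min_ioi"]), 5.0, tolerance = 1e-9)
  expect_equal(unname(f["decrement_on_ioi"]), 0, tolerance = 1e-9)
  expect_equal(unname(f["inverse_ioi_mean"]), 5.0, tolerance = 1e-9)
  expect_equal(unname(f["inverse_ioi_cov"]), 0, tolerance = 1e-9)

  # two-interval decrement case
  f2 <- onset_ioi_features(onsets_from_iois(c(0.1, 0.2)), 10)
  expect_equal(unname(f2["decrement_on_ioi"]), log(2) / 2,
               tolerance = 1e-9)
  expect_equal(unname(f2["inverse_ioi_mean"]), 7.5, tolerance = 1e-9)

  # counting arithmetic
  f3 <- onset_ioi_features(onsets_from_iois(rep(10 / 41, 39)), 10)
  expect_equal(unname(f3["onset_count"]), 40)
  expect_equal(unname(f3["onset_rate"]), 4.0)

  # sample-SD convention for the strength COV
  on4 <- onsets_from_iois(rep(0.2, 3), strengths = c(1, 0.5, 0.75, 1))
  f4 <- onset_ioi_features(on4, 10)
  expect_equal(unname(f4["onset_strength_cov"]),
               stats::sd(c(1, 0.5, 0.75, 1)) / mean(c(1, 0.5, 0.75, 1)),
               tolerance = 1e-12)
})

test_that("IOI features flag undefined values at low onset counts", {
  f1 <- onset_ioi_features(onsets_from_iois(numeric(0)), 10)
  expect_true(all(is.na(f1[c("ioi_mean", "ioi_sd", "inverse_min_ioi",
                             "decrement_on_ioi", "inverse_ioi_mean",
                             "inverse_ioi_cov")])))
  f2 <- onset_ioi_features(onsets_from_iois(0.25), 10)
  expect_false(is.na(f2["ioi_mean"]))
  expect_true(is.na(f2["ioi_sd"]))       # SD needs 3+ onsets
  expect_true(is.na(f2["inverse_ioi_cov"]))
})

test_that("onset analysis is time-shift equivariant and scale invariant", {
  a <- std_train(seed = 31, start_time = 0.5, n_repetitions = 20)
  b <- std_train(seed = 31, start_time = 0.8, n_repetitions = 20)
  on_a <- detect_onsets(onset_strength_envelope(a$clean),
                        refine = a$clean)
  on_b <- detect_onsets(onset_strength_envelope(b$clean),
                        refine = b$clean)
  expect_length(on_b$times, length(on_a$times))
  expect_lt(max(abs((on_b$times - on_a$times) - 0.3)), 0.011)

  # amplitude scaling leaves detections identical (log-flux + refine)
  sc <- a$clean; sc$samples <- sc$samples * 0.25
  on_sc <- detect_onsets(onset_strength_envelope(sc), refine = sc)
  expect_equal(on_sc$times, on_a$times)
  expect_equal(on_sc$strengths, on_a$strengths)
})

test_that("inverse of the minimum IOI dominates the inverse of the mean", {
  set.seed(8)
  for (i in 1:20) {
    iois <- abs(stats::rnorm(15, 0.22, 0.03)) + 0.05
    f <- onset_ioi_features(onsets_from_iois(iois), 10)
    expect_gte(f[["inverse_min_ioi"]], 1 / f[["ioi_mean"]])
  }
})
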