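#' Specification of a synthetic DDK syllable train
#'
#' Defines the generative parameters of a synthetic rapid
#' syllable-repetition recording.  Each repetition consists of a short
#' broadband plosive burst at the syllable onset followed by a voiced
#' vowel (3-harmonic tone with a 10-ms raised-cosine attack) that
#' starts `vot` seconds after the onset, the field definition of voice
#' onset time (voice onset minus speech onset).  Successive onsets are
#' separated by inter-onset intervals (IOIs) with mean `ioi_mean`,
#' jitter SD `ioi_sd` and a linear drift: the per-repetition IOI mean
#' runs from `ioi_mean * (1 - ioi_drift/2)` for the first IOI to
#' `ioi_mean * (1 + ioi_drift/2)` for the last, so positive drift means
#' slowing.  Gaussian background noise is added at `snr_db` decibels
#' relative to the RMS of the active-speech span (silence-heavy
#' recordings would otherwise distort a whole-file SNR).
#'
#' @param sample_rate Sampling rate, Hz.
#' @param duration Total recording length, seconds.
#' @param n_repetitions Number of syllable repetitions requested;
#'   repetitions that would overflow `duration` are truncated.
#' @param ioi_mean,ioi_sd Mean and SD of the inter-onset interval, s.
#' @param ioi_drift Fractional IOI change from first to last IOI.
#' @param syllable_duration Active span of each syllable, s.
#' @param burst_duration Plosive burst length, s.
#' @param vot Voice onset time (voice onset minus syllable onset), s.
#'   The burst may overlap the vowel when `vot < burst_duration`.
#' @param vowel_f0 Vowel fundamental frequency, Hz.
#' @param snr_db Signal-to-noise ratio on the active span, dB.
#' @param start_time Time of the first onset, s.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return A list of class `syllable_train_spec`.
#' @export
syllable_train_spec <- function(sample_rate = 16000,
                                duration = 10,
                                n_repetitions = 45,
                                ioi_mean = 0.22,
                                ioi_sd = 0.010,
                                ioi_drift = 0.05,
                                syllable_duration = 0.12,
                                burst_duration = 0.015,
                                vot = 0.040,
                                vowel_f0 = 120,
                                snr_db = 25,
                                start_time = 0.5,
                                seed = 1L) {
  spec <- list(sample_rate = sample_rate, duration = duration,
               n_repetitions = as.integer(n_repetitions),
               ioi_mean = ioi_mean, ioi_sd = ioi_sd,
               ioi_drift = ioi_drift,
               syllable_duration = syllable_duration,
               burst_duration = burst_duration, vot = vot,
               vowel_f0 = vowel_f0, snr_db = snr_db,
               start_time = start_time, seed = as.integer(seed))
  if (spec$duration <= 0) stop("duration must be positive")
  if (spec$n_repetitions < 0) stop("n_repetitions must be >= 0")
  if (spec$ioi_sd < 0) stop("ioi_sd must be >= 0")
  if (spec$vot < 0 || spec$burst_duration < 0)
    stop("burst_duration and vot must be >= 0")
  if (spec$syllable_duration < spec$burst_duration + spec$vot)
    stop("syllable_duration must be >= burst_duration + vot")
  if (spec$n_repetitions > 1 && spec$ioi_mean <= spec$syllable_duration)
    stop("ioi_mean must exceed syllable_duration")
  class(spec) <- "syllable_train_spec"
  spec
}

#' Synthesise a DDK recording with ground-truth timing
#'
#' Generates a syllable-train waveform from a [syllable_train_spec]
#' together with a [ddk_manifest] recording the exact onset times,
#' voice onset times and syllable/pause zones, so downstream onset
#' detection, segmentation and voice-onset-time measurement can be
#' validated against known truth.
#'
#' @param spec A [syllable_train_spec].
#' @return A list with elements `recording` ([ddk_recording]) and
#'   `manifest` ([ddk_manifest]).
#' @export
synthesize_ddk_recording <- function(spec) {
  stopifnot(inherits(spec, "syllable_train_spec"))
  set.seed(spec$seed)
  sr <- spec$sample_rate
  n <- round(spec$duration * sr)
  x <- numeric(n)

  onsets <- numeric(0)
  if (spec$n_repetitions > 0) {
    k <- spec$n_repetitions
    if (k > 1) {
      m <- k - 1                     # number of IOIs
      means <- spec$ioi_mean *
        (1 - spec$ioi_drift / 2 + spec$ioi_drift *
           (seq_len(m) - 1) / max(m - 1, 1))
      iois <- means + stats::rnorm(m, 0, spec$ioi_sd)
      # keep syllables non-overlapping under extreme jitter draws
      iois <- pmax(iois, spec$syllable_duration + 0.005)
      onsets <- spec$start_time + c(0, cumsum(iois))
    } else {
      onsets <- spec$start_time
    }
    # truncate repetitions whose syllable would overflow the file
    onsets <- onsets[onsets + spec$syllable_duration <= spec$duration]
  }

  k <- length(onsets)
  if (k > 0) {
    burst_n <- max(round(spec$burst_duration * sr), 1L)
    syl_n <- round(spec$syllable_duration * sr)
    vow_off <- round(spec$vot * sr)
    vow_n <- syl_n - vow_off
    vowel <- .synth_vowel(vow_n, sr, spec$vowel_f0)
    for (t0 in onsets) {
      i0 <- round(t0 * sr) + 1L
      # plosive burst: broadband noise with a sharp 1-ms attack
      bi <- i0:min(i0 + burst_n - 1L, n)
      env <- .raised_cosine_env(length(bi), round(0.001 * sr),
                                round(0.004 * sr))
      x[bi] <- x[bi] + 0.7 * stats::rnorm(length(bi)) * env
      # voiced vowel from t0 + vot to t0 + syllable_duration
      vi0 <- i0 + vow_off
      vi <- vi0:min(vi0 + vow_n - 1L, n)
      x[vi] <- x[vi] + vowel[seq_along(vi)]
    }
  }

  # background noise at snr_db relative to active-span RMS
  if (k > 0) {
    active <- logical(n)
    for (t0 in onsets) {
      i0 <- round(t0 * sr) + 1L
      active[i0:min(i0 + round(spec$syllable_duration * sr) - 1L, n)] <- TRUE
    }
    sig_rms <- sqrt(mean(x[active]^2))
  } else {
    sig_rms <- 1    # noise-only recording: unit-less floor
  }
  noise_sd <- sig_rms * 10^(-spec$snr_db / 20)
  x <- x + stats::rnorm(n, 0, noise_sd)

  syl <- cbind(start = onsets, end = onsets + spec$syllable_duration)
  pause <- if (k > 1) {
    cbind(start = syl[-k, 2], end = onsets[-1])
  } else matrix(numeric(), 0, 2)

  list(recording = ddk_recording(x, sr),
       manifest = ddk_manifest(
         onset_times = onsets,
         voice_onset_times = onsets + spec$vot,
         syllable_intervals = syl,
         pause_intervals = pause))
}

# 3-harmonic vowel with raised-cosine attack (10 ms) and decay (15 ms)
.synth_vowel <- function(n, sr, f0) {
  if (n <= 0) return(numeric(0))
  t <- (seq_len(n) - 1) / sr
  amp <- c(1, 0.5, 0.25)
  v <- amp[1] * sin(2 * pi * f0 * t) +
    amp[2] * sin(2 * pi * 2 * f0 * t) +
    amp[3] * sin(2 * pi * 3 * f0 * t)
  v * .raised_cosine_env(n, round(0.010 * sr), round(0.015 * sr))
}

.raised_cosine_env <- function(n, n_attack, n_decay) {
  env <- rep(1, n)
  n_attack <- min(n_attack, n)
  n_decay <- min(n_decay, n)
  if (n_attack > 0)
    env[seq_len(n_attack)] <-
      0.5 * (1 - cos(pi * seq_len(n_attack) / n_attack))
  if (n_decay > 0) {
    idx <- (n - n_decay + 1):n
    env[idx] <- pmin(env[idx],
                     0.5 * (1 + cos(pi * seq_len(n_decay) / n_decay)))
  }
  env
}
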