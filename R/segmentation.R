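#' Segment a recording into speech and pause zones
#'
#' Thresholds a smoothed short-time RMS energy envelope with
#' hysteresis (separate enter-speech and exit-speech thresholds placed
#' between an estimated noise floor and speech level), then enforces
#' minimum speech and minimum pause durations.  Pauses are defined as
#' the gaps *between* consecutive speech intervals; leading silence
#' before the first utterance and trailing silence after the last are
#' excluded from pause totals, so speech% + pause% can be below 100
#' against the full file duration.
#'
#' @param rec A denoised, normalized [ddk_recording].
#' @param frame RMS frame, seconds.
#' @param hop Envelope hop, seconds.
#' @param enter_frac,exit_frac Hysteresis thresholds as fractions of
#'   the (log-domain) floor-to-speech-level range.
#' @param min_speech,min_pause Minimum zone durations, seconds.
#' @return A list of class `ddk_segments` with `speech_intervals`,
#'   `pause_intervals` (two-column matrices, seconds) and
#'   `total_duration`.
#' @export
segment_speech_pause <- function(rec, frame = 0.025, hop = 0.005,
                                 enter_frac = 0.35, exit_frac = 0.20,
                                 min_speech = 0.030, min_pause = 0.025) {
  stopifnot(inherits(rec, "ddk_recording"))
  sr <- rec$sample_rate
  x <- rec$samples
  total <- duration(rec)
  empty <- structure(list(speech_intervals = matrix(numeric(), 0, 2),
                          pause_intervals = matrix(numeric(), 0, 2),
                          total_duration = total),
                     class = "ddk_segments")
  win <- round(frame * sr)
  if (length(x) < win) return(empty)

  # short-time RMS sampled every hop, window centred on the sample
  e2 <- .moving_mean(x^2, win)
  idx <- seq(1L, length(x), by = round(hop * sr))
  rms <- sqrt(pmax(e2[idx], 0))
  t <- (idx - 1) / sr
  # light smoothing (3-point) to suppress spurious crossings
  rms <- .moving_mean(rms, 3L)

  logr <- log10(pmax(rms, 1e-7))
  floor_l <- stats::quantile(logr, 0.10, names = FALSE)
  level_l <- stats::quantile(logr, 0.95, names = FALSE)
  if (level_l - floor_l < 0.3) {
    # no dynamic range: one continuous sound or nothing.  A sustained
    # periodic sound has a low crest factor (median RMS well above
    # a third of the peak); broadband noise does not.
    if (stats::median(rms) > 0.35 * max(abs(x))) {
      seg <- empty
      seg$speech_intervals <- cbind(start = 0, end = total)
      return(seg)
    }
    return(empty)
  }
  enter <- floor_l + enter_frac * (level_l - floor_l)
  exit <- floor_l + exit_frac * (level_l - floor_l)

  in_speech <- FALSE
  starts <- numeric(0); ends <- numeric(0)
  for (i in seq_along(logr)) {
    if (!in_speech && logr[i] >= enter) {
      in_speech <- TRUE; starts <- c(starts, t[i])
    } else if (in_speech && logr[i] < exit) {
      in_speech <- FALSE; ends <- c(ends, t[i])
    }
  }
  if (in_speech) ends <- c(ends, total)
  if (!length(starts)) return(empty)
  iv <- cbind(start = starts, end = ends)

  # merge speech intervals separated by sub-minimum pauses
  merged <- iv[1, , drop = FALSE]
  if (nrow(iv) > 1) for (i in 2:nrow(iv)) {
    if (iv[i, 1] - merged[nrow(merged), 2] < min_pause)
      merged[nrow(merged), 2] <- iv[i, 2]
    else merged <- rbind(merged, iv[i, ])
  }
  # compensate the centred-RMS-window smearing of onset/offset steps:
  # an ideal step crosses the threshold about frame/2 before (after)
  # its true time, so each interval is shrunk by frame/2 per side
  shrink <- frame / 2
  merged[, 1] <- pmax(merged[, 1] + shrink, 0)
  merged[, 2] <- pmin(merged[, 2] - shrink, total)
  merged <- merged[merged[, 2] - merged[, 1] >= min_speech, ,
                   drop = FALSE]
  if (!nrow(merged)) return(empty)

  pauses <- if (nrow(merged) > 1) {
    cbind(start = merged[-nrow(merged), 2], end = merged[-1, 1])
  } else matrix(numeric(), 0, 2)
  structure(list(speech_intervals = merged, pause_intervals = pauses,
                 total_duration = total),
            class = "ddk_segments")
}

#' @export
print.ddk_segments <- function(x, ...) {
  sp <- sum(x$speech_intervals[, 2] - x$speech_intervals[, 1])
  cat(sprintf(
    "<ddk_segments> %d speech / %d pause zones, speech %.1f%% of %.1f s\n",
    nrow(x$speech_intervals), nrow(x$pause_intervals),
    100 * sp / x$total_duration, x$total_duration))
  invisible(x)
}

#' Measure per-repetition voice onset time
#'
#' For each speech interval, the plosive burst onset is refined from
#' the interval start (first sample whose 5-ms local energy exceeds
#' 10% of the interval's peak local energy), and the voicing onset is
#' the first analysis frame whose normalized autocorrelation within
#' the 70--400 Hz fundamental-frequency lag band exceeds
#' `voicing_threshold` (30-ms window stepped at 5 ms, with linear
#' interpolation of the threshold crossing).  VOT is voicing onset
#' minus burst onset.  Repetitions with no detected voicing, or with
#' VOT above `vot_ceiling` (longer gaps are segmentation errors, not
#' plosive VOTs), are dropped; `n_attempted` still counts them.
#'
#' @param rec A denoised, normalized [ddk_recording].
#' @param segments A `ddk_segments` from [segment_speech_pause()].
#' @param voicing_threshold Normalized autocorrelation threshold.
#' @param f0_range Fundamental-frequency search band, Hz.
#' @param vot_ceiling Maximum admissible VOT, seconds.
#' @param window,step Voicing analysis window and step, seconds.
#' @return A list of class `ddk_vot` with `vots` (seconds) and
#'   `n_attempted`.
#' @export
measure_vot <- function(rec, segments, voicing_threshold = 0.5,
                        f0_range = c(70, 400), vot_ceiling = 0.150,
                        window = 0.030, step = 0.005) {
  stopifnot(inherits(rec, "ddk_recording"),
            inherits(segments, "ddk_segments"))
  sr <- rec$sample_rate
  x <- rec$samples
  w <- round(window * sr)
  lag_min <- max(2L, floor(sr / f0_range[2]))
  lag_max <- ceiling(sr / f0_range[1])
  nfft <- 2^ceiling(log2(w + lag_max + 1))
  vots <- numeric(0)
  n_attempted <- nrow(segments$speech_intervals)

  for (r in seq_len(n_attempted)) {
    s0 <- segments$speech_intervals[r, 1]
    s1 <- segments$speech_intervals[r, 2]
    # the burst may sit before the detected interval when a long
    # voicing gap splits the syllable; search back up to the VOT
    # ceiling, but never into the previous speech interval
    back <- if (r > 1)
      max(s0 - vot_ceiling, segments$speech_intervals[r - 1, 2] + 0.010)
    else s0 - 0.010
    burst_t <- .refine_burst_onset(x, sr, s0, s1, back)

    # scan frames centred from burst onwards, up to ceiling + window
    centres <- seq(burst_t + step,
                   min(s1, burst_t + vot_ceiling + window / 2), by = step)
    prev <- NULL
    found <- NA_real_
    for (ct in centres) {
      i0 <- max(1L, round((ct - window / 2) * sr) + 1L)
      seg <- x[i0:min(i0 + w - 1L, length(x))]
      if (length(seg) < w) break
      r_ncc <- .max_ncc(seg, lag_min, lag_max, nfft)
      if (!is.null(prev) && r_ncc >= voicing_threshold &&
          prev$v < voicing_threshold) {
        # linear interpolation of the threshold crossing
        frac <- (voicing_threshold - prev$v) / (r_ncc - prev$v)
        found <- prev$t + frac * (ct - prev$t)
        break
      }
      if (is.null(prev) && r_ncc >= voicing_threshold) {
        found <- ct
        break
      }
      prev <- list(t = ct, v = r_ncc)
    }
    if (!is.na(found)) {
      vot <- found - burst_t
      if (vot >= 0 && vot < vot_ceiling) vots <- c(vots, vot)
    }
  }
  structure(list(vots = vots, n_attempted = n_attempted),
            class = "ddk_vot")
}

# first sample in [back, s1] whose 5-ms local energy exceeds
# 10% of the interval's peak local energy
.refine_burst_onset <- function(x, sr, s0, s1, back = s0 - 0.010) {
  lw <- max(2L, round(0.005 * sr))
  i0 <- max(1L, round(min(back, s0) * sr) + 1L)
  i1 <- min(length(x), round(s1 * sr))
  seg <- x[i0:i1]
  e <- .moving_mean(seg^2, lw)
  hit <- which(e > 0.10 * max(e))[1]
  if (is.na(hit)) return(s0)
  (i0 + hit - 2) / sr
}

# maximum normalized cross-correlation over the lag band
.max_ncc <- function(seg, lag_min, lag_max, nfft) {
  n <- length(seg)
  seg <- seg - mean(seg)
  f <- stats::fft(c(seg, numeric(nfft - n)))
  ac <- Re(stats::fft(f * Conj(f), inverse = TRUE))[1:(lag_max + 1)] / nfft
  cs <- cumsum(seg^2)
  lags <- lag_min:min(lag_max, n - 2)
  e_head <- cs[n - lags]                       # energy of x[1:(n-l)]
  e_tail <- cs[n] - cs[lags]                   # energy of x[(l+1):n]
  denom <- sqrt(pmax(e_head * e_tail, 1e-20))
  max(ac[lags + 1] / denom)
}

#' Syllable, pause and voice-onset timing features
#'
#' Computes the syllable, pause and voice-onset feature groups:
#' \describe{
#'   \item{articulation_rate}{syllable (speech-interval) count / total
#'     speech duration (per s)}
#'   \item{syllable_duration_mean, syllable_duration_cov}{mean and COV
#'     of the speech-interval lengths}
#'   \item{speech_percent}{100 x total speech / total sample duration}
#'   \item{speech_to_pause_ratio}{total speech / total pause duration}
#'   \item{pause_mean, pause_cov}{mean and COV of pause lengths}
#'   \item{pause_percent}{100 x total pause / total sample duration}
#'   \item{vot_mean, vot_cov}{mean and COV of the measured VOTs}
#' }
#' COV = SD/mean (sample SD).  Entries whose defining set is empty or
#' whose denominator is zero are `NA` (e.g. `speech_to_pause_ratio`
#' with no pauses is `NA`, not infinity).
#'
#' @param segments A `ddk_segments`.
#' @param vots A `ddk_vot`.
#' @return Named numeric vector of the ten features.
#' @export
timing_features <- function(segments, vots) {
  stopifnot(inherits(segments, "ddk_segments"),
            inherits(vots, "ddk_vot"))
  sp <- segments$speech_intervals
  pa <- segments$pause_intervals
  total <- segments$total_duration
  sl <- sp[, 2] - sp[, 1]
  pl <- if (nrow(pa)) pa[, 2] - pa[, 1] else numeric(0)
  tot_sp <- sum(sl)
  tot_pa <- sum(pl)
  cov <- function(v) if (length(v) >= 2 && mean(v) > 0)
    stats::sd(v) / mean(v) else NA_real_

  c(articulation_rate =
      if (nrow(sp) && tot_sp > 0) nrow(sp) / tot_sp else NA_real_,
    syllable_duration_mean = if (nrow(sp)) mean(sl) else NA_real_,
    syllable_duration_cov = cov(sl),
    speech_percent = 100 * tot_sp / total,
    speech_to_pause_ratio =
      if (tot_pa > 0) tot_sp / tot_pa else NA_real_,
    pause_mean = if (length(pl)) mean(pl) else NA_real_,
    pause_cov = cov(pl),
    pause_percent = 100 * tot_pa / total,
    vot_mean = if (length(vots$vots)) mean(vots$vots) else NA_real_,
    vot_cov = cov(vots$vots))
}
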