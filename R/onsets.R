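#' Onset strength envelope
#'
#' Computes a spectral-flux style onset strength envelope: the
#' half-wave-rectified positive first difference of the log-magnitude
#' short-time spectrum, averaged across frequency bands, one value per
#' hop.  Envelope samples are stamped with the *end* time of their
#' analysis window, which places the flux peak produced by a broadband
#' burst entering the window at (or within one hop after) the true
#' burst time.
#'
#' @param rec A denoised, normalized [ddk_recording].
#' @param frame Frame length, seconds (default 46 ms).
#' @param hop Hop length, seconds (default 10 ms).
#' @return A list of class `ddk_envelope` with `times` (s) and
#'   `values` (dimensionless, `>= 0`), plus `hop`.
#' @export
onset_strength_envelope <- function(rec, frame = 0.046, hop = 0.010) {
  stopifnot(inherits(rec, "ddk_recording"))
  sr <- rec$sample_rate
  win <- round(frame * sr)
  if (length(rec$samples) < win)
    stop("recording shorter than one analysis frame")
  S <- .stft(rec$samples, win, round(hop * sr))
  nb <- S$nfft %/% 2 + 1L
  # trailing zero-padded frames smear any sustained sound into a
  # broadband edge artifact that mimics an onset; use full frames only
  full <- S$starts + win - 1L <= length(rec$samples)
  mag <- Mod(S$spec[seq_len(nb), full, drop = FALSE])
  # floor 80 dB below the recording maximum: keeps the flux of
  # near-empty bins (spectral-leakage flutter) out of the average
  logmag <- log(mag + max(max(mag) * 1e-4, 1e-10))
  flux <- logmag[, -1, drop = FALSE] - logmag[, -ncol(logmag), drop = FALSE]
  env <- colMeans(pmax(flux, 0))
  times <- (S$starts[full][-1] - 1) / sr + frame
  structure(list(times = times, values = env, hop = hop),
            class = "ddk_envelope")
}

#' Detect syllable onsets by adaptive peak picking
#'
#' Selects local maxima of the onset strength envelope that exceed an
#' adaptive threshold (`threshold_rel` times the local median plus a
#' margin of 5% of the global envelope maximum), then keeps peaks
#' greedily in descending strength subject to a minimum separation.
#' Returned strengths are normalized to a per-recording maximum of 1.
#'
#' When `refine` is supplied (the recording the envelope came from),
#' each coarse envelope peak time is refined against the waveform:
#' the local burst rise is located as the first 5-ms energy-window
#' sample after the preceding energy minimum that crosses 15% of the
#' local peak energy.  This removes the sub-frame bias of the
#' envelope time base (spectral flux only places an onset within its
#' analysis window).
#'
#' @param envelope A `ddk_envelope` from [onset_strength_envelope()].
#' @param min_separation Minimum onset separation, seconds.  The
#'   default 90 ms sits above human maximal syllable rates (~11/s).
#' @param threshold_rel Multiplier on the adaptive local baseline.
#' @param median_window Window for the local median, seconds.
#' @param refine Optional [ddk_recording] for waveform-level onset
#'   time refinement.
#' @return A list of class `ddk_onsets` with `times` and `strengths`.
#' @export
detect_onsets <- function(envelope, min_separation = 0.090,
                          threshold_rel = 1.5, median_window = 1.0,
                          refine = NULL) {
  stopifnot(inherits(envelope, "ddk_envelope"))
  v <- envelope$values
  t <- envelope$times
  empty <- structure(list(times = numeric(), strengths = numeric()),
                     class = "ddk_onsets")
  if (length(v) < 3 || max(v) <= 0) return(empty)

  half <- max(1L, round(median_window / envelope$hop / 2))
  loc_med <- vapply(seq_along(v), function(i)
    stats::median(v[max(1, i - half):min(length(v), i + half)]),
    numeric(1))
  margin <- 0.05 * max(v)
  thr <- threshold_rel * (loc_med + margin)

  is_peak <- c(FALSE, v[2:(length(v) - 1)] >= v[1:(length(v) - 2)] &
                 v[2:(length(v) - 1)] > v[3:length(v)], FALSE)
  cand <- which(is_peak & v > thr)
  if (!length(cand)) return(empty)

  # greedy selection in descending strength under min_separation
  cand <- cand[order(v[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (i in cand) {
    if (!length(keep) || all(abs(t[i] - t[keep]) >= min_separation))
      keep <- c(keep, i)
  }
  keep <- sort(keep)
  times <- t[keep]
  if (!is.null(refine)) {
    stopifnot(inherits(refine, "ddk_recording"))
    times <- vapply(times, .refine_onset_time, numeric(1),
                    x = refine$samples, sr = refine$sample_rate)
    ord <- order(times)
    times <- times[ord]
    keep <- keep[ord]
  }
  structure(list(times = times,
                 strengths = v[keep] / max(v[keep])),
            class = "ddk_onsets")
}

# waveform-level onset refinement: inside [t - 25 ms, t + 10 ms],
# find the 5-ms energy peak, the minimum preceding it, and the first
# crossing of min + 15% of (peak - min) after that minimum
.refine_onset_time <- function(t, x, sr) {
  i0 <- max(1L, round((t - 0.025) * sr) + 1L)
  i1 <- min(length(x), round((t + 0.010) * sr))
  if (i1 - i0 < 16) return(t)
  e <- .moving_mean(x[i0:i1]^2, max(2L, round(0.005 * sr)))
  p <- which.max(e)
  if (p == 1) return((i0 - 1) / sr)
  m <- which.min(e[1:p])
  thr <- e[m] + 0.15 * (e[p] - e[m])
  hit <- which(e[m:p] >= thr)[1]
  if (is.na(hit)) return(t)
  (i0 + m + hit - 3) / sr
}

#' @export
print.ddk_onsets <- function(x, ...) {
  cat(sprintf("<ddk_onsets> %d onsets", length(x$times)))
  if (length(x$times) > 1)
    cat(sprintf(", IOI mean %.3f s", mean(diff(x$times))))
  cat("\n")
  invisible(x)
}

#' Onset, inter-onset-interval and energy features
#'
#' Computes the onset, IOI and energy feature groups from a detected
#' onset series:
#' \describe{
#'   \item{onset_count}{total number of syllable onsets}
#'   \item{onset_rate}{onset count / total sample duration (per s)}
#'   \item{ioi_mean, ioi_sd}{mean and SD of the inter-onset intervals (s)}
#'   \item{inverse_min_ioi}{1 / min(IOI) (per s)}
#'   \item{decrement_on_ioi}{`log(IOI_last / IOI_first) / N_IOI` —
#'     the log ratio of last to first IOI normalized by the IOI count;
#'     positive values mean slowing.  (Natural log; the raw first and
#'     last detected intervals are used, not trimmed means.)}
#'   \item{inverse_ioi_mean}{mean of 1/IOI (per s)}
#'   \item{inverse_ioi_cov}{coefficient of variation (SD/mean) of 1/IOI}
#'   \item{onset_strength_cov}{COV of the normalized onset strengths}
#' }
#' SDs use the sample (n−1) denominator.  IOI-derived entries are `NA`
#' when fewer than 2 onsets are present (fewer than 3 for SD/COV).
#'
#' @param onsets A `ddk_onsets` object.
#' @param total_duration Recording duration, seconds.
#' @return Named numeric vector of the nine features.
#' @export
onset_ioi_features <- function(onsets, total_duration) {
  stopifnot(inherits(onsets, "ddk_onsets"), total_duration > 0)
  n <- length(onsets$times)
  f <- c(onset_count = as.numeric(n),
         onset_rate = n / total_duration,
         ioi_mean = NA_real_, ioi_sd = NA_real_,
         inverse_min_ioi = NA_real_, decrement_on_ioi = NA_real_,
         inverse_ioi_mean = NA_real_, inverse_ioi_cov = NA_real_,
         onset_strength_cov = NA_real_)
  if (n >= 2) {
    ioi <- diff(onsets$times)
    f["ioi_mean"] <- mean(ioi)
    f["inverse_min_ioi"] <- 1 / min(ioi)
    f["decrement_on_ioi"] <- log(ioi[length(ioi)] / ioi[1]) / length(ioi)
    f["inverse_ioi_mean"] <- mean(1 / ioi)
    if (n >= 3) {
      f["ioi_sd"] <- stats::sd(ioi)
      f["inverse_ioi_cov"] <- stats::sd(1 / ioi) / mean(1 / ioi)
    }
    if (n >= 3)
      f["onset_strength_cov"] <-
        stats::sd(onsets$strengths) / mean(onsets$strengths)
  }
  f
}
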