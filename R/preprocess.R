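#' Screen a recording for admission to the feature pipeline
#'
#' Applies the pre-analysis exclusion rules: recordings sampled at
#' 8 kHz are rejected outright (distorted capture quality), recordings
#' shorter than `min_duration` are rejected as negligible, and — when
#' `utterance_check` is on — recordings whose post-denoise
#' active-speech fraction falls below `utterance_floor` are rejected
#' as containing no utterances.
#'
#' @param rec A [ddk_recording].
#' @param min_duration Minimum admissible duration, seconds.  A 10-s
#'   protocol recording under 2 s cannot contain a usable trial.
#' @param utterance_check Run the active-speech check?
#' @param utterance_floor Minimum active-speech fraction.
#' @return A list of class `ddk_screening` with fields `admitted`
#'   (logical) and `reason` (one of `"ok"`, `"rate_8khz"`,
#'   `"negligible_length"`, `"no_utterance"`).
#' @export
screen_recording <- function(rec, min_duration = 2,
                             utterance_check = TRUE,
                             utterance_floor = 0.02) {
  stopifnot(inherits(rec, "ddk_recording"))
  out <- function(admitted, reason)
    structure(list(admitted = admitted, reason = reason),
              class = "ddk_screening")
  if (rec$sample_rate == 8000L) return(out(FALSE, "rate_8khz"))
  if (duration(rec) < min_duration) return(out(FALSE, "negligible_length"))
  if (utterance_check) {
    dn <- denoise(normalize(rec))
    seg <- segment_speech_pause(dn)
    speech <- sum(seg$speech_intervals[, 2] - seg$speech_intervals[, 1])
    if (speech / duration(rec) < utterance_floor)
      return(out(FALSE, "no_utterance"))
  }
  out(TRUE, "ok")
}

#' @export
print.ddk_screening <- function(x, ...) {
  cat(sprintf("<ddk_screening> %s (%s)\n",
              if (x$admitted) "admitted" else "excluded", x$reason))
  invisible(x)
}

#' Non-stationary spectral-gating noise reduction
#'
#' Reduces ambient noise by spectral gating: a short-time spectrum is
#' computed, a per-band noise floor is tracked over a sliding time
#' window (so the gate adapts to non-stationary backgrounds), and bins
#' whose magnitude falls below the floor plus a margin are attenuated
#' by a soft sigmoid mask.  Output has the same length and sample rate
#' as the input and is deterministic for fixed input and parameters.
#'
#' @param rec A [ddk_recording].
#' @param frame Analysis frame length, seconds.
#' @param hop Hop length, seconds.
#' @param floor_window Sliding window for noise-floor tracking, seconds.
#' @param floor_quantile Quantile of per-band magnitude taken as floor.
#' @param gate_margin_db Gate threshold above the floor, dB.
#' @param atten_db Maximum attenuation applied below the gate, dB.
#' @return A denoised [ddk_recording].
#' @export
denoise <- function(rec, frame = 0.032, hop = 0.016,
                    floor_window = 1.5, floor_quantile = 0.2,
                    gate_margin_db = 6, atten_db = 20) {
  stopifnot(inherits(rec, "ddk_recording"))
  sr <- rec$sample_rate
  win <- round(frame * sr)
  if (length(rec$samples) < win) return(rec)
  S <- .stft(rec$samples, win, round(hop * sr))
  nb <- S$nfft %/% 2 + 1L                      # non-redundant bins
  mag <- Mod(S$spec[seq_len(nb), , drop = FALSE])
  nt <- ncol(mag)

  # block-wise sliding noise floor: per-band low quantile over
  # floor_window, linearly interpolated across block centres
  block <- max(2L, round(floor_window / hop / 3))
  starts <- seq(1L, nt, by = block)
  centres <- pmin(starts + (block - 1) / 2, nt)
  floors <- vapply(starts, function(s) {
    idx <- s:min(s + block - 1L, nt)
    .row_kth_smallest(mag[, idx, drop = FALSE],
                      max(1L, ceiling(floor_quantile * length(idx))))
  }, numeric(nb))
  floors <- matrix(floors, nrow = nb)
  if (ncol(floors) > 2) {       # smooth floor over ~3 blocks
    sm <- floors
    for (j in seq_len(ncol(floors)))
      sm[, j] <- rowMeans(floors[, max(1, j - 1):min(ncol(floors), j + 1),
                                 drop = FALSE])
    floors <- sm
  }
  floor_t <- if (ncol(floors) == 1) {
    matrix(floors[, 1], nb, nt)
  } else {
    # linear interpolation across block centres, vectorized over bins
    ft <- matrix(0, nb, nt)
    j <- pmin(pmax(findInterval(seq_len(nt), centres), 1L),
              length(centres) - 1L)
    w <- (seq_len(nt) - centres[j]) / (centres[j + 1L] - centres[j])
    w <- pmin(pmax(w, 0), 1)
    for (blk in unique(j)) {
      cols <- which(j == blk)
      ft[, cols] <- floors[, blk] %o% (1 - w[cols]) +
        floors[, blk + 1L] %o% w[cols]
    }
    ft
  }

  gate <- floor_t * 10^(gate_margin_db / 20)
  atten <- 10^(-atten_db / 20)
  # soft sigmoid transition around the gate (scale ~ gate/4)
  z <- (mag - gate) / pmax(gate / 4, 1e-10)
  mask <- atten + (1 - atten) / (1 + exp(-z))

  full_mask <- rbind(mask,
                     mask[(nb - 1):2, , drop = FALSE])  # mirror bins
  S$spec <- S$spec * full_mask
  out <- rec
  out$samples <- .istft(S)
  out
}

#' Peak-normalize a recording
#'
#' Scales the waveform so the peak absolute amplitude is exactly 1.
#'
#' @param rec A [ddk_recording].
#' @return Normalized [ddk_recording].
#' @export
normalize <- function(rec) {
  stopifnot(inherits(rec, "ddk_recording"))
  peak <- max(abs(rec$samples))
  if (peak == 0) stop("silent recording")
  rec$samples <- rec$samples / peak
  rec
}

#' Resample a recording to the internal analysis rate
#'
#' All admitted recordings (sample rates 8--48 kHz, heterogeneous
#' consumer hardware) are resampled to one internal rate so that
#' frame and hop parameters are uniform downstream.
#'
#' @param rec A [ddk_recording].
#' @param rate Target rate, Hz (default 16000).
#' @return A [ddk_recording] at `rate`.
#' @export
resample_recording <- function(rec, rate = 16000) {
  stopifnot(inherits(rec, "ddk_recording"))
  if (rec$sample_rate == rate) return(rec)
  r <- .rat_approx(rate / rec$sample_rate)
  y <- signal::resample(rec$samples, r[1], r[2])
  n_target <- round(length(rec$samples) * rate / rec$sample_rate)
  if (length(y) > n_target) y <- y[seq_len(n_target)]
  if (length(y) < n_target) y <- c(y, numeric(n_target - length(y)))
  rec$samples <- as.numeric(y)
  rec$sample_rate <- as.integer(rate)
  rec
}

# row-wise k-th smallest value (quantile type 1), vectorized via
# repeated max.col row-minimum extraction
.row_kth_smallest <- function(M, k) {
  if (ncol(M) == 1L) return(M[, 1])
  k <- min(k, ncol(M))
  for (i in seq_len(k - 1L)) {
    j <- max.col(-M, ties.method = "first")
    M[cbind(seq_len(nrow(M)), j)] <- Inf
  }
  M[cbind(seq_len(nrow(M)), max.col(-M, ties.method = "first"))]
}

# small continued-fraction rational approximation p/q of x
.rat_approx <- function(x, max_den = 1000) {
  f <- .Machine$double.eps
  best <- c(1L, 1L)
  err <- Inf
  for (q in 1:max_den) {
    p <- round(x * q)
    e <- abs(x - p / q)
    if (e < err - f) { err <- e; best <- c(p, q) }
    if (err < 1e-9) break
  }
  as.integer(best)
}
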