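#' DDK recording container
#'
#' Lightweight container for one diadochokinesis (DDK) test recording:
#' a mono sample vector, its sample rate, the test label (`"pa"`,
#' `"ta"` or `"ka"`) and a participant identifier.
#'
#' @param samples Numeric vector of amplitudes (finite).
#' @param sample_rate Sampling rate in Hz (8000--48000).
#' @param test_label One of `"pa"`, `"ta"`, `"ka"` or `NA`.
#' @param participant_id Opaque identifier.
#' @return An object of class `ddk_recording`.
#' @export
ddk_recording <- function(samples, sample_rate,
                          test_label = NA_character_,
                          participant_id = NA_character_) {
  samples <- as.numeric(samples)
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("recording contains non-finite samples")
  if (sample_rate < 8000 || sample_rate > 48000)
    stop("sample_rate must be in [8000, 48000] Hz")
  structure(list(samples = samples,
                 sample_rate = as.integer(sample_rate),
                 test_label = test_label,
                 participant_id = participant_id),
            class = "ddk_recording")
}

#' @export
print.ddk_recording <- function(x, ...) {
  cat(sprintf("<ddk_recording> %s / %s: %.2f s @ %d Hz, peak %.3f\n",
              x$participant_id, x$test_label, duration(x),
              x$sample_rate, max(abs(x$samples), 0)))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec A [ddk_recording].
#' @return Duration in seconds.
#' @export
duration <- function(rec) length(rec$samples) / rec$sample_rate

#' Ground-truth timing manifest
#'
#' Records the exact event times of a synthesised DDK recording:
#' syllable onsets, voice onsets, and syllable/pause zone intervals.
#'
#' @param onset_times Strictly increasing onset times (s).
#' @param voice_onset_times Voice onset times, one per onset, each
#'   `>=` its onset.
#' @param syllable_intervals,pause_intervals Two-column matrices of
#'   `(start, end)` times in seconds.
#' @return An object of class `ddk_manifest`.
#' @export
ddk_manifest <- function(onset_times = numeric(),
                         voice_onset_times = numeric(),
                         syllable_intervals = matrix(numeric(), 0, 2),
                         pause_intervals = matrix(numeric(), 0, 2)) {
  onset_times <- as.numeric(onset_times)
  voice_onset_times <- as.numeric(voice_onset_times)
  if (is.unsorted(onset_times, strictly = TRUE))
    stop("onset_times must be strictly increasing")
  if (length(voice_onset_times) != length(onset_times))
    stop("one voice onset per onset required")
  if (any(voice_onset_times < onset_times - 1e-12))
    stop("voice onsets cannot precede their onsets")
  syllable_intervals <- matrix(as.numeric(syllable_intervals), ncol = 2)
  pause_intervals <- matrix(as.numeric(pause_intervals), ncol = 2)
  structure(list(onset_times = onset_times,
                 voice_onset_times = voice_onset_times,
                 syllable_intervals = syllable_intervals,
                 pause_intervals = pause_intervals),
            class = "ddk_manifest")
}

#' @export
print.ddk_manifest <- function(x, ...) {
  cat(sprintf("<ddk_manifest> %d onsets", length(x$onset_times)))
  if (length(x$onset_times) > 1) {
    ioi <- diff(x$onset_times)
    cat(sprintf(", IOI mean %.3f s (sd %.4f)", mean(ioi), stats::sd(ioi)))
  }
  cat(sprintf(", %d syllable / %d pause zones\n",
              nrow(x$syllable_intervals), nrow(x$pause_intervals)))
  invisible(x)
}
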