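#' Read a RIFF WAV file
#'
#' Minimal reader for single- or multi-channel RIFF WAV audio.  Supports
#' PCM 8/16/24/32-bit integer and IEEE float 32/64-bit encodings.
#' Multi-channel audio is averaged to mono on ingestion.
#'
#' @param path Path to a `.wav` file.
#' @param test_label Optional DDK test label (`"pa"`, `"ta"` or `"ka"`).
#' @param participant_id Optional participant identifier.
#' @return A [ddk_recording] object.
#' @export
read_wav <- function(path, test_label = NA_character_,
                     participant_id = NA_character_) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (!identical(hdr, "RIFF"))
    stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE"))
    stop("not a WAVE file: ", path)

  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(raw_fmt[1:2], "integer", 1, 2,
                               signed = FALSE, endian = "little"),
        n_channels   = readBin(raw_fmt[3:4], "integer", 1, 2,
                               signed = FALSE, endian = "little"),
        sample_rate  = readBin(raw_fmt[5:8], "integer", 1, 4,
                               endian = "little"),
        bits         = readBin(raw_fmt[15:16], "integer", 1, 2,
                               signed = FALSE, endian = "little"))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data chunk before fmt chunk")
      samples <- .decode_wav_data(con, size, fmt)
      break
    } else {
      # skip unknown chunk (word-aligned)
      invisible(readBin(con, "raw", size + size %% 2))
    }
  }
  if (is.null(samples))
    stop("corrupt or truncated WAV (no data chunk): ", path)

  if (fmt$n_channels > 1) {
    m <- matrix(samples, nrow = fmt$n_channels)
    samples <- colMeans(m)
  }
  ddk_recording(samples, fmt$sample_rate,
                test_label = test_label, participant_id = participant_id)
}

.decode_wav_data <- function(con, size, fmt) {
  bits <- fmt$bits
  if (fmt$audio_format == 1L) {            # integer PCM
    if (bits == 8L) {
      x <- readBin(con, "integer", size, 1, signed = FALSE,
                   endian = "little")
      (x - 128) / 128
    } else if (bits == 16L) {
      readBin(con, "integer", size / 2, 2, signed = TRUE,
              endian = "little") / 32768
    } else if (bits == 24L) {
      raw <- readBin(con, "raw", size)
      n <- length(raw) %/% 3
      b1 <- as.integer(raw[seq(1, by = 3, length.out = n)])
      b2 <- as.integer(raw[seq(2, by = 3, length.out = n)])
      b3 <- as.integer(raw[seq(3, by = 3, length.out = n)])
      v <- b1 + 256 * b2 + 65536 * b3
      v <- ifelse(v >= 8388608, v - 16777216, v)
      v / 8388608
    } else if (bits == 32L) {
      readBin(con, "integer", size / 4, 4, signed = TRUE,
              endian = "little") / 2147483648
    } else stop("unsupported PCM bit depth: ", bits)
  } else if (fmt$audio_format == 3L) {     # IEEE float
    if (bits == 32L) {
      readBin(con, "double", size / 4, 4, endian = "little")
    } else if (bits == 64L) {
      readBin(con, "double", size / 8, 8, endian = "little")
    } else stop("unsupported float bit depth: ", bits)
  } else stop("unsupported WAV audio format code: ", fmt$audio_format)
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param rec A [ddk_recording].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path) {
  stopifnot(inherits(rec, "ddk_recording"))
  x <- rec$samples
  peak <- max(abs(x), 1e-12)
  if (peak > 1) x <- x / peak
  pcm <- as.integer(round(pmax(pmin(x, 1), -1) * 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")                 # PCM
  writeBin(1L, con, 2, endian = "little")                 # mono
  writeBin(as.integer(rec$sample_rate), con, 4, endian = "little")
  writeBin(as.integer(rec$sample_rate * 2L), con, 4, endian = "little")
  writeBin(2L, con, 2, endian = "little")                 # block align
  writeBin(16L, con, 2, endian = "little")                # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}

#' Write / read a timing manifest as delimited text
#'
#' The sidecar manifest stores one event per row: `event` (one of
#' `onset`, `voice_onset`, `syllable`, `pause`), `start` and `end` in
#' seconds (`end` is empty for point events).
#'
#' @param manifest A [ddk_manifest].
#' @param path Output path (tab-separated text).
#' @return `path` invisibly; `read_manifest` returns a [ddk_manifest].
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "ddk_manifest"))
  rows <- rbind(
    if (length(manifest$onset_times))
      data.frame(event = "onset", start = manifest$onset_times,
                 end = NA_real_),
    if (length(manifest$voice_onset_times))
      data.frame(event = "voice_onset", start = manifest$voice_onset_times,
                 end = NA_real_),
    if (nrow(manifest$syllable_intervals))
      data.frame(event = "syllable",
                 start = manifest$syllable_intervals[, 1],
                 end = manifest$syllable_intervals[, 2]),
    if (nrow(manifest$pause_intervals))
      data.frame(event = "pause",
                 start = manifest$pause_intervals[, 1],
                 end = manifest$pause_intervals[, 2]))
  if (is.null(rows))
    rows <- data.frame(event = character(), start = numeric(),
                       end = numeric())
  utils::write.table(rows, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  iv <- function(ev) {
    s <- d[d$event == ev, , drop = FALSE]
    cbind(start = s$start, end = s$end)
  }
  ddk_manifest(
    onset_times = d$start[d$event == "onset"],
    voice_onset_times = d$start[d$event == "voice_onset"],
    syllable_intervals = iv("syllable"),
    pause_intervals = iv("pause"))
}
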