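# Internal short-time Fourier transform helpers (Hann window,
# fixed hop, mvfft-based).  Frames start at sample 1 and advance by
# `hop`; the final partial frame is zero-padded so inverse transforms
# reproduce the original length exactly.

.hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))

# centred moving average via cumulative sums, O(n); shorter windows
# at the edges
.moving_mean <- function(x, w) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  h <- w %/% 2
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + (w - h - 1L), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

.stft <- function(x, win, hop, nfft = NULL) {
  if (is.null(nfft)) nfft <- 2^ceiling(log2(win))
  n <- length(x)
  if (n < win) stop("signal shorter than one analysis frame")
  starts <- seq(1L, n, by = hop)
  w <- .hann(win)
  frames <- vapply(starts, function(s) {
    seg <- x[s:min(s + win - 1L, n)]
    if (length(seg) < win) seg <- c(seg, numeric(win - length(seg)))
    c(seg * w, numeric(nfft - win))
  }, numeric(nfft))
  list(spec = stats::mvfft(frames), starts = starts, win = win,
       hop = hop, nfft = nfft, n = n)
}

.istft <- function(S) {
  frames <- Re(stats::mvfft(S$spec, inverse = TRUE)) / S$nfft
  w <- .hann(S$win)
  x <- numeric(S$n + S$win)
  norm <- numeric(S$n + S$win)
  for (j in seq_along(S$starts)) {
    idx <- S$starts[j]:(S$starts[j] + S$win - 1L)
    x[idx] <- x[idx] + frames[seq_len(S$win), j] * w
    norm[idx] <- norm[idx] + w^2
  }
  (x / pmax(norm, 1e-8))[seq_len(S$n)]
}
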