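#' Analytic-signal envelope
#'
#' Magnitude of the analytic signal (FFT construction), optionally smoothed
#' with a centered moving average. The envelope of a narrowband transient
#' peaks at the transient's center, which is the fiducial used for latency
#' measurement.
#'
#' @param x Numeric waveform.
#' @param fs_hz Sampling rate in Hz (needed only when `smooth_ms > 0`).
#' @param smooth_ms Width of the centered moving-average smoother in ms;
#'   0 disables smoothing.
#' @return Numeric vector of the same length as `x`.
#' @export
analytic_envelope <- function(x, fs_hz = NULL, smooth_ms = 0) {
  n <- length(x)
  if (n < 2L) return(abs(x))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  env <- Mod(stats::fft(X * h, inverse = TRUE) / n)
  if (smooth_ms > 0) {
    stopifnot(!is.null(fs_hz))
    w <- max(1L, round(smooth_ms / 1000 * fs_hz))
    env <- moving_average(env, w)
  }
  env
}

# Centered moving average with shrinking windows at the edges (no NA padding).
moving_average <- function(x, w) {
  if (w <= 1L) return(x)
  n <- length(x)
  half <- w %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Indices of strict local maxima; flat-topped plateaus yield their first index.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- diff(x)
  s <- sign(d)
  # carry the last non-zero slope through plateaus
  nz <- s != 0
  if (!any(nz)) return(integer(0))
  s_f <- s
  idx <- cumsum(nz)
  s_f[idx > 0] <- s[nz][idx[idx > 0]]
  which(diff(s_f) < 0) + 1L
}

ms_to_samples <- function(ms, fs_hz) round(ms / 1000 * fs_hz)

samples_to_ms <- function(k, fs_hz) k / fs_hz * 1000

`%||%` <- function(a, b) if (is.null(a)) b else a
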