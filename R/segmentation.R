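#' Detect ECG R-peaks
#'
#' Polarity-robust threshold detector: the median-centered absolute ECG is
#' thresholded at half its maximum; candidate local maxima are accepted in
#' decreasing amplitude order subject to a refractory period.
#'
#' @param ecg Numeric ECG waveform (>= 2 s long).
#' @param fs_hz Sampling rate, Hz.
#' @param refractory_ms Minimum distance between accepted peaks, ms (>= 200
#'   by default).
#' @param threshold_frac Detection threshold as a fraction of the maximum
#'   absolute deflection.
#' @return Increasing integer vector of R-peak sample indices.
#' @export
detect_r_peaks <- function(ecg, fs_hz, refractory_ms = 200, threshold_frac = 0.5) {
  if (length(ecg) < 2 * fs_hz)
    stop("ECG shorter than 2 s: unsegmentable ECG", call. = FALSE)
  y <- abs(ecg - stats::median(ecg))
  m <- max(y)
  if (m == 0) stop("flat ECG: unsegmentable ECG", call. = FALSE)
  cand <- local_maxima(y)
  cand <- cand[y[cand] >= threshold_frac * m]
  if (length(cand) == 0L) stop("no QRS candidates: unsegmentable ECG", call. = FALSE)
  refr <- ms_to_samples(refractory_ms, fs_hz)
  cand <- cand[order(y[cand], decreasing = TRUE)]
  accepted <- integer(0)
  for (k in cand) {
    if (length(accepted) == 0L || all(abs(accepted - k) >= refr))
      accepted <- c(accepted, k)
  }
  sort(accepted)
}

#' Segment cardiac cycles and locate per-cycle windows
#'
#' Each consecutive R-peak pair delimits one cycle (R-to-R, half-open
#' `[start, end)`). Within each retained cycle three half-open windows are
#' placed: the S1 search window at `[R + s1_window_ms[1], R + s1_window_ms[2])`,
#' the S2 search window at `[start + s2_window_frac[1]*L,
#' start + s2_window_frac[2]*L)`, and the noise window at
#' `[start + 0.70*L, start + 0.85*L)` where no heart sound is expected
#' (L = cycle length). Cycles with RR outside `[rr_min_ms, rr_max_ms]` are
#' flagged and excluded; the partial cycle after the last R-peak is dropped.
#'
#' @param r_peaks Integer R-peak sample indices (>= 2).
#' @param fs_hz Sampling rate, Hz.
#' @param s1_window_ms Two offsets from the R-peak, ms.
#' @param s2_window_frac Two fractions of the cycle length.
#' @param noise_window_frac Two fractions of the cycle length.
#' @param rr_min_ms,rr_max_ms Artifact guard on cycle length, ms.
#' @return Object of class `beat_segmentation`: list with `r_peaks`, `fs_hz`,
#'   and `cycles`, a data frame with 1-based half-open sample windows
#'   (`start`, `end`, `s1_lo`, `s1_hi`, `s2_lo`, `s2_hi`, `noise_lo`,
#'   `noise_hi`) and a `retained` flag.
#' @export
segment_cycles <- function(r_peaks, fs_hz,
                           s1_window_ms = c(10, 200),
                           s2_window_frac = c(0.25, 0.55),
                           noise_window_frac = c(0.70, 0.85),
                           rr_min_ms = 300, rr_max_ms = 2000) {
  if (length(r_peaks) < 2L)
    return(structure(list(r_peaks = as.integer(r_peaks), fs_hz = fs_hz,
                          cycles = empty_cycles()),
                     class = "beat_segmentation"))
  start <- as.integer(r_peaks[-length(r_peaks)])
  end <- as.integer(r_peaks[-1])
  len <- end - start
  rr_ms <- samples_to_ms(len, fs_hz)
  retained <- rr_ms >= rr_min_ms & rr_ms <= rr_max_ms
  cycles <- data.frame(
    beat = seq_along(start), start = start, end = end,
    s1_lo = start + ms_to_samples(s1_window_ms[1], fs_hz),
    s1_hi = start + ms_to_samples(s1_window_ms[2], fs_hz),
    s2_lo = start + floor(s2_window_frac[1] * len),
    s2_hi = start + floor(s2_window_frac[2] * len),
    noise_lo = start + floor(noise_window_frac[1] * len),
    noise_hi = start + floor(noise_window_frac[2] * len),
    rr_ms = rr_ms, retained = retained
  )
  structure(list(r_peaks = as.integer(r_peaks), fs_hz = fs_hz, cycles = cycles,
                 params = list(s1_window_ms = s1_window_ms,
                               s2_window_frac = s2_window_frac,
                               noise_window_frac = noise_window_frac,
                               rr_min_ms = rr_min_ms, rr_max_ms = rr_max_ms)),
            class = "beat_segmentation")
}

empty_cycles <- function() {
  data.frame(beat = integer(0), start = integer(0), end = integer(0),
             s1_lo = integer(0), s1_hi = integer(0), s2_lo = integer(0),
             s2_hi = integer(0), noise_lo = integer(0), noise_hi = integer(0),
             rr_ms = numeric(0), retained = logical(0))
}

#' @export
print.beat_segmentation <- function(x, ...) {
  cat("<beat_segmentation> ", length(x$r_peaks), " R-peaks, ",
      nrow(x$cycles), " cycles (", sum(x$cycles$retained), " retained)\n",
      sep = "")
  invisible(x)
}

#' Segment a recording end-to-end
#'
#' Convenience wrapper: [detect_r_peaks()] on the ECG channel followed by
#' [segment_cycles()].
#'
#' @param recording A [pcg_recording()].
#' @param ... Passed to [segment_cycles()].
#' @return A `beat_segmentation`.
#' @export
segment_recording <- function(recording, ...) {
  stopifnot(is_pcg_recording(recording))
  rp <- detect_r_peaks(recording$ecg, recording$fs_hz)
  segment_cycles(rp, recording$fs_hz, ...)
}
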