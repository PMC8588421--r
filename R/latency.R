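#' Band-pass denoising of the PCG
#'
#' Zero-phase (forward-backward) 4th-order Butterworth band-pass, 20--250 Hz,
#' the band holding essentially all heart-sound energy. Latency estimation
#' runs on the denoised signal; the SNR metric always runs on the raw one.
#'
#' @param pcg Numeric PCG waveform.
#' @param fs_hz Sampling rate, Hz (>= 1000 so the upper band edge is well
#'   below Nyquist).
#' @param band_hz Passband edges, Hz.
#' @return Filtered waveform, sample-aligned with the input.
#' @export
denoise_pcg <- function(pcg, fs_hz, band_hz = c(20, 250)) {
  if (fs_hz < 1000)
    stop("fs_hz must be >= 1000 for the 20-250 Hz band", call. = FALSE)
  bf <- signal::butter(4, band_hz / (fs_hz / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, pcg))
}

#' Smoothed envelope of a (denoised) PCG
#'
#' Magnitude of the analytic signal smoothed with a 10 ms moving average;
#' the input to component peak picking.
#'
#' @inheritParams denoise_pcg
#' @param smooth_ms Smoother width, ms.
#' @return Envelope waveform.
#' @export
pcg_envelope <- function(pcg, fs_hz, smooth_ms = 10) {
  analytic_envelope(pcg, fs_hz, smooth_ms = smooth_ms)
}

# Pick the two most prominent envelope peaks in [lo, hi) separated by at
# least min_sep samples and at least prom_frac of the window maximum.
# Detectability gate: the window maximum must stand out against the window's
# own envelope level (median); a noise-only window has max/median ~1.5 and
# yields missing values rather than noise peaks.
# Returns c(earlier, later) absolute sample indices, or NAs.
two_peaks <- function(env, lo, hi, min_sep, prom_frac, gate = 3) {
  seg <- env[lo:(hi - 1L)]
  if (max(seg) < gate * stats::median(seg)) return(c(NA_integer_, NA_integer_))
  pk <- local_maxima(seg)
  pk <- pk[seg[pk] >= prom_frac * max(seg)]
  if (length(pk) < 2L) return(c(NA_integer_, NA_integer_))
  pk <- pk[order(seg[pk], decreasing = TRUE)]
  first <- pk[1]
  second <- pk[abs(pk - first) >= min_sep]
  if (length(second) == 0L) return(c(NA_integer_, NA_integer_))
  sel <- sort(c(first, second[1]))
  lo - 1L + sel
}

#' Per-beat component latencies
#'
#' Envelope-based two-peak estimator of the four R-to-component latencies.
#' Within the beat's S1 and S2 search windows the two most prominent envelope
#' peaks separated by at least `min_sep_ms` are taken; the earlier peak is
#' the mitral (S1) / aortic (S2) component, the later the tricuspid /
#' pulmonary one. Latencies are the peak positions minus the R-peak, in ms
#' at 1 ms resolution. Windows with fewer than two resolvable peaks yield
#' `NA` for that sound.
#'
#' @param env Envelope waveform from [pcg_envelope()] (of the denoised PCG).
#' @param segmentation A `beat_segmentation`.
#' @param beat_index Retained beat to evaluate.
#' @param min_sep_ms Minimum peak separation, ms.
#' @param prom_frac Minimum peak height as a fraction of the window envelope
#'   maximum.
#' @return One-row data frame: `beat_index`, `rs1m_ms`, `rs1t_ms`, `rs2a_ms`,
#'   `rs2p_ms`.
#' @export
estimate_beat_latencies <- function(env, segmentation, beat_index,
                                    min_sep_ms = 10, prom_frac = 0.1) {
  cy <- segmentation$cycles[beat_index, ]
  if (!isTRUE(cy$retained)) stop("beat not retained by segmentation", call. = FALSE)
  fs <- segmentation$fs_hz
  r <- cy$start
  sep <- ms_to_samples(min_sep_ms, fs)
  s1 <- two_peaks(env, cy$s1_lo, cy$s1_hi, sep, prom_frac)
  s2 <- two_peaks(env, cy$s2_lo, cy$s2_hi, sep, prom_frac)
  to_ms <- function(k) if (is.na(k)) NA_real_ else round(samples_to_ms(k - r, fs))
  data.frame(beat_index = cy$beat,
             rs1m_ms = to_ms(s1[1]), rs1t_ms = to_ms(s1[2]),
             rs2a_ms = to_ms(s2[1]), rs2p_ms = to_ms(s2[2]))
}

#' Per-beat latencies for every retained beat
#'
#' Denoises the PCG, computes the smoothed envelope once, and runs the
#' two-peak estimator on every retained beat.
#'
#' @param x A [pcg_recording()] or numeric raw PCG waveform.
#' @param segmentation A `beat_segmentation`.
#' @param fs_hz Sampling rate; taken from `x` when it is a recording.
#' @param ... Passed to [estimate_beat_latencies()].
#' @return Data frame of per-beat latency rows.
#' @export
estimate_latencies <- function(x, segmentation, fs_hz = NULL, ...) {
  pcg <- as_recording_pcg(x)
  fs <- if (is_pcg_recording(x)) x$fs_hz else fs_hz
  stopifnot(!is.null(fs))
  env <- pcg_envelope(denoise_pcg(pcg, fs), fs)
  keep <- which(segmentation$cycles$retained)
  if (length(keep) == 0L) stop("no retained beats", call. = FALSE)
  do.call(rbind, lapply(keep, function(b)
    estimate_beat_latencies(env, segmentation, b, ...)))
}

#' Aggregate per-beat latencies to a recording-level estimate
#'
#' Per-component arithmetic mean over beats with defined values, the
#' recording-level latency estimate.
#'
#' @param per_beat Data frame from [estimate_latencies()].
#' @return List: `latencies_ms` (named vector, `NA` when no beat
#'   contributed), `n_beats` (contributing counts), `sd_ms`, and `ci95_ms`
#'   (half-width of the 95% confidence interval of the mean,
#'   `1.96 * sd / sqrt(n)`).
#' @export
aggregate_latencies <- function(per_beat) {
  comp <- c("rs1m_ms", "rs1t_ms", "rs2a_ms", "rs2p_ms")
  est <- vapply(comp, function(k) mean(per_beat[[k]], na.rm = TRUE), numeric(1))
  est[is.nan(est)] <- NA_real_
  n <- vapply(comp, function(k) sum(!is.na(per_beat[[k]])), numeric(1))
  sdv <- vapply(comp, function(k) stats::sd(per_beat[[k]], na.rm = TRUE), numeric(1))
  ci <- ifelse(n > 0, 1.96 * sdv / sqrt(pmax(n, 1)), NA_real_)
  list(latencies_ms = est, n_beats = n, sd_ms = sdv, ci95_ms = ci)
}
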