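#' Paired PCG + ECG recording
#'
#' Container for a simultaneous phonocardiogram / electrocardiogram pair
#' sampled at a common rate. Synthetic recordings carry a `ground_truth`
#' element with the per-beat component latencies, noise sigma and amplitudes
#' used to synthesize them.
#'
#' @param pcg Numeric PCG waveform.
#' @param ecg Numeric ECG waveform, same length as `pcg`.
#' @param fs_hz Sampling rate in Hz (> 0).
#' @param ground_truth Optional list of synthesis ground truth
#'   (see [generate_recording()]).
#' @param label Identifier string.
#' @return An object of class `pcg_recording`.
#' @export
pcg_recording <- function(pcg, ecg, fs_hz, ground_truth = NULL, label = "recording") {
  if (length(pcg) != length(ecg))
    stop("pcg and ecg must have equal length", call. = FALSE)
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || fs_hz <= 0)
    stop("fs_hz must be a positive scalar", call. = FALSE)
  structure(
    list(pcg = as.numeric(pcg), ecg = as.numeric(ecg), fs_hz = fs_hz,
         ground_truth = ground_truth, label = label),
    class = "pcg_recording"
  )
}

#' @export
print.pcg_recording <- function(x, ...) {
  cat("<pcg_recording> ", x$label, "\n", sep = "")
  cat(sprintf("  %d samples @ %g Hz (%.1f s)\n",
              length(x$pcg), x$fs_hz, length(x$pcg) / x$fs_hz))
  if (!is.null(x$ground_truth))
    cat(sprintf("  synthetic, target S1 SNR %.1f dB, sigma0 %.4g, %d beats\n",
                x$ground_truth$target_snr_db, x$ground_truth$sigma0,
                length(x$ground_truth$r_peaks)))
  invisible(x)
}

is_pcg_recording <- function(x) inherits(x, "pcg_recording")

as_recording_pcg <- function(x) {
  if (is_pcg_recording(x)) x$pcg else as.numeric(x)
}
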