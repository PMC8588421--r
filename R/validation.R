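#' ECG admissibility filter
#'
#' Two admissibility criteria on the ECG channel before a recording enters
#' the validation stage: (1) the R-peak amplitude must be at least three
#' times the amplitude of the ECG noise 95% band (`4 * sigma`, sigma
#' measured in the same 70--85% cycle windows used for the PCG noise); and
#' (2) the R-wave must have the same polarity as the T-wave (dominant
#' deflection 150--400 ms after the R-peak).
#'
#' @param recording A [pcg_recording()].
#' @param segmentation Optional precomputed `beat_segmentation`.
#' @param min_ratio Minimum R-amplitude / noise-band ratio (boundary
#'   included: exactly 3 passes).
#' @return List of class `ecg_quality_verdict`: `r_amplitude_ratio`,
#'   `polarity_match`, `pass`, `reasons`.
#' @export
ecg_quality_filter <- function(recording, segmentation = NULL, min_ratio = 3) {
  stopifnot(is_pcg_recording(recording))
  seg <- tryCatch(segmentation %||% segment_recording(recording),
                  error = function(e) NULL)
  if (is.null(seg) || sum(seg$cycles$retained) == 0L)
    return(structure(list(r_amplitude_ratio = NA_real_, polarity_match = NA,
                          pass = FALSE, reasons = "unsegmentable ECG"),
                     class = "ecg_quality_verdict"))
  ecg <- recording$ecg
  fs <- recording$fs_hz
  cy <- seg$cycles[seg$cycles$retained, ]

  noise_samples <- unlist(lapply(seq_len(nrow(cy)), function(b)
    ecg[cy$noise_lo[b]:(cy$noise_hi[b] - 1L)]))
  baseline <- stats::median(noise_samples)
  sigma_ecg <- stats::sd(noise_samples)
  r_amp <- stats::median(abs(ecg[cy$start] - baseline))
  ratio <- if (sigma_ecg > 0) r_amp / (4 * sigma_ecg) else Inf

  r_sign <- sign(stats::median(ecg[cy$start] - baseline))
  t_sign <- stats::median(vapply(seq_len(nrow(cy)), function(b) {
    lo <- cy$start[b] + ms_to_samples(150, fs)
    hi <- min(cy$start[b] + ms_to_samples(400, fs), length(ecg))
    seg_t <- ecg[lo:hi] - baseline
    sign(seg_t[which.max(abs(seg_t))])
  }, numeric(1)))
  polarity <- isTRUE(r_sign == sign(t_sign)) && t_sign != 0

  reasons <- character(0)
  if (ratio < min_ratio)
    reasons <- c(reasons, sprintf("R amplitude ratio %.2f < %g", ratio, min_ratio))
  if (!polarity) reasons <- c(reasons, "R/T polarity mismatch")
  structure(list(r_amplitude_ratio = ratio, polarity_match = polarity,
                 pass = ratio >= min_ratio && polarity, reasons = reasons),
            class = "ecg_quality_verdict")
}

#' @export
print.ecg_quality_verdict <- function(x, ...) {
  cat(sprintf("<ecg_quality_verdict> %s (ratio %.2f, polarity %s)\n",
              if (x$pass) "PASS" else "FAIL", x$r_amplitude_ratio,
              x$polarity_match))
  if (length(x$reasons)) cat("  ", paste(x$reasons, collapse = "; "), "\n")
  invisible(x)
}

#' Select recordings admissible for validation
#'
#' A recording is admitted when its ECG passes [ecg_quality_filter()] and
#' its initial SNR is strictly higher than `min_initial_snr_db` for both
#' heart sounds.
#'
#' @param recordings List of [pcg_recording()]s.
#' @param min_initial_snr_db SNR admission bound, dB (strict).
#' @return List: `admitted` (recordings), `admitted_idx`, `verdicts` (data
#'   frame with per-recording filter outcomes).
#' @export
select_validation_recordings <- function(recordings, min_initial_snr_db = 14) {
  rows <- lapply(seq_along(recordings), function(i) {
    rec <- recordings[[i]]
    seg <- tryCatch(segment_recording(rec), error = function(e) NULL)
    ecg_ok <- FALSE; s1 <- NA_real_; s2 <- NA_real_
    if (!is.null(seg) && sum(seg$cycles$retained) > 0L) {
      ecg_ok <- ecg_quality_filter(rec, seg)$pass
      snr <- compute_recording_snr(rec, seg)
      s1 <- snr$snr_s1_db; s2 <- snr$snr_s2_db
    }
    snr_ok <- !is.na(s1) && !is.na(s2) &&
      s1 > min_initial_snr_db && s2 > min_initial_snr_db
    data.frame(index = i, ecg_pass = ecg_ok, snr_s1_db = s1, snr_s2_db = s2,
               snr_pass = snr_ok, admitted = ecg_ok && snr_ok)
  })
  verdicts <- do.call(rbind, rows)
  idx <- verdicts$index[verdicts$admitted]
  list(admitted = recordings[idx], admitted_idx = idx, verdicts = verdicts)
}

#' Validation sensitivity of the population thresholds
#'
#' For each admitted recording and uncertainty level, the recording is
#' degraded down to the population minimum acceptable SNR for each component
#' (one calibrated noise injection at the step count whose expected SNR
#' equals the threshold) and counted as satisfying the level when every
#' component's latency stays within the uncertainty band of the recording's
#' own high-SNR reference. For `epsilon = 0` the band is the 95% confidence
#' interval of the per-beat latency mean (`1.96 * sd / sqrt(n)`) instead of
#' 1 ms, the appropriate bound for short recordings with few beats.
#'
#' @param admitted List of [pcg_recording()]s (from
#'   [select_validation_recordings()]).
#' @param population_thresholds Data frame from [threshold_vs_uncertainty()]
#'   (`epsilon_pct`, `component`, `min_acceptable_snr_db`).
#' @param eps_list Uncertainty levels to evaluate (0 allowed).
#' @return List of class `validation_report`: `sensitivity` (data frame
#'   `epsilon_pct`, `fraction_within`, `n_evaluable`, `n_not_evaluable`),
#'   `per_recording` (logical matrix).
#' @export
compute_validation_sensitivity <- function(admitted, population_thresholds,
                                           eps_list = c(0, seq(2.5, 20, 2.5))) {
  if (length(eps_list) == 0L)
    return(structure(list(sensitivity = data.frame(epsilon_pct = numeric(0),
                                                   fraction_within = numeric(0),
                                                   n_evaluable = integer(0),
                                                   n_not_evaluable = integer(0)),
                          per_recording = NULL),
                     class = "validation_report"))
  comps <- names(comp_parent_snr)
  thr_for <- function(eps, cc) {
    tt <- population_thresholds
    row <- tt$epsilon_pct == (if (eps == 0) min(tt$epsilon_pct) else eps) &
      tt$component == cc
    # epsilon = 0 (CI95 band) reuses the tightest tabulated threshold
    tt$min_acceptable_snr_db[row][1]
  }
  per <- matrix(NA, nrow = length(admitted), ncol = length(eps_list),
                dimnames = list(NULL, paste0("eps", eps_list)))
  for (i in seq_along(admitted)) {
    rec <- admitted[[i]]
    seg <- segment_recording(rec)
    snr0 <- compute_recording_snr(rec, seg)
    ref <- aggregate_latencies(estimate_latencies(rec, seg))
    for (j in seq_along(eps_list)) {
      eps <- eps_list[j]
      ok_all <- TRUE; evaluable <- TRUE
      for (cc in comps) {
        target <- thr_for(eps, cc)
        init <- if (comp_parent_snr[[cc]] == "snr_s1_db") snr0$snr_s1_db else snr0$snr_s2_db
        if (!is.finite(target) || init <= target) { evaluable <- FALSE; break }
        i_step <- max(1L, round((init - target) / 0.1))
        x <- rec$pcg + stats::rnorm(length(rec$pcg), 0,
                                    noise_sigma_for_step(snr0$sigma0, i_step))
        lat <- aggregate_latencies(estimate_latencies(x, seg, fs_hz = rec$fs_hz))
        est <- lat$latencies_ms[[cc]]
        r0 <- ref$latencies_ms[[cc]]
        if (is.na(est) || is.na(r0)) { ok_all <- FALSE; break }
        half <- if (eps == 0) ref$ci95_ms[[cc]] else eps / 100 * r0
        if (abs(est - r0) > half) { ok_all <- FALSE; break }
      }
      per[i, j] <- if (!evaluable) NA else ok_all
    }
  }
  sens <- data.frame(
    epsilon_pct = eps_list,
    fraction_within = vapply(seq_along(eps_list), function(j)
      mean(per[, j], na.rm = TRUE), numeric(1)),
    n_evaluable = colSums(!is.na(per)),
    n_not_evaluable = colSums(is.na(per))
  )
  structure(list(sensitivity = sens, per_recording = per),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  print(x$sensitivity, row.names = FALSE)
  invisible(x)
}
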