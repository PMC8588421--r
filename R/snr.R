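#' Noise standard deviation in a window
#'
#' Sample standard deviation (mean removed) of the PCG inside a half-open
#' sample window, conventionally the 70--85% span of the cardiac cycle where
#' no heart sound is expected.
#'
#' @param pcg Numeric PCG waveform.
#' @param lo,hi Half-open window `[lo, hi)`, 1-based sample indices.
#' @return Standard deviation, or `NA` when the window holds fewer than 10
#'   samples.
#' @export
estimate_noise_sigma <- function(pcg, lo, hi) {
  if (hi - lo < 10) return(NA_real_)
  stats::sd(pcg[lo:(hi - 1L)])
}

window_pp <- function(pcg, lo, hi) {
  seg <- pcg[lo:(hi - 1L)]
  max(seg) - min(seg)
}

#' Per-beat signal-to-noise ratio
#'
#' The quality metric at the heart of the package:
#' `SNR = 20 * log10(A_S / (4 * sigma_N))` in dB, where `A_S` is the
#' peak-to-peak amplitude of the heart sound of interest inside its search
#' window and `4 * sigma_N` is the amplitude of the 95% band of the noise,
#' whose standard deviation `sigma_N` is measured in the beat's 70--85% noise
#' window. Computed separately for S1 and S2, on the raw (unfiltered) signal.
#'
#' @param pcg Numeric PCG waveform (raw).
#' @param segmentation A `beat_segmentation`.
#' @param beat_index Row of `segmentation$cycles` to evaluate (must be
#'   retained).
#' @return One-row data frame: `beat_index`, `a_s1`, `a_s2`, `sigma_n`,
#'   `snr_s1_db`, `snr_s2_db`. SNR values are `NA` (undefined) when
#'   `sigma_n` is 0 or unavailable.
#' @export
compute_beat_snr <- function(pcg, segmentation, beat_index) {
  cy <- segmentation$cycles[beat_index, ]
  if (!isTRUE(cy$retained)) stop("beat not retained by segmentation", call. = FALSE)
  a1 <- window_pp(pcg, cy$s1_lo, cy$s1_hi)
  a2 <- window_pp(pcg, cy$s2_lo, cy$s2_hi)
  sg <- estimate_noise_sigma(pcg, cy$noise_lo, cy$noise_hi)
  snr <- function(a) if (is.na(sg) || sg == 0) NA_real_ else 20 * log10(a / (4 * sg))
  data.frame(beat_index = beat_index, a_s1 = a1, a_s2 = a2, sigma_n = sg,
             snr_s1_db = snr(a1), snr_s2_db = snr(a2))
}

#' Recording-level SNR
#'
#' Evaluates the per-beat SNR for every retained beat and aggregates with the
#' median (robust to occasional artifact beats), separately for S1 and S2.
#' Full precision is kept; `round()` the aggregates to integer dB for
#' reporting.
#'
#' @param x A [pcg_recording()] or a numeric PCG waveform.
#' @param segmentation A `beat_segmentation`.
#' @return Object of class `recording_snr`: list with `beats` (per-beat data
#'   frame), `snr_s1_db`, `snr_s2_db` (medians, dB), `sigma0` (mean per-beat
#'   noise sd, the calibration sigma for noise injection) and `n_beats`.
#' @export
compute_recording_snr <- function(x, segmentation) {
  pcg <- as_recording_pcg(x)
  cy <- segmentation$cycles
  keep <- which(cy$retained)
  if (length(keep) == 0L) stop("no retained beats", call. = FALSE)
  # vectorized over beats
  a1 <- vapply(keep, function(b) window_pp(pcg, cy$s1_lo[b], cy$s1_hi[b]), numeric(1))
  a2 <- vapply(keep, function(b) window_pp(pcg, cy$s2_lo[b], cy$s2_hi[b]), numeric(1))
  sg <- vapply(keep, function(b) estimate_noise_sigma(pcg, cy$noise_lo[b], cy$noise_hi[b]),
               numeric(1))
  ok <- !is.na(sg) & sg > 0
  beats <- data.frame(beat_index = keep, a_s1 = a1, a_s2 = a2, sigma_n = sg,
                      snr_s1_db = ifelse(ok, 20 * log10(a1 / (4 * sg)), NA_real_),
                      snr_s2_db = ifelse(ok, 20 * log10(a2 / (4 * sg)), NA_real_))
  structure(list(beats = beats,
                 snr_s1_db = stats::median(beats$snr_s1_db, na.rm = TRUE),
                 snr_s2_db = stats::median(beats$snr_s2_db, na.rm = TRUE),
                 sigma0 = mean(sg[ok]),
                 n_beats = length(keep)),
            class = "recording_snr")
}

#' @export
print.recording_snr <- function(x, ...) {
  cat(sprintf("<recording_snr> %d beats, S1 %.1f dB, S2 %.1f dB\n",
              x$n_beats, x$snr_s1_db, x$snr_s2_db))
  invisible(x)
}

#' Chi-square normality check of the per-beat noise windows
#'
#' For each retained beat, a chi-square goodness-of-fit test of the noise
#' window samples against a normal distribution with mean and sd estimated
#' from the same segment. Binning uses equiprobable bins under the fitted
#' normal with the Sturges bin count, reduced so every expected count is at
#' least 5; degrees of freedom are `bins - 3` (two estimated parameters).
#'
#' @param x A [pcg_recording()] or numeric PCG waveform.
#' @param segmentation A `beat_segmentation` with at least 20 retained beats.
#' @param alpha Significance level.
#' @return List: `fraction_non_rejected`, `n_tested`, `n_skipped`, and the
#'   per-beat `p_values`.
#' @export
test_noise_normality <- function(x, segmentation, alpha = 0.05) {
  pcg <- as_recording_pcg(x)
  cy <- segmentation$cycles
  keep <- which(cy$retained)
  if (length(keep) < 20L) stop("need at least 20 retained beats", call. = FALSE)
  pv <- vapply(keep, function(b) {
    seg <- pcg[cy$noise_lo[b]:(cy$noise_hi[b] - 1L)]
    chisq_normal_gof(seg)
  }, numeric(1))
  tested <- !is.na(pv)
  list(fraction_non_rejected = mean(pv[tested] >= alpha),
       n_tested = sum(tested), n_skipped = sum(!tested),
       p_values = pv)
}

# Chi-square GOF p-value of x against N(mean(x), sd(x)); NA when x is too
# short or degenerate.
chisq_normal_gof <- function(x) {
  n <- length(x)
  if (n < 20L) return(NA_real_)
  m <- mean(x); s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(NA_real_)
  k <- ceiling(log2(n)) + 1L          # Sturges
  k <- min(k, floor(n / 5))           # expected count >= 5 per bin
  if (k < 4L) return(NA_real_)
  breaks <- stats::qnorm(seq(0, 1, length.out = k + 1), m, s)
  obs <- tabulate(findInterval(x, breaks[2:k]) + 1L, nbins = k)
  expd <- n / k
  stat <- sum((obs - expd)^2 / expd)
  stats::pchisq(stat, df = k - 3L, lower.tail = FALSE)
}
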