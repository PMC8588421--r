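#' Injected-noise standard deviation for a degradation step
#'
#' The calibrated schedule: adding white Gaussian noise of standard
#' deviation `sigma_i = sigma0 * sqrt(10^(0.1*i/10) - 1)` to a recording
#' whose original noise sd is `sigma0` raises the total noise sd to
#' `sigma0 * 10^(0.005*i)`, i.e. lowers the SNR by exactly `0.1*i` dB —
#' one tenth of a dB per step.
#'
#' @param sigma0 Original noise standard deviation (> 0), the average
#'   per-beat noise-window sd of the uncorrupted recording.
#' @param i Step index (>= 1).
#' @return `sigma_i` in signal units.
#' @export
noise_sigma_for_step <- function(sigma0, i) {
  if (any(i <= 0)) stop("step index must be >= 1", call. = FALSE)
  if (sigma0 <= 0) stop("sigma0 must be positive", call. = FALSE)
  sigma0 * sqrt(10^(0.01 * i) - 1)
}

#' Add calibrated white Gaussian noise to a recording
#'
#' Returns a copy of the recording whose PCG is the original plus i.i.d.
#' zero-mean Gaussian samples of sd `sigma_i`; the ECG is untouched. Noise
#' is drawn fresh from the current RNG state on every call.
#'
#' @param recording A [pcg_recording()].
#' @param sigma_i Noise standard deviation (>= 0).
#' @return A [pcg_recording()].
#' @export
inject_noise <- function(recording, sigma_i) {
  stopifnot(is_pcg_recording(recording), sigma_i >= 0)
  if (sigma_i == 0) return(recording)
  recording$pcg <- recording$pcg + stats::rnorm(length(recording$pcg), 0, sigma_i)
  recording
}

#' One degradation run
#'
#' Iteratively corrupts the *original* recording with fresh noise at the
#' step-`i` sd from [noise_sigma_for_step()], recomputing the recording
#' SNR (both sounds, raw corrupted signal) and the aggregated component
#' latencies (denoised corrupted signal) at every step. The loop terminates
#' when the monitored SNR fails to decrease in two consecutive iterations —
#' past that point the SNR computation itself has broken down — or at
#' `max_steps`.
#'
#' @param recording A [pcg_recording()].
#' @param segmentation Optional precomputed `beat_segmentation`; segmented
#'   from the ECG when `NULL`. Segmentation is done once, on the clean ECG.
#' @param compute_latencies Compute per-step latencies (set `FALSE` for
#'   SNR-schedule experiments; latency columns are then `NA`).
#' @param max_steps Safety cap on the number of steps.
#' @param monitor `"either"` (stop when either sound's SNR stalls twice,
#'   conservative), `"s1"` or `"s2"`.
#' @return Data frame of class `degradation_run`: one row per step (step 0 is
#'   the uncorrupted baseline) with `step`, `sigma_i`, `snr_s1_db`,
#'   `snr_s2_db`, `rs1m_ms`, `rs1t_ms`, `rs2a_ms`, `rs2p_ms`.
#' @export
run_degradation <- function(recording, segmentation = NULL,
                            compute_latencies = TRUE, max_steps = 400,
                            monitor = c("either", "s1", "s2")) {
  monitor <- match.arg(monitor)
  stopifnot(is_pcg_recording(recording))
  seg <- segmentation %||% segment_recording(recording)

  eval_signal <- function(pcg) {
    snr <- compute_recording_snr(pcg, seg)
    lat <- rep(NA_real_, 4)
    if (compute_latencies) {
      pb <- estimate_latencies(pcg, seg, fs_hz = recording$fs_hz)
      lat <- aggregate_latencies(pb)$latencies_ms
    }
    c(snr_s1_db = snr$snr_s1_db, snr_s2_db = snr$snr_s2_db,
      rs1m_ms = lat[[1]], rs1t_ms = lat[[2]], rs2a_ms = lat[[3]],
      rs2p_ms = lat[[4]])
  }

  base_snr <- compute_recording_snr(recording$pcg, seg)
  sigma0 <- base_snr$sigma0
  if (!is.finite(sigma0) || sigma0 <= 0)
    stop("initial SNR not computable: no usable noise windows", call. = FALSE)

  rows <- vector("list", max_steps + 1L)
  rows[[1]] <- c(step = 0, sigma_i = 0, eval_signal(recording$pcg))
  hist_s1 <- base_snr$snr_s1_db
  hist_s2 <- base_snr$snr_s2_db
  n_used <- 1L
  for (i in seq_len(max_steps)) {
    si <- noise_sigma_for_step(sigma0, i)
    x <- recording$pcg + stats::rnorm(length(recording$pcg), 0, si)
    v <- eval_signal(x)
    rows[[i + 1L]] <- c(step = i, sigma_i = si, v)
    n_used <- i + 1L
    hist_s1 <- c(hist_s1, v[["snr_s1_db"]])
    hist_s2 <- c(hist_s2, v[["snr_s2_db"]])
    stop_now <- switch(monitor,
      either = !is.na(snr_stop_index(hist_s1)) || !is.na(snr_stop_index(hist_s2)),
      s1 = !is.na(snr_stop_index(hist_s1)),
      s2 = !is.na(snr_stop_index(hist_s2)))
    if (stop_now) break
  }
  out <- as.data.frame(do.call(rbind, rows[seq_len(n_used)]))
  class(out) <- c("degradation_run", class(out))
  out
}

#' Stop index of a monitored SNR sequence
#'
#' The degradation loop terminates when the monitored SNR fails to decrease
#' in two consecutive iterations. Given the monitored sequence (baseline
#' first), returns the index of the element completing the second
#' consecutive non-decrease, or `NA` when the condition is never met.
#'
#' @param snr_seq Numeric monitored SNR sequence.
#' @return Integer index or `NA`.
#' @export
snr_stop_index <- function(snr_seq) {
  if (length(snr_seq) < 3L) return(NA_integer_)
  nd <- c(FALSE, diff(snr_seq) >= 0)
  j <- which(nd & c(FALSE, nd[-length(nd)]))
  if (length(j)) j[1] else NA_integer_
}

comp_parent_snr <- c(rs1m_ms = "snr_s1_db", rs1t_ms = "snr_s1_db",
                     rs2a_ms = "snr_s2_db", rs2p_ms = "snr_s2_db")

#' Summarize repeated degradation runs into a median sensitivity curve
#'
#' Each run's latency-vs-SNR trajectory is linearly interpolated onto a
#' common descending SNR grid at 0.1 dB resolution (each latency against its
#' parent sound's SNR: S1 SNR for the S1-component latencies, S2 SNR for the
#' S2 ones), restricted to the SNR range covered by every run; the pointwise
#' median across runs is the subject's representative curve. No
#' extrapolation outside a run's measured range.
#'
#' @param run_curves List of `degradation_run` data frames (>= 2).
#' @param grid_res_db Grid resolution, dB.
#' @return Object of class `sensitivity_curve`: list with `components`
#'   (per-component data frames `snr_db`, `latency_ms`, descending SNR),
#'   `n_runs` and `run_curves` (kept for audit).
#' @export
summarize_runs <- function(run_curves, grid_res_db = 0.1) {
  if (length(run_curves) < 2L) stop("need at least 2 runs", call. = FALSE)
  comps <- names(comp_parent_snr)
  components <- lapply(comps, function(cc) {
    sn <- comp_parent_snr[[cc]]
    lo <- max(vapply(run_curves, function(r) min(r[[sn]]), numeric(1)))
    hi <- min(vapply(run_curves, function(r) max(r[[sn]]), numeric(1)))
    glo <- ceiling(lo / grid_res_db) * grid_res_db
    ghi <- floor(hi / grid_res_db) * grid_res_db
    if (ghi < glo) stop("runs cover disjoint SNR ranges", call. = FALSE)
    grid <- round(seq(ghi, glo, by = -grid_res_db), 10)
    vals <- vapply(run_curves, function(r) {
      ok <- !is.na(r[[cc]])
      if (sum(ok) < 2L) return(rep(NA_real_, length(grid)))
      stats::approx(r[[sn]][ok], r[[cc]][ok], xout = grid, ties = mean,
                    rule = 1)$y
    }, numeric(length(grid)))
    data.frame(snr_db = grid,
               latency_ms = apply(as.matrix(vals), 1, stats::median, na.rm = TRUE))
  })
  names(components) <- comps
  structure(list(components = components, n_runs = length(run_curves),
                 run_curves = run_curves),
            class = "sensitivity_curve")
}

#' @export
print.sensitivity_curve <- function(x, ...) {
  rng <- range(x$components[[1]]$snr_db)
  cat(sprintf("<sensitivity_curve> %d runs, grid %.1f..%.1f dB\n",
              x$n_runs, rng[2], rng[1]))
  invisible(x)
}

#' Full sensitivity analysis of one recording
#'
#' Runs [run_degradation()] `n_runs` times (fresh noise each run) and
#' summarizes with [summarize_runs()].
#'
#' @inheritParams run_degradation
#' @param n_runs Number of repeated degradation runs.
#' @param seed Optional seed fixing the whole analysis.
#' @return A `sensitivity_curve`.
#' @export
run_sensitivity <- function(recording, n_runs = 10, segmentation = NULL,
                            seed = NULL, max_steps = 400) {
  if (!is.null(seed)) set.seed(seed)
  seg <- segmentation %||% segment_recording(recording)
  runs <- lapply(seq_len(n_runs), function(k)
    run_degradation(recording, seg, max_steps = max_steps))
  summarize_runs(runs)
}
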