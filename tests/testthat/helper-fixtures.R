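# Shared fixtures, generated once per test run.

fx_rec <- generate_recording(20, target_snr_db = 20, seed = 42)
fx_seg <- segment_recording(fx_rec)

# Build a sensitivity_curve directly from a latency function of (snr, comp);
# used to test the threshold scan independently of the degradation loop.
fake_curve <- function(latency_fun, snr_hi = 25, snr_lo = 5, n_runs = 10) {
  grid <- round(seq(snr_hi, snr_lo, by = -0.1), 10)
  comps <- c("rs1m_ms", "rs1t_ms", "rs2a_ms", "rs2p_ms")
  components <- lapply(comps, function(cc)
    data.frame(snr_db = grid, latency_ms = latency_fun(grid, cc)))
  names(components) <- comps
  structure(list(components = components, n_runs = n_runs, run_curves = NULL),
            class = "sensitivity_curve")
}

# Reference latencies for the fake curves.
fx_refs <- c(rs1m_ms = 44, rs1t_ms = 77, rs2a_ms = 368, rs2p_ms = 392)

# Flat at the reference above breakdown_snr; constant offset below it.
breakdown_curve <- function(breakdown_snr, offset_ms = 3, refs = fx_refs, ...) {
  fake_curve(function(snr, cc)
    ifelse(snr > breakdown_snr, refs[[cc]], refs[[cc]] + offset_ms), ...)
}

# Progressive drift below breakdown_snr: deviation grows linearly with the
# SNR deficit, reaching max_frac of the reference at snr_lo.
drift_curve <- function(breakdown_snr = 15, max_frac = 0.3, refs = fx_refs,
                        snr_hi = 25, snr_lo = 5, jitter_sd = 0, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  fake_curve(function(snr, cc) {
    deficit <- pmax(breakdown_snr - snr, 0) / (breakdown_snr - snr_lo)
    refs[[cc]] * (1 + max_frac * deficit) +
      if (jitter_sd > 0) stats::rnorm(length(snr), 0, jitter_sd) else 0
  }, snr_hi = snr_hi, snr_lo = snr_lo, ...)
}

# Fake degradation-run data frame on a given SNR trajectory.
fake_run <- function(snr, latency_offset = 0, refs = fx_refs) {
  data.frame(step = seq_along(snr) - 1, sigma_i = 0,
             snr_s1_db = snr, snr_s2_db = snr - 3,
             rs1m_ms = refs[["rs1m_ms"]] + latency_offset,
             rs1t_ms = refs[["rs1t_ms"]] + latency_offset,
             rs2a_ms = refs[["rs2a_ms"]] + latency_offset,
             rs2p_ms = refs[["rs2p_ms"]] + latency_offset)
}
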