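test_that("well-formed synthetic ECGs pass the admissibility filter", {
  v <- ecg_quality_filter(fx_rec, fx_seg)
  expect_true(v$pass)
  expect_gt(v$r_amplitude_ratio, 3)
  expect_true(v$polarity_match)

  # the amplitude criterion includes its boundary ("at least three times")
  expect_true(ecg_quality_filter(fx_rec, fx_seg,
                                 min_ratio = v$r_amplitude_ratio)$pass)
  expect_false(ecg_quality_filter(fx_rec, fx_seg,
                                  min_ratio = v$r_amplitude_ratio * 1.001)$pass)
})

test_that("polarity violations and noisy ECGs are rejected with reasons", {
  rec_t <- generate_recording(10, target_snr_db = 20, seed = 61,
                              t_wave_amplitude = -0.3)   # discordant T-wave
  v_t <- ecg_quality_filter(rec_t)
  expect_false(v_t$pass)
  expect_true(any(grepl("polarity", v_t$reasons)))

  # globally inverted ECG keeps R/T concordance: still admissible
  rec_i <- generate_recording(10, target_snr_db = 20, seed = 62,
                              ecg_polarity = -1)
  expect_true(ecg_quality_filter(rec_i)$pass)

  rec_n <- generate_recording(10, target_snr_db = 20, seed = 63,
                              ecg_noise_sd = 0.12)       # 4*sigma ~ 0.5 of R
  v_n <- ecg_quality_filter(rec_n)
  expect_false(v_n$pass)
  expect_true(any(grepl("ratio", v_n$reasons)))
})

test_that("validation admission requires ECG pass and SNR strictly above the bound", {
  recs <- list(generate_recording(10, target_snr_db = 10, seed = 64),
               generate_recording(10, target_snr_db = 22, seed = 65),
               generate_recording(10, target_snr_db = 22, seed = 66,
                                  t_wave_amplitude = -0.3))
  sel <- select_validation_recordings(recs, min_initial_snr_db = 14)
  v <- sel$verdicts
  expect_equal(v$admitted,
               v$ecg_pass & v$snr_s1_db > 14 & v$snr_s2_db > 14)
  expect_equal(sel$admitted_idx, 2L)

  # boundary is strict: a recording at exactly the bound is excluded
  sel2 <- select_validation_recordings(recs[2], min_initial_snr_db = v$snr_s1_db[2])
  expect_length(sel2$admitted, 0)

  sel3 <- select_validation_recordings(recs[c(1, 3)])
  expect_length(sel3$admitted, 0)
})

test_that("validation sensitivity is high at generous uncertainties and non-decreasing", {
  set.seed(67)
  recs <- lapply(68:70, function(s)
    generate_recording(20, target_snr_db = 24, seed = s))
  thr <- expand.grid(epsilon_pct = c(2.5, 5, 10, 20),
                     component = c("rs1m_ms", "rs1t_ms", "rs2a_ms", "rs2p_ms"),
                     stringsAsFactors = FALSE)
  thr$min_acceptable_snr_db <- 15        # degrade each recording to 15 dB
  rep_ <- compute_validation_sensitivity(recs, thr,
                                         eps_list = c(2.5, 5, 10, 20))
  s <- rep_$sensitivity
  expect_equal(s$epsilon_pct, c(2.5, 5, 10, 20))
  expect_true(all(s$fraction_within >= 0 & s$fraction_within <= 1))
  expect_true(all(diff(s$fraction_within) >= 0))
  expect_equal(s$fraction_within[s$epsilon_pct == 20], 1)
  expect_equal(s$n_evaluable, rep(3L, 4))
})

test_that("recordings below the threshold SNR are counted as not evaluable", {
  rec <- generate_recording(12, target_snr_db = 10, seed = 71)
  thr <- expand.grid(epsilon_pct = 5,
                     component = c("rs1m_ms", "rs1t_ms", "rs2a_ms", "rs2p_ms"),
                     stringsAsFactors = FALSE)
  thr$min_acceptable_snr_db <- 18        # above the recording's initial SNR
  rep_ <- compute_validation_sensitivity(list(rec), thr, eps_list = 5)
  expect_equal(rep_$sensitivity$n_not_evaluable, 1L)
  expect_equal(rep_$sensitivity$n_evaluable, 0L)

  empty <- compute_validation_sensitivity(list(rec), thr, eps_list = numeric(0))
  expect_equal(nrow(empty$sensitivity), 0)
})
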