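test_that("the injected-noise schedule follows the 0.1 dB composition law", {
  expect_error(noise_sigma_for_step(1, 0), "step index")
  expect_error(noise_sigma_for_step(0, 1), "sigma0")
  # closed form: total noise sd after step i is sigma0 * 10^(0.005 i)
  expect_equal(noise_sigma_for_step(2, 100), 2 * 3)          # sqrt(10 - 1) = 3
  expect_equal(noise_sigma_for_step(1, 200), sqrt(99))
  s <- noise_sigma_for_step(1, 1:50)
  expect_true(all(diff(s) > 0))
  expect_equal(s[1], sqrt(10^0.01 - 1))   # one step: a small fraction of sigma0
  expect_equal(sqrt(1 + s^2), 10^(0.005 * (1:50)), tolerance = 1e-12)
})

test_that("noise injection matches the requested variance and spares the ECG", {
  set.seed(41)
  rec <- pcg_recording(numeric(1e6), numeric(1e6), 2000)
  out <- inject_noise(rec, 0.37)
  expect_equal(var(out$pcg - rec$pcg), 0.37^2, tolerance = 0.01)
  expect_identical(out$ecg, rec$ecg)
  expect_identical(inject_noise(rec, 0)$pcg, rec$pcg)
  out2 <- inject_noise(rec, 0.37)
  expect_false(identical(out$pcg, out2$pcg))
})

test_that("the loop stops after two consecutive SNR non-decreases", {
  expect_equal(snr_stop_index(c(20.0, 19.9, 19.85, 19.87, 19.88)), 5)
  expect_true(is.na(snr_stop_index(c(20, 19.9, 19.8, 19.7))))
  expect_equal(snr_stop_index(c(10, 10, 10)), 3)
  expect_true(is.na(snr_stop_index(c(20, 19.9, 19.95, 19.9, 19.85))))
})

test_that("measured SNR tracks the expected schedule during a run", {
  set.seed(43)
  seg <- fx_seg
  snr0 <- compute_recording_snr(fx_rec, seg)
  i <- 50
  si <- noise_sigma_for_step(snr0$sigma0, i)
  drops <- replicate(10, {
    x <- fx_rec$pcg + rnorm(length(fx_rec$pcg), 0, si)
    snr0$snr_s1_db - compute_recording_snr(x, seg)$snr_s1_db
  })
  expect_equal(mean(drops), 0.1 * i, tolerance = 0.5 / 5)
})

test_that("degradation runs carry SNR and latency trajectories and terminate", {
  set.seed(44)
  # heavily noise-dominated from the start: SNR plateaus, loop stops early
  rec <- generate_recording(12, target_snr_db = 6, seed = 45)
  run <- run_degradation(rec, max_steps = 60, compute_latencies = FALSE)
  expect_s3_class(run, "degradation_run")
  expect_named(run, c("step", "sigma_i", "snr_s1_db", "snr_s2_db",
                      "rs1m_ms", "rs1t_ms", "rs2a_ms", "rs2p_ms"))
  expect_equal(run$step, seq_len(nrow(run)) - 1)
  expect_lt(nrow(run), 61)
  expect_true(all(diff(run$sigma_i) > 0))
})

test_that("repeated runs under one seed reproduce the median curve", {
  rec <- generate_recording(12, target_snr_db = 12, seed = 46)
  seg <- segment_recording(rec)
  a <- run_sensitivity(rec, n_runs = 2, segmentation = seg, seed = 7,
                       max_steps = 10)
  b <- run_sensitivity(rec, n_runs = 2, segmentation = seg, seed = 7,
                       max_steps = 10)
  expect_identical(a$components, b$components)
})

test_that("run summaries interpolate onto a common 0.1 dB median grid", {
  runs <- lapply(1:10, function(k) fake_run(seq(20, 10, by = -0.25)))
  cur <- summarize_runs(runs)
  g <- cur$components$rs1m_ms$snr_db
  expect_true(all(abs(g * 10 - round(g * 10)) < 1e-9))   # 0.1 dB multiples
  expect_equal(diff(g), rep(-0.1, length(g) - 1))
  # identical runs: median equals any run's (constant) latency
  expect_true(all(cur$components$rs1t_ms$latency_ms == fx_refs[["rs1t_ms"]]))

  # symmetric +/- 1 ms perturbations leave the median at the reference
  runs2 <- c(lapply(1:3, function(k) fake_run(seq(20, 10, -0.25), +1)),
             lapply(1:3, function(k) fake_run(seq(20, 10, -0.25), -1)),
             lapply(1:4, function(k) fake_run(seq(20, 10, -0.25), 0)))
  cur2 <- summarize_runs(runs2)
  expect_true(all(cur2$components$rs2a_ms$latency_ms == fx_refs[["rs2a_ms"]]))

  # disjoint SNR ranges cannot be summarized
  expect_error(summarize_runs(list(fake_run(seq(20, 15, -0.25)),
                                   fake_run(seq(10, 5, -0.25)))),
               "disjoint")
  expect_error(summarize_runs(list(fake_run(seq(20, 15, -0.25)))), "2 runs")
})

test_that("latency error grows as injected noise deepens", {
  set.seed(47)
  rec <- generate_recording(30, target_snr_db = 25, seed = 48)
  seg <- segment_recording(rec)
  snr0 <- compute_recording_snr(rec, seg)
  ref <- aggregate_latencies(estimate_latencies(rec, seg))$latencies_ms
  err_at <- function(step) {
    e <- replicate(3, {
      x <- rec$pcg + rnorm(length(rec$pcg),
                           0, noise_sigma_for_step(snr0$sigma0, step))
      lat <- aggregate_latencies(estimate_latencies(x, seg, rec$fs_hz))$latencies_ms
      mean(abs(lat - ref), na.rm = TRUE)
    })
    mean(e)
  }
  e_mild <- err_at(50)    # ~20 dB
  e_deep <- err_at(230)   # ~2 dB: approaching estimator breakdown
  expect_gt(e_deep, e_mild)
  expect_gt(e_deep, 0.3)
})
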