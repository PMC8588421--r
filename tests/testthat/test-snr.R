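test_that("noise sigma estimation is unbiased and homogeneous", {
  # constant segment: zero sd (SNR undefined downstream)
  expect_equal(estimate_noise_sigma(rep(2, 100), 1, 101), 0)
  set.seed(11)
  x <- rnorm(1e4)
  s <- estimate_noise_sigma(x, 1, 1e4 + 1)
  expect_equal(s, 1, tolerance = 0.02)
  expect_equal(estimate_noise_sigma(3 * x, 1, 1e4 + 1), 3 * s)
  expect_true(is.na(estimate_noise_sigma(x, 1, 9)))  # window too short
})

test_that("per-beat SNR evaluates the defining ratio exactly", {
  # one crafted cycle: known noise window and S1/S2 peak-to-peak amplitudes
  fs <- 1000
  pcg <- numeric(1000)
  seg <- segment_cycles(c(1L, 1001L, 1999L), fs)   # first cycle: [1, 1001)
  cy <- seg$cycles[1, ]
  noise <- rep(c(-1, 1), length.out = cy$noise_hi - cy$noise_lo) * 0.01
  pcg[cy$noise_lo:(cy$noise_hi - 1)] <- noise
  sig <- sd(noise)
  place <- function(lo, a) { pcg[lo] <<- a / 2; pcg[lo + 5] <<- -a / 2 }
  place(cy$s1_lo + 10, 4 * sig)      # A = 4 sigma -> 0 dB
  place(cy$s2_lo + 10, 40 * sig)     # A = 40 sigma -> 20 dB
  b <- compute_beat_snr(pcg, seg, 1)
  expect_equal(b$snr_s1_db, 0)
  expect_equal(b$snr_s2_db, 20)
  place(cy$s2_lo + 10, 400 * sig)    # A = 400 sigma -> 40 dB
  expect_equal(compute_beat_snr(pcg, seg, 1)$snr_s2_db, 40)
})

test_that("module SNR matches a brute-force recomputation to 1e-9 dB", {
  cy <- fx_seg$cycles
  snr <- compute_recording_snr(fx_rec, fx_seg)
  for (k in seq_len(nrow(snr$beats))) {
    b <- snr$beats[k, ]
    i <- b$beat_index
    s1 <- fx_rec$pcg[cy$s1_lo[i]:(cy$s1_hi[i] - 1)]
    nz <- fx_rec$pcg[cy$noise_lo[i]:(cy$noise_hi[i] - 1)]
    expect_equal(b$snr_s1_db, 20 * log10((max(s1) - min(s1)) / (4 * sd(nz))),
                 tolerance = 1e-9)
  }
})

test_that("SNR is invariant under rescaling the whole signal", {
  a <- compute_recording_snr(fx_rec$pcg, fx_seg)
  b <- compute_recording_snr(fx_rec$pcg * 7.3, fx_seg)
  expect_equal(a$beats$snr_s1_db, b$beats$snr_s1_db)
  expect_equal(a$beats$snr_s2_db, b$beats$snr_s2_db)
})

test_that("added noise compounds in quadrature and the median resists outliers", {
  set.seed(21)
  sig_add <- 2 * fx_rec$ground_truth$sigma0
  noisy <- fx_rec$pcg + rnorm(length(fx_rec$pcg), 0, sig_add)
  a <- compute_recording_snr(fx_rec$pcg, fx_seg)
  b <- compute_recording_snr(noisy, fx_seg)
  expected <- sqrt(a$sigma0^2 + sig_add^2)
  expect_equal(b$sigma0, expected, tolerance = 0.05)

  # one corrupted beat barely moves the median aggregate
  spoiled <- fx_rec$pcg
  cy <- fx_seg$cycles[3, ]
  spoiled[cy$s1_lo:(cy$s1_hi - 1)] <- spoiled[cy$s1_lo:(cy$s1_hi - 1)] * 50
  c_ <- compute_recording_snr(spoiled, fx_seg)
  expect_lt(abs(c_$snr_s1_db - a$snr_s1_db), 0.2)
})

test_that("Gaussian noise windows pass the normality check, uniform noise fails it", {
  rec <- generate_recording(120, target_snr_db = 18, seed = 31)
  seg <- segment_recording(rec)
  res <- test_noise_normality(rec, seg)
  expect_gte(res$fraction_non_rejected, 0.85)

  # substitute uniform noise of the same power: heavy rejection
  set.seed(32)
  sigma0 <- rec$ground_truth$sigma0
  unif <- rec$pcg
  cy <- seg$cycles
  for (b in which(cy$retained)) {
    idx <- cy$noise_lo[b]:(cy$noise_hi[b] - 1)
    unif[idx] <- runif(length(idx), -sqrt(3) * sigma0 * 3, sqrt(3) * sigma0 * 3)
  }
  res_u <- test_noise_normality(unif, seg)
  expect_lt(res_u$fraction_non_rejected, 0.5)

  # alpha = 1 rejects everything
  expect_equal(test_noise_normality(rec, seg, alpha = 1)$fraction_non_rejected, 0)
})
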