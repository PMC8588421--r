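test_that("uncertainty bands follow the percentage rule and the 1 ms rule", {
  b <- uncertainty_bounds(44, epsilon_pct = 10)
  expect_equal(c(b$lower_ms, b$upper_ms), c(39.6, 48.4))
  b0 <- uncertainty_bounds(44, epsilon_pct = 0)
  expect_equal(b0$lower_ms, b0$upper_ms)
  ba <- uncertainty_bounds(368, absolute_1ms = TRUE)
  expect_equal(c(ba$lower_ms, ba$upper_ms), c(367, 369))
  expect_error(uncertainty_bounds(44, epsilon_pct = -1), "epsilon")
  expect_error(uncertainty_bounds(0, epsilon_pct = 5), "positive")
})

test_that("the runs test flags clustered signs and spares alternating ones", {
  alt <- rep(c(1, -1), 10)                      # 20 runs: maximal mixing
  r1 <- runs_test_trend(alt)
  expect_false(r1$trend)
  expect_equal(r1$n_runs, 20)
  expect_gt(r1$p_value, 0.5)

  clust <- c(rep(1, 10), rep(-1, 10))           # 2 runs: maximal clustering
  r2 <- runs_test_trend(clust)
  expect_true(r2$trend)
  expect_lt(r2$p_value, 1e-4)
  expect_equal(r2$n_runs, 2)

  r3 <- runs_test_trend(rep(2.5, 15))           # single sign: candidate
  expect_true(r3$trend)
  expect_equal(r3$degenerate, "single-sign")

  r4 <- runs_test_trend(numeric(20))            # all zero: no trend
  expect_false(r4$trend)
  expect_equal(r4$degenerate, "all-zero")

  r5 <- runs_test_trend(c(1, -1, 1, -1))        # both signs but too short
  expect_false(r5$trend)
  expect_equal(r5$degenerate, "too-short")
})

test_that("the exact runs distribution matches a permutation oracle", {
  # null distribution of runs for n1 = n2 = 6 by full enumeration
  n1 <- 6; n2 <- 6
  pmf <- pcgsnr:::runs_pmf(n1, n2)
  combos <- utils::combn(12, n1)
  runs_of <- apply(combos, 2, function(pos) {
    s <- rep(-1, 12); s[pos] <- 1
    sum(s[-1] != s[-12]) + 1
  })
  emp <- tabulate(runs_of, nbins = 12)[2:12] / ncol(combos)
  expect_equal(pmf, emp, tolerance = 1e-12)
})

test_that("the scan finds a constructed breakdown point exactly", {
  cur <- breakdown_curve(14.0, offset_ms = 3)
  for (cc in c("rs1m_ms", "rs1t_ms", "rs2a_ms", "rs2p_ms")) {
    th <- find_min_acceptable_snr(cur, cc)
    expect_true(th$available)
    expect_equal(th$min_acceptable_snr_db, 14.0)
  }
  # flat curve: the condition is never met
  flat <- breakdown_curve(-Inf, offset_ms = 0)
  th_flat <- find_min_acceptable_snr(flat, "rs1m_ms")
  expect_false(th_flat$available)
  expect_true(is.na(th_flat$min_acceptable_snr_db))

  # a wider band can only trigger later (lower SNR)
  drift <- drift_curve(breakdown_snr = 15, max_frac = 0.3)
  th_1ms <- find_min_acceptable_snr(drift, "rs1m_ms")
  th_20 <- find_min_acceptable_snr(
    drift, "rs1m_ms", uncertainty_bounds(fx_refs[["rs1m_ms"]], 20))
  expect_lte(th_20$min_acceptable_snr_db, th_1ms$min_acceptable_snr_db)
})

test_that("scanning is deterministic", {
  cur <- drift_curve(breakdown_snr = 15, max_frac = 0.25, jitter_sd = 0.4,
                     seed = 51)
  band <- uncertainty_bounds(44, epsilon_pct = 5)
  a <- find_min_acceptable_snr(cur, "rs1m_ms", band)
  b <- find_min_acceptable_snr(cur, "rs1m_ms", band)
  expect_identical(a$min_acceptable_snr_db, b$min_acceptable_snr_db)
})

test_that("population aggregation takes the worst case and reports N/A counts", {
  mk <- function(v) structure(list(component = "rs1m_ms",
                                   min_acceptable_snr_db = v), class = "threshold_result")
  expect_equal(population_worst_case(lapply(c(6, 10, 12), mk))$worst_case_snr_db, 12)
  r <- population_worst_case(lapply(c(8, NA, 9), mk))
  expect_equal(r$worst_case_snr_db, 9)
  expect_equal(r$n_na, 1)
  expect_equal(population_worst_case(list(mk(7)))$worst_case_snr_db, 7)
  expect_true(is.na(population_worst_case(list(mk(NA)))$worst_case_snr_db))
})

test_that("thresholds are non-increasing in the acceptable uncertainty", {
  eps <- seq(2.5, 20, by = 2.5)
  curves <- list(
    drift_curve(breakdown_snr = 18, max_frac = 0.35, jitter_sd = 0.3, seed = 52),
    drift_curve(breakdown_snr = 12, max_frac = 0.25, jitter_sd = 0.3, seed = 53),
    breakdown_curve(-Inf, offset_ms = 0)          # never leaves any band
  )
  tab <- threshold_vs_uncertainty(curves, eps_list = eps, refs = fx_refs)
  for (cc in unique(tab$component)) {
    v <- tab$min_acceptable_snr_db[tab$component == cc][order(eps)]
    expect_true(all(diff(v) <= 1e-9))
  }
  # the flat subject falls back to the minimum SNR its curve reached
  expect_true(all(tab$n_fallback >= 1))
})

test_that("a single-subject table equals that subject's thresholds", {
  cur <- drift_curve(breakdown_snr = 16, max_frac = 0.3)
  tab <- threshold_vs_uncertainty(list(cur), eps_list = c(5, 10), refs = fx_refs)
  for (g in seq_len(nrow(tab))) {
    own <- find_min_acceptable_snr(
      cur, tab$component[g],
      uncertainty_bounds(fx_refs[[tab$component[g]]], tab$epsilon_pct[g]))
    expect_equal(tab$min_acceptable_snr_db[g],
                 if (own$available) own$min_acceptable_snr_db else own$min_snr_reached_db)
  }
})

test_that("the subject threshold table has the reporting shape", {
  curves <- list(s1 = drift_curve(breakdown_snr = 15, max_frac = 0.3),
                 s2 = breakdown_curve(-Inf, offset_ms = 0))
  tab <- subject_threshold_table(curves)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$subject, c("s1", "s2", "worst_case"))
  expect_true(all(c("rs1m_db", "rs1t_db", "rs2a_db", "rs2p_db") %in% names(tab)))
  expect_true(all(is.na(tab[2, c("rs1m_db", "rs2p_db")])))   # N/A convention
  expect_equal(tab$rs1m_db[3], tab$rs1m_db[1])               # worst case
})
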