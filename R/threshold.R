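#' Acceptability band around a reference latency
#'
#' In percentage mode the band is `rs_ref * (1 +/- epsilon_pct/100)`; in
#' absolute mode it is `rs_ref +/- 1 ms`, the resolution of a typical
#' acquisition system.
#'
#' @param rs_ref_ms Reference latency, ms (> 0).
#' @param epsilon_pct Acceptable uncertainty as a percentage of the
#'   reference; ignored when `absolute_1ms` is `TRUE`.
#' @param absolute_1ms Use the absolute 1 ms rule instead of a percentage.
#' @return List of class `uncertainty_band`: `rs_ref_ms`, `epsilon_pct`,
#'   `lower_ms`, `upper_ms`, `absolute_mode`.
#' @export
uncertainty_bounds <- function(rs_ref_ms, epsilon_pct = NULL, absolute_1ms = FALSE) {
  if (rs_ref_ms <= 0) stop("rs_ref_ms must be positive", call. = FALSE)
  if (absolute_1ms) {
    lo <- rs_ref_ms - 1; hi <- rs_ref_ms + 1
    epsilon_pct <- NA_real_
  } else {
    if (is.null(epsilon_pct) || epsilon_pct < 0)
      stop("epsilon_pct must be >= 0", call. = FALSE)
    half <- epsilon_pct / 100 * rs_ref_ms
    lo <- rs_ref_ms - half; hi <- rs_ref_ms + half
  }
  structure(list(rs_ref_ms = rs_ref_ms, epsilon_pct = epsilon_pct,
                 lower_ms = lo, upper_ms = hi, absolute_mode = absolute_1ms),
            class = "uncertainty_band")
}

# Exact null pmf of the Wald-Wolfowitz number of runs for n1 symbols of one
# kind and n2 of the other; vector over r = 2..(n1+n2).
runs_pmf <- function(n1, n2) {
  r <- 2:(n1 + n2)
  pm <- vapply(r, function(rr) {
    if (rr %% 2 == 0) {
      k <- rr / 2
      2 * choose(n1 - 1, k - 1) * choose(n2 - 1, k - 1)
    } else {
      k <- (rr - 1) / 2
      choose(n1 - 1, k) * choose(n2 - 1, k - 1) +
        choose(n1 - 1, k - 1) * choose(n2 - 1, k)
    }
  }, numeric(1))
  pm / choose(n1 + n2, n1)
}

#' Wald-Wolfowitz runs test for a trend in signed deviations
#'
#' Tests whether the sign sequence of latency deviations about the reference
#' clusters (too few runs), the signature of a systematic drift rather than
#' random estimator scatter. Zero deviations carry no sign and are dropped.
#' The test is the exact one-sided (lower-tail) runs test with a mid-p
#' correction for discreteness: `p = P(R < r) + 0.5 * P(R = r)` under the
#' null; a trend is flagged when `p < alpha`.
#'
#' Degenerate sequences are handled by convention: all-zero deviations mean
#' no trend; a single-signed sequence has an undefined test and is flagged
#' as a trend *candidate* (the band criterion then decides); fewer than 10
#' signed deviations with both signs present mean no trend.
#'
#' @param deviations Ordered numeric sequence of signed deviations.
#' @param alpha Significance level.
#' @return List: `trend` (logical), `p_value`, `n_runs`, `expected_runs`,
#'   `degenerate` (`NA` or a reason string).
#' @export
runs_test_trend <- function(deviations, alpha = 0.05) {
  s <- sign(deviations[!is.na(deviations)])
  s <- s[s != 0]
  out <- function(trend, p = NA_real_, r = NA_integer_, er = NA_real_,
                  why = NA_character_)
    list(trend = trend, p_value = p, n_runs = r, expected_runs = er,
         degenerate = why)
  if (length(s) == 0L) return(out(FALSE, why = "all-zero"))
  n1 <- sum(s > 0); n2 <- sum(s < 0)
  if (n1 == 0L || n2 == 0L) return(out(TRUE, why = "single-sign"))
  if (length(s) < 10L) return(out(FALSE, why = "too-short"))
  r <- sum(s[-1] != s[-length(s)]) + 1L
  pm <- runs_pmf(n1, n2)
  p <- sum(pm[seq_len(r - 2L)]) + 0.5 * pm[r - 1L]   # pmf index 1 <-> R = 2
  er <- 2 * n1 * n2 / (n1 + n2) + 1
  out(p < alpha, p, r, er)
}

#' Minimum acceptable SNR from a median sensitivity curve
#'
#' Scans the component's median curve in decreasing SNR order. The reference
#' latency is the curve value at the highest SNR grid point (the initial,
#' effectively true value). At each grid point two conditions are evaluated:
#' (a) a trend in the trailing `trend_window` deviations ending at the
#' candidate ([runs_test_trend()]), and (b) the latency lying outside the
#' acceptability band. The SNR of the first point satisfying both is the
#' minimum acceptable SNR; if no point ever satisfies both the result is
#' not available (`NA`), meaning the estimate never significantly departed
#' from its reference over the tested range.
#'
#' @param curve A `sensitivity_curve` from [summarize_runs()].
#' @param component One of `"rs1m_ms"`, `"rs1t_ms"`, `"rs2a_ms"`, `"rs2p_ms"`.
#' @param band An [uncertainty_bounds()] band. For the absolute 1 ms rule
#'   centered on the curve's own reference, pass `band = NULL` (the default
#'   builds it from the curve reference).
#' @param alpha Runs-test significance level.
#' @param trend_window Number of trailing grid points (0.1 dB apart) fed to
#'   the runs test.
#' @return List of class `threshold_result`: `component`,
#'   `min_acceptable_snr_db` (`NA` when not available), `available`,
#'   `reference_ms`, `band`, `trigger` (grid point and latency for audit),
#'   `min_snr_reached_db`.
#' @export
find_min_acceptable_snr <- function(curve, component, band = NULL,
                                    alpha = 0.05, trend_window = 20) {
  stopifnot(inherits(curve, "sensitivity_curve"))
  component <- match.arg(component, names(comp_parent_snr))
  df <- curve$components[[component]]
  ok <- !is.na(df$latency_ms)
  df <- df[ok, , drop = FALSE]
  if (nrow(df) < 2L) stop("curve too short", call. = FALSE)
  ref <- df$latency_ms[1]                  # highest-SNR grid point
  if (is.null(band)) band <- uncertainty_bounds(ref, absolute_1ms = TRUE)
  dev <- round(df$latency_ms) - round(ref) # 1 ms resolution
  lat_r <- round(df$latency_ms)
  outside <- lat_r < band$lower_ms | lat_r > band$upper_ms
  res <- list(component = component, min_acceptable_snr_db = NA_real_,
              available = FALSE, reference_ms = ref, band = band,
              trigger = NULL, min_snr_reached_db = min(df$snr_db))
  for (k in 2:nrow(df)) {
    if (!outside[k]) next
    w <- dev[max(1L, k - trend_window + 1L):k]
    if (runs_test_trend(w, alpha)$trend) {
      res$min_acceptable_snr_db <- df$snr_db[k]
      res$available <- TRUE
      res$trigger <- list(snr_db = df$snr_db[k], latency_ms = df$latency_ms[k])
      break
    }
  }
  class(res) <- "threshold_result"
  res
}

#' @export
print.threshold_result <- function(x, ...) {
  v <- if (x$available) sprintf("%.1f dB", x$min_acceptable_snr_db) else "N/A"
  cat(sprintf("<threshold_result> %s: min acceptable SNR %s (ref %.1f ms)\n",
              x$component, v, x$reference_ms))
  invisible(x)
}

#' Population worst-case minimum acceptable SNR
#'
#' The maximum minimum-acceptable SNR over subjects with an available
#' threshold (the worst case); not-available subjects are excluded but
#' counted.
#'
#' @param results List of `threshold_result`s for one component.
#' @return List: `worst_case_snr_db` (`NA` when every subject is N/A),
#'   `n_available`, `n_na`.
#' @export
population_worst_case <- function(results) {
  v <- vapply(results, function(r) r$min_acceptable_snr_db, numeric(1))
  av <- !is.na(v)
  list(worst_case_snr_db = if (any(av)) max(v[av]) else NA_real_,
       n_available = sum(av), n_na = sum(!av))
}

#' Subject-by-subject threshold table (1 ms rule)
#'
#' For each subject's sensitivity curve, the minimum acceptable SNR for all
#' four latencies under the absolute 1 ms rule (band centered on each
#' curve's own reference), plus the initial SNR values; the last row is the
#' population worst case. `NA` marks subjects whose estimate never left the
#' band.
#'
#' @param curves Named list of `sensitivity_curve`s.
#' @param initial_snr Optional data frame with `snr_s1_db`, `snr_s2_db` per
#'   subject (rounded to integer dB for reporting).
#' @param alpha,trend_window Passed to [find_min_acceptable_snr()].
#' @return Data frame shaped like the per-subject threshold table.
#' @export
subject_threshold_table <- function(curves, initial_snr = NULL, alpha = 0.05,
                                    trend_window = 20) {
  comps <- names(comp_parent_snr)
  rows <- lapply(seq_along(curves), function(i) {
    th <- vapply(comps, function(cc)
      find_min_acceptable_snr(curves[[i]], cc, alpha = alpha,
                              trend_window = trend_window)$min_acceptable_snr_db,
      numeric(1))
    data.frame(subject = names(curves)[i] %||% sprintf("subj%02d", i),
               snr_s1_db = if (!is.null(initial_snr)) round(initial_snr$snr_s1_db[i]) else NA,
               snr_s2_db = if (!is.null(initial_snr)) round(initial_snr$snr_s2_db[i]) else NA,
               rs1m_db = th[1], rs1t_db = th[2], rs2a_db = th[3], rs2p_db = th[4])
  })
  tab <- do.call(rbind, rows)
  worst <- vapply(c("rs1m_db", "rs1t_db", "rs2a_db", "rs2p_db"), function(k) {
    v <- tab[[k]]
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  }, numeric(1))
  rbind(tab, data.frame(subject = "worst_case", snr_s1_db = NA, snr_s2_db = NA,
                        rs1m_db = worst[1], rs1t_db = worst[2],
                        rs2a_db = worst[3], rs2p_db = worst[4]))
}

#' Minimum acceptable SNR as a function of the acceptable uncertainty
#'
#' For each uncertainty level and component: per-subject minimum acceptable
#' SNR with the percentage band centered on the *population* reference
#' latency (the cohort median), aggregated to the population worst case.
#' Subjects whose curve never leaves the band contribute the minimum SNR
#' their curve reached (reported in `n_fallback`), so a population value is
#' always defined.
#'
#' @param curves List of `sensitivity_curve`s (one per subject).
#' @param eps_list Percent uncertainties, default `c(2.5, 5, ..., 20)`.
#' @param refs Named numeric: population reference latency per component
#'   (ms); defaults to the medians of the curves' own references.
#' @param alpha,trend_window Passed to [find_min_acceptable_snr()].
#' @return Data frame: `epsilon_pct`, `component`,
#'   `min_acceptable_snr_db`, `n_available`, `n_fallback`.
#' @export
threshold_vs_uncertainty <- function(curves,
                                     eps_list = seq(2.5, 20, by = 2.5),
                                     refs = NULL, alpha = 0.05,
                                     trend_window = 20) {
  comps <- names(comp_parent_snr)
  if (is.null(refs)) {
    refs <- vapply(comps, function(cc)
      stats::median(vapply(curves, function(cu) cu$components[[cc]]$latency_ms[1],
                           numeric(1)), na.rm = TRUE), numeric(1))
  }
  grid <- expand.grid(epsilon_pct = eps_list, component = comps,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    eps <- grid$epsilon_pct[g]; cc <- grid$component[g]
    band <- uncertainty_bounds(refs[[cc]], epsilon_pct = eps)
    per <- vapply(curves, function(cu) {
      r <- find_min_acceptable_snr(cu, cc, band, alpha, trend_window)
      if (r$available) c(r$min_acceptable_snr_db, 0)
      else c(r$min_snr_reached_db, 1)        # band never left: min SNR reached
    }, numeric(2))
    data.frame(epsilon_pct = eps, component = cc,
               min_acceptable_snr_db = max(per[1, ]),
               n_available = sum(per[2, ] == 0),
               n_fallback = sum(per[2, ] == 1))
  })
  do.call(rbind, rows)
}
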