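# Multivariate-comparison module: physically coupled variable pairs
# (PPFD_IN~SW_IN, USTAR~WS, T_SONIC~TA, NETRAD~SW_IN) are screened with a
# robust regression per moving window; the windowed slopes expose gain
# drift and calibration steps, the residuals expose sporadic outliers and
# period-specific mismatches, and a perfect fit exposes variables derived
# one from another.

#' Multivariate consistency check
#'
#' Per pair and moving window (default 15 days stepping 5, so that a
#' defect confined to a couple of weeks dominates at least one window):
#' robust (Theil–Sen)
#' slope/intercept and residual MAD. Findings: `OUTLIER` (residuals beyond
#' `k * MAD` more often than the tolerated rate), `SHORT_TERM_MISMATCH`
#' (a window whose median residual is biased beyond tolerance),
#' `PERFECT_FIT` (full-record R-squared above 0.9999 — one variable is
#' derived from the other), `SLOPE_TREND` (systematic drift of the
#' windowed slope) and `SLOPE_STEP` (abrupt change of the windowed slope).
#'
#' @param table An `fp_table`.
#' @param pairs List of `c(y, x)` label pairs; defaults from `config`.
#' @param config [qaqc_config()].
#' @param registry Variable registry.
#' @return List of findings (module `multivariate`).
#' @export
multivariate_check <- function(table, pairs = NULL, config = qaqc_config(),
                               registry = fp_registry()) {
  cfg <- config$multivariate
  if (is.null(pairs)) pairs <- cfg$pairs
  res <- attr(table, "resolution")
  per_day <- 24 * 60 / res
  findings <- list()
  for (pr in pairs) {
    yl <- find_variable(table, pr[1], registry)
    xl <- find_variable(table, pr[2], registry)
    pair_id <- paste(pr, collapse = "~")
    if (is.null(yl) || is.null(xl)) {
      findings <- c(findings, list(finding(
        module = "multivariate", code = "SKIPPED", severity = "SKIPPED",
        variable = pair_id,
        message = sprintf("pair %s unavailable", pair_id))))
      next
    }
    y <- table[[yl]]; x <- table[[xl]]
    # exact (0,0) pairs (e.g. radiation at night) carry no information about
    # the relation and would collapse the residual MAD
    joint <- !is.na(y) & !is.na(x) & !(y == 0 & x == 0)
    if (sum(joint) < cfg$min_pts) {
      findings <- c(findings, list(finding(
        module = "multivariate", code = "SKIPPED", severity = "SKIPPED",
        variable = pair_id,
        message = sprintf("pair %s has insufficient joint coverage (%d points)",
                          pair_id, sum(joint)))))
      next
    }
    vars <- c(yl, xl)

    fit <- theil_sen(x[joint], y[joint], max_pairs_n = cfg$subsample)
    resid <- y - (fit$intercept + fit$slope * x)
    rmad <- stats::mad(resid[joint], na.rm = TRUE)

    r2 <- stats::cor(x[joint], y[joint])^2
    if (sum(joint) >= 1000 && is.finite(r2) && r2 > cfg$r2_perfect) {
      findings <- c(findings, list(finding(
        module = "multivariate", code = "PERFECT_FIT", severity = "WARNING",
        variable = vars,
        metrics = list(r_squared = r2, slope = fit$slope),
        message = sprintf("%s fits %s with R^2 = %.6f: one variable appears derived from the other",
                          yl, xl, r2))))
    }

    if (rmad > 0) {
      out_frac <- mean(abs(resid[joint]) > cfg$k_mad * rmad)
      if (out_frac > cfg$outlier_rate) {
        findings <- c(findings, list(finding(
          module = "multivariate", code = "OUTLIER", severity = "WARNING",
          variable = vars,
          metrics = list(frac = out_frac, k_mad = cfg$k_mad),
          message = sprintf("%.2f%% of %s residuals against %s exceed %g x MAD: sporadic erroneous data",
                            100 * out_frac, yl, xl, cfg$k_mad))))
      }
    }

    # windowed slopes and residual bias
    win <- cfg$window_days * per_day
    step <- cfg$step_days * per_day
    n <- nrow(table)
    starts <- seq(1, max(1, n - win + 1), by = step)
    slopes <- rep(NA_real_, length(starts))
    med_resid <- rep(NA_real_, length(starts))
    for (w in seq_along(starts)) {
      idx <- starts[w]:min(n, starts[w] + win - 1)
      jw <- joint[idx]
      if (sum(jw) < cfg$min_pts / 2) next
      fw <- theil_sen(x[idx][jw], y[idx][jw], max_pairs_n = 200)
      slopes[w] <- fw$slope
      med_resid[w] <- stats::median(resid[idx][jw])
    }
    if (rmad > 0) {
      bad_w <- which(abs(med_resid) > cfg$bias_tol * rmad)
      if (length(bad_w) > 0) {
        w0 <- bad_w[which.max(abs(med_resid[bad_w]))]
        idx <- starts[w0]:min(n, starts[w0] + win - 1)
        sp <- span_of(table, idx)
        findings <- c(findings, list(finding(
          module = "multivariate", code = "SHORT_TERM_MISMATCH", severity = "WARNING",
          variable = vars, span_start = sp$start, span_end = sp$end,
          metrics = list(n_windows = length(bad_w),
                         worst_bias = med_resid[w0], resid_mad = rmad),
          message = sprintf("%d window(s) where %s is biased against %s (worst median residual %.3g): erroneous data for a specific period",
                            length(bad_w), yl, xl, med_resid[w0]))))
      }
    }

    sv <- slopes[!is.na(slopes)]
    if (length(sv) >= 5 && abs(stats::median(sv)) > 0) {
      ref <- abs(stats::median(sv))
      wi <- which(!is.na(slopes))
      ts_fit <- theil_sen(wi, slopes[wi])
      drift_total <- ts_fit$slope * (max(wi) - min(wi))
      rho <- suppressWarnings(stats::cor(wi, slopes[wi], method = "spearman"))
      if (is.finite(drift_total) && abs(drift_total) / ref > cfg$drift_tol &&
          is.finite(rho) && abs(rho) >= 0.6) {
        findings <- c(findings, list(finding(
          module = "multivariate", code = "SLOPE_TREND", severity = "WARNING",
          variable = vars,
          metrics = list(slope_first = sv[1], slope_last = sv[length(sv)],
                         relative_drift = drift_total / ref),
          message = sprintf("regression slope of %s on %s drifts systematically (%.3g to %.3g): sensor degradation or calibration drift",
                            yl, xl, sv[1], sv[length(sv)]))))
      } else {
        # slope step: best two-segment split of the windowed slopes
        if (length(sv) >= 6) {
          splits <- 3:(length(sv) - 3)
          dstat <- vapply(splits, function(j) {
            abs(stats::median(sv[1:j]) - stats::median(sv[(j + 1):length(sv)]))
          }, numeric(1))
          if (max(dstat) / ref > cfg$slope_step_tol) {
            findings <- c(findings, list(finding(
              module = "multivariate", code = "SLOPE_STEP", severity = "WARNING",
              variable = vars,
              metrics = list(relative_step = max(dstat) / ref),
              message = sprintf("regression slope of %s on %s changes abruptly (relative step %.2f): calibration change",
                                yl, xl, max(dstat) / ref))))
          }
        }
      }
    }
  }
  findings
}
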