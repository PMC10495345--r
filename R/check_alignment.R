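# Timestamp-alignment module: timing defects (shifts, timezone mismatch,
# daylight saving, unsynchronized streams) detected by cross-correlating
# measured shortwave radiation against top-of-atmosphere potential
# radiation, plus radiation-magnitude issues (excess, tilt, shading) that
# share the same reference signal.

# first column whose parsed base matches `base`
find_variable <- function(table, base, registry = fp_registry()) {
  for (l in data_columns(table)) {
    if (parse_variable_name(l, registry)$base == base) return(l)
  }
  NULL
}

# best lag per sliding window: positive lag k means the data are displaced
# k rows late relative to their timestamps (data[i] belongs at time i - k)
lag_profile_for <- function(x, pot, table, cfg) {
  res <- attr(table, "resolution")
  per_day <- 24 * 60 / res
  win <- cfg$window_days * per_day
  step <- cfg$step_days * per_day
  n <- length(x)
  starts <- seq(1, max(1, n - win + 1), by = step)
  out <- data.frame(window_start = table$TIMESTAMP_START[starts],
                    lag = NA_real_, r = NA_real_, coverage = NA_real_)
  for (w in seq_along(starts)) {
    i <- starts[w]
    idx <- i:min(n, i + win - 1)
    xw <- x[idx]
    day <- pot[idx] > 0
    cov <- if (sum(day) == 0) 0 else mean(!is.na(xw[day]))
    out$coverage[w] <- cov
    if (cov < cfg$min_coverage) next
    ctr <- stats::median(xw, na.rm = TRUE)
    sc <- stats::mad(xw, na.rm = TRUE)
    if (!is.finite(sc) || sc == 0) sc <- stats::sd(xw, na.rm = TRUE)
    if (!is.finite(sc) || sc == 0) next
    xs <- (xw - ctr) / sc
    lags <- -cfg$max_lag:cfg$max_lag
    rs <- vapply(lags, function(L) {
      src <- idx - L
      ok <- src >= 1 & src <= n
      p <- rep(NA_real_, length(idx))
      p[ok] <- pot[src[ok]]
      keep <- !is.na(xs) & !is.na(p)
      if (sum(keep) < 10 || stats::sd(p[keep]) == 0 || stats::sd(xs[keep]) == 0) return(NA_real_)
      stats::cor(xs[keep], p[keep])
    }, numeric(1))
    if (all(is.na(rs))) next
    best <- which.max(rs)
    out$lag[w] <- lags[best]
    out$r[w] <- rs[best]
  }
  out
}

#' Timestamp-alignment check
#'
#' For each sliding window (default 15 days, stepping 5), cross-correlates
#' the measured radiation (SW_IN, falling back to PPFD_IN) against
#' potential radiation over lags of -10..+10 intervals, after
#' median/MAD-standardizing each window so amplitude faults cannot corrupt
#' the timing estimate. Window-lag patterns are classified:
#' a constant nonzero lag is a timestamp shift / timezone mismatch (a
#' persistent one-interval lag specifically suggests beginning-vs-ending
#' timestamp confusion); two season-long plateaus one hour apart indicate
#' daylight-saving time; different lags for SW_IN and PPFD_IN indicate
#' unsynchronized data streams.
#'
#' @param table An `fp_table`.
#' @param site [site_meta()] for the solar reference.
#' @param config [qaqc_config()].
#' @param registry Variable registry.
#' @return List with `lag_profile` (data.frame: variable, window start,
#'   best lag in intervals, peak correlation, coverage) and `findings`.
#' @export
timestamp_alignment <- function(table, site, config = qaqc_config(),
                                registry = fp_registry()) {
  cfg <- config$alignment
  res <- attr(table, "resolution")
  per_hour <- 60 / res
  rad_labels <- c(find_variable(table, "SW_IN", registry),
                  find_variable(table, "PPFD_IN", registry))
  if (length(rad_labels) == 0) {
    return(list(lag_profile = NULL, findings = list(finding(
      module = "timestamp_alignment", code = "SKIPPED", severity = "SKIPPED",
      message = "no usable radiation variable (SW_IN or PPFD_IN); timing cannot be assessed"))))
  }
  pot <- table_sw_pot(table, site)
  profiles <- lapply(rad_labels, function(l) {
    p <- lag_profile_for(table[[l]], pot, table, cfg)
    p$variable <- l
    p
  })
  findings <- list()
  modal_lags <- rep(NA_real_, length(rad_labels))
  primary_done <- FALSE
  for (k in seq_along(rad_labels)) {
    prof <- profiles[[k]]
    lags <- prof$lag[!is.na(prof$lag)]
    if (length(lags) < cfg$min_windows) next
    tab <- sort(table(lags), decreasing = TRUE)
    modal <- as.numeric(names(tab)[1])
    frac_modal <- tab[[1]] / length(lags)
    modal_lags[k] <- modal
    if (primary_done) next  # timing classification from the primary stream only
    primary_done <- TRUE
    # daylight saving: two plateaus separated by exactly one hour of intervals
    runs <- rle(prof$lag[!is.na(prof$lag)])
    plateau_vals <- unique(runs$values[runs$lengths >= cfg$plateau_min])
    is_dst <- length(plateau_vals) >= 2 &&
      any(abs(outer(plateau_vals, plateau_vals, "-")) == per_hour)
    if (is_dst) {
      findings <- c(findings, list(finding(
        module = "timestamp_alignment", code = "DST", severity = "ACTION_REQUIRED",
        variable = rad_labels[k],
        metrics = list(plateau_lags = plateau_vals, n_windows = length(lags)),
        message = sprintf(
          "window lags form plateaus at {%s} intervals, one hour apart: daylight-saving time appears to be encoded (timestamps must be local standard time)",
          paste(sort(plateau_vals), collapse = ", ")))))
    } else if (modal != 0 && frac_modal >= cfg$const_frac) {
      code <- if (abs(modal) == 1) "ENDPOINT_CONFUSION" else "TIMESTAMP_SHIFT"
      findings <- c(findings, list(finding(
        module = "timestamp_alignment", code = code, severity = "ACTION_REQUIRED",
        variable = rad_labels[k],
        metrics = list(modal_lag = modal, frac_windows = unname(frac_modal),
                       lag_minutes = modal * res),
        message = if (code == "ENDPOINT_CONFUSION")
          sprintf("persistent %+d-interval lag against potential radiation: beginning vs ending timestamp convention appears confused", modal)
        else
          sprintf("constant %+d-interval (%+d min) lag against potential radiation: timestamp shift or timezone mismatch", modal, modal * res))))
    }
  }
  ok <- !is.na(modal_lags)
  if (sum(ok) >= 2 && length(unique(modal_lags[ok])) > 1) {
    findings <- c(findings, list(finding(
      module = "timestamp_alignment", code = "STREAMS_NOT_SYNCED", severity = "WARNING",
      variable = rad_labels[ok],
      metrics = list(modal_lags = modal_lags[ok]),
      message = sprintf("radiation streams disagree in timing (modal lags: %s)",
                        paste(sprintf("%s=%+d", rad_labels[ok], modal_lags[ok]),
                              collapse = ", ")))))
  }
  list(lag_profile = do.call(rbind, profiles), findings = findings)
}

#' Radiation-measurement checks
#'
#' Uses the clearness ratio `SW_IN / SW_IN_POT` on bright intervals
#' (potential radiation above `pot_min`): readings above
#' `SW_IN_POT * headroom` beyond a tolerated fraction indicate
#' higher-than-expected radiation (unit or calibration error); a
#' persistent morning-vs-afternoon asymmetry of the ratio indicates a
#' tilted sensor; a contiguous time-of-day sector depressed relative to
#' its month's other daytime sectors indicates shading.
#'
#' @inheritParams timestamp_alignment
#' @return List of findings (module `timestamp_alignment`, which owns
#'   radiation measurement issues).
#' @export
radiation_issue_check <- function(table, site, config = qaqc_config(),
                                  registry = fp_registry()) {
  cfg <- config$radiation
  sw <- find_variable(table, "SW_IN", registry)
  if (is.null(sw)) {
    return(list(finding(module = "timestamp_alignment", code = "SKIPPED",
                        severity = "SKIPPED",
                        message = "no SW_IN; radiation measurement checks cannot run")))
  }
  x <- table[[sw]]
  pot <- table_sw_pot(table, site)
  findings <- list()
  bright <- pot > cfg$pot_min & !is.na(x)
  if (sum(bright) == 0) return(findings)

  excess <- mean(x[bright] > pot[bright] * cfg$headroom)
  if (excess > cfg$excess_frac) {
    findings <- c(findings, list(finding(
      module = "timestamp_alignment", code = "HIGH_RADIATION", severity = "WARNING",
      variable = sw,
      metrics = list(frac_above_ceiling = excess, headroom = cfg$headroom),
      message = sprintf("%.1f%% of bright intervals exceed potential radiation x %.2f: check units/calibration",
                        100 * excess, cfg$headroom))))
  }

  ratio <- ifelse(bright, x / pot, NA)
  lt <- as.POSIXlt(table_mid_times(table), tz = "UTC")
  hod <- lt$hour + lt$min / 60
  month <- format(table_start_times(table), "%Y%m")
  am <- hod < 12
  months <- unique(month)
  asym <- vapply(months, function(m) {
    ra <- ratio[month == m & am]; rp <- ratio[month == m & !am]
    ra <- ra[!is.na(ra)]; rp <- rp[!is.na(rp)]
    if (length(ra) < 20 || length(rp) < 20) return(NA_real_)
    stats::median(ra) - stats::median(rp)
  }, numeric(1))
  asym <- asym[!is.na(asym)]
  if (length(asym) >= 3 && mean(abs(asym) > cfg$asym_tol) >= cfg$asym_month_frac) {
    findings <- c(findings, list(finding(
      module = "timestamp_alignment", code = "TILTED", severity = "WARNING",
      variable = sw,
      metrics = list(median_am_pm_asymmetry = stats::median(asym),
                     months_affected = sum(abs(asym) > cfg$asym_tol)),
      message = sprintf("persistent morning/afternoon clearness asymmetry (median %+.2f): radiation sensor may be tilted",
                        stats::median(asym)))))
  }

  # shading: per month, daytime hour-bins depressed relative to the month's
  # other daytime bins; a contiguous sector depressed in most months
  hbin <- floor(hod)
  mm <- substr(month, 5, 6)
  depressed <- matrix(0L, nrow = 24, ncol = 0)
  for (m in unique(mm)) {
    sel <- mm == m
    med_by_bin <- vapply(0:23, function(b) {
      r <- ratio[sel & hbin == b]
      r <- r[!is.na(r)]
      if (length(r) < 10) NA_real_ else stats::median(r)
    }, numeric(1))
    base <- stats::median(med_by_bin, na.rm = TRUE)
    if (!is.finite(base) || base <= 0) next
    depressed <- cbind(depressed, as.integer(!is.na(med_by_bin) & med_by_bin < cfg$shade_tol * base))
  }
  if (ncol(depressed) >= 3) {
    frac_dep <- rowMeans(depressed)
    runs <- rle(frac_dep >= cfg$shade_month_frac)
    if (any(runs$values & runs$lengths >= 2)) {
      hrs <- which(frac_dep >= cfg$shade_month_frac) - 1
      findings <- c(findings, list(finding(
        module = "timestamp_alignment", code = "SHADED", severity = "WARNING",
        variable = sw,
        metrics = list(hours = hrs),
        message = sprintf("clearness ratio persistently depressed during hours %s: possible shading",
                          paste(range(hrs), collapse = "-")))))
    }
  }
  findings
}
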