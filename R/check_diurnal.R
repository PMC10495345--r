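# Diurnal-seasonal pattern module: monthly median diurnal composites
# reveal sign-convention flips, timing shifts at monthly resolution,
# physically unlikely composite levels, and year-over-year displacement.

#' Median diurnal composite
#'
#' Per calendar month of the record and time-of-day bin (one bin per
#' timestep, `24*60/resolution` bins per day): median, interquartile band
#' and count of non-missing values.
#'
#' @param table An `fp_table`.
#' @param variable Variable label.
#' @return data.frame: `month` (`YYYYMM`), `bin` (1-based time-of-day
#'   index), `median`, `q25`, `q75`, `n`.
#' @export
diurnal_composite <- function(table, variable) {
  res <- attr(table, "resolution")
  nb <- 24 * 60 / res
  month <- substr(table$TIMESTAMP_START, 1, 6)
  hh <- as.integer(substr(table$TIMESTAMP_START, 9, 10))
  mm <- as.integer(substr(table$TIMESTAMP_START, 11, 12))
  bin <- (hh * 60 + mm) / res + 1
  x <- table[[variable]]
  months <- unique(month)
  out <- expand.grid(bin = seq_len(nb), month = months,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- factor(paste(month, bin), levels = paste(out$month, out$bin))
  groups <- split(x, key)
  m <- vapply(groups, function(xs) {
    xs <- xs[!is.na(xs)]
    if (length(xs) == 0) return(c(NA_real_, NA_real_, NA_real_, 0))
    c(stats::median(xs), stats::quantile(xs, c(0.25, 0.75), names = FALSE), length(xs))
  }, numeric(4))
  out$median <- m[1, ]; out$q25 <- m[2, ]; out$q75 <- m[3, ]; out$n <- m[4, ]
  out[, c("month", "bin", "median", "q25", "q75", "n")]
}

# circular best lag (intervals) between two composite day-curves
composite_lag <- function(y, ref, max_lag = 3) {
  nb <- length(y)
  lags <- -max_lag:max_lag
  rs <- vapply(lags, function(L) {
    r <- ref[((seq_len(nb) - 1 - L) %% nb) + 1]
    keep <- !is.na(y) & !is.na(r)
    if (sum(keep) < 6 || stats::sd(y[keep]) == 0 || stats::sd(r[keep]) == 0) return(NA_real_)
    stats::cor(y[keep], r[keep])
  }, numeric(1))
  if (all(is.na(rs))) return(NA_integer_)
  lags[which.max(rs)]
}

#' Diurnal-seasonal pattern check
#'
#' Builds monthly median diurnal composites and screens them for:
#' a flipped CO2-flux sign convention (growing-season daytime composite
#' above the nighttime level while positively correlated with potential
#' radiation — daytime uptake must be negative); a timing shift of the
#' radiation composite against the potential-radiation composite
#' (corroborating the alignment check at monthly resolution); composite
#' levels outside the hard physical limits; and, for multi-year records, a
#' year-over-year displacement of the full composite range. Growing-season
#' months are those whose daytime composite amplitude exceeds a fraction
#' (default 25%) of the annual maximum, which avoids any external
#' phenology input.
#'
#' @param table An `fp_table`.
#' @param site [site_meta()].
#' @param config [qaqc_config()].
#' @param registry Variable registry.
#' @return List with `composites` (named list of composite data.frames)
#'   and `findings` (module `diurnal_seasonal`).
#' @export
diurnal_seasonal_check <- function(table, site, config = qaqc_config(),
                                   registry = fp_registry()) {
  cfg <- config$diurnal
  res <- attr(table, "resolution")
  nb <- 24 * 60 / res
  months <- unique(substr(table$TIMESTAMP_START, 1, 6))
  if (length(months) < cfg$min_months) {
    return(list(composites = NULL, findings = list(finding(
      module = "diurnal_seasonal", code = "SKIPPED", severity = "SKIPPED",
      message = sprintf("only %d month(s) of data; composites need at least %d",
                        length(months), cfg$min_months)))))
  }
  pot <- table_sw_pot(table, site)
  pot_tab <- table
  pot_tab$SW_IN_POT_INTERNAL <- pot
  pot_comp <- diurnal_composite(pot_tab, "SW_IN_POT_INTERNAL")
  findings <- list()
  composites <- list()

  # sign convention: CO2 flux only (uptake-negative convention)
  fc_label <- find_variable(table, "FC", registry)
  if (!is.null(fc_label)) {
    comp <- diurnal_composite(table, fc_label)
    composites[[fc_label]] <- comp
    amp <- vapply(months, function(m) {
      y <- comp$median[comp$month == m]
      if (all(is.na(y))) NA_real_ else diff(range(y, na.rm = TRUE))
    }, numeric(1))
    grow_months <- months[!is.na(amp) & amp >= cfg$grow_frac * max(amp, na.rm = TRUE)]
    flagged <- character(0)
    for (m in grow_months) {
      y <- comp$median[comp$month == m]
      p <- pot_comp$median[pot_comp$month == m]
      day <- !is.na(p) & p > cfg$pot_day_min
      night <- !is.na(p) & p == 0
      if (sum(day) < 4 || sum(night) < 4) next
      day_med <- stats::median(y[day], na.rm = TRUE)
      night_med <- stats::median(y[night], na.rm = TRUE)
      keep <- !is.na(y) & !is.na(p)
      rho <- if (sum(keep) > 6) stats::cor(y[keep], p[keep]) else NA_real_
      if (is.finite(day_med) && is.finite(night_med) && is.finite(rho) &&
          day_med > night_med + cfg$sign_margin && rho > cfg$sign_cor_min) {
        flagged <- c(flagged, m)
      }
    }
    if (length(flagged) > 0) {
      findings <- c(findings, list(finding(
        module = "diurnal_seasonal", code = "SIGN_FLIP", severity = "ACTION_REQUIRED",
        variable = fc_label,
        metrics = list(n_months = length(flagged), n_growing = length(grow_months)),
        message = sprintf("daytime %s composite exceeds nighttime in %d growing-season month(s) while tracking radiation: sign convention appears flipped (uptake must be negative)",
                          fc_label, length(flagged)))))
    }
  }

  # composite timing shift (monthly corroboration of the alignment check)
  sw_label <- find_variable(table, "SW_IN", registry)
  if (!is.null(sw_label)) {
    comp <- diurnal_composite(table, sw_label)
    composites[[sw_label]] <- comp
    lags <- vapply(months, function(m) {
      L <- composite_lag(comp$median[comp$month == m],
                         pot_comp$median[pot_comp$month == m])
      as.numeric(L)
    }, numeric(1))
    lags <- lags[!is.na(lags)]
    if (length(lags) >= cfg$min_months && mean(lags != 0) >= cfg$shift_month_frac) {
      findings <- c(findings, list(finding(
        module = "diurnal_seasonal", code = "COMPOSITE_SHIFT", severity = "WARNING",
        variable = sw_label,
        metrics = list(modal_lag = as.numeric(names(sort(table(lags), decreasing = TRUE))[1]),
                       n_months = sum(lags != 0)),
        message = sprintf("monthly diurnal composite of %s is lagged against potential radiation in %d month(s): corroborates a timestamp shift",
                          sw_label, sum(lags != 0)))))
    }
  }

  # physically unlikely composite levels
  for (v in data_columns(table)) {
    pv <- parse_variable_name(v, registry)
    entry <- registry_lookup(pv$base, registry)
    if (is.null(entry) || entry$kind == "quality_flag") next
    comp <- composites[[v]]
    if (is.null(comp)) comp <- diurnal_composite(table, v)
    bad <- sum(comp$median < entry$hard_min | comp$median > entry$hard_max, na.rm = TRUE)
    if (bad > 0) {
      findings <- c(findings, list(finding(
        module = "diurnal_seasonal", code = "UNLIKELY_VALUES", severity = "WARNING",
        variable = v,
        metrics = list(n_bins = bad),
        message = sprintf("%d composite bin(s) of %s lie outside the physical limits [%g, %g]",
                          bad, v, entry$hard_min, entry$hard_max))))
    }
  }

  # year-over-year displacement of the composite (multi-year records only)
  years <- unique(substr(months, 1, 4))
  if (length(years) >= 2) {
    for (v in data_columns(table)) {
      pv <- parse_variable_name(v, registry)
      entry <- registry_lookup(pv$base, registry)
      if (is.null(entry) || entry$kind == "quality_flag") next
      comp <- composites[[v]]
      if (is.null(comp)) comp <- diurnal_composite(table, v)
      comp$year <- substr(comp$month, 1, 4)
      comp$moy <- substr(comp$month, 5, 6)
      spread <- robust_spread(comp$median)
      if (!is.finite(spread) || spread == 0) next
      for (i in seq_len(length(years) - 1)) {
        a <- comp$median[comp$year == years[i]]
        b <- comp$median[comp$year == years[i + 1]]
        moys <- intersect(comp$moy[comp$year == years[i]], comp$moy[comp$year == years[i + 1]])
        if (length(moys) < 3 * nb) next
        sel_a <- comp$year == years[i] & comp$moy %in% moys
        sel_b <- comp$year == years[i + 1] & comp$moy %in% moys
        d <- stats::median(comp$median[sel_b], na.rm = TRUE) -
          stats::median(comp$median[sel_a], na.rm = TRUE)
        if (is.finite(d) && abs(d) > cfg$yoy_tol * spread) {
          findings <- c(findings, list(finding(
            module = "diurnal_seasonal", code = "FULL_RANGE_STEP", severity = "WARNING",
            variable = v,
            metrics = list(displacement = d, year_from = as.numeric(years[i]),
                           year_to = as.numeric(years[i + 1])),
            message = sprintf("composite of %s displaced by %.3g between %s and %s: step change in the full range",
                              v, d, years[i], years[i + 1]))))
        }
      }
    }
  }
  list(composites = composites, findings = findings)
}

#' USTAR-filtering detection
#'
#' Bins nighttime (computed potential radiation exactly zero, robust to
#' radiation-sensor faults) friction velocity into 0.05 m/s classes and
#' measures per-bin FC availability. If every bin below some edge has
#' availability under `low_avail` while the data above it are well covered
#' (`high_avail`), FC was filtered by a USTAR threshold before upload; the
#' estimated threshold is the highest such edge. A nighttime USTAR first
#' percentile above `ustar_floor` indicates the USTAR record itself was
#' truncated.
#'
#' @param table An `fp_table` with FC and USTAR.
#' @param site [site_meta()].
#' @param config [qaqc_config()].
#' @param registry Variable registry.
#' @return List with `bins` (data.frame: edge_lo, edge_hi, n,
#'   availability), `u_star_threshold` (m/s or `NA`), `verdict`
#'   (`"FC_FILTERED"`, `"USTAR_FILTERED"` or `"NONE"`) and `findings`
#'   (module `ustar_filtering`).
#' @export
ustar_filtering_check <- function(table, site, config = qaqc_config(),
                                  registry = fp_registry()) {
  cfg <- config$ustar
  fc_label <- find_variable(table, "FC", registry)
  us_label <- find_variable(table, "USTAR", registry)
  skip <- function(msg) list(bins = NULL, u_star_threshold = NA_real_, verdict = "NONE",
                             findings = list(finding(module = "ustar_filtering",
                                                     code = "SKIPPED", severity = "SKIPPED",
                                                     message = msg)))
  if (is.null(fc_label) || is.null(us_label)) {
    return(skip("FC and USTAR are both required for USTAR-filtering detection"))
  }
  pot <- table_sw_pot(table, site)
  night <- pot == 0 & !is.na(table[[us_label]])
  if (sum(night) < cfg$n_night_min) {
    return(skip(sprintf("only %d nighttime intervals with USTAR; need %d",
                        sum(night), cfg$n_night_min)))
  }
  u <- table[[us_label]][night]
  have_fc <- !is.na(table[[fc_label]][night])
  bw <- cfg$bin_width
  bin <- floor(u / bw)
  bins <- sort(unique(bin))
  df <- data.frame(edge_lo = bins * bw, edge_hi = (bins + 1) * bw,
                   n = as.numeric(tabulate(match(bin, bins), length(bins))),
                   availability = vapply(bins, function(b) mean(have_fc[bin == b]),
                                         numeric(1)))
  usable <- df$n >= cfg$bin_n_min
  findings <- list()
  u_th <- NA_real_
  verdict <- "NONE"
  # candidate edges: each usable bin's upper edge
  for (i in rev(which(usable))) {
    below <- usable & df$edge_hi <= df$edge_hi[i]
    above <- usable & df$edge_lo >= df$edge_hi[i]
    if (!any(below) || !any(above)) next
    avail_above <- sum(df$n[above] * df$availability[above]) / sum(df$n[above])
    if (all(df$availability[below] < cfg$low_avail) && avail_above >= cfg$high_avail) {
      u_th <- df$edge_hi[i]
      break
    }
  }
  if (is.finite(u_th)) {
    verdict <- "FC_FILTERED"
    findings <- c(findings, list(finding(
      module = "ustar_filtering", code = "FC_FILTERED", severity = "WARNING",
      variable = fc_label,
      metrics = list(u_star_threshold = u_th,
                     n_night = sum(night)),
      message = sprintf("nighttime FC is absent below USTAR = %.2f m/s but present above: FC appears USTAR-filtered before upload (unfiltered fluxes should be submitted)",
                        u_th))))
  }
  q01 <- stats::quantile(u, 0.01, names = FALSE)
  if (q01 > cfg$ustar_floor) {
    verdict <- if (verdict == "NONE") "USTAR_FILTERED" else verdict
    findings <- c(findings, list(finding(
      module = "ustar_filtering", code = "USTAR_FILTERED", severity = "WARNING",
      variable = us_label,
      metrics = list(night_q01 = q01, floor = cfg$ustar_floor),
      message = sprintf("1st percentile of nighttime USTAR is %.3f m/s (> %.2f): low-turbulence records appear deleted",
                        q01, cfg$ustar_floor))))
  }
  list(bins = df, u_star_threshold = u_th, verdict = verdict, findings = findings)
}
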