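# Physical-range module: site-specific plausible ranges (plausibility
# check) and the time-domain variability screens (trend, step change,
# filled constants, processing cut-offs).

season_of_month <- function(month) {
  c("DJF", "DJF", "MAM", "MAM", "MAM", "JJA",
    "JJA", "JJA", "SON", "SON", "SON", "DJF")[month]
}

# robust spread: MAD with an IQR fallback for strongly bimodal series
# (e.g. radiation, whose season median sits at the night value)
robust_spread <- function(x) {
  max(stats::mad(x, na.rm = TRUE), stats::IQR(x, na.rm = TRUE) / 1.349)
}

#' Site-specific plausible ranges
#'
#' For each variable and meteorological season (DJF/MAM/JJA/SON — for
#' southern-hemisphere sites the labels denote the same calendar months,
#' i.e. DJF is local summer), the plausible range is
#' `median +/- k * spread` with `spread = max(MAD, IQR/1.349)`, clipped to
#' the registry's hard physical limits. Constructed from the site's own
#' record so the wide climatic range across sites does not need a global
#' table.
#'
#' @param table An `fp_table`.
#' @param registry Variable registry.
#' @param config [qaqc_config()] (uses `range$k_mad`, `range$n_min`).
#' @return data.frame: `variable`, `season`, `n`, `center`, `spread`,
#'   `lower`, `upper`.
#' @export
plausible_ranges <- function(table, registry = fp_registry(), config = qaqc_config()) {
  cfg <- config$range
  month <- as.integer(substr(table$TIMESTAMP_START, 5, 6))
  season <- season_of_month(month)
  rows <- list()
  for (v in data_columns(table)) {
    pv <- parse_variable_name(v, registry)
    entry <- registry_lookup(pv$base, registry)
    if (is.null(entry) || entry$kind == "quality_flag") next
    for (s in unique(season)) {
      x <- table[[v]][season == s]
      x <- x[!is.na(x)]
      if (length(x) < cfg$n_min) next
      ctr <- stats::median(x)
      spr <- robust_spread(x)
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, season = s, n = length(x), center = ctr, spread = spr,
        lower = max(ctr - cfg$k_mad * spr, entry$hard_min),
        upper = min(ctr + cfg$k_mad * spr, entry$hard_max),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(NULL)
  do.call(rbind, rows)
}

#' Physical-range (plausibility) check
#'
#' Per variable: counts hard physical-limit violations (always
#' action-required), flags an excessive fraction of points outside the
#' seasonal plausible range, and detects percent-kind variables submitted
#' as ratios (non-missing maximum at or below 1.5 — a relative humidity or
#' soil-water-content series living in `[0, 1]` is a unit error, not dry
#' air).
#'
#' @param table An `fp_table`.
#' @param registry Variable registry.
#' @param ranges Optional precomputed [plausible_ranges()].
#' @param config [qaqc_config()].
#' @return List of findings (module `physical_range`).
#' @export
physical_range_check <- function(table, registry = fp_registry(), ranges = NULL,
                                 config = qaqc_config()) {
  cfg <- config$range
  if (is.null(ranges)) ranges <- plausible_ranges(table, registry, config)
  month <- as.integer(substr(table$TIMESTAMP_START, 5, 6))
  season <- season_of_month(month)
  findings <- list()
  for (v in data_columns(table)) {
    pv <- parse_variable_name(v, registry)
    entry <- registry_lookup(pv$base, registry)
    if (is.null(entry) || entry$kind == "quality_flag") next
    x <- table[[v]]
    n_ok <- sum(!is.na(x))
    if (n_ok == 0) next

    n_hard <- sum(x < entry$hard_min | x > entry$hard_max, na.rm = TRUE)
    if (n_hard > 0) {
      findings <- c(findings, list(finding(
        module = "physical_range", code = "OUT_OF_RANGE", severity = "ACTION_REQUIRED",
        variable = v,
        metrics = list(n_violations = n_hard, frac = n_hard / n_ok,
                       hard_min = entry$hard_min, hard_max = entry$hard_max),
        message = sprintf("%d value(s) outside the physical limits [%g, %g] %s",
                          n_hard, entry$hard_min, entry$hard_max, entry$units))))
    }

    if (!is.null(ranges)) {
      rr <- ranges[ranges$variable == v, , drop = FALSE]
      if (nrow(rr) > 0) {
        out_n <- 0L; tot <- 0L
        for (i in seq_len(nrow(rr))) {
          xs <- x[season == rr$season[i]]
          xs <- xs[!is.na(xs)]
          out_n <- out_n + sum(xs < rr$lower[i] | xs > rr$upper[i])
          tot <- tot + length(xs)
        }
        if (tot >= cfg$n_min && out_n / tot > cfg$outlier_frac) {
          findings <- c(findings, list(finding(
            module = "physical_range", code = "EXCESSIVE_OUTLIERS", severity = "WARNING",
            variable = v,
            metrics = list(frac_outliers = out_n / tot, n_outliers = out_n,
                           k_mad = cfg$k_mad),
            message = sprintf("%.2f%% of values fall outside the seasonal plausible range (median +/- %g spread)",
                              100 * out_n / tot, cfg$k_mad))))
        }
      }
    }

    if (isTRUE(entry$percent) && n_ok >= cfg$percent_n_min &&
        max(x, na.rm = TRUE) <= cfg$percent_max && min(x, na.rm = TRUE) >= -cfg$percent_max) {
      findings <- c(findings, list(finding(
        module = "physical_range", code = "PERCENT_AS_RATIO", severity = "ACTION_REQUIRED",
        variable = v,
        metrics = list(max_value = max(x, na.rm = TRUE), n = n_ok),
        message = sprintf("%s is a percent variable but its maximum is %.3g: values appear to be ratios (multiply by 100)",
                          v, max(x, na.rm = TRUE)))))
    }
  }
  findings
}

#' Theil–Sen slope estimator
#'
#' Median of pairwise slopes (pairs with zero abscissa difference are
#' excluded); intercept is `median(y - slope * x)`.
#'
#' @param x,y Numeric vectors.
#' @param max_pairs_n Subsample (evenly spaced, deterministic) to at most
#'   this many points before forming pairs.
#' @return List with `slope` and `intercept`.
#' @export
theil_sen <- function(x, y, max_pairs_n = 500) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2) return(list(slope = NA_real_, intercept = NA_real_))
  if (n > max_pairs_n) {
    idx <- unique(round(seq(1, n, length.out = max_pairs_n)))
    x <- x[idx]; y <- y[idx]; n <- length(x)
  }
  dx <- outer(x, x, "-"); dy <- outer(y, y, "-")
  keep <- upper.tri(dx) & dx != 0
  if (!any(keep)) return(list(slope = NA_real_, intercept = stats::median(y)))
  slope <- stats::median(dy[keep] / dx[keep])
  list(slope = slope, intercept = stats::median(y - slope * x))
}

# daily means (NA when a day has <25% coverage) plus their dates; the mean,
# not the median, because the daily median of a variable that is zero half
# the day (radiation) is a discontinuous function of day length
daily_medians <- function(table, v) {
  day <- substr(table$TIMESTAMP_START, 1, 8)
  x <- table[[v]]
  days <- unique(day)
  med <- vapply(split(x, factor(day, levels = days)), function(xs) {
    if (mean(!is.na(xs)) < 0.25) NA_real_ else mean(xs, na.rm = TRUE)
  }, numeric(1))
  list(day = days, median = unname(med))
}

# remove the smooth seasonal cycle (annual + semiannual harmonics) from a
# daily series; an abrupt step survives this because harmonics are smooth
deseasonalize_daily <- function(med) {
  ok <- !is.na(med)
  n <- length(med)
  if (sum(ok) < 60) return(med - stats::median(med, na.rm = TRUE))
  t <- (seq_len(n) - 1) / 365.25
  if (sum(ok) >= 300) {
    X <- cbind(1, sin(2 * pi * t), cos(2 * pi * t), sin(4 * pi * t), cos(4 * pi * t))
    fit <- stats::lm.fit(X[ok, , drop = FALSE], med[ok])
    r <- rep(NA_real_, n)
    r[ok] <- fit$residuals
    r
  } else {
    med - stats::median(med, na.rm = TRUE)
  }
}

#' Variability check
#'
#' Operates on daily medians after removing the smooth seasonal cycle:
#' a robust (Theil–Sen) trend over the record, a two-segment mean-shift
#' scan for step changes (adjacent-window medians around every candidate
#' breakpoint), runs of repeated identical non-missing values (filled
#' constants; exact zeros are exempt since they are physically meaningful
#' for e.g. radiation and precipitation), and excess probability mass at an
#' interior extreme (a measurement or processing cut-off).
#'
#' @param table An `fp_table`.
#' @param config [qaqc_config()].
#' @param registry Variable registry.
#' @return List of findings (module `physical_range`, variability
#'   category).
#' @export
variability_check <- function(table, config = qaqc_config(), registry = fp_registry()) {
  cfg <- config$variability
  res <- attr(table, "resolution")
  findings <- list()
  for (v in data_columns(table)) {
    pv <- parse_variable_name(v, registry)
    entry <- registry_lookup(pv$base, registry)
    if (!is.null(entry) && entry$kind == "quality_flag") next
    x <- table[[v]]
    n_ok <- sum(!is.na(x))
    if (n_ok < cfg$n_min) next

    # (c) filled constants
    r <- rle(ifelse(is.na(x), NA_real_, x))
    const_runs <- which(!is.na(r$values) & r$values != 0 & r$lengths >= cfg$run_min)
    if (length(const_runs) > 0) {
      ends <- cumsum(r$lengths)
      k <- const_runs[which.max(r$lengths[const_runs])]
      rows <- (ends[k] - r$lengths[k] + 1):ends[k]
      sp <- span_of(table, rows)
      findings <- c(findings, list(finding(
        module = "physical_range", code = "FILLED_CONSTANT", severity = "WARNING",
        variable = v, span_start = sp$start, span_end = sp$end,
        metrics = list(value = r$values[k], run_length = r$lengths[k],
                       n_runs = length(const_runs)),
        message = sprintf("value %g repeats for %d consecutive intervals: filled constant or stuck sensor",
                          r$values[k], r$lengths[k]))))
    }

    # (d) cut-off: mass piled at an interior extreme
    xs <- x[!is.na(x)]
    for (side in c("max", "min")) {
      ext <- if (side == "max") max(xs) else min(xs)
      if (ext == 0) next
      interior <- is.null(entry) ||
        (if (side == "max") ext < entry$hard_max else ext > entry$hard_min)
      frac <- mean(xs == ext)
      if (interior && frac > cfg$cutoff_frac) {
        findings <- c(findings, list(finding(
          module = "physical_range", code = "CUTOFF", severity = "WARNING",
          variable = v,
          metrics = list(value = ext, frac = frac, side = if (side == "max") 1 else -1),
          message = sprintf("%.1f%% of values sit exactly at %g (%simum): measurement or processing cut-off",
                            100 * frac, ext, side))))
        break
      }
    }

    # (a)/(b) trend and step change on deseasonalized daily medians
    dm <- daily_medians(table, v)
    resid <- deseasonalize_daily(dm$median)
    n_days <- sum(!is.na(resid))
    if (n_days >= 120) {
      t_years <- (seq_along(resid) - 1) / 365.25
      fit <- theil_sen(t_years, resid)
      span_years <- (length(resid) - 1) / 365.25
      spread <- robust_spread(resid)
      if (is.finite(fit$slope) && spread > 0 &&
          abs(fit$slope) * span_years > cfg$trend_tol * spread) {
        findings <- c(findings, list(finding(
          module = "physical_range", code = "TREND", severity = "WARNING",
          variable = v,
          metrics = list(slope_per_year = fit$slope, span_years = span_years,
                         spread = spread),
          message = sprintf("robust trend of %+.3g units/year over %.1f years exceeds the record's variability: drift or site change",
                            fit$slope, span_years))))
      }

      w <- cfg$step_window_days
      nr <- length(resid)
      if (nr >= 2 * w + 10) {
        # screen: adjacent-window median difference locates the candidate
        cand <- (w + 1):(nr - w + 1)
        stat <- vapply(cand, function(b) {
          a <- resid[(b - w):(b - 1)]; z <- resid[b:(b + w - 1)]
          a <- a[!is.na(a)]; z <- z[!is.na(z)]
          if (length(a) < w / 2 || length(z) < w / 2) return(NA_real_)
          abs(stats::median(z) - stats::median(a))
        }, numeric(1))
        if (any(!is.na(stat))) {
          b <- cand[which.max(stat)]
          # confirm: refit the seasonal harmonics jointly with a step dummy
          # at the candidate breakpoint, so the smooth fit cannot absorb an
          # abrupt shift; test the step amplitude against the residual scale
          y <- dm$median
          ok <- !is.na(y)
          tt <- (seq_len(nr) - 1) / 365.25
          X <- cbind(1, sin(2 * pi * tt), cos(2 * pi * tt),
                     sin(4 * pi * tt), cos(4 * pi * tt),
                     step = as.numeric(seq_len(nr) >= b))
          fit2 <- stats::lm.fit(X[ok, , drop = FALSE], y[ok])
          delta_hat <- fit2$coefficients["step"]
          s <- stats::mad(fit2$residuals, na.rm = TRUE)
          if (is.finite(delta_hat) && is.finite(s) && s > 0 &&
              abs(delta_hat) / s > cfg$step_tol) {
            findings <- c(findings, list(finding(
              module = "physical_range", code = "STEP_CHANGE", severity = "WARNING",
              variable = v, span_start = paste0(dm$day[b], "0000"),
              metrics = list(shift = unname(delta_hat),
                             stat = unname(abs(delta_hat) / s), day_index = b),
              message = sprintf("abrupt mean shift of %+.3g units around %s: step change",
                                delta_hat, dm$day[b]))))
          }
        }
      }
    }
  }
  findings
}
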