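#' Default QA/QC thresholds
#'
#' Every numeric threshold used by the format and data checks lives here and
#' is overridable, either programmatically (named nested overrides) or from
#' a YAML file via [load_config()]. Defaults are deliberately conservative:
#' the checks flag for expert review rather than auto-reject.
#'
#' @param ... Named nested overrides, e.g.
#'   `qaqc_config(alignment = list(max_lag = 6))`.
#' @return Nested list of class `qaqc_config`.
#' @export
qaqc_config <- function(...) {
  base <- list(
    alignment = list(
      window_days = 15, step_days = 5, max_lag = 10,
      min_coverage = 0.5, min_windows = 3,
      const_frac = 0.8,   # fraction of windows at the modal lag => constant shift
      plateau_min = 4     # consecutive windows forming a DST plateau
    ),
    radiation = list(
      headroom = 1.05,    # ceiling multiplier on SW_IN_POT
      excess_frac = 0.01, # tolerated fraction of daytime intervals above ceiling
      pot_min = 50,       # W m-2: intervals counted as clear-sky candidates
      asym_tol = 0.10,    # |median am - pm| clearness-ratio asymmetry
      asym_month_frac = 0.67,
      shade_tol = 0.6,    # sector ratio relative to same-month neighbours
      shade_month_frac = 0.5
    ),
    range = list(
      k_mad = 6, outlier_frac = 0.01, n_min = 200,
      percent_max = 1.5, percent_n_min = 100
    ),
    variability = list(
      n_min = 1000, run_min = 48, trend_tol = 1.0,
      step_tol = 4, step_window_days = 30, cutoff_frac = 0.01
    ),
    multivariate = list(
      pairs = list(c("PPFD_IN", "SW_IN"), c("USTAR", "WS"),
                   c("T_SONIC", "TA"), c("NETRAD", "SW_IN")),
      window_days = 15, step_days = 5, min_pts = 200, subsample = 400,
      k_mad = 6, outlier_rate = 0.01, bias_tol = 3,
      r2_perfect = 0.9999, drift_tol = 0.15, slope_step_tol = 0.15
    ),
    diurnal = list(
      min_months = 3, pot_day_min = 50, sign_margin = 2, sign_cor_min = 0.5,
      grow_frac = 0.25, shift_month_frac = 0.67, yoy_tol = 4
    ),
    ustar = list(
      bin_width = 0.05, low_avail = 0.1, high_avail = 0.5,
      ustar_floor = 0.1, n_night_min = 200, bin_n_min = 10
    ),
    coverage = list(gap_tol_days = 60),
    spectra = list(omega0 = 6, dj = 0.25, coverage_min = 0.25)
  )
  overrides <- list(...)
  merge_config(base, overrides)
}

merge_config <- function(base, overrides) {
  for (nm in names(overrides)) {
    if (is.list(overrides[[nm]]) && is.list(base[[nm]]) && nm != "pairs") {
      base[[nm]] <- merge_config(base[[nm]], overrides[[nm]])
    } else {
      base[[nm]] <- overrides[[nm]]
    }
  }
  class(base) <- "qaqc_config"
  base
}

#' Load QA/QC thresholds from a YAML file
#'
#' Values present in the file override the defaults of [qaqc_config()];
#' everything else keeps its default.
#'
#' @param path YAML file of nested threshold overrides.
#' @return `qaqc_config` list.
#' @export
load_config <- function(path) {
  overrides <- yaml::read_yaml(path)
  if (is.null(overrides)) overrides <- list()
  merge_config(qaqc_config(), overrides)
}
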