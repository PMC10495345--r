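# Variable-coverage module and record assembly: long gaps, empty columns,
# missing mandatory variables, label-set mismatches against the previously
# published record, and the combine step that merges a new upload with
# that record.

#' Variable-coverage check
#'
#' Per variable: total coverage and the longest run of missing values
#' (`LONG_GAP` beyond `gap_tol_days`, `EMPTY_COLUMN` at zero coverage).
#' Re-asserts the mandatory-variable rule on the combined record and
#' compares the uploaded label set against the previously published one
#' (`NAMING_MISMATCH` on any symmetric difference — renamed, dropped or
#' newly appearing labels break cross-upload continuity).
#'
#' @param table An `fp_table`.
#' @param prior_labels Character vector of variable labels of the
#'   previously published record, or `NULL`.
#' @param config [qaqc_config()].
#' @param registry Variable registry.
#' @return List of findings (module `variable_coverage`).
#' @export
variable_coverage_check <- function(table, prior_labels = NULL,
                                    config = qaqc_config(), registry = fp_registry()) {
  cfg <- config$coverage
  res <- attr(table, "resolution")
  per_day <- 24 * 60 / res
  findings <- list()
  labels <- data_columns(table)
  for (v in labels) {
    x <- table[[v]]
    if (all(is.na(x))) {
      findings <- c(findings, list(finding(
        module = "variable_coverage", code = "EMPTY_COLUMN", severity = "WARNING",
        variable = v, message = sprintf("column %s contains no data", v))))
      next
    }
    # interior gaps only (between the variable's first and last observation):
    # leading/trailing missing spans reflect the record period, not a gap,
    # and appending fully-missing rows must never change a verdict
    obs <- which(!is.na(x))
    inner <- seq(min(obs), max(obs))
    r <- rle(is.na(x[inner]))
    if (any(r$values)) {
      ends <- cumsum(r$lengths)
      na_runs <- which(r$values)
      k <- na_runs[which.max(r$lengths[na_runs])]
      longest <- r$lengths[k]
      if (longest / per_day > cfg$gap_tol_days) {
        rows <- inner[(ends[k] - longest + 1):ends[k]]
        sp <- span_of(table, rows)
        findings <- c(findings, list(finding(
          module = "variable_coverage", code = "LONG_GAP", severity = "WARNING",
          variable = v, span_start = sp$start, span_end = sp$end,
          metrics = list(gap_days = longest / per_day,
                         coverage = mean(!is.na(x))),
          message = sprintf("%s has a %.0f-day gap (tolerance %d days)",
                            v, longest / per_day, cfg$gap_tol_days))))
      }
    }
  }
  bases <- vapply(labels, function(l) parse_variable_name(l, registry)$base, character(1))
  if (!any(bases %in% c("FC", "FCH4"))) {
    findings <- c(findings, list(finding(
      module = "variable_coverage", code = "MISSING_MANDATORY", severity = "ACTION_REQUIRED",
      message = "combined record has no carbon flux observation (FC or FCH4)")))
  }
  if (!is.null(prior_labels)) {
    gone <- setdiff(prior_labels, labels)
    new <- setdiff(labels, prior_labels)
    if (length(gone) + length(new) > 0) {
      findings <- c(findings, list(finding(
        module = "variable_coverage", code = "NAMING_MISMATCH", severity = "WARNING",
        variable = c(gone, new),
        metrics = list(n_missing = length(gone), n_new = length(new)),
        message = sprintf("variable labels differ from the published record%s%s",
                          if (length(gone)) paste0("; no longer present: ", paste(gone, collapse = ", ")) else "",
                          if (length(new)) paste0("; new: ", paste(new, collapse = ", ")) else ""))))
    }
  }
  findings
}

#' Combine a new upload with the previously published record
#'
#' Union on the time axis (any interior gap between the two periods is
#' filled with missing rows so the result keeps a strictly regular axis);
#' rows whose start timestamp exists in the new upload are taken entirely
#' from it (replacement semantics); the label set is the union, with
#' missing values where a variable is absent from one side.
#'
#' @param new,prior `fp_table`s for the same site at the same resolution;
#'   `prior = NULL` returns `new` unchanged.
#' @return The combined `fp_table`.
#' @export
combine_with_prior <- function(new, prior) {
  if (is.null(prior) || nrow(prior) == 0) return(new)
  if (nrow(new) == 0) return(prior)
  res <- attr(new, "resolution")
  if (res != attr(prior, "resolution")) {
    stop("resolution mismatch between upload and published record", call. = FALSE)
  }
  sid_new <- attr(new, "site_id"); sid_old <- attr(prior, "site_id")
  if (nzchar(sid_new) && nzchar(sid_old) && sid_new != sid_old) {
    stop("site mismatch: ", sid_new, " vs ", sid_old, call. = FALSE)
  }
  t_new <- table_start_times(new)
  t_old <- table_start_times(prior)
  full <- seq_timestamps(min(t_new[1], t_old[1]),
                         max(t_new[length(t_new)], t_old[length(t_old)]), res)
  out <- data.frame(TIMESTAMP_START = format_timestamp(full),
                    TIMESTAMP_END = format_timestamp(full + res * 60),
                    stringsAsFactors = FALSE)
  i_new <- match(as.numeric(full), as.numeric(t_new))
  i_old <- match(as.numeric(full), as.numeric(t_old))
  i_old[!is.na(i_new)] <- NA  # replacement: rows present in `new` win whole
  for (v in union(data_columns(new), data_columns(prior))) {
    col <- rep(NA_real_, length(full))
    if (v %in% names(new)) col[!is.na(i_new)] <- new[[v]][i_new[!is.na(i_new)]]
    if (v %in% names(prior)) col[!is.na(i_old)] <- prior[[v]][i_old[!is.na(i_old)]]
    out[[v]] <- col
  }
  fp_table(out, site_id = if (nzchar(sid_new)) sid_new else sid_old,
           resolution = res,
           site_meta = if (!is.null(attr(new, "site_meta"))) attr(new, "site_meta")
                       else attr(prior, "site_meta"))
}

#' Run the Data QA/QC stage
#'
#' Combines the upload with the previously published record (if any) and
#' executes the six check modules in order — timestamp alignment (with the
#' radiation-measurement checks), physical range (with the variability
#' screens), multivariate comparison, diurnal-seasonal pattern, USTAR
#' filtering, and variable coverage — then assembles the findings into a
#' report. Deterministic given (inputs, config): the same input always
#' yields a byte-identical JSON report.
#'
#' @param table An `fp_table` that has passed Format QA/QC.
#' @param site [site_meta()].
#' @param prior Previously published `fp_table`, or `NULL`.
#' @param config [qaqc_config()].
#' @param registry Variable registry.
#' @param input_digest Optional md5 of the submitted file, for provenance.
#' @return A `qaqc_report` (stage `"DATA"`).
#' @export
run_data_qaqc <- function(table, site, prior = NULL, config = qaqc_config(),
                          registry = fp_registry(), input_digest = NA_character_) {
  combined <- combine_with_prior(table, prior)
  prior_labels <- if (is.null(prior)) NULL else data_columns(prior)
  al <- timestamp_alignment(combined, site, config, registry)
  findings <- c(
    al$findings,
    radiation_issue_check(combined, site, config, registry),
    physical_range_check(combined, registry, NULL, config),
    variability_check(combined, config, registry),
    multivariate_check(combined, NULL, config, registry),
    diurnal_seasonal_check(combined, site, config, registry)$findings,
    ustar_filtering_check(combined, site, config, registry)$findings,
    variable_coverage_check(combined, prior_labels, config, registry))
  assemble_report(findings, stage = "DATA", site_id = site$site_id,
                  config = config, input_digest = input_digest,
                  checks = c("timestamp_alignment", "physical_range", "multivariate",
                             "diurnal_seasonal", "ustar_filtering", "variable_coverage"))
}
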