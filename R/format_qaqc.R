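#' Structural format checks
#'
#' Flags non-monotonic start timestamps, rows where `end - start` differs
#' from the record resolution, skipped intervals (each gap reported with its
#' span), and duplicated start timestamps. Read-level diagnostics (wrong
#' delimiter, unparseable cells/timestamps) are passed through.
#'
#' @param table An `fp_table` as returned by [read_fp_file()] (possibly
#'   violating time-axis invariants).
#' @param diagnostics Parse diagnostics from [read_fp_file()].
#' @return List of findings.
#' @export
check_structure <- function(table, diagnostics = list()) {
  findings <- diagnostics
  res <- attr(table, "resolution")
  ts <- parse_timestamp(table$TIMESTAMP_START, strict = FALSE)
  te <- parse_timestamp(table$TIMESTAMP_END, strict = FALSE)
  ok <- !is.na(ts) & !is.na(te)

  bad_len <- which(ok & as.numeric(te - ts, units = "mins") != res)
  if (length(bad_len) > 0) {
    findings <- c(findings, list(finding(
      module = "format_qaqc", code = "BAD_TIMESTAMP_FORMAT", severity = "ACTION_REQUIRED",
      message = sprintf("%d row(s) where TIMESTAMP_END - TIMESTAMP_START != %d min (first at row %d)",
                        length(bad_len), res, bad_len[1]),
      metrics = list(rows = bad_len), fixable = FALSE)))
  }

  tsn <- as.numeric(ts[ok])
  dup <- which(duplicated(tsn))
  if (length(dup) > 0) {
    findings <- c(findings, list(finding(
      module = "format_qaqc", code = "DUPLICATE_ROWS", severity = "ACTION_REQUIRED",
      message = sprintf("%d duplicated start timestamp(s); cannot choose between rows automatically",
                        length(dup)),
      metrics = list(n_duplicates = length(dup)), fixable = FALSE)))
  }
  if (any(diff(tsn) < 0)) {
    findings <- c(findings, list(finding(
      module = "format_qaqc", code = "NONMONOTONIC_TIME", severity = "ACTION_REQUIRED",
      message = "start timestamps are not monotonically increasing",
      fixable = FALSE)))
  } else {
    # gaps: only meaningful on a sorted axis
    steps <- diff(tsn) / 60
    gap_at <- which(steps > res)
    for (g in gap_at) {
      n_skip <- steps[g] / res - 1
      findings <- c(findings, list(finding(
        module = "format_qaqc", code = "SKIPPED_INTERVALS", severity = "WARNING",
        span_start = format_timestamp(ts[ok][g] + res * 60),
        span_end = format_timestamp(ts[ok][g + 1]),
        metrics = list(n_intervals = n_skip),
        message = sprintf("%g skipped interval(s) before %s", n_skip,
                          format_timestamp(ts[ok][g + 1])),
        fixable = TRUE)))
    }
  }
  findings
}

#' Variable-name format checks
#'
#' Requires the paired timestamps plus at least one carbon flux observation
#' (`FC` or `FCH4` base). Labels failing the naming grammar, or matching a
#' registry base only after case-folding, yield `BAD_VARIABLE_NAME`
#' (fixable when the corrected label is unambiguous).
#'
#' @param table An `fp_table`.
#' @param registry Variable registry.
#' @return List of findings.
#' @export
check_variables <- function(table, registry = fp_registry()) {
  findings <- list()
  labels <- data_columns(table)
  bases <- vapply(labels, function(l) parse_variable_name(l, registry)$base, character(1))
  if (!any(bases %in% c("FC", "FCH4"))) {
    findings <- c(findings, list(finding(
      module = "format_qaqc", code = "MISSING_MANDATORY", severity = "ACTION_REQUIRED",
      message = "no carbon flux observation present (need at least one FC or FCH4 variable)",
      fixable = FALSE)))
  }
  for (l in labels) {
    pv <- parse_variable_name(l, registry)
    if (pv$known && length(pv$warnings) == 0) next
    # case-fold repair: unique registry base match after upper-casing
    fixed_label <- toupper(l)
    pv_up <- parse_variable_name(fixed_label, registry)
    fixable <- !identical(fixed_label, l) && pv_up$known && length(pv_up$warnings) == 0 &&
      !(fixed_label %in% labels)
    findings <- c(findings, list(finding(
      module = "format_qaqc", code = "BAD_VARIABLE_NAME", severity = "WARNING",
      variable = l,
      message = if (fixable) sprintf("label '%s' matches registry as '%s'", l, fixed_label)
                else sprintf("label '%s': %s", l, paste(pv$warnings, collapse = "; ")),
      metrics = if (fixable) list() else list(),
      fixable = fixable)))
  }
  findings
}

#' One automatic correction pass
#'
#' Applies, exactly once, the fully-automatic fixes: inserting `-9999` rows
#' for skipped intervals, unambiguous case-fold renames of variable labels,
#' and delimiter normalization (the corrected table always serializes as
#' CSV). Data values present in the input are never altered; unfixable
#' findings stay unfixed. Idempotent: correcting a corrected table changes
#' nothing.
#'
#' @param table An `fp_table`.
#' @param findings Findings from [check_structure()] / [check_variables()].
#' @param registry Variable registry.
#' @return List with `table` (corrected) and `findings` (fix status updated).
#' @export
autocorrect <- function(table, findings, registry = fp_registry()) {
  res <- attr(table, "resolution")
  for (i in seq_along(findings)) {
    f <- findings[[i]]
    if (!f$fixable || f$fixed) next
    if (f$code == "SKIPPED_INTERVALS") {
      table <- fill_time_axis(table)
      f$fixed <- TRUE
    } else if (f$code == "BAD_VARIABLE_NAME") {
      up <- toupper(f$variable)
      if (f$variable %in% names(table) && !(up %in% names(table))) {
        names(table)[names(table) == f$variable] <- up
        f$fixed <- TRUE
      }
    } else if (f$code %in% c("WRONG_DELIMITER", "NON_NUMERIC_CELL", "BAD_FILENAME")) {
      # already normalized at read (delimiter, cells mapped to missing);
      # the corrected output is canonical CSV
      f$fixed <- TRUE
    }
    findings[[i]] <- f
  }
  list(table = table, findings = findings)
}

# Insert fully-missing rows so the start axis is strictly regular.
fill_time_axis <- function(table) {
  res <- attr(table, "resolution")
  ts <- parse_timestamp(table$TIMESTAMP_START, strict = FALSE)
  keep <- !is.na(ts)
  full <- seq_timestamps(min(ts[keep]), max(ts[keep]), res)
  idx <- match(as.numeric(full), as.numeric(ts))
  out <- data.frame(TIMESTAMP_START = format_timestamp(full),
                    TIMESTAMP_END = format_timestamp(full + res * 60),
                    stringsAsFactors = FALSE)
  for (v in data_columns(table)) out[[v]] <- table[[v]][idx]
  # rows that existed keep their END verbatim (they may carry the diagnosed
  # end-timestamp defects; only inserted rows are synthesized)
  have <- !is.na(idx)
  out$TIMESTAMP_END[have] <- table$TIMESTAMP_END[idx[have]]
  fp_table(out, site_id = attr(table, "site_id"), resolution = res,
           site_meta = attr(table, "site_meta"), validate = FALSE)
}

#' Run the Format QA/QC stage
#'
#' Read, check, attempt one automatic correction pass, re-check, and report.
#' Overall status: `PASS` (no findings), `FIXED` (every finding fixed), or
#' `FAIL` (at least one unfixed finding).
#'
#' @param input Path to an FP-In file, or an `fp_table` directly.
#' @param site Optional [site_meta()]; used for the site id and embedded in
#'   the report.
#' @param config [qaqc_config()] thresholds.
#' @param registry Variable registry.
#' @return A `qaqc_report` (stage `"FORMAT"`) whose `$table` element holds
#'   the corrected table when status is `PASS` or `FIXED`.
#' @export
run_format_qaqc <- function(input, site = NULL, config = qaqc_config(),
                            registry = fp_registry()) {
  site_id <- if (!is.null(site)) site$site_id else ""
  digest <- NA_character_
  if (is.character(input)) {
    parsed <- tryCatch(read_fp_file(input, site_id = site_id), error = function(e) e)
    if (inherits(parsed, "error")) {
      fatal <- finding(module = "format_qaqc", code = "UNREADABLE_FILE",
                       severity = "ACTION_REQUIRED", message = conditionMessage(parsed))
      rep <- assemble_report(list(fatal), stage = "FORMAT", site_id = site_id,
                             config = config, input_digest = digest)
      rep$status <- "FAIL"
      return(rep)
    }
    digest <- unname(tools::md5sum(input))
    table <- parsed$table
    diagnostics <- parsed$diagnostics
    fname <- basename(input)
    if (!grepl("^[A-Za-z]{2}-[A-Za-z0-9]{3}_(HH|HR)_[0-9]{12}_[0-9]{12}\\.csv$", fname)) {
      # non-fatal: the pipeline names the corrected output canonically
      diagnostics <- c(diagnostics, list(finding(
        module = "format_qaqc", code = "BAD_FILENAME", severity = "WARNING",
        message = sprintf("filename '%s' does not follow SITEID_RES_START_END.csv", fname),
        fixable = TRUE)))
    }
  } else {
    table <- input
    diagnostics <- list()
  }
  findings <- c(check_structure(table, diagnostics), check_variables(table, registry))
  corrected <- autocorrect(table, findings, registry)
  findings <- corrected$findings
  table <- corrected$table

  fixed_flags <- vapply(findings, `[[`, logical(1), "fixed")
  status <- if (length(findings) == 0) "PASS" else if (all(fixed_flags)) "FIXED" else "FAIL"
  rep <- assemble_report(findings, stage = "FORMAT", site_id = site_id,
                         config = config, input_digest = digest)
  rep$status <- status
  if (status %in% c("PASS", "FIXED")) rep$table <- table
  rep
}
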