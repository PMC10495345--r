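.check_names <- c("format_qaqc", "fp_format", "timestamp_alignment",
                  "physical_range", "multivariate", "diurnal_seasonal",
                  "ustar_filtering", "variable_coverage")

#' Assemble findings into a QA/QC report
#'
#' Groups findings by check module, orders them by severity (most severe
#' first) then by time span, derives one status per check
#' (`PASS < SKIPPED < WARNING < ACTION_REQUIRED`) and the overall status as
#' the maximum across checks. Skipped checks stay visible with their reason.
#' The report embeds the configuration snapshot, tool version and input
#' digest so a published record's provenance is reconstructible.
#'
#' @param findings List of [finding()] objects from one pipeline stage.
#' @param stage `"FORMAT"` or `"DATA"`.
#' @param site_id Site identifier.
#' @param config The [qaqc_config()] used.
#' @param input_digest md5 of the input file (or `NA`).
#' @param checks Character vector of the checks that ran (each is reported
#'   even when it produced no findings); defaults to the modules present.
#' @return Object of class `qaqc_report`.
#' @export
assemble_report <- function(findings, stage, site_id = "", config = qaqc_config(),
                            input_digest = NA_character_, checks = NULL) {
  stopifnot(stage %in% c("FORMAT", "DATA"))
  mods <- vapply(findings, `[[`, character(1), "module")
  if (is.null(checks)) checks <- intersect(.check_names, unique(mods))
  if (length(findings) > 0) {
    sev <- vapply(findings, `[[`, character(1), "severity")
    spans <- vapply(findings, function(f) ifelse(is.na(f$span_start), "", f$span_start),
                    character(1))
    ord <- order(-match(sev, .severity_levels), spans,
                 vapply(findings, `[[`, character(1), "code"))
    findings <- findings[ord]
    mods <- mods[ord]
  }
  check_status <- setNames(vapply(checks, function(ck) {
    max_severity(vapply(findings[mods == ck], `[[`, character(1), "severity"))
  }, character(1)), checks)
  overall <- max_severity(unname(check_status))
  structure(list(
    site_id = site_id, stage = stage,
    overall = overall, check_status = as.list(check_status),
    findings = findings,
    config = unclass(config),
    tool_version = as.character(utils::packageVersion("fluxqaqc")),
    input_digest = input_digest), class = "qaqc_report")
}

#' Serialize a report to canonical JSON
#'
#' JSON is the canonical report form; the text rendering is derived from
#' it. Serialization is deterministic (stable ordering, no wall-clock
#' content) and lossless: `report_to_json(report_from_json(x)) == x`.
#'
#' @param report A `qaqc_report`.
#' @return A JSON string.
#' @export
report_to_json <- function(report) {
  obj <- unclass(report)
  obj$findings <- lapply(obj$findings, function(f) {
    f <- unclass(f)
    f$metrics <- lapply(f$metrics, function(m) I(unlist(m)))
    f
  })
  obj$table <- NULL  # in-memory convenience only; never serialized
  as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                                na = "null", pretty = TRUE))
}

#' Parse a report back from JSON
#' @param json JSON string produced by [report_to_json()].
#' @return A `qaqc_report`.
#' @export
report_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  obj$findings <- lapply(obj$findings, function(f) {
    f$metrics <- lapply(f$metrics, function(m) unlist(m))
    f$variable <- if (is.null(f$variable)) NA_character_ else unlist(f$variable)
    f$span_start <- if (is.null(f$span_start)) NA_character_ else f$span_start
    f$span_end <- if (is.null(f$span_end)) NA_character_ else f$span_end
    structure(f, class = "qaqc_finding")
  })
  obj$input_digest <- if (is.null(obj$input_digest)) NA_character_ else obj$input_digest
  obj$config <- canonicalize_json_list(obj$config)
  structure(obj, class = "qaqc_report")
}

# collapse unnamed lists of scalars back to atomic vectors so that
# object -> JSON -> object -> JSON is byte-stable
canonicalize_json_list <- function(x) {
  if (!is.list(x)) return(x)
  x <- lapply(x, canonicalize_json_list)
  if (is.null(names(x)) && length(x) > 1 &&
      all(vapply(x, function(e) is.atomic(e) && length(e) == 1, logical(1)))) {
    return(unlist(x))
  }
  x
}

#' Render a report as plain text
#'
#' Deterministic, stable ordering: a header, one summary line per check,
#' then one block per finding with span (`YYYYMMDDHHMM`–`YYYYMMDDHHMM`),
#' metric values and a suggested action phrase.
#'
#' @param report A `qaqc_report`.
#' @return Character vector of lines.
#' @export
render_text <- function(report) {
  lines <- c(
    sprintf("%s QA/QC report — site %s", report$stage, report$site_id),
    sprintf("overall status: %s",
            if (!is.null(report$status)) report$status else report$overall),
    sprintf("tool version: %s", report$tool_version),
    "",
    "per-check status:")
  for (ck in names(report$check_status)) {
    lines <- c(lines, sprintf("  %-20s %s", ck, report$check_status[[ck]]))
  }
  lines <- c(lines, "", sprintf("findings (%d):", length(report$findings)))
  if (length(report$findings) == 0) {
    lines <- c(lines, "  none — no action needed")
  } else {
    for (f in report$findings) {
      lines <- c(lines, format_finding(f), paste0("    action: ", action_phrase(f)))
    }
  }
  lines
}

action_phrase <- function(f) {
  switch(f$severity,
         ACTION_REQUIRED = "correct at the site/processing level and resubmit",
         WARNING = "review; explain or correct if the pattern is unintended",
         SKIPPED = "no action; check could not run on this submission",
         "none")
}

#' @export
print.qaqc_report <- function(x, ...) {
  cat(render_text(x), sep = "\n")
  invisible(x)
}

#' Write a report to disk
#' @param report A `qaqc_report`.
#' @param path Output path; `.json` writes canonical JSON, anything else the
#'   text rendering.
#' @return `path` invisibly.
#' @export
write_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    writeLines(report_to_json(report), path, useBytes = TRUE)
  } else {
    writeLines(render_text(report), path, useBytes = TRUE)
  }
  invisible(path)
}
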