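.severity_levels <- c("PASS", "SKIPPED", "WARNING", "ACTION_REQUIRED")

#' Create a QA/QC finding
#'
#' One detected issue: the emitting module/check, an issue code from the
#' issue taxonomy, a severity, the affected variable(s), the time span, any
#' numeric evidence, and a human-readable message. `SKIPPED` findings record
#' that a check could not run (missing inputs) — neither a pass nor a fail.
#'
#' @param module Emitting module (e.g. `"timestamp_alignment"`).
#' @param code Issue code (e.g. `"TIMESTAMP_SHIFT"`, `"PERCENT_AS_RATIO"`).
#' @param severity One of `SKIPPED`, `WARNING`, `ACTION_REQUIRED`.
#' @param variable Affected variable label(s), or `NA`.
#' @param span_start,span_end Affected time span as `YYYYMMDDHHMM` strings,
#'   or `NA` for whole-record findings.
#' @param metrics Named list of numeric evidence (lags, fractions, slopes...).
#' @param message Human-readable description.
#' @param fixable,fixed Format-stage autocorrection bookkeeping
#'   (`fixed` implies `fixable`).
#' @return Object of class `qaqc_finding`.
#' @export
finding <- function(module, code, severity = "WARNING", variable = NA_character_,
                    span_start = NA_character_, span_end = NA_character_,
                    metrics = list(), message = "", fixable = FALSE, fixed = FALSE) {
  stopifnot(severity %in% .severity_levels[-1])
  if (fixed && !fixable) stop("fixed implies fixable", call. = FALSE)
  structure(list(module = module, code = code, severity = severity,
                 variable = variable, span_start = span_start, span_end = span_end,
                 metrics = metrics, message = message,
                 fixable = fixable, fixed = fixed),
            class = "qaqc_finding")
}

#' @export
print.qaqc_finding <- function(x, ...) {
  cat(format_finding(x), sep = "\n")
  invisible(x)
}

format_finding <- function(f) {
  span <- if (!is.na(f$span_start)) sprintf(" %s–%s", f$span_start,
                                            ifelse(is.na(f$span_end), "", f$span_end)) else ""
  var <- if (all(is.na(f$variable))) "" else paste0(" [", paste(f$variable, collapse = ","), "]")
  met <- if (length(f$metrics)) {
    paste0("    metrics: ", paste(sprintf("%s=%s", names(f$metrics),
      vapply(f$metrics, function(m) paste(signif(unlist(m), 6), collapse = "/"),
             character(1))), collapse = ", "))
  } else NULL
  c(sprintf("  - %s/%s (%s)%s%s: %s%s", f$module, f$code, f$severity, var, span,
            f$message,
            if (isTRUE(f$fixed)) " [autocorrected]" else if (isTRUE(f$fixable)) " [fixable]" else ""),
    met)
}

# utilities over lists of findings
finding_codes <- function(findings) vapply(findings, `[[`, character(1), "code")
findings_with_code <- function(findings, code) {
  findings[finding_codes(findings) %in% code]
}
max_severity <- function(severities) {
  if (length(severities) == 0) return("PASS")
  .severity_levels[max(match(severities, .severity_levels))]
}

#' Index a run of rows as a timestamp span
#' @noRd
span_of <- function(table, rows) {
  list(start = table$TIMESTAMP_START[min(rows)], end = table$TIMESTAMP_END[max(rows)])
}
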