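#' Construct an FP table
#'
#' The central container: a regular time-series table of flux-met variables
#' with paired start/end timestamps. Internally missing values are `NA`;
#' the `-9999` sentinel exists only in serialized files.
#'
#' @param data data.frame with character columns `TIMESTAMP_START`,
#'   `TIMESTAMP_END` and numeric data columns.
#' @param site_id Site identifier (e.g. `"US-xyz"`).
#' @param resolution Timestep in minutes (30 or 60); inferred when `NULL`.
#' @param site_meta Optional site metadata list (see [site_meta()]).
#' @param validate Check invariants (regular strictly-increasing time axis,
#'   `end - start == resolution` on every row).
#' @return Object of class `fp_table` (a data.frame with attributes
#'   `site_id`, `resolution`, `site_meta`).
#' @export
fp_table <- function(data, site_id = "", resolution = NULL, site_meta = NULL,
                     validate = TRUE) {
  stopifnot(is.data.frame(data))
  if (!all(c("TIMESTAMP_START", "TIMESTAMP_END") %in% names(data))) {
    stop("fp_table needs TIMESTAMP_START and TIMESTAMP_END columns", call. = FALSE)
  }
  data$TIMESTAMP_START <- as.character(data$TIMESTAMP_START)
  data$TIMESTAMP_END <- as.character(data$TIMESTAMP_END)
  if (is.null(resolution)) resolution <- infer_resolution(data$TIMESTAMP_START)
  out <- structure(data, class = c("fp_table", "data.frame"),
                   site_id = site_id, resolution = resolution, site_meta = site_meta)
  if (validate) validate_fp_table(out)
  out
}

#' Validate FP table invariants
#'
#' @param table An `fp_table`.
#' @return `TRUE` invisibly; stops on violation.
#' @export
validate_fp_table <- function(table) {
  res <- attr(table, "resolution")
  if (!res %in% c(30, 60)) stop("resolution must be 30 or 60 minutes", call. = FALSE)
  ts <- parse_timestamp(table$TIMESTAMP_START)
  te <- parse_timestamp(table$TIMESTAMP_END)
  if (any(as.numeric(te - ts, units = "mins") != res)) {
    stop("end - start != resolution on some rows", call. = FALSE)
  }
  if (nrow(table) > 1) {
    steps <- diff(as.numeric(ts)) / 60
    if (any(steps != res)) {
      stop("start timestamps are not strictly regular at the stated resolution",
           call. = FALSE)
    }
  }
  for (v in data_columns(table)) {
    if (!is.numeric(table[[v]])) stop("column ", v, " is not numeric", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.fp_table <- function(x, ...) {
  cat(sprintf("<fp_table> site=%s  %d rows x %d variables  %d-min  %s..%s\n",
              attr(x, "site_id"), nrow(x), length(data_columns(x)),
              attr(x, "resolution"),
              if (nrow(x)) x$TIMESTAMP_START[1] else "-",
              if (nrow(x)) x$TIMESTAMP_END[nrow(x)] else "-"))
  invisible(x)
}

#' Data column labels of an FP table
#' @param table An `fp_table` (or data.frame with timestamp columns).
#' @return Character vector of non-timestamp column labels.
#' @export
data_columns <- function(table) {
  setdiff(names(table), c("TIMESTAMP_START", "TIMESTAMP_END"))
}

# POSIXct start times / interval midpoints
table_start_times <- function(table) parse_timestamp(table$TIMESTAMP_START, strict = FALSE)
table_mid_times <- function(table) {
  table_start_times(table) + attr(table, "resolution") * 60 / 2
}

#' Site metadata record
#'
#' @param site_id Site identifier.
#' @param lat_deg Latitude, decimal degrees (positive north), `|lat| <= 90`.
#' @param lon_deg Longitude, decimal degrees (positive east), `|lon| <= 180`.
#' @param utc_offset_hours Offset of local standard time from UTC, in
#'   `[-12, 14]`.
#' @param igbp Optional IGBP ecosystem class code.
#' @return List of class `site_meta`.
#' @export
site_meta <- function(site_id, lat_deg, lon_deg, utc_offset_hours, igbp = NA_character_) {
  if (abs(lat_deg) > 90) stop("|lat_deg| must be <= 90", call. = FALSE)
  if (abs(lon_deg) > 180) stop("|lon_deg| must be <= 180", call. = FALSE)
  if (utc_offset_hours < -12 || utc_offset_hours > 14) {
    stop("utc_offset_hours must be in [-12, 14]", call. = FALSE)
  }
  structure(list(site_id = site_id, lat_deg = lat_deg, lon_deg = lon_deg,
                 utc_offset_hours = utc_offset_hours, igbp = igbp),
            class = "site_meta")
}

#' Read site metadata from JSON
#' @param path Path to a JSON file with fields `site_id`, `lat_deg`,
#'   `lon_deg`, `utc_offset_hours` and optional `igbp`.
#' @return A [site_meta()] object.
#' @export
read_site_meta <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  site_meta(j$site_id, j$lat_deg, j$lon_deg, j$utc_offset_hours,
            if (is.null(j$igbp)) NA_character_ else j$igbp)
}

#' Read an FP-In flux-met file
#'
#' Comma-delimited, header of variable labels in the first row, one row per
#' half-hour/hour. The `-9999` sentinel (numerically matched, so `-9999.0`
#' variants too) maps to missing. Nothing is silently dropped: every
#' non-conforming cell or row yields a diagnostic finding carrying its
#' location.
#'
#' @param path Path to the file.
#' @param site_id Site identifier attached to the returned table.
#' @return List with elements `table` (an `fp_table`, unvalidated — the raw
#'   parse may violate time-axis invariants, which the structure check
#'   reports) and `diagnostics` (list of findings).
#' @export
read_fp_file <- function(path, site_id = "") {
  diagnostics <- list()
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0) stop("file is empty: ", path, call. = FALSE)
  # delimiter sniffing on the header line
  counts <- c("," = lengths(regmatches(first, gregexpr(",", first, fixed = TRUE))),
              ";" = lengths(regmatches(first, gregexpr(";", first, fixed = TRUE))),
              "\t" = lengths(regmatches(first, gregexpr("\t", first, fixed = TRUE))))
  sep <- ","
  if (counts[","] == 0 && any(counts > 0)) {
    sep <- names(counts)[which.max(counts)]
    diagnostics <- c(diagnostics, list(finding(
      module = "fp_format", code = "WRONG_DELIMITER", severity = "WARNING",
      message = sprintf("file is delimited by '%s', not ','",
                        ifelse(sep == "\t", "\\t", sep)),
      fixable = TRUE)))
  }
  raw <- utils::read.csv(path, sep = sep, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  ts_cols <- intersect(c("TIMESTAMP_START", "TIMESTAMP_END"), names(raw))
  if (length(ts_cols) < 2) {
    diagnostics <- c(diagnostics, list(finding(
      module = "fp_format", code = "MISSING_MANDATORY", severity = "ACTION_REQUIRED",
      message = paste("missing timestamp column(s):",
                      paste(setdiff(c("TIMESTAMP_START", "TIMESTAMP_END"), ts_cols),
                            collapse = ", ")),
      fixable = FALSE)))
  }
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (nm in names(raw)) {
    col <- raw[[nm]]
    if (nm %in% c("TIMESTAMP_START", "TIMESTAMP_END")) {
      out[[nm]] <- col
      t <- parse_timestamp(col, strict = FALSE)
      bad_rows <- which(is.na(t))
      if (length(bad_rows) > 0) {
        diagnostics <- c(diagnostics, list(finding(
          module = "fp_format", code = "BAD_TIMESTAMP_FORMAT", severity = "ACTION_REQUIRED",
          variable = nm,
          message = sprintf("%d unparseable timestamp(s) in %s (first at row %d: '%s')",
                            length(bad_rows), nm, bad_rows[1], col[bad_rows[1]]),
          metrics = list(rows = bad_rows), fixable = FALSE)))
      }
    } else {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col) & nzchar(col))
      if (length(bad) > 0) {
        diagnostics <- c(diagnostics, list(finding(
          module = "fp_format", code = "NON_NUMERIC_CELL", severity = "WARNING",
          variable = nm,
          message = sprintf("%d non-numeric cell(s) in %s (first at row %d: '%s') mapped to missing",
                            length(bad), nm, bad[1], col[bad[1]]),
          metrics = list(rows = bad), fixable = TRUE)))
      }
      num[!is.na(num) & num == -9999] <- NA_real_
      out[[nm]] <- num
    }
  }
  res <- tryCatch(infer_resolution(out$TIMESTAMP_START), error = function(e) 30)
  table <- structure(out, class = c("fp_table", "data.frame"),
                     site_id = site_id, resolution = res, site_meta = NULL)
  list(table = table, diagnostics = diagnostics)
}

# Serialize one numeric column: NA -> "-9999"; otherwise shortest exact
# decimal via %.17g (never scientific for magnitudes in [1e-3, 1e6)).
.fmt_num <- function(x) {
  s <- vapply(x, function(v) {
    if (is.na(v)) return("-9999")
    out <- sprintf("%.17g", v)
    if (as.numeric(sprintf("%.15g", v)) == v) out <- sprintf("%.15g", v)
    out
  }, character(1))
  s
}

#' Write an FP-In flux-met file
#'
#' Comma-delimited, header of labels, `YYYYMMDDHHMM` timestamps, missing
#' values written exactly as `-9999`, no quoting, newline-terminated rows.
#' Refuses to write a table that violates the FP table invariants.
#'
#' @param table A valid `fp_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fp_file <- function(table, path) {
  validate_fp_table(table)
  cols <- c("TIMESTAMP_START", "TIMESTAMP_END", data_columns(table))
  mat <- cbind(table$TIMESTAMP_START, table$TIMESTAMP_END)
  for (v in data_columns(table)) mat <- cbind(mat, .fmt_num(table[[v]]))
  lines <- c(paste(cols, collapse = ","),
             apply(mat, 1, paste, collapse = ","))
  con <- file(path, open = "wb")  # byte-stable: LF endings on every platform
  on.exit(close(con))
  writeLines(lines, con = con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
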