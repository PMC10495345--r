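#' Parse FP-In timestamps
#'
#' FP-In timestamps are 12-digit `YYYYMMDDHHMM` strings in local standard
#' time (no daylight-saving transitions are ever encoded; the UTC offset
#' lives in the site metadata, not in the file).
#'
#' @param x Character vector of 12-digit timestamp strings.
#' @param strict If `TRUE` (default) any malformed or impossible timestamp
#'   raises an error; if `FALSE` such entries become `NA` and the offending
#'   tokens are attached as attribute `"bad"`.
#' @return A `POSIXct` vector (tz `"UTC"`, standing in for local standard
#'   time). Inverse of [format_timestamp()].
#' @examples
#' parse_timestamp("202001011130")
#' format_timestamp(parse_timestamp("202001011130"))
#' @export
parse_timestamp <- function(x, strict = TRUE) {
  x <- as.character(x)
  well_formed <- !is.na(x) & grepl("^[0-9]{12}$", x)
  out <- rep(as.POSIXct(NA, tz = "UTC"), length(x))
  if (any(well_formed)) {
    parsed <- as.POSIXct(strptime(x[well_formed], "%Y%m%d%H%M", tz = "UTC"))
    # strptime normalizes some impossible instants; a round trip catches them
    ok <- !is.na(parsed) & format(parsed, "%Y%m%d%H%M", tz = "UTC") == x[well_formed]
    parsed[!ok] <- NA
    out[well_formed] <- parsed
  }
  bad <- x[is.na(out) & !is.na(x)]
  if (strict && length(bad) > 0) {
    stop("invalid FP-In timestamp(s): ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  attr(out, "bad") <- bad
  out
}

#' Format instants as FP-In timestamps
#'
#' @param t `POSIXct` vector (interpreted in UTC/local standard time).
#' @return Character vector of `YYYYMMDDHHMM` strings.
#' @export
format_timestamp <- function(t) {
  format(t, "%Y%m%d%H%M", tz = "UTC")
}

#' Infer the record resolution from start timestamps
#'
#' The resolution is the modal step between consecutive start timestamps and
#' must be 30 or 60 minutes. Larger gaps (missing rows) do not change the
#' inferred resolution; they are reported by the structure check instead.
#'
#' @param start Character vector of `YYYYMMDDHHMM` start timestamps (>= 2).
#' @return 30 or 60 (minutes).
#' @export
infer_resolution <- function(start) {
  if (length(start) < 2) stop("need at least 2 timestamps to infer resolution", call. = FALSE)
  t <- parse_timestamp(start, strict = FALSE)
  steps <- diff(as.numeric(t)) / 60
  steps <- steps[!is.na(steps)]
  if (length(steps) == 0) stop("no parseable timestamp steps", call. = FALSE)
  tab <- sort(table(steps), decreasing = TRUE)
  modal <- as.numeric(names(tab)[1])
  if (!modal %in% c(30, 60)) {
    stop("unsupported resolution: modal step is ", modal, " minutes (expected 30 or 60)",
         call. = FALSE)
  }
  modal
}

# Regular sequence of start timestamps covering [from, to] at `res` minutes.
seq_timestamps <- function(from, to, res) {
  seq(from, to, by = paste(res, "min"))
}
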