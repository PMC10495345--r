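# Independent oracles and fixture builders used across the suite.

# NOAA solar-position oracle (General Solar Position Calculations, NOAA
# Global Monitoring Division spreadsheet equations). Independent of the
# package's Spencer-series implementation: Julian-century polynomial
# ephemeris for the sun's geometric longitude/anomaly, apparent longitude,
# corrected obliquity, and the exact equation-of-time expression.
noaa_zenith_deg <- function(lat_deg, lon_deg, tz_hours, time_local) {
  rad <- pi / 180
  jd <- as.numeric(time_local) / 86400 + 2440587.5 - tz_hours / 24
  jc <- (jd - 2451545) / 36525
  gmls <- (280.46646 + jc * (36000.76983 + jc * 0.0003032)) %% 360
  gmas <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  eeo <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  seqc <- sin(rad * gmas) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(rad * 2 * gmas) * (0.019993 - 0.000101 * jc) +
    sin(rad * 3 * gmas) * 0.000289
  stl <- gmls + seqc
  sal <- stl - 0.00569 - 0.00478 * sin(rad * (125.04 - 1934.136 * jc))
  moe <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
  oc <- moe + 0.00256 * cos(rad * (125.04 - 1934.136 * jc))
  decl <- asin(sin(rad * oc) * sin(rad * sal))
  vary <- tan(rad * oc / 2)^2
  eqtime <- 4 / rad * (vary * sin(2 * rad * gmls) - 2 * eeo * sin(rad * gmas) +
                         4 * eeo * vary * sin(rad * gmas) * cos(2 * rad * gmls) -
                         0.5 * vary^2 * sin(4 * rad * gmls) -
                         1.25 * eeo^2 * sin(2 * rad * gmas))
  lt <- as.POSIXlt(time_local, tz = "UTC")
  mins <- lt$hour * 60 + lt$min + lt$sec / 60
  tst <- (mins + eqtime + 4 * lon_deg - 60 * tz_hours) %% 1440
  ha <- ifelse(tst / 4 < 0, tst / 4 + 180, tst / 4 - 180)
  cosz <- sin(rad * lat_deg) * sin(decl) + cos(rad * lat_deg) * cos(decl) * cos(rad * ha)
  acos(pmin(1, pmax(-1, cosz))) / rad
}

# small valid half-hourly fp_table starting at a given timestamp
tiny_table <- function(n = 6, vars = list(FC = NULL), start = "202006010000",
                       resolution = 30) {
  t0 <- parse_timestamp(start)
  starts <- seq(t0, by = paste(resolution, "min"), length.out = n)
  df <- data.frame(TIMESTAMP_START = format_timestamp(starts),
                   TIMESTAMP_END = format_timestamp(starts + resolution * 60),
                   stringsAsFactors = FALSE)
  for (v in names(vars)) {
    df[[v]] <- if (is.null(vars[[v]])) round(stats::rnorm(n, 1, 2), 3) else vars[[v]]
  }
  fp_table(df, site_id = "US-Tst", resolution = resolution)
}

# random valid fp_table for fuzzing the reader/writer round trip
random_table <- function(seed) {
  set.seed(seed)
  n <- sample(10:60, 1)
  res <- sample(c(30, 60), 1)
  vars <- sample(c("FC", "TA", "SW_IN", "RH", "LE", "USTAR", "SWC_1_1_1"),
                 sample(2:5, 1))
  t0 <- as.POSIXct("2019-01-01", tz = "UTC") + sample(0:300, 1) * 86400
  df <- data.frame(TIMESTAMP_START = format_timestamp(seq(t0, by = paste(res, "min"), length.out = n)),
                   TIMESTAMP_END = format_timestamp(seq(t0 + res * 60, by = paste(res, "min"), length.out = n)),
                   stringsAsFactors = FALSE)
  for (v in vars) {
    x <- stats::rnorm(n, 10, 100)
    x[stats::runif(n) < 0.15] <- NA
    df[[v]] <- x
  }
  fp_table(df, site_id = "US-Fuz", resolution = res)
}

expect_equal_fp <- function(a, b) {
  expect_identical(names(a), names(b))
  expect_identical(a$TIMESTAMP_START, b$TIMESTAMP_START)
  expect_identical(a$TIMESTAMP_END, b$TIMESTAMP_END)
  for (v in data_columns(a)) expect_identical(a[[v]], b[[v]], info = v)
}

test_site <- function() site_meta("US-Tst", 40, -105, -7)
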