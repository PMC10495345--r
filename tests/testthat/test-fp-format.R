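# FP-In parsing, variable-label grammar, registry, reader/writer.

test_that("timestamps parse, reject impossible instants, and round-trip", {
  t <- parse_timestamp("202001011130")
  lt <- as.POSIXlt(t, tz = "UTC")
  expect_equal(c(lt$year + 1900, lt$mon + 1, lt$mday, lt$hour, lt$min),
               c(2020, 1, 1, 11, 30))
  expect_error(parse_timestamp("202002300000"), "invalid")   # Feb 30
  expect_error(parse_timestamp("2020010100"), "invalid")     # wrong length
  expect_error(parse_timestamp("20200101abcd"), "invalid")

  # property: strings built independently from sampled valid calendar
  # components round-trip through parse/format
  set.seed(42)
  days_in_month <- function(y, m) {
    c(31, 28 + (m == 2 && ((y %% 4 == 0 && y %% 100 != 0) || y %% 400 == 0)),
      31, 30, 31, 30, 31, 31, 30, 31, 30, 31)[m]
  }
  for (i in 1:2000) {
    y <- sample(1990:2035, 1); m <- sample(1:12, 1)
    d <- sample(seq_len(days_in_month(y, m)), 1)
    hh <- sample(0:23, 1); mm <- sample(c(0, 30), 1)
    s <- sprintf("%04d%02d%02d%02d%02d", y, m, d, hh, mm)
    expect_identical(format_timestamp(parse_timestamp(s)), s)
  }
})

test_that("variable labels split base, positional triple, and qualifiers", {
  v <- parse_variable_name("FC")
  expect_equal(v$base, "FC"); expect_true(is.na(v$h_index)); expect_true(v$known)

  v <- parse_variable_name("TA_1_1_1")
  expect_equal(list(v$base, v$h_index, v$v_index, v$r_index), list("TA", 1L, 1L, 1L))

  v <- parse_variable_name("SWC_2_3_1")
  expect_equal(list(v$base, v$h_index, v$v_index, v$r_index), list("SWC", 2L, 3L, 1L))

  v <- parse_variable_name("SW_IN_F")
  expect_equal(v$base, "SW_IN"); expect_equal(v$general_qualifiers, "F")

  # partial positional triple: whole label becomes the base, plus a warning
  v <- parse_variable_name("TA_1_1")
  expect_equal(v$base, "TA_1_1")
  expect_false(v$known)
  expect_true(length(v$warnings) > 0)

  expect_error(parse_variable_name(""), "non-empty")
})

test_that("registry lookup knows common variables and refuses to guess", {
  fc <- registry_lookup("FC")
  expect_equal(fc$kind, "flux")
  expect_match(fc$units, "umolCO2")
  rh <- registry_lookup("RH")
  expect_true(rh$percent)
  expect_equal(c(rh$hard_min, rh$hard_max), c(0, 100))
  expect_null(registry_lookup("ZZZ"))
  reg <- registry_add(fp_registry(), "NIRV", "adimensional", -1, 2, "radiation")
  expect_equal(registry_lookup("NIRV", reg)$hard_max, 2)
  expect_true(all(fp_registry()$hard_min < fp_registry()$hard_max))
})

test_that("resolution inference takes the modal step and rejects others", {
  t0 <- as.POSIXct("2020-06-01", tz = "UTC")
  mk <- function(steps_min) format_timestamp(t0 + cumsum(c(0, steps_min)) * 60)
  expect_equal(infer_resolution(mk(c(30, 30, 30))), 30)
  expect_equal(infer_resolution(mk(c(60, 60, 120, 60))), 60)
  expect_error(infer_resolution(mk(c(15, 15))), "unsupported")
  # permutation invariance: depends only on the multiset of steps
  expect_equal(infer_resolution(mk(c(120, 60, 60, 60))), 60)
})

test_that("reader/writer round-trip is a fixed point and sentinel is total", {
  set.seed(7)
  tab <- tiny_table(10, vars = list(FC = NULL, TA = NULL))
  tab$FC[c(2, 5)] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  write_fp_file(tab, path)
  lines <- readLines(path)
  expect_equal(lines[1], "TIMESTAMP_START,TIMESTAMP_END,FC,TA")
  expect_match(lines[3], "-9999")     # missing serialized exactly as -9999
  back <- read_fp_file(path)
  expect_length(back$diagnostics, 0)
  expect_equal_fp(tab, back$table)
  # no -9999 survives as data; write again -> byte-identical
  expect_false(any(unlist(back$table[data_columns(back$table)]) == -9999, na.rm = TRUE))
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_fp_file(back$table, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("plain decimals are written for ordinary magnitudes", {
  tab <- tiny_table(2, vars = list(FC = c(21.5, 123456.25)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_fp_file(tab, path)
  cells <- vapply(strsplit(readLines(path)[-1], ","), `[[`, character(1), 3)
  expect_identical(cells, c("21.5", "123456.25"))
})

test_that("non-numeric cells map to missing with a located diagnostic", {
  tab <- tiny_table(3, vars = list(FC = c(1, 2, 3)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_fp_file(tab, path)
  lines <- readLines(path)
  lines[3] <- sub("2$", "NaN", lines[3])
  writeLines(lines, path)
  back <- read_fp_file(path)
  expect_true(is.na(back$table$FC[2]))
  codes <- vapply(back$diagnostics, `[[`, character(1), "code")
  expect_true("NON_NUMERIC_CELL" %in% codes)
})

test_that("-9999 variants all map to missing on read", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("TIMESTAMP_START,TIMESTAMP_END,FC",
               "202006010000,202006010030,-9999",
               "202006010030,202006010100,-9999.0",
               "202006010100,202006010130,-9999.00"), path)
  back <- read_fp_file(path)
  expect_true(all(is.na(back$table$FC)))
  expect_length(back$diagnostics, 0)
})

test_that("an all-missing column writes as rows of -9999", {
  tab <- tiny_table(3, vars = list(FC = rep(NA_real_, 3)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_fp_file(tab, path)
  expect_equal(vapply(strsplit(readLines(path)[-1], ","), `[[`, character(1), 3),
               rep("-9999", 3))
})

test_that("writer refuses a table violating the time-axis invariants", {
  tab <- tiny_table(5, vars = list(FC = NULL))
  broken <- as.data.frame(tab)[c(1, 3, 4, 5), ]
  broken <- fp_table(broken, resolution = 30, validate = FALSE)
  expect_error(write_fp_file(broken, tempfile()), "regular")
})

test_that("fuzzed valid tables survive read(write(t)) unchanged", {
  path <- withr::local_tempfile(fileext = ".csv")
  for (seed in 1:60) {
    tab <- random_table(seed)
    write_fp_file(tab, path)
    back <- read_fp_file(path)$table
    expect_equal_fp(tab, back)
  }
})

test_that("site metadata validates coordinates and reads from JSON", {
  expect_error(site_meta("X", 91, 0, 0), "lat")
  expect_error(site_meta("X", 0, 181, 0), "lon")
  expect_error(site_meta("X", 0, 0, 15), "utc")
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(site_id = "US-Tst", lat_deg = 40, lon_deg = -105,
                            utc_offset_hours = -7, igbp = "GRA"),
                       path, auto_unbox = TRUE)
  sm <- read_site_meta(path)
  expect_s3_class(sm, "site_meta")
  expect_equal(sm$lat_deg, 40)
})
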