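# Format QA/QC: structural checks, the single autocorrection pass, and the
# PASS / FIXED / FAIL trichotomy.

make_gappy <- function(n = 96, drop = c(10, 50)) {
  set.seed(1)
  tab <- tiny_table(n, vars = list(FC = NULL, TA = NULL))
  out <- as.data.frame(tab)[-drop, ]
  rownames(out) <- NULL
  fp_table(out, site_id = "US-Tst", resolution = 30, validate = FALSE)
}

test_that("a complete record yields no structural findings", {
  tab <- tiny_table(48, vars = list(FC = NULL))
  expect_length(check_structure(tab), 0)
})

test_that("gaps, duplicates and non-monotonic axes are diagnosed", {
  gappy <- make_gappy()
  f <- check_structure(gappy)
  codes <- vapply(f, `[[`, character(1), "code")
  expect_equal(sum(codes == "SKIPPED_INTERVALS"), 2)
  expect_true(all(vapply(f, `[[`, logical(1), "fixable")[codes == "SKIPPED_INTERVALS"]))

  tab <- tiny_table(6, vars = list(FC = NULL))
  dup <- as.data.frame(tab)[c(1, 2, 2, 3, 4, 5, 6), ]
  dup <- fp_table(dup, resolution = 30, validate = FALSE)
  codes <- vapply(check_structure(dup), `[[`, character(1), "code")
  expect_true("DUPLICATE_ROWS" %in% codes)

  rev_tab <- fp_table(as.data.frame(tab)[c(3, 1, 2, 4, 5, 6), ],
                      resolution = 30, validate = FALSE)
  codes <- vapply(check_structure(rev_tab), `[[`, character(1), "code")
  expect_true("NONMONOTONIC_TIME" %in% codes)
})

test_that("mandatory carbon flux and label grammar are enforced", {
  expect_length(check_variables(tiny_table(4, vars = list(FC = NULL))), 0)
  f <- check_variables(tiny_table(4, vars = list(TA = NULL)))
  expect_equal(vapply(f, `[[`, character(1), "code"), "MISSING_MANDATORY")
  expect_false(f[[1]]$fixable)

  f <- check_variables(tiny_table(4, vars = list(fc_1_1_1 = NULL)))
  codes <- vapply(f, `[[`, character(1), "code")
  bad <- f[codes == "BAD_VARIABLE_NAME"][[1]]
  expect_true(bad$fixable)
  expect_match(bad$message, "FC_1_1_1")
})

test_that("autocorrect fills every diagnosed gap with missing rows only", {
  gappy <- make_gappy()
  f <- check_structure(gappy)
  fixed <- autocorrect(gappy, f)
  n_gaps <- sum(vapply(f, function(x) {
    if (x$code == "SKIPPED_INTERVALS") x$metrics$n_intervals else 0
  }, numeric(1)))
  expect_equal(nrow(fixed$table), nrow(gappy) + n_gaps)
  expect_length(check_structure(fixed$table), 0)
  # conservatism: every input cell survives unchanged
  key <- gappy$TIMESTAMP_START
  idx <- match(key, fixed$table$TIMESTAMP_START)
  for (v in data_columns(gappy)) {
    expect_identical(fixed$table[[v]][idx], gappy[[v]])
  }
  # inserted rows are fully missing
  ins <- setdiff(seq_len(nrow(fixed$table)), idx)
  for (v in data_columns(fixed$table)) expect_true(all(is.na(fixed$table[[v]][ins])))
})

test_that("autocorrect is idempotent", {
  gappy <- make_gappy()
  once <- autocorrect(gappy, check_structure(gappy))
  twice <- autocorrect(once$table, check_structure(once$table))
  expect_equal_fp(once$table, twice$table)
})

test_that("ambiguous case-fold renames are never guessed", {
  tab <- tiny_table(4, vars = list(FC = NULL, ta = NULL, TA = NULL))
  f <- check_variables(tab)
  out <- autocorrect(tab, f)
  bad <- out$findings[vapply(out$findings, `[[`, character(1), "variable") %in% "ta"]
  expect_false(any(vapply(bad, `[[`, logical(1), "fixed")))
  expect_true("ta" %in% names(out$table))  # left untouched
})

test_that("run_format_qaqc yields PASS / FIXED / FAIL as defined", {
  path <- withr::local_tempfile(fileext = ".csv")
  clean <- tiny_table(48, vars = list(FC = NULL))
  write_fp_file(clean, path)
  rep <- run_format_qaqc(clean)
  expect_equal(rep$status, "PASS")
  expect_length(rep$findings, 0)

  rep <- run_format_qaqc(make_gappy())
  expect_equal(rep$status, "FIXED")
  expect_true(all(vapply(rep$findings, `[[`, logical(1), "fixed")))
  expect_length(check_structure(rep$table), 0)

  rep <- run_format_qaqc(tiny_table(48, vars = list(TA = NULL)))
  expect_equal(rep$status, "FAIL")
  expect_null(rep$table)

  rep <- run_format_qaqc(withr::local_tempfile(fileext = ".csv"))
  expect_equal(rep$status, "FAIL")
  expect_equal(rep$findings[[1]]$code, "UNREADABLE_FILE")
})

test_that("semicolon-delimited files are recognized and normalized", {
  tab <- tiny_table(4, vars = list(FC = 1:4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_fp_file(tab, path)
  writeLines(gsub(",", ";", readLines(path)), path)
  got <- read_fp_file(path)
  codes <- vapply(got$diagnostics, `[[`, character(1), "code")
  expect_true("WRONG_DELIMITER" %in% codes)
  expect_equal(got$table$FC, as.numeric(1:4))
})

test_that("status trichotomy holds under random mutations of a valid file", {
  set.seed(99)
  for (i in 1:25) {
    tab <- random_table(i + 500)
    df <- as.data.frame(tab)
    mutation <- sample(c("none", "gap", "dupe", "rename", "drop_flux"), 1)
    if (mutation == "gap" && nrow(df) > 6) df <- df[-sample(2:(nrow(df) - 1), 2), ]
    if (mutation == "dupe") df <- df[c(1, 1, seq_len(nrow(df))[-1]), ]
    if (mutation == "rename") {
      v <- sample(setdiff(names(df), c("TIMESTAMP_START", "TIMESTAMP_END")), 1)
      names(df)[names(df) == v] <- tolower(v)
    }
    if (mutation == "drop_flux") df <- df[, !grepl("^FC", names(df)), drop = FALSE]
    rownames(df) <- NULL
    tab2 <- fp_table(df, resolution = attr(tab, "resolution"), validate = FALSE)
    rep <- run_format_qaqc(tab2)
    expect_true(rep$status %in% c("PASS", "FIXED", "FAIL"))
    fixed_flags <- vapply(rep$findings, `[[`, logical(1), "fixed")
    if (rep$status == "PASS") expect_length(rep$findings, 0)
    if (rep$status == "FIXED") expect_true(length(fixed_flags) > 0 && all(fixed_flags))
    if (rep$status == "FAIL") expect_true(any(!fixed_flags) || length(rep$findings) == 0)
    # fixed implies fixable, always
    for (f in rep$findings) if (f$fixed) expect_true(f$fixable)
  }
})
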