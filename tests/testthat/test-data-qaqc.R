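# The six Data QA/QC check modules, exercised per operation with targeted
# injections on a shared synthetic year.

cfg <- synthetic_site_config(seed = 10L)
clean <- generate_clean(cfg)
site <- cfg$site
config <- qaqc_config()

codes_of <- function(findings) vapply(findings, `[[`, character(1), "code")

test_that("alignment: clean year has zero lag everywhere and no findings", {
  al <- timestamp_alignment(clean, site, config)
  expect_length(al$findings, 0)
  sw <- al$lag_profile[al$lag_profile$variable == "SW_IN", ]
  expect_true(all(sw$lag[!is.na(sw$lag)] == 0))
})

test_that("alignment: injected shifts are recovered as the modal lag", {
  for (k in c(-3L, 2L)) {
    sh <- inject_fault(clean, fault_spec("TIMESTAMP_SHIFT", shift = k))
    al <- timestamp_alignment(sh, site, config)
    f <- findings_with_code <- al$findings[codes_of(al$findings) == "TIMESTAMP_SHIFT"]
    expect_length(f, 1)
    expect_equal(f[[1]]$metrics$modal_lag, k)
    expect_equal(f[[1]]$severity, "ACTION_REQUIRED")
  }
})

test_that("alignment: daylight-saving injection yields the two-plateau signature", {
  dst <- make_fixture("dst", seed = 10L, config = cfg)
  al <- timestamp_alignment(dst$table, site, config)
  f <- al$findings[codes_of(al$findings) == "DST"]
  expect_length(f, 1)
  expect_setequal(f[[1]]$metrics$plateau_lags, c(0, 2))
  expect_length(al$findings[codes_of(al$findings) == "TIMESTAMP_SHIFT"], 0)
})

test_that("alignment: skipped cleanly when no radiation stream exists", {
  norad <- clean
  norad$SW_IN <- NULL; norad$PPFD_IN <- NULL; norad$NETRAD <- NULL
  al <- timestamp_alignment(norad, site, config)
  expect_equal(codes_of(al$findings), "SKIPPED")
  expect_equal(al$findings[[1]]$severity, "SKIPPED")
})

test_that("alignment: desynchronized radiation streams are flagged", {
  des <- clean
  n <- nrow(des)
  des$PPFD_IN <- c(rep(NA, 2), des$PPFD_IN[1:(n - 2)])
  al <- timestamp_alignment(des, site, config)
  expect_true("STREAMS_NOT_SYNCED" %in% codes_of(al$findings))
})

test_that("radiation: unit error and tilt are detected, clean is silent", {
  expect_length(radiation_issue_check(clean, site, config), 0)

  hi <- inject_fault(clean, fault_spec("UNIT_RATIO", var = "SW_IN", factor = 2))
  f <- radiation_issue_check(hi, site, config)
  f <- f[codes_of(f) == "HIGH_RADIATION"]
  expect_length(f, 1)
  expect_gt(f[[1]]$metrics$frac_above_ceiling, 0.5)  # ~all daytime intervals

  # multiplicative am/pm asymmetry emulating a tilted sensor
  tilt <- clean
  hod <- as.integer(substr(tilt$TIMESTAMP_START, 9, 10))
  tilt$SW_IN <- tilt$SW_IN * ifelse(hod < 12, 1.15, 0.85)
  f <- radiation_issue_check(tilt, site, config)
  expect_true("TILTED" %in% codes_of(f))
})

test_that("physical range: ratios, hard violations, outliers; clean silent", {
  expect_length(physical_range_check(clean, config = config), 0)

  rh <- inject_fault(clean, fault_spec("UNIT_RATIO", var = "RH", factor = 0.01))
  f <- physical_range_check(rh, config = config)
  expect_true("PERCENT_AS_RATIO" %in% codes_of(f))
  expect_equal(f[[which(codes_of(f) == "PERCENT_AS_RATIO")]]$severity, "ACTION_REQUIRED")

  hot <- clean
  set.seed(1)
  hot$TA[sample(nrow(hot), nrow(hot) * 0.05)] <- 80
  f <- physical_range_check(hot, config = config)
  expect_true("OUT_OF_RANGE" %in% codes_of(f))

  out <- inject_fault(clean, fault_spec("OUTLIERS", var = "SWC", rate = 0.03,
                                        scale = 10, seed = 10L))
  f <- physical_range_check(out, config = config)
  f <- f[codes_of(f) == "EXCESSIVE_OUTLIERS"]
  expect_length(f, 1)
  expect_gt(f[[1]]$metrics$frac_outliers, 0.01)
})

test_that("plausible ranges sit inside hard limits with positive width", {
  pr <- plausible_ranges(clean, config = config)
  expect_true(all(pr$lower < pr$upper))
  reg <- fp_registry()
  for (i in seq_len(nrow(pr))) {
    e <- registry_lookup(parse_variable_name(pr$variable[i])$base, reg)
    expect_gte(pr$lower[i], e$hard_min)
    expect_lte(pr$upper[i], e$hard_max)
  }
})

test_that("variability: filled constants carry their exact span", {
  fx <- make_fixture("constant_fill", seed = 10L, config = cfg)
  f <- variability_check(fx$table, config)
  f <- f[codes_of(f) == "FILLED_CONSTANT"]
  expect_length(f, 1)
  expect_equal(f[[1]]$variable, "TA")
  expect_equal(f[[1]]$metrics$value, 12.34)
  expect_equal(f[[1]]$metrics$run_length, 3 * 48)
  expect_equal(f[[1]]$span_start, "202106010000")
  expect_equal(f[[1]]$span_end, "202106040000")
})

test_that("variability: step changes localize within five days", {
  fx <- make_fixture("step_change", seed = 10L, config = cfg)
  f <- variability_check(fx$table, config)
  f <- f[codes_of(f) == "STEP_CHANGE"]
  expect_gte(length(f), 1)
  day <- as.Date(substr(f[[1]]$span_start, 1, 8), "%Y%m%d")
  expect_lte(abs(as.numeric(day - as.Date("2021-07-02"))), 5)
  expect_equal(f[[1]]$variable, "SWC")
})

test_that("variability: trend and cut-off injections are recovered", {
  fx <- make_fixture("drift", seed = 10L, config = cfg)
  expect_true("TREND" %in% codes_of(variability_check(fx$table, config)))
  fx <- make_fixture("cutoff", seed = 10L, config = cfg)
  f <- variability_check(fx$table, config)
  f <- f[codes_of(f) == "CUTOFF"]
  expect_gte(length(f), 1)
  expect_gt(f[[1]]$metrics$frac, 0.01)
})

test_that("variability: white-noise false-alarm rate stays under 5%", {
  n_hit <- 0
  n_seeds <- 100
  for (s in seq_len(n_seeds)) {
    set.seed(s + 2000)
    tab <- tiny_table(48 * 100, vars = list(TA = rnorm(48 * 100, 10, 3)),
                      start = "202101010000")
    n_hit <- n_hit + (length(variability_check(tab, config)) > 0)
  }
  expect_lt(n_hit / n_seeds, 0.05)
})

test_that("multivariate: derived variables give a perfect fit", {
  der <- clean
  der$PPFD_IN <- 2.04 * der$SW_IN
  f <- multivariate_check(der, config = config)
  f <- f[codes_of(f) == "PERFECT_FIT"]
  expect_length(f, 1)
  expect_gt(f[[1]]$metrics$r_squared, 0.9999)
})

test_that("multivariate: gain drift moves the windowed slope systematically", {
  dr <- clean
  frac <- seq(0, 1, length.out = nrow(dr))
  gain <- (2.04 + frac * (1.50 - 2.04)) / 2.04
  dr$PPFD_IN <- dr$PPFD_IN * gain
  f <- multivariate_check(dr, config = config)
  expect_true("SLOPE_TREND" %in% codes_of(f))
})

test_that("multivariate: a two-week bias is a short-term mismatch", {
  mm <- clean
  rows <- rows <- which(mm$TIMESTAMP_START >= "202106010000" &
                          mm$TIMESTAMP_START < "202106150000")
  mm$SW_IN[rows] <- mm$SW_IN[rows] * 0.5
  f <- multivariate_check(mm, pairs = list(c("PPFD_IN", "SW_IN")), config = config)
  stm <- f[codes_of(f) == "SHORT_TERM_MISMATCH"]
  expect_gte(length(stm), 1)
  expect_true(stm[[1]]$span_start <= "202106150000" &&
                stm[[1]]$span_end >= "202106010000")
})

test_that("multivariate: absent pair members are skipped per pair", {
  noppfd <- clean; noppfd$PPFD_IN <- NULL
  f <- multivariate_check(noppfd, config = config)
  sk <- f[codes_of(f) == "SKIPPED"]
  expect_equal(vapply(sk, function(x) x$variable[1], character(1)), "PPFD_IN~SW_IN")
})

test_that("diurnal-seasonal: sign flip fires on the flipped twin only", {
  ds <- diurnal_seasonal_check(clean, site, config)
  expect_length(ds$findings, 0)
  flip <- inject_fault(clean, fault_spec("SIGN_FLIP", var = "FC"))
  ds <- diurnal_seasonal_check(flip, site, config)
  f <- ds$findings[codes_of(ds$findings) == "SIGN_FLIP"]
  expect_length(f, 1)
  expect_equal(f[[1]]$severity, "ACTION_REQUIRED")
  expect_gte(f[[1]]$metrics$n_months, 1)
})

test_that("diurnal-seasonal: composite counts conserve the monthly sample", {
  gap <- inject_fault(clean, fault_spec("GAP", var = "FC",
                                        span_start = "202103050000",
                                        span_end = "202103200000"))
  comp <- diurnal_composite(gap, "FC")
  agg <- tapply(comp$n, comp$month, sum)
  month <- substr(gap$TIMESTAMP_START, 1, 6)
  for (m in unique(month)) {
    expect_equal(unname(agg[m]), sum(!is.na(gap$FC[month == m])))
  }
  expect_equal(sum(comp$month == "202103"), 48)   # one bin per timestep
})

test_that("diurnal-seasonal: too few months is a skip, not a verdict", {
  short <- fp_table(as.data.frame(clean)[1:(48 * 40), ], site_id = "US-Syn",
                    resolution = 30, site_meta = site)
  ds <- diurnal_seasonal_check(short, site, config)
  expect_equal(codes_of(ds$findings), "SKIPPED")
})

test_that("ustar: unfiltered record gives flat availability, verdict NONE", {
  uf <- ustar_filtering_check(clean, site, config)
  expect_equal(uf$verdict, "NONE")
  expect_length(uf$findings, 0)
  usable <- uf$bins$n >= config$ustar$bin_n_min
  expect_true(all(uf$bins$availability[usable] > 0.9))
})

test_that("ustar: injected FC thresholds recover within one bin width", {
  for (th in c(0.1, 0.2, 0.3, 0.4)) {
    filt <- inject_fault(clean, fault_spec("USTAR_FILTER", threshold = th))
    uf <- ustar_filtering_check(filt, site, config)
    expect_equal(uf$verdict, "FC_FILTERED")
    expect_lte(abs(uf$u_star_threshold - th), 0.05 + 1e-9)
  }
})

test_that("ustar: deleted low-USTAR records truncate the distribution", {
  del <- inject_fault(clean, fault_spec("USTAR_FILTER", threshold = 0.15,
                                        drop_ustar = TRUE))
  uf <- ustar_filtering_check(del, site, config)
  expect_true("USTAR_FILTERED" %in% codes_of(uf$findings))
})

test_that("coverage: empty columns, interior gaps, naming drift, mandatory", {
  expect_length(variable_coverage_check(clean, config = config), 0)

  empty <- clean; empty$LE <- NA_real_
  f <- variable_coverage_check(empty, config = config)
  expect_equal(codes_of(f), "EMPTY_COLUMN")

  fx <- make_fixture("gap", seed = 10L, config = cfg)
  f <- variable_coverage_check(fx$table, config = config)
  f <- f[codes_of(f) == "LONG_GAP"]
  expect_length(f, 1)
  expect_equal(f[[1]]$variable, "FCH4")
  expect_equal(f[[1]]$metrics$gap_days, 90)
  expect_equal(substr(f[[1]]$span_start, 1, 8), "20210201")

  f <- variable_coverage_check(clean, prior_labels = c(data_columns(clean), "TA_1_1_1"),
                               config = config)
  expect_true("NAMING_MISMATCH" %in% codes_of(f))

  noflux <- clean; noflux$FC <- NULL; noflux$FCH4 <- NULL
  f <- variable_coverage_check(noflux, config = config)
  expect_true("MISSING_MANDATORY" %in% codes_of(f))
})

test_that("combine: extension, replacement precedence, identity", {
  half1 <- fp_table(as.data.frame(clean)[1:(48 * 180), ], site_id = "US-Syn",
                    resolution = 30, site_meta = site)
  half2 <- fp_table(as.data.frame(clean)[(48 * 180 + 1):nrow(clean), ],
                    site_id = "US-Syn", resolution = 30, site_meta = site)
  joined <- combine_with_prior(half2, half1)
  expect_equal_fp(joined, clean)

  # replacement: overlapping rows come from the new upload wholesale
  repl <- half1
  repl$TA <- repl$TA + 100
  merged <- combine_with_prior(repl, clean)
  expect_equal(merged$TA[1:(48 * 180)], clean$TA[1:(48 * 180)] + 100)
  expect_equal(merged$TA[(48 * 180 + 1):nrow(clean)],
               clean$TA[(48 * 180 + 1):nrow(clean)])

  expect_equal_fp(combine_with_prior(clean, NULL), clean)
  expect_error(combine_with_prior(clean,
                                  fp_table(as.data.frame(half1), site_id = "US-Oth",
                                           resolution = 30)), "site mismatch")
})

test_that("combine: disjoint periods are bridged with missing rows", {
  a <- fp_table(as.data.frame(clean)[1:48, ], site_id = "US-Syn", resolution = 30)
  b <- fp_table(as.data.frame(clean)[(48 * 3 + 1):(48 * 4), ], site_id = "US-Syn",
                resolution = 30)
  j <- combine_with_prior(b, a)
  expect_equal(nrow(j), 48 * 4)
  expect_true(all(is.na(j$TA[49:(48 * 3)])))
  expect_silent(validate_fp_table(j))
})

test_that("checks are invariant to appending fully-missing rows", {
  pad_days <- 5
  df <- as.data.frame(clean)
  last <- parse_timestamp(df$TIMESTAMP_END[nrow(df)])
  extra_starts <- seq(last, by = "30 min", length.out = pad_days * 48)
  pad <- data.frame(TIMESTAMP_START = format_timestamp(extra_starts),
                    TIMESTAMP_END = format_timestamp(extra_starts + 1800))
  for (v in data_columns(clean)) pad[[v]] <- NA_real_
  padded <- fp_table(rbind(df, pad), site_id = "US-Syn", resolution = 30,
                     site_meta = site)
  rep_clean <- run_data_qaqc(clean, site)
  rep_pad <- run_data_qaqc(padded, site)
  expect_equal(rep_pad$overall, rep_clean$overall)
  expect_equal(codes_of(rep_pad$findings), codes_of(rep_clean$findings))
  expect_equal(rep_pad$check_status, rep_clean$check_status)
})

test_that("run_data_qaqc flags multiple distinct faults in one record", {
  faulted <- inject_fault(clean, list(
    fault_spec("SIGN_FLIP", var = "FC"),
    fault_spec("UNIT_RATIO", var = "RH", factor = 0.01),
    fault_spec("GAP", var = "FCH4", span_start = "202102010000",
               span_end = "202105020000")))
  rep <- run_data_qaqc(faulted, site)
  expect_equal(rep$overall, "ACTION_REQUIRED")
  expect_true(all(c("SIGN_FLIP", "PERCENT_AS_RATIO", "LONG_GAP") %in%
                    codes_of(rep$findings)))
})

test_that("run_data_qaqc is deterministic: byte-identical JSON reports", {
  r1 <- report_to_json(run_data_qaqc(clean, site))
  r2 <- report_to_json(run_data_qaqc(clean, site))
  expect_identical(r1, r2)
})
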