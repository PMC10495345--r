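#' Configuration for the synthetic flux-met site generator
#'
#' The generator emulates a temperate mid-latitude site: diurnal/seasonal
#' solar forcing, a light-response (rectangular hyperbola) CO2 flux with
#' Q10 respiration (micromet sign convention: daytime uptake negative),
#' energy partition by Bowen ratio, lognormal friction velocity with
#' diurnal modulation, and AR(1) noise on slow variables. A single global
#' seed expands to per-variable substreams, so adding a variable never
#' perturbs existing streams.
#'
#' @param site [site_meta()] of the emulated site.
#' @param start,end First and last day (`Date` or "YYYY-MM-DD").
#' @param resolution Timestep minutes (30 or 60).
#' @param clearness_mean,clearness_sd Mean and day-to-day variability of the
#'   atmospheric clearness index (SW_IN / SW_IN_POT), logistic-squashed into
#'   (0.35, 0.95) so clean radiation never exceeds the potential ceiling.
#' @param ta_mean,ta_seasonal,ta_diurnal,ta_ar1,ta_sd Air-temperature model
#'   (deg C): annual mean, seasonal and diurnal amplitudes, AR(1)
#'   coefficient in `[0,1)` and innovation SD.
#' @param alpha,pmax,r0,q10 FC light response: quantum yield
#'   (umolCO2 per W m-2 of SW_IN), GPP plateau (umol m-2 s-1), base
#'   respiration at 10 C (umol m-2 s-1), Q10.
#' @param bowen Bowen ratio H/LE for the energy partition.
#' @param ustar_gain Slope of USTAR on WS (m s-1 per m s-1).
#' @param fc_sd,le_sd,ppfd_sd Noise SDs for FC, LE/H, PPFD_IN.
#' @param seed Integer seed; two identical seeds give identical tables.
#' @return List of class `synthetic_site_config`.
#' @export
synthetic_site_config <- function(
    site = site_meta("US-Syn", 40, -105, -7, "GRA"),
    start = "2021-01-01", end = "2021-12-31", resolution = 30,
    clearness_mean = 0.65, clearness_sd = 0.15,
    ta_mean = 8, ta_seasonal = 12, ta_diurnal = 4, ta_ar1 = 0.95, ta_sd = 0.5,
    alpha = 0.1, pmax = 25, r0 = 1.8, q10 = 2,
    bowen = 0.5, ustar_gain = 0.1,
    fc_sd = 1.5, le_sd = 10, ppfd_sd = 10,
    seed = 1L) {
  stopifnot(resolution %in% c(30, 60), ta_ar1 >= 0, ta_ar1 < 1,
            clearness_sd > 0, fc_sd > 0)
  structure(as.list(environment()), class = "synthetic_site_config")
}

# Deterministic per-stream substream seed (< 2^31).
stream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name))) %% 65536
  as.integer((as.numeric(seed) %% 32749) * 65536 + h)
}

with_stream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(stream_seed(seed, name))
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  force(expr)
}

ar1_series <- function(n, phi, sd_innov) {
  x <- stats::rnorm(n, sd = sd_innov)
  if (phi > 0) x <- as.numeric(stats::filter(x, phi, method = "recursive"))
  x
}

#' Generate a clean synthetic flux-met record
#'
#' @param config A [synthetic_site_config()].
#' @return An `fp_table` with variables SW_IN, PPFD_IN, NETRAD, TA, T_SONIC,
#'   RH, FC, FCH4, LE, H, WS, USTAR, TS, SWC and full coverage. The site
#'   metadata is attached as an attribute.
#' @export
generate_clean <- function(config = synthetic_site_config()) {
  stopifnot(inherits(config, "synthetic_site_config"))
  res <- config$resolution
  t0 <- as.POSIXct(paste(config$start, "00:00"), tz = "UTC")
  t1 <- as.POSIXct(paste(config$end, "23:59"), tz = "UTC")
  starts <- seq_timestamps(t0, t1, res)
  n <- length(starts)
  per_day <- 24 * 60 / res
  lt <- as.POSIXlt(starts, tz = "UTC")
  doy <- lt$yday + 1
  hod <- lt$hour + lt$min / 60 + res / 60 / 2   # midpoint hour of day
  day_index <- rep(seq_len(ceiling(n / per_day)), each = per_day)[seq_len(n)]
  n_days <- max(day_index)
  seed <- config$seed

  pot <- potential_radiation(config$site, starts, res)

  # clearness: daily AR(1), logistic-squashed into (0.35, 0.95)
  cl_z <- with_stream(seed, "clearness", ar1_series(n_days, 0.6, 1))
  squash_lo <- max(0.05, config$clearness_mean - 2 * config$clearness_sd)
  squash_hi <- min(1.00, config$clearness_mean + 2 * config$clearness_sd)
  clearness <- (squash_lo + (squash_hi - squash_lo) * stats::plogis(0.8 * cl_z))[day_index]
  sw_in <- clearness * pot

  ppfd <- 2.04 * sw_in +
    ifelse(sw_in > 0, with_stream(seed, "ppfd", stats::rnorm(n, sd = config$ppfd_sd)), 0)
  ppfd <- pmax(ppfd, 0)

  season <- cos(2 * pi * (doy - 202) / 365)   # peaks late July (NH)
  ta <- config$ta_mean + config$ta_seasonal * season +
    config$ta_diurnal * cos(2 * pi * (hod - 14.5) / 24) +
    with_stream(seed, "ta", ar1_series(n, config$ta_ar1, config$ta_sd))
  t_sonic <- ta + 0.3 + with_stream(seed, "t_sonic", stats::rnorm(n, sd = 0.3))

  rh_z <- 0.8 - 0.06 * (ta - config$ta_mean) +
    with_stream(seed, "rh", ar1_series(n, 0.9, 0.2))
  rh <- 5 + 93 * stats::plogis(rh_z)

  netrad <- 0.85 * sw_in - 55 + with_stream(seed, "netrad", stats::rnorm(n, sd = 12))

  grow <- 0.1 + 0.9 * exp(-((doy - 202) / 60)^2)  # canopy phenology factor
  gpp <- grow * (config$alpha * sw_in * config$pmax) / (config$alpha * sw_in + config$pmax)
  resp <- config$r0 * config$q10^((ta - 10) / 10)
  fc <- resp - gpp + with_stream(seed, "fc", stats::rnorm(n, sd = config$fc_sd))

  avail <- pmax(netrad, 0) * 0.8
  le <- avail / (1 + config$bowen) + with_stream(seed, "le", stats::rnorm(n, sd = config$le_sd))
  h <- avail * config$bowen / (1 + config$bowen) +
    with_stream(seed, "h", stats::rnorm(n, sd = config$le_sd))

  ws_mu <- 0.6 + 0.25 * cos(2 * pi * (hod - 15) / 24) +
    with_stream(seed, "ws", ar1_series(n, 0.9, 0.15))
  ws <- exp(ws_mu)
  ustar <- pmax(config$ustar_gain * ws +
                  with_stream(seed, "ustar", stats::rnorm(n, sd = 0.015)), 0.001)

  ts_soil <- 8 + 9 * cos(2 * pi * (doy - 215) / 365) +
    with_stream(seed, "ts", ar1_series(n, 0.98, 0.1))
  swc <- 30 + with_stream(seed, "swc", ar1_series(n, 0.98, 0.2))

  fch4 <- 10 + 30 * exp(-((doy - 210) / 70)^2) +
    with_stream(seed, "fch4", ar1_series(n, 0.9, 1.5))

  out <- data.frame(
    TIMESTAMP_START = format_timestamp(starts),
    TIMESTAMP_END = format_timestamp(starts + res * 60),
    FC = fc, FCH4 = fch4, LE = le, H = h,
    SW_IN = sw_in, PPFD_IN = ppfd, NETRAD = netrad,
    TA = ta, T_SONIC = t_sonic, RH = rh,
    WS = ws, USTAR = ustar, TS = ts_soil, SWC = swc,
    stringsAsFactors = FALSE)
  fp_table(out, site_id = config$site$site_id, resolution = res,
           site_meta = config$site)
}

#' Declare a defect to inject
#'
#' @param kind One of `TIMESTAMP_SHIFT`, `DST`, `SIGN_FLIP`, `UNIT_RATIO`,
#'   `CONSTANT_FILL`, `STEP_CHANGE`, `DRIFT`, `CUTOFF`, `OUTLIERS`,
#'   `USTAR_FILTER`, `GAP`, `DROP_VARIABLE`, `ROW_SKIP`.
#' @param var Target variable label (where applicable).
#' @param ... Kind-specific parameters: `shift` (signed intervals),
#'   `span_start`/`span_end` (`YYYYMMDDHHMM`), `factor`, `value`, `delta`,
#'   `rate` (units per year), `bound`, `rate_frac`, `scale`, `threshold`,
#'   `seed`.
#' @return List of class `fault_spec`.
#' @export
fault_spec <- function(kind, var = NULL, ...) {
  kinds <- c("TIMESTAMP_SHIFT", "DST", "SIGN_FLIP", "UNIT_RATIO", "CONSTANT_FILL",
             "STEP_CHANGE", "DRIFT", "CUTOFF", "OUTLIERS", "USTAR_FILTER",
             "GAP", "DROP_VARIABLE", "ROW_SKIP")
  if (!kind %in% kinds) stop("unknown fault kind: ", kind, call. = FALSE)
  structure(c(list(kind = kind, var = var), list(...)), class = "fault_spec")
}

rows_in_span <- function(table, span_start, span_end) {
  which(table$TIMESTAMP_START >= span_start & table$TIMESTAMP_START < span_end)
}

shift_columns <- function(table, rows, k) {
  # data displaced by k rows relative to timestamps: new[i] <- old[i - k]
  n <- nrow(table)
  src <- rows - k
  src[src < 1 | src > n] <- NA
  for (v in data_columns(table)) {
    col <- table[[v]]
    table[[v]][rows] <- ifelse(is.na(src), NA, col[src])
  }
  table
}

#' Inject a fault into a flux-met record
#'
#' Returns a new table differing from the input only as the fault
#' prescribes; the input (clean twin) is untouched. Faults compose: apply a
#' list of specs in order.
#'
#' @param table An `fp_table` (typically from [generate_clean()]).
#' @param fault A [fault_spec()], or list of them.
#' @return The faulted `fp_table`.
#' @export
inject_fault <- function(table, fault) {
  if (is.list(fault) && !inherits(fault, "fault_spec")) {
    for (f in fault) table <- inject_fault(table, f)
    return(table)
  }
  f <- fault
  if (!is.null(f$var) && !f$var %in% names(table)) {
    stop("fault references absent variable: ", f$var, call. = FALSE)
  }
  res <- attr(table, "resolution")
  per_hour <- 60 / res
  switch(f$kind,
    TIMESTAMP_SHIFT = shift_columns(table, seq_len(nrow(table)), f$shift),
    DST = {
      rows <- rows_in_span(table, f$span_start, f$span_end)
      shift_columns(table, rows, per_hour)
    },
    SIGN_FLIP = { table[[f$var]] <- -table[[f$var]]; table },
    UNIT_RATIO = { table[[f$var]] <- table[[f$var]] * f$factor; table },
    CONSTANT_FILL = {
      rows <- rows_in_span(table, f$span_start, f$span_end)
      table[[f$var]][rows] <- f$value; table
    },
    STEP_CHANGE = {
      rows <- which(table$TIMESTAMP_START >= f$span_start)
      table[[f$var]][rows] <- table[[f$var]][rows] + f$delta; table
    },
    DRIFT = {
      tsec <- as.numeric(table_start_times(table))
      years <- (tsec - tsec[1]) / (365.25 * 86400)
      table[[f$var]] <- table[[f$var]] + f$rate * years; table
    },
    CUTOFF = { table[[f$var]] <- pmin(table[[f$var]], f$bound); table },
    OUTLIERS = {
      x <- table[[f$var]]
      idx <- which(!is.na(x))
      sseed <- if (is.null(f$seed)) 1L else f$seed
      pick <- with_stream(sseed, paste0("outliers_", f$var), {
        k <- max(1, round(f$rate * length(idx)))
        list(i = sample(idx, k), s = sample(c(-1, 1), k, replace = TRUE),
             m = stats::runif(k, 0.8, 1.2))
      })
      spread <- max(stats::mad(x, na.rm = TRUE),
                    stats::IQR(x, na.rm = TRUE) / 1.349, 1e-6)
      x[pick$i] <- stats::median(x, na.rm = TRUE) + pick$s * pick$m * f$scale * spread
      table[[f$var]] <- x; table
    },
    USTAR_FILTER = {
      site <- attr(table, "site_meta")
      if (is.null(site)) stop("USTAR_FILTER needs site metadata on the table", call. = FALSE)
      night <- table_sw_pot(table, site) == 0
      drop <- night & !is.na(table$USTAR) & table$USTAR < f$threshold
      if (!is.null(f$drop_ustar) && isTRUE(f$drop_ustar)) {
        table$USTAR[drop] <- NA
      } else {
        table$FC[drop] <- NA
      }
      table
    },
    GAP = {
      rows <- rows_in_span(table, f$span_start, f$span_end)
      table[[f$var]][rows] <- NA; table
    },
    DROP_VARIABLE = { table[[f$var]] <- NULL; table },
    ROW_SKIP = {
      rows <- rows_in_span(table, f$span_start, f$span_end)
      out <- table[-rows, , drop = FALSE]
      rownames(out) <- NULL
      fp_table(out, site_id = attr(table, "site_id"), resolution = res,
               site_meta = attr(table, "site_meta"), validate = FALSE)
    })
}

#' Fault-to-check oracle table
#'
#' Maps every injectable fault kind to the data/format check designated to
#' detect it and the finding code it must raise. This is the contract the
#' fault-recovery tests exercise: the designated check fires on the faulted
#' record and stays silent on the clean twin.
#'
#' @return data.frame with columns `kind`, `check`, `code`.
#' @export
fault_check_map <- function() {
  data.frame(
    kind = c("TIMESTAMP_SHIFT", "DST", "SIGN_FLIP", "UNIT_RATIO", "CONSTANT_FILL",
             "STEP_CHANGE", "DRIFT", "CUTOFF", "OUTLIERS", "USTAR_FILTER",
             "GAP", "DROP_VARIABLE", "ROW_SKIP"),
    check = c("timestamp_alignment", "timestamp_alignment", "diurnal_seasonal",
              "physical_range", "variability", "variability", "variability",
              "variability", "physical_range", "ustar_filtering",
              "variable_coverage", "variable_coverage", "format_qaqc"),
    code = c("TIMESTAMP_SHIFT", "DST", "SIGN_FLIP", "PERCENT_AS_RATIO",
             "FILLED_CONSTANT", "STEP_CHANGE", "TREND", "CUTOFF",
             "EXCESSIVE_OUTLIERS", "FC_FILTERED", "LONG_GAP",
             "NAMING_MISMATCH", "SKIPPED_INTERVALS"),
    stringsAsFactors = FALSE)
}

# Canonical fault parameters used by the shipped fixtures: one per issue,
# positioned mid-record on a one-year table.
canonical_fault <- function(kind, table, seed = 1L) {
  y <- substr(table$TIMESTAMP_START[1], 1, 4)
  ts <- function(md) paste0(y, md)
  switch(kind,
    TIMESTAMP_SHIFT = fault_spec("TIMESTAMP_SHIFT", shift = 2L),
    DST = fault_spec("DST", span_start = ts("03080200"), span_end = ts("11010200")),
    SIGN_FLIP = fault_spec("SIGN_FLIP", var = "FC"),
    UNIT_RATIO = fault_spec("UNIT_RATIO", var = "RH", factor = 0.01),
    CONSTANT_FILL = fault_spec("CONSTANT_FILL", var = "TA", value = 12.34,
                               span_start = ts("06010000"), span_end = ts("06040000")),
    STEP_CHANGE = fault_spec("STEP_CHANGE", var = "SWC", delta = 5,
                             span_start = ts("07020000")),
    DRIFT = fault_spec("DRIFT", var = "SWC", rate = 8),
    CUTOFF = fault_spec("CUTOFF", var = "TA",
                        bound = stats::quantile(table$TA, 0.9, na.rm = TRUE, names = FALSE)),
    OUTLIERS = fault_spec("OUTLIERS", var = "TA", rate = 0.03, scale = 10, seed = seed),
    USTAR_FILTER = fault_spec("USTAR_FILTER", threshold = 0.25),
    GAP = fault_spec("GAP", var = "FCH4",
                     span_start = ts("02010000"), span_end = ts("05020000")),
    DROP_VARIABLE = fault_spec("DROP_VARIABLE", var = "LE"),
    ROW_SKIP = fault_spec("ROW_SKIP", span_start = ts("06150000"), span_end = ts("06150200")),
    stop("unknown fault kind: ", kind, call. = FALSE))
}

#' Build a named test fixture
#'
#' Deterministic (seeded) faulted record plus the finding code(s) the
#' designated check must raise. The catalog holds one scenario per issue in
#' the fault taxonomy plus `"clean"`.
#'
#' @param name Fixture name: `"clean"`, a lower-case fault kind (e.g.
#'   `"dst"`, `"sign_flip"`), or the alias `"percent_ratio_rh"`.
#' @param seed Integer seed for the underlying clean record.
#' @param config Generator configuration.
#' @param clean Optional pregenerated clean table for `config` (avoids
#'   regenerating it when building many fixtures from one twin).
#' @return List with `table`, `clean` (the untouched twin), `fault`,
#'   `expected_codes`, `check`.
#' @export
make_fixture <- function(name, seed = 1L, config = NULL, clean = NULL) {
  if (is.null(config)) config <- synthetic_site_config(seed = seed)
  if (is.null(clean)) clean <- generate_clean(config)
  if (name == "percent_ratio_rh") name <- "unit_ratio"
  if (name == "clean") {
    return(list(table = clean, clean = clean, fault = NULL,
                expected_codes = character(0), check = NA_character_))
  }
  kind <- toupper(name)
  map <- fault_check_map()
  if (!kind %in% map$kind) stop("unknown fixture name: ", name, call. = FALSE)
  fault <- canonical_fault(kind, clean, seed = seed)
  list(table = inject_fault(clean, fault), clean = clean, fault = fault,
       expected_codes = map$code[map$kind == kind],
       check = map$check[map$kind == kind])
}
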