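#' The FP variable registry
#'
#' Units, hard physical limits, and variable kind for the flux-met variables
#' most commonly found in half-hourly/hourly exchange files (fluxes, energy,
#' radiation, meteorology, soil, concentrations, quality flags). Hard limits
#' are instrument-plausibility bounds used by the physical-range check;
#' values outside them are considered physically impossible rather than
#' merely unusual. The registry is user-extensible via [registry_add()].
#'
#' @return A data.frame with columns `base`, `units`, `hard_min`, `hard_max`,
#'   `kind`, `percent` (logical: variable is expressed in percent).
#' @export
fp_registry <- function() {
  e <- function(base, units, lo, hi, kind, percent = FALSE)
    data.frame(base = base, units = units, hard_min = lo, hard_max = hi,
               kind = kind, percent = percent, stringsAsFactors = FALSE)
  rbind(
    # carbon / trace-gas fluxes (micromet sign convention: uptake negative)
    e("FC",       "umolCO2 m-2 s-1",  -100,   100, "flux"),
    e("FCH4",     "nmolCH4 m-2 s-1",  -500,  3000, "flux"),
    e("SC",       "umolCO2 m-2 s-1",   -60,    60, "flux"),
    e("NEE",      "umolCO2 m-2 s-1",  -100,   100, "flux"),
    e("GPP",      "umolCO2 m-2 s-1",   -10,   100, "flux"),
    e("RECO",     "umolCO2 m-2 s-1",     0,    60, "flux"),
    # energy fluxes
    e("LE",       "W m-2",            -500,  1000, "flux"),
    e("H",        "W m-2",            -500,  1000, "flux"),
    e("G",        "W m-2",            -300,   500, "soil"),
    e("TAU",      "kg m-1 s-2",        -10,    10, "flux"),
    # radiation
    e("NETRAD",   "W m-2",            -500,  1200, "radiation"),
    e("SW_IN",    "W m-2",               0,  1500, "radiation"),
    e("SW_OUT",   "W m-2",               0,  1000, "radiation"),
    e("SW_DIF",   "W m-2",               0,  1000, "radiation"),
    e("LW_IN",    "W m-2",              50,   700, "radiation"),
    e("LW_OUT",   "W m-2",              50,   900, "radiation"),
    e("PPFD_IN",  "umolPhoton m-2 s-1",  0,  3000, "radiation"),
    e("PPFD_OUT", "umolPhoton m-2 s-1",  0,  2000, "radiation"),
    e("PPFD_DIF", "umolPhoton m-2 s-1",  0,  3000, "radiation"),
    e("ALB",      "%",                    0,   100, "radiation", TRUE),
    # atmosphere
    e("TA",       "deg C",             -60,    60, "meteorology"),
    e("T_SONIC",  "deg C",             -60,    60, "meteorology"),
    e("T_CANOPY", "deg C",             -60,    80, "meteorology"),
    e("RH",       "%",                    0,   100, "meteorology", TRUE),
    e("PA",       "kPa",                 50,   110, "meteorology"),
    e("VPD",      "hPa",                  0,   110, "meteorology"),
    e("WS",       "m s-1",                0,    50, "meteorology"),
    e("WS_MAX",   "m s-1",                0,    80, "meteorology"),
    e("WD",       "Decimal degrees",      0,   360, "meteorology"),
    e("USTAR",    "m s-1",                0,    10, "meteorology"),
    e("MO_LENGTH","m",                 -1e5,   1e5, "meteorology"),
    e("ZL",       "adimensional",      -1e3,   1e3, "meteorology"),
    e("P",        "mm",                   0,   200, "meteorology"),
    e("P_RAIN",   "mm",                   0,   200, "meteorology"),
    e("P_SNOW",   "mm",                   0,   200, "meteorology"),
    e("D_SNOW",   "cm",                   0,  1000, "meteorology"),
    # soil
    e("TS",       "deg C",             -40,    70, "soil"),
    e("SWC",      "%",                    0,   100, "soil", TRUE),
    e("WTD",      "m",                  -10,    10, "soil"),
    # concentrations
    e("CO2",      "umolCO2 mol-1",      150,  1200, "concentration"),
    e("H2O",      "mmolH2O mol-1",        0,   100, "concentration"),
    e("CH4",      "nmolCH4 mol-1",      500, 20000, "concentration"),
    # footprint
    e("FETCH_MAX","m",                    0,   1e5, "meteorology"),
    e("FETCH_90", "m",                    0,   1e5, "meteorology"),
    # quality flags (0-2 steady-state / integral turbulence class)
    e("FC_SSITC_TEST",   "adimensional", 0, 2, "quality_flag"),
    e("FCH4_SSITC_TEST", "adimensional", 0, 2, "quality_flag"),
    e("LE_SSITC_TEST",   "adimensional", 0, 2, "quality_flag"),
    e("H_SSITC_TEST",    "adimensional", 0, 2, "quality_flag"),
    e("TAU_SSITC_TEST",  "adimensional", 0, 2, "quality_flag")
  )
}

#' Look up a variable base name in a registry
#'
#' @param base Base variable name (e.g. `"FC"`).
#' @param registry Registry data.frame, defaults to [fp_registry()].
#' @return A one-row data.frame, or `NULL` when the base is not registered
#'   (not-found is a value, not an error; units are never guessed).
#' @export
registry_lookup <- function(base, registry = fp_registry()) {
  i <- match(base, registry$base)
  if (is.na(i)) return(NULL)
  registry[i, , drop = FALSE]
}

#' Extend a variable registry
#'
#' @param registry Registry data.frame.
#' @param base,units,hard_min,hard_max,kind,percent Entry fields;
#'   `hard_min < hard_max` is required.
#' @return The extended registry.
#' @export
registry_add <- function(registry, base, units, hard_min, hard_max,
                         kind = "meteorology", percent = FALSE) {
  stopifnot(is.character(base), nzchar(base), hard_min < hard_max)
  rbind(registry, data.frame(base = base, units = units, hard_min = hard_min,
                             hard_max = hard_max, kind = kind, percent = percent,
                             stringsAsFactors = FALSE))
}

.general_qualifiers <- c("PI", "F", "QC", "SD", "N")

#' Parse an FP variable label
#'
#' Labels are a base name, optional general qualifiers from
#' `{PI, F, QC, SD, N}`, and an optional trailing positional triple
#' `_<h>_<v>_<r>` of positive integers (horizontal / vertical / replicate).
#' A partial positional suffix (e.g. `TA_1_1`) is not split: the parse
#' succeeds with the full string as base plus a naming warning.
#'
#' @param label Non-empty variable label.
#' @param registry Registry used to recognise base names.
#' @return An object of class `fp_variable`: list with `label`, `base`,
#'   `h_index`, `v_index`, `r_index`, `general_qualifiers`, `known`
#'   (base found in registry), and `warnings` (character).
#' @examples
#' parse_variable_name("TA_1_1_1")
#' parse_variable_name("SWC_2_3_1")$v_index
#' @export
parse_variable_name <- function(label, registry = fp_registry()) {
  if (!is.character(label) || length(label) != 1 || is.na(label) || !nzchar(label)) {
    stop("variable label must be a non-empty string", call. = FALSE)
  }
  warnings <- character(0)
  rest <- label
  h <- v <- r <- NA_integer_
  m <- regmatches(rest, regexec("^(.*)_([0-9]+)_([0-9]+)_([0-9]+)$", rest))[[1]]
  if (length(m) == 5 && nzchar(m[2])) {
    idx <- as.integer(m[3:5])
    if (all(idx >= 1)) {
      rest <- m[2]
      h <- idx[1]; v <- idx[2]; r <- idx[3]
    }
  } else if (grepl("^(.+)_[0-9]+(_[0-9]+)?$", rest)) {
    warnings <- c(warnings, paste0(
      "partial positional suffix in '", label,
      "': expected the full _<h>_<v>_<r> triple; treating whole label as base"))
  }
  # peel general qualifiers off the tail of the remaining base
  quals <- character(0)
  repeat {
    m <- regmatches(rest, regexec("^(.*)_([A-Z0-9]+)$", rest))[[1]]
    if (length(m) == 3 && m[3] %in% .general_qualifiers && !is.null(registry_lookup(m[2], registry))) {
      quals <- c(m[3], quals)
      rest <- m[2]
    } else break
  }
  if (!grepl("^[A-Z][A-Z0-9_]*$", rest)) {
    warnings <- c(warnings, paste0("base '", rest, "' is not upper-case alphanumeric/underscore"))
  }
  known <- !is.null(registry_lookup(rest, registry))
  if (!known) {
    warnings <- c(warnings, paste0("base '", rest, "' is not in the variable registry"))
  }
  structure(list(label = label, base = rest, h_index = h, v_index = v, r_index = r,
                 general_qualifiers = quals, known = known, warnings = warnings),
            class = "fp_variable")
}

#' @export
print.fp_variable <- function(x, ...) {
  pos <- if (is.na(x$h_index)) "" else sprintf(" [h=%d v=%d r=%d]", x$h_index, x$v_index, x$r_index)
  qual <- if (length(x$general_qualifiers)) paste0(" {", paste(x$general_qualifiers, collapse = ","), "}") else ""
  cat(sprintf("<fp_variable> %s -> base=%s%s%s%s\n", x$label, x$base, qual, pos,
              if (x$known) "" else " (unregistered)"))
  invisible(x)
}
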