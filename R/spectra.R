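# Time-averaged, bias-rectified Morlet wavelet power spectra of long flux
# series. Rectification (power divided by scale, after an L1-style
# amplitude normalization of the mother wavelet) removes the systematic
# bias in favour of large scales, so that spectral levels are comparable
# across periods: a scale-free (white) series yields a flat rectified
# spectrum in expectation.

#' Rectified global Morlet wavelet spectrum
#'
#' The series is median-centered and MAD-scaled, missing values are then
#' replaced by zero (the simplest defensible gap treatment for records
#' with moderate gaps), and the continuous Morlet transform
#' (`omega0 = 6`) is evaluated by FFT over log2-spaced scales from 2
#' timesteps to a quarter of the record length (longer periods are outside
#' the cone of influence for most of the record and are excluded).
#' Time-averaged power is divided by scale (bias rectification) and
#' restored to the series' variance units, so scaling the input by `c`
#' scales the spectrum by `c^2`. Records with 25% or less data coverage
#' are refused.
#'
#' @param x Numeric series (regular timestep; `NA` = missing), or an
#'   `fp_table` together with `variable`.
#' @param resolution_minutes Timestep in minutes.
#' @param variable Variable label when `x` is an `fp_table`.
#' @param config Spectra settings from [qaqc_config()] (`omega0`, `dj`
#'   scale spacing in octaves, `coverage_min`).
#' @return Object of class `fp_spectrum`: data.frame with `scale`
#'   (timesteps), `period_hours`, `period_days`, `power` (rectified,
#'   variance per unit scale); attributes `coverage`, `variable`, `n`.
#' @examples
#' x <- sin(2 * pi * (1:4800) / 48)  # 24-h cycle at half-hourly steps
#' sp <- wavelet_global_spectrum(x, 30)
#' sp$period_hours[which.max(sp$power)]
#' @export
wavelet_global_spectrum <- function(x, resolution_minutes, variable = NA_character_,
                                    config = qaqc_config()$spectra) {
  if (inherits(x, "fp_table")) {
    stopifnot(!is.na(variable), variable %in% names(x))
    resolution_minutes <- attr(x, "resolution")
    x <- x[[variable]]
  }
  n <- length(x)
  coverage <- mean(!is.na(x))
  if (coverage <= config$coverage_min) {
    stop(sprintf("data coverage %.1f%% is at or below the %.0f%% inclusion gate",
                 100 * coverage, 100 * config$coverage_min), call. = FALSE)
  }
  omega0 <- config$omega0
  dj <- config$dj
  dt <- 1  # work in units of timesteps; convert periods afterwards
  s0 <- 2 * dt
  smax <- n * dt / 4
  if (smax < s0 * 2) stop("series too short for the requested scales", call. = FALSE)
  J <- floor(log2(smax / s0) / dj)
  scales <- s0 * 2^(dj * (0:J))

  ctr <- stats::median(x, na.rm = TRUE)
  sc <- stats::mad(x, na.rm = TRUE)
  if (!is.finite(sc) || sc == 0) sc <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(sc) || sc == 0) stop("series has no variability", call. = FALSE)
  z <- (x - ctr) / sc
  z[is.na(z)] <- 0

  n2 <- 2^ceiling(log2(n))
  zp <- c(z, rep(0, n2 - n))
  zh <- stats::fft(zp)
  k <- 0:(n2 - 1)
  omega <- ifelse(k <= n2 / 2, 2 * pi * k / (n2 * dt), 2 * pi * (k - n2) / (n2 * dt))

  power <- vapply(scales, function(s) {
    # L1-normalized Morlet daughter in the Fourier domain (analytic: omega>0)
    psi <- ifelse(omega > 0,
                  (2 * pi * s / dt) * pi^(-0.25) * exp(-(s * omega - omega0)^2 / 2),
                  0)
    w <- stats::fft(zh * psi, inverse = TRUE) / n2
    mean(Mod(w[seq_len(n)])^2)
  }, numeric(1))

  rectified <- power / scales * sc^2  # variance units of the input
  period_steps <- (4 * pi / (omega0 + sqrt(2 + omega0^2))) * scales
  out <- data.frame(scale = scales,
                    period_hours = period_steps * resolution_minutes / 60,
                    period_days = period_steps * resolution_minutes / 1440,
                    power = rectified)
  structure(out, class = c("fp_spectrum", "data.frame"),
            coverage = coverage, variable = variable, n = n)
}

#' Plot a rectified wavelet spectrum
#'
#' Log-log plot of rectified power against period (days), mirroring the
#' numbers in the spectrum table.
#'
#' @param x An `fp_spectrum`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.fp_spectrum <- function(x, ...) {
  graphics::plot(x$period_days, x$power, log = "xy", type = "l",
                 xlab = "period (days)", ylab = "rectified wavelet power",
                 main = if (!is.na(attr(x, "variable"))) attr(x, "variable") else "", ...)
  invisible(x)
}
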