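---
title: "Methods: screening flux-met records with fluxqaqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening flux-met records with fluxqaqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxqaqc)
```

## What the package screens, and why

Eddy-covariance sites submit half-hourly or hourly flux-meteorology
("flux-met") tables — CO~2~ and CH~4~ fluxes, latent and sensible heat,
radiation, meteorology and soil variables — processed independently by each
site team. Before such a record can be published in a network archive it
must (a) conform to the exchange format and (b) be free of the recurring
defect classes that independent processing produces: shifted or
daylight-saving timestamps, flipped sign conventions, percent variables
submitted as ratios, filled constants, sensor drift and calibration steps,
pre-filtered friction-velocity records, long gaps, renamed variables.

`fluxqaqc` implements both stages. Stage one (`run_format_qaqc()`) checks
the file against the FP-In conventions — comma-delimited, paired
`YYYYMMDDHHMM` start/end timestamps in local standard time, `-9999` missing
sentinel, controlled variable vocabulary — and makes exactly one automatic
correction pass for the minor, mechanical defects (skipped rows filled with
missing values, unambiguous case-fold renames, delimiter normalization).
Stage two (`run_data_qaqc()`) combines the upload with the previously
published record and runs six check modules: timestamp alignment, physical
range, multivariate comparison, diurnal–seasonal pattern, USTAR filtering,
and variable coverage. Checks *detect*; they never alter data — corrections
beyond the format pass are the site team's responsibility, so every finding
carries a severity (`WARNING` or `ACTION_REQUIRED`), the affected span, and
the numeric evidence.

## The solar reference

Most timing and radiation checks compare measured shortwave radiation
against top-of-atmosphere potential radiation
$SW_{pot} = S_0 \, E_0(t) \, \max(\cos\theta, 0)$ with $S_0 = 1361$ W m⁻²,
the Sun–Earth eccentricity factor $E_0$ and zenith angle $\theta$ from
$\cos\theta = \sin\phi\sin\delta + \cos\phi\cos\delta\cos h$.
Declination, equation of time and $E_0$ use Spencer's (1971) Fourier
series; the day angle is anchored to the 2000-01-01 epoch modulo the mean
tropical year (365.2422 d), which removes the ±0.75-day leap-cycle jitter
of calendar-anchored day counts and keeps worst-case zenith error below
0.2° against the NOAA solar-position equations. Two properties matter more
than absolute accuracy:

* **Translation**: $SW_{pot}$ is a pointwise function of the timestamp, so
  lag-shifting the time axis lag-shifts the series *exactly*. The
  cross-correlation lag estimator inherits this exactness.
* **Midpoint evaluation**: the reference is evaluated at interval
  midpoints, so a beginning-vs-ending timestamp confusion appears as
  exactly a ±1-interval lag rather than a smeared half-step.

## The six data checks

**Timestamp alignment.** Measured SW_IN (fallback PPFD_IN) is
cross-correlated against $SW_{pot}$ in 15-day windows stepping 5 days,
over lags of ±10 intervals. Each window is median/MAD-standardized first,
so amplitude faults (unit errors, degradation) cannot corrupt the timing
estimate. Window-lag patterns classify the defect: a constant nonzero lag
(timestamp shift / timezone mismatch; ±1 interval specifically suggests
endpoint confusion), two season-long plateaus exactly one hour apart
(daylight-saving time), or disagreeing lags between SW_IN and PPFD_IN
(unsynchronized streams). Radiation-magnitude issues live in the same
module: readings above $1.05 \times SW_{pot}$ (unit/calibration error), a
persistent morning–afternoon asymmetry of the clearness ratio (tilted
sensor), and a contiguous depressed time-of-day sector (shading).

**Physical range.** Hard physical limits per variable come from the
shipped registry (user-extensible). Plausible ranges are *site-specific*:
per variable and meteorological season, median ± 6 spread with
spread = max(MAD, IQR/1.349) — the IQR fallback matters for strongly
bimodal series such as radiation, whose seasonal median sits at the night
value — clipped to the hard limits. Percent-kind variables whose
non-missing maximum is ≤ 1.5 are flagged as ratios. The variability
screens operate on daily *means* (the daily median of a half-zero series
is a discontinuous function of day length) after removing annual +
semiannual harmonics: a Theil–Sen trend over the record; a step-change
scan that first locates the best breakpoint by adjacent 30-day window
medians and then refits the harmonics jointly with a step dummy (a smooth
fit alone absorbs about a third of an abrupt shift), flagging when the
step amplitude exceeds 4× the robust residual scale; runs of ≥ 48
identical non-zero values (filled constants — exact zeros are physically
meaningful for radiation or precipitation and are exempt); and excess
probability mass at an interior extreme (processing cut-off). Thresholds
were calibrated by Monte Carlo so that clean synthetic years and white
noise stay silent (type-I < 5%).

**Multivariate comparison.** Physically coupled pairs —
(PPFD_IN, SW_IN), (USTAR, WS), (T_SONIC, TA), (NETRAD, SW_IN) — are fit
with a deterministic Theil–Sen regression globally and in 15-day windows
stepping 5 days (short enough that a two-week defect dominates at least
one window). Exact (0, 0) pairs (radiation at night) are excluded: they
carry no information about the relation and would collapse the residual
MAD. Findings: excess residual outliers, a window median residual biased
beyond 3× the residual MAD (short-term mismatch), full-record R² >
0.9999 (one variable derived from the other), monotonic drift of the
windowed slope (sensor degradation) or an abrupt slope step (calibration
change).

**Diurnal–seasonal pattern.** Monthly median diurnal composites (one bin
per timestep, with interquartile band and counts). For FC the sign
convention is checked in growing-season months — defined internally as
months whose daytime composite amplitude exceeds 25% of the annual
maximum, avoiding any external phenology input: a daytime composite above
the nighttime level *while positively correlated with the potential
radiation composite* means daytime uptake is positive, i.e. the sign is
flipped. The module also corroborates timestamp shifts at monthly
resolution, flags composite levels outside hard limits, and (for
multi-year records) year-over-year composite displacement.

**USTAR filtering.** Nighttime is defined as computed $SW_{pot} = 0$ —
deliberately not measured radiation, so the definition survives radiation
faults. Nighttime USTAR is binned at 0.05 m s⁻¹; if every bin below some
edge has FC availability < 0.1 while the data above are ≥ 0.5 available,
FC was threshold-filtered before upload and the highest such edge
estimates the threshold (recovered within one bin width for thresholds of
0.1–0.4 m s⁻¹). A nighttime USTAR 1st percentile above 0.1 m s⁻¹ flags a
truncated USTAR record itself.

**Variable coverage.** Longest *interior* missing run per variable
(> 60 days flags a long gap; leading/trailing spans reflect the record
period, not a gap — this also makes every check invariant to padding the
record with missing rows), all-empty columns, the mandatory-variable rule
(timestamps plus at least one of FC/FCH4) re-asserted on the combined
record, and label-set drift against the previously published record.

Reports are assembled deterministically (`PASS < SKIPPED < WARNING <
ACTION_REQUIRED`, overall = maximum across checks); JSON is canonical and
byte-stable, text is derived from it.

## The synthetic site and fault taxonomy

`generate_clean()` emulates a temperate mid-latitude grassland
(40°N, 105°W, UTC−7, one half-hourly year by default): daily-varying
clearness times $SW_{pot}$ (logistic-squashed into (0.35, 0.95), so clean
radiation never exceeds the ceiling); PPFD_IN = 2.04 µmol J⁻¹ × SW_IN
plus noise (the canonical conversion, giving the multivariate pair a known
slope); air temperature as seasonal + diurnal sinusoids with AR(1) noise;
a rectangular-hyperbola light response with Q10 respiration for FC
(daytime uptake negative by construction); Bowen-ratio energy partition;
lognormal, diurnally modulated wind speed with USTAR ≈ 0.1·WS; slow AR(1)
soil moisture; and a seasonal-bump CH~4~ flux template. One global seed
expands into named substreams, so adding a variable never perturbs
existing ones. Defaults are fixed study conditions, not tuning knobs.

`fault_spec()` / `inject_fault()` implement the thirteen defect kinds of
the issue taxonomy (timestamp shift, DST, sign flip, unit ratio, constant
fill, step change, drift, cut-off, outliers, USTAR filtering, long gap,
dropped variable, skipped rows); `fault_check_map()` ships the
fault-to-check oracle and `make_fixture()` builds deterministic faulted /
clean twins. The package's core testable contract is the paired matrix:
across 20 seeds, every fault kind must trigger its designated check
(sensitivity ≥ 95%) while the clean twin stays silent (false-alarm ≤ 5%).

What the generator does *not* emulate — storm fronts, snow on the
radiometer, advection, instrument-specific spectra, heteroscedastic flux
error — bounds what the passing matrix shows: the detectors respond to
the defect signatures, at realistic noise levels, without tripping on a
well-behaved record. It is not evidence about false-alarm rates on messy
real sites; the configurable thresholds (`qaqc_config()`, YAML-overridable)
exist precisely because production use needs site-by-site judgment.

## Wavelet spectra and rectification

`wavelet_global_spectrum()` characterizes multi-year records: the series
is median-centered, MAD-scaled, gaps set to zero (the simplest defensible
treatment; the coverage must exceed 25% or the function refuses),
transformed with a continuous Morlet wavelet ($\omega_0 = 6$) by FFT over
log2-spaced scales (¼-octave spacing) from 2 timesteps to a quarter of
the record, time-averaged, divided by scale, and restored to variance
units.

The normalization is chosen for the rectification property: with an
L1-style amplitude normalization of the Morlet daughter
($\propto 2\pi s/dt$), expected power of scale-free (white) noise grows
linearly with scale, so dividing by scale yields a *flat* rectified
spectrum for an uncorrelated process — the point of rectification — while
a pure sinusoid still peaks within one scale step of its true period.
(Under the common $\sqrt{2\pi s/dt}$ normalization, white-noise power is
already flat and dividing by scale would tilt it to slope −1; that
combination cannot satisfy both properties at once.) Two invariants are
tested: homogeneity (scaling the series by $c$ scales power by $c^2$ to
machine precision) and white-noise flatness (|log–log slope| < 0.1
averaged over 50 seeds). Periods beyond a quarter of the record sit
outside the cone of influence for most of the series and are excluded.

## Problem sizes and numerical choices

The test suite and the acceptance script use one-year half-hourly
synthetic sites (17,520 rows) for the fault matrix, 20 seeds in the suite
and 10 in the script; fuzzed format round trips use 1,000 small files;
spectra use 2,048–4,096-point series for the noise properties and a
multi-year hourly record for the flux example. These sizes were chosen so
the full contract runs comfortably on a laptop-class single core while
every statistic is far from its decision boundary.

Numerical conventions worth knowing: missing is `NA` internally and
`-9999` only on disk (matched numerically on read, so `-9999.0` variants
collapse; serialized exactly as `-9999`); numbers are written with the
shortest decimal representation that round-trips exactly, never
scientific for ordinary magnitudes; Theil–Sen fits subsample
deterministically (evenly spaced) so reports are byte-reproducible; ties
in the modal-lag vote resolve toward the smaller lag via the ordering of
the lag grid; timestamps are local standard time throughout — encoding
daylight-saving time is itself a defect the alignment check detects.

## Known limitations

* The shipped registry covers the ~45 most commonly submitted variables,
  not the full FP vocabulary; unknown bases degrade to naming warnings
  and are excluded from range checks (`registry_add()` extends it).
* Shading and tilt detectors assume a reasonably stationary clearness
  climatology; persistent cloud regimes (maritime sites) may need looser
  `radiation` thresholds.
* The sign-convention check targets FC; CH~4~ has no reliable
  radiation-tracking diurnal signature at many sites, so a flipped FCH4
  record is only caught if its composite tracks radiation.
* Year-over-year composite displacement needs at least two calendar
  years; single-year uploads skip it silently.
* The step-change and trend screens share a daily-mean pathway and will
  both fire on severe faults; the report lists both rather than
  adjudicating a root cause, which mirrors how a reviewer reads it.
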