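# fluxqaqc

Quality assurance and quality control for half-hourly/hourly
eddy-covariance flux-meteorology ("flux-met") records, for the people who
curate them: network data teams screening site submissions before
publication, and site teams who want to run the same screens before
uploading.

Flux-met tables (CO₂/CH₄ flux FC/FCH4, latent/sensible heat LE/H,
radiation SW_IN/PPFD_IN/NETRAD, meteorology TA/RH/WS/USTAR, soil TS/SWC, …)
are produced independently at every site, which makes a handful of defect
classes endemic: shifted or daylight-saving timestamps, flipped sign
conventions, percent variables submitted as ratios, filled constants,
drift and calibration steps, friction-velocity-filtered fluxes, long gaps,
renamed variables. `fluxqaqc` implements the two screening stages such a
pipeline needs, plus the machinery to test them end to end:

* **Format QA/QC** — compliance with the FP-In exchange conventions
  (comma-delimited, paired `YYYYMMDDHHMM` start/end timestamps in local
  standard time, `-9999` missing sentinel, controlled variable
  vocabulary), with exactly one automatic correction pass for mechanical
  defects. Status: `PASS` / `FIXED` / `FAIL`.
* **Data QA/QC** — six detection modules run on the upload combined with
  the previously published record: timestamp alignment (windowed
  cross-correlation of measured radiation against top-of-atmosphere
  potential radiation `SW_pot = S0 · E0 · max(cos θ, 0)`), physical range
  (site-specific seasonal plausible ranges, median ± 6·spread, plus
  variability screens), multivariate comparison (Theil–Sen fits of
  coupled pairs such as PPFD_IN ~ SW_IN), diurnal–seasonal composites
  (sign-convention check), USTAR-filtering detection (nighttime FC
  availability by 0.05 m s⁻¹ friction-velocity bin), and variable
  coverage. Findings carry severity, span and numeric evidence; reports
  serialize to canonical, byte-deterministic JSON.
* **Synthetic sites + fault injection** — `generate_clean()` emulates a
  mid-latitude site (light-response CO₂ flux with Q10 respiration,
  Bowen-ratio energy partition, AR(1) noise); `inject_fault()` implements
  the thirteen-defect taxonomy; `fault_check_map()` pairs every fault
  with the check that must catch it.
* **Rectified wavelet spectra** — time-averaged Morlet (ω₀ = 6) power
  divided by scale, normalized so a scale-free process is flat, for
  characterizing sub-daily to interannual flux variability.

## Worked example

```r
library(fluxqaqc)

cfg  <- synthetic_site_config(seed = 10)   # one half-hourly year, 40°N
tab  <- generate_clean(cfg)
bad  <- inject_fault(tab, list(
  fault_spec("SIGN_FLIP",  var = "FC"),
  fault_spec("UNIT_RATIO", var = "RH", factor = 0.01)))

rep <- run_data_qaqc(bad, cfg$site)
rep
```

```
DATA QA/QC report — site US-Syn
overall status: ACTION_REQUIRED
tool version: 0.1.0

per-check status:
  timestamp_alignment  PASS
  physical_range       ACTION_REQUIRED
  multivariate         PASS
  diurnal_seasonal     ACTION_REQUIRED
  ustar_filtering      PASS
  variable_coverage    PASS

findings (2):
  - physical_range/PERCENT_AS_RATIO (ACTION_REQUIRED) [RH]: RH is a percent variable but its maximum is 0.938: values appear to be ratios (multiply by 100)
    metrics: max_value=0.938003, n=17520
    action: correct at the site/processing level and resubmit
  - diurnal_seasonal/SIGN_FLIP (ACTION_REQUIRED) [FC]: daytime FC composite exceeds nighttime in 6 growing-season month(s) while tracking radiation: sign convention appears flipped (uptake must be negative)
    metrics: n_months=6, n_growing=6
    action: correct at the site/processing level and resubmit
```

Both injected defects are flagged with the evidence a site team needs (the
RH maximum; the number of growing-season months whose daytime composite
sits above the nighttime level), and the clean twin `tab` produces an
all-`PASS` report with zero findings. `report_to_json(rep)` gives the
canonical machine-readable form.

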