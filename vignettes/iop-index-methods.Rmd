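---
title: "Monthly absorption baselines and the IOP index: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monthly absorption baselines and the IOP index: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(bloomindex)
```

## The problem and the model

Coastal phytoplankton blooms are deviations from a site's own typical
conditions, not exceedances of a universal biomass threshold. This package
operationalizes that idea for two satellite-retrieved inherent optical
properties at a fixed monitoring point: phytoplankton absorption
(`aphy`, m^-1^) and combined detritus + colored-dissolved-organic-matter
absorption (`adcdom`, m^-1^), both at a single blue reference band.

The procedure, per monitoring point and per calendar month:

1. **Climatology.** Pool every observed day of that month across the
   archive years (all Mays together, all Junes together) and compute each
   coefficient's mean and sample (n−1) standard deviation over its own
   valid days.
2. **Standardization.** Each day's pair becomes standardized anomalies
   `Z = (x − mean) / sd`, dimensionless, in SD units.
3. **SOEF index.** Eigen-decompose the 2×2 sample correlation matrix of
   the standardized pair. The first (leading-eigenvalue) unit eigenvector
   `(b11, b12)` weights the pair into the daily scalar
   `index = b11·Z_aphy + b12·Z_adcdom` — the direction of maximal joint
   variability of the two optically active constituents. For a 2×2
   correlation matrix with correlation r this is analytic:
   λ₁ = 1 + |r|, and the eigenvector is (1, sign(r))/√2.
4. **Baseline.** The mean index over the fitting period. On a gap-free fit
   it is exactly 0 (each Z averages to zero over its own fitting set);
   with realistic per-coefficient QC dropouts the standardization sets and
   the paired index set differ slightly, so real archives produce small
   magnitudes of order 10^-3^. The baseline's job is to be the reference
   that new seasons are compared against.
5. **Classification.** index < 1 → non-bloom; 1 ≤ index < 1.6 →
   pre-alert (a growing or decaying bloom); index ≥ 1.6 → active bloom.
   The 1.6 comes from the standard-normal inverse CDF: the two-sided 90%
   quantile `qnorm(0.95) = 1.645` rounds to 1.6 SD — values beyond it are
   unlikely to be noise under standardization.

Key assumptions: standardized anomalies are approximately Gaussian on
non-bloom days; the two coefficients co-vary positively enough that their
leading joint mode is bloom-like; and the month-by-month climatology
absorbs the seasonal cycle, so anomalies in different months are
comparable.

## Frozen models and scoring

`fit_baseline()` freezes climatology, eigenvector and thresholds together;
`compute_index_series()` scores any data — including seasons after the
fitting period — against the frozen model without refitting. Refitting is
an explicit act (call `fit_baseline()` again with a longer year range), as
an operational archive grows each year.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `pre_alert` | 1 | SD | one climatological SD: the conventional boundary of "average" conditions |
| `active` | 1.6 | SD | `round(qnorm((1+0.90)/2), 1)`: 90% two-sided noise bound |
| `confidence` | 0.90 | — | the confidence level the active threshold derives from |
| `window` | 3 | pixels | 3×3 averaging around the pixel of interest, standard for 1-km daily products |
| `min_valid` | 1 | pixels | permissive by default; raise to 5 for stricter QC |
| `max_hold_days` | 14 | days | held states older than this are flagged stale — the longest outage the monitoring narrative contemplates |

Classification bands are left-closed (`[1, 1.6)`, `[1.6, ∞)`), so every
finite index has exactly one label and interval frequencies sum to 100%.
Values ≤ −1 are anomalously clear water: classified non-bloom, flagged by
`negative_anomaly()`.

## Gap handling

Cloud cover makes the daily record sparse (in the emulated regime only a
quarter to a third of possible days are observed). Two rules:

* **Pair completeness.** The index needs both coefficients; a day with
  only one valid value keeps it in the raw series for QC but is missing
  for the index.
* **Conservative holding.** `hold_state()` makes each missing day inherit
  the last observed state — the worst known scenery persists until new
  imagery overrides it. Held states never escalate, holding never
  expires (only a `stale` flag after `max_hold_days`), and days before
  the first observation are `UNKNOWN` rather than assumed safe.

## What the synthetic generator emulates — and what it does not

`simulate_series()` draws standardized pairs from a bivariate normal with
unit variances and correlation `rho`, adds bloom anomalies in SD units,
then maps to the absorption scale as `mean·(1 + cv·z)`, floored at
10^-5^ m^-1^ (absorption is physically positive). Injecting blooms after
the correlation structure makes the injected amplitude directly
interpretable against the standardization. Defaults encode the emulated
study regime: years 2003–2016, months May–June, `base_mean_aphy` =
0.05 m^-1^ and `base_mean_adcdom` = 0.04 m^-1^ (typical coastal blue-band
magnitudes), `cv` = 0.4, `rho` = 0.6, `missing_prob` = 0.7 (yielding
roughly 100–150 observed days per month over 14 years, the satellite
archive's order of magnitude). Real calendar dates, leap days included,
exercise the month-grouping logic; an optional cloudy-spell mode gives
geometric multi-day outages instead of i.i.d. gaps.

Under this null, the index over a fitting set has sample variance λ₁ =
1 + r, so the bloom-free active rate is approximately
1 − Φ(1.6/√(1+ρ)) ≈ 10% at ρ = 0.6 — an intrinsic property of the
threshold, not a tunable. The tests verify exactly this calibration.

Deliberate simplifications, and hence what passing tests do *not* show
about real data:

* **Stationary climatology.** Outside injected events every year has the
  same distribution, so the only era contrast a trend split can find is
  the injected-event excess; a real archive whose later years genuinely
  sink below the long-term climatology would show after-era exceedance
  near zero, which the stationary generator cannot produce.
* **No spectral structure** (one reference band), no radiative transfer,
  no retrieval error model: satellite "noise" is the same lognormal-like
  daily variability as the signal.
* **Gaussian tails.** Real absorption distributions are right-skewed;
  extreme-quantile behavior of the real index may differ from the normal
  calibration above.
* **Missingness independent of state.** Real cloud cover can correlate
  with bloom-favorable weather.

## Numerical and design choices

* Sample (n−1) SD throughout: the climatology is a sample estimate.
* Eigenvector sign convention: orient so `b11 ≥ 0`; an unoriented
  eigenvector is defined only up to sign, which would flip bloom and
  non-bloom. At r = 0 exactly (λ₁ = λ₂) the direction is undefined; the
  model returns (1, 0), flagged `degenerate`.
* Degenerate inputs error early and by name: constant series (sd ≤ 0),
  fewer than 2 paired observations, windows larger than the grid.
* Percentages are computed at full precision; `round_half_up()` is
  applied only at presentation (so a printed 12.5 becomes 13).
* Matchups default to the nearest valid satellite day within ±8 days
  (ties to the earlier day); composite mode averages the window instead,
  mirroring multi-day satellite composites around a field campaign.
* Missing yearly exceedance is `NA`, never 0: an unobserved year is not a
  bloom-free year.
* One model per (point, month). Pooling May+June into one SOEF is
  possible in principle but mixes climatologies; per-month models keep
  the anomaly scale honest and match the separate per-month baselines the
  method reports.
* Granules travel as plain-text long-format CSV with a comment header;
  the same window-extraction surface would sit unchanged over a NetCDF
  reader.

## Problem sizes

The test suite and the analysis scripts run at desk scale by design: 14
simulated years × 2 months per point (~850 calendar days, ~250 observed at
the default missingness), 5 000+ gap-free days for the null-calibration
check, 1 000 random pairs for the eigensolver cross-check, and 100-day
fits for the baseline-zero check. All are fast, deterministic under fixed
seeds, and sized so the statistical tolerances (3 binomial SDs; 3 standard
errors) have comfortable margins.

## Known limitations

* Two variables only; the design deliberately stops short of multivariate
  or spatial EOF modes.
* The index inherits the ~10% null exceedance rate of a 1.6-SD threshold
  under correlated Gaussian noise; operational use relies on persistence
  and the pre-alert band, not on single red days.
* Held states are information-free repetitions; a 30-day hold of a chance
  red observation (visible in the demo season) is the price of the
  conservative rule and is why the `stale` flag exists.
* The Spearman validation with n = 6 stations has low power; it reports
  effect size and p-value but cannot sharply discriminate at that sample
  size.
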