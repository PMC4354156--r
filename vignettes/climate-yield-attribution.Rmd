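---
title: "Attributing crop-yield variability to climate variability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributing crop-yield variability to climate variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(yieldclim)
library(dplyr)
```

## The question and the model

Crop yields at a political unit (a county, district or department) change
from year to year for two broad reasons: slow technological and management
trends, and inter-annual fluctuations — of which climate is a leading
candidate driver. This package asks, for each unit: *how much of the
inter-annual (detrended) yield variability is explained by detrended
temperature and precipitation variability, and which climate drivers
describe it best?*

The statistical model is a per-unit ordinary least-squares regression of
detrended yields on detrended climate predictors,

$$Y_c = f(T_c, P_c) + \varepsilon,$$

where $Y_c$ is the detrended yield series (t/ha), and $T_c$ and $P_c$ enter
in two timescales — the growing-season aggregate (planting through harvest
month) and the annual aggregate (the 12 months ending at harvest, capturing
antecedent conditions) — and two powers, linear ("normal" variation) and
squared ("extreme" variation). That yields eight predictor forms; $f$ is
linear in parameters over a subset of them, optionally with a
temperature-by-precipitation interaction.

Fitting every subset would overfit 30-year series badly, so candidate
designs are restricted to a fixed set of 27 combinations
(`default_model_set()`): 12 single-variable designs, 10 same-timescale
combined designs, and 5 mixed-timescale designs. The set covers all eight
forms and all seven driver categories. The exact published composition of
such candidate sets is rarely available; ours is a reconstruction with the
documented block structure, and `read_model_set()` loads any alternative
set from CSV, so the enumeration is data, not code.

Per unit, every design is fit by OLS and scored with
$\mathrm{AIC} = n\ln(\mathrm{RSS}/n) + 2k$ ($k$ = terms + intercept; the
constant error-variance offset cancels within a unit). The minimum-AIC
design wins; ties within $10^{-9}$ go to fewer terms, then to the earlier
enumeration rank. The winner is then tested against the intercept-only null
with a nested F-test at $P = 0.10$ (0.05 and 0.01 flags are always emitted
alongside). Small-sample AICc is available via `ic = "aicc"`; AIC remains
the default because the plain criterion is the field's standard for this
procedure.

## Categories and variance decomposition

The selected design's *structure* (never its coefficients) maps to one of
seven categories: i/iii/v for temperature-only designs (normal, normal +
extreme, extreme), ii/iv/vi for precipitation-only, and vii for any design
involving both variables, including via an interaction.

Explained variance is split by refitting *reduced models*: only the
temperature terms of the winner, and only its precipitation terms.
Interaction terms are excluded from both reduced fits by default — they are
joint effects and would otherwise be double-counted; setting
`include_interactions = TRUE` keeps them in both instead. Because reduced
models are refit rather than carved out of the full fit's sums of squares,
suppressor configurations can in principle push a reduced $r^2$ above the
full one; the package guarantees only $[0,1]$ membership and the
`decomposition` autoplot makes such units visible.

## Aggregation

Unit results are averaged with each unit's 30-year mean harvested area as
its weight, and — deliberately — **only over units whose selected model is
significant**. The area fraction and production fraction (area × mean
yield) under significant climate influence are reported as the coverage of
those averages, at all three cutoffs. `production_fluctuation()` converts
an explained fraction into tonnage: fraction × yield s.d. × area.

```{r worked}
sim <- simulate_panel(sim_config(n_units = 200, seed = 1))
an  <- detrend_panel(sim$panel)
att <- attribute_units(an, select_models(an))
agg <- aggregate_results(att, sim$panel)
agg |> select(alpha, area_weighted_r2, significant_area_fraction)
```

## What the synthetic generator emulates — and what it does not

`simulate_panel()` draws, per unit: a constant harvested area, a baseline
yield and linear trend (t/ha per year), four climate series, a generating
design from a configurable mixture (or "none"), and Gaussian noise. The
signal evaluates the design on sample-centered climate anomalies with
coefficients scaled analytically, in expectation, so that
$\mathrm{Var(signal)}/(\mathrm{Var(signal)} + \sigma^2_\varepsilon)$ equals
the target `effect_size`; each term contributes equal expected variance.
The *realized* fraction is recorded per unit
(`truth$true_r2 = var(signal)/var(signal + noise)`), so recovery tests
never depend on the expectation holding exactly.

Defaults are chosen once to emulate the study regime: 30 harvest years
(1979–2008), yields around 4 t/ha with noise s.d. 0.5 t/ha, trend slopes
0.02–0.08 t/ha/yr, growing-season temperature 22 ± 1 °C, seasonal
precipitation totals 450 ± 90 mm, and a target explained fraction of 0.35
("roughly a third"). Climate is drawn independently across years (an AR(1)
knob exists; yield detrending targets trends, not persistence) and
independently across the four predictor series. Homoscedastic Gaussian
noise is an assumption matching the OLS inference, not an empirical claim
about yield residuals.

The generator does **not** emulate real gridded-climate statistics,
spatial autocorrelation across units, cross-timescale correlation of
predictors (in reality the growing season is part of the annual window),
heteroscedastic or skewed yield shocks, or evolving crop calendars. Passing
tests therefore certify the *procedure* — selection, testing,
decomposition, aggregation — under the model's own assumptions, not the
magnitude of real-world explained fractions.

The gridded tier (`simulate_grid()`) adds a toy monthly grid with a lead
year of months, per-unit cell weights and calendars (a configurable share
wrapping the year boundary, e.g. November–March) so the remap and
window-aggregation code paths are exercised; its fields persist as
long-format CSV (time × row × col), a plain-text stand-in for array
storage.

## Numerical and procedural choices

- **Detrending** defaults to linear OLS residuals per unit; quadratic
  residuals and first differences are provided because conventions differ
  across the literature and the choice is not always reported. With first
  differences, yield *and* climate are differenced identically so the
  panel stays aligned, at the cost of one year.
- **Seasonal precipitation is summed, temperature averaged** (standard
  agro-climatology); both are switchable to means. The choice rescales
  coefficients but cannot change $r^2$, AIC ranking, F statistics or
  categories, which are invariant to positive rescaling of predictors (a
  property test pins this).
- **Missing years** are handled by complete-case analysis per design;
  units under 15 usable years are flagged `insufficient_data` and excluded
  from aggregation. Designs need at least 5 residual degrees of freedom.
- **Perfect fits** (numerically zero RSS) get an AIC of $-\infty$ so they
  always win, with ties still resolved toward fewer terms.
- **The null model** for the F-test is intercept-only *on the winner's
  rows*, so the comparison is properly nested even with missing data.
- **Bootstrap bias** (`bootstrap_bias()`): 99 repetitions, exact
  80/20 partitions (training size $\lceil 0.8n\rceil$, test the
  complement), refitting the *fixed* selected design — re-running the full
  selection per repetition is available behaviourally by calling
  `select_model()` on subsets, but the default matches the cheaper
  fixed-design reading of leave-group-out validation. Prediction happens on
  the anomaly scale; the bias is standardized by the unit's mean raw yield.
- **No multiple-testing correction across units**: each unit is tested
  independently, matching the procedure this package implements; the
  selection step *does* inflate the per-unit false-positive rate above the
  nominal 10% (measured near 60% on null units with the full 27-design
  sweep), which is documented behaviour of best-of-set selection followed
  by an F-test on the winner, not an error.

## Known limitations

Category identity is only partially identifiable for minimal designs:
for a true single-term design (e.g. normal growing-season temperature), the
winner essentially always *contains* the true term, but AIC's +2-per-term
penalty admits a spurious extra term often enough — each one-extra-term
superset wins with probability $P(\chi^2_1 > 2) \approx 0.16$, and several
such supersets exist with mutually independent extra terms — that
exact-category recovery for category i plateaus near 40–55% regardless of
effect size or sample count. Richer categories (vii) are recovered
essentially always. Users comparing category maps across regions should
read the i↔iii↔vii distinctions, not the i-vs-ii distinction, as soft.

Problem sizes used in the shipped validation: 500 units for
explained-variance recovery, 1000 units for F-test calibration, 200 units
per category for recovery rates, 100 units for the bootstrap — all at 30
years, the study window length.
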