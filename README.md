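# yieldclim

Panel-regression attribution of inter-annual crop-yield variability to
climate variability, at the resolution of political units
(counties/districts/departments).

Yield statistics at subnational units drift upward with technology and
management; what remains after detrending is inter-annual variability, and
a first-order question for food security is how much of it temperature and
precipitation variability explain, unit by unit. `yieldclim` implements the
full procedure for answering that question on tabular yield/climate panels:

- **Candidate designs.** Detrended yields `Y` are regressed on detrended
  climate predictors built from eight forms — growing-season and annual
  (12 months ending at harvest) temperature and precipitation, each linear
  ("normal" variation) or squared ("extreme" variation) — via a fixed set
  of 27 OLS designs, `Y = f(T, P) + ε`, some with a `T × P` interaction.
- **Selection and testing.** Per unit, the minimum-AIC design wins
  (`AIC = n ln(RSS/n) + 2k`; ties to fewer terms) and is tested against the
  intercept-only null with a nested F-test at `P = 0.10` (0.05/0.01 flags
  emitted too).
- **Attribution.** The winner's term structure maps to one of seven driver
  categories (normal / normal+extreme / extreme temperature or
  precipitation, or combinations), and its explained variance is split by
  refitting temperature-only and precipitation-only reduced models.
- **Aggregation.** Unit `r²` values are averaged with mean harvested area
  as weights, **only over units with significant models**, alongside the
  harvested-area and production shares under significant climate influence,
  and `production_fluctuation()` converts explained fractions to tonnage
  (fraction × yield s.d. × area).
- **Validation surface.** A synthetic generator (`simulate_panel()`,
  `simulate_grid()`) produces panels — and a toy monthly climate grid with
  cell weights and crop calendars, including year-wrapping seasons — with
  per-unit ground-truth explained fractions, so the whole pipeline is
  testable without external data. A 99-repetition 80/20 bootstrap
  (`bootstrap_bias()`) assesses per-unit prediction bias.

Everything is data-frame-in / tibble-out and pipes cleanly; results have
`autoplot()` methods and fits support `tidy()`/`glance()`.

## Worked example

```r
library(yieldclim)
library(dplyr)

sim <- simulate_panel(sim_config(n_units = 200, seed = 1))  # known truth
an  <- detrend_panel(sim$panel)                 # linear detrending
sel <- select_models(an)                        # best of 27 designs + F-test
att <- attribute_units(an, sel)                 # categories + r2 split
agg <- aggregate_results(att, sim$panel)        # area-weighted summaries

agg |> select(alpha, area_weighted_r2, significant_area_fraction,
              n_units_significant)
#>   alpha area_weighted_r2 significant_area_fraction n_units_significant
#> 1  0.1             0.426                     0.966                 194
#> 2  0.05            0.434                     0.924                 183
#> 3  0.01            0.474                     0.758                 148

head(as_tibble(att) |> select(unit_id, design_id, category, r2_full,
                              r2_T, r2_P, dominant), 4)
#>   unit_id design_id category r2_full  r2_T  r2_P dominant
#> 1 u0001   m01       i          0.128 0.128 0     temperature
#> 2 u0002   m19       vii        0.612 0.327 0.158 temperature
#> 3 u0003   m09       vi         0.358 0     0.358 precipitation
#> 4 u0004   m08       iv         0.525 0     0.525 precipitation
```

Reading the output: at the default `P = 0.10` cutoff, 96.6% of harvested
area sits in units where the selected climate model beats the null, and
over those units climate variability explains 42.6% of detrended yield
variability (area-weighted). The generator's ground truth for the same
units is 34.1% — the gap is the documented optimism of best-of-set
selection. Per unit, e.g. `u0003` is best described by extreme
precipitation variation only (category vi), with all of its 35.8%
explained variance on the precipitation side.

`autoplot(att)` shows category counts, `autoplot(att, "decomposition")`
the T-vs-P split, and `autoplot(agg)` the aggregate across cutoffs. A YAML
config can drive the same flow end to end via `run_pipeline()` (or the
thin CLI at `inst/scripts/yieldclim-pipeline.R`), writing attribution,
aggregate and selection CSVs plus a run log.

The methods vignette (`vignettes/climate-yield-attribution.Rmd`) documents
the model, the candidate-set construction, detrending and aggregation
conventions, what the synthetic generator does and does not emulate, and
known limitations of category identifiability.

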