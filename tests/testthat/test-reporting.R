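# Descriptives, area weighting, production arithmetic, bootstrap bias.

test_that("coefficient of variation is sample sd over mean", {
  expect_equal(coefficient_of_variation(c(2, 4, 3)), sd(c(2, 4, 3)) / 3)
  expect_equal(coefficient_of_variation(rep(4, 10)), 0)
  # hand value: series (2, 4, 3, 3) -> sd 0.8164966, mean 3
  expect_equal(coefficient_of_variation(c(2, 4, 3, 3)),
               0.81649658092772603 / 3, tolerance = 1e-12)
  expect_error(coefficient_of_variation(c(1, 2)),
               class = "yieldclim_insufficient_data")
  expect_error(coefficient_of_variation(c(-2, -1, 0)),
               class = "yieldclim_config_error")
})

test_that("area-weighted mean weights by harvested area and honours the mask", {
  expect_equal(area_weighted_mean(c(0.2, 0.6), c(1, 3)), 0.5)
  expect_equal(area_weighted_mean(c(0.2, 0.8), c(5, 5)), 0.5) # equal areas
  expect_equal(area_weighted_mean(c(0.2, 0.8), c(1, 9),
                                  mask = c(FALSE, TRUE)), 0.8)
  expect_warning(out <- area_weighted_mean(c(0.2), c(1), mask = FALSE))
  expect_true(is.na(out))
  # bounded by the inputs
  set.seed(5)
  v <- runif(20); a <- runif(20, 1, 10)
  m <- area_weighted_mean(v, a)
  expect_gte(m, min(v)); expect_lte(m, max(v))
})

test_that("significant area fraction is the area share of significant units", {
  expect_equal(significant_area_fraction(c(TRUE, FALSE, TRUE), c(1, 1, 2)),
               0.75)
  expect_equal(significant_area_fraction(rep(TRUE, 3), 1:3), 1)
  expect_equal(significant_area_fraction(rep(FALSE, 3), 1:3), 0)
})

test_that("production fluctuation is the triple product, linear in each factor", {
  expect_equal(production_fluctuation(0.39, 0.6, 94e6), 21996000)
  expect_equal(production_fluctuation(0, 5, 1e9), 0)
  expect_equal(production_fluctuation(1, 1, 1), 1)
  expect_equal(production_fluctuation(0.2 * 3, 0.5, 10),
               3 * production_fluctuation(0.2, 0.5, 10))
  expect_error(production_fluctuation(-0.1, 1, 1),
               class = "yieldclim_config_error")
})

test_that("aggregation averages r2 only over significant units", {
  # two units: one clearly climate-driven, one pure noise
  set.seed(91)
  t1 <- rnorm(30); y1 <- 2 * t1 + rnorm(30, 0, 0.5)
  an <- dplyr::bind_rows(
    anomaly_unit(y1 - mean(y1), t_gs = t1, unit_id = "u0001"),
    anomaly_unit(rnorm(30), t_gs = rnorm(30), unit_id = "u0002"))
  an$t_an <- rnorm(60); an$p_gs <- rnorm(60); an$p_an <- rnorm(60)
  panel <- tibble::tibble(
    unit_id = an$unit_id, year = an$year,
    yield_t_ha = 4 + an$yield, area_ha = rep(c(100, 300), each = 30),
    t_gs_C = an$t_gs, t_an_C = an$t_an, p_gs_mm = an$p_gs, p_an_mm = an$p_an)
  sel <- select_models(an)
  att <- attribute_units(an, sel)
  agg <- aggregate_results(att, panel, alphas = 0.10)
  sig <- att$significant_0.10
  # the mask matters: masked and unmasked aggregates differ
  masked <- area_weighted_mean(att$r2_full, c(100, 300), sig)
  unmasked <- area_weighted_mean(att$r2_full, c(100, 300))
  expect_equal(agg$area_weighted_r2, masked)
  if (sum(sig) == 1) expect_false(isTRUE(all.equal(masked, unmasked)))
  expect_equal(agg$significant_area_fraction,
               significant_area_fraction(sig, c(100, 300)))
  expect_equal(agg$n_units, 2L)
})

test_that("aggregate summaries stay within bounds across alphas", {
  sim <- simulate_panel(sim_config(n_units = 40, effect_size = 0.4, seed = 17))
  an <- detrend_panel(sim$panel)
  att <- attribute_units(an, select_models(an))
  agg <- aggregate_results(att, sim$panel)
  expect_equal(nrow(agg), 3)
  frac_cols <- c("area_weighted_r2", "significant_area_fraction",
                 "significant_production_fraction", "mean_cv")
  for (cl in frac_cols) {
    expect_true(all(agg[[cl]] >= 0 & agg[[cl]] <= 1, na.rm = TRUE))
  }
  # stricter cutoffs cannot enlarge the significant area
  expect_true(all(diff(agg$significant_area_fraction) <= 1e-12))
})

test_that("bootstrap runs exactly n_reps splits and is seed-deterministic", {
  sim <- simulate_panel(sim_config(n_units = 1, effect_size = 0.5, seed = 27))
  an <- detrend_panel(sim$panel)
  sel <- select_model(an)
  design <- with(default_model_set(), terms[design_id == sel$design_id])
  b1 <- bootstrap_bias(an, design, mean_raw_yield = 4, seed = 123)
  b2 <- bootstrap_bias(an, design, mean_raw_yield = 4, seed = 123)
  expect_identical(b1$standardized_bias, b2$standardized_bias)
  expect_equal(b1$n_reps, 99L)
  expect_equal(b1$train_fraction, 0.8)
  b3 <- bootstrap_bias(an, design, mean_raw_yield = 4, seed = 124)
  expect_false(identical(b1$standardized_bias, b3$standardized_bias))
})

test_that("noise-free relationships have numerically zero bootstrap bias", {
  set.seed(37)
  t_gs <- rnorm(30)
  an <- anomaly_unit(yield = 1.7 * t_gs, t_gs = t_gs)
  b <- bootstrap_bias(an, "T:gs:1", mean_raw_yield = 4, seed = 11)
  expect_lt(abs(b$standardized_bias), 1e-10)
  expect_equal(b$status, "ok")
})

test_that("bootstrap over units derives yields from the panel", {
  sim <- simulate_panel(sim_config(n_units = 4, effect_size = 0.5, seed = 47))
  an <- detrend_panel(sim$panel)
  sel <- select_models(an)
  boot <- bootstrap_bias_units(an, sim$panel, sel, seed = 5)
  expect_equal(nrow(boot), 4)
  expect_true(all(boot$n_reps == 99L))
  expect_true(all(is.finite(boot$standardized_bias)))
})
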