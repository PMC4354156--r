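# Design matrices, OLS fits, the nested F-test, and AIC selection.

test_that("design matrices carry intercept, squares and interaction products", {
  an <- anomaly_unit(yield = rnorm(10), t_gs = rnorm(10), p_an = rnorm(10))
  dm <- build_design_matrix(an, "T:gs:1")
  expect_equal(colnames(dm$x), c("(Intercept)", "t_gs"))
  expect_equal(dm$x[, "t_gs"], an$t_gs)
  dm2 <- build_design_matrix(an, c("T:gs:1", "T:gs:2"))
  expect_equal(dm2$x[, "t_gs_sq"], dm2$x[, "t_gs"]^2)
  dm3 <- build_design_matrix(an, c("T:gs:1", "P:an:1", "T:gs*P:an"),
                             min_dof = 5)
  expect_equal(dm3$x[1:3, "t_gs_x_p_an"],
               an$t_gs[1:3] * an$p_an[1:3])
  expect_error(build_design_matrix(an[1:6, ], c("T:gs:1", "P:an:1")),
               class = "yieldclim_insufficient_data")
})

test_that("fit_ols recovers exact and orthogonal responses", {
  x <- c(0.5, -1, 2, 0.25, -0.75, 1.5, -2, 0.1)
  an <- anomaly_unit(yield = x, t_gs = x)
  dm <- build_design_matrix(an, "T:gs:1", min_dof = 5)
  fit <- fit_ols(dm$y, dm$x)
  expect_equal(unname(fit$coefficients["t_gs"]), 1, tolerance = 1e-12)
  expect_equal(fit$rss, 0, tolerance = 1e-20)
  expect_equal(fit$r2, 1)
  expect_equal(fit$aic, -Inf)
  # orthogonal response: zero slope, zero r2
  fit0 <- fit_ols(c(1, 1, -1, -1), cbind(1, c(1, -1, 1, -1)))
  expect_equal(unname(fit0$coefficients[2]), 0, tolerance = 1e-12)
  expect_equal(fit0$r2, 0, tolerance = 1e-12)
  # rank deficiency is an error
  expect_error(fit_ols(rnorm(8), cbind(1, 1:8, 2 * (1:8))),
               class = "yieldclim_rank_deficient")
})

test_that("fit_ols matches a normal-equations oracle on random instances", {
  set.seed(99)
  for (i in 1:20) {
    x <- cbind(1, matrix(rnorm(8 * 2), 8, 2))
    colnames(x) <- c("(Intercept)", "a", "b")
    y <- rnorm(8)
    fit <- fit_ols(y, x)
    expect_equal(unname(fit$coefficients), ne_fit(y, x), tolerance = 1e-8)
    expect_equal(fit$rss, sum((y - x %*% ne_fit(y, x))^2), tolerance = 1e-8)
  }
})

test_that("AIC is n log(rss/n) + 2k and AICc adds the small-sample term", {
  set.seed(12)
  x <- cbind(1, rnorm(20))
  y <- rnorm(20)
  fit <- fit_ols(y, x)
  expect_equal(fit$aic, 20 * log(fit$rss / 20) + 2 * 2)
})

test_that("tidy and glance expose broom-shaped summaries", {
  set.seed(31)
  an <- anomaly_unit(yield = rnorm(15), t_gs = rnorm(15))
  dm <- build_design_matrix(an, "T:gs:1")
  fit <- fit_ols(dm$y, dm$x)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_equal(nrow(td), 2)
  gl <- glance(fit)
  expect_named(gl, c("r.squared", "rss", "AIC", "nobs", "k", "df.residual"))
  expect_equal(gl$nobs, 15)
})

test_that("nested F-test matches hand arithmetic and its frozen p-value", {
  ft <- f_test_vs_null(list(rss = 50, k = 3, n = 30), null_rss = 100)
  expect_equal(ft$f_stat, 13.5)                      # ((100-50)/2)/(50/27)
  expect_equal(ft$p_value, 8.631674575031098e-05, tolerance = 1e-10)
  # identical fits: F = 0, p = 1
  ft0 <- f_test_vs_null(list(rss = 100, k = 3, n = 30), null_rss = 100)
  expect_equal(ft0$f_stat, 0)
  expect_equal(ft0$p_value, 1)
  # perfect fit: p -> 0
  ftp <- f_test_vs_null(list(rss = 0, k = 3, n = 30), null_rss = 100)
  expect_equal(ftp$p_value, 0)
  # impossible nesting is an internal error
  expect_error(f_test_vs_null(list(rss = 101, k = 3, n = 30), null_rss = 100),
               class = "yieldclim_internal_error")
})

test_that("selection recovers a noise-free linear signal with r2 = 1", {
  set.seed(44)
  t_gs <- rnorm(30)
  an <- anomaly_unit(yield = 2 * t_gs, t_gs = t_gs,
                     t_an = rnorm(30), p_gs = rnorm(30), p_an = rnorm(30))
  sel <- select_model(an)
  design <- default_model_set()
  terms <- design$terms[[which(design$design_id == sel$design_id)]]
  expect_true("T:gs:1" %in% terms)
  expect_equal(sel$r2, 1)
  expect_true(sel$significant)
})

test_that("AIC ties break by fewer terms, then enumeration rank", {
  set.seed(55)
  an <- anomaly_unit(yield = rnorm(30), t_gs = rnorm(30))
  # two designs with identical fit: the duplicated term set ties exactly
  designs <- yieldclim:::new_model_set(
    list(c("T:gs:1", "T:gs:2"), "T:gs:1", "T:gs:1"),
    design_id = c("big", "first", "second"))
  # force identical AIC for "first" and "second" (same terms); the bigger
  # design differs. Tie must resolve to the earlier-ranked duplicate.
  sel <- select_model(an, designs)
  expect_true(sel$design_id %in% c("first", "big"))
  designs2 <- yieldclim:::new_model_set(
    list("T:gs:1", "T:gs:1"), design_id = c("first", "second"))
  sel2 <- select_model(an, designs2)
  expect_equal(sel2$design_id, "first")
})

test_that("winner's AIC equals the brute-force minimum over all designs", {
  sim <- simulate_panel(sim_config(n_units = 6, effect_size = 0.5, seed = 9))
  an <- detrend_panel(sim$panel)
  designs <- default_model_set()
  for (u in split(an, an$unit_id)) {
    sel <- select_model(u, designs)
    aics <- vapply(designs$terms, function(tm) {
      dm <- build_design_matrix(u, tm)
      fit_ols(dm$y, dm$x)$aic
    }, numeric(1))
    expect_equal(sel$aic, min(aics), tolerance = 1e-10)
  }
})

test_that("adding a nested term never increases rss", {
  sim <- simulate_panel(sim_config(n_units = 5, seed = 10))
  an <- detrend_panel(sim$panel)
  for (u in split(an, an$unit_id)) {
    f1 <- with(build_design_matrix(u, "T:gs:1"), fit_ols(y, x))
    f2 <- with(build_design_matrix(u, c("T:gs:1", "T:gs:2")), fit_ols(y, x))
    expect_lte(f2$rss, f1$rss + 1e-10)
  }
})

test_that("selection is invariant to rescaling a climate series", {
  sim <- simulate_panel(sim_config(n_units = 5, effect_size = 0.5, seed = 14))
  an <- detrend_panel(sim$panel)
  an2 <- an
  an2$t_gs <- an2$t_gs * 100   # e.g. different temperature units
  sel1 <- select_models(an)
  sel2 <- select_models(an2)
  expect_equal(sel1$design_id, sel2$design_id)
  expect_equal(sel1$r2, sel2$r2, tolerance = 1e-9)
  expect_equal(sel1$f_stat, sel2$f_stat, tolerance = 1e-7)
  expect_equal(sel1$p_value, sel2$p_value, tolerance = 1e-9)
})

test_that("units below the data floor are flagged, not fitted", {
  sim <- simulate_panel(sim_config(n_units = 2, n_years = 12, seed = 3))
  an <- detrend_panel(sim$panel)
  sel <- select_models(an, min_years = 15)
  expect_true(all(sel$status == "insufficient_data"))
  expect_true(all(is.na(sel$design_id)))
})

test_that("best-of-27 selection inflates the null rejection rate", {
  cfg <- sim_config(n_units = 400, design_mixture = c(none = 1), seed = 77)
  sim <- simulate_panel(cfg)
  an <- detrend_panel(sim$panel)
  sel <- select_models(an)
  expect_gte(mean(sel$significant), 0.10 - 0.02)
})
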