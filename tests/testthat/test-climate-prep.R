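# Grid-to-unit remapping, calendar-window aggregation, and detrending.

test_that("remap takes the weighted mean over a unit's cells", {
  months <- tibble::tibble(year = rep(2000, 12), month = 1:12)
  fields <- list(
    t = array(rep(c(2, 6), each = 12), dim = c(12, 1, 2)),
    p = array(rep(c(10, 30), each = 12), dim = c(12, 1, 2)),
    months = months)
  w <- tibble::tibble(unit_id = "u1", row = 1L, col = 1:2,
                      weight = c(1, 3))
  out <- remap_grid_to_unit(fields, w)
  expect_equal(out$t_C, rep(5, 12))        # (1*2 + 3*6) / 4
  expect_equal(out$p_mm, rep(25, 12))
  # weight concentrated on one cell returns that cell exactly
  w1 <- tibble::tibble(unit_id = "u1", row = 1L, col = 1:2, weight = c(1, 0))
  expect_equal(remap_grid_to_unit(fields, w1)$t_C, rep(2, 12))
  # all-zero weights are a configuration error
  w0 <- tibble::tibble(unit_id = "u1", row = 1L, col = 1:2, weight = c(0, 0))
  expect_error(remap_grid_to_unit(fields, w0),
               class = "yieldclim_config_error")
})

test_that("remap output is a convex combination of the contributing cells", {
  set.seed(41)
  months <- tibble::tibble(year = rep(2000:2001, each = 12),
                           month = rep(1:12, 2))
  fields <- list(t = array(rnorm(24 * 6, 15, 5), dim = c(24, 2, 3)),
                 p = array(runif(24 * 6, 0, 200), dim = c(24, 2, 3)),
                 months = months)
  w <- tibble::tibble(unit_id = "u1", row = c(1L, 2L, 1L),
                      col = c(1L, 2L, 3L), weight = runif(3))
  out <- remap_grid_to_unit(fields, w)
  idx <- cbind(w$row, w$col)
  for (m in 1:24) {
    cells <- fields$t[m, , ][idx]
    expect_gte(out$t_C[m], min(cells) - 1e-12)
    expect_lte(out$t_C[m], max(cells) + 1e-12)
  }
})

test_that("missing months in needed cells are an error naming the month", {
  months <- tibble::tibble(year = rep(2000, 12), month = 1:12)
  tt <- array(1, dim = c(12, 1, 1)); tt[5, 1, 1] <- NA
  fields <- list(t = tt, p = array(1, dim = c(12, 1, 1)), months = months)
  w <- tibble::tibble(unit_id = "u1", row = 1L, col = 1L, weight = 1)
  expect_error(remap_grid_to_unit(fields, w), "2000-05",
               class = "yieldclim_missing_month")
})

test_that("growing-season aggregation averages T and sums P over the season", {
  monthly <- monthly_unit(2000:2001, t_C = 20, p_mm = 100)
  cal <- tibble::tibble(unit_id = "u0001", plant_month = 5L,
                        harvest_month = 9L)
  out <- seasonal_aggregate(monthly, cal, harvest_years = 2001)
  expect_equal(out$t_gs, 20)
  expect_equal(out$p_gs, 500)  # 5 months x 100 mm
  # mean option instead of total
  out_m <- seasonal_aggregate(monthly, cal, harvest_years = 2001,
                              sum_precip = FALSE)
  expect_equal(out_m$p_gs, 100)
})

test_that("wrap-around seasons pull months from the year before harvest", {
  # Nov-Mar season; monthly T cycle chosen so the window is (10,8,6,8,10)
  t_cycle <- c(6, 8, 10, rep(20, 7), 10, 8) # Jan..Dec
  monthly <- monthly_unit(2000:2001, t_C = rep(t_cycle, 2), p_mm = 10)
  cal <- tibble::tibble(unit_id = "u0001", plant_month = 11L,
                        harvest_month = 3L)
  out <- seasonal_aggregate(monthly, cal, harvest_years = 2001)
  expect_equal(out$t_gs, mean(c(10, 8, 6, 8, 10))) # 8.4
  expect_equal(out$p_gs, 50)
})

test_that("annual aggregation spans the 12 months ending at harvest", {
  monthly <- monthly_unit(2000:2001, t_C = 15, p_mm = 50)
  cal <- tibble::tibble(unit_id = "u0001", plant_month = 5L,
                        harvest_month = 9L)
  out <- annual_aggregate(monthly, cal, harvest_years = 2001)
  expect_equal(out$t_an, 15)
  expect_equal(out$p_an, 600)
  # January harvest: window is Feb(prev)..Jan; verify against hand-picked rows
  monthly2 <- monthly_unit(2000:2001, t_C = seq_len(24), p_mm = 1)
  cal2 <- tibble::tibble(unit_id = "u0001", plant_month = 10L,
                         harvest_month = 1L)
  out2 <- annual_aggregate(monthly2, cal2, harvest_years = 2001)
  expect_equal(out2$t_an, mean(2:13))
  # an incomplete window yields NA and is reported
  expect_message(
    out3 <- annual_aggregate(monthly2, cal2, harvest_years = 2000),
    "incomplete")
  expect_true(is.na(out3$t_an))
})

test_that("aggregation is linear in precipitation", {
  set.seed(11)
  monthly <- monthly_unit(2000:2002, t_C = rnorm(36, 15),
                          p_mm = runif(36, 0, 200))
  cal <- tibble::tibble(unit_id = "u0001", plant_month = 11L,
                        harvest_month = 3L)
  base <- seasonal_aggregate(monthly, cal, harvest_years = 2001:2002)
  scaled_in <- monthly
  scaled_in$p_mm <- scaled_in$p_mm * 2.5
  scaled <- seasonal_aggregate(scaled_in, cal, harvest_years = 2001:2002)
  expect_equal(scaled$p_gs, base$p_gs * 2.5)
  expect_equal(scaled$t_gs, base$t_gs)
})

test_that("detrending removes fitted trends and honours each method", {
  t <- 1:20
  expect_equal(detrend(2 + 0.1 * t, t, "linear"), rep(0, 20),
               tolerance = 1e-10)
  expect_equal(detrend(1 - 0.3 * t + 0.02 * t^2, t, "quadratic"),
               rep(0, 20), tolerance = 1e-9)
  expect_equal(detrend(rep(4, 20), t, "linear"), rep(0, 20))
  expect_equal(detrend(rep(4, 20), t, "quadratic"), rep(0, 20),
               tolerance = 1e-12)
  expect_equal(detrend(rep(4, 20), t, "first_difference"), rep(0, 19))
  expect_equal(detrend(c(1, 2, 4), method = "first_difference"), c(1, 2))
  expect_error(detrend(c(1, 2), method = "linear"),
               class = "yieldclim_insufficient_data")
})

test_that("linear and quadratic detrending are idempotent", {
  set.seed(8)
  x <- cumsum(rnorm(25)) + 0.2 * (1:25)
  for (m in c("linear", "quadratic")) {
    once <- detrend(x, method = m)
    twice <- detrend(once, method = m)
    expect_equal(twice, once, tolerance = 1e-9)
    expect_lt(abs(mean(once)), 1e-9)
  }
})

test_that("detrend_panel aligns all series and records provenance", {
  sim <- simulate_panel(sim_config(n_units = 3, n_years = 12, seed = 4))
  an <- detrend_panel(sim$panel, method = "linear")
  expect_named(an, c("unit_id", "year", "yield", "t_gs", "t_an", "p_gs",
                     "p_an", "area_ha", "detrend_method"))
  expect_equal(nrow(an), nrow(sim$panel))
  expect_true(all(an$detrend_method == "linear"))
  means <- tapply(an$yield, an$unit_id, mean)
  expect_true(all(abs(means) < 1e-9))
  # first differences lose one year per unit, in every series
  fd <- detrend_panel(sim$panel, method = "first_difference")
  expect_equal(nrow(fd), nrow(sim$panel) - 3)
  expect_true(all(fd$detrend_method == "first_difference"))
})
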