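# Toy gridded-climate tier: monthly temperature and precipitation fields on
# a small grid, per-unit harvested-area cell weights and crop calendars, and
# yields generated from the unit-level predictors those inputs imply. The
# generator stores its own predictors so a round trip through the
# remap/aggregate pipeline can be checked against them.

#' Simulate a toy monthly climate grid with unit weights and calendars
#'
#' Generates monthly temperature and precipitation fields over
#' `(n_years + 1) * 12` months (one lead year so every harvest year has a
#' complete 12-month antecedent window), assigns each unit a random set of
#' grid cells with positive harvested-area weights and a crop calendar — a
#' configurable fraction of which wrap the calendar-year boundary (e.g.
#' November--March) — and builds yields from the resulting unit-level
#' growing-season and annual predictors exactly as [simulate_panel()] does.
#' The predictors the generator used are stored, so
#' `remap_grid_to_unit()` + `seasonal_aggregate()` / `annual_aggregate()`
#' on the returned fields must reproduce them.
#'
#' @param config A [sim_config()] object.
#' @param grid_shape Integer vector `c(rows, cols)` (default `c(3, 3)`).
#' @param wrap_fraction Fraction of units whose growing season wraps the
#'   year boundary (default 0.3).
#' @return A list of class `yv_grid_sim`: `fields` (list with `t`, `p`
#'   arrays of dimension months x rows x cols and a `months` tibble),
#'   `weights`, `calendar`, `predictors` (the stored per-unit `t_gs`,
#'   `t_an`, `p_gs`, `p_an` by harvest year), `panel` and `truth` (as in
#'   [simulate_panel()]).
#' @export
simulate_grid <- function(config, grid_shape = c(3, 3), wrap_fraction = 0.3) {
  validate_sim_config(config)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2 || any(grid_shape < 1)) {
    abort("grid_shape must be two positive integers",
          class = "yieldclim_config_error")
  }
  withr::with_seed(config$seed,
                   simulate_grid_impl(config, grid_shape, wrap_fraction))
}

simulate_grid_impl <- function(config, grid_shape, wrap_fraction) {
  n_rows <- grid_shape[1]; n_cols <- grid_shape[2]
  n_cells <- n_rows * n_cols
  years_all <- (config$start_year - 1L):(config$start_year + config$n_years - 1L)
  months <- tidyr::expand_grid(year = years_all, month = 1:12)
  m <- nrow(months)

  # temperature: latitudinal gradient by row + seasonal cycle + noise;
  # precipitation: seasonal cycle + noise, floored at zero
  season_t <- 8 * sin(2 * pi * (months$month - 4) / 12)
  season_p <- 40 * sin(2 * pi * (months$month - 6) / 12)
  t_field <- array(NA_real_, dim = c(m, n_rows, n_cols))
  p_field <- array(NA_real_, dim = c(m, n_rows, n_cols))
  for (r in seq_len(n_rows)) {
    for (cc in seq_len(n_cols)) {
      t_field[, r, cc] <- 12 + 2 * r + season_t + rnorm(m, 0, 1.2)
      p_field[, r, cc] <- pmax(0, 75 + 5 * cc + season_p + rnorm(m, 0, 22))
    }
  }
  fields <- list(t = t_field, p = p_field, months = months)

  ids <- sprintf("u%04d", seq_len(config$n_units))
  weights <- purrr::map(seq_len(config$n_units), function(u) {
    k <- sample(seq_len(min(4, n_cells)), 1)
    cells <- sample(n_cells, k)
    tibble(unit_id = ids[u],
           row = ((cells - 1L) %% n_rows) + 1L,
           col = ((cells - 1L) %/% n_rows) + 1L,
           weight = runif(k, 0.5, 1.5))
  })
  weights <- dplyr::bind_rows(weights)

  wraps <- runif(config$n_units) < wrap_fraction
  calendar <- tibble(
    unit_id = ids,
    plant_month = ifelse(wraps, 11L, sample(3:6, config$n_units, TRUE)))
  calendar$harvest_month <- ifelse(
    wraps, 3L, calendar$plant_month + sample(3:5, config$n_units, TRUE))

  # the generator's own predictor computation (independent of climate_prep)
  harvest_years <- config$start_year:(config$start_year + config$n_years - 1L)
  abs_idx <- months$year * 12L + (months$month - 1L)
  t_mat <- matrix(t_field, nrow = m)
  p_mat <- matrix(p_field, nrow = m)
  predictors <- purrr::map(seq_len(config$n_units), function(u) {
    w <- weights[weights$unit_id == ids[u], ]
    cidx <- w$row + (w$col - 1L) * n_rows
    wt <- w$weight / sum(w$weight)
    t_series <- drop(t_mat[, cidx, drop = FALSE] %*% wt)
    p_series <- drop(p_mat[, cidx, drop = FALSE] %*% wt)
    cal <- calendar[calendar$unit_id == ids[u], ]
    len_gs <- ((cal$harvest_month - cal$plant_month) %% 12L) + 1L
    one_year <- function(y, len) {
      end <- match(y * 12L + (cal$harvest_month - 1L), abs_idx)
      win <- seq(end - len + 1L, end)
      c(t = mean(t_series[win]), p = sum(p_series[win]))
    }
    gs <- vapply(harvest_years, one_year, numeric(2), len = len_gs)
    an <- vapply(harvest_years, one_year, numeric(2), len = 12L)
    tibble(unit_id = ids[u], year = harvest_years,
           t_gs = gs["t", ], t_an = an["t", ],
           p_gs = gs["p", ], p_an = an["p", ])
  })
  predictors <- dplyr::bind_rows(predictors)

  # yields from the stored predictors, scaled by their realized spreads
  mix <- config$design_mixture
  panels <- vector("list", config$n_units)
  truths <- vector("list", config$n_units)
  for (u in seq_len(config$n_units)) {
    pred <- predictors[predictors$unit_id == ids[u], ]
    anoms <- tibble(
      t_gs = pred$t_gs - mean(pred$t_gs), t_an = pred$t_an - mean(pred$t_an),
      p_gs = pred$p_gs - mean(pred$p_gs), p_an = pred$p_an - mean(pred$p_an))
    sigmas <- list(t_gs = sd(pred$t_gs), t_an = sd(pred$t_an),
                   p_gs = sd(pred$p_gs), p_an = sd(pred$p_an))
    area <- runif(1, config$area_range[1], config$area_range[2])
    intercept <- runif(1, config$intercept_range[1], config$intercept_range[2])
    slope <- runif(1, config$trend_slope_range[1], config$trend_slope_range[2])
    pick <- sample(names(mix), 1, prob = mix)
    noise <- rnorm(config$n_years, 0, config$noise_sd)
    if (pick == "none") {
      signal <- rep(0, config$n_years); coefs <- numeric(0)
      category <- NA_character_
    } else {
      design <- config$designs[config$designs$design_id == pick, ]
      cs <- climate_signal(anoms, design$terms[[1]], sigmas,
                           config$effect_size, config$noise_sd)
      signal <- cs$signal; coefs <- cs$coefs
      category <- design$category
    }
    yield <- intercept + slope * (seq_len(config$n_years) - 1L) + signal + noise
    panels[[u]] <- tibble(
      unit_id = ids[u], year = harvest_years, yield_t_ha = yield,
      area_ha = area, t_gs_C = pred$t_gs, t_an_C = pred$t_an,
      p_gs_mm = pred$p_gs, p_an_mm = pred$p_an)
    truths[[u]] <- tibble(
      unit_id = ids[u], design_id = pick, category = category,
      true_r2 = if (pick == "none") 0 else var(signal) / var(signal + noise),
      noise_sd = config$noise_sd, area_ha = area,
      coefs = list(coefs), signal = list(signal), noise = list(noise))
  }
  structure(list(fields = fields, weights = weights, calendar = calendar,
                 predictors = predictors,
                 panel = dplyr::bind_rows(panels),
                 truth = dplyr::bind_rows(truths),
                 config = config),
            class = "yv_grid_sim")
}

#' Write / read monthly gridded fields as long-format CSV
#'
#' Persists monthly fields (dimensions time, row, col) as a tidy CSV with
#' columns `year`, `month`, `row`, `col`, `t_C`, `p_mm`, and reads them back
#' into the array form [remap_grid_to_unit()] consumes.
#'
#' @param fields A gridded-fields object (list with `t`, `p`, `months`).
#' @param path CSV path.
#' @return `write_grid_fields()` returns `path` invisibly;
#'   `read_grid_fields()` returns a gridded-fields list.
#' @export
write_grid_fields <- function(fields, path) {
  dims <- dim(fields$t)
  long <- tidyr::expand_grid(
    col = seq_len(dims[3]), row = seq_len(dims[2]),
    i = seq_len(dims[1]))
  out <- tibble(
    year = fields$months$year[long$i], month = fields$months$month[long$i],
    row = long$row, col = long$col,
    t_C = fields$t[cbind(long$i, long$row, long$col)],
    p_mm = fields$p[cbind(long$i, long$row, long$col)])
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_grid_fields
#' @export
read_grid_fields <- function(path) {
  long <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("year", "month", "row", "col", "t_C", "p_mm")
  missing_cols <- setdiff(need, names(long))
  if (length(missing_cols) > 0) {
    abort(sprintf("grid file lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "yieldclim_schema_error")
  }
  months <- dplyr::distinct(long[, c("year", "month")])
  months <- dplyr::arrange(months, .data$year, .data$month)
  n_rows <- max(long$row); n_cols <- max(long$col); m <- nrow(months)
  t_field <- array(NA_real_, dim = c(m, n_rows, n_cols))
  p_field <- array(NA_real_, dim = c(m, n_rows, n_cols))
  i <- match(long$year * 12L + long$month,
             months$year * 12L + months$month)
  t_field[cbind(i, long$row, long$col)] <- long$t_C
  p_field[cbind(i, long$row, long$col)] <- long$p_mm
  list(t = t_field, p = p_field, months = months)
}
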