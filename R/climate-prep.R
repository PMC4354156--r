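# From monthly gridded climate to per-unit regression inputs: harvested-area
# weighted remapping, growing-season / annual aggregation on a crop calendar,
# and detrending of yearly series.

#' Remap monthly gridded fields to political units
#'
#' Computes, for every unit and month, the harvested-area weighted average of
#' the gridded field over the unit's cells:
#' `value = sum(w_g * value_g) / sum(w_g)`. Weights must be non-negative and
#' not all zero for any unit; a needed month that is missing (NA) in any
#' contributing cell is an error naming the month.
#'
#' @param fields A gridded-climate object: list with `t` and `p` arrays of
#'   dimension (months, rows, cols) and a `months` tibble with columns
#'   `year`, `month` (as produced by [simulate_grid()] or
#'   [read_grid_fields()]).
#' @param weights Tibble with columns `unit_id`, `row`, `col`, `weight`.
#' @return A tibble: `unit_id`, `year`, `month`, `t_C`, `p_mm`.
#' @export
remap_grid_to_unit <- function(fields, weights) {
  stopifnot(all(c("unit_id", "row", "col", "weight") %in% names(weights)))
  if (any(weights$weight < 0)) {
    abort("cell weights must be non-negative",
          class = "yieldclim_config_error")
  }
  dims <- dim(fields$t)
  n_months <- dims[1]; n_rows <- dims[2]
  t_mat <- matrix(fields$t, nrow = n_months)
  p_mat <- matrix(fields$p, nrow = n_months)
  out <- purrr::map(split(weights, weights$unit_id), function(w) {
    if (sum(w$weight) <= 0) {
      abort(sprintf("unit %s has all-zero cell weights", w$unit_id[1]),
            class = "yieldclim_config_error")
    }
    idx <- w$row + (w$col - 1L) * n_rows
    wt <- w$weight / sum(w$weight)
    t_series <- drop(t_mat[, idx, drop = FALSE] %*% wt)
    p_series <- drop(p_mat[, idx, drop = FALSE] %*% wt)
    bad <- which(is.na(t_series) | is.na(p_series))
    if (length(bad) > 0) {
      abort(sprintf(
        "unit %s: missing gridded value(s) for month(s) %s", w$unit_id[1],
        paste(sprintf("%d-%02d", fields$months$year[bad],
                      fields$months$month[bad]), collapse = ", ")),
        class = "yieldclim_missing_month")
    }
    tibble(unit_id = w$unit_id[1], year = fields$months$year,
           month = fields$months$month, t_C = t_series, p_mm = p_series)
  })
  dplyr::bind_rows(out)
}

# Positions in a monthly tibble of the `len` months ending at
# (harvest_year, harvest_month); NA positions mean the month is absent.
window_positions <- function(monthly, harvest_year, harvest_month, len) {
  abs_idx <- monthly$year * 12L + (monthly$month - 1L)
  end <- harvest_year * 12L + (harvest_month - 1L)
  match(seq(end - len + 1L, end), abs_idx)
}

aggregate_windows <- function(monthly, calendar, harvest_years, len_fun,
                              t_name, p_name, sum_precip = TRUE,
                              what = "season") {
  stopifnot(all(c("unit_id", "plant_month", "harvest_month") %in%
                  names(calendar)))
  bad <- !(calendar$plant_month %in% 1:12 & calendar$harvest_month %in% 1:12)
  if (any(bad)) {
    abort("calendar months must be in 1..12", class = "yieldclim_config_error")
  }
  by_unit <- split(monthly, monthly$unit_id)
  n_missing <- 0L
  out <- purrr::map(split(calendar, calendar$unit_id), function(cal) {
    unit <- by_unit[[as.character(cal$unit_id[1])]]
    if (is.null(unit)) return(NULL)
    yrs <- harvest_years %||% sort(unique(unit$year))
    len <- len_fun(cal)
    res <- purrr::map(yrs, function(y) {
      pos <- window_positions(unit, y, cal$harvest_month[1], len)
      if (anyNA(pos) || anyNA(unit$t_C[pos]) || anyNA(unit$p_mm[pos])) {
        n_missing <<- n_missing + 1L
        return(tibble(unit_id = cal$unit_id[1], year = y,
                      !!t_name := NA_real_, !!p_name := NA_real_))
      }
      p_val <- if (sum_precip) sum(unit$p_mm[pos]) else mean(unit$p_mm[pos])
      tibble(unit_id = cal$unit_id[1], year = y,
             !!t_name := mean(unit$t_C[pos]), !!p_name := p_val)
    })
    dplyr::bind_rows(res)
  })
  if (n_missing > 0) {
    inform(sprintf("%d unit-year(s) dropped: incomplete %s climate window",
                   n_missing, what))
  }
  dplyr::bind_rows(out)
}

#' Growing-season climate predictors
#'
#' For each unit and harvest year, aggregates monthly climate over the
#' growing season: the `((harvest_month - plant_month) mod 12) + 1` months
#' ending at the harvest month of the harvest year, inclusive of both the
#' planting and harvest months. Seasons may wrap the calendar-year boundary
#' (e.g. November--March), in which case the early months come from the year
#' before harvest. Temperature is averaged; precipitation is summed by
#' default (`sum_precip = FALSE` averages it instead). A harvest year whose
#' window is incomplete gets NA predictors and is reported once per call.
#'
#' @param monthly Unit monthly series (`unit_id`, `year`, `month`, `t_C`,
#'   `p_mm`), e.g. from [remap_grid_to_unit()].
#' @param calendar Crop calendar tibble: `unit_id`, `plant_month`,
#'   `harvest_month` (1--12).
#' @param harvest_years Integer vector of harvest years; defaults to all
#'   years present for the unit.
#' @param sum_precip Sum monthly precipitation over the window (default) or
#'   average it.
#' @return A tibble: `unit_id`, `year`, `t_gs`, `p_gs`.
#' @export
seasonal_aggregate <- function(monthly, calendar, harvest_years = NULL,
                               sum_precip = TRUE) {
  aggregate_windows(
    monthly, calendar, harvest_years,
    len_fun = function(cal) {
      ((cal$harvest_month[1] - cal$plant_month[1]) %% 12L) + 1L
    },
    t_name = "t_gs", p_name = "p_gs", sum_precip = sum_precip,
    what = "growing-season")
}

#' Annual (antecedent) climate predictors
#'
#' For each unit and harvest year, aggregates monthly climate over the 12
#' months ending at the harvest month, capturing antecedent conditions in
#' the year before harvest. Temperature is averaged; precipitation is summed
#' by default.
#'
#' @inheritParams seasonal_aggregate
#' @return A tibble: `unit_id`, `year`, `t_an`, `p_an`.
#' @export
annual_aggregate <- function(monthly, calendar, harvest_years = NULL,
                             sum_precip = TRUE) {
  aggregate_windows(
    monthly, calendar, harvest_years,
    len_fun = function(cal) 12L,
    t_name = "t_an", p_name = "p_an", sum_precip = sum_precip,
    what = "annual")
}

#' Detrend a yearly series
#'
#' Removes the long-term (technology- and management-driven) trend from a
#' yearly series, leaving inter-annual anomalies. `"linear"` and
#' `"quadratic"` return residuals of an ordinary least-squares polynomial
#' fit on year (mean zero by construction); `"first_difference"` returns
#' consecutive differences, shortening the series by one.
#'
#' @param x Numeric series (may contain NA; NAs stay NA in the residual
#'   methods).
#' @param years Matching time index; defaults to `seq_along(x)`.
#' @param method One of `"linear"`, `"quadratic"`, `"first_difference"`.
#' @return The anomaly series: length `length(x)` for the residual methods,
#'   `length(x) - 1` for first differences.
#' @examples
#' detrend(2 + 0.1 * (1:10))          # ~ all zeros
#' detrend(c(1, 2, 4), method = "first_difference") # c(1, 2)
#' @export
detrend <- function(x, years = seq_along(x),
                    method = c("linear", "quadratic", "first_difference")) {
  method <- match.arg(method)
  ok <- !is.na(x)
  min_n <- if (method == "quadratic") 4L else 3L
  if (sum(ok) < min_n) {
    abort(sprintf("need at least %d non-missing values to detrend (%s)",
                  min_n, method),
          class = "yieldclim_insufficient_data")
  }
  if (method == "first_difference") {
    return(diff(x))
  }
  deg <- if (method == "quadratic") 2L else 1L
  basis <- stats::poly(years[ok], degree = deg, raw = FALSE)
  fit <- stats::lm.fit(cbind(1, basis), x[ok])
  out <- rep(NA_real_, length(x))
  out[ok] <- fit$residuals
  out
}

#' Detrend every series of a yield/climate panel
#'
#' Applies [detrend()] per unit to the yield and all four climate predictor
#' series of a panel, aligning them on harvest year. With
#' `method = "first_difference"` every series (yield and climate) is
#' differenced identically, so the regression stays aligned and one year is
#' lost.
#'
#' @param panel Panel tibble with columns `unit_id`, `year`, `yield_t_ha`,
#'   `area_ha`, `t_gs_C`, `t_an_C`, `p_gs_mm`, `p_an_mm` (the output schema
#'   of [simulate_panel()]).
#' @param method Detrending method, see [detrend()].
#' @return The anomaly panel: a tibble with columns `unit_id`, `year`,
#'   `yield`, `t_gs`, `t_an`, `p_gs`, `p_an`, `area_ha` and a provenance
#'   column `detrend_method`.
#' @export
detrend_panel <- function(panel,
                          method = c("linear", "quadratic",
                                     "first_difference")) {
  method <- match.arg(method)
  need <- c("unit_id", "year", "yield_t_ha", "area_ha",
            "t_gs_C", "t_an_C", "p_gs_mm", "p_an_mm")
  missing_cols <- setdiff(need, names(panel))
  if (length(missing_cols) > 0) {
    abort(sprintf("panel lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "yieldclim_schema_error")
  }
  out <- purrr::map(split(panel, panel$unit_id), function(unit) {
    unit <- dplyr::arrange(unit, .data$year)
    dt <- function(v) detrend(v, unit$year, method)
    yr <- if (method == "first_difference") unit$year[-1] else unit$year
    area <- if (method == "first_difference") unit$area_ha[-1] else unit$area_ha
    tibble(
      unit_id = unit$unit_id[1], year = yr,
      yield = dt(unit$yield_t_ha),
      t_gs = dt(unit$t_gs_C), t_an = dt(unit$t_an_C),
      p_gs = dt(unit$p_gs_mm), p_an = dt(unit$p_an_mm),
      area_ha = area, detrend_method = method)
  })
  dplyr::bind_rows(out)
}
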