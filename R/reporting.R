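# Descriptives and area-weighted aggregation of per-unit attribution results.

#' Coefficient of variation of a yield series
#'
#' Sample standard deviation over the mean: relative inter-annual yield
#' variability over the study window.
#'
#' @param yields Yearly yields (t/ha), at least 3 values, positive mean.
#' @return The CV as a fraction.
#' @examples
#' coefficient_of_variation(c(3.5, 4.2, 4.6, 3.9)) # sd/mean
#' @export
coefficient_of_variation <- function(yields) {
  yields <- yields[!is.na(yields)]
  if (length(yields) < 3) {
    abort("need at least 3 years for a coefficient of variation",
          class = "yieldclim_insufficient_data")
  }
  m <- mean(yields)
  if (m <= 0) {
    abort("mean yield must be positive", class = "yieldclim_config_error")
  }
  sd(yields) / m
}

#' Harvested-area weighted mean
#'
#' `sum(value * area) / sum(area)` over the units selected by `mask`
#' (typically the units whose selected model is significant). An empty mask
#' yields NA with a warning.
#'
#' @param values Per-unit values (e.g. full-model r-squared).
#' @param areas Per-unit harvested areas (ha), positive.
#' @param mask Logical mask selecting the units to average over.
#' @return The weighted mean, or NA if no unit is selected.
#' @examples
#' area_weighted_mean(c(0.2, 0.6), c(1, 3)) # 0.5
#' @export
area_weighted_mean <- function(values, areas, mask = rep(TRUE, length(values))) {
  stopifnot(length(values) == length(areas), length(mask) == length(values))
  if (any(areas <= 0, na.rm = TRUE)) {
    abort("areas must be positive", class = "yieldclim_config_error")
  }
  mask <- mask & !is.na(values) & !is.na(areas)
  if (!any(mask)) {
    warn("empty mask: no units to average over")
    return(NA_real_)
  }
  sum(values[mask] * areas[mask]) / sum(areas[mask])
}

#' Fraction of harvested area with significant climate influence
#'
#' @param significant Logical per-unit significance flags.
#' @param areas Per-unit harvested areas (ha).
#' @return `sum(areas[significant]) / sum(areas)`.
#' @examples
#' significant_area_fraction(c(TRUE, FALSE, TRUE), c(1, 1, 2)) # 0.75
#' @export
significant_area_fraction <- function(significant, areas) {
  stopifnot(length(significant) == length(areas))
  ok <- !is.na(significant) & !is.na(areas)
  sum(areas[ok & significant]) / sum(areas[ok])
}

#' Climate-driven production fluctuation
#'
#' Converts an explained-variance fraction into absolute tonnage: the
#' climate-explained share of yield variability times the yield standard
#' deviation times the harvested area,
#' `mean_r2 * mean_yield_sd * total_area` (tons/year).
#'
#' @param mean_r2 Explained-variance fraction.
#' @param mean_yield_sd Yield standard deviation (t/ha/year).
#' @param total_area Harvested area (ha).
#' @return Tons per year. Linear in each argument.
#' @examples
#' production_fluctuation(0.39, 0.6, 94e6) # ~22 million tons
#' @export
production_fluctuation <- function(mean_r2, mean_yield_sd, total_area) {
  if (any(c(mean_r2, mean_yield_sd, total_area) < 0, na.rm = TRUE)) {
    abort("all inputs must be non-negative", class = "yieldclim_config_error")
  }
  mean_r2 * mean_yield_sd * total_area
}

#' Area-weighted aggregate summaries of attribution results
#'
#' Aggregates per-unit attribution into summaries in the style of global or
#' national statistics: harvested-area weighted mean explained variance over
#' significant units, the harvested-area and production shares under
#' significant climate influence, and yield-variability descriptives. All
#' r-squared aggregates are averaged **only over units whose selected model
#' is significant** at the given level; the area and production fractions
#' use all analyzed units as the denominator. Production weights are
#' `area * mean yield`. Summaries are produced at each requested alpha.
#'
#' @param attribution Attribution tibble from [attribute_units()].
#' @param panel Raw panel (for per-unit mean yield, yield sd, CV and area).
#' @param alphas Significance levels to summarize at.
#' @param by Optional name of a grouping column present in `attribution`
#'   (e.g. a country label); `NULL` aggregates globally.
#' @return A tibble of class `yv_aggregate`: one row per (scope, alpha) with
#'   `area_weighted_r2`, `area_weighted_r2_T`, `area_weighted_r2_P`,
#'   `significant_area_fraction`, `significant_production_fraction`,
#'   `mean_yield_sd`, `mean_cv`, `n_units`, `n_units_significant`.
#' @export
aggregate_results <- function(attribution, panel,
                              alphas = c(0.10, 0.05, 0.01), by = NULL) {
  unit_stats <- panel |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::summarise(
      area_ha = mean(.data$area_ha),
      mean_yield = mean(.data$yield_t_ha, na.rm = TRUE),
      yield_sd = sd(.data$yield_t_ha, na.rm = TRUE),
      .groups = "drop") |>
    dplyr::mutate(cv = .data$yield_sd / .data$mean_yield)
  dat <- dplyr::inner_join(as_tibble(attribution), unit_stats, by = "unit_id")
  dat <- dat[dat$status == "ok", , drop = FALSE]
  if (nrow(dat) == 0) {
    abort("no analyzable units to aggregate",
          class = "yieldclim_no_data")
  }
  groups <- if (is.null(by)) list(global = dat) else split(dat, dat[[by]])
  rows <- purrr::imap(groups, function(g, scope) {
    purrr::map(alphas, function(a) {
      sig <- !is.na(g$p_value) & g$p_value < a
      production <- g$area_ha * g$mean_yield
      tibble(
        scope = scope, alpha = a,
        area_weighted_r2 = area_weighted_mean(g$r2_full, g$area_ha, sig),
        area_weighted_r2_T = area_weighted_mean(g$r2_T, g$area_ha, sig),
        area_weighted_r2_P = area_weighted_mean(g$r2_P, g$area_ha, sig),
        significant_area_fraction = significant_area_fraction(sig, g$area_ha),
        significant_production_fraction =
          sum(production[sig]) / sum(production),
        mean_yield_sd = area_weighted_mean(g$yield_sd, g$area_ha, sig),
        mean_cv = area_weighted_mean(g$cv, g$area_ha, sig),
        n_units = nrow(g),
        n_units_significant = sum(sig))
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  class(out) <- c("yv_aggregate", class(out))
  out
}
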