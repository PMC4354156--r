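# ggplot2 views of attribution results.

category_palette <- c(
  i = "#f5d547", iii = "#c8a26b", v = "#c0392b",
  ii = "#a7c6ed", iv = "#5b8dd6", vi = "#1f4e9c",
  vii = "#7d3c98")

#' Plot attribution results
#'
#' * `type = "categories"`: counts of units per climate-driver category,
#'   split by significance of the selected model (warm colours for
#'   temperature-driven categories, blues for precipitation, purple for
#'   combinations);
#' * `type = "decomposition"`: per-unit temperature-only vs
#'   precipitation-only reduced-model r-squared, coloured by category;
#' * `type = "r2"`: distribution of full-model explained variance, filled by
#'   significance.
#'
#' @param object A `yv_attribution` tibble from [attribute_units()].
#' @param type One of `"categories"`, `"decomposition"`, `"r2"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot yv_attribution
#' @export
autoplot.yv_attribution <- function(object,
                                    type = c("categories", "decomposition",
                                             "r2"), ...) {
  type <- match.arg(type)
  dat <- as_tibble(object)
  dat <- dat[dat$status == "ok", , drop = FALSE]
  dat$category <- factor(dat$category, levels = categories()$code)
  if (type == "categories") {
    ggplot2::ggplot(dat, ggplot2::aes(x = .data$category,
                                      fill = .data$category,
                                      alpha = .data$significant_0.10)) +
      ggplot2::geom_bar() +
      ggplot2::scale_fill_manual(values = category_palette, drop = FALSE,
                                 guide = "none") +
      ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.35),
                                  name = "significant (P < 0.10)") +
      ggplot2::labs(x = "climate-driver category", y = "political units")
  } else if (type == "decomposition") {
    ggplot2::ggplot(dat, ggplot2::aes(x = .data$r2_T, y = .data$r2_P,
                                      colour = .data$category)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                           colour = "grey60") +
      ggplot2::geom_point(alpha = 0.7) +
      ggplot2::scale_colour_manual(values = category_palette, drop = FALSE) +
      ggplot2::coord_equal() +
      ggplot2::labs(x = "temperature-only r²",
                    y = "precipitation-only r²")
  } else {
    ggplot2::ggplot(dat, ggplot2::aes(x = .data$r2_full,
                                      fill = .data$significant_0.10)) +
      ggplot2::geom_histogram(bins = 30, boundary = 0) +
      ggplot2::scale_fill_manual(values = c(`TRUE` = "#2c7fb8",
                                            `FALSE` = "grey70"),
                                 name = "significant (P < 0.10)") +
      ggplot2::labs(x = "explained yield variability (r²)",
                    y = "political units")
  }
}

#' Plot aggregate summaries across significance cutoffs
#'
#' Area-weighted explained variance and the significant-area fraction at
#' each alpha, one panel per scope.
#'
#' @param object A `yv_aggregate` tibble from [aggregate_results()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot yv_aggregate
#' @export
autoplot.yv_aggregate <- function(object, ...) {
  dat <- as_tibble(object) |>
    tidyr::pivot_longer(
      c("area_weighted_r2", "significant_area_fraction"),
      names_to = "measure", values_to = "value")
  dat$measure <- dplyr::recode(dat$measure,
    area_weighted_r2 = "area-weighted r² (significant units)",
    significant_area_fraction = "significant area fraction")
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$alpha), y = .data$value,
                                    fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~ .data$scope) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "significance level (alpha)", y = NULL, fill = NULL)
}
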