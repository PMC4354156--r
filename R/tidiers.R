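# broom-style accessors for fitted objects.

#' Tidy a per-unit OLS fit
#'
#' @param x A `yv_fit` object from [fit_ols()].
#' @param ... Unused.
#' @return A tibble with one row per model term: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @method tidy yv_fit
#' @export
tidy.yv_fit <- function(x, ...) {
  stat <- x$coefficients / x$std_error
  tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$std_error),
    statistic = unname(stat),
    p.value = unname(2 * stats::pt(abs(stat), x$df_residual,
                                   lower.tail = FALSE)))
}

#' Glance at a per-unit OLS fit
#'
#' @param x A `yv_fit` object from [fit_ols()].
#' @param ... Unused.
#' @return A one-row tibble: `r.squared`, `rss`, `AIC`, `nobs`, `k`,
#'   `df.residual`.
#' @method glance yv_fit
#' @export
glance.yv_fit <- function(x, ...) {
  tibble(r.squared = x$r2, rss = x$rss, AIC = x$aic,
         nobs = x$n, k = x$k, df.residual = x$df_residual)
}

#' Glance at a pipeline run
#'
#' @param x A `yv_pipeline` object from [run_pipeline()].
#' @param ... Unused.
#' @return The global aggregate row at the pipeline's alpha.
#' @method glance yv_pipeline
#' @export
glance.yv_pipeline <- function(x, ...) {
  out <- x$aggregate[x$aggregate$alpha == x$config$alpha, ]
  as_tibble(out)
}
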