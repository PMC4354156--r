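# Per-unit regression machinery: design matrices, OLS fits, AIC selection
# among the candidate set, and the nested F-test against the intercept-only
# null.

#' Build the design matrix for one regression design
#'
#' One column per term — squared terms are elementwise squares of the
#' detrended anomaly, interactions elementwise products of the two detrended
#' anomalies — plus an intercept column. Rows are the unit's complete cases
#' over the response and every column the design needs.
#'
#' @param anomalies Anomaly panel rows for one unit, with columns `yield`,
#'   `t_gs`, `t_an`, `p_gs`, `p_an` (see [detrend_panel()]).
#' @param design Character vector of term strings, or a one-row model-set
#'   tibble.
#' @param min_dof Minimum residual degrees of freedom required (default 5);
#'   fewer usable rows than `k + min_dof` is an error.
#' @return A list: `x` (n x k matrix, first column the intercept), `y`
#'   (response vector), `years`, `n`, `k`.
#' @export
build_design_matrix <- function(anomalies, design, min_dof = 5) {
  terms <- design_terms(design)
  cols <- unique(unlist(lapply(terms, term_columns)))
  missing_cols <- setdiff(c("yield", cols), names(anomalies))
  if (length(missing_cols) > 0) {
    abort(sprintf("anomaly panel lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "yieldclim_schema_error")
  }
  rows <- stats::complete.cases(anomalies[, c("yield", cols)])
  sub <- anomalies[rows, , drop = FALSE]
  k <- length(terms) + 1L
  if (nrow(sub) < k + min_dof) {
    abort(sprintf("only %d usable years for a %d-parameter design (need >= %d)",
                  nrow(sub), k, k + min_dof),
          class = "yieldclim_insufficient_data")
  }
  x <- vapply(terms, term_values, numeric(nrow(sub)), data = sub)
  x <- cbind("(Intercept)" = 1, x)
  colnames(x) <- c("(Intercept)",
                   unname(vapply(terms, term_label, character(1))))
  list(x = x, y = sub$yield,
       years = if ("year" %in% names(sub)) sub$year else seq_len(nrow(sub)),
       n = nrow(sub), k = k)
}

#' Ordinary least squares fit of one design
#'
#' Fits `y` on the columns of `x` (which must include the intercept) by QR
#' decomposition and reports the quantities model selection needs: residual
#' sum of squares, r-squared against the mean-only baseline, and
#' `AIC = n log(rss / n) + 2 k` with `k = ncol(x)`. The Gaussian error
#' variance term constant across designs on the same rows is omitted, so AIC
#' values are comparable only within one unit. A perfect fit (`rss = 0`) gets
#' `aic = -Inf`.
#'
#' @param y Response vector (detrended yields).
#' @param x Design matrix including the intercept column.
#' @param design_id Optional identifier carried into the result.
#' @return An object of class `yv_fit`: coefficients, `rss`, `tss`, `r2`,
#'   `aic`, `n`, `k`, `df_residual`, fitted values and residuals. Supports
#'   [tidy()] and [glance()].
#' @export
fit_ols <- function(y, x, design_id = NA_character_) {
  x <- as.matrix(x)
  if (nrow(x) <= ncol(x)) {
    abort("need more rows than columns to fit",
          class = "yieldclim_insufficient_data")
  }
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    abort("design matrix is rank deficient",
          class = "yieldclim_rank_deficient")
  }
  coefs <- qr.coef(qx, y)
  fitted <- drop(x %*% coefs)
  res <- y - fitted
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  n <- length(y)
  k <- ncol(x)
  r2 <- if (tss > 0) min(max(1 - rss / tss, 0), 1) else NA_real_
  # a numerically perfect fit gets the -Inf sentinel so it always wins
  perfect <- rss <= 0 || rss <= tss * 1e-14
  aic <- if (perfect) -Inf else n * log(rss / n) + 2 * k
  sigma2 <- rss / (n - k)
  xtx_inv <- chol2inv(qr.R(qx))
  se <- sqrt(pmax(diag(xtx_inv) * sigma2, 0))
  names(se) <- names(coefs)
  structure(list(
    design_id = design_id,
    coefficients = coefs,
    std_error = se,
    rss = rss, tss = tss, r2 = r2, aic = aic,
    n = n, k = k, df_residual = n - k,
    fitted = fitted, residuals = res
  ), class = "yv_fit")
}

#' @export
print.yv_fit <- function(x, ...) {
  cat(sprintf("<yv_fit> design %s: n = %d, k = %d, r2 = %.4f, AIC = %.2f\n",
              x$design_id, x$n, x$k, x$r2, x$aic))
  invisible(x)
}

#' Nested F-test of a fitted design against the intercept-only null
#'
#' Tests whether the selected climate design improves on the null model that
#' assumes yield anomalies carry no climate information, using the standard
#' nested-model F statistic
#' `F = ((rss0 - rss1) / q) / (rss1 / (n - k))` with `q = k - 1` climate
#' terms, referred to an F distribution with `(q, n - k)` degrees of freedom.
#' The null model must be the intercept-only fit on the same rows, so
#' `null_rss` equals the winner's total sum of squares.
#'
#' @param fit A `yv_fit` object, or any list with elements `rss`, `k`, `n`.
#' @param null_rss Residual sum of squares of the intercept-only null on the
#'   same rows.
#' @return A list with `f_stat` and `p_value`.
#' @examples
#' f_test_vs_null(list(rss = 50, k = 3, n = 30), null_rss = 100)
#' @export
f_test_vs_null <- function(fit, null_rss) {
  rss <- fit$rss; k <- fit$k; n <- fit$n
  q <- k - 1L
  stopifnot(q >= 1, n - k >= 1)
  if (rss > null_rss * (1 + 1e-10) + 1e-12) {
    abort("full-model RSS exceeds null RSS; models are not nested on the same rows",
          class = "yieldclim_internal_error")
  }
  if (rss <= 0) {
    return(list(f_stat = Inf, p_value = 0))
  }
  f_stat <- ((null_rss - rss) / q) / (rss / (n - k))
  f_stat <- max(f_stat, 0)
  list(f_stat = f_stat,
       p_value = stats::pf(f_stat, q, n - k, lower.tail = FALSE))
}

#' Select the best candidate design for one unit
#'
#' Fits every design in the candidate set to one unit's anomaly panel, ranks
#' them by AIC (or small-sample corrected AICc), and applies the nested
#' F-test only to the winner. AIC ties within `aic_tol` are broken first by
#' fewer terms, then by lower enumeration rank, so selection is
#' deterministic. Designs that cannot be fit (insufficient rows, rank
#' deficiency) are skipped; if every design fails the unit is flagged
#' `"unfittable"`.
#'
#' @param anomalies Anomaly panel rows for one unit.
#' @param designs Candidate model set (default [default_model_set()]).
#' @param alpha Significance level for the F-test flag (default 0.10).
#' @param ic `"aic"` (default) or `"aicc"`.
#' @param min_dof Minimum residual degrees of freedom per design.
#' @param aic_tol Ties closer than this are resolved by the tie-break rules.
#' @param keep_fits Attach the per-design audit table (design_id, aic, r2,
#'   rss) as attribute `"fits"`?
#' @return A one-row tibble: `unit_id`, `status`, `design_id`, `n`, `k`,
#'   `r2`, `rss`, `aic`, `null_rss`, `f_stat`, `p_value`, `significant`.
#' @export
select_model <- function(anomalies, designs = default_model_set(),
                         alpha = 0.10, ic = c("aic", "aicc"),
                         min_dof = 5, aic_tol = 1e-9, keep_fits = FALSE) {
  ic <- match.arg(ic)
  unit_id <- anomalies$unit_id[1]
  fits <- purrr::map(seq_len(nrow(designs)), function(i) {
    tryCatch({
      dm <- build_design_matrix(anomalies, designs$terms[[i]],
                                min_dof = min_dof)
      fit <- fit_ols(dm$y, dm$x, design_id = designs$design_id[i])
      score <- fit$aic
      if (ic == "aicc" && is.finite(score)) {
        score <- score + 2 * fit$k * (fit$k + 1) / (fit$n - fit$k - 1)
      }
      list(fit = fit, score = score, i = i)
    }, yieldclim_insufficient_data = function(e) NULL,
       yieldclim_rank_deficient = function(e) NULL)
  })
  fits <- purrr::compact(fits)
  empty <- tibble(
    unit_id = unit_id, status = "unfittable", design_id = NA_character_,
    n = NA_integer_, k = NA_integer_, r2 = NA_real_, rss = NA_real_,
    aic = NA_real_, null_rss = NA_real_, f_stat = NA_real_,
    p_value = NA_real_, significant = NA)
  if (length(fits) == 0) return(empty)

  scores <- vapply(fits, `[[`, numeric(1), "score")
  n_terms <- designs$n_terms[vapply(fits, `[[`, integer(1), "i")]
  ranks <- designs$enumeration_rank[vapply(fits, `[[`, integer(1), "i")]
  tied <- which(scores <= min(scores) + aic_tol)
  best_idx <- tied[order(n_terms[tied], ranks[tied])][1]
  best <- fits[[best_idx]]$fit

  null_rss <- best$tss # intercept-only RSS on the winner's rows
  ft <- f_test_vs_null(best, null_rss)
  out <- tibble(
    unit_id = unit_id, status = "ok", design_id = best$design_id,
    n = best$n, k = best$k, r2 = best$r2, rss = best$rss, aic = best$aic,
    null_rss = null_rss, f_stat = ft$f_stat, p_value = ft$p_value,
    significant = ft$p_value < alpha)
  if (keep_fits) {
    attr(out, "fits") <- dplyr::bind_rows(purrr::map(fits, function(f) {
      tibble(design_id = f$fit$design_id, aic = f$fit$aic,
             score = f$score, r2 = f$fit$r2, rss = f$fit$rss, k = f$fit$k)
    }))
  }
  out
}

#' Select the best design for every unit in an anomaly panel
#'
#' Maps [select_model()] over units. Units with fewer than `min_years`
#' non-missing yield anomalies are flagged `"insufficient_data"` and skipped;
#' both flags propagate so aggregation can exclude those units.
#'
#' @inheritParams select_model
#' @param anomalies Anomaly panel for any number of units.
#' @param min_years Minimum non-missing yield years for eligibility
#'   (default 15).
#' @return A tibble with one row per unit, in the shape of [select_model()].
#' @export
select_models <- function(anomalies, designs = default_model_set(),
                          alpha = 0.10, ic = c("aic", "aicc"),
                          min_years = 15, min_dof = 5, aic_tol = 1e-9) {
  ic <- match.arg(ic)
  by_unit <- split(anomalies, anomalies$unit_id)
  rows <- purrr::map(by_unit, function(unit) {
    if (sum(!is.na(unit$yield)) < min_years) {
      return(tibble(
        unit_id = unit$unit_id[1], status = "insufficient_data",
        design_id = NA_character_, n = NA_integer_, k = NA_integer_,
        r2 = NA_real_, rss = NA_real_, aic = NA_real_, null_rss = NA_real_,
        f_stat = NA_real_, p_value = NA_real_, significant = NA))
    }
    select_model(unit, designs, alpha = alpha, ic = ic,
                 min_dof = min_dof, aic_tol = aic_tol)
  })
  dplyr::bind_rows(rows)
}
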