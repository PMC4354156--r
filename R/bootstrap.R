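# Leave-group-out bootstrap bias assessment: refit the selected design on
# 80% of the years, predict the held-out 20%, 99 times, and standardize the
# average bias by the unit's mean raw yield.

#' Bootstrap bias of a selected design for one unit
#'
#' Per repetition, a training set of `ceiling(train_fraction * n)` years is
#' sampled without replacement, the selected design is refit on it, the
#' held-out complement is predicted, and the repetition's bias is the mean
#' of (predicted - observed) yield anomalies. The standardized bias is the
#' average of the repetition biases divided by the unit's mean raw yield.
#' Repetitions whose training split is rank deficient are dropped; if more
#' than half fail the unit is flagged and the result is NA. Fixed seeds give
#' bit-identical results.
#'
#' @param anomalies Anomaly panel rows for one unit (see [detrend_panel()]).
#' @param design Selected design (terms vector or one-row model-set tibble).
#' @param mean_raw_yield The unit's mean raw yield (t/ha) over the study
#'   window, used to standardize.
#' @param n_reps Number of repetitions (default 99).
#' @param train_fraction Fraction of years in each training split
#'   (default 0.8).
#' @param seed Integer seed.
#' @return A one-row tibble: `unit_id`, `standardized_bias`, `n_reps`,
#'   `train_fraction`, `n_failed`, `status`.
#' @export
bootstrap_bias <- function(anomalies, design, mean_raw_yield,
                           n_reps = 99, train_fraction = 0.8, seed = 1L) {
  stopifnot(n_reps >= 1, train_fraction > 0, train_fraction < 1)
  dm <- build_design_matrix(anomalies, design, min_dof = 1)
  n <- dm$n
  n_train <- ceiling(train_fraction * n)
  if (n_train <= dm$k || n_train >= n) {
    abort(sprintf(
      "training split of %d years cannot support a %d-parameter design with a non-empty test set",
      n_train, dm$k),
      class = "yieldclim_insufficient_data")
  }
  biases <- withr::with_seed(seed, {
    vapply(seq_len(n_reps), function(rep) {
      train <- sample(n, n_train)
      test <- setdiff(seq_len(n), train)
      x_tr <- dm$x[train, , drop = FALSE]
      if (qr(x_tr)$rank < ncol(x_tr)) return(NA_real_)
      fit <- fit_ols(dm$y[train], x_tr)
      pred <- drop(dm$x[test, , drop = FALSE] %*% fit$coefficients)
      mean(pred - dm$y[test])
    }, numeric(1))
  })
  n_failed <- sum(is.na(biases))
  failed <- n_failed > n_reps / 2
  tibble(
    unit_id = anomalies$unit_id[1],
    standardized_bias = if (failed) NA_real_ else {
      mean(biases, na.rm = TRUE) / mean_raw_yield
    },
    n_reps = as.integer(n_reps), train_fraction = train_fraction,
    n_failed = as.integer(n_failed),
    status = if (failed) "rank_deficient" else "ok")
}

#' Bootstrap bias for every selected unit
#'
#' Maps [bootstrap_bias()] over the units of a selection result, deriving
#' each unit's mean raw yield from the panel. Per-unit seeds are derived
#' deterministically from `seed`.
#'
#' @param anomalies Anomaly panel for all units.
#' @param panel Raw panel (for mean yields).
#' @param selections Selection results from [select_models()].
#' @param designs Model set used in selection.
#' @inheritParams bootstrap_bias
#' @return A tibble with one row per selected unit.
#' @export
bootstrap_bias_units <- function(anomalies, panel, selections,
                                 designs = default_model_set(),
                                 n_reps = 99, train_fraction = 0.8,
                                 seed = 1L) {
  mean_yields <- panel |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::summarise(mean_yield = mean(.data$yield_t_ha, na.rm = TRUE),
                     .groups = "drop")
  by_unit <- split(anomalies, anomalies$unit_id)
  sel_ok <- selections[selections$status == "ok", , drop = FALSE]
  rows <- purrr::map(seq_len(nrow(sel_ok)), function(i) {
    sel <- sel_ok[i, ]
    design <- designs[designs$design_id == sel$design_id, ]
    my <- mean_yields$mean_yield[mean_yields$unit_id == sel$unit_id]
    bootstrap_bias(by_unit[[as.character(sel$unit_id)]], design, my,
                   n_reps = n_reps, train_fraction = train_fraction,
                   seed = (seed + i) %% .Machine$integer.max)
  })
  dplyr::bind_rows(rows)
}
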