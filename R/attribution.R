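# Classification of selected designs into seven climate-driver categories and
# temperature-only / precipitation-only variance decomposition.

#' The seven climate-driver categories
#'
#' @return A tibble with columns `code` (`"i"` .. `"vii"`) and `label`.
#' @export
categories <- function() {
  tibble(
    code = c("i", "ii", "iii", "iv", "v", "vi", "vii"),
    label = c(
      "normal temperature",
      "normal precipitation",
      "normal and extreme temperature",
      "normal and extreme precipitation",
      "extreme temperature",
      "extreme precipitation",
      "temperature and precipitation combinations"
    )
  )
}

#' Classify a regression design into a climate-driver category
#'
#' Linear (power-1) terms represent *normal* variation and squared (power-2)
#' terms *extreme* variation. Designs involving only temperature map to
#' category i (all linear), iii (linear and squared) or v (all squared);
#' precipitation-only designs map to ii, iv, vi analogously; any design
#' containing both temperature and precipitation atoms — including through an
#' interaction term — maps to vii. Classification uses the design's term
#' structure only, never fitted coefficients.
#'
#' @param terms Character vector of term strings (see [parse_term()]), or a
#'   one-row model-set tibble.
#' @return A single category code, `"i"` .. `"vii"`.
#' @examples
#' classify_design("T:gs:1")                         # "i"
#' classify_design(c("P:an:1", "P:an:2"))            # "iv"
#' classify_design(c("T:gs:1", "P:an:1", "T:gs*P:an")) # "vii"
#' @export
classify_design <- function(terms) {
  terms <- design_terms(terms)
  if (length(terms) == 0) {
    abort("cannot classify an empty design", class = "yieldclim_design_error")
  }
  vars <- unique(unlist(lapply(terms, term_vars)))
  if (all(c("T", "P") %in% vars)) return("vii")
  powers <- unique(vapply(terms, function(tm) parse_term(tm)$power, integer(1)))
  if (identical(vars, "T")) {
    if (setequal(powers, 1L)) "i" else if (setequal(powers, 2L)) "v" else "iii"
  } else {
    if (setequal(powers, 1L)) "ii" else if (setequal(powers, 2L)) "vi" else "iv"
  }
}

# Accept either a bare character vector of terms, a list-column element, or a
# one-row model-set tibble.
design_terms <- function(design) {
  if (is.data.frame(design)) {
    stopifnot(nrow(design) == 1, "terms" %in% names(design))
    design$terms[[1]]
  } else if (is.list(design)) {
    unlist(design)
  } else {
    design
  }
}

#' Reduced-model explained variance for a selected design
#'
#' Refits the selected design keeping only its temperature terms, and only its
#' precipitation terms, on the same rows the full design uses, and reports the
#' two coefficients of determination. Interaction terms belong to neither
#' reduced model by default and are dropped from both; set
#' `include_interactions = TRUE` to keep them in both reduced fits. An empty
#' reduced term set yields an r-squared of 0 without fitting. Because the
#' reduced models are refit (not carved out of the full fit), suppressor
#' configurations can in principle push a reduced r-squared above the full
#' model's; only membership of \[0, 1\] is guaranteed.
#'
#' @param anomalies Anomaly panel rows for one unit (see [detrend_panel()]).
#' @param design Terms of the selected design (character vector or one-row
#'   model-set tibble).
#' @param include_interactions Keep interaction terms in both reduced fits?
#' @return A named numeric vector `c(r2_T = , r2_P = )`.
#' @export
reduced_r2 <- function(anomalies, design, include_interactions = FALSE) {
  terms <- design_terms(design)
  is_int <- vapply(terms, function(tm) {
    parse_term(tm)$kind == "interaction"
  }, logical(1))
  keep_for <- function(v) {
    main <- terms[!is_int & vapply(terms, function(tm) {
      identical(term_vars(tm), v)
    }, logical(1))]
    if (include_interactions) c(main, terms[is_int]) else main
  }
  # same rows as the full design: complete cases over all its columns
  rows <- stats::complete.cases(
    anomalies[, unique(c("yield", unlist(lapply(terms, term_columns))))])
  sub <- anomalies[rows, , drop = FALSE]
  one <- function(reduced) {
    if (length(reduced) == 0) return(0)
    dm <- build_design_matrix(sub, reduced, min_dof = 1)
    fit_ols(dm$y, dm$x)$r2
  }
  c(r2_T = one(keep_for("T")), r2_P = one(keep_for("P")))
}

#' Which driver explains more yield variance?
#'
#' @param r2_T,r2_P Temperature-only and precipitation-only reduced-model
#'   r-squared values, both in \[0, 1\]. Vectorized.
#' @param tol Ties closer than `tol` are reported as `"tie"`.
#' @return Character vector in `{"temperature", "precipitation", "tie"}`.
#' @examples
#' dominant_driver(0.5, 0.2) # "temperature"
#' @export
dominant_driver <- function(r2_T, r2_P, tol = 1e-6) {
  stopifnot(all(r2_T >= 0 & r2_T <= 1, na.rm = TRUE),
            all(r2_P >= 0 & r2_P <= 1, na.rm = TRUE))
  out <- rep("tie", length(r2_T))
  out[r2_T - r2_P > tol] <- "temperature"
  out[r2_P - r2_T > tol] <- "precipitation"
  out[is.na(r2_T) | is.na(r2_P)] <- NA_character_
  out
}

#' Per-unit attribution of yield variability to climate drivers
#'
#' Joins model-selection results with their variance decomposition: for every
#' unit with a selected design, computes the full-model r-squared, the
#' temperature-only and precipitation-only reduced-model r-squared, the
#' design's climate-driver category, the dominant driver, and significance
#' flags at the 0.10, 0.05 and 0.01 levels. Units whose selected model is not
#' significant at `alpha` get `dominant = "none"`.
#'
#' @param anomalies Anomaly panel (see [detrend_panel()]).
#' @param selections Selection results from [select_models()].
#' @param designs Model set used in selection.
#' @param alpha Significance level gating the `dominant` call (default 0.10).
#' @param include_interactions Passed to [reduced_r2()].
#' @param tol Passed to [dominant_driver()].
#' @return A tibble of class `yv_attribution`, one row per unit: `unit_id`,
#'   `design_id`, `category`, `r2_full`, `r2_T`, `r2_P`, `dominant`,
#'   `p_value`, `significant_0.10`, `significant_0.05`, `significant_0.01`,
#'   `status`.
#' @export
attribute_units <- function(anomalies, selections, designs = default_model_set(),
                            alpha = 0.10, include_interactions = FALSE,
                            tol = 1e-6) {
  by_unit <- split(anomalies, anomalies$unit_id)
  rows <- purrr::map(seq_len(nrow(selections)), function(i) {
    sel <- selections[i, ]
    if (!identical(sel$status, "ok")) {
      return(tibble(
        unit_id = sel$unit_id, design_id = NA_character_,
        category = NA_character_, r2_full = NA_real_,
        r2_T = NA_real_, r2_P = NA_real_, dominant = NA_character_,
        p_value = NA_real_, status = sel$status))
    }
    design <- designs[designs$design_id == sel$design_id, ]
    rr <- reduced_r2(by_unit[[as.character(sel$unit_id)]], design,
                     include_interactions = include_interactions)
    tibble(
      unit_id = sel$unit_id, design_id = sel$design_id,
      category = design$category, r2_full = sel$r2,
      r2_T = unname(rr["r2_T"]), r2_P = unname(rr["r2_P"]),
      dominant = if (sel$p_value < alpha) {
        dominant_driver(rr["r2_T"], rr["r2_P"], tol)
      } else "none",
      p_value = sel$p_value, status = "ok")
  })
  out <- dplyr::bind_rows(rows)
  out$significant_0.10 <- !is.na(out$p_value) & out$p_value < 0.10
  out$significant_0.05 <- !is.na(out$p_value) & out$p_value < 0.05
  out$significant_0.01 <- !is.na(out$p_value) & out$p_value < 0.01
  class(out) <- c("yv_attribution", class(out))
  out
}
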