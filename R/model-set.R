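# The candidate model set: 27 regression designs over the 8 climate predictor
# forms. Kept deliberately small to avoid over-fitting 30-year series.

#' The default 27-design candidate model set
#'
#' Builds the shipped candidate set of 27 regression designs over the eight
#' climate predictor forms (growing-season and annual temperature and
#' precipitation, each linear and squared). The set has three blocks:
#'
#' * **single-variable** (12): for each variable V in \{T, P\} and timescale s
#'   in \{gs, an\}: \{V_s\}, \{V_s, V_s^2\}, \{V_s^2\};
#' * **combined, same timescale** (10): for each s: \{T_s, P_s\},
#'   \{T_s, T_s^2, P_s, P_s^2\}, \{T_s^2, P_s^2\}, \{T_s, P_s, T_s x P_s\},
#'   \{T_s, T_s^2, P_s, P_s^2, T_s x P_s\};
#' * **mixed timescale** (5): \{T_gs, P_an\}, \{T_an, P_gs\},
#'   \{T_gs, T_gs^2, P_an, P_an^2\}, \{T_an, T_an^2, P_gs, P_gs^2\},
#'   \{T_gs, P_an, T_gs x P_an\}.
#'
#' Every design maps to exactly one of the seven climate-driver categories
#' (see [classify_design()]) and the set covers all seven. Alternative sets
#' can be loaded with [read_model_set()].
#'
#' @return A tibble with one row per design: `design_id`, `terms`
#'   (list-column of term strings, see [parse_term()]), `n_terms`,
#'   `enumeration_rank` (the canonical tie-break order), `category` and a
#'   human-readable `label`.
#' @examples
#' designs <- default_model_set()
#' nrow(designs) # 27
#' @export
default_model_set <- function() {
  single <- list()
  for (v in c("T", "P")) {
    for (s in c("gs", "an")) {
      a <- sprintf("%s:%s:1", v, s)
      b <- sprintf("%s:%s:2", v, s)
      single <- c(single, list(a, c(a, b), b))
    }
  }
  combined <- list()
  for (s in c("gs", "an")) {
    t1 <- sprintf("T:%s:1", s); t2 <- sprintf("T:%s:2", s)
    p1 <- sprintf("P:%s:1", s); p2 <- sprintf("P:%s:2", s)
    tx <- sprintf("T:%s*P:%s", s, s)
    combined <- c(combined, list(
      c(t1, p1),
      c(t1, t2, p1, p2),
      c(t2, p2),
      c(t1, p1, tx),
      c(t1, t2, p1, p2, tx)
    ))
  }
  mixed <- list(
    c("T:gs:1", "P:an:1"),
    c("T:an:1", "P:gs:1"),
    c("T:gs:1", "T:gs:2", "P:an:1", "P:an:2"),
    c("T:an:1", "T:an:2", "P:gs:1", "P:gs:2"),
    c("T:gs:1", "P:an:1", "T:gs*P:an")
  )
  terms <- c(single, combined, mixed)
  new_model_set(terms)
}

new_model_set <- function(terms, design_id = NULL) {
  n <- length(terms)
  design_id <- design_id %||% sprintf("m%02d", seq_len(n))
  for (tm in unlist(terms)) parse_term(tm) # validate
  dup <- vapply(terms, function(x) anyDuplicated(x) > 0, logical(1))
  if (any(dup)) {
    abort(sprintf("duplicate terms in design(s): %s",
                  paste(design_id[dup], collapse = ", ")),
          class = "yieldclim_design_error")
  }
  sizes <- lengths(terms)
  if (any(sizes < 1L | sizes > 5L)) {
    abort("each design must have between 1 and 5 terms",
          class = "yieldclim_design_error")
  }
  out <- tibble(
    design_id = design_id,
    terms = terms,
    n_terms = sizes,
    enumeration_rank = seq_len(n),
    category = vapply(terms, classify_design, character(1)),
    label = vapply(terms, function(x) {
      paste(vapply(x, term_label, character(1)), collapse = " + ")
    }, character(1))
  )
  class(out) <- c("yv_model_set", class(out))
  out
}

# Distinct variable x timescale x power predictor forms used by a model set.
model_set_forms <- function(designs) {
  sort(unique(unlist(lapply(unlist(designs$terms), term_forms))))
}

#' Read or write a candidate model set
#'
#' The on-disk format is a CSV with columns `design_id`, `terms`
#' (semicolon-separated term strings in the grammar of [parse_term()]) and
#' `enumeration_rank`; `category` and `label` are derived on read.
#'
#' @param path Path to the CSV file.
#' @return `read_model_set()` returns a model-set tibble in the shape of
#'   [default_model_set()]; `write_model_set()` returns `path`, invisibly.
#' @export
read_model_set <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("design_id", "terms", "enumeration_rank")
  if (!all(need %in% names(raw))) {
    abort(sprintf("model-set file must have columns %s",
                  paste(need, collapse = ", ")),
          class = "yieldclim_schema_error")
  }
  raw <- dplyr::arrange(raw, .data$enumeration_rank)
  terms <- strsplit(raw$terms, ";", fixed = TRUE)
  terms <- lapply(terms, trimws)
  new_model_set(terms, design_id = as.character(raw$design_id))
}

#' @param designs A model-set tibble, e.g. from [default_model_set()].
#' @rdname read_model_set
#' @export
write_model_set <- function(designs, path) {
  out <- tibble(
    design_id = designs$design_id,
    terms = vapply(designs$terms, paste, character(1), collapse = ";"),
    enumeration_rank = designs$enumeration_rank
  )
  readr::write_csv(out, path)
  invisible(path)
}
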