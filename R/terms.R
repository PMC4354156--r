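# Climate predictor term grammar.
#
# A main-effect term is "VAR:TIMESCALE:POWER", e.g. "T:gs:1" (growing-season
# temperature, linear) or "P:an:2" (annual precipitation, squared). An
# interaction term is "T:ts*P:ts", e.g. "T:gs*P:an", and always pairs exactly
# one temperature atom with one precipitation atom. Squared terms are squares
# of the detrended anomaly; interactions are products of detrended anomalies.

VALID_VARS <- c("T", "P")
VALID_TIMESCALES <- c("gs", "an")

parse_atom <- function(x, term) {
  parts <- strsplit(x, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !parts[1] %in% VALID_VARS ||
      !parts[2] %in% VALID_TIMESCALES) {
    abort(sprintf("malformed term atom '%s' in term '%s'", x, term),
          class = "yieldclim_term_error")
  }
  list(var = parts[1], ts = parts[2])
}

#' Parse a climate predictor term
#'
#' Parses one term of the predictor mini-grammar into a structured list.
#' Main-effect terms look like `"T:gs:1"` (variable, timescale, power);
#' interaction terms look like `"T:gs*P:an"` and must pair one temperature
#' atom with one precipitation atom.
#'
#' @param term A single term string.
#' @return A list with `kind` (`"main"` or `"interaction"`) plus, for main
#'   terms, `var`, `ts` and `power`; for interactions, `t_ts` and `p_ts`.
#' @examples
#' parse_term("T:gs:2")
#' parse_term("T:gs*P:an")
#' @export
parse_term <- function(term) {
  stopifnot(is.character(term), length(term) == 1)
  if (grepl("*", term, fixed = TRUE)) {
    halves <- strsplit(term, "*", fixed = TRUE)[[1]]
    if (length(halves) != 2) {
      abort(sprintf("malformed interaction term '%s'", term),
            class = "yieldclim_term_error")
    }
    atoms <- lapply(halves, parse_atom, term = term)
    vars <- vapply(atoms, `[[`, character(1), "var")
    if (!setequal(vars, c("T", "P"))) {
      abort(sprintf(
        "interaction term '%s' must pair one T atom with one P atom", term),
        class = "yieldclim_term_error")
    }
    t_atom <- atoms[[which(vars == "T")]]
    p_atom <- atoms[[which(vars == "P")]]
    list(kind = "interaction", t_ts = t_atom$ts, p_ts = p_atom$ts)
  } else {
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    if (length(parts) != 3 || !parts[1] %in% VALID_VARS ||
        !parts[2] %in% VALID_TIMESCALES || !parts[3] %in% c("1", "2")) {
      abort(sprintf("malformed term '%s'", term),
            class = "yieldclim_term_error")
    }
    list(kind = "main", var = parts[1], ts = parts[2],
         power = as.integer(parts[3]))
  }
}

# Anomaly-panel column backing a (var, timescale) atom.
atom_column <- function(var, ts) {
  paste0(tolower(var), "_", ts)
}

# Column label used in design matrices and coefficient tables.
term_label <- function(term) {
  p <- parse_term(term)
  if (p$kind == "interaction") {
    paste0("t_", p$t_ts, "_x_p_", p$p_ts)
  } else {
    paste0(atom_column(p$var, p$ts), if (p$power == 2) "_sq" else "")
  }
}

# Anomaly-panel columns a term needs.
term_columns <- function(term) {
  p <- parse_term(term)
  if (p$kind == "interaction") {
    c(atom_column("T", p$t_ts), atom_column("P", p$p_ts))
  } else {
    atom_column(p$var, p$ts)
  }
}

# Variables ("T", "P") a term involves.
term_vars <- function(term) {
  p <- parse_term(term)
  if (p$kind == "interaction") c("T", "P") else p$var
}

# Evaluate one term on a data frame of anomaly predictors
# (columns t_gs, t_an, p_gs, p_an).
term_values <- function(term, data) {
  p <- parse_term(term)
  if (p$kind == "interaction") {
    data[[atom_column("T", p$t_ts)]] * data[[atom_column("P", p$p_ts)]]
  } else {
    v <- data[[atom_column(p$var, p$ts)]]
    if (p$power == 2) v^2 else v
  }
}

# The predictor form(s) a term exercises, out of the eight
# variable x timescale x power forms; an interaction exercises the linear
# form of each of its atoms.
term_forms <- function(term) {
  p <- parse_term(term)
  if (p$kind == "interaction") {
    c(paste0("T:", p$t_ts, ":1"), paste0("P:", p$p_ts, ":1"))
  } else {
    paste0(p$var, ":", p$ts, ":", p$power)
  }
}
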