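# Independent oracles and tiny fixture builders used across tests.

# Normal-equations least squares, independent of the package's QR path.
ne_fit <- function(y, x) {
  unname(drop(solve(crossprod(x), crossprod(x, y))))
}

# Minimal anomaly panel for one unit from raw predictor/response vectors
# (already detrended / mean-zero by construction in the tests that use it).
anomaly_unit <- function(yield, t_gs = NULL, t_an = NULL, p_gs = NULL,
                         p_an = NULL, unit_id = "u0001") {
  n <- length(yield)
  zero <- rep(0, n)
  tibble::tibble(
    unit_id = unit_id, year = seq_len(n),
    yield = yield,
    t_gs = t_gs %||% zero, t_an = t_an %||% zero,
    p_gs = p_gs %||% zero, p_an = p_an %||% zero,
    area_ha = 1000, detrend_method = "linear")
}

# Unit monthly climate series over full calendar years.
monthly_unit <- function(years, t_C, p_mm, unit_id = "u0001") {
  grid <- expand.grid(month = 1:12, year = years)
  tibble::tibble(
    unit_id = unit_id, year = grid$year, month = grid$month,
    t_C = rep_len(t_C, nrow(grid)), p_mm = rep_len(p_mm, nrow(grid)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
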