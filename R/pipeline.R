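# End-to-end orchestration: panel in (synthetic or CSV), detrend, select,
# attribute, aggregate, optional bootstrap, results and log out.

#' Run the full attribution pipeline
#'
#' Drives the whole analysis from a single configuration: obtain a panel
#' (synthetic, from a generator configuration, or read from CSV), detrend
#' yields and climate, select the best candidate design per unit, test it
#' against the intercept-only null, classify and decompose the winners, and
#' aggregate under harvested-area weighting. Identical configuration and
#' seed give identical outputs.
#'
#' The configuration is a named list (or path to a YAML file) with entries:
#' * `mode`: `"synthetic_panel"` (default), `"synthetic_grid"`, or
#'   `"panel_csv"`;
#' * `panel`: input CSV path (mode `"panel_csv"`);
#' * `synthetic`: arguments for [sim_config()] (synthetic modes), e.g.
#'   `n_units`, `effect_size`, `seed`;
#' * `detrend`: `"linear"` (default), `"quadratic"` or
#'   `"first_difference"`;
#' * `model_set`: path to a model-set CSV, or `NULL` for the default 27;
#' * `alpha` (default 0.10), `alphas` (default `c(0.10, 0.05, 0.01)`);
#' * `ic`: `"aic"` (default) or `"aicc"`;
#' * `bootstrap`: logical, run the 99-rep bias assessment (default FALSE);
#' * `out_dir`: if set, write `attribution.csv`, `aggregate.csv`,
#'   `selections.csv` (and `bootstrap.csv`) plus a plain-text run log there;
#' * `seed`: pipeline seed (default 1).
#'
#' @param config Named list or path to a YAML configuration file.
#' @return A list of class `yv_pipeline`: `panel`, `truth` (synthetic modes),
#'   `anomalies`, `selections`, `attribution`, `aggregate`, optionally
#'   `bootstrap`, and `config_hash`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(mode = "synthetic_panel", detrend = "linear",
                   model_set = NULL, alpha = 0.10,
                   alphas = c(0.10, 0.05, 0.01), ic = "aic",
                   bootstrap = FALSE, out_dir = NULL, seed = 1L,
                   min_years = 15)
  config <- utils::modifyList(defaults, config)
  cfg_hash <- rlang::hash(config[setdiff(names(config), "out_dir")])
  log_lines <- c(sprintf("yieldclim pipeline | config hash %s", cfg_hash),
                 sprintf("mode: %s | detrend: %s | alpha: %.2f",
                         config$mode, config$detrend, config$alpha))

  designs <- if (is.null(config$model_set)) {
    default_model_set()
  } else {
    read_model_set(config$model_set)
  }

  truth <- NULL
  if (config$mode == "panel_csv") {
    if (is.null(config$panel)) {
      abort("mode 'panel_csv' requires a 'panel' path",
            class = "yieldclim_schema_error")
    }
    panel <- read_panel(config$panel)
  } else if (config$mode %in% c("synthetic_panel", "synthetic_grid")) {
    syn_args <- config$synthetic %||% list(n_units = 50)
    if (is.null(syn_args$seed)) syn_args$seed <- config$seed
    scfg <- do.call(sim_config, syn_args)
    sim <- if (config$mode == "synthetic_grid") {
      simulate_grid(scfg)
    } else {
      simulate_panel(scfg)
    }
    panel <- sim$panel
    truth <- sim$truth
  } else {
    abort(sprintf("unknown mode '%s'", config$mode),
          class = "yieldclim_schema_error")
  }
  log_lines <- c(log_lines,
                 sprintf("panel: %d units, %d rows",
                         dplyr::n_distinct(panel$unit_id), nrow(panel)))

  anomalies <- detrend_panel(panel, method = config$detrend)
  selections <- select_models(anomalies, designs, alpha = config$alpha,
                              ic = config$ic, min_years = config$min_years)
  n_bad <- sum(selections$status != "ok")
  if (n_bad > 0) {
    log_lines <- c(log_lines,
                   sprintf("%d unit(s) excluded (insufficient data or unfittable)",
                           n_bad))
  }
  if (all(selections$status != "ok")) {
    abort("no unit could be analyzed", class = "yieldclim_no_data")
  }
  attribution <- attribute_units(anomalies, selections, designs,
                                 alpha = config$alpha)
  aggregate <- aggregate_results(attribution, panel, alphas = config$alphas)

  boot <- NULL
  if (isTRUE(config$bootstrap)) {
    boot <- bootstrap_bias_units(anomalies, panel, selections, designs,
                                 seed = config$seed)
    log_lines <- c(log_lines,
                   sprintf("bootstrap: %d unit(s), 99 reps each", nrow(boot)))
  }

  out <- structure(list(
    panel = panel, truth = truth, anomalies = anomalies,
    selections = selections, attribution = attribution,
    aggregate = aggregate, bootstrap = boot,
    designs = designs, config = config, config_hash = cfg_hash,
    log = log_lines), class = "yv_pipeline")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(as_tibble(attribution),
                     file.path(config$out_dir, "attribution.csv"))
    readr::write_csv(as_tibble(aggregate),
                     file.path(config$out_dir, "aggregate.csv"))
    readr::write_csv(selections,
                     file.path(config$out_dir, "selections.csv"))
    if (!is.null(boot)) {
      readr::write_csv(boot, file.path(config$out_dir, "bootstrap.csv"))
    }
    writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  }
  out
}

#' @export
print.yv_pipeline <- function(x, ...) {
  cat(sprintf("<yv_pipeline> %s\n", x$config_hash))
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  g <- x$aggregate[x$aggregate$alpha == x$config$alpha, ]
  if (nrow(g) > 0) {
    cat(sprintf("  area-weighted r2 (alpha %.2f): %.3f over %.0f%% of area\n",
                g$alpha[1], g$area_weighted_r2[1],
                100 * g$significant_area_fraction[1]))
  }
  invisible(x)
}
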