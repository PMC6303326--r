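#' Pipeline configuration
#'
#' A validated bundle of settings for [run_pipeline()]. Provide either a
#' generator `scenario` (with optional `n_plots` override) or an
#' `input_path` to an existing plot table.
#'
#' @param out_dir Output directory (created if absent).
#' @param scenario Generator scenario name, or `NULL` to read a file.
#' @param input_path Path to a plot table, or `NULL` to simulate.
#' @param n_plots Plot count override for the generator.
#' @param k Quantile classes per climate axis (default 10).
#' @param alpha Significance level of the bivariate z tests.
#' @param level Credible level for the posterior rules.
#' @param seed Base seed for every stochastic stage.
#' @param mcmc MCMC settings for the hierarchical stage (default: desk
#'   profile seeded from `seed`).
#' @param min_n_bivariate,min_n_hbm Per-unit plot minima.
#' @param run_boundary,run_hbm Stage toggles.
#' @param figures Also render the climate-space figure as a PNG.
#' @return A `bpr_pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            scenario = NULL, input_path = NULL,
                            n_plots = NULL, k = 10,
                            alpha = 0.05, level = 0.95, seed = 42,
                            mcmc = NULL,
                            min_n_bivariate = 4, min_n_hbm = 30,
                            run_boundary = TRUE, run_hbm = TRUE,
                            figures = FALSE) {
  if (is.null(scenario) == is.null(input_path)) {
    abort("Provide exactly one of 'scenario' or 'input_path'.")
  }
  if (!is.null(input_path) && !file.exists(input_path)) {
    abort(paste0("Input file does not exist: ", input_path))
  }
  if (k < 2) abort("k must be at least 2.")
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie in (0, 1).")
  structure(list(
    out_dir = out_dir, scenario = scenario, input_path = input_path,
    n_plots = n_plots, k = k, alpha = alpha, level = level,
    seed = as.integer(seed),
    mcmc = mcmc %||% desk_profile(seed = seed),
    min_n_bivariate = min_n_bivariate, min_n_hbm = min_n_hbm,
    run_boundary = run_boundary, run_hbm = run_hbm, figures = figures
  ), class = "bpr_pipeline_config")
}

write_stage <- function(tbl, dir, name) {
  path <- file.path(dir, name)
  readr::write_tsv(tbl, path, na = "NA", progress = FALSE)
  path
}

#' Run the full BPR analysis pipeline
#'
#' Executes, in order: simulate (or read) the plot table, derive
#' productivity, drop incomplete plots, bin plots into the MAT x TAP
#' quantile grid, classify the bivariate BPR of every unit, fit the
#' logistic boundary between the two BPR types, fit the hierarchical model
#' per unit and classify its posterior BPR, and write every stage output as
#' delimited text into `config$out_dir`. All stages are deterministic given
#' `config$seed`; no timestamps are written, so reruns with the same
#' configuration are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return A `bpr_run_report`: per-stage row counts and reconciliation,
#'   skipped units, file paths, and the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "bpr_pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  if (!is.null(config$scenario)) {
    params <- default_params(config$scenario)
    if (!is.null(config$n_plots)) params$n_plots <- as.integer(config$n_plots)
    params$seed <- config$seed
    plots <- simulate_plots(params)
    paths$plots <- write_stage(plots, config$out_dir, "plots.tsv")
    paths$truth <- write_truth(plots, file.path(config$out_dir, "truth.json"))
  } else {
    plots <- read_plot_table(config$input_path)
  }
  n_input <- nrow(plots)

  plots <- derive_productivity(plots)
  n_flagged <- attr(plots, "derive_report")$n_flagged
  filtered <- filter_complete(plots, c(bpr_required_columns(), "productivity"))
  frep <- filter_report(filtered)
  if (nrow(filtered) == 0) abort("Stage filter_complete: no complete plots remain.")

  grid <- tryCatch(
    assign_units(filtered, build_climate_grid(filtered, k = config$k)),
    error = function(e) abort(paste0("Stage binning failed: ", conditionMessage(e)))
  )
  units <- summarize_units(filtered, grid)
  paths$units <- write_stage(units, config$out_dir, "units.tsv")

  bpr_units <- bivariate_by_unit(filtered, grid, alpha = config$alpha,
                                 min_n = config$min_n_bivariate)
  paths$bivariate <- write_stage(dplyr::select(bpr_units, -"fit"),
                                 config$out_dir, "bpr_units.tsv")

  boundary <- NULL
  if (config$run_boundary) {
    unit_tbl <- dplyr::inner_join(units,
                                  dplyr::select(bpr_units, "unit", "bpr_type"),
                                  by = "unit")
    boundary <- tryCatch(fit_type_boundary(unit_tbl), error = function(e) {
      inform(paste0("Boundary stage skipped: ", conditionMessage(e)))
      NULL
    })
    if (!is.null(boundary)) {
      mat_grid <- seq(min(units$mat_mean), max(units$mat_mean),
                      length.out = 50)
      paths$boundary <- write_stage(
        boundary_line(boundary, mat_grid), config$out_dir, "boundary.tsv")
      paths$boundary_coefficients <- write_stage(
        tidy(boundary), config$out_dir, "boundary_coefficients.tsv")
    }
  }

  hbm <- NULL; posterior_types <- NULL
  if (config$run_hbm) {
    settings <- config$mcmc
    settings$seed <- config$seed
    hbm <- fit_all_units(filtered, grid, settings = settings,
                         min_n = config$min_n_hbm, level = config$level)
    summaries <- purrr::imap(hbm$posteriors, function(p, uid) {
      dplyr::mutate(p$summary, unit = as.integer(uid))
    }) |>
      purrr::list_rbind() |>
      dplyr::relocate("unit")
    paths$posterior <- write_stage(summaries, config$out_dir, "posterior.tsv")
    paths$hbm_report <- write_stage(hbm$report, config$out_dir,
                                    "hbm_report.tsv")
    posterior_types <- classify_units_posterior(hbm, level = config$level)
    paths$posterior_types <- write_stage(posterior_types, config$out_dir,
                                         "bpr_posterior.tsv")
  }

  if (config$figures) {
    unit_types <- dplyr::select(bpr_units, "unit", "bpr_type")
    fig <- plot_climate_units(units, unit_types, boundary)
    paths$figure <- file.path(config$out_dir, "climate_units.png")
    ggplot2::ggsave(paths$figure, fig, width = 7, height = 5, dpi = 150)
    paths$figure_data <- write_stage(
      climate_figure_data(units, unit_types, boundary),
      config$out_dir, "climate_units_data.tsv")
  }

  report <- structure(list(
    counts = tibble(
      stage = c("input", "productivity_flagged", "filtered_removed",
                "filtered_kept", "populated_units", "bivariate_classified",
                "hbm_fitted", "hbm_skipped"),
      n = c(n_input, n_flagged, frep$n_removed, frep$n_kept, nrow(units),
            nrow(bpr_units),
            if (is.null(hbm)) NA_integer_ else length(hbm$posteriors),
            if (is.null(hbm)) NA_integer_ else
              sum(hbm$report$status != "fitted"))
    ),
    filter_by_column = frep$by_column,
    paths = paths,
    config = config,
    results = list(plots = filtered, grid = grid, units = units,
                   bivariate = bpr_units, boundary = boundary,
                   hbm = hbm, posterior_types = posterior_types)
  ), class = "bpr_run_report")
  report_json <- list(
    counts = report$counts,
    filter_by_column = frep$by_column,
    seed = config$seed, k = config$k, alpha = config$alpha,
    level = config$level
  )
  jsonlite::write_json(report_json, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  report
}

#' @export
print.bpr_run_report <- function(x, ...) {
  cat("<bpr_run_report>\n")
  print(x$counts)
  invisible(x)
}
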