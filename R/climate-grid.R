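#' Quantile breakpoints for one climate axis
#'
#' Empirical quantiles (default interpolation, type 7) at probabilities
#' i/k, with the first and last breakpoints pinned to the data minimum and
#' maximum. On tie-free data this yields exactly balanced classes under the
#' lower-closed interval convention of [assign_units()]. Duplicate interior
#' breakpoints (heavy ties) are collapsed with a warning, yielding fewer
#' effective classes.
#'
#' @param values Numeric vector (missing values ignored).
#' @param k Number of quantile classes (default 10).
#' @return Numeric vector of at most `k + 1` strictly increasing breakpoints.
#' @export
quantile_breaks <- function(values, k = 10) {
  values <- values[!is.na(values)]
  if (k < 2) abort("k must be at least 2.")
  if (length(unique(values)) < k) {
    abort(paste0("Need at least ", k, " distinct values to form ", k,
                 " quantile classes (got ", length(unique(values)), ")."))
  }
  br <- unname(quantile(values, probs = seq(0, 1, length.out = k + 1),
                        type = 7, names = FALSE))
  br[1] <- min(values)
  br[k + 1] <- max(values)
  dedup <- unique(br)
  if (length(dedup) < length(br)) {
    warn(paste0("Collapsed ", length(br) - length(dedup),
                " duplicate breakpoint(s); fewer than ", k,
                " effective classes."))
  }
  dedup
}

#' Build the MAT x TAP quantile grid for a plot table
#'
#' Crosses `k` quantile classes of mean annual temperature with `k` quantile
#' classes of total annual precipitation, defining up to `k^2` climatic
#' units over the plot population.
#'
#' @param table Plot tibble with `mat` and `tap` columns (bin after
#'   filtering incomplete rows; the breakpoints describe the analysed
#'   population).
#' @param k Classes per axis (default 10, i.e. deciles and 100 units).
#' @return A `climate_grid` object (breakpoints per axis, class counts,
#'   empty assignment). Pass to [assign_units()].
#' @export
build_climate_grid <- function(table, k = 10) {
  stopifnot(all(c("mat", "tap") %in% names(table)))
  mat_breaks <- quantile_breaks(table$mat, k)
  tap_breaks <- quantile_breaks(table$tap, k)
  structure(list(
    k = k,
    mat_breaks = mat_breaks,
    tap_breaks = tap_breaks,
    k_mat = length(mat_breaks) - 1L,
    k_tap = length(tap_breaks) - 1L,
    assignment = NULL
  ), class = "climate_grid")
}

# class index for values against breakpoints: intervals [b_i, b_{i+1}),
# last interval closed; values exactly at an interior breakpoint ascend.
interval_class <- function(x, breaks, axis) {
  if (any(x < breaks[1] | x > breaks[length(breaks)], na.rm = TRUE)) {
    abort(paste0(axis, " values fall outside the grid breakpoints [",
                 breaks[1], ", ", breaks[length(breaks)],
                 "]; build the grid from the same (or enclosing) data."))
  }
  cls <- findInterval(x, breaks, rightmost.closed = TRUE, left.open = FALSE)
  pmin(cls, length(breaks) - 1L)
}

#' Assign plots to climatic units
#'
#' Maps each plot to its (MAT class, TAP class) cell and a unit id in
#' `1..k_mat * k_tap`.
#'
#' @param table Plot tibble with `plot_id`, `mat`, `tap`.
#' @param grid A `climate_grid` from [build_climate_grid()].
#' @return The grid with `assignment` populated: a tibble of `plot_id`,
#'   `mat_class`, `tap_class`, `unit`.
#' @export
assign_units <- function(table, grid) {
  stopifnot(inherits(grid, "climate_grid"))
  mat_class <- interval_class(table$mat, grid$mat_breaks, "MAT")
  tap_class <- interval_class(table$tap, grid$tap_breaks, "TAP")
  grid$assignment <- tibble(
    plot_id = table$plot_id,
    mat_class = mat_class,
    tap_class = tap_class,
    unit = (mat_class - 1L) * grid$k_tap + tap_class
  )
  grid
}

#' Classify an aridity index into the four aridity classes
#'
#' Thresholds: `[0.03, 0.2)` arid, `[0.2, 0.5)` semi-arid, `[0.5, 0.65)`
#' dry sub-humid, `>= 0.65` humid. Values below 0.03 (hyper-arid) are
#' labelled arid with a warning; non-positive values are an error.
#'
#' @param aridity Positive numeric vector.
#' @return Factor with levels arid, semi-arid, dry sub-humid, humid.
#' @export
aridity_class <- function(aridity) {
  if (any(aridity <= 0, na.rm = TRUE)) {
    abort("Aridity index must be positive.")
  }
  if (any(aridity < 0.03, na.rm = TRUE)) {
    warn(paste0(sum(aridity < 0.03, na.rm = TRUE),
                " aridity value(s) below 0.03 labelled 'arid'."))
  }
  cut(aridity, breaks = c(0, 0.2, 0.5, 0.65, Inf), right = FALSE,
      labels = c("arid", "semi-arid", "dry sub-humid", "humid"))
}

#' Summarize climatic units
#'
#' One row per populated unit: plot count, climate means, mean aridity, the
#' unit's aridity class (from the aggregated aridity of member plots), and
#' `log_n` (natural log of the plot count, the circle radius used in the
#' climate-space figure).
#'
#' @param table Plot tibble.
#' @param grid A `climate_grid` with assignment populated.
#' @param aggregate Aggregation for unit aridity: `"mean"` (default) or
#'   `"median"`.
#' @return Tibble of unit summaries.
#' @export
summarize_units <- function(table, grid, aggregate = c("mean", "median")) {
  stopifnot(inherits(grid, "climate_grid"))
  if (is.null(grid$assignment)) abort("Grid assignment not populated; call assign_units().")
  aggregate <- match.arg(aggregate)
  agg <- if (aggregate == "mean") mean else stats::median

  dplyr::inner_join(table, grid$assignment, by = "plot_id") |>
    dplyr::group_by(.data$unit, .data$mat_class, .data$tap_class) |>
    dplyr::summarise(
      n_plots = dplyr::n(),
      mat_mean = mean(.data$mat, na.rm = TRUE),
      tap_mean = mean(.data$tap, na.rm = TRUE),
      aridity_mean = agg(.data$aridity, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      aridity_class = aridity_class(.data$aridity_mean),
      log_n = log(.data$n_plots)
    ) |>
    dplyr::arrange(.data$unit)
}

#' @export
print.climate_grid <- function(x, ...) {
  cat("<climate_grid> ", x$k_mat, "x", x$k_tap, " classes (k = ", x$k, ")\n",
      sep = "")
  cat("  MAT breaks: ", paste(signif(x$mat_breaks, 4), collapse = ", "), "\n")
  cat("  TAP breaks: ", paste(signif(x$tap_breaks, 4), collapse = ", "), "\n")
  if (!is.null(x$assignment)) {
    cat("  assigned plots:", nrow(x$assignment), " populated units:",
        dplyr::n_distinct(x$assignment$unit), "\n")
  }
  invisible(x)
}
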