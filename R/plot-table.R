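#' Read a plot-level forest inventory table
#'
#' Reads a delimited text table (TSV by default, CSV by file extension or
#' explicit `delim`) with one row per forest plot and the standard column
#' set: `plot_id`, `ecoregion`, `mat`, `tap`, `aridity`, `soil_cn`,
#' `stem_density`, `stand_age`, `agb`, `richness`. `"NA"`, `"NaN"` and empty
#' cells are parsed as missing. Unknown extra columns are preserved.
#' Rows with `richness` 0 (unforested plots) are dropped with a warning,
#' since the log-link richness model and the BPR analysis presuppose at
#' least one tree species.
#'
#' @param path Path to the delimited file.
#' @param delim Field delimiter; inferred from the extension when `NULL`.
#' @return A tibble; attribute `"provenance"` records the source path.
#' @export
read_plot_table <- function(path, delim = NULL) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  header <- strsplit(readr::read_lines(path, n_max = 1), delim, fixed = TRUE)[[1]]
  absent <- setdiff(bpr_required_columns(), header)
  if (length(absent) > 0) {
    abort(paste0("Plot table is missing mandatory column(s): ",
                 paste(absent, collapse = ", "), "."))
  }

  spec <- readr::cols(
    plot_id = readr::col_character(),
    ecoregion = readr::col_character(),
    .default = readr::col_double()
  )
  # malformed cells are re-reported as an error below, so readr's own
  # parsing-issue warning is redundant
  tbl <- withCallingHandlers(
    readr::read_delim(path, delim = delim, col_types = spec,
                      na = c("NA", "", "NaN"),
                      show_col_types = FALSE, progress = FALSE),
    warning = function(w) {
      if (grepl("parsing issues", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0) {
    colname <- ifelse(is.na(probs$col) | probs$col > length(header),
                      "<row>", header[pmin(probs$col, length(header))])
    lines <- paste0("line ", probs$row, ", column '", colname,
                    "': expected ", probs$expected, ", got '", probs$actual, "'")
    abort(paste0("Malformed cells in ", path, ":\n  ",
                 paste(utils::head(lines, 10), collapse = "\n  ")))
  }
  if (anyDuplicated(tbl$plot_id)) {
    abort("plot_id values must be unique.")
  }

  unforested <- !is.na(tbl$richness) & tbl$richness < 1
  if (any(unforested)) {
    warn(paste0("Dropped ", sum(unforested),
                " unforested row(s) with richness = 0."))
    tbl <- tbl[!unforested, , drop = FALSE]
  }
  tbl$richness <- as.integer(round(tbl$richness))
  attr(tbl, "provenance") <- path
  tbl
}

#' Write a plot table as delimited text
#'
#' Missing values are written as `"NA"`; TSV unless the path ends in `.csv`.
#'
#' @param table Plot tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plot_table <- function(table, path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(table, path, na = "NA", progress = FALSE)
  } else {
    readr::write_tsv(table, path, na = "NA", progress = FALSE)
  }
  invisible(path)
}

#' Derive plot productivity from biomass and stand age
#'
#' Productivity is the mean annual increment in above-ground tree biomass:
#' total above-ground live biomass divided by stand age (below-ground
#' productivity is not included). Rows with missing or non-positive stand
#' age get a missing productivity and are counted in the attached report
#' rather than dropped.
#'
#' @param table Plot tibble with `agb` and `stand_age` columns.
#' @return The tibble with a `productivity` column added; attribute
#'   `"derive_report"` holds the number of flagged rows.
#' @export
derive_productivity <- function(table) {
  if (!all(c("agb", "stand_age") %in% names(table))) {
    abort("derive_productivity() needs 'agb' and 'stand_age' columns.")
  }
  bad <- is.na(table$stand_age) | table$stand_age <= 0
  out <- dplyr::mutate(
    table,
    productivity = ifelse(bad, NA_real_, .data$agb / .data$stand_age)
  )
  attr(out, "derive_report") <- list(n_flagged = sum(bad))
  attr(out, "provenance") <- attr(table, "provenance")
  attr(out, "truth") <- attr(table, "truth")
  out
}

#' Keep only plots complete in the required columns
#'
#' Mirrors the exclusion of plots with missing values before analysis: rows
#' with any missing value in a required column are removed, preserving row
#' order. The per-column missing counts and totals are attached as a report
#' (see [filter_report()]). Idempotent.
#'
#' @param table Plot tibble.
#' @param required Columns that must be non-missing (default: the standard
#'   plot column set).
#' @return Filtered tibble with attribute `"filter_report"`.
#' @export
filter_complete <- function(table, required = bpr_required_columns()) {
  absent <- setdiff(required, names(table))
  if (length(absent) > 0) {
    abort(paste0("Required column(s) not in table: ",
                 paste(absent, collapse = ", "), "."))
  }
  keep <- complete.cases(table[, required, drop = FALSE])
  report <- tibble(
    column = required,
    n_missing = purrr::map_int(required, ~ sum(is.na(table[[.x]])))
  )
  out <- table[keep, , drop = FALSE]
  attr(out, "filter_report") <- list(
    n_input = nrow(table), n_kept = sum(keep), n_removed = sum(!keep),
    by_column = report
  )
  attr(out, "provenance") <- attr(table, "provenance")
  attr(out, "truth") <- attr(table, "truth")
  out
}

#' Retrieve the filtering report attached by [filter_complete()]
#'
#' @param table A tibble returned by [filter_complete()].
#' @return A list with `n_input`, `n_kept`, `n_removed` and a per-column
#'   missing-count tibble.
#' @export
filter_report <- function(table) {
  rep <- attr(table, "filter_report")
  if (is.null(rep)) abort("No filter report attached to this table.")
  rep
}
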