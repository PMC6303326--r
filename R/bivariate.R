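#' Fit linear and quadratic bivariate BPR models for one unit
#'
#' Models log productivity as a Gaussian GLM of tree species richness,
#' fitting both a linear model and a quadratic model (richness and
#' richness squared), and selects the one with lower AIC (ties go to the
#' simpler linear model). Coefficient significance uses Wald z statistics
#' (estimate / SE referred to the standard normal), and AIC counts the
#' Gaussian error variance as an estimated parameter, matching standard
#' GLM software conventions. Plots with non-positive productivity (log
#' undefined) are dropped and counted.
#'
#' @param richness Integer vector of species counts.
#' @param log_productivity Log-productivity vector, same length; may contain
#'   `-Inf`/`NA` from non-positive productivity (such rows are dropped).
#' @param min_n Minimum rows needed for an estimable fit (default 4).
#' @return A `bpr_bivariate_fit` list: `n`, `n_dropped`, per-model
#'   coefficient tables (`estimate`, `se`, `z`, `p`), `loglik` and `aic`
#'   for both models, `selected`, and `estimable` (+ `reason` when not).
#' @export
fit_bivariate <- function(richness, log_productivity, min_n = 4) {
  stopifnot(length(richness) == length(log_productivity))
  ok <- is.finite(richness) & is.finite(log_productivity)
  n_dropped <- sum(!ok)
  s <- as.numeric(richness[ok])
  y <- as.numeric(log_productivity[ok])

  not_estimable <- function(reason) {
    structure(list(
      n = length(y), n_dropped = n_dropped, estimable = FALSE,
      reason = reason, linear = NULL, quadratic = NULL, selected = NA_character_
    ), class = "bpr_bivariate_fit")
  }
  if (length(y) < min_n) return(not_estimable("too few plots"))
  if (sd(s) == 0) return(not_estimable("zero variance in richness"))

  lin <- glm(y ~ s, family = gaussian())
  qua <- glm(y ~ s + I(s^2), family = gaussian())
  if (qua$rank < 3) return(not_estimable("quadratic design rank-deficient"))

  coef_table <- function(fit, labels) {
    sm <- summary(fit)$coefficients
    est <- sm[, "Estimate"]; se <- sm[, "Std. Error"]
    z <- est / se
    tibble(term = labels, estimate = unname(est), se = unname(se),
           z = unname(z), p = 2 * pnorm(-abs(unname(z))))
  }

  structure(list(
    n = length(y), n_dropped = n_dropped, estimable = TRUE, reason = NA_character_,
    linear = list(
      coefficients = coef_table(lin, c("intercept", "richness")),
      loglik = as.numeric(logLik(lin)), aic = AIC(lin)
    ),
    quadratic = list(
      coefficients = coef_table(qua, c("intercept", "richness", "richness_sq")),
      loglik = as.numeric(logLik(qua)), aic = AIC(qua)
    ),
    selected = if (AIC(qua) < AIC(lin)) "quadratic" else "linear"
  ), class = "bpr_bivariate_fit")
}

#' @export
print.bpr_bivariate_fit <- function(x, ...) {
  cat("<bpr_bivariate_fit> n =", x$n)
  if (!x$estimable) {
    cat("  (non-estimable:", x$reason, ")\n")
    return(invisible(x))
  }
  cat("  selected:", x$selected,
      sprintf(" (AIC linear %.2f, quadratic %.2f)\n",
              x$linear$aic, x$quadratic$aic))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.bpr_bivariate_fit <- function(x, ...) {
  if (!x$estimable) return(tibble())
  dplyr::bind_rows(
    dplyr::mutate(x$linear$coefficients, model = "linear"),
    dplyr::mutate(x$quadratic$coefficients, model = "quadratic")
  ) |>
    dplyr::relocate("model")
}

#' @exportS3Method generics::glance
glance.bpr_bivariate_fit <- function(x, ...) {
  if (!x$estimable) {
    return(tibble(n = x$n, estimable = FALSE, reason = x$reason))
  }
  tibble(
    n = x$n, estimable = TRUE, reason = NA_character_,
    selected = x$selected,
    aic_linear = x$linear$aic, aic_quadratic = x$quadratic$aic,
    loglik_linear = x$linear$loglik, loglik_quadratic = x$quadratic$loglik
  )
}

bpr_type_levels <- function() {
  c("linear_positive", "linear_negative", "concave_negative",
    "concave_positive", "non_significant")
}

#' Classify the BPR type of a bivariate fit
#'
#' Applies the decision rules to the AIC-selected model: if the linear model
#' was selected, the unit is `linear_positive`/`linear_negative` when the
#' richness slope is significant (two-sided z test at `alpha`) and positive/
#' negative, otherwise `non_significant`; if the quadratic model was
#' selected, the unit is `concave_negative`/`concave_positive` when the
#' quadratic term is significant and negative/positive, otherwise
#' `non_significant`. Non-estimable fits classify as `non_significant`.
#'
#' @param fit A `bpr_bivariate_fit`.
#' @param alpha Significance level (default 0.05).
#' @return A single BPR type label (character).
#' @export
classify_bivariate <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "bpr_bivariate_fit"))
  if (!fit$estimable) return("non_significant")
  if (fit$selected == "linear") {
    b1 <- fit$linear$coefficients$estimate[2]
    p1 <- fit$linear$coefficients$p[2]
    if (p1 <= alpha && b1 > 0) return("linear_positive")
    if (p1 <= alpha && b1 < 0) return("linear_negative")
    return("non_significant")
  }
  b2 <- fit$quadratic$coefficients$estimate[3]
  p2 <- fit$quadratic$coefficients$p[3]
  if (p2 <= alpha && b2 < 0) return("concave_negative")
  if (p2 <= alpha && b2 > 0) return("concave_positive")
  "non_significant"
}

#' Bivariate BPR classification for every climatic unit
#'
#' Runs [fit_bivariate()] and [classify_bivariate()] on the plots of each
#' populated climatic unit.
#'
#' @param table Plot tibble with a `productivity` column (see
#'   [derive_productivity()]).
#' @param grid A `climate_grid` with assignment populated.
#' @param alpha Significance level for the z tests (default 0.05).
#' @param min_n Minimum plots per unit for an estimable fit (default 4).
#' @return A tibble with one row per populated unit: `unit`, `n`,
#'   `n_dropped`, `estimable`, `selected`, the linear-model slope (`b1`,
#'   `p1`), the quadratic-model terms (`b1_quad`, `b2`, `p2`),
#'   `aic_linear`, `aic_quadratic`, `bpr_type`, and the list-column `fit`.
#' @export
bivariate_by_unit <- function(table, grid, alpha = 0.05, min_n = 4) {
  stopifnot(inherits(grid, "climate_grid"))
  if (is.null(grid$assignment)) abort("Grid assignment not populated; call assign_units().")
  if (!"productivity" %in% names(table)) {
    abort("Table has no 'productivity' column; call derive_productivity() first.")
  }
  if (nrow(table) == 0) abort("Empty plot table.")

  joined <- dplyr::inner_join(
    dplyr::select(table, "plot_id", "richness", "productivity"),
    grid$assignment, by = "plot_id"
  ) |>
    dplyr::mutate(log_productivity = ifelse(
      !is.na(.data$productivity) & .data$productivity > 0,
      log(.data$productivity), NA_real_))

  joined |>
    dplyr::group_by(.data$unit) |>
    dplyr::group_map(function(df, key) {
      fit <- fit_bivariate(df$richness, df$log_productivity, min_n = min_n)
      row <- tibble(
        unit = key$unit,
        n = fit$n,
        n_dropped = fit$n_dropped,
        estimable = fit$estimable,
        selected = fit$selected,
        b1 = NA_real_, p1 = NA_real_,
        b1_quad = NA_real_, b2 = NA_real_, p2 = NA_real_,
        aic_linear = NA_real_, aic_quadratic = NA_real_,
        bpr_type = classify_bivariate(fit, alpha = alpha),
        fit = list(fit)
      )
      if (fit$estimable) {
        row$b1 <- fit$linear$coefficients$estimate[2]
        row$p1 <- fit$linear$coefficients$p[2]
        row$b1_quad <- fit$quadratic$coefficients$estimate[2]
        row$b2 <- fit$quadratic$coefficients$estimate[3]
        row$p2 <- fit$quadratic$coefficients$p[3]
        row$aic_linear <- fit$linear$aic
        row$aic_quadratic <- fit$quadratic$aic
      }
      row
    }) |>
    purrr::list_rbind() |>
    dplyr::arrange(.data$unit)
}
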