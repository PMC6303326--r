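#' Classify a unit's BPR from posterior draws of the richness terms
#'
#' Applies the posterior decision rules to the draws of the linear (`b17`)
#' and quadratic (`b18`) standardized-richness effects on log productivity:
#' * `concave_negative` if P(b18 < 0) > `level`;
#' * `concave_positive` if P(b18 > 0) > `level`;
#' * `linear_positive` if P(b17 > 0) > `level` and the equal-tailed
#'   credible interval for b18 overlaps zero;
#' * `linear_negative` (an extension label: the rule set leaves a
#'   significantly negative linear effect with a null quadratic unlabelled,
#'   and we label it explicitly rather than fold it into non-significance)
#'   if P(b17 < 0) > `level` and the CI for b18 overlaps zero;
#' * `non_significant` otherwise (both CIs overlap zero).
#'
#' The concavity rules take precedence: as written the rules are not
#' mutually exclusive (a strong positive linear effect can accompany a
#' significant negative quadratic), and hump-shaped units typically have a
#' significant linear term too.
#'
#' @param draws_b17,draws_b18 Equal-length numeric vectors of posterior
#'   draws (at least 100 each).
#' @param level Probability threshold / CI level (default 0.95).
#' @return A one-row tibble: `bpr_type`, `p17_gt0`, `p18_gt0`, `ci17_lo`,
#'   `ci17_hi`, `ci18_lo`, `ci18_hi`.
#' @export
classify_posterior <- function(draws_b17, draws_b18, level = 0.95) {
  if (length(draws_b17) != length(draws_b18)) {
    abort("draws_b17 and draws_b18 must have the same length.")
  }
  if (length(draws_b17) < 100) {
    abort("Need at least 100 posterior draws to classify.")
  }
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ci17 <- unname(quantile(draws_b17, qs))
  ci18 <- unname(quantile(draws_b18, qs))
  p17 <- mean(draws_b17 > 0)
  p18 <- mean(draws_b18 > 0)
  ci18_overlaps_zero <- ci18[1] <= 0 && ci18[2] >= 0

  type <- if (1 - p18 > level) {
    "concave_negative"
  } else if (p18 > level) {
    "concave_positive"
  } else if (p17 > level && ci18_overlaps_zero) {
    "linear_positive"
  } else if (1 - p17 > level && ci18_overlaps_zero) {
    "linear_negative"
  } else {
    "non_significant"
  }

  tibble(
    bpr_type = type,
    p17_gt0 = p17, p18_gt0 = p18,
    ci17_lo = ci17[1], ci17_hi = ci17[2],
    ci18_lo = ci18[1], ci18_hi = ci18[2]
  )
}

#' Posterior BPR classification for every fitted unit
#'
#' @param unit_posteriors A `bpr_unit_posteriors` from [fit_all_units()].
#' @param level Probability threshold / CI level (default 0.95).
#' @return A tibble with one row per fitted unit: the [classify_posterior()]
#'   columns plus `unit` and `converged`.
#' @export
classify_units_posterior <- function(unit_posteriors, level = 0.95) {
  stopifnot(inherits(unit_posteriors, "bpr_unit_posteriors"))
  purrr::imap(unit_posteriors$posteriors, function(post, uid) {
    classify_posterior(posterior_draws(post, "b17"),
                       posterior_draws(post, "b18"), level = level) |>
      dplyr::mutate(unit = as.integer(uid), converged = post$converged)
  }) |>
    purrr::list_rbind() |>
    dplyr::relocate("unit") |>
    dplyr::arrange(.data$unit)
}

#' Coefficient map of one structural slope across climate space
#'
#' Joins the posterior summary of one coefficient (any of b1-b18) with the
#' unit climate summaries, giving the table behind the coefficient-map
#' figures: one point per fitted unit at its mean MAT and TAP, with the
#' posterior mean and a significance flag (95% credible interval excludes
#' zero).
#'
#' @param unit_posteriors A `bpr_unit_posteriors`.
#' @param unit_summaries Tibble from [summarize_units()].
#' @param coefficient Coefficient label, `"b1"` to `"b18"`.
#' @return Tibble: `unit`, `mat_mean`, `tap_mean`, `log_n`, `estimate`,
#'   `ci_lo`, `ci_hi`, `significant`.
#' @export
coefficient_map <- function(unit_posteriors, unit_summaries, coefficient) {
  stopifnot(inherits(unit_posteriors, "bpr_unit_posteriors"))
  valid <- beta_labels()
  if (!(length(coefficient) == 1 && coefficient %in% valid)) {
    abort(paste0("Unknown coefficient '", paste(coefficient, collapse = ","),
                 "'. Valid labels: ", paste(valid, collapse = ", "), "."))
  }
  rows <- purrr::imap(unit_posteriors$posteriors, function(post, uid) {
    s <- post$summary[post$summary$term == coefficient, ]
    tibble(unit = as.integer(uid), estimate = s$mean,
           ci_lo = s$ci_lo, ci_hi = s$ci_hi, significant = s$significant)
  }) |>
    purrr::list_rbind()
  dplyr::inner_join(
    dplyr::select(unit_summaries, "unit", "mat_mean", "tap_mean", "log_n"),
    rows, by = "unit"
  ) |>
    dplyr::arrange(.data$unit)
}
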