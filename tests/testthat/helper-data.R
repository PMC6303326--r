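# Small parameter bundles and fixtures built in code.

small_params <- function(scenario = "continental", n = 2000L, seed = 1L,
                         n_ecoregions = 8L, missing_rate = 0) {
  p <- default_params(scenario)
  p$n_plots <- as.integer(n)
  p$seed <- as.integer(seed)
  p$n_ecoregions <- as.integer(n_ecoregions)
  p$missing_rate <- missing_rate
  p
}

complete_plot_table <- function(params) {
  tbl <- suppressWarnings(simulate_plots(params))
  tbl <- derive_productivity(tbl)
  filter_complete(tbl, c(forestbpr:::bpr_required_columns(), "productivity"))
}

# hand-built bivariate fit object for classifier truth tables
fake_bivariate_fit <- function(selected, b, p) {
  coefs <- function(est, pv, labels) {
    tibble::tibble(term = labels, estimate = est, se = 1, z = est,
                   p = pv)
  }
  structure(list(
    n = 100L, n_dropped = 0L, estimable = TRUE, reason = NA_character_,
    linear = list(
      coefficients = coefs(c(0, if (selected == "linear") b else 0),
                           c(1, if (selected == "linear") p else 1),
                           c("intercept", "richness")),
      loglik = 0, aic = if (selected == "linear") 10 else 20
    ),
    quadratic = list(
      coefficients = coefs(
        c(0, 0.1, if (selected == "quadratic") b else 0),
        c(1, 0.5, if (selected == "quadratic") p else 1),
        c("intercept", "richness", "richness_sq")),
      loglik = 1, aic = if (selected == "quadratic") 10 else 20
    ),
    selected = selected
  ), class = "bpr_bivariate_fit")
}

# symmetric draws straddling zero (CI overlaps 0, P(>0) = 0.5)
null_draws <- function(n = 2000) {
  x <- seq(-1, 1, length.out = n)
  x - mean(x)
}
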