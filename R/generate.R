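#' Generate plot climates for a synthetic FIA-like table
#'
#' Draws plot locations in climate space from a correlated bivariate
#' distribution truncated to the configured MAT and TAP ranges — normal in
#' MAT, lognormal in TAP (annual precipitation is strongly right-skewed in
#' real inventories, and a symmetric cloud would leave the dry aridity
#' classes empty) — computes the aridity index, and assigns ecoregion
#' labels by k-means clustering of the climate cloud.
#' `climate_correlation` is the latent correlation between MAT and log TAP.
#' The smooth cloud keeps every decile of both axes populated at moderate
#' sample sizes and all four aridity classes occupied; it does not attempt
#' to reproduce the irregular empirical distribution of real plots.
#'
#' @param params A `bpr_generator_params` object, see [default_params()].
#' @return A tibble with columns `plot_id`, `ecoregion`, `mat`, `tap`,
#'   `aridity`. Reproducible given `params$seed`.
#' @export
generate_climate <- function(params) {
  validate_generator_params(params)
  n <- as.integer(params$n_plots)
  set.seed(params$seed)

  mat_mu <- mean(params$mat_range)
  mat_sd <- diff(params$mat_range) / 5
  ltap_mu <- mean(log(params$tap_range))
  ltap_sd <- diff(log(params$tap_range)) / 6
  rho <- params$climate_correlation

  mat <- numeric(0); tap <- numeric(0)
  while (length(mat) < n) {
    m <- max(2L * (n - length(mat)), 1000L)
    z1 <- rnorm(m); z2 <- rnorm(m)
    x <- mat_mu + mat_sd * z1
    y <- exp(ltap_mu + ltap_sd * (rho * z1 + sqrt(1 - rho^2) * z2))
    keep <- x >= params$mat_range[1] & x <= params$mat_range[2] &
            y >= params$tap_range[1] & y <= params$tap_range[2]
    mat <- c(mat, x[keep]); tap <- c(tap, y[keep])
  }
  mat <- mat[seq_len(n)]; tap <- tap[seq_len(n)]

  k <- min(params$n_ecoregions, n)
  if (k > 1) {
    cl <- kmeans(cbind(scale(mat), scale(tap)), centers = k,
                 nstart = 3, iter.max = 100, algorithm = "Lloyd")$cluster
  } else {
    cl <- rep(1L, n)
  }

  tibble(
    plot_id = sprintf("P%06d", seq_len(n)),
    ecoregion = sprintf("E%03d", cl),
    mat = mat,
    tap = tap,
    aridity = aridity_index(mat, tap)
  )
}

#' Simulate stand structure, richness and productivity for generated climates
#'
#' Completes a climate-only plot table into a full synthetic inventory table
#' by simulating the five sub-models of the structural graph in causal order:
#' log stem density, log stand age and log soil C:N as normal responses to
#' 2-SD-standardized climate; tree species richness as a Poisson count (log
#' link, floored at one species, since a forested plot has at least one tree
#' species); and log productivity as a normal response to all five upstream
#' predictors plus the planted linear and quadratic effects of standardized
#' richness from the regime map. Every sub-model receives its own i.i.d.
#' normal ecoregion random intercept. Above-ground biomass is back-computed
#' as productivity x stand age, and missing values are injected completely
#' at random over the measured covariate cells (`soil_cn`, `stem_density`,
#' `stand_age`).
#'
#' The generating-truth (planted coefficients, per-plot regime, ecoregion
#' effects, standardization constants) is attached as attribute `"truth"`,
#' retrievable with [generator_truth()].
#'
#' @param climate Tibble from [generate_climate()] (columns `plot_id`,
#'   `ecoregion`, `mat`, `tap` required).
#' @param params The same `bpr_generator_params` used for the climate.
#' @return A complete plot tibble with the standard column set (see
#'   [read_plot_table()]).
#' @export
generate_plots <- function(climate, params) {
  validate_generator_params(params)
  need <- c("plot_id", "ecoregion", "mat", "tap")
  missing_cols <- setdiff(need, names(climate))
  if (length(missing_cols) > 0) {
    abort(paste0("Climate table is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  n <- nrow(climate)
  set.seed(params$seed + 1L)

  b <- params$structural_betas
  a <- params$intercepts
  s <- params$noise_sds

  eco_levels <- sort(unique(climate$ecoregion))
  g <- match(climate$ecoregion, eco_levels)
  submodels <- c("density", "age", "soil_cn", "richness", "productivity")
  u <- matrix(rnorm(5 * length(eco_levels), 0, params$ecoregion_sd),
              nrow = 5, dimnames = list(submodels, eco_levels))

  zmat <- standardize_2sd(climate$mat)
  ztap <- standardize_2sd(climate$tap)

  log_den <- a["density"] + b["b1"] * zmat + b["b2"] * ztap +
    u["density", g] + rnorm(n, 0, s["density"])
  log_age <- a["age"] + b["b3"] * zmat + b["b4"] * ztap +
    u["age", g] + rnorm(n, 0, s["age"])
  log_cn <- a["soil_cn"] + b["b5"] * zmat + b["b6"] * ztap +
    u["soil_cn", g] + rnorm(n, 0, s["soil_cn"])

  zden <- standardize_2sd(log_den)
  zage <- standardize_2sd(log_age)
  zcn <- standardize_2sd(log_cn)

  log_lambda <- a["richness"] + b["b7"] * zmat + b["b8"] * ztap +
    b["b9"] * zden + b["b10"] * zage + b["b11"] * zcn + u["richness", g]
  richness <- pmax(1L, rpois(n, exp(log_lambda)))

  zric <- standardize_2sd(richness)
  regime <- regime_coefficients(params$bpr_regime_map, climate$mat, climate$tap)

  log_prod <- a["productivity"] + b["b12"] * zmat + b["b13"] * ztap +
    b["b14"] * zden + b["b15"] * zage + b["b16"] * zcn +
    regime$b17 * zric + regime$b18 * zric^2 +
    u["productivity", g] + rnorm(n, 0, s["productivity"])

  stand_age <- exp(log_age)
  productivity <- exp(log_prod)

  out <- tibble(
    plot_id = climate$plot_id,
    ecoregion = climate$ecoregion,
    mat = climate$mat,
    tap = climate$tap,
    aridity = if ("aridity" %in% names(climate)) climate$aridity else
      aridity_index(climate$mat, climate$tap),
    soil_cn = exp(log_cn),
    stem_density = exp(log_den),
    stand_age = stand_age,
    agb = productivity * stand_age,
    richness = as.integer(richness)
  )

  if (params$missing_rate > 0) {
    for (col in c("soil_cn", "stem_density", "stand_age")) {
      out[[col]][runif(n) < params$missing_rate] <- NA_real_
    }
  }

  attr(out, "truth") <- list(
    params = params,
    intercepts = a,
    betas = b,
    regime = tibble(plot_id = out$plot_id, b17 = regime$b17,
                    b18 = regime$b18, regime = regime$regime),
    ecoregion_effects = tibble(
      submodel = rep(submodels, times = length(eco_levels)),
      ecoregion = rep(eco_levels, each = 5),
      effect = as.vector(u)
    ),
    standardization = list(
      mat = attributes(zmat), tap = attributes(ztap),
      log_density = attributes(zden), log_age = attributes(zage),
      log_soil_cn = attributes(zcn), richness = attributes(zric)
    ),
    latent_productivity = productivity
  )
  out
}

#' Generate a complete synthetic plot table in one call
#'
#' @param params A `bpr_generator_params` object.
#' @return A complete plot tibble (see [generate_plots()]).
#' @export
simulate_plots <- function(params) {
  generate_plots(generate_climate(params), params)
}

#' Retrieve the generating truth attached to a synthetic plot table
#'
#' @param plots A tibble produced by [generate_plots()].
#' @return A list with the generator parameters, planted coefficients,
#'   per-plot regime, ecoregion effects and standardization constants.
#' @export
generator_truth <- function(plots) {
  truth <- attr(plots, "truth")
  if (is.null(truth)) abort("No generator truth attached to this table.")
  truth
}

#' Write generator truth as JSON
#'
#' Serializes the planted parameter values and the per-plot regime of a
#' synthetic table so recovery checks can run without the generating session.
#'
#' @param plots A tibble produced by [generate_plots()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(plots, path) {
  truth <- generator_truth(plots)
  p <- truth$params
  payload <- list(
    scenario = p$scenario,
    n_plots = p$n_plots,
    n_ecoregions = p$n_ecoregions,
    mat_range = p$mat_range,
    tap_range = p$tap_range,
    climate_correlation = p$climate_correlation,
    ecoregion_sd = p$ecoregion_sd,
    structural_betas = as.list(p$structural_betas),
    regime_map = unclass(p$bpr_regime_map),
    intercepts = as.list(truth$intercepts),
    noise_sds = as.list(p$noise_sds),
    missing_rate = p$missing_rate,
    seed = p$seed,
    plot_regime = truth$regime
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
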