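#' The structural graph of the hierarchical BPR model
#'
#' Defines the five sub-models and the 18 directed slope edges of the
#' hierarchical structural model: climate (MAT, TAP) drives log stem
#' density, log stand age and log soil C:N (b1-b6); climate and the three
#' stand/soil variables drive tree species richness through a Poisson
#' log-link sub-model (b7-b11); and the same five predictors plus the
#' linear and quadratic standardized-richness terms (b17, b18) drive log
#' productivity (b12-b18). Every sub-model carries an ecoregion random
#' intercept. The graph is acyclic in this causal order.
#'
#' @return A `bpr_model_graph` with tibbles `submodels` (response,
#'   distribution, link) and `edges` (beta label, from, to).
#' @export
bpr_model_graph <- function() {
  submodels <- tibble(
    submodel = c("density", "age", "soil_cn", "richness", "productivity"),
    response = c("log_stem_density", "log_stand_age", "log_soil_cn",
                 "richness", "log_productivity"),
    distribution = c("normal", "normal", "normal", "poisson", "normal"),
    link = c("identity", "identity", "identity", "log", "identity")
  )
  edges <- tibble(
    beta = paste0("b", 1:18),
    from = c("mat", "tap",
             "mat", "tap",
             "mat", "tap",
             "mat", "tap", "log_stem_density", "log_stand_age", "log_soil_cn",
             "mat", "tap", "log_stem_density", "log_stand_age", "log_soil_cn",
             "richness", "richness_sq"),
    to = c("density", "density",
           "age", "age",
           "soil_cn", "soil_cn",
           rep("richness", 5),
           rep("productivity", 7))
  )
  structure(list(submodels = submodels, edges = edges),
            class = "bpr_model_graph")
}

#' @export
print.bpr_model_graph <- function(x, ...) {
  cat("<bpr_model_graph>", nrow(x$submodels), "sub-models,",
      nrow(x$edges), "slope coefficients\n")
  for (m in x$submodels$submodel) {
    e <- x$edges[x$edges$to == m, ]
    cat("  ", m, " <- ", paste0(e$from, " (", e$beta, ")", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Priors for the hierarchical BPR model
#'
#' Intercepts and slope coefficients get diffuse normal priors with mean 0
#' and variance `slope_variance` (default 1000). The ecoregion
#' random-intercept SDs and the residual SDs of the normal sub-models get
#' weakly informative half-normal priors; their scales default to 1, which
#' is weakly informative on the standardized/log scale of the model.
#'
#' @param slope_variance Variance of the normal prior on intercepts and
#'   slopes.
#' @param ranef_sd_scale Half-normal scale for ecoregion-intercept SDs.
#' @param resid_sd_scale Half-normal scale for residual SDs.
#' @return A `bpr_priors` list.
#' @export
bpr_priors <- function(slope_variance = 1000, ranef_sd_scale = 1,
                       resid_sd_scale = 1) {
  stopifnot(slope_variance > 0, ranef_sd_scale > 0, resid_sd_scale > 0)
  structure(list(slope_variance = slope_variance,
                 ranef_sd_scale = ranef_sd_scale,
                 resid_sd_scale = resid_sd_scale),
            class = "bpr_priors")
}

#' MCMC settings for the hierarchical model
#'
#' Defaults follow the full analysis protocol: 3 parallel chains of
#' 100,000 iterations with a 5,000-iteration burn-in and no thinning. The
#' desk profile ([desk_profile()]) shrinks this to 3 chains of 2,000
#' iterations with a 500-iteration burn-in for interactive work and
#' simulation studies.
#'
#' @param chains Number of chains (>= 2, for convergence diagnostics).
#' @param iterations Total iterations per chain (burn-in included).
#' @param burn_in Burn-in iterations discarded per chain.
#' @param thin Thinning interval.
#' @param seed Integer seed controlling all chain RNGs.
#' @return An `mcmc_settings` list.
#' @export
mcmc_settings <- function(chains = 3, iterations = 100000, burn_in = 5000,
                          thin = 1, seed = 1) {
  if (chains < 2) abort("At least 2 chains are required for convergence diagnostics.")
  if (burn_in >= iterations) abort("burn_in must be smaller than iterations.")
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in),
                 thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "mcmc_settings")
}

#' @rdname mcmc_settings
#' @export
desk_profile <- function(seed = 1) {
  mcmc_settings(chains = 3, iterations = 2000, burn_in = 500, thin = 1,
                seed = seed)
}
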