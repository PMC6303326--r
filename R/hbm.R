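# Hierarchical Bayesian structural model: construction, log density, sampling.

predictor_symbol <- function(from) {
  switch(from,
    mat = "zmat", tap = "ztap",
    log_stem_density = "zden", log_stand_age = "zage", log_soil_cn = "zcn",
    richness = "zric", richness_sq = "zric2",
    abort(paste0("Unknown predictor node '", from, "'."))
  )
}

response_symbol <- function(submodel) {
  switch(submodel,
    density = "ldn", age = "lag", soil_cn = "lcn",
    richness = "rich", productivity = "lpr"
  )
}

# Linear-predictor JAGS expression for one sub-model, assembled from the
# graph edges so the code always mirrors the declared structure.
linear_predictor <- function(graph, submodel, m, hierarchical) {
  e <- graph$edges[graph$edges$to == submodel, ]
  idx <- as.integer(sub("^b", "", e$beta))
  terms <- paste0("b[", idx, "]*", vapply(e$from, predictor_symbol, ""), "[i]")
  # hierarchical centering: the ecoregion intercept u[m,g] ~ N(a[m], sigma_u)
  # replaces the fixed intercept in the linear predictor (much better mixing
  # than the non-centred a + u parameterization)
  icpt <- if (hierarchical) paste0("u[", m, ",eco[i]]") else paste0("a[", m, "]")
  paste0(icpt, " + ", paste(terms, collapse = " + "))
}

jags_model_code <- function(graph, priors, hierarchical) {
  sm <- graph$submodels$submodel
  normal_idx <- which(graph$submodels$distribution == "normal")
  lik <- character(0)
  s_counter <- 0
  for (m in seq_along(sm)) {
    lp <- linear_predictor(graph, sm[m], m, hierarchical)
    if (graph$submodels$distribution[m] == "normal") {
      s_counter <- s_counter + 1
      lik <- c(lik, paste0(
        "    ", response_symbol(sm[m]), "[i] ~ dnorm(", lp, ", prec[",
        s_counter, "])"))
    } else {
      lik <- c(lik, paste0(
        "    lambda[i] <- exp(", lp, ")",
        "\n    ", response_symbol(sm[m]), "[i] ~ dpois(lambda[i])"))
    }
  }
  prec_slope <- 1 / priors$slope_variance
  ranef <- if (hierarchical) paste0(
    "  for (m in 1:5) {\n",
    "    sigma_u[m] ~ dnorm(0, ", 1 / priors$ranef_sd_scale^2, ") T(0,)\n",
    "    prec_u[m] <- pow(sigma_u[m], -2)\n",
    "    for (g in 1:G) { u[m,g] ~ dnorm(a[m], prec_u[m]) }\n",
    "  }\n") else ""
  paste0(
    "model {\n",
    "  for (i in 1:N) {\n",
    paste(lik, collapse = "\n"), "\n",
    "  }\n",
    "  for (m in 1:5) { a[m] ~ dnorm(0, ", prec_slope, ") }\n",
    "  for (j in 1:", nrow(graph$edges), ") { b[j] ~ dnorm(0, ",
    prec_slope, ") }\n",
    "  for (s in 1:", length(normal_idx), ") {\n",
    "    sigma[s] ~ dnorm(0, ", 1 / priors$resid_sd_scale^2, ") T(0,)\n",
    "    prec[s] <- pow(sigma[s], -2)\n",
    "  }\n",
    ranef,
    "}\n"
  )
}

#' Build the hierarchical BPR model for one climatic unit
#'
#' Prepares the data and JAGS program of the five-sub-model structural
#' model for the plots of one climatic unit (or any plot subset). Stem
#' density, stand age, soil C:N and productivity are log-transformed;
#' every predictor role (including richness, which is standardized first
#' and then squared for the quadratic term) is standardized by two sample
#' SDs. Ecoregion random intercepts are hierarchical normal per sub-model;
#' with a single ecoregion in the subset, the random intercept would be
#' confounded with the fixed intercept, so it degenerates to the fixed
#' intercept alone (with a warning).
#'
#' @param unit_table Complete-case plot tibble with a positive
#'   `productivity` column.
#' @param graph Model structure from [bpr_model_graph()].
#' @param priors Priors from [bpr_priors()].
#' @param min_n Minimum plots needed to build (default 30).
#' @return A `bpr_model`: JAGS `code`, `data` list, ecoregion levels,
#'   `hierarchical` flag, the graph and priors, and the standardization
#'   constants.
#' @export
build_model <- function(unit_table, graph = bpr_model_graph(),
                        priors = bpr_priors(), min_n = 30) {
  stopifnot(inherits(graph, "bpr_model_graph"), inherits(priors, "bpr_priors"))
  need <- c("ecoregion", "mat", "tap", "soil_cn", "stem_density",
            "stand_age", "richness", "productivity")
  absent <- setdiff(need, names(unit_table))
  if (length(absent) > 0) {
    abort(paste0("Unit table is missing column(s): ",
                 paste(absent, collapse = ", "), "."))
  }
  keep <- complete.cases(unit_table[, need]) & unit_table$productivity > 0 &
    unit_table$stand_age > 0 & unit_table$stem_density > 0 &
    unit_table$soil_cn > 0
  dat <- unit_table[keep, , drop = FALSE]
  if (nrow(dat) < min_n) {
    abort(paste0("Only ", nrow(dat), " usable plots (< ", min_n,
                 ") in this unit."),
          class = "forestbpr_too_few_plots")
  }

  eco_levels <- sort(unique(dat$ecoregion))
  hierarchical <- length(eco_levels) > 1
  if (!hierarchical) {
    warn("Single ecoregion in unit; random intercept degenerates to the fixed intercept.")
  }

  zmat <- standardize_2sd(dat$mat)
  ztap <- standardize_2sd(dat$tap)
  zden <- standardize_2sd(log(dat$stem_density))
  zage <- standardize_2sd(log(dat$stand_age))
  zcn <- standardize_2sd(log(dat$soil_cn))
  zric <- standardize_2sd(dat$richness)

  jdata <- list(
    N = nrow(dat),
    ldn = log(dat$stem_density),
    lag = log(dat$stand_age),
    lcn = log(dat$soil_cn),
    rich = as.integer(dat$richness),
    lpr = log(dat$productivity),
    zmat = as.numeric(zmat), ztap = as.numeric(ztap),
    zden = as.numeric(zden), zage = as.numeric(zage),
    zcn = as.numeric(zcn), zric = as.numeric(zric),
    zric2 = as.numeric(zric)^2
  )
  if (hierarchical) {
    jdata$eco <- match(dat$ecoregion, eco_levels)
    jdata$G <- length(eco_levels)
  }

  structure(list(
    code = jags_model_code(graph, priors, hierarchical),
    data = jdata,
    graph = graph,
    priors = priors,
    hierarchical = hierarchical,
    eco_levels = eco_levels,
    n = nrow(dat),
    standardization = list(
      mat = attributes(zmat), tap = attributes(ztap),
      log_stem_density = attributes(zden), log_stand_age = attributes(zage),
      log_soil_cn = attributes(zcn), richness = attributes(zric)
    )
  ), class = "bpr_model")
}

#' @export
print.bpr_model <- function(x, ...) {
  cat("<bpr_model>", x$n, "plots,", length(x$eco_levels), "ecoregion(s),",
      nrow(x$graph$edges), "slope coefficients,",
      nrow(x$graph$submodels), "sub-models\n")
  invisible(x)
}

half_normal_logpdf <- function(x, scale) {
  if (any(x < 0)) return(-Inf)
  sum(log(2) + dnorm(x, 0, scale, log = TRUE))
}

#' Joint log density of the hierarchical model at a parameter point
#'
#' Evaluates the unnormalized joint log posterior density: the sum of the
#' five sub-model log likelihoods, the normal priors on intercepts and
#' slopes, the half-normal priors on SDs, and the random-effect terms.
#'
#' @param model A `bpr_model`.
#' @param pars List with `a` (5 population intercepts), `b` (18 slopes),
#'   `sigma` (4 residual SDs for the normal sub-models), and, for
#'   hierarchical models, `sigma_u` (5 random-intercept SDs) and `u`
#'   (5 x G matrix of ecoregion intercepts, centred on `a`: each
#'   `u[m, g] ~ N(a[m], sigma_u[m])` and the sub-model mean uses
#'   `u[m, g]` in place of the fixed intercept).
#' @return A single numeric log density.
#' @export
model_log_density <- function(model, pars) {
  stopifnot(inherits(model, "bpr_model"))
  d <- model$data
  a <- pars$a; b <- pars$b; sigma <- pars$sigma
  stopifnot(length(a) == 5, length(b) == 18, length(sigma) == 4)
  if (model$hierarchical) {
    u <- pars$u
    stopifnot(is.matrix(u), nrow(u) == 5, ncol(u) == d$G,
              length(pars$sigma_u) == 5)
    icpt <- function(m) u[m, d$eco]
  } else {
    icpt <- function(m) a[m]
  }
  if (any(sigma <= 0)) return(-Inf)

  eta <- function(m, terms) icpt(m) + Reduce(`+`, terms)
  lp <- 0
  lp <- lp + sum(dnorm(d$ldn, eta(1, list(b[1] * d$zmat, b[2] * d$ztap)),
                       sigma[1], log = TRUE))
  lp <- lp + sum(dnorm(d$lag, eta(2, list(b[3] * d$zmat, b[4] * d$ztap)),
                       sigma[2], log = TRUE))
  lp <- lp + sum(dnorm(d$lcn, eta(3, list(b[5] * d$zmat, b[6] * d$ztap)),
                       sigma[3], log = TRUE))
  lp <- lp + sum(dpois(d$rich, exp(eta(4, list(
    b[7] * d$zmat, b[8] * d$ztap, b[9] * d$zden, b[10] * d$zage,
    b[11] * d$zcn))), log = TRUE))
  lp <- lp + sum(dnorm(d$lpr, eta(5, list(
    b[12] * d$zmat, b[13] * d$ztap, b[14] * d$zden, b[15] * d$zage,
    b[16] * d$zcn, b[17] * d$zric, b[18] * d$zric2)),
    sigma[4], log = TRUE))

  pv <- sqrt(model$priors$slope_variance)
  lp <- lp + sum(dnorm(a, 0, pv, log = TRUE)) +
    sum(dnorm(b, 0, pv, log = TRUE)) +
    half_normal_logpdf(sigma, model$priors$resid_sd_scale)
  if (model$hierarchical) {
    if (any(pars$sigma_u <= 0)) return(-Inf)
    lp <- lp + half_normal_logpdf(pars$sigma_u, model$priors$ranef_sd_scale)
    for (m in 1:5) {
      lp <- lp + sum(dnorm(pars$u[m, ], a[m], pars$sigma_u[m], log = TRUE))
    }
  }
  lp
}

submodel_names <- function() {
  c("density", "age", "soil_cn", "richness", "productivity")
}

# human-readable labels for monitored JAGS nodes
relabel_terms <- function(terms) {
  sm <- submodel_names()
  normal_sm <- sm[-4]
  out <- terms
  out <- sub("^b\\[(\\d+)\\]$", "b\\1", out)
  for (i in 1:5) {
    out[out == paste0("a[", i, "]")] <- paste0("intercept_", sm[i])
    out[out == paste0("sigma_u[", i, "]")] <- paste0("sigma_u_", sm[i])
  }
  for (i in 1:4) {
    out[out == paste0("sigma[", i, "]")] <- paste0("sigma_", normal_sm[i])
  }
  out
}

split_rhat <- function(chains) {
  # chains: list of numeric vectors (one per chain); split-halves R-hat
  halves <- unlist(lapply(chains, function(x) {
    h <- floor(length(x) / 2)
    list(x[seq_len(h)], x[seq(h + 1, 2 * h)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Shared seeded-chain harness: compile, adapt, burn, sample, summarize.
# Used by sample_posterior() and the conjugate sampler check so the chain
# seeding, pooling and summary path are identical.
run_jags <- function(code, data, inits_base, monitors, settings, level) {
  rjags::load.module("glm", quiet = TRUE)
  inits <- vector("list", settings$chains)
  base_seed <- (abs(settings$seed) %% 21000000L) * 100L
  for (ch in seq_len(settings$chains)) {
    ini <- inits_base
    ini$.RNG.name <- "base::Mersenne-Twister"
    ini$.RNG.seed <- base_seed + ch
    inits[[ch]] <- ini
  }
  adapt <- min(200L, settings$burn_in)
  jm <- rjags::jags.model(textConnection(code), data = data,
                          inits = inits, n.chains = settings$chains,
                          n.adapt = adapt, quiet = TRUE)
  if (settings$burn_in > 0) {
    stats::update(jm, n.iter = settings$burn_in, progress.bar = "none")
  }
  samp <- rjags::coda.samples(
    jm, variable.names = monitors,
    n.iter = settings$iterations - settings$burn_in,
    thin = settings$thin, progress.bar = "none"
  )

  terms_raw <- colnames(samp[[1]])
  ess <- coda::effectiveSize(samp)
  pooled <- do.call(rbind, lapply(samp, as.matrix))
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  summary_tbl <- purrr::imap(terms_raw, function(raw, i) {
    per_chain <- lapply(samp, function(ch) as.numeric(ch[, raw]))
    x <- pooled[, i]
    ci <- unname(quantile(x, qs))
    ess_i <- unname(ess[raw])
    tibble(
      term = raw,
      mean = mean(x), ci_lo = ci[1], ci_hi = ci[2],
      p_gt0 = mean(x > 0),
      rhat = split_rhat(per_chain),
      ess = ess_i
    )
  }) |>
    purrr::list_rbind() |>
    dplyr::mutate(significant = .data$ci_lo > 0 | .data$ci_hi < 0)
  list(summary = summary_tbl, pooled = pooled)
}

#' Sample the posterior mean of a normal with known error SD
#'
#' A one-parameter conjugate model (`y ~ N(mu, sigma)` with `sigma` known
#' and `mu ~ N(prior_mean, prior_var)`) run through the package's seeded
#' MCMC harness. The exact posterior is available in closed form, so this
#' is the standard validation that the chain seeding, burn-in handling and
#' summary pipeline reproduce a known answer; tests compare the sampled
#' posterior mean and SD with the analytic values.
#'
#' @param y Numeric data vector.
#' @param sigma Known error SD.
#' @param prior_mean,prior_var Normal prior on the mean.
#' @param settings An [mcmc_settings()].
#' @param level Credible level.
#' @return A one-row summary tibble (same columns as
#'   [sample_posterior()]'s summary), with the pooled draws as attribute
#'   `"draws"`.
#' @export
sample_conjugate_mean <- function(y, sigma, prior_mean = 0, prior_var = 1000,
                                  settings = desk_profile(), level = 0.95) {
  stopifnot(inherits(settings, "mcmc_settings"), sigma > 0, prior_var > 0)
  code <- paste0(
    "model {\n",
    "  for (i in 1:N) { y[i] ~ dnorm(mu, prec) }\n",
    "  mu ~ dnorm(", prior_mean, ", ", 1 / prior_var, ")\n",
    "}\n"
  )
  res <- run_jags(code, list(N = length(y), y = y, prec = 1 / sigma^2),
                  list(mu = 0), "mu", settings, level)
  out <- res$summary
  attr(out, "draws") <- as.numeric(res$pooled[, 1])
  out
}

#' Sample the posterior of a hierarchical BPR model
#'
#' Runs JAGS with the requested number of parallel chains, discards the
#' burn-in, pools the post-burn-in draws, and summarizes every monitored
#' parameter (posterior mean, equal-tailed credible interval, posterior
#' probability of being positive, split potential-scale-reduction and
#' effective sample size). A run is flagged non-converged when any
#' monitored parameter has split-Rhat above 1.05 or effective sample size
#' below 100. Fully reproducible given `settings$seed` (each chain gets a
#' seeded Mersenne-Twister RNG).
#'
#' @param model A `bpr_model` from [build_model()].
#' @param settings An [mcmc_settings()] object.
#' @param level Credible-interval level (default 0.95, equal-tailed).
#' @return A `bpr_posterior`: `summary` tibble (term, mean, ci_lo, ci_hi,
#'   p_gt0, rhat, ess, significant), pooled `draws` matrix, `converged`
#'   flag, `n`, and the settings used.
#' @export
sample_posterior <- function(model, settings = desk_profile(), level = 0.95) {
  stopifnot(inherits(model, "bpr_model"), inherits(settings, "mcmc_settings"))
  monitors <- c("a", "b", "sigma")
  inits_base <- list(
    a = rep(0, 5), b = rep(0, nrow(model$graph$edges)), sigma = rep(1, 4)
  )
  if (model$hierarchical) {
    monitors <- c(monitors, "sigma_u")
    inits_base$sigma_u <- rep(0.5, 5)
    inits_base$u <- matrix(0, 5, model$data$G)
  }

  res <- run_jags(model$code, model$data, inits_base, monitors, settings,
                  level)
  summary_tbl <- dplyr::mutate(res$summary, term = relabel_terms(.data$term))
  pooled <- res$pooled
  colnames(pooled) <- summary_tbl$term

  structure(list(
    summary = summary_tbl,
    draws = pooled,
    converged = all(summary_tbl$rhat <= 1.05) && all(summary_tbl$ess >= 100),
    n = model$n,
    hierarchical = model$hierarchical,
    level = level,
    settings = settings
  ), class = "bpr_posterior")
}

#' @export
print.bpr_posterior <- function(x, ...) {
  cat("<bpr_posterior>", nrow(x$draws), "pooled draws over",
      nrow(x$summary), "parameters;",
      if (x$converged) "converged" else "NOT converged", "\n")
  print(x$summary, n = 10)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.bpr_posterior <- function(x, ...) x$summary

#' @exportS3Method generics::glance
glance.bpr_posterior <- function(x, ...) {
  tibble(
    n = x$n, draws = nrow(x$draws), converged = x$converged,
    max_rhat = max(x$summary$rhat), min_ess = min(x$summary$ess),
    level = x$level
  )
}

#' Extract pooled posterior draws for one term
#'
#' @param posterior A `bpr_posterior`.
#' @param term Term label (e.g. `"b17"`).
#' @return Numeric vector of pooled post-burn-in draws.
#' @export
posterior_draws <- function(posterior, term) {
  stopifnot(inherits(posterior, "bpr_posterior"))
  if (!term %in% colnames(posterior$draws)) {
    abort(paste0("Unknown term '", term, "'. Available: ",
                 paste(colnames(posterior$draws), collapse = ", "), "."))
  }
  as.numeric(posterior$draws[, term])
}

#' Fit the hierarchical model in every climatic unit
#'
#' Independently fits and samples the structural model for each populated
#' climatic unit. Units below the plot minimum are skipped (with a reason),
#' failures are isolated per unit, and each unit's chains are seeded as
#' `settings$seed + unit`, so the whole collection is reproducible.
#'
#' @param table Complete-case plot tibble with `productivity`.
#' @param grid A `climate_grid` with assignment populated.
#' @param graph,priors Model structure and priors.
#' @param settings MCMC settings (defaults to the desk profile).
#' @param min_n Minimum usable plots per unit (default 30).
#' @param level Credible-interval level.
#' @return A `bpr_unit_posteriors`: named list `posteriors` (one
#'   `bpr_posterior` per fitted unit) and a `report` tibble (unit, n plots,
#'   status, converged).
#' @export
fit_all_units <- function(table, grid, graph = bpr_model_graph(),
                          priors = bpr_priors(), settings = desk_profile(),
                          min_n = 30, level = 0.95) {
  stopifnot(inherits(grid, "climate_grid"))
  if (is.null(grid$assignment)) abort("Grid assignment not populated; call assign_units().")
  joined <- dplyr::inner_join(table, grid$assignment, by = "plot_id")
  units <- sort(unique(joined$unit))

  posteriors <- list()
  report <- purrr::map(units, function(uid) {
    sub <- joined[joined$unit == uid, , drop = FALSE]
    res <- tryCatch({
      m <- withCallingHandlers(
        build_model(sub, graph = graph, priors = priors, min_n = min_n),
        warning = function(w) invokeRestart("muffleWarning")
      )
      st <- settings
      st$seed <- settings$seed + as.integer(uid)
      post <- sample_posterior(m, settings = st, level = level)
      posteriors[[as.character(uid)]] <<- post
      tibble(unit = uid, n = nrow(sub), status = "fitted",
             converged = post$converged)
    },
    forestbpr_too_few_plots = function(e) {
      tibble(unit = uid, n = nrow(sub), status = "skipped: too few plots",
             converged = NA)
    },
    error = function(e) {
      tibble(unit = uid, n = nrow(sub),
             status = paste0("failed: ", conditionMessage(e)), converged = NA)
    })
    res
  }) |>
    purrr::list_rbind()

  structure(list(posteriors = posteriors, report = report),
            class = "bpr_unit_posteriors")
}

#' @export
print.bpr_unit_posteriors <- function(x, ...) {
  cat("<bpr_unit_posteriors>", length(x$posteriors), "fitted unit(s);",
      sum(x$report$status != "fitted"), "skipped/failed\n")
  invisible(x)
}
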