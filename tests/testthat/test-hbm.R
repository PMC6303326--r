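test_that("two-SD standardization has the stated scale and fixed point", {
  z <- standardize_2sd(c(0, 2))
  expect_equal(attr(z, "center"), 1)
  expect_equal(attr(z, "scale"), sqrt(2))
  expect_equal(as.numeric(z), c(-0.35355339, 0.35355339), tolerance = 1e-7)

  set.seed(1)
  x <- rnorm(500, 10, 3)
  z <- standardize_2sd(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(sd(z) - 0.5), 1e-12)

  # a vector already on the (mean 0, sd 0.5) scale is a fixed point
  expect_equal(as.numeric(standardize_2sd(as.numeric(z))), as.numeric(z),
               tolerance = 1e-12)

  expect_error(standardize_2sd(rep(3, 10)), "constant")
})

test_that("the structural graph has five sub-models and 18 acyclic edges", {
  g <- bpr_model_graph()
  expect_equal(nrow(g$submodels), 5)
  expect_equal(nrow(g$edges), 18)
  expect_equal(g$edges$beta, paste0("b", 1:18))
  expect_equal(sum(g$submodels$distribution == "poisson"), 1)

  # acyclicity in the causal order: a response never feeds an earlier one
  order <- c("mat", "tap", "log_stem_density", "log_stand_age",
             "log_soil_cn", "richness", "richness_sq", "log_productivity")
  resp <- g$submodels$response[match(g$edges$to, g$submodels$submodel)]
  expect_true(all(match(g$edges$from, order) < match(resp, order)))
})

test_that("built models carry the declared structure and standardized data", {
  p <- small_params("continental", n = 300L, seed = 17L, n_ecoregions = 4L)
  plots <- complete_plot_table(p)
  m <- build_model(plots)
  expect_equal(nrow(m$graph$edges), 18)
  expect_equal(nrow(m$graph$submodels), 5)
  expect_true(m$hierarchical)
  expect_lt(abs(sd(m$data$zric) - 0.5), 1e-10)
  expect_equal(m$data$zric2, m$data$zric^2)  # standardized first, then squared
  expect_match(m$code, "dpois")

  expect_error(build_model(plots, min_n = 1000),
               class = "forestbpr_too_few_plots")
  expect_error(build_model(dplyr::select(plots, -"soil_cn")), "soil_cn")

  single <- dplyr::mutate(plots, ecoregion = "E001")
  expect_warning(m1 <- build_model(single), "Single ecoregion")
  expect_false(m1$hierarchical)
})

test_that("the joint log density matches a term-by-term oracle", {
  p <- small_params("continental", n = 60L, seed = 19L, n_ecoregions = 3L)
  plots <- complete_plot_table(p)
  m <- build_model(plots, min_n = 30)
  for (s in 1:5) {
    pars <- random_hbm_pars(m, seed = s)
    expect_equal(model_log_density(m, pars), hbm_logdensity_oracle(m, pars),
                 tolerance = 1e-8)
  }
  expect_equal(model_log_density(m, modifyList(random_hbm_pars(m, 1),
                                               list(sigma = c(-1, 1, 1, 1)))),
               -Inf)

  single <- dplyr::mutate(plots, ecoregion = "E001")
  m1 <- suppressWarnings(build_model(single, min_n = 30))
  pars <- random_hbm_pars(m1, seed = 6)
  expect_equal(model_log_density(m1, pars), hbm_logdensity_oracle(m1, pars),
               tolerance = 1e-8)
})

test_that("MCMC settings enforce their invariants", {
  expect_error(mcmc_settings(chains = 1), "2 chains")
  expect_error(mcmc_settings(iterations = 100, burn_in = 100), "burn_in")
  d <- desk_profile(seed = 9)
  expect_equal(d$chains, 3L)
  expect_equal(d$iterations, 2000L)
  expect_equal(d$burn_in, 500L)
  expect_equal(d$seed, 9L)
})

test_that("the seeded sampler reproduces a conjugate posterior and itself", {
  set.seed(4)
  y <- rnorm(40, 2, 1)
  res <- sample_conjugate_mean(y, sigma = 1,
                               settings = mcmc_settings(chains = 2,
                                                        iterations = 3000,
                                                        burn_in = 500,
                                                        seed = 11))
  exact <- conjugate_normal_mean(y, 1)
  draws <- attr(res, "draws")
  mc_se <- exact$sd / sqrt(res$ess)
  expect_lt(abs(res$mean - exact$mean), 4 * mc_se)
  expect_lt(abs(sd(draws) / exact$sd - 1), 0.1)

  res2 <- sample_conjugate_mean(y, sigma = 1,
                                settings = mcmc_settings(chains = 2,
                                                         iterations = 3000,
                                                         burn_in = 500,
                                                         seed = 11))
  expect_identical(res$mean, res2$mean)
  expect_identical(attr(res, "draws"), attr(res2, "draws"))
})

test_that("posterior sampling is seed-deterministic with full summaries", {
  p <- small_params("dry_positive", n = 150L, seed = 23L, n_ecoregions = 3L)
  plots <- complete_plot_table(p)
  m <- build_model(plots, min_n = 50)
  st <- mcmc_settings(chains = 2, iterations = 600, burn_in = 200, seed = 5)
  post <- sample_posterior(m, st)
  expect_equal(sum(grepl("^b\\d+$", post$summary$term)), 18)
  expect_equal(sum(grepl("^intercept_", post$summary$term)), 5)
  expect_true(all(post$summary$ci_lo < post$summary$ci_hi))
  expect_true(all(post$summary$p_gt0 >= 0 & post$summary$p_gt0 <= 1))

  post2 <- sample_posterior(build_model(plots, min_n = 50), st)
  expect_identical(post$summary, post2$summary)

  expect_error(posterior_draws(post, "b99"), "Unknown term")
  expect_length(posterior_draws(post, "b17"), 2 * 400)
})

test_that("per-unit fitting isolates failures and reconciles counts", {
  p <- small_params("continental", n = 700L, seed = 29L, n_ecoregions = 6L)
  plots <- complete_plot_table(p)
  grid <- assign_units(plots, build_climate_grid(plots, k = 2))
  st <- mcmc_settings(chains = 2, iterations = 500, burn_in = 200, seed = 3)
  res <- fit_all_units(plots, grid, settings = st, min_n = 120)
  n_units <- dplyr::n_distinct(grid$assignment$unit)
  expect_equal(nrow(res$report), n_units)
  expect_equal(length(res$posteriors) +
                 sum(res$report$status != "fitted"), n_units)
  expect_true(all(res$report$status[res$report$n < 120] != "fitted"))
})
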