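test_that("an exact linear relationship is recovered exactly", {
  fit <- fit_bivariate(1:4, as.numeric(1:4))
  expect_true(fit$estimable)
  co <- fit$linear$coefficients
  expect_equal(co$estimate[co$term == "intercept"], 0, tolerance = 1e-8)
  expect_equal(co$estimate[co$term == "richness"], 1, tolerance = 1e-8)
})

test_that("the generating slope is recovered within sampling error", {
  set.seed(42)
  s <- rpois(500, 8)
  y <- 2 + 0.5 * s + rnorm(500, 0, 0.5)
  fit <- fit_bivariate(s, y)
  co <- fit$linear$coefficients
  slope <- co$estimate[co$term == "richness"]
  se <- co$se[co$term == "richness"]
  expect_lt(abs(slope - 0.5), 3 * se)
})

test_that("both models match the normal-equations + analytic-likelihood oracle", {
  set.seed(99)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    s <- rpois(n, 6) + 1
    y <- rnorm(n, 1 + 0.1 * s - 0.01 * s^2, 0.5)
    fit <- fit_bivariate(s, y)

    lin <- ols_oracle(cbind(1, s), y)
    qua <- ols_oracle(cbind(1, s, s^2), y)
    expect_equal(fit$linear$coefficients$estimate, unname(lin$beta),
                 tolerance = 1e-8)
    expect_equal(fit$linear$coefficients$se, unname(lin$se), tolerance = 1e-8)
    expect_equal(fit$linear$coefficients$p, unname(lin$p), tolerance = 1e-8)
    expect_equal(fit$linear$loglik, lin$loglik, tolerance = 1e-8)
    expect_equal(fit$linear$aic, lin$aic, tolerance = 1e-8)
    expect_equal(fit$quadratic$coefficients$estimate, unname(qua$beta),
                 tolerance = 1e-8)
    expect_equal(fit$quadratic$aic, qua$aic, tolerance = 1e-8)

    # nesting: the quadratic model can never fit worse
    expect_gte(fit$quadratic$loglik, fit$linear$loglik - 1e-10)
  }
})

test_that("shifting log productivity by a constant never changes the label", {
  set.seed(5)
  for (i in 1:10) {
    s <- rpois(80, 7) + 1
    y <- rnorm(80, 0.5 + 0.05 * s - 0.004 * s^2, 0.3)
    f1 <- fit_bivariate(s, y)
    f2 <- fit_bivariate(s, y + 5)
    expect_equal(classify_bivariate(f1), classify_bivariate(f2))
    expect_equal(f1$linear$coefficients$estimate[2],
                 f2$linear$coefficients$estimate[2], tolerance = 1e-10)
  }
})

test_that("classification reproduces the decision rules exhaustively", {
  cases <- list(
    list(fit = fake_bivariate_fit("linear", b = 0.4, p = 0.001),
         expected = "linear_positive"),
    list(fit = fake_bivariate_fit("linear", b = -0.4, p = 0.001),
         expected = "linear_negative"),
    list(fit = fake_bivariate_fit("linear", b = 0.4, p = 0.2),
         expected = "non_significant"),
    list(fit = fake_bivariate_fit("linear", b = -0.4, p = 0.2),
         expected = "non_significant"),
    list(fit = fake_bivariate_fit("quadratic", b = -0.02, p = 0.0003),
         expected = "concave_negative"),
    list(fit = fake_bivariate_fit("quadratic", b = 0.02, p = 0.0003),
         expected = "concave_positive"),
    list(fit = fake_bivariate_fit("quadratic", b = -0.02, p = 0.3),
         expected = "non_significant"),
    list(fit = fake_bivariate_fit("quadratic", b = 0.02, p = 0.3),
         expected = "non_significant"),
    list(fit = fake_bivariate_fit("linear", b = 0, p = 1),
         expected = "non_significant")
  )
  for (case in cases) {
    expect_equal(classify_bivariate(case$fit), case$expected)
  }
  # labels form a total function onto the 5-level enum
  labels <- vapply(cases, function(cs) classify_bivariate(cs$fit), "")
  expect_true(all(labels %in% c("linear_positive", "linear_negative",
                                "concave_negative", "concave_positive",
                                "non_significant")))
})

test_that("degenerate inputs are marked non-estimable, not errors", {
  too_few <- fit_bivariate(1:3, c(1, 2, 3))
  expect_false(too_few$estimable)
  expect_match(too_few$reason, "few")
  expect_equal(classify_bivariate(too_few), "non_significant")

  const <- fit_bivariate(rep(5L, 10), rnorm(10))
  expect_false(const$estimable)
  expect_match(const$reason, "variance")

  # zero-productivity plots are dropped and counted
  fit <- fit_bivariate(c(1:9, 10), c(rnorm(9), -Inf))
  expect_equal(fit$n_dropped, 1)
  expect_equal(fit$n, 9)
})

test_that("per-unit classification covers every populated unit", {
  p <- small_params("continental", n = 1500L, seed = 13L)
  plots <- complete_plot_table(p)
  grid <- assign_units(plots, build_climate_grid(plots, k = 4))
  res <- bivariate_by_unit(plots, grid)
  expect_equal(nrow(res), dplyr::n_distinct(grid$assignment$unit))
  expect_true(all(!is.na(res$bpr_type)))
  expect_true(all(res$estimable))
  expect_equal(res$selected[res$aic_quadratic < res$aic_linear],
               rep("quadratic", sum(res$aic_quadratic < res$aic_linear)))

  expect_error(bivariate_by_unit(dplyr::select(plots, -"productivity"), grid),
               "productivity")
})
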