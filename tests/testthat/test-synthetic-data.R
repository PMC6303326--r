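test_that("scenario presets encode the planted BPR regimes", {
  null <- default_params("null")
  expect_equal(unname(null$structural_betas["b17"]), 0)
  expect_equal(unname(null$structural_betas["b18"]), 0)
  expect_equal(null$bpr_regime_map$dry, c(0, 0))
  # the null instrument severs the indirect pathways too
  expect_equal(unname(null$structural_betas[paste0("b", 7:11)]), rep(0, 5))
  expect_equal(null$ecoregion_sd, 0)

  cont <- default_params("continental")
  expect_equal(cont$mat_range, c(-3.8, 23.9))
  expect_equal(cont$tap_range, c(79, 3375))
  expect_equal(cont$bpr_regime_map$kind, "blend")
  expect_gt(cont$bpr_regime_map$dry[1], 0)
  expect_equal(cont$bpr_regime_map$dry[2], 0)
  expect_lt(cont$bpr_regime_map$wet[2], 0)

  expect_gt(default_params("dry_positive")$bpr_regime_map$dry[1], 0)
  expect_lt(default_params("mesic_hump")$bpr_regime_map$dry[2], 0)

  expect_error(default_params("tropical"), "Valid scenarios")
})

test_that("generated climates respect ranges, correlation and determinism", {
  p <- small_params("continental", n = 10000L, seed = 1L)
  p$climate_correlation <- 0
  clim <- generate_climate(p)

  expect_equal(nrow(clim), 10000L)
  expect_true(all(clim$mat >= -3.8 & clim$mat <= 23.9))
  expect_true(all(clim$tap >= 79 & clim$tap <= 3375))
  expect_lt(abs(cor(clim$mat, clim$tap)), 0.05)
  expect_equal(dplyr::n_distinct(clim$ecoregion), 8L)

  clim2 <- generate_climate(p)
  expect_identical(clim, clim2)

  p_bad <- p
  p_bad$n_plots <- 0L
  expect_error(generate_climate(p_bad), "positive")
})

test_that("generate_plots follows the causal structure and its contracts", {
  p <- small_params("continental", n = 3000L, seed = 3L, missing_rate = 0.02)
  clim <- generate_climate(p)
  expect_error(generate_plots(dplyr::select(clim, -"mat"), p), "mat")

  plots <- generate_plots(clim, p)
  expect_identical(plots, generate_plots(clim, p))
  expect_true(all(plots$richness >= 1))
  expect_true(all(plots$stand_age > 0, na.rm = TRUE))
  expect_true(all(plots$agb > 0, na.rm = TRUE))

  # biomass / stand age reproduces the simulated productivity exactly
  truth <- generator_truth(plots)
  ok <- !is.na(plots$stand_age)
  expect_equal(plots$agb[ok] / plots$stand_age[ok],
               truth$latent_productivity[ok], tolerance = 1e-12)
})

test_that("null generator yields constant-mean Poisson richness", {
  p <- small_params("null", n = 10000L, seed = 5L, n_ecoregions = 4L)
  p$structural_betas[] <- 0
  p$ecoregion_sd <- 0
  p$noise_sds[] <- 1e-12
  p$bpr_regime_map <- bpr_regime_map("constant", dry = c(0, 0))
  plots <- generate_plots(generate_climate(p), p)
  lambda <- exp(unname(p$intercepts["richness"]))
  se <- sqrt(lambda / nrow(plots))
  # floor at 1 species is negligible at this mean
  expect_lt(abs(mean(plots$richness) - lambda), 3 * se)
  expect_lt(abs(stats::var(plots$richness) / lambda - 1), 0.1)
})

test_that("missingness is injected completely at random at the stated rate", {
  p <- small_params("continental", n = 10000L, seed = 7L, missing_rate = 0.05)
  plots <- suppressWarnings(simulate_plots(p))
  frac <- mean(!stats::complete.cases(
    plots[, c("soil_cn", "stem_density", "stand_age")]))
  expect_lt(abs(frac - (1 - (1 - 0.05)^3)), 0.02)
})

test_that("continental truth plants the regimes on the right side of the aridity split", {
  p <- small_params("continental", n = 5000L, seed = 9L)
  plots <- suppressWarnings(simulate_plots(p))
  truth <- generator_truth(plots)
  reg <- dplyr::inner_join(truth$regime,
                           dplyr::select(plots, "plot_id", "aridity"),
                           by = "plot_id")
  w <- p$bpr_regime_map$width

  dry_core <- reg[reg$aridity <= 0.5 - w, ]
  expect_true(all(dry_core$b18 == 0))
  expect_true(all(dry_core$b17 > 0))
  expect_true(all(dry_core$regime == "dry"))

  wet_core <- reg[reg$aridity >= 0.5 + w, ]
  expect_true(all(wet_core$b18 < 0))
  expect_true(all(wet_core$regime == "wet"))

  # all four aridity classes are populated under the continental preset
  expect_setequal(as.character(unique(aridity_class(plots$aridity))),
                  c("arid", "semi-arid", "dry sub-humid", "humid"))
})

test_that("truth serialization round-trips the planted parameters", {
  p <- small_params("continental", n = 200L, seed = 2L)
  plots <- suppressWarnings(simulate_plots(p))
  path <- withr::local_tempfile(fileext = ".json")
  write_truth(plots, path)
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(tr$scenario, "continental")
  expect_equal(unlist(tr$structural_betas[["b17"]]),
               unname(p$structural_betas["b17"]), ignore_attr = TRUE)
  expect_equal(nrow(tr$plot_regime), 200L)
})
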