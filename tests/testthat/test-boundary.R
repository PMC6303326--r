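planted_units <- function(n = 60, threshold = 1000, seed = 3,
                          flip_near = 150) {
  set.seed(seed)
  tbl <- tibble::tibble(
    mat_mean = runif(n, 0, 20),
    tap_mean = runif(n, 400, 1600),
    n = rpois(n, 200)
  )
  type <- ifelse(tbl$tap_mean > threshold, "concave_negative", "linear_positive")
  # jitter labels near the threshold so the classes overlap (no separation)
  near <- abs(tbl$tap_mean - threshold) < flip_near
  flip <- near & runif(n) < 0.3
  type[flip] <- ifelse(type[flip] == "concave_negative",
                       "linear_positive", "concave_negative")
  tbl$bpr_type <- type
  tbl
}

test_that("a planted TAP threshold is recovered by the logistic boundary", {
  units <- planted_units()
  fit <- fit_type_boundary(units)
  expect_false(fit$separation)
  expect_true(fit$reliable)
  # boundary is ~horizontal in MAT and close to the planted TAP threshold
  line <- boundary_line(fit, c(5, 10, 15))
  expect_true(all(abs(line$tap - 1000) < 100))
  expect_lt(abs(fit$coefficients["mat"] / fit$coefficients["tap"]), 30)
})

test_that("every boundary point has predicted probability one half", {
  units <- planted_units(seed = 8)
  fit <- fit_type_boundary(units)
  line <- boundary_line(fit, seq(0, 20, length.out = 7))
  eta <- fit$coefficients["intercept"] + fit$coefficients["mat"] * line$mat +
    fit$coefficients["tap"] * line$tap
  expect_true(all(abs(plogis(eta) - 0.5) < 1e-9))
})

test_that("boundary algebra matches the closed form", {
  mk <- function(coefs) structure(list(coefficients = coefs),
                                  class = "bpr_boundary")
  horizontal <- mk(c(intercept = 0, mat = 0, tap = 1))
  expect_equal(boundary_line(horizontal, c(-5, 0, 5))$tap, c(0, 0, 0))

  shifted <- mk(c(intercept = -10, mat = 0, tap = 0.01))
  expect_equal(boundary_line(shifted, c(0, 10))$tap, c(1000, 1000))

  vertical <- mk(c(intercept = -5, mat = 0.5, tap = 0))
  v <- boundary_line(vertical, c(0, 1))
  expect_true(isTRUE(attr(v, "vertical")))
  expect_equal(v$mat, c(10, 10))
})

test_that("the logit fit matches an IRLS oracle on separable-free instances", {
  set.seed(21)
  for (i in 1:10) {
    n <- 80
    units <- tibble::tibble(
      mat_mean = rnorm(n, 10, 4),
      tap_mean = rnorm(n, 1000, 250)
    )
    eta <- -2 + 0.002 * units$tap_mean - 0.05 * units$mat_mean
    y <- runif(n) < plogis(eta)
    units$bpr_type <- ifelse(y, "concave_negative", "linear_positive")
    if (sum(y) < 2 || sum(!y) < 2) next
    fit <- fit_type_boundary(units)
    if (fit$separation) next
    oracle <- irls_logit_oracle(cbind(1, units$mat_mean, units$tap_mean),
                                as.integer(y))
    expect_equal(unname(fit$coefficients), oracle, tolerance = 1e-6)
  }
})

test_that("complete separation is flagged and a penalized boundary still reported", {
  set.seed(2)
  units <- tibble::tibble(
    mat_mean = runif(40, 0, 20),
    tap_mean = c(runif(20, 400, 900), runif(20, 1100, 1600)),
    bpr_type = rep(c("linear_positive", "concave_negative"), each = 20)
  )
  fit <- suppressWarnings(fit_type_boundary(units))
  expect_true(fit$separation)
  expect_true(fit$penalized)
  expect_false(fit$reliable)
  line <- boundary_line(fit, 10)
  expect_gt(line$tap, 900)
  expect_lt(line$tap, 1100)
})

test_that("degenerate class counts are rejected", {
  units <- planted_units()
  one_sided <- dplyr::mutate(units,
    bpr_type = ifelse(dplyr::row_number() == 1, "concave_negative",
                      "linear_positive"))
  expect_error(fit_type_boundary(one_sided), "at least 2")
  expect_error(fit_type_boundary(dplyr::select(units, -"tap_mean")), "tap_mean")
})

test_that("random labels yield an unreliable boundary", {
  set.seed(31)
  units <- tibble::tibble(
    mat_mean = rnorm(50, 10, 4),
    tap_mean = rnorm(50, 1000, 250),
    bpr_type = sample(c("linear_positive", "concave_negative"), 50,
                      replace = TRUE)
  )
  fit <- fit_type_boundary(units)
  expect_false(fit$reliable)
  expect_gt(min(fit$p_values[c("mat", "tap")]), 0.05)
})
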