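#' Logistic boundary between the two BPR types in climate space
#'
#' Fits a binomial logit model of unit BPR type (linear-positive vs.
#' concave-negative; all other labels are excluded) on the unit climate
#' means, one observation per unit. The decision boundary is the line where
#' the predicted probability of a concave-negative BPR is 0.5. Complete (or
#' quasi-complete) separation of the two classes is detected and flagged;
#' in that case a lightly ridge-penalized logit refit is reported so a
#' boundary always exists.
#'
#' @param units Tibble with one row per unit, columns `mat_mean`,
#'   `tap_mean`, `bpr_type` and (optionally, for `weight_by_n`) `n`.
#'   Typically a join of [summarize_units()] and [bivariate_by_unit()].
#' @param weight_by_n Weight units by their plot counts (default `FALSE`:
#'   each unit counts once).
#' @param ridge Ridge penalty used by the separation fallback (default
#'   1e-3, on the standardized-predictor scale).
#' @return A `bpr_boundary` object: `coefficients` (intercept, `mat`,
#'   `tap`, on the raw climate scale), `converged`, `separation`,
#'   `penalized`, `reliable`, the per-coefficient `p` values (unpenalized
#'   fit), and class counts.
#' @export
fit_type_boundary <- function(units, weight_by_n = FALSE, ridge = 1e-3) {
  need <- c("mat_mean", "tap_mean", "bpr_type")
  absent <- setdiff(need, names(units))
  if (length(absent) > 0) {
    abort(paste0("Unit table is missing column(s): ",
                 paste(absent, collapse = ", "), "."))
  }
  dat <- dplyr::filter(units,
                       .data$bpr_type %in% c("linear_positive", "concave_negative"))
  n_pos <- sum(dat$bpr_type == "linear_positive")
  n_neg <- sum(dat$bpr_type == "concave_negative")
  if (n_pos < 2 || n_neg < 2) {
    abort(paste0("Need at least 2 units of each BPR type for the boundary fit ",
                 "(got ", n_pos, " linear_positive, ", n_neg,
                 " concave_negative)."))
  }
  y <- as.integer(dat$bpr_type == "concave_negative")
  w <- if (weight_by_n) dat$n else rep(1, nrow(dat))

  fit <- suppressWarnings(
    glm(y ~ mat_mean + tap_mean, data = dat, family = binomial(),
        weights = w)
  )
  eta <- predict(fit)
  separation <- !fit$converged || max(abs(coef(fit)[-1]), na.rm = TRUE) > 50 ||
    all(abs(eta) > 8)
  sm <- summary(fit)$coefficients
  pvals <- setNames(sm[, "Pr(>|z|)"], c("intercept", "mat", "tap"))

  penalized <- FALSE
  if (separation) {
    # ridge-penalized IRLS on 2-SD standardized predictors, intercept unpenalized
    zm <- standardize_2sd(dat$mat_mean)
    zt <- standardize_2sd(dat$tap_mean)
    X <- cbind(1, as.numeric(zm), as.numeric(zt))
    beta <- c(0, 0, 0)
    P <- diag(c(0, ridge, ridge))
    for (it in 1:200) {
      mu <- plogis(drop(X %*% beta))
      wt <- pmax(w * mu * (1 - mu), 1e-10)
      z <- drop(X %*% beta) + (y - mu) / pmax(mu * (1 - mu), 1e-10)
      beta_new <- solve(crossprod(X, wt * X) + P, crossprod(X, wt * z))
      if (max(abs(beta_new - beta)) < 1e-10) { beta <- drop(beta_new); break }
      beta <- drop(beta_new)
    }
    # back-transform to the raw climate scale
    cm <- attr(zm, "center"); sm2 <- 2 * attr(zm, "scale")
    ct <- attr(zt, "center"); st <- 2 * attr(zt, "scale")
    coefs <- c(
      intercept = beta[1] - beta[2] * cm / sm2 - beta[3] * ct / st,
      mat = beta[2] / sm2,
      tap = beta[3] / st
    )
    penalized <- TRUE
  } else {
    coefs <- setNames(unname(coef(fit)), c("intercept", "mat", "tap"))
  }

  structure(list(
    coefficients = coefs,
    converged = fit$converged,
    separation = separation,
    penalized = penalized,
    p_values = pvals,
    reliable = !separation && any(pvals[c("mat", "tap")] < 0.05),
    n_linear_positive = n_pos,
    n_concave_negative = n_neg,
    data = dplyr::mutate(dat, y = y, weight = w)
  ), class = "bpr_boundary")
}

#' @export
print.bpr_boundary <- function(x, ...) {
  cat("<bpr_boundary> P(concave_negative) = 0.5 along\n  ",
      sprintf("%.4g + %.4g * MAT + %.4g * TAP = 0\n",
              x$coefficients["intercept"], x$coefficients["mat"],
              x$coefficients["tap"]))
  cat("  units:", x$n_linear_positive, "linear_positive,",
      x$n_concave_negative, "concave_negative\n")
  if (x$separation) cat("  [separation detected; ridge-penalized fit]\n")
  if (!x$reliable) cat("  [boundary flagged unreliable]\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.bpr_boundary <- function(x, ...) {
  tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    p = unname(x$p_values)
  )
}

#' @exportS3Method generics::glance
glance.bpr_boundary <- function(x, ...) {
  tibble(
    converged = x$converged, separation = x$separation,
    penalized = x$penalized, reliable = x$reliable,
    n_linear_positive = x$n_linear_positive,
    n_concave_negative = x$n_concave_negative
  )
}

#' Evaluate the BPR boundary line over a MAT grid
#'
#' Solves `intercept + coef_mat * MAT + coef_tap * TAP = 0` for TAP at each
#' requested MAT; every returned point has predicted probability exactly
#' 0.5. When the TAP coefficient is (numerically) zero the boundary is
#' vertical in climate space and is reported as a constant-MAT locus
#' instead.
#'
#' @param fit A `bpr_boundary`.
#' @param mat_grid Numeric vector of MAT values.
#' @return Tibble with columns `mat` and `tap` (vertical boundaries return
#'   the constant `mat` with `tap = NA` and an attribute
#'   `"vertical" = TRUE`).
#' @export
boundary_line <- function(fit, mat_grid) {
  stopifnot(inherits(fit, "bpr_boundary"))
  b <- fit$coefficients
  if (abs(b["tap"]) < .Machine$double.eps) {
    if (abs(b["mat"]) < .Machine$double.eps) {
      abort("Degenerate boundary: both climate coefficients are zero.")
    }
    out <- tibble(mat = rep(-b[["intercept"]] / b[["mat"]], length(mat_grid)),
                  tap = NA_real_)
    attr(out, "vertical") <- TRUE
    return(out)
  }
  tibble(mat = mat_grid,
         tap = -(b[["intercept"]] + b[["mat"]] * mat_grid) / b[["tap"]])
}
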