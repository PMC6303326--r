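# Independent oracles used to cross-check the fitting code. These are
# deliberately written from first principles (normal equations, analytic
# likelihoods, textbook IRLS) and share no code with the package internals.

# Gaussian ML fit by normal equations; conventions match standard GLM
# software: ML error variance in the likelihood, (n - p) denominator in
# the coefficient SEs, error variance counted as a parameter in AIC.
ols_oracle <- function(X, y) {
  n <- length(y)
  p <- ncol(X)
  XtX <- crossprod(X)
  beta <- drop(solve(XtX, crossprod(X, y)))
  resid <- y - drop(X %*% beta)
  rss <- sum(resid^2)
  sigma2_ml <- rss / n
  loglik <- -n / 2 * (log(2 * pi * sigma2_ml) + 1)
  se <- sqrt(diag(solve(XtX)) * rss / (n - p))
  z <- beta / se
  list(
    beta = beta, se = se, z = z,
    p = 2 * stats::pnorm(-abs(z)),
    loglik = loglik,
    aic = -2 * loglik + 2 * (p + 1)
  )
}

# plain Newton/IRLS logistic regression
irls_logit_oracle <- function(X, y, tol = 1e-12, max_iter = 100) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    beta_new <- drop(solve(crossprod(X, w * X), crossprod(X, w * z)))
    if (max(abs(beta_new - beta)) < tol) return(beta_new)
    beta <- beta_new
  }
  beta
}

# Term-by-term recomputation of the hierarchical joint log density,
# hard-coded against the model description (not the package generator).
hbm_logdensity_oracle <- function(model, pars) {
  d <- model$data
  pv <- sqrt(model$priors$slope_variance)
  hn <- function(x, s) sum(log(2) + stats::dnorm(x, 0, s, log = TRUE))
  if (model$hierarchical) {
    ic <- function(m) pars$u[m, d$eco]
  } else {
    ic <- function(m) rep(pars$a[m], d$N)
  }
  b <- pars$b
  mu1 <- ic(1) + b[1] * d$zmat + b[2] * d$ztap
  mu2 <- ic(2) + b[3] * d$zmat + b[4] * d$ztap
  mu3 <- ic(3) + b[5] * d$zmat + b[6] * d$ztap
  eta4 <- ic(4) + b[7] * d$zmat + b[8] * d$ztap + b[9] * d$zden +
    b[10] * d$zage + b[11] * d$zcn
  mu5 <- ic(5) + b[12] * d$zmat + b[13] * d$ztap + b[14] * d$zden +
    b[15] * d$zage + b[16] * d$zcn + b[17] * d$zric + b[18] * d$zric2
  ll <- sum(stats::dnorm(d$ldn, mu1, pars$sigma[1], log = TRUE)) +
    sum(stats::dnorm(d$lag, mu2, pars$sigma[2], log = TRUE)) +
    sum(stats::dnorm(d$lcn, mu3, pars$sigma[3], log = TRUE)) +
    sum(stats::dpois(d$rich, exp(eta4), log = TRUE)) +
    sum(stats::dnorm(d$lpr, mu5, pars$sigma[4], log = TRUE))
  lp <- sum(stats::dnorm(pars$a, 0, pv, log = TRUE)) +
    sum(stats::dnorm(pars$b, 0, pv, log = TRUE)) +
    hn(pars$sigma, model$priors$resid_sd_scale)
  if (model$hierarchical) {
    lp <- lp + hn(pars$sigma_u, model$priors$ranef_sd_scale)
    for (m in 1:5) {
      lp <- lp + sum(stats::dnorm(pars$u[m, ], pars$a[m], pars$sigma_u[m],
                                  log = TRUE))
    }
  }
  ll + lp
}

# conjugate posterior of a normal mean with known sigma
conjugate_normal_mean <- function(y, sigma, prior_mean = 0, prior_var = 1000) {
  n <- length(y)
  post_var <- 1 / (1 / prior_var + n / sigma^2)
  post_mean <- post_var * (prior_mean / prior_var + sum(y) / sigma^2)
  list(mean = post_mean, sd = sqrt(post_var))
}

# random parameter point for the hierarchical model, valid for either
# parameterization
random_hbm_pars <- function(model, seed) {
  set.seed(seed)
  pars <- list(
    a = rnorm(5, 0, 0.5),
    b = rnorm(18, 0, 0.3),
    sigma = runif(4, 0.2, 1.5)
  )
  if (model$hierarchical) {
    pars$sigma_u <- runif(5, 0.1, 0.8)
    pars$u <- matrix(rnorm(5 * model$data$G, pars$a, 0.3), nrow = 5)
  }
  pars
}
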