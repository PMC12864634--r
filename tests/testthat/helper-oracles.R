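# Shared fixtures and independent brute-force oracles. The oracles
# integrate the likelihood against the priors by dense Riemann sums /
# grids in the original parameterization -- a route deliberately different
# from the package's prior-quantile Gauss-Legendre quadrature.

make_ds <- function(y, se, year = NULL, label = NULL) {
  meta_dataset(label = if (is.null(label)) paste0("s", seq_along(y)) else label,
               y = y, se = se, year = year)
}

dataset_subset_for_test <- function(d, idx) {
  s <- d$studies[idx, , drop = FALSE]
  meta_dataset(label = s$label, y = s$y, se = s$se,
               year = if (all(is.na(s$year))) NULL else s$year)
}

lse <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

loglik_fe_oracle <- function(mu, y, v) {
  vapply(mu, function(m) sum(dnorm(y, m, sqrt(v), log = TRUE)), numeric(1))
}

ldcauchy <- function(x, prior) {
  dcauchy(x, prior$cauchy_location, prior$cauchy_scale, log = TRUE)
}

ldinvgamma <- function(x, prior) {
  a <- prior$tau_shape; b <- prior$tau_scale
  a * log(b) - lgamma(a) - (a + 1) * log(x) - b / x
}

# m(y | fe1) by Riemann sum over mu in [-50, 50].
riemann_fe_alt <- function(y, se, prior = prior_spec(), n = 1e6) {
  mu <- seq(-50, 50, length.out = n)
  h <- mu[2] - mu[1]
  lse(loglik_fe_oracle(mu, y, se^2) + ldcauchy(mu, prior)) + log(h)
}

# m(y | re0) by Riemann sum over log tau.
riemann_re_null <- function(y, se, prior = prior_spec(), n = 1e6) {
  s <- seq(-25, 10, length.out = n)
  tau <- exp(s)
  h <- s[2] - s[1]
  ll <- vapply(tau, function(t) {
    sum(dnorm(y, 0, sqrt(se^2 + t^2), log = TRUE))
  }, numeric(1))
  lse(ll + ldinvgamma(tau, prior) + s) + log(h)  # + s: Jacobian d tau = tau ds
}

# m(y | re1) by a dense 2-D grid: mu uniform, tau on a log grid.
grid_re_alt <- function(y, se, prior = prior_spec(), n_mu = 2000,
                        n_tau = 2000) {
  mu <- seq(-50, 50, length.out = n_mu)
  s <- seq(-25, 10, length.out = n_tau)
  tau <- exp(s)
  h_mu <- mu[2] - mu[1]
  h_s <- s[2] - s[1]
  ll <- matrix(0, n_mu, n_tau)
  for (j in seq_len(n_tau)) {
    sd_j <- sqrt(se^2 + tau[j]^2)
    ll[, j] <- vapply(mu, function(m) sum(dnorm(y, m, sd_j, log = TRUE)),
                      numeric(1))
  }
  lp <- outer(ldcauchy(mu, prior), ldinvgamma(tau, prior) + s, `+`)
  lse(ll + lp) + log(h_mu) + log(h_s)
}

# Posterior mean of theta_i under re1 from the same dense 2-D grid.
grid_shrinkage_mean <- function(y, se, i, prior = prior_spec(),
                                n_mu = 1200, n_tau = 1200) {
  fe <- sum(y / se^2) / sum(1 / se^2)
  mu <- seq(fe - 12, fe + 12, length.out = n_mu)
  s <- seq(-18, 5, length.out = n_tau)
  tau <- exp(s)
  ll <- matrix(0, n_mu, n_tau)
  for (j in seq_len(n_tau)) {
    sd_j <- sqrt(se^2 + tau[j]^2)
    ll[, j] <- vapply(mu, function(m) sum(dnorm(y, m, sd_j, log = TRUE)),
                      numeric(1))
  }
  lw <- ll + outer(ldcauchy(mu, prior), ldinvgamma(tau, prior) + s, `+`)
  W <- exp(lw - lse(lw))
  prec <- outer(rep(1 / se[i]^2, n_mu), 1 / tau^2, `+`)
  m <- (y[i] / se[i]^2 + outer(mu, 1 / tau^2)) / prec
  sum(W * m)
}

# Restricted log-likelihood of the marginal RE model (for the REML grid
# search oracle).
restricted_ll <- function(tau2, y, v) {
  w <- 1 / (v + tau2)
  mu <- sum(w * y) / sum(w)
  -0.5 * sum(log(v + tau2)) - 0.5 * log(sum(w)) -
    0.5 * sum(w * (y - mu)^2)
}
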