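# Prior specification for the Bayesian model-averaged engine.

#' Prior specification for Bayesian model-averaged meta-analysis
#'
#' The engine averages over four models: fixed-effect null (`fe0`, pooled
#' log odds ratio mu = 0 and no heterogeneity), fixed-effect alternative
#' (`fe1`, mu drawn from a Cauchy prior), random-effects null (`re0`, mu = 0,
#' between-study standard deviation tau drawn from an inverse-gamma prior)
#' and random-effects alternative (`re1`, both priors jointly).
#'
#' Defaults are deliberately weak: a Cauchy prior with location 0 and scale
#' 0.707 on the pooled log odds ratio, and an inverse-gamma prior with shape
#' 1 and *scale* 0.15 on tau. Note the inverse-gamma is placed on the
#' standard deviation tau, not the variance tau^2, and `tau_scale` is the
#' scale (the numerator of the exponential term `exp(-scale/tau)`), not a
#' rate; both conventions appear in the literature, so the argument names
#' here are explicit.
#'
#' @param cauchy_location,cauchy_scale Location and scale of the Cauchy
#'   prior on the pooled log odds ratio (scale > 0).
#' @param tau_shape,tau_scale Shape and scale of the inverse-gamma prior on
#'   the between-study standard deviation tau (both > 0; log odds ratio
#'   units).
#' @param model_prior Prior model probabilities over `(fe0, fe1, re0, re1)`,
#'   nonnegative and summing to 1. Default uniform.
#' @return A list of class `prior_spec`.
#' @export
prior_spec <- function(cauchy_location = 0, cauchy_scale = 0.707,
                       tau_shape = 1, tau_scale = 0.15,
                       model_prior = c(fe0 = 0.25, fe1 = 0.25,
                                       re0 = 0.25, re1 = 0.25)) {
  if (!is.finite(cauchy_location)) stop("cauchy_location must be finite")
  if (!is.finite(cauchy_scale) || cauchy_scale <= 0) {
    stop("cauchy_scale must be > 0")
  }
  if (!is.finite(tau_shape) || tau_shape <= 0) stop("tau_shape must be > 0")
  if (!is.finite(tau_scale) || tau_scale <= 0) stop("tau_scale must be > 0")
  model_prior <- as.numeric(model_prior)
  if (length(model_prior) != 4L || any(model_prior < 0) ||
      abs(sum(model_prior) - 1) > 1e-12) {
    stop("model_prior must be 4 nonnegative probabilities summing to 1")
  }
  structure(list(cauchy_location = cauchy_location,
                 cauchy_scale = cauchy_scale,
                 tau_shape = tau_shape, tau_scale = tau_scale,
                 model_prior = setNames(model_prior,
                                        c("fe0", "fe1", "re0", "re1"))),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("prior_spec:\n")
  cat("  effect prior: Cauchy(location =", x$cauchy_location,
      ", scale =", x$cauchy_scale, ") on the pooled log OR\n")
  cat("  heterogeneity prior: inverse-gamma(shape =", x$tau_shape,
      ", scale =", x$tau_scale, ") on tau (SD scale)\n")
  cat("  model prior (fe0, fe1, re0, re1):",
      paste(signif(x$model_prior, 4), collapse = ", "), "\n")
  invisible(x)
}

assert_prior <- function(prior) {
  if (!inherits(prior, "prior_spec")) {
    stop("expected a prior_spec (see prior_spec())", call. = FALSE)
  }
  prior
}

# Quantile of the inverse-gamma(shape, scale) distribution on tau.
# If X ~ InvGamma(a, b) then 1/X ~ Gamma(a, rate = b), so
# F_X(t) = u  <=>  1/t = upper-tail Gamma quantile at u.
qinvgamma <- function(u, shape, scale) {
  1 / qgamma(u, shape = shape, rate = scale, lower.tail = FALSE)
}

dinvgamma_log <- function(x, shape, scale) {
  shape * log(scale) - lgamma(shape) - (shape + 1) * log(x) - scale / x
}

# Prior quantile maps used by the quadrature substitution.
mu_quantile <- function(u, prior) {
  qcauchy(u, location = prior$cauchy_location, scale = prior$cauchy_scale)
}

tau_quantile <- function(u, prior) {
  qinvgamma(u, shape = prior$tau_shape, scale = prior$tau_scale)
}
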