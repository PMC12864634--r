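# Conventional inverse-variance meta-analysis: fixed-effect and
# random-effects pooling, Cochran's Q, I^2, DerSimonian-Laird and REML
# estimators of the between-study variance.
#
# Wald machinery uses the conventional fixed 1.96 multiplier for 95%
# intervals throughout (not qnorm(0.975)), so printed bounds reproduce the
# usual exp(mu_hat -/+ 1.96 se) arithmetic exactly.

freq_result <- function(model, mu_hat, se_mu, tau2, tau2_method, Q, df, I2, K) {
  z <- mu_hat / se_mu
  p <- 2 * pnorm(-abs(z))
  ci <- c(mu_hat - 1.96 * se_mu, mu_hat + 1.96 * se_mu)
  structure(list(model = model, K = K,
                 mu_hat = mu_hat, se_mu = se_mu,
                 ci_low = ci[1], ci_high = ci[2],
                 z = z, p = p,
                 tau2 = tau2, tau2_method = tau2_method,
                 Q = Q, df = df, I2 = I2,
                 or = exp(mu_hat), or_ci = exp(ci)),
            class = "meta_freq")
}

#' @export
print.meta_freq <- function(x, ...) {
  cat(sprintf("%s meta-analysis of %d studies\n",
              if (x$model == "FE") "Fixed-effect" else "Random-effects", x$K))
  cat(sprintf("  log OR %.3f (%.3f, %.3f)   OR %.3f (%.3f, %.3f)\n",
              x$mu_hat, x$ci_low, x$ci_high, x$or, x$or_ci[1], x$or_ci[2]))
  cat(sprintf("  z = %.3f, p = %.4f\n", x$z, x$p))
  if (x$model == "RE") {
    cat(sprintf("  tau^2 = %.4f (%s)", x$tau2, x$tau2_method))
  } else {
    cat("  tau^2 = 0 (fixed-effect)")
  }
  if (!is.na(x$Q)) {
    cat(sprintf("; Q = %.3f (df = %d), I^2 = %.2f%%\n", x$Q, x$df, x$I2))
  } else cat("\n")
  invisible(x)
}

#' Fixed-effect inverse-variance pooling
#'
#' Pools study log odds ratios with weights `w_i = 1/se_i^2`:
#' `mu_hat = sum(w*y)/sum(w)`, `se = sum(w)^(-1/2)`, with a Wald z test and
#' 95% interval `mu_hat +/- 1.96 se`. Heterogeneity statistics (Q, I^2) are
#' attached when at least two studies are present.
#'
#' @param dataset A [meta_dataset()].
#' @return A `meta_freq` result.
#' @export
meta_fixed <- function(dataset) {
  assert_dataset(dataset)
  s <- dataset$studies
  w <- 1 / s$se^2
  mu <- sum(w * s$y) / sum(w)
  se_mu <- 1 / sqrt(sum(w))
  het <- if (nrow(s) >= 2) cochran_q(dataset) else list(Q = NA_real_,
                                                        df = NA_integer_,
                                                        I2 = NA_real_)
  freq_result("FE", mu, se_mu, tau2 = 0, tau2_method = "none",
              Q = het$Q, df = het$df, I2 = het$I2, K = nrow(s))
}

#' Cochran's Q and I-squared
#'
#' `Q = sum(w_i (y_i - mu_FE)^2)` with fixed-effect weights, on `K - 1`
#' degrees of freedom, and the derived heterogeneity fraction
#' `I^2 = max(0, (Q - df)/Q) * 100` (0 when Q = 0).
#'
#' @param dataset A [meta_dataset()] with at least two studies.
#' @return List with `Q`, `df`, `I2`.
#' @export
cochran_q <- function(dataset) {
  assert_dataset(dataset)
  s <- dataset$studies
  K <- nrow(s)
  if (K < 2) {
    stop(errorCondition("heterogeneity statistics require at least 2 studies",
                        class = c("metabf_heterogeneity_undefined_error",
                                  "error", "condition")))
  }
  w <- 1 / s$se^2
  mu <- sum(w * s$y) / sum(w)
  Q <- sum(w * (s$y - mu)^2)
  df <- K - 1L
  I2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  list(Q = Q, df = df, I2 = I2)
}

#' DerSimonian-Laird estimate of the between-study variance
#'
#' Method-of-moments estimator
#' `tau^2 = max(0, (Q - (K-1)) / (sum(w) - sum(w^2)/sum(w)))` with
#' fixed-effect weights `w_i = 1/se_i^2`.
#'
#' @param dataset A [meta_dataset()] with at least two studies.
#' @return Nonnegative scalar `tau^2`.
#' @export
tau2_dl <- function(dataset) {
  het <- cochran_q(dataset)
  s <- dataset$studies
  w <- 1 / s$se^2
  denom <- sum(w) - sum(w^2) / sum(w)
  max(0, (het$Q - het$df) / denom)
}

#' REML estimate of the between-study variance
#'
#' Restricted maximum likelihood under the marginal model
#' `y_i ~ Normal(mu, se_i^2 + tau^2)`, fitted with [metafor::rma.uni()]
#' (Fisher scoring, lower-bounded at zero). Only the `tau^2` estimate is
#' taken from the fit; pooling and intervals are built in
#' [meta_random()].
#'
#' @param dataset A [meta_dataset()] with at least two studies.
#' @param tol Convergence threshold passed to the optimizer.
#' @param maxiter Maximum Fisher-scoring iterations.
#' @return Nonnegative scalar `tau^2`.
#' @export
tau2_reml <- function(dataset, tol = 1e-10, maxiter = 200) {
  assert_dataset(dataset)
  s <- dataset$studies
  if (nrow(s) < 2) {
    stop(errorCondition("REML requires at least 2 studies",
                        class = c("metabf_heterogeneity_undefined_error",
                                  "error", "condition")))
  }
  # Fisher scoring can oscillate near the tau^2 = 0 boundary; retry with
  # progressively damped steps before giving up
  last_err <- NULL
  for (stepadj in c(1, 0.5, 0.25)) {
    fit <- tryCatch(
      metafor::rma.uni(yi = s$y, sei = s$se, method = "REML",
                       control = list(threshold = tol, maxiter = maxiter,
                                      stepadj = stepadj)),
      error = function(e) {
        last_err <<- conditionMessage(e)
        NULL
      })
    if (!is.null(fit)) return(as.numeric(fit$tau2))
  }
  stop(errorCondition(paste0("REML did not converge: ", last_err),
                      class = c("metabf_convergence_error",
                                "error", "condition")))
}

#' Random-effects inverse-variance pooling
#'
#' Pools with weights `w_i* = 1/(se_i^2 + tau^2)`, where `tau^2` comes from
#' REML (default) or DerSimonian-Laird. Test, interval and back-transformed
#' odds ratio as in [meta_fixed()]. With a single study the random-effects
#' model is not identifiable; `tau^2` is forced to 0 with a warning so
#' sequential analyses can start at k = 1.
#'
#' @param dataset A [meta_dataset()].
#' @param tau2_method `"REML"` (default) or `"DL"`.
#' @return A `meta_freq` result carrying `tau2`, `Q`, `I2`.
#' @export
meta_random <- function(dataset, tau2_method = c("REML", "DL")) {
  assert_dataset(dataset)
  tau2_method <- match.arg(tau2_method)
  s <- dataset$studies
  K <- nrow(s)
  if (K < 2) {
    warning("random-effects model with a single study: tau^2 forced to 0",
            call. = FALSE)
    tau2 <- 0
    het <- list(Q = NA_real_, df = NA_integer_, I2 = NA_real_)
  } else {
    tau2 <- if (tau2_method == "DL") tau2_dl(dataset) else tau2_reml(dataset)
    het <- cochran_q(dataset)
  }
  w <- 1 / (s$se^2 + tau2)
  mu <- sum(w * s$y) / sum(w)
  se_mu <- 1 / sqrt(sum(w))
  freq_result("RE", mu, se_mu, tau2 = tau2, tau2_method = tau2_method,
              Q = het$Q, df = het$df, I2 = het$I2, K = K)
}

#' Pseudo likelihood ratio from a p-value
#'
#' The didactic quantity `(1 - p)/p`: the ratio one would (incorrectly)
#' read off a p-value if the alternative were treated as the exact
#' complement of the null. Provided purely as a comparator to the Bayes
#' factor -- it is not an inferential quantity, and frequentist theory
#' assigns no probability to either hypothesis.
#'
#' @param p A p-value strictly inside (0, 1).
#' @return `(1 - p)/p`.
#' @export
pseudo_lr <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("p must lie strictly inside (0, 1)", call. = FALSE)
  }
  (1 - p) / p
}
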