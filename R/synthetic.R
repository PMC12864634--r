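# Seeded synthetic-trial generator and operating-characteristic
# experiments. Defaults mirror the kind of evidence base the analysis
# functions are aimed at: a handful of two-arm surgical RCTs with an
# uncommon binary outcome (baseline event risk ~10%, a few hundred
# patients per arm) and a protective intervention of moderate size with
# moderate between-study heterogeneity on the log odds ratio scale.

#' Configuration for the synthetic-trial generator
#'
#' Two generation modes. `"binomial-trials"` (default) draws full 2x2
#' tables: per-arm sizes uniform on `n_range`, control events
#' `Binomial(n, p_ctrl)`, treatment events
#' `Binomial(n, plogis(qlogis(p_ctrl) + theta_i))` with study effects
#' `theta_i ~ Normal(mu_true, tau_true^2)`, then `(y, se)` via
#' [log_odds_ratio()] with the continuity correction on.
#' `"normal-effects"` skips the binomial layer and draws
#' `y_i ~ Normal(theta_i, se_i^2)` with `se_i` uniform on `se_range` --
#' data that match the pooling model exactly, for calibration tests.
#'
#' @param mu_true True pooled log odds ratio.
#' @param tau_true True between-study SD (log odds ratio units), >= 0.
#' @param K Number of studies, >= 1.
#' @param n_range Inclusive per-arm size bounds (binomial mode).
#' @param p_ctrl Control-arm event probability in (0, 1).
#' @param mode `"binomial-trials"` or `"normal-effects"`.
#' @param se_range Bounds for the per-study standard errors (normal mode).
#' @param seed Integer seed; fully determines the generated studies.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(mu_true = -0.5, tau_true = 0.2, K = 6,
                       n_range = c(100, 400), p_ctrl = 0.10,
                       mode = c("binomial-trials", "normal-effects"),
                       se_range = c(0.2, 0.6), seed = 1) {
  mode <- match.arg(mode)
  stopifnot(is.finite(mu_true), is.finite(tau_true), tau_true >= 0,
            K >= 1, length(n_range) == 2, n_range[1] >= 1,
            n_range[2] >= n_range[1], p_ctrl > 0, p_ctrl < 1,
            length(se_range) == 2, se_range[1] > 0,
            se_range[2] >= se_range[1], is.finite(seed))
  if (mode == "binomial-trials" && p_ctrl * n_range[1] < 1) {
    warning("expected control-arm events below 1: degenerate ",
            "(all-zero) tables are likely", call. = FALSE)
  }
  structure(list(mu_true = mu_true, tau_true = tau_true, K = as.integer(K),
                 n_range = as.integer(n_range), p_ctrl = p_ctrl,
                 mode = mode, se_range = se_range,
                 seed = as.integer(seed)),
            class = "sim_config")
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic set of trials
#'
#' Draws a [meta_dataset()] per the [sim_config()]; the seed fully
#' determines the output. Labels are `study_01, study_02, ...` with
#' consecutive publication years so sequential ordering is well defined.
#' In binomial mode, tables that are degenerate even after correction
#' (zero events in both arms) are redrawn -- such trials carry no odds
#' ratio information and would be excluded from a real meta-analysis.
#'
#' @param config A [sim_config()].
#' @return A [meta_dataset()].
#' @export
simulate_trials <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("config must be a sim_config()", call. = FALSE)
  }
  K <- config$K
  labels <- sprintf("study_%02d", seq_len(K))
  years <- 2000L + seq_len(K)
  with_seed(config$seed, {
    theta <- rnorm(K, config$mu_true, config$tau_true)
    if (config$mode == "normal-effects") {
      se <- runif(K, config$se_range[1], config$se_range[2])
      y <- rnorm(K, theta, se)
      meta_dataset(label = labels, y = y, se = se, year = years,
                   outcome_label = "synthetic outcome")
    } else {
      n_t <- n_c <- e_t <- e_c <- integer(K)
      for (i in seq_len(K)) {
        repeat {
          n_t[i] <- sample(config$n_range[1]:config$n_range[2], 1)
          n_c[i] <- sample(config$n_range[1]:config$n_range[2], 1)
          e_c[i] <- rbinom(1, n_c[i], config$p_ctrl)
          p_t <- plogis(qlogis(config$p_ctrl) + theta[i])
          e_t[i] <- rbinom(1, n_t[i], p_t)
          degenerate <- (e_t[i] == 0 && e_c[i] == 0) ||
            (e_t[i] == n_t[i] && e_c[i] == n_c[i])
          if (!degenerate) break
        }
      }
      meta_dataset(label = labels, events_treat = e_t, n_treat = n_t,
                   events_ctrl = e_c, n_ctrl = n_c, year = years,
                   outcome_label = "synthetic outcome", correction = TRUE)
    }
  })
}

# Derive one sub-seed per replicate from the top-level seed, so any single
# replicate can be regenerated in isolation.
replicate_seeds <- function(seed, replicates) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, replicates))
}

#' Parameter-recovery / operating-characteristic experiment
#'
#' Repeatedly generates datasets from one [sim_config()] (one sub-seed per
#' replicate, derived from the top-level seed) and summarizes how well each
#' estimator recovers the true pooled effect: bias and RMSE of the point
#' estimate, empirical coverage of the 95% interval, and -- for the
#' frequentist estimators -- the rejection rate of the two-sided test at
#' alpha = 0.05, or -- for the Bayesian estimator -- the median Bayes
#' factor and the fraction of replicates with BF10 > 1.
#'
#' @param config A [sim_config()].
#' @param replicates Number of replicate datasets, >= 1.
#' @param estimators Subset of `c("FE", "RE-DL", "RE-REML", "BMA")`.
#' @param prior,control Bayesian settings (used when `"BMA"` requested).
#' @return Data frame with one row per estimator, plus attribute
#'   `bf10` (the per-replicate BF10 values) when `"BMA"` is included.
#' @export
recovery_experiment <- function(config, replicates = 200,
                                estimators = c("FE", "RE-DL", "RE-REML",
                                               "BMA"),
                                prior = prior_spec(),
                                control = quad_control()) {
  stopifnot(replicates >= 1)
  estimators <- match.arg(estimators, several.ok = TRUE)
  seeds <- replicate_seeds(config$seed, replicates)
  est <- array(NA_real_, dim = c(replicates, length(estimators), 4),
               dimnames = list(NULL, estimators,
                               c("mu", "low", "high", "reject_or_bf")))
  for (r in seq_len(replicates)) {
    cfg_r <- config
    cfg_r$seed <- seeds[r]
    d <- simulate_trials(cfg_r)
    for (e in estimators) {
      res <- switch(e,
        "FE" = meta_fixed(d),
        "RE-DL" = meta_random(d, tau2_method = "DL"),
        "RE-REML" = meta_random(d, tau2_method = "REML"),
        "BMA" = meta_bayes(d, prior = prior, control = control,
                           shrinkage = FALSE))
      if (e == "BMA") {
        est[r, e, ] <- c(res$mu_mean, res$cri_low, res$cri_high, res$bf10)
      } else {
        est[r, e, ] <- c(res$mu_hat, res$ci_low, res$ci_high,
                         as.numeric(res$p < 0.05))
      }
    }
  }
  mu <- config$mu_true
  out <- do.call(rbind, lapply(estimators, function(e) {
    m <- est[, e, , drop = TRUE]
    if (replicates == 1) m <- matrix(m, nrow = 1,
                                     dimnames = list(NULL, dimnames(est)[[3]]))
    data.frame(
      estimator = e,
      bias = mean(m[, "mu"]) - mu,
      rmse = sqrt(mean((m[, "mu"] - mu)^2)),
      coverage = mean(m[, "low"] <= mu & mu <= m[, "high"]),
      rejection_rate = if (e == "BMA") NA_real_ else mean(m[, "reject_or_bf"]),
      median_bf10 = if (e == "BMA") median(m[, "reject_or_bf"]) else NA_real_,
      prop_bf10_gt_1 = if (e == "BMA") mean(m[, "reject_or_bf"] > 1)
                       else NA_real_)
  }))
  if ("BMA" %in% estimators) attr(out, "bf10") <- est[, "BMA", "reject_or_bf"]
  out
}

#' Median sequential Bayes factor trajectory over replicates
#'
#' Generates `replicates` study sequences from `config`, runs the Bayesian
#' model-averaged analysis on every prefix of each, and returns the
#' per-step median BF10 across replicates -- the summary used to check
#' that evidence accumulates when all studies share a common true effect.
#'
#' @param config A [sim_config()].
#' @param replicates Number of replicate sequences.
#' @param prior,control Bayesian settings.
#' @return List with `median_bf10` (length K) and the `trajectories`
#'   matrix (replicates x K).
#' @export
bf_trajectory_experiment <- function(config, replicates = 200,
                                     prior = prior_spec(),
                                     control = quad_control()) {
  stopifnot(replicates >= 1)
  seeds <- replicate_seeds(config$seed, replicates)
  traj <- matrix(NA_real_, replicates, config$K)
  for (r in seq_len(replicates)) {
    cfg_r <- config
    cfg_r$seed <- seeds[r]
    d <- simulate_trials(cfg_r)
    for (k in seq_len(config$K)) {
      marg <- model_marginals(dataset_subset(d, seq_len(k)), prior, control)
      traj[r, k] <- model_average(marg, prior)$bf10
    }
  }
  list(median_bf10 = apply(traj, 2, median), trajectories = traj)
}
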