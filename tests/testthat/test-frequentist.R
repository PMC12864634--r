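test_that("fixed-effect pooling equals the inverse-variance weighted mean", {
  # K = 1 returns the study itself
  d1 <- make_ds(0.3, 0.2)
  f1 <- meta_fixed(d1)
  expect_equal(f1$mu_hat, 0.3)
  expect_equal(f1$se_mu, 0.2)
  # equal weights force the midpoint
  f2 <- meta_fixed(make_ds(c(0, 1), c(1, 1)))
  expect_equal(f2$mu_hat, 0.5)
  expect_equal(f2$se_mu, 1 / sqrt(2))
  # three unequal studies: brute-force weighted mean, and metafor agrees
  y <- c(-0.3, -0.8, 0.2); se <- c(0.25, 0.5, 0.4)
  f3 <- meta_fixed(make_ds(y, se))
  w <- 1 / se^2
  expect_equal(f3$mu_hat, sum(w * y) / sum(w), tolerance = 1e-14)
  expect_equal(f3$se_mu, 1 / sqrt(sum(w)), tolerance = 1e-14)
  mf <- metafor::rma.uni(yi = y, sei = se, method = "FE")
  expect_equal(f3$mu_hat, as.numeric(mf$b), tolerance = 1e-10)
  expect_equal(f3$se_mu, mf$se, tolerance = 1e-10)
  # Wald interval uses the fixed 1.96 multiplier
  expect_equal(f3$ci_low, f3$mu_hat - 1.96 * f3$se_mu, tolerance = 1e-12)
  expect_equal(f3$ci_high, f3$mu_hat + 1.96 * f3$se_mu, tolerance = 1e-12)
})

test_that("Cochran's Q, I^2 and DerSimonian-Laird behave per definition", {
  # homogeneity
  hom <- cochran_q(make_ds(c(0.2, 0.2, 0.2), c(0.3, 0.4, 0.5)))
  expect_equal(hom$Q, 0, tolerance = 1e-12)
  expect_equal(hom$I2, 0)
  expect_equal(tau2_dl(make_ds(c(0.2, 0.2, 0.2), c(0.3, 0.4, 0.5))), 0)
  # hand computation: y = (0, 1), se = (1, 1) -> mu = 0.5, Q = 0.5
  het <- cochran_q(make_ds(c(0, 1), c(1, 1)))
  expect_equal(het$Q, 0.5, tolerance = 1e-12)
  expect_equal(het$df, 1L)
  expect_equal(het$I2, 0)  # Q < df clamps to zero
  expect_equal(tau2_dl(make_ds(c(0, 1), c(1, 1))), 0)
  expect_error(cochran_q(make_ds(0.1, 0.2)),
               class = "metabf_heterogeneity_undefined_error")
  # I^2 stays inside [0, 100] and matches metafor's DL fit
  set.seed(21)
  for (i in 1:10) {
    y <- rnorm(6, 0, 0.6); se <- runif(6, 0.1, 0.5)
    d <- make_ds(y, se)
    het <- cochran_q(d)
    expect_gte(het$I2, 0); expect_lte(het$I2, 100)
    mf <- metafor::rma.uni(yi = y, sei = se, method = "DL")
    expect_equal(het$Q, as.numeric(mf$QE), tolerance = 1e-10)
    expect_equal(tau2_dl(d), as.numeric(mf$tau2), tolerance = 1e-10)
  }
})

test_that("DerSimonian-Laird recovers the true tau^2 on simulated data", {
  # true tau = 0.3 (tau^2 = 0.09), K = 200 per replicate
  reps <- 40
  est <- vapply(seq_len(reps), function(r) {
    cfg <- sim_config(mu_true = -0.5, tau_true = 0.3, K = 200,
                      mode = "normal-effects", seed = 5000 + r)
    tau2_dl(simulate_trials(cfg))
  }, numeric(1))
  mc_se <- sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - 0.09), 3 * mc_se)
})

test_that("REML tau^2 maximizes the restricted likelihood", {
  y <- c(-0.6, -0.1, 0.3, -0.9, 0.1)
  se <- c(0.2, 0.3, 0.25, 0.4, 0.35)
  t2 <- tau2_reml(make_ds(y, se))
  grid <- seq(0, 10, length.out = 200001)
  rl <- vapply(grid, restricted_ll, numeric(1), y = y, v = se^2)
  t2_grid <- grid[which.max(rl)]
  expect_equal(t2, t2_grid, tolerance = 1e-4)
  # the optimum is a maximum: no grid neighbour does better
  expect_gte(restricted_ll(t2, y, se^2), max(rl) - 1e-8)
  # boundary agreement with DL on homogeneous data
  hom <- make_ds(c(0.2, 0.2, 0.2), c(0.3, 0.4, 0.5))
  expect_equal(tau2_reml(hom), 0, tolerance = 1e-10)
  expect_equal(tau2_dl(hom), 0)
})

test_that("random-effects pooling reduces to FE at tau^2 = 0 and widens otherwise", {
  hom <- make_ds(c(0.2, 0.2, 0.2), c(0.3, 0.4, 0.5))
  fe <- meta_fixed(hom)
  re <- meta_random(hom)
  expect_equal(re$mu_hat, fe$mu_hat, tolerance = 1e-12)
  expect_equal(re$se_mu, fe$se_mu, tolerance = 1e-12)
  # heterogeneous data: RE interval at least as wide as FE
  set.seed(31)
  y <- rnorm(8, -0.4, 0.5); se <- runif(8, 0.15, 0.4)
  d <- make_ds(y, se)
  expect_gte(meta_random(d)$se_mu, meta_fixed(d)$se_mu)
  # hand-built K = 3 check with DL weights
  y3 <- c(-0.3, -0.8, 0.2); se3 <- c(0.25, 0.5, 0.4)
  d3 <- make_ds(y3, se3)
  t2 <- tau2_dl(d3)
  w <- 1 / (se3^2 + t2)
  re3 <- meta_random(d3, tau2_method = "DL")
  expect_equal(re3$mu_hat, sum(w * y3) / sum(w), tolerance = 1e-12)
  expect_equal(re3$se_mu, 1 / sqrt(sum(w)), tolerance = 1e-12)
  expect_warning(meta_random(make_ds(0.3, 0.2)), "single study")
})

test_that("negating all effects flips the estimate but not the uncertainty", {
  set.seed(41)
  y <- rnorm(5, -0.4, 0.4); se <- runif(5, 0.2, 0.5)
  a <- meta_random(make_ds(y, se))
  b <- meta_random(make_ds(-y, se))
  expect_equal(b$mu_hat, -a$mu_hat, tolerance = 1e-12)
  expect_equal(b$z, -a$z, tolerance = 1e-12)
  expect_identical(b$se_mu, a$se_mu)
  expect_identical(b$p, a$p)
  expect_identical(b$Q, a$Q)
  expect_identical(b$tau2, a$tau2)
  expect_identical(b$I2, a$I2)
})

test_that("the pseudo likelihood ratio is (1-p)/p on (0,1) only", {
  expect_equal(pseudo_lr(0.005), 199)
  expect_equal(pseudo_lr(0.5), 1)
  expect_equal(pseudo_lr(0.0005), 1999)
  expect_error(pseudo_lr(0))
  expect_error(pseudo_lr(1))
  expect_error(pseudo_lr(-0.1))
})
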