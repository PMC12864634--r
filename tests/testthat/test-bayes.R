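test_that("fixed-effect null marginal is the closed-form likelihood at zero", {
  m1 <- model_marginals(make_ds(0, 1))
  expect_equal(m1$logml[["fe0"]], log(1 / sqrt(2 * pi)), tolerance = 1e-12)
  m2 <- model_marginals(make_ds(1, 1))
  expect_equal(m2$logml[["fe0"]], log(1 / sqrt(2 * pi)) - 0.5,
               tolerance = 1e-12)
  # K = 4: independence means the per-study closed forms add
  y <- c(-0.2, 0.5, 0.1, -0.7); se <- c(0.3, 0.4, 0.2, 0.5)
  m4 <- model_marginals(make_ds(y, se))
  expect_equal(m4$logml[["fe0"]], sum(dnorm(y, 0, se, log = TRUE)),
               tolerance = 1e-12)
})

test_that("quadrature marginals match dense brute-force oracles", {
  prior <- prior_spec()
  # single study at the null
  d1 <- make_ds(0, 1)
  m1 <- model_marginals(d1, prior)
  expect_equal(m1$logml[["fe1"]], riemann_fe_alt(0, 1, prior),
               tolerance = 1e-6)
  expect_equal(m1$logml[["re0"]], riemann_re_null(0, 1, prior),
               tolerance = 1e-6)
  # K = 3 off-null dataset
  y <- c(-0.55, -0.2, -0.8); se <- c(0.25, 0.35, 0.3)
  m3 <- model_marginals(make_ds(y, se), prior)
  expect_equal(m3$logml[["fe1"]], riemann_fe_alt(y, se, prior),
               tolerance = 1e-5)
  expect_equal(m3$logml[["re0"]], riemann_re_null(y, se, prior),
               tolerance = 1e-5)
  # K = 2 for the 2-D integral
  y2 <- c(-0.6, -0.1); se2 <- c(0.3, 0.4)
  m2 <- model_marginals(make_ds(y2, se2), prior)
  expect_equal(m2$logml[["re1"]], grid_re_alt(y2, se2, prior),
               tolerance = 1e-5)
})

test_that("marginals respect the priors' symmetry and limiting behaviour", {
  prior <- prior_spec()
  y <- c(-0.5, 0.2, -0.9); se <- c(0.3, 0.25, 0.4)
  pos <- model_marginals(make_ds(y, se), prior)
  neg <- model_marginals(make_ds(-y, se), prior)
  for (m in c("fe1", "re0", "re1")) {
    expect_equal(neg$logml[[m]], pos$logml[[m]], tolerance = 1e-8)
  }
  # dominated-variance limit: huge within-study SEs make tau irrelevant
  big <- make_ds(c(-0.5, 0.2), c(100, 100))
  mb <- model_marginals(big, prior)
  expect_equal(mb$logml[["re0"]], mb$logml[["fe0"]], tolerance = 1e-3)
  # tau prior collapsing to zero turns re1 into fe1; the near-degenerate
  # integrand is allowed to exhaust refinement with a warning
  tiny_tau <- prior_spec(tau_scale = 1e-6)
  mt <- suppressWarnings(model_marginals(make_ds(y, se), tiny_tau))
  expect_equal(mt$logml[["re1"]], mt$logml[["fe1"]], tolerance = 1e-3)
})

test_that("model averaging combines marginals with the stated arithmetic", {
  eq <- structure(list(logml = c(fe0 = -3, fe1 = -3, re0 = -3, re1 = -3)),
                  class = "model_marginals")
  avg <- model_average(eq)
  expect_equal(avg$bf10, 1, tolerance = 1e-12)
  expect_equal(avg$bf_rf, 1, tolerance = 1e-12)
  expect_equal(unname(avg$post_model_probs), rep(0.25, 4))
  # hand-set marginals m = (1, 2, 3, 4) for (fe0, fe1, re0, re1)
  hand <- structure(list(logml = c(fe0 = log(1), fe1 = log(2),
                                   re0 = log(3), re1 = log(4))),
                    class = "model_marginals")
  avg2 <- model_average(hand)
  expect_equal(avg2$bf10, 6 / 4, tolerance = 1e-12)
  expect_equal(avg2$bf_rf, 7 / 3, tolerance = 1e-12)
  expect_equal(sum(avg2$post_model_probs), 1, tolerance = 1e-12)
  # swapping the hypothesis labels inverts the Bayes factor exactly
  swapped <- structure(list(logml = c(fe0 = log(2), fe1 = log(1),
                                      re0 = log(4), re1 = log(3))),
                       class = "model_marginals")
  expect_equal(model_average(swapped)$bf10 * avg2$bf10, 1,
               tolerance = 1e-10)
  expect_error(model_average(hand, prior_spec(model_prior = c(0.5, 0.5, 0, 0))),
               "zero mass")
})

test_that("the model-averaged posterior is a proper, well-centred density", {
  # single study at the null: median at 0 by symmetry
  p1 <- posterior_mu(make_ds(0, 1))
  expect_lt(abs(p1$mu_median), 1e-6)
  f <- p1$density
  trapz <- sum((f[-1] + f[-length(f)]) / 2 * diff(p1$grid))
  expect_equal(trapz, 1, tolerance = 1e-6)
  expect_lt(p1$cri_low, p1$mu_median)
  expect_gt(p1$cri_high, p1$mu_median)
  # precise, homogeneous studies: posterior concentrates at the common
  # value (the razor-thin likelihood may exhaust refinement of the re0
  # integral, which this summary does not use)
  p2 <- suppressWarnings(posterior_mu(make_ds(rep(-0.5, 3), rep(1e-3, 3))))
  expect_equal(p2$mu_mean, -0.5, tolerance = 1e-4)
  expect_lt(p2$cri_high - p2$cri_low, 0.01)
})

test_that("negating the data negates the posterior and preserves evidence", {
  y <- c(-0.5, -0.1, -0.8); se <- c(0.3, 0.35, 0.25)
  a <- meta_bayes(make_ds(y, se), shrinkage = FALSE)
  b <- meta_bayes(make_ds(-y, se), shrinkage = FALSE)
  expect_equal(b$bf10, a$bf10, tolerance = 1e-8)
  expect_equal(b$bf_rf, a$bf_rf, tolerance = 1e-8)
  expect_equal(b$mu_mean, -a$mu_mean, tolerance = 1e-8)
  expect_equal(b$cri_high - b$cri_low, a$cri_high - a$cri_low,
               tolerance = 1e-8)
})

test_that("shrinkage pulls every study toward the pooled mean", {
  y <- c(-1.1, 0.3, -0.5, -0.2); se <- c(0.45, 0.5, 0.3, 0.6)
  d <- make_ds(y, se)
  b <- meta_bayes(d)
  shr <- b$shrinkage
  mu_star <- b$posterior$components$re1$mean
  expect_true(all(abs(shr$theta_mean - mu_star) <= abs(y - mu_star) + 1e-10))
  expect_true(all(shr$cri_low < shr$theta_mean))
  expect_true(all(shr$cri_high > shr$theta_mean))
  # an uninformative study collapses onto the pooled posterior
  d2 <- make_ds(c(-0.5, -0.4, 2), c(0.2, 0.25, 100))
  shr2 <- shrinkage_estimates(d2)
  p2 <- posterior_mu(d2)
  expect_lt(abs(shr2$theta_mean[3] - p2$components$re1$mean), 0.01)
  # K = 2: agreement with the dense 2-D grid oracle
  y2 <- c(-0.7, 0.1); se2 <- c(0.3, 0.4)
  shr3 <- shrinkage_estimates(make_ds(y2, se2))
  for (i in 1:2) {
    expect_equal(shr3$theta_mean[i], grid_shrinkage_mean(y2, se2, i),
                 tolerance = 1e-4)
  }
})

test_that("Savage-Dickey density ratio agrees with the marginal-likelihood identity", {
  prior <- prior_spec()
  expect_equal(savage_dickey_bf_fe(make_ds(0, 1), prior)$prior_at_0,
               1 / (pi * 0.707), tolerance = 1e-12)
  # data at the null favour the null
  expect_gt(savage_dickey_bf_fe(make_ds(0, 1), prior)$bf01, 1)
  for (d in list(make_ds(0, 1),
                 make_ds(c(-0.55, -0.2, -0.8), c(0.25, 0.35, 0.3)),
                 make_ds(c(0.9, 0.4), c(0.2, 0.5)))) {
    m <- model_marginals(d, prior)
    expect_equal(savage_dickey_bf_fe(d, prior)$bf01,
                 exp(m$logml[["fe0"]] - m$logml[["fe1"]]),
                 tolerance = 1e-6)
  }
})

test_that("Bayes factors fold into a plain-language reading", {
  r <- interpret_bf(0.681)
  expect_identical(r$direction, "H0")
  expect_equal(r$ratio, 1 / 0.681, tolerance = 1e-12)
  expect_identical(interpret_bf(1)$direction, "equivocal")
  r2 <- interpret_bf(18.93)
  expect_identical(r2$direction, "H1")
  expect_equal(r2$ratio, 18.93)
  expect_error(interpret_bf(0))
  expect_error(interpret_bf(-2))
})

test_that("hpd intervals are no wider than equal-tailed ones", {
  d <- make_ds(c(-0.6, -0.3, -0.9), c(0.3, 0.4, 0.35))
  central <- posterior_mu(d, cri_method = "central")
  hpd <- posterior_mu(d, cri_method = "hpd")
  expect_lte(hpd$cri_high - hpd$cri_low,
             central$cri_high - central$cri_low + 1e-3)
})
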