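test_that("threshold conversion matches the closed form", {
  # f_thresh = f_half + log(q/(1-q)) / beta
  expect_equal(threshold_from_midpoint(0, 1), log(1 / 99), tolerance = 1e-12)
  expect_equal(threshold_from_midpoint(0.3, 2), 0.3 + log(1 / 99) / 2,
    tolerance = 1e-12
  )
  # q_thresh = 0.5 collapses threshold onto the midpoint
  expect_equal(threshold_from_midpoint(0.7, 3, q_thresh = 0.5), 0.7)
  # round trip
  expect_equal(
    midpoint_from_threshold(threshold_from_midpoint(0.2, 5), 5), 0.2
  )
  # beta = 0 undefined
  expect_true(is.na(threshold_from_midpoint(0, 0)))
})

test_that("mean rate has the right symmetries and limits", {
  # symmetric density + midpoint at 0 gives mu = 0.5 at any slope
  for (b in c(0.5, 2, 20)) {
    expect_equal(mean_rate(b, threshold_from_midpoint(0, b)), 0.5,
      tolerance = 1e-9
    )
  }
  expect_equal(mean_rate(0, 3), 0.5)
  # step-function limit: mu = Phi(-f_half) (Gaussian tail oracle)
  expect_equal(mean_rate(Inf, 1.2816), pnorm(-1.2816), tolerance = 1e-12)
  # large finite slope approaches the step limit
  expect_equal(mean_rate(1e4, 1.2816), pnorm(-1.2816), tolerance = 1e-3)
})

test_that("quadrature mean rate and correlation match Monte Carlo", {
  grid <- expand.grid(beta = c(0.5, 2, 8), f_thresh = c(-2, 0, 1))
  for (i in seq_len(nrow(grid))) {
    b <- grid$beta[i]; th <- grid$f_thresh[i]
    mc <- mc_rate_corr(b, th, n = 1e6, seed = 100 + i)
    expect_lt(abs(mean_rate(b, th) - mc$mu), 4 * mc$se_mu)
    expect_lt(
      abs(pair_correlation(b, th) - mc$corr),
      4 * mc$se_corr + 1e-4
    )
  }
})

test_that("pair correlation has the stated trivial values", {
  expect_equal(pair_correlation(0, 1), 0)
  # step pair at any rate is perfectly correlated: E[q^2] = mu
  for (mu in c(0.1, 0.3, 0.5)) {
    expect_equal(pair_correlation(Inf, qnorm(1 - mu)), 1, tolerance = 1e-9)
  }
  # saturated pairs flagged undefined, reported 0
  expect_equal(pair_correlation(5, -50), 0)
  expect_false(corr_defined(5, -50))
  expect_true(corr_defined(5, -1))
})

test_that("fixed-rate contour is correct and correlation grows with slope", {
  bg <- c(0.1, 0.5, 2, 8, 30)
  ct <- rate_contour(0.1, bg)
  expect_true(all(ct$converged))
  expect_equal(ct$mean_rate, rep(0.1, 5), tolerance = 1e-8)
  # mu = 0.5 contour: midpoint 0 for every slope, so f_thresh = log(1/99)/b
  ct5 <- rate_contour(0.5, bg)
  expect_equal(ct5$f_half, rep(0, 5), tolerance = 1e-7)
  expect_equal(ct5$f_thresh, log(1 / 99) / bg, tolerance = 1e-6)
  # correlation is monotone non-decreasing in slope along the contour
  expect_true(all(diff(ct$corr) > 0))
  # and approaches 1 in the steep limit
  expect_gt(rate_contour(0.1, 500)$corr, 0.98)
})

test_that("mean rate decreases in threshold; contour spans low and high corr", {
  th <- seq(-3, 3, by = 0.5)
  mu <- mean_rate(rep(2, length(th)), th)
  expect_true(all(diff(mu) < 0))
  ct <- rate_contour(0.1, exp(seq(log(0.1), log(50), length.out = 12)))
  expect_lt(min(ct$corr), 0.01)
  expect_gt(max(ct$corr), 0.4)
})

test_that("local sensitivity matches the analytic derivative integrand", {
  # dmu/dtheta = -beta * E_f[q(1-q)] in the (slope, threshold) parameterization
  b <- 2; th <- -1; L <- log(0.01 / 0.99)
  integrand <- function(f) {
    q <- plogis(b * (f - th) + L)
    -b * q * (1 - q) * dnorm(f)
  }
  analytic <- integrate(integrand, -12, 12, rel.tol = 1e-12)$value
  sens <- local_sensitivity(b, th)
  est <- sens$estimate[sens$response == "mean_rate" & sens$wrt == "f_thresh"]
  expect_equal(est, analytic, tolerance = 1e-5)
})

test_that("sensitivity signs match the rate/correlation maps in the data regime", {
  # sub-saturation points (mu < 0.5), the regime of the recorded populations:
  # steeper slope or lower threshold raises both rate and correlation
  pts <- list(c(1, -1.5), c(2, -0.5), c(4, 0.5), c(8, 0.5))
  for (pt in pts) {
    b <- pt[1]; th <- pt[2]
    expect_lt(mean_rate(b, th), 0.5)
    {
      s <- local_sensitivity(b, th)
      expect_gt(s$estimate[s$response == "mean_rate" & s$wrt == "beta"], 0)
      expect_lt(s$estimate[s$response == "mean_rate" & s$wrt == "f_thresh"], 0)
      expect_gt(s$estimate[s$response == "corr" & s$wrt == "beta"], 0)
      expect_lt(s$estimate[s$response == "corr" & s$wrt == "f_thresh"], 0)
    }
  }
})

test_that("central differences converge at second order in the step", {
  b <- 2; th <- -1
  d1 <- local_sensitivity(b, th, h = 2e-3)
  d2 <- local_sensitivity(b, th, h = 1e-3)
  d0 <- local_sensitivity(b, th, h = 1e-5) # near-exact reference
  err1 <- abs(d1$estimate - d0$estimate)
  err2 <- abs(d2$estimate - d0$estimate)
  # halving h should shrink the error by ~4; allow slack for roundoff
  expect_true(all(err2 <= err1 / 2 + 1e-10))
  # downward step crossing beta <= 0 falls back to one-sided, flagged
  s <- local_sensitivity(1e-4, 0, h = 1)
  expect_true(any(s$one_sided))
})

test_that("params_for_stats inverts the rate/correlation map", {
  sol <- params_for_stats(0.2, 0.3)
  expect_equal(sol$mean_rate, 0.2, tolerance = 1e-7)
  expect_equal(sol$corr, 0.3, tolerance = 1e-7)
})
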