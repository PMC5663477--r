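test_that("two independent fair coins are fit and scored exactly", {
  set.seed(2)
  ras <- matrix(rbinom(2 * 20000, 1, 0.5), 2)
  m <- fit_poptrack(ras)
  expect_equal(m$p_k, c(0.25, 0.5, 0.25), tolerance = 0.02)
  expect_equal(m$p_cond[, 2], c(0.5, 0.5), tolerance = 0.03)
  # entropy of the ideal model is exactly 2 bits
  ideal <- poptrack_model(c(0.25, 0.5, 0.25), cbind(c(0, 0), c(0.5, 0.5), c(1, 1)))
  expect_equal(entropy_estimate(ideal)$h_bits, 2, tolerance = 1e-12)
  expect_equal(entropy_estimate(ideal, "enumeration")$h_bits, 2,
    tolerance = 1e-12
  )
})

test_that("an all-silent raster concentrates the synchrony distribution at zero", {
  m <- fit_poptrack(matrix(0L, 5, 100))
  expect_gt(m$p_k[1], 0.9)
  expect_equal(which.max(m$p_k), 1)
  expect_lt(entropy_estimate(m)$h_per_neuron, 0.1)
})

test_that("refitting data sampled from a known model recovers it", {
  set.seed(7)
  ras <- sample_raster(ground_truth_spec(pp_moderate(), 8, 4000, seed = 3))
  truth <- fit_poptrack(ras$binary)
  draws <- sample_poptrack(truth, 8000, seed = 11)
  refit <- fit_poptrack(t(draws))
  expect_equal(refit$p_k, truth$p_k, tolerance = 0.03)
  mid <- 2:8 # count classes with data
  expect_equal(refit$p_cond[, mid], truth$p_cond[, mid], tolerance = 0.12)
})

test_that("pattern probabilities are a distribution with the stated symmetries", {
  # homogeneous conditionals: every count-k pattern has probability p_k/C(N,k)
  N <- 6
  p_k <- c(0.1, 0.2, 0.25, 0.2, 0.15, 0.07, 0.03)
  hom <- poptrack_model(p_k, outer(rep(1, N), 0:N) / N)
  pats <- as.matrix(expand.grid(rep(list(0:1), N)))
  lp <- pattern_logprob(hom, pats)
  k <- rowSums(pats)
  expect_equal(2^lp, p_k[k + 1] / choose(N, k), tolerance = 1e-9)
  # probabilities over all patterns sum to 1 (heterogeneous model too)
  set.seed(5)
  ras <- matrix(rbinom(8 * 3000, 1, runif(8, 0.1, 0.6)), 8)
  het <- fit_poptrack(ras)
  pats8 <- as.matrix(expand.grid(rep(list(0:1), 8)))
  expect_equal(sum(2^pattern_logprob(het, pats8)), 1, tolerance = 1e-9)
  # a count with zero synchrony mass is floored
  m0 <- poptrack_model(c(0.5, 0.5, 0), cbind(c(0, 0), c(0.5, 0.5), c(1, 1)))
  expect_equal(pattern_logprob(m0, c(1, 1)), -1074)
})

test_that("analytic, enumeration, and sampling entropies agree", {
  set.seed(9)
  ras <- sample_raster(ground_truth_spec(pp_moderate(), 10, 3000, seed = 5))
  m <- fit_poptrack(ras$binary)
  ana <- entropy_estimate(m)
  enu <- entropy_estimate(m, "enumeration")
  sam <- entropy_estimate(m, "sampling", n_samples = 4000, seed = 2)
  expect_equal(ana$h_bits, enu$h_bits, tolerance = 1e-9)
  expect_lt(abs(sam$h_bits - enu$h_bits), 3 * sam$se)
  # entropy is invariant to neuron relabeling
  perm <- c(3, 1, 2, 5, 4, 7, 6, 10, 9, 8)
  mp <- poptrack_model(m$p_k, m$p_cond[perm, ])
  expect_equal(entropy_estimate(mp)$h_bits, ana$h_bits, tolerance = 1e-9)
})

test_that("independent neurons give additive entropy; deterministic model zero", {
  # model built from independent non-identical Bernoulli neurons
  # the count-conditioned weight family represents independence exactly when
  # every column carries the same odds ratios as the marginal probabilities
  # (the logit-shift renormalization preserves them)
  p <- c(0.1, 0.25, 0.4, 0.6, 0.3)
  N <- 5
  pk <- popcircuit:::pb_dist(p)
  m <- poptrack_model(pk, matrix(p, N, N + 1))
  bern_h <- sum(-p * log2(p) - (1 - p) * log2(1 - p))
  expect_equal(entropy_estimate(m)$h_bits, bern_h, tolerance = 1e-9)
  expect_equal(entropy_estimate(m, "enumeration")$h_bits, bern_h,
    tolerance = 1e-9
  )
  # single-pattern model has zero entropy
  det <- poptrack_model(c(0, 0, 1), cbind(c(0, 0), c(0.5, 0.5), c(1, 1)))
  expect_equal(entropy_estimate(det)$h_bits, 0)
})

test_that("entropy per neuron stays within [0, 1] bits across regimes", {
  set.seed(31)
  for (rate in c(0.05, 0.5)) {
    for (nn in c(12, 40)) {
      ras <- matrix(rbinom(nn * 800, 1, rate), nn)
      h <- entropy_estimate(fit_poptrack(ras))$h_per_neuron
      expect_gte(h, 0)
      expect_lte(h, 1)
    }
  }
})

test_that("cumulative mass curves are exact for small N and honest for large N", {
  det <- poptrack_model(c(0, 0, 1), cbind(c(0, 0), c(0.5, 0.5), c(1, 1)))
  cm <- cumulative_mass_curve(det)
  expect_equal(cm$cum_prob[1], 1)
  # uniform model over C(4,2) count-2 patterns is linear in rank
  unif <- poptrack_model(
    c(0, 0, 1, 0, 0), outer(rep(1, 4), 0:4) / 4
  )
  cmu <- cumulative_mass_curve(unif)
  nz <- cmu$log2_prob > -50
  expect_equal(sum(nz), 6)
  expect_equal(cmu$cum_prob[nz], (1:6) / 6, tolerance = 1e-9)
  # sampled curve agrees with the exact one at shared ranks
  set.seed(3)
  ras <- matrix(rbinom(10 * 2000, 1, 0.3), 10)
  m <- fit_poptrack(ras)
  exact <- cumulative_mass_curve(m)
  approx <- cumulative_mass_curve(m, n_samples = 5000, seed = 8, exact = FALSE)
  expect_false(approx$exact[1])
  expect_lte(max(approx$coverage), 1 + 1e-9)
  k <- min(20, nrow(approx))
  expect_equal(approx$log2_prob[1:k], exact$log2_prob[1:k], tolerance = 1e-6)
})

test_that("entropy vs population size behaves as theory predicts", {
  set.seed(17)
  # independent identical neurons: H/N flat, h100 near single-neuron entropy
  p <- 0.2
  ind <- matrix(rbinom(60 * 3000, 1, p), 60)
  ec <- entropy_vs_N(ind, sizes = seq(10, 60, by = 10), n_subsets = 6,
    seed = 2
  )
  h1 <- -p * log2(p) - (1 - p) * log2(1 - p)
  expect_lt(max(ec$by_size$h_per_neuron) - min(ec$by_size$h_per_neuron), 0.06)
  expect_equal(ec$h100, h1, tolerance = 0.08)

  # correlated raster: H/N decreases with N
  cor_ras <- sample_raster(
    ground_truth_spec(pp_moderate(), 60, 3000, seed = 23)
  )$binary
  ec2 <- entropy_vs_N(cor_ras, sizes = seq(10, 60, by = 10), n_subsets = 6,
    seed = 3
  )
  h <- ec2$by_size$h_per_neuron
  expect_lt(h[length(h)], h[1])
  expect_true(all(diff(h) < 0.02))
})

test_that("double-exponential size-curve fit recovers a noiseless ground truth", {
  truth <- c(A = 0.3, b = 0.08, C = 0.15, d = 0.01, e = 0.35)
  sizes <- seq(10, 100, by = 10)
  h <- truth[["A"]] * exp(-truth[["b"]] * sizes) +
    truth[["C"]] * exp(-truth[["d"]] * sizes) + truth[["e"]]
  fit <- fit_double_exponential(sizes, h)
  expect_true(fit$converged)
  h100_hat <- fit$coef[["A"]] * exp(-fit$coef[["b"]] * 100) +
    fit$coef[["C"]] * exp(-fit$coef[["d"]] * 100) + fit$coef[["e"]]
  h100_true <- truth[["A"]] * exp(-truth[["b"]] * 100) +
    truth[["C"]] * exp(-truth[["d"]] * 100) + truth[["e"]]
  expect_equal(h100_hat, h100_true, tolerance = 1e-6)
  # small noise: recovery within a noise-propagated tolerance
  set.seed(4)
  fitn <- fit_double_exponential(sizes, h + rnorm(10, 0, 0.002))
  h100_n <- fitn$coef[["A"]] * exp(-fitn$coef[["b"]] * 100) +
    fitn$coef[["C"]] * exp(-fitn$coef[["d"]] * 100) + fitn$coef[["e"]]
  expect_equal(h100_n, h100_true, tolerance = 0.02)
})

test_that("probabilistic rasters: Bernoulli draws agree with the exact synchrony path", {
  set.seed(41)
  ras <- sample_raster(ground_truth_spec(pp_moderate(), 15, 1500, seed = 19))
  m_draw <- fit_poptrack(ras$p_on, n_draws = 40, seed = 3)
  m_exact <- fit_poptrack(ras$p_on, n_draws = 40, seed = 3,
    pk_method = "exact"
  )
  # both synchrony distributions estimate the same Poisson-binomial mixture
  expect_equal(m_draw$p_k, m_exact$p_k, tolerance = 0.02)
  expect_equal(
    entropy_estimate(m_draw)$h_per_neuron,
    entropy_estimate(m_exact)$h_per_neuron,
    tolerance = 0.05
  )
  # seeded draws are reproducible
  m_draw2 <- fit_poptrack(ras$p_on, n_draws = 40, seed = 3)
  expect_identical(m_draw$p_k, m_draw2$p_k)
})
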