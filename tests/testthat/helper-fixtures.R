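# shared fixtures: small, fast parameter sets used across test files

pp_moderate <- function() {
  pop_params(
    mu_thresh = -1.5, mu_slope = 3, sd_thresh = 0.5, sd_slope = 0.8,
    rho = 0.3
  )
}

pp_sparse <- function() {
  pop_params(
    mu_thresh = -1.8, mu_slope = 4, sd_thresh = 0.3, sd_slope = 0.5, rho = 0
  )
}

# tiny circuit for fast simulator tests
tiny_params <- function(...) circuit_params(scale = 0.1, ...)

# Monte-Carlo estimate of (mu, corr) for a homogeneous logistic pair
mc_rate_corr <- function(beta, f_thresh, n = 1e6, seed = 1,
                         q_thresh = 0.01) {
  set.seed(seed)
  f <- stats::rnorm(n)
  L <- log(q_thresh / (1 - q_thresh))
  q <- stats::plogis(beta * (f - f_thresh) + L)
  mu <- mean(q)
  v <- mu * (1 - mu)
  list(
    mu = mu, se_mu = stats::sd(q) / sqrt(n),
    corr = (mean(q^2) - mu^2) / v,
    se_corr = stats::sd((q - mu)^2 / v) / sqrt(n)
  )
}
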