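#' Logistic spike-probability function
#'
#' Probability that a neuron fires at least one spike given an input drive
#' `f`, under the two-parameter logistic input-output model
#' \deqn{q(f) = 1 / (1 + \exp(-\beta (f - f_{1/2})))}
#' where `beta` is the slope and `f_half` the input level at which the
#' response probability is 0.5.
#'
#' @param f Numeric vector of input drive values.
#' @param beta Slope (non-negative). `beta = Inf` gives a hard step at
#'   `f_half`; `beta = 0` gives a constant 0.5.
#' @param f_half Input level of half-maximal response.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
#' @examples
#' logistic_prob(0, beta = 2, f_half = 0)
logistic_prob <- function(f, beta, f_half) {
  if (any(beta < 0, na.rm = TRUE)) stop("`beta` must be non-negative", call. = FALSE)
  out <- stats::plogis(beta * (f - f_half))
  step <- is.infinite(beta) & (f == f_half) # plogis gives NaN at Inf * 0
  out[step] <- 0.5
  out
}

#' Convert between the logistic midpoint and the response threshold
#'
#' The threshold is defined as the input level at which the response
#' probability equals `q_thresh` (0.01 throughout unless overridden):
#' \deqn{f_{thresh} = f_{1/2} + \log(q_{thresh} / (1 - q_{thresh})) / \beta}
#'
#' @param f_half Midpoint of the logistic (q = 0.5).
#' @param beta Slope, strictly positive (finite threshold requires beta > 0).
#' @param q_thresh Response probability defining the threshold, in (0, 0.5].
#' @return Threshold `f_thresh` (or midpoint, for the inverse). `beta = 0`
#'   returns `NA` (undefined); `beta = Inf` returns `f_half`.
#' @export
threshold_from_midpoint <- function(f_half, beta, q_thresh = 0.01) {
  stopifnot(q_thresh > 0, q_thresh <= 0.5)
  L <- log(q_thresh / (1 - q_thresh))
  out <- f_half + L / beta
  out[beta == 0] <- NA_real_
  out[is.infinite(beta)] <- (f_half + 0 * beta)[is.infinite(beta)]
  out
}

#' @rdname threshold_from_midpoint
#' @param f_thresh Threshold value to convert back to a midpoint.
#' @export
midpoint_from_threshold <- function(f_thresh, beta, q_thresh = 0.01) {
  stopifnot(q_thresh > 0, q_thresh <= 0.5)
  L <- log(q_thresh / (1 - q_thresh))
  out <- f_thresh - L / beta
  out[beta == 0] <- NA_real_
  out[is.infinite(beta)] <- (f_thresh + 0 * beta)[is.infinite(beta)]
  out
}

# q as a function of drive in the (slope, threshold) parameterization:
# q(f) = plogis(beta * (f - theta) + L), L = log(q_thresh / (1 - q_thresh)).
q_of_f <- function(f, beta, f_thresh, q_thresh = 0.01) {
  L <- log(q_thresh / (1 - q_thresh))
  if (is.infinite(beta)) {
    # step at the midpoint (threshold and midpoint coincide in the limit)
    return(as.numeric(f > f_thresh) + 0.5 * (f == f_thresh))
  }
  if (beta == 0) return(rep(0.5, length(f)))
  stats::plogis(beta * (f - f_thresh) + L)
}

#' Mean firing probability under a standard-normal input drive
#'
#' Expectation of the logistic response over the input distribution
#' \eqn{f \sim N(0, 1)}: \eqn{\mu = \int q(f) \phi(f) df}, computed by
#' adaptive quadrature to absolute accuracy ~1e-10. Vectorized over
#' parameters.
#'
#' @param beta Slope(s), non-negative (`Inf` allowed: hard threshold unit).
#' @param f_thresh Threshold(s) on the standard-normal drive scale.
#' @param q_thresh Probability defining the threshold (default 0.01).
#' @return Mean rate(s) in `[0, 1]` (per-bin ON probability).
#' @export
#' @examples
#' mean_rate(beta = 2, f_thresh = -1)
mean_rate <- function(beta, f_thresh, q_thresh = 0.01) {
  n <- max(length(beta), length(f_thresh))
  beta <- rep_len(beta, n); f_thresh <- rep_len(f_thresh, n)
  vapply(seq_len(n), function(i) {
    b <- beta[i]; th <- f_thresh[i]
    if (b == 0) return(0.5)
    if (is.infinite(b)) return(stats::pnorm(-th))
    fh <- midpoint_from_threshold(th, b, q_thresh)
    drive_expectation(function(f) q_of_f(f, b, th, q_thresh), center = fh)
  }, numeric(1))
}

# E[ g(f) ] for f ~ N(0,1) by adaptive quadrature, split at `center` so that
# steep sigmoids (large beta) are resolved.
drive_expectation <- function(g, center = 0) {
  integrand <- function(f) g(f) * stats::dnorm(f)
  lo <- min(-10, center - 2); hi <- max(10, center + 2)
  cuts <- sort(unique(pmin(pmax(c(lo, center - 1e-3, center, center + 1e-3, hi), lo), hi)))
  tot <- 0
  for (j in seq_len(length(cuts) - 1L)) {
    tot <- tot + stats::integrate(integrand, cuts[j], cuts[j + 1L],
      rel.tol = 1e-11, abs.tol = 1e-12, subdivisions = 400L
    )$value
  }
  tot
}

#' Pairwise correlation of two logistic neurons sharing a common drive
#'
#' Two neurons with logistic parameters (`beta_a`, `f_thresh_a`) and
#' (`beta_b`, `f_thresh_b`) share the same standard-normal drive `f` and spike
#' conditionally independently given their probabilities. The covariance of
#' their binary outputs is \eqn{cov = E_f[q_a q_b] - \mu_a \mu_b} and the
#' correlation normalizes by the Bernoulli standard deviations
#' \eqn{\sqrt{\mu_a(1-\mu_a)\,\mu_b(1-\mu_b)}}.
#'
#' Saturated neurons (mu of 0 or 1) have zero variance; the correlation is
#' then undefined and reported as 0 (check [corr_defined()] where the
#' distinction matters).
#'
#' @param beta_a,f_thresh_a Parameters of the first neuron.
#' @param beta_b,f_thresh_b Parameters of the second neuron (defaults make a
#'   homogeneous pair).
#' @param q_thresh Probability defining the threshold (default 0.01).
#' @return Correlation in `[-1, 1]` (non-negative for homogeneous pairs).
#' @export
pair_correlation <- function(beta_a, f_thresh_a, beta_b = beta_a,
                             f_thresh_b = f_thresh_a, q_thresh = 0.01) {
  n <- max(length(beta_a), length(f_thresh_a), length(beta_b), length(f_thresh_b))
  beta_a <- rep_len(beta_a, n); f_thresh_a <- rep_len(f_thresh_a, n)
  beta_b <- rep_len(beta_b, n); f_thresh_b <- rep_len(f_thresh_b, n)
  vapply(seq_len(n), function(i) {
    pair_corr_one(beta_a[i], f_thresh_a[i], beta_b[i], f_thresh_b[i], q_thresh)
  }, numeric(1))
}

pair_corr_one <- function(ba, tha, bb, thb, q_thresh = 0.01) {
  mu_a <- mean_rate(ba, tha, q_thresh)
  mu_b <- mean_rate(bb, thb, q_thresh)
  va <- mu_a * (1 - mu_a); vb <- mu_b * (1 - mu_b)
  if (va <= 0 || vb <= 0) return(0)
  if (ba == 0 || bb == 0) return(0) # a constant q carries no shared signal
  fh <- midpoint_from_threshold(c(tha, thb), c(ba, bb), q_thresh)
  fh <- fh[is.finite(fh)]
  center <- if (length(fh)) mean(fh) else 0
  Eqq <- drive_expectation(
    function(f) q_of_f(f, ba, tha, q_thresh) * q_of_f(f, bb, thb, q_thresh),
    center = center
  )
  r <- (Eqq - mu_a * mu_b) / sqrt(va * vb)
  min(max(r, -1), 1) # guard quadrature overshoot at perfect correlation
}

#' @rdname pair_correlation
#' @return `corr_defined()`: logical, `FALSE` where either neuron is
#'   saturated or has zero slope so the correlation is undefined.
#' @export
corr_defined <- function(beta_a, f_thresh_a, beta_b = beta_a,
                         f_thresh_b = f_thresh_a, q_thresh = 0.01) {
  mu_a <- mean_rate(beta_a, f_thresh_a, q_thresh)
  mu_b <- mean_rate(beta_b, f_thresh_b, q_thresh)
  mu_a > 0 & mu_a < 1 & mu_b > 0 & mu_b < 1 & beta_a > 0 & beta_b > 0
}

#' Slope-threshold map of firing rate and correlation
#'
#' Evaluates the mean firing probability and the homogeneous-pair correlation
#' over a grid of logistic slope and threshold values, for phase-plane style
#' maps of the model's activity statistics.
#'
#' @param beta_grid Numeric vector of slopes.
#' @param thresh_grid Numeric vector of thresholds.
#' @param q_thresh Probability defining the threshold (default 0.01).
#' @return A tibble with columns `beta`, `f_thresh`, `mean_rate`, `corr`.
#' @export
rate_corr_map <- function(beta_grid, thresh_grid, q_thresh = 0.01) {
  grid <- tidyr::expand_grid(beta = beta_grid, f_thresh = thresh_grid)
  grid$mean_rate <- mean_rate(grid$beta, grid$f_thresh, q_thresh)
  grid$corr <- pair_correlation(grid$beta, grid$f_thresh, q_thresh = q_thresh)
  grid
}

#' Fixed firing-rate contour in slope-threshold space
#'
#' For each slope in `beta_grid`, solves for the threshold at which the mean
#' firing probability equals `target_mu` (bracketed root-finding, tolerance
#' ~1e-10 in mu), and evaluates the homogeneous-pair correlation at that
#' point. Along such a contour the firing rate is constant while the
#' correlation varies, so the contour exposes activity changes invisible to
#' rate alone.
#'
#' @param target_mu Target mean firing probability, in (0, 1).
#' @param beta_grid Positive slopes, typically log-spaced.
#' @param q_thresh Probability defining the threshold (default 0.01).
#' @return A tibble with columns `beta`, `f_thresh`, `f_half`, `mean_rate`,
#'   `corr`, and `converged` (root-finding status per grid point).
#' @export
#' @examples
#' rate_contour(0.1, beta_grid = c(0.5, 2, 8))
rate_contour <- function(target_mu, beta_grid, q_thresh = 0.01) {
  stopifnot(target_mu > 0, target_mu < 1, all(beta_grid > 0))
  beta_grid <- sort(beta_grid)
  rows <- purrr::map(beta_grid, function(b) {
    th <- solve_thresh_for_mu(b, target_mu, q_thresh)
    tibble::tibble(
      beta = b, f_thresh = th$root,
      f_half = midpoint_from_threshold(th$root, b, q_thresh),
      mean_rate = mean_rate(b, th$root, q_thresh),
      corr = pair_correlation(b, th$root, q_thresh = q_thresh),
      converged = th$converged
    )
  })
  dplyr::bind_rows(rows)
}

# mu is strictly decreasing in the threshold at fixed beta > 0; bracket and
# bisect with uniroot, widening the bracket if needed.
solve_thresh_for_mu <- function(beta, target_mu, q_thresh = 0.01) {
  g <- function(th) mean_rate(beta, th, q_thresh) - target_mu
  lo <- -10; hi <- 10
  for (k in 1:8) {
    if (g(lo) > 0 && g(hi) < 0) break
    lo <- lo * 2; hi <- hi * 2
  }
  if (!(g(lo) > 0 && g(hi) < 0)) {
    return(list(root = NA_real_, converged = FALSE))
  }
  r <- stats::uniroot(g, c(lo, hi), tol = 1e-12)
  list(root = r$root, converged = abs(r$f.root) < 1e-8)
}

#' Local sensitivity of rate and correlation to slope and threshold
#'
#' Central finite differences of the mean firing probability and the
#' homogeneous-pair correlation with respect to the logistic slope and
#' threshold, evaluated at a point in (slope, threshold) space. The relative
#' step is `h * max(|param|, 1)` per parameter. If the downward slope step
#' would cross zero, a one-sided (forward) difference is used and flagged.
#'
#' @param beta Slope, strictly positive.
#' @param f_thresh Threshold on the standard-normal drive scale.
#' @param h Relative finite-difference step (default 1e-3).
#' @param q_thresh Probability defining the threshold (default 0.01).
#' @return A tibble with one row per derivative: columns `response`
#'   (`mean_rate` or `corr`), `wrt` (`beta` or `f_thresh`), `estimate`,
#'   `one_sided`.
#' @export
local_sensitivity <- function(beta, f_thresh, h = 1e-3, q_thresh = 0.01) {
  stopifnot(beta > 0, h > 0)
  hb <- h * max(abs(beta), 1)
  ht <- h * max(abs(f_thresh), 1)
  one_sided_beta <- (beta - hb) <= 0
  bvals <- if (one_sided_beta) c(beta, beta + hb) else c(beta - hb, beta + hb)
  bstep <- if (one_sided_beta) hb else 2 * hb

  fmu <- function(b, th) mean_rate(b, th, q_thresh)
  fco <- function(b, th) pair_correlation(b, th, q_thresh = q_thresh)

  tibble::tibble(
    response = rep(c("mean_rate", "corr"), each = 2),
    wrt = rep(c("beta", "f_thresh"), times = 2),
    estimate = c(
      (fmu(bvals[2], f_thresh) - fmu(bvals[1], f_thresh)) / bstep,
      (fmu(beta, f_thresh + ht) - fmu(beta, f_thresh - ht)) / (2 * ht),
      (fco(bvals[2], f_thresh) - fco(bvals[1], f_thresh)) / bstep,
      (fco(beta, f_thresh + ht) - fco(beta, f_thresh - ht)) / (2 * ht)
    ),
    one_sided = rep(c(one_sided_beta, FALSE), times = 2)
  )
}

# Gauss-Hermite nodes/weights transformed for E over N(0,1); cached.
gh_cache <- new.env(parent = emptyenv())
gh_rule <- function(n = 201L) {
  key <- as.character(n)
  if (is.null(gh_cache[[key]])) {
    r <- pracma::gaussHermite(n)
    gh_cache[[key]] <- list(f = sqrt(2) * r$x, w = r$w / sqrt(pi))
  }
  gh_cache[[key]]
}

#' Solve homogeneous logistic parameters for target rate and correlation
#'
#' Finds the (slope, threshold) pair at which a homogeneous population has
#' the requested mean firing probability and pairwise correlation: the
#' threshold is solved along the fixed-rate contour, and the slope by
#' root-finding on the (monotone) correlation along that contour.
#' A correlation of 0 returns slope 0 is not attainable at rates other than
#' 0.5, so `corr` must be positive.
#'
#' @param target_mu Target mean firing probability in (0, 1).
#' @param target_corr Target pairwise correlation in (0, 1).
#' @param q_thresh Probability defining the threshold (default 0.01).
#' @param beta_range Slope search interval (default `c(0.01, 200)`).
#' @return A one-row tibble: `beta`, `f_thresh`, `mean_rate`, `corr`.
#' @export
params_for_stats <- function(target_mu, target_corr, q_thresh = 0.01,
                             beta_range = c(0.01, 200)) {
  stopifnot(
    target_mu > 0, target_mu < 1, target_corr > 0, target_corr < 1
  )
  g <- function(lb) {
    b <- exp(lb)
    th <- solve_thresh_for_mu(b, target_mu, q_thresh)$root
    pair_correlation(b, th, q_thresh = q_thresh) - target_corr
  }
  lb <- stats::uniroot(g, log(beta_range), tol = 1e-10)$root
  beta <- exp(lb)
  th <- solve_thresh_for_mu(beta, target_mu, q_thresh)$root
  tibble::tibble(
    beta = beta, f_thresh = th,
    mean_rate = mean_rate(beta, th, q_thresh),
    corr = pair_correlation(beta, th, q_thresh = q_thresh)
  )
}
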