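#' Population logistic model parameters
#'
#' The population model places a 2D Gaussian over each neuron's (threshold,
#' slope) pair: five parameters in total (two means, two standard deviations,
#' and the slope-threshold correlation). Neurons share a common
#' standard-normal input drive but have independent parameter draws, which
#' captures cell-to-cell heterogeneity in activity statistics.
#'
#' Slope draws (and quadrature nodes) are truncated at zero so that every
#' neuron's response stays monotone in the drive.
#'
#' @param mu_thresh,mu_slope Means of threshold and slope.
#' @param sd_thresh,sd_slope Standard deviations (non-negative).
#' @param rho Correlation between slope and threshold, in `[-1, 1]`.
#' @return An object of class `pop_params` (named list).
#' @export
#' @examples
#' pop_params(mu_thresh = -1.5, mu_slope = 3, sd_thresh = 0.5,
#'            sd_slope = 0.5, rho = 0.2)
pop_params <- function(mu_thresh, mu_slope, sd_thresh, sd_slope, rho = 0) {
  if (sd_thresh < 0 || sd_slope < 0) {
    stop("standard deviations must be non-negative", call. = FALSE)
  }
  if (abs(rho) > 1) {
    stop("`rho` must lie in [-1, 1] (covariance must be positive semi-definite)",
      call. = FALSE
    )
  }
  structure(
    list(
      mu_thresh = mu_thresh, mu_slope = mu_slope,
      sd_thresh = sd_thresh, sd_slope = sd_slope, rho = rho
    ),
    class = "pop_params"
  )
}

#' @export
print.pop_params <- function(x, ...) {
  cat("Population logistic parameters (2D Gaussian over threshold, slope):\n")
  cat(sprintf(
    "  threshold: mean %.4g, sd %.4g\n  slope:     mean %.4g, sd %.4g\n  rho: %.4g\n",
    x$mu_thresh, x$sd_thresh, x$mu_slope, x$sd_slope, x$rho
  ))
  invisible(x)
}

as_pop_params <- function(x) {
  if (inherits(x, "pop_params")) return(x)
  x <- as.list(x)
  pop_params(x$mu_thresh, x$mu_slope, x$sd_thresh, x$sd_slope, x$rho)
}

# Tensor-product Gauss-Hermite nodes over the (threshold, slope) Gaussian.
# Returns theta, beta (slope clamped at 0) and weights summing to 1.
param_nodes <- function(params, n = 12L) {
  r <- gh_rule(n)
  z1 <- rep(r$f, each = n); z2 <- rep(r$f, times = n)
  w <- rep(r$w, each = n) * rep(r$w, times = n)
  a21 <- params$rho * params$sd_slope
  a22 <- params$sd_slope * sqrt(max(0, 1 - params$rho^2))
  theta <- params$mu_thresh + params$sd_thresh * z1
  beta <- pmax(0, params$mu_slope + a21 * z1 + a22 * z2)
  list(theta = theta, beta = beta, w = w)
}

#' Predict population activity statistics from the population logistic model
#'
#' Computes the three activity statistics implied by a [pop_params()] model:
#' the mean ON probability across neurons, the standard deviation of
#' per-neuron ON probabilities, and the mean pairwise correlation between
#' neurons with independent parameter draws sharing a common drive. All three
#' are evaluated by Gauss-Hermite quadrature over the parameter Gaussian and
#' the standard-normal drive; results are deterministic for a fixed
#' quadrature order.
#'
#' @param params A [pop_params()] object (or coercible list).
#' @param q_thresh Probability defining the threshold (default 0.01).
#' @param n_param_nodes Quadrature nodes per parameter dimension (default 12).
#' @param n_drive_nodes Quadrature nodes over the input drive (default 101).
#' @return A one-row tibble with `mean_rate`, `sd_rate`, `mean_corr`.
#' @export
#' @examples
#' predict_stats(pop_params(-1.5, 3, 0.5, 0.5, 0))
predict_stats <- function(params, q_thresh = 0.01, n_param_nodes = 12L,
                          n_drive_nodes = 101L) {
  params <- as_pop_params(params)
  nd <- param_nodes(params, n_param_nodes)
  dr <- gh_rule(n_drive_nodes)
  L <- log(q_thresh / (1 - q_thresh))

  # Q[m, j] = q(f_j; beta_m, theta_m); beta 0 rows are constant 0.5
  arg <- outer(nd$beta, dr$f) - (nd$beta * nd$theta - L)
  Q <- stats::plogis(arg)
  Q[nd$beta == 0, ] <- 0.5

  mu <- drop(Q %*% dr$w)
  mbar <- sum(nd$w * mu)
  m2 <- sum(nd$w * mu^2)
  sd_rate <- sqrt(max(0, m2 - mbar^2))

  # mean over independent parameter pairs of corr_ab
  #   = sum_ab w_a w_b (E_f[q_a q_b] - mu_a mu_b) / (s_a s_b)
  #   = sum_f w_f (Q' u)^2 - (u' mu)^2,  u_a = w_a / s_a
  # (saturated nodes have s = 0, undefined correlation counted as 0: u = 0)
  v <- mu * (1 - mu)
  u <- ifelse(v > 1e-14, nd$w / sqrt(pmax(v, 1e-300)), 0)
  a <- drop(crossprod(Q, u))
  mean_corr <- sum(dr$w * a^2) - sum(u * mu)^2

  tibble::tibble(mean_rate = mbar, sd_rate = sd_rate, mean_corr = mean_corr)
}

# squared error between predicted and target statistics (raw sum of squares,
# as in the fitting procedure; optional normalization by target scale)
stats_error <- function(pred, target, normalize = FALSE) {
  d <- c(
    pred$mean_rate - target$mean_rate,
    pred$sd_rate - target$sd_rate,
    pred$mean_corr - target$mean_corr
  )
  if (normalize) {
    sc <- pmax(abs(c(target$mean_rate, target$sd_rate, target$mean_corr)), 0.01)
    d <- d / sc
  }
  sum(d^2)
}

# heuristic starting point: homogeneous (beta, theta) matching the target
# mean rate and correlation, heterogeneity from a local linearization
default_init <- function(target, q_thresh = 0.01) {
  m <- min(max(target$mean_rate, 1e-3), 1 - 1e-3)
  cc <- min(max(target$mean_corr, 1e-3), 0.95)
  g <- function(lb) {
    b <- exp(lb)
    th <- solve_thresh_for_mu(b, m, q_thresh)$root
    pair_correlation(b, th, q_thresh = q_thresh) - cc
  }
  lb <- tryCatch(stats::uniroot(g, c(log(0.05), log(80)), tol = 1e-4)$root,
    error = function(e) log(2)
  )
  b0 <- exp(lb)
  th0 <- solve_thresh_for_mu(b0, m, q_thresh)$root
  dmu_dth <- local_sensitivity(b0, th0, q_thresh = q_thresh)
  dmu_dth <- dmu_dth$estimate[dmu_dth$response == "mean_rate" &
    dmu_dth$wrt == "f_thresh"]
  sd_th <- min(abs(target$sd_rate / dmu_dth), 2)
  pop_params(
    mu_thresh = th0, mu_slope = b0,
    sd_thresh = max(sd_th, 1e-3), sd_slope = max(0.05 * b0, 1e-3), rho = 0
  )
}

#' Fit the population logistic model to target activity statistics
#'
#' Accept/reject stochastic descent on the summed squared difference between
#' the model-predicted and target statistics (mean rate, s.d. of rates, mean
#' pairwise correlation): starting from an initial guess, a zero-mean
#' Gaussian perturbation is added to every parameter, the new error is
#' computed, and the update is kept only if the error decreased; iteration
#' stops when the error falls below `tol` or the iteration budget is spent.
#'
#' When `adapt = TRUE` (default) the proposal scale is halved every time
#' `patience` consecutive proposals are rejected, which lets the walk settle
#' into tight tolerances; with `adapt = FALSE` the proposal s.d. is fixed and
#' the fit returns best-so-far (flagged) once `patience` rejections accrue.
#' Multiple seeded restarts are run from jittered initial points and the best
#' trajectory is returned. The whole procedure is deterministic given `seed`.
#'
#' @param target One-row data frame (or list) with `mean_rate`, `sd_rate`,
#'   `mean_corr`.
#' @param init Optional [pop_params()] starting guess; by default a
#'   moment-matching heuristic from the target statistics.
#' @param step_frac Proposal s.d. as a fraction of each parameter's scale
#'   (default 0.02).
#' @param tol Target summed squared error (default 1e-6).
#' @param max_iter Iteration budget per restart (default 2e4).
#' @param n_restarts Number of seeded restarts (default 5; stops early once
#'   one restart converges).
#' @param patience Rejections tolerated before adapting/stopping (default 100).
#' @param adapt Halve the proposal scale after each `patience` window
#'   (default `TRUE`).
#' @param seed Integer seed controlling the entire fit.
#' @param normalize Use error terms normalized by the target scale instead of
#'   raw squared error (default `FALSE`, the raw form).
#' @inheritParams predict_stats
#' @return An object of class `pop_logistic_fit` with elements `params`
#'   ([pop_params()]), `error`, `converged`, `n_iter`, `trajectory` (tibble of
#'   accepted-step errors), `target`, `predicted`, and the settings used.
#' @export
fit_population <- function(target, init = NULL, step_frac = 0.02, tol = 1e-6,
                           max_iter = 2e4, n_restarts = 5, patience = 100,
                           adapt = TRUE, seed = 1, normalize = FALSE,
                           q_thresh = 0.01, n_param_nodes = 12L,
                           n_drive_nodes = 101L) {
  target <- as.list(target)
  stopifnot(
    target$mean_rate >= 0, target$mean_rate <= 1, target$sd_rate >= 0,
    target$mean_corr >= -1, target$mean_corr <= 1
  )
  predict1 <- function(p) {
    predict_stats(vec_to_params(p),
      q_thresh = q_thresh,
      n_param_nodes = n_param_nodes, n_drive_nodes = n_drive_nodes
    )
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  init <- if (is.null(init)) default_init(target, q_thresh) else as_pop_params(init)
  p_init <- params_to_vec(init)
  scales <- pmax(abs(p_init), c(0.5, 0.5, 0.1, 0.1, 0.1))

  best <- NULL
  for (r in seq_len(n_restarts)) {
    p <- if (r == 1) p_init else clamp_vec(p_init + stats::rnorm(5, 0, 0.25 * scales))
    run <- descend(p, predict1, target, scales * step_frac, tol, max_iter,
      patience, adapt, normalize
    )
    if (is.null(best) || run$error < best$error) best <- run
    if (best$error < tol) break
  }

  structure(
    list(
      params = vec_to_params(best$p),
      error = best$error,
      converged = best$error < tol,
      n_iter = best$n_iter,
      trajectory = best$trajectory,
      target = tibble::as_tibble(target[c("mean_rate", "sd_rate", "mean_corr")]),
      predicted = predict1(best$p),
      settings = list(
        step_frac = step_frac, tol = tol, max_iter = max_iter,
        n_restarts = n_restarts, patience = patience, adapt = adapt,
        seed = seed, normalize = normalize, q_thresh = q_thresh,
        n_param_nodes = n_param_nodes, n_drive_nodes = n_drive_nodes
      )
    ),
    class = "pop_logistic_fit"
  )
}

params_to_vec <- function(p) {
  c(p$mu_thresh, p$mu_slope, p$sd_thresh, p$sd_slope, p$rho)
}

vec_to_params <- function(v) {
  pop_params(v[1], v[2], v[3], v[4], v[5])
}

# keep proposals in the valid region: sds reflected at 0, rho clamped
clamp_vec <- function(v) {
  v[3] <- abs(v[3]); v[4] <- abs(v[4])
  v[5] <- min(max(v[5], -0.999), 0.999)
  v
}

descend <- function(p, predict1, target, step_sd, tol, max_iter, patience,
                    adapt, normalize) {
  err <- stats_error(predict1(p), target, normalize)
  traj_iter <- 0L; traj_err <- err
  stall <- 0L; it <- 0L
  while (it < max_iter && err >= tol) {
    it <- it + 1L
    cand <- clamp_vec(p + stats::rnorm(5, 0, step_sd))
    e2 <- stats_error(predict1(cand), target, normalize)
    if (e2 < err) {
      p <- cand; err <- e2; stall <- 0L
      traj_iter <- c(traj_iter, it); traj_err <- c(traj_err, err)
    } else {
      stall <- stall + 1L
      if (stall >= patience) {
        if (!adapt || max(step_sd) < 1e-10) break
        step_sd <- step_sd / 2
        stall <- 0L
      }
    }
  }
  list(
    p = p, error = err, n_iter = it,
    trajectory = tibble::tibble(iter = traj_iter, error = traj_err)
  )
}

#' @export
print.pop_logistic_fit <- function(x, ...) {
  cat("Population logistic fit (accept/reject stochastic descent)\n")
  print(x$params)
  cat(sprintf(
    "  final error %.3g after %d iterations (%s)\n",
    x$error, x$n_iter, if (x$converged) "converged" else "NOT converged"
  ))
  invisible(x)
}

#' @export
tidy.pop_logistic_fit <- function(x, ...) {
  tibble::tibble(
    term = c("mu_thresh", "mu_slope", "sd_thresh", "sd_slope", "rho"),
    estimate = params_to_vec(x$params)
  )
}

#' @export
glance.pop_logistic_fit <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(
      error = x$error, converged = x$converged, n_iter = x$n_iter
    ),
    stats::setNames(x$predicted, paste0("pred_", names(x$predicted)))
  )
}

#' @export
autoplot.pop_logistic_fit <- function(object, ...) {
  ggplot2::ggplot(object$trajectory, ggplot2::aes(x = .data$iter, y = .data$error)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "iteration", y = "summed squared error",
      title = "Accept/reject descent trajectory"
    )
}

#' Validate a population logistic fit by forward sampling
#'
#' Draws a synthetic raster from the fitted parameters, computes the three
#' activity statistics on the sampled binary data, and compares them with the
#' target, with Monte-Carlo standard errors from a block bootstrap over time
#' bins.
#'
#' @param params A [pop_params()] object (typically from [fit_population()]).
#' @param target One-row data frame with `mean_rate`, `sd_rate`, `mean_corr`.
#' @param n_neurons,n_bins Size of the validation raster.
#' @param seed Integer seed.
#' @param n_boot Bootstrap resamples for the error bars (default 200).
#' @return A tibble with one row per statistic: `statistic`, `target`,
#'   `sampled`, `se`, `within_3se`.
#' @export
validate_fit <- function(params, target, n_neurons = 100, n_bins = 2000,
                         seed = 1, n_boot = 200) {
  params <- as_pop_params(params)
  target <- as.list(target)
  spec <- ground_truth_spec(params, n_neurons = n_neurons, n_bins = n_bins,
    seed = seed
  )
  ras <- sample_raster(spec)
  s <- summary_stats(ras$binary)
  obs <- c(s$mean_rate, s$sd_rate, s$mean_corr)

  set.seed(as.integer(seed) %% .Machine$integer.max + 1L)
  boot <- replicate(n_boot, {
    idx <- sample.int(n_bins, n_bins, replace = TRUE)
    b <- summary_stats(ras$binary[, idx, drop = FALSE])
    c(b$mean_rate, b$sd_rate, b$mean_corr)
  })
  se <- apply(boot, 1, stats::sd)

  tgt <- c(target$mean_rate, target$sd_rate, target$mean_corr)
  tibble::tibble(
    statistic = c("mean_rate", "sd_rate", "mean_corr"),
    target = tgt, sampled = obs, se = se,
    within_3se = abs(obs - tgt) <= 3 * pmax(se, 1e-12)
  )
}
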