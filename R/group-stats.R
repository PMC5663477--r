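#' Bootstrap test for a difference in group means
#'
#' Nonparametric two-sided test: the two groups are pooled into a null set;
#' hypothetical groups of the original sizes are drawn with replacement from
#' the pool and their mean difference recorded, building the null
#' distribution of mean differences (centered at zero by construction). The
#' p-value is the two-sided tail mass at the observed difference, with an
#' add-one correction so it is never exactly zero:
#' `p = (1 + #{|d_null| >= |d_obs|}) / (n_boot + 1)`.
#'
#' @param group1,group2 Numeric vectors of per-animal (or per-unit) values.
#' @param n_boot Number of resamples (default 1e5; increase for small p).
#' @param seed Integer seed.
#' @return An object of class `bootstrap_test`: `delta_obs`, `p_value`,
#'   `n1`, `n2`, `n_boot`, `seed`, and the null draws (`null_samples`).
#' @export
#' @examples
#' bootstrap_mean_diff(rnorm(10), rnorm(10, 2), n_boot = 1000, seed = 1)$p_value
bootstrap_mean_diff <- function(group1, group2, n_boot = 1e5, seed = 1) {
  stopifnot(length(group1) >= 1, length(group2) >= 1, n_boot >= 1)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  n1 <- length(group1); n2 <- length(group2)
  pool <- c(group1, group2)
  delta_obs <- mean(group1) - mean(group2)
  m1 <- matrix(sample(pool, n1 * n_boot, replace = TRUE), nrow = n_boot)
  m2 <- matrix(sample(pool, n2 * n_boot, replace = TRUE), nrow = n_boot)
  null <- rowMeans(m1) - rowMeans(m2)
  p <- (1 + sum(abs(null) >= abs(delta_obs))) / (n_boot + 1)
  structure(
    list(
      delta_obs = delta_obs, p_value = p, n1 = n1, n2 = n2,
      n_boot = n_boot, seed = seed, null_samples = null
    ),
    class = "bootstrap_test"
  )
}

#' @export
print.bootstrap_test <- function(x, ...) {
  cat(sprintf(
    "Bootstrap group-mean test: delta = %.4g, p = %.4g (n1 = %d, n2 = %d, %g resamples)\n",
    x$delta_obs, x$p_value, x$n1, x$n2, x$n_boot
  ))
  invisible(x)
}

#' @export
tidy.bootstrap_test <- function(x, ...) {
  tibble::tibble(
    delta_obs = x$delta_obs, p_value = x$p_value,
    n1 = x$n1, n2 = x$n2, n_boot = x$n_boot
  )
}

#' Bootstrap chi-squared confidence ellipse for a 2D mean
#'
#' Bootstraps the mean of a cloud of 2D samples to estimate the sampling
#' covariance of the mean, then builds the confidence ellipse from the
#' chi-squared quantile with 2 degrees of freedom: semi-axes are
#' `sqrt(qchisq(level, 2) * eigenvalues)` along the covariance eigenvectors.
#'
#' @param samples_2d Matrix or data frame with >= 3 rows and 2 columns
#'   (e.g. per-animal mean slope and threshold shifts).
#' @param level Confidence level (default 0.95).
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed Integer seed.
#' @return An object of class `confidence_ellipse`: `center`, `covariance`,
#'   `level`, `chi2_quantile`, `axes` (semi-axis lengths), `angle_rad`
#'   (orientation of the major axis), `degenerate` (rank < 2 flag).
#' @export
confidence_ellipse <- function(samples_2d, level = 0.95, n_boot = 2000,
                               seed = 1) {
  x <- as.matrix(samples_2d)
  stopifnot(ncol(x) == 2, nrow(x) >= 3, level > 0, level < 1)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  n <- nrow(x)
  boot_means <- t(vapply(
    seq_len(n_boot),
    function(i) colMeans(x[sample.int(n, n, replace = TRUE), , drop = FALSE]),
    numeric(2)
  ))
  covm <- stats::cov(boot_means)
  eg <- eigen(covm, symmetric = TRUE)
  degenerate <- eg$values[2] <= 1e-12 * max(eg$values[1], 1e-300)
  q <- stats::qchisq(level, df = 2)
  structure(
    list(
      center = colMeans(x), covariance = covm, level = level,
      chi2_quantile = q,
      axes = sqrt(q * pmax(eg$values, 0)),
      angle_rad = atan2(eg$vectors[2, 1], eg$vectors[1, 1]),
      degenerate = degenerate, n_boot = n_boot, seed = seed
    ),
    class = "confidence_ellipse"
  )
}

#' @export
print.confidence_ellipse <- function(x, ...) {
  cat(sprintf(
    "%.0f%% confidence ellipse: center (%.4g, %.4g), semi-axes (%.4g, %.4g)%s\n",
    100 * x$level, x$center[1], x$center[2], x$axes[1], x$axes[2],
    if (x$degenerate) " [degenerate: rank < 2]" else ""
  ))
  invisible(x)
}

#' @export
tidy.confidence_ellipse <- function(x, ...) {
  tibble::tibble(
    center_x = x$center[1], center_y = x$center[2],
    axis_major = x$axes[1], axis_minor = x$axes[2],
    angle_rad = x$angle_rad, level = x$level, degenerate = x$degenerate
  )
}

#' Points on the ellipse boundary (for plotting or containment checks)
#'
#' @param x A [confidence_ellipse()].
#' @param n Number of boundary points.
#' @return A tibble with `x`, `y` boundary coordinates.
#' @export
ellipse_boundary <- function(x, n = 181) {
  stopifnot(inherits(x, "confidence_ellipse"))
  th <- seq(0, 2 * pi, length.out = n)
  R <- matrix(
    c(cos(x$angle_rad), sin(x$angle_rad),
      -sin(x$angle_rad), cos(x$angle_rad)),
    2, 2
  )
  pts <- cbind(x$axes[1] * cos(th), x$axes[2] * sin(th)) %*% t(R)
  bx <- pts[, 1] + x$center[1]
  by <- pts[, 2] + x$center[2]
  tibble::tibble(x = bx, y = by)
}

#' Is a point inside a confidence ellipse?
#'
#' @param ellipse A [confidence_ellipse()].
#' @param point Numeric length-2 vector.
#' @return Logical. Degenerate ellipses return `NA`.
#' @export
ellipse_contains <- function(ellipse, point) {
  stopifnot(inherits(ellipse, "confidence_ellipse"), length(point) == 2)
  if (ellipse$degenerate) return(NA)
  d <- point - ellipse$center
  stat <- drop(t(d) %*% solve(ellipse$covariance) %*% d)
  stat <= ellipse$chi2_quantile
}

#' @export
autoplot.confidence_ellipse <- function(object, ...) {
  b <- ellipse_boundary(object)
  ggplot2::ggplot(b, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path() +
    ggplot2::annotate("point",
      x = object$center[1], y = object$center[2], shape = 3
    ) +
    ggplot2::labs(
      title = sprintf("%.0f%% confidence ellipse", 100 * object$level)
    )
}

#' Confidence ellipse for the difference between two group means (2D)
#'
#' Resamples each group independently with replacement and records the
#' difference of group means, giving the bootstrap covariance of the 2D
#' mean shift (e.g. the shift in mean slope-threshold between genotypes).
#'
#' @param group1,group2 Matrices/data frames with 2 columns, one row per
#'   animal.
#' @inheritParams confidence_ellipse
#' @return A [confidence_ellipse()] object centered at
#'   `colMeans(group1) - colMeans(group2)`.
#' @export
ellipse_mean_diff <- function(group1, group2, level = 0.95, n_boot = 2000,
                              seed = 1) {
  g1 <- as.matrix(group1); g2 <- as.matrix(group2)
  stopifnot(ncol(g1) == 2, ncol(g2) == 2, nrow(g1) >= 2, nrow(g2) >= 2)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  n1 <- nrow(g1); n2 <- nrow(g2)
  boot <- t(vapply(seq_len(n_boot), function(i) {
    colMeans(g1[sample.int(n1, n1, replace = TRUE), , drop = FALSE]) -
      colMeans(g2[sample.int(n2, n2, replace = TRUE), , drop = FALSE])
  }, numeric(2)))
  covm <- stats::cov(boot)
  eg <- eigen(covm, symmetric = TRUE)
  q <- stats::qchisq(level, df = 2)
  structure(
    list(
      center = colMeans(g1) - colMeans(g2), covariance = covm, level = level,
      chi2_quantile = q,
      axes = sqrt(q * pmax(eg$values, 0)),
      angle_rad = atan2(eg$vectors[2, 1], eg$vectors[1, 1]),
      degenerate = eg$values[2] <= 1e-12 * max(eg$values[1], 1e-300),
      n_boot = n_boot, seed = seed
    ),
    class = "confidence_ellipse"
  )
}
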