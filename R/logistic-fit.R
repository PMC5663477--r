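#' Fit a logistic response curve to binomial spike counts
#'
#' Maximum-likelihood fit of the two-parameter logistic response model to
#' per-level spike counts (binomial GLM with a logit link). The fitted
#' midpoint is converted to the response threshold at `q_thresh`.
#'
#' Degenerate data (all-zero or all-one responses, or perfectly separated
#' responses) cannot identify both parameters; such fits are flagged rather
#' than erroring, with the slope capped at `beta_max`, and should be excluded
#' from downstream averages.
#'
#' @param f_levels Input drive levels (at least two distinct values).
#' @param successes Number of trials with a response at each level.
#' @param trials Number of trials at each level (scalar or per-level).
#' @param q_thresh Response probability defining the threshold (default 0.01).
#' @param beta_max Cap on the fitted slope under separation (default 1e4).
#' @param domain Tag for the input scale the fit lives on.
#' @return An object of class `logistic_fit`: a list with `beta`, `f_half`,
#'   `f_thresh`, `q_thresh`, `degenerate`, `separated`, `domain` and the
#'   input data. `domain` tags the input scale (e.g. `"l4_fraction"` for
#'   circuit simulations, `"standard_normal"` for the analytic model) so fits
#'   on different scales are not silently mixed.
#' @export
#' @examples
#' f <- seq(0, 0.3, by = 0.05)
#' q <- logistic_prob(f, beta = 25, f_half = 0.15)
#' fit_logistic(f, round(100 * q), 100)
fit_logistic <- function(f_levels, successes, trials, q_thresh = 0.01,
                         beta_max = 1e4, domain = "l4_fraction") {
  stopifnot(length(unique(f_levels)) >= 2)
  trials <- rep_len(trials, length(f_levels))
  if (any(successes > trials) || any(successes < 0)) {
    stop("`successes` must lie in [0, trials]", call. = FALSE)
  }

  all0 <- all(successes == 0)
  all1 <- all(successes == trials)
  degenerate <- all0 || all1
  separated <- FALSE
  beta <- NA_real_; f_half <- NA_real_

  if (!degenerate) {
    sep_warn <- FALSE
    fit <- withCallingHandlers(
      stats::glm(cbind(successes, trials - successes) ~ f_levels,
        family = stats::binomial()
      ),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
          sep_warn <<- TRUE
        }
        invokeRestart("muffleWarning")
      }
    )
    co <- stats::coef(fit)
    beta <- unname(co[2]); f_half <- unname(-co[1] / co[2])
    separated <- sep_warn || !fit$converged || abs(beta) > beta_max
    if (separated) {
      # separation: slope estimate diverges; cap it and place the midpoint
      # between the highest all-OFF and lowest any-ON levels
      p_hat <- successes / trials
      lo <- suppressWarnings(max(f_levels[p_hat == 0]))
      hi <- suppressWarnings(min(f_levels[p_hat > 0]))
      f_half <- mean(c(lo, hi)[is.finite(c(lo, hi))])
      beta <- sign(beta) * beta_max
    }
    if (is.finite(beta) && beta < 0) degenerate <- TRUE # non-monotone response
  }

  structure(
    list(
      beta = beta, f_half = f_half,
      f_thresh = if (is.finite(beta) && beta > 0) {
        threshold_from_midpoint(f_half, beta, q_thresh)
      } else {
        NA_real_
      },
      q_thresh = q_thresh, degenerate = degenerate, separated = separated,
      domain = domain,
      data = tibble::tibble(
        f = f_levels, successes = successes, trials = trials
      )
    ),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic response fit (domain: ", x$domain, ")\n", sep = "")
  cat(sprintf(
    "  slope beta = %.4g, midpoint = %.4g, threshold (q = %g) = %.4g\n",
    x$beta, x$f_half, x$q_thresh, x$f_thresh
  ))
  if (x$degenerate) cat("  flagged: degenerate (unidentifiable) fit\n")
  if (x$separated) cat("  flagged: separated data, slope capped\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.logistic_fit <- function(x, ...) {
  tibble::tibble(
    term = c("beta", "f_half", "f_thresh"),
    estimate = c(x$beta, x$f_half, x$f_thresh)
  )
}

#' @export
glance.logistic_fit <- function(x, ...) {
  tibble::tibble(
    beta = x$beta, f_half = x$f_half, f_thresh = x$f_thresh,
    q_thresh = x$q_thresh, degenerate = x$degenerate, separated = x$separated,
    domain = x$domain
  )
}

#' @export
autoplot.logistic_fit <- function(object, ...) {
  dat <- object$data
  dat$p_hat <- dat$successes / dat$trials
  curve <- tibble::tibble(f = seq(min(dat$f), max(dat$f), length.out = 200))
  curve$q <- logistic_prob(curve$f, object$beta, object$f_half)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$f, y = .data$p_hat)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(
      data = curve, ggplot2::aes(x = .data$f, y = .data$q),
      colour = "firebrick"
    ) +
    ggplot2::labs(
      x = "input drive", y = "response probability",
      title = sprintf(
        "beta = %.3g, threshold = %.3g", object$beta, object$f_thresh
      )
    )
}

#' Fit logistic response curves to many neurons at once
#'
#' Applies [fit_logistic()] to each row of a neurons-by-levels response
#' probability matrix (as produced by [response_curve()]).
#'
#' @param q_matrix Matrix of response probabilities, neurons x levels.
#' @param f_levels Input levels, one per column of `q_matrix`.
#' @param n_trials Trials underlying each probability (scalar).
#' @inheritParams fit_logistic
#' @return A tibble with one row per neuron: `neuron`, `beta`, `f_half`,
#'   `f_thresh`, `degenerate`, `separated`.
#' @export
fit_logistic_many <- function(q_matrix, f_levels, n_trials, q_thresh = 0.01,
                              beta_max = 1e4, domain = "l4_fraction") {
  stopifnot(ncol(q_matrix) == length(f_levels))
  rows <- purrr::map(seq_len(nrow(q_matrix)), function(i) {
    k <- round(q_matrix[i, ] * n_trials)
    g <- glance(fit_logistic(f_levels, k, n_trials,
      q_thresh = q_thresh, beta_max = beta_max, domain = domain
    ))
    g$neuron <- i
    g
  })
  dplyr::bind_rows(rows)[, c(
    "neuron", "beta", "f_half", "f_thresh", "degenerate", "separated", "domain"
  )]
}
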