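#' Population tracking model
#'
#' A low-parameter model of the distribution over binary population activity
#' patterns, combining (i) the synchrony distribution `p_k` over the number
#' of neurons simultaneously ON, and (ii) the conditional probability that
#' each neuron is ON given the population count, `p_cond[i, k]`. A pattern
#' `x` with population count `K = sum(x)` has probability
#' \deqn{P(x) = p_k(K) \; w(x \mid K) / Z_K,}
#' where `w` is the product of per-neuron Bernoulli factors at the
#' conditional probabilities for count `K` and `Z_K` normalizes `w` over all
#' count-`K` patterns. `Z_K` and all conditional-count quantities are
#' computed exactly with Poisson-binomial dynamic programming (stable in the
#' probability domain), so no enumeration over the `2^N` patterns is needed.
#'
#' @param p_k Numeric vector of length `N + 1`: probability of each
#'   population count `0..N` (must sum to 1).
#' @param p_cond Matrix `N x (N + 1)`: `p_cond[i, k + 1]` is the probability
#'   that neuron `i` is ON given count `k`. Columns are renormalized so that
#'   their sums match `k` (within clamping).
#' @return An object of class `poptrack_model`.
#' @export
#' @examples
#' # two independent fair coins
#' m <- poptrack_model(c(0.25, 0.5, 0.25),
#'                     cbind(c(0, 0), c(0.5, 0.5), c(1, 1)))
#' entropy_estimate(m)$h_per_neuron # 1 bit
poptrack_model <- function(p_k, p_cond) {
  N <- nrow(p_cond)
  stopifnot(length(p_k) == N + 1, ncol(p_cond) == N + 1, all(p_k >= 0))
  if (abs(sum(p_k) - 1) > 1e-8) stop("`p_k` must sum to 1", call. = FALSE)
  stopifnot(all(p_cond >= 0), all(p_cond <= 1))
  p_cond <- renorm_cond(p_cond)
  structure(
    list(N = N, p_k = p_k / sum(p_k), p_cond = p_cond),
    class = "poptrack_model"
  )
}

#' @export
print.poptrack_model <- function(x, ...) {
  cat("Population tracking model:", x$N, "neurons\n")
  cat(
    "  synchrony distribution support:",
    paste(range(which(x$p_k > 0) - 1), collapse = ".."), "\n"
  )
  invisible(x)
}

# Renormalize each count column so the conditional ON probabilities sum to
# k. The correction is a common shift on the logit scale (an exponential
# tilt): it preserves the odds ratios between neurons, so distributions that
# are representable by the count-conditioned weight family (e.g. independent
# neurons) stay exactly representable after renormalization.
renorm_cond <- function(p_cond, eps = 1e-9) {
  N <- nrow(p_cond)
  for (k in 0:N) {
    j <- k + 1
    if (k == 0) {
      p_cond[, j] <- 0
    } else if (k == N) {
      p_cond[, j] <- 1
    } else {
      p <- pmin(pmax(p_cond[, j], eps), 1 - eps)
      lo <- stats::qlogis(p)
      g <- function(c) sum(stats::plogis(lo + c)) - k
      if (abs(g(0)) > 1e-12) {
        c_star <- stats::uniroot(g, c(-60, 60), tol = 1e-12)$root
        p <- stats::plogis(lo + c_star)
      }
      p_cond[, j] <- pmin(pmax(p, eps), 1 - eps)
    }
  }
  p_cond
}

#' Fit the population tracking model to a raster
#'
#' Probabilistic (ON-probability) rasters are converted to spikes by drawing
#' `n_draws` seeded Bernoulli realizations per time bin, which regularizes
#' the synchrony distribution; binary rasters are used as-is. The synchrony
#' distribution gets an additive pseudocount of 1 per count bin, and the
#' conditional ON frequencies a Jeffreys-style 0.5 pseudocount, before
#' renormalization. Counts never observed fall back to the homogeneous
#' profile `k/N`.
#'
#' @param raster Neurons x bins matrix, binary or of ON probabilities.
#' @param n_draws Bernoulli realizations per bin for probabilistic rasters
#'   (default 20).
#' @param pseudocount Additive smoothing mass per synchrony bin (default 1).
#' @param seed Integer seed for the Bernoulli draws.
#' @param pk_method `"draws"` (empirical, default) or `"exact"`: the exact
#'   Poisson-binomial synchrony distribution implied by the per-bin ON
#'   probabilities (validation path; `p_cond` still uses draws).
#' @return A [poptrack_model()].
#' @export
fit_poptrack <- function(raster, n_draws = 20, pseudocount = 1, seed = 1,
                         pk_method = c("draws", "exact")) {
  stopifnot(is.matrix(raster), ncol(raster) >= 2)
  stopifnot(all(raster >= 0), all(raster <= 1))
  pk_method <- match.arg(pk_method)
  N <- nrow(raster)
  is_binary <- all(raster %in% c(0, 1))

  if (is_binary) {
    samp <- raster
  } else {
    set.seed(as.integer(seed) %% .Machine$integer.max)
    samp <- matrix(
      stats::rbinom(length(raster) * n_draws, 1L,
        rep(as.vector(raster), n_draws)
      ),
      nrow = N
    )
  }

  counts <- colSums(samp)
  if (pk_method == "exact" && !is_binary) {
    p_k_raw <- exact_synchrony(raster)
    p_k <- (p_k_raw * ncol(raster) + pseudocount) /
      (ncol(raster) + pseudocount * (N + 1))
  } else {
    p_k <- (tabulate(counts + 1L, nbins = N + 1) + pseudocount) /
      (ncol(samp) + pseudocount * (N + 1))
  }

  p_cond <- matrix(NA_real_, N, N + 1)
  for (k in 0:N) {
    sel <- counts == k
    n_k <- sum(sel)
    if (k == 0 || k == N || n_k == 0) {
      p_cond[, k + 1] <- k / N
    } else {
      on_i <- rowSums(samp[, sel, drop = FALSE])
      p_cond[, k + 1] <- (on_i + 0.5) / (n_k + 1)
    }
  }
  poptrack_model(p_k, p_cond)
}

# average Poisson-binomial count distribution over bins of a probabilistic
# raster (vectorized DP across bins)
exact_synchrony <- function(p_on) {
  N <- nrow(p_on); B <- ncol(p_on)
  P <- matrix(0, B, N + 1)
  P[, 1] <- 1
  for (i in seq_len(N)) {
    p <- p_on[i, ]
    P <- P * (1 - p) + cbind(0, P[, -(N + 1), drop = FALSE]) * p
  }
  colMeans(P)
}

# Poisson-binomial pmf for one probability vector (counts 0..N)
pb_dist <- function(p) {
  N <- length(p)
  v <- c(1, numeric(N))
  for (i in seq_len(N)) {
    v <- v * (1 - p[i]) + c(0, v[-(N + 1)]) * p[i]
  }
  v
}

# P(x_i = 1 | total count = k) for every i, given conditional probabilities
# p and their Poisson-binomial pmf: m_i = p_i * PB_without_i(k-1) / PB(k).
# Leave-one-out pmfs come from deconvolving PB, run from whichever end is
# numerically stable for each neuron.
cond_count_means <- function(p, PB, k) {
  N <- length(p)
  if (k == 0) return(numeric(N))
  if (k == N) return(rep(1, N))
  m <- numeric(N)
  lo <- p <= 0.5
  if (any(lo)) {
    pl <- p[lo]
    q <- PB[1] / (1 - pl) # q_i(0)
    if (k - 1 >= 1) {
      for (j in seq_len(k - 1)) {
        q <- (PB[j + 1] - pl * q) / (1 - pl)
        q[q < 0] <- 0
      }
    }
    m[lo] <- pl * q / PB[k + 1]
  }
  if (any(!lo)) {
    ph <- p[!lo]
    q <- PB[N + 1] / ph # q_i(N-1)
    if (N - 1 >= k) {
      for (j in seq(N - 1, k, by = -1)) {
        q <- (PB[j + 1] - (1 - ph) * q) / ph
        q[q < 0] <- 0
      }
    }
    m[!lo] <- ph * q / PB[k + 1]
  }
  pmin(pmax(m, 0), 1)
}

#' Log2 probability of a population pattern under the model
#'
#' @param model A [poptrack_model()].
#' @param pattern Binary vector of length `N` (or a patterns-in-rows matrix).
#' @param floor_log2 Lower floor for the returned log2 probability
#'   (default -1074, the smallest double exponent).
#' @return Log2 probabilities, one per pattern.
#' @export
pattern_logprob <- function(model, pattern, floor_log2 = -1074) {
  stopifnot(inherits(model, "poptrack_model"))
  x <- if (is.matrix(pattern)) pattern else matrix(pattern, nrow = 1)
  stopifnot(ncol(x) == model$N, all(x %in% c(0, 1)))
  ks <- rowSums(x)
  out <- numeric(nrow(x))
  for (k in unique(ks)) {
    idx <- which(ks == k)
    pk <- model$p_k[k + 1]
    if (pk <= 0) {
      out[idx] <- floor_log2
      next
    }
    p <- model$p_cond[, k + 1]
    if (k == 0 || k == model$N) {
      out[idx] <- log2(pk) # single pattern in the count class
      next
    }
    lw <- x[idx, , drop = FALSE] %*% log2(p) +
      (1 - x[idx, , drop = FALSE]) %*% log2(1 - p)
    lZ <- log2(pb_dist(p)[k + 1])
    out[idx] <- pmax(log2(pk) + drop(lw) - lZ, floor_log2)
  }
  out
}

#' Entropy of a population tracking model
#'
#' The pattern-distribution entropy in bits. Because the log pattern weight
#' is linear in the pattern, the conditional entropy within each count class
#' has the closed form
#' \eqn{H(X|K{=}k) = \log_2 Z_k - \sum_i [m_i \log_2 p_i + (1-m_i)\log_2(1-p_i)]}
#' with `m_i = P(x_i = 1 | K = k)`, all computable by Poisson-binomial
#' dynamic programming; the default `"analytic"` method is therefore exact
#' for any population size. `"enumeration"` sums over all `2^N` patterns
#' (N <= 20) and `"sampling"` draws patterns from the model and averages
#' `-log2 P(x)` with a standard error, both kept as independent
#' cross-checks.
#'
#' @param model A [poptrack_model()].
#' @param method `"analytic"` (default), `"enumeration"`, or `"sampling"`.
#' @param n_samples Patterns drawn for the sampling method (default 5000).
#' @param seed Integer seed (sampling method).
#' @return A one-row tibble: `h_bits`, `h_per_neuron`, `se` (NA except for
#'   sampling), `method`, `n` (population size).
#' @export
entropy_estimate <- function(model, method = c("analytic", "enumeration", "sampling"),
                             n_samples = 5000, seed = 1) {
  stopifnot(inherits(model, "poptrack_model"))
  method <- match.arg(method)
  N <- model$N
  se <- NA_real_

  if (method == "analytic") {
    pk <- model$p_k
    h <- -sum(ifelse(pk > 0, pk * log2(pk), 0))
    for (k in seq_len(N - 1)) { # K = 0 and K = N classes have zero entropy
      if (pk[k + 1] <= 0) next
      p <- model$p_cond[, k + 1]
      PB <- pb_dist(p)
      if (PB[k + 1] <= 0) next
      m <- cond_count_means(p, PB, k)
      elw <- sum(m * log2(p) + (1 - m) * log2(1 - p))
      h <- h + pk[k + 1] * (log2(PB[k + 1]) - elw)
    }
  } else if (method == "enumeration") {
    stopifnot(N <= 20)
    pats <- as.matrix(expand.grid(rep(list(0:1), N)))
    dimnames(pats) <- NULL
    lp <- pattern_logprob(model, pats)
    pr <- 2^lp
    h <- -sum(ifelse(pr > 0, pr * lp, 0))
  } else {
    pats <- sample_poptrack(model, n_samples, seed)
    lp <- pattern_logprob(model, pats)
    h <- mean(-lp)
    se <- stats::sd(-lp) / sqrt(n_samples)
  }
  tibble::tibble(
    h_bits = h, h_per_neuron = h / N, se = se, method = method, n = N
  )
}

#' Sample population patterns from a population tracking model
#'
#' Draws the population count from the synchrony distribution, then an exact
#' count-conditioned pattern by sequential conditional Bernoulli sampling
#' (suffix Poisson-binomial tables).
#'
#' @param model A [poptrack_model()].
#' @param n_samples Number of patterns.
#' @param seed Integer seed.
#' @return Matrix `n_samples x N` of 0/1 patterns.
#' @export
sample_poptrack <- function(model, n_samples, seed = 1) {
  stopifnot(inherits(model, "poptrack_model"))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  N <- model$N
  ks <- sample.int(N + 1, n_samples, replace = TRUE, prob = model$p_k) - 1L
  out <- matrix(0L, n_samples, N)
  for (k in unique(ks)) {
    rows <- which(ks == k)
    if (k == 0) next
    if (k == N) {
      out[rows, ] <- 1L
      next
    }
    p <- model$p_cond[, k + 1]
    # suffix tables: Tsuf[i, j + 1] = P(sum of x_i..x_N = j)
    Tsuf <- matrix(0, N + 1, N + 2)
    Tsuf[N + 1, 1] <- 1
    for (i in N:1) {
      row <- Tsuf[i + 1, 1:(N + 1)]
      Tsuf[i, 1:(N + 1)] <- row * (1 - p[i]) + c(0, row[-(N + 1)]) * p[i]
    }
    for (r in rows) {
      j <- k
      for (i in seq_len(N)) {
        if (j == 0) break
        pr1 <- p[i] * Tsuf[i + 1, j] / Tsuf[i, j + 1]
        if (stats::runif(1) < pr1) {
          out[r, i] <- 1L
          j <- j - 1L
        }
      }
    }
  }
  out
}

#' Cumulative pattern-probability mass curve
#'
#' Orders activity patterns from most to least probable and accumulates
#' their probabilities: how many distinct patterns are needed to account for
#' a given fraction of the time. Exact for `N <= 15` (full enumeration);
#' for larger populations the curve is estimated from sampled, deduplicated
#' patterns and covers only the sampled mass (`coverage` column).
#'
#' @param model A [poptrack_model()].
#' @param n_samples Sampled patterns for the large-N estimate (default 1e4).
#' @param seed Integer seed.
#' @param exact Force the enumeration (`TRUE`) or sampling (`FALSE`) path;
#'   defaults to enumeration for `N <= 15`.
#' @return A tibble with `rank`, `log2_prob`, `cum_prob`, `exact`,
#'   `coverage` (total mass represented; 1 for exact curves).
#' @export
cumulative_mass_curve <- function(model, n_samples = 1e4, seed = 1,
                                  exact = model$N <= 15) {
  stopifnot(inherits(model, "poptrack_model"))
  if (exact) {
    stopifnot(model$N <= 20)
    pats <- as.matrix(expand.grid(rep(list(0:1), model$N)))
    dimnames(pats) <- NULL
    lp <- sort(pattern_logprob(model, pats), decreasing = TRUE)
    pr <- 2^lp
    tibble::tibble(
      rank = seq_along(pr), log2_prob = lp, cum_prob = cumsum(pr),
      exact = TRUE, coverage = 1
    )
  } else {
    pats <- sample_poptrack(model, n_samples, seed)
    pats <- unique(pats)
    lp <- sort(pattern_logprob(model, pats), decreasing = TRUE)
    pr <- 2^lp
    tibble::tibble(
      rank = seq_along(pr), log2_prob = lp, cum_prob = cumsum(pr),
      exact = FALSE, coverage = sum(pr)
    )
  }
}

#' Entropy per neuron as a function of population size
#'
#' Estimates the entropy/neuron for random neuron subsets of increasing size
#' (default 10 to 100 in steps of 10, truncated to the available neurons),
#' fits the double exponential
#' \deqn{H/N = A e^{-bN} + C e^{-dN} + e}
#' to the size curve, and evaluates the fit at `N = 100` to give a
#' standardized 100-neuron entropy/neuron. Recordings differ in neuron
#' count, so this standardization makes groups comparable.
#'
#' @param raster Neurons x bins matrix (binary or ON probabilities).
#' @param sizes Subset sizes (default `seq(10, 100, by = 10)`).
#' @param n_subsets Random subsets per size (default 20).
#' @param n_draws,pseudocount,seed Passed to [fit_poptrack()].
#' @return An object of class `entropy_curve`: tibble of per-size mean
#'   entropy/neuron (`by_size`), fit coefficients, `h100`, `converged`.
#' @export
entropy_vs_N <- function(raster, sizes = seq(10, 100, by = 10),
                         n_subsets = 20, n_draws = 20, pseudocount = 1,
                         seed = 1) {
  stopifnot(is.matrix(raster))
  sizes <- sort(unique(sizes[sizes <= nrow(raster)]))
  stopifnot(length(sizes) >= 1)
  set.seed(as.integer(seed) %% .Machine$integer.max)

  rows <- purrr::map(sizes, function(sz) {
    h <- vapply(seq_len(n_subsets), function(s) {
      sub <- raster[sample.int(nrow(raster), sz), , drop = FALSE]
      m <- fit_poptrack(sub,
        n_draws = n_draws, pseudocount = pseudocount,
        seed = seed + s
      )
      entropy_estimate(m)$h_per_neuron
    }, numeric(1))
    tibble::tibble(
      size = sz, h_per_neuron = mean(h), sd = stats::sd(h),
      n_subsets = n_subsets
    )
  })
  by_size <- dplyr::bind_rows(rows)
  fit <- fit_double_exponential(by_size$size, by_size$h_per_neuron)
  h100 <- if (fit$converged) {
    double_exp(100, fit$coef)
  } else {
    by_size$h_per_neuron[which.max(by_size$size)]
  }
  structure(
    list(by_size = by_size, coef = fit$coef, converged = fit$converged,
      h100 = h100),
    class = "entropy_curve"
  )
}

double_exp <- function(N, cf) {
  cf[["A"]] * exp(-cf[["b"]] * N) + cf[["C"]] * exp(-cf[["d"]] * N) + cf[["e"]]
}

#' Fit the double-exponential entropy size curve
#'
#' Nonlinear least squares for `H/N = A exp(-b N) + C exp(-d N) + e` with a
#' non-negative asymptote `e` (entropy cannot go below zero), from multiple
#' starting points via Levenberg-Marquardt.
#'
#' @param sizes Population sizes.
#' @param h Entropy/neuron at each size (bits).
#' @return A list with `coef` (named A, b, C, d, e), `converged`, and `rss`.
#' @export
fit_double_exponential <- function(sizes, h) {
  dat <- data.frame(N = sizes, h = h)
  rng <- max(h) - min(h)
  starts <- list(
    c(A = rng / 2, b = 0.1, C = rng / 2, d = 0.01, e = max(min(h), 0)),
    c(A = rng, b = 0.05, C = 0, d = 0.005, e = max(min(h), 0)),
    c(A = rng / 4, b = 0.3, C = rng / 4, d = 0.02, e = max(mean(h), 0))
  )
  best <- NULL
  for (st in starts) {
    f <- tryCatch(
      minpack.lm::nlsLM(
        h ~ A * exp(-b * N) + C * exp(-d * N) + e,
        data = dat, start = as.list(st),
        lower = c(A = -2, b = 0, C = -2, d = 0, e = 0),
        upper = c(A = 2, b = 10, C = 2, d = 10, e = 1),
        control = minpack.lm::nls.lm.control(maxiter = 500)
      ),
      error = function(e) NULL
    )
    if (!is.null(f)) {
      rss <- sum(stats::resid(f)^2)
      if (is.null(best) || rss < best$rss) {
        best <- list(coef = stats::coef(f), rss = rss)
      }
    }
  }
  if (is.null(best)) {
    list(coef = c(A = NA, b = NA, C = NA, d = NA, e = NA), converged = FALSE)
  } else {
    list(coef = best$coef, converged = TRUE, rss = best$rss)
  }
}

#' @export
print.entropy_curve <- function(x, ...) {
  cat("Entropy/neuron vs population size\n")
  print(x$by_size)
  cat(sprintf(
    "  standardized 100-neuron entropy/neuron: %.4g bits (%s)\n",
    x$h100, if (x$converged) "double-exponential fit" else
      "fit did not converge; largest-size value"
  ))
  invisible(x)
}

#' @export
tidy.entropy_curve <- function(x, ...) x$by_size

#' @export
glance.entropy_curve <- function(x, ...) {
  tibble::tibble(
    h100 = x$h100, converged = x$converged,
    A = x$coef[["A"]], b = x$coef[["b"]], C = x$coef[["C"]],
    d = x$coef[["d"]], e = x$coef[["e"]]
  )
}

#' @export
autoplot.entropy_curve <- function(object, ...) {
  grid <- tibble::tibble(size = seq(min(object$by_size$size), 100,
    length.out = 200
  ))
  p <- ggplot2::ggplot(
    object$by_size,
    ggplot2::aes(x = .data$size, y = .data$h_per_neuron)
  ) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "number of neurons", y = "entropy / neuron (bits)")
  if (object$converged) {
    grid$h <- double_exp(grid$size, object$coef)
    p <- p + ggplot2::geom_line(
      data = grid, ggplot2::aes(x = .data$size, y = .data$h),
      colour = "firebrick"
    )
  }
  p
}
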