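#' Estimate firing rates from dF/F fluorescence traces
#'
#' The standard preprocessing chain for slow calcium-indicator movies:
#' each trace is low-pass filtered with a Butterworth filter (normalized
#' cutoff 0.16; order 2, applied forward-backward for zero phase),
#' deconvolved with a 2 s single-exponential kernel (inverse filtering,
#' `y[n] - a y[n-1]` with `a = exp(-1/(tau * fs))`), floored at twice the
#' standard deviation of the negative deconvolved points (values below the
#' floor are set to zero), and scaled by 78.4 to convert to spikes/s (a
#' calibration factor derived from cell-attached recordings).
#'
#' @param dff Numeric matrix of dF/F values (neurons x frames), or a vector
#'   for a single neuron.
#' @param frame_rate_hz Imaging frame rate in Hz (default 3.9).
#' @param butter_cutoff Normalized Butterworth cutoff (default 0.16).
#' @param butter_order Filter order (default 2).
#' @param kernel_tau_s Deconvolution kernel time constant (default 2 s).
#' @param rate_scale Deconvolved-trace to spikes/s factor (default 78.4).
#' @param noise_mult Noise-floor multiplier on the s.d. of negative
#'   deconvolved values (default 2).
#' @return Matrix of non-negative firing rates (spikes/s), neurons x frames,
#'   with attribute `frame_rate_hz`. Traces whose deconvolution has no
#'   negative points get a zero noise floor (nothing is suppressed).
#' @export
dff_to_rate <- function(dff, frame_rate_hz = 3.9, butter_cutoff = 0.16,
                        butter_order = 2, kernel_tau_s = 2,
                        rate_scale = 78.4, noise_mult = 2) {
  if (is.null(dim(dff))) dff <- matrix(dff, nrow = 1)
  stopifnot(all(is.finite(dff)), frame_rate_hz > 0, kernel_tau_s > 0)
  bf <- signal::butter(butter_order, butter_cutoff, type = "low")
  a <- exp(-1 / (kernel_tau_s * frame_rate_hz))

  out <- matrix(0, nrow(dff), ncol(dff))
  for (i in seq_len(nrow(dff))) {
    x <- dff[i, ]
    if (all(x == 0)) next
    sm <- if (length(x) > 3 * (butter_order + 1)) {
      as.numeric(signal::filtfilt(bf, x))
    } else {
      x # too short for a stable zero-phase filter; pass through
    }
    dec <- c(sm[1], sm[-1] - a * sm[-length(sm)])
    neg <- dec[dec < 0]
    floor_lev <- if (length(neg)) noise_mult * stats::sd(neg) else 0
    dec[dec < floor_lev] <- 0
    out[i, ] <- dec * rate_scale
  }
  attr(out, "frame_rate_hz") <- frame_rate_hz
  out
}

#' Convert firing rates to 1-s-bin ON probabilities
#'
#' Assuming spikes follow an inhomogeneous Poisson process with rate `r(t)`,
#' the expected spike count in a 1 s bin is `lambda = mean(r)` over the bin's
#' frames, and the probability that the neuron fires at least once is
#' `p_on = 1 - exp(-lambda)`.
#'
#' @param rate Neurons x frames matrix of firing rates (spikes/s), e.g. from
#'   [dff_to_rate()]; frames are aggregated into 1-s bins by averaging.
#' @param frame_rate_hz Frame rate; taken from the `frame_rate_hz` attribute
#'   of `rate` if present.
#' @return Neurons x bins matrix of ON probabilities in `[0, 1]`.
#' @export
#' @examples
#' rate_to_pon(matrix(log(2), 1, 4), frame_rate_hz = 4) # 0.5 per bin
rate_to_pon <- function(rate, frame_rate_hz = attr(rate, "frame_rate_hz")) {
  if (is.null(dim(rate))) rate <- matrix(rate, nrow = 1)
  stopifnot(all(rate >= 0), !is.null(frame_rate_hz), frame_rate_hz > 0)
  n_bins <- floor(ncol(rate) / frame_rate_hz)
  stopifnot(n_bins >= 1)
  bin_of <- pmin(floor((seq_len(ncol(rate)) - 1) / frame_rate_hz) + 1L, n_bins)
  lambda <- t(apply(rate, 1, function(r) tapply(r, bin_of, mean)))
  if (n_bins == 1L) lambda <- matrix(lambda, nrow = nrow(rate))
  1 - exp(-lambda)
}

#' Population activity summary statistics
#'
#' The three statistics used throughout: the mean over neurons of the
#' time-averaged ON probability, the standard deviation across neurons of
#' those time averages, and the mean Pearson correlation over all unordered
#' neuron pairs of the ON-probability time series. Pairs involving a
#' constant time series are skipped (and counted in `n_pairs_skipped`).
#'
#' @param raster Neurons x bins matrix of ON probabilities or binary values
#'   (>= 2 neurons, >= 2 bins).
#' @return A one-row tibble: `mean_rate`, `sd_rate`, `mean_corr`,
#'   `n_neurons`, `n_bins`, `n_pairs_skipped`. `mean_corr` is `NA` when every
#'   pair is constant.
#' @export
summary_stats <- function(raster) {
  stopifnot(is.matrix(raster), nrow(raster) >= 2, ncol(raster) >= 2)
  per_neuron <- rowMeans(raster)
  vr <- apply(raster, 1, stats::var)
  ok <- vr > 0
  n_ok <- sum(ok)
  if (n_ok >= 2) {
    cm <- suppressWarnings(stats::cor(t(raster[ok, , drop = FALSE])))
    mean_corr <- mean(cm[upper.tri(cm)])
    n_pairs_ok <- n_ok * (n_ok - 1) / 2
  } else {
    mean_corr <- NA_real_
    n_pairs_ok <- 0
  }
  n <- nrow(raster)
  tibble::tibble(
    mean_rate = mean(per_neuron),
    sd_rate = stats::sd(per_neuron),
    mean_corr = mean_corr,
    n_neurons = n,
    n_bins = ncol(raster),
    n_pairs_skipped = n * (n - 1) / 2 - n_pairs_ok
  )
}

#' Full calcium pipeline: dF/F movie to ON-probability raster and statistics
#'
#' Convenience wrapper chaining [dff_to_rate()] and [rate_to_pon()], and
#' summarizing with [summary_stats()].
#'
#' @inheritParams dff_to_rate
#' @return A list with `rate`, `p_on`, and `stats` (one-row tibble).
#' @export
binarize_dff <- function(dff, frame_rate_hz = 3.9, ...) {
  rate <- dff_to_rate(dff, frame_rate_hz = frame_rate_hz, ...)
  p_on <- rate_to_pon(rate, frame_rate_hz)
  list(rate = rate, p_on = p_on, stats = summary_stats(p_on))
}
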