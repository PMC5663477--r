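#' Specification for a synthetic ground-truth recording
#'
#' Bundles everything needed to generate a synthetic population recording
#' with known ground truth: the population logistic parameters, the raster
#' dimensions, the fluorescence forward-model options, and a seed. Bins are
#' 1 s wide, matching the analysis timebase.
#'
#' The fluorescence options emulate a slow calcium indicator sampled at
#' 3.9 Hz with a 2 s single-exponential impulse response; `unit_amplitude` is
#' the dF/F jump per spike and `noise_sd` the i.i.d. Gaussian noise s.d. Both
#' are generator knobs for testing the deconvolution pipeline, not claims
#' about indicator photophysics.
#'
#' @param pop_params A [pop_params()] object.
#' @param n_neurons Number of neurons (>= 2).
#' @param n_bins Number of 1-s time bins (>= 1).
#' @param frame_rate_hz Imaging frame rate (default 3.9 Hz).
#' @param kernel_tau_s Indicator decay time constant (default 2 s).
#' @param unit_amplitude dF/F per spike (default 0.1).
#' @param noise_sd Gaussian noise s.d. on the dF/F trace (default 0.02).
#' @param seed Integer seed.
#' @return An object of class `ground_truth_spec`.
#' @export
ground_truth_spec <- function(pop_params, n_neurons, n_bins,
                              frame_rate_hz = 3.9, kernel_tau_s = 2,
                              unit_amplitude = 0.1, noise_sd = 0.02,
                              seed = 1) {
  pop_params <- as_pop_params(pop_params)
  stopifnot(
    n_neurons >= 2, n_bins >= 1, noise_sd >= 0, kernel_tau_s > 0,
    frame_rate_hz > 0, unit_amplitude >= 0
  )
  structure(
    list(
      pop_params = pop_params, n_neurons = as.integer(n_neurons),
      n_bins = as.integer(n_bins), frame_rate_hz = frame_rate_hz,
      kernel_tau_s = kernel_tau_s, unit_amplitude = unit_amplitude,
      noise_sd = noise_sd, seed = as.integer(seed)
    ),
    class = "ground_truth_spec"
  )
}

#' Sample a synthetic ON-probability and binary raster
#'
#' Draws per-neuron (slope, threshold) pairs once from the population 2D
#' Gaussian (slopes truncated at zero), then for every 1-s bin draws a shared
#' standard-normal input drive, maps it through each neuron's logistic to an
#' ON probability, and finally draws conditionally independent Bernoulli
#' spikes. The same spec and seed always produce bit-identical output.
#'
#' @param spec A [ground_truth_spec()].
#' @param q_thresh Probability defining the threshold (default 0.01).
#' @return A list with `p_on` and `binary` (neurons x bins matrices),
#'   `neuron_params` (tibble of per-neuron `beta`, `f_thresh`), and `drive`
#'   (the shared input per bin).
#' @export
#' @examples
#' spec <- ground_truth_spec(pop_params(-1.5, 3, 0.3, 0.3, 0),
#'                           n_neurons = 20, n_bins = 50, seed = 7)
#' ras <- sample_raster(spec)
#' dim(ras$binary)
sample_raster <- function(spec, q_thresh = 0.01) {
  stopifnot(inherits(spec, "ground_truth_spec"))
  p <- spec$pop_params
  set.seed(spec$seed)

  z1 <- stats::rnorm(spec$n_neurons)
  z2 <- stats::rnorm(spec$n_neurons)
  theta <- p$mu_thresh + p$sd_thresh * z1
  beta <- pmax(0, p$mu_slope + p$rho * p$sd_slope * z1 +
    p$sd_slope * sqrt(max(0, 1 - p$rho^2)) * z2)

  f <- stats::rnorm(spec$n_bins)
  L <- log(q_thresh / (1 - q_thresh))
  q <- stats::plogis(outer(beta, f) - (beta * theta - L))
  q[beta == 0, ] <- 0.5

  binary <- matrix(
    stats::rbinom(length(q), 1L, as.vector(q)),
    nrow = spec$n_neurons
  )
  list(
    p_on = q, binary = binary,
    neuron_params = tibble::tibble(
      neuron = seq_len(spec$n_neurons), beta = beta, f_thresh = theta
    ),
    drive = f
  )
}

#' Forward-model dF/F fluorescence from a binary raster
#'
#' Places each spike uniformly at random within its 1-s bin on the imaging
#' frame grid, convolves the spike train with a causal single-exponential
#' kernel (`unit_amplitude * exp(-t / kernel_tau_s)`), and adds i.i.d.
#' Gaussian noise. The output has `floor(n_bins * frame_rate_hz)` frames.
#' This is the forward counterpart of the deconvolution in [dff_to_rate()].
#'
#' @param binary Neurons x bins binary spike raster.
#' @param spec The [ground_truth_spec()] providing frame rate, kernel and
#'   noise settings (and the seed offset used for spike placement and noise).
#' @return Neurons x frames matrix of dF/F values, with attribute
#'   `frame_rate_hz`.
#' @export
gen_fluorescence <- function(binary, spec) {
  stopifnot(inherits(spec, "ground_truth_spec"))
  fs <- spec$frame_rate_hz
  n_frames <- floor(ncol(binary) * fs)
  decay <- exp(-1 / (fs * spec$kernel_tau_s))
  set.seed(spec$seed + 1L)

  out <- matrix(0, nrow(binary), n_frames)
  for (i in seq_len(nrow(binary))) {
    bins <- which(binary[i, ] == 1L)
    impulses <- numeric(n_frames)
    if (length(bins)) {
      t_spk <- (bins - 1) + stats::runif(length(bins))
      frames <- pmin(floor(t_spk * fs) + 1L, n_frames)
      for (fr in frames) impulses[fr] <- impulses[fr] + spec$unit_amplitude
    }
    out[i, ] <- stats::filter(impulses, decay, method = "recursive")
  }
  if (spec$noise_sd > 0) {
    out <- out + matrix(
      stats::rnorm(length(out), 0, spec$noise_sd),
      nrow(out), ncol(out)
    )
  }
  attr(out, "frame_rate_hz") <- fs
  out
}

#' Read and write neuron-by-timebin rasters as TSV
#'
#' Plain tab-separated matrices (neurons in rows, bins in columns) with an
#' optional JSON sidecar (`<file>.json`) carrying metadata such as the frame
#' rate.
#'
#' @param x Numeric matrix, neurons x bins.
#' @param path Output TSV path.
#' @param meta Optional named list written as a JSON sidecar.
#' @return `write_raster_tsv()` returns `path` invisibly; `read_raster_tsv()`
#'   returns the matrix with any sidecar metadata attached as attributes.
#' @export
write_raster_tsv <- function(x, path, meta = NULL) {
  utils::write.table(x, path,
    sep = "\t", row.names = FALSE, col.names = FALSE
  )
  if (!is.null(meta)) {
    json <- paste0(
      "{", paste(sprintf('"%s": %s', names(meta), vapply(meta, function(v) {
        if (is.character(v)) sprintf('"%s"', v) else format(v, digits = 15)
      }, character(1))), collapse = ", "), "}"
    )
    writeLines(json, paste0(path, ".json"))
  }
  invisible(path)
}

#' @rdname write_raster_tsv
#' @export
read_raster_tsv <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(m) <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- tryCatch(
      as.list(jsonlite_parse(paste(readLines(sidecar), collapse = ""))),
      error = function(e) NULL
    )
    for (nm in names(meta)) attr(m, nm) <- meta[[nm]]
  }
  m
}

jsonlite_parse <- function(txt) {
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::fromJSON(txt)
  } else {
    stop("reading sidecar metadata requires the jsonlite package", call. = FALSE)
  }
}
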