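#' Define a synthetic cohort of animal-like recordings
#'
#' A cohort groups several "animals" (independent synthetic recordings) under
#' labelled conditions (e.g. genotype x age), each generated from its group's
#' population logistic parameters. Per-animal seeds are derived
#' deterministically from the master seed, so a cohort is fully reproducible
#' and per-animal results are independent of execution order.
#'
#' @param groups A data frame with one row per group: columns `label`,
#'   `n_animals`, and the five population parameters `mu_thresh`, `mu_slope`,
#'   `sd_thresh`, `sd_slope`, `rho`.
#' @param n_neurons,n_bins Per-animal raster dimensions.
#' @param master_seed Integer master seed.
#' @return An object of class `cohort_spec`.
#' @export
#' @examples
#' groups <- tibble::tibble(
#'   label = c("WT", "KO"), n_animals = c(3, 3),
#'   mu_thresh = c(-1.5, -1.2), mu_slope = c(3, 3.5),
#'   sd_thresh = 0.4, sd_slope = 0.4, rho = 0
#' )
#' cohort_spec(groups, n_neurons = 40, n_bins = 180)
cohort_spec <- function(groups, n_neurons = 100, n_bins = 180,
                        master_seed = 1) {
  groups <- tibble::as_tibble(groups)
  need <- c(
    "label", "n_animals", "mu_thresh", "mu_slope", "sd_thresh",
    "sd_slope", "rho"
  )
  stopifnot(all(need %in% names(groups)))
  if (anyDuplicated(groups$label)) stop("group labels must be unique", call. = FALSE)
  structure(
    list(
      groups = groups, n_neurons = n_neurons, n_bins = n_bins,
      master_seed = as.integer(master_seed)
    ),
    class = "cohort_spec"
  )
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' For each animal: generates a ground-truth raster (and optionally a dF/F
#' movie pushed back through the calcium pipeline), computes the three
#' activity statistics, fits the population logistic model, and estimates
#' the standardized 100-neuron entropy/neuron. Group-level comparisons
#' (bootstrap mean tests on each statistic and on the fitted mean
#' slope/threshold, plus the 2D mean-shift confidence ellipse) are computed
#' between every pair of groups.
#'
#' @param spec A [cohort_spec()].
#' @param stages Character subset of `c("stats", "fit", "entropy")`;
#'   group comparisons cover whichever stages ran.
#' @param via_calcium If `TRUE`, statistics are computed from a synthetic
#'   dF/F movie through [binarize_dff()] instead of directly from the
#'   ON-probability raster.
#' @param fit_args,entropy_args Named lists of extra arguments passed to
#'   [fit_population()] and [entropy_vs_N()].
#' @param n_boot Bootstrap resamples for the group tests (default 1e4).
#' @return A list of class `cohort_result`: `animals` (one tibble row per
#'   animal with statistics, fitted parameters and entropy), `comparisons`
#'   (tibble of pairwise bootstrap tests), `ellipses` (named list of
#'   [confidence_ellipse()] objects for the slope-threshold shift), and
#'   `manifest` (seeds and settings for reproducibility).
#' @export
run_cohort <- function(spec, stages = c("stats", "fit", "entropy"),
                       via_calcium = FALSE, fit_args = list(),
                       entropy_args = list(), n_boot = 1e4) {
  stopifnot(inherits(spec, "cohort_spec"))
  stages <- match.arg(stages, c("stats", "fit", "entropy"), several.ok = TRUE)

  animal_rows <- list()
  animal_id <- 0L
  for (gi in seq_len(nrow(spec$groups))) {
    g <- spec$groups[gi, ]
    for (a in seq_len(g$n_animals)) {
      animal_id <- animal_id + 1L
      seed_a <- spec$master_seed + 7919L * animal_id
      row <- tibble::tibble(
        animal = animal_id, group = g$label, seed = seed_a
      )
      res <- tryCatch(
        run_animal(g, spec, seed_a, stages, via_calcium, fit_args,
          entropy_args
        ),
        error = function(e) {
          warning("animal ", animal_id, " failed: ", conditionMessage(e),
            call. = FALSE
          )
          NULL
        }
      )
      if (is.null(res)) {
        row$failed <- TRUE
      } else {
        row <- dplyr::bind_cols(row, res)
        row$failed <- FALSE
      }
      animal_rows[[animal_id]] <- row
    }
  }
  animals <- dplyr::bind_rows(animal_rows)

  comparisons <- list()
  ellipses <- list()
  labels <- spec$groups$label
  stat_cols <- intersect(
    c(
      "mean_rate", "sd_rate", "mean_corr",
      "fit_mu_slope", "fit_mu_thresh", "h100"
    ),
    names(animals)
  )
  if (length(labels) >= 2) {
    pairs <- utils::combn(labels, 2, simplify = FALSE)
    for (pr in pairs) {
      a1 <- animals[animals$group == pr[1] & !animals$failed, ]
      a2 <- animals[animals$group == pr[2] & !animals$failed, ]
      for (sc in stat_cols) {
        bt <- bootstrap_mean_diff(a1[[sc]], a2[[sc]],
          n_boot = n_boot,
          seed = spec$master_seed + 13L
        )
        comparisons[[length(comparisons) + 1L]] <- tibble::tibble(
          group1 = pr[1], group2 = pr[2], statistic = sc,
          delta = bt$delta_obs, p_value = bt$p_value
        )
      }
      if (all(c("fit_mu_slope", "fit_mu_thresh") %in% names(animals)) &&
        nrow(a1) >= 2 && nrow(a2) >= 2) {
        ellipses[[paste(pr, collapse = "_vs_")]] <- ellipse_mean_diff(
          a1[, c("fit_mu_slope", "fit_mu_thresh")],
          a2[, c("fit_mu_slope", "fit_mu_thresh")],
          seed = spec$master_seed + 17L
        )
      }
    }
  }

  structure(
    list(
      animals = animals,
      comparisons = dplyr::bind_rows(comparisons),
      ellipses = ellipses,
      manifest = list(
        master_seed = spec$master_seed, stages = stages,
        via_calcium = via_calcium, n_neurons = spec$n_neurons,
        n_bins = spec$n_bins, n_boot = n_boot,
        animal_seeds = animals$seed, groups = spec$groups
      )
    ),
    class = "cohort_result"
  )
}

run_animal <- function(g, spec, seed_a, stages, via_calcium, fit_args,
                       entropy_args) {
  pp <- pop_params(g$mu_thresh, g$mu_slope, g$sd_thresh, g$sd_slope, g$rho)
  gt <- ground_truth_spec(pp,
    n_neurons = spec$n_neurons, n_bins = spec$n_bins, seed = seed_a
  )
  ras <- sample_raster(gt)
  # Statistics live on the spiking scale. Through the calcium route the
  # ON-probability raster estimates spiking from dF/F (as for real movies);
  # on the direct route the binary raster itself is the spiking record. The
  # exact per-bin q traces are not used for correlations: all neurons share
  # the input drive, so noiseless q traces are near-perfectly correlated
  # regardless of the parameters.
  p_on <- if (via_calcium) {
    dff <- gen_fluorescence(ras$binary, gt)
    binarize_dff(dff, frame_rate_hz = gt$frame_rate_hz)$p_on
  } else {
    ras$binary
  }

  out <- tibble::tibble(.rows = 1)
  st <- summary_stats(p_on)
  if ("stats" %in% stages) {
    out <- dplyr::bind_cols(out, st[, c("mean_rate", "sd_rate", "mean_corr")])
  }
  if ("fit" %in% stages) {
    fit <- do.call(fit_population, c(
      list(target = st, seed = seed_a + 1L), fit_args
    ))
    out$fit_mu_thresh <- fit$params$mu_thresh
    out$fit_mu_slope <- fit$params$mu_slope
    out$fit_sd_thresh <- fit$params$sd_thresh
    out$fit_sd_slope <- fit$params$sd_slope
    out$fit_rho <- fit$params$rho
    out$fit_error <- fit$error
    out$fit_converged <- fit$converged
  }
  if ("entropy" %in% stages) {
    ec <- do.call(entropy_vs_N, c(
      list(raster = p_on, seed = seed_a + 2L), entropy_args
    ))
    out$h100 <- ec$h100
    out$entropy_fit_converged <- ec$converged
  }
  out
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("Cohort result:", nrow(x$animals), "animals,",
    nrow(x$comparisons), "group comparisons\n")
  invisible(x)
}
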