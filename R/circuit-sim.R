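#' Convert a PSP amplitude to a peak synaptic conductance
#'
#' Synaptic strengths are reported in the literature as PSP amplitudes, but
#' the model's synapses are conductance-based. This returns the peak
#' conductance (in units of the target neuron's leak conductance) such that
#' the analytic peak of the linearized single-synapse voltage response - a
#' bi-exponential with the target's membrane and synaptic time constants,
#' driving force evaluated at the holding potential (rest for EPSPs, -55 mV
#' for IPSPs) - equals the requested amplitude. When the synaptic and
#' membrane time constants coincide the bi-exponential degenerates to an
#' alpha function, handled in closed form.
#'
#' @param psp_mv PSP amplitude magnitude in mV (vectorized).
#' @param post_type Target cell type: `"E"`, `"Ipv"`, `"I5ht"` or `"Isom"`.
#' @param syn_kind `"e"` (excitatory) or `"i"` (inhibitory).
#' @param params A [circuit_params()] object.
#' @return Peak conductance(s), dimensionless (leak-conductance units).
#' @export
#' @examples
#' psp_to_conductance(0.5, "E", "e", circuit_params())
psp_to_conductance <- function(psp_mv, post_type, syn_kind = c("e", "i"),
                               params = circuit_params()) {
  syn_kind <- match.arg(syn_kind)
  stopifnot(all(psp_mv >= 0), post_type %in% names(params$taum))
  taum <- params$taum[[post_type]]
  taus <- if (syn_kind == "e") {
    params$tausyn_e[[post_type]]
  } else {
    params$tausyn_i[[post_type]]
  }
  drive <- if (syn_kind == "e") {
    params$erev_e[[post_type]] - params$vrest[[post_type]]
  } else {
    params$erev_i[[post_type]] - params$ipsp_hold
  }
  psp_mv / (abs(drive) * biexp_peak_factor(taum, taus))
}

# peak of (taus/(taum - taus)) * (exp(-t/taum) - exp(-t/taus)) over t >= 0;
# limit taus -> taum is the alpha-function peak exp(-1)
biexp_peak_factor <- function(taum, taus) {
  if (abs(taum - taus) < 1e-9 * taum) {
    return(exp(-1))
  }
  tstar <- log(taum / taus) * taum * taus / (taum - taus)
  (taus / (taum - taus)) * (exp(-tstar / taum) - exp(-tstar / taus))
}

#' Build a random network realization of the circuit
#'
#' Draws Bernoulli connectivity for every connection class with non-zero
#' connection probability (no self-synapses), draws each synapse's PSP
#' amplitude from the class log-normal (location `log(median)`, ln-scale
#' variance `2 log(mean/median)`, capped at 8 mV), and converts amplitudes
#' to peak conductances via [psp_to_conductance()]. Deterministic per seed.
#'
#' @param params A [circuit_params()] object.
#' @param seed Integer build seed.
#' @return An object of class `network_realization`: CSR synapse arrays over
#'   presynaptic units (L4 sources first, then L2/3 neurons), per-neuron
#'   intrinsic vectors, scaled population counts, a cell-type factor, and
#'   the build seed.
#' @export
build_network <- function(params, seed = 1) {
  stopifnot(inherits(params, "circuit_params"))
  validate_circuit_params(params)
  set.seed(as.integer(seed) %% .Machine$integer.max)

  types <- c("E", "Ipv", "I5ht", "Isom")
  n_pop <- pmax(1L, as.integer(round(params$counts * params$scale)))
  names(n_pop) <- names(params$counts)
  n_neurons <- sum(n_pop[types])
  n_l4 <- n_pop[["EL4"]]

  cell_type <- factor(rep(types, times = n_pop[types]), levels = types)
  offset <- c(0, cumsum(n_pop[types]))[seq_along(types)]
  names(offset) <- types

  w_fac <- if (params$scale_compensation == "weights") 1 / params$scale else 1

  pre_u <- integer(0); post_i <- integer(0)
  g_all <- numeric(0); prel_all <- numeric(0); inh_all <- integer(0)

  for (pre in c("EL4", types)) {
    n_pre <- if (pre == "EL4") n_l4 else n_pop[[pre]]
    pre_base <- if (pre == "EL4") 0L else n_l4 + offset[[pre]]
    is_inh <- !(pre %in% c("E", "EL4"))
    kind <- if (is_inh) "i" else "e"
    for (post in types) {
      pc <- params$pcon[pre, post]
      if (pc <= 0) next
      n_post <- n_pop[[post]]
      hit <- which(stats::runif(n_pre * n_post) < pc)
      if (!length(hit)) next
      pre_loc <- ((hit - 1L) %% n_pre) + 1L
      post_loc <- ((hit - 1L) %/% n_pre) + 1L
      if (pre == post) {
        keep <- pre_loc != post_loc
        pre_loc <- pre_loc[keep]; post_loc <- post_loc[keep]
      }
      n_syn <- length(pre_loc)
      if (!n_syn) next
      mn <- params$w_mean[pre, post] * w_fac
      md <- params$w_median[pre, post] * w_fac
      sdlog2 <- 2 * log(mn / md)
      psp <- if (sdlog2 <= 0) {
        rep(md, n_syn)
      } else {
        stats::rlnorm(n_syn, meanlog = log(md), sdlog = sqrt(sdlog2))
      }
      psp <- pmin(psp, params$psp_cap)
      gfac <- psp_to_conductance(1, post, kind, params)
      pre_u <- c(pre_u, pre_base + pre_loc - 1L)
      post_i <- c(post_i, offset[[post]] + post_loc - 1L)
      g_all <- c(g_all, psp * gfac)
      prel_all <- c(prel_all, rep(params$prel[pre, post], n_syn))
      inh_all <- c(inh_all, rep(as.integer(is_inh), n_syn))
    }
  }

  ord <- order(pre_u)
  pre_u <- pre_u[ord]
  n_units <- n_l4 + n_neurons
  ptr <- c(0L, cumsum(tabulate(pre_u + 1L, nbins = n_units)))

  net <- list(
    n_neurons = n_neurons, n_l4 = n_l4, n_pop = n_pop,
    cell_type = cell_type,
    syn_ptr = as.integer(ptr), syn_post = as.integer(post_i[ord]),
    syn_g = g_all[ord], syn_prel = prel_all[ord], syn_inh = inh_all[ord],
    vrest = unname(params$vrest[as.character(cell_type)]),
    vth = unname(params$vth[as.character(cell_type)]),
    taum = unname(params$taum[as.character(cell_type)]),
    tref = unname(params$tref[as.character(cell_type)]),
    tausyn_e = unname(params$tausyn_e[as.character(cell_type)]),
    tausyn_i = unname(params$tausyn_i[as.character(cell_type)]),
    erev_e = unname(params$erev_e[as.character(cell_type)]),
    erev_i = unname(params$erev_i[as.character(cell_type)]),
    dt = params$dt, trial_ms = params$trial_ms,
    l4_center_ms = params$l4_center_ms, l4_jitter_ms = params$l4_jitter_ms,
    build_seed = seed
  )
  class(net) <- "network_realization"
  net
}

#' @export
print.network_realization <- function(x, ...) {
  cat("Network realization:", x$n_neurons, "L2/3 neurons,", x$n_l4,
    "L4 sources,", length(x$syn_post), "synapses\n")
  invisible(x)
}

#' Simulate one stimulation trial
#'
#' Runs a 50 ms forward-Euler trial: each active L4 source emits a single
#' spike at a time drawn from a Gaussian (s.d. 2 ms) centered mid-window,
#' clipped to the trial; every presynaptic spike gates its synapses through
#' independent Bernoulli release draws. A neuron is scored as responding if
#' it crosses its spike threshold at least once (extra spikes are
#' disregarded).
#'
#' @param net A [build_network()] realization.
#' @param l4_active Integer indices (1-based) of the active L4 sources.
#' @param spike_times_ms Optional spike time (ms) per active source; drawn
#'   from the jittered Gaussian if omitted.
#' @param seed Optional seed (set before time/release draws).
#' @return Logical vector, length `n_neurons`: responded or not. Spike
#'   counts are attached as attribute `n_spikes`.
#' @export
run_trial <- function(net, l4_active, spike_times_ms = NULL, seed = NULL) {
  stopifnot(inherits(net, "network_realization"))
  if (length(l4_active)) {
    stopifnot(all(l4_active >= 1), all(l4_active <= net$n_l4))
  }
  if (!is.null(seed)) set.seed(as.integer(seed) %% .Machine$integer.max)
  if (is.null(spike_times_ms) && length(l4_active)) {
    spike_times_ms <- pmin(
      pmax(stats::rnorm(length(l4_active), net$l4_center_ms, net$l4_jitter_ms), 0),
      net$trial_ms - net$dt
    )
  }
  n_steps <- as.integer(round(net$trial_ms / net$dt))
  step_of <- rep(-1L, net$n_l4)
  if (length(l4_active)) {
    step_of[l4_active] <- as.integer(floor(spike_times_ms / net$dt))
  }
  counts <- lif_trial_cpp(
    net$n_neurons, net$n_l4,
    net$syn_ptr, net$syn_post, net$syn_g, net$syn_prel, net$syn_inh,
    step_of,
    net$vrest, net$vth, net$taum, net$tref,
    net$tausyn_e, net$tausyn_i, net$erev_e, net$erev_i,
    net$dt, n_steps
  )
  out <- counts >= 1L
  attr(out, "n_spikes") <- counts
  out
}

#' Per-neuron response probability curves over L4 activity levels
#'
#' For each fraction `f` of active L4 sources: draws `n_perm` random ON
#' subsets; for each subset, draws one set of spike times and repeats the
#' trial `n_rep` times over the vesicle-release randomness. A neuron's ON
#' probability at `f` is the fraction of the `n_perm * n_rep` trials in
#' which it responded.
#'
#' @param net A [build_network()] realization.
#' @param f_levels Fractions of L4 activated, in `[0, 1]` (default
#'   `seq(0, 1, by = 0.1)`).
#' @param n_perm Random ON-subset allocations per level (default 10).
#' @param n_rep Release-noise repeats per allocation (default 10).
#' @param seed Integer seed for subsets, spike times and release draws.
#' @return An object of class `response_curve`: list with `q` (neurons x
#'   levels matrix of ON probabilities), `f_levels`, `cell_type`,
#'   `n_trials`.
#' @export
response_curve <- function(net, f_levels = seq(0, 1, by = 0.1),
                           n_perm = 10, n_rep = 10, seed = 1) {
  stopifnot(
    inherits(net, "network_realization"),
    all(f_levels >= 0), all(f_levels <= 1), !is.unsorted(f_levels)
  )
  set.seed(as.integer(seed) %% .Machine$integer.max)
  q <- matrix(0, net$n_neurons, length(f_levels))
  for (k in seq_along(f_levels)) {
    n_on <- round(f_levels[k] * net$n_l4)
    hits <- integer(net$n_neurons)
    for (perm in seq_len(n_perm)) {
      active <- if (n_on > 0) sample.int(net$n_l4, n_on) else integer(0)
      times <- if (n_on > 0) {
        pmin(pmax(
          stats::rnorm(n_on, net$l4_center_ms, net$l4_jitter_ms), 0
        ), net$trial_ms - net$dt)
      } else {
        numeric(0)
      }
      for (rep_i in seq_len(n_rep)) {
        hits <- hits + run_trial(net, active, spike_times_ms = times)
      }
    }
    q[, k] <- hits / (n_perm * n_rep)
  }
  structure(
    list(
      q = q, f_levels = f_levels, cell_type = net$cell_type,
      n_trials = n_perm * n_rep
    ),
    class = "response_curve"
  )
}

#' @export
tidy.response_curve <- function(x, ...) {
  tibble::tibble(
    neuron = rep(seq_len(nrow(x$q)), times = ncol(x$q)),
    cell_type = rep(as.character(x$cell_type), times = ncol(x$q)),
    f = rep(x$f_levels, each = nrow(x$q)),
    q = as.vector(x$q)
  )
}

#' @export
autoplot.response_curve <- function(object, ...) {
  ggplot2::ggplot(
    tidy(object),
    ggplot2::aes(
      x = .data$f, y = .data$q,
      group = .data$neuron, colour = .data$cell_type
    )
  ) +
    ggplot2::geom_line(alpha = 0.25) +
    ggplot2::labs(x = "fraction of L4 activated", y = "ON probability")
}

#' Fit logistic curves to a response-curve object
#'
#' Convenience wrapper: per-neuron logistic fits of the simulated ON
#' probabilities against the L4 activity fraction.
#'
#' @param rc A [response_curve()] result.
#' @inheritParams fit_logistic
#' @return Tibble as from [fit_logistic_many()], plus `cell_type`.
#' @export
fit_response_curve <- function(rc, q_thresh = 0.01, beta_max = 1e4) {
  fits <- fit_logistic_many(rc$q, rc$f_levels, rc$n_trials,
    q_thresh = q_thresh, beta_max = beta_max, domain = "l4_fraction"
  )
  fits$cell_type <- as.character(rc$cell_type)
  fits
}

# mean (slope, threshold) over valid excitatory fits
mean_e_fit <- function(fits) {
  ok <- fits$cell_type == "E" & !fits$degenerate & !fits$separated &
    is.finite(fits$f_thresh)
  tibble::tibble(
    mean_slope = mean(fits$beta[ok]),
    mean_thresh = mean(fits$f_thresh[ok]),
    n_valid = sum(ok)
  )
}

#' Single-parameter sensitivity sweep of the circuit input-output function
#'
#' For each parameter perturbation (name x direction), rebuilds the network,
#' reruns the stimulation protocol, refits the per-neuron logistics, and
#' reports the shift in mean (slope, threshold) of the excitatory neurons
#' relative to the default network. The same seeds are reused across
#' conditions for variance reduction; degenerate fits are excluded and
#' counted.
#'
#' @param params Baseline [circuit_params()].
#' @param names Parameters to perturb (subset of [sweep_param_names()]).
#' @param directions Perturbation directions (default `c(1, -1)`). A
#'   direction of `0` reruns the unperturbed model (null perturbation).
#' @param delta Relative perturbation size (default 0.2).
#' @param f_levels,n_perm,n_rep Stimulation protocol (see [response_curve()]).
#' @param n_seeds Independent network/stimulus seeds to average over.
#' @param seed Master seed.
#' @return A tibble with one row per (param, direction, seed): `d_slope`,
#'   `d_thresh` (shift vs the same-seed default network), `n_valid_neurons`,
#'   and the default means.
#' @export
sweep_sensitivity <- function(params, names, directions = c(1, -1),
                              delta = 0.2, f_levels = seq(0, 1, by = 0.1),
                              n_perm = 10, n_rep = 10, n_seeds = 3, seed = 1) {
  out <- list()
  for (s in seq_len(n_seeds)) {
    build_seed <- seed + 1000L * s
    stim_seed <- seed + 1000L * s + 1L
    net0 <- build_network(params, build_seed)
    rc0 <- response_curve(net0, f_levels, n_perm, n_rep, seed = stim_seed)
    base <- mean_e_fit(fit_response_curve(rc0))
    for (nm in names) {
      for (dir in directions) {
        p2 <- if (dir == 0) params else perturb_params(params, nm, dir, delta)
        net2 <- build_network(p2, build_seed)
        rc2 <- response_curve(net2, f_levels, n_perm, n_rep, seed = stim_seed)
        alt <- mean_e_fit(fit_response_curve(rc2))
        out[[length(out) + 1L]] <- tibble::tibble(
          param = nm, direction = dir, seed = s,
          d_slope = alt$mean_slope - base$mean_slope,
          d_thresh = alt$mean_thresh - base$mean_thresh,
          n_valid_neurons = alt$n_valid,
          default_slope = base$mean_slope,
          default_thresh = base$mean_thresh
        )
      }
    }
  }
  dplyr::bind_rows(out)
}
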