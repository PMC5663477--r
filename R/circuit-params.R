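#' Default L2/3 barrel-cortex circuit parameters
#'
#' The full parameter set of the conductance-based LIF model of the layer 2/3
#' somatosensory microcircuit: four reciprocally connected L2/3 populations
#' (excitatory `E`, parvalbumin `Ipv`, 5HT3aR `I5ht`, somatostatin `Isom`)
#' driven by a population of L4 excitatory spike sources (`EL4`). Values are
#' the published in-vitro estimates for juvenile wild-type mice; PSP
#' amplitudes are stated as mean/median magnitudes of a per-synapse
#' log-normal distribution, capped at 8 mV.
#'
#' `scale` shrinks all five population counts proportionally for fast
#' experimentation. Because per-neuron synaptic convergence shrinks with the
#' populations, `scale_compensation = "weights"` (the default) multiplies all
#' PSP amplitudes by `1/scale` so the aggregate synaptic drive per neuron is
#' preserved; `"none"` rescales nothing.
#'
#' @param scale Population scale factor in (0, 1] (default 1).
#' @param scale_compensation `"weights"` or `"none"` (see above).
#' @return An object of class `circuit_params`: a list of named vectors and
#'   matrices (counts; per-type intrinsic properties; synaptic time constants
#'   and reversal potentials; connection/release probability and PSP
#'   amplitude matrices indexed pre x post; integration settings).
#' @export
#' @examples
#' p <- circuit_params(scale = 0.1)
#' p$counts
circuit_params <- function(scale = 1, scale_compensation = c("weights", "none")) {
  stopifnot(scale > 0, scale <= 1)
  scale_compensation <- match.arg(scale_compensation)
  types <- c("E", "Ipv", "I5ht", "Isom")
  pre_types <- c("EL4", types)

  m <- function(x) {
    matrix(x,
      nrow = 5, ncol = 4, byrow = TRUE,
      dimnames = list(pre_types, types)
    )
  }

  p <- list(
    counts = c(E = 1700, Ipv = 70, I5ht = 115, Isom = 45, EL4 = 1500),
    vrest = c(E = -68, Ipv = -68, I5ht = -62, Isom = -57),
    vth = c(E = -38, Ipv = -37.4, I5ht = -36, Isom = -40),
    rin = c(E = 160, Ipv = 100, I5ht = 200, Isom = 250), # MOhm
    taum = c(E = 28, Ipv = 21, I5ht = 10, Isom = 30), # ms
    tref = c(E = 55.5, Ipv = 5.4, I5ht = 21.3, Isom = 20), # ms
    tausyn_e = c(E = 2, Ipv = 2, I5ht = 2, Isom = 2), # ms
    tausyn_i = c(E = 40, Ipv = 16, I5ht = 40, Isom = 40), # ms
    erev_e = c(E = 0, Ipv = 0, I5ht = 0, Isom = 0), # mV
    erev_i = c(E = -68, Ipv = -68, I5ht = -62, Isom = -57), # mV
    pcon = m(c(
      0.15, 0.15, 0, 0.15, # EL4 ->
      0.17, 0.575, 0.24, 0.5, # E ->
      0.6, 0.55, 0.24, 0, # Ipv ->
      0.465, 0.38, 0.38, 0, # I5ht ->
      0.5, 0, 0, 0 # Isom ->
    )),
    prel = m(c(
      0.25, 0.25, 0, 0.25,
      0.25, 0.25, 0.25, 0.25,
      0.25, 0.25, 0.25, 0,
      0.25, 0.25, 0.25, 0,
      0.25, 0, 0, 0
    )),
    w_mean = m(c(
      0.80, 0.80, 0, 0.80,
      0.37, 0.82, 0.39, 0.50,
      0.52, 0.56, 0.83, 0,
      0.49, 0.49, 0.37, 0,
      0.50, 0, 0, 0
    )),
    w_median = m(c(
      0.48, 0.48, 0, 0.48,
      0.20, 0.68, 0.19, 0.40,
      0.29, 0.44, 0.60, 0,
      0.30, 0.15, 0.23, 0,
      0.40, 0, 0, 0
    )),
    psp_cap = 8, # mV
    ipsp_hold = -55, # mV holding potential defining IPSP amplitudes
    dt = 0.01, # ms
    trial_ms = 50,
    l4_center_ms = 25,
    l4_jitter_ms = 2,
    n_perm = 10,
    n_rep = 10,
    scale = scale,
    scale_compensation = scale_compensation
  )
  class(p) <- "circuit_params"
  validate_circuit_params(p)
  p
}

validate_circuit_params <- function(p) {
  stopifnot(
    all(p$pcon >= 0 & p$pcon <= 1), all(p$prel >= 0 & p$prel <= 1),
    all(p$taum > 0), all(p$tausyn_e > 0), all(p$tausyn_i > 0),
    all(p$rin > 0), p$dt > 0, all(p$vrest < p$vth)
  )
  conn <- p$pcon > 0
  if (any(p$w_mean[conn] < p$w_median[conn])) {
    stop("log-normal PSP pairs require mean >= median", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.circuit_params <- function(x, ...) {
  cat("L2/3 circuit parameters (scale ", x$scale, ")\n", sep = "")
  cat("  populations:", paste(names(x$counts), x$counts, sep = "="), "\n")
  cat("  connected classes:", sum(x$pcon > 0), "of", length(x$pcon), "\n")
  invisible(x)
}

#' Names of the parameters included in the perturbation sweep
#'
#' The 76 tested parameters: all population counts, intrinsic properties
#' (excluding refractory periods, which are irrelevant when responses are
#' scored as any-spike), synaptic time constants and reversal potentials,
#' the non-zero connection and release probabilities, and the 14 PSP
#' amplitude mean/median pairs (perturbed in tandem).
#'
#' @return Character vector of 76 parameter names accepted by
#'   [perturb_params()].
#' @export
sweep_param_names <- function() {
  types <- c("E", "Ipv", "I5ht", "Isom")
  p <- circuit_params()
  conn <- which(p$pcon > 0, arr.ind = TRUE)
  classes <- paste0(rownames(p$pcon)[conn[, 1]], colnames(p$pcon)[conn[, 2]])
  c(
    paste0("N_", c(types, "EL4")),
    paste0("Vrest_", types), paste0("Vth_", types),
    paste0("Rin_", types), paste0("taum_", types),
    paste0("tausyn_", rep(types, each = 2), "_", c("e", "i")),
    "Erev_e", paste0("Erev_", types, "i"),
    paste0("pcon_", classes), paste0("prel_", classes), paste0("w_", classes)
  )
}

#' Perturb one circuit parameter by a relative amount
#'
#' Applies the single-parameter perturbation used in the sensitivity sweep.
#' Parameters that naturally range upward from zero (counts, probabilities,
#' resistances, time constants, PSP amplitudes) are scaled multiplicatively
#' by `1 + direction * delta`. Voltages are perturbed relative to a natural
#' reference instead: resting voltage moves toward spike threshold by
#' `delta * (Vth - Vrest)`; spike threshold moves away from rest by the same
#' fraction of the gap; excitatory reversal potentials scale their distance
#' from rest; inhibitory reversal potentials scale their distance from spike
#' threshold. PSP mean/median pairs move in tandem. Probabilities pushed
#' above 1 are clamped with a warning.
#'
#' @param params A [circuit_params()] object.
#' @param name One of [sweep_param_names()].
#' @param direction `+1` (increase) or `-1` (decrease).
#' @param delta Relative perturbation size (default 0.2).
#' @return A new `circuit_params` object.
#' @export
#' @examples
#' p2 <- perturb_params(circuit_params(), "prel_EE", +1)
#' p2$prel["E", "E"] # 0.30
perturb_params <- function(params, name, direction, delta = 0.2) {
  stopifnot(inherits(params, "circuit_params"), direction %in% c(-1, 1))
  if (!name %in% sweep_param_names()) {
    stop("unknown or untestable parameter: ", name, call. = FALSE)
  }
  fac <- 1 + direction * delta
  p <- params
  split_class <- function(cls) {
    pre <- c("EL4", "E", "Ipv", "I5ht", "Isom")
    hit <- pre[startsWith(cls, pre)]
    hit <- hit[which.max(nchar(hit))]
    c(hit, substring(cls, nchar(hit) + 1))
  }
  clamp01 <- function(x, what) {
    if (x > 1) {
      warning(what, " perturbed above 1; clamped", call. = FALSE)
      x <- 1
    }
    x
  }

  if (startsWith(name, "N_")) {
    t <- sub("N_", "", name)
    p$counts[t] <- max(1, round(p$counts[t] * fac))
  } else if (startsWith(name, "Vrest_")) {
    t <- sub("Vrest_", "", name)
    gap <- p$vth[t] - p$vrest[t]
    p$vrest[t] <- p$vrest[t] + direction * delta * gap
  } else if (startsWith(name, "Vth_")) {
    t <- sub("Vth_", "", name)
    gap <- p$vth[t] - p$vrest[t]
    p$vth[t] <- p$vth[t] + direction * delta * gap
  } else if (startsWith(name, "Rin_")) {
    t <- sub("Rin_", "", name)
    p$rin[t] <- p$rin[t] * fac
  } else if (startsWith(name, "taum_")) {
    t <- sub("taum_", "", name)
    p$taum[t] <- p$taum[t] * fac
  } else if (grepl("^tausyn_", name)) {
    parts <- strsplit(sub("tausyn_", "", name), "_")[[1]]
    slot <- paste0("tausyn_", parts[2])
    p[[slot]][parts[1]] <- p[[slot]][parts[1]] * fac
  } else if (name == "Erev_e") {
    p$erev_e <- p$vrest + fac * (p$erev_e - p$vrest)
  } else if (grepl("^Erev_.*i$", name)) {
    t <- sub("i$", "", sub("Erev_", "", name))
    p$erev_i[t] <- p$vth[t] + fac * (p$erev_i[t] - p$vth[t])
  } else if (startsWith(name, "pcon_")) {
    cls <- split_class(sub("pcon_", "", name))
    p$pcon[cls[1], cls[2]] <- clamp01(p$pcon[cls[1], cls[2]] * fac, name)
  } else if (startsWith(name, "prel_")) {
    cls <- split_class(sub("prel_", "", name))
    p$prel[cls[1], cls[2]] <- clamp01(p$prel[cls[1], cls[2]] * fac, name)
  } else if (startsWith(name, "w_")) {
    cls <- split_class(sub("w_", "", name))
    p$w_mean[cls[1], cls[2]] <- p$w_mean[cls[1], cls[2]] * fac
    p$w_median[cls[1], cls[2]] <- p$w_median[cls[1], cls[2]] * fac
  } else {
    stop("unhandled parameter: ", name, call. = FALSE)
  }
  validate_circuit_params(p)
  p
}

#' Read circuit parameters from a YAML config file
#'
#' Loads a structured-text parameter file in the layout of the shipped
#' default (`system.file("extdata", "circuit-params.yaml", package =
#' "popcircuit")`), which carries the full default parameter table. Entries
#' omitted from the file keep their defaults.
#'
#' @param path Path to a YAML file; default is the shipped parameter table.
#' @inheritParams circuit_params
#' @return A [circuit_params()] object.
#' @export
read_circuit_params <- function(path = system.file("extdata",
                                  "circuit-params.yaml",
                                  package = "popcircuit"
                                ), scale = 1,
                                scale_compensation = c("weights", "none")) {
  cfg <- yaml::read_yaml(path)
  p <- circuit_params(scale = scale, scale_compensation = scale_compensation)
  as_named <- function(x) unlist(x)
  for (nm in c(
    "counts", "vrest", "vth", "rin", "taum", "tref", "tausyn_e",
    "tausyn_i", "erev_e", "erev_i"
  )) {
    if (!is.null(cfg[[nm]])) {
      v <- as_named(cfg[[nm]])
      p[[nm]][names(v)] <- v
    }
  }
  for (nm in c("pcon", "prel", "w_mean", "w_median")) {
    if (!is.null(cfg[[nm]])) {
      for (pre in names(cfg[[nm]])) {
        v <- as_named(cfg[[nm]][[pre]])
        p[[nm]][pre, names(v)] <- v
      }
    }
  }
  for (nm in c(
    "psp_cap", "ipsp_hold", "dt", "trial_ms", "l4_center_ms", "l4_jitter_ms"
  )) {
    if (!is.null(cfg[[nm]])) p[[nm]] <- cfg[[nm]]
  }
  validate_circuit_params(p)
  p
}
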