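test_that("PSP-to-conductance conversion is linear and matches an ODE oracle", {
  p <- circuit_params()
  expect_equal(psp_to_conductance(0, "E", "e", p), 0)
  g1 <- psp_to_conductance(0.5, "E", "e", p)
  expect_equal(psp_to_conductance(1.0, "E", "e", p), 2 * g1)

  skip_if_not_installed("deSolve")
  # linearized single-PSP response integrated numerically (driving force at
  # the holding potential), peak must equal the requested amplitude within 1%
  cases <- list(
    list(type = "E", kind = "e", amp = 0.5, hold = -68),
    list(type = "Ipv", kind = "i", amp = 0.6, hold = -55),
    list(type = "Isom", kind = "e", amp = 0.3, hold = -57)
  )
  for (cs in cases) {
    g <- psp_to_conductance(cs$amp, cs$type, cs$kind, p)
    taum <- p$taum[[cs$type]]
    taus <- if (cs$kind == "e") p$tausyn_e[[cs$type]] else p$tausyn_i[[cs$type]]
    erev <- if (cs$kind == "e") p$erev_e[[cs$type]] else p$erev_i[[cs$type]]
    drive <- erev - cs$hold
    rhs <- function(t, y, parms) {
      list((g * exp(-t / taus) * drive - y[1]) / taum)
    }
    out <- deSolve::ode(c(u = 0), seq(0, 300, 0.01), rhs, NULL)
    expect_equal(max(abs(out[, 2])), cs$amp, tolerance = 0.01)
  }
})

test_that("degenerate equal time constants use the alpha-function limit", {
  p <- circuit_params()
  p$tausyn_e["E"] <- p$taum[["E"]]
  g <- psp_to_conductance(0.5, "E", "e", p)
  expect_true(is.finite(g) && g > 0)
  # alpha function peak factor is exp(-1)
  expect_equal(g, 0.5 / (68 * exp(-1)), tolerance = 1e-9)
})

test_that("network realization honors connectivity and weight statistics", {
  p <- tiny_params()
  expect_error(
    {
      bad <- p; bad$w_mean["E", "E"] <- 0.1 # below the median
      build_network(bad, 1)
    },
    "mean >= median"
  )

  full <- circuit_params()
  net <- build_network(full, seed = 8)
  # no self-synapses
  pre_of <- rep(seq_along(net$syn_ptr[-1]) - 1L,
    times = diff(net$syn_ptr)
  )
  l23 <- pre_of >= net$n_l4
  expect_false(any(pre_of[l23] - net$n_l4 == net$syn_post[l23]))

  # E->E synapse count within binomial bounds of pcon * N * (N-1)
  e_idx <- which(net$cell_type == "E")
  is_ee <- l23 & (pre_of - net$n_l4) < length(e_idx) &
    net$syn_post < length(e_idx)
  n_ee <- sum(is_ee)
  exp_ee <- 0.17 * 1700 * 1699
  sd_ee <- sqrt(1700 * 1699 * 0.17 * 0.83)
  expect_lt(abs(n_ee - exp_ee), 4 * sd_ee)

  # E->E sample median amplitude ~ 0.2 mV (invert the conductance factor)
  gfac <- psp_to_conductance(1, "E", "e", full)
  psp_ee <- net$syn_g[is_ee] / gfac
  expect_equal(median(psp_ee), 0.2, tolerance = 0.02)
  expect_lte(max(psp_ee), 8 + 1e-9)

  # mean = median collapses the log-normal to a point mass
  pm <- tiny_params()
  pm$w_mean["E", "E"] <- pm$w_median["E", "E"]
  netm <- build_network(pm, 1)
  # scale compensation multiplies amplitudes by 1/scale
  med <- pm$w_median["E", "E"] / pm$scale
  pre_m <- rep(seq_along(netm$syn_ptr[-1]) - 1L, times = diff(netm$syn_ptr))
  e_n <- sum(netm$cell_type == "E")
  is_ee_m <- pre_m >= netm$n_l4 & (pre_m - netm$n_l4) < e_n &
    netm$syn_post < e_n
  gf <- psp_to_conductance(1, "E", "e", pm)
  expect_equal(unique(round(netm$syn_g[is_ee_m] / gf, 9)), med)
})

test_that("zero-probability connection classes produce no synapses", {
  p <- tiny_params()
  net <- build_network(p, 3)
  pre_of <- rep(seq_along(net$syn_ptr[-1]) - 1L, times = diff(net$syn_ptr))
  # SOM neurons (last block) must have no outgoing synapses except to E
  types <- as.character(net$cell_type)
  som_pre <- which(types == "Isom") + net$n_l4 - 1L
  som_syn <- pre_of %in% som_pre
  expect_true(all(types[net$syn_post[som_syn] + 1L] == "E"))
  # 5HT3aR neurons receive nothing from L4
  i5 <- which(types == "I5ht") - 1L
  l4_syn <- pre_of < net$n_l4
  expect_false(any(net$syn_post[l4_syn] %in% i5))
})

test_that("trials are silent without input, deterministic, and refractory-capped", {
  p <- tiny_params()
  net <- build_network(p, 5)
  # no spontaneous drive: empty L4 set gives an all-zero response
  expect_true(all(!run_trial(net, integer(0))))
  r1 <- run_trial(net, 1:100, seed = 9)
  r2 <- run_trial(net, 1:100, seed = 9)
  expect_identical(r1, r2)
  # excitatory neurons (tref 55.5 ms > trial) can spike at most once
  counts <- attr(run_trial(net, seq_len(net$n_l4), seed = 1), "n_spikes")
  expect_true(all(counts[net$cell_type == "E"] <= 1))
})

test_that("a neuron relaxes to rest with its membrane time constant", {
  # passive exponential decay against the closed form, to Euler accuracy
  tr <- popcircuit:::lif_passive_trace_cpp(-48, -68, 28, 0.01, 5000)
  t_ms <- (1:5000) * 0.01
  expect_equal(tr, -68 + 20 * exp(-t_ms / 28), tolerance = 1e-4)
})

test_that("saturating drive activates E cells and responses rise with input", {
  p <- tiny_params()
  p$prel[] <- pmin(p$prel[] * 4, 1) # release certainty for the saturation probe
  net <- build_network(p, 7)
  on <- run_trial(net, seq_len(net$n_l4), seed = 2)
  expect_gt(mean(on[net$cell_type == "E"]), 0.9)
  # 5HT3aR cells respond despite receiving no direct L4 projection: they are
  # driven disynaptically by the L2/3 excitatory population
  expect_gt(mean(on[net$cell_type == "I5ht"]), 0)

  # mean E response is non-decreasing in the L4 activity level (100 trials)
  p2 <- tiny_params()
  net2 <- build_network(p2, 11)
  rc <- response_curve(net2, c(0, 0.3, 0.6, 1), n_perm = 10, n_rep = 10,
    seed = 13
  )
  e_mean <- colMeans(rc$q[net2$cell_type == "E", ])
  expect_equal(e_mean[1], 0) # f = 0 gives q = 0 everywhere
  expect_true(all(diff(e_mean) >= -0.02))
  expect_gt(e_mean[4], e_mean[1])
  expect_true(all(rc$q >= 0 & rc$q <= 1))
})

test_that("perturbations follow the relative scaling rules", {
  p <- circuit_params()
  expect_equal(perturb_params(p, "prel_EE", +1)$prel["E", "E"], 0.30)
  p2 <- perturb_params(p, "w_EE", +1)
  expect_equal(p2$w_mean["E", "E"], 0.444)
  expect_equal(p2$w_median["E", "E"], 0.24)
  # resting voltage moves 20% of the gap toward threshold
  expect_equal(perturb_params(p, "Vrest_E", +1)$vrest[["E"]], -62)
  expect_equal(perturb_params(p, "Vrest_E", -1)$vrest[["E"]], -74)
  # spike threshold moves away from rest
  expect_equal(perturb_params(p, "Vth_E", +1)$vth[["E"]], -32)
  # excitatory reversal scales its distance from rest
  expect_equal(perturb_params(p, "Erev_e", +1)$erev_e[["E"]], -68 + 1.2 * 68)
  # inhibitory reversal scales its distance from spike threshold
  expect_equal(
    perturb_params(p, "Erev_Ei", +1)$erev_i[["E"]], -38 + 1.2 * (-68 + 38)
  )
  # probabilities clamp at 1 with a warning
  phigh <- p
  phigh$pcon["Ipv", "E"] <- 0.9
  expect_warning(perturb_params(phigh, "pcon_IpvE", +1), "clamped")
  # unknown and untestable names rejected
  expect_error(perturb_params(p, "tref_E", +1), "unknown")
  expect_error(perturb_params(p, "pcon_IsomIsom", +1), "unknown")
  expect_equal(length(sweep_param_names()), 76)
})

test_that("the shipped YAML parameter table reproduces the in-code defaults", {
  path <- system.file("extdata", "circuit-params.yaml", package = "popcircuit")
  expect_true(nzchar(path))
  p_yaml <- read_circuit_params(path)
  p_code <- circuit_params()
  for (nm in c(
    "counts", "vrest", "vth", "rin", "taum", "tref", "tausyn_e", "tausyn_i",
    "erev_e", "erev_i", "pcon", "prel", "w_mean", "w_median", "psp_cap", "dt"
  )) {
    expect_equal(p_yaml[[nm]], p_code[[nm]], info = nm)
  }
})
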