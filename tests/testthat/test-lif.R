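# Leaky integrate-and-fire simulation: weights, dynamics, invariants.

chain_graph <- function(syn, nt = "ACH") {
  toy_graph(toy_edges(list("S", "T", "GNG", nt, as.character(syn))),
            nt_neuron = c(S = nt))
}

test_that("network weights are signed pair totals times the unit weight", {
  g <- toy_graph(toy_edges(
    list("E", "X", "GNG", "ACH", "10"),
    list("I", "X", "GNG", "GABA", "10"),
    list("U", "X", "GNG", "unknown", "10"),
    list("E", "Y", "GNG", "ACH", "4"),
    list("E", "Y", "SLP_L", "ACH", "6")    # neuropil rows summed before weighting
  ), nt_neuron = c(E = "ACH", I = "GABA", U = "unknown"))
  net <- build_lif_network(g)
  w <- function(pre, post) net$edges$weight[net$edges$pre_id == pre &
                                              net$edges$post_id == post]
  expect_equal(w("E", "X"), 2.75)
  expect_equal(w("I", "X"), -2.75)
  expect_length(w("U", "X"), 0)         # unknown NT: dropped by default
  expect_equal(w("E", "Y"), 2.75)       # 4 + 6 synapses pooled
  pt <- g$pair_totals
  for (i in seq_len(nrow(net$edges))) {
    tot <- pt$total_syn[pt$pre_id == net$edges$pre_id[i] &
                          pt$post_id == net$edges$post_id[i]]
    expect_equal(abs(net$edges$weight[i]), 0.275 * tot)
  }
})

test_that("zero stimulation leaves the network quiescent", {
  net <- build_lif_network(chain_graph(100))
  res <- simulate_lif(net, "S", 0, n_trials = 2, rng_seed = 1)
  expect_true(all(res$mean_rate_hz == 0))
  expect_false(any(res$activated))
})

test_that("sub-threshold drive never activates the target", {
  # 10 synapses = 2.75 mV per presynaptic spike; at 20 Hz the drive decays
  # long before the 7 mV threshold distance is reached
  net <- build_lif_network(chain_graph(10))
  res <- simulate_lif(net, "S", 20, n_trials = 3, rng_seed = 2,
                      stim_mode = "regular")
  expect_equal(res$mean_rate_hz[res$neuron_id == "T"], 0)
  expect_gt(res$mean_rate_hz[res$neuron_id == "S"], 0)
})

test_that("a strong two-neuron chain matches fine-step reference integration", {
  # one stimulus pulse; the 100-synapse connection (27.5 mV) fires the target
  params <- lif_params(n_trials = 1, stim_duration = 0.05)
  rate <- 25
  net <- build_lif_network(chain_graph(100))
  res <- simulate_lif(net, "S", rate, params = params, rng_seed = 3,
                      stim_mode = "regular", record_spikes = TRUE)
  expect_true(res$activated[res$neuron_id == "T"])

  # reference: independent forward-Euler integration at dt = 0.005 ms, fed
  # the same grid-realized stimulus train the integrator saw
  stim_s <- seq(1 / rate, params$stim_duration, by = 1 / rate)
  stim_ms <- (floor(stim_s * 1000 / params$dt) + 1) * params$dt
  oracle <- oracle_lif_motif(
    data.frame(pre = 1L, post = 2L, w = 0.275 * 100),
    list(stim_ms, numeric()), n_neurons = 2, params = params
  )
  got_steps <- attr(res, "spike_steps")[[1]][["T"]]
  got_ms <- (got_steps + 1) * params$dt
  want_ms <- oracle[[2]]
  expect_equal(length(got_ms), length(want_ms))
  expect_true(all(abs(got_ms - want_ms) <= params$dt + 1e-9))
})

test_that("a three-neuron chain propagates with reference timing", {
  g <- toy_graph(toy_edges(
    list("S", "A", "GNG", "ACH", "100"),
    list("A", "B", "GNG", "ACH", "100")
  ), nt_neuron = c(S = "ACH", A = "ACH"))
  params <- lif_params(n_trials = 1, stim_duration = 0.05)
  res <- simulate_lif(build_lif_network(g), "S", 25, params = params,
                      rng_seed = 3, stim_mode = "regular", record_spikes = TRUE)
  stim_ms <- (floor(seq(1 / 25, params$stim_duration, by = 1 / 25) *
                      1000 / params$dt) + 1) * params$dt
  oracle <- oracle_lif_motif(
    data.frame(pre = c(1L, 2L), post = c(2L, 3L), w = 27.5),
    list(stim_ms, numeric(), numeric()), n_neurons = 3, params = params
  )
  for (nm in c("A", "B")) {
    got_ms <- (attr(res, "spike_steps")[[1]][[nm]] + 1) * params$dt
    want_ms <- oracle[[match(nm, c("A", "B")) + 1]]
    expect_equal(length(got_ms), length(want_ms))
    if (length(got_ms)) {
      expect_true(all(abs(got_ms - want_ms) <= 2 * params$dt + 1e-9))
    }
  }
})

test_that("an inhibitory chain cannot fire its target", {
  net <- build_lif_network(chain_graph(100, nt = "GABA"))
  res <- simulate_lif(net, "S", 200, n_trials = 2, rng_seed = 4)
  expect_equal(res$mean_rate_hz[res$neuron_id == "T"], 0)
})

test_that("adding an inhibitory input never increases a firing neuron's rate", {
  excite_only <- toy_graph(toy_edges(
    list("S", "T", "GNG", "ACH", "100")
  ), nt_neuron = c(S = "ACH"))
  with_inh <- toy_graph(toy_edges(
    list("S", "T", "GNG", "ACH", "100"),
    list("S2", "T", "GNG", "GABA", "80")
  ), nt_neuron = c(S = "ACH", S2 = "GABA"))
  r1 <- simulate_lif(build_lif_network(excite_only), "S", 150,
                     n_trials = 3, rng_seed = 5)
  r2 <- simulate_lif(build_lif_network(with_inh), c("S", "S2"), 150,
                     n_trials = 3, rng_seed = 5)
  expect_lte(r2$mean_rate_hz[r2$neuron_id == "T"],
             r1$mean_rate_hz[r1$neuron_id == "T"])
})

test_that("no per-trial rate exceeds the refractory bound", {
  gen <- generate_connectome(small_spec(seed = 71))
  net <- build_lif_network(gen$graph)
  stim <- gen$seeds$neuron_id[gen$seeds$modality == "sugar"]
  res <- simulate_lif(net, stim, 200, n_trials = 1, rng_seed = 6)
  bound <- 1000 / lif_params()$t_refractory   # ~454.5 Hz
  expect_true(all(res$mean_rate_hz <= bound + 1e-9))
})

test_that("identical seeds give identical spike rasters", {
  gen <- generate_connectome(small_spec(seed = 73))
  net <- build_lif_network(gen$graph)
  stim <- gen$seeds$neuron_id[gen$seeds$modality == "bitter"]
  a <- simulate_lif(net, stim, 100, n_trials = 2, rng_seed = 9,
                    record_spikes = TRUE)
  b <- simulate_lif(net, stim, 100, n_trials = 2, rng_seed = 9,
                    record_spikes = TRUE)
  expect_identical(attr(a, "spike_steps"), attr(b, "spike_steps"))
  expect_identical(a$mean_rate_hz, b$mean_rate_hz)
  c <- simulate_lif(net, stim, 100, n_trials = 2, rng_seed = 10)
  expect_false(identical(a$mean_rate_hz, c$mean_rate_hz))
})

test_that("activation is monotone in stimulus rate on a purely excitatory network", {
  gen <- generate_connectome(small_spec(
    seed = 79,
    ei_fraction = list("2N" = c(sugar = 1, water = 1, bitter = 1, ir94e = 1),
                       "3N" = c(sugar = 1, water = 1, bitter = 1, ir94e = 1))
  ))
  net <- build_lif_network(gen$graph)
  l2 <- trace_second_order(gen$graph, gen$seeds)
  l3 <- trace_third_order(gen$graph, gen$seeds, l2)
  sw <- intensity_sweep(net, gen$seeds, l2, l3, "sugar",
                        rates = c(0, 25, 50, 100, 200), n_trials = 1,
                        rng_seed = 11, stim_mode = "regular")
  expect_true(all(sw$fraction[sw$rate_hz == 0] == 0))
  for (pop in unique(sw$population)) {
    fr <- sw$fraction[sw$population == pop][order(sw$rate_hz[sw$population == pop])]
    expect_true(all(diff(fr) >= 0))
  }
})

test_that("activation-vs-input summaries separate strong from weak targets", {
  # one strong and one weak 2N; only the strong one fires
  g <- toy_graph(toy_edges(
    list("G", "STRONG", "GNG", "ACH", "120"),
    list("G", "WEAK", "GNG", "ACH", "6")
  ), nt_neuron = c(G = "ACH"))
  seeds <- seed_sets(tibble::tibble(modality = "sugar", neuron_id = "G"))
  l2 <- trace_second_order(g, seeds)
  net <- build_lif_network(g)
  res <- simulate_lif(net, "G", 100, n_trials = 2, rng_seed = 12,
                      stim_mode = "regular")
  avs <- activation_vs_input_strength(res, l2)
  med_act <- avs$median[avs$activated & avs$metric == "total_syn"]
  med_non <- avs$median[!avs$activated & avs$metric == "total_syn"]
  expect_gt(med_act, med_non)
  # all-activated case flags the empty group rather than dropping it
  res2 <- simulate_lif(net, "G", 250, n_trials = 2, rng_seed = 13)
  strong_only <- dplyr::filter(tibble::as_tibble(l2), neuron_id == "STRONG")
  avs2 <- activation_vs_input_strength(
    res2, fake_layer_map(strong_only, "2N"))
  empty_row <- avs2[avs2$activated == FALSE, ]
  expect_equal(empty_row$n, 0L)
  expect_true(is.na(empty_row$median))
})

test_that("parameter validation rejects unstable steps and bad thresholds", {
  expect_error(lif_params(dt = 5), class = "tastetrace_validation_error")
  expect_error(lif_params(v_threshold = -60), class = "tastetrace_validation_error")
  net <- build_lif_network(chain_graph(10))
  expect_error(simulate_lif(net, "NOPE", 50), class = "tastetrace_integrity_error")
  expect_error(simulate_lif(net, "S", -5), class = "tastetrace_validation_error")
})
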