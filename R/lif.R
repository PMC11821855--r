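# lif_simulation: leaky integrate-and-fire whole-network simulation of
# taste-evoked activity, plus activation-vs-connectivity summaries.

#' Default sign convention for LIF synaptic weights
#'
#' ACH, DA, SER and OCT depolarize (+1), GABA and GLUT hyperpolarize (-1);
#' neurons with unknown transmitter contribute no drive (0) by default
#' (set `unknown = 1` to treat them as excitatory).
#'
#' @return Named numeric vector over [nt_levels()].
#' @export
lif_sign_map <- function() {
  c(ACH = 1, DA = 1, SER = 1, OCT = 1, GABA = -1, GLUT = -1, unknown = 0)
}

#' Parameters of the leaky integrate-and-fire model
#'
#' Defaults follow the published whole-brain point-neuron model fitted to
#' experimental data: -52 mV resting and reset potential, -45 mV spike
#' threshold, 2.2 ms refractory period, 5 ms synaptic decay constant,
#' 1.8 ms spike-to-effect delay, and 0.275 mV of membrane deflection per
#' synapse. The membrane time constant `tau_mem` is adopted from the
#' reference model's configuration (20 ms) and is always echoed in
#' simulation results.
#'
#' @param v_rest,v_reset,v_threshold Potentials in mV.
#' @param t_refractory Refractory period, ms.
#' @param tau_syn Synaptic decay constant, ms.
#' @param t_delay Spike-to-effect delay, ms.
#' @param w_unit Synaptic weight per synapse, mV.
#' @param tau_mem Membrane time constant, ms.
#' @param dt Integration step, ms (must be smaller than every time constant).
#' @param stim_duration Stimulation length, s.
#' @param n_trials Trials to average over.
#' @return A list of class `lif_params`.
#' @export
lif_params <- function(v_rest = -52, v_reset = -52, v_threshold = -45,
                       t_refractory = 2.2, tau_syn = 5, t_delay = 1.8,
                       w_unit = 0.275, tau_mem = 20, dt = 0.1,
                       stim_duration = 1, n_trials = 30) {
  if (v_threshold <= v_rest) {
    stop_tastetrace("v_threshold must exceed v_rest", "tastetrace_validation_error")
  }
  if (any(c(t_refractory, tau_syn, t_delay, tau_mem, dt, stim_duration) <= 0)) {
    stop_tastetrace("all time constants must be positive", "tastetrace_validation_error")
  }
  if (dt >= min(tau_syn, tau_mem, t_refractory, t_delay)) {
    stop_tastetrace("dt must be smaller than every time constant",
                    "tastetrace_validation_error")
  }
  structure(list(v_rest = v_rest, v_reset = v_reset, v_threshold = v_threshold,
                 t_refractory = t_refractory, tau_syn = tau_syn,
                 t_delay = t_delay, w_unit = w_unit, tau_mem = tau_mem,
                 dt = dt, stim_duration = stim_duration, n_trials = n_trials),
            class = "lif_params")
}

#' Build a weighted signed network from a connectome
#'
#' One directed weight per neuron pair: `w_unit` times the pair-total
#' synapse count, signed by the presynaptic neuron-level neurotransmitter
#' label. Pairs with zero weight (unknown transmitter under the default
#' convention) are dropped.
#'
#' @param graph A `connectome`.
#' @param sign_map Named numeric sign per NT label, see [lif_sign_map()].
#' @param w_unit Weight per synapse in mV.
#' @return Object of class `lif_network`: neuron id index plus an edge
#'   tibble (`pre_id`, `post_id`, `weight`).
#' @export
build_lif_network <- function(graph, sign_map = lif_sign_map(), w_unit = 0.275) {
  stopifnot(inherits(graph, "connectome"))
  nt_lookup <- setNames(graph$neurons$nt_neuron, graph$neurons$neuron_id)
  edges <- graph$pair_totals |>
    mutate(sign = unname(sign_map[unname(nt_lookup[.data$pre_id])]),
           weight = w_unit * .data$total_syn * .data$sign) |>
    filter(.data$weight != 0) |>
    select("pre_id", "post_id", "weight")
  structure(list(neuron_ids = graph$neurons$neuron_id, edges = edges,
                 w_unit = w_unit, sign_map = sign_map),
            class = "lif_network")
}

#' @export
print.lif_network <- function(x, ...) {
  cat("<lif_network>", length(x$neuron_ids), "neurons,",
      nrow(x$edges), "weighted connections\n")
  invisible(x)
}

# restore RNG state on exit
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  force(code)
}

# spike times in seconds mapped onto the integration grid (dt in ms)
stim_spike_steps <- function(rate, duration_s, dt_ms, mode) {
  n_steps <- round(duration_s * 1000 / dt_ms)
  if (rate <= 0) return(integer())
  if (mode == "regular") {
    times <- seq(1 / rate, duration_s, by = 1 / rate)
  } else {
    times <- cumsum(rexp(ceiling(rate * duration_s * 3 + 20), rate))
    times <- times[times < duration_s]
  }
  steps <- unique(as.integer(floor(times * 1000 / dt_ms)))
  steps[steps < n_steps]
}

#' Simulate taste-evoked activity
#'
#' Stimulated neurons emit spike trains at `stim_rate` for the configured
#' duration (Poisson by default; `"regular"` gives deterministic trains for
#' testing); every spike is propagated to postsynaptic neurons after the
#' synaptic delay and decays with the synaptic time constant. Firing rates
#' are averaged over trials; any neuron with a mean rate above zero counts
#' as activated.
#'
#' @param network A `lif_network`.
#' @param stim_ids Ids of stimulated neurons (must exist in the network).
#' @param stim_rate Stimulation rate in Hz (>= 0).
#' @param params A [lif_params()].
#' @param rng_seed Integer seed; identical seeds give identical spike rasters.
#' @param n_trials Number of trials (default from `params`).
#' @param stim_mode `"poisson"` (default) or `"regular"`.
#' @param record_spikes Keep per-trial spike steps (for small fixtures).
#' @return Object of class `lif_result`: tibble (`neuron_id`,
#'   `mean_rate_hz`, `activated`) with the simulation configuration in
#'   attributes (`params` including `tau_mem`, `stim_ids`, `stim_rate`,
#'   `n_trials`, `rng_seed`; `spike_steps` when recorded).
#' @export
simulate_lif <- function(network, stim_ids, stim_rate, params = lif_params(),
                         rng_seed = 1L, n_trials = params$n_trials,
                         stim_mode = c("poisson", "regular"),
                         record_spikes = FALSE) {
  stopifnot(inherits(network, "lif_network"), inherits(params, "lif_params"))
  stim_mode <- match.arg(stim_mode)
  if (stim_rate < 0) {
    stop_tastetrace("stim_rate must be >= 0", "tastetrace_validation_error")
  }
  missing <- setdiff(stim_ids, network$neuron_ids)
  if (length(missing) > 0) {
    stop_tastetrace(sprintf("stim id(s) not in network: %s",
                            paste(head(missing, 5), collapse = ", ")),
                    "tastetrace_integrity_error")
  }
  ids <- network$neuron_ids
  idx <- setNames(seq_along(ids) - 1L, ids)
  n_steps <- as.integer(round(params$stim_duration * 1000 / params$dt))
  delay_steps <- max(1L, as.integer(round(params$t_delay / params$dt)))
  refr_steps <- as.integer(round(params$t_refractory / params$dt))
  stim_idx <- unname(idx[as.character(stim_ids)])

  counts <- matrix(0L, nrow = length(ids), ncol = n_trials)
  spike_logs <- if (record_spikes) vector("list", n_trials) else NULL
  with_seed(rng_seed, {
    for (trial in seq_len(n_trials)) {
      stim_steps <- lapply(stim_ids, function(i) {
        stim_spike_steps(stim_rate, params$stim_duration, params$dt, stim_mode)
      })
      res <- lif_run_cpp(
        length(ids),
        unname(idx[network$edges$pre_id]), unname(idx[network$edges$post_id]),
        network$edges$weight,
        stim_idx, stim_steps,
        params$v_rest, params$v_reset, params$v_threshold,
        params$tau_mem, params$tau_syn,
        refr_steps, delay_steps, params$dt, n_steps, record_spikes
      )
      counts[, trial] <- res$spike_count
      if (record_spikes) spike_logs[[trial]] <- setNames(res$spike_steps, ids)
    }
  })
  mean_rate <- rowMeans(counts) / params$stim_duration
  out <- tibble(neuron_id = ids, mean_rate_hz = mean_rate,
                activated = mean_rate > 0)
  structure(out, class = c("lif_result", class(out)),
            params = params, stim_ids = stim_ids, stim_rate = stim_rate,
            n_trials = n_trials, rng_seed = rng_seed,
            spike_steps = spike_logs)
}

#' Activation fractions across stimulation intensities
#'
#' Runs one simulation per stimulation rate for a modality's GRNs and
#' reports the fraction of activated neurons among all neurons (seed GRNs
#' of every modality excluded), that modality's 2Ns, and its 3Ns.
#'
#' @param network A `lif_network`.
#' @param seeds A `seed_sets` tibble.
#' @param layer2,layer3 `layer_map`s.
#' @param modality Modality whose GRNs are stimulated.
#' @param rates Stimulation rates in Hz (default 25-200 Hz grid).
#' @param params A [lif_params()].
#' @param rng_seed Base seed; each rate uses `rng_seed + i - 1`.
#' @param n_trials Trials per rate.
#' @param stim_mode Passed to [simulate_lif()].
#' @return Tibble of class `intensity_sweep`: `modality`, `rate_hz`,
#'   `population` (`all`/`2N`/`3N`), `n`, `n_activated`, `fraction`.
#' @export
intensity_sweep <- function(network, seeds, layer2, layer3, modality,
                            rates = c(25, 50, 100, 150, 200),
                            params = lif_params(), rng_seed = 1L,
                            n_trials = params$n_trials,
                            stim_mode = c("poisson", "regular")) {
  stim_mode <- match.arg(stim_mode)
  stim_ids <- seeds$neuron_id[seeds$modality == modality]
  if (length(stim_ids) == 0) {
    stop_tastetrace(sprintf("no seed GRNs for modality '%s'", modality),
                    "tastetrace_validation_error")
  }
  all_grn <- unique(seeds$neuron_id)
  pops <- list(
    all = setdiff(network$neuron_ids, all_grn),
    "2N" = unique(as_tibble(layer2)$neuron_id[as_tibble(layer2)$modality == modality]),
    "3N" = unique(as_tibble(layer3)$neuron_id[as_tibble(layer3)$modality == modality])
  )
  out <- purrr::imap(setNames(as.list(rates), rates), function(rate, nm) {
    i <- match(rate, rates)
    res <- simulate_lif(network, stim_ids, rate, params,
                        rng_seed = rng_seed + i - 1L, n_trials = n_trials,
                        stim_mode = stim_mode)
    act <- res$neuron_id[res$activated]
    purrr::imap(pops, function(ids, pop) {
      tibble(population = pop, n = length(ids),
             n_activated = length(intersect(ids, act)),
             fraction = if (length(ids)) length(intersect(ids, act)) / length(ids) else NA_real_)
    }) |> bind_rows() |> mutate(rate_hz = rate)
  }) |> bind_rows() |>
    mutate(modality = modality) |>
    select("modality", "rate_hz", "population", "n", "n_activated", "fraction")
  structure(out, class = c("intensity_sweep", class(out)))
}

#' Input strength of activated versus non-activated neurons
#'
#' Compares the distribution of input synapse counts between neurons that
#' were and were not activated in a simulation. For a 2N layer map, the
#' metric is total GRN input synapses; when a [net_excitation()] table is
#' supplied (3N analyses), total, excitatory, and net-excitatory 2N input
#' synapses are compared.
#'
#' @param result A `lif_result`.
#' @param layer_map A `layer_map` for the population of interest.
#' @param netexc Optional tibble from [net_excitation()].
#' @return Tibble: `modality`, `metric`, `activated`, `n`, `median`, `q1`,
#'   `q3`. Empty groups are reported with `n = 0` and `NA` quartiles.
#' @export
activation_vs_input_strength <- function(result, layer_map, netexc = NULL) {
  stopifnot(inherits(result, "lif_result"))
  lm_tbl <- as_tibble(layer_map)
  values <- if (is.null(netexc)) {
    select(lm_tbl, "modality", "neuron_id", total_syn = "total_syn") |>
      tidyr::pivot_longer("total_syn", names_to = "metric", values_to = "value")
  } else {
    as_tibble(netexc) |>
      select("modality", "neuron_id", "total_syn", "e_syn", "net") |>
      tidyr::pivot_longer(c("total_syn", "e_syn", "net"),
                          names_to = "metric", values_to = "value")
  }
  act <- select(as_tibble(result), "neuron_id", "activated")
  joined <- inner_join(values, act, by = "neuron_id")
  grid <- tidyr::expand_grid(
    modality = unique(values$modality), metric = unique(values$metric),
    activated = c(TRUE, FALSE)
  )
  joined |>
    group_by(.data$modality, .data$metric, .data$activated) |>
    summarise(n = n(), median = median(.data$value),
              q1 = unname(quantile(.data$value, 0.25)),
              q3 = unname(quantile(.data$value, 0.75)), .groups = "drop") |>
    right_join(grid, by = c("modality", "metric", "activated")) |>
    mutate(n = coalesce(.data$n, 0L)) |>
    arrange(.data$modality, .data$metric, dplyr::desc(.data$activated))
}
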