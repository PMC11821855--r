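# Independent oracles: deliberately naive base-R implementations working
# straight off the raw edge table, kept free of the package's code paths.

# pair totals by plain aggregation over raw edge rows
oracle_pair_totals <- function(edges) {
  agg <- aggregate(syn_count ~ pre_id + post_id, data = as.data.frame(edges), sum)
  agg
}

# brute-force 2N scan: loop over every neuron, test the membership rule
oracle_trace_2n <- function(graph, seeds, threshold = 5) {
  pt <- oracle_pair_totals(graph$edges)
  all_grn <- unique(seeds$neuron_id)
  out <- list()
  for (m in unique(seeds$modality)) {
    grn_m <- seeds$neuron_id[seeds$modality == m]
    for (post in unique(graph$neurons$neuron_id)) {
      if (post %in% all_grn) next
      rows <- pt[pt$post_id == post & pt$pre_id %in% grn_m &
                   pt$syn_count >= threshold, ]
      if (nrow(rows) > 0) {
        out[[length(out) + 1L]] <- data.frame(
          modality = m, neuron_id = post, n_inputs = nrow(rows),
          total_syn = sum(rows$syn_count))
      }
    }
  }
  do.call(rbind, out)
}

# brute-force two-hop scan for 3Ns
oracle_trace_3n <- function(graph, seeds, oracle2, hop1 = 10, hop2 = 10) {
  pt <- oracle_pair_totals(graph$edges)
  all_grn <- unique(seeds$neuron_id)
  out <- list()
  for (m in unique(seeds$modality)) {
    two_m <- oracle2[oracle2$modality == m, ]
    expanded <- two_m$neuron_id[two_m$total_syn >= hop1]
    for (post in unique(graph$neurons$neuron_id)) {
      if (post %in% all_grn || post %in% two_m$neuron_id) next
      rows <- pt[pt$post_id == post & pt$pre_id %in% expanded &
                   pt$syn_count >= hop2, ]
      if (nrow(rows) > 0) {
        out[[length(out) + 1L]] <- data.frame(
          modality = m, neuron_id = post, n_inputs = nrow(rows),
          total_syn = sum(rows$syn_count))
      }
    }
  }
  do.call(rbind, out)
}

expect_same_layer <- function(layer_map, oracle_df) {
  got <- as.data.frame(tibble::as_tibble(layer_map))
  got <- got[order(got$modality, got$neuron_id), ]
  if (is.null(oracle_df)) {
    expect_equal(nrow(got), 0L)
    return(invisible())
  }
  want <- oracle_df[order(oracle_df$modality, oracle_df$neuron_id), ]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got[c("modality", "neuron_id")], want[c("modality", "neuron_id")])
  expect_equal(got$n_inputs, want$n_inputs)
  expect_equal(got$total_syn, want$total_syn)
}

# textbook chi-squared goodness of fit
oracle_chi2 <- function(observed, expected_prop) {
  expected <- expected_prop * sum(observed)
  keep <- expected > 0
  stat <- sum((observed[keep] - expected[keep])^2 / expected[keep])
  list(stat = stat, df = sum(keep) - 1L,
       p = stats::pchisq(stat, sum(keep) - 1L, lower.tail = FALSE))
}

# two-sided Fisher exact p by enumerating all tables with fixed margins
oracle_fisher <- function(a, b, c, d) {
  n <- a + b + c + d
  row1 <- a + b
  col1 <- a + c
  lo <- max(0L, row1 + col1 - n)
  hi <- min(row1, col1)
  probs <- vapply(lo:hi, function(x) {
    stats::dhyper(x, col1, n - col1, row1)
  }, numeric(1))
  p_obs <- stats::dhyper(a, col1, n - col1, row1)
  sum(probs[probs <= p_obs * (1 + 1e-07)])
}

# fine-step reference LIF integration of a small motif (forward Euler on the
# same continuous-time equations, independent of the compiled path)
oracle_lif_motif <- function(edges, stim_spikes_ms, n_neurons, params,
                             dt = 0.005) {
  steps <- round(params$stim_duration * 1000 / dt)
  delay <- params$t_delay
  v <- rep(params$v_rest, n_neurons)
  g <- rep(0, n_neurons)
  refr_until <- rep(-Inf, n_neurons)
  pending <- list()  # (time, target, weight)
  spikes <- vector("list", n_neurons)
  is_stim <- rep(FALSE, n_neurons)
  for (s in seq_along(stim_spikes_ms)) {
    if (length(stim_spikes_ms[[s]]) > 0) is_stim[s] <- TRUE
  }
  schedule <- function(i, t) {
    rows <- edges[edges$pre == i, , drop = FALSE]
    for (r in seq_len(nrow(rows))) {
      pending[[length(pending) + 1L]] <<- c(t + delay, rows$post[r], rows$w[r])
    }
  }
  stim_queue <- lapply(stim_spikes_ms, sort)
  for (k in seq_len(steps)) {
    t <- k * dt
    # deliver pending increments due by t
    if (length(pending) > 0) {
      due <- vapply(pending, function(p) p[1] <= t, logical(1))
      for (p in pending[due]) g[p[2]] <- g[p[2]] + p[3]
      pending <- pending[!due]
    }
    for (i in seq_len(n_neurons)) {
      if (is_stim[i]) {
        if (length(stim_queue[[i]]) > 0 && stim_queue[[i]][1] <= t) {
          spikes[[i]] <- c(spikes[[i]], t)
          schedule(i, t)
          stim_queue[[i]] <- stim_queue[[i]][-1]
        }
        next
      }
      if (t < refr_until[i]) {
        v[i] <- params$v_reset
      } else {
        dv <- (params$v_rest - v[i]) / params$tau_mem + g[i] / params$tau_syn
        v[i] <- v[i] + dv * dt
        if (v[i] >= params$v_threshold) {
          spikes[[i]] <- c(spikes[[i]], t)
          schedule(i, t)
          v[i] <- params$v_reset
          refr_until[i] <- t + params$t_refractory
        }
      }
    }
    g <- g * exp(-dt / params$tau_syn)
  }
  spikes
}
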