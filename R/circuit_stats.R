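# circuit_statistics: E/I-resolved feedback and lateral matrices, net
# excitation, convergence observed-vs-expected analysis, sign-motif censuses
# and cross-modality correlations.
#
# Sign conventions follow the two-source rule: synapse-count matrices use
# edge-level neurotransmitter labels; convergence, net excitation and motif
# censuses use neuron-level labels so each neuron pair is counted once.

#' Excitatory/inhibitory feedback or lateral matrix
#'
#' Sums synapses over all edges from members of one traced set onto members
#' of another, split by modality pair and by the sign of the edge-level
#' neurotransmitter label. Neurons belonging to several modalities are
#' counted in each. No connection threshold is applied: the matrix reports
#' raw synapse counts.
#'
#' @param graph A `connectome`.
#' @param sources,targets Tibbles with `modality` and `neuron_id` columns
#'   (a `layer_map` or `seed_sets` both qualify).
#' @param sign_map Map from NT label to sign, see [nt_sign_map()].
#' @return Tibble of class `feedback_matrix`: `source_modality`,
#'   `target_modality`, `sign` (`excitatory`/`inhibitory`/`other`) and
#'   `synapses`, zero-filled over the full grid. The E + I + other total
#'   equals the raw synapse total between the two sets.
#' @export
feedback_matrix <- function(graph, sources, targets, sign_map = nt_sign_map()) {
  stopifnot(inherits(graph, "connectome"))
  src <- as_tibble(sources)[c("modality", "neuron_id")]
  tgt <- as_tibble(targets)[c("modality", "neuron_id")]
  hits <- graph$edges |>
    inner_join(rename(src, source_modality = "modality"),
               by = c(pre_id = "neuron_id"), relationship = "many-to-many") |>
    inner_join(rename(tgt, target_modality = "modality"),
               by = c(post_id = "neuron_id"), relationship = "many-to-many") |>
    mutate(sign = nt_sign(.data$nt_edge, sign_map))
  grid <- tidyr::expand_grid(
    source_modality = intersect(taste_modalities(), unique(src$modality)),
    target_modality = intersect(taste_modalities(), unique(tgt$modality)),
    sign = c("excitatory", "inhibitory", "other")
  )
  out <- hits |>
    group_by(.data$source_modality, .data$target_modality, .data$sign) |>
    summarise(synapses = sum(.data$syn_count), .groups = "drop") |>
    right_join(grid, by = c("source_modality", "target_modality", "sign")) |>
    mutate(synapses = coalesce(.data$synapses, 0L)) |>
    arrange(match(.data$source_modality, taste_modalities()),
            match(.data$target_modality, taste_modalities()), .data$sign)
  structure(out, class = c("feedback_matrix", class(out)))
}

# Qualifying same-modality 2N inputs onto 3Ns of one modality, with the
# neuron-level sign of each 2N input. One row per (2N, 3N) pair.
qualifying_3n_inputs <- function(graph, layer2, layer3, modality,
                                 hop1_total_threshold = 10, hop2_threshold = 10,
                                 sign_map = nt_sign_map()) {
  l2 <- filter(as_tibble(layer2), .data$modality == !!modality)
  l3 <- filter(as_tibble(layer3), .data$modality == !!modality)
  expanded <- l2$neuron_id[l2$total_syn >= hop1_total_threshold]
  nt_lookup <- setNames(graph$neurons$nt_neuron, graph$neurons$neuron_id)
  graph$pair_totals |>
    filter(.data$pre_id %in% expanded, .data$post_id %in% l3$neuron_id,
           .data$total_syn >= hop2_threshold) |>
    mutate(sign = nt_sign(unname(nt_lookup[.data$pre_id]), sign_map))
}

#' Net excitation onto third-order neurons
#'
#' For each 3N of a modality, the difference between total excitatory and
#' total inhibitory input synapses from qualifying same-modality 2N inputs
#' (pair-total >= `hop2_threshold`, from 2Ns above the hop-1 gate). Input
#' sign comes from the presynaptic neuron-level neurotransmitter label so
#' each 2N-3N pair is counted once; inputs with sign `other` are excluded
#' from both tallies but reported.
#'
#' @param graph A `connectome`.
#' @param layer2,layer3 `layer_map`s from tracing.
#' @param modality One of [taste_modalities()].
#' @param hop1_total_threshold,hop2_threshold Tracing thresholds (defaults 10).
#' @param sign_map See [nt_sign_map()].
#' @return Tibble: `modality`, `neuron_id`, `n_inputs`, `total_syn` (all
#'   qualifying inputs), `e_syn`, `i_syn`, `other_syn`, `net` (= e - i).
#' @export
net_excitation <- function(graph, layer2, layer3, modality,
                           hop1_total_threshold = 10, hop2_threshold = 10,
                           sign_map = nt_sign_map()) {
  stopifnot(inherits(graph, "connectome"))
  if (!modality %in% unique(as_tibble(layer3)$modality)) {
    stop_tastetrace(sprintf("no 3Ns traced for modality '%s'", modality),
                    "tastetrace_validation_error")
  }
  inputs <- qualifying_3n_inputs(graph, layer2, layer3, modality,
                                 hop1_total_threshold, hop2_threshold, sign_map)
  inputs |>
    group_by(neuron_id = .data$post_id) |>
    summarise(
      n_inputs = n(),
      e_syn = sum(.data$total_syn[.data$sign == "excitatory"]),
      i_syn = sum(.data$total_syn[.data$sign == "inhibitory"]),
      other_syn = sum(.data$total_syn[.data$sign == "other"]),
      total_syn = sum(.data$total_syn),
      .groups = "drop"
    ) |>
    mutate(net = .data$e_syn - .data$i_syn, modality = modality) |>
    select("modality", "neuron_id", "n_inputs", "total_syn",
           "e_syn", "i_syn", "other_syn", "net")
}

#' Expected sign-convergence proportions under independence
#'
#' Binomial null for the composition of k same-modality inputs when each
#' input is independently excitatory with probability `p_exc`: all-excitatory
#' with probability p^k, all-inhibitory with (1-p)^k, mixed otherwise.
#'
#' @param p_exc Proportion of excitatory inputs in the analyzed population.
#' @param k Number of inputs per neuron (2 or 3).
#' @return Tibble with `category` (`all_excitatory`, `all_inhibitory`,
#'   `mixed`) and `expected` proportions summing to 1.
#' @export
convergence_expected <- function(p_exc, k) {
  if (!is.numeric(p_exc) || p_exc < 0 || p_exc > 1) {
    stop_tastetrace("p_exc must lie in [0, 1]", "tastetrace_validation_error")
  }
  if (!k %in% c(2, 3)) {
    stop_tastetrace("k must be 2 or 3", "tastetrace_validation_error")
  }
  all_e <- p_exc^k
  all_i <- (1 - p_exc)^k
  tibble(category = c("all_excitatory", "all_inhibitory", "mixed"),
         expected = c(all_e, all_i, 1 - all_e - all_i))
}

#' Observed versus expected sign convergence onto 3Ns
#'
#' Restricts to 3Ns of one modality receiving exactly `k` qualifying
#' same-modality 2N inputs, excludes neurons where any input's neuron-level
#' label is neither excitatory nor inhibitory, estimates `p_exc` from the
#' analyzed population's inputs (each 2N-3N pair counted once), and runs a
#' chi-squared goodness-of-fit of observed category counts against the
#' binomial null of [convergence_expected()]. Results based on fewer than
#' `min_n` neurons are flagged as unreliable.
#'
#' @inheritParams net_excitation
#' @param k Exact number of qualifying 2N inputs (2 or 3).
#' @param min_n Minimum analyzable 3Ns before the result is trusted.
#' @return Object of class `convergence_test`; see [tidy()] / [glance()].
#' @export
convergence_test <- function(graph, layer2, layer3, modality, k,
                             hop1_total_threshold = 10, hop2_threshold = 10,
                             min_n = 10, sign_map = nt_sign_map()) {
  if (!k %in% c(2, 3)) {
    stop_tastetrace("k must be 2 or 3", "tastetrace_validation_error")
  }
  inputs <- qualifying_3n_inputs(graph, layer2, layer3, modality,
                                 hop1_total_threshold, hop2_threshold, sign_map)
  by_post <- split(inputs, inputs$post_id)
  keep <- purrr::keep(by_post, function(d) {
    nrow(d) == k && all(d$sign %in% c("excitatory", "inhibitory"))
  })
  n <- length(keep)
  signs <- unlist(purrr::map(keep, "sign"), use.names = FALSE)
  p_exc <- if (length(signs)) mean(signs == "excitatory") else NA_real_
  categories <- vapply(keep, function(d) {
    if (all(d$sign == "excitatory")) "all_excitatory"
    else if (all(d$sign == "inhibitory")) "all_inhibitory"
    else "mixed"
  }, character(1))
  observed <- table(factor(categories,
                           levels = c("all_excitatory", "all_inhibitory", "mixed")))
  observed <- setNames(as.integer(observed), names(observed))

  if (n == 0) {
    warn(sprintf("no analyzable 3Ns for modality '%s' with k = %d", modality, k))
    res <- list(modality = modality, k = k, n = 0L, p_exc = NA_real_,
                observed = observed, expected = rep(NA_real_, 3),
                chi2 = NA_real_, df = NA_integer_, p_value = NA_real_,
                flagged = TRUE)
    class(res) <- "convergence_test"
    return(res)
  }

  expected_prop <- convergence_expected(p_exc, k)$expected
  expected <- expected_prop * n
  usable <- expected > 0
  if (any(!usable & observed > 0)) {
    warn("zero expected count in a category with nonzero observations; chi-squared computed over remaining categories")
  }
  chi2 <- sum((observed[usable] - expected[usable])^2 / expected[usable])
  df <- sum(usable) - 1L
  p_value <- pchisq(chi2, df = df, lower.tail = FALSE)
  res <- list(modality = modality, k = k, n = n, p_exc = p_exc,
              observed = observed, expected = expected, chi2 = chi2, df = df,
              p_value = p_value, flagged = n < min_n)
  class(res) <- "convergence_test"
  res
}

#' @export
print.convergence_test <- function(x, ...) {
  cat(sprintf("<convergence_test> %s, k = %d, n = %d%s\n", x$modality, x$k,
              x$n, if (x$flagged) " (flagged: small n)" else ""))
  print(tidy(x))
  cat(sprintf("chi2 = %.4g, df = %d, p = %.3g (p_exc = %.3f)\n",
              x$chi2, x$df, x$p_value, x$p_exc))
  invisible(x)
}

#' Tidy a convergence test
#'
#' @param x A `convergence_test`.
#' @param ... Unused.
#' @return Tibble with per-category observed and expected counts/proportions.
#' @export
tidy.convergence_test <- function(x, ...) {
  tibble(category = names(x$observed),
         observed = unname(x$observed),
         expected = unname(x$expected),
         observed_prop = if (x$n > 0) unname(x$observed) / x$n else NA_real_,
         expected_prop = unname(x$expected) / max(x$n, 1L))
}

#' Glance at a convergence test
#'
#' @param x A `convergence_test`.
#' @param ... Unused.
#' @return One-row tibble: modality, k, n, p_exc, chi2, df, p_value, flagged.
#' @export
glance.convergence_test <- function(x, ...) {
  tibble(modality = x$modality, k = x$k, n = x$n, p_exc = x$p_exc,
         chi2 = x$chi2, df = x$df, p_value = x$p_value, flagged = x$flagged)
}

#' Cross-modality correlation of net excitation
#'
#' For 3Ns receiving at least `min_inputs` qualifying same-modality 2N
#' inputs in *both* modalities of a pair, regresses net excitation in one
#' modality on net excitation in the other (OLS). 2Ns belonging to both
#' modalities are counted as inputs for each, mirroring the layer
#' definitions; the shared-input double-counting convention is recorded in
#' the result.
#'
#' @inheritParams net_excitation
#' @param modality_pair Character vector of two modalities.
#' @param min_inputs Minimum qualifying inputs per modality (default 2).
#' @return Object of class `xmod_netexc` with the paired values and an OLS
#'   fit; see [tidy()] / [glance()].
#' @export
cross_modality_net_excitation <- function(graph, layer2, layer3, modality_pair,
                                          hop1_total_threshold = 10,
                                          hop2_threshold = 10, min_inputs = 2,
                                          sign_map = nt_sign_map()) {
  stopifnot(length(modality_pair) == 2)
  a <- modality_pair[[1]]; b <- modality_pair[[2]]
  na <- net_excitation(graph, layer2, layer3, a, hop1_total_threshold,
                       hop2_threshold, sign_map) |>
    filter(.data$n_inputs >= min_inputs)
  nb <- net_excitation(graph, layer2, layer3, b, hop1_total_threshold,
                       hop2_threshold, sign_map) |>
    filter(.data$n_inputs >= min_inputs)
  paired <- inner_join(select(na, "neuron_id", net_a = "net"),
                       select(nb, "neuron_id", net_b = "net"),
                       by = "neuron_id")
  if (nrow(paired) < 3) {
    stop_tastetrace(
      sprintf("fewer than 3 shared 3Ns between '%s' and '%s'; fit undefined", a, b),
      "tastetrace_undefined_fit_error"
    )
  }
  if (length(unique(paired$net_a)) < 2) {
    stop_tastetrace("net excitation is constant in the predictor modality; fit undefined",
                    "tastetrace_undefined_fit_error")
  }
  fit <- lm(net_b ~ net_a, data = paired)
  structure(list(modality_pair = c(a, b), data = paired, fit = fit,
                 shared_inputs_double_counted = TRUE),
            class = "xmod_netexc")
}

#' @export
print.xmod_netexc <- function(x, ...) {
  print(glance(x))
  invisible(x)
}

#' Tidy a cross-modality net-excitation fit
#'
#' @param x An `xmod_netexc`.
#' @param ... Unused.
#' @return The paired per-neuron net-excitation values.
#' @export
tidy.xmod_netexc <- function(x, ...) as_tibble(x$data)

#' Glance at a cross-modality net-excitation fit
#'
#' @param x An `xmod_netexc`.
#' @param ... Unused.
#' @return One-row tibble: modalities, slope, r_squared, p_value, n.
#' @export
glance.xmod_netexc <- function(x, ...) {
  s <- summary(x$fit)
  tibble(modality_a = x$modality_pair[[1]], modality_b = x$modality_pair[[2]],
         slope = unname(coef(x$fit)[2]), r_squared = s$r.squared,
         p_value = s$coefficients[2, 4], n = nrow(x$data))
}

#' Census of input-sign by output-sign motifs
#'
#' Tallies qualifying 2N-to-3N connections by the neuron-level sign of the
#' presynaptic 2N and of the postsynaptic 3N (E->E, E->I, I->E, I->I).
#' Connections where either side's label has sign `other` are excluded and
#' counted separately.
#'
#' @inheritParams net_excitation
#' @param modalities Modalities to include (default: all traced).
#' @return Tibble of class `sign_motifs`: `modality`, `input_sign`,
#'   `target_sign`, `n_connections`, zero-filled over the four motifs;
#'   attribute `"n_excluded"` counts dropped connections.
#' @export
sign_motif_census <- function(graph, layer2, layer3,
                              modalities = NULL,
                              hop1_total_threshold = 10, hop2_threshold = 10,
                              sign_map = nt_sign_map()) {
  l3 <- as_tibble(layer3)
  modalities <- modalities %||% intersect(taste_modalities(), unique(l3$modality))
  if (nrow(l3) == 0) {
    warn("empty 3N layer; returning empty motif census")
  }
  nt_lookup <- setNames(graph$neurons$nt_neuron, graph$neurons$neuron_id)
  excluded <- 0L
  out <- purrr::map(modalities, function(m) {
    inputs <- qualifying_3n_inputs(graph, layer2, layer3, m,
                                   hop1_total_threshold, hop2_threshold, sign_map)
    inputs <- mutate(inputs,
                     target_sign = nt_sign(unname(nt_lookup[.data$post_id]), sign_map))
    drop <- inputs$sign == "other" | inputs$target_sign == "other"
    excluded <<- excluded + sum(drop)
    inputs <- filter(inputs, !drop)
    grid <- tidyr::expand_grid(input_sign = c("excitatory", "inhibitory"),
                               target_sign = c("excitatory", "inhibitory"))
    inputs |>
      count(input_sign = .data$sign, .data$target_sign, name = "n_connections") |>
      right_join(grid, by = c("input_sign", "target_sign")) |>
      mutate(n_connections = coalesce(.data$n_connections, 0L), modality = m) |>
      select("modality", "input_sign", "target_sign", "n_connections")
  }) |> bind_rows()
  out <- bind_rows(tibble(modality = character(), input_sign = character(),
                          target_sign = character(), n_connections = integer()),
                   out)
  structure(out, class = c("sign_motifs", class(out)), n_excluded = excluded)
}

#' Proportion of excitatory inputs onto excitatory versus inhibitory 3Ns
#'
#' @param motifs A `sign_motifs` census.
#' @return Tibble: `modality`, `target_sign`, `n_connections`,
#'   `prop_excitatory_inputs`.
#' @export
motif_input_proportions <- function(motifs) {
  as_tibble(motifs) |>
    group_by(.data$modality, .data$target_sign) |>
    summarise(
      prop_excitatory_inputs = if (sum(.data$n_connections) > 0) {
        sum(.data$n_connections[.data$input_sign == "excitatory"]) /
          sum(.data$n_connections)
      } else NA_real_,
      n_connections = sum(.data$n_connections),
      .groups = "drop"
    ) |>
    select("modality", "target_sign", "n_connections", "prop_excitatory_inputs")
}
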