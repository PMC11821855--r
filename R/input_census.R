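# input_census: fraction of input synapses from annotated GRNs and from
# known taste neurons, and censuses of all input partners.

#' Union of known taste neurons
#'
#' All annotated GRNs plus all traced 2Ns and 3Ns across modalities. This
#' set underestimates total taste input (it omits right-hemisphere and
#' non-labellar taste neurons by construction).
#'
#' @param seeds A `seed_sets` tibble.
#' @param layer2,layer3 `layer_map`s.
#' @return Character vector of neuron ids.
#' @export
known_taste_neurons <- function(seeds, layer2, layer3) {
  unique(c(seeds$neuron_id, as_tibble(layer2)$neuron_id,
           as_tibble(layer3)$neuron_id))
}

#' Fractions of input synapses from taste sources
#'
#' For every neuron of a traced layer, the fraction of its total input
#' synapses (all presynaptic partners, no threshold on the denominator)
#' arriving from annotated seed GRNs and from known taste neurons (GRNs,
#' 2Ns or 3Ns of any modality). Neurons with zero input synapses are
#' excluded with a note.
#'
#' @param graph A `connectome`.
#' @param seeds A `seed_sets` tibble.
#' @param layer2,layer3 `layer_map`s (both are needed to define the
#'   known-taste set even when only one layer is summarized).
#' @param target_layer `"2N"` or `"3N"`.
#' @return Tibble of class `input_fractions`: `modality`, `neuron_id`,
#'   `layer`, `total_input_synapses`, `frac_from_seed_grns`,
#'   `frac_from_known_taste`.
#' @export
input_fractions <- function(graph, seeds, layer2, layer3,
                            target_layer = c("2N", "3N")) {
  stopifnot(inherits(graph, "connectome"))
  target_layer <- match.arg(target_layer)
  targets <- as_tibble(if (target_layer == "2N") layer2 else layer3)
  known <- known_taste_neurons(seeds, layer2, layer3)
  grn_ids <- unique(seeds$neuron_id)

  totals <- graph$pair_totals |>
    filter(.data$post_id %in% targets$neuron_id) |>
    group_by(.data$post_id) |>
    summarise(
      total_input_synapses = sum(.data$total_syn),
      syn_from_grns = sum(.data$total_syn[.data$pre_id %in% grn_ids]),
      syn_from_known = sum(.data$total_syn[.data$pre_id %in% known]),
      .groups = "drop"
    )
  out <- targets |>
    select("modality", "neuron_id") |>
    left_join(totals, by = c(neuron_id = "post_id")) |>
    mutate(across(c("total_input_synapses", "syn_from_grns", "syn_from_known"),
                  ~ coalesce(.x, 0L)))
  n_zero <- sum(out$total_input_synapses == 0)
  if (n_zero > 0) {
    inform(sprintf("%d neuron(s) with zero input synapses excluded from fractions",
                   n_zero))
    out <- filter(out, .data$total_input_synapses > 0)
  }
  out <- out |>
    mutate(layer = target_layer,
           frac_from_seed_grns = .data$syn_from_grns / .data$total_input_synapses,
           frac_from_known_taste = .data$syn_from_known / .data$total_input_synapses) |>
    select("modality", "neuron_id", "layer", "total_input_synapses",
           "frac_from_seed_grns", "frac_from_known_taste")
  structure(out, class = c("input_fractions", class(out)))
}

#' Per-modality medians of input fractions
#'
#' @param fractions An `input_fractions` tibble.
#' @return Tibble: `modality`, `n`, `median_frac_seed_grns`,
#'   `median_frac_known_taste`.
#' @export
input_fraction_medians <- function(fractions) {
  as_tibble(fractions) |>
    group_by(.data$modality) |>
    summarise(n = n(),
              median_frac_seed_grns = median(.data$frac_from_seed_grns),
              median_frac_known_taste = median(.data$frac_from_known_taste),
              .groups = "drop")
}

#' Census of input partners to a traced layer
#'
#' Counts distinct presynaptic partners (per target modality) whose
#' pair-total connection onto any neuron of the layer meets the connection
#' threshold, tallied by superclass and by class. Each partner is counted
#' once per modality regardless of how many targets it contacts; a
#' synapse-weighted variant is available with `weight = "synapses"`.
#'
#' @inheritParams input_fractions
#' @param conn_threshold Minimum pair-total synapses for a partner to count
#'   (default 5; set 0 to disable).
#' @param weight Count distinct `"neurons"` (default) or total `"synapses"`.
#' @return Tibble: `modality`, `field` (`superclass`/`class_label`),
#'   `category`, `n`.
#' @export
input_partner_census <- function(graph, seeds, layer2, layer3,
                                 target_layer = c("2N", "3N"),
                                 conn_threshold = 5,
                                 weight = c("neurons", "synapses")) {
  stopifnot(inherits(graph, "connectome"))
  target_layer <- match.arg(target_layer)
  weight <- match.arg(weight)
  targets <- as_tibble(if (target_layer == "2N") layer2 else layer3)

  partners <- graph$pair_totals |>
    filter(.data$total_syn >= conn_threshold) |>
    inner_join(select(targets, "modality", "neuron_id"),
               by = c(post_id = "neuron_id"), relationship = "many-to-many") |>
    left_join(graph$neurons[c("neuron_id", "superclass", "class_label")],
              by = c(pre_id = "neuron_id"))

  tally_field <- function(field) {
    if (weight == "neurons") {
      partners |>
        distinct(.data$modality, .data$pre_id, .data[[field]]) |>
        count(.data$modality, category = .data[[field]], name = "n")
    } else {
      partners |>
        group_by(.data$modality, category = .data[[field]]) |>
        summarise(n = sum(.data$total_syn), .groups = "drop")
    }
  }
  bind_rows(
    mutate(tally_field("superclass"), field = "superclass"),
    mutate(tally_field("class_label"), field = "class_label")
  ) |>
    select("modality", "field", "category", "n") |>
    arrange(.data$modality, .data$field, dplyr::desc(.data$n))
}
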