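# In-code fixtures: compact builders for hand-specified connectomes.

# Build a connectome from a compact edge description. `edges` is a data
# frame with pre, post, neuropil, nt, syn; neurons are inferred, with
# optional overrides for nt_neuron / superclass / class_label per id.
toy_graph <- function(edges, nt_neuron = character(), superclass = character(),
                      class_label = character(), side = character(),
                      extra_neurons = character()) {
  ids <- unique(c(edges$pre, edges$post, extra_neurons))
  neurons <- tibble::tibble(
    neuron_id = ids,
    superclass = ifelse(ids %in% names(superclass), superclass[ids], "central"),
    class_label = ifelse(ids %in% names(class_label), class_label[ids], "unknown"),
    side = ifelse(ids %in% names(side), side[ids], "left"),
    nt_neuron = ifelse(ids %in% names(nt_neuron), nt_neuron[ids], "ACH")
  )
  edge_tbl <- tibble::tibble(
    pre_id = edges$pre, post_id = edges$post, neuropil = edges$neuropil,
    syn_count = edges$syn, nt_edge = edges$nt
  )
  connectome(neurons, edge_tbl)
}

toy_edges <- function(...) {
  rows <- list(...)
  tibble::tibble(
    pre = vapply(rows, `[[`, "", 1),
    post = vapply(rows, `[[`, "", 2),
    neuropil = vapply(rows, `[[`, "", 3),
    nt = vapply(rows, `[[`, "", 4),
    syn = as.integer(vapply(rows, `[[`, "", 5))
  )
}

# layer-map-shaped tibble for functions that only need the columns
fake_layer_map <- function(df, layer) {
  structure(tibble::as_tibble(df),
            class = c("layer_map", class(tibble::tibble())), layer = layer)
}

# A small planted circuit: quick to brute-force, still exercises overlaps,
# weak 2Ns, decoys, feedback and background.
small_spec <- function(seed = 42, ...) {
  args <- utils::modifyList(list(
    rng_seed = seed,
    n_grn = c(sugar = 3L, water = 3L, bitter = 3L, ir94e = 2L),
    n_2n = c(sugar = 8L, water = 6L, bitter = 6L, ir94e = 4L),
    n_3n = c(sugar = 14L, water = 10L, bitter = 10L, ir94e = 6L),
    overlap_2n = list("sugar:water" = 2L, "bitter:ir94e" = 1L),
    overlap_3n = list("sugar:water" = 4L, "bitter:ir94e" = 2L),
    grn_grn_per_grn = c(sugar = 5, water = 3, bitter = 1, ir94e = 6,
                        water_to_sugar = 2),
    n_background = 15L,
    n_decoy_per_modality = 2L
  ), list(...))
  do.call(synth_spec, args)
}

# Mid-size planted circuit kept under 1,000 neurons for oracle comparisons.
medium_spec <- function(seed = 1, ...) {
  args <- utils::modifyList(list(
    rng_seed = seed,
    n_3n = c(sugar = 180L, water = 120L, bitter = 140L, ir94e = 80L),
    overlap_3n = list("sugar:water" = 60L, "sugar:bitter" = 35L,
                      "sugar:ir94e" = 20L, "water:bitter" = 20L,
                      "water:ir94e" = 12L, "bitter:ir94e" = 20L),
    n_background = 60L
  ), list(...))
  do.call(synth_spec, args)
}
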