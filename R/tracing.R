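# layer_tracing: identify second- and third-order taste neurons under
# synapse-count thresholds, plus overlap, GRN-GRN matrices, input-strength
# summaries and fan-in/strength regressions.

empty_layer_tbl <- function() {
  tibble(modality = character(), neuron_id = character(),
         n_inputs = integer(), total_syn = integer())
}

new_layer_map <- function(df, layer, seeds, thresholds) {
  df <- bind_rows(empty_layer_tbl(), df)  # guarantee the schema when empty
  df <- arrange(df, .data$modality, .data$neuron_id)
  structure(df,
            class = c("layer_map", class(tibble())),
            layer = layer, thresholds = thresholds)
}

#' @export
print.layer_map <- function(x, ...) {
  cat("<layer_map>", attr(x, "layer"), "layer;",
    paste(sprintf("%s=%d", names(table(x$modality)), table(x$modality)),
          collapse = ", "), "\n")
  NextMethod()
}

# Qualifying directed connections from `pre_ids` under a synapse threshold.
# mode "pair_total": pair-total synapses (summed across neuropils) >= threshold.
# mode "per_neuropil": at least one single-neuropil connection >= threshold
# (totals reported are still pair totals).
qualifying_connections <- function(graph, pre_ids, threshold,
                                   mode = c("pair_total", "per_neuropil")) {
  mode <- match.arg(mode)
  pt <- filter(graph$pair_totals, .data$pre_id %in% pre_ids)
  if (mode == "pair_total") {
    filter(pt, .data$total_syn >= threshold)
  } else {
    per_np <- graph$edges |>
      filter(.data$pre_id %in% pre_ids) |>
      group_by(.data$pre_id, .data$post_id, .data$neuropil) |>
      summarise(np_syn = sum(.data$syn_count), .groups = "drop") |>
      filter(.data$np_syn >= threshold) |>
      distinct(.data$pre_id, .data$post_id)
    inner_join(pt, per_np, by = c("pre_id", "post_id"))
  }
}

#' Identify second-order taste neurons (2Ns)
#'
#' A neuron is a 2N for a modality iff at least one GRN of that modality
#' connects to it with pair-total synapses at or above `threshold`
#' (default 5, the false-positive cutoff for single connections) and the
#' neuron is not itself an annotated GRN of any modality. Fan-in
#' (`n_inputs`) and total GRN synapses (`total_syn`) are tallied over the
#' qualifying GRN connections.
#'
#' @param graph A `connectome`.
#' @param seeds A `seed_sets` tibble of GRN ids per modality.
#' @param threshold Minimum synapse count for a GRN-2N connection.
#' @param mode Apply the threshold to pair-total synapses (default) or to
#'   single-neuropil connections (`"per_neuropil"`).
#' @return A `layer_map` tibble: `modality`, `neuron_id`, `n_inputs`,
#'   `total_syn`.
#' @export
trace_second_order <- function(graph, seeds, threshold = 5,
                               mode = c("pair_total", "per_neuropil")) {
  stopifnot(inherits(graph, "connectome"))
  if (threshold < 1) {
    stop_tastetrace("threshold must be >= 1", "tastetrace_validation_error")
  }
  mode <- match.arg(mode)
  all_grn <- unique(seeds$neuron_id)
  out <- purrr::map(split(seeds$neuron_id, seeds$modality), function(grn_ids) {
    qualifying_connections(graph, grn_ids, threshold, mode) |>
      filter(!(.data$post_id %in% all_grn)) |>
      group_by(neuron_id = .data$post_id) |>
      summarise(n_inputs = n_distinct(.data$pre_id),
                total_syn = sum(.data$total_syn), .groups = "drop")
  }) |>
    bind_rows(.id = "modality")
  new_layer_map(out, "2N", seeds, c(threshold_2n = threshold))
}

#' Identify third-order taste neurons (3Ns)
#'
#' Only 2Ns receiving at least `hop1_total_threshold` total same-modality GRN
#' synapses are expanded. A neuron is a 3N for a modality iff it receives at
#' least `hop2_threshold` pair-total synapses from at least one such 2N, is
#' not an annotated GRN of any modality, and is not a 2N of the same modality
#' (it may be a 2N of a different modality).
#'
#' @inheritParams trace_second_order
#' @param layer2 The `layer_map` from [trace_second_order()].
#' @param hop1_total_threshold Minimum total GRN synapses a 2N needs before
#'   its partners are traced (default 10).
#' @param hop2_threshold Minimum synapse count for a 2N-3N connection
#'   (default 10).
#' @return A `layer_map` tibble: `modality`, `neuron_id`, `n_inputs`,
#'   `total_syn` (tallied over qualifying 2N connections).
#' @export
trace_third_order <- function(graph, seeds, layer2,
                              hop1_total_threshold = 10, hop2_threshold = 10,
                              mode = c("pair_total", "per_neuropil")) {
  stopifnot(inherits(graph, "connectome"), inherits(layer2, "layer_map"))
  if (hop1_total_threshold < 1 || hop2_threshold < 1) {
    stop_tastetrace("thresholds must be >= 1", "tastetrace_validation_error")
  }
  mode <- match.arg(mode)
  all_grn <- unique(seeds$neuron_id)
  l2 <- as_tibble(layer2)
  out <- purrr::map(split(l2, l2$modality), function(two) {
    expanded <- two$neuron_id[two$total_syn >= hop1_total_threshold]
    if (length(expanded) == 0) {
      return(tibble(neuron_id = character(), n_inputs = integer(),
                    total_syn = integer()))
    }
    qualifying_connections(graph, expanded, hop2_threshold, mode) |>
      filter(!(.data$post_id %in% all_grn),
             !(.data$post_id %in% two$neuron_id)) |>
      group_by(neuron_id = .data$post_id) |>
      summarise(n_inputs = n_distinct(.data$pre_id),
                total_syn = sum(.data$total_syn), .groups = "drop")
  }) |>
    bind_rows(.id = "modality")
  new_layer_map(out, "3N", seeds,
                c(hop1_total_threshold = hop1_total_threshold,
                  hop2_threshold = hop2_threshold))
}

#' Cross-modality overlap of a traced layer
#'
#' Counts shared neurons for every pairwise and higher-order combination of
#' modalities present in the layer map (a Venn-diagram table).
#'
#' @param layer_map A `layer_map`.
#' @return A tibble with `modalities` (e.g. `"sugar:water"`), `degree`
#'   (number of modalities intersected) and `n_shared` (neurons belonging to
#'   all of them, regardless of further memberships).
#' @export
modality_overlap <- function(layer_map) {
  df <- as_tibble(layer_map)
  mods <- intersect(taste_modalities(), unique(df$modality))
  if (length(mods) < 2) {
    stop_tastetrace("need at least two modalities to compute overlap",
                    "tastetrace_validation_error")
  }
  sets <- split(df$neuron_id, df$modality)
  purrr::map(seq.int(2, length(mods)), function(k) {
    combos <- utils::combn(mods, k, simplify = FALSE)
    purrr::map(combos, function(cc) {
      tibble(modalities = paste(cc, collapse = ":"), degree = k,
             n_shared = length(Reduce(intersect, sets[cc])))
    }) |> bind_rows()
  }) |> bind_rows()
}

#' Per-neuron modality membership counts
#'
#' Flags multimodal neurons: members of two or more modality sets at the
#' same layer.
#'
#' @param layer_map A `layer_map`.
#' @return Tibble with `neuron_id`, `n_modalities`, `modalities`
#'   (colon-separated) and `multimodal` (logical).
#' @export
neuron_modalities <- function(layer_map) {
  as_tibble(layer_map) |>
    group_by(.data$neuron_id) |>
    summarise(n_modalities = n_distinct(.data$modality),
              modalities = paste(sort(unique(.data$modality)), collapse = ":"),
              .groups = "drop") |>
    mutate(multimodal = .data$n_modalities > 1)
}

#' GRN-GRN connectivity matrix
#'
#' Sums synapses from GRNs of each modality onto GRNs of each modality.
#' No connection threshold is applied by default (raw synapse sums);
#' `threshold` filters neuron pairs by pair-total synapses first.
#'
#' @inheritParams trace_second_order
#' @param threshold Minimum pair-total synapse count for a GRN-GRN pair to be
#'   included (default 0, i.e. all).
#' @return Tibble with `source_modality`, `target_modality`, `synapses`, and
#'   `synapses_per_grn` (normalized by the number of source GRNs); every
#'   modality pair appears, zero-filled.
#' @export
grn_grn_matrix <- function(graph, seeds, threshold = 0) {
  stopifnot(inherits(graph, "connectome"))
  mods <- intersect(taste_modalities(), unique(seeds$modality))
  lookup <- setNames(seeds$modality, seeds$neuron_id)
  pt <- graph$pair_totals |>
    filter(.data$pre_id %in% seeds$neuron_id,
           .data$post_id %in% seeds$neuron_id,
           .data$total_syn >= threshold) |>
    mutate(source_modality = unname(lookup[.data$pre_id]),
           target_modality = unname(lookup[.data$post_id]))
  grid <- tidyr::expand_grid(source_modality = mods, target_modality = mods)
  n_grn <- count(as_tibble(seeds), .data$modality)
  pt |>
    group_by(.data$source_modality, .data$target_modality) |>
    summarise(synapses = sum(.data$total_syn), .groups = "drop") |>
    right_join(grid, by = c("source_modality", "target_modality")) |>
    mutate(synapses = dplyr::coalesce(.data$synapses, 0L)) |>
    left_join(n_grn, by = c(source_modality = "modality")) |>
    mutate(synapses_per_grn = .data$synapses / .data$n) |>
    select(-"n") |>
    arrange(match(.data$source_modality, mods),
            match(.data$target_modality, mods))
}

#' Input-strength summary for a traced layer
#'
#' Per-modality distribution of total input synapses and input-cell counts
#' recorded during tracing (e.g. GRN-2N connection strength).
#'
#' @param layer_map A `layer_map`.
#' @return Tibble of class `input_strength`: `modality`, `n_neurons`,
#'   `median_total_syn`, `median_n_inputs`; the underlying per-neuron values
#'   are retained in attribute `"data"` for plotting.
#' @export
input_strength_distribution <- function(layer_map) {
  df <- as_tibble(layer_map)
  if (nrow(df) == 0) {
    warn("layer map is empty; returning empty distribution")
  }
  out <- df |>
    group_by(.data$modality) |>
    summarise(n_neurons = n(),
              median_total_syn = median(.data$total_syn),
              median_n_inputs = median(.data$n_inputs), .groups = "drop")
  structure(out, class = c("input_strength", class(out)),
            data = df, layer = attr(layer_map, "layer"))
}

#' Fan-in versus connection-strength regression
#'
#' For each modality, ordinary least squares of the mean synapses per input
#' cell (`total_syn / n_inputs`) against the number of input cells
#' (`n_inputs`). A positive slope indicates that neurons sampling more input
#' cells also receive stronger individual connections.
#'
#' @param layer_map A `layer_map` with at least 3 neurons per modality.
#' @return Object of class `fanin_fit`; see [tidy()] and [glance()] methods.
#' @export
fanin_strength_regression <- function(layer_map) {
  df <- as_tibble(layer_map) |>
    mutate(mean_syn_per_input = .data$total_syn / .data$n_inputs)
  fits <- purrr::map(split(df, df$modality), function(d) {
    if (nrow(d) < 3) {
      stop_tastetrace(
        sprintf("modality '%s' has fewer than 3 neurons", d$modality[[1]]),
        "tastetrace_validation_error"
      )
    }
    if (length(unique(d$n_inputs)) < 2) {
      stop_tastetrace(
        sprintf("modality '%s': all neurons have identical fan-in; fit undefined",
                d$modality[[1]]),
        "tastetrace_undefined_fit_error"
      )
    }
    lm(mean_syn_per_input ~ n_inputs, data = d)
  })
  structure(list(fits = fits, data = df), class = "fanin_fit")
}

#' @export
print.fanin_fit <- function(x, ...) {
  print(glance(x))
  invisible(x)
}

#' Tidy a fan-in regression
#'
#' @param x A `fanin_fit`.
#' @param ... Unused.
#' @return Per-modality coefficient table (term, estimate, std.error, p.value).
#' @export
tidy.fanin_fit <- function(x, ...) {
  purrr::imap(x$fits, function(fit, m) {
    co <- summary(fit)$coefficients
    tibble(modality = m, term = rownames(co), estimate = co[, 1],
           std.error = co[, 2], p.value = co[, 4])
  }) |> bind_rows()
}

#' Glance at a fan-in regression
#'
#' @param x A `fanin_fit`.
#' @param ... Unused.
#' @return One row per modality: `slope`, `r_squared`, `p_value`, `n`.
#' @export
glance.fanin_fit <- function(x, ...) {
  purrr::imap(x$fits, function(fit, m) {
    s <- summary(fit)
    tibble(modality = m,
           slope = unname(coef(fit)[2]),
           r_squared = s$r.squared,
           p_value = s$coefficients[2, 4],
           n = length(s$residuals))
  }) |> bind_rows()
}
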