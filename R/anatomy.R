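# anatomy: SEZ/hemisphere synapse partitions, local-vs-projection
# classification, superclass/class/NT censuses, Fisher proportion tests.

#' Classify neurons as local, projection, or without brain output
#'
#' A neuron is *local* iff all of its qualifying output connections
#' (per-neuropil, at least `conn_threshold` synapses) lie within SEZ
#' neuropils; *projection* (non-local) iff at least one qualifying
#' connection lies outside; and *no_brain_output* if it has no qualifying
#' output connection in an annotated neuropil at all.
#'
#' @param graph A `connectome`.
#' @param neuron_ids Character vector of neuron ids.
#' @param sez SEZ neuropil base codes, default [sez_neuropils()].
#' @param conn_threshold Per-neuropil connection threshold (default 5).
#' @return Tibble: `neuron_id`, `classification`.
#' @export
classify_local_projection <- function(graph, neuron_ids, sez = sez_neuropils(),
                                      conn_threshold = 5) {
  stopifnot(inherits(graph, "connectome"))
  conns <- graph$edges |>
    filter(.data$pre_id %in% neuron_ids) |>
    group_by(.data$pre_id, .data$neuropil) |>
    summarise(np_syn = sum(.data$syn_count), .groups = "drop") |>
    filter(.data$np_syn >= conn_threshold)
  np <- parse_neuropil(conns$neuropil)
  conns <- mutate(conns, region = np$region, in_sez = np$region %in% sez)
  conns <- filter(conns, !is.na(.data$region))
  status <- conns |>
    group_by(neuron_id = .data$pre_id) |>
    summarise(all_sez = all(.data$in_sez), .groups = "drop")
  tibble(neuron_id = unique(neuron_ids)) |>
    left_join(status, by = "neuron_id") |>
    mutate(classification = dplyr::case_when(
      is.na(.data$all_sez) ~ "no_brain_output",
      .data$all_sez ~ "local",
      TRUE ~ "projection"
    )) |>
    select("neuron_id", "classification")
}

#' Partition output synapses by SEZ membership, hemisphere and region
#'
#' Synapse-level tallies of all outputs of a neuron set: within vs outside
#' the SEZ; non-SEZ synapses split into ipsilateral / contralateral
#' (hemisphere read from the `_L`/`_R` neuropil suffix, relative to
#' `ipsi_side`) or non-lateralized; and pooled per-region profiles
#' (homologous `_L`/`_R` regions combined) split by edge-level NT sign.
#' Synapses in unannotated neuropils are counted separately with a warning
#' and excluded from the SEZ/non-SEZ identity.
#'
#' @param graph A `connectome`.
#' @param members Tibble with `modality` and `neuron_id` (e.g. a `layer_map`
#'   or `seed_sets`), or a bare character vector of ids (single group).
#' @param sez SEZ neuropil base codes.
#' @param ipsi_side `"left"` (default; the side of the traced GRN arbors) or
#'   `"right"`.
#' @param sign_map See [nt_sign_map()].
#' @return Object of class `synapse_partition`: list with `summary` (per
#'   modality: `total`, `sez`, `outside`, `ipsi`, `contra`, `nonlateralized`,
#'   `unannotated`) and `regions` (per modality and pooled region: `in_sez`,
#'   `sign`, `synapses`).
#' @export
partition_output_synapses <- function(graph, members, sez = sez_neuropils(),
                                      ipsi_side = c("left", "right"),
                                      sign_map = nt_sign_map()) {
  stopifnot(inherits(graph, "connectome"))
  ipsi_side <- match.arg(ipsi_side)
  ipsi_hemi <- if (ipsi_side == "left") "L" else "R"
  if (is.character(members)) {
    members <- tibble(modality = "all", neuron_id = members)
  }
  members <- as_tibble(members)[c("modality", "neuron_id")]

  hits <- graph$edges |>
    inner_join(members, by = c(pre_id = "neuron_id"),
               relationship = "many-to-many")
  np <- parse_neuropil(hits$neuropil)
  hits <- mutate(hits,
                 region = np$region, hemi = np$hemi,
                 in_sez = !is.na(np$region) & np$region %in% sez,
                 sign = nt_sign(.data$nt_edge, sign_map))
  n_unann <- sum(hits$syn_count[is.na(hits$region)])
  if (n_unann > 0) {
    warn(sprintf("%d output synapse(s) in unannotated neuropils counted separately",
                 n_unann))
  }

  summary_tbl <- hits |>
    group_by(.data$modality) |>
    summarise(
      total = sum(.data$syn_count[!is.na(.data$region)]),
      sez = sum(.data$syn_count[.data$in_sez]),
      outside = sum(.data$syn_count[!.data$in_sez & !is.na(.data$region)]),
      ipsi = sum(.data$syn_count[!.data$in_sez & !is.na(.data$hemi) &
                                   .data$hemi == ipsi_hemi]),
      contra = sum(.data$syn_count[!.data$in_sez & !is.na(.data$hemi) &
                                     .data$hemi != ipsi_hemi]),
      nonlateralized = sum(.data$syn_count[!.data$in_sez & is.na(.data$hemi) &
                                             !is.na(.data$region)]),
      unannotated = sum(.data$syn_count[is.na(.data$region)]),
      .groups = "drop"
    )
  stopifnot(all(summary_tbl$sez + summary_tbl$outside == summary_tbl$total),
            all(summary_tbl$ipsi + summary_tbl$contra +
                  summary_tbl$nonlateralized == summary_tbl$outside))

  regions <- hits |>
    filter(!is.na(.data$region)) |>
    group_by(.data$modality, .data$region, .data$in_sez, .data$sign) |>
    summarise(synapses = sum(.data$syn_count), .groups = "drop")

  structure(list(summary = summary_tbl, regions = regions,
                 ipsi_side = ipsi_side, sez = sez),
            class = "synapse_partition")
}

#' @export
print.synapse_partition <- function(x, ...) {
  cat("<synapse_partition> ipsi side:", x$ipsi_side, "\n")
  print(x$summary)
  invisible(x)
}

#' Top output regions outside the SEZ
#'
#' Ranks pooled non-SEZ regions by synapse count for each modality and keeps
#' the top `k`. Ties are broken by count, then lexicographic region code
#' (flagged in the `tie` column). The coverage fraction reports how much of
#' each modality's non-SEZ output the selected regions account for.
#'
#' @param partition A `synapse_partition`.
#' @param k Number of regions per modality (e.g. 6 for 2Ns, 12 for 3Ns).
#' @return Tibble: `modality`, `rank`, `region`, `synapses`, `tie`,
#'   `coverage` (cumulative fraction of the modality's non-SEZ synapses).
#' @export
region_profile_topk <- function(partition, k) {
  stopifnot(inherits(partition, "synapse_partition"))
  pooled <- partition$regions |>
    filter(!.data$in_sez) |>
    group_by(.data$modality, .data$region) |>
    summarise(synapses = sum(.data$synapses), .groups = "drop")
  purrr::map(split(pooled, pooled$modality), function(d) {
    if (k > nrow(d)) {
      inform(sprintf("modality '%s' has only %d non-SEZ regions (k = %d); returning all",
                     d$modality[[1]], nrow(d), k))
    }
    d <- arrange(d, dplyr::desc(.data$synapses), .data$region)
    d$tie <- duplicated(d$synapses) | duplicated(d$synapses, fromLast = TRUE)
    total <- sum(d$synapses)
    d <- head(d, k)
    mutate(d, rank = dplyr::row_number(),
           coverage = cumsum(.data$synapses) / total) |>
      select("modality", "rank", "region", "synapses", "tie", "coverage")
  }) |> bind_rows()
}

#' Categorical census of a neuron set
#'
#' Exhaustive counts of superclass, class, or neuron-level NT labels over a
#' neuron set, including `unknown`.
#'
#' @param graph A `connectome`.
#' @param members Tibble with `modality` and `neuron_id`, or a character
#'   vector of ids.
#' @param field One of `superclass`, `class_label`, `nt_neuron`.
#' @return Tibble: `modality`, `category`, `n`.
#' @export
census <- function(graph, members,
                   field = c("superclass", "class_label", "nt_neuron")) {
  stopifnot(inherits(graph, "connectome"))
  field <- match.arg(field)
  if (is.character(members)) {
    members <- tibble(modality = "all", neuron_id = members)
  }
  members <- as_tibble(members)[c("modality", "neuron_id")]
  missing <- setdiff(members$neuron_id, graph$neurons$neuron_id)
  if (length(missing) > 0) {
    stop_tastetrace(
      sprintf("id(s) absent from the connectome: %s",
              paste(head(missing, 5), collapse = ", ")),
      "tastetrace_integrity_error"
    )
  }
  members |>
    left_join(graph$neurons[c("neuron_id", field)], by = "neuron_id") |>
    count(.data$modality, category = .data[[field]], name = "n") |>
    arrange(.data$modality, dplyr::desc(.data$n))
}

#' Fisher's exact test for a difference in proportions
#'
#' Two-sided exact test on the 2x2 table `rbind(c(a1, a2), c(b1, b2))`,
#' e.g. SEZ vs non-SEZ synapse counts for two modalities.
#'
#' @param count_a1,count_a2 First group's counts in the two categories.
#' @param count_b1,count_b2 Second group's counts.
#' @return Two-sided p-value (double).
#' @export
fisher_proportion_test <- function(count_a1, count_a2, count_b1, count_b2) {
  counts <- c(count_a1, count_a2, count_b1, count_b2)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_tastetrace("counts must be non-negative integers",
                    "tastetrace_validation_error")
  }
  if (sum(counts) == 0) {
    stop_tastetrace("all-zero contingency table", "tastetrace_validation_error")
  }
  tab <- matrix(counts, nrow = 2, byrow = TRUE)
  fisher.test(tab, alternative = "two.sided")$p.value
}
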