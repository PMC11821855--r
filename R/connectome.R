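# connectome_io: reading, validating and indexing neuron/edge tables and
# GRN seed lists into a queryable connectome graph.

#' Default column aliases for FlyWire-dialect tables
#'
#' Connectome dumps name their columns differently across releases (e.g.
#' `root_id` vs `pre_root_id`). The loader maps whichever alias it finds onto
#' one canonical internal schema. Supply a modified copy of this list to
#' [load_connectome()] to support other dialects.
#'
#' @return A named list with elements `neurons` and `edges`; each is a named
#'   list mapping canonical column names to a character vector of accepted
#'   aliases (first match wins).
#' @export
dialect_aliases <- function() {
  list(
    neurons = list(
      neuron_id   = c("neuron_id", "root_id", "id"),
      superclass  = c("superclass", "super_class"),
      class_label = c("class_label", "class", "cell_class"),
      side        = c("side", "hemisphere"),
      nt_neuron   = c("nt_neuron", "nt_type", "predicted_nt", "top_nt")
    ),
    edges = list(
      pre_id    = c("pre_id", "pre_root_id", "pre_pt_root_id"),
      post_id   = c("post_id", "post_root_id", "post_pt_root_id"),
      neuropil  = c("neuropil", "region"),
      syn_count = c("syn_count", "n_syn", "syn_cnt", "count", "weight"),
      nt_edge   = c("nt_edge", "nt_type", "predicted_nt")
    )
  )
}

# Rename raw columns to the canonical schema; error names the first missing
# canonical column. Optional columns may be listed in `optional`.
apply_aliases <- function(df, aliases, table_name, optional = character()) {
  out <- list()
  for (canonical in names(aliases)) {
    hit <- intersect(aliases[[canonical]], names(df))
    if (length(hit) == 0) {
      if (canonical %in% optional) {
        next
      }
      stop_tastetrace(
        sprintf("%s table is missing required column '%s' (accepted aliases: %s)",
                table_name, canonical, paste(aliases[[canonical]], collapse = ", ")),
        "tastetrace_format_error"
      )
    }
    out[[canonical]] <- df[[hit[[1]]]]
  }
  as_tibble(out)
}

#' Construct a connectome graph from neuron and edge tables
#'
#' Validates and indexes in-memory tables. Duplicate
#' `(pre_id, post_id, neuropil, nt_edge)` rows are summed; `pair_totals`
#' aggregates synapse counts per directed neuron pair across neuropils.
#'
#' @param neurons Data frame with columns `neuron_id`, `superclass`,
#'   `class_label`, `side`, `nt_neuron`.
#' @param edges Data frame with columns `pre_id`, `post_id`, `neuropil`,
#'   `syn_count`, `nt_edge`.
#' @param missing_neurons How to treat edges whose endpoints are absent from
#'   the neuron table: `"error"` (default) or `"drop"` (warn and discard).
#' @return An object of class `connectome`: a list with tibbles `neurons`,
#'   `edges` (one row per pre/post/neuropil/nt), and `pair_totals`
#'   (`pre_id`, `post_id`, `total_syn`).
#' @export
connectome <- function(neurons, edges, missing_neurons = c("error", "drop")) {
  missing_neurons <- match.arg(missing_neurons)
  neurons <- as_tibble(neurons)
  edges <- as_tibble(edges)

  neurons <- mutate(
    neurons,
    neuron_id   = as.character(.data$neuron_id),
    superclass  = normalize_levels(.data$superclass, neuron_superclasses()),
    class_label = ifelse(is.na(as.character(.data$class_label)) |
                           !nzchar(as.character(.data$class_label)),
                         "unknown", as.character(.data$class_label)),
    side        = normalize_levels(.data$side, c("left", "right", "center")),
    nt_neuron   = normalize_levels(.data$nt_neuron, nt_levels())
  )
  if (anyDuplicated(neurons$neuron_id)) {
    dup <- unique(neurons$neuron_id[duplicated(neurons$neuron_id)])
    stop_tastetrace(
      sprintf("duplicate neuron ids in neuron table: %s",
              paste(head(dup, 5), collapse = ", ")),
      "tastetrace_format_error"
    )
  }

  edges <- mutate(
    edges,
    pre_id    = as.character(.data$pre_id),
    post_id   = as.character(.data$post_id),
    neuropil  = as.character(.data$neuropil),
    syn_count = as.integer(.data$syn_count),
    nt_edge   = normalize_levels(.data$nt_edge, nt_levels())
  )
  if (any(is.na(edges$syn_count)) || any(edges$syn_count < 1)) {
    stop_tastetrace("edge syn_count must be a positive integer",
                    "tastetrace_format_error")
  }

  known <- neurons$neuron_id
  orphan <- setdiff(unique(c(edges$pre_id, edges$post_id)), known)
  if (length(orphan) > 0) {
    if (missing_neurons == "error") {
      stop_tastetrace(
        sprintf("edge table references %d neuron id(s) absent from the neuron table: %s",
                length(orphan), paste(head(orphan, 10), collapse = ", ")),
        "tastetrace_integrity_error"
      )
    }
    warn(sprintf("dropping edges touching %d unknown neuron id(s)", length(orphan)))
    edges <- filter(edges, !(.data$pre_id %in% orphan) & !(.data$post_id %in% orphan))
  }

  edges <- edges |>
    group_by(.data$pre_id, .data$post_id, .data$neuropil, .data$nt_edge) |>
    summarise(syn_count = sum(.data$syn_count), .groups = "drop") |>
    arrange(.data$pre_id, .data$post_id, .data$neuropil, .data$nt_edge)

  pair_totals <- edges |>
    group_by(.data$pre_id, .data$post_id) |>
    summarise(total_syn = sum(.data$syn_count), .groups = "drop")

  structure(
    list(neurons = neurons, edges = edges, pair_totals = pair_totals),
    class = "connectome"
  )
}

#' @export
print.connectome <- function(x, ...) {
  cat("<connectome>", nrow(x$neurons), "neurons,",
      nrow(x$edges), "neuropil-level edges,",
      sum(x$edges$syn_count), "synapses\n")
  invisible(x)
}

#' Load a connectome from FlyWire-dialect CSV tables
#'
#' Reads (optionally gzipped) neuron and edge CSVs, maps column aliases onto
#' the canonical schema, and indexes them with [connectome()]. Neuron ids are
#' read as character so 64-bit identifiers survive intact.
#'
#' @param neuron_path,edge_path Paths to the neuron and edge CSV files.
#' @param aliases Column-alias table, see [dialect_aliases()].
#' @param missing_neurons Passed to [connectome()].
#' @return A `connectome` object.
#' @export
load_connectome <- function(neuron_path, edge_path,
                            aliases = dialect_aliases(),
                            missing_neurons = c("error", "drop")) {
  for (p in c(neuron_path, edge_path)) {
    if (!file.exists(p)) {
      stop_tastetrace(sprintf("file not found: %s", p), "tastetrace_io_error")
    }
  }
  raw_neurons <- readr::read_csv(neuron_path, col_types = readr::cols(.default = "c"),
                                 progress = FALSE)
  raw_edges <- readr::read_csv(edge_path, col_types = readr::cols(.default = "c"),
                               progress = FALSE)
  neurons <- apply_aliases(raw_neurons, aliases$neurons, "neuron",
                           optional = c("class_label", "side", "nt_neuron"))
  for (opt in c("class_label", "side", "nt_neuron")) {
    if (is.null(neurons[[opt]])) neurons[[opt]] <- "unknown"
  }
  edges <- apply_aliases(raw_edges, aliases$edges, "edge", optional = "nt_edge")
  if (is.null(edges$nt_edge)) edges$nt_edge <- "unknown"
  edges$syn_count <- suppressWarnings(as.integer(edges$syn_count))
  if (any(is.na(edges$syn_count))) {
    stop_tastetrace("edge syn_count contains non-numeric values",
                    "tastetrace_format_error")
  }
  connectome(neurons, edges, missing_neurons = match.arg(missing_neurons))
}

#' Write a connectome back to the CSV dialect
#'
#' Emits `neurons.csv` and `edges.csv` (canonical column names) such that
#' [load_connectome()] reproduces identical pair totals and neuropil-level
#' counts.
#'
#' @param graph A `connectome`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_connectome <- function(graph, dir) {
  stopifnot(inherits(graph, "connectome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(neurons = file.path(dir, "neurons.csv"),
             edges = file.path(dir, "edges.csv"))
  readr::write_csv(graph$neurons, paths[["neurons"]], progress = FALSE)
  readr::write_csv(graph$edges, paths[["edges"]], progress = FALSE)
  invisible(paths)
}

#' Load per-modality GRN seed lists
#'
#' Seed lists name the gustatory receptor neurons (GRNs) that anchor layer
#' tracing. Accepts either a named list of per-modality files (one id per
#' line, or a CSV with a `neuron_id` column) or a single CSV with `modality`
#' and `neuron_id` columns. Ids are deduplicated within a modality; an id
#' claimed by two modalities is an error, as is an id absent from the graph.
#'
#' @param paths Named list/vector of file paths (names are modalities), or a
#'   single path to a CSV with a `modality` column.
#' @param graph A `connectome` the ids must resolve against.
#' @return A tibble of class `seed_sets` with columns `modality`, `neuron_id`.
#' @export
load_seed_sets <- function(paths, graph) {
  stopifnot(inherits(graph, "connectome"))
  if (length(paths) == 1 && is.null(names(paths))) {
    df <- readr::read_csv(paths[[1]], col_types = readr::cols(.default = "c"),
                          progress = FALSE)
    if (!all(c("modality", "neuron_id") %in% names(df))) {
      stop_tastetrace("seed CSV must have 'modality' and 'neuron_id' columns",
                      "tastetrace_format_error")
    }
    df <- select(df, "modality", "neuron_id")
  } else {
    df <- purrr::imap(as.list(paths), function(p, modality) {
      lines <- readr::read_lines(p, progress = FALSE)
      lines <- trimws(lines)
      # tolerate a CSV with a neuron_id column as well as bare id-per-line
      if (length(lines) > 0 && grepl("neuron_id", lines[[1]])) {
        ids <- readr::read_csv(p, col_types = readr::cols(.default = "c"),
                               progress = FALSE)$neuron_id
      } else {
        ids <- lines[nzchar(lines)]
      }
      if (length(ids) == 0) {
        warn(sprintf("seed list for modality '%s' is empty", modality))
      }
      tibble(modality = modality, neuron_id = as.character(ids))
    }) |> bind_rows()
  }
  seed_sets(df, graph)
}

#' Construct seed sets from a data frame
#'
#' @param df Data frame with columns `modality` and `neuron_id`.
#' @param graph Optional `connectome` for referential checks.
#' @return A `seed_sets` tibble.
#' @export
seed_sets <- function(df, graph = NULL) {
  df <- as_tibble(df) |>
    mutate(modality = tolower(as.character(.data$modality)),
           neuron_id = as.character(.data$neuron_id)) |>
    distinct(.data$modality, .data$neuron_id)
  bad_mod <- setdiff(unique(df$modality), taste_modalities())
  if (length(bad_mod) > 0) {
    stop_tastetrace(sprintf("unknown modality: %s", paste(bad_mod, collapse = ", ")),
                    "tastetrace_format_error")
  }
  dup <- df |> count(.data$neuron_id) |> filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop_tastetrace(
      sprintf("seed id(s) assigned to more than one modality: %s",
              paste(head(dup$neuron_id, 5), collapse = ", ")),
      "tastetrace_ambiguity_error"
    )
  }
  if (!is.null(graph)) {
    missing <- setdiff(df$neuron_id, graph$neurons$neuron_id)
    if (length(missing) > 0) {
      stop_tastetrace(
        sprintf("seed id(s) absent from the connectome: %s",
                paste(head(missing, 10), collapse = ", ")),
        "tastetrace_integrity_error"
      )
    }
  }
  structure(df, class = c("seed_sets", class(df)))
}

#' Default neurotransmitter sign map
#'
#' Acetylcholine is the fly brain's major excitatory transmitter; GABA and
#' glutamate are the major inhibitory transmitters. Dopamine, serotonin,
#' octopamine and unknown labels have an unclear postsynaptic sign and are
#' classed `other`.
#'
#' @return Named character vector mapping NT labels to
#'   `excitatory`/`inhibitory`/`other`.
#' @export
nt_sign_map <- function() {
  c(ACH = "excitatory", GABA = "inhibitory", GLUT = "inhibitory",
    DA = "other", SER = "other", OCT = "other", unknown = "other")
}

#' Map neurotransmitter labels to synaptic sign
#'
#' @param nt Character vector of NT labels (see [nt_levels()]).
#' @param sign_map Named map from NT label to sign; see [nt_sign_map()].
#' @return Character vector of `excitatory`/`inhibitory`/`other`.
#' @export
nt_sign <- function(nt, sign_map = nt_sign_map()) {
  nt <- normalize_levels(nt, nt_levels())
  unname(sign_map[nt])
}
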