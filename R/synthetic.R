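# synthetic_connectome: generate a small connectome with planted taste layers
# and full ground truth, in the same dialect the loader reads.
#
# Layer sizes, pairwise overlaps, E/I composition, SEZ/laterality fractions
# and synapse-count distributions default to the study conditions for the
# left-hemisphere labellar pathways; every quantity is configurable through
# synth_spec(). All randomness flows through one seeded RNG.

canonical_pair <- function(a, b) {
  ord <- match(c(a, b), taste_modalities())
  paste(c(a, b)[order(ord)], collapse = ":")
}

#' Specification for a synthetic taste connectome
#'
#' Defaults emulate the traced left-hemisphere labellar circuit: GRN counts
#' 22/18/20/9 (sugar/water/bitter/IR94e), second-order (2N) layer sizes
#' 76/51/64/24 with planted sugar:water overlap of 28 neurons (water:bitter 6,
#' bitter:ir94e 8), and third-order (3N) layers 515/324/396/222 with heavier
#' cross-modality sharing. Suprathreshold connection strengths follow a
#' shifted geometric law (threshold + geometric tail), giving the heavy right
#' tail seen in connection-strength distributions.
#'
#' @param rng_seed Integer seed; the single source of randomness.
#' @param n_grn,n_2n,n_3n Named integer vectors (per modality) of layer sizes.
#' @param overlap_2n,overlap_3n Named lists of planted shared-neuron counts
#'   per modality pair (names like `"sugar:water"`); a shared neuron belongs
#'   to exactly the two modalities of its pair.
#' @param syn_geom_p Geometric tail parameters for edge synapse counts:
#'   `grn_2n` and `n2_3n` (count = threshold + rgeom(p)).
#' @param fanin_lambda Poisson fan-in parameters (inputs per neuron =
#'   1 + rpois(lambda)): `grn_2n` and `n2_3n`.
#' @param fanin_strength_coupling Non-negative coupling constant; when > 0,
#'   neurons with more inputs also receive more synapses per input (adds
#'   rpois(coupling * (fan_in - 1)) to each edge). Default 0 (off).
#' @param ei_fraction List with elements `"2N"` and `"3N"`, each a named
#'   per-modality vector of the proportion of planted neurons that are
#'   excitatory (ACH); the rest split evenly between GABA and GLUT.
#' @param p_feedback Named numeric vector of feedback/lateral edge rates
#'   (expected edges per source neuron): `n2_grn`, `n2_n2`, `n3_n2`, `n3_grn`.
#'   Feedback synapse counts are drawn in 5..9 so they register as
#'   connections without promoting extra neurons into planted layers.
#' @param weak_2n_fraction Fraction of exclusive 2Ns per modality planted
#'   with 5-9 total GRN synapses (below the 10-synapse expansion gate).
#' @param sez_fraction,contra_fraction Lists (`"2N"`, `"3N"`) of named
#'   per-modality proportions: probability an output edge is placed in a SEZ
#'   neuropil, and probability a non-SEZ edge lands in the right (contralateral)
#'   hemisphere.
#' @param grn_grn_per_grn Named per-modality within-type GRN-GRN synapses per
#'   GRN; `water_to_sugar` adds cross-type water-to-sugar synapses per water GRN.
#' @param n_background Number of non-taste background neurons.
#' @param bg_in_lambda Poisson mean number of background input partners per
#'   2N (`"2N"`) and 3N (`"3N"`).
#' @param n_decoy_per_modality Decoy edges per modality at each filtering
#'   boundary (GRN edges at 4 synapses; qualified-2N edges at 9; weak-2N
#'   edges at 15).
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(
    rng_seed = 1L,
    n_grn = c(sugar = 22L, water = 18L, bitter = 20L, ir94e = 9L),
    n_2n = c(sugar = 76L, water = 51L, bitter = 64L, ir94e = 24L),
    n_3n = c(sugar = 515L, water = 324L, bitter = 396L, ir94e = 222L),
    overlap_2n = list("sugar:water" = 28L, "water:bitter" = 6L,
                      "bitter:ir94e" = 8L),
    overlap_3n = list("sugar:water" = 201L, "sugar:bitter" = 129L,
                      "sugar:ir94e" = 67L, "water:bitter" = 60L,
                      "water:ir94e" = 40L, "bitter:ir94e" = 70L),
    syn_geom_p = list(grn_2n = 0.35, n2_3n = 0.30),
    fanin_lambda = list(grn_2n = 1.5, n2_3n = 0.7),
    fanin_strength_coupling = 0,
    ei_fraction = list(
      "2N" = c(sugar = 0.50, water = 0.50, bitter = 0.27, ir94e = 0.19),
      "3N" = c(sugar = 0.46, water = 0.47, bitter = 0.62, ir94e = 0.63)),
    p_feedback = c(n2_grn = 0.30, n2_n2 = 0.40, n3_n2 = 0.10, n3_grn = 0.02),
    weak_2n_fraction = 0.10,
    sez_fraction = list(
      "2N" = c(sugar = 0.97, water = 0.94, bitter = 0.79, ir94e = 0.79),
      "3N" = c(sugar = 0.89, water = 0.87, bitter = 0.84, ir94e = 0.82)),
    contra_fraction = list(
      "2N" = c(sugar = 0.03, water = 0.03, bitter = 0.34, ir94e = 0.22),
      "3N" = c(sugar = 0.40, water = 0.44, bitter = 0.35, ir94e = 0.40)),
    grn_grn_per_grn = c(sugar = 23, water = 9, bitter = 0.5, ir94e = 35,
                        water_to_sugar = 4),
    n_background = 120L,
    bg_in_lambda = c("2N" = 3, "3N" = 4),
    n_decoy_per_modality = 3L) {
  spec <- list(
    rng_seed = as.integer(rng_seed), n_grn = n_grn, n_2n = n_2n, n_3n = n_3n,
    overlap_2n = overlap_2n, overlap_3n = overlap_3n,
    syn_geom_p = syn_geom_p, fanin_lambda = fanin_lambda,
    fanin_strength_coupling = fanin_strength_coupling,
    ei_fraction = ei_fraction, p_feedback = p_feedback,
    weak_2n_fraction = weak_2n_fraction,
    sez_fraction = sez_fraction, contra_fraction = contra_fraction,
    grn_grn_per_grn = grn_grn_per_grn,
    n_background = as.integer(n_background), bg_in_lambda = bg_in_lambda,
    n_decoy_per_modality = as.integer(n_decoy_per_modality)
  )
  class(spec) <- "synth_spec"
  validate_synth_spec(spec)
  spec
}

validate_synth_spec <- function(spec) {
  mods <- names(spec$n_grn)
  if (is.null(mods) || !all(mods %in% taste_modalities())) {
    stop_tastetrace("n_grn must be named by modality", "tastetrace_spec_error")
  }
  props <- c(unlist(spec$ei_fraction), unlist(spec$sez_fraction),
             unlist(spec$contra_fraction), spec$weak_2n_fraction)
  if (any(props < 0 | props > 1)) {
    stop_tastetrace("all proportions must lie in [0, 1]", "tastetrace_spec_error")
  }
  for (layer in c("2N", "3N")) {
    sizes <- if (layer == "2N") spec$n_2n else spec$n_3n
    overlaps <- if (layer == "2N") spec$overlap_2n else spec$overlap_3n
    for (key in names(overlaps)) {
      pair <- strsplit(key, ":", fixed = TRUE)[[1]]
      if (overlaps[[key]] > min(sizes[pair])) {
        stop_tastetrace(
          sprintf("planted %s overlap %s (%d) exceeds a layer size", layer, key,
                  overlaps[[key]]),
          "tastetrace_spec_error"
        )
      }
    }
    shared_per_mod <- vapply(names(sizes), function(m) {
      sum(vapply(names(overlaps), function(key) {
        if (m %in% strsplit(key, ":", fixed = TRUE)[[1]]) overlaps[[key]] else 0L
      }, numeric(1)))
    }, numeric(1))
    if (any(shared_per_mod > sizes[names(shared_per_mod)])) {
      stop_tastetrace(
        sprintf("planted %s overlaps exceed layer size for modality %s", layer,
                paste(names(sizes)[shared_per_mod > sizes], collapse = ", ")),
        "tastetrace_spec_error"
      )
    }
  }
  invisible(spec)
}

# Assign layer membership with planted pairwise overlaps. Returns a tibble
# (neuron_id, modality) where shared neurons appear once per modality.
plant_memberships <- function(sizes, overlaps, id_start) {
  mods <- names(sizes)
  members <- list()
  next_id <- id_start
  for (key in names(overlaps)) {
    k <- overlaps[[key]]
    if (k == 0) next
    pair <- strsplit(key, ":", fixed = TRUE)[[1]]
    ids <- as.character(seq.int(next_id, length.out = k))
    next_id <- next_id + k
    members[[length(members) + 1L]] <-
      tibble(neuron_id = rep(ids, 2L), modality = rep(pair, each = k))
  }
  shared <- if (length(members)) bind_rows(members) else
    tibble(neuron_id = character(), modality = character())
  for (m in mods) {
    n_shared <- sum(shared$modality == m)
    n_excl <- sizes[[m]] - n_shared
    if (n_excl > 0) {
      ids <- as.character(seq.int(next_id, length.out = n_excl))
      next_id <- next_id + n_excl
      members[[length(members) + 1L]] <- tibble(neuron_id = ids, modality = m)
    }
  }
  list(members = bind_rows(members), next_id = next_id)
}

draw_nt <- function(n, p_exc) {
  exc <- runif(n) < p_exc
  inh <- sample(c("GABA", "GLUT"), n, replace = TRUE)
  ifelse(exc, "ACH", inh)
}

# Neuropil for output edges of a taste neuron: SEZ w.p. p_sez, else a
# lateralized higher-brain region, contralateral (_R) w.p. p_contra.
draw_neuropil <- function(n, p_sez, p_contra) {
  higher <- c("SLP", "SMP", "LH", "SCL", "AVLP", "LAL", "MB_CA", "VES")
  p_sez <- rep_len(p_sez, n)
  p_contra <- rep_len(p_contra, n)
  in_sez <- runif(n) < p_sez
  out <- character(n)
  out[in_sez] <- sample(sez_neuropils(), sum(in_sez), replace = TRUE,
                        prob = c(0.6, 0.1, 0.1, 0.1, 0.1))
  n_out <- sum(!in_sez)
  if (n_out > 0) {
    base <- sample(higher, n_out, replace = TRUE)
    hemi <- ifelse(runif(n_out) < p_contra[!in_sez], "R", "L")
    out[!in_sez] <- paste(base, hemi, sep = "_")
  }
  out
}

#' Generate a synthetic connectome with planted ground truth
#'
#' Builds GRN, 2N and 3N layers per modality with planted overlaps, draws
#' suprathreshold feed-forward edges (every planted GRN-2N pair totals >= 5
#' synapses, every planted 2N-3N pair >= 10, and every expanded 2N receives
#' >= 10 total GRN synapses), then adds GRN-GRN connections, sub-threshold
#' decoy edges at each filtering boundary, capped feedback/lateral edges, and
#' non-taste background inputs. Edge-level neurotransmitter labels equal the
#' presynaptic neuron's label, so planted signs are exact.
#'
#' @param spec A [synth_spec()].
#' @return A list with elements `graph` (a [connectome()]), `seeds`
#'   (a `seed_sets` tibble) and `truth` (planted ground truth: `layers`,
#'   per-membership input records `input_2n` / `input_3n`, planted overlap
#'   tables, feedback edge list, per-neuron signs, and the spec itself).
#' @export
generate_connectome <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(spec$rng_seed)

  mods <- names(spec$n_grn)
  edges <- list()
  truth_feedback <- list()

  ## --- neurons ---------------------------------------------------------
  next_id <- 1000L
  grn <- purrr::imap(as.list(spec$n_grn), function(k, m) {
    ids <- as.character(seq.int(next_id + 1000L * (match(m, mods) - 1L),
                                length.out = k))
    tibble(neuron_id = ids, modality = m)
  }) |> bind_rows()

  p2 <- plant_memberships(spec$n_2n, spec$overlap_2n, 20000L)
  m2 <- p2$members
  p3 <- plant_memberships(spec$n_3n, spec$overlap_3n, 30000L)
  m3 <- p3$members

  bg_ids <- if (spec$n_background > 0) {
    as.character(seq.int(90000L, length.out = spec$n_background))
  } else character()

  # primary modality of a (possibly shared) neuron: first membership row
  primary_mod <- function(members) {
    members |> group_by(.data$neuron_id) |>
      summarise(modality = .data$modality[[1]], .groups = "drop")
  }
  u2 <- primary_mod(m2)
  u3 <- primary_mod(m3)

  nt_of <- c(
    setNames(rep("ACH", nrow(grn)), grn$neuron_id),
    setNames(draw_nt(nrow(u2), spec$ei_fraction[["2N"]][u2$modality]), u2$neuron_id),
    setNames(draw_nt(nrow(u3), spec$ei_fraction[["3N"]][u3$modality]), u3$neuron_id)
  )
  if (length(bg_ids)) {
    nt_of <- c(nt_of, setNames(
      sample(c("ACH", "GABA", "GLUT", "DA", "unknown"), length(bg_ids),
             replace = TRUE, prob = c(0.45, 0.2, 0.15, 0.1, 0.1)),
      bg_ids))
  }

  bg_classes <- c("mechanosensory", "ALPN", "ALLN", "LHLN", "LHCENT", "MBON",
                  "AN", "DN", "unknown")
  bg_superclass <- c(mechanosensory = "sensory", ALPN = "central",
                     ALLN = "central", LHLN = "central", LHCENT = "central",
                     MBON = "central", AN = "ascending", DN = "descending",
                     unknown = "central")
  draw_superclass <- function(n, m, layer) {
    if (layer == "2N") {
      p_desc <- if (m == "ir94e") 0 else 0.10
      sample(c("central", "ascending", "descending"), n, replace = TRUE,
             prob = c(1 - 0.10 - p_desc, 0.10, p_desc))
    } else {
      sample(c("central", "ascending", "descending", "motor", "sensory"),
             n, replace = TRUE, prob = c(0.68, 0.04, 0.12, 0.06, 0.10))
    }
  }
  sc2 <- setNames(draw_superclass(nrow(u2), "any", "2N"), u2$neuron_id)
  for (m in mods) {
    idx <- u2$modality == m
    sc2[u2$neuron_id[idx]] <- draw_superclass(sum(idx), m, "2N")
  }
  # IR94e 2Ns contain no descending neurons; apply to every membership,
  # including neurons shared with another modality
  if ("ir94e" %in% mods) {
    ir_ids <- m2$neuron_id[m2$modality == "ir94e"]
    hit <- names(sc2) %in% ir_ids & sc2 == "descending"
    sc2[hit] <- "central"
  }
  sc3 <- setNames(draw_superclass(nrow(u3), "any", "3N"), u3$neuron_id)
  bg_cls <- setNames(sample(bg_classes, length(bg_ids), replace = TRUE), bg_ids)

  class_from_superclass <- function(sc) {
    ifelse(sc == "ascending", "AN", ifelse(sc == "descending", "DN", "unknown"))
  }
  neurons <- bind_rows(
    tibble(neuron_id = grn$neuron_id, superclass = "sensory",
           class_label = "gustatory", side = "left",
           nt_neuron = nt_of[grn$neuron_id]),
    tibble(neuron_id = u2$neuron_id, superclass = unname(sc2[u2$neuron_id]),
           class_label = class_from_superclass(unname(sc2[u2$neuron_id])),
           side = "left", nt_neuron = unname(nt_of[u2$neuron_id])),
    tibble(neuron_id = u3$neuron_id, superclass = unname(sc3[u3$neuron_id]),
           class_label = class_from_superclass(unname(sc3[u3$neuron_id])),
           side = "left", nt_neuron = unname(nt_of[u3$neuron_id])),
    if (length(bg_ids)) tibble(
      neuron_id = bg_ids, superclass = unname(bg_superclass[bg_cls]),
      class_label = unname(bg_cls),
      side = sample(c("left", "right"), length(bg_ids), replace = TRUE),
      nt_neuron = unname(nt_of[bg_ids]))
  )

  add_edges <- function(pre, post, syn, neuropil) {
    edges[[length(edges) + 1L]] <<- tibble(
      pre_id = pre, post_id = post, neuropil = neuropil,
      syn_count = as.integer(syn), nt_edge = unname(nt_of[pre]))
  }

  # Decoy and feedback synapse counts sit deliberately below the tracing
  # thresholds; a repeated (pre, post) pair would sum past them and corrupt
  # the planted layers, so such pairs are drawn at most once.
  used_pairs <- new.env(parent = emptyenv())
  claim_pair <- function(pre, post) {
    key <- paste(pre, post, sep = "|")
    if (!is.null(used_pairs[[key]])) return(FALSE)
    used_pairs[[key]] <- TRUE
    TRUE
  }

  ## --- GRN -> 2N feed-forward ------------------------------------------
  grn_by_mod <- split(grn$neuron_id, grn$modality)
  weak_2n <- character()
  input_2n <- list()
  for (m in mods) {
    mem <- m2$neuron_id[m2$modality == m]
    excl <- setdiff(mem, m2$neuron_id[duplicated(m2$neuron_id) |
                                        duplicated(m2$neuron_id, fromLast = TRUE)])
    n_weak <- floor(spec$weak_2n_fraction * length(excl))
    weak_m <- if (n_weak > 0) sample(excl, n_weak) else character()
    weak_2n <- c(weak_2n, weak_m)
    for (nid in mem) {
      if (nid %in% weak_m) {
        g <- sample(grn_by_mod[[m]], 1)
        syn <- sample(5:9, 1)
        add_edges(g, nid, syn, "GNG")
        input_2n[[length(input_2n) + 1L]] <-
          tibble(modality = m, neuron_id = nid, n_inputs = 1L,
                 total_syn = as.integer(syn))
        next
      }
      k <- min(1L + rpois(1, spec$fanin_lambda$grn_2n), length(grn_by_mod[[m]]))
      g <- sample(grn_by_mod[[m]], k)
      syn <- 5L + rgeom(k, spec$syn_geom_p$grn_2n)
      if (spec$fanin_strength_coupling > 0 && k > 1) {
        syn <- syn + rpois(k, spec$fanin_strength_coupling * (k - 1))
      }
      if (sum(syn) < 10L) syn[[1]] <- syn[[1]] + (10L - sum(syn))
      npil <- rep("GNG", k)
      # occasionally split a connection across two SEZ neuropils to exercise
      # pair-total aggregation
      for (j in seq_len(k)) {
        if (syn[[j]] >= 10L && runif(1) < 0.05) {
          part <- sample(3:(syn[[j]] - 3), 1)
          add_edges(g[[j]], nid, part, "GNG")
          add_edges(g[[j]], nid, syn[[j]] - part, "SAD")
        } else {
          add_edges(g[[j]], nid, syn[[j]], npil[[j]])
        }
      }
      input_2n[[length(input_2n) + 1L]] <-
        tibble(modality = m, neuron_id = nid, n_inputs = k,
               total_syn = as.integer(sum(syn)))
    }
  }
  input_2n <- bind_rows(input_2n)

  ## --- GRN -> GRN ------------------------------------------------------
  grn_grn_block <- function(pre_pool, post_pool, total) {
    while (total > 0) {
      syn <- min(total, sample(2:8, 1))
      pre <- sample(pre_pool, 1)
      post <- sample(setdiff(post_pool, pre), 1)
      add_edges(pre, post, syn, "GNG")
      total <- total - syn
    }
  }
  for (m in mods) {
    rate <- spec$grn_grn_per_grn[m]
    if (is.na(rate)) next
    tot <- round(rate * spec$n_grn[[m]])
    if (tot >= 2 && spec$n_grn[[m]] >= 2) grn_grn_block(grn_by_mod[[m]], grn_by_mod[[m]], tot)
  }
  if (!is.na(spec$grn_grn_per_grn["water_to_sugar"]) &&
      all(c("water", "sugar") %in% mods)) {
    tot <- round(spec$grn_grn_per_grn[["water_to_sugar"]] * spec$n_grn[["water"]])
    if (tot >= 2) grn_grn_block(grn_by_mod$water, grn_by_mod$sugar, tot)
  }

  ## --- 2N -> 3N feed-forward -------------------------------------------
  qualified_2n <- lapply(mods, function(m) {
    setdiff(m2$neuron_id[m2$modality == m], weak_2n)
  })
  names(qualified_2n) <- mods
  # parents of planted 3Ns come from modality-EXCLUSIVE qualified 2Ns: a 2N
  # shared between two modalities is above the expansion gate in both, so its
  # children would join both 3N layers and break the planted memberships
  shared_2n <- m2$neuron_id[duplicated(m2$neuron_id) |
                              duplicated(m2$neuron_id, fromLast = TRUE)]
  parent_2n <- lapply(qualified_2n, function(ids) setdiff(ids, shared_2n))
  input_3n <- list()
  used_parents <- new.env(parent = emptyenv())
  for (m in mods) {
    pool <- parent_2n[[m]]
    for (nid in m3$neuron_id[m3$modality == m]) {
      taken <- used_parents[[nid]] %||% character()
      avail <- setdiff(pool, taken)
      k <- min(1L + rpois(1, spec$fanin_lambda$n2_3n), length(avail))
      parents <- sample(avail, k)
      used_parents[[nid]] <- c(taken, parents)
      syn <- 10L + rgeom(k, spec$syn_geom_p$n2_3n)
      p_mod <- u2$modality[match(parents, u2$neuron_id)]
      npil <- draw_neuropil(k, spec$sez_fraction[["2N"]][p_mod],
                            spec$contra_fraction[["2N"]][p_mod])
      for (j in seq_len(k)) add_edges(parents[[j]], nid, syn[[j]], npil[[j]])
      input_3n[[length(input_3n) + 1L]] <-
        tibble(modality = m, neuron_id = nid, n_inputs = k,
               total_syn = as.integer(sum(syn)))
    }
  }
  input_3n <- bind_rows(input_3n)

  ## --- decoys at the filtering boundaries ------------------------------
  if (length(bg_ids) && spec$n_decoy_per_modality > 0) {
    for (m in mods) {
      for (i in seq_len(spec$n_decoy_per_modality)) {
        # GRN edge just under the 2N threshold
        pre <- sample(grn_by_mod[[m]], 1); post <- sample(bg_ids, 1)
        if (claim_pair(pre, post)) add_edges(pre, post, 4L, "GNG")
        # qualified-2N edge just under the 3N hop-2 threshold
        pre <- sample(qualified_2n[[m]], 1); post <- sample(bg_ids, 1)
        if (claim_pair(pre, post)) add_edges(pre, post, 9L, "GNG")
        # strong edge from a weak (unexpanded) 2N: blocked by the hop-1 gate
        weak_m <- intersect(weak_2n, m2$neuron_id[m2$modality == m])
        if (length(weak_m)) {
          pre <- sample(weak_m, 1); post <- sample(bg_ids, 1)
          if (claim_pair(pre, post)) add_edges(pre, post, 15L, "GNG")
        }
      }
    }
  }

  ## --- feedback / lateral edges (synapse counts capped in 5..9) --------
  sample_pairs <- function(pre_pool, post_pool, rate, type, layer, same_cell_ok = FALSE) {
    n_edges <- rpois(1, rate * length(pre_pool))
    if (n_edges == 0 || length(pre_pool) == 0 || length(post_pool) == 0) return()
    for (i in seq_len(n_edges)) {
      pre <- sample(pre_pool, 1)
      post_opts <- if (same_cell_ok) post_pool else setdiff(post_pool, pre)
      if (length(post_opts) == 0) next
      post <- sample(post_opts, 1)
      if (!claim_pair(pre, post)) next
      syn <- sample(5:9, 1)
      p_mod <- if (pre %in% u2$neuron_id) u2$modality[match(pre, u2$neuron_id)]
               else u3$modality[match(pre, u3$neuron_id)]
      npil <- draw_neuropil(1, spec$sez_fraction[[layer]][p_mod],
                            spec$contra_fraction[[layer]][p_mod])
      add_edges(pre, post, syn, npil)
      truth_feedback[[length(truth_feedback) + 1L]] <<-
        tibble(type = type, pre_id = pre, post_id = post, syn_count = syn)
    }
  }
  all_2n <- unique(m2$neuron_id)
  all_3n <- unique(m3$neuron_id)
  sample_pairs(all_2n, grn$neuron_id, spec$p_feedback[["n2_grn"]], "2N->GRN", "2N")
  sample_pairs(all_2n, all_2n, spec$p_feedback[["n2_n2"]], "2N->2N", "2N")
  sample_pairs(all_3n, all_2n, spec$p_feedback[["n3_n2"]], "3N->2N", "3N")
  sample_pairs(all_3n, grn$neuron_id, spec$p_feedback[["n3_grn"]], "3N->GRN", "3N")

  ## --- background inputs ------------------------------------------------
  if (length(bg_ids)) {
    bg_inputs <- function(targets, lambda) {
      for (nid in targets) {
        nb <- rpois(1, lambda)
        if (nb == 0) next
        pres <- sample(bg_ids, min(nb, length(bg_ids)))
        syn <- 5L + rgeom(length(pres), 0.2)
        side <- neurons$side[match(pres, neurons$neuron_id)]
        npil <- ifelse(runif(length(pres)) < 0.5, "GNG",
                       paste0(sample(c("SLP", "SMP", "AVLP"), length(pres),
                                     replace = TRUE),
                              ifelse(side == "right", "_R", "_L")))
        for (j in seq_along(pres)) add_edges(pres[[j]], nid, syn[[j]], npil[[j]])
      }
    }
    bg_inputs(all_2n, spec$bg_in_lambda[["2N"]])
    bg_inputs(all_3n, spec$bg_in_lambda[["3N"]])
  }

  ## --- assemble ---------------------------------------------------------
  edge_tbl <- bind_rows(edges)
  graph <- connectome(neurons, edge_tbl)
  seeds <- seed_sets(tibble(modality = grn$modality, neuron_id = grn$neuron_id))

  overlap_table <- function(members) {
    pairs <- utils::combn(mods, 2, simplify = FALSE)
    purrr::map(pairs, function(p) {
      shared <- length(intersect(members$neuron_id[members$modality == p[[1]]],
                                 members$neuron_id[members$modality == p[[2]]]))
      tibble(pair = canonical_pair(p[[1]], p[[2]]), n_shared = shared)
    }) |> bind_rows()
  }

  truth <- list(
    layers = bind_rows(
      tibble(modality = grn$modality, layer = "GRN", neuron_id = grn$neuron_id),
      tibble(modality = m2$modality, layer = "2N", neuron_id = m2$neuron_id),
      tibble(modality = m3$modality, layer = "3N", neuron_id = m3$neuron_id)
    ),
    input_2n = input_2n,
    input_3n = input_3n,
    weak_2n = weak_2n,
    overlap_2n = overlap_table(m2),
    overlap_3n = overlap_table(m3),
    feedback = if (length(truth_feedback)) bind_rows(truth_feedback) else
      tibble(type = character(), pre_id = character(), post_id = character(),
             syn_count = integer()),
    nt_neuron = tibble(neuron_id = names(nt_of), nt = unname(nt_of)),
    rng_seed = spec$rng_seed,
    spec = spec
  )
  list(graph = graph, seeds = seeds, truth = truth)
}

#' Write a synthetic connectome in the loadable CSV dialect
#'
#' Emits `neurons.csv`, `edges.csv` and `seeds.csv` (modality column format)
#' under `dir`, plus `ground_truth.json` when `truth` is supplied, so that
#' [load_connectome()] and [load_seed_sets()] round-trip the generated data
#' with zero loss.
#'
#' @param graph A `connectome`.
#' @param seeds A `seed_sets` tibble.
#' @param dir Output directory.
#' @param truth Optional ground-truth list from [generate_connectome()].
#' @return Invisibly, the paths written.
#' @export
write_dialect <- function(graph, seeds, dir, truth = NULL) {
  paths <- write_connectome(graph, dir)
  seed_path <- file.path(dir, "seeds.csv")
  readr::write_csv(as_tibble(seeds), seed_path, progress = FALSE)
  paths <- c(paths, seeds = seed_path)
  if (!is.null(truth)) {
    gt_path <- file.path(dir, "ground_truth.json")
    gt <- truth
    gt$spec <- NULL
    jsonlite::write_json(gt, gt_path, dataframe = "columns", auto_unbox = TRUE)
    paths <- c(paths, ground_truth = gt_path)
  }
  invisible(paths)
}
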