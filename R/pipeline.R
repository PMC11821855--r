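# pipeline: end-to-end orchestration with a single config, writing per-stage
# CSVs, a hashed manifest, and a panel-keyed report.

#' Pipeline configuration
#'
#' Bundles every tunable of the analysis: file paths (or a synthetic spec),
#' tracing thresholds, SEZ definition, ipsilateral side, NT sign map, top-k
#' region settings, simulation parameters and the RNG seed.
#'
#' @param neuron_path,edge_path,seed_path Input CSVs (ignored when
#'   `synthetic` is supplied).
#' @param synthetic Optional [synth_spec()]; when given, the pipeline runs
#'   on a generated connectome instead of files.
#' @param threshold_2n,threshold_3n_hop1,threshold_3n_hop2 Tracing thresholds.
#' @param sez SEZ neuropil base codes.
#' @param ipsi_side `"left"` or `"right"`.
#' @param sign_map NT sign map for E/I splits.
#' @param topk_2n,topk_3n Regions kept in output profiles.
#' @param lif [lif_params()] used for simulations.
#' @param sim_rates Stimulation rates for the intensity sweep (Hz).
#' @param run_simulation Run the LIF stage (the slowest stage).
#' @param rng_seed Seed fanned out to the synthetic generator and simulations.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(neuron_path = NULL, edge_path = NULL,
                            seed_path = NULL, synthetic = NULL,
                            threshold_2n = 5, threshold_3n_hop1 = 10,
                            threshold_3n_hop2 = 10,
                            sez = sez_neuropils(), ipsi_side = "left",
                            sign_map = nt_sign_map(),
                            topk_2n = 6, topk_3n = 12,
                            lif = lif_params(),
                            sim_rates = c(25, 50, 100, 150, 200),
                            run_simulation = TRUE,
                            rng_seed = 1L) {
  if (is.null(synthetic) && (is.null(neuron_path) || is.null(edge_path) ||
                             is.null(seed_path))) {
    stop_tastetrace("either file paths or a synthetic spec must be supplied",
                    "tastetrace_validation_error")
  }
  structure(list(neuron_path = neuron_path, edge_path = edge_path,
                 seed_path = seed_path, synthetic = synthetic,
                 threshold_2n = threshold_2n,
                 threshold_3n_hop1 = threshold_3n_hop1,
                 threshold_3n_hop2 = threshold_3n_hop2,
                 sez = sez, ipsi_side = ipsi_side, sign_map = sign_map,
                 topk_2n = topk_2n, topk_3n = topk_3n, lif = lif,
                 sim_rates = sim_rates, run_simulation = run_simulation,
                 rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop_tastetrace(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
                    "tastetrace_stage_error")
  })
}

#' Run the full taste-circuit analysis
#'
#' Executes load/generate, tracing, circuit statistics, anatomy, input
#' census and (optionally) LIF simulation, writing each stage's tables as
#' CSV under `out_dir` together with a manifest listing every output file
#' with its MD5 hash, the seed, and a content hash of the configuration.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a named list with every stage result plus
#'   `manifest`.
#' @export
run_taste_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()

  run_stage("io", {
    if (!is.null(config$synthetic)) {
      gen <- generate_connectome(config$synthetic)
      res$graph <- gen$graph
      res$seeds <- gen$seeds
      res$truth <- gen$truth
    } else {
      res$graph <- load_connectome(config$neuron_path, config$edge_path)
      res$seeds <- load_seed_sets(config$seed_path, res$graph)
    }
  })

  run_stage("trace", {
    res$layer2 <- trace_second_order(res$graph, res$seeds, config$threshold_2n)
    res$layer3 <- trace_third_order(res$graph, res$seeds, res$layer2,
                                    config$threshold_3n_hop1,
                                    config$threshold_3n_hop2)
    safe_overlap <- function(lm) {
      if (dplyr::n_distinct(as_tibble(lm)$modality) < 2) {
        tibble(modalities = character(), degree = integer(),
               n_shared = integer())
      } else {
        modality_overlap(lm)
      }
    }
    res$overlap_2n <- safe_overlap(res$layer2)
    res$overlap_3n <- safe_overlap(res$layer3)
    res$grn_matrix <- grn_grn_matrix(res$graph, res$seeds)
    res$strength_2n <- input_strength_distribution(res$layer2)
    res$strength_3n <- input_strength_distribution(res$layer3)
  })

  mods <- intersect(taste_modalities(), unique(res$seeds$modality))
  run_stage("stats", {
    res$feedback_2n_grn <- feedback_matrix(res$graph, res$layer2, res$seeds,
                                           config$sign_map)
    res$lateral_2n_2n <- feedback_matrix(res$graph, res$layer2, res$layer2,
                                         config$sign_map)
    res$feedback_3n_2n <- feedback_matrix(res$graph, res$layer3, res$layer2,
                                          config$sign_map)
    res$feedback_3n_grn <- feedback_matrix(res$graph, res$layer3, res$seeds,
                                           config$sign_map)
    mods3 <- intersect(mods, unique(as_tibble(res$layer3)$modality))
    res$net_excitation <- purrr::map(mods3, function(m) {
      net_excitation(res$graph, res$layer2, res$layer3, m,
                     config$threshold_3n_hop1, config$threshold_3n_hop2,
                     config$sign_map)
    }) |> bind_rows() |>
      bind_rows(tibble(modality = character(), neuron_id = character(),
                       n_inputs = integer(), total_syn = integer(),
                       e_syn = integer(), i_syn = integer(),
                       other_syn = integer(), net = integer()))
    res$convergence <- purrr::map(mods3, function(m) {
      glance(convergence_test(res$graph, res$layer2, res$layer3, m, k = 2,
                              config$threshold_3n_hop1,
                              config$threshold_3n_hop2,
                              sign_map = config$sign_map))
    }) |> bind_rows() |>
      bind_rows(tibble(modality = character(), k = numeric(), n = integer(),
                       p_exc = numeric(), chi2 = numeric(), df = integer(),
                       p_value = numeric(), flagged = logical()))
    res$motifs <- sign_motif_census(res$graph, res$layer2, res$layer3, mods3,
                                    config$threshold_3n_hop1,
                                    config$threshold_3n_hop2, config$sign_map)
  })

  run_stage("anatomy", {
    res$local_projection_2n <- classify_local_projection(
      res$graph, unique(as_tibble(res$layer2)$neuron_id), config$sez,
      config$threshold_2n)
    res$partition_2n <- partition_output_synapses(res$graph, res$layer2,
                                                  config$sez, config$ipsi_side,
                                                  config$sign_map)
    res$partition_3n <- partition_output_synapses(res$graph, res$layer3,
                                                  config$sez, config$ipsi_side,
                                                  config$sign_map)
    res$regions_2n <- region_profile_topk(res$partition_2n, config$topk_2n)
    res$regions_3n <- region_profile_topk(res$partition_3n, config$topk_3n)
    res$superclass_2n <- census(res$graph, res$layer2, "superclass")
    res$superclass_3n <- census(res$graph, res$layer3, "superclass")
    res$class_2n <- census(res$graph, res$layer2, "class_label")
    res$class_3n <- census(res$graph, res$layer3, "class_label")
  })

  run_stage("census", {
    res$input_fractions_2n <- input_fractions(res$graph, res$seeds, res$layer2,
                                              res$layer3, "2N")
    res$input_fractions_3n <- input_fractions(res$graph, res$seeds, res$layer2,
                                              res$layer3, "3N")
    res$input_partners_2n <- input_partner_census(res$graph, res$seeds,
                                                  res$layer2, res$layer3, "2N",
                                                  config$threshold_2n)
    res$input_partners_3n <- input_partner_census(res$graph, res$seeds,
                                                  res$layer2, res$layer3, "3N",
                                                  config$threshold_2n)
  })

  if (isTRUE(config$run_simulation)) {
    run_stage("simulate", {
      network <- build_lif_network(res$graph, w_unit = config$lif$w_unit)
      res$sweep <- purrr::imap(setNames(mods, mods), function(m, nm) {
        intensity_sweep(network, res$seeds, res$layer2, res$layer3, m,
                        rates = config$sim_rates, params = config$lif,
                        rng_seed = config$rng_seed + 100L * match(m, mods))
      }) |> bind_rows()
    })
  }

  # --- write outputs ----------------------------------------------------
  writeable <- list(
    layer2 = as_tibble(res$layer2), layer3 = as_tibble(res$layer3),
    overlap_2n = res$overlap_2n, overlap_3n = res$overlap_3n,
    grn_matrix = res$grn_matrix,
    strength_2n = as_tibble(res$strength_2n),
    strength_3n = as_tibble(res$strength_3n),
    feedback_2n_grn = as_tibble(res$feedback_2n_grn),
    lateral_2n_2n = as_tibble(res$lateral_2n_2n),
    feedback_3n_2n = as_tibble(res$feedback_3n_2n),
    feedback_3n_grn = as_tibble(res$feedback_3n_grn),
    net_excitation = res$net_excitation, convergence = res$convergence,
    motifs = as_tibble(res$motifs),
    local_projection_2n = res$local_projection_2n,
    partition_2n = res$partition_2n$summary,
    partition_3n = res$partition_3n$summary,
    regions_2n = res$regions_2n, regions_3n = res$regions_3n,
    superclass_2n = res$superclass_2n, superclass_3n = res$superclass_3n,
    class_2n = res$class_2n, class_3n = res$class_3n,
    input_fractions_2n = as_tibble(res$input_fractions_2n),
    input_fractions_3n = as_tibble(res$input_fractions_3n),
    input_partners_2n = res$input_partners_2n,
    input_partners_3n = res$input_partners_3n
  )
  if (!is.null(res$sweep)) writeable$sweep <- as_tibble(res$sweep)
  paths <- purrr::imap_chr(writeable, function(tbl, nm) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    readr::write_csv(tbl, p, progress = FALSE)
    p
  })

  config_for_hash <- config
  config_for_hash$sign_map <- as.list(config$sign_map)
  config_json <- jsonlite::toJSON(
    config_for_hash[!vapply(config_for_hash, is.null, logical(1))],
    auto_unbox = TRUE, force = TRUE, digits = NA)
  config_path <- file.path(out_dir, "config.json")
  writeLines(config_json, config_path)

  manifest <- tibble(
    file = basename(c(paths, config_path)),
    md5 = unname(tools::md5sum(c(paths, config_path))),
    bytes = file.size(c(paths, config_path))
  )
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"), progress = FALSE)
  run_info <- list(rng_seed = config$rng_seed,
                   config_md5 = unname(tools::md5sum(config_path)),
                   n_neurons = nrow(res$graph$neurons),
                   n_edges = nrow(res$graph$edges),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(run_info, file.path(out_dir, "run_info.json"),
                       auto_unbox = TRUE)
  res$manifest <- manifest
  invisible(res)
}

#' Summarize pipeline outputs as panel-keyed tables
#'
#' Collects the stage results into a named list whose keys mirror the
#' figure panels of the analysis (e.g. `fig1e_overlap`, `fig7b_activation`).
#' Missing stages produce a partial report with a warning.
#'
#' @param results The list returned by [run_taste_pipeline()].
#' @return Named list of tibbles.
#' @export
pipeline_report <- function(results) {
  panels <- list(
    fig1c_grn_matrix = results$grn_matrix,
    fig1e_overlap = results$overlap_2n,
    fig1f_strength = if (!is.null(results$strength_2n)) as_tibble(results$strength_2n),
    fig2ab_feedback_2n_grn = if (!is.null(results$feedback_2n_grn)) as_tibble(results$feedback_2n_grn),
    fig2cd_lateral_2n_2n = if (!is.null(results$lateral_2n_2n)) as_tibble(results$lateral_2n_2n),
    fig2e_superclass = results$superclass_2n,
    fig2g_partition = if (!is.null(results$partition_2n)) results$partition_2n$summary,
    fig2k_regions = results$regions_2n,
    fig3c_overlap_3n = results$overlap_3n,
    fig4_convergence = results$convergence,
    fig4c_net_excitation = results$net_excitation,
    fig5ab_feedback_3n_2n = if (!is.null(results$feedback_3n_2n)) as_tibble(results$feedback_3n_2n),
    fig5h_partition_3n = if (!is.null(results$partition_3n)) results$partition_3n$summary,
    fig5k_motifs = if (!is.null(results$motifs)) as_tibble(results$motifs),
    fig5l_regions_3n = results$regions_3n,
    fig6b_input_fractions = if (!is.null(results$input_fractions_2n))
      input_fraction_medians(results$input_fractions_2n),
    fig6de_input_partners = results$input_partners_2n,
    fig7b_activation = if (!is.null(results$sweep)) as_tibble(results$sweep)
  )
  missing <- names(panels)[vapply(panels, is.null, logical(1))]
  if (length(missing) > 0) {
    warn(sprintf("partial report; missing panels: %s",
                 paste(missing, collapse = ", ")))
  }
  panels[!vapply(panels, is.null, logical(1))]
}
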