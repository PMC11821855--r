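# Layer identification rules, thresholds and exclusions.

grn_seeds <- function(...) {
  df <- tibble::tibble(modality = purrr::map_chr(list(...), 1),
                       neuron_id = purrr::map_chr(list(...), 2))
  seed_sets(df)
}

test_that("the 2N threshold gates single connections and excludes GRNs", {
  g <- toy_graph(toy_edges(
    list("G1", "X", "GNG", "ACH", "4"),   # below threshold
    list("G1", "Y", "GNG", "ACH", "5"),   # at threshold
    list("G1", "G2", "GNG", "ACH", "50"), # GRN of another modality: excluded
    list("G2", "Z", "GNG", "ACH", "7")
  ))
  seeds <- grn_seeds(c("sugar", "G1"), c("water", "G2"))
  l2 <- trace_second_order(g, seeds)
  expect_setequal(l2$neuron_id[l2$modality == "sugar"], "Y")
  expect_setequal(l2$neuron_id[l2$modality == "water"], "Z")
  expect_error(trace_second_order(g, seeds, threshold = 0),
               class = "tastetrace_validation_error")
})

test_that("pair-total vs per-neuropil threshold modes differ on split connections", {
  g <- toy_graph(toy_edges(
    list("G1", "X", "GNG", "ACH", "3"),
    list("G1", "X", "SAD", "ACH", "3")
  ))
  seeds <- grn_seeds(c("sugar", "G1"))
  expect_equal(trace_second_order(g, seeds, mode = "pair_total")$neuron_id, "X")
  expect_equal(nrow(trace_second_order(g, seeds, mode = "per_neuropil")), 0L)
})

test_that("the hop-1 gate blocks expansion of weakly connected 2Ns", {
  g <- toy_graph(toy_edges(
    list("G1", "A", "GNG", "ACH", "9"),    # 2N below hop-1 gate
    list("G1", "B", "GNG", "ACH", "12"),   # expanded 2N
    list("A", "T1", "GNG", "ACH", "40"),   # blocked by gate
    list("B", "T2", "GNG", "ACH", "10"),   # 3N
    list("B", "T3", "GNG", "ACH", "9")     # below hop-2 threshold
  ))
  seeds <- grn_seeds(c("sugar", "G1"))
  l2 <- trace_second_order(g, seeds)
  l3 <- trace_third_order(g, seeds, l2)
  expect_equal(l3$neuron_id, "T2")
  expect_equal(l3$total_syn, 10L)
})

test_that("3Ns exclude same-modality 2Ns and all GRNs but allow cross-modality 2Ns", {
  g <- toy_graph(toy_edges(
    list("G1", "A", "GNG", "ACH", "20"),
    list("G2", "C", "GNG", "ACH", "20"),  # C is a water 2N
    list("A", "C", "GNG", "ACH", "15"),   # C becomes a sugar 3N
    list("A", "G2", "GNG", "ACH", "15"),  # GRN: never a 3N
    list("G1", "B", "GNG", "ACH", "20"),
    list("A", "B", "GNG", "ACH", "15")    # B is a sugar 2N: not a sugar 3N
  ))
  seeds <- grn_seeds(c("sugar", "G1"), c("water", "G2"))
  l2 <- trace_second_order(g, seeds)
  l3 <- trace_third_order(g, seeds, l2)
  expect_setequal(l3$neuron_id[l3$modality == "sugar"], "C")
})

test_that("tracing equals the brute-force enumerator on planted circuits", {
  gen <- generate_connectome(small_spec(seed = 13))
  l2 <- trace_second_order(gen$graph, gen$seeds)
  o2 <- oracle_trace_2n(gen$graph, gen$seeds)
  expect_same_layer(l2, o2)
  l3 <- trace_third_order(gen$graph, gen$seeds, l2)
  o3 <- oracle_trace_3n(gen$graph, gen$seeds, o2)
  expect_same_layer(l3, o3)
})

test_that("raising thresholds never adds layer members", {
  gen <- generate_connectome(small_spec(seed = 17))
  l2_lo <- trace_second_order(gen$graph, gen$seeds, threshold = 5)
  for (thr in c(8, 12, 20)) {
    l2_hi <- trace_second_order(gen$graph, gen$seeds, threshold = thr)
    expect_true(all(paste(l2_hi$modality, l2_hi$neuron_id) %in%
                      paste(l2_lo$modality, l2_lo$neuron_id)))
  }
  l3_lo <- trace_third_order(gen$graph, gen$seeds, l2_lo)
  l3_hi <- trace_third_order(gen$graph, gen$seeds, l2_lo,
                             hop1_total_threshold = 15, hop2_threshold = 15)
  expect_true(all(paste(l3_hi$modality, l3_hi$neuron_id) %in%
                    paste(l3_lo$modality, l3_lo$neuron_id)))
})

test_that("layer maps respect the exclusion invariants", {
  gen <- generate_connectome(small_spec(seed = 19))
  l2 <- trace_second_order(gen$graph, gen$seeds)
  l3 <- trace_third_order(gen$graph, gen$seeds, l2)
  expect_length(intersect(l2$neuron_id, gen$seeds$neuron_id), 0)
  expect_length(intersect(l3$neuron_id, gen$seeds$neuron_id), 0)
  for (m in unique(l3$modality)) {
    expect_length(intersect(l3$neuron_id[l3$modality == m],
                            l2$neuron_id[l2$modality == m]), 0)
  }
})

test_that("overlap tables are inclusion-exclusion consistent", {
  gen <- generate_connectome(small_spec(seed = 23))
  l3 <- trace_third_order(gen$graph, gen$seeds,
                          trace_second_order(gen$graph, gen$seeds))
  ov <- modality_overlap(l3)
  mods <- unique(l3$modality)
  sizes <- table(l3$modality)
  # |union| from inclusion-exclusion must equal the distinct neuron count
  get <- function(mm) ov$n_shared[ov$modalities == paste(sort2(mm), collapse = ":")]
  sort2 <- function(mm) mm[order(match(mm, taste_modalities()))]
  total <- sum(sizes)
  for (k in 2:length(mods)) {
    combos <- combn(mods, k, simplify = FALSE)
    sgn <- (-1)^(k - 1)
    total <- total + sgn * sum(vapply(combos, function(cc) get(cc), numeric(1)))
  }
  expect_equal(total, length(unique(l3$neuron_id)))
  nm <- neuron_modalities(l3)
  expect_equal(sum(nm$multimodal),
               sum(table(l3$neuron_id) > 1))
})

test_that("GRN-GRN matrix equals a hand sum and zero-fills", {
  g <- toy_graph(toy_edges(
    list("G1", "G2", "GNG", "ACH", "3"),
    list("G1", "G2", "SAD", "ACH", "2"),
    list("G2", "G3", "GNG", "ACH", "7"),
    list("G1", "X", "GNG", "ACH", "50")   # non-GRN target ignored
  ))
  seeds <- grn_seeds(c("sugar", "G1"), c("sugar", "G2"), c("water", "G3"))
  m <- grn_grn_matrix(g, seeds)
  expect_equal(m$synapses[m$source_modality == "sugar" &
                            m$target_modality == "sugar"], 5L)
  expect_equal(m$synapses[m$source_modality == "sugar" &
                            m$target_modality == "water"], 7L)
  expect_equal(m$synapses[m$source_modality == "water" &
                            m$target_modality == "sugar"], 0L)
  expect_equal(m$synapses_per_grn[m$source_modality == "sugar" &
                                    m$target_modality == "sugar"], 2.5)
})

test_that("input strength summaries report totals, cells, and medians", {
  lm2 <- fake_layer_map(tibble::tibble(
    modality = "sugar", neuron_id = c("a", "b", "c"),
    n_inputs = c(2L, 1L, 1L), total_syn = c(16L, 7L, 7L)), "2N")
  d <- input_strength_distribution(lm2)
  expect_equal(d$median_total_syn, 7)
  expect_equal(d$median_n_inputs, 1)
  empty <- fake_layer_map(tibble::tibble(modality = character(),
                                         neuron_id = character(),
                                         n_inputs = integer(),
                                         total_syn = integer()), "2N")
  expect_warning(input_strength_distribution(empty), regexp = "empty")
})

test_that("fan-in regression recovers exact fits and rejects degenerate input", {
  lm2 <- fake_layer_map(tibble::tibble(
    modality = "sugar", neuron_id = c("a", "b", "c"),
    n_inputs = c(1L, 2L, 3L), total_syn = c(2L, 8L, 18L)), "2N")
  fit <- fanin_strength_regression(lm2)
  gl <- suppressWarnings(glance(fit))  # perfect fit warns in summary.lm
  expect_equal(gl$slope, 2, tolerance = 1e-12)
  expect_equal(gl$r_squared, 1, tolerance = 1e-12)
  td <- suppressWarnings(tidy(fit))
  expect_true(all(c("(Intercept)", "n_inputs") %in% td$term))

  degenerate <- fake_layer_map(tibble::tibble(
    modality = "sugar", neuron_id = c("a", "b", "c"),
    n_inputs = c(2L, 2L, 2L), total_syn = c(10L, 12L, 14L)), "2N")
  expect_error(fanin_strength_regression(degenerate),
               class = "tastetrace_undefined_fit_error")
})
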