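# E/I matrices, convergence null, net excitation, motifs, correlations.

test_that("feedback matrix splits by edge-level sign and conserves totals", {
  g <- toy_graph(toy_edges(
    list("N1", "G1", "GNG", "ACH", "6"),
    list("N1", "G1", "SAD", "GABA", "4"),
    list("N2", "G2", "GNG", "DA", "3")
  ))
  src <- tibble::tibble(modality = c("sugar", "water"), neuron_id = c("N1", "N2"))
  tgt <- tibble::tibble(modality = c("sugar", "water"), neuron_id = c("G1", "G2"))
  fm <- feedback_matrix(g, src, tgt)
  pick <- function(s, t, sg) fm$synapses[fm$source_modality == s &
                                           fm$target_modality == t & fm$sign == sg]
  expect_equal(pick("sugar", "sugar", "excitatory"), 6L)
  expect_equal(pick("sugar", "sugar", "inhibitory"), 4L)
  expect_equal(pick("water", "water", "other"), 3L)
  expect_equal(pick("sugar", "water", "excitatory"), 0L)
  # conservation: E + I + other equals raw synapse total between the sets
  raw <- sum(g$edges$syn_count[g$edges$pre_id %in% src$neuron_id &
                                 g$edges$post_id %in% tgt$neuron_id])
  expect_equal(sum(fm$synapses), raw)
})

test_that("an all-GABA circuit has an all-zero excitatory matrix", {
  g <- toy_graph(toy_edges(
    list("N1", "G1", "GNG", "GABA", "8"),
    list("N2", "G1", "GNG", "GABA", "5")
  ))
  sets <- tibble::tibble(modality = "sugar", neuron_id = c("N1", "N2"))
  tgt <- tibble::tibble(modality = "sugar", neuron_id = "G1")
  fm <- feedback_matrix(g, sets, tgt)
  expect_equal(sum(fm$synapses[fm$sign == "excitatory"]), 0L)
  expect_equal(sum(fm$synapses[fm$sign == "inhibitory"]), 13L)
})

test_that("feedback matrix equals a brute-force triple loop on a planted circuit", {
  gen <- generate_connectome(small_spec(seed = 31))
  l2 <- trace_second_order(gen$graph, gen$seeds)
  fm <- feedback_matrix(gen$graph, l2, gen$seeds)
  edges <- as.data.frame(gen$graph$edges)
  l2df <- as.data.frame(tibble::as_tibble(l2))
  seeds <- as.data.frame(tibble::as_tibble(gen$seeds))
  for (sm in unique(l2df$modality)) {
    for (tm in unique(seeds$modality)) {
      for (sg in c("excitatory", "inhibitory", "other")) {
        want <- 0L
        for (i in seq_len(nrow(edges))) {
          if (edges$pre_id[i] %in% l2df$neuron_id[l2df$modality == sm] &&
              edges$post_id[i] %in% seeds$neuron_id[seeds$modality == tm] &&
              nt_sign(edges$nt_edge[i]) == sg) {
            want <- want + edges$syn_count[i]
          }
        }
        got <- fm$synapses[fm$source_modality == sm &
                             fm$target_modality == tm & fm$sign == sg]
        expect_equal(got, want)
      }
    }
  }
})

test_that("net excitation is the signed difference of qualifying input synapses", {
  g <- toy_graph(
    toy_edges(
      list("G1", "E2", "GNG", "ACH", "30"),
      list("G1", "I2", "GNG", "ACH", "30"),
      list("G1", "B2", "GNG", "ACH", "30"),
      list("E2", "T1", "GNG", "ACH", "30"),
      list("I2", "T1", "GNG", "GABA", "10"),
      list("E2", "T2", "GNG", "ACH", "20"),
      list("I2", "T2", "GNG", "GABA", "20"),
      list("B2", "T2", "GNG", "ACH", "9")   # sub-threshold: ignored
    ),
    nt_neuron = c(E2 = "ACH", I2 = "GABA", B2 = "ACH")
  )
  seeds <- seed_sets(tibble::tibble(modality = "sugar", neuron_id = "G1"))
  l2 <- trace_second_order(g, seeds)
  l3 <- trace_third_order(g, seeds, l2)
  ne <- net_excitation(g, l2, l3, "sugar")
  expect_equal(ne$net[ne$neuron_id == "T1"], 20L)   # E 30, I 10
  expect_equal(ne$net[ne$neuron_id == "T2"], 0L)    # E 20, I 20
  expect_equal(ne$n_inputs[ne$neuron_id == "T2"], 2L)
  expect_error(net_excitation(g, l2, l3, "bitter"),
               class = "tastetrace_validation_error")
})

test_that("net excitation distribution matches recomputation from planted signs", {
  gen <- generate_connectome(small_spec(seed = 37))
  l2 <- trace_second_order(gen$graph, gen$seeds)
  l3 <- trace_third_order(gen$graph, gen$seeds, l2)
  ne <- net_excitation(gen$graph, l2, l3, "sugar")
  nt <- setNames(gen$truth$nt_neuron$nt, gen$truth$nt_neuron$neuron_id)
  pt <- oracle_pair_totals(gen$graph$edges)
  l2df <- tibble::as_tibble(l2)
  expanded <- l2df$neuron_id[l2df$modality == "sugar" & l2df$total_syn >= 10]
  for (i in seq_len(nrow(ne))) {
    rows <- pt[pt$post_id == ne$neuron_id[i] & pt$pre_id %in% expanded &
                 pt$syn_count >= 10, ]
    sgn <- nt_sign(unname(nt[rows$pre_id]))
    expect_equal(ne$e_syn[i], sum(rows$syn_count[sgn == "excitatory"]))
    expect_equal(ne$i_syn[i], sum(rows$syn_count[sgn == "inhibitory"]))
  }
})

test_that("expected convergence proportions follow the binomial null", {
  e <- convergence_expected(0.3, 2)
  expect_equal(e$expected, c(0.09, 0.49, 0.42), tolerance = 1e-12)
  e2 <- convergence_expected(1, 3)
  expect_equal(e2$expected, c(1, 0, 0))
  # enumeration oracle at p = 0.5, k = 3: all 8 sign sequences equally likely
  seqs <- expand.grid(rep(list(c("E", "I")), 3))
  all_e <- mean(apply(seqs, 1, function(x) all(x == "E")))
  all_i <- mean(apply(seqs, 1, function(x) all(x == "I")))
  e3 <- convergence_expected(0.5, 3)
  expect_equal(e3$expected, c(all_e, all_i, 1 - all_e - all_i), tolerance = 1e-12)
  # proportions always sum to 1
  for (p in seq(0, 1, by = 0.1)) {
    for (k in 2:3) expect_equal(sum(convergence_expected(p, k)$expected), 1)
  }
  expect_error(convergence_expected(0.5, 4), class = "tastetrace_validation_error")
  expect_error(convergence_expected(1.2, 2), class = "tastetrace_validation_error")
})

test_that("the convergence chi-squared matches textbook implementations", {
  gen <- generate_connectome(medium_spec(seed = 41))
  l2 <- trace_second_order(gen$graph, gen$seeds)
  l3 <- trace_third_order(gen$graph, gen$seeds, l2)
  ct <- convergence_test(gen$graph, l2, l3, "sugar", k = 2)
  expect_gte(ct$n, 10)
  exp_prop <- convergence_expected(ct$p_exc, 2)$expected
  want <- oracle_chi2(ct$observed, exp_prop)
  expect_equal(ct$chi2, want$stat, tolerance = 1e-10)
  expect_equal(ct$p_value, want$p, tolerance = 1e-10)
  # and against stats::chisq.test when every expected count is positive
  if (all(exp_prop > 0)) {
    ref <- suppressWarnings(stats::chisq.test(ct$observed, p = exp_prop))
    expect_equal(ct$chi2, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ct$p_value, unname(ref$p.value), tolerance = 1e-10)
  }
  expect_equal(sum(ct$observed), ct$n)
})

test_that("an all-excitatory circuit yields zero chi-squared", {
  g <- toy_graph(toy_edges(
    list("G1", "A", "GNG", "ACH", "20"),
    list("G1", "B", "GNG", "ACH", "20"),
    list("A", "T1", "GNG", "ACH", "15"),
    list("B", "T1", "GNG", "ACH", "15"),
    list("A", "T2", "GNG", "ACH", "15"),
    list("B", "T2", "GNG", "ACH", "15")
  ))
  seeds <- seed_sets(tibble::tibble(modality = "sugar", neuron_id = "G1"))
  l2 <- trace_second_order(g, seeds)
  l3 <- trace_third_order(g, seeds, l2)
  ct <- convergence_test(g, l2, l3, "sugar", k = 2)
  expect_equal(ct$p_exc, 1)
  expect_equal(ct$chi2, 0)
  expect_true(ct$flagged)  # n = 2 < 10
})

test_that("the chi-squared test is not anti-conservative under the null", {
  # independent random input signs: the rejection rate at alpha = 0.05 must
  # not exceed the nominal level by much (estimating p_exc from the data
  # makes the test conservative)
  set.seed(99)
  n_rep <- 300
  rejections <- 0
  for (r in seq_len(n_rep)) {
    n3 <- 40
    p <- 0.4
    n2 <- 12
    nt2 <- ifelse(runif(n2) < p, "ACH", "GABA")
    names(nt2) <- paste0("N", seq_len(n2))
    rows <- list(list("G1", "dummy", "GNG", "ACH", "10"))
    for (j in seq_len(n2)) {
      rows[[length(rows) + 1L]] <- list("G1", names(nt2)[j], "GNG", "ACH", "20")
    }
    for (t in seq_len(n3)) {
      pair <- sample(names(nt2), 2)
      for (pp in pair) {
        rows[[length(rows) + 1L]] <- list(pp, paste0("T", t), "GNG",
                                          ifelse(nt2[pp] == "ACH", "ACH", "GABA"),
                                          "12")
      }
    }
    g <- toy_graph(do.call(toy_edges, rows), nt_neuron = nt2)
    seeds <- seed_sets(tibble::tibble(modality = "sugar", neuron_id = "G1"))
    l2 <- trace_second_order(g, seeds)
    l3 <- trace_third_order(g, seeds, l2)
    ct <- convergence_test(g, l2, l3, "sugar", k = 2)
    if (!is.na(ct$p_value) && ct$p_value < 0.05) rejections <- rejections + 1
  }
  expect_lte(rejections / n_rep, 0.08)
})

test_that("cross-modality net excitation detects identical planted inputs", {
  rows <- list()
  for (m in c("G1", "G2")) rows[[length(rows) + 1L]] <- list(m, "dummy", "GNG", "ACH", "4")
  # shared 2Ns driven by both modalities; identical inputs onto shared 3Ns
  nts <- c(A = "ACH", B = "GABA", C = "ACH")
  for (n2 in names(nts)) {
    rows[[length(rows) + 1L]] <- list("G1", n2, "GNG", "ACH", "15")
    rows[[length(rows) + 1L]] <- list("G2", n2, "GNG", "ACH", "15")
  }
  set.seed(7)
  for (t in paste0("T", 1:6)) {
    for (n2 in names(nts)) {
      rows[[length(rows) + 1L]] <- list(n2, t, "GNG",
                                        ifelse(nts[n2] == "ACH", "ACH", "GABA"),
                                        as.character(sample(10:30, 1)))
    }
  }
  g <- toy_graph(do.call(toy_edges, rows), nt_neuron = nts)
  seeds <- seed_sets(tibble::tibble(modality = c("sugar", "water"),
                                    neuron_id = c("G1", "G2")))
  l2 <- trace_second_order(g, seeds)
  l3 <- trace_third_order(g, seeds, l2)
  x <- cross_modality_net_excitation(g, l2, l3, c("sugar", "water"))
  gl <- suppressWarnings(glance(x))  # perfect fit warns in summary.lm
  expect_equal(gl$r_squared, 1, tolerance = 1e-12)
  expect_equal(gl$slope, 1, tolerance = 1e-12)
  # closed-form OLS on the paired values
  d <- tidy(x)
  sxx <- sum((d$net_a - mean(d$net_a))^2)
  sxy <- sum((d$net_a - mean(d$net_a)) * (d$net_b - mean(d$net_b)))
  expect_equal(gl$slope, sxy / sxx, tolerance = 1e-12)
  expect_error(cross_modality_net_excitation(g, l2, l3, c("sugar", "bitter")),
               class = "tastetrace_validation_error")
})

test_that("sign motif census matches planted signs and flags exclusions", {
  g <- toy_graph(
    toy_edges(
      list("G1", "A", "GNG", "ACH", "20"),
      list("G1", "B", "GNG", "ACH", "20"),
      list("A", "TE", "GNG", "ACH", "12"),
      list("B", "TE", "GNG", "GABA", "12"),
      list("A", "TI", "GNG", "ACH", "12"),
      list("B", "TO", "GNG", "GABA", "12")
    ),
    nt_neuron = c(A = "ACH", B = "GABA", TE = "ACH", TI = "GABA", TO = "DA")
  )
  seeds <- seed_sets(tibble::tibble(modality = "sugar", neuron_id = "G1"))
  l2 <- trace_second_order(g, seeds)
  l3 <- trace_third_order(g, seeds, l2)
  mo <- sign_motif_census(g, l2, l3)
  pick <- function(i, t) mo$n_connections[mo$input_sign == i & mo$target_sign == t]
  expect_equal(pick("excitatory", "excitatory"), 1L)  # A -> TE
  expect_equal(pick("inhibitory", "excitatory"), 1L)  # B -> TE
  expect_equal(pick("excitatory", "inhibitory"), 1L)  # A -> TI
  expect_equal(pick("inhibitory", "inhibitory"), 0L)
  expect_equal(attr(mo, "n_excluded"), 1L)            # B -> TO (DA target)
  props <- motif_input_proportions(mo)
  expect_equal(props$prop_excitatory_inputs[props$target_sign == "excitatory"], 0.5)
})

test_that("an all-ACH planted circuit produces only the E->E motif", {
  gen <- generate_connectome(small_spec(
    seed = 43,
    ei_fraction = list("2N" = c(sugar = 1, water = 1, bitter = 1, ir94e = 1),
                       "3N" = c(sugar = 1, water = 1, bitter = 1, ir94e = 1))
  ))
  l2 <- trace_second_order(gen$graph, gen$seeds)
  l3 <- trace_third_order(gen$graph, gen$seeds, l2)
  mo <- sign_motif_census(gen$graph, l2, l3)
  other <- mo$n_connections[!(mo$input_sign == "excitatory" &
                                mo$target_sign == "excitatory")]
  expect_true(all(other == 0))
  expect_gt(sum(mo$n_connections), 0)
})
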