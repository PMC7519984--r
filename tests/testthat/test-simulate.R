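test_that("config validation enforces fractions, sizes and a mandatory seed", {
  expect_error(simulation_config(frac_de_mirnas = 1.2, seed = 1),
               class = "mirheat_config_error")
  expect_error(simulation_config(n_mirnas = 10, n_genes = 50),
               class = "mirheat_config_error")  # no seed
  cfg <- simulation_config(n_mirnas = 10, n_genes = 50, seed = 1)
  expect_s3_class(cfg, "mh_sim_config")
  expect_identical(cfg$timepoints, heat_timepoints())
  expect_equal(cfg$n_replicates, 2L)
})

test_that("the generator is deterministic in its seed and honours zero fractions", {
  cfg <- simulation_config(n_mirnas = 15, n_genes = 60, seed = 5)
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$matrix$flags, b$matrix$flags)
  expect_identical(a$truth$pairs, b$truth$pairs)

  cfg2 <- simulation_config(n_mirnas = 15, n_genes = 60,
                            frac_de_mirnas = 0, seed = 5)
  t2 <- simulate_expression(cfg2)$truth
  expect_equal(nrow(t2$de_mirnas), 0)
  expect_equal(nrow(t2$pairs), 0)

  # different seed, different data
  c3 <- simulate_expression(simulation_config(n_mirnas = 15, n_genes = 60,
                                              seed = 6))
  expect_false(identical(a$matrix$values, c3$matrix$values))
})

test_that("planted effects sit where the ground truth says", {
  cfg <- simulation_config(n_mirnas = 20, n_genes = 100, noise_sd = 0.05,
                           effect_profile = "step", seed = 9)
  sim <- simulate_expression(cfg)
  m <- sim$matrix; truth <- sim$truth
  tp <- as.character(m$samples$timepoint)
  for (i in seq_len(nrow(truth$de_genes))) {
    ent <- truth$de_genes$entity_id[i]
    diff <- mean(m$values[ent, tp == "2h"]) - mean(m$values[ent, tp == "0min"])
    expect_equal(diff, truth$de_genes$sign[i] * cfg$effect_size,
                 tolerance = 0.3)
  }
  # planted pairs have opposite signs by construction
  if (nrow(truth$pairs) > 0) {
    expect_true(all(truth$pairs$family_sign != truth$pairs$gene_sign))
  }
  # flags: absent calls only below the dropout threshold
  expect_true(all(m$values[m$flags == "A"] < cfg$dropout_threshold))
})

test_that("sequence simulation plants scorable sites and identifiable members", {
  cfg <- simulation_config(n_mirnas = 12, n_genes = 50,
                           frac_de_mirnas = 0.5, frac_de_genes = 0.4,
                           frac_anticorrelated_pairs = 0.6, seed = 13)
  truth <- simulate_expression(cfg)$truth
  seqs <- simulate_sequences(cfg, truth, n_decoys = 5)
  expect_identical(sort(names(seqs$mirnas)), sort(truth$families$mirna_id))
  expect_true(all(nchar(seqs$mirnas) == cfg$mirna_length))
  expect_true(all(nchar(seqs$transcripts) == cfg$transcript_length))
  # same seed reproduces sequences exactly
  seqs2 <- simulate_sequences(cfg, truth, n_decoys = 5)
  expect_identical(seqs, seqs2)
  # intended expectations are at or below the cutoff, decoys above
  expect_true(all(seqs$sites$intended_expectation <= 3))
  expect_true(all(seqs$decoys$intended_expectation >= 3.5))
})

test_that("site construction hits requested expectations or refuses", {
  set.seed(17)
  m <- rand_rna(21)
  for (e in c(0, 0.5, 1, 2, 3)) {
    s <- try(make_target_site(m, e), silent = TRUE)
    if (!inherits(s, "try-error")) {
      expect_equal(score_duplex(m, s), e)
    }
  }
  s_ti <- make_target_site(m, 2, "translation_inhibition")
  expect_equal(score_duplex(m, s_ti), 2)
  expect_error(make_target_site(m, 0.25), class = "mirheat_config_error")
  expect_error(make_target_site(m, 1, "translation_inhibition"),
               class = "mirheat_config_error")
})

test_that("PPI simulation separates planted modules from background by score", {
  cfg <- simulation_config(n_mirnas = 20, n_genes = 100,
                           frac_de_mirnas = 0.5, frac_de_genes = 0.5,
                           frac_anticorrelated_pairs = 0.8,
                           n_ppi_modules = 2, ppi_module_size = 4, seed = 21)
  truth <- simulate_expression(cfg)$truth
  ppi <- simulate_ppi(cfg, truth)
  expect_equal(nrow(ppi$modules), 8)
  expect_identical(ppi, simulate_ppi(cfg, truth))  # seeded

  strong <- dplyr::filter(ppi$edges, combined_score > 0.7)
  g <- igraph::graph_from_data_frame(strong[1:2], directed = FALSE)
  comp <- igraph::components(g)
  found <- split(names(comp$membership), comp$membership)
  planted <- split(ppi$modules$gene_id, ppi$modules$module)
  expect_equal(length(found), length(planted))
  for (mod in planted) {
    expect_true(any(vapply(found, function(f) setequal(f, mod), logical(1))))
  }

  # with no planted modules nothing survives the cutoff
  cfg0 <- simulation_config(n_mirnas = 20, n_genes = 100,
                            n_ppi_modules = 0, seed = 23)
  truth0 <- simulate_expression(cfg0)$truth
  ppi0 <- simulate_ppi(cfg0, truth0)
  expect_true(all(ppi0$edges$combined_score <= 0.7))
})

test_that("quantile normalization never flips a planted DE sign", {
  cfg <- simulation_config(n_mirnas = 30, n_genes = 270, seed = 27)
  sim <- simulate_expression(cfg)
  norm <- baseline_to_median(quantile_normalize(sim$matrix))
  tp <- as.character(norm$samples$timepoint)
  truth_de <- dplyr::bind_rows(
    dplyr::select(sim$truth$de_mirnas, entity_id, sign),
    sim$truth$de_genes)
  for (i in seq_len(nrow(truth_de))) {
    d <- mean(norm$values[truth_de$entity_id[i], tp == "2h"]) -
      mean(norm$values[truth_de$entity_id[i], tp == "0min"])
    expect_equal(sign(d), truth_de$sign[i])
  }
})
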