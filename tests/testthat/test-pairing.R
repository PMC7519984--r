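make_pairing_fixture <- function() {
  # two DE families, three genes; predictions cover all crosses
  mir_prof <- toy_profiles(list(
    "osa-miR1a" = list("60min" = c(2, 0.01), "2h" = c(2, 0.01)),
    "osa-miR2a" = list("10min" = c(-2, 0.01))))
  fams <- aggregate_families(call_de(mir_prof))
  gene_prof <- toy_profiles(list(
    g_opp_same_tp = list("2h" = c(-2, 0.01)),
    g_same_dir = list("10min" = c(2, 0.01), "20min" = c(2, 0.01)),
    g_opp_other_tp = list("60min" = c(2, 0.01)),
    g_not_de = list()))
  genes <- call_de(gene_prof)
  preds <- tidyr::expand_grid(
    family = c("osa-miR1", "osa-miR2"),
    transcript_id = c("g_opp_same_tp", "g_same_dir", "g_opp_other_tp",
                      "g_not_de")) |>
    dplyr::mutate(mirna_id = paste0(family, "a"), mode = "cleavage",
                  expectation = 0)
  list(fams = fams, genes = genes, preds = preds)
}

test_that("candidate pairs require both sides to be differentially expressed", {
  fx <- make_pairing_fixture()
  cand <- candidate_pairs(fx$preds, fx$fams, fx$genes)
  expect_false("g_not_de" %in% cand$gene_id)
  expect_setequal(unique(cand$gene_id),
                  c("g_opp_same_tp", "g_same_dir", "g_opp_other_tp"))
  # brute-force enumeration: predictions x DE x DE
  de_genes <- unique(dplyr::filter(fx$genes, de)$entity_id)
  want <- fx$preds[fx$preds$transcript_id %in% de_genes, ]
  expect_equal(nrow(cand), nrow(unique(want[c("family", "transcript_id")])))
})

test_that("strict mode keeps only same-timepoint opposition with its support", {
  fx <- make_pairing_fixture()
  cand <- candidate_pairs(fx$preds, fx$fams, fx$genes)
  hc <- high_confidence_pairs(cand, fx$fams, fx$genes, mode = "strict")
  key <- paste(hc$family, hc$gene_id)
  # family up at {60min,2h}, gene down at {2h}: kept, support 2h
  expect_true("osa-miR1 g_opp_same_tp" %in% key)
  expect_identical(
    hc$supporting_timepoints[key == "osa-miR1 g_opp_same_tp"], "2h")
  # family up at 10min, gene up at {10min,20min}: never opposite
  expect_false("osa-miR1 g_same_dir" %in% key)
  # family down at 10min only, gene up at 60min only: excluded (strict)
  expect_false("osa-miR2 g_opp_other_tp" %in% key)
  # but the down-family vs up-at-10min gene IS same-timepoint opposition
  expect_true("osa-miR2 g_same_dir" %in% key)

  lenient <- high_confidence_pairs(cand, fx$fams, fx$genes, mode = "lenient")
  lkey <- paste(lenient$family, lenient$gene_id)
  expect_true("osa-miR2 g_opp_other_tp" %in% lkey)
  expect_true(all(key %in% lkey))  # strict is a subset of lenient here
})

test_that("retained pairs are invariant under a global up/down relabel", {
  fx <- make_pairing_fixture()
  flip_profiles <- function(prof) {
    dplyr::mutate(prof, log2fc = -log2fc)
  }
  mir_prof <- toy_profiles(list(
    "osa-miR1a" = list("60min" = c(2, 0.01), "2h" = c(2, 0.01)),
    "osa-miR2a" = list("10min" = c(-2, 0.01))))
  gene_prof <- toy_profiles(list(
    g_opp_same_tp = list("2h" = c(-2, 0.01)),
    g_same_dir = list("10min" = c(2, 0.01))))
  run <- function(mp, gp) {
    fams <- aggregate_families(call_de(mp))
    genes <- call_de(gp)
    preds <- tidyr::expand_grid(family = c("osa-miR1", "osa-miR2"),
                                transcript_id = unique(gp$entity_id)) |>
      dplyr::mutate(mode = "cleavage")
    hc <- high_confidence_pairs(candidate_pairs(preds, fams, genes),
                                fams, genes)
    sort(paste(hc$family, hc$gene_id))
  }
  expect_identical(run(mir_prof, gene_prof),
                   run(flip_profiles(mir_prof), flip_profiles(gene_prof)))
})

test_that("timecourse counts match hand enumeration and handle empty input", {
  mir_prof <- toy_profiles(list(
    m_up_all = list("10min" = c(2, 0.01), "20min" = c(2, 0.01),
                    "60min" = c(2, 0.01), "2h" = c(2, 0.01)),
    m_down_late = list("2h" = c(-2, 0.01))))
  gene_prof <- toy_profiles(list(
    g_down = list("60min" = c(-2, 0.01), "2h" = c(-2, 0.01))))
  counts <- timecourse_counts(call_de(mir_prof), call_de(gene_prof))
  pick <- function(tp, side, dir) {
    counts$n[counts$timepoint == tp & counts$side == side &
               counts$direction == dir]
  }
  expect_equal(sapply(c("10min", "20min", "60min", "2h"),
                      pick, side = "mirna", dir = "up"),
               c(`10min` = 1L, `20min` = 1L, `60min` = 1L, `2h` = 1L))
  expect_equal(pick("2h", "mirna", "down"), 1L)
  expect_equal(pick("10min", "mirna", "down"), 0L)
  expect_equal(pick("60min", "target", "down"), 1L)
  expect_equal(pick("10min", "target", "down"), 0L)

  empty <- call_de(toy_profiles(list(x = list())))
  zero <- timecourse_counts(empty, empty)
  expect_true(all(zero$n == 0))
})

test_that("planted anti-correlated pairs are recovered with high precision and recall", {
  cfg <- simulation_config(n_mirnas = 40, n_genes = 300,
                           frac_anticorrelated_pairs = 0.5,
                           n_ppi_modules = 0, seed = 73)
  study <- simulate_study(cfg)
  m <- preprocess_matrix(study$matrix)
  parts <- split_by_probe_type(m)
  de_mir <- de_profiles(parts$mirna)
  de_gene <- de_profiles(parts$gene)
  fams <- aggregate_families(de_mir)
  de_ids <- unique(dplyr::filter(de_mir, de)$entity_id)
  preds <- predict_targets(study$seqs$mirnas[names(study$seqs$mirnas) %in% de_ids],
                           study$seqs$transcripts)
  hc <- high_confidence_pairs(candidate_pairs(preds, fams, de_gene),
                              fams, de_gene)
  truth_keys <- paste(study$truth$pairs$family, study$truth$pairs$gene_id)
  got_keys <- paste(hc$family, hc$gene_id)
  expect_gte(mean(truth_keys %in% got_keys), 0.9)   # recall
  expect_gte(mean(got_keys %in% truth_keys), 0.9)   # precision
  # each reduction step is a subset of the one before
  cand <- candidate_pairs(preds, fams, de_gene)
  expect_true(all(paste(hc$family, hc$gene_id) %in%
                    paste(cand$family, cand$gene_id)))
  expect_true(all(paste(cand$family, cand$gene_id) %in%
                    paste(preds$family, preds$transcript_id)))
})
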