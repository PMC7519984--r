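test_that("duplex expectation reproduces the worked penalty examples", {
  m <- "ACGUACGUACGUACGUACGUA"
  expect_equal(score_duplex(m, rna_revcomp(m)), 0)

  # single G:U wobble at miRNA position 5 (seed region): 0.5 x 2
  m2 <- "ACGUGCGUACGUACGUACGUA"
  s2 <- rna_revcomp(m2)
  substr(s2, 17, 17) <- "U"   # site base opposite position 5
  expect_equal(score_duplex(m2, s2), 1.0)

  # mismatch at position 1 (1.0) plus mismatch at position 10 (2.0)
  s3 <- rna_revcomp(m)
  substr(s3, 21, 21) <- "C"
  substr(s3, 12, 12) <- "A"
  expect_equal(score_duplex(m, s3), 3.0)
})

test_that("an identical defect costs exactly twice as much inside the seed", {
  set.seed(41)
  for (rep in 1:10) {
    m <- rand_rna(21)
    base <- rna_revcomp(m)
    defect_at <- function(p) {
      s <- base
      mb <- substr(m, p, p)
      comp <- c(A = "U", C = "G", G = "C", U = "A")[[mb]]
      wob <- c(G = "U", U = "G")[mb]
      pick <- setdiff(c("A", "C", "G", "U"), c(comp, wob[!is.na(wob)]))[1]
      substr(s, 21 - p + 1, 21 - p + 1) <- pick
      score_duplex(m, s)
    }
    seed_p <- sample(2:13, 1)
    out_p <- sample(c(1, 14:21), 1)
    expect_equal(defect_at(seed_p), 2 * defect_at(out_p))
  }
})

test_that("expectation never decreases when defects are added", {
  set.seed(43)
  m <- rand_rna(21)
  s <- rna_revcomp(m)
  prev <- score_duplex(m, s)
  expect_equal(prev, 0)
  for (p in sample(1:21, 8)) {
    cur_base <- substr(s, 21 - p + 1, 21 - p + 1)
    substr(s, 21 - p + 1, 21 - p + 1) <-
      sample(setdiff(c("A", "C", "G", "U"), cur_base), 1)
    cur <- score_duplex(m, s)
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("alignment validation rejects codes inconsistent with the bases", {
  m <- "ACGUACGUACGUACGUACGUA"
  s <- rna_revcomp(m)
  ok <- paste(rep("M", 21), collapse = "")
  expect_equal(score_duplex(m, s, ok), 0)
  bad <- paste(c("X", rep("M", 20)), collapse = "")
  expect_error(score_duplex(m, s, bad), class = "mirheat_alignment_error")
  expect_error(score_duplex(m, s, "MM"), class = "mirheat_alignment_error")
})

test_that("regulation mode turns on disruption of the central positions", {
  perfect <- paste(rep("M", 21), collapse = "")
  expect_identical(classify_mode(perfect), "cleavage")
  mm10 <- paste(c(rep("M", 9), "X", rep("M", 11)), collapse = "")
  expect_identical(classify_mode(mm10), "translation_inhibition")
  mm3 <- paste(c("M", "M", "X", rep("M", 18)), collapse = "")
  expect_identical(classify_mode(mm3), "cleavage")
  wob11 <- paste(c(rep("M", 10), "W", rep("M", 10)), collapse = "")
  expect_identical(classify_mode(wob11), "cleavage")
  gap10 <- paste(c(rep("M", 9), "g", rep("M", 11)), collapse = "")
  expect_identical(classify_mode(gap10), "translation_inhibition")
})

test_that("scanner finds a planted exact site at the right coordinates", {
  set.seed(47)
  m <- rand_rna(21)
  tx <- rand_rna(400)
  substr(tx, 123, 143) <- rna_revcomp(m)
  hits <- scan_transcript(m, tx)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 123L)
  expect_equal(hits$end, 143L)
  expect_equal(hits$expectation, 0)
  expect_identical(hits$mode, "cleavage")
  # the reported substring re-scores to the reported expectation
  expect_equal(score_duplex(m, substr(tx, hits$start, hits$end),
                            hits$alignment), hits$expectation)
  expect_error(scan_transcript(m, "ACGU"), class = "mirheat_format_error")
  expect_error(scan_transcript("", "ACGU"), class = "mirheat_format_error")
})

test_that("compiled scan equals brute-force enumeration on random instances", {
  set.seed(53)
  for (i in 1:50) {
    m <- rand_rna(sample(18:22, 1))
    tx <- rand_rna(sample(60:200, 1))
    if (i %% 5 == 0) {  # guarantee some instances with passing windows
      s <- make_target_site(m, sample(c(0, 1, 2, 3), 1))
      p <- sample.int(nchar(tx) - nchar(s) + 1, 1)
      substr(tx, p, p + nchar(s) - 1) <- s
    }
    cutoff <- sample(c(3, 6, 10), 1)
    got <- mirheat:::scan_windows_cpp(
      mirheat:::encode_rna(m), mirheat:::encode_rna(tx),
      mirheat:::pair_penalty_lookup(scoring_scheme()),
      mirheat:::position_weights(nchar(m), scoring_scheme()),
      2, cutoff, 1L)
    got <- as.data.frame(got)
    got <- got[order(got$start, got$gap_type, got$gap_pos), ]
    want <- bf_scan(m, tx, cutoff = cutoff)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("a random transcript with no sub-cutoff window yields no sites", {
  set.seed(59)
  m <- rand_rna(21)
  tx <- rand_rna(1000)
  want <- bf_scan(m, tx, cutoff = 3)
  # brute force confirms the negative before asserting it of the scanner
  expect_equal(nrow(want), 0)
  expect_equal(nrow(scan_transcript(m, tx, cutoff = 3)), 0)
})

test_that("overlapping sites collapse to the best-scoring one", {
  set.seed(61)
  m <- rand_rna(21)
  tx <- rand_rna(200)
  substr(tx, 50, 70) <- rna_revcomp(m)
  # a perfect site also matches its own shifted gapped variants; after
  # collapsing only one site per locus remains
  hits <- scan_transcript(m, tx, cutoff = 6)
  overlaps <- function(h) {
    if (nrow(h) < 2) return(FALSE)
    any(sapply(2:nrow(h), function(i)
      any(h$start[i] <= h$end[-i] & h$end[i] >= h$start[-i])))
  }
  expect_false(overlaps(hits))
  expect_equal(min(hits$expectation), 0)
})

test_that("prediction keeps one best row per pair and deduplicates families", {
  set.seed(67)
  mir_a <- rand_rna(21)
  # second family member: one non-seed substitution
  mir_b <- mir_a
  substr(mir_b, 16, 16) <- setdiff(c("A", "C", "G", "U"),
                                   substr(mir_a, 16, 16))[1]
  txs <- setNames(replicate(3, rand_rna(300)), paste0("g", 1:3))
  substr(txs[["g2"]], 100, 120) <- rna_revcomp(mir_a)
  preds <- predict_targets(
    c("osa-miR7a" = mir_a, "osa-miR7b" = mir_b), txs)
  # both members hit g2, but the family keeps a single record
  expect_equal(nrow(preds), 1)
  expect_identical(preds$family, "osa-miR7")
  expect_identical(preds$transcript_id, "g2")
  expect_equal(preds$expectation, 0)
  expect_identical(preds$mirna_id, "osa-miR7a")
})

test_that("planted sites are recovered and constructed decoys never pass", {
  cfg <- simulation_config(n_mirnas = 10, n_genes = 60,
                           frac_de_mirnas = 0.4, frac_de_genes = 0.4,
                           frac_anticorrelated_pairs = 0.5, seed = 71)
  truth <- simulate_expression(cfg)$truth
  seqs <- simulate_sequences(cfg, truth, n_decoys = 10)
  expect_gt(nrow(seqs$sites), 0)
  for (i in seq_len(nrow(seqs$sites))) {
    st <- seqs$sites[i, ]
    hits <- scan_transcript(seqs$mirnas[[st$mirna_id]],
                            seqs$transcripts[[st$gene_id]])
    hit <- dplyr::filter(hits, start == st$start)
    expect_equal(nrow(hit), 1)
    expect_equal(hit$expectation, st$intended_expectation)
    expect_identical(hit$mode, st$intended_mode)
  }
  preds <- predict_targets(seqs$mirnas, seqs$transcripts, cutoff = 3)
  decoy_hit <- dplyr::inner_join(preds, seqs$decoys,
                                 by = c(transcript_id = "gene_id"))
  expect_equal(nrow(decoy_hit), 0)
  # recall over planted (family, gene) pairs is total by construction
  planted <- unique(paste(seqs$sites$family, seqs$sites$gene_id))
  got <- unique(paste(preds$family, preds$transcript_id))
  expect_true(all(planted %in% got))
})
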