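test_that("log2 fold change and degenerate variance follow the definitions", {
  vals <- rbind(c(5, 5, 5, 5), c(3, 3, 4, 4))
  m <- toy_matrix(vals, timepoints = c("0min", "2h"), reps = 2)
  de <- compute_de(m, "0min", "2h", method = "student_t")
  # identical replicates in both groups: lfc 0, p 1
  expect_equal(de$log2fc[1], 0)
  expect_equal(de$pvalue[1], 1)
  # treatment exactly 2x control on the linear scale: log2 diff 1.0
  expect_equal(de$log2fc[2], 1.0)
  expect_error(compute_de(m, "0min", "0min"), class = "mirheat_config_error")
})

test_that("student t matches an independent textbook computation", {
  set.seed(19)
  vals <- matrix(rnorm(6 * 4, 8), 6, 4)
  m <- toy_matrix(vals, timepoints = c("0min", "2h"), reps = 2)
  de <- compute_de(m, "0min", "2h", method = "student_t")
  for (i in 1:6) {
    x <- vals[i, 1:2]; y <- vals[i, 3:4]
    # pooled-variance two-sample t from first principles
    sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / 2
    tt <- (mean(y) - mean(x)) / sqrt(sp2 * (1 / 2 + 1 / 2))
    p <- 2 * pt(-abs(tt), df = 2)
    expect_equal(de$pvalue[i], p, tolerance = 1e-10)
    expect_equal(de$log2fc[i], mean(y) - mean(x), tolerance = 1e-12)
  }
})

test_that("swapping control and treatment negates fold changes, keeps p-values", {
  set.seed(23)
  m <- toy_matrix(matrix(rnorm(40, 8), 10, 4),
                  timepoints = c("0min", "2h"), reps = 2)
  for (method in c("student_t", "moderated_t")) {
    a <- compute_de(m, "0min", "2h", method = method)
    b <- compute_de(m, "2h", "0min", method = method)
    expect_equal(b$log2fc, -a$log2fc)
    expect_equal(b$pvalue, a$pvalue)
  }
})

test_that("moderated t collapses to the plain t as the prior weight vanishes", {
  set.seed(29)
  m <- toy_matrix(matrix(rnorm(200, 8), 50, 4),
                  timepoints = c("0min", "2h"), reps = 2)
  plain <- compute_de(m, "0min", "2h", method = "student_t")
  mod0 <- compute_de(m, "0min", "2h", method = "moderated_t", prior_df = 0)
  expect_equal(mod0$pvalue, plain$pvalue, tolerance = 1e-12)
})

test_that("moderated t agrees with limma's empirical-Bayes ranking", {
  set.seed(31)
  n <- 500
  vals <- matrix(rnorm(n * 4, 8, 0.3), n, 4)
  vals[1:50, 3:4] <- vals[1:50, 3:4] + 2
  m <- toy_matrix(vals, timepoints = c("0min", "2h"), reps = 2)
  mine <- compute_de(m, "0min", "2h", method = "moderated_t")
  design <- cbind(1, c(0, 0, 1, 1))
  fit <- limma::eBayes(limma::lmFit(vals, design))
  expect_equal(mine$log2fc, unname(fit$coefficients[, 2]), tolerance = 1e-10)
  expect_gt(cor(rank(mine$pvalue), rank(fit$p.value[, 2]),
                method = "spearman"), 0.99)
})

test_that("DE calling uses an inclusive fold threshold and a strict p cutoff", {
  prof <- toy_profiles(list(
    boundary = list("10min" = c(1.0, 0.049)),
    under_fold = list("10min" = c(0.99, 0.001), "20min" = c(0.99, 0.001),
                      "60min" = c(0.99, 0.001), "2h" = c(0.99, 0.001)),
    p_exact = list("2h" = c(2.0, 0.05))))
  calls <- call_de(prof)
  de <- dplyr::distinct(calls, entity_id, de)
  expect_true(de$de[de$entity_id == "boundary"])
  expect_false(de$de[de$entity_id == "under_fold"])
  expect_false(de$de[de$entity_id == "p_exact"])
})

test_that("DE calling is monotone in its thresholds", {
  set.seed(37)
  prof <- toy_profiles(setNames(
    lapply(1:100, function(i) list("2h" = c(rnorm(1, 0, 1.2), runif(1)))),
    paste0("e", 1:100)))
  de_set <- function(lfc, a) {
    d <- dplyr::distinct(call_de(prof, lfc, a), entity_id, de)
    d$entity_id[d$de]
  }
  base <- de_set(1.0, 0.05)
  expect_true(all(base %in% de_set(1.0, 0.10)))   # raising alpha grows
  expect_true(all(base %in% de_set(0.5, 0.05)))   # lowering lfc grows
  expect_true(all(de_set(1.5, 0.05) %in% base))
})

test_that("miRNA ids collapse to family names idempotently", {
  expect_identical(map_to_family("osa-miR169g"), "osa-miR169")
  expect_identical(map_to_family("osa-miR166"), "osa-miR166")
  expect_identical(map_to_family("osa-miR397b.2"), "osa-miR397")
  expect_identical(map_to_family("ath-miR166a-5p"), "ath-miR166")
  expect_identical(map_to_family(map_to_family("osa-miR169g")),
                   "osa-miR169")
  expect_error(map_to_family("totally-wrong"),
               class = "mirheat_format_error")
  expect_warning(out <- map_to_family("totally-wrong", lenient = TRUE))
  expect_identical(out, "totally-wrong")
})

test_that("family aggregation labels agreement, disagreement and conflicts", {
  prof <- toy_profiles(list(
    "osa-miR1a" = list("60min" = c(2, 0.01)),
    "osa-miR1b" = list("60min" = c(1.5, 0.02)),
    "osa-miR2a" = list("10min" = c(2, 0.01)),
    "osa-miR2b" = list("10min" = c(-2, 0.01)),
    "osa-miR3a" = list("2h" = c(-3, 0.001)),
    "osa-miR4a" = list()))
  calls <- call_de(prof)
  fams <- aggregate_families(calls)
  ov <- dplyr::distinct(tibble::as_tibble(fams), family, overall_direction)
  expect_identical(ov$overall_direction[ov$family == "osa-miR1"], "up")
  expect_identical(ov$overall_direction[ov$family == "osa-miR2"], "up_down")
  expect_identical(ov$overall_direction[ov$family == "osa-miR3"], "down")
  expect_false("osa-miR4" %in% ov$family)  # non-DE members excluded

  tp <- tibble::as_tibble(fams)
  expect_identical(tp$direction[tp$family == "osa-miR2" &
                                  tp$timepoint == "10min"], "conflict")
  expect_identical(tp$direction[tp$family == "osa-miR1" &
                                  tp$timepoint == "10min"], "none")
  expect_error(aggregate_families(call_de(toy_profiles(list(
    "osa-miR9" = list())))), class = "mirheat_empty_error")

  g <- glance(fams)
  expect_equal(g$n_families, 3)
  expect_equal(g$n_up_down, 1)
})
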