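#' Filter probes by detection-flag support
#'
#' Keeps exactly the probes whose number of present (`P`) calls across
#' samples is at least `min_present`, preserving probe order. The study
#' design this mirrors required a present call in at least 6 of its 10
#' arrays; by default the rule generalizes as `ceiling(0.6 * n_samples)`.
#'
#' @param m An [expr_matrix()] with flags.
#' @param min_present Minimum number of `P` calls a probe must have.
#'   Default `ceiling(0.6 * ncol(m))`.
#' @return The filtered `expr_matrix`.
#' @export
#' @examples
#' m <- simulate_expression(simulation_config(n_mirnas = 5, n_genes = 20,
#'                                            seed = 1))$matrix
#' filter_by_flags(m)
filter_by_flags <- function(m, min_present = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  if (is.null(m$flags)) {
    mh_abort("filter_by_flags() needs detection flags", "config_error")
  }
  n <- ncol(m$values)
  min_present <- min_present %||% ceiling(0.6 * n)
  if (min_present < 0 || min_present > n) {
    mh_abort("min_present must lie in [0, n_samples]", "config_error")
  }
  keep <- rowSums(m$flags == "P") >= min_present
  filter_probes(m, which(keep))
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) onto the common distribution given by
#' the cross-sample mean of order statistics, preserving within-sample
#' ranks. Ties within a column receive the mean of the tied target
#' quantiles. Probes containing missing values are removed first (with a
#' message) since the transform is defined on complete rows.
#'
#' @param m An [expr_matrix()] with at least two samples.
#' @return The normalized `expr_matrix`.
#' @export
quantile_normalize <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (ncol(m$values) < 2) {
    mh_abort("quantile normalization needs at least two samples",
             "config_error")
  }
  ok <- stats::complete.cases(m$values)
  if (!all(ok)) {
    rlang::inform(sprintf("quantile_normalize: dropping %d probe(s) with missing values",
                          sum(!ok)))
    m <- filter_probes(m, which(ok))
  }
  norm <- limma::normalizeQuantiles(m$values, ties = TRUE)
  dimnames(norm) <- dimnames(m$values)
  m$values <- norm
  m
}

#' Center each probe at its median across all samples
#'
#' Subtracts, per probe, the median log2 intensity over all samples
#' ("baseline to median"); after the transform every probe row has
#' median zero. Idempotent.
#'
#' @param m An [expr_matrix()].
#' @return The centered `expr_matrix`.
#' @export
baseline_to_median <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  med <- apply(m$values, 1, stats::median)
  m$values <- m$values - med
  m
}

#' Run the full preprocessing chain
#'
#' Flag filter, then quantile normalization, then baseline-to-median
#' centering, in the order the upstream array workflow applies them.
#'
#' @inheritParams filter_by_flags
#' @param log_floor Values are assumed log2 already; if `log2_input` is
#'   FALSE raw intensities are clipped at `log_floor` and log2-transformed
#'   first.
#' @param log2_input Set to FALSE when the matrix holds raw intensities.
#' @return The preprocessed `expr_matrix`.
#' @export
preprocess_matrix <- function(m, min_present = NULL, log2_input = TRUE,
                              log_floor = 1.0) {
  if (!log2_input) {
    m$values <- log2(pmax(m$values, log_floor))
  }
  if (!is.null(m$flags)) m <- filter_by_flags(m, min_present)
  m <- quantile_normalize(m)
  baseline_to_median(m)
}
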