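#' Expression matrix with detection flags and sample metadata
#'
#' An `expr_matrix` bundles a probes x samples matrix of log2 intensities
#' with an optional matrix of P/A/M detection calls (present / absent /
#' marginal) of identical shape, per-sample metadata (timepoint and
#' replicate), and an optional per-probe type label ("mirna" or "gene")
#' for designs where miRNA and mRNA probes share one array.
#'
#' Samples are stored in canonical order (timepoint, then replicate) so
#' that downstream column indexing is deterministic.
#'
#' @param values Numeric matrix, probes x samples, with unique rownames
#'   (probe ids) and colnames (sample ids).
#' @param samples Data frame with columns `sample_id`, `timepoint`,
#'   `replicate` covering every column of `values`.
#' @param flags Optional character matrix with cells in `{"P","A","M"}`,
#'   same dimensions and dimnames as `values`.
#' @param probe_type Optional character vector (one of `"mirna"`,
#'   `"gene"`) named by probe id, covering all probes.
#' @param timepoint_levels Ordered timepoint labels; defaults to the
#'   order of first appearance in `samples`.
#'
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, samples, flags = NULL, probe_type = NULL,
                        timepoint_levels = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    mh_abort("`values` must be a numeric matrix", "format_error")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    mh_abort("`values` must carry probe ids as rownames and sample ids as colnames",
             "format_error")
  }
  if (anyDuplicated(rownames(values))) {
    mh_abort("duplicate probe id in expression matrix", "format_error")
  }
  if (anyDuplicated(colnames(values))) {
    mh_abort("duplicate sample id in expression matrix", "format_error")
  }
  samples <- as_tibble(samples)
  need <- c("sample_id", "timepoint", "replicate")
  if (!all(need %in% names(samples))) {
    mh_abort("sample sheet needs columns sample_id, timepoint, replicate",
             "metadata_error")
  }
  missing_meta <- setdiff(colnames(values), samples$sample_id)
  if (length(missing_meta)) {
    mh_abort(paste0("sample(s) in matrix missing from sample sheet: ",
                    paste(missing_meta, collapse = ", ")), "metadata_error")
  }
  samples <- samples[match(colnames(values), samples$sample_id), ]
  if (anyDuplicated(samples[c("timepoint", "replicate")])) {
    mh_abort("duplicate (timepoint, replicate) pair in sample sheet",
             "metadata_error")
  }
  lev <- timepoint_levels %||% unique(as.character(samples$timepoint))
  if (!all(as.character(samples$timepoint) %in% lev)) {
    mh_abort("sample timepoint outside the declared timepoint set",
             "metadata_error")
  }
  samples$timepoint <- factor(as.character(samples$timepoint),
                              levels = lev, ordered = TRUE)
  samples$replicate <- as.integer(samples$replicate)
  if (any(samples$replicate < 1)) {
    mh_abort("replicate indices must be positive", "metadata_error")
  }
  ord <- order(samples$timepoint, samples$replicate)
  samples <- samples[ord, ]
  values <- values[, samples$sample_id, drop = FALSE]

  if (!is.null(flags)) {
    if (!identical(dim(flags), dim(values))) {
      mh_abort("flag matrix dimensions differ from value matrix", "format_error")
    }
    flags <- flags[, samples$sample_id, drop = FALSE]
    bad <- which(matrix(!(flags %in% c("P", "A", "M")), nrow(flags)),
                 arr.ind = TRUE)
    if (nrow(bad)) {
      mh_abort(sprintf("unknown flag symbol '%s' at probe %s, sample %s",
                       flags[bad[1, 1], bad[1, 2]],
                       rownames(values)[bad[1, 1]],
                       colnames(values)[bad[1, 2]]), "format_error")
    }
    rownames(flags) <- rownames(values)
  }
  if (!is.null(probe_type)) {
    if (is.null(names(probe_type)) ||
        !all(rownames(values) %in% names(probe_type))) {
      mh_abort("`probe_type` must be named and cover every probe", "format_error")
    }
    probe_type <- probe_type[rownames(values)]
    if (!all(probe_type %in% c("mirna", "gene"))) {
      mh_abort("probe types must be 'mirna' or 'gene'", "format_error")
    }
  }
  structure(list(values = values, flags = flags, samples = samples,
                 probe_type = probe_type),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d probes x %d samples (%s flags)\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$flags)) "no" else "with"))
  cat("  timepoints:", paste(levels(x$samples$timepoint), collapse = " < "), "\n")
  if (!is.null(x$probe_type)) {
    tt <- table(x$probe_type)
    cat("  probe types:", paste(names(tt), tt, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Probe identifiers of an expression matrix
#' @param m An `expr_matrix`.
#' @return Character vector of probe ids.
#' @export
probe_ids <- function(m) rownames(m$values)

#' Subset an expression matrix by probe
#'
#' @param m An `expr_matrix`.
#' @param probes Probe ids (or logical/integer index) to keep.
#' @return The subsetted `expr_matrix`.
#' @export
filter_probes <- function(m, probes) {
  stopifnot(inherits(m, "expr_matrix"))
  expr_matrix(m$values[probes, , drop = FALSE], m$samples,
              flags = if (is.null(m$flags)) NULL else m$flags[probes, , drop = FALSE],
              probe_type = m$probe_type,
              timepoint_levels = levels(m$samples$timepoint))
}

#' Split an expression matrix by probe type
#'
#' @param m An `expr_matrix` whose `probe_type` field is set.
#' @return Named list with `mirna` and `gene` expression matrices.
#' @export
split_by_probe_type <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (is.null(m$probe_type)) {
    mh_abort("expression matrix carries no probe_type labels", "config_error")
  }
  lapply(stats::setNames(c("mirna", "gene"), c("mirna", "gene")), function(tp) {
    filter_probes(m, names(m$probe_type)[m$probe_type == tp])
  })
}

#' @describeIn expr_matrix Long-format view: one row per (probe, sample)
#'   cell with its value, flag and sample metadata.
#' @param x An `expr_matrix`.
#' @param ... Unused.
#' @export
tidy.expr_matrix <- function(x, ...) {
  long <- tibble(
    probe_id = rep(rownames(x$values), times = ncol(x$values)),
    sample_id = rep(colnames(x$values), each = nrow(x$values)),
    value = as.vector(x$values),
    flag = if (is.null(x$flags)) NA_character_ else as.vector(x$flags)
  )
  left_join(long, x$samples, by = "sample_id")
}

#' @describeIn expr_matrix One-row summary of dimensions and flag coverage.
#' @export
glance.expr_matrix <- function(x, ...) {
  tibble(
    n_probes = nrow(x$values),
    n_samples = ncol(x$values),
    n_timepoints = length(levels(x$samples$timepoint)),
    has_flags = !is.null(x$flags),
    frac_present = if (is.null(x$flags)) NA_real_ else mean(x$flags == "P")
  )
}
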