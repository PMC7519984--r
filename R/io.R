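#' Read a tab-delimited expression matrix with optional detection flags
#'
#' Expression files are TSV with the probe id in the first column
#' (header `probe_id`) and one column per sample. The flag file, when
#' given, has the identical layout with cells in `{P, A, M}`. The sample
#' sheet maps every sample id to a timepoint label and replicate index;
#' samples are reordered canonically by (timepoint, replicate).
#'
#' @param path Path to the expression value TSV.
#' @param sample_sheet Path to a sample sheet TSV with columns
#'   `sample_id`, `timepoint`, `replicate`.
#' @param flag_path Optional path to the P/A/M flag TSV.
#' @param probe_type_path Optional path to a TSV with columns `probe_id`,
#'   `probe_type` for mixed miRNA/mRNA arrays.
#' @param timepoint_levels Optional ordered timepoint labels; default is
#'   order of first appearance in the sample sheet.
#' @return An [expr_matrix()].
#' @export
read_expression_matrix <- function(path, sample_sheet, flag_path = NULL,
                                   probe_type_path = NULL,
                                   timepoint_levels = NULL) {
  vals <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (anyDuplicated(vals[[1]])) {
    mh_abort(paste0("duplicate probe id in ", path), "format_error")
  }
  m <- as.matrix(vals[, -1, drop = FALSE])
  rownames(m) <- vals[[1]]
  if (!is.numeric(m)) mh_abort("non-numeric expression values", "format_error")

  flags <- NULL
  if (!is.null(flag_path)) {
    fl <- readr::read_tsv(flag_path, show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(.default = "c"))
    fm <- as.matrix(fl[, -1, drop = FALSE])
    rownames(fm) <- fl[[1]]
    if (!identical(dim(fm), dim(m)) ||
        !identical(rownames(fm), rownames(m)) ||
        !identical(colnames(fm), colnames(m))) {
      mh_abort("flag file layout does not match the value file", "format_error")
    }
    flags <- fm
  }
  probe_type <- NULL
  if (!is.null(probe_type_path)) {
    pt <- readr::read_tsv(probe_type_path, show_col_types = FALSE, progress = FALSE)
    probe_type <- stats::setNames(pt$probe_type, pt$probe_id)
  }
  sheet <- readr::read_tsv(sample_sheet, show_col_types = FALSE, progress = FALSE)
  expr_matrix(m, sheet, flags = flags, probe_type = probe_type,
              timepoint_levels = timepoint_levels)
}

#' Write an expression matrix (and companions) as TSV
#'
#' Inverse of [read_expression_matrix()]: writes the value matrix, and
#' optionally the flag matrix, sample sheet and probe-type table, in the
#' layouts the reader expects.
#'
#' @param m An [expr_matrix()].
#' @param path Output path for the value TSV.
#' @param flag_path,sample_sheet_path,probe_type_path Optional output
#'   paths for the companion files.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path, flag_path = NULL,
                                    sample_sheet_path = NULL,
                                    probe_type_path = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  df <- bind_cols(tibble(probe_id = rownames(m$values)),
                  as_tibble(m$values))
  readr::write_tsv(df, path, progress = FALSE)
  if (!is.null(flag_path)) {
    if (is.null(m$flags)) mh_abort("matrix has no flags to write", "config_error")
    fdf <- bind_cols(tibble(probe_id = rownames(m$flags)), as_tibble(m$flags))
    readr::write_tsv(fdf, flag_path, progress = FALSE)
  }
  if (!is.null(sample_sheet_path)) {
    sheet <- m$samples
    sheet$timepoint <- as.character(sheet$timepoint)
    readr::write_tsv(sheet, sample_sheet_path, progress = FALSE)
  }
  if (!is.null(probe_type_path)) {
    readr::write_tsv(tibble(probe_id = names(m$probe_type),
                            probe_type = unname(m$probe_type)),
                     probe_type_path, progress = FALSE)
  }
  invisible(path)
}

#' Read a FASTA file into a named RNA character vector
#'
#' Sequences are uppercased and unified to the RNA alphabet (T becomes
#' U); only `A`, `C`, `G`, `U`, `N` are accepted afterwards. Duplicate
#' ids and empty records are errors.
#'
#' @param path FASTA file path.
#' @return Named character vector of RNA sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    mh_abort(paste0("duplicate sequence id: ",
                    ids[duplicated(ids)][1]), "format_error")
  }
  seqs <- chartr("tT", "uU", as.character(set))
  seqs <- toupper(seqs)
  if (any(nchar(seqs) == 0)) mh_abort("empty FASTA record", "format_error")
  bad <- grepl("[^ACGUN]", seqs)
  if (any(bad)) {
    mh_abort(paste0("illegal character in sequence ", ids[bad][1]),
             "format_error")
  }
  stats::setNames(seqs, ids)
}

#' Write RNA sequences to FASTA
#'
#' @param seqs Named character vector of sequences (U alphabet on output).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(chartr("tT", "uU", toupper(seqs)))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a protein-protein interaction edge table
#'
#' Three tab-separated columns: protein a, protein b, combined score.
#' Scores are normalized to `[0, 1]`; STRING-style integer scores in
#' `[0, 1000]` are declared with `score_scale = "thousand"`. Self edges
#' are dropped with a warning and duplicate undirected edges are
#' collapsed keeping the maximum score.
#'
#' @param path Edge table path.
#' @param score_scale Either `"unit"` (scores already in `[0,1]`) or
#'   `"thousand"` (integer scores in `[0,1000]`).
#' @return Tibble with columns `protein_a`, `protein_b`, `combined_score`.
#' @export
read_ppi_edges <- function(path, score_scale = c("unit", "thousand")) {
  score_scale <- match.arg(score_scale)
  df <- readr::read_tsv(path, col_names = c("protein_a", "protein_b", "combined_score"),
                        show_col_types = FALSE, progress = FALSE, skip = 0)
  # tolerate a header line
  if (is.character(df$combined_score)) {
    suppressWarnings(num <- as.numeric(df$combined_score))
    if (is.na(num[1]) && !is.na(df$combined_score[1])) {
      df <- df[-1, ]
      num <- num[-1]
    }
    df$combined_score <- num
  }
  if (anyNA(df$combined_score)) mh_abort("non-numeric PPI score", "format_error")
  hi <- if (score_scale == "thousand") 1000 else 1
  if (any(df$combined_score < 0 | df$combined_score > hi)) {
    mh_abort(sprintf("PPI score outside declared [0, %g] range", hi),
             "format_error")
  }
  df$combined_score <- df$combined_score / hi
  self <- df$protein_a == df$protein_b
  if (any(self)) {
    rlang::warn(sprintf("dropped %d self edge(s) from %s", sum(self), path))
    df <- df[!self, ]
  }
  # collapse undirected duplicates, keeping the max score
  a <- pmin(df$protein_a, df$protein_b)
  b <- pmax(df$protein_a, df$protein_b)
  df$protein_a <- a
  df$protein_b <- b
  df |>
    group_by(.data$protein_a, .data$protein_b) |>
    summarise(combined_score = max(.data$combined_score), .groups = "drop")
}

loc_pattern <- "^LOC_Os\\d{2}g\\d{5}$"

#' Read the packaged high-confidence family/target direction table
#'
#' Loads a TSV of miRNA-family/target-gene records with the overall
#' regulation direction of each side (`up`, `down` or `up_down`), as in
#' the packaged transcription of the study's high-confidence pair table
#' (`system.file("extdata", "table1_hc_pairs.tsv", package = "mirheat")`).
#'
#' @param path TSV with columns `family`, `family_direction`, `gene_id`,
#'   `gene_direction`.
#' @return Tibble of validated records.
#' @export
read_family_targets <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("family", "family_direction", "gene_id", "gene_direction")
  if (!all(need %in% names(df))) {
    mh_abort("family/target table must have family, family_direction, gene_id, gene_direction",
             "format_error")
  }
  bad_dir <- setdiff(unique(c(df$family_direction, df$gene_direction)),
                     direction_levels())
  if (length(bad_dir)) {
    mh_abort(paste0("unknown direction token: ", bad_dir[1]), "format_error")
  }
  bad_loc <- !grepl(loc_pattern, df$gene_id)
  if (any(bad_loc)) {
    mh_abort(paste0("malformed locus id: ", df$gene_id[bad_loc][1]),
             "format_error")
  }
  as_tibble(df[need])
}

#' Read a characterized-gene (OGRO-style) record table
#'
#' @param path TSV with columns `locus_id`, `gene_symbol`,
#'   `character_major`, `character_minor`, `isolation`, `objective`,
#'   `reference_doi`. A locus may have several records. The packaged
#'   snapshot lives at
#'   `system.file("extdata", "table2_ogro.tsv", package = "mirheat")`.
#' @return Tibble of records.
#' @export
read_ogro_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("locus_id", "gene_symbol", "character_major", "character_minor",
            "isolation", "objective", "reference_doi")
  if (!all(need %in% names(df))) {
    mh_abort("characterized-gene table is missing required columns",
             "format_error")
  }
  bad <- !grepl(loc_pattern, df$locus_id)
  if (any(bad)) {
    mh_abort(paste0("malformed locus id: ", df$locus_id[bad][1]),
             "format_error")
  }
  as_tibble(df[need])
}

#' Read a GO-Slim annotation table
#'
#' @param path TSV with columns `gene_id`, `aspect` (`BP`, `CC` or `MF`)
#'   and `term`.
#' @return Tibble of annotations.
#' @export
read_goslim_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("gene_id", "aspect", "term") %in% names(df))) {
    mh_abort("GO-Slim table must have gene_id, aspect, term", "format_error")
  }
  bad <- setdiff(unique(df$aspect), c("BP", "CC", "MF"))
  if (length(bad)) {
    mh_abort(paste0("unknown GO aspect: ", bad[1]), "format_error")
  }
  as_tibble(df)
}
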