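#' GO-Slim category counts over a gene list
#'
#' Counts, within each GO aspect (`BP`, `CC`, `MF`), how many of the
#' supplied genes carry each term, and expresses the count as a
#' percentage of the aspect's annotated genes (a gene with several terms
#' contributes to each, so percentages can sum above 100). Genes with no
#' annotation at all are reported in the `unannotated` attribute.
#'
#' @param genes Character vector of gene ids.
#' @param annotation Annotation tibble with columns `gene_id`, `aspect`
#'   (`BP`/`CC`/`MF`), `term` (see [read_goslim_table()]).
#' @return Tibble `aspect`, `term`, `n_genes`, `pct`, ordered by aspect
#'   then descending count; attribute `unannotated` holds the
#'   unannotated gene ids.
#' @export
goslim_counts <- function(genes, annotation) {
  bad <- setdiff(unique(annotation$aspect), c("BP", "CC", "MF"))
  if (length(bad)) {
    mh_abort(paste0("unknown GO aspect: ", bad[1]), "format_error")
  }
  genes <- unique(genes)
  ann <- annotation |>
    filter(.data$gene_id %in% genes) |>
    distinct(.data$gene_id, .data$aspect, .data$term)
  aspect_sizes <- ann |>
    group_by(.data$aspect) |>
    summarise(n_annotated = n_distinct(.data$gene_id), .groups = "drop")
  out <- ann |>
    count(.data$aspect, .data$term, name = "n_genes") |>
    left_join(aspect_sizes, by = "aspect") |>
    mutate(pct = 100 * .data$n_genes / .data$n_annotated) |>
    select("aspect", "term", "n_genes", "pct") |>
    arrange(.data$aspect, dplyr::desc(.data$n_genes), .data$term)
  attr(out, "unannotated") <- setdiff(genes, unique(ann$gene_id))
  out
}

#' Look up genes in a characterized-gene (OGRO-style) table
#'
#' Inner join of a gene list against the record table on the locus id:
#' one output row per (locus, characterization record). The number of
#' distinct characterized loci is attached as the `n_characterized`
#' attribute.
#'
#' @param genes Character vector of locus ids.
#' @param ogro Record tibble (see [read_ogro_table()]).
#' @return Tibble of matching records; attribute `n_characterized`.
#' @export
ogro_lookup <- function(genes, ogro) {
  out <- ogro |>
    filter(.data$locus_id %in% unique(genes)) |>
    arrange(.data$locus_id, .data$character_major, .data$character_minor)
  attr(out, "n_characterized") <- n_distinct(out$locus_id)
  out
}
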