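#' Build the heterogeneous miRNA-family / PPI network
#'
#' Nodes are the miRNA families and target genes of the high-confidence
#' pair table; family-to-gene edges carry the regulation kind of the
#' pair's best site (`cleavage` or `translation_inhibition`), and
#' gene-gene edges carry protein-protein interactions whose combined
#' score strictly exceeds `min_ppi_score` and whose two endpoints are
#' both network genes. Construction is deterministic: nodes and edges
#' are inserted in sorted order, so identical inputs yield identical
#' GraphML bytes.
#'
#' @param hc_pairs High-confidence pair table (columns `family`,
#'   `gene_id`, `family_overall`, `gene_overall`, optionally `mode`;
#'   pairs without a `mode` are taken as cleavage).
#' @param ppi_edges Optional PPI tibble from [read_ppi_edges()].
#' @param min_ppi_score Strict lower bound on the combined score
#'   (default 0.7).
#' @return An `mh_network`: a list with the igraph `graph` and the
#'   cutoff used.
#' @export
build_mirna_ppi_network <- function(hc_pairs, ppi_edges = NULL,
                                    min_ppi_score = 0.7) {
  stopifnot(all(c("family", "gene_id") %in% names(hc_pairs)))
  if (!"mode" %in% names(hc_pairs)) hc_pairs$mode <- "cleavage"
  if (!"family_overall" %in% names(hc_pairs)) hc_pairs$family_overall <- NA_character_
  if (!"gene_overall" %in% names(hc_pairs)) hc_pairs$gene_overall <- NA_character_

  fam_nodes <- hc_pairs |>
    distinct(id = .data$family, direction = .data$family_overall) |>
    distinct(.data$id, .keep_all = TRUE) |>
    mutate(type = "family")
  gene_nodes <- hc_pairs |>
    distinct(id = .data$gene_id, direction = .data$gene_overall) |>
    distinct(.data$id, .keep_all = TRUE) |>
    mutate(type = "gene")
  nodes <- bind_rows(fam_nodes, gene_nodes) |> arrange(.data$id)
  nodes$direction <- ifelse(is.na(nodes$direction), "", nodes$direction)

  target_edges <- hc_pairs |>
    distinct(from = .data$family, to = .data$gene_id, kind = .data$mode) |>
    mutate(score = NA_real_)
  edges <- target_edges
  if (!is.null(ppi_edges) && nrow(ppi_edges) > 0) {
    genes <- gene_nodes$id
    keep <- ppi_edges |>
      filter(.data$combined_score > min_ppi_score,
             .data$protein_a %in% genes, .data$protein_b %in% genes) |>
      mutate(from = pmin(.data$protein_a, .data$protein_b),
             to = pmax(.data$protein_a, .data$protein_b),
             kind = "ppi", score = .data$combined_score) |>
      select("from", "to", "kind", "score")
    edges <- bind_rows(edges, keep)
  }
  edges <- arrange(edges, .data$kind, .data$from, .data$to)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  structure(list(graph = g, min_ppi_score = min_ppi_score),
            class = "mh_network")
}

#' @export
print.mh_network <- function(x, ...) {
  g <- x$graph
  cat(sprintf("<mh_network> %d nodes (%d families, %d genes), %d edges (%d ppi; score > %g)\n",
              igraph::vcount(g),
              sum(igraph::V(g)$type == "family"),
              sum(igraph::V(g)$type == "gene"),
              igraph::ecount(g),
              sum(igraph::E(g)$kind == "ppi"),
              x$min_ppi_score))
  invisible(x)
}

#' @export
tidy.mh_network <- function(x, ...) {
  e <- igraph::as_data_frame(x$graph, what = "edges")
  as_tibble(e)
}

#' @export
glance.mh_network <- function(x, ...) {
  g <- x$graph
  tibble(n_nodes = igraph::vcount(g),
         n_families = sum(igraph::V(g)$type == "family"),
         n_genes = sum(igraph::V(g)$type == "gene"),
         n_edges = igraph::ecount(g),
         n_ppi_edges = sum(igraph::E(g)$kind == "ppi"),
         min_ppi_score = x$min_ppi_score)
}

#' Find coregulatory modules
#'
#' A coregulatory module is a connected component of the heterogeneous
#' network that contains at least two miRNA families: families joined
#' through shared target genes and/or interactions among their target
#' proteins. Within each module the hub is the family of maximum degree
#' (ties broken by lexicographically smallest id). Modules are sorted by
#' size, largest first.
#'
#' @param net An `mh_network`.
#' @return Tibble, one row per module: `module`, `n_nodes`,
#'   `n_families`, `n_genes`, `hub_family`, and list-columns `families`
#'   and `genes`.
#' @export
find_coregulatory_modules <- function(net) {
  g <- net$graph
  comp <- igraph::components(g)
  vs <- tibble(id = igraph::V(g)$name,
               type = igraph::V(g)$type,
               degree = igraph::degree(g),
               member = comp$membership)
  mods <- vs |>
    group_by(.data$member) |>
    filter(sum(.data$type == "family") >= 2) |>
    ungroup()
  if (nrow(mods) == 0) {
    return(tibble(module = integer(), n_nodes = integer(),
                  n_families = integer(), n_genes = integer(),
                  hub_family = character(), families = list(),
                  genes = list()))
  }
  out <- mods |>
    group_by(.data$member) |>
    summarise(
      n_nodes = n(),
      n_families = sum(.data$type == "family"),
      n_genes = sum(.data$type == "gene"),
      hub_family = {
        fams <- .data$id[.data$type == "family"]
        degs <- .data$degree[.data$type == "family"]
        sort(fams[degs == max(degs)])[1]
      },
      families = list(sort(.data$id[.data$type == "family"])),
      genes = list(sort(.data$id[.data$type == "gene"])),
      .groups = "drop") |>
    arrange(dplyr::desc(.data$n_nodes), .data$hub_family) |>
    mutate(module = row_number()) |>
    select("module", "n_nodes", "n_families", "n_genes", "hub_family",
           "families", "genes")
  out
}

#' Bipartite stress-to-family network
#'
#' Links one stress node to every DE miRNA family; each family node
#' carries its overall direction.
#'
#' @param family_profiles An `mh_family_profiles` table.
#' @param stress_label Name of the stress node (default `"heat_stress"`).
#' @return An undirected igraph object.
#' @export
build_family_stress_bipartite <- function(family_profiles,
                                          stress_label = "heat_stress") {
  ov <- distinct(as_tibble(family_profiles), .data$family,
                 .data$overall_direction) |>
    arrange(.data$family)
  nodes <- bind_rows(
    tibble(id = stress_label, type = "stress", direction = ""),
    tibble(id = ov$family, type = "family", direction = ov$overall_direction))
  edges <- tibble(from = stress_label, to = ov$family)
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}

#' Node degree report
#'
#' Per-node degree, plus for every family the number of distinct target
#' genes it regulates and for every gene the number of distinct families
#' regulating it. Sorted by degree (descending), then id.
#'
#' @param net An `mh_network`.
#' @return Tibble `node`, `type`, `direction`, `degree`, `target_count`
#'   (families: distinct targets; genes: distinct regulating families).
#' @export
degree_report <- function(net) {
  g <- net$graph
  e <- as_tibble(igraph::as_data_frame(g, what = "edges"))
  te <- filter(e, .data$kind != "ppi")
  fam_counts <- te |> group_by(node = .data$from) |>
    summarise(target_count = n_distinct(.data$to), .groups = "drop")
  gene_counts <- te |> group_by(node = .data$to) |>
    summarise(target_count = n_distinct(.data$from), .groups = "drop")
  tibble(node = igraph::V(g)$name,
         type = igraph::V(g)$type,
         direction = igraph::V(g)$direction,
         degree = unname(igraph::degree(g))) |>
    left_join(bind_rows(fam_counts, gene_counts), by = "node") |>
    mutate(target_count = dplyr::coalesce(.data$target_count, 0L)) |>
    arrange(dplyr::desc(.data$degree), .data$node)
}

#' Write a network to GraphML, SIF or TSV
#'
#' GraphML keeps every node and edge attribute and is the lossless
#' interchange format; SIF encodes the edge kind as the relation token;
#' TSV writes a flat edge table. Output is deterministic for a given
#' graph.
#'
#' @param net An `mh_network` or igraph object.
#' @param path Output file.
#' @param format `"graphml"`, `"sif"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("graphml", "sif", "tsv")) {
  format <- match.arg(format)
  g <- if (inherits(net, "mh_network")) net$graph else net
  if (!igraph::is_igraph(g)) mh_abort("not a network object", "format_error")
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    e <- as_tibble(igraph::as_data_frame(g, what = "edges"))
    if (!"kind" %in% names(e)) e$kind <- "edge"
    e <- arrange(e, .data$kind, .data$from, .data$to)
    if (format == "sif") {
      readr::write_lines(paste(e$from, e$kind, e$to, sep = "\t"), path)
    } else {
      readr::write_tsv(e, path, progress = FALSE)
    }
  }
  invisible(path)
}

#' Read a GraphML network written by [write_network()]
#'
#' @param path GraphML file.
#' @return An igraph object.
#' @export
read_network <- function(path) {
  igraph::read_graph(path, format = "graphml")
}
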