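#' Candidate miRNA-family / target-gene pairs
#'
#' Restricts family-level target predictions to the pairs where both
#' sides respond: the family is differentially expressed and the gene is
#' differentially expressed.
#'
#' @param predictions Family-level prediction table from
#'   [predict_targets()] (columns `family`, `transcript_id`, and
#'   optionally `mode`, `expectation`).
#' @param family_profiles An `mh_family_profiles` table (DE families).
#' @param gene_calls An `mh_de` table for genes.
#' @return Tibble of candidate pairs, one row per (family, gene).
#' @export
candidate_pairs <- function(predictions, family_profiles, gene_calls) {
  de_fams <- unique(family_profiles$family)
  de_genes <- gene_calls |> filter(.data$de) |> pull("entity_id") |> unique()
  predictions |>
    rename(gene_id = "transcript_id") |>
    filter(.data$family %in% de_fams, .data$gene_id %in% de_genes) |>
    distinct(.data$family, .data$gene_id, .keep_all = TRUE)
}

#' High-confidence pairs by opposite regulation
#'
#' A candidate pair is kept when miRNA family and target gene moved in
#' opposite directions during the time course. Under the default
#' `"strict"` mode this requires a timepoint at which both sides are
#' significant with opposite directions (the supporting timepoints are
#' reported); under `"lenient"` mode the overall directions are
#' compared, an `up_down` side being compatible with any opposite call.
#' A family timepoint in `conflict` supports no pair at that timepoint,
#' while an `up_down` family can support pairs in either direction at
#' the timepoints where its direction is defined.
#'
#' @param pairs Candidate pairs from [candidate_pairs()].
#' @param family_profiles An `mh_family_profiles` table.
#' @param gene_calls An `mh_de` table for genes.
#' @param mode `"strict"` (same-timepoint opposition) or `"lenient"`
#'   (overall-direction opposition).
#' @return Tibble of retained pairs with `family_overall`,
#'   `gene_overall` and `supporting_timepoints` (comma-separated; empty
#'   under lenient mode when no same-timepoint opposition exists).
#' @export
high_confidence_pairs <- function(pairs, family_profiles, gene_calls,
                                  mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  fam_tp <- family_profiles |>
    select("family", "timepoint", fam_dir = "direction")
  gene_tp <- gene_calls |>
    select(gene_id = "entity_id", "timepoint", gene_dir = "direction")
  fam_ov <- distinct(family_profiles, .data$family,
                     family_overall = .data$overall_direction)
  gene_ov <- overall_directions(gene_calls) |>
    rename(gene_id = "entity_id", gene_overall = "overall_direction")

  support <- pairs |>
    select("family", "gene_id") |>
    left_join(fam_tp, by = "family", relationship = "many-to-many") |>
    left_join(gene_tp, by = c("gene_id", "timepoint")) |>
    filter((.data$fam_dir == "up" & .data$gene_dir == "down") |
             (.data$fam_dir == "down" & .data$gene_dir == "up")) |>
    group_by(.data$family, .data$gene_id) |>
    summarise(supporting_timepoints = paste(sort(as.character(.data$timepoint)),
                                            collapse = ","),
              .groups = "drop")

  annotated <- pairs |>
    left_join(fam_ov, by = "family") |>
    left_join(gene_ov, by = "gene_id") |>
    left_join(support, by = c("family", "gene_id")) |>
    mutate(supporting_timepoints =
             dplyr::coalesce(.data$supporting_timepoints, ""))

  if (mode == "strict") {
    out <- filter(annotated, .data$supporting_timepoints != "")
  } else {
    opposite <- function(a, b) {
      (a == "up" & b == "down") | (a == "down" & b == "up") |
        a == "up_down" | b == "up_down"
    }
    out <- filter(annotated,
                  opposite(.data$family_overall, .data$gene_overall))
  }
  structure(out, class = c("mh_pairs", class(out)), mode = mode)
}

#' @export
glance.mh_pairs <- function(x, ...) {
  tibble(n_pairs = nrow(x),
         n_families = n_distinct(x$family),
         n_genes = n_distinct(x$gene_id),
         mode = attr(x, "mode"))
}

#' Per-timepoint up/down counts of DE miRNAs and their targets
#'
#' The tabulation behind the time-lag bar chart: for every treatment
#' timepoint, how many DE miRNAs and how many high-confidence target
#' genes are significantly up and significantly down.
#'
#' @param mirna_calls An `mh_de` table of miRNA entities (DE miRNAs are
#'   selected internally).
#' @param target_calls An `mh_de` table restricted to the
#'   high-confidence target genes.
#' @return Tibble `timepoint`, `side` (`mirna` or `target`),
#'   `direction` (`up`/`down`), `n`, complete over all combinations.
#' @export
timecourse_counts <- function(mirna_calls, target_calls) {
  one_side <- function(calls, side) {
    calls |>
      filter(.data$de, .data$direction %in% c("up", "down")) |>
      count(.data$timepoint, .data$direction, name = "n") |>
      mutate(side = side)
  }
  tp_levels <- function(x) {
    if (is.factor(x)) levels(x) else unique(as.character(x))
  }
  tps <- unique(c(tp_levels(mirna_calls$timepoint),
                  tp_levels(target_calls$timepoint)))
  grid <- tidyr::expand_grid(timepoint = tps, side = c("mirna", "target"),
                             direction = c("up", "down"))
  bind_rows(one_side(mirna_calls, "mirna"),
            one_side(target_calls, "target")) |>
    mutate(timepoint = as.character(.data$timepoint)) |>
    dplyr::right_join(grid, by = c("timepoint", "side", "direction")) |>
    mutate(n = dplyr::coalesce(.data$n, 0L),
           timepoint = factor(.data$timepoint, levels = tps,
                              ordered = TRUE)) |>
    arrange(.data$timepoint, .data$side, .data$direction)
}
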