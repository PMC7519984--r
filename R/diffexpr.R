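#' Two-group differential expression at one timepoint
#'
#' Computes, for every probe, the log2 fold change (treatment mean minus
#' control mean on the log2 scale) and a two-sided p-value from either a
#' pooled-variance Student t test (`student_t`) or a moderated t test
#' (`moderated_t`). The moderated test shrinks each probe's pooled
#' variance toward a prior variance estimated across all probes by the
#' method of moments (a scaled-inverse-chi-square prior), and augments
#' the degrees of freedom accordingly; with only two replicates per group
#' this stabilizes the otherwise 2-df variance estimates, which is why it
#' is the pipeline default.
#'
#' Probes with zero pooled variance (identical values in both groups)
#' get `pvalue = 1` under `student_t`; the moderated test handles them
#' through the prior.
#'
#' @param m A normalized [expr_matrix()].
#' @param control,treatment Timepoint labels of the two groups.
#' @param method `"moderated_t"` (default) or `"student_t"`.
#' @param prior_df Optional override of the estimated prior degrees of
#'   freedom for `moderated_t`; `0` recovers the plain Student t exactly.
#' @return Tibble with columns `entity_id`, `log2fc`, `pvalue`.
#' @export
compute_de <- function(m, control, treatment,
                       method = c("moderated_t", "student_t"),
                       prior_df = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  method <- match.arg(method)
  tp <- as.character(m$samples$timepoint)
  if (identical(control, treatment)) {
    mh_abort("control and treatment timepoints must differ", "config_error")
  }
  for (grp in c(control, treatment)) {
    k <- sum(tp == grp)
    if (k < 2) {
      mh_abort(sprintf("group '%s' has %d replicate(s); at least 2 required",
                       grp, k), "config_error")
    }
  }
  x <- m$values[, tp == control, drop = FALSE]
  y <- m$values[, tp == treatment, drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  lfc <- my - mx
  df <- n1 + n2 - 2
  vx <- rowSums((x - mx)^2)
  vy <- rowSums((y - my)^2)
  s2 <- (vx + vy) / df
  se_fac <- 1 / n1 + 1 / n2

  if (method == "student_t") {
    se <- sqrt(s2 * se_fac)
    tstat <- ifelse(se > 0, lfc / se, 0)
    p <- ifelse(se > 0, 2 * stats::pt(-abs(tstat), df), 1)
  } else {
    prior <- fit_variance_prior(s2, df)
    d0 <- prior_df %||% prior$prior_df
    s02 <- prior$prior_var
    if (is.infinite(d0)) {
      s2_post <- rep(s02, length(s2))
      df_post <- Inf
    } else {
      s2_post <- (d0 * s02 + df * s2) / (d0 + df)
      df_post <- d0 + df
    }
    se <- sqrt(s2_post * se_fac)
    tstat <- ifelse(se > 0, lfc / se, 0)
    p <- ifelse(se > 0, 2 * stats::pt(-abs(tstat), df_post), 1)
  }
  tibble(entity_id = rownames(m$values), log2fc = unname(lfc),
         pvalue = unname(p))
}

#' Method-of-moments fit of the variance prior
#'
#' Fits a scaled-inverse-chi-square prior to per-entity pooled variances:
#' under the model `s2 ~ s02 * F(df, prior_df)`, the squared coefficient
#' of variation of the observed variances identifies `prior_df`, and the
#' mean identifies `s02`. When the observed spread is no larger than
#' sampling noise alone explains, the prior degrees of freedom are
#' infinite and every variance shrinks to the common mean.
#'
#' @param s2 Numeric vector of pooled variances.
#' @param df Residual degrees of freedom of each variance (equal design).
#' @return List with `prior_df` and `prior_var`.
#' @export
fit_variance_prior <- function(s2, df) {
  s2 <- s2[is.finite(s2)]
  m1 <- mean(s2)
  if (length(s2) < 2 || m1 <= 0) {
    return(list(prior_df = Inf, prior_var = max(m1, .Machine$double.eps)))
  }
  cv2 <- stats::var(s2) / m1^2
  if (cv2 * df <= 2) {
    # no excess spread beyond chi-square sampling noise: complete pooling
    return(list(prior_df = Inf, prior_var = m1))
  }
  d0 <- (4 * cv2 * df + 2 * df - 4) / (cv2 * df - 2)
  if (!is.finite(d0) || d0 <= 0) {
    return(list(prior_df = Inf, prior_var = m1))
  }
  s02 <- if (d0 > 2) m1 * (d0 - 2) / d0 else m1
  list(prior_df = d0, prior_var = s02)
}

#' Per-timepoint differential expression profiles versus the control
#'
#' Runs [compute_de()] for every treatment timepoint against the control
#' and applies the significance rule of [call_de()].
#'
#' @inheritParams compute_de
#' @inheritParams call_de
#' @param control Control timepoint label (default `"0min"`).
#' @return An `mh_de` tibble, one row per (entity, timepoint); see
#'   [call_de()].
#' @export
de_profiles <- function(m, control = "0min",
                        method = c("moderated_t", "student_t"),
                        lfc_threshold = 1.0, alpha = 0.05) {
  method <- match.arg(method)
  tps <- levels(m$samples$timepoint)
  if (!control %in% tps) {
    mh_abort(sprintf("control timepoint '%s' absent from the design", control),
             "config_error")
  }
  treats <- setdiff(tps, control)
  prof <- purrr::map(treats, function(t) {
    mutate(compute_de(m, control, t, method = method), timepoint = t)
  }) |> bind_rows()
  prof$timepoint <- factor(prof$timepoint, levels = treats, ordered = TRUE)
  call_de(prof, lfc_threshold = lfc_threshold, alpha = alpha)
}

#' Call differentially expressed entities
#'
#' An entity is significant at a timepoint when `|log2fc| >=
#' lfc_threshold` (inclusive) and `pvalue < alpha` (strict), and is DE
#' overall when significant at one or more timepoints. A
#' Benjamini-Hochberg adjusted p-value column (`padj`, per timepoint) is
#' added for reference but plays no part in the calls.
#'
#' @param profiles Tibble with columns `entity_id`, `timepoint`,
#'   `log2fc`, `pvalue` (as from [compute_de()] over several timepoints).
#' @param lfc_threshold Minimum absolute log2 fold change (default 1.0).
#' @param alpha P-value cutoff, strict (default 0.05).
#' @return The input plus `padj`, `significant`, `direction` (`up`,
#'   `down` or `none` per timepoint) and `de` (per entity), with class
#'   `mh_de`.
#' @export
call_de <- function(profiles, lfc_threshold = 1.0, alpha = 0.05) {
  need <- c("entity_id", "timepoint", "log2fc", "pvalue")
  stopifnot(all(need %in% names(profiles)))
  out <- profiles |>
    group_by(.data$timepoint) |>
    mutate(padj = stats::p.adjust(.data$pvalue, method = "BH")) |>
    ungroup() |>
    mutate(significant = abs(.data$log2fc) >= lfc_threshold &
             .data$pvalue < alpha,
           direction = dplyr::case_when(
             .data$significant & .data$log2fc > 0 ~ "up",
             .data$significant & .data$log2fc < 0 ~ "down",
             TRUE ~ "none")) |>
    group_by(.data$entity_id) |>
    mutate(de = any(.data$significant)) |>
    ungroup()
  structure(out, class = c("mh_de", class(out)),
            lfc_threshold = lfc_threshold, alpha = alpha)
}

#' @export
glance.mh_de <- function(x, ...) {
  per_entity <- distinct(x, .data$entity_id, .data$de)
  tibble(n_entities = nrow(per_entity),
         n_de = sum(per_entity$de),
         lfc_threshold = attr(x, "lfc_threshold"),
         alpha = attr(x, "alpha"))
}

#' @export
tidy.mh_de <- function(x, ...) as_tibble(x)

#' Collapse a mature miRNA identifier to its family name
#'
#' Mature miRNA names follow `<prefix>-miR<number>` plus optional
#' variant letters and arm/isoform suffixes (`osa-miR169g`,
#' `osa-miR397b.2`, `ath-miR166a-5p`); family membership is carried by
#' the prefix and number alone. The mapping is idempotent.
#'
#' @param mirna_id Character vector of miRNA ids.
#' @param lenient If TRUE, ids that do not match the naming convention
#'   are passed through unchanged with a warning instead of erroring.
#' @return Character vector of family names.
#' @export
#' @examples
#' map_to_family(c("osa-miR169g", "osa-miR397b.2", "osa-miR166"))
map_to_family <- function(mirna_id, lenient = FALSE) {
  full <- "^([A-Za-z0-9]+-miR\\d+)([a-zA-Z]*)([.-].*)?$"
  ok <- grepl(full, mirna_id)
  if (!all(ok)) {
    if (lenient) {
      rlang::warn(paste0("id(s) outside the miRNA naming convention passed through: ",
                         paste(utils::head(mirna_id[!ok], 3), collapse = ", ")))
    } else {
      mh_abort(paste0("miRNA id does not match the naming convention: ",
                      mirna_id[!ok][1]), "format_error")
    }
  }
  ifelse(ok, sub(full, "\\1", mirna_id), mirna_id)
}

#' Aggregate DE miRNAs into family direction profiles
#'
#' Non-DE members are excluded first. At each timepoint a family is
#' `up` when at least one member is significantly up and none down,
#' `down` symmetrically, `conflict` when both occur and `none` when
#' neither. The overall family direction is `up` (`down`) when every
#' significant member call at every timepoint agrees, and `up_down` when
#' members disagree anywhere.
#'
#' @param de_calls An `mh_de` table of miRNA entities (see [call_de()]).
#' @param families Optional tibble `entity_id`, `family`; by default
#'   families are derived from the ids with [map_to_family()].
#' @param lenient Passed to [map_to_family()].
#' @return An `mh_family_profiles` tibble: one row per (family,
#'   timepoint) with `direction`, plus `overall_direction`, `n_members`
#'   and the comma-separated member ids.
#' @export
aggregate_families <- function(de_calls, families = NULL, lenient = FALSE) {
  de_only <- filter(de_calls, .data$de)
  if (nrow(de_only) == 0) {
    mh_abort("no DE miRNAs to aggregate", "empty_error")
  }
  if (is.null(families)) {
    families <- tibble(entity_id = unique(de_only$entity_id)) |>
      mutate(family = map_to_family(.data$entity_id, lenient = lenient))
  }
  joined <- inner_join(de_only, families, by = "entity_id")
  if (nrow(joined) == 0) mh_abort("family map covers no DE miRNA", "empty_error")

  per_tp <- joined |>
    group_by(.data$family, .data$timepoint) |>
    summarise(any_up = any(.data$direction == "up"),
              any_down = any(.data$direction == "down"),
              .groups = "drop") |>
    mutate(direction = dplyr::case_when(
      .data$any_up & .data$any_down ~ "conflict",
      .data$any_up ~ "up",
      .data$any_down ~ "down",
      TRUE ~ "none")) |>
    select("family", "timepoint", "direction")

  overall <- joined |>
    group_by(.data$family) |>
    summarise(
      n_members = n_distinct(.data$entity_id),
      members = paste(sort(unique(.data$entity_id)), collapse = ","),
      any_up = any(.data$direction == "up"),
      any_down = any(.data$direction == "down"),
      .groups = "drop") |>
    mutate(overall_direction = dplyr::case_when(
      .data$any_up & .data$any_down ~ "up_down",
      .data$any_up ~ "up",
      TRUE ~ "down")) |>
    select("family", "overall_direction", "n_members", "members")

  out <- left_join(per_tp, overall, by = "family") |>
    arrange(.data$family, .data$timepoint)
  structure(out, class = c("mh_family_profiles", class(out)))
}

#' @export
glance.mh_family_profiles <- function(x, ...) {
  ov <- distinct(as_tibble(x), .data$family, .data$overall_direction)
  tibble(n_families = nrow(ov),
         n_up = sum(ov$overall_direction == "up"),
         n_down = sum(ov$overall_direction == "down"),
         n_up_down = sum(ov$overall_direction == "up_down"))
}

#' Overall direction of each entity across the time course
#'
#' Applies the family direction rule to single entities: `up` when all
#' significant calls are up, `down` when all are down, `up_down` when
#' both occur. Entities with no significant call are dropped.
#'
#' @param de_calls An `mh_de` table.
#' @return Tibble `entity_id`, `overall_direction`.
#' @export
overall_directions <- function(de_calls) {
  de_calls |>
    filter(.data$de) |>
    group_by(.data$entity_id) |>
    summarise(any_up = any(.data$direction == "up"),
              any_down = any(.data$direction == "down"),
              .groups = "drop") |>
    mutate(overall_direction = dplyr::case_when(
      .data$any_up & .data$any_down ~ "up_down",
      .data$any_up ~ "up",
      TRUE ~ "down")) |>
    select("entity_id", "overall_direction")
}
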