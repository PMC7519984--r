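# run code under a local RNG state seeded from one integer, restoring
# the caller's state afterwards; all simulator randomness flows through
# this so the generator has no global side effects
with_rng_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults emulate the array study the package models: five timepoints
#' (a 0-min control and 10 min / 20 min / 60 min / 2 h of heat), two
#' replicates per timepoint (ten arrays), log2 baselines uniform on
#' [6, 14], a planted log2 effect of 2.0 against replicate noise of sd
#' 0.2, and a ramp effect profile that reaches full size at the last
#' timepoint, mirroring differential-expression counts that grow toward
#' 2 h. 150 miRNA and 1850 mRNA probes (2000 entities) keep a full
#' simulated run at desk scale.
#'
#' @param n_mirnas,n_genes Number of miRNA and mRNA probes.
#' @param timepoints Ordered timepoint labels; the first is the control.
#' @param n_replicates Replicates per timepoint.
#' @param frac_de_mirnas,frac_de_genes Fractions of entities planted as
#'   differentially expressed.
#' @param effect_size Planted absolute log2 effect at full strength.
#' @param noise_sd Replicate noise sd, log2 units.
#' @param frac_anticorrelated_pairs Fraction of DE genes planted as
#'   anti-correlated targets of a DE miRNA family.
#' @param flag_dropout Probability that a cell below
#'   `dropout_threshold` log2 units is flagged absent.
#' @param dropout_threshold Intensity below which dropout can occur.
#' @param effect_profile `"ramp"` (effect grows linearly over the
#'   treatment timepoints) or `"step"` (full effect at every one).
#' @param baseline_range Range of per-probe log2 baselines.
#' @param mirna_length,transcript_length Sequence lengths for the
#'   sequence generator.
#' @param n_ppi_modules,ppi_module_size,n_ppi_background Planted PPI
#'   module count and size, and number of background edges.
#' @param seed Integer seed; mandatory, all randomness derives from it.
#' @return A validated `mh_sim_config` list.
#' @export
simulation_config <- function(n_mirnas = 150, n_genes = 1850,
                              timepoints = heat_timepoints(),
                              n_replicates = 2,
                              frac_de_mirnas = 0.10, frac_de_genes = 0.10,
                              effect_size = 2.0, noise_sd = 0.2,
                              frac_anticorrelated_pairs = 0.30,
                              flag_dropout = 0.30, dropout_threshold = 7,
                              effect_profile = c("ramp", "step"),
                              baseline_range = c(6, 14),
                              mirna_length = 21, transcript_length = 500,
                              n_ppi_modules = 2, ppi_module_size = 4,
                              n_ppi_background = 100,
                              seed) {
  if (missing(seed) || is.null(seed)) {
    mh_abort("a seed is mandatory for reproducibility", "config_error")
  }
  effect_profile <- match.arg(effect_profile)
  fracs <- c(frac_de_mirnas, frac_de_genes, frac_anticorrelated_pairs,
             flag_dropout)
  if (any(fracs < 0 | fracs > 1)) {
    mh_abort("fractions must lie in [0, 1]", "config_error")
  }
  stopifnot(n_mirnas >= 1, n_genes >= 1, n_replicates >= 1,
            noise_sd > 0, length(timepoints) >= 2,
            mirna_length >= 15, transcript_length > mirna_length)
  structure(list(
    n_mirnas = as.integer(n_mirnas), n_genes = as.integer(n_genes),
    timepoints = timepoints, n_replicates = as.integer(n_replicates),
    frac_de_mirnas = frac_de_mirnas, frac_de_genes = frac_de_genes,
    effect_size = effect_size, noise_sd = noise_sd,
    frac_anticorrelated_pairs = frac_anticorrelated_pairs,
    flag_dropout = flag_dropout, dropout_threshold = dropout_threshold,
    effect_profile = effect_profile, baseline_range = baseline_range,
    mirna_length = as.integer(mirna_length),
    transcript_length = as.integer(transcript_length),
    n_ppi_modules = as.integer(n_ppi_modules),
    ppi_module_size = as.integer(ppi_module_size),
    n_ppi_background = as.integer(n_ppi_background),
    seed = as.integer(seed)), class = "mh_sim_config")
}

# miRNA family structure: families of 1-2 members named sim-miR<k><letter>
sim_family_table <- function(cfg) {
  sizes <- integer(0)
  k <- 0
  while (sum(sizes) < cfg$n_mirnas) {
    k <- k + 1
    sizes[k] <- sample(c(1L, 1L, 2L), 1)
  }
  over <- sum(sizes) - cfg$n_mirnas
  if (over > 0) sizes[k] <- sizes[k] - over
  sizes <- sizes[sizes > 0]
  purrr::imap(sizes, function(sz, fk) {
    tibble(family = sprintf("sim-miR%d", fk),
           mirna_id = sprintf("sim-miR%d%s", fk, letters[seq_len(sz)]))
  }) |> bind_rows()
}

#' Simulate a joint miRNA/mRNA expression matrix with ground truth
#'
#' Each entity gets a uniform log2 baseline; planted DE entities add a
#' signed effect profile over the treatment timepoints (ramp or step);
#' replicate noise is Gaussian. Planted anti-correlated pairs tie a DE
#' gene to a DE miRNA family of opposite sign, so the two sides are
#' significant with opposite directions at every shared timepoint where
#' the effect clears the thresholds. Cells below the dropout threshold
#' are flagged absent with the configured probability, all others are
#' present. All members of a DE family share the family's effect, so
#' families aggregate to a clean direction.
#'
#' @param cfg A [simulation_config()].
#' @return List with `matrix` (an [expr_matrix()] with flags and probe
#'   types) and `truth` (DE sets with signed effects, planted pairs,
#'   the family table, and per-timepoint effects).
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "mh_sim_config"))
  with_rng_seed(cfg$seed, {
    fams <- sim_family_table(cfg)
    gene_ids <- sprintf("gene_%04d", seq_len(cfg$n_genes))
    treats <- cfg$timepoints[-1]
    mult <- if (cfg$effect_profile == "ramp") {
      seq_along(treats) / length(treats)
    } else rep(1, length(treats))

    # DE families: pick families until ~frac_de_mirnas of miRNAs covered,
    # alternating signs so both directions exist for pairing
    n_de_mir <- round(cfg$frac_de_mirnas * cfg$n_mirnas)
    fam_order <- sample(unique(fams$family))
    de_fams <- character(0); covered <- 0
    for (f in fam_order) {
      if (covered >= n_de_mir) break
      de_fams <- c(de_fams, f)
      covered <- covered + sum(fams$family == f)
    }
    fam_sign <- stats::setNames(rep(c(1, -1), length.out = length(de_fams)),
                                de_fams)
    de_mirnas <- fams |>
      filter(.data$family %in% de_fams) |>
      mutate(sign = unname(fam_sign[.data$family]))

    n_de_gene <- round(cfg$frac_de_genes * cfg$n_genes)
    de_gene_ids <- sample(gene_ids, n_de_gene)
    gene_sign <- rep(c(-1, 1), length.out = n_de_gene)

    # planted anti-correlated pairs: DE genes tied to an opposite-signed
    # DE family
    n_pairs <- round(cfg$frac_anticorrelated_pairs * n_de_gene)
    pairs <- tibble(family = character(), mirna_id = character(),
                    gene_id = character(), family_sign = double(),
                    gene_sign = double())
    if (n_pairs > 0 && length(de_fams) > 0) {
      pool_up <- de_fams[fam_sign[de_fams] > 0]
      pool_down <- de_fams[fam_sign[de_fams] < 0]
      sel <- seq_len(n_pairs)
      pf <- character(n_pairs)
      for (i in sel) {
        pool <- if (gene_sign[i] < 0) pool_up else pool_down
        if (length(pool) == 0) pool <- de_fams
        pf[i] <- pool[(i - 1) %% length(pool) + 1]
      }
      members <- split(fams$mirna_id, fams$family)
      pairs <- tibble(
        family = pf,
        mirna_id = purrr::map_chr(pf, ~ members[[.x]][1]),
        gene_id = de_gene_ids[sel],
        family_sign = unname(fam_sign[pf]),
        gene_sign = gene_sign[sel])
      ok <- pairs$family_sign != pairs$gene_sign
      pairs <- pairs[ok, ]
    }

    ids <- c(fams$mirna_id, gene_ids)
    n_ent <- length(ids)
    sign_vec <- stats::setNames(rep(0, n_ent), ids)
    sign_vec[de_mirnas$mirna_id] <- de_mirnas$sign
    sign_vec[de_gene_ids] <- gene_sign

    reps <- seq_len(cfg$n_replicates)
    samples <- tidyr::expand_grid(timepoint = cfg$timepoints,
                                  replicate = reps) |>
      mutate(sample_id = sprintf("%s_r%d", .data$timepoint,
                                 .data$replicate)) |>
      select("sample_id", "timepoint", "replicate")

    eff_tp <- stats::setNames(c(0, mult * cfg$effect_size), cfg$timepoints)
    baseline <- stats::runif(n_ent, cfg$baseline_range[1],
                             cfg$baseline_range[2])
    vals <- matrix(0, n_ent, nrow(samples),
                   dimnames = list(ids, samples$sample_id))
    for (s in seq_len(nrow(samples))) {
      mu <- baseline + sign_vec * eff_tp[samples$timepoint[s]]
      vals[, s] <- mu + stats::rnorm(n_ent, 0, cfg$noise_sd)
    }
    low <- vals < cfg$dropout_threshold
    absent <- low & matrix(stats::runif(length(vals)) < cfg$flag_dropout,
                           nrow(vals))
    flags <- matrix(ifelse(absent, "A", "P"), nrow(vals),
                    dimnames = dimnames(vals))
    probe_type <- stats::setNames(
      c(rep("mirna", nrow(fams)), rep("gene", cfg$n_genes)), ids)

    m <- expr_matrix(vals, samples, flags = flags, probe_type = probe_type,
                     timepoint_levels = cfg$timepoints)
    effects <- tidyr::expand_grid(entity_id = ids, timepoint = treats) |>
      mutate(effect = sign_vec[.data$entity_id] *
               eff_tp[.data$timepoint])
    truth <- list(
      families = fams,
      de_mirnas = rename(de_mirnas, entity_id = "mirna_id"),
      de_genes = tibble(entity_id = de_gene_ids, sign = gene_sign),
      pairs = pairs,
      effects = effects,
      baselines = tibble(entity_id = ids, baseline = baseline))
    list(matrix = m, truth = truth)
  })
}

#' Construct a target site with a chosen expectation and mode
#'
#' Starts from the perfect reverse complement of the miRNA and plants
#' defects whose penalties sum exactly to `expectation` under the
#' scheme: seed-region mismatches cost 2, non-seed mismatches 1,
#' non-seed wobbles 0.5 (wobbles are only available where the miRNA has
#' a G or U outside the seed). For `mode = "translation_inhibition"` the
#' first seed mismatch is placed on a central position; for cleavage the
#' central positions are left intact.
#'
#' @param mirna miRNA sequence (RNA, 5'->3').
#' @param expectation Intended expectation penalty (multiple of 0.5).
#' @param mode Intended regulation mode.
#' @param scheme A [scoring_scheme()].
#' @return The site sequence (RNA, 5'->3') scoring exactly
#'   `expectation`; errors when the request is infeasible for this
#'   miRNA.
#' @export
make_target_site <- function(mirna, expectation = 0,
                             mode = c("cleavage", "translation_inhibition"),
                             scheme = scoring_scheme()) {
  mode <- match.arg(mode)
  mirna <- chartr("tT", "uU", toupper(mirna))
  L <- nchar(mirna)
  mb <- strsplit(mirna, "")[[1]]
  site <- strsplit(rna_revcomp(mirna), "")[[1]]  # site 5'->3'
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  wob <- c(G = "U", U = "G", A = NA, C = NA)
  site_idx <- function(p) L - p + 1  # miRNA pos -> site index (gapless)
  mismatch_base <- function(p) {
    avoid <- c(comp[[mb[p]]], wob[[mb[p]]])
    setdiff(c("A", "C", "G", "U"), avoid[!is.na(avoid)])[1]
  }
  if (expectation < 0 || (expectation * 2) %% 1 != 0) {
    mh_abort("expectation must be a non-negative multiple of 0.5",
             "config_error")
  }
  seed_pos <- setdiff(seq(scheme$seed_from, min(scheme$seed_to, L)),
                      scheme$central)
  nonseed_pos <- setdiff(seq_len(L),
                         seq(scheme$seed_from, min(scheme$seed_to, L)))
  used <- integer(0)
  budget <- expectation
  if (mode == "translation_inhibition") {
    p <- scheme$central[1]
    if (budget < 2) {
      mh_abort("translation-inhibition sites need expectation >= 2 (a central mismatch)",
               "config_error")
    }
    site[site_idx(p)] <- mismatch_base(p)
    used <- c(used, p)
    budget <- budget - 2
  }
  while (budget >= 2 && length(setdiff(seed_pos, used)) > 0) {
    p <- setdiff(seed_pos, used)[1]
    site[site_idx(p)] <- mismatch_base(p)
    used <- c(used, p); budget <- budget - 2
  }
  while (budget >= 1 && length(setdiff(nonseed_pos, used)) > 0) {
    p <- setdiff(nonseed_pos, used)[1]
    site[site_idx(p)] <- mismatch_base(p)
    used <- c(used, p); budget <- budget - 1
  }
  if (budget > 0) {
    cand <- setdiff(nonseed_pos, used)
    cand <- cand[mb[cand] %in% c("G", "U")]
    if (budget != 0.5 || length(cand) == 0) {
      mh_abort(sprintf("cannot construct a site with expectation %g for this miRNA",
                       expectation), "config_error")
    }
    p <- cand[1]
    site[site_idx(p)] <- wob[[mb[p]]]
    used <- c(used, p); budget <- 0
  }
  paste(site, collapse = "")
}

#' Simulate miRNA and transcript sequences with planted target sites
#'
#' Generates random miRNA sequences (family members differ by one
#' substitution outside the seed region) and random transcripts. Every
#' planted anti-correlated pair from the expression ground truth gets a
#' target site of its member miRNA embedded in the gene's transcript at
#' a recorded position, built by [make_target_site()] with an intended
#' expectation at most the cutoff; a set of decoy genes receives
#' near-sites constructed to score at least `decoy_margin` above the
#' cutoff, which the scanner must never report.
#'
#' @param cfg A [simulation_config()].
#' @param truth Ground truth from [simulate_expression()].
#' @param cutoff Prediction cutoff the sites are planted against.
#' @param n_decoys Number of decoy genes (default 20, capped by the
#'   available non-target genes).
#' @param decoy_margin How far above the cutoff decoy sites score.
#' @return List with `mirnas`, `transcripts` (named vectors), `sites`
#'   (planted site table) and `decoys`.
#' @export
simulate_sequences <- function(cfg, truth, cutoff = 3, n_decoys = 20,
                               decoy_margin = 0.5) {
  stopifnot(inherits(cfg, "mh_sim_config"))
  with_rng_seed(cfg$seed + 1L, {
    fams <- truth$families
    L <- cfg$mirna_length
    scheme <- scoring_scheme()
    rand_seq <- function(n) {
      paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
    }
    fam_seed <- stats::setNames(
      purrr::map_chr(unique(fams$family), ~ rand_seq(L)),
      unique(fams$family))
    nonseed <- setdiff(seq_len(L), seq(scheme$seed_from,
                                       min(scheme$seed_to, L)))
    mirnas <- purrr::map2_chr(fams$mirna_id, fams$family, function(mid, f) {
      s <- strsplit(fam_seed[[f]], "")[[1]]
      nth <- match(mid, fams$mirna_id[fams$family == f])
      if (nth > 1) {  # later members: one non-seed substitution
        p <- nonseed[1 + (nth - 2) %% length(nonseed)]
        s[p] <- sample(setdiff(c("A", "C", "G", "U"), s[p]), 1)
      }
      paste(s, collapse = "")
    })
    names(mirnas) <- fams$mirna_id

    gene_ids <- sprintf("gene_%04d", seq_len(cfg$n_genes))
    transcripts <- stats::setNames(
      purrr::map_chr(gene_ids, ~ rand_seq(cfg$transcript_length)), gene_ids)

    site_rows <- list()
    if (nrow(truth$pairs) > 0) {
      exp_pool <- c(0, 1, 2)
      mode_pool <- c(rep("cleavage", 4), "translation_inhibition")
      for (i in seq_len(nrow(truth$pairs))) {
        pr <- truth$pairs[i, ]
        mode <- sample(mode_pool, 1)
        e <- if (mode == "translation_inhibition") 2 else sample(exp_pool, 1)
        site <- make_target_site(mirnas[[pr$mirna_id]], e, mode)
        tx <- transcripts[[pr$gene_id]]
        start <- sample.int(cfg$transcript_length - nchar(site) + 1, 1)
        substr(tx, start, start + nchar(site) - 1) <- site
        transcripts[[pr$gene_id]] <- tx
        site_rows[[i]] <- tibble(
          mirna_id = pr$mirna_id, family = pr$family, gene_id = pr$gene_id,
          start = start, intended_expectation = e, intended_mode = mode)
      }
    }
    sites <- bind_rows(site_rows)

    decoy_pool <- setdiff(gene_ids, truth$pairs$gene_id)
    n_decoys <- min(n_decoys, length(decoy_pool))
    decoy_rows <- list()
    if (n_decoys > 0 && nrow(fams) > 0) {
      decoy_genes <- sample(decoy_pool, n_decoys)
      for (i in seq_len(n_decoys)) {
        mid <- fams$mirna_id[1 + (i - 1) %% nrow(fams)]
        # two seed mismatches beyond the cutoff: expectation cutoff+margin,
        # rounded up to a reachable multiple of 0.5
        e <- ceiling((cutoff + decoy_margin) * 2) / 2
        e <- 2 * ceiling(e / 2)  # seed mismatches only: multiples of 2
        site <- make_target_site(mirnas[[mid]], e, "cleavage")
        tx <- transcripts[[decoy_genes[i]]]
        start <- sample.int(cfg$transcript_length - nchar(site) + 1, 1)
        substr(tx, start, start + nchar(site) - 1) <- site
        transcripts[[decoy_genes[i]]] <- tx
        decoy_rows[[i]] <- tibble(mirna_id = mid, gene_id = decoy_genes[i],
                                  start = start, intended_expectation = e)
      }
    }
    list(mirnas = mirnas, transcripts = transcripts, sites = sites,
         decoys = bind_rows(decoy_rows))
  })
}

#' Simulate a PPI edge table with planted modules
#'
#' Module genes are drawn from the planted target genes so the modules
#' surface in the assembled network; every within-module pair scores
#' uniform on [0.75, 0.99] and background pairs uniform on [0, 0.65],
#' so a 0.7 cutoff separates them with margin.
#'
#' @param cfg A [simulation_config()].
#' @param truth Ground truth from [simulate_expression()].
#' @return List with `edges` (tibble `protein_a`, `protein_b`,
#'   `combined_score`) and `modules` (tibble `module`, `gene_id`).
#' @export
simulate_ppi <- function(cfg, truth) {
  stopifnot(inherits(cfg, "mh_sim_config"))
  with_rng_seed(cfg$seed + 2L, {
    # module genes come from planted pairs whose probes sit far enough
    # above the dropout threshold that the flag filter cannot remove
    # either side, keeping planted modules recoverable by construction
    base <- stats::setNames(truth$baselines$baseline,
                            truth$baselines$entity_id)
    safe <- function(id, sign) {
      min_mu <- base[[id]] + min(0, sign * cfg$effect_size)
      min_mu - 6 * cfg$noise_sd > cfg$dropout_threshold
    }
    pr <- truth$pairs
    safe_pair <- if (nrow(pr)) {
      purrr::map_lgl(seq_len(nrow(pr)),
                     function(i) safe(pr$gene_id[i], pr$gene_sign[i]))
    } else logical(0)
    pool <- unique(pr$gene_id[safe_pair])
    need <- cfg$n_ppi_modules * cfg$ppi_module_size
    if (length(pool) < need) pool <- unique(pr$gene_id)
    if (cfg$n_ppi_modules > 0 && length(pool) < need) {
      mh_abort(sprintf("need %d planted target genes for %d module(s), have %d",
                       need, cfg$n_ppi_modules, length(pool)),
               "config_error")
    }
    modules <- tibble(module = integer(), gene_id = character())
    edge_rows <- list()
    if (cfg$n_ppi_modules > 0) {
      picked <- sample(pool, need)
      modules <- tibble(
        module = rep(seq_len(cfg$n_ppi_modules), each = cfg$ppi_module_size),
        gene_id = picked)
      for (mnum in seq_len(cfg$n_ppi_modules)) {
        gs <- sort(modules$gene_id[modules$module == mnum])
        cmb <- utils::combn(gs, 2)
        edge_rows[[length(edge_rows) + 1]] <- tibble(
          protein_a = cmb[1, ], protein_b = cmb[2, ],
          combined_score = stats::runif(ncol(cmb), 0.75, 0.99))
      }
    }
    all_genes <- sprintf("gene_%04d", seq_len(cfg$n_genes))
    if (cfg$n_ppi_background > 0) {
      a <- sample(all_genes, cfg$n_ppi_background, replace = TRUE)
      b <- sample(all_genes, cfg$n_ppi_background, replace = TRUE)
      keep <- a != b
      # background pairs must not duplicate a within-module pair
      in_mod <- paste(pmin(a, b), pmax(a, b)) %in%
        (if (nrow(modules) > 0) {
          unlist(purrr::map(split(modules$gene_id, modules$module),
                            function(gs) {
                              cmb <- utils::combn(sort(gs), 2)
                              paste(cmb[1, ], cmb[2, ])
                            }))
        } else character(0))
      keep <- keep & !in_mod
      edge_rows[[length(edge_rows) + 1]] <- tibble(
        protein_a = a[keep], protein_b = b[keep],
        combined_score = stats::runif(sum(keep), 0, 0.65))
    }
    edges <- bind_rows(edge_rows)
    if (nrow(edges) > 0) {
      a <- pmin(edges$protein_a, edges$protein_b)
      b <- pmax(edges$protein_a, edges$protein_b)
      edges$protein_a <- a; edges$protein_b <- b
      edges <- edges |>
        group_by(.data$protein_a, .data$protein_b) |>
        summarise(combined_score = max(.data$combined_score),
                  .groups = "drop")
    }
    list(edges = edges, modules = modules)
  })
}

#' Simulate a complete study
#'
#' Convenience wrapper running [simulate_expression()],
#' [simulate_sequences()] and [simulate_ppi()] from one config.
#'
#' @param cfg A [simulation_config()].
#' @return List `matrix`, `truth`, `seqs`, `ppi`.
#' @export
simulate_study <- function(cfg) {
  expr <- simulate_expression(cfg)
  seqs <- simulate_sequences(cfg, expr$truth)
  ppi <- simulate_ppi(cfg, expr$truth)
  truth <- expr$truth
  truth$sites <- seqs$sites
  truth$decoys <- seqs$decoys
  truth$ppi_modules <- ppi$modules
  list(matrix = expr$matrix, truth = truth, seqs = seqs, ppi = ppi)
}
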