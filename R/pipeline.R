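default_config <- function() {
  list(
    seed = NULL,
    mode = "simulate",            # simulate | files | fixture
    outdir = NULL,
    simulate = list(
      n_mirnas = 150, n_genes = 1850, timepoints = heat_timepoints(),
      n_replicates = 2, frac_de_mirnas = 0.10, frac_de_genes = 0.10,
      effect_size = 2.0, noise_sd = 0.2, frac_anticorrelated_pairs = 0.30,
      flag_dropout = 0.30, dropout_threshold = 7, effect_profile = "ramp",
      baseline_range = c(6, 14), mirna_length = 21, transcript_length = 500,
      n_ppi_modules = 2, ppi_module_size = 4, n_ppi_background = 100),
    input = list(
      expression = NULL, flags = NULL, sample_sheet = NULL,
      probe_types = NULL, mirna_fasta = NULL, transcript_fasta = NULL,
      ppi = NULL, ppi_score_scale = "unit", goslim = NULL, ogro = NULL,
      table1 = NULL, table2 = NULL),
    preprocess = list(min_present = NULL, log_floor = 1.0,
                      log2_input = TRUE),
    de = list(method = "moderated_t", lfc_threshold = 1.0, alpha = 0.05,
              control_timepoint = "0min"),
    targets = list(cutoff = 3.0, max_gaps = 1),
    pairing = list(mode = "strict"),
    network = list(min_ppi_score = 0.7)
  )
}

# recursive merge keeping every default key; unknown user keys error
# with their dotted path
merge_config <- function(def, user, path = "") {
  for (nm in names(user)) {
    key <- if (path == "") nm else paste0(path, ".", nm)
    if (!nm %in% names(def)) {
      mh_abort(paste0("unknown config key: ", key), "config_error")
    }
    if (is.list(def[[nm]]) && !is.null(names(def[[nm]]))) {
      if (!is.list(user[[nm]])) {
        mh_abort(paste0("config key ", key, " must be a section"),
                 "config_error")
      }
      def[[nm]] <- merge_config(def[[nm]], user[[nm]], key)
    } else {
      def[nm] <- list(user[[nm]])
    }
  }
  def
}

#' Validate and normalize a pipeline configuration
#'
#' Accepts a YAML file path or a nested list, rejects unknown keys
#' (naming the dotted key path), fills every documented default, and
#' returns the normalized config. Normalization is idempotent. A seed
#' is required.
#'
#' @param config Path to a YAML config or a nested list.
#' @return Normalized config list of class `mh_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config <- unclass(config)
  cfg <- merge_config(default_config(), config)
  if (is.null(cfg$seed) && cfg$mode != "fixture") {
    mh_abort("config requires a seed", "config_error")
  }
  if (!cfg$mode %in% c("simulate", "files", "fixture")) {
    mh_abort("mode must be simulate, files or fixture", "config_error")
  }
  structure(cfg, class = "mh_config")
}

write_tsv_artifact <- function(df, dir, name) {
  df <- as_tibble(df)
  # flatten list columns for serialization
  for (cn in names(df)) {
    if (is.list(df[[cn]])) {
      df[[cn]] <- purrr::map_chr(df[[cn]], paste, collapse = ",")
    }
    if (is.factor(df[[cn]])) df[[cn]] <- as.character(df[[cn]])
  }
  readr::write_tsv(df, file.path(dir, name), progress = FALSE)
  name
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    mh_abort(paste0("pipeline stage '", stage, "' failed: ",
                    conditionMessage(e)), "stage_error")
  })
}

#' Run the full analysis pipeline
#'
#' Executes preprocess, differential expression, family aggregation,
#' target prediction, anti-correlation pairing, network construction,
#' module discovery and annotation, and writes every result table and
#' network plus a manifest to `outdir`. In `simulate` mode the inputs
#' come from the seeded generator; in `files` mode from the configured
#' paths; `fixture` mode bypasses expression processing and drives
#' pairing, network and annotation directly from the packaged
#' high-confidence pair and characterized-gene tables (the in-study
#' summaries are then reproduced offline).
#'
#' @param config A YAML path or config list (see [validate_config()]).
#' @param outdir Output directory (overrides the config's `outdir`).
#' @return Invisibly, a list with the main result objects and the
#'   manifest.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  cfg <- validate_config(config)
  outdir <- outdir %||% cfg$outdir
  if (is.null(outdir)) mh_abort("an output directory is required", "config_error")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  if (cfg$mode == "fixture") {
    return(invisible(run_fixture_pipeline(cfg, outdir)))
  }

  if (cfg$mode == "simulate") {
    sim_cfg <- run_stage("simulate", do.call(simulation_config,
      c(cfg$simulate, list(seed = cfg$seed))))
    study <- run_stage("simulate", simulate_study(sim_cfg))
    m <- study$matrix
    mirnas <- study$seqs$mirnas
    transcripts <- study$seqs$transcripts
    ppi <- study$ppi$edges
    goslim <- NULL; ogro <- NULL
  } else {
    inp <- cfg$input
    m <- run_stage("read", read_expression_matrix(
      inp$expression, inp$sample_sheet, flag_path = inp$flags,
      probe_type_path = inp$probe_types))
    mirnas <- if (!is.null(inp$mirna_fasta)) read_fasta(inp$mirna_fasta)
    transcripts <- if (!is.null(inp$transcript_fasta)) read_fasta(inp$transcript_fasta)
    ppi <- if (!is.null(inp$ppi)) read_ppi_edges(inp$ppi, inp$ppi_score_scale)
    goslim <- if (!is.null(inp$goslim)) read_goslim_table(inp$goslim)
    ogro <- if (!is.null(inp$ogro)) read_ogro_table(inp$ogro)
    study <- NULL
  }

  m <- run_stage("preprocess", preprocess_matrix(
    m, min_present = cfg$preprocess$min_present,
    log2_input = cfg$preprocess$log2_input,
    log_floor = cfg$preprocess$log_floor))
  parts <- run_stage("preprocess", split_by_probe_type(m))

  de_mir <- run_stage("diffexpr", de_profiles(
    parts$mirna, control = cfg$de$control_timepoint,
    method = cfg$de$method, lfc_threshold = cfg$de$lfc_threshold,
    alpha = cfg$de$alpha))
  de_gene <- run_stage("diffexpr", de_profiles(
    parts$gene, control = cfg$de$control_timepoint,
    method = cfg$de$method, lfc_threshold = cfg$de$lfc_threshold,
    alpha = cfg$de$alpha))
  fams <- run_stage("family", aggregate_families(de_mir))

  de_mir_ids <- unique(filter(de_mir, .data$de)$entity_id)
  predictions <- run_stage("targets", predict_targets(
    mirnas[names(mirnas) %in% de_mir_ids], transcripts,
    cutoff = cfg$targets$cutoff, max_gaps = cfg$targets$max_gaps))

  cand <- run_stage("pairing", candidate_pairs(predictions, fams, de_gene))
  hc <- run_stage("pairing", high_confidence_pairs(
    cand, fams, de_gene, mode = cfg$pairing$mode))
  hc_gene_calls <- filter(de_gene, .data$entity_id %in% hc$gene_id)
  counts <- run_stage("pairing", timecourse_counts(de_mir, hc_gene_calls))

  net <- run_stage("network", build_mirna_ppi_network(
    hc, ppi_edges = ppi, min_ppi_score = cfg$network$min_ppi_score))
  modules <- run_stage("network", find_coregulatory_modules(net))
  bip <- run_stage("network", build_family_stress_bipartite(fams))
  deg <- run_stage("network", degree_report(net))

  art <- c(
    write_tsv_artifact(as_tibble(de_mir), outdir, "de_mirnas.tsv"),
    write_tsv_artifact(as_tibble(de_gene), outdir, "de_genes.tsv"),
    write_tsv_artifact(as_tibble(fams), outdir, "family_profiles.tsv"),
    write_tsv_artifact(predictions, outdir, "predictions.tsv"),
    write_tsv_artifact(as_tibble(hc), outdir, "hc_pairs.tsv"),
    write_tsv_artifact(counts, outdir, "timecourse_counts.tsv"),
    write_tsv_artifact(modules, outdir, "modules.tsv"),
    write_tsv_artifact(deg, outdir, "degree_report.tsv"))
  write_network(net, file.path(outdir, "network.graphml"), "graphml")
  write_network(net, file.path(outdir, "network.sif"), "sif")
  write_network(bip, file.path(outdir, "family_stress.graphml"), "graphml")
  art <- c(art, "network.graphml", "network.sif", "family_stress.graphml")

  annots <- list()
  if (!is.null(goslim)) {
    annots$goslim <- goslim_counts(unique(hc$gene_id), goslim)
    art <- c(art, write_tsv_artifact(annots$goslim, outdir, "goslim_counts.tsv"))
  }
  if (!is.null(ogro)) {
    annots$ogro <- ogro_lookup(unique(hc$gene_id), ogro)
    art <- c(art, write_tsv_artifact(annots$ogro, outdir, "ogro_hits.tsv"))
  }
  manifest <- write_manifest(cfg, outdir, art)
  invisible(list(matrix = m, de_mirnas = de_mir, de_genes = de_gene,
                 family_profiles = fams, predictions = predictions,
                 hc_pairs = hc, timecourse_counts = counts,
                 network = net, modules = modules, bipartite = bip,
                 degree_report = deg, annotations = annots,
                 truth = if (!is.null(study)) study$truth,
                 manifest = manifest))
}

write_manifest <- function(cfg, outdir, artifacts) {
  files <- sort(artifacts)
  sums <- unname(tools::md5sum(file.path(outdir, files)))
  manifest <- list(
    package = "mirheat",
    version = as.character(utils::packageVersion("mirheat")),
    seed = cfg$seed,
    config = unclass(cfg),
    artifacts = stats::setNames(as.list(sums), files))
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  manifest
}

#' Reproduce the fixture-table summaries
#'
#' Drives pairing, network assembly and annotation directly from the
#' packaged transcriptions of the study's high-confidence pair table
#' and characterized-gene table: counts the DE miRNA families and
#' distinct high-confidence target genes, builds the family-gene
#' network and its degree report, and joins the genes against the
#' characterized-gene records.
#'
#' @param table1 Path to the family/target direction TSV; default the
#'   packaged transcription.
#' @param table2 Path to the characterized-gene TSV; default packaged.
#' @return List with `records`, `hc_pairs`, `network`, `degree_report`,
#'   `ogro_hits`, and a one-row `summary` tibble (`n_families`,
#'   `n_target_genes`, `max_target_count`, `top_family`,
#'   `n_characterized_loci`).
#' @export
run_fixture_analysis <- function(
    table1 = system.file("extdata", "table1_hc_pairs.tsv", package = "mirheat"),
    table2 = system.file("extdata", "table2_ogro.tsv", package = "mirheat")) {
  records <- read_family_targets(table1)
  ogro <- read_ogro_table(table2)
  hc <- records |>
    rename(family_overall = "family_direction",
           gene_overall = "gene_direction") |>
    mutate(mode = "cleavage", supporting_timepoints = "")
  net <- build_mirna_ppi_network(hc)
  deg <- degree_report(net)
  hits <- ogro_lookup(unique(hc$gene_id), ogro)
  top <- filter(deg, .data$type == "family") |>
    arrange(dplyr::desc(.data$target_count), .data$node)
  summary <- tibble(
    n_families = n_distinct(hc$family),
    n_target_genes = n_distinct(hc$gene_id),
    max_target_count = top$target_count[1],
    top_family = top$node[1],
    n_characterized_loci = attr(hits, "n_characterized"))
  list(records = records, hc_pairs = hc, network = net,
       degree_report = deg, ogro_hits = hits, summary = summary)
}

run_fixture_pipeline <- function(cfg, outdir) {
  t1 <- cfg$input$table1 %||%
    system.file("extdata", "table1_hc_pairs.tsv", package = "mirheat")
  t2 <- cfg$input$table2 %||%
    system.file("extdata", "table2_ogro.tsv", package = "mirheat")
  res <- run_fixture_analysis(t1, t2)
  art <- c(
    write_tsv_artifact(res$hc_pairs, outdir, "hc_pairs.tsv"),
    write_tsv_artifact(res$degree_report, outdir, "degree_report.tsv"),
    write_tsv_artifact(res$ogro_hits, outdir, "ogro_hits.tsv"),
    write_tsv_artifact(res$summary, outdir, "fixture_summary.tsv"),
    write_tsv_artifact(find_coregulatory_modules(res$network), outdir,
                       "modules.tsv"))
  write_network(res$network, file.path(outdir, "network.graphml"), "graphml")
  write_network(res$network, file.path(outdir, "network.sif"), "sif")
  art <- c(art, "network.graphml", "network.sif")
  res$manifest <- write_manifest(cfg, outdir, art)
  res
}
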