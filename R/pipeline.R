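#' Pipeline configuration
#'
#' One structure drives a full reproducible run: either a simulation block
#' (synthetic data generated in place) or paths to an evidence manifest plus
#' per-run tables, together with annotation and known-edge inputs, the
#' cascade thresholds and the enrichment settings. A single seed governs
#' every stochastic stage.
#'
#' @param simulation A [simulation_config()], or `NULL` to read evidence from
#'   disk.
#' @param evidence_manifest Path to a run manifest (required when
#'   `simulation` is `NULL`); evidence files are looked up as
#'   `<evidence_dir>/<run_id>.tsv`.
#' @param evidence_dir Directory of per-run evidence tables.
#' @param annotations_path Annotation pairs file (`NULL`: plant synthetic
#'   annotations from the simulation ground truth).
#' @param annotations_meta_path Sidecar term-metadata TSV.
#' @param known_edges_path Known-interaction table (`NULL`: plant synthetic
#'   edges from the ground truth).
#' @param cascade A [cascade_config()].
#' @param namespaces Namespaces for the enrichment stage.
#' @param min_genes_reported,p_adj_threshold Enrichment reporting gates.
#' @param known_edge_floor Confidence floor for known edges.
#' @param seed Integer master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            evidence_manifest = NULL,
                            evidence_dir = NULL,
                            annotations_path = NULL,
                            annotations_meta_path = NULL,
                            known_edges_path = NULL,
                            cascade = cascade_config(),
                            namespaces = c("biological_process",
                                           "cellular_component",
                                           "molecular_function"),
                            min_genes_reported = 3L,
                            p_adj_threshold = 0.01,
                            known_edge_floor = 0.5,
                            seed = 1L) {
  if (is.null(simulation) && is.null(evidence_manifest))
    config_error("either a simulation block or an evidence manifest is required")
  structure(list(
    simulation = simulation, evidence_manifest = evidence_manifest,
    evidence_dir = evidence_dir, annotations_path = annotations_path,
    annotations_meta_path = annotations_meta_path,
    known_edges_path = known_edges_path, cascade = cascade,
    namespaces = namespaces, min_genes_reported = min_genes_reported,
    p_adj_threshold = p_adj_threshold, known_edge_floor = known_edge_floor,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised top-level keys mirror the [pipeline_config()] arguments;
#' `simulation:` and `cascade:` sub-sections are passed to
#' [simulation_config()] and [cascade_config()].
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$simulation)) {
    if (!is.null(y$simulation$class_fractions))
      y$simulation$class_fractions <- unlist(y$simulation$class_fractions)
    sim <- do.call(simulation_config, y$simulation)
  }
  casc <- if (is.null(y$cascade)) cascade_config() else do.call(cascade_config, y$cascade)
  args <- y[setdiff(names(y), c("simulation", "cascade"))]
  do.call(pipeline_config, c(list(simulation = sim, cascade = casc), args))
}

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full BioID analysis pipeline
#'
#' Orchestrates simulate (or load) -> quantify -> filter -> compare ->
#' enrich -> network as one run. All stage outputs are written under
#' `outdir`; a machine-readable run summary (row counts per stage, retained
#' candidates per condition, reported GO terms per namespace, the seed and a
#' config echo) is written as JSON and returned. Identical configuration and
#' seed reproduce identical summaries. Referenced input files are checked
#' before any output is written; any stage failure aborts with the stage name
#' in the message.
#'
#' @param config A [pipeline_config()] or path to a YAML config file.
#' @param outdir Output directory (created).
#' @param seed Optional seed override.
#' @return The run summary, invisibly.
#' @export
run_bioid_pipeline <- function(config = pipeline_config(), outdir, seed = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(seed)) {
    config$seed <- as.integer(seed)
    if (!is.null(config$simulation)) config$simulation$seed <- as.integer(seed)
  }
  # validate declared inputs before creating any output
  for (p in c(config$evidence_manifest, config$annotations_path,
              config$annotations_meta_path, config$known_edges_path)) {
    if (!is.null(p) && !file.exists(p))
      config_error("input file does not exist: %s", p)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  # --- stage: evidence -------------------------------------------------------
  if (!is.null(config$simulation)) {
    log_stage("simulate", "generating synthetic experiment (seed %d)", config$simulation$seed)
    sim <- generate_experiment(config$simulation)
    evidence <- sim$evidence
    manifest <- sim$manifest
    truth <- sim$truth
    write_simulation(sim, file.path(outdir, "evidence"))
    bait_gene <- config$simulation$bait_gene
  } else {
    log_stage("load", "reading evidence manifest %s", config$evidence_manifest)
    manifest <- read_run_manifest(config$evidence_manifest)
    dir <- config$evidence_dir %||% dirname(config$evidence_manifest)
    evidence <- lapply(seq_len(nrow(manifest)), function(i) {
      read_evidence(file.path(dir, paste0(manifest$run_id[i], ".tsv")),
                    manifest[i, , drop = FALSE])
    })
    names(evidence) <- manifest$run_id
    truth <- NULL
    bait_gene <- config$cascade$bait_gene
  }

  # --- stage: quantify -------------------------------------------------------
  log_stage("quantify", "normalizing %d runs in %d batches",
            length(evidence), length(unique(manifest$batch_id)))
  ratios <- tryCatch(compute_ratio_table(evidence, manifest),
                     error = function(e) bioid_error("bioid_stage_error",
                       "stage quantify failed: %s", conditionMessage(e)))
  write_ratio_table(ratios, file.path(outdir, "ratio_table.tsv"))

  # --- stage: filter ---------------------------------------------------------
  cascade_cfg <- config$cascade
  if (cascade_cfg$bait_gene != toupper(bait_gene))
    cascade_cfg <- cascade_config(
      bait_peptide_min_exclusive = cascade_cfg$bait_peptide_min_exclusive,
      control_peptide_min = cascade_cfg$control_peptide_min,
      ratio_threshold_exclusive = cascade_cfg$ratio_threshold_exclusive,
      peptide_rule = cascade_cfg$peptide_rule,
      bait_gene = bait_gene)
  candidates <- run_cascade(ratios, cascade_cfg)
  log_stage("filter", "%d proteins assessed, %d retained",
            nrow(candidates), sum(candidates$status == "retained"))
  write_candidates(candidates, file.path(outdir, "candidates.tsv"))
  write_condition_lists(candidates, file.path(outdir, "condition_lists"))

  # --- stage: compare --------------------------------------------------------
  cl <- attr(candidates, "condition_lists")
  venn <- NULL
  if (length(cl) >= 2) {
    venn <- compute_overlaps(cl)
    write_venn_summary(venn, file.path(outdir, "overlaps.json"))
  }
  matrix <- NULL
  if (sum(candidates$status == "retained") > 0) {
    matrix <- build_ratio_matrix(candidates)
    write_ratio_matrix(matrix, file.path(outdir, "ratio_matrix.tsv"))
  }
  log_stage("compare", "ratio matrix %s",
            if (is.null(matrix)) "skipped (no candidates)"
            else paste(dim(matrix), collapse = " x "))

  # --- stage: enrich ---------------------------------------------------------
  if (!is.null(config$annotations_path)) {
    annotations <- read_annotations(config$annotations_path,
                                    term_meta_path = config$annotations_meta_path)
  } else if (!is.null(truth)) {
    annotations <- plant_annotations(truth, seed = config$seed)
  } else {
    config_error("stage enrich: no annotation source (annotations_path missing)")
  }
  query <- retained(candidates)$gene
  enrichment <- NULL
  if (length(intersect(toupper(query), annotations$background)) > 0) {
    enrichment <- run_enrichment(query, annotations,
                                 namespaces = config$namespaces,
                                 min_genes_reported = config$min_genes_reported,
                                 p_adj_threshold = config$p_adj_threshold)
    write_enrichment(enrichment, file.path(outdir, "enrichment.tsv"))
    log_stage("enrich", "%d terms tested, %d reported",
              nrow(enrichment), sum(enrichment$reported))
  } else {
    log_stage("enrich", "skipped: no retained gene maps to the annotation background")
  }

  # --- stage: network --------------------------------------------------------
  if (!is.null(config$known_edges_path)) {
    known <- read_known_edges(config$known_edges_path,
                              min_confidence = config$known_edge_floor)
  } else if (!is.null(truth)) {
    known <- plant_known_edges(truth, seed = config$seed)
  } else {
    known <- NULL
  }
  graph <- NULL
  if (sum(candidates$status == "retained") > 0) {
    graph <- build_network(candidates, known,
                           min_confidence = config$known_edge_floor)
    export_graph(graph, file.path(outdir, "network"))
    log_stage("network", "%d nodes, %d edges", nrow(graph$nodes), nrow(graph$edges))
  }

  # --- summary ---------------------------------------------------------------
  reported_by_ns <- if (is.null(enrichment)) list() else
    as.list(tapply(enrichment$reported, enrichment$namespace, sum))
  summary <- list(
    seed = config$seed,
    n_runs = length(evidence),
    n_proteins = length(unique(ratios$accession)),
    n_ratio_rows = nrow(ratios),
    n_assessed = nrow(candidates),
    n_retained = sum(candidates$status == "retained"),
    candidates_per_condition = lapply(cl, length),
    union_candidates = if (is.null(venn)) sum(candidates$status == "retained")
                       else venn$union_size,
    removed_by_stage = as.list(table(candidates$stage[candidates$status == "removed"])),
    reported_terms_per_namespace = reported_by_ns,
    n_network_nodes = if (is.null(graph)) 0L else nrow(graph$nodes),
    n_network_edges = if (is.null(graph)) 0L else nrow(graph$edges),
    config = echo_config(config)
  )
  jsonlite::write_json(summary, file.path(outdir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

echo_config <- function(config) {
  out <- unclass(config)
  if (!is.null(out$simulation)) {
    out$simulation <- unclass(out$simulation)
    out$simulation$class_fractions <- as.list(out$simulation$class_fractions)
  }
  if (!is.null(out$cascade)) {
    out$cascade <- unclass(out$cascade)
    out$cascade$exclusions <- unclass(out$cascade$exclusions)
  }
  out
}
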