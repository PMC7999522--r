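#' Simulation configuration for synthetic BioID experiments
#'
#' The generator emulates the statistical structure of a BioID LFQ dataset:
#' log-normal baseline protein abundances shared across runs; a multiplicative
#' bait-vs-control labeling enrichment planted on true interactors; strong
#' self-biotinylation of the bait (the largest planted effect); keratin and
#' endogenously biotinylated contaminants present at equal abundance in both
#' constructs (ratio about 1, so only the exclusion lists can remove them);
#' abundance-dependent detection dropout (logistic in log abundance); and
#' unique-peptide counts that grow with log abundance above the detection
#' limit (shifted Poisson). Under ER stress, labeling effects of interactors
#' shrink towards 1 on the log scale by the fraction `stress_shrinkage`,
#' while bait self-biotinylation is unaffected — the ligase keeps labeling
#' its own fusion protein when translation stalls.
#'
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @param n_proteins Total simulated proteins (exactly one is the bait).
#' @param class_fractions Named proportions over classes `bait`,
#'   `true_interactor`, `background`, `keratin`, `endogenous_biotin`; must sum
#'   to 1 (tolerance 1e-9). Counts are allocated by largest remainder with the
#'   bait fixed at one protein.
#' @param interactor_effect Multiplicative bait-vs-control enrichment planted
#'   on true interactors (> 1).
#' @param bait_self_effect Enrichment of the bait itself; must exceed
#'   `interactor_effect` so the bait tops every ratio ranking.
#' @param stress_shrinkage Fraction of the log labeling effect removed under
#'   `treatment = "stress"`: the stressed effect is
#'   `effect^(1 - stress_shrinkage)` — multiplicative effects shrink towards 1
#'   on their natural (log) scale. 0 leaves effects untouched, 1 collapses
#'   them to 1. Applied to interactors only, never to the bait's self-labeling
#'   and never to baseline abundance.
#' @param abundance_log_mean,abundance_log_sd Natural-log mean and sd of the
#'   baseline abundance distribution.
#' @param noise_log_sd Natural-log sd of the per-run multiplicative
#'   measurement noise.
#' @param detection_k Slope of the logistic detection model in log abundance.
#' @param detection_x0 Log-abundance at which detection probability is 50%
#'   (default 3.5 baseline standard deviations below the mean, so dropout is
#'   confined to the lowest-abundance tail, as in intensity-dependent LFQ
#'   missingness).
#' @param peptide_rate Links abundance to peptide yield: detected proteins get
#'   `1 + Poisson(peptide_rate * max(0, log1p(abundance) - detection_x0))`
#'   unique peptides — counts grow with log abundance above the detection
#'   limit and collapse to single peptides at the limit, which is where the
#'   unique-peptide filters must bite.
#' @param replicates Independent replicates per condition (default 3).
#' @param cell_lines,biotin_hours,treatments Condition grid.
#' @param bait_gene,bait_accession Identity of the bait protein.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_proteins = 120L,
                              class_fractions = c(bait = 1, true_interactor = 10,
                                                  keratin = 8, endogenous_biotin = 7,
                                                  background = 94) / 120,
                              interactor_effect = 5,
                              bait_self_effect = 30,
                              stress_shrinkage = 0.9,
                              abundance_log_mean = log(1e6),
                              abundance_log_sd = 1.2,
                              noise_log_sd = 0.2,
                              detection_k = 4,
                              detection_x0 = abundance_log_mean - 3.5 * abundance_log_sd,
                              peptide_rate = 2,
                              replicates = 3L,
                              cell_lines = c("HCT116", "HEK293T"),
                              biotin_hours = c(6, 24),
                              treatments = c("vehicle", "stress"),
                              bait_gene = "EIF3A",
                              bait_accession = "BAIT0001") {
  classes <- c("bait", "true_interactor", "background", "keratin", "endogenous_biotin")
  if (is.null(names(class_fractions)) || !all(names(class_fractions) %in% classes))
    config_error("class_fractions must be named with: %s", paste(classes, collapse = ", "))
  frac <- stats::setNames(numeric(length(classes)), classes)
  frac[names(class_fractions)] <- class_fractions
  if (abs(sum(frac) - 1) > 1e-9)
    config_error("class_fractions must sum to 1 (got %.12f)", sum(frac))
  if (interactor_effect <= 1) config_error("interactor_effect must be > 1")
  if (bait_self_effect <= interactor_effect)
    config_error("bait_self_effect must exceed interactor_effect")
  if (stress_shrinkage < 0 || stress_shrinkage > 1)
    config_error("stress_shrinkage must lie in [0, 1]")
  if (replicates < 1) config_error("replicates must be positive")
  structure(list(
    seed = as.integer(seed), n_proteins = as.integer(n_proteins),
    class_fractions = frac, interactor_effect = interactor_effect,
    bait_self_effect = bait_self_effect, stress_shrinkage = stress_shrinkage,
    abundance_log_mean = abundance_log_mean, abundance_log_sd = abundance_log_sd,
    noise_log_sd = noise_log_sd, detection_k = detection_k,
    detection_x0 = detection_x0, peptide_rate = peptide_rate,
    replicates = as.integer(replicates), cell_lines = cell_lines,
    biotin_hours = biotin_hours, treatments = treatments,
    bait_gene = toupper(bait_gene), bait_accession = bait_accession
  ), class = "simulation_config")
}

# largest-remainder allocation of n proteins over classes, bait fixed at 1
allocate_classes <- function(config) {
  n <- config$n_proteins
  frac <- config$class_fractions
  rest <- frac[names(frac) != "bait"]
  rest <- rest / sum(rest)
  target <- rest * (n - 1L)
  counts <- floor(target)
  short <- (n - 1L) - sum(counts)
  if (short > 0) {
    order_rem <- order(target - counts, decreasing = TRUE)
    counts[order_rem[seq_len(short)]] <- counts[order_rem[seq_len(short)]] + 1
  }
  counts <- c(bait = 1L, counts)
  max_endog <- length(exclusion_lists()$endogenous_biotin_genes)
  if (counts["endogenous_biotin"] > max_endog)
    config_error("at most %d endogenous-biotin proteins supported (requested %d)",
                 max_endog, counts["endogenous_biotin"])
  counts
}

build_ground_truth <- function(config) {
  counts <- allocate_classes(config)
  class <- rep(names(counts), counts)
  n <- length(class)
  gene <- character(n)
  gene[class == "bait"] <- config$bait_gene
  gene[class == "true_interactor"] <-
    sprintf("INT%02d", seq_len(counts["true_interactor"]))
  gene[class == "background"] <-
    sprintf("BGD%03d", seq_len(counts["background"]))
  gene[class == "keratin"] <-
    sprintf("KRT%d", seq_len(counts["keratin"]))
  gene[class == "endogenous_biotin"] <-
    exclusion_lists()$endogenous_biotin_genes[seq_len(counts["endogenous_biotin"])]
  accession <- sprintf("SIM%04d", seq_len(n))
  accession[class == "bait"] <- config$bait_accession
  effect_vehicle <- rep(1, n)
  effect_vehicle[class == "true_interactor"] <- config$interactor_effect
  effect_vehicle[class == "bait"] <- config$bait_self_effect
  effect_stress <- effect_vehicle^(1 - config$stress_shrinkage)
  effect_stress[class == "bait"] <- config$bait_self_effect
  structure(data.frame(
    accession = accession, gene = gene, class = class,
    effect_vehicle = effect_vehicle, effect_stress = effect_stress,
    stringsAsFactors = FALSE
  ), class = c("ground_truth", "data.frame"))
}

#' Generate a complete synthetic BioID experiment
#'
#' Produces one evidence table per run over the full condition grid
#' (cell line x biotin time x treatment x construct x replicate), a run
#' manifest, and a ground-truth manifest recording each protein's class and
#' planted effect per treatment. Within a batch (one cell line, time and
#' treatment) runs share the quantification context the ratio step assumes.
#' Per run, each protein's observed abundance is
#' `baseline * effect * exp(N(0, noise_log_sd))`, zeroed with probability
#' `1 - plogis(detection_k * (log(abundance) - detection_x0))`; detected
#' proteins receive `1 + Poisson(peptide_rate * max(0, log1p(abundance) -
#' detection_x0))` unique peptides. Keratin contaminants are given a 5-fold
#' abundance boost in both
#' constructs, so they carry high peptide counts yet a ratio near 1 — only the
#' exclusion stage can remove them.
#'
#' @param config A [simulation_config()].
#' @return A `bioid_simulation` list: `evidence` (named list of
#'   `evidence_table`s), `manifest` (run manifest), `truth` (ground-truth data
#'   frame), `config`.
#' @export
generate_experiment <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  truth <- build_ground_truth(config)
  n <- nrow(truth)
  set.seed(config$seed)
  baseline <- exp(stats::rnorm(n, config$abundance_log_mean, config$abundance_log_sd))
  baseline[truth$class == "keratin"] <- baseline[truth$class == "keratin"] * 5

  grid <- expand.grid(
    replicate = seq_len(config$replicates),
    construct = c("bait_fusion", "control"),
    treatment = config$treatments,
    biotin_hours = config$biotin_hours,
    cell_line = config$cell_lines,
    stringsAsFactors = FALSE
  )
  grid$batch_id <- sprintf("%s_%gh_%s", grid$cell_line, grid$biotin_hours, grid$treatment)
  grid$run_id <- sprintf("%s_%s_r%d", grid$batch_id,
                         ifelse(grid$construct == "bait_fusion", "bait", "ctrl"),
                         grid$replicate)
  manifest <- grid[, c("run_id", "cell_line", "construct", "biotin_hours",
                       "treatment", "replicate", "batch_id")]
  validate_manifest(manifest)

  evidence <- vector("list", nrow(manifest))
  names(evidence) <- manifest$run_id
  for (i in seq_len(nrow(manifest))) {
    md <- manifest[i, , drop = FALSE]
    effect <- rep(1, n)
    if (md$construct == "bait_fusion") {
      effect <- if (md$treatment == "stress") truth$effect_stress else truth$effect_vehicle
    }
    true_abund <- baseline * effect
    observed <- true_abund * exp(stats::rnorm(n, 0, config$noise_log_sd))
    p_detect <- stats::plogis(config$detection_k * (log(observed) - config$detection_x0))
    detected <- stats::runif(n) < p_detect
    observed[!detected] <- 0
    peptides <- integer(n)
    peptides[detected] <- 1L + stats::rpois(sum(detected),
      config$peptide_rate * pmax(0, log1p(observed[detected]) - config$detection_x0))
    evidence[[i]] <- evidence_table(
      data.frame(accession = truth$accession, gene = truth$gene,
                 unique_peptides = peptides, abundance = observed,
                 stringsAsFactors = FALSE),
      md
    )
  }
  structure(list(evidence = evidence, manifest = manifest,
                 truth = truth, config = config),
            class = "bioid_simulation")
}

#' @export
print.bioid_simulation <- function(x, ...) {
  cat(sprintf("Synthetic BioID experiment: %d runs x %d proteins (seed %d)\n",
              length(x$evidence), nrow(x$truth), x$config$seed))
  print(table(x$truth$class))
  invisible(x)
}

#' Plant a GO annotation set over simulated proteins
#'
#' Enriched terms draw most of their members from the planted true-interactor
#' class (plus a few other proteins, so term size exceeds the interactor
#' overlap); null terms sample genes uniformly. The background is every
#' simulated gene, which is the background the enrichment stage will use.
#'
#' @param truth Ground-truth data frame from [generate_experiment()].
#' @param n_terms Total number of terms.
#' @param enriched_terms Number of interactor-enriched terms (<= `n_terms`).
#' @param seed Integer seed.
#' @param term_size_range Size range for null terms.
#' @param interactors_per_term How many true interactors an enriched term
#'   contains (capped at the number available, default 8).
#' @return An `annotation_set`; enriched term ids start with `"TERM_ENR"`.
#' @export
plant_annotations <- function(truth, n_terms = 50L, enriched_terms = 1L,
                              seed = 1L, term_size_range = c(5, 30),
                              interactors_per_term = 8L) {
  if (enriched_terms > n_terms)
    config_error("enriched_terms (%d) exceeds n_terms (%d)", enriched_terms, n_terms)
  interactors <- truth$gene[truth$class == "true_interactor"]
  if (enriched_terms > 0 && length(interactors) < 3)
    config_error("enriched terms require at least 3 planted interactors (have %d)",
                 length(interactors))
  genes <- truth$gene
  set.seed(seed)
  namespaces <- rep(unname(gaf_aspects), length.out = n_terms)
  term <- character(0); gene <- character(0)
  ids <- character(n_terms)
  for (i in seq_len(n_terms)) {
    if (i <= enriched_terms) {
      ids[i] <- sprintf("TERM_ENR%02d", i)
      core <- sample(interactors, min(interactors_per_term, length(interactors)))
      pad <- sample(setdiff(genes, core), 4)
      members <- c(core, pad)
    } else {
      ids[i] <- sprintf("TERM%03d", i)
      size <- sample(seq(term_size_range[1], term_size_range[2]), 1)
      members <- sample(genes, size)
    }
    term <- c(term, rep(ids[i], length(members)))
    gene <- c(gene, members)
  }
  # the whole background must be annotated somewhere so |background| = n genes
  term <- c(term, rep("TERM_ROOT", length(genes)))
  gene <- c(gene, genes)
  meta <- data.frame(
    term_id = c(ids, "TERM_ROOT"),
    name = c(sprintf("synthetic term %d", seq_len(n_terms)), "all simulated proteins"),
    namespace = c(namespaces, "cellular_component"),
    stringsAsFactors = FALSE
  )
  annotation_set(term = term, gene = gene, term_meta = meta)
}

#' Plant a known-interaction edge table over simulated proteins
#'
#' Convenience generator for the network stage: draws high-confidence edges
#' among true interactors (and from the bait) plus uniformly random
#' lower-confidence edges among all proteins.
#'
#' @param truth Ground-truth data frame.
#' @param seed Integer seed.
#' @param p_within Probability of an edge between any two true interactors.
#' @param n_random Number of random background edges.
#' @return A `known_edge_table` (unfiltered; apply a floor on read/use).
#' @export
plant_known_edges <- function(truth, seed = 1L, p_within = 0.5, n_random = 40L) {
  set.seed(seed)
  interactors <- truth$gene[truth$class == "true_interactor"]
  bait <- truth$gene[truth$class == "bait"]
  a <- character(0); b <- character(0); conf <- numeric(0)
  if (length(interactors) >= 2) {
    pairs <- utils::combn(interactors, 2)
    keep <- stats::runif(ncol(pairs)) < p_within
    a <- c(a, pairs[1, keep]); b <- c(b, pairs[2, keep])
    conf <- c(conf, stats::runif(sum(keep), 0.6, 0.99))
  }
  a <- c(a, rep(bait, length(interactors))); b <- c(b, interactors)
  conf <- c(conf, stats::runif(length(interactors), 0.6, 0.99))
  ra <- sample(truth$gene, n_random, replace = TRUE)
  rb <- sample(truth$gene, n_random, replace = TRUE)
  a <- c(a, ra); b <- c(b, rb)
  conf <- c(conf, stats::runif(n_random, 0.1, 0.9))
  known_edge_table(a, b, conf)
}

#' Write a simulated experiment to disk
#'
#' Emits exactly the formats the readers accept: one evidence TSV per run, the
#' run manifest, the ground-truth manifest, and the configuration as YAML.
#'
#' @param sim A `bioid_simulation`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (run_id in names(sim$evidence))
    write_evidence(sim$evidence[[run_id]], file.path(dir, paste0(run_id, ".tsv")))
  write_run_manifest(sim$manifest, file.path(dir, "manifest.tsv"))
  write_delim_table(as.data.frame(sim$truth), file.path(dir, "ground_truth.tsv"))
  cfg <- sim$config
  cfg$class_fractions <- as.list(cfg$class_fractions)
  yaml::write_yaml(unclass(cfg), file.path(dir, "simulation_config.yaml"))
  invisible(dir)
}
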