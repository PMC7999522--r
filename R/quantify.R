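#' Normalize runs within one quantification batch
#'
#' Label-free abundances are only comparable across runs after removing
#' per-run global scale differences (loading, ionisation efficiency). Each run
#' is rescaled by a single multiplicative factor: the median, over proteins
#' quantified (abundance > 0) in both that run and the batch reference run, of
#' reference/run abundance. The reference run is the run quantifying the most
#' proteins, ties broken by lexicographic `run_id` (its factor is exactly 1).
#'
#' @param tables List of `evidence_table`s belonging to one batch.
#' @param method `"median_ratio"` (default) or `"none"` (raw abundances kept).
#' @return A `protein_quant` object: abundance and peptide matrices
#'   (proteins x runs), the per-run manifest, the scale factors applied, and
#'   the reference run id.
#' @export
normalize_runs <- function(tables, method = c("median_ratio", "none")) {
  method <- match.arg(method)
  if (length(tables) < 2)
    normalization_error("need at least 2 runs in a batch, got %d", length(tables))
  mds <- do.call(rbind, lapply(tables, attr, "metadata"))
  if (length(unique(mds$batch_id)) != 1)
    normalization_error("runs span multiple batches: %s",
                        paste(unique(mds$batch_id), collapse = ", "))
  accession <- sort(unique(unlist(lapply(tables, `[[`, "accession"))))
  gene_map <- stats::setNames(character(length(accession)), accession)
  abund <- matrix(0, length(accession), length(tables),
                  dimnames = list(accession, mds$run_id))
  pep <- matrix(0L, length(accession), length(tables),
                dimnames = list(accession, mds$run_id))
  for (j in seq_along(tables)) {
    t <- tables[[j]]
    abund[t$accession, j] <- t$abundance
    pep[t$accession, j] <- t$unique_peptides
    gene_map[t$accession] <- t$gene
  }
  n_quant <- colSums(abund > 0)
  ref <- order(-n_quant, colnames(abund))[1]
  factors <- rep(1, ncol(abund))
  names(factors) <- colnames(abund)
  if (method == "median_ratio") {
    for (j in seq_len(ncol(abund))) {
      if (j == ref) next
      shared <- abund[, ref] > 0 & abund[, j] > 0
      if (!any(shared))
        normalization_error("run %s shares no quantified protein with reference run %s",
                            colnames(abund)[j], colnames(abund)[ref])
      factors[j] <- stats::median(abund[shared, ref] / abund[shared, j])
      abund[, j] <- abund[, j] * factors[j]
    }
  }
  structure(list(
    accession = accession, gene = unname(gene_map[accession]),
    abundance = abund, peptides = pep, manifest = mds,
    scale_factors = factors, reference_run = colnames(abund)[ref],
    method = method
  ), class = "protein_quant")
}

#' @export
print.protein_quant <- function(x, ...) {
  cat(sprintf("Protein quantification: %d proteins x %d runs (batch %s)\n",
              nrow(x$abundance), ncol(x$abundance), x$manifest$batch_id[1]))
  cat(sprintf("reference run: %s; scale factors: %s\n", x$reference_run,
              paste(sprintf("%.3g", x$scale_factors), collapse = ", ")))
  invisible(x)
}

#' Compute per-protein biotinylation ratios for one experiment
#'
#' The biotinylation ratio is the enrichment statistic of a BioID screen:
#' mean normalized abundance over bait-fusion replicates divided by the mean
#' over control replicates, per protein, within one batch. Replicates where a
#' protein was not detected contribute 0 to the mean (absence is information,
#' not a missing value). The ratio is undefined — flagged, not an error — when
#' the control mean is 0. Unique-peptide counts are aggregated across
#' replicates per construct (default: maximum).
#'
#' @param quant A `protein_quant` from [normalize_runs()].
#' @param peptide_agg How to aggregate unique peptides over replicates:
#'   `"max"` (default, most permissive), `"sum"`, or `"min"`.
#' @return A `ratio_table` data frame, one row per protein:
#'   `accession`, `gene`, `cell_line`, `biotin_hours`, `treatment`,
#'   `batch_id`, `ratio` (NA when undefined), `ratio_defined`,
#'   `bait_peptides`, `control_peptides`.
#' @export
compute_ratios <- function(quant, peptide_agg = c("max", "sum", "min")) {
  peptide_agg <- match.arg(peptide_agg)
  md <- quant$manifest
  bait_runs <- md$run_id[md$construct == "bait_fusion"]
  ctrl_runs <- md$run_id[md$construct == "control"]
  if (length(bait_runs) == 0 || length(ctrl_runs) == 0)
    lookup_error("batch %s lacks %s runs", md$batch_id[1],
                 if (length(bait_runs) == 0) "bait_fusion" else "control")
  agg <- switch(peptide_agg, max = function(m) apply(m, 1, max),
                sum = rowSums, min = function(m) apply(m, 1, min))
  bait_mean <- rowMeans(quant$abundance[, bait_runs, drop = FALSE])
  ctrl_mean <- rowMeans(quant$abundance[, ctrl_runs, drop = FALSE])
  defined <- ctrl_mean > 0
  ratio <- ifelse(defined, bait_mean / ctrl_mean, NA_real_)
  out <- data.frame(
    accession = quant$accession, gene = quant$gene,
    cell_line = md$cell_line[1], biotin_hours = md$biotin_hours[1],
    treatment = md$treatment[1], batch_id = md$batch_id[1],
    ratio = ratio, ratio_defined = defined,
    bait_peptides = as.integer(agg(quant$peptides[, bait_runs, drop = FALSE])),
    control_peptides = as.integer(agg(quant$peptides[, ctrl_runs, drop = FALSE])),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out, class = c("ratio_table", "data.frame"))
}

#' Quantify a whole experiment: normalize each batch and compute ratios
#'
#' Groups runs by `batch_id`, normalizes within each batch, computes the
#' biotinylation ratio per protein and batch, and stacks the results. One
#' batch corresponds to one experiment column of the downstream ratio matrix:
#' a (cell line, biotin time, treatment) combination.
#'
#' @param evidence Named list of `evidence_table`s (e.g. from
#'   [generate_experiment()]) or a `bioid_simulation`.
#' @param manifest Run manifest; taken from the simulation when omitted.
#' @inheritParams normalize_runs
#' @inheritParams compute_ratios
#' @return A `ratio_table` covering all batches.
#' @export
compute_ratio_table <- function(evidence, manifest = NULL,
                                method = c("median_ratio", "none"),
                                peptide_agg = c("max", "sum", "min")) {
  if (inherits(evidence, "bioid_simulation")) {
    manifest <- evidence$manifest
    evidence <- evidence$evidence
  }
  if (is.null(manifest))
    manifest <- do.call(rbind, lapply(evidence, attr, "metadata"))
  method <- match.arg(method); peptide_agg <- match.arg(peptide_agg)
  batches <- split(manifest$run_id, manifest$batch_id)
  out <- lapply(names(batches), function(b) {
    quant <- normalize_runs(evidence[batches[[b]]], method = method)
    compute_ratios(quant, peptide_agg = peptide_agg)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  structure(out, class = c("ratio_table", "data.frame"))
}

#' @rdname compute_ratio_table
#' @param ratios A `ratio_table`.
#' @param path Output file for the delimited ratio table.
#' @export
write_ratio_table <- function(ratios, path) {
  write_delim_table(as.data.frame(ratios), path)
}
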