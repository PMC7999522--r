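#' Candidate-selection cascade configuration
#'
#' The candidate filters of a BioID screen, applied in a fixed order with a
#' per-protein audit trail: (1) peptide floor — more than
#' `bait_peptide_min_exclusive` unique peptides on the bait-fusion side and at
#' least `control_peptide_min` on the control side; (2) direction — a protein
#' whose control peptide count strictly exceeds its bait count in an
#' experiment cannot qualify there; (3) exclusion lists — keratins and
#' endogenously biotinylated proteins are contaminants, removed whatever their
#' ratio (the bait's own gene is never excluded); (4) ratio threshold — a
#' biotinylation ratio strictly above `ratio_threshold_exclusive` (default
#' 1.5, i.e. a 50% abundance increase) in at least one experiment.
#'
#' @param bait_peptide_min_exclusive Bait-side unique-peptide floor,
#'   exclusive: a count of exactly this value fails (default 3).
#' @param control_peptide_min Control-side floor, inclusive (default 1).
#' @param ratio_threshold_exclusive Ratio threshold, exclusive: a ratio of
#'   exactly this value fails (default 1.5).
#' @param peptide_rule `"any"` (default): the peptide floor must hold in at
#'   least one experiment; `"all"`: in every experiment where the protein has
#'   a defined ratio.
#' @param exclusions An [exclusion_lists()] object.
#' @param bait_gene Bait gene symbol (exempt from exclusion; used for ranking
#'   checks downstream).
#' @return A `cascade_config` list.
#' @export
cascade_config <- function(bait_peptide_min_exclusive = 3L,
                           control_peptide_min = 1L,
                           ratio_threshold_exclusive = 1.5,
                           peptide_rule = c("any", "all"),
                           exclusions = NULL,
                           bait_gene = "EIF3A") {
  if (bait_peptide_min_exclusive < 0 || control_peptide_min < 0 ||
      ratio_threshold_exclusive < 0)
    config_error("cascade thresholds must be non-negative")
  exclusions <- exclusions %||% exclusion_lists(bait_gene = bait_gene)
  structure(list(
    bait_peptide_min_exclusive = bait_peptide_min_exclusive,
    control_peptide_min = control_peptide_min,
    ratio_threshold_exclusive = ratio_threshold_exclusive,
    peptide_rule = match.arg(peptide_rule),
    exclusions = exclusions,
    bait_gene = toupper(bait_gene)
  ), class = "cascade_config")
}

#' Individual cascade stage predicates
#'
#' Vectorised pass/fail rules for single experiments; [run_cascade()] composes
#' them over all experiments of a protein. Missing counts are treated as 0.
#'
#' @param bait_peptides,control_peptides Unique-peptide counts aggregated over
#'   replicates for one experiment.
#' @param config A [cascade_config()].
#' @return Logical vector (`apply_exclusions` returns a character vector:
#'   `"pass"`, `"keratin"` or `"endogenous_biotin"`).
#' @export
apply_peptide_floor <- function(bait_peptides, control_peptides, config = cascade_config()) {
  bait_peptides[is.na(bait_peptides)] <- 0L
  control_peptides[is.na(control_peptides)] <- 0L
  bait_peptides > config$bait_peptide_min_exclusive &
    control_peptides >= config$control_peptide_min
}

#' @rdname apply_peptide_floor
#' @export
apply_direction_filter <- function(bait_peptides, control_peptides) {
  bait_peptides[is.na(bait_peptides)] <- 0L
  control_peptides[is.na(control_peptides)] <- 0L
  !(control_peptides > bait_peptides)
}

#' @rdname apply_peptide_floor
#' @param gene Gene symbol vector.
#' @param lists An [exclusion_lists()] object.
#' @param bait_gene The bait's own symbol, always passed through.
#' @export
apply_exclusions <- function(gene, lists = exclusion_lists(), bait_gene = "EIF3A") {
  out <- rep("pass", length(gene))
  out[is_keratin(gene, lists)] <- "keratin"
  out[is_endogenous_biotin(gene, lists)] <- "endogenous_biotin"
  out[toupper(gene) == toupper(bait_gene)] <- "pass"
  out
}

#' @rdname apply_peptide_floor
#' @param ratio Per-experiment ratio vector (NA = undefined, skipped).
#' @export
apply_ratio_threshold <- function(ratio, config = cascade_config()) {
  !is.na(ratio) & ratio > config$ratio_threshold_exclusive
}

#' Run the full candidate-selection cascade
#'
#' Applies the four stages in order (peptide floor, direction, exclusion
#' lists, ratio threshold) across every experiment of every protein, recording
#' for each removed protein the first stage that removed it. A protein is
#' retained when at least one experiment survives all per-experiment rules;
#' those experiments are its qualifying set, which also defines the
#' per-condition candidate lists.
#'
#' @param ratios A `ratio_table` from [compute_ratio_table()] covering one or
#'   more experiments (batches).
#' @param config A [cascade_config()].
#' @return A `candidate_set`: data frame with one row per protein
#'   (`accession`, `gene`, `status`, `stage`, `max_ratio`, `n_qualifying`,
#'   `qualifying` as a comma-separated batch list), with attributes
#'   `condition_lists` (named list of retained gene vectors per experiment),
#'   `ratios` (the input table) and `config`.
#' @export
run_cascade <- function(ratios, config = cascade_config()) {
  if (nrow(ratios) == 0) {
    warning("empty ratio table: empty candidate set")
    out <- data.frame(accession = character(0), gene = character(0),
                      status = character(0), stage = character(0),
                      max_ratio = numeric(0), n_qualifying = integer(0),
                      qualifying = character(0), stringsAsFactors = FALSE)
    return(structure(out, condition_lists = list(), ratios = ratios,
                     config = config, class = c("candidate_set", "data.frame")))
  }
  ratios <- as.data.frame(ratios)
  per_exp_floor <- apply_peptide_floor(ratios$bait_peptides, ratios$control_peptides, config)
  per_exp_dir <- apply_direction_filter(ratios$bait_peptides, ratios$control_peptides)
  per_exp_ratio <- apply_ratio_threshold(ratios$ratio, config)

  by_prot <- split(seq_len(nrow(ratios)), ratios$accession)
  res <- lapply(by_prot, function(idx) {
    gene <- ratios$gene[idx[1]]
    floor_ok <- per_exp_floor[idx]
    if (config$peptide_rule == "all" && !all(floor_ok[ratios$ratio_defined[idx]]))
      floor_ok[] <- FALSE
    if (!any(floor_ok))
      return(list(gene = gene, status = "removed", stage = "peptide_floor",
                  qualifying = character(0)))
    dir_ok <- floor_ok & per_exp_dir[idx]
    if (!any(dir_ok))
      return(list(gene = gene, status = "removed", stage = "direction",
                  qualifying = character(0)))
    excl <- apply_exclusions(gene, config$exclusions, config$bait_gene)
    if (excl != "pass")
      return(list(gene = gene, status = "removed", stage = excl,
                  qualifying = character(0)))
    ratio_ok <- dir_ok & per_exp_ratio[idx]
    if (!any(ratio_ok))
      return(list(gene = gene, status = "removed", stage = "ratio_threshold",
                  qualifying = character(0)))
    list(gene = gene, status = "retained", stage = NA_character_,
         qualifying = ratios$batch_id[idx][ratio_ok])
  })
  max_ratio <- vapply(by_prot, function(idx) {
    r <- ratios$ratio[idx]
    if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE)
  }, numeric(1))
  out <- data.frame(
    accession = names(by_prot),
    gene = vapply(res, `[[`, character(1), "gene"),
    status = vapply(res, `[[`, character(1), "status"),
    stage = vapply(res, `[[`, character(1), "stage"),
    max_ratio = max_ratio,
    n_qualifying = vapply(res, function(r) length(r$qualifying), integer(1)),
    qualifying = vapply(res, function(r) paste(r$qualifying, collapse = ","), character(1)),
    stringsAsFactors = FALSE
  )
  out <- out[order(-ifelse(is.na(out$max_ratio), -Inf, out$max_ratio), out$gene), ]
  rownames(out) <- NULL
  batches <- sort(unique(ratios$batch_id))
  condition_lists <- lapply(batches, function(b) {
    sort(out$gene[out$status == "retained" &
                    vapply(strsplit(out$qualifying, ","), function(q) b %in% q, logical(1))])
  })
  names(condition_lists) <- batches
  structure(out, condition_lists = condition_lists, ratios = ratios,
            config = config, class = c("candidate_set", "data.frame"))
}

#' @export
print.candidate_set <- function(x, ...) {
  n_ret <- sum(x$status == "retained")
  cat(sprintf("Candidate set: %d proteins assessed, %d retained\n", nrow(x), n_ret))
  if (nrow(x) > 0) {
    removed <- table(x$stage[x$status == "removed"])
    if (length(removed) > 0) {
      cat("removed by stage:\n")
      for (s in names(removed)) cat(sprintf("  %-18s %d\n", s, removed[[s]]))
    }
    cl <- attr(x, "condition_lists")
    if (length(cl) > 0) {
      cat("candidates per experiment:\n")
      for (b in names(cl)) cat(sprintf("  %-24s %d\n", b, length(cl[[b]])))
    }
  }
  invisible(x)
}

#' @export
summary.candidate_set <- function(object, ...) {
  list(
    n_assessed = nrow(object),
    n_retained = sum(object$status == "retained"),
    removed_by_stage = table(object$stage[object$status == "removed"]),
    candidates_per_condition = vapply(attr(object, "condition_lists"), length, integer(1))
  )
}

#' Retained candidates of a candidate set
#'
#' @param candidates A `candidate_set`.
#' @return Data frame of retained rows, in ratio-rank order.
#' @export
retained <- function(candidates) {
  as.data.frame(candidates)[candidates$status == "retained", , drop = FALSE]
}

#' @rdname run_cascade
#' @param candidates A `candidate_set`.
#' @param path Output file for the audit table.
#' @export
write_candidates <- function(candidates, path) {
  write_delim_table(as.data.frame(candidates), path)
}

#' @rdname run_cascade
#' @param dir Directory for per-condition membership lists (one gene per line,
#'   one file per experiment) ready for overlap/Venn tools.
#' @export
write_condition_lists <- function(candidates, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cl <- attr(candidates, "condition_lists")
  for (b in names(cl))
    writeLines(cl[[b]], file.path(dir, paste0(b, ".txt")))
  invisible(dir)
}
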