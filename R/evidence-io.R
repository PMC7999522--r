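#' Run metadata record
#'
#' Describes one mass-spectrometry run of a BioID experiment: which cell line
#' and construct it came from, how long cells were labeled with biotin, whether
#' they were stressed, and which quantification batch the run belongs to. Runs
#' are only ever ratio-compared within one `batch_id`.
#'
#' @param run_id Unique run identifier.
#' @param cell_line Cell line label (e.g. `"HCT116"`).
#' @param construct `"bait_fusion"` (promiscuous ligase fused to the bait) or
#'   `"control"` (ligase alone).
#' @param biotin_hours Biotin labeling duration in hours; 6 or 24.
#' @param treatment `"vehicle"` or `"stress"` (ER-stress arm).
#' @param replicate Positive integer replicate index.
#' @param batch_id Identifier grouping runs quantified together.
#' @return A one-row data frame of run metadata.
#' @export
run_metadata <- function(run_id, cell_line, construct, biotin_hours,
                         treatment, replicate, batch_id) {
  md <- data.frame(
    run_id = as.character(run_id), cell_line = as.character(cell_line),
    construct = as.character(construct), biotin_hours = as.numeric(biotin_hours),
    treatment = as.character(treatment), replicate = as.integer(replicate),
    batch_id = as.character(batch_id), stringsAsFactors = FALSE
  )
  validate_manifest(md)
  md
}

#' Validate a run manifest
#'
#' @param manifest Data frame with columns `run_id`, `cell_line`, `construct`,
#'   `biotin_hours`, `treatment`, `replicate`, `batch_id`.
#' @return The manifest, invisibly, if valid; otherwise an error.
#' @export
validate_manifest <- function(manifest) {
  required <- c("run_id", "cell_line", "construct", "biotin_hours",
                "treatment", "replicate", "batch_id")
  missing <- setdiff(required, names(manifest))
  if (length(missing) > 0)
    format_error("manifest is missing column(s): %s", paste(missing, collapse = ", "))
  if (anyDuplicated(manifest$run_id))
    validation_error("duplicate run_id in manifest: %s",
                     paste(unique(manifest$run_id[duplicated(manifest$run_id)]), collapse = ", "))
  bad <- !manifest$construct %in% c("bait_fusion", "control")
  if (any(bad))
    validation_error("construct must be 'bait_fusion' or 'control' (run %s)",
                     manifest$run_id[which(bad)[1]])
  bad <- !manifest$treatment %in% c("vehicle", "stress")
  if (any(bad))
    validation_error("treatment must be 'vehicle' or 'stress' (run %s)",
                     manifest$run_id[which(bad)[1]])
  if (any(!manifest$biotin_hours %in% c(6, 24)))
    validation_error("biotin_hours must be 6 or 24")
  if (any(manifest$replicate < 1))
    validation_error("replicate must be a positive integer")
  invisible(manifest)
}

#' @rdname validate_manifest
#' @param path File to read from or write to (tab- or comma-delimited by extension).
#' @export
read_run_manifest <- function(path) {
  m <- read_delim_table(path)
  validate_manifest(m)
  m
}

#' @rdname validate_manifest
#' @export
write_run_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  write_delim_table(manifest, path)
}

# default header aliases, matched case-insensitively
evidence_aliases <- function() {
  list(
    accession       = c("accession", "protein", "protein_id", "protein accession"),
    gene            = c("gene", "gene_symbol", "symbol", "gene name"),
    unique_peptides = c("unique_peptides", "unique peptides", "peptides", "n_unique_peptides"),
    abundance       = c("abundance", "intensity", "lfq_intensity", "normalized abundance")
  )
}

#' Read a per-run protein evidence table
#'
#' One row per protein quantified in a single MS run: accession, gene symbol,
#' unique-peptide count and summed LFQ abundance (0 means not quantified).
#' Column headers may use common aliases (`protein`, `intensity`, ...),
#' matched case-insensitively. Validation is strict: any malformed row is an
#' error, never silently dropped.
#'
#' @param path Delimited text file (`.tsv`/`.txt` tab, `.csv` comma).
#' @param metadata One-row manifest data frame from [run_metadata()].
#' @param aliases Optional named list overriding header aliases.
#' @param sep Optional delimiter override.
#' @return An `evidence_table`: data frame with columns `accession`, `gene`,
#'   `unique_peptides`, `abundance`, run metadata attached as attribute
#'   `metadata`.
#' @export
read_evidence <- function(path, metadata, aliases = NULL, sep = NULL) {
  raw <- read_delim_table(path, sep = sep)
  al <- utils::modifyList(evidence_aliases(), aliases %||% list())
  cols <- vapply(names(al), function(field) {
    hit <- which(tolower(names(raw)) %in% tolower(al[[field]]))
    if (length(hit) == 0)
      format_error("evidence file '%s' has no column for '%s' (aliases: %s)",
                   path, field, paste(al[[field]], collapse = ", "))
    hit[1]
  }, integer(1))
  tab <- data.frame(
    accession = as.character(raw[[cols["accession"]]]),
    gene = as.character(raw[[cols["gene"]]]),
    unique_peptides = suppressWarnings(as.integer(raw[[cols["unique_peptides"]]])),
    abundance = suppressWarnings(as.numeric(raw[[cols["abundance"]]])),
    stringsAsFactors = FALSE
  )
  evidence_table(tab, metadata)
}

#' @rdname read_evidence
#' @param table Data frame with the four evidence columns.
#' @export
evidence_table <- function(table, metadata) {
  validate_manifest(metadata)
  if (nrow(metadata) != 1L)
    validation_error("evidence table metadata must describe exactly one run")
  bad <- which(is.na(table$unique_peptides) | table$unique_peptides < 0)
  if (length(bad) > 0)
    validation_error("negative or missing unique_peptides at row %d", bad[1])
  bad <- which(is.na(table$abundance) | table$abundance < 0)
  if (length(bad) > 0)
    validation_error("negative or missing abundance at row %d", bad[1])
  bad <- which(table$unique_peptides == 0 & table$abundance > 0)
  if (length(bad) > 0)
    validation_error("abundance > 0 with unique_peptides = 0 at row %d", bad[1])
  if (anyDuplicated(table$accession))
    validation_error("duplicate accession within run %s: %s", metadata$run_id,
                     table$accession[which(duplicated(table$accession))[1]])
  structure(table, metadata = metadata,
            class = c("evidence_table", "data.frame"))
}

#' @rdname read_evidence
#' @export
write_evidence <- function(table, path, sep = NULL) {
  write_delim_table(as.data.frame(table)[, c("accession", "gene", "unique_peptides", "abundance")],
                    path, sep = sep)
}

#' @export
print.evidence_table <- function(x, ...) {
  md <- attr(x, "metadata")
  cat(sprintf("Evidence table: run %s (%s, %s, %g h, %s, rep %d), %d proteins\n",
              md$run_id, md$cell_line, md$construct, md$biotin_hours,
              md$treatment, md$replicate, nrow(x)))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Contaminant exclusion lists
#'
#' BioID candidate lists are purged of two systematic contaminant classes:
#' keratins (ubiquitous sample-handling contamination, recognised by gene-symbol
#' prefix) and endogenously biotinylated carboxylases, which bind streptavidin
#' regardless of proximity labeling.
#'
#' @param keratin_prefix Gene-symbol prefix marking keratins (default `"KRT"`).
#' @param keratin_genes Extra explicit keratin symbols.
#' @param endogenous_biotin_genes Symbols of endogenously biotinylated proteins;
#'   defaults to the human biotin-dependent carboxylase genes.
#' @param bait_gene Optional bait symbol; the lists must not contain it.
#' @return An `exclusion_lists` object.
#' @export
exclusion_lists <- function(keratin_prefix = "KRT",
                            keratin_genes = character(0),
                            endogenous_biotin_genes = c("ACACA", "ACACB", "PC",
                                                        "PCCA", "PCCB", "MCCC1", "MCCC2"),
                            bait_gene = NULL) {
  lists <- structure(list(
    keratin_prefix = toupper(keratin_prefix),
    keratin_genes = toupper(keratin_genes),
    endogenous_biotin_genes = toupper(endogenous_biotin_genes)
  ), class = "exclusion_lists")
  if (!is.null(bait_gene)) {
    bg <- toupper(bait_gene)
    if (is_keratin(bg, lists) || bg %in% lists$endogenous_biotin_genes)
      validation_error("exclusion lists must be disjoint from the bait gene '%s'", bait_gene)
  }
  lists
}

# gene symbols matched case-insensitively throughout
is_keratin <- function(gene, lists) {
  g <- toupper(gene)
  startsWith(g, lists$keratin_prefix) | g %in% lists$keratin_genes
}

is_endogenous_biotin <- function(gene, lists) {
  toupper(gene) %in% lists$endogenous_biotin_genes
}

gaf_aspects <- c(P = "biological_process", C = "cellular_component",
                 F = "molecular_function")

#' Read a GO annotation set
#'
#' Two supported layouts: `two_column_tsv` — (term_id, gene) pairs plus a
#' sidecar term-metadata table (term_id, name, namespace) — or `gaf_like` —
#' GAF 2.x column positions (gene symbol in column 3, GO id in column 5,
#' aspect code P/C/F in column 9), `!`-comment lines skipped. Duplicate
#' (term, gene) pairs collapse to one; the background is the union of all
#' annotated genes.
#'
#' @param path Annotation file.
#' @param format `"two_column_tsv"` or `"gaf_like"`.
#' @param term_meta_path Sidecar term metadata TSV for `two_column_tsv`
#'   (columns `term_id`, `name`, `namespace`); optional.
#' @return An `annotation_set`: list with `term_to_genes` (named list of
#'   gene-symbol vectors), `term_meta` (data frame), `background` (character).
#' @export
read_annotations <- function(path, format = c("two_column_tsv", "gaf_like"),
                             term_meta_path = NULL) {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "!")]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) validation_error("annotation file '%s' is empty", path)
  if (format == "two_column_tsv") {
    has_header <- grepl("^term", tolower(lines[1]))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (has_header) fields <- fields[-1]
    if (length(fields) == 0) validation_error("annotation file '%s' has no data rows", path)
    term <- vapply(fields, `[`, character(1), 1)
    gene <- vapply(fields, `[`, character(1), 2)
    meta <- NULL
    if (!is.null(term_meta_path)) {
      meta <- read_delim_table(term_meta_path)
      names(meta) <- tolower(names(meta))
    }
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    short <- vapply(fields, length, integer(1)) < 9
    if (any(short))
      validation_error("GAF-like line %d has fewer than 9 columns", which(short)[1])
    gene <- vapply(fields, `[`, character(1), 3)
    term <- vapply(fields, `[`, character(1), 5)
    aspect <- vapply(fields, `[`, character(1), 9)
    bad <- !aspect %in% names(gaf_aspects)
    if (any(bad))
      validation_error("unknown GAF aspect code '%s' (line %d)",
                       aspect[which(bad)[1]], which(bad)[1])
    meta <- data.frame(term_id = term, name = term,
                       namespace = unname(gaf_aspects[aspect]),
                       stringsAsFactors = FALSE)
    meta <- meta[!duplicated(meta$term_id), ]
  }
  annotation_set(term = term, gene = gene, term_meta = meta)
}

#' @rdname read_annotations
#' @param term,gene Parallel vectors of (term id, gene symbol) pairs.
#' @param term_meta Optional data frame `term_id`, `name`, `namespace`.
#' @export
annotation_set <- function(term, gene, term_meta = NULL) {
  gene <- toupper(gene)
  keep <- !duplicated(paste(term, gene, sep = "\r"))
  term <- term[keep]; gene <- gene[keep]
  term_to_genes <- split(gene, term)
  if (any(lengths(term_to_genes) == 0))
    validation_error("annotation set contains an empty term")
  if (is.null(term_meta)) {
    ids <- names(term_to_genes)
    term_meta <- data.frame(term_id = ids, name = ids,
                            namespace = "biological_process",
                            stringsAsFactors = FALSE)
  }
  bad <- !term_meta$namespace %in% unname(gaf_aspects)
  if (any(bad))
    validation_error("unknown namespace '%s' in term metadata",
                     term_meta$namespace[which(bad)[1]])
  missing <- setdiff(names(term_to_genes), term_meta$term_id)
  if (length(missing) > 0)
    term_meta <- rbind(term_meta,
                       data.frame(term_id = missing, name = missing,
                                  namespace = "biological_process",
                                  stringsAsFactors = FALSE))
  structure(list(
    term_to_genes = term_to_genes,
    term_meta = term_meta[term_meta$term_id %in% names(term_to_genes), ],
    background = sort(unique(gene))
  ), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("Annotation set: %d terms, %d background genes\n",
              length(x$term_to_genes), length(x$background)))
  print(table(x$term_meta$namespace))
  invisible(x)
}

#' @rdname read_annotations
#' @param annotations An `annotation_set`.
#' @param pairs_path,meta_path Output paths for the pair and term-metadata TSVs.
#' @export
write_annotations <- function(annotations, pairs_path, meta_path = NULL) {
  pairs <- data.frame(
    term_id = rep(names(annotations$term_to_genes), lengths(annotations$term_to_genes)),
    gene = unlist(annotations$term_to_genes, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  write_delim_table(pairs, pairs_path, sep = "\t")
  if (!is.null(meta_path)) write_delim_table(annotations$term_meta, meta_path, sep = "\t")
  invisible(pairs_path)
}

#' Read a known-interaction edge table
#'
#' Three delimited columns: gene_a, gene_b, confidence. Scores may be on the
#' unit scale or the STRING 0-1000 scale (rescaled to 0-1). Edges are
#' unordered: reversed duplicates collapse keeping the maximum confidence;
#' self-loops are dropped. Only edges at or above `min_confidence` are kept —
#' the confidence floor standing in for a STRING import selectivity of 0.5.
#'
#' @param path Delimited edge file; an empty file yields an empty table.
#' @param min_confidence Inclusive confidence floor on the unit scale.
#' @param score_scale `"unit"` (0-1) or `"string"` (0-1000).
#' @return A `known_edge_table` data frame: `gene_a`, `gene_b`, `confidence`,
#'   with `gene_a < gene_b` lexicographically.
#' @export
read_known_edges <- function(path, min_confidence = 0.5,
                             score_scale = c("unit", "string")) {
  score_scale <- match.arg(score_scale)
  empty <- structure(
    data.frame(gene_a = character(0), gene_b = character(0),
               confidence = numeric(0), stringsAsFactors = FALSE),
    class = c("known_edge_table", "data.frame"))
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) return(empty)
  raw <- read_delim_table(path)
  if (nrow(raw) == 0) return(empty)
  conf <- as.numeric(raw[[3]])
  hi <- if (score_scale == "string") 1000 else 1
  bad <- which(is.na(conf) | conf < 0 | conf > hi)
  if (length(bad) > 0)
    validation_error("edge confidence outside declared scale [0, %g] at row %d", hi, bad[1])
  known_edge_table(as.character(raw[[1]]), as.character(raw[[2]]),
                   conf / hi, min_confidence = min_confidence)
}

#' @rdname read_known_edges
#' @param gene_a,gene_b,confidence Parallel edge vectors (confidence on 0-1).
#' @export
known_edge_table <- function(gene_a, gene_b, confidence, min_confidence = 0) {
  gene_a <- toupper(gene_a); gene_b <- toupper(gene_b)
  keep <- gene_a != gene_b
  gene_a <- gene_a[keep]; gene_b <- gene_b[keep]; confidence <- confidence[keep]
  lo <- pmin(gene_a, gene_b); hi <- pmax(gene_a, gene_b)
  key <- paste(lo, hi, sep = "\r")
  conf <- tapply(confidence, key, max)
  parts <- strsplit(names(conf), "\r", fixed = TRUE)
  out <- data.frame(
    gene_a = vapply(parts, `[`, character(1), 1),
    gene_b = vapply(parts, `[`, character(1), 2),
    confidence = as.numeric(conf), stringsAsFactors = FALSE
  )
  out <- out[out$confidence >= min_confidence, , drop = FALSE]
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("known_edge_table", "data.frame"))
}

#' @rdname read_known_edges
#' @param edges A `known_edge_table`.
#' @export
write_known_edges <- function(edges, path) {
  write_delim_table(as.data.frame(edges), path)
}
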