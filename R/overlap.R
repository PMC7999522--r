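#' Pairwise overlaps between candidate lists
#'
#' Exact set algebra over named candidate lists: for every pair, how many
#' genes are exclusive to each and how many are shared — the numbers a
#' two-set Venn diagram displays — plus the size of the global union.
#'
#' @param lists Named list of character vectors (gene symbols).
#' @return A `venn_summary`: list with `sizes`, `pairs` (data frame `a`, `b`,
#'   `a_only`, `intersection`, `b_only`) and `union_size`.
#' @export
compute_overlaps <- function(lists) {
  if (length(lists) < 2) validation_error("need at least 2 candidate lists")
  if (is.null(names(lists)) || any(!nzchar(names(lists))))
    validation_error("candidate lists must be named")
  if (anyDuplicated(names(lists)))
    validation_error("duplicate list name: %s",
                     names(lists)[which(duplicated(names(lists)))[1]])
  lists <- lapply(lists, unique)
  nm <- names(lists)
  pairs_idx <- utils::combn(seq_along(lists), 2)
  pairs <- data.frame(
    a = nm[pairs_idx[1, ]], b = nm[pairs_idx[2, ]],
    a_only = integer(ncol(pairs_idx)), intersection = integer(ncol(pairs_idx)),
    b_only = integer(ncol(pairs_idx)), stringsAsFactors = FALSE
  )
  for (i in seq_len(ncol(pairs_idx))) {
    A <- lists[[pairs_idx[1, i]]]; B <- lists[[pairs_idx[2, i]]]
    pairs$intersection[i] <- length(intersect(A, B))
    pairs$a_only[i] <- length(setdiff(A, B))
    pairs$b_only[i] <- length(setdiff(B, A))
  }
  structure(list(
    sizes = vapply(lists, length, integer(1)),
    pairs = pairs,
    union_size = length(unique(unlist(lists)))
  ), class = "venn_summary")
}

#' @export
print.venn_summary <- function(x, ...) {
  cat(sprintf("Overlap summary over %d lists (union %d genes)\n",
              length(x$sizes), x$union_size))
  print(x$pairs, row.names = FALSE)
  invisible(x)
}

#' @rdname compute_overlaps
#' @param venn A `venn_summary`.
#' @param path Output JSON path.
#' @export
write_venn_summary <- function(venn, path) {
  jsonlite::write_json(
    list(sizes = as.list(venn$sizes), pairs = venn$pairs,
         union_size = venn$union_size),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Build the protein-by-experiment ratio matrix
#'
#' The heatmap backbone: retained proteins as rows, experiments (batches) as
#' columns, biotinylation ratios as cells. Undefined ratios stay `NA` — a
#' sentinel distinct from a low ratio, never imputed. Rows are ordered by
#' descending maximum ratio (ties by gene symbol), which places the
#' self-biotinylated bait first. The attribute `qualified` marks cells whose
#' ratio exceeds the cascade threshold.
#'
#' @param candidates A `candidate_set` from [run_cascade()].
#' @return A `ratio_matrix`: numeric matrix (genes x experiments) with
#'   attributes `qualified` (logical matrix) and `threshold`.
#' @export
build_ratio_matrix <- function(candidates) {
  ret <- retained(candidates)
  if (nrow(ret) == 0) validation_error("no retained candidates to build a matrix from")
  ratios <- attr(candidates, "ratios")
  config <- attr(candidates, "config")
  batches <- sort(unique(ratios$batch_id))
  ord <- order(-ret$max_ratio, ret$gene)
  genes <- ret$gene[ord]
  acc <- ret$accession[ord]
  m <- matrix(NA_real_, length(genes), length(batches),
              dimnames = list(genes, batches))
  for (i in seq_along(acc)) {
    rows <- ratios[ratios$accession == acc[i], ]
    m[i, rows$batch_id] <- rows$ratio
  }
  q <- !is.na(m) & m > config$ratio_threshold_exclusive
  structure(m, qualified = q, threshold = config$ratio_threshold_exclusive,
            class = c("ratio_matrix", class(m)))
}

#' @export
print.ratio_matrix <- function(x, ...) {
  cat(sprintf("Ratio matrix: %d proteins x %d experiments (threshold %.3g)\n",
              nrow(x), ncol(x), attr(x, "threshold")))
  print(round(unclass(x)[seq_len(min(10, nrow(x))), , drop = FALSE], 2))
  if (nrow(x) > 10) cat(sprintf("... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' @export
plot.ratio_matrix <- function(x, main = "Biotinylation ratio heatmap", ...) {
  m <- log2(unclass(x))
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  graphics::image(t(m), axes = FALSE, main = main,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  graphics::axis(1, at = seq(0, 1, length.out = ncol(m)), labels = colnames(m),
                 las = 2, cex.axis = 0.7)
  graphics::axis(2, at = seq(0, 1, length.out = nrow(m)), labels = rownames(m),
                 las = 2, cex.axis = 0.5)
  invisible(x)
}

#' @rdname build_ratio_matrix
#' @param matrix A `ratio_matrix`.
#' @param path Output TSV path (genes x experiment columns; `NA` for
#'   undefined cells).
#' @export
write_ratio_matrix <- function(matrix, path) {
  df <- data.frame(gene = rownames(matrix), as.data.frame(unclass(matrix)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_delim_table(df, path)
}

#' Summarise biotinylation ratios of a GO term's proteins
#'
#' Box-plot statistics for the ratios (one experiment column) of retained
#' proteins annotated to a term, with the bait excluded by default — its
#' self-biotinylation ratio would dominate any distribution it joins.
#' Quartiles follow the inclusive-median (Tukey hinge) convention; whiskers
#' extend to the most extreme data point within 1.5 x IQR of the hinges;
#' points beyond are outliers.
#'
#' @param matrix A `ratio_matrix`.
#' @param annotations An `annotation_set`.
#' @param term Term id to summarise.
#' @param experiment Experiment (column) name; defaults to the first column.
#' @param exclude Gene symbols to omit (default: attribute-free — pass the
#'   bait gene; [run_bioid_pipeline()] passes it automatically).
#' @return List: `n`, `quartiles` (q1, median, q3), `whiskers` (lo, hi),
#'   `outliers`, `genes`; `n = 0` with empty fields when no protein is
#'   eligible.
#' @export
summarize_ratios_by_term <- function(matrix, annotations, term,
                                     experiment = colnames(matrix)[1],
                                     exclude = character(0)) {
  if (!term %in% names(annotations$term_to_genes))
    lookup_error("unknown term '%s'", term)
  if (!experiment %in% colnames(matrix))
    lookup_error("unknown experiment column '%s'", experiment)
  members <- annotations$term_to_genes[[term]]
  genes <- rownames(matrix)[toupper(rownames(matrix)) %in% toupper(members)]
  genes <- genes[!toupper(genes) %in% toupper(exclude)]
  vals <- unclass(matrix)[genes, experiment]
  genes <- genes[!is.na(vals)]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0)
    return(list(n = 0L, quartiles = c(q1 = NA_real_, median = NA_real_, q3 = NA_real_),
                whiskers = c(lo = NA_real_, hi = NA_real_),
                outliers = numeric(0), genes = character(0), empty = TRUE))
  fn <- stats::fivenum(vals)  # Tukey hinges = inclusive-median quartiles
  q1 <- fn[2]; med <- fn[3]; q3 <- fn[4]
  iqr <- q3 - q1
  lo_fence <- q1 - 1.5 * iqr; hi_fence <- q3 + 1.5 * iqr
  inside <- vals >= lo_fence & vals <= hi_fence
  list(
    n = length(vals),
    quartiles = c(q1 = q1, median = med, q3 = q3),
    whiskers = c(lo = min(vals[inside]), hi = max(vals[inside])),
    outliers = sort(unname(vals[!inside])),
    genes = genes[order(vals)],
    empty = FALSE
  )
}
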