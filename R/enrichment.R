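#' Hypergeometric upper-tail p-value
#'
#' Probability of drawing at least `k` annotated genes when sampling `n`
#' genes without replacement from a background of `N` genes of which `K`
#' carry the annotation: `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`.
#' The tail is accumulated in log space (log-sum-exp over log binomial
#' coefficients) for numerical stability at extreme counts; `k = 0` returns
#' exactly 1.
#'
#' @param k Observed annotated genes in the query (0 <= k <= min(K, n)).
#' @param K Annotated genes in the background.
#' @param n Query size.
#' @param N Background size.
#' @return The upper-tail p-value in (0, 1].
#' @export
hypergeom_pvalue <- function(k, K, n, N) {
  if (length(k) > 1 || length(K) > 1 || length(n) > 1 || length(N) > 1)
    return(mapply(hypergeom_pvalue, k, K, n, N))
  if (is.na(k) || is.na(K) || is.na(n) || is.na(N) ||
      k < 0 || K < 0 || n < 0 || K > N || n > N || k > min(K, n))
    bioid_error("bioid_domain_error",
                "invalid hypergeometric arguments k=%s K=%s n=%s N=%s", k, K, n, N)
  if (k == 0) return(1)
  i <- k:min(K, n)
  log_terms <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(log_terms)
  min(1, exp(m + log(sum(exp(log_terms - m)))))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Controls the false discovery rate across a family of tests: with the raw
#' p-values sorted ascending, `p_adj(i) = min over j >= i of min(1, p(j) * m / j)`,
#' returned in the original order.
#'
#' @param p Vector of raw p-values in (0, 1].
#' @return Adjusted p-values, same order and length.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p) | p <= 0 | p > 1))
    bioid_error("bioid_domain_error", "p-values must lie in (0, 1]")
  m <- length(p)
  ord <- order(p)
  scaled <- pmin(1, p[ord] * m / seq_len(m))
  adj <- rev(cummin(rev(scaled)))
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' GO term over-representation analysis
#'
#' For each term with at least one query hit, tests whether the query set
#' contains more of the term's genes than expected under hypergeometric
#' sampling from the annotation background. P-values are adjusted by
#' Benjamini-Hochberg within each namespace (the three GO aspects are
#' separate test families). A term is `reported` when it has at least
#' `min_genes_reported` query hits and an adjusted p-value below
#' `p_adj_threshold` — the reporting gate applied on top of the statistics,
#' not part of them.
#'
#' @param query Character vector of gene symbols (case-folded, deduplicated;
#'   genes outside the background are dropped from `n`).
#' @param annotations An `annotation_set`.
#' @param namespaces Which namespaces to test (default all three).
#' @param min_genes_reported Minimum query hits for reporting (default 3).
#' @param p_adj_threshold Adjusted-p gate for reporting (default 0.01).
#' @return An `enrichment_result` data frame sorted by `p_adj` then term id:
#'   `term_id`, `name`, `namespace`, `k`, `K`, `n`, `N`, `p_raw`, `p_adj`,
#'   `reported`.
#' @export
run_enrichment <- function(query, annotations,
                           namespaces = c("biological_process",
                                          "cellular_component",
                                          "molecular_function"),
                           min_genes_reported = 3L,
                           p_adj_threshold = 0.01) {
  query <- unique(toupper(query))
  bg <- annotations$background
  mapped <- intersect(query, bg)
  if (length(mapped) == 0)
    validation_error("no query gene maps to the annotation background (unmapped: %s)",
                     paste(utils::head(query, 10), collapse = ", "))
  n <- length(mapped)
  N <- length(bg)
  meta <- annotations$term_meta
  meta <- meta[meta$namespace %in% namespaces, , drop = FALSE]
  rows <- lapply(seq_len(nrow(meta)), function(i) {
    tid <- meta$term_id[i]
    members <- unique(toupper(annotations$term_to_genes[[tid]]))
    K <- length(members)
    k <- length(intersect(mapped, members))
    if (k < 1) return(NULL)
    data.frame(term_id = tid, name = meta$name[i], namespace = meta$namespace[i],
               k = k, K = K, n = n, N = N,
               p_raw = hypergeom_pvalue(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows))
    rows <- data.frame(term_id = character(0), name = character(0),
                       namespace = character(0), k = integer(0), K = integer(0),
                       n = integer(0), N = integer(0), p_raw = numeric(0),
                       stringsAsFactors = FALSE)
  rows$p_adj <- NA_real_
  for (ns in unique(rows$namespace)) {
    idx <- rows$namespace == ns
    rows$p_adj[idx] <- bh_adjust(rows$p_raw[idx])
  }
  rows$reported <- rows$k >= min_genes_reported & rows$p_adj < p_adj_threshold
  rows <- rows[order(rows$p_adj, rows$term_id), , drop = FALSE]
  rownames(rows) <- NULL
  structure(rows,
            adjust_method = "benjamini_hochberg",
            query_mapped = mapped,
            class = c("enrichment_result", "data.frame"))
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Over-representation analysis: %d terms tested (n = %d query genes, N = %d background), %d reported\n",
              nrow(x), if (nrow(x) > 0) x$n[1] else 0L,
              if (nrow(x) > 0) x$N[1] else 0L, sum(x$reported)))
  top <- as.data.frame(x)[seq_len(min(8, nrow(x))),
                          c("term_id", "namespace", "k", "K", "p_adj", "reported")]
  print(top, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @rdname run_enrichment
#' @param result An `enrichment_result`.
#' @param path Output TSV path (term, annotation, genes found, genes in term,
#'   raw and adjusted p, reporting flag).
#' @export
write_enrichment <- function(result, path) {
  write_delim_table(as.data.frame(result), path)
}
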