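#' Select genes co-expressed with a set of query genes
#'
#' From an expression matrix, computes the Pearson correlation of every
#' candidate gene with every query gene and the two-sided p-value from the
#' t transform `t = r * sqrt((m - 2) / (1 - r^2))` with `m` samples. Pairs
#' with `r >= r_min` (signed) and `p <= p_max` are kept, capped at `top_k`
#' per query by descending correlation, and the union over queries is
#' returned. Alternatively a precomputed co-expression table
#' (`query_gene`, `partner_gene`, `r`, `p`) is filtered with the same
#' rules. Self-pairs, and candidates whose expression vector duplicates the
#' query's, are excluded; constant candidates (undefined correlation) are
#' skipped with a logged warning.
#'
#' @param source Numeric matrix (rows = genes, columns = samples, with
#'   rownames) or a data frame with columns `query_gene`, `partner_gene`,
#'   `r`, `p`.
#' @param query_genes Character vector of query gene ids.
#' @param r_min Signed correlation threshold (default 0.7).
#' @param p_max Correlation p-value threshold (default 0.05).
#' @param top_k Maximum partners retained per query (default 20000).
#' @param method Correlation measure for the matrix route: `"pearson"`
#'   (default) or `"spearman"` (rank-transform then the same t test).
#' @return A [gene_set()]; its provenance holds one row per retained
#'   (query, partner) pair with `r` and `p`.
#' @export
coexpression_filter <- function(source, query_genes, r_min = 0.7,
                                p_max = 0.05, top_k = 20000L,
                                method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (is.matrix(source)) {
    pairs <- .coexpr_from_matrix(source, query_genes, method)
  } else {
    stopifnot(all(c("query_gene", "partner_gene", "r", "p") %in% names(source)))
    pairs <- source[source$query_gene %in% query_genes, , drop = FALSE]
    pairs <- pairs[pairs$query_gene != pairs$partner_gene, , drop = FALSE]
  }
  pairs <- pairs[!is.na(pairs$r) & pairs$r >= r_min & pairs$p <= p_max, ,
                 drop = FALSE]
  kept <- lapply(split(pairs, pairs$query_gene), function(d) {
    d <- d[order(-d$r, d$partner_gene), , drop = FALSE]
    head(d, top_k)
  })
  prov <- if (length(kept)) do.call(rbind, kept) else pairs
  rownames(prov) <- NULL
  gs <- gene_set(label = paste0("coexpr:", paste(query_genes, collapse = "+")),
                 genes = unique(prov$partner_gene), provenance = prov)
  gs
}

.coexpr_from_matrix <- function(expr, query_genes, method) {
  if (is.null(rownames(expr))) stop("expression matrix needs gene rownames")
  missing_q <- setdiff(query_genes, rownames(expr))
  if (length(missing_q)) {
    stop("query genes absent from expression matrix: ",
         paste(missing_q, collapse = ", "))
  }
  m <- ncol(expr)
  if (m < 3L) stop("need at least 3 samples per gene")
  if (method == "spearman") expr <- t(apply(expr, 1, rank))
  sds <- apply(expr, 1, sd)
  if (any(sds[query_genes] == 0)) {
    stop("query gene has constant expression: ",
         paste(query_genes[sds[query_genes] == 0], collapse = ", "))
  }
  const <- names(sds)[sds == 0]
  if (length(const)) {
    arfnet_log("WARN", length(const),
               " candidate gene(s) with constant expression skipped")
  }
  cand <- setdiff(rownames(expr), const)
  r <- suppressWarnings(
    cor(t(expr[query_genes, , drop = FALSE]), t(expr[cand, , drop = FALSE])))
  out <- list()
  for (q in query_genes) {
    rv <- r[q, ]
    # self and exact duplicates of the query vector are excluded
    near <- names(rv)[!is.na(rv) & rv > 1 - 1e-12]
    dup <- near[vapply(near, function(g)
      isTRUE(all.equal(unname(expr[g, ]), unname(expr[q, ]))), logical(1))]
    keep <- setdiff(names(rv), c(q, dup))
    rv <- pmin(pmax(rv[keep], -1), 1)
    tt <- rv * sqrt((m - 2) / pmax(1 - rv^2, .Machine$double.eps))
    pp <- 2 * pt(abs(tt), df = m - 2, lower.tail = FALSE)
    pp[abs(rv) >= 1 - 1e-15] <- 0
    out[[q]] <- data.frame(query_gene = q, partner_gene = keep,
                           r = unname(rv), p = unname(pp),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Restrict a co-expressed gene set to genes with promoter motif hits
#'
#' Keeps genes with at least `min_hits` motif occurrences in their upstream
#' sequence. Genes whose promoter was never scanned (absent from
#' `scanned_ids`) are dropped and counted in a logged "no-promoter" tally.
#'
#' @param coexpressed A [gene_set()] from [coexpression_filter()].
#' @param hits Hit table from [scan_promoters()] (`sequence_id` = gene id).
#' @param min_hits Minimum number of hits required (default 1).
#' @param scanned_ids Ids of the promoters that were scanned; defaults to
#'   the ids present in `hits` plus the co-expressed genes (i.e. no gene is
#'   treated as promoter-less) when `NULL`.
#' @return A `target_gene_set`: a [gene_set()] whose provenance records,
#'   per gene, the co-expression support and the best motif hit, and which
#'   carries the co-expressed input size as attribute `n_coexpressed`.
#' @export
filter_by_motif <- function(coexpressed, hits, min_hits = 1L,
                            scanned_ids = NULL) {
  stopifnot(inherits(coexpressed, "gene_set"))
  genes <- coexpressed$genes
  if (is.null(scanned_ids)) scanned_ids <- union(genes, hits$sequence_id)
  no_promoter <- setdiff(genes, scanned_ids)
  if (length(no_promoter)) {
    arfnet_log("WARN", length(no_promoter),
               " co-expressed gene(s) without a promoter sequence dropped")
  }
  genes <- intersect(genes, scanned_ids)
  nh <- table(factor(hits$sequence_id, levels = genes))
  keep <- names(nh)[nh >= min_hits]
  best <- lapply(keep, function(g) {
    h <- hits[hits$sequence_id == g, , drop = FALSE]
    h[which.min(h$p), c("motif_id", "start", "strand", "score", "p")]
  })
  prov <- if (length(keep)) {
    b <- do.call(rbind, best)
    data.frame(gene_id = keep, n_hits = as.integer(nh[keep]),
               best_motif = b$motif_id, best_start = b$start,
               best_strand = b$strand, best_score = b$score, best_p = b$p,
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    data.frame(gene_id = character(), n_hits = integer(),
               best_motif = character(), best_start = integer(),
               best_strand = character(), best_score = numeric(),
               best_p = numeric(), stringsAsFactors = FALSE)
  }
  coex_prov <- coexpressed$provenance
  if (!is.null(coex_prov) && nrow(prov)) {
    cp <- coex_prov[match(prov$gene_id, coex_prov$partner_gene), c("r", "p")]
    prov$coexpr_r <- cp$r
    prov$coexpr_p <- cp$p
  }
  out <- gene_set(label = paste0(coexpressed$label, " + motif"),
                  genes = keep, provenance = prov)
  attr(out, "n_coexpressed") <- length(coexpressed$genes)
  attr(out, "n_no_promoter") <- length(no_promoter)
  class(out) <- c("target_gene_set", class(out))
  out
}
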