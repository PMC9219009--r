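#' Propagate annotations up the ontology (true-path rule)
#'
#' A gene annotated to a term is implicitly annotated to every ancestor of
#' that term, over both `is_a` and `part_of` edges. Annotations to term ids
#' absent from the ontology are logged and skipped. Idempotent.
#'
#' @param annotations An `annotation_table` (see [read_annotation_table()]).
#' @param dag An [ontology_graph()].
#' @return Named list: term id -> character vector of annotated genes
#'   (direct or inherited), for every term with at least one gene.
#' @export
propagate_annotations <- function(annotations, dag) {
  stopifnot(inherits(dag, "ontology_graph"))
  known <- annotations$term_id %in% dag$terms$id
  if (any(!known)) {
    arfnet_log("WARN", sum(!known),
               " annotation(s) to terms absent from the ontology skipped")
  }
  ann <- annotations[known, , drop = FALSE]
  direct <- lapply(split(ann$gene_id, ann$term_id), unique)
  order_cf <- .topo_order(dag)  # children first; errors on cycles
  parents_of <- split(dag$edges$parent, factor(dag$edges$child,
                                               levels = dag$terms$id))
  acc <- new.env(parent = emptyenv())
  for (t in names(direct)) assign(t, direct[[t]], envir = acc)
  for (t in order_cf) {
    genes_t <- if (exists(t, envir = acc, inherits = FALSE))
      get(t, envir = acc) else NULL
    if (is.null(genes_t)) next
    for (p in parents_of[[t]]) {
      prev <- if (exists(p, envir = acc, inherits = FALSE))
        get(p, envir = acc) else character()
      assign(p, union(prev, genes_t), envir = acc)
    }
  }
  out <- mget(ls(acc), envir = acc)
  out[order(names(out))]
}

#' Hypergeometric enrichment p-value (upper tail)
#'
#' Probability of drawing at least `x` genes of a term of size `n` when
#' sampling `k` genes from a population of `N`:
#' `p = sum_{i=x}^{min(n,k)} C(n,i) C(N-n,k-i) / C(N,k)`.
#'
#' @param x Study genes annotated to the term.
#' @param n Population genes annotated to the term.
#' @param k Study-set size.
#' @param N Population size.
#' @return The upper-tail p-value in (0, 1].
#' @export
hypergeometric_test <- function(x, n, k, N) {
  if (any(x < 0) || any(x > pmin(n, k)) || any(k > N) || any(n > N)) {
    stop("require 0 <= x <= min(n, k), k <= N, n <= N")
  }
  phyper(x - 1, n, N - n, k, lower.tail = FALSE)
}

#' Multiple-testing correction for enrichment p-values
#'
#' @param ps Vector of p-values in (0, 1].
#' @param method `"BH"` (Benjamini-Hochberg step-up, the default),
#'   `"bonferroni"`, or `"none"`.
#' @return Corrected q-values, in the input order, clipped at 1.
#' @export
correct_pvalues <- function(ps, method = c("BH", "bonferroni", "none")) {
  method <- match.arg(method)
  if (any(ps <= 0 | ps > 1, na.rm = TRUE)) stop("p-values must lie in (0, 1]")
  p.adjust(ps, method = method)
}

#' Build a GO enrichment network map from a target gene set
#'
#' Propagates annotations, tests every namespace term with at least one
#' study and one population gene by the hypergeometric upper tail, corrects
#' the p-values, and assembles the network of significant terms (q <=
#' `q_max`) together with their ancestors up to the namespace root as
#' non-significant context nodes. Node attributes carry the term name, the
#' study gene count, and p and q.
#'
#' @param targets A [gene_set()] (typically a `target_gene_set` from
#'   [filter_by_motif()]).
#' @param annotations An `annotation_table`.
#' @param dag An [ontology_graph()].
#' @param population Optional [gene_set()] defining the reference
#'   population; defaults to all genes with at least one namespace
#'   annotation after propagation.
#' @param q_max Significance threshold on corrected p-values.
#' @param namespace Ontology namespace to test (default
#'   `"biological_process"`).
#' @param correction Passed to [correct_pvalues()].
#' @return An `enrichment_network`: list with `graph` (igraph, edges child
#'   -> parent, vertex attributes `term_name`, `gene_count`, `p`, `q`,
#'   `significant`), `results` (data frame of all tested terms), `label`,
#'   and the funnel counts `n_coexpressed` / `n_targets` when the target
#'   set carries them.
#' @export
build_map <- function(targets, annotations, dag, population = NULL,
                      q_max = 0.05, namespace = "biological_process",
                      correction = "BH") {
  stopifnot(inherits(targets, "gene_set"), inherits(dag, "ontology_graph"))
  ns_terms <- dag$terms$id[dag$terms$namespace == namespace]
  term_genes <- propagate_annotations(annotations, dag)
  term_genes <- term_genes[names(term_genes) %in% ns_terms]
  pop <- if (is.null(population)) {
    unique(unlist(term_genes, use.names = FALSE))
  } else {
    population$genes
  }
  study <- intersect(targets$genes, pop)
  if (length(study) < length(targets$genes)) {
    arfnet_log("WARN", length(targets$genes) - length(study),
               " target gene(s) outside the population ignored")
  }
  N <- length(pop)
  k <- length(study)
  rows <- lapply(names(term_genes), function(t) {
    g <- intersect(term_genes[[t]], pop)
    n <- length(g)
    x <- length(intersect(g, study))
    if (n < 1L || x < 1L) return(NULL)
    data.frame(term_id = t, x = x, n = n, k = k, N = N,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(term_id = character(), x = integer(), n = integer(),
                      k = integer(), N = integer(), p = numeric(),
                      q = numeric(), significant = logical(),
                      stringsAsFactors = FALSE)
  } else {
    res$p <- hypergeometric_test(res$x, res$n, res$k, res$N)
    res$q <- correct_pvalues(res$p, method = correction)
    res$significant <- res$q <= q_max
  }
  res$term_name <- dag$terms$name[match(res$term_id, dag$terms$id)]
  res <- res[order(res$p, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  # network: significant terms plus their ancestors as context
  sig <- res$term_id[res$significant]
  anc <- .ancestors_of(dag, sig)
  nodes <- union(sig, anc)
  g <- .map_graph(dag, nodes, res)
  structure(list(graph = g, results = res, label = targets$label,
                 q_max = q_max, namespace = namespace,
                 n_coexpressed = attr(targets, "n_coexpressed"),
                 n_targets = length(targets$genes)),
            class = "enrichment_network")
}

.ancestors_of <- function(dag, terms) {
  parents_of <- split(dag$edges$parent, factor(dag$edges$child,
                                               levels = dag$terms$id))
  seen <- character()
  frontier <- terms
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(parents_of[frontier], use.names = FALSE)),
                   seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

.map_graph <- function(dag, nodes, res) {
  e <- dag$edges[dag$edges$child %in% nodes & dag$edges$parent %in% nodes, ,
                 drop = FALSE]
  g <- igraph::graph_from_data_frame(
    d = e[, c("child", "parent"), drop = FALSE], directed = TRUE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  idx <- match(igraph::V(g)$name, res$term_id)
  igraph::V(g)$term_name <-
    dag$terms$name[match(igraph::V(g)$name, dag$terms$id)]
  igraph::V(g)$gene_count <- ifelse(is.na(idx), 0L, res$x[idx])
  igraph::V(g)$p <- ifelse(is.na(idx), NA_real_, res$p[idx])
  igraph::V(g)$q <- ifelse(is.na(idx), NA_real_, res$q[idx])
  igraph::V(g)$significant <- !is.na(idx) & res$significant[idx]
  g
}

#' @export
print.enrichment_network <- function(x, ...) {
  cat("enrichment_network '", x$label, "': ",
      sum(x$results$significant), " significant term(s), ",
      igraph::vcount(x$graph), " node(s) incl. ancestors\n", sep = "")
  invisible(x)
}

#' Count significant keyword-matching nodes of an enrichment map
#'
#' Number of significant nodes whose term name contains any of the
#' keywords, case-insensitively. Context (ancestor-only) nodes are display
#' scaffolding and are not counted.
#'
#' @param net An `enrichment_network`.
#' @param keywords Character vector (default `"root"`).
#' @return Integer count.
#' @export
count_keyword_nodes <- function(net, keywords = "root") {
  stopifnot(inherits(net, "enrichment_network"))
  sig <- net$results[net$results$significant, , drop = FALSE]
  if (!nrow(sig)) return(0L)
  hit <- rep(FALSE, nrow(sig))
  for (kw in keywords) hit <- hit | grepl(kw, sig$term_name, ignore.case = TRUE)
  sum(hit)
}

#' Compare enrichment maps across query sets
#'
#' Produces the funnel-summary table: co-expressed gene count, motif-passing
#' gene count, significant node count, and keyword node count, one column
#' per map.
#'
#' @param maps Named list of `enrichment_network` objects (>= 2).
#' @param keywords Passed to [count_keyword_nodes()].
#' @return Data frame with a `quantity` column and one column per map.
#' @export
compare_maps <- function(maps, keywords = "root") {
  stopifnot(length(maps) >= 2L,
            all(vapply(maps, inherits, logical(1), "enrichment_network")))
  labels <- names(maps) %||% vapply(maps, `[[`, character(1), "label")
  cols <- lapply(maps, function(m) c(
    coexpressed_genes = m$n_coexpressed %||% NA_integer_,
    motif_genes = m$n_targets,
    nodes = sum(m$results$significant),
    keyword_nodes = count_keyword_nodes(m, keywords)))
  out <- data.frame(quantity = names(cols[[1]]), stringsAsFactors = FALSE)
  for (i in seq_along(cols)) out[[labels[i]]] <- unname(cols[[i]])
  out
}
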