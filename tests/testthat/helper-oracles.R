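# Independent oracles used across the suite. Each recomputes the target
# quantity by brute force or closed form, never through the code path it
# checks.

# Exact hypergeometric upper tail by direct combinatorial sum (log-space).
hyper_enum_p <- function(x, n, k, N) {
  i <- seq(x, min(n, k))
  sum(exp(lchoose(n, i) + lchoose(N - n, k - i) - lchoose(N, k)))
}

# Exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled values into groups of size |a| and |b|; uses the symmetry of the
# null U distribution about mn/2.
mw_enum_p <- function(a, b) {
  vals <- c(a, b)
  m <- length(a); n <- length(b)
  r <- rank(vals)
  U_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  idx <- utils::combn(m + n, m)
  Us <- apply(idx, 2, function(ii) sum(r[ii]) - m * (m + 1) / 2)
  mean(abs(Us - m * n / 2) >= abs(U_obs - m * n / 2) - 1e-9)
}

# Tail probabilities of the discretized PWM score by enumerating all 4^w
# words (w <= 8): for each query integer score s, P(S >= s).
pwm_enum_pvalues <- function(scheme, query_scores) {
  w <- nrow(scheme$int)
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  S <- integer(nrow(words))
  prob <- rep(1, nrow(words))
  for (j in seq_len(w)) {
    S <- S + scheme$int[j, words[, j]]
    prob <- prob * scheme$background[words[, j]]
  }
  vapply(query_scores, function(s) sum(prob[S >= s]), numeric(1))
}

# Random PWM of the given width (Dirichlet-ish positions).
random_pwm <- function(width, id = "rand") {
  m <- matrix(rexp(width * 4), width, 4)
  pwm(id, m / rowSums(m))
}

# Random additive distance matrix from a random tree with known branch
# lengths; returns both.
random_additive <- function(n) {
  tr <- ape::rtree(n, br = function(k) runif(k, 0.05, 1))
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

# Least-squares branch-length fit of a fixed topology to a distance matrix
# via the split-based design matrix; returns the residual sum of squares.
# An additive matrix has residual ~0 exactly for its generating topology.
ls_residual <- function(tree, d) {
  tips <- tree$tip.label
  n <- length(tips)
  pairs <- t(utils::combn(n, 2))
  splits <- .edge_splits(tree)
  X <- sapply(splits, function(s) {
    (tips[pairs[, 1]] %in% s) != (tips[pairs[, 2]] %in% s)
  })
  y <- d[cbind(tips[pairs[, 1]], tips[pairs[, 2]])]
  fit <- lm.fit(X * 1, y)
  sum(fit$residuals^2)
}

# For each edge of a phylo tree, the tip set on the child side.
.edge_splits <- function(tree) {
  tips <- tree$tip.label
  n <- length(tips)
  desc <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) desc[[i]] <- tips[i]
  edges <- tree$edge[order(tree$edge[, 1], decreasing = TRUE), , drop = FALSE]
  # accumulate in reverse-node order (children have larger ids than... not
  # guaranteed, so iterate until fixed point)
  repeat {
    done <- TRUE
    for (k in seq_len(nrow(tree$edge))) {
      p <- tree$edge[k, 1]; c <- tree$edge[k, 2]
      if (!is.null(desc[[c]]) && !all(desc[[c]] %in% (desc[[p]] %||% character()))) {
        desc[[p]] <- union(desc[[p]] %||% character(), desc[[c]])
        done <- FALSE
      }
    }
    if (done) break
  }
  lapply(seq_len(nrow(tree$edge)), function(k) desc[[tree$edge[k, 2]]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small aligned protein-ish fixture with two clean clades {A1,A2,A3} and
# {B1,B2} plus a stray sequence closer to the A clade.
tiny_alignment <- function() {
  structure(data.frame(
    id = c("A1", "A2", "A3", "B1", "B2", "stray"),
    description = "",
    residues = c("MKLVVAAA-T", "MKLVVAAA-T", "MKLVIAAA-T",
                 "MRHEEGGGCT", "MRHEEGGACT", "MKLVIAGA-T"),
    stringsAsFactors = FALSE), class = c("sequence_set", "data.frame"))
}

# Tiny ontology: root -> {dev, metab}; dev -> {root_dev, leaf_dev};
# root_dev -> root_hair.
tiny_dag <- function() {
  ontology_graph(
    terms = data.frame(
      id = c("T:0", "T:dev", "T:met", "T:rdev", "T:ldev", "T:rhair"),
      name = c("biological_process", "organ development",
               "metabolic process", "root development",
               "leaf development", "root hair cell differentiation"),
      namespace = "biological_process", stringsAsFactors = FALSE),
    edges = data.frame(
      child = c("T:dev", "T:met", "T:rdev", "T:ldev", "T:rhair"),
      parent = c("T:0", "T:0", "T:dev", "T:dev", "T:rdev"),
      relation = c("is_a", "is_a", "is_a", "is_a", "part_of"),
      stringsAsFactors = FALSE))
}

tiny_annotations <- function(genes, terms) {
  out <- data.frame(gene_id = genes, term_id = terms,
                    term_name = terms, aspect = "P", evidence = "IEA",
                    slim_name = NA_character_, stringsAsFactors = FALSE)
  class(out) <- c("annotation_table", "data.frame")
  out
}
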