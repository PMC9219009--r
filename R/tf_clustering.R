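#' Pairwise p-distances from a multiple sequence alignment
#'
#' Proportion of mismatching columns per sequence pair, with pairwise
#' deletion: alignment columns where either sequence carries a gap (`-`)
#' are excluded for that pair.
#'
#' @param aln A `sequence_set` (see [read_fasta()]) of aligned sequences:
#'   at least two records, all of equal length.
#' @return A `dist_matrix`: list with `labels` and the symmetric matrix `d`.
#' @export
p_distance <- function(aln) {
  stopifnot(nrow(aln) >= 2L)
  lens <- nchar(aln$residues)
  if (length(unique(lens)) != 1L) {
    stop("aligned sequences must all have equal length")
  }
  chars <- do.call(rbind, strsplit(toupper(aln$residues), ""))
  gap <- chars == "-"
  n <- nrow(chars)
  d <- matrix(0, n, n, dimnames = list(aln$id, aln$id))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      ok <- !gap[i, ] & !gap[j, ]
      if (!any(ok)) {
        stop("no comparable columns between '", aln$id[i], "' and '",
             aln$id[j], "'")
      }
      d[i, j] <- d[j, i] <- mean(chars[i, ok] != chars[j, ok])
    }
  }
  structure(list(labels = aln$id, d = d), class = "dist_matrix")
}

.as_dist_matrix <- function(dm) {
  if (inherits(dm, "dist_matrix")) return(dm)
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  if (is.matrix(dm)) {
    labels <- rownames(dm) %||% paste0("t", seq_len(nrow(dm)))
    return(structure(list(labels = labels, d = dm), class = "dist_matrix"))
  }
  stop("expected a dist_matrix, matrix or dist object")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration on the Q criterion. For an additive distance
#' matrix the returned tree reproduces every pairwise path length exactly.
#' Ties in the Q matrix are broken by the lowest pair position (current
#' ordering), so the construction is fully deterministic. Negative branch
#' lengths are clamped to zero with the deficit transferred to the sister
#' edge, preserving the pair's path length.
#'
#' @param dm A `dist_matrix` (see [p_distance()]), symmetric matrix or
#'   `dist` object; n >= 2 taxa.
#' @return An [ape::read.tree()]-style `phylo` object, unrooted (basal
#'   trichotomy) for n >= 3.
#' @export
neighbor_joining <- function(dm) {
  dm <- .as_dist_matrix(dm)
  d <- unname(dm$d)
  labels <- dm$labels
  n <- length(labels)
  if (n < 2L) stop("need at least 2 taxa")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    stop("distance matrix must be symmetric")
  }
  if (any(diag(d) != 0)) stop("distance matrix must have a zero diagonal")
  if (n == 2L) {
    tr <- list(edge = rbind(c(3L, 1L), c(3L, 2L)),
               edge.length = rep(d[1, 2] / 2, 2),
               tip.label = labels, Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }
  # active[i] = node id of cluster i; internal ids n+2, n+3, ...; the final
  # trichotomy node gets id n+1 so that ape's root-numbering convention holds.
  active <- seq_len(n)
  next_internal <- n + 2L
  edges <- matrix(integer(), 0, 2)
  elens <- numeric()
  while (length(active) > 3L) {
    r <- length(active)
    R <- rowSums(d)
    Q <- (r - 2) * d - outer(R, R, "+")
    diag(Q) <- Inf
    # lowest (i, j) among ties, scanning rows then columns
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    i <- best[1, 1]; j <- best[1, 2]
    li <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    li <- max(li, 0); lj <- max(lj, 0)
    u <- next_internal
    next_internal <- next_internal + 1L
    edges <- rbind(edges, c(u, active[i]), c(u, active[j]))
    elens <- c(elens, li, lj)
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]), c(du[keep], 0))
    active <- c(active[keep], u)
  }
  # join the last three clusters at the basal trichotomy node n + 1
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  root <- n + 1L
  edges <- rbind(edges, c(root, active[1]), c(root, active[2]),
                 c(root, active[3]))
  elens <- c(elens, pmax(c(la, lb, lc), 0))
  # edges were recorded children-before-root; ape expects cladewise order,
  # which reorder() restores.
  tr <- list(edge = edges, edge.length = elens, tip.label = labels,
             Nnode = next_internal - 1L - n)
  class(tr) <- "phylo"
  tr <- ape::reorder.phylo(tr, "cladewise")
  tr
}

# Canonical bipartition keys of a phylo tree: each internal edge splits the
# leaves in two; the key is the sorted label list of the side NOT containing
# the alphabetically first leaf, so complements collapse to one key.
.bipartition_keys <- function(tree) {
  tips <- tree$tip.label
  anchor <- sort(tips)[1]
  parts <- ape::prop.part(tree)
  keys <- vapply(parts, function(idx) {
    side <- tips[idx]
    if (anchor %in% side) side <- setdiff(tips, side)
    if (length(side) < 2L || length(side) > length(tips) - 2L) return(NA_character_)
    paste(sort(side), collapse = "|")
  }, character(1))
  keys
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the p-distance
#' neighbor-joining tree per replicate and reports, for each internal
#' bipartition of the full-alignment tree, the percentage of replicate
#' trees containing it. Deterministic for a fixed seed.
#'
#' @param aln A `sequence_set` of aligned sequences.
#' @param replicates Number of bootstrap replicates (>= 1).
#' @param seed Integer seed.
#' @return The full-alignment `phylo` tree with `node.label` set to the
#'   support percentages (NA for the basal node, which carries no
#'   bipartition).
#' @export
bootstrap_support <- function(aln, replicates = 100L, seed = 1L) {
  stopifnot(replicates >= 1L)
  ref <- neighbor_joining(p_distance(aln))
  ref_keys <- .bipartition_keys(ref)
  counts <- setNames(numeric(length(ref_keys)), ref_keys)
  L <- nchar(aln$residues[1])
  chars <- do.call(rbind, strsplit(aln$residues, ""))
  with_seed(derive_seed(seed, "bootstrap"), {
    for (b in seq_len(replicates)) {
      cols <- sample.int(L, L, replace = TRUE)
      boot <- aln
      boot$residues <- apply(chars[, cols, drop = FALSE], 1, paste, collapse = "")
      keys <- .bipartition_keys(neighbor_joining(p_distance(boot)))
      present <- ref_keys %in% keys[!is.na(keys)]
      counts[present] <- counts[present] + 1
    }
  })
  support <- 100 * counts / replicates
  support[is.na(ref_keys)] <- NA
  ref$node.label <- as.character(round(support, 1))
  ref$node.label[is.na(ref_keys)] <- ""
  attr(ref, "support") <- support
  ref
}

#' Assign unlabeled leaves to families using anchor taxa
#'
#' Each unlabeled leaf receives the family label of the smallest
#' bipartition side (clade, in the unrooted sense) that contains the leaf
#' and at least one anchor, provided all anchors inside that side belong to
#' one family. Leaves whose smallest anchored side mixes families are
#' reported unassigned.
#'
#' @param tree A `phylo` tree.
#' @param anchors Named character vector: `names(anchors)` are leaf ids,
#'   values are family labels. Every anchor must be a leaf of the tree.
#' @return Named list of [gene_set()]s, one per family label, plus an
#'   `"unassigned"` set (possibly empty).
#' @export
extract_family_groups <- function(tree, anchors) {
  tips <- tree$tip.label
  missing_anchor <- setdiff(names(anchors), tips)
  if (length(missing_anchor)) {
    stop("anchor leaves absent from tree: ",
         paste(missing_anchor, collapse = ", "))
  }
  parts <- ape::prop.part(tree)
  sides <- lapply(parts, function(idx) tips[idx])
  sides <- c(sides, lapply(sides, function(s) setdiff(tips, s)))
  sides <- c(sides, list(tips))
  sides <- sides[vapply(sides, length, integer(1)) > 0]
  assign_of <- function(leaf) {
    if (leaf %in% names(anchors)) return(unname(anchors[leaf]))
    cand <- sides[vapply(sides, function(s)
      leaf %in% s && any(names(anchors) %in% s), logical(1))]
    if (!length(cand)) return(NA_character_)
    cand <- cand[order(vapply(cand, length, integer(1)))]
    fams <- unique(unname(anchors[intersect(names(anchors), cand[[1]])]))
    if (length(fams) == 1L) fams else NA_character_
  }
  lab <- vapply(tips, assign_of, character(1))
  fams <- sort(unique(unname(anchors)))
  out <- lapply(fams, function(f) gene_set(f, tips[!is.na(lab) & lab == f]))
  names(out) <- fams
  out$unassigned <- gene_set("unassigned", tips[is.na(lab)])
  out
}
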