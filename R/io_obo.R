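#' Construct an ontology graph
#'
#' @param terms Data frame with columns `id`, `name`, `namespace`.
#' @param edges Data frame with columns `child`, `parent`, `relation`
#'   (`is_a` or `part_of`); edges point child -> parent.
#' @return An object of class `ontology_graph`.
#' @export
ontology_graph <- function(terms, edges) {
  stopifnot(all(c("id", "name", "namespace") %in% names(terms)),
            all(c("child", "parent", "relation") %in% names(edges)))
  unknown <- setdiff(unique(c(edges$child, edges$parent)), terms$id)
  if (length(unknown)) {
    stop("ontology edges reference unknown terms: ",
         paste(head(unknown, 5), collapse = ", "))
  }
  structure(list(terms = terms, edges = edges), class = "ontology_graph")
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat("ontology_graph:", nrow(x$terms), "terms,", nrow(x$edges), "edges;",
      "namespaces:", paste(unique(x$terms$namespace), collapse = ", "), "\n")
  invisible(x)
}

#' Read an OBO-format ontology (subset)
#'
#' Parses the OBO stanza fields this pipeline needs: `id`, `name`,
#' `namespace`, `is_a`, and `relationship: part_of`. Obsolete terms are
#' skipped. This is intentionally a small subset parser, not a complete OBO
#' implementation.
#'
#' @param path Path to an `.obo` file.
#' @return An [ontology_graph()].
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) stop("OBO file not found: ", path)
  lines <- readLines(path)
  term_starts <- which(lines == "[Term]")
  ids <- names <- nss <- character()
  ch <- pa <- rel <- character()
  blocks_end <- c(which(grepl("^\\[", lines)), length(lines) + 1L)
  for (s in term_starts) {
    e <- min(blocks_end[blocks_end > s]) - 1L
    block <- lines[seq(s + 1L, length.out = max(0L, e - s))]
    get1 <- function(key) {
      v <- sub(paste0("^", key, ": "), "", grep(paste0("^", key, ": "), block, value = TRUE))
      if (length(v)) v[1] else NA_character_
    }
    if (any(block == "is_obsolete: true")) next
    id <- get1("id")
    if (is.na(id)) next
    ids <- c(ids, id)
    names <- c(names, get1("name") %||% "")
    nss <- c(nss, get1("namespace"))
    isa <- grep("^is_a: ", block, value = TRUE)
    for (v in sub("^is_a: ", "", isa)) {
      ch <- c(ch, id); pa <- c(pa, sub("\\s*!.*$", "", v)); rel <- c(rel, "is_a")
    }
    po <- grep("^relationship: part_of ", block, value = TRUE)
    for (v in sub("^relationship: part_of ", "", po)) {
      ch <- c(ch, id); pa <- c(pa, sub("\\s*!.*$", "", v)); rel <- c(rel, "part_of")
    }
  }
  nss[is.na(nss)] <- "unknown"
  ontology_graph(
    terms = data.frame(id = ids, name = names, namespace = nss,
                       stringsAsFactors = FALSE),
    edges = data.frame(child = ch, parent = pa, relation = rel,
                       stringsAsFactors = FALSE))
}

#' Write an ontology graph as OBO
#'
#' @param dag An [ontology_graph()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_obo <- function(dag, path) {
  stopifnot(inherits(dag, "ontology_graph"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (i in seq_len(nrow(dag$terms))) {
    t <- dag$terms[i, ]
    writeLines(c("", "[Term]", paste0("id: ", t$id), paste0("name: ", t$name),
                 paste0("namespace: ", t$namespace)), con)
    e <- dag$edges[dag$edges$child == t$id, , drop = FALSE]
    for (j in seq_len(nrow(e))) {
      if (e$relation[j] == "is_a") {
        writeLines(paste0("is_a: ", e$parent[j]), con)
      } else {
        writeLines(paste0("relationship: part_of ", e$parent[j]), con)
      }
    }
  }
  invisible(path)
}

# Topological order of terms, children before parents. Errors on cycles.
.topo_order <- function(dag) {
  ids <- dag$terms$id
  parents_of <- split(dag$edges$parent, factor(dag$edges$child, levels = ids))
  emitted <- character()
  pending <- ids
  while (length(pending)) {
    # a term is ready once none of its parents is still pending (Kahn)
    ready <- pending[vapply(pending, function(t) {
      !any(parents_of[[t]] %in% pending)
    }, logical(1))]
    if (!length(ready)) {
      stop("ontology contains a cycle involving: ",
           paste(head(pending, 5), collapse = ", "))
    }
    emitted <- c(emitted, ready)
    pending <- setdiff(pending, ready)
  }
  rev(emitted)  # children first
}
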