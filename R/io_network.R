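#' Export an enrichment network to SIF or GraphML
#'
#' SIF rows have the shape `parent<TAB>isa<TAB>child` (one row per ontology
#' edge; an empty network yields an empty file). GraphML embeds all node
#' attributes (`term_id`, `term_name`, `gene_count`, `p`, `q`,
#' `significant`) and round-trips losslessly through [read_network()].
#'
#' @param network An `enrichment_network` (see [build_map()]) or an igraph
#'   graph whose vertices carry the node attributes above.
#' @param path Output path.
#' @param dialect `"SIF"` or `"GraphML"`.
#' @return Invisibly, `path`.
#' @export
write_network <- function(network, path, dialect = c("SIF", "GraphML")) {
  dialect <- match.arg(dialect)
  g <- if (inherits(network, "enrichment_network")) network$graph else network
  stopifnot(igraph::is_igraph(g))
  if (dialect == "SIF") {
    el <- igraph::as_edgelist(g, names = TRUE)  # rows: child -> parent
    rows <- if (nrow(el)) paste(el[, 2], "isa", el[, 1], sep = "\t") else character()
    ok <- tryCatch({ writeLines(rows, path); TRUE },
                   error = function(e) stop("cannot write SIF to ", path, ": ",
                                            conditionMessage(e)))
  } else {
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a GraphML network written by [write_network()]
#'
#' @param path Path to a GraphML file.
#' @return An igraph graph with the embedded node attributes.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("network file not found: ", path)
  igraph::read_graph(path, format = "graphml")
}
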