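#' Construct a gene set
#'
#' @param label Human-readable label recording how the set was made.
#' @param genes Character vector of gene ids; duplicates are dropped.
#' @param provenance Optional data frame with one row per gene of supporting
#'   evidence (matched terms, correlations, motif hits, ...).
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(label, genes, provenance = NULL) {
  genes <- unique(as.character(genes))
  structure(list(label = label, genes = genes, provenance = provenance),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("gene_set '", x$label, "': ", length(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

#' Select genes whose annotations match any of a list of keywords
#'
#' Reproduces keyword-based GO datamining: a gene is kept if at least one of
#' its annotation records contains any keyword in the selected text fields.
#' Matching is case-insensitive; by default a plain substring match, or
#' whole-word when `word_boundary = TRUE`.
#'
#' @param table An `annotation_table` (see [read_annotation_table()]).
#' @param keywords Non-empty character vector, e.g.
#'   `c("transcription factor")` or `c("root")`.
#' @param fields Which record fields to search: any subset of
#'   `c("term_name", "slim_name")`.
#' @param word_boundary Match at word boundaries instead of raw substrings.
#' @return A [gene_set()] labelled with the keyword list; its provenance
#'   lists, per gene, the supporting term ids and the first matched keyword.
#' @export
keyword_filter <- function(table, keywords,
                           fields = c("term_name", "slim_name"),
                           word_boundary = FALSE) {
  if (!length(keywords) || !all(nzchar(keywords))) {
    stop("keywords must be a non-empty character vector")
  }
  fields <- match.arg(fields, several.ok = TRUE)
  if (!length(fields)) stop("at least one field must be selected")
  hay <- do.call(paste, c(lapply(fields, function(f) {
    v <- table[[f]]
    v[is.na(v)] <- ""
    v
  }), sep = "\n"))
  hit_kw <- rep(NA_character_, nrow(table))
  hit <- rep(FALSE, nrow(table))
  for (kw in keywords) {
    esc <- gsub("([][(){}.|^$*+?\\\\])", "\\\\\\1", kw)
    pat <- if (word_boundary) paste0("\\b", esc, "\\b") else esc
    m <- grepl(pat, hay, ignore.case = TRUE)
    hit_kw[m & !hit] <- kw
    hit <- hit | m
  }
  rec <- table[hit, , drop = FALSE]
  rec$matched_keyword <- hit_kw[hit]
  prov <- if (nrow(rec)) {
    agg <- split(rec, rec$gene_id)
    data.frame(
      gene_id = names(agg),
      term_ids = vapply(agg, function(d) paste(unique(d$term_id), collapse = ","),
                        character(1)),
      matched_keyword = vapply(agg, function(d) d$matched_keyword[1], character(1)),
      row.names = NULL, stringsAsFactors = FALSE)
  } else {
    data.frame(gene_id = character(), term_ids = character(),
               matched_keyword = character(), stringsAsFactors = FALSE)
  }
  gene_set(label = paste0("keyword:", paste(keywords, collapse = "|")),
           genes = unique(rec$gene_id), provenance = prov)
}

#' Intersect two gene sets
#'
#' @param a,b [gene_set()] objects.
#' @return A [gene_set()] holding the intersection; the label concatenates
#'   the input labels.
#' @export
intersect_gene_sets <- function(a, b) {
  stopifnot(inherits(a, "gene_set"), inherits(b, "gene_set"))
  common <- intersect(a$genes, b$genes)
  prov <- NULL
  if (!is.null(a$provenance) && nrow(a$provenance)) {
    prov <- a$provenance[a$provenance$gene_id %in% common, , drop = FALSE]
    rownames(prov) <- NULL
  }
  gene_set(label = paste(a$label, b$label, sep = " & "),
           genes = common, provenance = prov)
}

#' Export gene sets as a tab-delimited report
#'
#' One TSV per set, named `<prefix><set label, sanitized>.tsv`, with columns
#' `gene_id`, `term_ids`, `matched_keyword` (empty when a set carries no
#' provenance).
#'
#' @param sets List of [gene_set()] objects.
#' @param dir Output directory (created if needed).
#' @param prefix Filename prefix.
#' @return Character vector of written paths, invisibly.
#' @export
export_gene_report <- function(sets, dir, prefix = "genes_") {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(sets))
  for (i in seq_along(sets)) {
    s <- sets[[i]]
    fn <- paste0(prefix, gsub("[^A-Za-z0-9._-]+", "_", s$label), ".tsv")
    paths[i] <- file.path(dir, fn)
    df <- data.frame(gene_id = s$genes, stringsAsFactors = FALSE)
    if (!is.null(s$provenance) && nrow(s$provenance)) {
      df <- merge(df, s$provenance, by = "gene_id", all.x = TRUE, sort = FALSE)
    } else {
      df$term_ids <- rep("", nrow(df))
      df$matched_keyword <- rep("", nrow(df))
    }
    write.table(df, paths[i], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}
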