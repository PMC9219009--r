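#' Read a tab-delimited GO annotation table
#'
#' Parses GAF-like flat annotation files (e.g. the TAIR GO/GO-slim export).
#' Comment lines starting with `!` are skipped. The parser is permissive
#' about extra columns: only the mapped columns are interpreted, everything
#' else is ignored. Duplicated (gene, term) lines are retained; deduplication
#' is left to consumers.
#'
#' @param path Path to the annotation file.
#' @param col_map Named vector mapping the required record fields to columns
#'   of the file, either by header name (character) or by 1-based position
#'   (integer, for headerless files). Required names: `gene_id`, `term_id`,
#'   `term_name`, `aspect`, `evidence`; optional: `slim_name`.
#' @param header Logical; does the file carry a header line? Defaults to
#'   `TRUE` when `col_map` is character.
#' @return A data frame of class `c("annotation_table", "data.frame")` with
#'   columns `gene_id`, `term_id`, `term_name`, `aspect`, `evidence`,
#'   `slim_name` (NA when unmapped), in file order.
#' @export
read_annotation_table <- function(path,
                                  col_map = c(gene_id = "gene_id",
                                              term_id = "term_id",
                                              term_name = "term_name",
                                              aspect = "aspect",
                                              evidence = "evidence",
                                              slim_name = "slim_name"),
                                  header = is.character(col_map)) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  required <- c("gene_id", "term_id", "term_name", "aspect", "evidence")
  missing_map <- setdiff(required, names(col_map))
  if (length(missing_map)) {
    stop("col_map must name columns for: ", paste(required, collapse = ", "),
         " (missing: ", paste(missing_map, collapse = ", "), ")")
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "!")]
  empty <- data.frame(gene_id = character(), term_id = character(),
                      term_name = character(), aspect = character(),
                      evidence = character(), slim_name = character(),
                      stringsAsFactors = FALSE)
  if (!length(lines) || (header && length(lines) == 1L)) {
    class(empty) <- c("annotation_table", "data.frame")
    return(empty)
  }
  raw <- read.delim(text = lines, header = header, sep = "\t", quote = "",
                    colClasses = "character", check.names = FALSE)
  pick <- function(field) {
    key <- col_map[[field]]
    if (is.character(col_map)) {
      if (!key %in% names(raw)) {
        if (field == "slim_name") return(rep(NA_character_, nrow(raw)))
        stop("annotation file lacks expected column '", key,
             "'; expected columns: ",
             paste(unname(col_map[required]), collapse = ", "))
      }
      raw[[key]]
    } else {
      if (key > ncol(raw)) {
        if (field == "slim_name") return(rep(NA_character_, nrow(raw)))
        stop("annotation file has ", ncol(raw), " columns but column ", key,
             " was requested for '", field, "'")
      }
      raw[[key]]
    }
  }
  slim <- if ("slim_name" %in% names(col_map)) pick("slim_name") else
    rep(NA_character_, nrow(raw))
  out <- data.frame(gene_id = pick("gene_id"), term_id = pick("term_id"),
                    term_name = pick("term_name"), aspect = pick("aspect"),
                    evidence = pick("evidence"), slim_name = slim,
                    stringsAsFactors = FALSE)
  bad <- !nzchar(out$gene_id) | !nzchar(out$term_id)
  if (any(bad)) {
    stop("annotation record ", which(bad)[1], " has an empty gene or term id")
  }
  class(out) <- c("annotation_table", "data.frame")
  out
}

#' Write an annotation table back to disk
#'
#' @param table An `annotation_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_annotation_table <- function(table, path) {
  write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
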