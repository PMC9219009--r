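#' Read a FASTA file into sequence records
#'
#' Thin wrapper over [Biostrings::readBStringSet()] returning plain records:
#' a data frame with one row per sequence. The first whitespace-delimited
#' token of the header is the record id, the remainder the description.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id`, `description`, `residues`
#'   (character), of class `c("sequence_set", "data.frame")`. An empty file
#'   yields zero rows.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">g1 demo", "ACGT"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  headers <- names(ss)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  res <- as.character(ss)
  bad <- which(ids == "" | nchar(res) == 0L)
  if (length(bad)) {
    stop("malformed FASTA record at position ", bad[1],
         " (header: '", headers[bad[1]], "'): empty id or sequence")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  out <- data.frame(id = ids, description = desc, residues = unname(res),
                    stringsAsFactors = FALSE)
  class(out) <- c("sequence_set", "data.frame")
  out
}

#' Write sequence records to FASTA
#'
#' Lines are wrapped at 60 characters.
#'
#' @param records A data frame with columns `id`, `description`, `residues`
#'   (as returned by [read_fasta()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("id", "residues") %in% names(records)))
  desc <- records$description %||% rep("", nrow(records))
  hdr <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  ss <- Biostrings::BStringSet(records$residues)
  names(ss) <- hdr
  Biostrings::writeXStringSet(ss, filepath = path, width = 60L)
  invisible(path)
}
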