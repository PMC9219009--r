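#' Construct a position-weight matrix object
#'
#' @param motif_id Motif identifier.
#' @param matrix Numeric matrix, one row per motif position and one column
#'   per base in the fixed order A, C, G, T. Entries may be counts or
#'   frequencies; each row is normalized to sum to one.
#' @return An object of class `pwm`: a list with elements `motif_id`,
#'   `alphabet` and `matrix` (row-stochastic, width >= 4).
#' @export
pwm <- function(motif_id, matrix) {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != 4L) stop("PWM '", motif_id, "': each position needs 4 numbers")
  if (nrow(matrix) < 4L) stop("PWM '", motif_id, "': width must be >= 4")
  if (any(!is.finite(matrix)) || any(matrix < 0)) {
    stop("PWM '", motif_id, "': entries must be finite and non-negative")
  }
  rs <- rowSums(matrix)
  if (any(rs <= 0)) stop("PWM '", motif_id, "': a position has zero total weight")
  matrix <- matrix / rs
  dimnames(matrix) <- list(NULL, c("A", "C", "G", "T"))
  structure(list(motif_id = motif_id, alphabet = c("A", "C", "G", "T"),
                 matrix = matrix),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM", x$motif_id, "- width", nrow(x$matrix), "\n")
  print(round(x$matrix, 3))
  invisible(x)
}

#' Read position-weight matrices from a motif-matrix text file
#'
#' Expects the common plain-text motif layout: a header line starting with
#' `>` (or `MOTIF`) carrying the motif id, followed by one row of four
#' numbers (A C G T) per motif position. Counts are normalized to
#' position-stochastic probabilities. Several motifs may follow each other
#' in one file.
#'
#' @param path Path to the motif file.
#' @return A list of [pwm()] objects.
#' @export
read_pwm <- function(path) {
  if (!file.exists(path)) stop("motif file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  is_hdr <- grepl("^>", lines) | grepl("^MOTIF\\b", lines)
  if (!any(is_hdr)) stop("no motif header ('>' or 'MOTIF') found in ", path)
  idx <- which(is_hdr)
  bounds <- c(idx, length(lines) + 1L)
  out <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    hdr <- lines[idx[i]]
    id <- sub("^(>|MOTIF)\\s*", "", hdr)
    id <- sub("\\s.*$", "", id)
    body <- lines[seq(idx[i] + 1L, length.out = bounds[i + 1L] - idx[i] - 1L)]
    rows <- lapply(body, function(l) {
      v <- suppressWarnings(as.numeric(strsplit(l, "[[:space:],]+")[[1]]))
      if (length(v) != 4L || anyNA(v)) {
        stop("motif '", id, "': row '", l, "' is not 4 numbers")
      }
      if (any(v < 0)) stop("motif '", id, "': negative entry in row '", l, "'")
      v
    })
    out[[i]] <- pwm(id, do.call(rbind, rows))
  }
  out
}

#' Write position-weight matrices to a motif-matrix text file
#'
#' @param pwms A [pwm()] object or list of them.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pwm <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$motif_id), con)
    writeLines(apply(p$matrix, 1, function(r) paste(format(r, digits = 10), collapse = "\t")),
               con)
  }
  invisible(path)
}

#' Consensus sequence of a PWM
#'
#' The highest-probability base at each position; ties broken by alphabet
#' order (A < C < G < T).
#'
#' @param p A [pwm()] object.
#' @return A character scalar over \{A,C,G,T\}.
#' @export
pwm_consensus <- function(p) {
  stopifnot(inherits(p, "pwm"))
  paste(c("A", "C", "G", "T")[apply(p$matrix, 1, which.max)], collapse = "")
}
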