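# PWM promoter scanning with exact score p-values.
#
# Scoring follows the classic log-odds scheme: for a window w_1..w_k and a
# 0-order background b, score = sum_j log2((p_j(w_j) + eps) / b(w_j)), with a
# small pseudocount eps per PWM cell. P-values are exact tail probabilities
# of the score under the background model. To make the null distribution
# computable for any width, scores are discretized onto an integer grid
# (finest column range / `bins` per column); both the hit classification and
# the dynamic-programming null distribution use this same discretized score,
# so the reported p-value is the exact tail of the discretized score - not
# an approximation to it. The raw (undiscretized) log-odds sum is reported
# as the hit score.

#' Build a scoring scheme from a PWM and a background model
#'
#' @param p A [pwm()] object.
#' @param background Numeric length-4 base probability vector (A,C,G,T),
#'   summing to one.
#' @param pseudocount Pseudocount added to every PWM cell before log-odds
#'   (the matrix is renormalized afterwards).
#' @param bins Number of discretization bins spanning the widest column's
#'   score range.
#' @return A `pwm_scheme`: log-odds matrix, integer score matrix, grid step
#'   `eps`, additive `offset` mapping integers back to raw scores, and the
#'   exact integer-score null distribution (`pval[s+1] = P(S >= s)`).
#' @export
pwm_scoring_scheme <- function(p, background, pseudocount = 0.01, bins = 1000L) {
  stopifnot(inherits(p, "pwm"))
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-6 ||
      any(background <= 0)) {
    stop("background must be 4 positive probabilities summing to 1")
  }
  probs <- (p$matrix + pseudocount) / (1 + 4 * pseudocount)
  lod <- log2(sweep(probs, 2, background, "/"))  # width x 4
  colmin <- apply(lod, 1, min)
  ranges <- apply(lod, 1, max) - colmin
  eps <- max(ranges) / bins
  if (eps <= 0) eps <- 1e-9
  int <- round(sweep(lod, 1, colmin, "-") / eps)
  storage.mode(int) <- "integer"
  # exact null distribution of the integer score by column-wise convolution
  dist <- 1
  for (i in seq_len(nrow(int))) {
    mx <- max(int[i, ])
    new <- numeric(length(dist) + mx)
    for (b in 1:4) {
      s <- int[i, b]
      idx <- seq_along(dist) + s
      new[idx] <- new[idx] + dist * background[b]
    }
    dist <- new
  }
  pval <- rev(cumsum(rev(dist)))
  pval <- pmin(pval, 1)
  structure(list(motif_id = p$motif_id, lod = lod, int = int, eps = eps,
                 offset = sum(colmin), background = background,
                 null_dist = dist, pval = pval),
            class = "pwm_scheme")
}

#' Exact p-value of a window's integer score under the background
#'
#' @param scheme A `pwm_scheme`.
#' @param int_score Integer score(s) as produced by the scheme's integer
#'   matrix (sum over columns).
#' @return P(S >= int_score) under the 0-order background, exactly.
#' @export
pwm_score_pvalue <- function(scheme, int_score) {
  p <- rep(1, length(int_score))
  ok <- is.finite(int_score)
  idx <- pmax(pmin(int_score[ok] + 1L, length(scheme$pval)), 1L)
  p[ok] <- scheme$pval[idx]
  p[is.finite(int_score) & int_score + 1L > length(scheme$pval)] <- 0
  p
}

# Encode A,C,G,T as 1..4; anything else (incl. N) as NA.
.encode_dna <- function(s) {
  v <- match(strsplit(toupper(s), "")[[1]], c("A", "C", "G", "T"))
  v
}

# Sliding-window sums of per-column lookups. codes: integer vector (NA = N);
# m: width x 4 matrix. Returns vector of length L - w + 1 (NA where any
# window base is ambiguous).
.window_scores <- function(codes, m) {
  L <- length(codes)
  w <- nrow(m)
  if (L < w) return(numeric(0))
  nwin <- L - w + 1L
  total <- numeric(nwin)
  na <- logical(nwin)
  for (j in seq_len(w)) {
    cj <- codes[j:(nwin + j - 1L)]
    na <- na | is.na(cj)
    v <- m[j, ][cj]
    v[is.na(v)] <- 0
    total <- total + v
  }
  total[na] <- NA
  total
}

#' Estimate the 0-order base composition of a sequence set
#'
#' @param promoters A `sequence_set`.
#' @return Length-4 probability vector over A,C,G,T (ambiguous bases are
#'   ignored).
#' @export
base_composition <- function(promoters) {
  counts <- integer(4)
  for (s in promoters$residues) {
    v <- .encode_dna(s)
    counts <- counts + tabulate(v[!is.na(v)], 4L)
  }
  if (sum(counts) == 0) stop("no unambiguous bases in the sequence set")
  counts / sum(counts)
}

#' Reverse complement of a DNA string
#' @param s Character scalar over A,C,G,T,N.
#' @return The reverse complement.
#' @export
reverse_complement <- function(s) {
  chartr("ACGTNacgtn", "TGCANtgcan", vapply(s, function(x)
    paste(rev(strsplit(x, "")[[1]]), collapse = ""), character(1),
    USE.NAMES = FALSE))
}

#' Scan promoter sequences for PWM motif occurrences
#'
#' Scores every window of every sequence against the PWM log-odds scheme and
#' keeps windows whose exact score p-value is at most `p_max`. With
#' `strand_policy = "both"`, the reverse strand is scanned as well; reverse
#' hits are reported on the forward coordinate of their leftmost base.
#' Windows containing ambiguous bases (N) are skipped.
#'
#' @param promoters A `sequence_set` (see [read_fasta()]).
#' @param p A [pwm()] object, or a list of them (a window hit for any motif
#'   is reported; see `motif_id` column).
#' @param background `"from-input"` (0-order composition of the scanned
#'   set, the default), `"uniform"`, or a length-4 probability vector.
#' @param p_max Hit threshold on the exact p-value.
#' @param strand_policy `"both"` or `"forward"`.
#' @param pseudocount,bins Passed to [pwm_scoring_scheme()].
#' @return Data frame of hits: `sequence_id`, `motif_id`, `start` (0-based),
#'   `strand`, `score` (log2-odds), `p`.
#' @export
scan_promoters <- function(promoters, p, background = "from-input",
                           p_max = 1e-4, strand_policy = c("both", "forward"),
                           pseudocount = 0.01, bins = 1000L) {
  strand_policy <- match.arg(strand_policy)
  pwms <- if (inherits(p, "pwm")) list(p) else p
  stopifnot(all(vapply(pwms, inherits, logical(1), "pwm")))
  empty <- data.frame(sequence_id = character(), motif_id = character(),
                      start = integer(), strand = character(),
                      score = numeric(), p = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(promoters) == 0L) return(empty)
  bg <- if (identical(background, "from-input")) {
    base_composition(promoters)
  } else if (identical(background, "uniform")) {
    rep(0.25, 4)
  } else {
    if (abs(sum(background) - 1) > 1e-6) {
      stop("background vector must sum to 1")
    }
    background
  }
  out <- list()
  for (pw in pwms) {
    scheme <- pwm_scoring_scheme(pw, bg, pseudocount = pseudocount, bins = bins)
    w <- nrow(pw$matrix)
    for (i in seq_len(nrow(promoters))) {
      seq_id <- promoters$id[i]
      s <- promoters$residues[i]
      L <- nchar(s)
      if (L < w) next
      codes <- .encode_dna(s)
      strands <- if (strand_policy == "both") c("+", "-") else "+"
      for (st in strands) {
        cds <- if (st == "+") codes else rev(5L - codes)
        ints <- .window_scores(cds, scheme$int)
        pv <- pwm_score_pvalue(scheme, ifelse(is.na(ints), -Inf, ints))
        keep <- which(!is.na(ints) & pv <= p_max)
        if (!length(keep)) next
        raw <- .window_scores(cds, scheme$lod)[keep]
        start0 <- if (st == "+") keep - 1L else L - w - (keep - 1L)
        out[[length(out) + 1L]] <- data.frame(
          sequence_id = seq_id, motif_id = pw$motif_id, start = start0,
          strand = st, score = raw, p = pv[keep], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$sequence_id, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}
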