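#' Relative fold change by the delta-delta-Ct method
#'
#' Technical replicates are averaged first; per biological replicate,
#' `dCt = Ct_target - Ct_reference`; `ddCt = dCt_sample - mean(dCt_calibrator)`
#' within the same tissue; the per-replicate fold change is `2^-ddCt`
#' (amplification efficiency assumed to be 2). The reported fold change is
#' `2^-mean(ddCt)` - the geometric mean of the per-replicate fold changes -
#' so the calibrator line evaluates to exactly 1 by construction; the
#' standard error is that of the per-replicate fold changes. Significance
#' versus the calibrator is a two-sided Mann-Whitney test on the
#' per-replicate fold changes.
#'
#' @param records Data frame with columns `line`, `tissue`, `gene`,
#'   `bio_rep`, `tech_rep`, `ct`.
#' @param target_gene Gene to quantify.
#' @param reference_gene Internal reference (normalizer) gene.
#' @param calibrator_line Line whose expression defines fold change 1.
#' @return Data frame with one row per (line, tissue): `rfc`, `se`, `p`,
#'   `n_bio`, `n_tech`.
#' @export
delta_delta_ct <- function(records, target_gene, reference_gene,
                           calibrator_line) {
  need <- c("line", "tissue", "gene", "bio_rep", "tech_rep", "ct")
  stopifnot(all(need %in% names(records)))
  rec <- records[records$gene %in% c(target_gene, reference_gene), , drop = FALSE]
  if (!any(rec$line == calibrator_line)) {
    stop("calibrator line '", calibrator_line, "' absent from the Ct table")
  }
  # average technical replicates
  agg <- aggregate(ct ~ line + tissue + gene + bio_rep, data = rec, FUN = mean)
  n_tech <- aggregate(tech_rep ~ line + tissue + gene + bio_rep, data = rec,
                      FUN = function(v) length(unique(v)))
  tgt <- agg[agg$gene == target_gene, , drop = FALSE]
  ref <- agg[agg$gene == reference_gene, , drop = FALSE]
  key <- function(d) paste(d$line, d$tissue, d$bio_rep, sep = "\r")
  m <- match(key(tgt), key(ref))
  if (anyNA(m)) {
    miss <- tgt[is.na(m), , drop = FALSE][1, ]
    stop("missing reference-gene Ct for line '", miss$line, "', tissue '",
         miss$tissue, "', biological replicate ", miss$bio_rep)
  }
  tgt$dct <- tgt$ct - ref$ct[m]
  calib_mean <- with(tgt[tgt$line == calibrator_line, , drop = FALSE],
                     tapply(dct, tissue, mean))
  if (any(!unique(tgt$tissue) %in% names(calib_mean))) {
    stop("calibrator line lacks Ct records for tissue(s): ",
         paste(setdiff(unique(tgt$tissue), names(calib_mean)), collapse = ", "))
  }
  tgt$ddct <- tgt$dct - calib_mean[tgt$tissue]
  groups <- split(tgt, list(tgt$line, tgt$tissue), drop = TRUE)
  calib <- function(tissue) {
    d <- tgt[tgt$line == calibrator_line & tgt$tissue == tissue, , drop = FALSE]
    2^(-d$ddct)
  }
  out <- lapply(groups, function(d) {
    fc <- 2^(-d$ddct)
    mw <- mann_whitney(fc, calib(d$tissue[1]))
    data.frame(line = d$line[1], tissue = d$tissue[1], gene = target_gene,
               rfc = 2^(-mean(d$ddct)),
               se = if (length(fc) > 1) sd(fc) / sqrt(length(fc)) else NA_real_,
               p = mw$p, n_bio = nrow(d),
               n_tech = max(n_tech$tech_rep), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$line, out$tissue), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' U from rank sums with midranks for ties. The two-sided p-value is exact
#' (full enumeration of labelings) when the groups are small
#' (`|a| + |b| <= 12`) and tie-free, and otherwise uses the normal
#' approximation with tie and continuity corrections.
#'
#' @param a,b Numeric vectors, each non-empty.
#' @return List with elements `U` (for group `a`) and `p`.
#' @export
mann_whitney <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  r <- rank(c(a, b))
  U <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  if (length(unique(c(a, b))) == 1L) {
    return(list(U = U, p = 1))  # every observation tied: no evidence
  }
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && (length(a) + length(b)) <= 12
  wt <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = TRUE, alternative = "two.sided"))
  list(U = U, p = min(unname(wt$p.value), 1))
}

#' Chi-square goodness of fit for a transgene segregation ratio
#'
#' Tests observed resistant/sensitive seedling counts against an expected
#' ratio `a:b` with the uncorrected (no Yates continuity correction)
#' statistic on 1 degree of freedom. A line "passes" (is consistent with
#' the ratio) when the statistic does not exceed the upper-alpha critical
#' value.
#'
#' @param resistant,sensitive Observed counts (non-negative, positive sum).
#' @param ratio Length-2 numeric, the expected ratio `c(a, b)` (e.g.
#'   `c(3, 1)`).
#' @param alpha Significance level for the pass/fail call.
#' @param line Optional line label.
#' @return One-row data frame: `line`, `resistant`, `sensitive`,
#'   `expected_ratio`, `chi2`, `df`, `critical`, `pass`.
#' @export
chi_square_gof <- function(resistant, sensitive, ratio = c(3, 1),
                           alpha = 0.05, line = NA_character_) {
  stopifnot(length(ratio) == 2L, all(ratio > 0),
            resistant >= 0, sensitive >= 0)
  total <- resistant + sensitive
  if (total == 0) stop("total seed count must be positive")
  expected <- total * ratio / sum(ratio)
  obs <- c(resistant, sensitive)
  chi2 <- sum((obs - expected)^2 / expected)
  crit <- chi2_critical(alpha, df = 1)
  data.frame(line = line, resistant = resistant, sensitive = sensitive,
             expected_ratio = paste(ratio, collapse = ":"), chi2 = chi2,
             df = 1L, critical = crit, pass = chi2 <= crit,
             stringsAsFactors = FALSE)
}

#' Upper-tail critical value of the chi-square distribution
#'
#' @param alpha Significance level in (0, 1).
#' @param df Degrees of freedom (>= 1).
#' @return The upper-`alpha` quantile; 3.84 at `(0.05, 1)` to two decimals.
#' @export
chi2_critical <- function(alpha = 0.05, df = 1) {
  stopifnot(alpha > 0, alpha < 1, df >= 1)
  qchisq(1 - alpha, df = df)
}

#' Segregation analysis of a counts table
#'
#' Applies [chi_square_gof()] to every row of a counts table.
#'
#' @param counts Data frame with columns `line`, `resistant`, `sensitive`,
#'   `expected_ratio` (string `"a:b"`).
#' @param alpha Significance level.
#' @return Data frame of per-line results (see [chi_square_gof()]).
#' @export
segregation_analysis <- function(counts, alpha = 0.05) {
  need <- c("line", "resistant", "sensitive", "expected_ratio")
  stopifnot(all(need %in% names(counts)))
  out <- lapply(seq_len(nrow(counts)), function(i) {
    ratio <- as.numeric(strsplit(counts$expected_ratio[i], ":")[[1]])
    chi_square_gof(counts$resistant[i], counts$sensitive[i], ratio,
                   alpha = alpha, line = counts$line[i])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
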