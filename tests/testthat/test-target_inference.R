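test_that("co-expression filter matches the t-transform p-value oracle", {
  set.seed(17)
  m <- 10
  x <- rnorm(m)
  y <- 0.8 * scale(x)[, 1] + sqrt(1 - 0.8^2) * rnorm(m)
  expr <- rbind(q = x, cand = y, other = rnorm(m))
  gs <- coexpression_filter(expr, "q", r_min = -1, p_max = 1)
  prov <- gs$provenance
  for (g in c("cand", "other")) {
    ct <- cor.test(x, expr[g, ])  # independent implementation
    row <- prov[prov$partner_gene == g, ]
    expect_equal(row$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(row$p, ct$p.value, tolerance = 1e-12)
  }
})

test_that("co-expression filter applies signed threshold, self and constant rules", {
  set.seed(18)
  m <- 12
  q <- rnorm(m)
  expr <- rbind(q = q,
                dupq = q,                       # exact duplicate of the query
                anti = -q + rnorm(m, sd = 0.01), # strong negative correlation
                flat = rep(3, m),               # constant: undefined r
                pos = q + rnorm(m, sd = 0.1))
  gs <- suppressMessages(coexpression_filter(expr, "q"))
  expect_false("q" %in% gs$genes)      # self excluded
  expect_false("dupq" %in% gs$genes)   # duplicate excluded
  expect_false("anti" %in% gs$genes)   # r_min is signed
  expect_false("flat" %in% gs$genes)   # constant skipped
  expect_true("pos" %in% gs$genes)
  # monotone non-increasing in r_min
  sizes <- vapply(c(0.5, 0.7, 0.9, 0.99),
                  function(r) length(suppressMessages(
                    coexpression_filter(expr, "q", r_min = r))$genes),
                  numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("precomputed co-expression tables filter with the same rules", {
  tab <- data.frame(query_gene = "q",
                    partner_gene = c("a", "b", "c", "q"),
                    r = c(0.9, 0.75, 0.71, 1),
                    p = c(1e-5, 0.01, 0.2, 0))
  gs <- coexpression_filter(tab, "q")
  expect_setequal(gs$genes, c("a", "b"))  # c fails p, q is a self-pair
  # top_k caps per query by descending r
  gs1 <- coexpression_filter(tab, "q", top_k = 1)
  expect_equal(gs1$genes, "a")
})

test_that("a PWM identical to the background scores zero with p = 1", {
  p <- pwm("flat", matrix(0.25, 6, 4))
  prom <- structure(data.frame(id = "s", description = "",
                               residues = strrep("ACGT", 30),
                               stringsAsFactors = FALSE),
                    class = c("sequence_set", "data.frame"))
  hits <- scan_promoters(prom, p, background = "uniform", p_max = 0.5)
  expect_equal(nrow(hits), 0L)  # every window has p = 1
  scheme <- pwm_scoring_scheme(p, rep(0.25, 4))
  expect_equal(pwm_score_pvalue(scheme, 0L), 1)
})

test_that("DP p-values equal brute-force enumeration for small widths", {
  set.seed(19)
  for (rep in 1:8) {
    w <- sample(4:7, 1)
    p <- random_pwm(w)
    bg <- c(0.3, 0.2, 0.2, 0.3)
    scheme <- pwm_scoring_scheme(p, bg)
    qs <- unique(round(seq(0, sum(apply(scheme$int, 1, max)), length.out = 25)))
    expect_equal(pwm_score_pvalue(scheme, qs), pwm_enum_pvalues(scheme, qs),
                 tolerance = 1e-12)
    # the full null distribution is a probability distribution
    expect_equal(sum(scheme$null_dist), 1, tolerance = 1e-12)
  }
})

test_that("planted consensus motifs are recovered at their offsets on both strands", {
  p <- synthetic_auxre_pwm()
  cons <- pwm_consensus(p)
  set.seed(20)
  bgseq <- function() paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  s_fwd <- bgseq(); substr(s_fwd, 101, 108) <- cons
  s_rev <- bgseq(); substr(s_rev, 101, 108) <- reverse_complement(cons)
  prom <- structure(data.frame(id = c("fwd", "rev"), description = "",
                               residues = c(s_fwd, s_rev),
                               stringsAsFactors = FALSE),
                    class = c("sequence_set", "data.frame"))
  hits <- scan_promoters(prom, p, background = "uniform")
  hf <- hits[hits$sequence_id == "fwd", ]
  hr <- hits[hits$sequence_id == "rev", ]
  expect_true(any(hf$start == 100 & hf$strand == "+"))
  expect_true(any(hr$start == 100 & hr$strand == "-"))
  # same consensus, same score and exact p on either strand
  expect_equal(hr$score[hr$start == 100], hf$score[hf$start == 100])
  expect_equal(hr$p[hr$start == 100], hf$p[hf$start == 100])
  # consensus p agrees with exhaustive enumeration over all 4^8 words
  scheme <- pwm_scoring_scheme(p, rep(0.25, 4))
  cons_int <- sum(vapply(seq_len(8), function(j)
    scheme$int[j, match(substr(cons, j, j), c("A", "C", "G", "T"))],
    integer(1)))
  expect_equal(pwm_score_pvalue(scheme, cons_int),
               pwm_enum_pvalues(scheme, cons_int), tolerance = 1e-15)
})

test_that("reverse-complementing the input mirrors coordinates and strands", {
  spec <- simulation_spec(seed = 23, n_genes = 4)
  prom <- generate_promoters(spec)[1:2, ]
  class(prom) <- c("sequence_set", "data.frame")
  p <- synthetic_auxre_pwm()
  fwd <- scan_promoters(prom, p, background = "uniform")
  rc <- prom
  rc$residues <- reverse_complement(prom$residues)
  rev <- scan_promoters(rc, p, background = "uniform")
  L <- nchar(prom$residues[1]); w <- nrow(p$matrix)
  key <- function(h, flip) {
    st <- if (flip) L - w - h$start else h$start
    sd <- if (flip) chartr("+-", "-+", h$strand) else h$strand
    sort(paste(h$sequence_id, st, sd, round(h$score, 9)))
  }
  expect_equal(key(rev, TRUE), key(fwd, FALSE))
})

test_that("hit counts are monotone non-increasing in the p threshold", {
  spec <- simulation_spec(seed = 29, n_genes = 6)
  prom <- generate_promoters(spec)
  p <- synthetic_auxre_pwm()
  ns <- vapply(c(1e-3, 1e-4, 1e-5, 1e-6), function(th)
    nrow(scan_promoters(prom, p, p_max = th)), numeric(1))
  expect_true(all(diff(ns) <= 0))
  # N-containing windows are never hits
  promN <- prom[1, ]
  class(promN) <- c("sequence_set", "data.frame")
  tr <- attr(prom, "truth")
  off <- tr$offset[tr$gene == promN$id]
  substr(promN$residues, off + 1, off + 3) <- "NNN"
  hN <- scan_promoters(promN, p, background = "uniform")
  expect_false(any(hN$start >= off - 7 & hN$start <= off + 2))
})

test_that("motif filter keeps hit-bearing genes and tallies missing promoters", {
  spec <- simulation_spec(seed = 31, n_genes = 30,
                          coexpr_block = list(size = 5L, r = 0.95))
  prom <- generate_promoters(spec)
  expr <- generate_expression(spec)
  coex <- coexpression_filter(expr, spec$query_gene)
  # plant list = block genes; only those promoters carry the consensus
  p <- synthetic_auxre_pwm()
  scanned <- prom[prom$id %in% coex$genes, ]
  class(scanned) <- c("sequence_set", "data.frame")
  hits <- scan_promoters(scanned, p, background = "uniform")
  targets <- filter_by_motif(coex, hits, scanned_ids = scanned$id)
  # exactly the genes with >= 1 hit pass; every planted gene is among them
  expect_setequal(targets$genes, intersect(unique(hits$sequence_id), coex$genes))
  expect_true(all(intersect(coex$genes, spec$block_genes) %in% targets$genes))
  expect_equal(attr(targets, "n_coexpressed"), length(coex$genes))
  # no hits anywhere -> empty target set
  none <- filter_by_motif(coex, hits[0, , drop = FALSE],
                          scanned_ids = scanned$id)
  expect_length(none$genes, 0L)
  # promoter missing for a co-expressed gene -> dropped and tallied
  some <- suppressMessages(
    filter_by_motif(coex, hits, scanned_ids = setdiff(scanned$id, coex$genes[1])))
  expect_false(coex$genes[1] %in% some$genes)
  expect_gte(attr(some, "n_no_promoter"), 1L)
})
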