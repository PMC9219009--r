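test_that("p-distance counts mismatches with pairwise gap deletion", {
  aln <- structure(data.frame(
    id = c("s1", "s2", "s3"), description = "",
    residues = c("ACGT", "ACGA", "AC-T"), stringsAsFactors = FALSE),
    class = c("sequence_set", "data.frame"))
  dm <- p_distance(aln)
  expect_equal(dm$d["s1", "s1"], 0)
  expect_equal(dm$d["s1", "s2"], 0.25)     # 1 mismatch / 4 columns
  expect_equal(dm$d["s1", "s3"], 0)        # gap column dropped, 3 compared
  expect_equal(dm$d, t(dm$d))
  bad <- aln
  bad$residues <- c("----", "AC-T", "ACGT")
  expect_error(p_distance(bad), "no comparable columns")
})

test_that("neighbor joining splits a two-taxon distance evenly", {
  d <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  tr <- neighbor_joining(d)
  expect_equal(sort(tr$tip.label), c("a", "b"))
  expect_equal(unname(tr$edge.length), c(0.2, 0.2))
})

test_that("neighbor joining recovers a known 4-taxon tree exactly", {
  # quartet ((A:0.1,B:0.2):0.05,(C:0.3,D:0.4)) written as additive distances
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 0.1 + 0.2
  d["A", "C"] <- d["C", "A"] <- 0.1 + 0.05 + 0.3
  d["A", "D"] <- d["D", "A"] <- 0.1 + 0.05 + 0.4
  d["B", "C"] <- d["C", "B"] <- 0.2 + 0.05 + 0.3
  d["B", "D"] <- d["D", "B"] <- 0.2 + 0.05 + 0.4
  d["C", "D"] <- d["D", "C"] <- 0.3 + 0.4
  tr <- neighbor_joining(d)
  expect_equal(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)], d,
               tolerance = 1e-12)
  # the unique internal split is {A,B} | {C,D}
  splits <- arfnet:::.bipartition_keys(tr)
  expect_true("C|D" %in% splits | "A|B" %in% splits)
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("neighbor joining is exact on random additive matrices", {
  set.seed(41)
  for (rep in 1:25) {
    n <- sample(4:12, 1)
    ra <- random_additive(n)
    tr <- neighbor_joining(ra$d)
    expect_lt(max(abs(ape::cophenetic.phylo(tr)[rownames(ra$d), colnames(ra$d)] -
                        ra$d)), 1e-9)
    # 2n - 3 edges for an unrooted binary tree
    expect_equal(nrow(tr$edge), 2 * n - 3)
  }
})

test_that("neighbor joining agrees with an independent implementation", {
  set.seed(42)
  for (rep in 1:5) {
    ra <- random_additive(8)
    ours <- neighbor_joining(ra$d)
    apes <- ape::nj(ra$d)
    expect_equal(ape::dist.topo(ape::unroot(ours), ape::unroot(apes)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("5-taxon topology matches the exhaustive best-fit search", {
  skip_if_not_installed("phangorn")
  set.seed(43)
  for (rep in 1:10) {
    ra <- random_additive(5)
    ours <- neighbor_joining(ra$d)
    all15 <- phangorn::allTrees(5, rooted = FALSE,
                                tip.label = rownames(ra$d))
    rss <- vapply(all15, ls_residual, numeric(1), d = ra$d)
    best <- all15[[which.min(rss)]]
    expect_lt(min(rss), 1e-12)
    expect_equal(ape::dist.topo(ape::unroot(ours), best), 0,
                 ignore_attr = TRUE)
  }
})

test_that("bootstrap support is deterministic and finds unanimous splits", {
  # every informative column separates {A,B} from {C,D}
  aln <- structure(data.frame(
    id = c("A", "B", "C", "D"), description = "",
    residues = c("AAAGGG", "AAAGGG", "TTTCCC", "TTTCCC"),
    stringsAsFactors = FALSE), class = c("sequence_set", "data.frame"))
  t1 <- bootstrap_support(aln, replicates = 30, seed = 5)
  t2 <- bootstrap_support(aln, replicates = 30, seed = 5)
  expect_equal(attr(t1, "support"), attr(t2, "support"))
  sup <- attr(t1, "support")
  expect_equal(unname(sup[!is.na(sup)]), 100)
  # a single replicate can only produce supports of 0 or 100
  s1 <- attr(bootstrap_support(aln, replicates = 1, seed = 9), "support")
  expect_true(all(s1[!is.na(s1)] %in% c(0, 100)))
  # supports are percentages
  expect_true(all(sup[!is.na(sup)] >= 0 & sup[!is.na(sup)] <= 100))
})

test_that("family extraction labels strays by smallest anchored clade", {
  tr <- ape::read.tree(text = "((a1:1,(a2:1,x:1):1):1,(b1:1,b2:1):1,out:3);")
  anchors <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  fams <- extract_family_groups(tr, anchors)
  expect_true("x" %in% fams$A$genes)        # stray inside the A clade
  expect_setequal(setdiff(fams$B$genes, "out"), c("b1", "b2"))
  # conflict rule: a leaf whose only anchored side mixes families stays out
  tr2 <- ape::read.tree(text = "((a1:1,b1:1):1,y:1,c:1);")
  fams_conflict <- extract_family_groups(tr2, c(a1 = "A", b1 = "B"))
  expect_setequal(fams_conflict$unassigned$genes, c("y", "c"))
  # all leaves anchored -> identity mapping
  all_anchored <- setNames(c("A", "A", "A", "B", "B", "B"), tr$tip.label)
  fams2 <- extract_family_groups(tr, all_anchored)
  expect_setequal(fams2$A$genes, names(all_anchored)[all_anchored == "A"])
  expect_length(fams2$unassigned$genes, 0L)
  expect_error(extract_family_groups(tr, c(zz = "A")), "absent")
})
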