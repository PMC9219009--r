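test_that("true-path propagation carries genes to every ancestor", {
  dag <- tiny_dag()
  ann <- tiny_annotations(c("g1", "g2"), c("T:rhair", "T:0"))
  tg <- propagate_annotations(ann, dag)
  # chain rhair -> rdev -> dev -> root
  for (t in c("T:rhair", "T:rdev", "T:dev", "T:0")) {
    expect_true("g1" %in% tg[[t]])
  }
  expect_false("g1" %in% (tg[["T:met"]] %||% character()))
  # annotation to the root stays at the root only
  expect_equal(sum(vapply(tg, function(g) "g2" %in% g, logical(1))), 1L)
  # idempotence: propagating the propagated annotation set changes nothing
  flat <- do.call(rbind, lapply(names(tg), function(t)
    data.frame(gene_id = tg[[t]], term_id = t)))
  ann2 <- tiny_annotations(flat$gene_id, flat$term_id)
  tg2 <- propagate_annotations(ann2, dag)
  for (t in names(tg)) expect_setequal(tg2[[t]], tg[[t]])
})

test_that("propagation matches the boolean transitive-closure oracle", {
  set.seed(57)
  n_terms <- 50
  ids <- sprintf("T:%02d", seq_len(n_terms))
  ch <- pa <- character()
  for (i in 2:n_terms) {
    for (p in sample(seq_len(i - 1), min(i - 1, sample(1:2, 1)))) {
      ch <- c(ch, ids[i]); pa <- c(pa, ids[p])
    }
  }
  dag <- ontology_graph(
    data.frame(id = ids, name = ids, namespace = "biological_process"),
    data.frame(child = ch, parent = pa, relation = "is_a"))
  genes <- sprintf("g%02d", 1:30)
  ann <- tiny_annotations(sample(genes, 60, TRUE), sample(ids, 60, TRUE))
  tg <- propagate_annotations(ann, dag)
  # oracle: reflexive-transitive closure by boolean matrix powers
  A <- matrix(FALSE, n_terms, n_terms, dimnames = list(ids, ids))
  A[cbind(ch, pa)] <- TRUE
  R <- diag(n_terms) > 0
  repeat {
    R2 <- R | (R %*% A > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  G <- matrix(FALSE, 30, n_terms, dimnames = list(genes, ids))
  G[cbind(ann$gene_id, ann$term_id)] <- TRUE
  closure <- (G %*% R) > 0
  for (t in ids) {
    expect_setequal(tg[[t]] %||% character(), genes[closure[, t]])
  }
})

test_that("cyclic ontologies are rejected", {
  dag <- ontology_graph(
    data.frame(id = c("a", "b"), name = c("a", "b"),
               namespace = "biological_process"),
    data.frame(child = c("a", "b"), parent = c("b", "a"), relation = "is_a"))
  ann <- tiny_annotations("g1", "a")
  expect_error(propagate_annotations(ann, dag), "cycle")
})

test_that("hypergeometric test matches the combinatorial sum", {
  # x=3, n=4, k=5, N=20: [C(4,3)C(16,2) + C(4,4)C(16,1)] / C(20,5)
  manual <- (choose(4, 3) * choose(16, 2) + choose(4, 4) * choose(16, 1)) /
    choose(20, 5)
  expect_equal(hypergeometric_test(3, 4, 5, 20), manual, tolerance = 1e-12)
  expect_equal(hypergeometric_test(0, 4, 5, 20), 1)      # upper tail from 0
  expect_equal(hypergeometric_test(2, 20, 5, 20), 1)     # term = population
  expect_error(hypergeometric_test(5, 4, 5, 20), "min")
  set.seed(59)
  for (rep in 1:40) {
    N <- sample(5:25, 1); n <- sample(1:N, 1); k <- sample(1:N, 1)
    x <- sample(0:min(n, k), 1)
    expect_equal(hypergeometric_test(x, n, k, N), hyper_enum_p(x, n, k, N),
                 tolerance = 1e-11)
  }
})

test_that("BH correction reproduces the step-up rule and dominates p", {
  expect_equal(correct_pvalues(0.03), 0.03)                   # m = 1
  expect_equal(correct_pvalues(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))                                  # hand step-up
  set.seed(61)
  for (rep in 1:10) {
    ps <- runif(sample(2:30, 1))
    qs <- correct_pvalues(ps)
    expect_true(all(qs >= ps - 1e-15))
    expect_true(all(qs <= 1))
    # q is monotone in p order
    o <- order(ps)
    expect_true(all(diff(qs[o]) >= -1e-15))
  }
  expect_error(correct_pvalues(c(0.5, 0)), "0, 1")
})

test_that("build_map flags a planted term and includes its ancestors", {
  spec <- simulation_spec(seed = 67)
  dag <- generate_ontology(spec)
  ann <- generate_annotations(spec, dag)
  planted_id <- dag$terms$id[nrow(dag$terms)]
  targets <- gene_set("block", spec$block_genes)
  net <- build_map(targets, ann, dag)
  res <- net$results
  expect_true(res$significant[res$term_id == planted_id])
  # invariants of the result rows
  expect_true(all(res$x <= pmin(res$n, res$k)))
  expect_true(all(res$q >= res$p - 1e-15))
  # ancestors of the significant set are present as context nodes
  anc <- arfnet:::.ancestors_of(dag, res$term_id[res$significant])
  expect_true(all(anc %in% igraph::V(net$graph)$name))
  expect_gte(igraph::vcount(net$graph), sum(res$significant))
  # empty target set -> empty network, not an error
  net0 <- build_map(gene_set("none", character()), ann, dag)
  expect_equal(sum(net0$results$significant), 0)
})

test_that("keyword node counting looks only at significant term names", {
  spec <- simulation_spec(seed = 71)
  dag <- generate_ontology(spec)
  ann <- generate_annotations(spec, dag)
  net <- build_map(gene_set("block", spec$block_genes), ann, dag)
  sig <- net$results[net$results$significant, ]
  expect_equal(count_keyword_nodes(net, "root"),
               sum(grepl("root", sig$term_name, ignore.case = TRUE)))
  expect_equal(count_keyword_nodes(net, "zzz-no-such-term"), 0L)
  net0 <- build_map(gene_set("none", character()), ann, dag)
  expect_equal(count_keyword_nodes(net0), 0L)
})

test_that("map comparison has the funnel-table shape", {
  spec <- simulation_spec(seed = 73)
  netA <- run_synthetic_pipeline(spec)
  netB <- run_synthetic_pipeline(null_spec(spec))
  cmp <- compare_maps(list(planted = netA, null = netB))
  expect_equal(cmp$quantity,
               c("coexpressed_genes", "motif_genes", "nodes", "keyword_nodes"))
  expect_named(cmp, c("quantity", "planted", "null"))
  expect_gt(cmp$planted[cmp$quantity == "keyword_nodes"],
            cmp$null[cmp$quantity == "keyword_nodes"])
  # identical maps give identical columns
  cmp2 <- compare_maps(list(a = netA, b = netA))
  expect_equal(cmp2$a, cmp2$b)
})
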