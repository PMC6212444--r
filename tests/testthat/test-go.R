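chain_dag <- function() {
  # root <- A <- B
  go_dag(data.frame(id = c("GO:0000001", "GO:0000002", "GO:0000003"),
                    name = c("root", "A", "B"),
                    namespace = "biological_process"),
         list("GO:0000002" = "GO:0000001",
              "GO:0000003" = "GO:0000002"))
}

test_that("OBO round-trip, obsolete handling and cycle detection", {
  sim <- small_cohort()
  p <- file.path(tempdir(), "toy.obo")
  diffscan:::write_obo(sim$go_terms, sim$go_edges, p)
  dag <- load_obo(p)
  expect_equal(sort(dag$terms$id), sort(sim$go_terms$id))
  expect_length(dag$roots, 1)

  obo <- c("format-version: 1.2", "",
           "[Term]", "id: GO:1", "name: a", "namespace: biological_process", "",
           "[Term]", "id: GO:2", "name: b", "namespace: biological_process",
           "is_a: GO:1 ! a", "is_obsolete: true", "")
  p2 <- file.path(tempdir(), "obs.obo")
  writeLines(obo, p2)
  expect_warning(d2 <- load_obo(p2), "obsolete")
  expect_equal(d2$terms$id, "GO:1")

  expect_error(go_dag(data.frame(id = c("x", "y"), name = "", namespace = ""),
                      list(x = "y", y = "x")), "cyclic")
})

test_that("true-path propagation is complete and idempotent", {
  dag <- chain_dag()
  g2g <- data.frame(gene_id = c("g1", "g2"), term = "GO:0000003")
  ann <- annotate_genes(g2g, dag)
  expect_setequal(ann[["GO:0000001"]], c("g1", "g2"))
  expect_setequal(ann[["GO:0000002"]], c("g1", "g2"))
  # idempotence: re-annotating from the propagated sets changes nothing
  flat <- do.call(rbind, lapply(names(ann), function(t) {
    if (length(ann[[t]])) data.frame(gene_id = ann[[t]], term = t)
  }))
  ann2 <- annotate_genes(flat, dag)
  expect_identical(ann2[names(ann)], ann[names(ann)])
  # empty annotation and unknown terms
  empty <- annotate_genes(data.frame(gene_id = character(),
                                     term = character()), dag)
  expect_true(all(lengths(empty) == 0))
  expect_error(annotate_genes(data.frame(gene_id = "g", term = "GO:9999999"),
                              dag), "unknown term")
})

test_that("classic Fisher over-representation matches the hypergeometric", {
  dag <- chain_dag()
  universe <- sprintf("u%03d", 1:200)
  cand <- universe[1:10]
  ann <- list("GO:0000003" = cand,        # all candidates, nothing else
              "GO:0000002" = universe[1:50],
              "GO:0000001" = universe)
  res <- classic_fisher(cand, universe, ann, min_sig = 5)
  r3 <- res[res$term == "GO:0000003", ]
  expect_lt(r3$p, 1e-6)
  # hypergeometric tail oracle: P(X >= 10) drawing 10 of 10 in-term genes
  expect_equal(r3$p, phyper(9, 10, 190, 10, lower.tail = FALSE),
               tolerance = 1e-12)
  # term = universe: no information
  expect_equal(res$p[res$term == "GO:0000001"], 1)
  # a term with fewer than min_sig candidates is absent
  ann$small <- universe[c(1:4, 100:120)]
  res2 <- classic_fisher(cand, universe, ann, min_sig = 5)
  expect_false("small" %in% res2$term)
})

test_that("KS score test is one-sided toward high scores", {
  set.seed(17)
  scores <- setNames(c(sort(rnorm(90)), rnorm(10) + 50), sprintf("g%03d", 1:100))
  ann <- list(hi = sprintf("g%03d", 91:100),   # the 10 largest scores
              lo = sprintf("g%03d", 1:10))
  res <- ks_score_test(scores, ann, min_size = 5)
  expect_lt(res$p[res$term == "hi"], 0.001)
  expect_gt(res$p[res$term == "lo"], 0.5)
  # terms below min_size are skipped
  res2 <- ks_score_test(scores, list(tiny = sprintf("g%03d", 1:3)))
  expect_equal(nrow(res2), 0)
})

test_that("elim discounts ancestors of significant specific terms", {
  dag <- chain_dag()
  universe <- sprintf("u%03d", 1:100)
  cand <- universe[1:10]
  ann <- list("GO:0000003" = universe[1:12],
              "GO:0000002" = universe[1:40],
              "GO:0000001" = universe[1:60])
  res <- elim_test(ann, dag, base = "fisher", cutoff = 0.01,
                   candidates = cand, universe = universe, min_sig = 0)
  rA <- res[res$term == "GO:0000002", ]
  rroot <- res[res$term == "GO:0000001", ]
  expect_gt(rA$p_elim, rA$p_classic)
  expect_gt(rroot$p_elim, rroot$p_classic)
  # manual application of the elimination rule: B is significant, so A and
  # the root are tested with B's original genes removed
  manual_A <- fisher.test(matrix(c(
    0, length(setdiff(ann[["GO:0000002"]], ann[["GO:0000003"]])),
    10, 100 - length(setdiff(ann[["GO:0000002"]], ann[["GO:0000003"]])) - 10
  ), 2, 2), alternative = "greater")$p.value
  expect_equal(rA$p_elim, manual_A, tolerance = 1e-12)

  # cutoff 0: nothing eliminated, elim equals classic
  res0 <- elim_test(ann, dag, base = "fisher", cutoff = 0,
                    candidates = cand, universe = universe, min_sig = 0)
  expect_equal(res0$p_elim, res0$p_classic)

  # single-term DAG: elim equals classic
  d1 <- go_dag(data.frame(id = "GO:0000009", name = "only",
                          namespace = "biological_process"), list())
  res1 <- elim_test(list("GO:0000009" = universe[1:20]), d1, base = "fisher",
                    candidates = cand, universe = universe)
  expect_equal(res1$p_elim, res1$p_classic)
})

test_that("elim with the KS base test runs end to end on the toy ontology", {
  sim <- small_cohort()
  dag <- go_dag(sim$go_terms, split(sim$go_edges$parent, sim$go_edges$child))
  ann <- annotate_genes(sim$gene2go, dag)
  set.seed(18)
  scores <- setNames(rnorm(nrow(sim$gene_models$genes)),
                     sim$gene_models$genes$gene_id)
  res <- elim_test(ann, dag, base = "ks", scores = scores)
  expect_true(all(res$p_elim >= 0 & res$p_elim <= 1))
  expect_true(all(res$term %in% sim$go_terms$id))
})
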