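write_tiny_obo <- function(path) {
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0", "name: root", "namespace: biological_process", "",
    "[Term]", "id: GO:A", "name: A", "namespace: biological_process",
    "is_a: GO:0 ! root", "",
    "[Term]", "id: GO:B", "name: B", "namespace: biological_process",
    "is_a: GO:A", "",
    "[Term]", "id: GO:C", "name: C", "namespace: biological_process",
    "is_a: GO:0", "",
    "[Term]", "id: GO:X", "name: other-branch",
    "namespace: molecular_function", "is_a: GO:0", "",
    "[Term]", "id: GO:OBS", "name: gone", "namespace: biological_process",
    "is_a: GO:0", "is_obsolete: true"), path)
  path
}

test_that("OBO/GAF loading restricts to the namespace and known terms", {
  obo <- write_tiny_obo(withr::local_tempfile(fileext = ".obo"))
  gaf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("g1\tGO:B", "g2\tGO:C", "g3\tGO:X", "g4\tGO:UNKNOWN"), gaf)
  expect_warning(go <- load_go(obo, gaf), "unknown terms")
  expect_setequal(go$dag$terms, c("GO:0", "GO:A", "GO:B", "GO:C"))
  expect_equal(go$dag$root, "GO:0")
  expect_equal(unname(go$dag$depth[c("GO:0", "GO:A", "GO:B", "GO:C")]),
               c(0L, 1L, 2L, 1L))
  expect_setequal(names(go$annotations), c("g1", "g2"))
})

test_that("term separation counts intermediate nodes", {
  dag <- go_dag(c("r", "a", "b", "c"),
                list(r = character(), a = "r", b = "a", c = "r"))
  expect_equal(term_path_separation(dag, "a", "a"), 0)
  expect_equal(term_path_separation(dag, "r", "a"), 0)   # parent-child
  expect_equal(term_path_separation(dag, "a", "c"), 1)   # siblings via r
  expect_equal(term_path_separation(dag, "b", "c"), 2)   # b-a-r-c
  expect_error(term_path_separation(dag, "a", "zz"), "zz")
  expect_error(go_dag(c("r", "a"), list(r = "a", a = "r")), "root|cyclic")
})

test_that("gene GFD matches the closed form on a 4-term DAG", {
  dag <- go_dag(c("r", "a", "b", "c"),
                list(r = character(), a = "r", b = "a", c = "r"))
  ann <- list(g1 = "b", g2 = "c", g3 = c("b", "c"), g4 = "b")
  # sep(b, c) = 2, depths 2 and 1
  expect_equal(gene_gfd(dag, ann, "g1", "g2"), 2 / 3)
  expect_equal(gene_gfd(dag, ann, "g2", "g1"), 2 / 3)    # symmetric
  expect_equal(gene_gfd(dag, ann, "g1", "g3"), 0)        # shared term
  expect_equal(gene_gfd(dag, ann, "g1", "g4"), 0)
  # adding a farther term never increases the minimum
  ann2 <- list(g1 = "b", g2 = c("c", "a"))
  expect_lte(gene_gfd(dag, ann2, "g1", "g2"),
             gene_gfd(dag, ann, "g1", "g2"))
  expect_error(gene_gfd(dag, ann, "g1", "nope"), "annotated")
})

test_that("cluster penalty is non-negative and vanishes as specified", {
  go <- gen_synthetic_go(seed = 13L, n_terms = 80L, n_genes = 60L)
  sc <- go_scorer(go$dag, go$annotations)
  set.seed(99)
  for (i in 1:50) {
    cl <- sample(sc$genes, sample(2:8, 1L))
    expect_gte(cluster_penalty(sc, cl), 0)
  }
  # the whole annotated genome has penalty 0
  expect_equal(cluster_penalty(sc, sc$genes), 0)
  expect_message(v <- cluster_penalty(sc, sc$genes[1L]), "fewer than two")
  expect_true(is.na(v))
})

test_that("penalty equals an exhaustive hand computation on 3 genes", {
  dag <- go_dag(c("r", "a", "b", "c", "d"),
                list(r = character(), a = "r", b = "a", c = "r", d = "c"))
  ann <- list(gx = "b", gy = "d", gz = "a", gw = "c")
  sc <- go_scorer(dag, ann)
  pair <- function(g1, g2) gene_gfd(dag, ann, g1, g2)
  genes <- c("gx", "gy", "gz")
  phi_hand <- sum(vapply(genes, function(g) {
    co <- setdiff(genes, g)
    all_g <- setdiff(names(ann), g)
    min(vapply(co, pair, 0, g1 = g)) - min(vapply(all_g, pair, 0, g1 = g))
  }, 0))
  expect_equal(cluster_penalty(sc, genes), phi_hand)
  expect_gte(phi_hand, 0)
})

test_that("null pools and empirical p-values follow the counting formula", {
  go <- gen_synthetic_go(seed = 17L, n_terms = 60L, n_genes = 40L)
  sc <- go_scorer(go$dag, go$annotations)
  p1 <- sample_null(sc, 3L, 5L, seed = 7L)
  p2 <- sample_null(sc, 3L, 5L, seed = 7L)
  expect_identical(p1, p2)
  expect_length(sample_null(sc, 2L, 1L, seed = 1L), 1L)
  expect_true(all(sample_null(sc, length(sc$genes), 3L, seed = 1L) == 0))
  expect_error(sample_null(sc, length(sc$genes) + 1L, 1L, 1L), "exceeds")
  expect_error(sample_null(sc, 1L, 10L, 1L), ">= 2")

  pool <- c(0, 0, 1, 2)
  expect_equal(empirical_pvalue(0, pool), 3 / 5)
  expect_equal(empirical_pvalue(5, pool), 1)
  expect_equal(empirical_pvalue(-1, pool), 1 / 5)
  expect_equal(empirical_pvalue(0, c(0, 1)), 2 / 3)
  # N = 1: p is 1/2 or 1
  expect_true(empirical_pvalue(0, 1) %in% c(1 / 2))
  expect_true(empirical_pvalue(2, 1) %in% c(1))
  # floor of the estimator is 1/(N+1); at N = 1e7 that is 1e-7
  expect_equal(empirical_pvalue(-1, rep(1, 1e4)), 1 / (1e4 + 1))
  expect_equal(1 / (1e7 + 1), 1e-7, tolerance = 1e-6)
})

test_that("ranking orders by p, then penalty, size, id", {
  res <- data.frame(cluster_id = c("c1", "c2", "c3", "c4", "c5"),
                    size = c(3L, 5L, 3L, 4L, 2L),
                    phi = c(0.006, 0, 0.5, 0, NA),
                    p_value = c(1e-7, 0.5, 1e-7, 0.5, NA))
  r <- rank_clusters(res)
  expect_equal(r$cluster_id, c("c1", "c3", "c2", "c4", "c5"))
  expect_equal(r$significant[1:2], c(TRUE, TRUE))
  expect_equal(nrow(rank_clusters(res[0, ])), 0L)
})

test_that("score_clusters scores, caches pools per size, flags unscorable", {
  go <- gen_synthetic_go(seed = 19L, n_terms = 80L, n_genes = 50L,
                         n_modules = 1L, module_size = 4L)
  sc <- go_scorer(go$dag, go$annotations)
  clusters <- list(planted = go$modules[[1L]],
                   random = sc$genes[1:4],
                   tiny = sc$genes[1L])
  rep <- score_clusters(sc, clusters, n_pool = 500, seed = 3L)
  expect_equal(rep$phi[rep$cluster_id == "planted"], 0)
  expect_true(is.na(rep$p_value[rep$cluster_id == "tiny"]))
  expect_true(all(rep$p_value[!is.na(rep$p_value)] > 0))
  expect_true(all(rep$p_value[!is.na(rep$p_value)] <= 1))
})
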