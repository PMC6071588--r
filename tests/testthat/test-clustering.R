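test_that("kappa similarity matches the contingency-table definition", {
  uni <- sprintf("g%d", 1:10)
  expect_equal(kappa_similarity(c("g1", "g2"), c("g1", "g2"), uni), 1)
  k <- kappa_similarity(c("g1", "g2", "g3"), c("g1", "g2", "g4"), uni)
  expect_equal(k, (0.8 - 0.58) / 0.42, tolerance = 1e-12)
  # complementary partition of the universe disagrees systematically
  expect_lt(kappa_similarity(uni[1:5], uni[6:10], uni), 0)
  # symmetric; matches the independent contingency oracle on random sets
  for (seed in 1:20) {
    set.seed(seed)
    i <- sample(uni, sample(1:8, 1)); j <- sample(uni, sample(1:8, 1))
    expect_equal(kappa_similarity(i, j, uni),
                 kappa_similarity(j, i, uni))
    expect_equal(kappa_similarity(i, j, uni),
                 kappa_contingency(i, j, uni), tolerance = 1e-12)
  }
  # both sets equal to the whole universe: no variation, kappa 0
  expect_equal(kappa_similarity(uni, uni, uni), 0)
  expect_error(kappa_similarity("a", "a", "a"),
               class = "famseg_domain_error")
})

toy_graph <- function(term_genes, input_genes,
                      settings = cluster_settings()) {
  results <- tibble::tibble(
    term = names(term_genes),
    p_raw = 0.01
  )
  amap <- list(term_genes = term_genes, universe = input_genes,
               term_names = NULL)
  build_term_graph(results, amap, input_genes, settings)
}

test_that("term graph edges require both kappa and overlap thresholds", {
  uni <- sprintf("g%02d", 1:20)
  tg <- toy_graph(list(t1 = uni[1:3], t2 = uni[4:6]), uni)
  expect_equal(igraph::ecount(tg$graph), 0)    # disjoint: overlap 0

  tg2 <- toy_graph(list(t1 = uni[1:3], t2 = uni[1:3]), uni)
  expect_equal(igraph::ecount(tg2$graph), 1)   # identical: kappa 1, overlap 3

  # large overlap but kappa below threshold: no edge
  tg3 <- toy_graph(list(t1 = uni[1:12], t2 = uni[5:20]), uni)
  expect_lt(kappa_similarity(uni[1:12], uni[5:20], uni), 0.5)
  expect_equal(igraph::ecount(tg3$graph), 0)
})

test_that("hand-engineered six-term fixture yields the drawn adjacency", {
  uni <- sprintf("g%02d", 1:30)
  sets <- list(
    a = uni[1:5], b = uni[1:5], c = uni[c(1:4, 6)],
    d = uni[10:14], e = uni[c(10:13, 15)], f = uni[20:22]
  )
  tg <- toy_graph(sets, uni)
  adj <- igraph::as_adjacency_matrix(tg$graph, sparse = FALSE)
  expected_edges <- list(c("a", "b"), c("a", "c"), c("b", "c"),
                         c("d", "e"))
  for (e in expected_edges) expect_equal(adj[e[1], e[2]], 1)
  expect_equal(sum(adj) / 2, length(expected_edges))
  expect_equal(igraph::degree(tg$graph)[["f"]], 0)
})

test_that("terms above the EASE threshold never enter the graph", {
  uni <- sprintf("g%02d", 1:20)
  results <- tibble::tibble(term = c("t1", "t2"), p_raw = c(0.01, 0.5))
  amap <- list(term_genes = list(t1 = uni[1:3], t2 = uni[1:3]),
               universe = uni, term_names = NULL)
  tg <- build_term_graph(results, amap, uni, cluster_settings())
  expect_equal(igraph::vcount(tg$graph), 1)
})

test_that("raising the similarity threshold only prunes edges", {
  uni <- sprintf("g%02d", 1:30)
  set.seed(4)
  sets <- lapply(setNames(1:8, paste0("t", 1:8)),
                 function(i) sample(uni, 6))
  previous <- Inf
  for (thr in c(0.2, 0.5, 0.8)) {
    tg <- toy_graph(sets, uni,
                    cluster_settings(similarity_threshold = thr,
                                     similarity_term_overlap = 2))
    expect_lte(igraph::ecount(tg$graph), previous)
    previous <- igraph::ecount(tg$graph)
  }
})

test_that("cliques cluster together and components stay apart", {
  uni <- sprintf("g%02d", 1:40)
  clique1 <- lapply(setNames(1:4, paste0("a", 1:4)),
                    function(i) uni[1:5])
  clique2 <- lapply(setNames(1:3, paste0("b", 1:3)),
                    function(i) uni[10:14])
  tg <- toy_graph(c(clique1, clique2), uni)
  cl <- cluster_terms(tg)
  expect_equal(nrow(cl), 2)
  expect_setequal(cl$terms[[1]], paste0("a", 1:4))
  expect_setequal(cl$terms[[2]], paste0("b", 1:3))
  # clusters are disjoint
  expect_equal(anyDuplicated(unlist(cl$terms)), 0)
})

test_that("chain clustering follows the seed-merge-prune trace", {
  # chain a-b-c-d: seeds are closed neighbourhoods {a,b}, {a,b,c},
  # {b,c,d}, {c,d}; all successive pairs share >= half of the smaller
  # group, so everything merges into one cluster {a,b,c,d}
  uni <- sprintf("g%02d", 1:40)
  sets <- list(a = uni[1:4], b = uni[c(1:3, 5)], c = uni[c(1, 3, 5, 6)],
               d = uni[c(3, 5, 6, 7)])
  tg <- toy_graph(sets, uni)
  edges <- igraph::as_edgelist(tg$graph)
  expect_setequal(paste(edges[, 1], edges[, 2]),
                  c("a b", "b c", "c d"))
  cl <- cluster_terms(tg)
  expect_equal(nrow(cl), 1)
  expect_setequal(cl$terms[[1]], c("a", "b", "c", "d"))
})

test_that("clustering output ignores input term order", {
  uni <- sprintf("g%02d", 1:40)
  set.seed(7)
  sets <- c(
    lapply(setNames(1:3, paste0("x", 1:3)), function(i) uni[1:5]),
    lapply(setNames(1:3, paste0("y", 1:3)), function(i) uni[20:24])
  )
  cl1 <- cluster_terms(toy_graph(sets, uni))
  cl2 <- cluster_terms(toy_graph(sets[sample(length(sets))], uni))
  expect_equal(cl1$terms, cl2$terms)
  expect_equal(cl1$enrichment_score, cl2$enrichment_score)
})

test_that("cluster enrichment scores average -log10 EASE p-values", {
  expect_equal(cluster_enrichment_score(c("a", "b"),
                                        c(a = 0.1, b = 0.1)), 1)
  expect_equal(cluster_enrichment_score(c("a", "b"),
                                        c(a = 0.01, b = 1e-4)), 3)
  expect_error(cluster_enrichment_score("z", c(a = 0.1)),
               class = "famseg_input_error")
  expect_warning(s <- cluster_enrichment_score("a", c(a = 0)),
                 "clamped")
  expect_true(is.finite(s) && s > 300)
})

test_that("clusters report descending enrichment scores", {
  uni <- sprintf("g%02d", 1:40)
  sets <- c(
    lapply(setNames(1:3, paste0("weak", 1:3)), function(i) uni[1:5]),
    lapply(setNames(1:3, paste0("strong", 1:3)), function(i) uni[20:24])
  )
  results <- tibble::tibble(
    term = names(sets),
    p_raw = ifelse(grepl("strong", names(sets)), 1e-6, 0.05)
  )
  amap <- list(term_genes = sets, universe = uni, term_names = NULL)
  tg <- build_term_graph(results, amap, uni, cluster_settings())
  cl <- cluster_terms(tg)
  expect_equal(nrow(cl), 2)
  expect_true(all(grepl("strong", cl$terms[[1]])))
  expect_equal(cl$enrichment_score, sort(cl$enrichment_score,
                                         decreasing = TRUE))
  expect_equal(cl$enrichment_score[1], 6)
})
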