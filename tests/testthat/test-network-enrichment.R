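# Deleteriousness scaling and interaction-network enrichment.

test_that("CADD scaling converts rank fractions to scaled scores", {
  expect_equal(cadd_scaled_score(0.1), 10)
  expect_equal(cadd_scaled_score(0.01), 20)
  expect_equal(cadd_scaled_score(0.001), 30)
  expect_equal(cadd_scaled_score(1), 0)
  expect_error(cadd_scaled_score(0), "\\(0, 1\\]")
  expect_error(cadd_scaled_score(-0.5), "\\(0, 1\\]")
})

test_that("threshold partition keeps gene-level maxima with multiplicity", {
  hits <- data.frame(gene = c("CACNA1C", "CACNA1C", "RYR2", "SYN1", "LOW1"),
                     score = c(10, 22, 28, 15.0, 3),
                     stringsAsFactors = FALSE)
  part <- partition_by_deleteriousness(hits, threshold = 15)
  expect_setequal(part$high$gene, c("CACNA1C", "RYR2"))
  expect_equal(part$high$multiplicity[part$high$gene == "CACNA1C"], 2)
  # score exactly at the threshold goes low (strict inequality)
  expect_true("SYN1" %in% part$low$gene)
  # a partition: union is the input, intersection empty
  expect_setequal(c(part$high$gene, part$low$gene), unique(hits$gene))
  expect_length(intersect(part$high$gene, part$low$gene), 0)

  empty <- partition_by_deleteriousness(hits[0, ])
  expect_equal(nrow(empty$high), 0)
  expect_equal(nrow(empty$low), 0)
})

test_that("complete and edgeless graphs give the degenerate enrichment answers", {
  k10 <- igraph::make_full_graph(10)
  igraph::V(k10)$name <- paste0("g", 1:10)
  res <- edge_enrichment(k10, paste0("g", c(2, 4, 6, 8)),
                         n_permutations = 99, seed = 1)
  expect_equal(res$observed_edges, 6)
  expect_equal(res$p_value, 1)

  empty <- igraph::make_empty_graph(8, directed = FALSE)
  igraph::V(empty)$name <- paste0("g", 1:8)
  res0 <- edge_enrichment(empty, paste0("g", 1:4), n_permutations = 99)
  expect_equal(res0$observed_edges, 0)
  expect_equal(res0$expected_edges, 0)
  expect_equal(res0$p_value, 1)
})

test_that("uniform-null expected edges match the closed form on a random graph", {
  g <- with_seed(42, igraph::sample_gnp(100, 0.05))
  igraph::V(g)$name <- paste0("g", 1:100)
  res <- edge_enrichment(g, paste0("g", 1:10), n_permutations = 2000,
                         null = "uniform", seed = 4)
  closed_form <- choose(10, 2) * igraph::ecount(g) / choose(100, 2)
  # 3 Monte-Carlo SE on the null mean
  mc_se <- res$null_sd / sqrt(res$n_permutations)
  expect_lt(abs(res$expected_edges - closed_form), 3 * mc_se)
})

test_that("permutation p-values are valid, reproducible and hit-set monotone", {
  g <- with_seed(7, igraph::sample_gnp(60, 0.08))
  igraph::V(g)$name <- paste0("g", 1:60)
  hits <- paste0("g", 1:8)
  a <- edge_enrichment(g, hits, n_permutations = 499, seed = 3)
  b <- edge_enrichment(g, hits, n_permutations = 499, seed = 3)
  expect_identical(a, b)
  expect_gt(a$p_value, 0)
  expect_lte(a$p_value, 1)

  # adding an internal edge cannot lower the observed count or raise p
  non_edges <- setdiff(utils::combn(hits, 2, paste, collapse = "|"),
                       apply(igraph::as_edgelist(
                         igraph::induced_subgraph(g, hits)), 1, paste,
                         collapse = "|"))
  pair <- strsplit(non_edges[1], "|", fixed = TRUE)[[1]]
  g2 <- igraph::add_edges(g, match(pair, igraph::V(g)$name))
  a2 <- edge_enrichment(g2, hits, n_permutations = 499, seed = 3)
  expect_gte(a2$observed_edges, a$observed_edges)
  expect_lte(a2$p_value, a$p_value)
})

test_that("degree-matched null preserves the hit set's degree-bin composition", {
  g <- with_seed(9, igraph::sample_pa(200, m = 2, directed = FALSE))
  igraph::V(g)$name <- paste0("g", 1:200)
  hubs <- paste0("g", order(igraph::degree(g), decreasing = TRUE)[1:10])
  u <- edge_enrichment(g, hubs, n_permutations = 500, null = "uniform",
                       seed = 2)
  d <- edge_enrichment(g, hubs, n_permutations = 500,
                       null = "degree-matched", seed = 2)
  # matching on degree must raise the null expectation for a hub-heavy set
  expect_gt(d$expected_edges, u$expected_edges)
})

test_that("hits absent from the graph are dropped with a message", {
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- paste0("g", 1:5)
  expect_message(res <- edge_enrichment(k5, c("g1", "g2", "NOPE"),
                                        n_permutations = 99),
                 "absent from graph")
  expect_equal(res$n_hits, 2)
  expect_error(suppressMessages(
    edge_enrichment(k5, c(paste0("g", 1:5), "x1"), n_permutations = 9)),
    NA)
})

test_that("clusters are induced components above the size floor, ordered stably", {
  edges <- rbind(
    t(utils::combn(paste0("big", 1:8), 2))[1:10, ],   # 8-node component
    c("pairA", "pairB"),                              # too small
    cbind(paste0("mid", c(1, 1, 2)), paste0("mid", c(2, 3, 3))),
    cbind(paste0("alt", c(1, 1, 2)), paste0("alt", c(2, 3, 3))))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  hits <- igraph::V(g)$name
  cl <- extract_clusters(g, hits, min_size = 3)
  expect_equal(lengths(cl), c(8, 3, 3))
  # ties broken lexicographically by smallest member
  expect_equal(cl[[2]][1], "alt1")
  expect_equal(cl[[3]][1], "mid1")
  expect_false(any(grepl("pair", unlist(cl))))

  none <- extract_clusters(g, c("pairA", "big1"), min_size = 3)
  expect_equal(length(none), 0)
})

test_that("cluster coding lengths are arithmetic means in kilobases", {
  genome <- data.frame(symbol = c("a", "b", "c", "d", "e", "f"),
                       length = c(4000, 5000, 6000, 10000, 10000, 250),
                       stringsAsFactors = FALSE)
  expect_equal(cluster_length_check(list(c("a", "b", "c")), genome), 5)
  expect_equal(cluster_length_check(list("f"), genome), 0.25)
  # large-gene vs small-gene clusters with a known 2:1 ratio
  lens <- cluster_length_check(list(c("d", "e"), c("a", "c")), genome)
  expect_equal(lens[1] / lens[2], 2)
  expect_warning(res <- cluster_length_check(list(c("a", "missing")), genome),
                 "no gene model")
  expect_equal(res, 4)
})
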