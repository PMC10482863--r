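test_that("density and average-degree formulas behave on counts and graphs", {
  expect_equal(bipartite_density(6, 3, 4), 0.5)
  expect_equal(projection_density(6, 4), 0.5)
  expect_equal(node_average_degree(6, 4), 3)
  expect_equal(links_per_node(6, 3), 2)
  g <- two_triangles()
  expect_equal(projection_density(g), 6 / (6 * 5))
  expect_equal(node_average_degree(g), 2)
})

test_that("degree vectors recount naively per snapshot", {
  # star and path sanity
  star <- igraph::make_star(4, mode = "undirected")
  igraph::V(star)$name <- paste0("s", 1:4)
  igraph::V(star)$nd <- 0
  dv <- degree_vectors(event_series(star))
  expect_equal(sort(dv$nodes[[1]]$alldegree, decreasing = TRUE),
               c(3, 1, 1, 1))

  path <- igraph::make_graph(c(1,2, 2,3), directed = TRUE)
  igraph::V(path)$name <- letters[1:3]
  igraph::V(path)$nd <- c(0, 0.5, 1)
  dvp <- degree_vectors(event_series(path))
  last <- dvp$nodes[[3]]
  expect_equal(last$outdegree[match(letters[1:3], last$name)], c(1, 1, 0))
  expect_equal(last$indegree[match(letters[1:3], last$name)], c(0, 1, 1))
  expect_equal(last$alldegree, last$indegree + last$outdegree)

  # weighted cumulative degrees match a brute recount on each snapshot
  g <- random_aged_graph(15, 0.3, directed = TRUE)
  ser <- event_series(g)
  dv2 <- degree_vectors(ser, weighted = TRUE)
  for (i in seq_along(ser$events)) {
    A <- oracle_adjacency(ser$snapshots[[i]])
    expect_equal(dv2$nodes[[i]]$alldegree, unname(rowSums(A)))
  }
})

test_that("Newman-Girvan modularity equals the formula oracle", {
  g <- two_triangles()
  expect_equal(ng_modularity(g, rep(1, 6)), 0)                 # trivial
  expect_equal(ng_modularity(g, c(1,1,1,2,2,2)), 0.5)          # components
  # path L1(0.1)-D1(0.1)-L2(0.2) partitioned by age
  p <- igraph::make_graph(c(1,2, 2,3), directed = FALSE)
  igraph::V(p)$name <- c("L1", "D1", "L2")
  igraph::V(p)$nd <- c(0.1, 0.1, 0.2)
  expect_equal(ng_modularity(p, partition_by_age(p)), -0.125)
  expect_error(ng_modularity(g, c(a1 = 1)), "missing node|length")
})

test_that("modularity matches brute force and igraph on random graphs", {
  set.seed(99)
  for (i in 1:60) {
    n <- sample(3:12, 1)
    g <- random_aged_graph(n, runif(1, 0.2, 0.7),
                           weighted = runif(1) < 0.5)
    memb <- sample(1:3, n, replace = TRUE)
    q <- ng_modularity(g, memb)
    expect_equal(q, oracle_modularity(g, memb), tolerance = 1e-12)
    expect_gte(q, -1); expect_lte(q, 1)
    if (igraph::ecount(g) > 0) {
      w <- if ("weight" %in% igraph::edge_attr_names(g))
        igraph::E(g)$weight else NULL
      expect_equal(q, igraph::modularity(g, memb, weights = w),
                   tolerance = 1e-12)
    }
  }
})

test_that("community detection finds planted and optimal structure", {
  g <- two_triangles()
  det <- detect_communities(g, "greedy")
  expect_equal(det$n_communities, 2L)
  expect_equal(det$quality, 0.5)
  # exhaustive search over all 6-node partitions confirms the optimum
  best <- max(vapply(oracle_all_partitions(6),
                     function(m) oracle_modularity(g, m), 0))
  expect_equal(det$quality, best)

  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- paste0("k", 1:5)
  igraph::V(k5)$nd <- 0
  d5 <- detect_communities(k5, "greedy")
  expect_equal(d5$n_communities, 1L)
  expect_equal(d5$quality, 0)

  # greedy quality never exceeds the exhaustive optimum on small graphs
  set.seed(5)
  for (i in 1:5) {
    n <- sample(4:8, 1)
    g <- random_aged_graph(n, 0.5, weighted = FALSE)
    if (igraph::ecount(g) == 0) next
    det <- detect_communities(g, "greedy")
    best <- max(vapply(oracle_all_partitions(n),
                       function(m) oracle_modularity(g, m), 0))
    expect_lte(det$quality, best + 1e-12)
  }

  # planted two-block graph recovered by both methods
  pp <- generate_planted_partition(80, 2, p_in = 0.35, p_out = 0.02,
                                   seed = 3)
  for (meth in c("greedy", "vos_like")) {
    det <- detect_communities(pp, meth, seed = 8)
    tab <- table(det$partition, igraph::V(pp)$block)
    agree <- sum(apply(tab, 1, max)) / igraph::vcount(pp)
    expect_gte(agree, 0.9)
  }
  expect_error(detect_communities(igraph::make_empty_graph(0)), "empty")
})

test_that("clustering coefficients match exhaustive triangle/triad counting", {
  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- paste0("a", 1:3); igraph::V(tri)$nd <- 0
  expect_equal(average_clustering(tri), 1)
  path <- igraph::make_graph(c(1,2, 2,3), directed = FALSE)
  igraph::V(path)$name <- paste0("p", 1:3); igraph::V(path)$nd <- 0
  expect_equal(average_clustering(path), 0)

  set.seed(13)
  for (i in 1:5) {
    g <- random_aged_graph(20, 0.25, directed = i %% 2 == 0)
    expect_equal(average_clustering(g), oracle_avg_clustering(g),
                 tolerance = 1e-12)
  }

  # triangle-free graphs have c = 0; series stats respect bipartite absence
  ring <- igraph::make_ring(8)
  igraph::V(ring)$name <- paste0("r", 1:8)
  igraph::V(ring)$nd <- seq(0, 1, length.out = 8)
  expect_equal(average_clustering(ring), 0)
  cs <- clustering_stats(event_series(ring))
  expect_true(all(cs$per_event$c[cs$per_event$n_nodes > 0] >= 0))

  tt <- toy_tables()
  bip <- build_bipartite(tt$mapping, tt$chronology)
  cb <- clustering_stats(event_series(bip))
  expect_true(all(is.na(cb$per_event$c)))
})

test_that("pairwise modularity matrices sum to zero and scale as specified", {
  # single edge: off-diagonal +0.5, diagonal -0.5
  e1 <- igraph::make_graph(c(1, 2), directed = FALSE)
  igraph::V(e1)$name <- c("L", "D")
  igraph::V(e1)$nd <- c(0.1, 0.1)
  igraph::V(e1)$type <- c(FALSE, TRUE)
  e1$ef_kind <- "bipartite"
  pm <- suppressWarnings(pairwise_modularity_matrix(e1))
  expect_equal(unname(pm$unscaled),
               matrix(c(-0.5, 0.5, 0.5, -0.5), 2))
  expect_equal(sum(pm$unscaled), 0, tolerance = 1e-12)
  expect_equal(sum(pm$matrix), 0, tolerance = 1e-12)

  tt <- toy_tables()
  bip <- build_bipartite(tt$mapping, tt$chronology)
  pm2 <- pairwise_modularity_matrix(bip)
  expect_equal(sum(pm2$unscaled), 0, tolerance = 1e-9)
  expect_equal(pm2$m_nd, abs(log10(abs(pm2$ng_age))))
  expect_equal(pm2$matrix, pm2$unscaled * pm2$m_nd)
  expect_equal(dim(pm2$block),
               c(sum(!igraph::V(bip)$type), sum(igraph::V(bip)$type)))
  expect_error(pairwise_modularity_matrix(bip, event = -1), "empty")
})

test_that("Ward dendrograms agree with the Lance-Williams oracle", {
  x <- rbind(a = c(0, 0), b = c(0, 0), c = c(5, 5))
  hc <- ward_dendrogram(x)
  expect_equal(hc$height[1], 0)
  merged_first <- sort(-hc$merge[1, ])
  expect_equal(rownames(x)[merged_first], c("a", "b"))

  set.seed(21)
  y <- matrix(rnorm(8 * 4), 8)
  rownames(y) <- paste0("r", 1:8)
  hc2 <- ward_dendrogram(y)
  expect_true(all(diff(hc2$height) >= -1e-12))
  expect_equal(hc2$height, oracle_ward_heights(y), tolerance = 1e-9)
  expect_error(ward_dendrogram(y[1, , drop = FALSE]), "2 rows")

  nwk <- tempfile(fileext = ".nwk")
  write_newick(hc2, nwk)
  tr <- ape::read.tree(nwk)
  expect_setequal(tr$tip.label, rownames(y))
})

test_that("connectivity accumulation conserves arcs across age bins", {
  g <- igraph::make_graph(c(1, 2), directed = TRUE)
  igraph::V(g)$name <- c("a", "b")
  igraph::V(g)$nd <- c(0.05, 0.95)
  acc <- accumulate_connectivity(g, 10)
  expect_equal(acc$bin[acc$node == "b" & acc$direction == "in"], 1L)
  expect_equal(acc$bin[acc$node == "a" & acc$direction == "out"], 10L)

  ds <- generate_dataset(synth_config(n_domains = 80, n_events = 16,
                                      seed = 12))
  bip <- build_bipartite(ds$mapping, ds$chronology, subset = "all")
  pr <- project(bip, "domain", seed = 2)
  acc2 <- accumulate_connectivity(pr, 10)
  n_arcs <- igraph::ecount(pr)
  expect_equal(sum(acc2$count[acc2$direction == "in"]), n_arcs)
  expect_equal(sum(acc2$count[acc2$direction == "out"]), n_arcs)
  # brute tally for one direction
  el <- igraph::as_edgelist(pr)
  nd <- setNames(igraph::V(pr)$nd, igraph::V(pr)$name)
  for (v in unique(el[, 2])) {
    partners <- nd[el[el[, 2] == v, 1]]
    bins <- pmin(10, floor(partners * 10) + 1)
    got <- acc2[acc2$node == v & acc2$direction == "in", ]
    expect_equal(sum(got$count), length(partners))
    expect_equal(sort(rep(got$bin, got$count)), sort(unname(bins)))
  }
})

test_that("reference growth models are deterministic with known structure", {
  a <- generate_reference_network(300, "barabasi", 1, seed = 5)
  b <- generate_reference_network(300, "barabasi", 1, seed = 5)
  expect_identical(igraph::as_edgelist(a), igraph::as_edgelist(b))
  # one edge per node -> tree -> no triangles for every seed
  for (s in 1:4)
    expect_equal(average_clustering(
      generate_reference_network(400, "barabasi", 1, seed = s)), 0)
  # tail of the degree distribution carries the preferential-attachment
  # exponent (asymptotically 3; finite-size fits sit lower)
  g <- generate_reference_network(2000, "barabasi", 1, seed = 1)
  f <- fit_power_law(igraph::degree(g, mode = "all"), bootstrap_reps = 0,
                     xmin = 2)
  expect_gte(f$alpha, 2.5); expect_lte(f$alpha, 3.5)
  # age-weighted variant builds the requested number of arcs
  ga <- generate_reference_network(200, "barabasi_age", 2, seed = 2)
  expect_equal(igraph::ecount(ga), 1 + 2 * 198)
  expect_true(all(diff(igraph::V(ga)$nd) > 0))
})

test_that("modularity reports expose the six indices coherently", {
  ds <- generate_dataset(synth_config(n_domains = 100, n_events = 20,
                                      seed = 3))
  bip <- build_bipartite(ds$mapping, ds$chronology, subset = "M")
  pr <- project(bip, "loop", seed = 1)
  mr <- modularity_report(pr, seed = 2)
  expect_true(is.na(modularity_report(bip)$c))   # bipartite: no triangles
  expect_true(mr$c >= 0 && mr$c <= 1)
  expect_true(mr$c_ratio >= 0 && mr$c_ratio <= 1)
  expect_true(abs(mr$ng_age) <= 1 && abs(mr$ng_vos) <= 1)
  expect_equal(mr$vq, mr$ng_vos)
  expect_gte(mr$fgc, 0)
})
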