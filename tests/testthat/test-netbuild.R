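test_that("bipartite construction attaches ages and respects subsets", {
  mapping <- as_mapping_table(data.frame(
    loop = c("DS.HE.3.1.1", "DS.EH.0.1.17", "DS.EH.0.1.17"),
    domain = c("c.1.1.1", "c.1.1.1", "c.2.1.1")))
  chron <- as_chronology(data.frame(domain = c("c.1.1.1", "c.2.1.1"),
                                    nd = c(0.1, 0.5)))
  g <- build_bipartite(mapping, chron, subset = "all")
  expect_equal(igraph::vcount(g), 4L)
  expect_equal(igraph::ecount(g), 3L)
  expect_true(igraph::is_bipartite(g))
  expect_false(any(is.na(igraph::V(g)$nd)))

  # NM subset is 1:1
  nm <- build_bipartite(mapping, chron, subset = "NM")
  expect_equal(igraph::ecount(nm), sum(!igraph::V(nm)$type))

  # no M loops -> empty network with a warning
  solo <- as_mapping_table(data.frame(loop = "DS.HE.3.1.1",
                                      domain = "c.1.1.1"))
  expect_warning(e <- build_bipartite(solo, chron, subset = "M"), "empty")
  expect_equal(igraph::vcount(e), 0L)

  # bipartite graphs 2-color: no odd cycles
  ds <- generate_dataset(synth_config(n_domains = 120, n_events = 20,
                                      seed = 4))
  big <- build_bipartite(ds$mapping, ds$chronology, subset = "all")
  expect_true(igraph::is_bipartite(big))
  expect_silent(igraph::bipartite_mapping(igraph::delete_vertex_attr(big, "type")))
})

test_that("projections carry brute-force shared-partner weights and point old to young", {
  mapping <- as_mapping_table(data.frame(
    loop = c("DS.HE.3.1.1", "DS.EH.0.1.17", "DS.EH.0.1.17"),
    domain = c("c.1.1.1", "c.1.1.1", "c.2.1.1")))
  chron <- as_chronology(data.frame(domain = c("c.1.1.1", "c.2.1.1"),
                                    nd = c(0.1, 0.5)))
  ages <- assign_loop_ages(mapping, chron, 2)
  bip <- build_bipartite(mapping, chron, ages)
  lp <- project(bip, "loop", seed = 1)
  expect_equal(igraph::ecount(lp), 1L)
  el <- igraph::as_edgelist(lp)
  # L1 (age 0.1) -> L2 (age 0.5): HE.3.1.1 age 0.1; EH.0.1.17 scheme2 age 0.5
  expect_equal(igraph::E(lp)$weight, 1)
  dp <- project(bip, "domain", seed = 1)
  expect_equal(igraph::ecount(dp), 1L)
  expect_equal(igraph::as_edgelist(dp)[1, ], c("c.1.1.1", "c.2.1.1"))

  # two loops sharing two domains -> one arc of weight 2
  m2 <- as_mapping_table(data.frame(
    loop = rep(c("DS.HE.3.1.1", "DS.EH.0.1.17"), each = 2),
    domain = rep(c("c.1.1.1", "c.2.1.1"), 2)))
  b2 <- build_bipartite(m2, chron)
  l2 <- project(b2, "loop", seed = 1)
  expect_equal(igraph::ecount(l2), 1L)
  expect_equal(igraph::E(l2)$weight, 2)
})

test_that("projection weights and directions match the exhaustive oracle on synthetic nets", {
  for (s in 1:3) {
    ds <- generate_dataset(synth_config(n_domains = 40, n_events = 10,
                                        seed = s))
    bip <- build_bipartite(ds$mapping, ds$chronology, subset = "all")
    expect_lte(igraph::vcount(bip), 100)
    for (side in c("loop", "domain")) {
      pr <- project(bip, side, seed = s + 10)
      orc <- oracle_projection(bip, side)
      n_expected <- if (is.null(orc)) 0L else nrow(orc)
      expect_equal(igraph::ecount(pr), n_expected)
      if (n_expected > 0) {
        el <- igraph::as_edgelist(pr)
        w <- igraph::E(pr)$weight
        key_pr <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
        key_or <- paste(pmin(orc$a, orc$b), pmax(orc$a, orc$b))
        expect_setequal(key_pr, key_or)
        expect_equal(w[match(key_or, key_pr)], orc$w)
        # temporal soundness: never younger -> strictly older
        nd <- setNames(igraph::V(pr)$nd, igraph::V(pr)$name)
        expect_true(all(nd[el[, 1]] <= nd[el[, 2]]))
      }
    }
  }
})

test_that("contemporaneous arcs are seeded deterministically", {
  mapping <- as_mapping_table(data.frame(
    loop = c("DS.HE.3.1.1", "DS.EH.0.1.17"),
    domain = c("c.1.1.1", "c.1.1.1")))
  chron <- as_chronology(data.frame(domain = "c.1.1.1", nd = 0.2))
  bip <- build_bipartite(mapping, chron)
  a <- igraph::as_edgelist(project(bip, "loop", seed = 7))
  b <- igraph::as_edgelist(project(bip, "loop", seed = 7))
  expect_identical(a, b)
})

test_that("event series grow monotonically and close over the full edge set", {
  ds <- generate_dataset(synth_config(n_domains = 60, n_events = 12,
                                      seed = 6))
  bip <- build_bipartite(ds$mapping, ds$chronology, subset = "all")
  ser <- event_series(bip)
  expect_equal(length(ser$events), length(unique(igraph::V(bip)$nd)))
  sizes_v <- vapply(ser$snapshots, igraph::vcount, 0)
  sizes_e <- vapply(ser$snapshots, igraph::ecount, 0)
  expect_true(all(diff(sizes_v) >= 0))
  expect_true(all(diff(sizes_e) >= 0))
  final <- ser$snapshots[[length(ser$snapshots)]]
  expect_equal(igraph::ecount(final), igraph::ecount(bip))

  # per-event edge counts equal a naive recount of induced edges
  el <- igraph::as_edgelist(bip)
  nd <- setNames(igraph::V(bip)$nd, igraph::V(bip)$name)
  for (i in seq_along(ser$events)) {
    naive <- sum(nd[el[, 1]] <= ser$events[i] & nd[el[, 2]] <= ser$events[i])
    expect_equal(sizes_e[i], naive)
  }

  # all nodes the same age -> a single event equal to the full network
  one <- as_mapping_table(data.frame(loop = "DS.HE.3.1.1",
                                     domain = "c.1.1.1"))
  ser1 <- event_series(build_bipartite(
    one, as_chronology(data.frame(domain = "c.1.1.1", nd = 0.4))))
  expect_equal(length(ser1$events), 1L)
})

test_that("hub subnetworks keep top-percentile nodes and drop contemporaneous arcs", {
  g <- igraph::make_graph(c(5,1, 5,2, 5,3, 5,4), directed = TRUE)
  igraph::V(g)$name <- paste0("n", 1:5)
  igraph::V(g)$nd <- c(0.5, 0.5, 0.6, 0.7, 0.1)
  igraph::E(g)$weight <- c(1, 1, 1, 7)   # combined degrees 1,1,1,7,10
  hub <- hub_subnetwork(g, 99)
  expect_equal(igraph::vcount(hub), 1L)
  expect_equal(igraph::V(hub)$name, "n5")

  # equal-age survivors lose their connecting arc
  h <- igraph::make_graph(c(1,2), directed = TRUE)
  igraph::V(h)$name <- c("a", "b")
  igraph::V(h)$nd <- c(0.3, 0.3)
  igraph::E(h)$weight <- 1
  kept <- hub_subnetwork(h, 0)
  expect_equal(igraph::vcount(kept), 2L)   # percentile 0 retains all nodes
  expect_equal(igraph::ecount(kept), 0L)   # contemporaneous arc dropped
  expect_error(hub_subnetwork(h, 100), "percentile")
})
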