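# Brute-force oracles kept deliberately independent of the package's
# implementation paths: everything here works from edge lists and dense
# matrices with nested loops.

# shared-partner projection by exhaustive pairwise intersection
oracle_projection <- function(bip, side) {
  el <- igraph::as_edgelist(bip, names = TRUE)
  kinds <- setNames(igraph::V(bip)$kind, igraph::V(bip)$name)
  nd <- setNames(igraph::V(bip)$nd, igraph::V(bip)$name)
  own <- names(kinds)[kinds == side]
  partners <- lapply(own, function(v) {
    unique(c(el[el[, 1] == v, 2], el[el[, 2] == v, 1]))
  })
  names(partners) <- own
  out <- NULL
  if (length(own) >= 2) {
    for (i in seq_len(length(own) - 1)) for (j in (i + 1):length(own)) {
      shared <- length(intersect(partners[[i]], partners[[j]]))
      if (shared > 0)
        out <- rbind(out, data.frame(a = own[i], b = own[j], w = shared,
                                     nd_a = nd[own[i]], nd_b = nd[own[j]],
                                     stringsAsFactors = FALSE))
    }
  }
  out
}

# weighted undirected adjacency built edge by edge (parallel edges summed)
oracle_adjacency <- function(net) {
  n <- igraph::vcount(net)
  A <- matrix(0, n, n)
  el <- igraph::as_edgelist(net, names = FALSE)
  w <- if (igraph::ecount(net) > 0 &&
           "weight" %in% igraph::edge_attr_names(net))
    igraph::E(net)$weight else rep(1, nrow(el))
  if (nrow(el) > 0) for (e in seq_len(nrow(el))) {
    i <- el[e, 1]; j <- el[e, 2]
    A[i, j] <- A[i, j] + w[e]
    if (i != j) A[j, i] <- A[j, i] + w[e]
  }
  A
}

# direct double-sum Newman-Girvan formula
oracle_modularity <- function(net, memb) {
  A <- oracle_adjacency(net)
  k <- rowSums(A)
  m <- sum(A) / 2
  if (m == 0) return(0)
  q <- 0
  n <- nrow(A)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (memb[i] == memb[j]) q <- q + A[i, j] - k[i] * k[j] / (2 * m)
  }
  q / (2 * m)
}

# mean ratio of triangles to connected triads by exhaustive triple counting
oracle_avg_clustering <- function(net) {
  A <- oracle_adjacency(net) > 0
  diag(A) <- FALSE
  n <- nrow(A)
  cc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(A[v, ])
    d <- length(nb)
    if (d < 2) { cc[v] <- 0; next }
    tri <- 0
    for (i in seq_len(d - 1)) for (j in (i + 1):d)
      if (A[nb[i], nb[j]]) tri <- tri + 1
    cc[v] <- tri / (d * (d - 1) / 2)
  }
  mean(cc)
}

# naive O(n^3) Ward clustering via the Lance-Williams update on squared
# Euclidean distances; returns merge heights in order
oracle_ward_heights <- function(x) {
  d <- as.matrix(stats::dist(x))^2
  n <- nrow(d)
  active <- seq_len(n)
  size <- rep(1, n)
  heights <- numeric(n - 1)
  for (s in seq_len(n - 1)) {
    best <- c(Inf, NA, NA)
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (ii < jj) {
        i <- active[ii]; j <- active[jj]
        if (d[i, j] < best[1]) best <- c(d[i, j], i, j)
      }
    }
    i <- best[2]; j <- best[3]
    heights[s] <- best[1]
    for (k in setdiff(active, c(i, j))) {
      ai <- (size[i] + size[k]) / (size[i] + size[j] + size[k])
      aj <- (size[j] + size[k]) / (size[i] + size[j] + size[k])
      b <- -size[k] / (size[i] + size[j] + size[k])
      d[i, k] <- d[k, i] <- ai * d[i, k] + aj * d[j, k] + b * d[i, j]
    }
    size[i] <- size[i] + size[j]
    active <- setdiff(active, j)
  }
  heights
}

# all set partitions of 1..n as membership vectors (restricted growth)
oracle_all_partitions <- function(n) {
  out <- list()
  rec <- function(memb, maxb) {
    pos <- length(memb) + 1
    if (pos > n) { out[[length(out) + 1]] <<- memb; return(invisible()) }
    for (b in seq_len(maxb + 1)) rec(c(memb, b), max(maxb, b))
  }
  rec(integer(0), 0L)
  out
}

# small random graph with ages and weights for property suites
random_aged_graph <- function(n, p = 0.4, directed = FALSE, weighted = TRUE) {
  g <- igraph::sample_gnp(n, p, directed = directed)
  igraph::V(g)$name <- paste0("n", seq_len(n))
  igraph::V(g)$nd <- round(runif(n), 2)
  if (weighted && igraph::ecount(g) > 0)
    igraph::E(g)$weight <- sample(1:4, igraph::ecount(g), replace = TRUE)
  g
}

# two disjoint triangles with ages
two_triangles <- function() {
  g <- igraph::make_graph(c(1,2, 2,3, 3,1, 4,5, 5,6, 6,4), directed = FALSE)
  igraph::V(g)$name <- paste0("t", 1:6)
  igraph::V(g)$nd <- c(0, 0, 0, 1, 1, 1)
  g
}

# tiny mapping + chronology fixture used across module tests
toy_tables <- function() {
  mapping <- as_mapping_table(data.frame(
    loop = c("DS.HE.3.1.1", "DS.EH.0.1.17", "DS.EH.0.1.17",
             "DS.HH.1.1.1", "DS.HH.1.1.1", "DS.GH.2.2.2"),
    domain = c("c.2.1.2", "c.2.1.2", "c.37.1.12",
               "a.4.5.28", "b.40.4.5", "c.37.1.12"),
    stringsAsFactors = FALSE))
  chronology <- as_chronology(data.frame(
    domain = c("c.37.1.12", "a.4.5.28", "c.2.1.2", "b.40.4.5"),
    nd = c(0, 0.1, 0.25, 0.1), stringsAsFactors = FALSE))
  list(mapping = mapping, chronology = chronology)
}

write_tsv_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
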