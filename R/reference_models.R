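#' Grow a preferential-attachment reference network
#'
#' Controls for the per-event power-law statistics. `barabasi` grows a
#' network in which every new node attaches to existing nodes with
#' probability proportional to their current degree (the growth starts from
#' a single edge so every node has positive degree). `barabasi_age` weights
#' the attachment by both degree and age: the probability is proportional to
#' degree * (t - birth + 1) / t at step t, a linear bonus for older nodes.
#' Birth order is recorded as the node age (`nd`, normalized to \[0, 1\]).
#'
#' With one edge per node the `barabasi` network is a tree, so its average
#' clustering coefficient is exactly 0.
#'
#' @param n Number of nodes (>= 2).
#' @param kind `"barabasi"` or `"barabasi_age"`.
#' @param edges_per_node Edges added with each new node (>= 1).
#' @param seed Integer seed; the same seed reproduces the edge list.
#' @return Directed igraph network (arcs old -> young) with vertex
#'   attributes `nd` and `birth`, edge weight 1, `ef_kind = "projection"`.
#' @export
generate_reference_network <- function(n, kind = c("barabasi", "barabasi_age"),
                                       edges_per_node = 1, seed = 1L) {
  kind <- match.arg(kind)
  if (!is_count(n) || n < 2) stopf("n must be an integer >= 2")
  if (!is_count(edges_per_node) || edges_per_node < 1)
    stopf("edges_per_node must be >= 1")
  edges <- with_seed(seed, {
    deg <- integer(n)
    # seed graph: nodes 1 and 2 joined, both with positive degree
    from <- integer(0); to <- integer(0)
    from <- 1L; to <- 2L
    deg[1:2] <- 1L
    if (n > 2) for (t in 3:n) {
      m <- min(edges_per_node, t - 1L)
      w <- deg[seq_len(t - 1L)]
      if (kind == "barabasi_age") {
        # age factor: older nodes (smaller birth index) weigh more
        w <- w * (t - seq_len(t - 1L) + 1) / t
      }
      targets <- sample.int(t - 1L, m, replace = FALSE, prob = w)
      from <- c(from, targets)
      to <- c(to, rep.int(t, m))
      deg[targets] <- deg[targets] + 1L
      deg[t] <- deg[t] + m
    }
    cbind(from, to)
  })
  g <- make_empty_graph(n = n, directed = TRUE)
  V(g)$name <- paste0("v", seq_len(n))
  V(g)$birth <- seq_len(n)
  V(g)$nd <- (seq_len(n) - 1) / (n - 1)
  g <- add_edges(g, t(edges))
  E(g)$weight <- 1
  g$ef_kind <- "projection"
  g$side <- paste0("reference_", kind)
  g
}

#' Generate a planted-partition benchmark graph
#'
#' Nodes are split into `n_blocks` equal communities; edges appear with
#' probability `p_in` within a community and `p_out` across, giving a known
#' ground-truth partition for community-detection checks.
#'
#' @param n Number of nodes.
#' @param n_blocks Number of planted communities.
#' @param p_in,p_out Within/between edge probabilities.
#' @param seed Integer seed.
#' @return Undirected igraph graph with vertex attribute `block`.
#' @export
generate_planted_partition <- function(n, n_blocks = 2, p_in = 0.25,
                                       p_out = 0.01, seed = 1L) {
  assert_prob(p_in, "p_in"); assert_prob(p_out, "p_out")
  sizes <- rep(n %/% n_blocks, n_blocks)
  sizes[seq_len(n %% n_blocks)] <- sizes[seq_len(n %% n_blocks)] + 1L
  pm <- matrix(p_out, n_blocks, n_blocks)
  diag(pm) <- p_in
  g <- with_seed(seed, sample_sbm(n, pref.matrix = pm, block.sizes = sizes))
  V(g)$name <- paste0("v", seq_len(n))
  V(g)$block <- rep(seq_len(n_blocks), sizes)
  g
}
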