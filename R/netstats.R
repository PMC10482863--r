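#' Density and average-degree summaries
#'
#' Elementary network summaries used throughout the per-event analysis.
#' Each accepts either raw counts or an igraph network.
#'
#' `bipartite_density()` is links / (n1 * n2), the realized fraction of
#' possible loop-domain links. `projection_density()` is arcs / (n * (n - 1)),
#' the directed density. `node_average_degree()` is 2 * links / nodes.
#' `links_per_node()` is links / nodes on one side (e.g. loops recruited per
#' domain).
#'
#' @param links,arcs Number of links/arcs, or an igraph graph from which the
#'   counts are taken.
#' @param n1,n2 Node counts of the two bipartite sides.
#' @param n_nodes Node count.
#' @return A single number.
#' @examples
#' bipartite_density(2546, 1937, 1442)
#' node_average_degree(2546, 1937 + 1442)
#' @export
bipartite_density <- function(links, n1 = NULL, n2 = NULL) {
  if (inherits(links, "igraph")) {
    g <- links
    links <- ecount(g)
    n1 <- sum(!V(g)$type); n2 <- sum(V(g)$type)
  }
  if (n1 == 0 || n2 == 0) return(NA_real_)
  links / (n1 * n2)
}

#' @rdname bipartite_density
#' @export
projection_density <- function(arcs, n_nodes = NULL) {
  if (inherits(arcs, "igraph")) {
    g <- arcs
    arcs <- ecount(g); n_nodes <- vcount(g)
  }
  if (n_nodes < 2) return(NA_real_)
  arcs / (n_nodes * (n_nodes - 1))
}

#' @rdname bipartite_density
#' @export
node_average_degree <- function(links, n_nodes = NULL) {
  if (inherits(links, "igraph")) {
    g <- links
    links <- ecount(g); n_nodes <- vcount(g)
  }
  if (n_nodes == 0) return(NA_real_)
  2 * links / n_nodes
}

#' @rdname bipartite_density
#' @export
links_per_node <- function(links, n_nodes = NULL) {
  if (inherits(links, "igraph")) stopf("links_per_node takes counts")
  if (n_nodes == 0) return(NA_real_)
  links / n_nodes
}

#' Per-event degree vectors
#'
#' Cumulative per-node degrees for every snapshot of an event series, plus a
#' normalized average-degree curve (mean degree / max degree at each event).
#'
#' @param series An `ef_event_series`.
#' @param weighted Use arc weights (strength) where present.
#' @return List with `nodes` (one data frame per event: `name`, `kind`,
#'   `indegree`, `outdegree`, `alldegree`) and `summary` (data frame with one
#'   row per event: `event`, `n_nodes`, `n_links`, `mean_degree`,
#'   `max_degree`, `norm_avg_degree`).
#' @export
degree_vectors <- function(series, weighted = TRUE) {
  per_event <- lapply(seq_along(series$events), function(i) {
    g <- series$snapshots[[i]]
    use_w <- weighted && "weight" %in% edge_attr_names(g)
    degs <- if (use_w) {
      list(inn = strength(g, mode = "in"),
           out = strength(g, mode = "out"),
           all = strength(g, mode = "all"))
    } else {
      list(inn = degree(g, mode = "in"),
           out = degree(g, mode = "out"),
           all = degree(g, mode = "all"))
    }
    data.frame(name = V(g)$name,
               kind = if ("kind" %in% vertex_attr_names(g)) V(g)$kind else NA,
               indegree = unname(degs$inn), outdegree = unname(degs$out),
               alldegree = unname(degs$all), stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, lapply(seq_along(per_event), function(i) {
    d <- per_event[[i]]$alldegree
    mx <- if (length(d)) max(d) else NA_real_
    data.frame(event = series$events[i],
               n_nodes = nrow(per_event[[i]]),
               n_links = ecount(series$snapshots[[i]]),
               mean_degree = if (length(d)) mean(d) else NA_real_,
               max_degree = mx,
               norm_avg_degree = if (!is.na(mx) && mx > 0) mean(d) / mx
                                 else NA_real_)
  }))
  list(nodes = per_event, summary = summary)
}

simplify_undirected <- function(net) {
  if (ecount(net) > 0 && !"weight" %in% edge_attr_names(net))
    E(net)$weight <- 1
  as_undirected(net, mode = "collapse",
                edge.attr.comb = list(weight = "sum", "ignore"))
}

#' Newman-Girvan modularity of a partition
#'
#' Q = (1/2m) * sum_ij (A_ij - k_i k_j / 2m) * delta(c_i, c_j) on the
#' weighted, undirected simplification of the network. Partitioning by time
#' event gives `NG_age` (assortative mixing of ages across modules);
#' partitioning by detected communities gives `NG_vos`.
#'
#' @param net An igraph network (direction ignored, weights used).
#' @param partition Community labels: a vector aligned with the vertices or
#'   named by vertex name.
#' @return Modularity in \[-1, 1\]; 0 for the single-community partition.
#' @export
ng_modularity <- function(net, partition) {
  memb <- align_partition(net, partition)
  und <- simplify_undirected(net)
  m <- if (ecount(und) > 0) sum(E(und)$weight) else 0
  if (m == 0) return(0)
  el <- as_edgelist(und, names = FALSE)
  w <- E(und)$weight
  within <- memb[el[, 1]] == memb[el[, 2]]
  k <- strength(und, mode = "all")
  kc <- tapply(k, memb, sum)
  sum(w[within]) / m - sum((kc / (2 * m))^2)
}

align_partition <- function(net, partition) {
  n <- vcount(net)
  if (!is.null(names(partition))) {
    idx <- match(V(net)$name, names(partition))
    if (anyNA(idx))
      stopf("partition missing node(s): %s",
            paste(V(net)$name[is.na(idx)], collapse = ", "))
    partition <- partition[idx]
  } else if (length(partition) != n) {
    stopf("partition length %d does not match %d nodes",
          length(partition), n)
  }
  as.integer(factor(partition))
}

#' Partition of a network's nodes by time event
#'
#' @param net Network with vertex attribute `nd`.
#' @return Named integer vector of event ranks.
#' @export
partition_by_age <- function(net) {
  setNames(match(V(net)$nd, sort(unique(V(net)$nd))), V(net)$name)
}

#' Detect communities
#'
#' `greedy` runs fast-greedy agglomerative modularity maximization;
#' `vos_like` runs a multi-level modularity-maximizing clustering standing in
#' for the VOS similarity clustering of the reference toolchain. Both operate
#' on the weighted undirected simplification.
#'
#' @param net Network with at least one edge.
#' @param method `"greedy"` or `"vos_like"`.
#' @param seed Seed for the randomized multi-level method.
#' @return List with `partition` (named membership vector), `quality`
#'   (Newman-Girvan modularity of the partition) and `n_communities`.
#' @export
detect_communities <- function(net, method = c("greedy", "vos_like"),
                               seed = 1L) {
  method <- match.arg(method)
  if (vcount(net) == 0) stopf("cannot detect communities in an empty graph")
  und <- simplify_undirected(net)
  if (ecount(und) == 0) {
    memb <- setNames(seq_len(vcount(und)), V(und)$name)
  } else {
    cl <- if (method == "greedy") cluster_fast_greedy(und)
          else with_seed(seed, cluster_louvain(und))
    memb <- setNames(membership(cl), V(und)$name)
    # a modularity maximizer must never do worse than the trivial partition
    if (ng_modularity(net, memb) < 0)
      memb <- setNames(rep(1L, vcount(und)), V(und)$name)
  }
  list(partition = memb,
       quality = ng_modularity(net, memb),
       n_communities = length(unique(memb)))
}

#' Per-event clustering-coefficient statistics
#'
#' The average clustering coefficient C is the mean ratio of triangles to
#' connected triads over all nodes of the simplified (undirected, unweighted)
#' network; nodes of degree < 2 contribute 0. C is not meaningful for
#' bipartite graphs (no triangles) and is reported as `NA` there. Log-log
#' regression exponents of C against network size N and against age nd are
#' returned for the event series.
#'
#' @param series An `ef_event_series` of a one-mode (projection) network;
#'   bipartite series yield `NA` coefficients.
#' @return List with `per_event` (data frame `event`, `n_nodes`, `c`,
#'   `c_ratio`, `n_communities`) and `exponents` (named numeric:
#'   `c_vs_n`, `c_vs_nd`).
#' @export
clustering_stats <- function(series) {
  is_bip <- identical(series$full$ef_kind, "bipartite")
  rows <- lapply(seq_along(series$events), function(i) {
    g <- series$snapshots[[i]]
    cc <- if (is_bip || vcount(g) == 0) NA_real_ else
      average_clustering(g)
    nc <- NA_integer_; cr <- NA_real_
    if (ecount(g) > 0) {
      det <- detect_communities(g, "greedy")
      nc <- det$n_communities
      n_conn <- sum(degree(g, mode = "all") >= 1)
      cr <- nc / n_conn
    }
    data.frame(event = series$events[i], n_nodes = vcount(g), c = cc,
               c_ratio = cr, n_communities = nc)
  })
  per_event <- do.call(rbind, rows)
  exponents <- c(c_vs_n = NA_real_, c_vs_nd = NA_real_)
  ok <- !is.na(per_event$c) & per_event$c > 0 & per_event$n_nodes > 0
  if (sum(ok) >= 2 && length(unique(per_event$n_nodes[ok])) > 1)
    exponents["c_vs_n"] <- unname(coef(lm(
      log(per_event$c[ok]) ~ log(per_event$n_nodes[ok])))[2])
  ok2 <- ok & per_event$event > 0
  if (sum(ok2) >= 2 && length(unique(per_event$event[ok2])) > 1)
    exponents["c_vs_nd"] <- unname(coef(lm(
      log(per_event$c[ok2]) ~ log(per_event$event[ok2])))[2])
  list(per_event = per_event, exponents = exponents)
}

#' Average clustering coefficient of a single network
#'
#' @param net igraph network; direction and weights ignored.
#' @return Mean local clustering coefficient; degree < 2 nodes count as 0.
#' @export
average_clustering <- function(net) {
  und <- simplify_undirected(net)
  if (vcount(und) == 0) return(NA_real_)
  transitivity(und, type = "localaverage", isolates = "zero")
}

#' All six modularity indices of one network snapshot
#'
#' Computes the clustering coefficient `c` (one-mode networks only), the
#' clustering ratio `c_ratio` (communities per connected node), fast-greedy
#' community modularity `fgc`, the Newman-Girvan index partitioned by age
#' (`ng_age`) and by the VOS-like clustering (`ng_vos`), and the VOS quality
#' `vq` (the sum over communities of e_cc - a_c^2, which is the modularity of
#' the VOS-like partition).
#'
#' @param net Network snapshot with vertex ages.
#' @param seed Seed for the randomized clustering.
#' @return List of class `ef_modreport` with fields `vq`, `c`, `c_ratio`,
#'   `fgc`, `ng_age`, `ng_vos`, `n_communities`.
#' @export
modularity_report <- function(net, seed = 1L) {
  is_bip <- identical(net$ef_kind, "bipartite")
  cc <- if (is_bip) NA_real_ else average_clustering(net)
  ng_age <- ng_modularity(net, partition_by_age(net))
  vq <- fgc <- ng_vos <- NA_real_
  nc <- NA_integer_; cr <- NA_real_
  if (ecount(net) > 0) {
    greedy <- detect_communities(net, "greedy")
    fgc <- greedy$quality
    vos <- detect_communities(net, "vos_like", seed = seed)
    ng_vos <- vos$quality
    vq <- vos$quality
    nc <- vos$n_communities
    cr <- greedy$n_communities / sum(degree(net, mode = "all") >= 1)
  }
  structure(list(vq = vq, c = cc, c_ratio = cr, fgc = fgc,
                 ng_age = ng_age, ng_vos = ng_vos, n_communities = nc),
            class = "ef_modreport")
}

#' @export
print.ef_modreport <- function(x, ...) {
  cat(sprintf("<ef_modreport> NG_age %.3f | NG_vos %.3f | VQ %.3f | FGC %.3f | C %s | C-ratio %s (%s communities)\n",
              x$ng_age, x$ng_vos, x$vq, x$fgc,
              format(x$c), format(x$c_ratio), format(x$n_communities)))
  invisible(x)
}

#' Scaled pairwise modularity matrix of a bipartite snapshot
#'
#' Elements are (A_ij - k_i k_j / 2m) * M_nd over all node pairs of the
#' snapshot at the given event, where M_nd = |log10(|NG_age|)| of the
#' snapshot. The unscaled matrix always sums to zero. The loop x domain
#' rectangular block drives the recruitment heat maps.
#'
#' @param bip Bipartite network.
#' @param event Time event (nd); the snapshot keeps nodes with age <= event.
#'   Defaults to the full network.
#' @return List of class `ef_modmatrix`: `matrix` (scaled, full square),
#'   `unscaled`, `block` (scaled loop x domain block), `m`, `m_nd`, `ng_age`,
#'   `event`.
#' @export
pairwise_modularity_matrix <- function(bip, event = NULL) {
  nd <- V(bip)$nd
  if (is.null(event)) event <- if (vcount(bip)) max(nd) else NA_real_
  keep <- which(nd <= event)
  if (length(keep) == 0) stopf("empty snapshot at event %s", format(event))
  g <- induced_subgraph(bip, keep)
  A <- as.matrix(as_adjacency_matrix(g, sparse = FALSE))
  m <- ecount(g)
  if (m == 0) stopf("snapshot at event %s has no links", format(event))
  k <- degree(g, mode = "all")
  B <- A - outer(k, k) / (2 * m)
  dimnames(B) <- list(V(g)$name, V(g)$name)
  ng_age <- ng_modularity(g, partition_by_age(g))
  if (ng_age == 0) {
    warnf("NG_age is 0 at event %s; using M_nd = 1", format(event))
    m_nd <- 1
  } else {
    m_nd <- abs(log10(abs(ng_age)))
  }
  scaled <- B * m_nd
  loops <- V(g)$name[!V(g)$type]
  doms <- V(g)$name[V(g)$type]
  structure(list(matrix = scaled, unscaled = B,
                 block = scaled[loops, doms, drop = FALSE],
                 m = m, m_nd = m_nd, ng_age = ng_age, event = event),
            class = "ef_modmatrix")
}

#' Ward dendrogram over the rows of a modularity matrix
#'
#' Agglomerative hierarchical clustering with Ward's minimum-variance
#' linkage on squared Euclidean row distances.
#'
#' @param mat An `ef_modmatrix` or a plain numeric matrix (rows clustered).
#' @return An `hclust` tree.
#' @export
ward_dendrogram <- function(mat) {
  x <- if (inherits(mat, "ef_modmatrix")) mat$matrix else as.matrix(mat)
  if (nrow(x) < 2) stopf("need at least 2 rows to build a dendrogram")
  stats::hclust(stats::dist(x)^2, method = "ward.D")
}

#' Write a dendrogram as a Newick tree
#'
#' @param hc An `hclust` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Connectivity accumulation by partner-age bin
#'
#' For every node of a directed projection, counts incoming and outgoing
#' arcs split by the age bin of the partner node (the timeline \[0, 1\]
#' coarse-grained into `n_bins` equal bins). Totals over bins equal the
#' in/out degree vectors. Nodes in the 99th percentile of combined degree
#' are flagged for labeling.
#'
#' @param net Directed projection network.
#' @param n_bins Number of age bins (>= 1).
#' @return Data frame `node`, `nd`, `direction` (`in`/`out`), `bin`,
#'   `count`, `is_hub`.
#' @export
accumulate_connectivity <- function(net, n_bins = 10) {
  if (!is_count(n_bins) || n_bins < 1) stopf("n_bins must be >= 1")
  age_bin <- function(a) pmin(n_bins, floor(a * n_bins) + 1L)
  el <- as_edgelist(net, names = FALSE)
  nd <- V(net)$nd
  nm <- V(net)$name
  rows <- list()
  if (nrow(el) > 0) {
    # arc u -> v: v records an in-arc from u's bin, u an out-arc to v's bin
    in_tab <- table(node = nm[el[, 2]], bin = age_bin(nd[el[, 1]]))
    out_tab <- table(node = nm[el[, 1]], bin = age_bin(nd[el[, 2]]))
    to_df <- function(tab, dir) {
      df <- as.data.frame(tab, stringsAsFactors = FALSE)
      df <- df[df$Freq > 0, , drop = FALSE]
      if (nrow(df) == 0) return(NULL)
      data.frame(node = df$node, direction = dir,
                 bin = as.integer(df$bin), count = df$Freq,
                 stringsAsFactors = FALSE)
    }
    rows <- list(to_df(in_tab, "in"), to_df(out_tab, "out"))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(node = character(), direction = character(),
                      bin = integer(), count = integer(),
                      stringsAsFactors = FALSE)
  comb <- strength(net, mode = "all")
  hubs <- nm[comb >= quantile(comb, 0.99)]
  out$nd <- nd[match(out$node, nm)]
  out$is_hub <- out$node %in% hubs
  out[order(out$node, out$direction, out$bin),
      c("node", "nd", "direction", "bin", "count", "is_hub")]
}
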