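#' @import igraph
NULL

#' Build a bipartite loop-domain network
#'
#' Nodes are loop prototypes and fold-family domains; an (unweighted,
#' undirected) edge records that the loop maps to the domain. The `subset`
#' argument restricts the loop side to modular (`M`) or non-modular (`NM`)
#' prototypes, giving the elementary-functionome (EF) network and the
#' ripple-structured NM network respectively.
#'
#' @param mapping An `ef_mapping`.
#' @param chronology An `ef_chronology`.
#' @param loop_ages Optional result of [assign_loop_ages()]; computed with
#'   scheme 2 when omitted.
#' @param subset One of `"all"`, `"M"`, `"NM"` (the `M` subset keeps `M`
#'   loops only, `M'` loops are excluded as in the reference analysis).
#' @return An igraph graph with logical vertex attribute `type`
#'   (`FALSE` = loop, `TRUE` = domain), vertex attributes `nd` and `kind`,
#'   and graph attributes `ef_kind = "bipartite"` and `subset`.
#' @export
build_bipartite <- function(mapping, chronology, loop_ages = NULL,
                            subset = c("all", "M", "NM")) {
  subset <- match.arg(subset)
  if (is.null(loop_ages)) loop_ages <- assign_loop_ages(mapping, chronology, 2)
  map <- as.data.frame(mapping)
  if (subset != "all") {
    cls <- classify_prototypes(mapping, chronology)
    keep_loops <- cls$loop[cls$label == subset]
    map <- map[map$loop %in% keep_loops, , drop = FALSE]
    if (nrow(map) == 0)
      warnf("subset '%s' is empty after filtering; returning empty network",
            subset)
  }
  loops <- sort(unique(map$loop))
  doms <- sort(unique(map$domain))
  g <- make_empty_graph(n = 0, directed = FALSE)
  g <- add_vertices(g, length(loops), name = loops, type = FALSE,
                    kind = "loop",
                    nd = loop_ages$age[match(loops, loop_ages$loop)])
  g <- add_vertices(g, length(doms), name = doms, type = TRUE,
                    kind = "domain",
                    nd = unname(domain_ages(chronology, doms)))
  if (nrow(map) > 0)
    g <- add_edges(g, rbind(match(map$loop, loops),
                            length(loops) + match(map$domain, doms)))
  g$ef_kind <- "bipartite"
  g$subset <- subset
  g
}

#' One-mode projection of a bipartite network
#'
#' Two nodes of the chosen side are connected when they share at least one
#' partner on the other side; the arc weight counts the shared partners.
#' Arcs point from the older to the younger node; pairs of equal age are
#' oriented by a seeded coin flip so runs are reproducible.
#'
#' @param bip Bipartite network from [build_bipartite()].
#' @param side `"loop"` or `"domain"`.
#' @param seed Integer seed for the contemporaneous-pair coin flips.
#' @return Directed igraph graph with edge attribute `weight`, vertex
#'   attributes `nd` and `kind`, and graph attributes
#'   `ef_kind = "projection"` and `side`.
#' @export
project <- function(bip, side = c("loop", "domain"), seed = 1L) {
  side <- match.arg(side)
  if (vcount(bip) == 0) {
    g <- make_empty_graph(0, directed = TRUE)
    g$ef_kind <- "projection"; g$side <- side
    return(g)
  }
  proj <- bipartite_projection(bip, multiplicity = TRUE)
  und <- if (side == "loop") proj$proj1 else proj$proj2
  el <- as_edgelist(und, names = FALSE)
  nd <- V(und)$nd
  dir_el <- el
  if (nrow(el) > 0) {
    swap <- nd[el[, 1]] > nd[el[, 2]]
    ties <- nd[el[, 1]] == nd[el[, 2]]
    if (any(ties)) {
      flips <- with_seed(seed, runif(sum(ties)) < 0.5)
      swap[ties] <- flips
    }
    dir_el[swap, ] <- el[swap, c(2, 1)]
  }
  g <- make_empty_graph(n = vcount(und), directed = TRUE)
  V(g)$name <- V(und)$name
  V(g)$nd <- nd
  V(g)$kind <- side
  if (nrow(dir_el) > 0) {
    g <- add_edges(g, t(dir_el))
    E(g)$weight <- E(und)$weight
  }
  g$ef_kind <- "projection"
  g$side <- side
  g
}

#' Cumulative time-event series of a growing network
#'
#' Each distinct node age present in the network defines one time event; the
#' snapshot at an event is the subgraph induced by all nodes whose age does
#' not exceed the event, so the series grows monotonically and the final
#' snapshot is the full network.
#'
#' @param net Bipartite or projection network with vertex attribute `nd`.
#' @return Object of class `ef_event_series`: list with `events` (sorted nd
#'   values), `snapshots` (list of igraph graphs) and `full`.
#' @export
event_series <- function(net) {
  nd <- V(net)$nd
  if (vcount(net) > 0 && anyNA(nd)) stopf("every node needs an nd age")
  events <- sort(unique(nd))
  snapshots <- lapply(events, function(e)
    induced_subgraph(net, which(nd <= e)))
  structure(list(events = events, snapshots = snapshots, full = net),
            class = "ef_event_series")
}

#' @export
print.ef_event_series <- function(x, ...) {
  cat(sprintf("<ef_event_series> %d events; final snapshot %d nodes / %d links\n",
              length(x$events), vcount(x$full), ecount(x$full)))
  invisible(x)
}

#' Hub subnetwork of a projection
#'
#' Keeps the nodes whose combined weighted degree (in + out strength) lies
#' strictly above the given percentile of all nodes, then removes arcs
#' between surviving nodes of equal age (contemporaneous pairs carry no
#' temporal information).
#'
#' @param net Directed projection network.
#' @param percentile Percentile cut in \[0, 100); 0 retains every node.
#' @return Induced subgraph of `net` on the hub nodes.
#' @export
hub_subnetwork <- function(net, percentile = 99) {
  if (percentile < 0 || percentile >= 100)
    stopf("percentile must lie in [0, 100)")
  deg <- strength(net, mode = "all")
  thr <- if (percentile <= 0) -Inf else
    unname(quantile(deg, percentile / 100))
  keep <- which(deg > thr)
  if (length(keep) == 0) {
    warnf("hub subnetwork is empty at percentile %g", percentile)
  }
  sub <- induced_subgraph(net, keep)
  if (ecount(sub) > 0) {
    el <- as_edgelist(sub, names = FALSE)
    same_age <- V(sub)$nd[el[, 1]] == V(sub)$nd[el[, 2]]
    sub <- delete_edges(sub, which(same_age))
  }
  sub
}
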