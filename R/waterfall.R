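#' Waterfall layout of an aged network
#'
#' Places nodes with age on the vertical axis (y is the age-event rank,
#' increasing down the page so older nodes sit at the top) and a
#' community-constrained horizontal spread: a seeded Kamada-Kawai pass is run
#' inside each community and communities are tiled left to right. Node sizes
#' follow the reference convention: horizontal size proportional to the
#' weighted outdegree and vertical size to the weighted indegree, both
#' shifted by 10 so 0-degree nodes stay visible.
#'
#' @param net Network with vertex ages (`nd`).
#' @param partition Community labels (named vector or aligned to vertices);
#'   detected with the VOS-like method when omitted.
#' @param seed Integer seed; identical seeds give identical coordinates.
#' @param size_shift Degree shift applied before scaling (default 10).
#' @param size_scale Multiplier on the shifted degrees.
#' @return Object of class `ef_layout`: list with `nodes` (data frame `name`,
#'   `kind`, `nd`, `x`, `y`, `width`, `height`, `community`, `color_key`) and
#'   `arcs` (`from`, `to`, `width`, `color_key` = destination age).
#' @export
waterfall_layout <- function(net, partition = NULL, seed = 1L,
                             size_shift = 10, size_scale = 1) {
  if (vcount(net) == 0) stopf("cannot lay out an empty network")
  if (is.null(partition)) {
    partition <- if (ecount(net) > 0)
      detect_communities(net, "vos_like", seed = seed)$partition
    else setNames(seq_len(vcount(net)), V(net)$name)
  }
  memb <- align_partition(net, partition)
  nd <- V(net)$nd
  y <- match(nd, sort(unique(nd)))

  # horizontal spread: Kamada-Kawai inside each community, communities tiled
  x <- numeric(vcount(net))
  offset <- 0
  gap <- 1
  for (cm in sort(unique(memb))) {
    idx <- which(memb == cm)
    sub <- induced_subgraph(net, idx)
    xs <- if (length(idx) == 1) 0 else
      with_seed(seed + cm, layout_with_kk(as_undirected(sub, mode = "collapse"))[, 1])
    xs <- xs - min(xs)
    span <- max(xs)
    if (span > 0) xs <- xs / span * (length(idx) - 1)
    x[idx] <- offset + xs
    offset <- offset + max(xs, 0) + gap
  }

  directed <- is_directed(net)
  w_out <- if (directed) strength(net, mode = "out") else
    strength(net, mode = "all")
  w_in <- if (directed) strength(net, mode = "in") else
    strength(net, mode = "all")
  nodes <- data.frame(
    name = V(net)$name,
    kind = if ("kind" %in% vertex_attr_names(net)) V(net)$kind else NA,
    nd = nd, x = x, y = y,
    width = (unname(w_out) + size_shift) * size_scale,
    height = (unname(w_in) + size_shift) * size_scale,
    community = unname(memb), color_key = nd,
    stringsAsFactors = FALSE)

  arcs <- data.frame(from = character(), to = character(),
                     width = numeric(), color_key = numeric())
  if (ecount(net) > 0) {
    el <- as_edgelist(net, names = TRUE)
    wt <- if ("weight" %in% edge_attr_names(net)) E(net)$weight else
      rep(1, ecount(net))
    arcs <- data.frame(from = el[, 1], to = el[, 2],
                       width = wt * size_scale,
                       color_key = nd[match(el[, 2], V(net)$name)],
                       stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, arcs = arcs), class = "ef_layout")
}

#' @export
print.ef_layout <- function(x, ...) {
  cat(sprintf("<ef_layout> %d nodes / %d arcs, %d communities\n",
              nrow(x$nodes), nrow(x$arcs), length(unique(x$nodes$community))))
  invisible(x)
}

#' Export a network (Pajek, GraphML or TSV edge list)
#'
#' Pajek export writes `<base>.net` (vertices with coordinates; the node age
#' nd is stored as the z coordinate so round trips preserve it) plus
#' `<base>.clu` carrying the age-event partition. GraphML carries all node
#' and arc attributes. The edge list is a plain TSV.
#'
#' @param net Network to export.
#' @param base Output path without extension.
#' @param layout Optional `ef_layout` supplying x/y coordinates.
#' @param format `"pajek"`, `"graphml"` or `"edgelist"`.
#' @return Character vector of the files written, invisibly.
#' @export
export_graph <- function(net, base, layout = NULL,
                         format = c("pajek", "graphml", "edgelist")) {
  format <- match.arg(format)
  files <- switch(format,
    pajek = export_pajek(net, base, layout),
    graphml = {
      f <- paste0(base, ".graphml")
      write_graph(net, f, format = "graphml")
      f
    },
    edgelist = {
      f <- paste0(base, ".tsv")
      el <- as_edgelist(net, names = TRUE)
      wt <- if (ecount(net) > 0 && "weight" %in% edge_attr_names(net))
        E(net)$weight else rep(1, nrow(el))
      df <- data.frame(from = el[, 1], to = el[, 2], weight = wt)
      write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
      f
    })
  invisible(files)
}

export_pajek <- function(net, base, layout = NULL) {
  n <- vcount(net)
  nm <- V(net)$name
  nd <- V(net)$nd
  if (!is.null(layout)) {
    xi <- layout$nodes$x[match(nm, layout$nodes$name)]
    yi <- layout$nodes$y[match(nm, layout$nodes$name)]
    norm01 <- function(v) if (diff(range(v)) > 0)
      (v - min(v)) / diff(range(v)) else rep(0.5, length(v))
    xi <- norm01(xi); yi <- norm01(yi)
  } else {
    xi <- rep(0.5, n); yi <- rep(0.5, n)
  }
  net_file <- paste0(base, ".net")
  lines <- c(sprintf("*Vertices %d", n),
             sprintf('%d "%s" %.6f %.6f %.6f', seq_len(n), nm, xi, yi, nd))
  el <- as_edgelist(net, names = FALSE)
  wt <- if (ecount(net) > 0 && "weight" %in% edge_attr_names(net))
    E(net)$weight else rep(1, nrow(el))
  section <- if (is_directed(net)) "*Arcs" else "*Edges"
  lines <- c(lines, section)
  if (nrow(el) > 0)
    lines <- c(lines, sprintf("%d %d %g", el[, 1], el[, 2], wt))
  writeLines(lines, net_file)
  clu_file <- paste0(base, ".clu")
  events <- match(nd, sort(unique(nd)))
  writeLines(c(sprintf("*Vertices %d", n), as.character(events)), clu_file)
  invisible(c(net_file, clu_file))
}

#' Re-import an exported network
#'
#' Inverse of [export_graph()] for the `pajek` and `graphml` formats; node
#' names, arcs, weights and ages round-trip.
#'
#' @param base Path without extension (pajek) or with it stripped (graphml).
#' @param format `"pajek"` or `"graphml"`.
#' @return igraph network.
#' @export
import_graph <- function(base, format = c("pajek", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml")
    return(read_graph(paste0(base, ".graphml"), format = "graphml"))
  lines <- readLines(paste0(base, ".net"))
  nv <- as.integer(sub("\\*Vertices\\s+", "", lines[1], ignore.case = TRUE))
  vx <- lines[seq_len(nv) + 1]
  m <- regmatches(vx, regexec('^\\s*(\\d+)\\s+"([^"]*)"\\s+(\\S+)\\s+(\\S+)\\s+(\\S+)', vx))
  nm <- vapply(m, `[`, "", 3)
  nd <- as.numeric(vapply(m, `[`, "", 6))
  header <- lines[nv + 2]
  directed <- grepl("^\\*Arcs", header, ignore.case = TRUE)
  edge_lines <- lines[-seq_len(nv + 2)]
  edge_lines <- edge_lines[nzchar(trimws(edge_lines))]
  g <- make_empty_graph(n = nv, directed = directed)
  V(g)$name <- nm
  V(g)$nd <- nd
  if (length(edge_lines)) {
    parts <- do.call(rbind, strsplit(trimws(edge_lines), "\\s+"))
    g <- add_edges(g, t(cbind(as.integer(parts[, 1]), as.integer(parts[, 2]))))
    E(g)$weight <- as.numeric(parts[, 3])
  }
  g
}
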