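#' Configuration for an end-to-end run
#'
#' Either `mapping_path` + `chronology_path` or a [synth_config()] must be
#' supplied. A single global seed fans out to fixed per-stage offsets so each
#' stage is independently reproducible.
#'
#' @param out_dir Output directory (created if needed).
#' @param mapping_path,chronology_path Input TSV paths, or `NULL` to
#'   simulate.
#' @param synth A [synth_config()] used when no input paths are given.
#' @param evalue_max E-value filter for the mapping table.
#' @param scheme Age-transfer scheme (1 or 2).
#' @param seed Global integer seed.
#' @param bootstrap_reps Bootstrap replicates per power-law fit.
#' @param percentile Hub-subnetwork percentile.
#' @param n_bins Age bins for connectivity accumulation.
#' @return List of class `ef_run_config`.
#' @export
run_config <- function(out_dir, mapping_path = NULL, chronology_path = NULL,
                       synth = synth_config(), evalue_max = 0.001,
                       scheme = 2, seed = 42L, bootstrap_reps = 50,
                       percentile = 99, n_bins = 10) {
  if (is.null(mapping_path) != is.null(chronology_path))
    stopf("supply both mapping_path and chronology_path, or neither")
  structure(list(out_dir = out_dir, mapping_path = mapping_path,
                 chronology_path = chronology_path, synth = synth,
                 evalue_max = evalue_max, scheme = scheme,
                 seed = as.integer(seed), bootstrap_reps = bootstrap_reps,
                 percentile = percentile, n_bins = n_bins),
            class = "ef_run_config")
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Per-event statistics table for a network
#'
#' One row per time event: size, cumulative degrees, power-law fit and all
#' modularity indices of the snapshot. Events whose snapshot is too small for
#' a power-law fit carry NA fit columns.
#'
#' @param net Aged network (bipartite or projection).
#' @param bootstrap_reps,seed Passed to [fit_power_law()].
#' @return Data frame, one row per event.
#' @export
per_event_stats <- function(net, bootstrap_reps = 50, seed = 1L) {
  series <- event_series(net)
  degs <- degree_vectors(series, weighted = TRUE)
  rows <- lapply(seq_along(series$events), function(i) {
    g <- series$snapshots[[i]]
    mr <- modularity_report(g, seed = seed)
    fit <- tryCatch(
      fit_power_law(degs$nodes[[i]]$alldegree,
                    bootstrap_reps = bootstrap_reps, seed = seed + i),
      error = function(e) NULL)
    data.frame(event = series$events[i],
               n_nodes = vcount(g), n_links = ecount(g),
               mean_degree = degs$summary$mean_degree[i],
               max_degree = degs$summary$max_degree[i],
               norm_avg_degree = degs$summary$norm_avg_degree[i],
               c = mr$c, c_ratio = mr$c_ratio, vq = mr$vq, fgc = mr$fgc,
               ng_age = mr$ng_age, ng_vos = mr$ng_vos,
               n_communities = mr$n_communities,
               gamma = if (is.null(fit)) NA_real_ else fit$gamma,
               r_squared = if (is.null(fit)) NA_real_ else fit$r_squared,
               alpha = if (is.null(fit)) NA_real_ else fit$alpha,
               ks_stat = if (is.null(fit)) NA_real_ else fit$ks_stat,
               ks_p = if (is.null(fit)) NA_real_ else fit$ks_p,
               loglik = if (is.null(fit)) NA_real_ else fit$loglik)
  })
  do.call(rbind, rows)
}

#' Run the full analysis pipeline
#'
#' validate/read -> classify -> build networks -> per-event statistics ->
#' layouts and exports, writing all tables plus a JSON manifest into
#' `cfg$out_dir`. Reruns with the same configuration are deterministic.
#'
#' @param cfg An [run_config()].
#' @return The manifest (list), invisibly; side effect: files under
#'   `cfg$out_dir`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "ef_run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "validate"
  res <- tryCatch({
    if (!is.null(cfg$mapping_path)) {
      if (!file.exists(cfg$mapping_path))
        stopf("mapping file not found: %s", cfg$mapping_path)
      if (!file.exists(cfg$chronology_path))
        stopf("chronology file not found: %s", cfg$chronology_path)
      mapping <- read_mapping_table(cfg$mapping_path, cfg$evalue_max)
      chronology <- read_chronology(cfg$chronology_path)
      source_desc <- list(mapping = cfg$mapping_path,
                          chronology = cfg$chronology_path)
    } else {
      synth <- cfg$synth
      synth$seed <- cfg$seed
      ds <- generate_dataset(synth)
      mapping <- ds$mapping
      chronology <- ds$chronology
      write_tsv(as.data.frame(mapping), file.path(cfg$out_dir, "mapping.tsv"))
      write_tsv(as.data.frame(chronology),
                file.path(cfg$out_dir, "chronology.tsv"))
      write_tsv(ds$truth$labels, file.path(cfg$out_dir, "truth_labels.tsv"))
      source_desc <- list(synthetic = unclass(synth))
    }

    stage <- "classify"
    ages <- assign_loop_ages(mapping, chronology, cfg$scheme)
    cls <- classify_prototypes(mapping, chronology)
    venn <- venn_domains(mapping, cls, chronology)
    write_tsv(merge(ages, as.data.frame(cls)[, c("loop", "label")], by = "loop"),
              file.path(cfg$out_dir, "classification.tsv"))
    write_tsv(data.frame(set = c("m_only", "nm_only", "both", "unmapped"),
                         n_domains = c(length(venn$m_only),
                                       length(venn$nm_only),
                                       length(venn$both),
                                       length(venn$unmapped))),
              file.path(cfg$out_dir, "venn.tsv"))

    stage <- "build"
    ef <- build_bipartite(mapping, chronology, ages, subset = "M")
    nm_net <- suppressWarnings(
      build_bipartite(mapping, chronology, ages, subset = "NM"))
    loop_proj <- project(ef, "loop", seed = cfg$seed + 1L)
    dom_proj <- project(ef, "domain", seed = cfg$seed + 2L)
    nets <- list(ef_bipartite = ef, loop_projection = loop_proj,
                 domain_projection = dom_proj)
    for (nm in names(nets))
      export_graph(nets[[nm]], file.path(cfg$out_dir, nm),
                   format = "edgelist")
    events_index <- do.call(rbind, lapply(names(nets), function(nm)
      data.frame(network = nm, event = sort(unique(V(nets[[nm]])$nd)))))
    write_tsv(events_index, file.path(cfg$out_dir, "events_index.tsv"))

    stage <- "stats"
    stats_tables <- lapply(seq_along(nets), function(i)
      per_event_stats(nets[[i]], bootstrap_reps = cfg$bootstrap_reps,
                      seed = cfg$seed + 3L + i))
    names(stats_tables) <- names(nets)
    for (nm in names(nets))
      write_tsv(stats_tables[[nm]],
                file.path(cfg$out_dir, paste0("stats_", nm, ".tsv")))
    if (ecount(ef) > 0) {
      pm <- pairwise_modularity_matrix(ef)
      write_tsv(data.frame(node = rownames(pm$matrix),
                           round(pm$matrix, 8), check.names = FALSE),
                file.path(cfg$out_dir, "pairwise_modularity_final.tsv"))
      if (nrow(pm$matrix) >= 2)
        write_newick(ward_dendrogram(pm),
                     file.path(cfg$out_dir, "pairwise_modularity_ward.nwk"))
    }
    conn <- accumulate_connectivity(loop_proj, n_bins = cfg$n_bins)
    write_tsv(conn, file.path(cfg$out_dir, "loop_connectivity_bins.tsv"))

    stage <- "layout"
    for (nm in names(nets)) {
      g <- nets[[nm]]
      if (vcount(g) == 0) next
      lay <- waterfall_layout(g, seed = cfg$seed + 7L)
      export_graph(g, file.path(cfg$out_dir, nm), layout = lay,
                   format = "pajek")
    }
    hubs <- hub_subnetwork(loop_proj, cfg$percentile)

    manifest <- list(
      package_version = as.character(utils::packageVersion("efnet")),
      seed = cfg$seed, scheme = cfg$scheme,
      evalue_max = cfg$evalue_max,
      bootstrap_reps = cfg$bootstrap_reps,
      inputs = source_desc,
      counts = list(
        mapping_records = nrow(mapping),
        loops = length(unique(mapping$loop)),
        domains = length(unique(mapping$domain)),
        labels = as.list(setNames(as.integer(attr(cls, "counts")),
                                  names(attr(cls, "counts")))),
        ef_nodes = vcount(ef), ef_links = ecount(ef),
        nm_nodes = vcount(nm_net), nm_links = ecount(nm_net),
        loop_projection_arcs = ecount(loop_proj),
        domain_projection_arcs = ecount(dom_proj),
        hub_nodes = vcount(hubs),
        events = as.list(setNames(
          vapply(nets, function(g) length(unique(V(g)$nd)), 0L),
          names(nets)))))
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    manifest
  }, error = function(e) {
    stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })
  invisible(res)
}
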