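#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis in one validated object.
#' Either the three input table paths or a synthetic spec must be given.
#' All randomness (co-clustering restarts, synthetic generation) flows from
#' the single `seed`.
#'
#' @param plants_path,pc_edges_path,predictions_path,annotations_path input
#'   table paths (see [read_tables()]); ignored when `synthetic` is given.
#' @param synthetic optional [synthetic_spec()] to generate inputs instead
#'   of reading them.
#' @param out_dir output directory (created if absent).
#' @param p_min activity-probability cut-off in \[0, 1\].
#' @param k_range candidate cluster counts for [select_k()].
#' @param seed root seed.
#' @param h_max dendrogram cut height in \[0, 1\].
#' @param tps_min minimum TPS to report.
#' @param min_target_chemicals minimum `|C_T|` for a target to be scored.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(plants_path = NULL, pc_edges_path = NULL,
                            predictions_path = NULL, annotations_path = NULL,
                            synthetic = NULL, out_dir = tempfile("phytonet_"),
                            p_min = 0.9, k_range = 2:10, seed = 1L,
                            h_max = 1 - 1e-9, tps_min = 0.1,
                            min_target_chemicals = 20L) {
  if (is.null(synthetic) &&
      (is.null(plants_path) || is.null(pc_edges_path) ||
       is.null(predictions_path)))
    stop("either a synthetic spec or all three input paths are required",
         call. = FALSE)
  if (length(k_range) == 0L)
    stop("k_range must be nonempty", call. = FALSE)
  if (p_min < 0 || p_min > 1) stop("p_min must be in [0, 1]", call. = FALSE)
  if (h_max < 0 || h_max > 1) stop("h_max must be in [0, 1]", call. = FALSE)
  if (tps_min < 0 || tps_min > 1)
    stop("tps_min must be in [0, 1]", call. = FALSE)
  structure(list(plants_path = plants_path, pc_edges_path = pc_edges_path,
                 predictions_path = predictions_path,
                 annotations_path = annotations_path, synthetic = synthetic,
                 out_dir = out_dir, p_min = p_min,
                 k_range = as.integer(k_range), seed = as.integer(seed),
                 h_max = h_max, tps_min = tps_min,
                 min_target_chemicals = as.integer(min_target_chemicals)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields map one-to-one onto [pipeline_config()] arguments; a
#' `synthetic:` mapping is passed to [synthetic_spec()]; `k_range` may be
#' given as `[k_min, k_max]`.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synthetic)) y$synthetic <- do.call(synthetic_spec, y$synthetic)
  if (!is.null(y$k_range) && length(y$k_range) == 2L)
    y$k_range <- seq(y$k_range[[1L]], y$k_range[[2L]])
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input acquisition (read or synthesize), the
#' preprocessing cascade with stage reports, spectral co-clustering over
#' `k_range` with modularity-based selection of k, structural statistics of
#' the network and of each subnetwork, Bray-Curtis/complete-linkage
#' clustering of the plants, the dendrogram cut, and TPS ranking of targets
#' for every plant cluster. Each product is written under `out_dir`
#' (`stage_reports.tsv`, `network/` + `network.graphml`, `partition.tsv`,
#' `modularity_curve.tsv`, `stats.json`, `dendrogram.nwk`, `clusters.tsv`,
#' `tps_results.tsv`) and listed with an MD5 content hash in
#' `manifest.json`; `pipeline.log` records every threshold and the seed. A
#' failing stage aborts with the stage name; outputs of completed stages
#' are left in place.
#'
#' @param config a [pipeline_config()] or path to a YAML config.
#' @return Invisibly, the manifest (list), with elements `seed`,
#'   `parameters`, `k_best` and `files` (name, path, md5).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat(sprintf("phytonet pipeline started %s\n",
              format(Sys.time(), "%Y-%m-%d %H:%M:%S")), file = log_path)
  logf("seed = %d", config$seed)
  logf("p_min = %g", config$p_min)
  logf("k_range = %d..%d", min(config$k_range), max(config$k_range))
  logf("h_max = %.12g", config$h_max)
  logf("tps_min = %g", config$tps_min)
  logf("min_target_chemicals = %d", config$min_target_chemicals)

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  files <- character()
  add_file <- function(name, path) files[[name]] <<- path

  inputs <- run_stage("inputs", {
    if (!is.null(config$synthetic)) {
      synth_generate(config$synthetic, out_dir = file.path(out_dir, "inputs"))
    } else {
      read_tables(config$plants_path, config$pc_edges_path,
                  config$predictions_path, config$annotations_path)
    }
  })

  pp <- run_stage("preprocess", run_preprocess(
    inputs$plants, inputs$pc_edges, inputs$predictions,
    p_min = config$p_min))
  net <- pp$network
  write_outputs(as.data.frame(pp$reports),
                file.path(out_dir, "stage_reports.tsv"), "tsv")
  add_file("stage_reports", file.path(out_dir, "stage_reports.tsv"))
  write_outputs(net, file.path(out_dir, "network"), "tsv")
  add_file("network_nodes", file.path(out_dir, "network", "nodes.tsv"))
  add_file("network_edges", file.path(out_dir, "network", "edges.tsv"))
  write_outputs(net, file.path(out_dir, "network.graphml"), "graphml")
  add_file("network_graphml", file.path(out_dir, "network.graphml"))

  curve <- run_stage("cocluster", {
    k_range <- config$k_range
    kmax_feasible <- min(length(net$plants) + length(net$targets),
                         length(net$chemicals))
    k_range <- k_range[k_range <= kmax_feasible]
    if (length(k_range) == 0L)
      stop("no feasible k in k_range for this network size")
    select_k(net, k_range = k_range, seed = config$seed)
  })
  part <- curve$best_partition
  utils::write.table(curve$entries, file.path(out_dir, "modularity_curve.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  add_file("modularity_curve", file.path(out_dir, "modularity_curve.tsv"))
  utils::write.table(partition_table(part, net),
                     file.path(out_dir, "partition.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  add_file("partition", file.path(out_dir, "partition.tsv"))
  logf("k_best = %d (modularity %.6f, normalized cut %.6f)",
       curve$k_best, part$modularity, part$normalized_cut)

  stats_all <- run_stage("stats", {
    whole <- structural_stats(net)
    subs <- subnetwork_stats(net, part)
    c(list(whole_network = whole), subs)
  })
  jsonlite::write_json(lapply(stats_all, unclass),
                       file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  add_file("stats", file.path(out_dir, "stats.json"))

  clusters <- run_stage("hcluster", {
    D <- distance_matrix(net)
    dend <- complete_linkage_tree(D)
    write_newick(dend, file.path(out_dir, "dendrogram.nwk"))
    cut_clusters(dend, h_max = config$h_max, net = net)
  })
  add_file("dendrogram", file.path(out_dir, "dendrogram.nwk"))
  cl_tab <- data.frame(
    plant_id = unlist(lapply(clusters, `[[`, "members"), use.names = FALSE),
    cluster_id = rep(names(clusters),
                     vapply(clusters, function(x) length(x$members),
                            integer(1))),
    stringsAsFactors = FALSE)
  utils::write.table(cl_tab, file.path(out_dir, "clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  add_file("clusters", file.path(out_dir, "clusters.tsv"))
  logf("dendrogram cut at h_max yields %d cluster(s)", length(clusters))

  tps_res <- run_stage("tps", tps_table(
    clusters, net, tps_min = config$tps_min,
    min_target_chemicals = config$min_target_chemicals))
  utils::write.table(tps_res, file.path(out_dir, "tps_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  add_file("tps_results", file.path(out_dir, "tps_results.tsv"))

  manifest <- list(
    seed = config$seed,
    parameters = list(p_min = config$p_min,
                      k_range = range(config$k_range),
                      h_max = config$h_max, tps_min = config$tps_min,
                      min_target_chemicals = config$min_target_chemicals),
    k_best = curve$k_best,
    n_clusters = length(clusters),
    files = lapply(names(files), function(nm) list(
      name = nm, path = files[[nm]],
      md5 = unname(tools::md5sum(files[[nm]])))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
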