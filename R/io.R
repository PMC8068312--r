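#' Read the input relation tables
#'
#' Reads the three (optionally four) tab-separated input tables: plant
#' records, plant-chemical membership edges, chemical-target activity
#' predictions, and optional chemical classification annotations. Every row
#' is either parsed or rejected with a row-numbered error. Prediction
#' probabilities are validated to lie in \[0, 1\]; duplicated
#' (chemical, target) prediction rows are collapsed to the maximum
#' probability (the most permissive reading under a strict probability
#' cut-off). Plant categories are lower-cased and unknown values map to
#' `"other"`; name fields are whitespace-trimmed but otherwise opaque.
#'
#' @param plants_path TSV with columns `record_id`, `scientific_name`,
#'   `latin_name`, `use_target`, `category`.
#' @param pc_edges_path TSV with columns `plant_id`, `chemical_id`.
#' @param predictions_path TSV with columns `chemical_id`, `target_id`,
#'   `probability`.
#' @param annotations_path optional TSV with columns `chemical_id`,
#'   `kingdom`, `superclass`, `class`, `subclass`, `direct_parent`.
#' @return list with elements `plants`, `pc_edges`, `predictions`,
#'   `annotations` (NULL when not supplied).
#' @export
read_tables <- function(plants_path, pc_edges_path, predictions_path,
                        annotations_path = NULL) {
  plants <- read_checked(plants_path,
                         c("record_id", "scientific_name", "latin_name",
                           "use_target", "category"))
  for (col in c("scientific_name", "latin_name", "use_target"))
    plants[[col]] <- trimws(plants[[col]])
  cat_norm <- tolower(trimws(plants$category))
  known <- c("plant", "fungus", "animal", "mineral", "other")
  cat_norm[!(cat_norm %in% known) | is.na(cat_norm)] <- "other"
  plants$category <- cat_norm
  if (anyDuplicated(plants$record_id))
    stop("duplicated record_id in plant table: ",
         plants$record_id[duplicated(plants$record_id)][1L], call. = FALSE)

  pc <- read_checked(pc_edges_path, c("plant_id", "chemical_id"))

  preds <- read_checked(predictions_path,
                        c("chemical_id", "target_id", "probability"))
  p <- suppressWarnings(as.numeric(preds$probability))
  bad <- which(is.na(p) | p < 0 | p > 1)
  if (length(bad) > 0L)
    stop(sprintf("probability outside [0, 1] (or non-numeric) in '%s' at data row %s (value '%s')",
                 predictions_path, bad[1L], preds$probability[bad[1L]]),
         call. = FALSE)
  preds$probability <- p
  preds <- collapse_predictions(preds)

  annotations <- NULL
  if (!is.null(annotations_path)) {
    annotations <- read_checked(annotations_path,
                                c("chemical_id", "kingdom", "superclass",
                                  "class", "subclass", "direct_parent"))
  }

  list(plants = plants, pc_edges = pc, predictions = preds,
       annotations = annotations)
}

read_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop(sprintf("'%s' is missing required column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  df[required]
}

# duplicates of one (chemical, target) pair keep the maximum probability;
# the surviving rows stay in first-appearance order
collapse_predictions <- function(preds) {
  if (nrow(preds) < 2L) return(preds)
  key <- paste(preds$chemical_id, preds$target_id, sep = "\r")
  o <- order(factor(key, levels = unique(key)), -preds$probability)
  preds <- preds[o, , drop = FALSE]
  preds <- preds[!duplicated(key[o]), , drop = FALSE]
  rownames(preds) <- NULL
  preds
}

#' Write analysis objects to disk
#'
#' A single dispatching writer for the package's result objects. Supported
#' combinations: a [multinet] as `"tsv"` (node/edge TSV pair) or
#' `"graphml"`; a plant dendrogram as `"newick"`; a co-clustering partition,
#' a modularity curve, stage reports or TPS result tables as `"tsv"`.
#' Unsupported format names are fatal and the error lists the supported
#' formats.
#'
#' @param x object to write.
#' @param path output path: a directory for network TSV export, a file
#'   otherwise.
#' @param format output format name (see Details).
#' @param ... unused.
#' @return Invisibly, the path(s) written.
#' @export
write_outputs <- function(x, path, format, ...) UseMethod("write_outputs")

#' @export
write_outputs.multinet <- function(x, path, format = c("tsv", "graphml"), ...) {
  format <- check_format(format, c("tsv", "graphml"))
  if (format == "tsv") return(write_network_tsv(x, path))
  ig <- multinet_to_igraph(x)
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' @export
write_outputs.plant_dendrogram <- function(x, path, format = "newick", ...) {
  format <- check_format(format, "newick")
  write_newick(x, path)
}

#' @export
write_outputs.multinet_partition <- function(x, path, format = "tsv", ...) {
  format <- check_format(format, "tsv")
  utils::write.table(partition_table(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
write_outputs.data.frame <- function(x, path, format = "tsv", ...) {
  format <- check_format(format, "tsv")
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

check_format <- function(format, supported) {
  format <- format[1L]
  if (!format %in% supported)
    stop(sprintf("unsupported format '%s'; supported: %s", format,
                 paste(supported, collapse = ", ")), call. = FALSE)
  format
}

write_network_tsv <- function(net, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nodes <- network_nodes(net)
  edges <- network_edges(net)
  np <- file.path(dir, "nodes.tsv")
  ep <- file.path(dir, "edges.tsv")
  utils::write.table(nodes, np, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(edges, ep, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(np, ep))
}

#' Read a network written by [write_outputs()]
#'
#' @param path directory with `nodes.tsv`/`edges.tsv` (TSV format) or a
#'   `.graphml` file.
#' @param format `"tsv"` or `"graphml"`.
#' @return a [multinet]; reading a written network reproduces an identical
#'   network (same node and edge sets).
#' @export
read_network <- function(path, format = c("tsv", "graphml")) {
  format <- check_format(format, c("tsv", "graphml"))
  if (format == "tsv") {
    nodes <- utils::read.delim(file.path(path, "nodes.tsv"),
                               stringsAsFactors = FALSE,
                               colClasses = "character")
    edges <- utils::read.delim(file.path(path, "edges.tsv"),
                               stringsAsFactors = FALSE,
                               colClasses = "character")
  } else {
    ig <- igraph::read_graph(path, format = "graphml")
    nodes <- data.frame(node = igraph::V(ig)$name,
                        layer = igraph::V(ig)$layer,
                        stringsAsFactors = FALSE)
    el <- igraph::as_edgelist(ig)
    edges <- data.frame(from = el[, 1L], to = el[, 2L],
                        stringsAsFactors = FALSE)
  }
  plants <- nodes$node[nodes$layer == "plant"]
  chems <- nodes$node[nodes$layer == "chemical"]
  targs <- nodes$node[nodes$layer == "target"]
  is_pc <- edges$from %in% plants | edges$to %in% plants
  pc_raw <- edges[is_pc, , drop = FALSE]
  ct_raw <- edges[!is_pc, , drop = FALSE]
  # orient edges as (plant, chemical) and (chemical, target)
  pc <- data.frame(
    plant = ifelse(pc_raw$from %in% plants, pc_raw$from, pc_raw$to),
    chemical = ifelse(pc_raw$from %in% plants, pc_raw$to, pc_raw$from),
    stringsAsFactors = FALSE)
  ct <- data.frame(
    chemical = ifelse(ct_raw$from %in% chems, ct_raw$from, ct_raw$to),
    target = ifelse(ct_raw$from %in% chems, ct_raw$to, ct_raw$from),
    stringsAsFactors = FALSE)
  multinet(plants = plants, chemicals = chems, targets = targs,
           pc_edges = pc, ct_edges = ct)
}

#' Export a plant dendrogram as a Newick tree
#'
#' Branch lengths are differences of merge heights, so the total path length
#' from the root to any leaf equals the height of the final merge
#' (an ultrametric tree). A single-leaf dendrogram is written as
#' `leafname;`.
#'
#' @param dend a `plant_dendrogram` from [complete_linkage_tree()].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(dend, path) {
  stopifnot(inherits(dend, "plant_dendrogram"))
  n <- length(dend$labels)
  if (n == 1L) {
    writeLines(paste0(dend$labels, ";"), path)
    return(invisible(path))
  }
  phy <- dendrogram_to_phylo(dend)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Convert a plant dendrogram to an ape phylo tree
#'
#' Leaves sit at depth equal to the root merge height; edge lengths are
#' parent minus child merge height (leaves have height 0).
#'
#' @param dend a `plant_dendrogram` with at least two leaves.
#' @return an [ape::as.phylo] style `phylo` object.
#' @export
dendrogram_to_phylo <- function(dend) {
  m <- dend$merge
  h <- dend$height
  labs <- dend$labels
  n <- length(labs)
  if (n < 2L) stop("need at least two leaves for a phylo tree", call. = FALSE)
  # ape numbering: tips 1..n, root n+1, internals n+1..2n-1.
  # merge row i (1 = first, n-1 = root) becomes internal node n + (n - i).
  node_of <- function(j) if (j < 0L) -j else n + (n - j)
  height_of <- function(j) if (j < 0L) 0 else h[j]
  edge <- matrix(0L, nrow = 2L * (n - 1L), ncol = 2L)
  elen <- numeric(2L * (n - 1L))
  r <- 0L
  for (i in seq_len(n - 1L)) {
    for (child in m[i, ]) {
      r <- r + 1L
      edge[r, ] <- c(n + (n - i), node_of(child))
      elen[r] <- h[i] - height_of(child)
    }
  }
  phy <- list(edge = edge, edge.length = elen, tip.label = labs,
              Nnode = n - 1L)
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}
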