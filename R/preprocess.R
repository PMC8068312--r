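#' Multipartite network density
#'
#' Density of a tripartite network with edges restricted to plant-chemical
#' and chemical-target pairs: the number of realized edges over the number
#' of possible edges, `E / (Np * Nc + Nc * Nt)`. A zero denominator yields
#' density 0 with a warning.
#'
#' @param n_plants,n_chemicals,n_targets layer sizes.
#' @param n_edges total edge count.
#' @return density as a plain number.
#' @export
multipartite_density <- function(n_plants, n_chemicals, n_targets, n_edges) {
  denom <- as.numeric(n_plants) * n_chemicals + as.numeric(n_chemicals) * n_targets
  if (denom == 0) {
    if (n_edges > 0) warning("zero possible edges but positive edge count")
    else warning("empty network: density reported as 0")
    return(0)
  }
  n_edges / denom
}

#' Remove non-plant records
#'
#' Keeps records whose category is `plant` or `fungus`; minerals, animals
#' and unknown categories are dropped. Input order is preserved.
#'
#' @param records plant record table with a `category` column.
#' @return the retained rows of `records`.
#' @export
filter_non_plants <- function(records) {
  keep <- records$category %in% c("plant", "fungus")
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Deduplicate plant records
#'
#' Records identical on the key triple (scientific name, Latin name, use
#' target) are collapsed; the first occurrence in input order survives. The
#' return value carries an attribute `duplicate_map`, a named character
#' vector mapping each removed `record_id` to its surviving `record_id`, so
#' that edges of removed duplicates can be re-pointed at the survivor.
#'
#' @param records plant record table.
#' @return deduplicated records with attribute `duplicate_map`.
#' @export
deduplicate_plants <- function(records) {
  key <- paste(records$scientific_name, records$latin_name,
               records$use_target, sep = "\r")
  dup <- duplicated(key)
  out <- records[!dup, , drop = FALSE]
  rownames(out) <- NULL
  first_id <- stats::setNames(out$record_id[match(unique(key), key[!dup])],
                              unique(key))
  dup_map <- stats::setNames(as.character(first_id[key[dup]]),
                             records$record_id[dup])
  attr(out, "duplicate_map") <- dup_map
  out
}

#' Threshold chemical-target activity predictions
#'
#' Retains exactly the predictions with probability strictly greater than
#' `p_min` (default 0.9, the 10-uM activity cut-off model convention: an
#' interaction is called at probability > 0.9). A prediction at exactly
#' `p_min` is removed.
#'
#' @param predictions data frame with columns `chemical_id`, `target_id`,
#'   `probability`.
#' @param p_min probability cut-off in \[0, 1\].
#' @return data frame of retained edges (`chemical_id`, `target_id`).
#' @export
threshold_predictions <- function(predictions, p_min = 0.9) {
  if (!is.numeric(p_min) || length(p_min) != 1L || is.na(p_min) ||
      p_min < 0 || p_min > 1)
    stop("p_min must be a single number in [0, 1]", call. = FALSE)
  keep <- predictions$probability > p_min
  out <- predictions[keep, c("chemical_id", "target_id"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove isolated (degree-zero) nodes
#'
#' Drops plants, chemicals and targets not linked to any other entity. Edge
#' sets are unchanged (a degree-zero node has no edges), so a single pass
#' suffices.
#'
#' @param net a [multinet].
#' @return list with `network` (the pruned [multinet]) and `removed` (a
#'   named list of removed identifiers per layer).
#' @export
prune_isolated <- function(net) {
  stopifnot(is_multinet(net))
  deg <- node_degrees(net)
  iso <- names(deg)[deg == 0L]
  removed <- list(plants = intersect(net$plants, iso),
                  chemicals = intersect(net$chemicals, iso),
                  targets = intersect(net$targets, iso))
  pruned <- multinet(plants = setdiff(net$plants, iso),
                     chemicals = setdiff(net$chemicals, iso),
                     targets = setdiff(net$targets, iso),
                     pc_edges = net$pc_edges, ct_edges = net$ct_edges,
                     node_attrs = net$node_attrs)
  list(network = pruned, removed = removed)
}

#' Per-stage accounting of nodes, edges and density
#'
#' Summarizes one preprocessing stage: per-layer node counts, per-relation
#' edge counts, their totals, and the multipartite density
#' `E / (Np * Nc + Nc * Nt)`.
#'
#' @param net a [multinet].
#' @param stage_name label for the stage.
#' @return one-row data frame of class `stage_report` with columns
#'   `stage`, `n_plants`, `n_chemicals`, `n_targets`, `n_total_nodes`,
#'   `n_pc_edges`, `n_ct_edges`, `n_total_edges`, `density`.
#' @export
stage_report <- function(net, stage_name = "stage") {
  stopifnot(is_multinet(net))
  np <- length(net$plants); nc <- length(net$chemicals)
  nt <- length(net$targets)
  epc <- nrow(net$pc_edges); ect <- nrow(net$ct_edges)
  dens <- if (np * nc + nc * nt == 0 && epc + ect == 0)
    suppressWarnings(multipartite_density(np, nc, nt, epc + ect))
  else multipartite_density(np, nc, nt, epc + ect)
  out <- data.frame(stage = stage_name, n_plants = np, n_chemicals = nc,
                    n_targets = nt, n_total_nodes = np + nc + nt,
                    n_pc_edges = epc, n_ct_edges = ect,
                    n_total_edges = epc + ect, density = dens,
                    stringsAsFactors = FALSE)
  class(out) <- c("stage_report", class(out))
  out
}

#' Run the full preprocessing cascade
#'
#' Applies, in order: (1) raw network construction over all records and all
#' predictions; (2) removal of non-plant records and their edges;
#' (3) deduplication of plant records on the (scientific name, Latin name,
#' use target) key, with edges of removed duplicates merged into the
#' survivor; (4) restriction to predictions with probability > `p_min`,
#' dropping targets left with no retained prediction; (5) pruning of all
#' degree-zero nodes. The chemical and target universes are fixed at the
#' raw stage (entities, not edge endpoints), so layer counts only shrink
#' when a rule removes them. One stage report is produced per stage.
#'
#' @param records plant record table (see [read_tables()]).
#' @param pc_edges plant-chemical edge table (`plant_id`, `chemical_id`).
#' @param predictions prediction table (`chemical_id`, `target_id`,
#'   `probability`).
#' @param p_min probability cut-off passed to [threshold_predictions()].
#' @param verbose logical; message per-stage bookkeeping (merged duplicate
#'   edges, removed node counts).
#' @return list with `network` (the final pruned [multinet]), `reports`
#'   (single data frame of the five stage reports), and `removed` (isolated
#'   nodes dropped at the final stage).
#' @export
run_preprocess <- function(records, pc_edges, predictions, p_min = 0.9,
                           verbose = FALSE) {
  pc <- normalize_edges(pc_edges, c("plant", "chemical"))
  ct_all <- predictions[, c("chemical_id", "target_id"), drop = FALSE]
  chem_universe <- unique(c(pc$chemical, ct_all$chemical_id))
  targ_universe <- unique(ct_all$target_id)

  net1 <- build_network(records, pc, ct_all, chemicals = chem_universe,
                        targets = targ_universe)
  reports <- list(stage_report(net1, "raw"))

  rec2 <- filter_non_plants(records)
  pc2 <- pc[pc$plant %in% rec2$record_id, , drop = FALSE]
  net2 <- build_network(rec2, pc2, ct_all, chemicals = chem_universe,
                        targets = targ_universe)
  reports$plants_only <- stage_report(net2, "plants_only")

  rec3 <- deduplicate_plants(rec2)
  dup_map <- attr(rec3, "duplicate_map")
  pc3 <- pc2
  hit <- pc3$plant %in% names(dup_map)
  pc3$plant[hit] <- as.character(dup_map[pc3$plant[hit]])
  pc3 <- unique(pc3)
  if (verbose && length(dup_map) > 0L)
    message(sprintf("deduplication: %d duplicate record(s) removed; their edges merged into survivors",
                    length(dup_map)))
  net3 <- build_network(rec3, pc3, ct_all, chemicals = chem_universe,
                        targets = targ_universe)
  reports$deduplicated <- stage_report(net3, "deduplicated")

  ct4 <- threshold_predictions(predictions, p_min)
  targ4 <- intersect(targ_universe, unique(ct4$target_id))
  net4 <- build_network(rec3, pc3, ct4, chemicals = chem_universe,
                        targets = targ4)
  reports$thresholded <- stage_report(net4, "thresholded")

  pruned <- prune_isolated(net4)
  if (verbose)
    message(sprintf("pruning: removed %d plant(s), %d chemical(s), %d target(s) of degree zero",
                    length(pruned$removed$plants),
                    length(pruned$removed$chemicals),
                    length(pruned$removed$targets)))
  reports$pruned <- stage_report(pruned$network, "pruned")

  reports_df <- do.call(rbind, unname(reports))
  class(reports_df) <- c("stage_report", "data.frame")
  list(network = pruned$network, reports = reports_df,
       removed = pruned$removed)
}
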