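#' Target Potency Score of a plant cluster against a target
#'
#' `TPS(P, T) = |C_P n C_T| / |C_T|`: the fraction of the chemicals
#' connected to target `T` that are also connected to at least one plant of
#' cluster `P`. A connectivity fraction in \[0, 1\]; 1 when the cluster
#' covers all of the target's chemicals, 0 when they share none. Undefined
#' (fatal) for a target with no connected chemicals, which cannot occur
#' after pruning.
#'
#' @param cluster a `plant_cluster` (from [cut_clusters()] with the network
#'   supplied) or a character vector of plant identifiers.
#' @param target_id a target identifier in the network.
#' @param net a [multinet].
#' @return object of class `tps_result`: list with `cluster_id`,
#'   `target_id`, `tps`, `n_target_chemicals`, `n_overlap`,
#'   `overlap_chemicals`.
#' @export
tps_score <- function(cluster, target_id, net) {
  cl <- as_plant_cluster(cluster, net)
  ct <- chemicals_of_target(net, target_id)
  if (length(ct) == 0L)
    stop(sprintf("target '%s' has no connected chemicals; TPS undefined",
                 target_id), call. = FALSE)
  overlap <- intersect(cl$chemical_union, ct)
  structure(list(cluster_id = cl$cluster_id, target_id = target_id,
                 tps = length(overlap) / length(ct),
                 n_target_chemicals = length(ct),
                 n_overlap = length(overlap),
                 overlap_chemicals = sort(overlap)),
            class = "tps_result")
}

as_plant_cluster <- function(cluster, net) {
  if (inherits(cluster, "plant_cluster")) {
    if (length(cluster$chemical_union) == 0L && length(cluster$members) > 0L) {
      profs <- chemical_profiles(net)
      cluster$chemical_union <-
        sort(unique(unlist(profs[cluster$members], use.names = FALSE)))
    }
    return(cluster)
  }
  members <- as.character(cluster)
  profs <- chemical_profiles(net)
  unknown <- setdiff(members, net$plants)
  if (length(unknown) > 0L)
    stop("unknown plant(s) in cluster: ", paste(head(unknown, 5L),
                                                collapse = ", "),
         call. = FALSE)
  structure(list(cluster_id = NA_character_, members = members,
                 chemical_union = sort(unique(
                   unlist(profs[members], use.names = FALSE)))),
            class = "plant_cluster")
}

#' @export
print.tps_result <- function(x, ...) {
  cat(sprintf("TPS(%s, %s) = %.4f (%d of %d target chemicals covered)\n",
              x$cluster_id, x$target_id, x$tps, x$n_overlap,
              x$n_target_chemicals))
  invisible(x)
}

#' Rank targets for a plant cluster by TPS
#'
#' Targets whose chemical set is too small to give a reliable score
#' (`|C_T| < min_target_chemicals`, default 20) are excluded before
#' thresholding; among the survivors, those with `tps >= tps_min` are
#' returned sorted by decreasing TPS, ties broken by target identifier.
#'
#' @param cluster a `plant_cluster` or character vector of plant ids.
#' @param net a [multinet].
#' @param tps_min minimum TPS to report, in \[0, 1\].
#' @param min_target_chemicals minimum `|C_T|` for a target to be scored.
#' @return data frame with columns `cluster_id`, `target_id`, `tps`,
#'   `n_target_chemicals`, `n_overlap` (possibly zero rows).
#' @export
rank_targets_for_cluster <- function(cluster, net, tps_min,
                                     min_target_chemicals = 20L) {
  if (!is.numeric(tps_min) || tps_min < 0 || tps_min > 1)
    stop("tps_min must be in [0, 1]", call. = FALSE)
  cl <- as_plant_cluster(cluster, net)
  ct_sizes <- table(net$ct_edges$target)
  eligible <- intersect(net$targets,
                        names(ct_sizes)[ct_sizes >= min_target_chemicals])
  rows <- lapply(eligible, function(t) {
    r <- tps_score(cl, t, net)
    data.frame(cluster_id = r$cluster_id, target_id = r$target_id,
               tps = r$tps, n_target_chemicals = r$n_target_chemicals,
               n_overlap = r$n_overlap, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster_id = character(), target_id = character(),
               tps = numeric(), n_target_chemicals = integer(),
               n_overlap = integer(), stringsAsFactors = FALSE)
  out <- out[out$tps >= tps_min, , drop = FALSE]
  out <- out[order(-out$tps, out$target_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Best plant cluster for a target
#'
#' Scores every cluster against the target and returns the one with the
#' highest TPS; ties are broken toward the smaller cluster (fewest plants)
#' and then by lexicographic cluster identifier.
#'
#' @param clusters list of `plant_cluster` objects (e.g. from
#'   [cut_clusters()]).
#' @param target_id a target identifier in the network (unknown is fatal).
#' @param net a [multinet].
#' @return the winning `tps_result`, with an extra field `n_members`.
#' @export
best_cluster_for_target <- function(clusters, target_id, net) {
  if (length(clusters) == 0L) stop("need at least one cluster", call. = FALSE)
  scores <- lapply(clusters, tps_score, target_id = target_id, net = net)
  tps <- vapply(scores, `[[`, numeric(1), "tps")
  sizes <- vapply(clusters, function(cl) length(cl$members), integer(1))
  ids <- vapply(clusters, function(cl) as.character(cl$cluster_id),
                character(1))
  o <- order(-tps, sizes, ids)
  best <- scores[[o[1L]]]
  best$n_members <- sizes[o[1L]]
  best
}

#' Shared chemistry across several targets
#'
#' For two or more targets, reports each target's chemical set `C_T`, all
#' pairwise intersection sizes, the set of chemicals acting on every listed
#' target simultaneously, and -- for each such chemical -- the plants
#' containing it (the multi-target shared-chemical breakdown).
#'
#' @param target_ids character vector of at least two target identifiers.
#' @param net a [multinet].
#' @return object of class `multi_target_report`: list with `targets`,
#'   `chemical_sets`, `pairwise` (symmetric integer matrix of intersection
#'   sizes, diagonal = set sizes), `shared_chemicals`, and `shared_plants`
#'   (named list chemical -> plants connected to it).
#' @export
multi_target_report <- function(target_ids, net) {
  target_ids <- as.character(target_ids)
  if (length(target_ids) < 2L)
    stop("need at least two targets", call. = FALSE)
  sets <- lapply(target_ids, chemicals_of_target, net = net)
  names(sets) <- target_ids
  if (any(lengths(sets) == 0L))
    stop("target(s) with no connected chemicals: ",
         paste(target_ids[lengths(sets) == 0L], collapse = ", "),
         call. = FALSE)
  kk <- length(sets)
  pw <- matrix(0L, kk, kk, dimnames = list(target_ids, target_ids))
  for (i in seq_len(kk)) for (j in seq_len(kk))
    pw[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  shared <- Reduce(intersect, sets)
  shared <- sort(shared)
  shared_plants <- lapply(shared, function(ch)
    sort(unique(net$pc_edges$plant[net$pc_edges$chemical == ch])))
  names(shared_plants) <- shared
  structure(list(targets = target_ids, chemical_sets = sets,
                 pairwise = pw, shared_chemicals = shared,
                 shared_plants = shared_plants),
            class = "multi_target_report")
}

#' @export
print.multi_target_report <- function(x, ...) {
  cat(sprintf("multi_target_report over %d targets; %d chemical(s) act on all of them\n",
              length(x$targets), length(x$shared_chemicals)))
  print(x$pairwise)
  invisible(x)
}

#' Extract the plant-chemical-target subnetwork behind a TPS score
#'
#' Induces the subnetwork over the cluster's plants, the listed targets,
#' and exactly the chemicals connected to at least one cluster plant and at
#' least one listed target (the chemicals that mediate the interaction),
#' together with their incident edges within the selection. The mediating
#' chemicals are recorded in `node_attrs$overlap_chemicals` for rendering.
#' An empty induced network is returned with a warning.
#'
#' @param cluster a `plant_cluster` or character vector of plant ids.
#' @param target_ids one or more target identifiers.
#' @param net a [multinet].
#' @return a [multinet].
#' @export
extract_subnetwork <- function(cluster, target_ids, net) {
  cl <- as_plant_cluster(cluster, net)
  target_ids <- as.character(target_ids)
  unknown <- setdiff(target_ids, net$targets)
  if (length(unknown) > 0L)
    stop("unknown target(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  ct_union <- unique(net$ct_edges$chemical[net$ct_edges$target %in% target_ids])
  chems <- intersect(cl$chemical_union, ct_union)
  if (length(chems) == 0L)
    warning("cluster shares no chemical with the listed target(s); subnetwork is empty")
  keep <- c(cl$members, chems, target_ids)
  sub <- induced_network(net, keep)
  sub$node_attrs$overlap_chemicals <- chems
  sub
}

#' TPS results for every (cluster, target) combination
#'
#' Convenience wrapper running [rank_targets_for_cluster()] over a list of
#' clusters and stacking the results.
#'
#' @param clusters list of `plant_cluster` objects.
#' @param net a [multinet].
#' @param tps_min minimum TPS to report.
#' @param min_target_chemicals minimum `|C_T|` for a target to be scored.
#' @return data frame as in [rank_targets_for_cluster()].
#' @export
tps_table <- function(clusters, net, tps_min = 0,
                      min_target_chemicals = 20L) {
  rows <- lapply(clusters, rank_targets_for_cluster, net = net,
                 tps_min = tps_min,
                 min_target_chemicals = min_target_chemicals)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
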