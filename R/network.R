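#' Construct a multipartite (tripartite) plant-chemical-target network
#'
#' A `multinet` holds three disjoint node layers -- plants, chemicals and
#' protein targets -- and two unweighted, undirected edge sets: plant-chemical
#' and chemical-target. Plants and targets never connect directly, and there
#' are no within-layer edges; every edge has a chemical at exactly one end.
#' Duplicate edges are collapsed to a single edge.
#'
#' @param plants,chemicals,targets character vectors of node identifiers,
#'   unique within and across layers. Identifiers are opaque, case-sensitive
#'   strings.
#' @param pc_edges data frame (or NULL) whose first two columns are plant and
#'   chemical identifiers.
#' @param ct_edges data frame (or NULL) whose first two columns are chemical
#'   and target identifiers.
#' @param node_attrs optional named list of per-layer attribute tables, e.g.
#'   `list(plants = <record table>, chemicals = <annotation table>)`.
#' @return An object of class `multinet`.
#' @seealso [build_network()] for construction from relation tables.
#' @export
multinet <- function(plants = character(), chemicals = character(),
                     targets = character(), pc_edges = NULL, ct_edges = NULL,
                     node_attrs = list()) {
  plants <- as.character(plants)
  chemicals <- as.character(chemicals)
  targets <- as.character(targets)
  if (anyDuplicated(plants) || anyDuplicated(chemicals) || anyDuplicated(targets))
    stop("node identifiers must be unique within each layer", call. = FALSE)
  if (length(intersect(plants, chemicals)) > 0L ||
      length(intersect(plants, targets)) > 0L ||
      length(intersect(chemicals, targets)) > 0L)
    stop("plant, chemical and target layers must be pairwise disjoint",
         call. = FALSE)

  pc_edges <- normalize_edges(pc_edges, c("plant", "chemical"))
  ct_edges <- normalize_edges(ct_edges, c("chemical", "target"))

  check_endpoints(pc_edges$plant, plants, "plant",
                  list(chemical = chemicals, target = targets))
  check_endpoints(pc_edges$chemical, chemicals, "chemical",
                  list(plant = plants, target = targets))
  check_endpoints(ct_edges$chemical, chemicals, "chemical",
                  list(plant = plants, target = targets))
  check_endpoints(ct_edges$target, targets, "target",
                  list(plant = plants, chemical = chemicals))

  pc_edges <- unique(pc_edges)
  ct_edges <- unique(ct_edges)
  rownames(pc_edges) <- NULL
  rownames(ct_edges) <- NULL

  structure(list(plants = plants, chemicals = chemicals, targets = targets,
                 pc_edges = pc_edges, ct_edges = ct_edges,
                 node_attrs = node_attrs),
            class = "multinet")
}

normalize_edges <- function(edges, cols) {
  if (is.null(edges) || (is.data.frame(edges) && nrow(edges) == 0L)) {
    out <- data.frame(a = character(), b = character(),
                      stringsAsFactors = FALSE)
    names(out) <- cols
    return(out)
  }
  if (!is.data.frame(edges) || ncol(edges) < 2L)
    stop("edge input must be a data frame with at least two columns",
         call. = FALSE)
  out <- data.frame(a = as.character(edges[[1L]]),
                    b = as.character(edges[[2L]]),
                    stringsAsFactors = FALSE)
  names(out) <- cols
  out
}

check_endpoints <- function(ids, layer_ids, layer_name, other_layers) {
  if (length(ids) == 0L) return(invisible(NULL))
  bad <- unique(ids[!(ids %in% layer_ids)])
  if (length(bad) == 0L) return(invisible(NULL))
  for (other in names(other_layers)) {
    hit <- intersect(bad, other_layers[[other]])
    if (length(hit) > 0L)
      stop(sprintf("edge endpoint '%s' should be a %s but is a %s node; edges may only join plant-chemical or chemical-target",
                   hit[1L], layer_name, other), call. = FALSE)
  }
  stop(sprintf("edge endpoint(s) not registered as %s nodes: %s",
               layer_name, paste(head(bad, 5L), collapse = ", ")),
       call. = FALSE)
}

#' Test for a multinet object
#' @param x object to test.
#' @return Logical scalar.
#' @export
is_multinet <- function(x) inherits(x, "multinet")

#' @export
print.multinet <- function(x, ...) {
  cat(sprintf("multinet: %d plants, %d chemicals, %d targets; %d plant-chemical + %d chemical-target edges\n",
              length(x$plants), length(x$chemicals), length(x$targets),
              nrow(x$pc_edges), nrow(x$ct_edges)))
  invisible(x)
}

#' Build the tripartite network from relation tables
#'
#' Combines the plant-chemical and chemical-target bipartite relations into
#' one multipartite network. Node layers are derived from the inputs: plants
#' from the record table, chemicals from the union of both edge tables (or an
#' explicit universe), targets from the chemical-target edges (or an explicit
#' universe). Edge endpoints that name no known node are auto-registered as
#' bare nodes with a warning, unless `strict = TRUE`, in which case they are
#' fatal. Edges joining two nodes of one layer, or a plant to a target, are
#' always fatal.
#'
#' @param records plant record table with a `record_id` column, or a
#'   character vector of plant identifiers.
#' @param pc_edges data frame of plant-chemical edges (first two columns).
#' @param ct_edges data frame of chemical-target edges (first two columns).
#' @param chemicals,targets optional explicit node universes; useful to keep
#'   nodes that currently have no edges (e.g. fixed entity lists during
#'   preprocessing).
#' @param strict logical; if TRUE unknown edge endpoints are an error rather
#'   than auto-registered.
#' @return A [multinet] object.
#' @export
build_network <- function(records, pc_edges, ct_edges,
                          chemicals = NULL, targets = NULL, strict = FALSE) {
  if (is.data.frame(records)) {
    plants <- as.character(records$record_id)
    plant_attrs <- records
  } else {
    plants <- as.character(records)
    plant_attrs <- NULL
  }
  pc <- normalize_edges(pc_edges, c("plant", "chemical"))
  ct <- normalize_edges(ct_edges, c("chemical", "target"))

  chem_universe <- if (is.null(chemicals))
    unique(c(pc$chemical, ct$chemical)) else as.character(chemicals)
  targ_universe <- if (is.null(targets))
    unique(ct$target) else as.character(targets)

  # cross-layer misuse is fatal regardless of strict mode
  if (any(pc$chemical %in% targ_universe))
    stop("plant-chemical edge points at a target node: direct plant-target edges are not allowed",
         call. = FALSE)
  if (any(pc$chemical %in% plants) || any(pc$plant %in% chem_universe))
    stop("plant-chemical edge joins two nodes of the same layer", call. = FALSE)
  if (any(ct$chemical %in% plants))
    stop("chemical-target edge points at a plant node: direct plant-target edges are not allowed",
         call. = FALSE)
  if (any(ct$target %in% chem_universe) || any(ct$chemical %in% targ_universe))
    stop("chemical-target edge joins two nodes of the same layer", call. = FALSE)

  unknown_plants <- setdiff(pc$plant, plants)
  unknown_chems <- setdiff(c(pc$chemical, ct$chemical), chem_universe)
  unknown_targs <- setdiff(ct$target, targ_universe)
  n_unknown <- length(unknown_plants) + length(unknown_chems) +
    length(unknown_targs)
  if (n_unknown > 0L) {
    if (strict)
      stop(sprintf("%d edge endpoint(s) reference unknown nodes (strict mode): %s",
                   n_unknown,
                   paste(head(c(unknown_plants, unknown_chems, unknown_targs), 5L),
                         collapse = ", ")), call. = FALSE)
    warning(sprintf("auto-registered %d edge endpoint(s) with no matching record",
                    n_unknown), call. = FALSE)
    plants <- c(plants, unknown_plants)
    chem_universe <- c(chem_universe, unknown_chems)
    targ_universe <- c(targ_universe, unknown_targs)
  }

  attrs <- list()
  if (!is.null(plant_attrs)) attrs$plants <- plant_attrs
  multinet(plants = plants, chemicals = chem_universe,
           targets = targ_universe, pc_edges = pc, ct_edges = ct,
           node_attrs = attrs)
}

#' All node identifiers of a network, with their layer
#' @param net a [multinet].
#' @return data frame with columns `node` and `layer`.
#' @export
network_nodes <- function(net) {
  stopifnot(is_multinet(net))
  data.frame(node = c(net$plants, net$chemicals, net$targets),
             layer = rep(c("plant", "chemical", "target"),
                         c(length(net$plants), length(net$chemicals),
                           length(net$targets))),
             stringsAsFactors = FALSE)
}

#' All edges of a network as a two-column data frame
#' @param net a [multinet].
#' @return data frame with columns `from` and `to` (plant-chemical edges
#'   first, then chemical-target edges).
#' @export
network_edges <- function(net) {
  stopifnot(is_multinet(net))
  rbind(stats::setNames(net$pc_edges, c("from", "to")),
        stats::setNames(net$ct_edges, c("from", "to")))
}

#' Node degrees
#' @param net a [multinet].
#' @return named integer vector over all nodes (isolated nodes have 0).
#' @export
node_degrees <- function(net) {
  nodes <- c(net$plants, net$chemicals, net$targets)
  d <- stats::setNames(integer(length(nodes)), nodes)
  ends <- c(net$pc_edges$plant, net$pc_edges$chemical,
            net$ct_edges$chemical, net$ct_edges$target)
  if (length(ends) > 0L) {
    tab <- table(ends)
    d[names(tab)] <- as.integer(tab)
  }
  d
}

#' Number of edges in a network
#' @param net a [multinet].
#' @return integer edge count.
#' @export
n_edges <- function(net) nrow(net$pc_edges) + nrow(net$ct_edges)

#' Convert a multinet to an igraph graph
#'
#' Vertices carry a `layer` attribute (`"plant"`, `"chemical"`, `"target"`).
#' @param net a [multinet].
#' @return an undirected [igraph::igraph] graph.
#' @export
multinet_to_igraph <- function(net) {
  nodes <- network_nodes(net)
  names(nodes)[1L] <- "name"
  igraph::graph_from_data_frame(network_edges(net), directed = FALSE,
                                vertices = nodes)
}

#' Neighbor sets of every node
#' @param net a [multinet].
#' @return named list mapping each node to the character vector of its
#'   neighbors (possibly empty).
#' @keywords internal
neighbor_list <- function(net) {
  nodes <- c(net$plants, net$chemicals, net$targets)
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_along(adj)) adj[[i]] <- character()
  ek <- network_edges(net)
  if (nrow(ek) > 0L) {
    by_from <- split(ek$to, ek$from)
    by_to <- split(ek$from, ek$to)
    for (nm in names(by_from)) adj[[nm]] <- c(adj[[nm]], by_from[[nm]])
    for (nm in names(by_to)) adj[[nm]] <- c(adj[[nm]], by_to[[nm]])
    adj <- lapply(adj, unique)
  }
  adj
}

#' Induced subnetwork on a set of nodes
#' @param net a [multinet].
#' @param nodes character vector of node identifiers to keep.
#' @return a [multinet] containing the named nodes and all edges between them.
#' @export
induced_network <- function(net, nodes) {
  stopifnot(is_multinet(net))
  nodes <- as.character(nodes)
  pc <- net$pc_edges[net$pc_edges$plant %in% nodes &
                       net$pc_edges$chemical %in% nodes, , drop = FALSE]
  ct <- net$ct_edges[net$ct_edges$chemical %in% nodes &
                       net$ct_edges$target %in% nodes, , drop = FALSE]
  multinet(plants = intersect(net$plants, nodes),
           chemicals = intersect(net$chemicals, nodes),
           targets = intersect(net$targets, nodes),
           pc_edges = pc, ct_edges = ct, node_attrs = net$node_attrs)
}

#' Chemical sets attached to plants and targets
#'
#' `chemicals_of_target` returns the set of chemicals adjacent to one target
#' (C_T); `chemical_profiles` returns, for every plant, the set of chemicals
#' it contains (its binary chemical profile, stored sparsely).
#'
#' @param net a [multinet].
#' @param target_id a target identifier present in the network.
#' @return `chemicals_of_target`: character vector; `chemical_profiles`:
#'   named list of character vectors, one per plant.
#' @export
chemicals_of_target <- function(net, target_id) {
  stopifnot(is_multinet(net))
  if (!target_id %in% net$targets)
    stop(sprintf("unknown target '%s'", target_id), call. = FALSE)
  unique(net$ct_edges$chemical[net$ct_edges$target == target_id])
}

#' @rdname chemicals_of_target
#' @export
chemical_profiles <- function(net) {
  stopifnot(is_multinet(net))
  prof <- stats::setNames(vector("list", length(net$plants)), net$plants)
  for (i in seq_along(prof)) prof[[i]] <- character()
  if (nrow(net$pc_edges) > 0L) {
    sp <- split(net$pc_edges$chemical, net$pc_edges$plant)
    sp <- lapply(sp, unique)
    prof[names(sp)] <- sp
  }
  prof
}
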