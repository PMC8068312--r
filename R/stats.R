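#' Structural statistics of a multipartite network
#'
#' Computes the standard descriptive measures: layer and edge counts, the
#' multipartite density `E / (Np*Nc + Nc*Nt)`, the diameter of the largest
#' connected component, the average bipartite clustering coefficient (see
#' [bipartite_clustering()]), the degree assortativity (Pearson correlation
#' of end-degrees over edges; `NA` when undefined, e.g. zero degree
#' variance), and per-layer degree histograms.
#'
#' @param net a [multinet].
#' @return object of class `multinet_stats`: a list with fields `n_plants`,
#'   `n_chemicals`, `n_targets`, `n_pc_edges`, `n_ct_edges`, `density`,
#'   `diameter_lcc`, `avg_bipartite_clustering`, `degree_assortativity`,
#'   `degree_histograms` (named list of `degree`/`count` data frames).
#' @export
structural_stats <- function(net) {
  stopifnot(is_multinet(net))
  deg <- node_degrees(net)
  E <- n_edges(net)
  out <- list(
    n_plants = length(net$plants), n_chemicals = length(net$chemicals),
    n_targets = length(net$targets),
    n_pc_edges = nrow(net$pc_edges), n_ct_edges = nrow(net$ct_edges),
    density = if (length(deg) == 0L) 0 else
      suppressWarnings(multipartite_density(length(net$plants),
                                            length(net$chemicals),
                                            length(net$targets), E)),
    diameter_lcc = NA_integer_,
    avg_bipartite_clustering = NA_real_,
    degree_assortativity = NA_real_,
    degree_histograms = list(
      plants = degree_hist(deg[net$plants]),
      chemicals = degree_hist(deg[net$chemicals]),
      targets = degree_hist(deg[net$targets])))

  if (E > 0L) {
    g <- multinet_to_igraph(net)
    comp <- igraph::components(g)
    lcc <- igraph::induced_subgraph(
      g, which(comp$membership == which.max(comp$csize)))
    out$diameter_lcc <- as.integer(igraph::diameter(lcc, unconnected = FALSE))
    assort <- suppressWarnings(igraph::assortativity_degree(g))
    out$degree_assortativity <- if (is.nan(assort)) NA_real_ else assort
    cc <- bipartite_clustering(net)
    out$avg_bipartite_clustering <- if (length(cc)) mean(cc) else NA_real_
  }
  class(out) <- "multinet_stats"
  out
}

degree_hist <- function(d) {
  if (length(d) == 0L)
    return(data.frame(degree = integer(), count = integer()))
  tab <- table(d)
  data.frame(degree = as.integer(names(tab)), count = as.integer(tab))
}

#' @export
print.multinet_stats <- function(x, ...) {
  cat(sprintf("multinet_stats: %d/%d/%d plants/chemicals/targets, %d edges, density %.3g\n",
              x$n_plants, x$n_chemicals, x$n_targets,
              x$n_pc_edges + x$n_ct_edges, x$density))
  cat(sprintf("  diameter (LCC) %s, avg bipartite clustering %.3f, assortativity %s\n",
              x$diameter_lcc, x$avg_bipartite_clustering,
              format(x$degree_assortativity, digits = 3)))
  invisible(x)
}

#' Bipartite clustering coefficient per node
#'
#' For bipartite-structured graphs the triangle-based clustering coefficient
#' is always zero, so the pairwise coefficient is used instead: for a node
#' `u` with second-order neighbors `v` (nodes at distance two),
#' `cc(u, v) = |N(u) n N(v)| / |N(u) u N(v)|`, and `cc(u)` is the mean of
#' `cc(u, v)` over all second-order neighbors of `u`. Nodes without
#' second-order neighbors score 0.
#'
#' @param net a [multinet].
#' @return named numeric vector of per-node coefficients in \[0, 1\].
#' @export
bipartite_clustering <- function(net) {
  adj <- neighbor_list(net)
  nodes <- names(adj)
  cc <- stats::setNames(numeric(length(nodes)), nodes)
  for (u in nodes) {
    nu <- adj[[u]]
    if (length(nu) == 0L) next
    second <- setdiff(unique(unlist(adj[nu], use.names = FALSE)), u)
    if (length(second) == 0L) next
    vals <- vapply(second, function(v) {
      nv <- adj[[v]]
      length(intersect(nu, nv)) / length(union(nu, nv))
    }, numeric(1))
    cc[u] <- mean(vals)
  }
  cc
}

#' Per-subnetwork structural statistics
#'
#' Splits the network along a partition and computes [structural_stats()]
#' for each induced subnetwork.
#'
#' @param net a [multinet].
#' @param partition a `multinet_partition` covering the network.
#' @return named list of `multinet_stats`, one per cluster index.
#' @export
subnetwork_stats <- function(net, partition) {
  a <- partition_assignment(partition, net)
  ks <- sort(unique(a))
  out <- lapply(ks, function(i) structural_stats(
    induced_network(net, names(a)[a == i])))
  names(out) <- paste0("subnetwork_", ks)
  out
}
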