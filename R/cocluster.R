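#' Spectral co-clustering of the multipartite network
#'
#' Because plants and targets both connect only to chemicals, the tripartite
#' network is encoded as one bipartite incidence matrix with rows = plants
#' and targets and columns = chemicals, and Dhillon-style spectral
#' co-clustering is applied: the incidence is degree-normalized
#' (`D_r^{-1/2} A D_c^{-1/2}`), a truncated SVD taken, rows and columns
#' jointly embedded through singular vectors 2..k (rescaled by
#' `D^{-1/2}`), and k-means run on the joint embedding with multiple
#' seeded restarts. Row and column clusters sharing an index form one
#' subnetwork, so every node is assigned exactly once.
#'
#' Degree-zero nodes carry no spectral information; they are assigned to
#' cluster 1 with a warning (the pipeline prunes them beforehand).
#'
#' @param net a [multinet].
#' @param k number of clusters (k = 1 returns the trivial partition).
#' @param seed integer seed controlling the k-means restarts.
#' @param nstart number of k-means restarts.
#' @return object of class `multinet_partition`: list with `k`,
#'   `assignment` (named integer vector over all nodes), `normalized_cut`
#'   and `modularity`.
#' @export
spectral_cocluster <- function(net, k, seed = 1L, nstart = 10L) {
  stopifnot(is_multinet(net))
  if (!is.numeric(k) || length(k) != 1L || k < 1L || k != round(k))
    stop("k must be a positive integer", call. = FALSE)
  k <- as.integer(k)
  nodes <- c(net$plants, net$chemicals, net$targets)
  if (length(nodes) == 0L) stop("network is empty", call. = FALSE)

  if (k == 1L) {
    a <- stats::setNames(rep(1L, length(nodes)), nodes)
    return(new_partition(net, a))
  }

  row_ids <- c(net$plants, net$targets)
  col_ids <- net$chemicals
  # incidence rows are plants and targets, columns are chemicals
  ri <- match(c(net$pc_edges$plant, net$ct_edges$target), row_ids)
  ci <- match(c(net$pc_edges$chemical, net$ct_edges$chemical), col_ids)
  A <- Matrix::sparseMatrix(i = ri, j = ci, x = 1,
                            dims = c(length(row_ids), length(col_ids)))
  A@x[] <- 1  # duplicate collapse is upstream, but be safe
  rd <- Matrix::rowSums(A)
  cd <- Matrix::colSums(A)
  live_r <- which(rd > 0)
  live_c <- which(cd > 0)
  if (k > min(length(live_r), length(live_c)))
    stop(sprintf("k = %d exceeds the number of nonempty incidence rows (%d) or columns (%d)",
                 k, length(live_r), length(live_c)), call. = FALSE)
  if (length(live_r) < length(rd) || length(live_c) < length(cd))
    warning("degree-zero nodes assigned to cluster 1; prune the network first for meaningful clusters")

  An <- as.matrix(A[live_r, live_c, drop = FALSE])
  sr <- 1 / sqrt(rd[live_r]); sc <- 1 / sqrt(cd[live_c])
  An <- An * sr
  An <- sweep(An, 2L, sc, `*`)
  nsv <- min(k, length(live_r), length(live_c))
  sv <- svd(An, nu = nsv, nv = nsv)
  take <- 2:nsv
  U <- sv$u[, take, drop = FALSE] * sr
  V <- sv$v[, take, drop = FALSE] * sc
  Z <- rbind(U, V)

  km <- with_seed(seed, stats::kmeans(Z, centers = k, nstart = nstart,
                                      iter.max = 100L))
  lab <- km$cluster

  a <- stats::setNames(rep(1L, length(nodes)), nodes)
  a[row_ids[live_r]] <- lab[seq_along(live_r)]
  a[col_ids[live_c]] <- lab[length(live_r) + seq_along(live_c)]
  new_partition(net, a)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

new_partition <- function(net, assignment) {
  k <- max(assignment)
  p <- structure(list(k = as.integer(k), assignment = assignment,
                      normalized_cut = NA_real_, modularity = NA_real_),
                 class = "multinet_partition")
  p$normalized_cut <- normalized_cut(net, p)
  p$modularity <- modularity_score(net, p)
  p
}

#' @export
print.multinet_partition <- function(x, ...) {
  cat(sprintf("multinet_partition: k = %d over %d nodes; normalized cut %.4f, modularity %.4f\n",
              x$k, length(x$assignment), x$normalized_cut, x$modularity))
  invisible(x)
}

#' Partition as a node table
#' @param partition a `multinet_partition`.
#' @param net optionally the network, to attach a `layer` column.
#' @return data frame with columns `node`, (`layer`,) `cluster`.
#' @export
partition_table <- function(partition, net = NULL) {
  out <- data.frame(node = names(partition$assignment),
                    cluster = as.integer(partition$assignment),
                    stringsAsFactors = FALSE)
  if (!is.null(net)) {
    nodes <- network_nodes(net)
    out$layer <- nodes$layer[match(out$node, nodes$node)]
    out <- out[, c("node", "layer", "cluster")]
  }
  out
}

partition_assignment <- function(partition, net) {
  a <- if (inherits(partition, "multinet_partition"))
    partition$assignment else partition
  nodes <- c(net$plants, net$chemicals, net$targets)
  if (!all(nodes %in% names(a)))
    stop("partition does not cover every network node", call. = FALSE)
  a[nodes]
}

#' Normalized cut of a partition
#'
#' The partition-quality criterion
#' `(1/k) * sum_i cut(V_i, complement) / vol(V_i)`, where the cut is the
#' number of edges leaving cluster `V_i` and the volume is the sum of
#' degrees of its nodes. Smaller values indicate better-separated clusters;
#' a partition along connected components scores 0. Clusters with zero
#' volume contribute 0 with a warning.
#'
#' @param net a [multinet].
#' @param partition a `multinet_partition` or a named cluster vector
#'   covering all nodes.
#' @param k number of clusters; defaults to the partition's `k` (or the
#'   maximum label).
#' @return the normalized cut value (>= 0).
#' @export
normalized_cut <- function(net, partition, k = NULL) {
  a <- partition_assignment(partition, net)
  if (is.null(k))
    k <- if (inherits(partition, "multinet_partition")) partition$k
  else max(a)
  ek <- network_edges(net)
  deg <- node_degrees(net)
  terms <- numeric(k)
  for (i in seq_len(k)) {
    vol <- sum(deg[a == i])
    if (vol == 0) {
      warning(sprintf("cluster %d has zero volume; contributes 0 to the normalized cut", i))
      next
    }
    ca <- a[ek$from] == i
    cb <- a[ek$to] == i
    cut_i <- sum(xor(ca, cb))
    terms[i] <- cut_i / vol
  }
  sum(terms) / k
}

#' Modularity of a partition
#'
#' Newman modularity of the (unweighted, undirected) multipartite graph:
#' `(1/2E) * sum_i sum_{m,n in V_i} (w_mn - d_m d_n / 2E)`, the double sum
#' running over ordered node pairs including the diagonal. Under this
#' convention the one-cluster partition has modularity exactly 0, and two
#' disconnected equal-volume components split into their components score
#' `1 - 2 (1/2)^2 = 0.5`.
#'
#' @inheritParams normalized_cut
#' @return modularity in \[-1, 1\].
#' @export
modularity_score <- function(net, partition, k = NULL) {
  a <- partition_assignment(partition, net)
  if (is.null(k))
    k <- if (inherits(partition, "multinet_partition")) partition$k
  else max(a)
  E <- n_edges(net)
  if (E == 0L) stop("modularity is undefined on a graph with no edges",
                    call. = FALSE)
  ek <- network_edges(net)
  deg <- node_degrees(net)
  q <- 0
  for (i in seq_len(k)) {
    within <- sum(a[ek$from] == i & a[ek$to] == i)
    vol <- sum(deg[a == i])
    q <- q + (2 * within) / (2 * E) - (vol / (2 * E))^2
  }
  q
}

#' Choose the number of clusters by maximizing modularity
#'
#' Runs [spectral_cocluster()] for each candidate `k` and evaluates the
#' modularity of the resulting partition; the optimal `k` attains the
#' maximum modularity, ties broken toward the smallest `k` (parsimony).
#'
#' @param net a [multinet].
#' @param k_range integer vector of candidate cluster counts.
#' @param seed seed forwarded to every co-clustering run.
#' @param nstart k-means restarts per run.
#' @return object of class `modularity_curve`: list with `entries` (data
#'   frame of `k`, `modularity`), `k_best`, and `best_partition`.
#' @export
select_k <- function(net, k_range = 2:20, seed = 1L, nstart = 10L) {
  if (length(k_range) == 0L) stop("k_range must be nonempty", call. = FALSE)
  k_range <- sort(unique(as.integer(k_range)))
  mods <- numeric(length(k_range))
  parts <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    p <- spectral_cocluster(net, k_range[i], seed = seed, nstart = nstart)
    parts[[i]] <- p
    mods[i] <- p$modularity
  }
  best <- pick_k_best(k_range, mods)
  structure(list(entries = data.frame(k = k_range, modularity = mods),
                 k_best = best,
                 best_partition = parts[[match(best, k_range)]]),
            class = "modularity_curve")
}

# argmax of modularity over k; ties go to the smallest k
pick_k_best <- function(ks, mods) {
  stopifnot(length(ks) == length(mods), length(ks) > 0L)
  o <- order(ks)
  ks <- ks[o]; mods <- mods[o]
  ks[which.max(mods)]
}

#' @export
print.modularity_curve <- function(x, ...) {
  cat(sprintf("modularity_curve over k in [%d, %d]; k_best = %d (modularity %.4f)\n",
              min(x$entries$k), max(x$entries$k), x$k_best,
              max(x$entries$modularity)))
  invisible(x)
}
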