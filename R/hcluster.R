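#' Bray-Curtis distance between binary chemical profiles
#'
#' For two plants with binary chemical indicator vectors the Bray-Curtis
#' distance reduces to `|symmetric difference| / (deg u + deg v)`, i.e. one
#' minus the Dice similarity `2|A n B| / (|A| + |B|)`. It lies in \[0, 1\]
#' (0 for identical profiles, 1 for disjoint ones) and is scale-free:
#' chemicals connected to neither plant do not enter, so padding the
#' chemical universe never changes a distance.
#'
#' @param u,v character vectors: the sets of chemicals connected to each
#'   plant (sparse binary profiles).
#' @return distance in \[0, 1\].
#' @export
bray_curtis <- function(u, v) {
  u <- unique(as.character(u)); v <- unique(as.character(v))
  denom <- length(u) + length(v)
  if (denom == 0L)
    stop("Bray-Curtis distance is undefined for two empty profiles (0/0)",
         call. = FALSE)
  n_common <- length(intersect(u, v))
  (denom - 2 * n_common) / denom
}

#' Plant-by-plant Bray-Curtis distance matrix
#'
#' Pairwise Bray-Curtis distances over the binary chemical profiles of all
#' plants in the network. Preprocessing guarantees every plant has at least
#' one chemical, so the 0/0 case cannot arise in the pipeline.
#'
#' @param net a [multinet].
#' @return symmetric numeric matrix with zero diagonal, dimnames = plant
#'   identifiers, entries in \[0, 1\].
#' @export
distance_matrix <- function(net) {
  stopifnot(is_multinet(net))
  plants <- net$plants
  n <- length(plants)
  B <- Matrix::sparseMatrix(
    i = match(net$pc_edges$plant, plants),
    j = match(net$pc_edges$chemical, net$chemicals),
    x = 1, dims = c(n, length(net$chemicals)))
  B@x[] <- 1
  deg <- Matrix::rowSums(B)
  if (any(deg == 0))
    warning("plant(s) with empty chemical profile; distances to them are 1 (or undefined between two empty profiles)")
  inter <- as.matrix(Matrix::tcrossprod(B))
  denom <- outer(deg, deg, `+`)
  D <- 1 - 2 * inter / denom
  D[denom == 0] <- NaN
  diag(D) <- 0
  dimnames(D) <- list(plants, plants)
  D
}

#' Complete-linkage hierarchical clustering of plants
#'
#' Agglomerative clustering where the distance between two clusters is the
#' distance between their two farthest members. With the Bray-Curtis metric
#' every merge height lies in \[0, 1\] and heights are non-decreasing along
#' every root path, so cutting strictly below 1 guarantees that every pair
#' of plants in a cluster shares at least one chemical (d < 1 implies a
#' common chemical). Ties in the minimum inter-cluster distance are broken
#' deterministically toward the lexicographically smallest pair of cluster
#' representatives (a cluster's representative is its smallest member
#' identifier), so trees are bitwise reproducible.
#'
#' @param D symmetric distance matrix with dimnames (e.g. from
#'   [distance_matrix()]).
#' @return object of class `plant_dendrogram` (also a valid
#'   [stats::hclust] object) with `merge`, `height`, `labels`, `order`.
#' @export
complete_linkage_tree <- function(D) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  labs <- rownames(D)
  if (is.null(labs)) labs <- paste0("p", seq_len(nrow(D)))
  n <- nrow(D)
  if (n == 1L) {
    out <- list(merge = matrix(integer(), 0L, 2L), height = numeric(),
                labels = labs, order = 1L,
                method = "complete", dist.method = "bray-curtis")
    class(out) <- c("plant_dendrogram", "hclust")
    return(out)
  }

  Dc <- D
  diag(Dc) <- Inf
  active <- seq_len(n)                 # indices into Dc rows still live
  cl_id <- -seq_len(n)                 # hclust merge coding
  reps <- labs                         # smallest member label per cluster
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    sub <- Dc[active, active, drop = FALSE]
    mn <- min(sub)
    hits <- which(sub == mn, arr.ind = TRUE)
    hits <- hits[hits[, 1L] < hits[, 2L], , drop = FALSE]
    # deterministic tie-break: lexicographically smallest representative pair
    keys <- apply(hits, 1L, function(rw) {
      pr <- sort(c(reps[active[rw[1L]]], reps[active[rw[2L]]]))
      paste(pr, collapse = "\r")
    })
    pick <- hits[order(keys)[1L], ]
    ia <- active[pick[1L]]; ib <- active[pick[2L]]

    pair <- sort(c(cl_id[ia], cl_id[ib]))
    merge[step, ] <- pair
    height[step] <- mn

    # complete linkage: new cluster distance is the max of the two rows
    newd <- pmax(Dc[ia, ], Dc[ib, ])
    Dc[ia, ] <- newd
    Dc[, ia] <- newd
    Dc[ia, ia] <- Inf
    cl_id[ia] <- step
    reps[ia] <- min(reps[ia], reps[ib])
    active <- setdiff(active, ib)
  }

  out <- list(merge = merge, height = height, labels = labs,
              order = dendrogram_order(merge, n),
              method = "complete", dist.method = "bray-curtis")
  class(out) <- c("plant_dendrogram", "hclust")
  out
}

dendrogram_order <- function(merge, n) {
  walk <- function(j) {
    if (j < 0L) return(-j)
    c(walk(merge[j, 1L]), walk(merge[j, 2L]))
  }
  if (n == 1L) return(1L)
  as.integer(walk(nrow(merge)))
}

#' Cut a plant dendrogram into clusters
#'
#' Clusters are the maximal subtrees all of whose merge heights are strictly
#' below `h_max`. With Bray-Curtis distances and complete linkage, any
#' `h_max <= 1` guarantees that every pair of plants within a cluster
#' shares at least one chemical. The default `h_max = 1 - 1e-9` is the
#' largest cut preserving that guarantee. At `h_max = 0` only plants with
#' exactly identical profiles (merged at height zero) stay together.
#'
#' @param dend a `plant_dendrogram`.
#' @param h_max cut height (merges at height `>= h_max` are not applied).
#' @param net optional [multinet]; when given, each cluster carries its
#'   chemical union `C_P` (chemicals connected to at least one member).
#' @return list of `plant_cluster` objects (fields `cluster_id`, `members`,
#'   `chemical_union`), ordered by decreasing size then member order.
#' @export
cut_clusters <- function(dend, h_max = 1 - 1e-9, net = NULL) {
  stopifnot(inherits(dend, "plant_dendrogram"))
  if (h_max < 0) stop("h_max must be >= 0", call. = FALSE)
  labs <- dend$labels
  n <- length(labs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  cluster_of_merge <- integer(max(0L, n - 1L))
  for (j in seq_along(dend$height)) {
    l <- dend$merge[j, 1L]; r <- dend$merge[j, 2L]
    li <- if (l < 0L) -l else cluster_of_merge[l]
    ri <- if (r < 0L) -r else cluster_of_merge[r]
    li <- find(li); ri <- find(ri)
    if (dend$height[j] < h_max) parent[ri] <- li
    cluster_of_merge[j] <- li
  }
  root <- vapply(seq_len(n), find, integer(1))
  groups <- split(labs, root)
  groups <- groups[order(-lengths(groups),
                         vapply(groups, function(g) g[1L], character(1)))]
  profs <- if (!is.null(net)) chemical_profiles(net) else NULL
  out <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    members <- groups[[i]]
    cu <- if (is.null(profs)) character() else
      sort(unique(unlist(profs[members], use.names = FALSE)))
    out[[i]] <- structure(list(cluster_id = paste0("C", i),
                               members = members, chemical_union = cu),
                          class = "plant_cluster")
  }
  names(out) <- vapply(out, `[[`, character(1), "cluster_id")
  out
}

#' @export
print.plant_cluster <- function(x, ...) {
  cat(sprintf("plant_cluster %s: %d plant(s), %d chemical(s) in C_P\n",
              x$cluster_id, length(x$members), length(x$chemical_union)))
  invisible(x)
}

#' Tally chemical classification labels within a plant cluster
#'
#' For each classification level, counts the distinct labels represented
#' among the cluster's chemical union `C_P` and the number of chemicals per
#' label. Chemicals without an annotation are counted under
#' `"unclassified"`.
#'
#' @param cluster a `plant_cluster` (with a populated `chemical_union`).
#' @param annotations annotation table keyed by `chemical_id` (see
#'   [read_tables()]); may be NULL or empty.
#' @param levels classification levels to tally.
#' @return named list, one element per level: list with `n_distinct` (count
#'   of distinct labels) and `counts` (data frame `label`, `n_chemicals`,
#'   sorted by decreasing count).
#' @export
tally_classes <- function(cluster, annotations,
                          levels = c("subclass", "direct_parent")) {
  stopifnot(inherits(cluster, "plant_cluster"))
  chems <- cluster$chemical_union
  out <- vector("list", length(levels))
  names(out) <- levels
  for (lv in levels) {
    lab <- rep("unclassified", length(chems))
    if (!is.null(annotations) && nrow(annotations) > 0L &&
        lv %in% names(annotations)) {
      idx <- match(chems, annotations$chemical_id)
      got <- !is.na(idx) & !is.na(annotations[[lv]][idx]) &
        nzchar(annotations[[lv]][idx])
      lab[got] <- annotations[[lv]][idx[got]]
    }
    tab <- sort(table(lab), decreasing = TRUE)
    out[[lv]] <- list(
      n_distinct = length(setdiff(names(tab), "unclassified")),
      counts = data.frame(label = names(tab), n_chemicals = as.integer(tab),
                          stringsAsFactors = FALSE))
  }
  out
}
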