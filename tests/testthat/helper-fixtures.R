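# Shared fixtures and independent brute-force oracles.

# three plants with profiles {c1,c2}, {c2,c3}, {c4}; one target on c1
toy_net3 <- function(with_target = TRUE) {
  pc <- data.frame(plant = c("p1", "p1", "p2", "p2", "p3"),
                   chemical = c("c1", "c2", "c2", "c3", "c4"))
  ct <- if (with_target) data.frame(chemical = "c1", target = "t1") else NULL
  multinet(plants = c("p1", "p2", "p3"),
           chemicals = c("c1", "c2", "c3", "c4"),
           targets = if (with_target) "t1" else character(),
           pc_edges = pc, ct_edges = ct)
}

# 4-node path a - b - c - d (a, c plants; b, d chemicals)
path4_net <- function() {
  multinet(plants = c("a", "c"), chemicals = c("b", "d"),
           pc_edges = data.frame(plant = c("a", "c", "c"),
                                 chemical = c("b", "b", "d")))
}

# two disconnected single-edge components
two_component_net <- function() {
  multinet(plants = c("q1", "q2"), chemicals = c("x1", "x2"),
           pc_edges = data.frame(plant = c("q1", "q2"),
                                 chemical = c("x1", "x2")))
}

# random small tripartite network; every plant/target gets >= 1 edge
random_multinet <- function(seed, n_plants = 5, n_chemicals = 6,
                            n_targets = 3, p_pc = 0.4, p_ct = 0.4) {
  set.seed(seed)
  plants <- paste0("p", seq_len(n_plants))
  chems <- paste0("c", seq_len(n_chemicals))
  targs <- paste0("t", seq_len(n_targets))
  pc <- expand.grid(plant = plants, chemical = chems,
                    stringsAsFactors = FALSE)
  pc <- pc[runif(nrow(pc)) < p_pc, ]
  # guarantee degree >= 1 per plant
  missing_p <- setdiff(plants, pc$plant)
  if (length(missing_p))
    pc <- rbind(pc, data.frame(plant = missing_p,
                               chemical = sample(chems, length(missing_p),
                                                 replace = TRUE)))
  ct <- expand.grid(chemical = chems, target = targs,
                    stringsAsFactors = FALSE)
  ct <- ct[runif(nrow(ct)) < p_ct, ]
  missing_t <- setdiff(targs, ct$target)
  if (length(missing_t))
    ct <- rbind(ct, data.frame(chemical = sample(chems, length(missing_t),
                                                 replace = TRUE),
                               target = missing_t))
  multinet(plants = plants, chemicals = chems, targets = targs,
           pc_edges = pc, ct_edges = ct)
}

adjacency_matrix <- function(net) {
  nodes <- c(net$plants, net$chemicals, net$targets)
  W <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  ek <- network_edges(net)
  for (r in seq_len(nrow(ek))) {
    W[ek$from[r], ek$to[r]] <- 1
    W[ek$to[r], ek$from[r]] <- 1
  }
  W
}

# Eq-level oracle: ordered-pair double sum including the diagonal
brute_modularity <- function(net, assignment) {
  W <- adjacency_matrix(net)
  nodes <- rownames(W)
  a <- assignment[nodes]
  d <- rowSums(W)
  E2 <- sum(W)                      # 2E
  q <- 0
  for (m in nodes) for (n in nodes) {
    if (a[m] == a[n]) q <- q + W[m, n] - d[m] * d[n] / E2
  }
  unname(q / E2)
}

# Eq-level oracle: (1/k) sum_i cut(V_i, complement)/vol(V_i)
brute_normalized_cut <- function(net, assignment, k = max(assignment)) {
  W <- adjacency_matrix(net)
  nodes <- rownames(W)
  a <- assignment[nodes]
  d <- rowSums(W)
  total <- 0
  for (i in seq_len(k)) {
    vi <- nodes[a == i]
    vol <- sum(d[vi])
    if (vol == 0) next
    cut <- sum(W[vi, setdiff(nodes, vi), drop = FALSE])
    total <- total + cut / vol
  }
  unname(total / k)
}

random_assignment <- function(net, k, seed) {
  set.seed(seed)
  nodes <- c(net$plants, net$chemicals, net$targets)
  # ensure every label 1..k occurs so vol-0 warnings stay out of oracle tests
  a <- c(seq_len(k), sample(seq_len(k), length(nodes) - k, replace = TRUE))
  stats::setNames(sample(a), nodes)
}

write_input_fixture <- function(dir, plants, pc, preds, annotations = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(plants, file.path(dir, "plants.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(pc, file.path(dir, "plant_chemical.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(preds, file.path(dir, "predictions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(annotations))
    write.table(annotations, file.path(dir, "annotations.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  dir
}

plant_records <- function(ids, category = "plant", sci = NULL,
                          use_target = "root") {
  if (is.null(sci)) sci <- paste("Species", ids)
  data.frame(record_id = ids, scientific_name = sci,
             latin_name = paste0(sci, " L."),
             use_target = rep_len(use_target, length(ids)),
             category = rep_len(category, length(ids)),
             stringsAsFactors = FALSE)
}
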