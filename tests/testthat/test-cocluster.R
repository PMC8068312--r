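test_that("normalized cut matches hand-evaluated cases", {
  # 4-node path split in the middle: (1/2)(1/3 + 1/3) = 1/3
  net <- path4_net()
  a <- c(a = 1L, b = 1L, c = 2L, d = 2L)
  expect_equal(normalized_cut(net, a, k = 2), 1 / 3)

  # partition along connected components: no cross edges, cut 0
  net2 <- two_component_net()
  a2 <- c(q1 = 1L, x1 = 1L, q2 = 2L, x2 = 2L)
  expect_equal(normalized_cut(net2, a2, k = 2), 0)

  # k = 1: complement empty
  a1 <- stats::setNames(rep(1L, 4), c("a", "b", "c", "d"))
  expect_equal(normalized_cut(net, a1, k = 1), 0)
})

test_that("modularity has its closed-form values and matches the pair-sum oracle", {
  # one-cluster partition scores exactly 0 on every graph
  for (s in 1:5) {
    net <- random_multinet(s)
    nodes <- c(net$plants, net$chemicals, net$targets)
    a <- stats::setNames(rep(1L, length(nodes)), nodes)
    expect_equal(modularity_score(net, a, k = 1), 0, tolerance = 1e-14)
  }

  # two disconnected equal-volume components as clusters: 1 - 2*(1/2)^2
  net2 <- two_component_net()
  a2 <- c(q1 = 1L, x1 = 1L, q2 = 2L, x2 = 2L)
  expect_equal(modularity_score(net2, a2, k = 2), 0.5)

  # exhaustive double-loop oracle on random small graphs and partitions
  for (s in 1:20) {
    net <- random_multinet(s, n_plants = 3, n_chemicals = 4, n_targets = 2)
    k <- sample(2:3, 1)
    a <- random_assignment(net, k, seed = s + 100)
    expect_equal(modularity_score(net, a, k = k), brute_modularity(net, a),
                 tolerance = 1e-12)
    expect_equal(suppressWarnings(normalized_cut(net, a, k = k)),
                 brute_normalized_cut(net, a, k),
                 tolerance = 1e-12)
  }

  expect_error(modularity_score(multinet(plants = "p", chemicals = "c"),
                                c(p = 1L, c = 1L), k = 1),
               "no edges")
})

test_that("in-package modularity agrees with igraph on co-clustering partitions", {
  for (s in 1:5) {
    net <- random_multinet(s, n_plants = 6, n_chemicals = 8, n_targets = 3)
    # random networks may hold isolated chemicals; their fallback assignment
    # is warned about but does not affect the modularity identity
    p <- suppressWarnings(spectral_cocluster(net, 3, seed = s))
    g <- multinet_to_igraph(net)
    memb <- p$assignment[igraph::V(g)$name]
    expect_equal(p$modularity, igraph::modularity(g, memb),
                 tolerance = 1e-12)
  }
})

test_that("spectral co-clustering recovers connected components exactly", {
  # {p1, p2, c1, c2} and {p3, c3} disconnected bipartite blocks, k = 2
  net <- multinet(plants = c("p1", "p2", "p3"),
                  chemicals = c("c1", "c2", "c3"),
                  pc_edges = data.frame(
                    plant = c("p1", "p2", "p2", "p3"),
                    chemical = c("c1", "c1", "c2", "c3")))
  p <- spectral_cocluster(net, 2, seed = 1)
  a <- p$assignment
  expect_equal(length(unique(a[c("p1", "p2", "c1", "c2")])), 1L)
  expect_equal(length(unique(a[c("p3", "c3")])), 1L)
  expect_false(a[["p1"]] == a[["p3"]])
  expect_equal(p$normalized_cut, 0)

  # k = 1 is the trivial partition with zero cut
  p1 <- spectral_cocluster(net, 1)
  expect_true(all(p1$assignment == 1L))
  expect_equal(p1$normalized_cut, 0)

  # k beyond the incidence dimensions is fatal
  expect_error(spectral_cocluster(net, 10), "exceeds")
})

test_that("planted blocks are recovered with high adjusted Rand index", {
  make_planted <- function(seed, n_blocks = 3, plants_per = 8, chems_per = 10,
                           p_in = 0.5, p_out = 0.02) {
    set.seed(seed)
    plants <- sprintf("p%02d", seq_len(n_blocks * plants_per))
    chems <- sprintf("c%02d", seq_len(n_blocks * chems_per))
    pb <- rep(seq_len(n_blocks), each = plants_per)
    cb <- rep(seq_len(n_blocks), each = chems_per)
    grid <- expand.grid(pi = seq_along(plants), ci = seq_along(chems))
    pr <- ifelse(pb[grid$pi] == cb[grid$ci], p_in, p_out)
    sel <- runif(nrow(grid)) < pr
    pc <- data.frame(plant = plants[grid$pi[sel]],
                     chemical = chems[grid$ci[sel]])
    # anchor edge so no node is isolated
    pc <- unique(rbind(pc, data.frame(
      plant = plants, chemical = chems[(pb - 1) * chems_per + 1])))
    list(net = multinet(plants = plants, chemicals = chems, pc_edges = pc),
         labels = stats::setNames(c(pb, cb), c(plants, chems)))
  }
  aris <- vapply(1:5, function(s) {
    pl <- make_planted(s)
    p <- spectral_cocluster(pl$net, 3, seed = s)
    mclust::adjustedRandIndex(p$assignment[names(pl$labels)], pl$labels)
  }, numeric(1))
  expect_gte(stats::median(aris), 0.9)
})

test_that("modularity-based selection picks the argmax with ties to smallest k", {
  expect_equal(phytonet:::pick_k_best(c(2, 3, 4), c(0.1, 0.3, 0.2)), 3)
  expect_equal(phytonet:::pick_k_best(c(2, 3, 4), c(0.2, 0.2, 0.2)), 2)
  expect_equal(phytonet:::pick_k_best(c(4, 2, 3), c(0.5, 0.1, 0.5)), 3)

  expect_error(select_k(two_component_net(), integer()), "nonempty")
  curve <- select_k(two_component_net(), 2:2, seed = 1)
  expect_equal(curve$k_best, 2L)
  expect_equal(curve$best_partition$modularity, 0.5)
})

test_that("structural statistics match hand-computed toy values", {
  # star K_{1,4}: one chemical hub, four plant leaves
  star <- multinet(plants = paste0("p", 1:4), chemicals = "hub",
                   pc_edges = data.frame(plant = paste0("p", 1:4),
                                         chemical = "hub"))
  st <- structural_stats(star)
  expect_equal(st$diameter_lcc, 2L)
  cc <- bipartite_clustering(star)
  expect_equal(unname(cc[paste0("p", 1:4)]), rep(1, 4))
  expect_equal(unname(cc["hub"]), 0)

  # 4-node path has diameter 3
  expect_equal(structural_stats(path4_net())$diameter_lcc, 3L)

  # single edge: zero degree variance, assortativity undefined -> NA
  one <- multinet(plants = "p", chemicals = "c",
                  pc_edges = data.frame(plant = "p", chemical = "c"))
  expect_true(is.na(structural_stats(one)$degree_assortativity))

  # degree histograms sum to layer sizes
  net <- random_multinet(4)
  st2 <- structural_stats(net)
  expect_equal(sum(st2$degree_histograms$plants$count), length(net$plants))
  expect_equal(sum(st2$degree_histograms$chemicals$count),
               length(net$chemicals))
  expect_equal(sum(st2$degree_histograms$targets$count), length(net$targets))
  expect_equal(st2$density, multipartite_density(
    st2$n_plants, st2$n_chemicals, st2$n_targets,
    st2$n_pc_edges + st2$n_ct_edges))
})
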