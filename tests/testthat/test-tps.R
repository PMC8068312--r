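# a small network with controllable C_P / C_T overlap
tps_toy <- function() {
  chems <- paste0("c", 1:10)
  pc <- data.frame(plant = c(rep("p1", 3), rep("p2", 3)),
                   chemical = c("c1", "c2", "c3", "c3", "c4", "c5"))
  ct <- rbind(data.frame(chemical = c("c1", "c2", "c3"), target = "tA"),
              data.frame(chemical = c("c6", "c7"), target = "tB"),
              data.frame(chemical = c("c3", "c4", "c5", "c6"), target = "tC"))
  multinet(plants = c("p1", "p2"), chemicals = chems,
           targets = c("tA", "tB", "tC"), pc_edges = pc, ct_edges = ct)
}

test_that("TPS is the covered fraction of the target's chemical set", {
  net <- tps_toy()
  # C_T(tA) = {c1,c2,c3} subset of C_P({p1,p2}) -> TPS 1
  r <- tps_score(c("p1", "p2"), "tA", net)
  expect_equal(r$tps, 1)
  expect_equal(r$n_overlap, 3L)
  # disjoint: C_T(tB) = {c6,c7}, plants never contain them
  expect_equal(tps_score(c("p1", "p2"), "tB", net)$tps, 0)
  # partial: C_T(tC) = {c3,c4,c5,c6}; p1 covers only c3
  r2 <- tps_score("p1", "tC", net)
  expect_equal(r2$tps, 0.25)
  expect_equal(r2$overlap_chemicals, "c3")

  # |C_T| = 20 with 5 covered -> 0.25, on a constructed network
  big <- multinet(plants = "P", chemicals = paste0("k", 1:20), targets = "T",
                  pc_edges = data.frame(plant = "P",
                                        chemical = paste0("k", 1:5)),
                  ct_edges = data.frame(chemical = paste0("k", 1:20),
                                        target = "T"))
  expect_equal(tps_score("P", "T", big)$tps, 0.25)
  expect_error(tps_score("P", "nope", big), "unknown target")
})

test_that("TPS is bounded, monotone under cluster growth, and matches a set oracle", {
  for (s in 1:10) {
    net <- random_multinet(s, n_plants = 8, n_chemicals = 10, n_targets = 4)
    profs <- chemical_profiles(net)
    set.seed(s)
    members <- sample(net$plants, 4)
    grown <- union(members, sample(net$plants, 2))
    for (t in net$targets) {
      ct <- unique(net$ct_edges$chemical[net$ct_edges$target == t])
      r <- tps_score(members, t, net)
      expect_gte(r$tps, 0); expect_lte(r$tps, 1)
      # exhaustive double-loop oracle
      cp <- unique(unlist(profs[members], use.names = FALSE))
      overlap <- sum(vapply(ct, function(ch) ch %in% cp, logical(1)))
      expect_equal(r$tps, overlap / length(ct))
      # growing the cluster can only grow C_P
      expect_gte(tps_score(grown, t, net)$tps, r$tps)
      # TPS = 0 iff the overlap is empty
      expect_equal(r$tps == 0, r$n_overlap == 0L)
    }
  }
})

test_that("target ranking filters small targets then sorts by TPS", {
  # target with 19 chemicals and perfect coverage is excluded by the size filter
  chems <- paste0("k", 1:40)
  net <- multinet(plants = "P", chemicals = chems,
                  targets = c("small", "big1", "big2"),
                  pc_edges = data.frame(plant = "P", chemical = chems),
                  ct_edges = rbind(
                    data.frame(chemical = chems[1:19], target = "small"),
                    data.frame(chemical = chems[1:20], target = "big1"),
                    data.frame(chemical = chems[1:25], target = "big2")))
  r <- rank_targets_for_cluster("P", net, tps_min = 0.1)
  expect_false("small" %in% r$target_id)
  expect_equal(r$target_id, c("big1", "big2"))  # tie at TPS 1: id order

  # thresholding: survivors sorted by decreasing TPS
  net2 <- multinet(plants = c("P", "Q"), chemicals = chems,
                   targets = c("hi", "lo"),
                   pc_edges = data.frame(
                     plant = c(rep("P", 10), "Q"),
                     chemical = c(chems[1:10], chems[30])),
                   ct_edges = rbind(
                     data.frame(chemical = chems[1:20], target = "hi"),
                     data.frame(chemical = chems[11:35], target = "lo")))
  r2 <- rank_targets_for_cluster("P", net2, tps_min = 0.1,
                                 min_target_chemicals = 20)
  expect_equal(r2$target_id, "hi")
  expect_equal(r2$tps, 0.5)
  # nothing passes an impossible threshold: empty result, not an error
  expect_equal(nrow(rank_targets_for_cluster("Q", net2, tps_min = 0.5)), 0L)
})

test_that("best cluster for a target maximizes TPS with deterministic ties", {
  net <- tps_toy()
  cls <- list(
    structure(list(cluster_id = "C1", members = "p1",
                   chemical_union = c("c1", "c2", "c3")),
              class = "plant_cluster"),
    structure(list(cluster_id = "C2", members = "p2",
                   chemical_union = c("c3", "c4", "c5")),
              class = "plant_cluster"))
  best <- best_cluster_for_target(cls, "tC", net)
  expect_equal(best$cluster_id, "C2")   # 3/4 beats 1/4
  expect_equal(best$tps, 0.75)

  # single cluster containing all plants
  all_cl <- list(structure(list(cluster_id = "ALL",
                                members = c("p1", "p2"),
                                chemical_union = paste0("c", 1:5)),
                           class = "plant_cluster"))
  expect_equal(best_cluster_for_target(all_cl, "tA", net)$tps, 1)
  expect_error(best_cluster_for_target(list(), "tA", net), "at least one")
})

test_that("multi-target reports decompose shared chemistry", {
  # C_T1 = {a,b,c}, C_T2 = {b,c,d}, C_T3 = {c,d,e}
  net <- multinet(plants = "P", chemicals = letters[1:5],
                  targets = c("T1", "T2", "T3"),
                  pc_edges = data.frame(plant = "P", chemical = c("c", "d")),
                  ct_edges = data.frame(
                    chemical = c("a", "b", "c", "b", "c", "d", "c", "d", "e"),
                    target = rep(c("T1", "T2", "T3"), each = 3)))
  rep3 <- multi_target_report(c("T1", "T2", "T3"), net)
  expect_equal(rep3$pairwise["T1", "T2"], 2L)
  expect_equal(rep3$pairwise["T1", "T3"], 1L)
  expect_equal(rep3$pairwise["T2", "T3"], 2L)
  expect_equal(rep3$shared_chemicals, "c")
  expect_equal(rep3$shared_plants[["c"]], "P")
  # the all-targets intersection is inside every pairwise intersection
  expect_true(all(rep3$pairwise[upper.tri(rep3$pairwise)] >=
                    length(rep3$shared_chemicals)))

  # identical sets; then disjoint sets
  net_id <- multinet(plants = "P", chemicals = c("x", "y"),
                     targets = c("U", "V"),
                     pc_edges = data.frame(plant = "P", chemical = "x"),
                     ct_edges = data.frame(chemical = c("x", "y", "x", "y"),
                                           target = c("U", "U", "V", "V")))
  rid <- multi_target_report(c("U", "V"), net_id)
  expect_setequal(rid$shared_chemicals, c("x", "y"))
  net_dis <- multinet(plants = "P", chemicals = c("x", "y"),
                      targets = c("U", "V"),
                      pc_edges = data.frame(plant = "P", chemical = "x"),
                      ct_edges = data.frame(chemical = c("x", "y"),
                                            target = c("U", "V")))
  rdis <- multi_target_report(c("U", "V"), net_dis)
  expect_equal(length(rdis$shared_chemicals), 0L)
  expect_equal(rdis$pairwise["U", "V"], 0L)

  expect_error(multi_target_report("T1", net), "at least two")
})

test_that("subnetwork extraction keeps exactly the mediating chemicals", {
  net <- tps_toy()
  sub <- extract_subnetwork(c("p1", "p2"), "tC", net)
  # chemicals connected to >= 1 cluster plant AND the target
  expect_setequal(sub$chemicals, c("c3", "c4", "c5"))
  expect_setequal(sub$node_attrs$overlap_chemicals, c("c3", "c4", "c5"))
  expect_true(all(sub$pc_edges$chemical %in% c("c3", "c4", "c5")))
  expect_true(all(sub$ct_edges$target == "tC"))

  # full containment: subnetwork chemicals = C_T
  sub_a <- extract_subnetwork(c("p1", "p2"), "tA", net)
  expect_setequal(sub_a$chemicals, c("c1", "c2", "c3"))

  # no shared chemical: empty subnetwork with a warning
  expect_warning(sub0 <- extract_subnetwork("p1", "tB", net), "empty")
  expect_equal(n_edges(sub0), 0L)
  expect_equal(length(sub0$chemicals), 0L)
})
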