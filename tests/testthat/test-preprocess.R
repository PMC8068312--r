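test_that("category filter keeps plants and fungi only, preserving order", {
  recs <- plant_records(c("a", "b", "c", "d"),
                        category = c("plant", "fungus", "animal", "mineral"))
  kept <- filter_non_plants(recs)
  expect_equal(kept$record_id, c("a", "b"))
  expect_equal(filter_non_plants(recs[recs$category == "plant", ])$record_id, "a")
  expect_equal(nrow(filter_non_plants(recs[recs$category == "mineral", ])), 0L)
})

test_that("deduplication keys on (scientific name, Latin name, use target), first kept", {
  recs <- plant_records(c("r1", "r2"), sci = c("Aster alpinus", "Aster alpinus"))
  out <- deduplicate_plants(recs)
  expect_equal(out$record_id, "r1")
  expect_equal(attr(out, "duplicate_map"), c(r2 = "r1"))

  # same species, different used part: both kept
  recs2 <- plant_records(c("r1", "r2"), sci = c("Aster alpinus", "Aster alpinus"),
                         use_target = c("root", "leaf"))
  expect_equal(nrow(deduplicate_plants(recs2)), 2L)

  recs3 <- plant_records(c("r1", "r2"))
  expect_equal(deduplicate_plants(recs3)$record_id, c("r1", "r2"))
})

test_that("probability threshold is strictly greater-than", {
  preds <- data.frame(chemical_id = c("c1", "c2", "c3"),
                      target_id = "t1",
                      probability = c(0.95, 0.90, 0.89))
  expect_equal(threshold_predictions(preds)$chemical_id, "c1")
  expect_equal(nrow(threshold_predictions(
    data.frame(chemical_id = "c", target_id = "t", probability = 1.0))), 1L)
  all_pos <- data.frame(chemical_id = c("c1", "c2"), target_id = "t1",
                        probability = c(0.1, 0.99))
  expect_equal(nrow(threshold_predictions(all_pos, p_min = 0)), 2L)
  expect_error(threshold_predictions(all_pos, p_min = 1.5), "p_min")

  # brute-force oracle on random inputs
  for (s in 1:10) {
    set.seed(s)
    p <- data.frame(chemical_id = paste0("c", 1:50),
                    target_id = sample(paste0("t", 1:5), 50, replace = TRUE),
                    probability = round(runif(50), 3))
    got <- threshold_predictions(p, 0.5)
    want <- p[vapply(seq_len(50), function(i) p$probability[i] > 0.5,
                     logical(1)), c("chemical_id", "target_id")]
    expect_equal(got$chemical_id, want$chemical_id)
    expect_equal(got$target_id, want$target_id)
  }
})

test_that("pruning removes exactly the degree-zero nodes and no edges", {
  # chemical with one plant edge and no target edge has degree 1: kept
  net <- multinet(plants = c("p1", "lone"), chemicals = c("c1", "c0"),
                  targets = "t1",
                  pc_edges = data.frame(plant = "p1", chemical = "c1"),
                  ct_edges = data.frame(chemical = "c1", target = "t1"))
  pr <- prune_isolated(net)
  expect_true("c1" %in% pr$network$chemicals)
  expect_equal(pr$removed$plants, "lone")
  expect_equal(pr$removed$chemicals, "c0")
  expect_equal(n_edges(pr$network), n_edges(net))

  clean <- toy_net3()
  pr2 <- prune_isolated(clean)
  expect_equal(pr2$network$plants, clean$plants)
  expect_equal(lengths(pr2$removed), c(plants = 0L, chemicals = 0L,
                                       targets = 0L))
})

test_that("stage reports apply the density formula E/(Np*Nc + Nc*Nt)", {
  rep1 <- stage_report(toy_net3(), "toy")
  np <- 3; nc <- 4; nt <- 1; e <- 6
  expect_equal(rep1$density, e / (np * nc + nc * nt))
  expect_equal(rep1$n_total_nodes, rep1$n_plants + rep1$n_chemicals +
                 rep1$n_targets)
  expect_equal(rep1$n_total_edges, rep1$n_pc_edges + rep1$n_ct_edges)

  empty <- suppressWarnings(stage_report(multinet(), "empty"))
  expect_equal(empty$n_total_nodes, 0L)
  expect_equal(empty$density, 0)

  expect_warning(multipartite_density(0, 0, 0, 0), "empty")
})

test_that("the full cascade reproduces a hand-traced fixture", {
  recs <- rbind(
    plant_records(c("p1", "p2"), sci = c("Aster alpinus", "Betula alba")),
    plant_records("p2d", sci = "Betula alba"),        # duplicate of p2
    plant_records(c("m1", "m2"), category = "mineral",
                  sci = c("Quartz", "Calcite")))
  pc <- data.frame(plant_id = c("p1", "p2", "p2d", "m1"),
                   chemical_id = c("c1", "c2", "c2", "c3"))
  preds <- data.frame(chemical_id = c("c1", "c2"), target_id = c("t1", "t2"),
                      probability = c(0.95, 0.5))
  res <- run_preprocess(recs, pc, preds)
  r <- as.data.frame(res$reports)
  expect_equal(r$stage, c("raw", "plants_only", "deduplicated",
                          "thresholded", "pruned"))
  expect_equal(r$n_plants, c(5L, 3L, 2L, 2L, 2L))
  expect_equal(r$n_chemicals, c(3L, 3L, 3L, 3L, 2L))
  expect_equal(r$n_targets, c(2L, 2L, 2L, 1L, 1L))
  expect_equal(r$n_pc_edges, c(4L, 3L, 2L, 2L, 2L))
  expect_equal(r$n_ct_edges, c(2L, 2L, 2L, 1L, 1L))
  # node and edge counts never increase across stages
  expect_true(all(diff(r$n_total_nodes) <= 0))
  expect_true(all(diff(r$n_total_edges) <= 0))
  # density recomputes exactly from each report's own counts
  expect_equal(r$density,
               r$n_total_edges / (r$n_plants * r$n_chemicals +
                                    r$n_chemicals * r$n_targets))
})

test_that("the cascade is idempotent on already-clean input", {
  d <- synth_generate(synthetic_spec(seed = 11, n_blocks = 3, block_size = 6,
                                     block_profile_size = 10,
                                     n_background_chemicals = 15,
                                     n_decoy_targets = 3, n_nonplants = 2,
                                     n_isolated_chemicals = 2))
  res1 <- run_preprocess(d$plants, d$pc_edges, d$predictions)
  net1 <- res1$network
  # feed the preprocessed data back through the cascade
  recs2 <- d$plants[d$plants$record_id %in% net1$plants, ]
  pc2 <- data.frame(plant_id = net1$pc_edges$plant,
                    chemical_id = net1$pc_edges$chemical)
  preds2 <- data.frame(chemical_id = net1$ct_edges$chemical,
                       target_id = net1$ct_edges$target, probability = 1.0)
  res2 <- run_preprocess(recs2, pc2, preds2)
  r2 <- as.data.frame(res2$reports)
  expect_equal(length(unique(r2$n_total_nodes)), 1L)  # all stages identical
  expect_setequal(res2$network$plants, net1$plants)
  expect_setequal(res2$network$chemicals, net1$chemicals)
  expect_setequal(res2$network$targets, net1$targets)
  expect_equal(n_edges(res2$network), n_edges(net1))
})
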