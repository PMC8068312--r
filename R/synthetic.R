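#' Parameterization of a synthetic plant-chemical-target dataset
#'
#' Defines the generating conditions for [synth_generate()]: a sparse
#' tripartite network with planted plant blocks that share a designed
#' chemical profile, one designated target per block whose chemical set is
#' that profile, decoy targets whose predictions fall below the activity
#' threshold, heavy-tailed background chemical degrees, a ubiquitous
#' phytosterol-like chemical spread across blocks, plus the preprocessing
#' irritants of real registry data: non-plant decoy records, duplicated
#' records and isolated nodes.
#'
#' Activity probabilities are drawn from two Beta-shaped laws that straddle
#' the 0.9 interaction cut-off exactly: designated chemical-target edges
#' from `prob_high_params` mapped into (0.95, 1), decoy edges from
#' `prob_low_params` mapped into (0, 0.8). Every designated prediction
#' therefore survives thresholding and every decoy prediction is removed,
#' by construction.
#'
#' @param seed integer; fully determines the generated tables.
#' @param n_blocks number of planted plant blocks.
#' @param block_size plants per planted block.
#' @param n_background_plants plants outside any block (background edges
#'   only; default 0, so the planted blocks partition all plants and the
#'   block count is the ground-truth community count).
#' @param block_profile_size chemicals in each block's designed profile.
#' @param n_background_chemicals background chemicals shared across all
#'   plants.
#' @param n_decoy_targets targets receiving only sub-threshold predictions.
#' @param n_nonplants mineral/animal decoy records.
#' @param dup_rate fraction of plant records duplicated verbatim (same
#'   scientific name, Latin name and use target, new record id, same
#'   edges).
#' @param n_isolated_chemicals chemicals emitted with no edges at all.
#' @param within_block_connect_prob probability that a block plant carries
#'   each chemical of its block profile.
#' @param background_edge_rate mean number of background chemicals per
#'   plant (Poisson).
#' @param degree_tail_exponent exponent of the heavy-tailed popularity law
#'   used to pick background chemicals (larger = lighter tail).
#' @param ubiquitous_prob probability that any plant carries the
#'   ubiquitous chemical.
#' @param n_decoy_predictions_per_target sub-threshold predictions per
#'   decoy target.
#' @param prob_high_params,prob_low_params `shape1`/`shape2` of the two
#'   Beta laws.
#' @return object of class `synthetic_spec` (a validated list).
#' @export
synthetic_spec <- function(seed = 1L,
                           n_blocks = 5L,
                           block_size = 20L,
                           n_background_plants = 0L,
                           block_profile_size = 40L,
                           n_background_chemicals = 60L,
                           n_decoy_targets = 10L,
                           n_nonplants = 5L,
                           dup_rate = 0.05,
                           n_isolated_chemicals = 4L,
                           within_block_connect_prob = 0.85,
                           background_edge_rate = 2,
                           degree_tail_exponent = 2.5,
                           ubiquitous_prob = 0.6,
                           n_decoy_predictions_per_target = 30L,
                           prob_high_params = c(2, 2),
                           prob_low_params = c(2, 2)) {
  spec <- list(seed = as.integer(seed), n_blocks = as.integer(n_blocks),
               block_size = as.integer(block_size),
               n_background_plants = as.integer(n_background_plants),
               block_profile_size = as.integer(block_profile_size),
               n_background_chemicals = as.integer(n_background_chemicals),
               n_decoy_targets = as.integer(n_decoy_targets),
               n_nonplants = as.integer(n_nonplants),
               dup_rate = dup_rate,
               n_isolated_chemicals = as.integer(n_isolated_chemicals),
               within_block_connect_prob = within_block_connect_prob,
               background_edge_rate = background_edge_rate,
               degree_tail_exponent = degree_tail_exponent,
               ubiquitous_prob = ubiquitous_prob,
               n_decoy_predictions_per_target =
                 as.integer(n_decoy_predictions_per_target),
               prob_high_params = prob_high_params,
               prob_low_params = prob_low_params)
  spec$n_plants <- spec$n_blocks * spec$block_size + spec$n_background_plants
  spec$n_chemicals <- spec$n_blocks * spec$block_profile_size +
    spec$n_background_chemicals + spec$n_isolated_chemicals + 1L
  spec$n_targets <- spec$n_blocks + spec$n_decoy_targets
  probs <- c(spec$within_block_connect_prob, spec$ubiquitous_prob,
             spec$dup_rate)
  if (any(probs < 0 | probs > 1))
    stop("probabilities in the spec must lie in [0, 1]", call. = FALSE)
  if (spec$n_blocks * spec$block_size > spec$n_plants)
    stop("planted blocks exceed the plant count", call. = FALSE)
  class(spec) <- "synthetic_spec"
  spec
}

#' Generate a synthetic dataset
#'
#' Emits the four input tables ([read_tables()] schema) and the ground
#' truth of the construction. The same spec (same seed) always produces
#' byte-identical tables.
#'
#' @param spec a [synthetic_spec()].
#' @param out_dir optional directory; when given, `plants.tsv`,
#'   `plant_chemical.tsv`, `predictions.tsv`, `annotations.tsv` and
#'   `ground_truth.json` are written there.
#' @return list with `plants`, `pc_edges`, `predictions`, `annotations`
#'   (data frames) and `ground_truth` (list: `block_labels` named vector
#'   plant -> block, `designated` data frame of block/target pairs,
#'   `duplicates`, `nonplants`, `isolated_chemicals`, `ubiquitous_chemical`,
#'   `decoy_targets`).
#' @export
synth_generate <- function(spec = synthetic_spec(), out_dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, synth_generate_impl(spec, out_dir))
}

synth_generate_impl <- function(spec, out_dir) {
  nb <- spec$n_blocks
  plant_ids <- sprintf("P%04d", seq_len(spec$n_plants))
  block_of <- c(rep(seq_len(nb), each = spec$block_size),
                rep(NA_integer_, spec$n_background_plants))

  profile_chems <- lapply(seq_len(nb), function(b)
    sprintf("C%04d", (b - 1L) * spec$block_profile_size +
              seq_len(spec$block_profile_size)))
  n_prof <- nb * spec$block_profile_size
  bg_chems <- sprintf("C%04d", n_prof + seq_len(spec$n_background_chemicals))
  ubiq <- sprintf("C%04d", n_prof + spec$n_background_chemicals + 1L)
  iso_chems <- if (spec$n_isolated_chemicals > 0L)
    sprintf("C%04d", n_prof + spec$n_background_chemicals + 1L +
              seq_len(spec$n_isolated_chemicals)) else character()
  chem_ids <- c(unlist(profile_chems), bg_chems, ubiq, iso_chems)

  target_ids <- sprintf("T%03d", seq_len(spec$n_targets))
  designated <- target_ids[seq_len(nb)]
  decoys <- setdiff(target_ids, designated)

  # heavy-tailed popularity weights for background chemicals
  w <- (1 - stats::runif(length(bg_chems)))^(-1 / (spec$degree_tail_exponent - 1))
  w <- w / sum(w)

  pc <- vector("list", spec$n_plants)
  for (i in seq_len(spec$n_plants)) {
    chems <- character()
    b <- block_of[i]
    if (!is.na(b)) {
      keep <- stats::runif(spec$block_profile_size) <
        spec$within_block_connect_prob
      chems <- profile_chems[[b]][keep]
    }
    n_bg <- stats::rpois(1L, spec$background_edge_rate)
    if (n_bg > 0L)
      chems <- c(chems, sample(bg_chems, min(n_bg, length(bg_chems)),
                               prob = w))
    if (stats::runif(1L) < spec$ubiquitous_prob) chems <- c(chems, ubiq)
    chems <- unique(chems)
    if (length(chems))
      pc[[i]] <- data.frame(plant_id = plant_ids[i], chemical_id = chems,
                            stringsAsFactors = FALSE)
  }
  pc <- do.call(rbind, pc)

  genus <- sprintf("Genus%02d", ifelse(is.na(block_of), 99L, block_of))
  species <- sprintf("%s species%03d", genus, seq_len(spec$n_plants))
  use_parts <- c("root", "leaf", "seed", "whole plant", "bark")
  plants <- data.frame(
    record_id = plant_ids,
    scientific_name = species,
    latin_name = paste0(species, " L."),
    use_target = sample(use_parts, spec$n_plants, replace = TRUE),
    category = sample(c("plant", "fungus"), spec$n_plants, replace = TRUE,
                      prob = c(0.95, 0.05)),
    stringsAsFactors = FALSE)

  # non-plant decoy records, each with a couple of chemical edges
  nonplant_ids <- character()
  if (spec$n_nonplants > 0L) {
    nonplant_ids <- sprintf("N%03d", seq_len(spec$n_nonplants))
    nonplants <- data.frame(
      record_id = nonplant_ids,
      scientific_name = sprintf("Decoy entity %03d", seq_len(spec$n_nonplants)),
      latin_name = sprintf("Decoyus entitus %03d", seq_len(spec$n_nonplants)),
      use_target = "whole",
      category = sample(c("mineral", "animal"), spec$n_nonplants,
                        replace = TRUE),
      stringsAsFactors = FALSE)
    plants <- rbind(plants, nonplants)
    np_edges <- data.frame(
      plant_id = rep(nonplant_ids, each = 2L),
      chemical_id = sample(bg_chems, 2L * spec$n_nonplants, replace = TRUE),
      stringsAsFactors = FALSE)
    pc <- rbind(pc, unique(np_edges))
  }

  # duplicated plant records: identical key fields and identical edges
  n_dups <- floor(spec$dup_rate * spec$n_plants)
  dup_ids <- character()
  if (n_dups > 0L) {
    src <- sample(plant_ids, n_dups)
    dup_ids <- paste0(src, "D")
    dup_rows <- plants[match(src, plants$record_id), , drop = FALSE]
    dup_rows$record_id <- dup_ids
    plants <- rbind(plants, dup_rows)
    dup_edges <- pc[pc$plant_id %in% src, , drop = FALSE]
    dup_edges$plant_id <- paste0(dup_edges$plant_id, "D")
    pc <- rbind(pc, dup_edges)
  }
  rownames(plants) <- NULL
  rownames(pc) <- NULL

  # predictions: designated targets cover their block profile (above the
  # cut-off), decoy targets and extra designated-target rows stay below it
  rbeta_in <- function(n, lo, hi, pars)
    lo + (hi - lo) * stats::rbeta(n, pars[1L], pars[2L])
  preds <- list()
  for (b in seq_len(nb)) {
    ch <- profile_chems[[b]]
    preds[[length(preds) + 1L]] <- data.frame(
      chemical_id = ch, target_id = designated[b],
      probability = round(rbeta_in(length(ch), 0.95, 1 - 1e-6,
                                   spec$prob_high_params), 6L),
      stringsAsFactors = FALSE)
    sub <- sample(setdiff(chem_ids, c(ch, iso_chems)), 10L)
    preds[[length(preds) + 1L]] <- data.frame(
      chemical_id = sub, target_id = designated[b],
      probability = round(rbeta_in(10L, 1e-6, 0.8, spec$prob_low_params), 6L),
      stringsAsFactors = FALSE)
  }
  for (t in decoys) {
    ch <- sample(setdiff(chem_ids, iso_chems),
                 spec$n_decoy_predictions_per_target)
    preds[[length(preds) + 1L]] <- data.frame(
      chemical_id = ch, target_id = t,
      probability = round(rbeta_in(length(ch), 1e-6, 0.8,
                                   spec$prob_low_params), 6L),
      stringsAsFactors = FALSE)
  }
  preds <- do.call(rbind, preds)
  rownames(preds) <- NULL

  # chemical classification annotations: one subclass per block profile,
  # a handful of background subclasses, nested direct parents
  subclass_of <- function(ch) {
    idx <- match(ch, chem_ids)
    prof_block <- (idx - 1L) %/% spec$block_profile_size + 1L
    ifelse(idx <= n_prof, sprintf("Subclass %02d", prof_block),
           sprintf("Subclass %02d", nb + 1L + (idx %% 3L)))
  }
  annotations <- data.frame(
    chemical_id = chem_ids,
    kingdom = "Organic compounds",
    superclass = "Lipids and lipid-like molecules",
    class = sprintf("Class %02d", (match(chem_ids, chem_ids) %% 4L) + 1L),
    subclass = subclass_of(chem_ids),
    direct_parent = sprintf("%s parent %d", subclass_of(chem_ids),
                            (seq_along(chem_ids) %% 2L) + 1L),
    stringsAsFactors = FALSE)

  ground_truth <- list(
    block_labels = stats::setNames(block_of[!is.na(block_of)],
                                   plant_ids[!is.na(block_of)]),
    designated = data.frame(block = seq_len(nb), target_id = designated,
                            stringsAsFactors = FALSE),
    duplicates = dup_ids,
    nonplants = nonplant_ids,
    isolated_chemicals = iso_chems,
    ubiquitous_chemical = ubiq,
    decoy_targets = decoys)

  out <- list(plants = plants, pc_edges = pc, predictions = preds,
              annotations = annotations, ground_truth = ground_truth)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.table(plants, file.path(out_dir, "plants.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(pc, file.path(out_dir, "plant_chemical.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(preds, file.path(out_dir, "predictions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(annotations, file.path(out_dir, "annotations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    gt <- ground_truth
    gt$block_labels <- as.list(gt$block_labels)
    jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

#' Recovery metrics against the planted ground truth
#'
#' Compares a clustering of the plants with the planted block labels:
#' adjusted Rand index (chance-corrected agreement) over the planted
#' plants, plus per-block purity (the largest fraction of a block's plants
#' assigned to one predicted cluster).
#'
#' @param labels a named cluster vector over plants, a `multinet_partition`,
#'   or a list of `plant_cluster`s.
#' @param ground_truth the `ground_truth` element of [synth_generate()],
#'   or any named vector of planted labels.
#' @return list with `ari` and `purity` (named numeric vector per block).
#' @export
evaluate_recovery <- function(labels, ground_truth) {
  planted <- if (is.list(ground_truth) && !is.null(ground_truth$block_labels))
    ground_truth$block_labels else ground_truth
  if (inherits(labels, "multinet_partition")) labels <- labels$assignment
  if (is.list(labels) && all(vapply(labels, inherits, logical(1),
                                    "plant_cluster"))) {
    labels <- stats::setNames(
      rep(seq_along(labels), lengths(lapply(labels, `[[`, "members"))),
      unlist(lapply(labels, `[[`, "members"), use.names = FALSE))
  }
  plants <- names(planted)
  if (!all(plants %in% names(labels)))
    stop("labels do not cover every planted plant", call. = FALSE)
  pred <- labels[plants]
  ari <- mclust::adjustedRandIndex(as.vector(pred), as.vector(planted))
  purity <- vapply(split(pred, planted), function(x)
    max(table(x)) / length(x), numeric(1))
  list(ari = ari, purity = purity)
}
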