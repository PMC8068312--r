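---
title: "Methods: multipartite networks of plants, chemicals and targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multipartite networks of plants, chemicals and targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`phytonet` works on an unweighted, undirected tripartite graph. The three
node layers are medicinal-plant records, chemical compounds, and protein
targets; edges exist only between a plant and a chemical it contains, and
between a chemical and a target it is predicted to act on. Plants and
targets never touch directly: every pharmacological statement the package
makes is mediated by chemicals. Chemical–target edges come from a
ligand-based activity-prediction model that emits a probability per
(chemical, target) pair; an edge is called when that probability is
*strictly* greater than a cut-off (default 0.9). The package consumes the
probability table as given — the prediction model itself, and the mapping
of registry chemical names onto prediction-database identifiers, are out
of scope; inputs are assumed pre-joined on shared chemical identifiers.

Edge weights are the 0/1 adjacency indicator throughout: the degree of a
node is its neighbor count and `E` is the number of edges. The density of
the tripartite graph is the realized fraction of *possible* edges,
`E / (Np·Nc + Nc·Nt)`, since only plant–chemical and chemical–target
pairs can be adjacent.

# Preprocessing

Real registry data contains non-plant entries, duplicated records and
entities that lose all their links after filtering. The cascade applies,
in order:

1. **Raw accounting** over every record and prediction.
2. **Non-plant removal**: records keep their curated `category`; only
   `plant` and `fungus` survive (minerals and animals are removed, fungi
   deliberately retained). Detection is driven by the category column, not
   name heuristics — manual curation cannot be replicated algorithmically.
3. **Deduplication** on the exact key (scientific name, Latin name, use
   target). The first occurrence in file order survives — the choice of
   survivor is otherwise arbitrary, and fixing it makes runs reproducible.
   Plant–chemical edges of removed duplicates are re-pointed at the
   survivor and the union deduplicated, so merging can shrink the edge
   count when duplicates shared chemistry.
4. **Probability thresholding** with strict inequality: a prediction at
   exactly the cut-off is removed. Targets left with no retained
   prediction leave the target layer at this stage (they are entities of
   the prediction table, so they expire with their last prediction),
   while the chemical universe stays fixed until the final stage.
5. **Pruning** of all degree-zero nodes in one pass (removing a
   degree-zero node removes no edges, so one pass suffices).

Each stage emits a report row (node counts per layer, edge counts per
relation, density). Node and edge counts are non-increasing across stages
and the cascade is idempotent; both properties are tested.

# Spectral co-clustering and model selection

Plants and targets both connect exclusively to chemicals, so the whole
graph is encoded as a single bipartite incidence matrix `A` with rows =
plants ∪ targets and columns = chemicals. This is the package's resolution
of how target nodes enter the co-clustering; it preserves exactly the
bipartite structure the normalized-cut criterion operates on, and it is
logged as a design decision rather than presented as canonical. Clustering
follows the classic spectral co-clustering recipe: normalize
`An = D_r^{-1/2} A D_c^{-1/2}`, take the truncated SVD, embed rows and
columns jointly with singular vectors 2..k (rescaled by `D^{-1/2}`), and
run k-means on the joint embedding. K-means uses 10 restarts seeded
deterministically from the user seed, so partitions are reproducible.
Row and column clusters sharing an index form one subnetwork.

Two partition functionals are computed in-package:

- the **normalized cut** `(1/k) Σ_i cut(V_i, V̄_i)/vol(V_i)` — zero
  exactly when no edge crosses clusters; clusters of zero volume
  contribute 0 with a warning rather than dividing by zero;
- **modularity** `(1/2E) Σ_i Σ_{m,n∈V_i} (w_mn − d_m d_n/2E)`, the double
  sum over *ordered* pairs including the diagonal (the standard Newman
  convention). This convention makes the one-cluster partition score 0
  exactly, and two disconnected equal-volume components split into their
  components score 0.5 — both are frozen tests, alongside an exhaustive
  pair-sum oracle on random small graphs and an independent igraph
  cross-check.

The number of clusters is chosen by scanning a k range (default 2–20; the
pipeline clamps the range to the incidence dimensions), computing the
modularity of each partition, and taking the argmax with ties broken
toward the smallest k (parsimony). Whether a published five-way split of
such a network arose from this selection rule or was fixed a priori is
generally not recoverable; the package treats the rule as the definition.

Structural statistics reported per network and per subnetwork: layer/edge
counts, density, diameter of the largest connected component, degree
assortativity (Pearson correlation of end degrees; `NA` when degree
variance is zero, e.g. a single edge), per-layer degree histograms (raw
counts; no power-law fitting), and the average *bipartite* clustering
coefficient. Triangle-based clustering is identically zero here, so the
pairwise definition is used: `cc(u,v) = |N(u)∩N(v)| / |N(u)∪N(v)|`
averaged over the second-order neighbors `v` of `u`, then over nodes.

# Plant clustering by chemical profile

Each plant's profile is the binary indicator of its chemical set, stored
sparsely. The Bray–Curtis distance on binary profiles is
`|symmetric difference| / (deg u + deg v)` — one minus the Dice
similarity. Two properties make it the right metric here: it ignores the
(overwhelmingly many) chemicals absent from both plants, so it is
invariant under padding the chemical universe — essential in a network
where most indicators are zero — and it only uses edge counts, matching
the unweighted graph. Both identities are property-tested, and the matrix
route is cross-checked against an independent community-ecology
implementation.

Agglomeration is complete linkage: the distance between clusters is the
distance between their farthest members. The payoff of this pairing is a
theorem: merging clusters only while their distance is below one
guarantees that *every* pair of plants in a cluster has distance < 1,
i.e. shares at least one chemical. The default cut height is therefore
`1 − 1e-9`, the largest cut preserving that guarantee; the cut is a
parameter because published analyses do not state theirs. Plants with
identical profiles (same species, different used part, typically) merge
at height exactly 0 and survive any cut.

Complete linkage is implemented in-package rather than via `hclust`
because ties in the minimum inter-cluster distance are broken
lexicographically by the smallest member-identifier pair, making trees
bitwise reproducible across platforms; merge heights are cross-checked
against `stats::hclust` on random tie-free matrices. Dendrograms export
to Newick with branch lengths equal to merge-height differences, so the
root-to-leaf path length equals the final merge height.

# Target Potency Score

For a plant cluster `P` with chemical union `C_P` and a target `T` with
chemical set `C_T`, `TPS(P, T) = |C_P ∩ C_T| / |C_T|`: the fraction of
the target's chemistry covered by the cluster. It is a connectivity
fraction, not an efficacy claim. It is 1 exactly when the cluster covers
the target's chemical set, 0 exactly when they are disjoint, and it is
monotone non-decreasing as the cluster grows — which is why cluster
retrieval always scores the fixed clusters of a dendrogram cut, never
nested supersets.

Two retrieval modes: ranking targets for a cluster (targets with fewer
than `min_target_chemicals = 20` chemicals are excluded *before*
thresholding, because a small denominator makes the fraction unreliable;
survivors with `tps >= tps_min` are sorted by descending TPS, ties by
identifier) and finding the best cluster for a target (argmax TPS, ties
toward the smaller cluster then lexicographic identifier — the paper-level
sources are silent on ties, so determinism is the package's own
convention). `tps_min` has no single canonical value (published figures
use 0.05–0.5), so it is a required argument of the ranking surface with a
0.1 default in the pipeline. A multi-target report decomposes shared
chemistry across several targets (pairwise intersection sizes, the
chemicals acting on all listed targets, and the plants carrying each),
and `extract_subnetwork()` returns the induced plant–chemical–target
subnetwork in which the mediating chemicals — those connected to at least
one cluster plant *and* one listed target — are flagged.

# The synthetic generator

The generator emulates the statistical structure the analysis assumes,
not any real database's content: (i) a sparse tripartite topology in
which plants and targets only touch chemicals; (ii) planted plant blocks
(default 5 blocks × 20 plants) each sharing a designed 40-chemical
profile, carried per plant with probability 0.85; (iii) one designated
target per block wired to exactly that block's profile with activity
probabilities drawn in (0.95, 1), plus decoy targets and decoy
predictions drawn in (0, 0.8) — the two Beta-shaped laws straddle the 0.9
cut-off with a gap, so thresholding separates designated from decoy edges
*exactly*, and that separation is assertable from the emitted ground
truth; (iv) heavy-tailed background chemical popularity (Pareto-style
weights, default tail exponent 2.5) echoing the log-scale degree spread
of real phytochemical registries; (v) a ubiquitous phytosterol-like
chemical carried by ~60% of plants across blocks, reproducing the way
widely shared metabolites blur family-level clustering; and (vi)
preprocessing irritants — non-plant records, verbatim duplicates,
isolated chemicals — whose removal is checked against the ground truth.

By default the planted blocks partition all plants, so the block count
*is* the ground-truth community count; optional background plants (off by
default) otherwise form a real extra community of their own and make the
"planted k" ambiguous as a recovery criterion. A fixed seed makes the
emitted tables byte-identical across runs.

What passing on this generator does **not** show: recovery of any real
published cluster memberships or target lists (those depend on the full
registry and prediction databases, which are not redistributed), realism
of marginal statistics beyond order-of-magnitude sparsity, and robustness
to block overlap or annotation noise the generator does not model.

# Numerical choices and degenerate inputs

- Duplicated (chemical, target) prediction rows collapse to the maximum
  probability — the most permissive reading under a strict cut-off.
- Thresholding is strict (`> p_min`); a prediction at exactly 0.9 is
  removed. The boundary is a frozen test.
- Unknown edge endpoints auto-register as bare nodes with a warning
  (keeps sparse real-world joins usable); a strict mode makes them fatal.
  Cross-layer edges (plant–target, within-layer) are always fatal.
- `modularity` is fatal on an edgeless graph (undefined); `bray_curtis`
  is fatal on two empty profiles (0/0); neither can occur after pruning.
- Degree-zero nodes reaching the co-clustering are assigned to cluster 1
  with a warning; the pipeline prunes them first.
- Identifiers are opaque, case-sensitive strings; names are trimmed of
  whitespace but never normalized further.

# Problem sizes

The test suite and the pipeline defaults run the generator at 100 plants,
~260 chemicals and 15 targets, with k scanned over 2–10 and 20 replicate
seeds for the recovery properties; exhaustive pair-sum oracles run on
graphs of ≤ 10 nodes. These sizes give stable recovery statistics
(median ARI and modularity argmax) while keeping the full suite in the
tens of seconds on one CPU.

# Limitations

TPS quantifies network connectivity only; it inherits every bias of the
upstream activity-prediction model and of registry curation. The
incidence orientation for co-clustering (rows = plants ∪ targets) is a
modeling choice, not the only possible adaptation. No alternative
community detection (Louvain/Leiden), no statistical test of
scale-freeness, no chemical structure handling, and no taxonomy
inference beyond tallying supplied classification labels.
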