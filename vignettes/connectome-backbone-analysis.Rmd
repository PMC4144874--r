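---
title: "Weighted connectome backbones and small-world group analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted connectome backbones and small-world group analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tractnet)
```

## The analysis

`tractnet` implements a group study of white-matter structural networks at
the level probabilistic tractography delivers them: for each subject and
scan, a directed matrix of streamline counts between the 90 regions of the
AAL parcellation, plus the number of seed voxels per region. The pipeline
is:

1. **Motion screening.** Scans whose realignment parameters exceed 1 mm of
   translation or 1 degree of rotation (maximum absolute value over volumes
   and axes) are excluded. The summary statistic is the per-axis maximum —
   the conservative reading of a "translation > 1 mm or rotation > 1 degree"
   rule; framewise displacement or a Euclidean norm would be laxer
   alternatives.
2. **Weight matrices.** The connection weight between regions A and B is
   the count of streamlines seeded in A reaching B divided by the seed-voxel
   count of A, plus the symmetric term from B: `w_ij = c_ij/v_i + c_ji/v_j`.
   Voxel normalization removes the head start that large seed regions get
   in streamline counts; the sum makes the matrix symmetric.
   Self-connections are excluded. Surviving scans of a subject are averaged
   entrywise.
3. **Backbone extraction.** A maximum spanning tree guarantees a connected
   scaffold; remaining edges are added in descending weight order until the
   average degree reaches `k = 4` (180 edges at N = 90). This keeps the
   strongest, most reproducible connections while fixing the edge budget
   across subjects, so group differences in metrics are not density
   artefacts. Weights are kept as they are — no binarization. Ties are
   broken by lexicographic node-pair order so the backbone is deterministic
   across platforms.
4. **Graph metrics** (below), computed on the weighted backbone.
5. **Null models.** Each backbone is compared against 100 degree-preserving
   rewired networks (Markov-chain edge swaps, weights travelling with their
   edges). The efficiency ratios `E_loc(G)/E_loc(rand)` and
   `E_glob(G)/E_glob(rand)` classify small-world organization.
6. **Group statistics.** Pooled-variance two-sample two-tailed t-tests per
   (metric, node) and per global feature; Pearson correlation of
   significant features with training-onset age within the trained group.

## Metric definitions and conventions

Distances between connected regions are inverse weights, `1/w_ij`: strong
connections are short. On that metric:

* **Degree / strength.** `K_i` counts positive-weight neighbours; the
  strength `S_i = sum_j w_ij` is its weighted analogue.
* **Generalized clustering.**
  `C_i = 2/(K_i(K_i-1)) * sum_{j<h} (w_ij w_ih w_jh)^(1/3)`, i.e. the mean
  geometric triple product over closed neighbour pairs, evaluated on *raw*
  weights. Tractography weights have no natural ceiling and normalizing by
  the network maximum would make the coefficient hostage to a single edge,
  so the raw-weight form is used; its values are unbounded and meaningful
  for contrasts between groups rather than as absolute quantities. `C_i = 0`
  when `K_i < 2`.
* **Path lengths.** `L_i` is the mean distance from node *i* to all others
  (infinite if the node is cut off); the characteristic path length `L(G)`
  is the *harmonic* mean over ordered pairs — the reciprocal of the mean
  reciprocal distance with `1/Inf = 0` — which stays finite when rewired
  null networks fragment.
* **Betweenness.** `BC_i` sums, over ordered pairs `(k, j)` with
  `k != i != j`, the fraction of shortest `k -> j` paths through `i`.
  Ordered pairs are *not* halved; on symmetric networks this doubles the
  unordered count uniformly, which cancels in any group contrast. Ties
  between path lengths are detected with a relative tolerance of `1e-12`
  on accumulated distances, because floating-point path sums essentially
  never tie exactly.
* **Efficiencies.** `E_glob` is the mean inverse distance over ordered
  pairs; `E_loc` averages `E_glob` of each node's neighbour-induced
  subgraph, with the original weights (not renormalized, consistent with
  the raw-weight convention) and zero for nodes with fewer than two
  neighbours.

Infinite distances are represented as `Inf`, never as a sentinel value.

Small-world classification requires `E_glob` ratio below 1 together with an
`E_loc` ratio above a margin whose default is 1; "much greater" is not a
sharp threshold, so the margin is an explicit parameter. Rewired ensembles
use 10 attempted swaps per edge (the usual mixing heuristic) and do not
enforce connectivity — the harmonic-mean and efficiency conventions absorb
fragmentation. Ensemble efficiencies are averaged first and the ratio taken
once, not averaged over per-member ratios.

## The synthetic cohort generator

No tract-count data ship with the package, so the generator is a
first-class module: it emulates the *design* of a two-group cross-sectional
study — 16 subjects per group, 90 nodes, up to three repeated scans — with
a known ground truth, so that every downstream stage can be tested for
calibration and power.

What it draws, and why:

* **Spatial structure.** Nodes receive mirrored 3-D coordinates (two
  hemispheres); connection probability *and* expected streamline count
  decay exponentially with Euclidean distance (length scale
  `distance_decay = 0.25` in unit-box coordinates), calibrated so the mean
  connection density equals `base_density = 0.3`. Distance-dependent
  connectivity is the dominant regularity of real tractography matrices and
  is what gives their backbones high local clustering next to short global
  paths; a flat random mask cannot produce that signature, because its
  backbones are locally tree-like and already statistically
  indistinguishable from their own degree-preserving rewirings. A flat mask
  remains available (`mask_type = "erdos-renyi"`) for tests where topology
  is irrelevant.
* **Counts.** Directed counts are negative binomial with mean from the
  distance kernel (scaled so present connections average
  `mean_count = 100`) and size `dispersion = 5` — overdispersion mimicking
  the run-to-run variability of probabilistic tracking.
* **Shared cohort structure.** The connection mask and the region voxel
  counts (uniform integers in 400–4000, roughly the AAL region volumes at
  DWI resolution) are drawn once per cohort and shared across subjects, as
  template-space region properties are in practice. This makes
  `expected_weight_matrix()` an exact conditional oracle:
  `E[w_ij] = mu_ij (1/v_i + 1/v_j)`. The mask is redrawn (up to 100
  times) until connected — per-subject structural networks are connected
  in practice, and backbone extraction requires it.
* **Group effect.** In the musician group, expected counts on edges
  incident to `effect_nodes` are multiplied by `effect_multiplier`. At
  `effect_multiplier = 1` the groups are draws from the same distribution
  (exchangeability, the basis of the type-I calibration tests). A pilot
  Monte-Carlo (40 cohorts) showed that a multiplier near 1.10 realizes a
  standardized backbone-strength difference of d of about 1.0 at the effect
  nodes: the backbone amplifies the raw 10% count increase because
  strengthened edges are also promoted into the backbone more often.
* **Template vs. subjects.** The cohort-level structure is controlled by
  `geometry_seed` (default: the main seed). Replicate cohorts sharing a
  `geometry_seed` but not a `seed` emulate repeated studies of the same
  population — the atlas and typical region sizes are fixed population
  structure, while subjects are fresh draws. The power checks use this
  mode. Because the coefficient of variation of backbone strength — and
  with it the standardized effect realized by a given count multiplier —
  is node-specific, `effect_multiplier` also accepts one value per effect
  node. Two pilot rounds (20 cohorts each) measure each node's realized d
  at trial multipliers; d is very nearly linear in
  `effect_multiplier - 1`, so a per-node least-squares slope through the
  origin sets the multipliers that inject d = 1.0 at every effect node
  under that template, and detection is then measured on fresh replicate
  cohorts. Without this standardization, realized d varies
  across nodes and cohorts and, power being concave in d, the mean
  detection rate understates the power at d = 1.
* **Motion.** Rigid-body parameters are cumulative Gaussian random walks
  (21 volumes, increment sd `motion_sd = 0.05` mm/deg), which keeps
  ordinary scans comfortably inside the 1 mm / 1 degree limits;
  `qc_fail_rate` can force scans over threshold to exercise the exclusion
  path.
* **Onset ages.** Uniform in 4–12 years, independent of network features:
  the null against which onset correlations are checked.

Determinism: the cohort is a pure function of its spec. Every subject,
scan and purpose uses a random stream derived by stable integer hashing of
`(seed, keys...)`, so subsets are reproducible and ensemble member *k* of a
null-model run never shares a stream with the data.

What the generator does **not** emulate: spatial autocorrelation of counts
beyond the distance kernel, hemispheric asymmetries, realistic voxel-size
gradients, age/sex structure, or scanner drift between repeated scans.
Passing tests therefore show that the pipeline is correct and calibrated
under a plausible generative model of tract-count data — not that any
particular neuroscientific finding generalizes.

## Numerical and design choices

* Maximum spanning trees are computed by Kruskal's algorithm on descending
  weights with lexicographic `(i, j)` tie-breaking; greedy backbone
  addition considers only non-tree edges, in the same order. With an odd
  `N * k` the edge budget is `floor(N k / 2)`.
* The all-pairs solver is a vectorized Floyd–Warshall; path counts are
  accumulated per source in order of increasing distance, which is valid
  because predecessors on a shortest path are always strictly closer
  (edge lengths are positive).
* Degenerate inputs: zero-voxel regions, non-square or asymmetric
  matrices, empty motion logs, disconnected inputs to the backbone and
  too-sparse graphs all raise errors naming the offending field or
  component sizes; rewiring a network with fewer than two edges returns it
  unchanged with a warning.
* The two-sample test is the pooled-variance Student t (`df = n1+n2-2`):
  exact under the null of equal distributions and the standard choice for
  balanced designs of this size; Welch is available
  (`var_equal = FALSE`). P-values are
  uncorrected by default, with Benjamini–Hochberg as an option.
* Reports round T to 2 decimals and p to 3 significant figures for
  display; stored CSVs keep full precision.

## Problem sizes used by the checks

The packaged checks run, per invocation: the brute-force metric oracle on
1000 random graphs with 4–6 nodes; maximum-spanning-tree verification on
25–40 downsampled 5–7-node subnetworks; one full 32-subject cohort with a
100-member rewired ensemble per subject; 500 null cohorts (24 nodes, one
scan, 16 subjects per group, so the t-tests keep df = 30) for type-I
calibration — node count does not enter the size of a per-node t-test, and
24 nodes keep the sweep affordable; and two 20-cohort calibration pilots
plus 200 effect cohorts at the full 90-node design for power, computing
the strength metric at the four effect nodes. These sizes put Monte-Carlo
standard errors well below the margins being tested.

## Limitations

* The analysis starts at count matrices; tractography, registration and
  parcellation quality are out of scope and their biases propagate into
  any real-data application.
* The raw-weight clustering coefficient is scale-dependent by design;
  compare it only within a study, never across acquisition protocols.
* The betweenness ordered-pair convention doubles unordered counts; use
  the same convention when comparing against other toolboxes.
* Rewired null networks may be disconnected; efficiency ratios absorb
  this, but characteristic-path-length ratios would not, which is why the
  small-world criterion is stated in efficiencies.
* With 16 subjects per group, only large effects (d near 1) are reliably
  detectable; uncorrected p-values across 450 nodal features imply about
  22 false positives per cohort in expectation — the package reports them
  as exploratory, and the multiple-testing option exists for stricter use.
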