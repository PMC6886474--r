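---
title: "Methods: CFS-driven classification and consensus virtual screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CFS-driven classification and consensus virtual screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfscreen)
```

## The problem this package addresses

Ligand-based virtual screening (LBVS) builds activity classifiers from a
small set of assayed compounds plus presumed-inactive decoys, then
applies them to multi-million-compound vendor libraries. The practical
bottleneck is the feature matrix: a few hundred compounds described by
thousands of 2D descriptors and fingerprint bits. `cfscreen` implements
that workflow end to end: activity binarization under several IC50
cutoffs, two-stage feature filtering, correlation-based feature subset
selection (CFS) under four search strategies, tree / forest / naive
Bayes classification with cross-validated tuning, and strict unanimous
consensus voting over a model panel for the final screen.

## The model and its pieces

### Activity binarization

Each assayed compound carries an IC50 (uM). Under a cutoff `t`, a
compound is *active* iff IC50 <= `t`; decoys are inactive under every
cutoff. The canonical cutoffs are 4, 3, 2, 1 uM plus the maximum
observed IC50 (11.4 uM), under which every assayed compound is active.
The `<=` convention is forced by that maximum-value dataset: the
compound sitting exactly at the cutoff must be active for the
"all assayed compounds active" labeling to hold.

### Two-stage filtering

Columns are min-max normalized to [0, 1] (constants map to 0; the
recorded per-column min/max de-normalizes survivors exactly, round-trip
tested to 1e-12 relative error). The variance filter removes columns
with variance <= `variance_threshold` (default 0: constants only — the
narrow reading of "zero variance"; the knob is exposed because the
broader "low variance" reading is equally defensible). The redundancy
filter computes the pairwise Kendall tau-a matrix — tau-a =
(concordant − discordant) / (n(n−1)/2), ties counting as neither — and
for every pair with |tau-a| > 0.9 drops the *later* column in column
order. Three choices deserve notice:

* **Magnitude, not signed tau.** Strong negative rank dependency is the
  same redundancy as strong positive dependency, so the filter compares
  |tau-a| to the threshold.
* **Keep-the-earlier tie rule.** Deterministic and order-stable; the
  drop log records (kept, dropped, tau) for every removal.
* **tau-a is nearly blind to binary bits.** Two *identical*
  Bernoulli(0.3) bits have tau-a ≈ 0.42 because tied pairs count as
  neither concordant nor discordant. A tau-a > 0.9 filter therefore
  removes graded (descriptor-like) redundancy but passes duplicated
  fingerprint bits — consistent with filter bookkeeping in this
  workflow's source material, where the correlation stage removed only
  descriptor columns. The synthetic generator consequently plants its
  redundant near-duplicates on continuous sources.

The per-pair kernel is an O(n log n) merge-sort inversion counter in
C++; the O(n^2) explicit pair count lives only in the test suite as the
independent oracle.

### CFS merit

A subset S of k features is scored by

    Merit_S = k * rcf / sqrt(k + k(k-1) * rff)

with `rcf` the mean |Pearson| correlation between member features and
the {0,1} class (point-biserial / phi, since binary features stay 0/1
and no discretization is applied — a deliberate divergence from Weka's
symmetric-uncertainty CFS, matching the literal "Pearson's correlation"
reading), and `rff` the mean |Pearson| over within-subset pairs (0 when
k = 1, so a singleton's merit is exactly its class correlation).
Zero-variance columns get correlation 0 by convention.

**A quirk worth knowing.** Adding an exact duplicate of a subset member
does *not* always lower merit. For k = 1 it is exactly neutral
(2r/sqrt(4) = r), and the smaller-subset tie-break discards the
duplicate; but for k >= 2 a duplicate of a strong feature can *raise*
merit by inflating k and the rcf mean faster than the rff penalty
grows (e.g. rcf = {0.6, 0.3}, independent: merit 0.636 → 0.671 after
duplicating the 0.6 feature). The redundancy penalty is a tendency, not
a theorem; the tau-a pre-filter exists precisely to remove duplicates
before CFS sees them. Ties in all searchers are resolved by higher
merit, then smaller k, then lexicographically smallest column list,
with merits within 1e-12 relative tolerance treated as tied so
floating-point fuzz cannot defeat the size tie-break.

### The four searchers

* **Best-first (BF).** Forward search from the empty set with an open
  list ordered by merit and backtracking to the next-best open node;
  stops after 5 consecutive non-improving expansions (the `patience`
  default). Deterministic.
* **Genetic (GS).** Inclusion bitstrings, 20 generations x 20
  individuals, crossover probability 0.6, per-individual single-bit
  mutation at 0.33, roulette selection, 1-elitism. Selection scheme,
  crossover type and elitism were unspecified in the source; the
  simplest reproducible choices were taken. Empty individuals repair to
  a random singleton.
* **Geometric PSO (PSO).** Binary-space particles updated by
  three-parent mask recombination: per bit, inherit from the current
  position / global best / particle best with probabilities w1/w2/w3 =
  0.33/0.33/0.34 (must be positive, sum to 1). No mutation by default
  (none is described for the source configuration); an optional bit-flip
  rate is exposed. 20 particles, 20 iterations.
* **Subset-size forward selection (SSFS).** Rank features by class
  correlation, keep the top 50 (`top_k`), run greedy forward selection
  recording the best subset at each size, and choose the size by 5-fold
  cross-validation: per fold the ranking and path are rebuilt on the
  training portion and each size is scored by *held-out merit*. The CV
  objective was left open by the source text; held-out merit keeps the
  stage classifier-free. One deliberate deviation: the size is the
  smallest within one standard error of the best mean held-out merit
  (the 1-SE rule) rather than the strict argmax — at realistic fold
  sizes the held-out merit curve is noise-dominated past its knee, and
  the strict argmax frequently returned *larger* subsets than BF,
  contradicting the compactness that motivates SSFS.

An exhaustive enumerator (guarded at 15 columns) serves as the test
oracle: every searcher's merit is verified against it on small
instances, and oracle dominance (exhaustive >= heuristic) is asserted
always.

### Classifiers

No tree or forest package is assumed: the CART-style grower is
first-party, shared by both tree-based models.

* **DT** — binary tree, Gini impurity splits, depth bound,
  cost-complexity post-pruning on training misclassification with
  complexity parameter `cp` (default 0.01). This substitutes a
  contract-level equivalent for the source's SPRINT/MDL machinery,
  whose pruning details are not reproducible from the text.
* **RF** — bagged trees with information-gain-ratio splits, per-node
  feature sampling of ceiling(sqrt(d)), depth bound; the active
  probability is the fraction of trees voting active (ties count half).
  `bootstrap = FALSE` with full `mtry` reduces a 1-tree forest to a
  single gain-ratio tree (tested equivalence).
* **NB** — Gaussian likelihoods for continuous columns (sd floored at
  1e-6), Laplace-smoothed Bernoulli for binary columns, class priors
  from frequencies.

Validation follows the 65/35 stratified split (train size floor(0.65 n),
per-class floors with largest-remainder top-up, so 402 rows give
261/141) plus stratified 10-fold cross-validation. CV metrics are
computed on *pooled* out-of-fold predictions — one AUC and one MCC per
run, not per-fold averages — because the source does not say which; the
pooled form is the lower-variance choice at n ≈ 400. AUC is the
rank-based (Mann-Whitney) estimator with midrank ties; MCC uses the
standard formula with the 0-on-zero-denominator convention and a 0.5
probability threshold (unstated in the source; 0.5 is the neutral
default). Hyperparameters are tuned by full grid search on CV AUC with
ties broken toward the cheaper model; the default grid (depth 2-10,
trees {10, 25, ..., 250}) covers the tuned optima this design emulates
(depth 2-10, trees 13-245).

### Consensus screening

A compound is a hit iff *every* panel model's active probability is
**strictly** greater than 0.9 ("higher than 0.9" read as strict; the
boundary case is tested). The library streams in chunks
(`chunk_size`, default 250,000) with output provably invariant to the
chunking. Hits — and only hits — are annotated with their maximal
Tanimoto similarity (intersection over union of on-bits, 0 when neither
has an on-bit) to the training actives over binary columns only, ties
to the first active in row order. Strict unanimity is precision-first:
at moderate class separation (generator effect size 2) panel recall of
planted actives plateaus near 0.7 because borderline actives rarely get
more than 90% of bootstrap trees in every model, while the false-hit
rate stays at or below ~0.2%; recall crosses 0.8 once classes separate
clearly (effect ≥ ~2.5). Tests assert exactly that shape.

## The synthetic-data generator

The generator emulates the statistical skeleton of the original data,
not its chemistry: no SMILES, no descriptor distributions. Defaults are
the stated world of the source design:

| knob | default | why |
|---|---|---|
| n_active / n_inactive | 266 / 136 | the pooled actives vs decoys composition (N = 402, 66.17% active) |
| frac_binary | 0.46 | fingerprint bits were 1,354 of 2,798 original columns |
| effect_size | 1.0 | standardized shift for continuous columns; binary bits get a Bernoulli gap min(0.2 e, 0.6) on a 0.3 base rate |
| redundancy_noise | 0.01 | per-entry corruption when cloning a source column |
| IC50 for actives | log-uniform on [0.05, 11.4] uM | all five canonical cutoffs partition the actives nontrivially; decoys carry no IC50 |
| column counts | 20 inf / 10 red / 10 zv / 60 noise | a desk-scale stand-in for the 2,798-column matrix |

Each column block (layout, informative, redundant, zero-variance,
noise, IC50) draws from its own derived seed, so enlarging one block
never perturbs another. Redundant columns clone *continuous*
informative sources (see the tau-a blindness note above). A green test
on this generator establishes that the pipeline recovers planted
statistical structure; it says nothing about descriptor chemistry,
DUD-E property matching (the decoy selection protocol is not described
in the source and is not modeled), or the identity of any real hit.

Two calibration facts constrain what tests may demand. At the capped
binary gap, fingerprint-bit informativeness is deliberately weak
(phi ≈ 0.19 at effect 1), so subset-recovery checks that require >= 80%
of informative columns are run in the continuous-descriptor world
(frac_binary = 0), where recovery is complete; in mixed worlds CFS
merit saturation caps recovery near 0.7 regardless of search effort.
And the Monte-Carlo acceptance worlds are instantiated once at
effect 1.25 (recovery/ranking checks), 1.5 (singleton recovery) and
3.0 (separable-classification checks), inside the regimes the checks
state.

## Numerical choices and degenerate inputs

* Kendall tau-a demands n >= 2 and equal lengths; the matrix kernel
  returns a unit diagonal.
* Merit of an empty subset is an error everywhere; stochastic searchers
  repair empty bitstrings to random singletons (PSO keeps the previous
  position instead, so a w1 = 1 swarm is exactly frozen).
* Constant columns: correlation 0, normalized to 0, removed by the
  default variance filter.
* `hit_rate()` reports percent to 3 significant figures (0.000713% for
  46 of 6,447,184).
* k = n cross-validation degenerates to leave-one-out; fold counts
  above n are errors.
* All randomness flows through explicit seeds; every stochastic stage
  is a pure function of (inputs, config-with-seed), and reruns are
  byte-identical (tested via serialization digests).

## Known limitations

* Descriptor/fingerprint *generation* is out of scope; the package
  consumes precomputed tables.
* The DT pruning is cost-complexity, not MDL; the source's pre-pruning
  parameters were never published.
* Merit values, selected-feature counts and AUC/MCC heat-maps of the
  original study depend on its proprietary descriptor matrix and are
  not numeric targets here; only its arithmetic identities (dataset
  composition, library totals, hit rate, reduction ratios) are
  reproduced exactly.
* ADME prediction, PCA visualization and docking are out of scope.
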