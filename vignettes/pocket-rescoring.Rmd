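---
title: "Rescoring geometric pocket candidates with an E(3)-invariant graph transformer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rescoring geometric pocket candidates with an E(3)-invariant graph transformer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Geometric pocket detectors such as Fpocket find concave patches of a
protein surface with high recall: the true ligand binding site is almost
always among the candidates, but so are many false positives. `pocketgt`
implements the second half of a hybrid pipeline: each candidate pocket is
converted into a small residue graph and a learned classifier assigns it a
probability of being a true binding site, so the candidates can be
re-ranked.

## From structure to pocket graph

For each candidate (a set of alpha-sphere center coordinates), the
pipeline:

1. strips waters and bound ligands from the structure
   (`strip_for_detection()`);
2. selects every residue whose C-alpha lies within **10 Å** of *any*
   pocket vertex (boundary inclusive);
3. builds a graph with one node per selected residue and an undirected
   edge between every C-alpha pair within **25 Å** (inclusive);
4. attaches node features — the amino-acid identity (21-way one-hot: 20
   standard residues plus an unknown token) and the residue's
   solvent-accessible surface area (SASA) — and edge features, a radial
   basis expansion of the C-alpha pair distance.

Truth labels for training come from the DCA criterion: the minimum
Euclidean distance from the pocket's vertex barycenter to any atom of any
bound ligand. A pocket is *true* iff DCA < 4 Å, strictly: a DCA of
exactly 4 Å labels false. When a structure carries several ligands the
minimum over all of them is used.

SASA is computed by the Shrake–Rupley method (1.4 Å probe, ≥ 100
deterministic golden-spiral sphere points per atom, heavy atoms only,
ligands and waters excluded). The method itself is unambiguous; the only
numerical freedom is the sphere-point count, which enters as an O(1/n)
discretization error — doubling the count changes per-residue values by
well under 2% on our fixtures, and rigid-motion invariance holds to < 1%.

Both continuous inputs are embedded with radial basis functions
`exp(-γ (x − μ_k)²)`: SASA with centers equally spaced on 0–350 Å²
(350 Å² is the practical upper end of per-residue SASA), distances with
centers on 3–25 Å. The widths default to `γ = 1/(2Δ²)` with `Δ` the
center spacing — the standard smooth-overlap choice; the source
literature fixes only the center ranges, so the width is a package
decision.

## The model

The classifier is a stack of `L` graph transformer layers of hidden width
`d`. Node inputs are embedded as `f⁰ = E^aa · aa(v)`, and, when SASA is
enabled, the SASA RBF block is concatenated and mapped back to width `d`
by a learned linear projection (the concatenation has width `2d`, which
the layers cannot consume directly). Each layer computes, per head `h`
and per *existing edge* `(i, j)` only:

* query/key/value projections `q_i, k_j, v_j` and an edge projection
  `b_ij` of the distance RBF;
* an attention logit that is the **elementwise triple product** summed
  over the head dimension, `z_ij = (1/√d_h) Σ_c q_ic · k_jc · b_ijc` —
  not a dot product plus bias; with an all-ones edge vector it reduces to
  the familiar scaled dot product;
* a softmax over each node's neighbor set, after clamping the logits to
  `[-5, 5]`. (Clamping the softmax *output*, which lies in (0, 1), would
  be a no-op; clamping the logits is the only reading that stabilizes
  anything, and since all logits then lie in a bounded range the softmax
  needs no max-subtraction either.)
* the attention-weighted value sum, head concatenation, output
  projection, dropout, residual connection and layer normalization,
  followed by a feed-forward block (Linear–ReLU–dropout–Linear) with its
  own residual and normalization.

Edge features are read by every layer but never updated. A node with no
neighbors receives a zero attention output (the empty softmax is
undefined; the residual path keeps the node alive). After `L` layers the
node features are **sum-pooled** and a two-layer ReLU MLP plus sigmoid
yields the score; training minimizes binary cross-entropy, computed from
the pre-sigmoid logit in log-sum-exp form so it is finite for any
parameters.

Because coordinates enter only through pairwise distances (and SASA,
itself rigid-motion invariant), the score is exactly invariant under all
of E(3) — rotations, translations and reflections. The test suite checks
this to 10⁻⁴ over random rigid motions, and checks the sparse
edge-restricted attention against a dense masked-attention reference
implementation to 10⁻⁵.

Unstated architecture details were fixed as follows: 8 heads (divides
both 128 and 256), feed-forward hidden width `2d`, head MLP `d → d → 1`,
dropout 0.1, per-node layer normalization, uniform fan-in initialization.
With `L = 8, d = 128` these choices give 1.244 M trainable parameters,
and 7.318 M for `L = 12, d = 256` — both within a few percent of the
published ~1.28 M and ~7.34 M sizes, which is the tolerance those
figures allow given the unstated details.

Forward and reverse passes are written out explicitly (R plus a small
C++ kernel for the per-edge message passing); the analytic gradients are
verified against central finite differences to a relative error below
10⁻³. Mini-batches are packed into one disjoint block-graph so the whole
batch runs through the same layer code.

## Training recipe

Candidate sets are heavily imbalanced (typically ~7% positives), and two
measures address this:

* **Label balancing** — every epoch contains each false-label pocket
  once, plus true-label pockets resampled uniformly with replacement up
  to the false count.
* **Noise augmentation** — repeated positives invite overfitting, so
  every training graph is perturbed on the fly: bootstrap node
  resampling (`round((1 − σ_node) N)` draws with replacement,
  σ_node = 0.03), additive Gaussian positional noise (σ_pos = 0.5 Å) and
  multiplicative Gaussian SASA noise (σ_SASA = 0.3, floored at 0). Edges
  and distance features are rebuilt from the noised coordinates so the
  graph stays self-consistent. Noise is redrawn every epoch.

Validation and test data are never balanced or augmented.

Optimization is Adam with an epoch-level schedule: linear warm-up over 25
epochs to a maximum learning rate of 2×10⁻⁴, then half-cosine decay to 0
(300 epochs and batch size 128 by default). After each epoch the
validation partition is scored and the parameters with the highest
validation PR-AUC are kept (ties keep the earlier epoch). The full
procedure is a 5-fold cross-validation at pocket level; predictions are
the arithmetic mean of the five fold models' sigmoid outputs, ranked per
protein with ties broken by pocket identifier.

Metrics: PR-AUC (step-wise interpolation over all thresholds — the
average-precision form), ROC-AUC (rank statistic, ties half-credited) and
the Top-(n+i) success rate — for a protein with `n` ligands, a ligand
counts as hit when some pocket ranked in the top `n+i` lies within 4 Å
DCA of it (strict inequality, matching the labeling rule); the rate
aggregates per ligand over the dataset.

## The synthetic fixture generator

Training the published model needs curated structure databases and
GPU-scale compute, so the package ships a generator of protein-like
fixtures that makes the full pipeline testable offline:

* chains are self-avoiding random walks of C-alpha positions (3.8 Å
  steps, ≥ 3.5 Å clearance) decorated with 1–4 pseudo side-chain atoms;
* pockets are planted at surface loci as 5–20 vertices in a 3 Å ball;
  a positive pocket gets a 5–15 atom ligand whose nearest atom sits at a
  uniform 0.5–3.5 Å from the vertex barycenter (DCA < 4 by
  construction), a negative pocket keeps every ligand > 4.5 Å away;
* the learnable signal is lining composition: residues within 10 Å of a
  positive pocket's vertices are drawn from a six-residue "binding"
  palette (Trp, Tyr, Phe, His, Met, Cys) with probability
  `signal_strength`, while the background palette is all 20 amino acids
  — so negatives carry the binding residues at a ~30% base rate, as a
  real background composition would, and the classes are separated by
  enrichment rather than by a forbidden alphabet. Opposite-label pocket
  loci are kept ≥ 26 Å apart so their linings cannot share residues;
  without that, shared residues would contaminate the composition signal
  that the generator exists to plant. Same-label overlap is harmless and
  allowed.
* a protein that happens to receive no positive pocket gets one decoy
  ligand far outside all pockets, so DCA labels remain computable (and
  false) everywhere.

What the generator does *not* emulate: real fold geometry, side-chain
chemistry, conserved sequence context, and any correlation between SASA
and the label. Passing tests on these fixtures therefore demonstrates
that the pipeline's plumbing, features, invariances and training dynamics
behave as specified — not that the shipped code reaches the published
accuracy on real structures, which would require the original training
databases.

The training-sanity check uses 600 pockets (100 proteins × 6 candidates)
at 7% positives and `signal_strength = 0.9`, a reduced model
(`d = 32, L = 2`) and 50 epochs; balanced-plus-noise training should
reach held-out PR-AUC ≥ 0.9 while plain unbalanced training on the same
data stays lower — the qualitative ordering that motivates the recipe.
Because each validation part holds only on the order of ten positives,
the PR-AUC of a single fold is coarse (one swapped rank moves it by
~0.1); the check therefore averages the best validation PR-AUC over
three of the five cross-validation folds, the same averaging-over-folds
protocol used for ensemble reporting. These problem sizes keep the whole
check to a few minutes on one CPU while leaving the class imbalance
severe enough for balancing to matter.

## Degenerate inputs and numerical corner cases

* Residues without a C-alpha are kept in the atom table but cannot become
  nodes; candidates whose 10 Å neighborhood selects no residue raise an
  empty-pocket error and are dropped (with a warning) by the featurizer.
* Alternate locations resolve to the highest occupancy, ties to file
  order; insertion codes are folded into the residue key.
* Missing SASA for a node (non-standard residue) becomes 0 Å² with a
  warning.
* Bootstrap node resampling can duplicate nodes; duplicates are distinct
  node identities and a duplicated pair at distance 0 is connected by a
  zero-length edge. A resample count below 1 clamps to 1 with a warning.
* All randomness flows through R's RNG; a fixed seed reproduces datasets
  bitwise and training checkpoints exactly (single-threaded).

## Known limitations

* PDB only (no mmCIF), first model by default, no symmetry expansion or
  hydrogen handling.
* The built-in cavity detector is deliberately simple grid plumbing for
  when Fpocket output is unavailable; it flags buried voids and makes no
  claim of equivalence to alpha-sphere detection.
* The parameter counts above depend on head count, FFN width and head-MLP
  shape, which the source description leaves open; they are reproduced to
  within the tolerance that ambiguity implies, not exactly.
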