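---
title: "ABT-MPNN: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ABT-MPNN: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, the numerical choices,
and the places where the design was genuinely open.

## The model

`abtmpnn` predicts molecular properties from SMILES with a directed
message-passing neural network augmented by two attention mechanisms.

A molecule is a graph over heavy atoms; hydrogens are implicit and folded
into an attached-H-count feature. Every chemical bond contributes **two
directed bonds**, each with its own hidden state. The message for bond
(v → w) sums the hidden states of bonds arriving at v but **excludes the
reverse bond** (w → v), so information never bounces straight back — the
core idea of directed message passing, which removes the immediate
back-and-forth loops of atom-centred MPNNs.

Two attention blocks extend this scheme:

1. **Bond attention** (inside every one of the T message-passing
   iterations) is an additive, global-context block in the Fastformer
   style. Query, key and value all equal the incoming bond message matrix.
   Per head, softmax-normalized additive weights pool a single *global
   query*, which modulates every key by an element-wise product; a second
   additive pooling gives a *global key*, which modulates every value.
   The pooled interactions are concatenated over heads, linearly
   transformed, added to the queries through a skip connection and layer
   normalized. Cost is linear in the number of bonds, which is why it is
   affordable inside each of the T iterations.
2. **Atom attention** (once, after aggregation to atoms) is standard
   multi-head scaled dot-product self-attention with one modification:
   each head receives one molecule-level M × M matrix as an additive bias
   on its pre-softmax logits, softmax(Q Kᵀ/√d_head + B). Heads 1–2 use
   the bond adjacency matrix, heads 3–4 the 3D inter-atomic distance
   matrix, heads 5–6 the Coulomb matrix (diagonal 0.5 Z^2.4, off-diagonal
   Z_i Z_j/|R_i − R_j|). Both heads of a pair receive the same matrix and
   differ only in their learned projections. The biases inject
   connectivity, geometry and electrostatics into an otherwise purely
   learned attention, at zero parameter cost.

Readout sums the attended atom states into one molecule vector,
concatenates a 200-entry descriptor vector and applies a two-layer
feed-forward network. Classification applies the sigmoid outside the
model; regression is trained on Z-scored targets and un-scaled for
metrics.

Assumptions worth stating: single largest organic fragment only (salts
and mixtures are reduced with a warning); chirality and bond stereo are
carried as feature slots but not perceived (always "none"); the valence
model covers H, B, C, N, O, F, Si, P, S and halogens — other elements get
zero implicit hydrogens and fall into the "other" one-hot slots.

## Tunable parameters

| Parameter | Meaning | Default | Search space |
|---|---|---|---|
| `T` | message-passing iterations | 3 | 2, 3, 4, 5, 6 |
| `d` | hidden dimension | 300 | 300–2400, step 100 |
| `lambda` | inter-atomic bias scale (unitless) | 0.1 | 0–0.5, step 0.05 |
| `dropout` | dropout probability | 0 | 0–0.4, step 0.05 |

`lambda` multiplies each Z-score-normalized bias matrix; 0 disables the
biases exactly (the package tests that the block then equals plain
multi-head attention). `d` must be divisible by the number of heads (6),
so examples in this package use 66 rather than 64. The Bayesian search
(`bayesianHyperopt`) is a Gaussian-process surrogate with an RBF kernel
(length scale 0.3 on the unit-normalized grid, nugget 1e-4) maximizing
expected improvement, with the conventional budget of 20 evaluations of
30-epoch trainings. Optimization uses Adam with either a constant rate or
a warmup/exponential-decay schedule (1e-4 → 1e-3 over two epochs, then
decay back to 1e-4).

The seven-member ablation family — no attention, Transformer or
Fastformer bond attention alone, atom attention with or without
inter-atomic biases, and the combinations — is fully expressible through
`abtModel(bondAttention=, atomAttention=, atomBias=)`.

## Synthetic data: what it does and does not emulate

`makeCorpus()` enumerates 1–12-heavy-atom molecules (alkanes, alcohols,
amines, halides, ethers, carbonyls, thioethers, simple aromatics and
rings) from valence-safe templates, canonicalizes and de-duplicates them,
and draws a seeded sample; the first four slots always cover the
structural edge cases (a zero-bond molecule, a linear chain, a branch
point, an aromatic ring). Targets are pure functions of the molecule
(heavy-atom count, heteroatom fraction, ring count, or SMARTS
substructure presence) plus optional seeded Gaussian noise or label
flips.

This establishes that the implementation can *learn a known signal
end-to-end* — the overfitting checks drive training RMSE below 0.1 atoms
on 32 molecules and AUROC above 0.95 on the hydroxyl task with 64
molecules, sizes chosen so the whole suite runs in minutes on one CPU.
It does **not** emulate real assay data: no activity cliffs, no scaffold
imbalance, no label noise structure, no molecules beyond 12 heavy atoms,
and no train/test distribution shift. Passing these tests therefore
demonstrates correctness of the machinery, not predictive performance on
screening libraries.

## Numerical choices

* **Conformers.** 3D coordinates come from a deterministic
  distance-geometry embedding written in this package: classical MDS of
  the topological distance matrix scaled by covalent-radius bond lengths,
  followed by 400 gradient-descent steps on a harmonic pseudo-force-field
  (bond terms, 1–3 angle terms from the central atom's hybridization, a
  2.4 Å repulsion floor for distant pairs). A seeded 0.05 Å jitter breaks
  planar degeneracy, so the same seed always yields the same coordinates.
  This produces chemically plausible geometry (C–C ≈ 1.52 Å) rather than
  refined conformers; since every bias matrix is Z-score normalized per
  molecule, the attention sees relative, not absolute, geometry. If the
  embedding ever fails, the topological bond-count matrix stands in for
  the distance matrix and the molecule is flagged.
* **Per-molecule normalization.** Bias matrices are Z-scored over all M²
  entries of that molecule's matrix (population standard deviation; a
  constant matrix maps to zero). Dataset-level statistics would leak
  split information and mix molecules of different sizes.
* **Descriptors.** The 200-descriptor registry combines OpenBabel
  physicochemical properties, composition/topology counts, ring
  statistics, functional-group counts, Moreau–Broto-style topological
  autocorrelations and typed atom-pair counts. Non-finite values are
  imputed to 0; normalization statistics come from the training split
  only. Regression targets are likewise Z-scored on the training split.
* **Initialization and determinism.** Weights are Glorot-uniform from a
  user seed; shuffling, dropout and noise all derive from the training
  seed, so two runs with the same seed are bit-identical. Linear maps
  W_i and W_h carry no additive bias; W_o, the attention output
  projections and the FFN do.
* **Degenerate inputs.** Zero-bond molecules skip message passing and
  bond attention entirely (the atom stage receives a zero bond sum);
  single-atom attention maps are the 1 × 1 identity; softmax uses
  max-subtraction; layer normalization uses eps = 1e-5.
* **Metrics.** AUROC is the Mann–Whitney rank statistic with midrank
  ties; AUPRC is step-function average precision with a stable
  descending-score sort. Multi-task scores are unweighted means over
  tasks with at least one valid target; one-class AUROC/AUPRC tasks are
  skipped with a warning. Missing targets are masked out of the loss, and
  a test verifies that masking one task leaves the other tasks' gradients
  unchanged.
* **Scaffold split.** Bemis–Murcko frameworks are obtained by iteratively
  pruning degree-1 atoms (acyclic molecules share the empty scaffold) and
  canonicalized; groups are sorted by size descending with the scaffold
  string as tie-break, then fill train, validation, test in that order —
  fully deterministic.

## Open design choices

* **Aggregation direction.** The algorithmic statement sums the bond
  hidden states *originating* at an atom, while a figure-level reading
  suggests *incoming* states. The outgoing form is the default;
  `abtModel(aggregate = "incoming")` selects the variant. For symmetric
  reverse-pair structures the two differ only in which member of each
  pair is summed.
* **Bond attention projections.** Query, key and value are set equal to
  the input bond messages (no Q/K/V projections), with per-head additive
  score vectors and one shared post-concatenation linear transform +
  layer normalization. This is the leanest reading consistent with the
  additive-attention design; it keeps the block strictly linear in bond
  count.
* **Distance semantics.** "Distance" is 3D Euclidean from the embedded
  conformer by default; `featurizeMolecule(distanceKind =
  "topological")` switches to graph distances, which is also the
  automatic fallback.
* **Attention-to-atom collapse.** An M × M map is collapsed to per-atom
  weights by the column mean (attention *received*), centered by 1/M so
  uniform attention gives exactly zero everywhere; the row-mean
  (attention *paid*) alternative is exposed via
  `atomContributions(mode = "row")`. Negative values arise from
  centering, since softmax outputs are nonnegative.
* **Cross-validation.** `trainCV` defaults to k independent seeded
  80:10:10 re-partitions; `scheme = "kfold"` gives rotating folds where
  every index is tested exactly once.
* **Dropout placement** follows common practice: after each ReLU in the
  bond update, atom aggregation and FFN hidden layer, and on attention
  maps and block outputs.

## Known limitations

* The network runs on dense per-molecule matrices in plain R; it is
  sized for method development and small corpora (tens to thousands of
  small molecules), not for GPU-scale screening.
* No stereochemistry, no reactions or multi-fragment inputs, no
  pretraining, no 3D-equivariant message passing.
* The conformer embedder targets plausibility, not energy minimization;
  torsional preferences are not modeled.
* The 200-descriptor registry is this package's own fixed set; models
  trained here are not feature-compatible with descriptor sets from
  other toolkits.
* Attention visualization is descriptive, not causal: a highlighted atom
  receives attention weight, which is not evidence of mechanistic
  importance.
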