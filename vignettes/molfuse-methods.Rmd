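---
title: "Methods: untrained graph-branch fusion with a BiLSTM classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: untrained graph-branch fusion with a BiLSTM classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

molfuse classifies binary molecular properties from SMILES strings. The
central idea is to separate representation from learning: three graph
neural network branches with *frozen, randomly initialised* weights act as
fixed nonlinear projections of the molecular graph, and only a downstream
bidirectional LSTM classifier is trained. Because the branches are never
trained, featurization is a single forward pass per molecule —
deterministic, cheap, and reproducible bit for bit from a seed.

A molecule is encoded as $M = \{A, X, E\}$: a symmetric binary heavy-atom
adjacency matrix $A \in \{0,1\}^{N \times N}$ with zero diagonal, an atom
feature matrix $X \in \mathbb{R}^{N \times d}$ of one-hot blocks (element,
formal charge, hybridization, heavy-atom degree, plus an aromaticity bit;
$d = 27$ under the default schema), and a map $E$ from bonded atom pairs to
bond feature vectors (order one-hot, conjugation, ring membership).

The three branches, each two layers wide (64 then 32):

* **Convolutional branch.** With $\hat A = D^{-1/2}(A + I)D^{-1/2}$ the
  symmetrically normalised adjacency, the forward pass is
  $H_1 = \mathrm{ReLU}(\hat A X W_1)$, $H_2 = \mathrm{ReLU}(\hat A H_1 W_2)$.
  No bias is used. The inter-layer ReLU is required: without it the two
  frozen linear layers would collapse into one linear map and the second
  layer would add nothing.
* **Isomorphism branch.** Sum aggregation with a weighted self term,
  $m_i = (1+\varepsilon)x_i + \sum_{j \in N(i)} x_j$, followed by a
  two-layer affine MLP with ReLU. $\varepsilon$ is fixed at 0 — it is
  normally learnable, but nothing in the branches is trained here.
* **Attention branch.** Per head $k$, scores
  $e_{ij} = \mathrm{LeakyReLU}(a^{(k)\top}[W^{(k)}x_i \| W^{(k)}x_j])$
  (slope 0.2, the canonical choice) are softmax-normalised over each node's
  neighborhood to coefficients $\alpha^{(k)}_{ij}$, and node features are
  updated as $\sum_j \alpha^{(k)}_{ij} W^{(k)} x_j$. Layer 1 concatenates
  8 heads of width 8 (ReLU applied per head); layer 2 runs 8 heads of
  width 32 and *averages* them before the ReLU, mirroring the standard
  output-layer convention for multi-head attention. Self-loops are included
  in the neighborhoods by default so the softmax is defined for every node;
  with self-loops disabled, an isolated node gets an all-zero attention row
  and its output falls back to its own projected features.

Mean pooling reduces node features to one 32-vector per branch (sum and max
are selectable; mean is the default for its scale stability across molecule
sizes), and the branch vectors are concatenated in the fixed order
GIN ‖ GCN ‖ GAT into a 96-wide fused descriptor. Ablation modes select any
non-empty subset of branches; the width is 32 per selected branch.

All branch parameters are Glorot-uniform draws from a seeded generator.
The distribution is a deliberate design choice — for untrained projections
the field default is Glorot scaling, which keeps activations in a usable
range across layer widths. Weights are created once and never mutated; the
test suite asserts the frozen-weight law (identical parameters before and
after featurizing 1,000 molecules, bitwise-identical feature matrices
across reruns with one seed).

## Edge features and their (non-)use

$E$ is constructed and exposed but not consumed by the three branch
forwards: the implemented update rules act on $A$ and $X$ alone. Storing
bond features anyway keeps the graph container complete and leaves room for
edge-aware extensions without changing the data model.

## The classifier

The fused descriptors feed a stacked bidirectional LSTM: 128 units per
direction, then 64, dropout 0.4 after each recurrent layer, and a sigmoid
head; Adam (learning rate 0.0005), binary cross-entropy, batch size 64, up
to 250 epochs. Each sample is a length-1 sequence (`timesteps = 1`): the
descriptor is not a time series, so both directions see the same single
step. A configuration option reshapes the 96-vector into a length-3
sequence of 32-wide branch blocks for experimentation; it is off by
default.

With one timestep the recurrent weights multiply a zero state and can never
influence the output or receive gradient, so the trainer drops them and
folds each gate bias into the weight matrix (a ones-column trick); the
general backpropagation-through-time path is used for `timesteps > 1`.
Both paths are validated against finite-difference gradients, and the cell
itself against a scalar evaluation of the gate equations.

Training choices worth noting:

* Forget-gate biases initialise to 1 (standard practice; irrelevant at one
  timestep, where the forget gate meets an empty cell state, but kept for
  the sequence mode).
* Features are z-scored with training-set statistics by default. The
  untrained branches produce coordinates on very different scales, and
  saturating gates benefit from standardised input.
* Early stopping watches validation ROC-AUC with patience 20 and restores
  the best epoch's weights; histories retain every epoch, and reports show
  the restored (best-epoch) model's metrics.
* The full metric suite — binary cross-entropy, ROC-AUC, PRC-AUC, recall
  and zero-one loss at threshold 0.5 — is recorded on the training and
  validation sets at every epoch.
* Dropout applies only during training (inverted dropout, seeded);
  inference is deterministic. The branch configuration also lists dropout
  rates, but a deterministic feature extractor gains nothing from
  stochastic masking, so the branch forwards apply none.

## Metrics

ROC-AUC is the Mann–Whitney pairwise statistic computed from average ranks,
so tied scores receive half credit — this makes the brute-force pair-count
oracle exact. PRC-AUC is average precision (step interpolation), chosen
over trapezoidal interpolation because the latter is optimistically biased
on precision–recall curves. Recall and zero-one loss threshold at 0.5.

## Augmentation

One molecule admits many valid SMILES renderings; enumeration augmentation
adds renderings as extra training rows without changing chemistry. The
package parses each molecule with Open Babel, rewrites it along seeded
random depth-first atom orders (Kekulé notation, stereo annotations
dropped — stereo-aware augmentation is out of scope), and keeps a candidate
only if Open Babel canonicalization maps it back to its parent molecule.
Duplicate control is strict: no two records in the augmented corpus may
share a raw SMILES string, and variants equal to the parent's canonical
form are discarded. Labels and fold assignments are inherited from the
parent. Up to 10 × factor renderings are attempted per molecule before
accepting fewer — small or highly symmetric molecules (methane being the
extreme case) exhaust their rendering space.

The train/test split (default 70:30) keeps each parent and all of its
variants on one side (`group_by_parent = TRUE`). The source protocol is
silent on this point; grouping is the defensible default because split
variants of one molecule are near-duplicates and would leak label
information. A flag disables grouping for strict replication experiments.
K-fold labels (`assign_folds`, round-robin after a seeded shuffle, sizes
within one of each other) are provided alongside the single split; both
modes exist because published protocols mention both, and neither is
asserted to be canonical.

## Synthetic data

`synthetic_dataset()` generates valence-valid molecules by random tree
growth with per-element valence bookkeeping (C:4, N:3, O:2, S:2,
halogens:1) and optional ring closure between non-adjacent atoms with free
valence. Defaults: 8–26 heavy atoms (the size range of typical screening
benchmarks), a carbon-dominated element distribution, ring probability
0.3, labels from the contains-nitrogen predicate, 10% label noise, target
prevalence 0.5 enforced by per-class quotas during generation (the corpus
is shuffled afterwards so record order carries no label information). All
bonds are single; the generator emulates the size, composition and
structure-label dependence of benchmark data, not aromatic systems, charge
states, drug-likeness or realistic property distributions — so a passing
end-to-end test demonstrates signal recovery through the pipeline, not
benchmark-level chemistry.

Label rules are cheap structural predicates (nitrogen presence, ring
presence, aromatic ring, heavy-atom count, halogen presence) so tests can
compute ground truth without the pipeline. Noise flips each label
independently; at noise 0.5 the labels are independent of structure and the
pipeline must score at chance, which the test suite asserts.

## Problem sizes and numerical choices

The end-to-end checks run 2,000 molecules with fivefold augmentation
(12,000 records), 50 training epochs, and three seeds on a shared corpus;
the ablation harness runs all seven branch subsets on 500 molecules at 15
epochs. These sizes give stable statistics (validation AUC varies by only
a few hundredths across seeds) while keeping a full run in minutes on one
CPU. Oracle-equivalence checks use graphs of at most 10 nodes where
explicit-loop reference implementations are fast and exact; forward passes
agree with them to 1e-6, attention rows to 1e-8, the LSTM cell to 1e-8.
Softmaxes subtract the row maximum before exponentiation; the binary
cross-entropy clips probabilities to [1e-7, 1 - 1e-7].

## Chemistry backend

Parsing, canonicalization and perception go through Open Babel
(ChemmineOB/ChemmineR). Atom typing comes from MOL2 output: SYBYL types
supply hybridization (sp/sp2/sp3 via the type suffix; planar types count as
sp2) and aromaticity; formal charges come from the MOL2 atom-attribute
records; ring membership of bonds is computed by bridge detection (a bond
is in a ring iff it is not a bridge). A bond is encoded aromatic only when
both of its atoms are aromatic — Open Babel also marks resonance systems
such as carboxylates with "ar" bond records, which are folded back to
single bonds with the conjugation flag set. The 256-atom default cap on
molecule size bounds the dense adjacency representation; larger molecules
are rejected with a warning naming the record.

## Known limitations

* Stereochemistry is not preserved through augmentation, and molecule
  identity checks ignore it.
* The branch forwards ignore bond features; $E$ is carried, not consumed.
* Training reproducibility is run-level (same seed, same machine, same
  BLAS); exact bitwise agreement across numeric backends is not promised.
* The synthetic generator produces uncharged, non-aromatic, single-bonded
  molecules; aromatic perception paths are exercised by real SMILES in the
  unit tests instead.
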