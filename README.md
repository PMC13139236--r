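# molfuse

Binary molecular property classification from SMILES, built around one
idea: **untrained graph neural networks as fixed feature extractors**.
Three parallel graph branches with frozen, seeded random weights — a graph
convolutional network (GCN), a graph attention network (GAT) and a graph
isomorphism network (GIN) — each project a molecular graph to a 32-wide
descriptor in a single forward pass. The three descriptors are fused by
concatenation (96-wide) and only a downstream bidirectional LSTM classifier
is trained. The package is aimed at cheminformatics practitioners who want
cheap, reproducible molecular descriptors with a trainable head, and a
testbed for comparing the three graph-branch families and their
combinations on binary tasks (MoleculeNet-style CSVs or synthetic corpora).

## The method in brief

A molecule is the triple `M = {A, X, E}`: symmetric heavy-atom adjacency
`A`, one-hot atom features `X` (element, formal charge, hybridization,
degree, aromaticity; width 27 by default), and bond features `E`. The
branches compute, with frozen Glorot-initialised weights:

- GCN: `H₂ = ReLU(Â ReLU(Â X W₁) W₂)` with `Â = D^{-1/2}(A+I)D^{-1/2}`
- GIN: `H₂ = MLP((1+ε)·x_i + Σ_{j∈N(i)} x_j)`, ε = 0, two-layer MLP
- GAT: 8 attention heads per layer; `α_ij = softmax_j LeakyReLU(aᵀ[Wx_i ∥ Wx_j])`,
  heads concatenated in layer 1, averaged in layer 2

Mean pooling gives one vector per branch; fusion concatenates them in the
fixed order GIN ∥ GCN ∥ GAT. The classifier is a stacked BiLSTM
(128 → 64 units per direction, dropout 0.4, sigmoid head, Adam at 5e-4,
binary cross-entropy, batch 64, timesteps = 1), trained with early stopping
on validation ROC-AUC. Datasets are expanded beforehand by seeded SMILES
enumeration augmentation (default fivefold) with strict duplicate control,
and split 70:30 with parent grouping so variants never straddle the split.

## Worked example

Generate a labelled synthetic corpus (contains-nitrogen rule, 10% label
noise), augment it, extract fused features and train the classifier:

```r
library(molfuse)

spec <- synthetic_spec(n_molecules = 300, label_noise = 0.1, seed = 7)
recs <- synthetic_dataset(spec)
aug  <- augment_dataset(recs, factor = 5, seed = 8)
nrow(aug)
#> [1] 1800

graphs <- graphs_from_smiles(aug$smiles, ids = aug$record_id)
w <- init_branch_weights(atom_feature_schema()$d_atom, seed = 9)
feats <- extract_features(graphs, w)          # 1800 x 96, deterministic
sp <- split_train_test(aug, 0.7, seed = 10, group_by_parent = TRUE)
tr <- match(sp$train$record_id, rownames(feats))
te <- match(sp$test$record_id, rownames(feats))

model <- train_bilstm(feats[tr, ], sp$train$label,
                      classifier_config(epochs = 30, seed = 11),
                      feats[te, ], sp$test$label)
round(unlist(evaluate_scores(predict(model, feats[te, ]),
                             sp$test$label)), 3)
#>          loss       roc_auc       prc_auc        recall zero_one_loss
#>         0.581         0.808         0.859         0.702         0.244
```

The held-out ROC-AUC of ~0.81 on this deliberately small corpus rises to
~0.90 at the 2,000-molecule study size used by the acceptance script —
close to the ceiling that 10% label noise permits. Recall and zero-one
loss are read at the 0.5 threshold. `run_pipeline(run_config(...))`
wraps the same flow and writes the augmented corpus, feature matrix, model
checkpoint, per-epoch history and a seed manifest to an output directory,
and `run_ablation()` repeats training for any subset of branches at
identical classifier settings (feature width is 32 per branch).

A thin command-line interface over these functions ships in
`inst/scripts/molfuse` (subcommands `synth`, `augment`, `run`, `ablate`).

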