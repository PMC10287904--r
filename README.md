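# hybridDTA

Drug–target binding-affinity (DTA) regression with a node-adaptive hybrid
graph neural network, for computational chemists and method developers who
want a structure-aware DTA model that runs, trains and explains itself on a
single CPU.

## The method

Given a drug SMILES and a protein sequence, the model predicts a
real-valued affinity (pKd-like) through two cooperating branches:

**Sequence branch (feature generator).** An atomic-level tokenizer maps
every heavy atom (and residue) to exactly one token position — `Cl`, `Br`
and bracket atoms are never split — so encoder outputs are addressable per
atom. Two independent bidirectional recurrent encoders produce per-token
embeddings h; multi-head *linear attention* pools them per molecule
(weights `softmax(w·h_i / d_K)` over positions), and a joint attention over
the concatenated drug+protein positions yields the interaction pool O_con.
A dense head on concat(O_d, O_p, O_con) predicts affinity.

**Graph branch (hybrid GIN).** The drug bond graph G_d and the protein
contact map G_p (distances < 8 Å) become diagonal blocks of one hybrid
adjacency with a single central node adjacent to every atom and residue —
the only bridge between the molecules:

    G_H' = [ G_p  0   1 ]
           [ 0   G_d  1 ]
           [ 1    1   0 ]

Node features are the generator's token embeddings, gathered by the
token↔node maps, row-wise layer normalized, with the central node set to
the mean of the two [CLS] embeddings. A multilayer GIN
(`h_v' = MLP((1+ε)h_v + Σ_{j∈N(v)} h_j)`) with central+mean readout
predicts affinity from structure.

**Adaptive training.** The generator is pre-trained on sequences alone,
then its normalized node features are transferred to the GIN at fixed
epoch intervals while both branches train jointly on the ensembled
prediction (a trained sigmoid gate combines the branches). Cold-start
splits (unseen drugs, unseen targets, or both), concordance index and rm2
metrics, and attention-based per-residue/per-atom explanations are
included, plus a synthetic benchmark generator with a planted
structure–activity rule so everything is testable offline.

## Worked example

```r
library(hybridDTA)

# a small planted-rule benchmark: affinity = 5 + 0.8*motif + 0.8*fragment
#                                + 1.2*(motif & fragment) + N(0, 0.3)
data <- generate_dataset(synthetic_spec(n_records = 600, n_drugs = 60,
                                        n_proteins = 30, seed = 1))
cfg  <- encoder_config(d_k = 1, fc_dims = c(128, 64))
md   <- prepare_model_data(data, cfg)
sp   <- make_split(md$records, split_spec("random", seed = 1))

model <- joint_train(md, sp$train, sp$val,
                     gin_config(),
                     train_config(pretrain_epochs = 15, joint_epochs = 5,
                                  batch_size = 64, aux_branch_weight = 0.3,
                                  seed = 1))
preds <- predict_affinity(model, md, sp$test)
basic_metrics(md$records$affinity[sp$test], preds$final_pred)
#> n=60  MSE=0.3350  CI=0.8226  rm2=0.6047  pearson=0.8928  spearman=0.8382

# which residues does the joint attention credit?
rec <- md$records[sp$test[1], ]
map <- attention_map(model, rec$smiles, rec$sequence)
top_k_nodes(map, 5, side = "protein")
#> [1]  2  7 12 33 31
```

The metrics line reads: held-out mean squared error on the affinity
scale, concordance index (fraction of correctly ordered pairs; 0.5 is
random, and the Bayes optimum under these noise settings is only ≈ 0.8 —
see the vignette), the rm2 regression metric, and the two correlations.
`top_k_nodes` ranks residues by their share of the joint attention mass.
At this two-minute training scale the per-record rankings are noisy; the
aggregate motif-enrichment of the attention is what the test suite
checks, at the full reference-study size.

A command-line interface wrapping the same functions is installed at
`inst/cli/hybriddta` (subcommands: `simulate split pretrain train predict
explain evaluate replicate` — the last repeats a study over several seeds
and reports mean ± sd).

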