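# dtiscreen

Latent-space screening of drug compounds against adverse-effect-associated
protein targets, in R.

Adverse effects are a leading cause of clinical-trial failure, yet the
biological targets behind them are rarely screened before a compound enters
trials. `dtiscreen` implements a deep cross-modal attention framework for
exactly that: it learns a shared latent space for compounds and proteins
from known drug–target interactions, sharpens it contrastively against
structurally similar decoy compounds, and then reads off a compound's
off-target risk as its Euclidean distance to adverse-effect-annotated
proteins in a 2-D projection of that space — close means likely
interaction. Predicted adverse-effect term sets are evaluated against
ground-truth side-effect lists after normalisation to a preferred-term
vocabulary. The audience is computational drug-discovery researchers who
want a fully seeded, self-contained reimplementation they can train, probe
and extend on commodity hardware.

## The model

Compounds are featurised as Morgan (circular) fingerprints `E2 = f2(X2)`
(default radius 2, 2048 bits); proteins as summed skip-gram embeddings of
their overlapping 3-mers across shifted reading frames, `E1 = f1(X1)`
(default dimension 100). Each modality passes through a 3-layer ReLU
projection stack,

    L1_i = ReLU(W1_i' E_i + b1_i),  L2_i = ReLU(W2_i' L1_i + b2_i),
    L3_i = ReLU(W3_i' L2_i + b3_i),          i = 1 (target), 2 (compound),

into a shared latent of width `p`. A dual-headed cross-modal attention
block lets each modality query the other: head 1 builds `Q1` from the
target stream and `K2, V2` from the compound stream, head 2 reverses the
roles, each head has width `p/2` and scaling `sqrt(p/2)`, and a global
weight `W_G` mixes the concatenated heads into the attention output `A`.
A residual sum `Â = L3_1 + L3_2 + A` is layer-normalised (empirical mean
and variance, stabiliser ε, learned gain α and shift β) and a linear head
`W4, b4` produces the interaction logit; training minimises sigmoid
binary cross-entropy. Contrastive fine-tuning then draws, for every
positive pair, decoy compounds that do not bind the anchor target and
minimises the triplet loss `mean over decoys of
max(0, d(a, p) − d(a, n) + margin)` in the latent space, optionally mixed
with the BCE term.

Screening projects entity embeddings to 2-D (seeded UMAP; principal axes
below a documented point floor), ranks targets by Euclidean distance per
compound, compares distances to adverse-effect targets against a sampled
control proteome with a one-sided Welch t-test, and aggregates
mean ± standard error per organ group over repeated projections. A
knowledge layer merges target→adverse-effect→organ annotation tables,
ranks organ sources by term count, and clusters targets by the
Levenshtein distance of their adverse-effect profiles.

Because the original training corpora are external resources, the package
ships a seeded synthetic-world generator with a planted interaction rule
(fragment-bearing compounds × motif-bearing proteins) and
composition-matched decoys, so the full pipeline is trainable and
testable offline.

## Worked example

Train on the default planted world (200 compounds, 100 annotated targets,
100 control proteins, seed 7; latent width 64) and screen one compound:

```r
library(dtiscreen)

world     <- generate_world(seed = 7)
compounds <- compound_records(world$compounds$compound_id, world$compounds$smiles)
kmers     <- train_kmer_embeddings(world$proteins$sequence, seed = 42)
proteins  <- protein_records(world$proteins$protein_id, world$proteins$sequence, kmers)

split <- split_pairs(world$pairs, seed = 3)
model <- interaction_model(dim_target = 100, dim_compound = 2048, p = 64, seed = 2)
pre   <- pretrain(model, interaction_dataset(split$train, compounds, proteins),
                  training_config(epochs = 30, seed = 4))
positives <- split$train[split$train$label == 1, c("compound_id", "target_id")]
fin   <- contrastive_finetune(pre$model, positives, world$decoy_pool,
                              compounds, proteins,
                              training_config(epochs = 10, n_decoys = 50, seed = 5))

scores <- predict_interaction(fin$model, compounds, proteins, split$validation)
pr_auc(scores, split$validation$label)
```

which prints (alongside the per-epoch traces):

```
pretrain loss, epochs 1/15/30: 0.613 0.000396 0.000103
separation, epochs 1/5/10:     -2.15 -2.99 -3.01
held-out PR-AUC: 0.959
```

The pre-training loss collapses as the planted rule is learned; the
fine-tuning separation (mean anchor–positive minus anchor–decoy latent
distance) goes increasingly negative, meaning active compounds sit closer
to their targets than decoys do; and held-out interaction ranking reaches
a precision-recall AUC of 0.959. Screening the first ground-truth
compound against annotated targets plus controls:

```r
screened <- sort(unique(world$ground_truth$compound_id))
emb <- extract_entity_embeddings(fin$model,
         subset_compound_set(compounds, screened), proteins,
         kinds = setNames(world$proteins$kind, world$proteins$protein_id))
pts <- manifold_project_2d(emb, seed = 99)
rk  <- rank_targets(pts[pts$entity_id == screened[1], ],
                    pts[pts$entity_kind != "compound", ])
head(rk[, c("target_id", "entity_kind", "distance", "rank")], 3)
compare_to_controls(rk$distance[rk$entity_kind == "ae_target"],
                    rk$distance[rk$entity_kind == "control_protein"])
```

```
 target_id entity_kind distance rank
    AET081   ae_target 17.29582    1
    AET064   ae_target 17.30362    2
    AET054   ae_target 17.30415    3
one-sided Welch test: t = -13.76, p = 5.87e-31
```

The compound's nearest neighbours are all adverse-effect targets (rank 1
= strongest predicted interaction) and the one-sided test confirms it
sits significantly closer to them than to the control proteome — the
signature of a compound with real off-target liability in this world.

`run_pipeline(run_config("test", seed = 7), "out/")` runs the whole chain
(simulate → featurize → pretrain → finetune → screen → aggregate →
evaluate) and writes seeded, byte-reproducible CSVs; a thin command-line
front end lives at `inst/cli/dtiscreen.R`.

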