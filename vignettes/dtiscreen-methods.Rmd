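---
title: "Cross-modal attention screening: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-modal attention screening: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`dtiscreen` screens drug compounds against proteins associated with
adverse effects by learning a shared latent space from drug–target
interaction data and reading interaction strength off as distance in
that space. This vignette documents the model, every tunable that
matters, the places where the design was genuinely open and what we
chose, and what the synthetic benchmark does and does not establish.

## Featurisation

**Compounds** become Morgan (circular) fingerprints. SMILES parsing and
kekulisation are delegated to OpenBabel (through `ChemmineOB`); the
environment hashing is implemented in the package so radius and width
are free parameters. The initial atom invariant is (element, heavy-atom
degree, bond-order sum, formal charge, implicit hydrogen count);
neighbour contributions are sorted before hashing, and duplicate
environments — identical covered bond sets, which arise at symmetric
ring positions — are emitted once with the group-minimum identifier, so
the fingerprint is invariant to the atom ordering of the input SMILES.
A ring-membership flag is deliberately not part of the invariant; for
the discrimination tasks here the degree/valence signature of ring
atoms proved sufficient, and the invariance and count contracts do not
depend on it. Defaults: radius 2, 2048 bits (the community-standard
ECFP4-like setting; the source description does not fix these, so both
are configurable).

**Proteins** become summed skip-gram k-mer embeddings. Each sequence is
split into `frames` shifted reading-frame sentences (frame `f` holds
the k-mers starting at `f+1, f+1+frames, ...`; with `frames = k` the
frames jointly cover every overlapping k-mer, the classic convention),
a word2vec-style skip-gram model with negative sampling is trained on
those sentences (Rcpp, internal deterministic RNG, fixed sentence
order: bit-reproducible under one seed), and a protein's embedding is
the **sum** of its k-mer vectors. Sum is the original composition rule;
a mean is available by flag. K-mers unseen at training time contribute
the zero vector rather than failing — at screening time a protein with
unfamiliar composition should degrade gracefully, not crash a run.
Non-standard residue symbols are kept as literal characters so synthetic
alphabets also work. Defaults: k = 3, frames = 3, dimension 100,
window 5, 5 epochs. The embedding table round-trips through the
plain-text word2vec format, so externally trained vectors can be
loaded instead.

## The interaction model

Both embeddings pass through separate 3-layer ReLU projection stacks
into a latent of width `p` (all hidden widths default to `p`; the
shipped full-scale configuration uses `p = 1024`, the test preset
`p = 64`). Two design points in the attention block required
interpretation:

* **The attention nonlinearity.** Each entity is a single vector, so a
  softmax over a one-element key axis is identically 1 and would cancel
  the query/key parameters entirely. The default semantics is therefore
  a *scalar sigmoid gate*: head output
  `sigmoid(<q, k> / sqrt(p/2)) * v`, which keeps all six maps live and
  degenerates gracefully (orthogonal query/key gives gate 0.5). A
  *token mode* — the head vector reshaped into `n_tokens` tokens with
  standard softmax attention across tokens — is available behind the
  `attention_mode` flag for users who prefer the sequence-attention
  reading; it shares the same parameters. Training backpropagation is
  implemented for the gate mode; token mode is a forward-only scoring
  variant.
* **The residual.** The residual sum feeding layer normalisation cannot
  involve the raw embeddings (their dimensions, 100 and 2048, differ
  from `p`); the only dimension-consistent reading is
  `Â = L3_target + L3_compound + A`, which is what the package
  computes. This is an interpretation, recorded here, not an assertion
  about the original design.

Layer normalisation uses the population variance of `Â` with stabiliser
`eps = 1e-5` (any positive value is accepted; zero is rejected because a
constant `Â` would otherwise divide by zero), followed by elementwise
gain and shift and a linear readout. Parameters are initialised with
He-style fan-in uniform draws under a fixed seed. Checkpoints store
every tensor plus a JSON configuration block and validate shape
consistency on load; save → load → predict is bit-identical.

## Training

Pre-training minimises sigmoid binary cross-entropy (computed in the
log-sum-exp form, so ±500 logits are finite) over shuffled mini-batches
with Adam. Optimiser and schedule are not fixed by the source
description; we use Adam at `lr = 1e-3`, batch 32, because the two input
modalities differ in scale by orders of magnitude (binary fingerprints
vs summed embeddings) and Adam's per-parameter scaling absorbs that
without input standardisation.

Contrastive fine-tuning walks the positive pairs; for each anchor it
samples `n_decoys = 50` compounds uniformly without replacement,
excluding the active compound and anything positively paired with the
anchor target. Decoys are **re-sampled every epoch** (fresh
augmentation): nothing in the source fixes them once, and re-sampling is
the stronger regulariser. The triplet loss uses Euclidean distance
between the target projection (anchor) and compound projections
(positive/negatives), consistent with the Euclidean convention of the
screening stage, margin 1 by default. Whether the classification
objective stays on during fine-tuning was open; we blend
`total = (1 − λ)·triplet + λ·BCE` with `λ = 0.5` by default — `λ = 0`
recovers the pure triplet objective. The hinge gradient is clamped to
zero when a distance underflows `1e-12` (the direction `u = diff/d` is
undefined at coincident points). Splits are 85/15 stratified by label,
seeded. Every stochastic step derives its seed from the master seed, so
a full pretrain + finetune is bit-reproducible on one platform.

## Screening

The per-entity representation is the modality's **L3 projection** — the
only representation defined for an entity in isolation (the
post-attention fused vector exists only for pairs; a flag exposes it
for pair diagnostics). Entities are projected to 2-D and distances are
computed **in the projected plane**, not the p-dimensional latent: at
`p` in the hundreds plain Euclidean distances concentrate and lose
contrast, which is the stated rationale for projecting first; a flag
enables latent-space distances for diagnostics. The projector is UMAP
(`uwot`, single-threaded, seeded — identical input and seed give
identical coordinates), a neighbour-embedding method from the same
family as pairwise-controlled manifold approximation, preserving local
and global structure; below 30 points the neighbour graph degenerates
and the implementation falls back to a deterministic principal-axes
projection (sign-fixed so LAPACK conventions cannot flip results).
The set of entities projected together defines the geometry: screens
project exactly the screened compounds, the annotated targets and the
controls, and distances are only comparable within one projection run —
mixing runs raises an error.

Ranks are assigned ascending in distance (rank 1 = strongest predicted
interaction), ties broken lexicographically by id for determinism.
Control proteins are sampled uniformly without replacement, excluding
the annotated accessions *and their isoforms* (an id whose base
accession — the part before a "-" suffix — is excluded is itself
ineligible). The distance distributions are compared with a one-sided
Welch t-test (adverse-effect targets closer as the alternative); Welch
over pooled variance for robustness to unequal spread, with the
convention p = 0.5 when both samples are constant and equal. What
varies across the "repetitions" of the organ-level aggregation is the
projection seed — the only stochastic stage after training — with
derived seeds `master + repetition index`; per (compound, target) the
mean and standard error `sd/sqrt(n)` are reported, and a target
annotated to several organ groups contributes to each of them. Organ
aggregation covers annotated targets only.

## Term normalisation and evaluation

The original normalisation stage used an external learned normaliser
whose weights are not distributable, so the package's default is a
deterministic normaliser behind the same interface: clean the raw term
(case, whitespace, punctuation), look it up among preferred terms and
synonyms, otherwise accept the nearest dictionary entry by Levenshtein
distance when the distance is at most `max_edit_fraction = 0.2` of the
longer string, ties broken by smallest distance then alphabetically.
Normalisation is idempotent by construction. The shipped dictionary is a
small openly composed vocabulary (with British/American spelling swaps
and pluralisation as synonyms), not a licensed medical dictionary; the
CSV format accepts a real preferred-term export unchanged.

How latent distances become a predicted *term set* is not specified by
the source; the package uses an explicit, configurable rule: a target is
a predicted interactor when its distance falls below the
`threshold_quantile` (default 0.05) quantile of the compound's control
distances, and the predicted terms are the union of the interactors'
annotations. Recall is monotone in the quantile by construction.
Precision and recall are set-level on preferred terms; undefined ratios
(empty prediction or truth) are reported as `NA`, never 0, so averages
stay honest.

## The synthetic world

The generator builds the statistical structure the framework assumes,
with none of the chemistry: compounds come from a small grammar over
C/N/O chains, branches and carbon rings (guaranteed parseable), a
planted subset carries a fragment (default an imide-like
`C(=O)NC(=O)`); proteins are uniform random sequences, a planted subset
carries a 12-residue motif. Interaction is the conjunction of the two
motifs: all positives satisfy it, all sampled negatives and all decoys
violate it. Decoys carry the hydroxyl analogue of the carbonyl fragment
— same heavy-atom composition, different local environments — a toy
version of property-matched decoy sets. Annotations draw 2–8 vocabulary
terms and 1–3 organ groups per target; ground-truth lists corrupt a
`variant_rate` fraction of terms with spelling swaps, pluralisation or
single-character misspellings (only words long enough that one edit
stays inside the normaliser's budget). The default world has 200
compounds, 100 annotated targets, 100 controls, 2 positives per target,
variant rate 0.1, seed 7; the `full-scale` preset scales to 118
annotated targets, 1000 controls and a handful of active compounds,
matching the relative proportions of the application setting.

The test suite trains the default configuration on this world
(30 pre-training + 10 fine-tuning epochs, `p = 64`) and verifies
held-out precision-recall AUC of at least 0.9, chance-level AUC on a
label-shuffled null world (no leakage), strictly decreasing
anchor–decoy separation under fine-tuning, a significant
interactor-vs-control distance contrast with a uniform p-value
distribution under label shuffling, and recovery of injected term
variants by the normaliser. Passing these says the implementation can
learn a planted bilinear rule and that its statistics are calibrated —
it says nothing about real pharmacology: synthetic molecules are tiny
acyclic/monocyclic scaffolds, sequences have no homology structure,
decoys are string-level analogues, and annotation terms are assigned
independently of structure. Treat results on real data as requiring the
usual external validation.

## Numerical and degenerate-input conventions

* Layer-norm: population variance, `eps = 1e-5`; standardised output has
  |mean| < 1e-6 and |var − 1| < 10·eps on any non-constant input.
* BCE: log-sum-exp form; empty batches are errors, not NaN.
* Triplet: empty decoy sets are errors; zero distances give zero
  gradient, not Inf.
* Ranking ties: lexicographic id; ranking is always a bijection onto
  1..N.
* Projection: < 2 points is an error; 2–29 points use principal axes;
  UMAP seeds derive from the master seed.
* Welch test on constant samples: sign of the mean difference, p = 0.5
  on exact equality.
* Unknown targets in the organ map go to an explicit `"unmapped"` group
  with a warning rather than being dropped.
* All file outputs of the pipeline carry a metadata block (tool version,
  configuration hash, master seed) and contain no timestamps, so reruns
  are byte-identical.

## Problem sizes

Unit tests run on a miniature world (40 compounds, 10 targets); the
benchmark fixtures use the default world above, which trains in about a
minute on one CPU at `p = 64`. The `full-scale` preset (`p = 1024`,
1000 controls) is the configuration a full-scale study would use and is
correspondingly slower; nothing in the implementation is specific to
either size.

## Known limitations

* Backpropagation covers the gate attention mode; token mode is
  forward-only.
* The SMILES subset understood is what OpenBabel accepts; fingerprints
  use heavy-atom invariants without ring flags or chirality.
* The skip-gram trainer is single-threaded by design (determinism over
  speed); large corpora would want the usual asynchronous
  implementations.
* The deterministic term normaliser handles spelling variation, not
  semantic synonymy ("high blood pressure" → "hypertension" needs a
  dictionary entry or a plugged-in learned normaliser).
* Latent-distance screening is a prioritisation signal, not a binding
  assay; organ-level aggregates inherit every bias of the annotation
  source.
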