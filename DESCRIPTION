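Package: dtiscreen
Title: Cross-Modal Attention Screening of Drug Compounds Against
    Adverse-Effect-Associated Protein Targets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for latent-space screening of drug compounds against
    protein targets associated with adverse effects. Compounds are
    featurised with Morgan (circular) fingerprints and proteins with
    k-mer skip-gram embeddings; a dual-headed cross-modal attention
    network is trained on interaction pairs with binary cross-entropy
    and fine-tuned contrastively against property-matched decoys using a
    triplet loss. Trained entity embeddings are projected to two
    dimensions and compound-target interaction is scored by Euclidean
    distance, ranked, compared against a sampled control proteome, and
    aggregated by organ system. A target-to-adverse-effect knowledge
    layer supports annotation merging, organ-source ranking and
    edit-distance clustering, and predicted adverse-effect term sets are
    evaluated against ground truth after normalisation to a preferred
    term vocabulary. A seeded synthetic-world generator with planted
    interaction motifs makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineOB,
    Biostrings,
    uwot,
    ape,
    jsonlite,
    withr,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
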