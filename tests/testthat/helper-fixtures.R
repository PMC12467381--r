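# Shared fixtures, built in code and cached for the session. The tiny
# world keeps unit tests fast; the benchmark state (full default world,
# pre-trained + fine-tuned model) is computed once and shared by the
# acceptance tests.

.fixture_env <- new.env(parent = emptyenv())

tiny_world <- function() {
  if (is.null(.fixture_env$tiny)) {
    .fixture_env$tiny <- generate_world(
      n_compounds = 40L, n_targets = 10L, n_controls = 10L,
      n_positive_per_target = 2L, variant_rate = 0.2, seed = 11L
    )
  }
  .fixture_env$tiny
}

tiny_features <- function() {
  if (is.null(.fixture_env$tiny_feats)) {
    w <- tiny_world()
    cs <- compound_records(w$compounds$compound_id, w$compounds$smiles,
                           n_bits = 512L)
    kt <- train_kmer_embeddings(w$proteins$sequence, dimension = 32L,
                                epochs = 3L, seed = 21L)
    ps <- protein_records(w$proteins$protein_id, w$proteins$sequence, kt)
    .fixture_env$tiny_feats <- list(compounds = cs, proteins = ps,
                                    kmer_table = kt)
  }
  .fixture_env$tiny_feats
}

# full benchmark under the default study conditions: default world
# (200 compounds, 100 annotated targets, seed 7), latent width 64,
# 30 pre-training + 10 fine-tuning epochs
benchmark_state <- function() {
  if (is.null(.fixture_env$bench)) {
    w <- generate_world(seed = 7L)
    cs <- compound_records(w$compounds$compound_id, w$compounds$smiles)
    kt <- train_kmer_embeddings(w$proteins$sequence, seed = 42L)
    ps <- protein_records(w$proteins$protein_id, w$proteins$sequence, kt)
    sp <- split_pairs(w$pairs, seed = 3L)
    model0 <- interaction_model(kt$dimension, cs$n_bits, p = 64L, seed = 2L)
    ds <- interaction_dataset(sp$train, cs, ps)
    pre <- pretrain(model0, ds, training_config(epochs = 30L, seed = 4L))
    pos <- sp$train[sp$train$label == 1, c("compound_id", "target_id")]
    fin <- contrastive_finetune(pre$model, pos, w$decoy_pool, cs, ps,
                                training_config(epochs = 10L, seed = 5L,
                                                n_decoys = 50L))
    .fixture_env$bench <- list(
      world = w, compounds = cs, proteins = ps, split = sp,
      positives = pos, model_init = model0, model_pre = pre$model,
      model = fin$model, pre_trace = pre$trace, fin_trace = fin$trace
    )
  }
  .fixture_env$bench
}

# the same conditions with the planted rule disabled (random labels)
null_benchmark_state <- function() {
  if (is.null(.fixture_env$null_bench)) {
    w <- generate_world(seed = 7L, planted = FALSE)
    cs <- compound_records(w$compounds$compound_id, w$compounds$smiles)
    kt <- train_kmer_embeddings(w$proteins$sequence, seed = 42L)
    ps <- protein_records(w$proteins$protein_id, w$proteins$sequence, kt)
    sp <- split_pairs(w$pairs, seed = 3L)
    model0 <- interaction_model(kt$dimension, cs$n_bits, p = 64L, seed = 2L)
    ds <- interaction_dataset(sp$train, cs, ps)
    pre <- pretrain(model0, ds, training_config(epochs = 30L, seed = 4L))
    pos <- sp$train[sp$train$label == 1, c("compound_id", "target_id")]
    fin <- contrastive_finetune(pre$model, pos, w$decoy_pool, cs, ps,
                                training_config(epochs = 10L, seed = 5L,
                                                n_decoys = 50L))
    .fixture_env$null_bench <- list(world = w, compounds = cs, proteins = ps,
                                    split = sp, model = fin$model)
  }
  .fixture_env$null_bench
}

# projected screen of the trained benchmark: 2-D points and per-compound
# distances to annotated targets and controls
benchmark_screen <- function() {
  if (is.null(.fixture_env$screen)) {
    st <- benchmark_state()
    screened <- sort(unique(st$world$ground_truth$compound_id))
    cs_sub <- subset_compound_set(st$compounds, screened)
    emb <- extract_entity_embeddings(
      st$model, cs_sub, st$proteins,
      kinds = stats::setNames(st$world$proteins$kind,
                              st$world$proteins$protein_id)
    )
    pts <- manifold_project_2d(emb, seed = 99L)
    tgt <- pts[pts$entity_kind != "compound", , drop = FALSE]
    ranks <- lapply(screened, function(cid) {
      rank_targets(pts[pts$entity_id == cid, , drop = FALSE], tgt)
    })
    names(ranks) <- screened
    .fixture_env$screen <- list(embeddings = emb, points = pts,
                                ranks = ranks, screened = screened)
  }
  .fixture_env$screen
}
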