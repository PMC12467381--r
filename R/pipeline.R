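## End-to-end pipeline: simulate -> featurize -> pretrain -> finetune ->
## screen -> aggregate -> evaluate, driven by a single serialisable
## configuration with presets. Every output CSV carries a metadata block
## (tool version, config hash, master seed) and reruns are
## byte-identical under one seed.

#' Build a run configuration
#'
#' @param preset `"test"` (latent width 64, minutes on one CPU) or
#'   `"full-scale"` (latent width 1024 and the full-scale world
#'   proportions: 118 annotated targets, 1000 controls, a handful of
#'   screened compounds).
#' @param seed master seed for the whole run.
#' @param ... named overrides of individual fields (nested lists are
#'   replaced wholesale).
#' @return a `run_config` list with components `world`, `features`,
#'   `model`, `pretrain`, `finetune`, `screen`, `evaluate`, `seed`,
#'   `preset`.
#' @export
run_config <- function(preset = c("test", "full-scale"), seed = 7L, ...) {
  preset <- match.arg(preset)
  cfg <- list(
    preset = preset,
    seed = as.integer(seed),
    world = list(n_compounds = 200L, n_targets = 100L, n_controls = 100L,
                 n_positive_per_target = 2L,
                 motif_smiles_fragment = "C(=O)NC(=O)",
                 motif_sequence = "WHMKFWHMKFWH",
                 ae_vocab_size = 40L, variant_rate = 0.1,
                 frac_active = 0.4, planted = TRUE),
    features = list(radius = 2L, n_bits = 2048L, k = 3L, dimension = 100L,
                    window = 5L, sg_epochs = 5L, frames = 3L),
    model = list(p = 64L, attention_mode = "gate", eps = 1e-5),
    pretrain = list(epochs = 30L, batch_size = 32L, lr = 1e-3,
                    train_fraction = 0.85),
    finetune = list(epochs = 10L, lr = 1e-3, n_decoys = 50L,
                    margin = 1, lambda_bce = 0.5, anchors_per_batch = 4L),
    screen = list(n_repetitions = 5L, umap_floor = 30L, n_neighbors = 15L),
    evaluate = list(threshold_quantile = 0.05, max_edit_fraction = 0.2)
  )
  if (preset == "full-scale") {
    cfg$model$p <- 1024L
    cfg$world$n_targets <- 118L
    cfg$world$n_controls <- 1000L
    cfg$world$frac_active <- 0.03
  }
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as JSON
#' @param path JSON file.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- run_config(preset = raw$preset %||% "test", seed = raw$seed %||% 7L)
  for (nm in intersect(names(raw), names(cfg))) {
    if (is.list(cfg[[nm]]) && is.list(raw[[nm]])) {
      cfg[[nm]][names(raw[[nm]])] <- raw[[nm]]
    } else {
      cfg[[nm]] <- raw[[nm]]
    }
  }
  cfg
}

#' @rdname read_run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

.stage <- function(name, log, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) {
    stop("stage ", sQuote(name), " failed: ", conditionMessage(e),
         call. = FALSE)
  })
  log(sprintf("stage %-10s done in %.1fs", name, proc.time()[["elapsed"]] - t0))
  res
}

.validate_config <- function(config, out_dir) {
  if (is.null(out_dir) || !nzchar(out_dir)) {
    stop("config validation: output directory is required")
  }
  for (f in c("world", "features", "model", "pretrain", "finetune",
              "screen", "evaluate", "seed")) {
    if (is.null(config[[f]])) stop("config validation: missing field ", sQuote(f))
  }
  if (config$model$p %% 2 != 0) stop("config validation: p must be even")
  invisible(TRUE)
}

#' Run the full screening pipeline
#'
#' Executes simulate, featurize, pretrain, finetune, screen, aggregate
#' and evaluate on a synthetic world, writing all result tables (with
#' metadata headers), the loss traces, the model checkpoint and the
#' effective configuration into `out_dir`. Deterministic: rerunning with
#' the same config yields byte-identical CSVs.
#'
#' @param config a [run_config()] (or path to a JSON config).
#' @param out_dir output directory.
#' @param quiet suppress console log messages.
#' @return invisibly, a list with the trained model, the world, result
#'   tables and output paths.
#' @export
run_pipeline <- function(config = run_config(), out_dir, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  .validate_config(config, out_dir)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con), add = TRUE)
  log <- function(msg) {
    if (!quiet) message(msg)
    writeLines(msg, log_con)
  }
  seed <- config$seed
  meta <- run_meta(config, seed)
  log(sprintf("dtiscreen pipeline, master seed %d, config %s",
              seed, meta$config_hash))
  write_run_config(config, file.path(out_dir, "config.json"))

  world <- .stage("simulate", log, do.call(generate_world,
    c(config$world, list(seed = seed))))

  ft <- config$features
  feats <- .stage("featurize", log, {
    compounds <- compound_records(world$compounds$compound_id,
                                  world$compounds$smiles,
                                  radius = ft$radius, n_bits = ft$n_bits)
    kt <- train_kmer_embeddings(world$proteins$sequence, k = ft$k,
                                dimension = ft$dimension, window = ft$window,
                                epochs = ft$sg_epochs,
                                seed = derive_seed(seed, 1L),
                                frames = ft$frames)
    proteins <- protein_records(world$proteins$protein_id,
                                world$proteins$sequence, kt,
                                frames = ft$frames)
    list(compounds = compounds, proteins = proteins, kmer_table = kt)
  })

  model <- interaction_model(
    dim_target = ft$dimension, dim_compound = ft$n_bits,
    p = config$model$p, attention_mode = config$model$attention_mode,
    eps = config$model$eps, seed = derive_seed(seed, 2L)
  )

  split <- split_pairs(world$pairs,
                       train_fraction = config$pretrain$train_fraction,
                       seed = derive_seed(seed, 3L))
  pre <- .stage("pretrain", log, {
    ds <- interaction_dataset(split$train, feats$compounds, feats$proteins)
    pretrain(model, ds, training_config(
      lr = config$pretrain$lr, batch_size = config$pretrain$batch_size,
      epochs = config$pretrain$epochs, seed = derive_seed(seed, 4L)
    ))
  })
  model <- pre$model

  fin <- .stage("finetune", log, {
    pos_train <- split$train[split$train$label == 1, c("compound_id", "target_id")]
    contrastive_finetune(model, pos_train, world$decoy_pool,
                         feats$compounds, feats$proteins, training_config(
      lr = config$finetune$lr, epochs = config$finetune$epochs,
      seed = derive_seed(seed, 5L), margin = config$finetune$margin,
      n_decoys = min(config$finetune$n_decoys,
                     length(world$decoy_pool) - 1L),
      lambda_bce = config$finetune$lambda_bce,
      anchors_per_batch = config$finetune$anchors_per_batch
    ))
  })
  model <- fin$model
  save_model(model, file.path(out_dir, "model.rds"))
  write_csv_meta(pre$trace, file.path(out_dir, "pretrain_trace.csv"), meta)
  write_csv_meta(fin$trace, file.path(out_dir, "finetune_trace.csv"), meta)

  screened <- sort(unique(world$ground_truth$compound_id))
  sc <- config$screen
  screen_res <- .stage("screen", log, {
    cs_sub <- subset_compound_set(feats$compounds, screened)
    emb <- extract_entity_embeddings(
      model, cs_sub, feats$proteins,
      kinds = stats::setNames(world$proteins$kind, world$proteins$protein_id)
    )
    pts <- manifold_project_2d(emb, seed = derive_seed(seed, 6L),
                               umap_floor = sc$umap_floor,
                               n_neighbors = sc$n_neighbors)
    tgt_pts <- pts[pts$entity_kind != "compound", , drop = FALSE]
    ranks <- do.call(rbind, lapply(screened, function(cid) {
      rank_targets(pts[pts$entity_id == cid, , drop = FALSE], tgt_pts)
    }))
    list(embeddings = emb, points = pts, ranks = ranks)
  })
  write_csv_meta(screen_res$ranks, file.path(out_dir, "screen.csv"), meta)

  organ_map <- lapply(world$annotations$records, function(r) names(r$organ_terms))
  # organ aggregation covers the annotated targets only, not the controls
  agg <- .stage("aggregate", log, {
    emb <- screen_res$embeddings
    keep <- emb$kinds != "control_protein"
    emb_ae <- structure(list(ids = emb$ids[keep], kinds = emb$kinds[keep],
                             vectors = emb$vectors[keep, , drop = FALSE]),
                        class = "latent_embedding")
    aggregate_by_organ(emb_ae, organ_map, n_repetitions = sc$n_repetitions,
                       master_seed = derive_seed(seed, 7L))
  })
  write_csv_meta(agg, file.path(out_dir, "aggregate.csv"), meta)

  ev <- config$evaluate
  eval_res <- .stage("evaluate", log, {
    dict <- world$dictionary
    rows <- list()
    detail <- list()
    for (cid in screened) {
      rk <- screen_res$ranks[screen_res$ranks$compound_id == cid, , drop = FALSE]
      ae_rk <- rk[rk$entity_kind == "ae_target", , drop = FALSE]
      ctrl_d <- rk$distance[rk$entity_kind == "control_protein"]
      pred_raw <- predict_adverse_effect_terms(
        cid, ae_rk, world$annotations, ctrl_d,
        threshold_quantile = ev$threshold_quantile
      )
      pred <- normalize_term_set(cid, pred_raw$terms, dict,
                                 max_edit_fraction = ev$max_edit_fraction)
      truth_terms <- world$ground_truth$ae_term[world$ground_truth$compound_id == cid]
      truth <- normalize_term_set(cid, truth_terms, dict,
                                  max_edit_fraction = ev$max_edit_fraction)
      pr <- precision_recall(pred, truth)
      rows[[cid]] <- data.frame(
        compound_id = cid,
        precision = pr$precision %||% NA_real_,
        recall = pr$recall %||% NA_real_,
        n_tp = length(pr$tp), n_fp = length(pr$fp), n_fn = length(pr$fn),
        n_interactors = length(pred_raw$interactors),
        threshold_quantile = ev$threshold_quantile,
        stringsAsFactors = FALSE
      )
      detail[[cid]] <- list(compound_id = cid, tp = pr$tp, fp = pr$fp,
                            fn = pr$fn,
                            unmapped_truth = truth$unmapped$raw,
                            interactors = pred_raw$interactors)
    }
    list(table = do.call(rbind, rows), detail = detail)
  })
  eval_tab <- eval_res$table
  rownames(eval_tab) <- NULL
  write_csv_meta(eval_tab, file.path(out_dir, "evaluation.csv"), meta)
  jsonlite::write_json(eval_res$detail, file.path(out_dir, "evaluation_detail.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log("pipeline complete")

  invisible(list(model = model, world = world, features = feats,
                 split = split, pretrain_trace = pre$trace,
                 finetune_trace = fin$trace, screen = screen_res,
                 aggregate = agg, evaluation = eval_tab,
                 out_dir = out_dir))
}
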