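## Pre-training on labelled interaction pairs (binary cross-entropy) and
## contrastive fine-tuning with per-epoch resampled decoys (triplet loss,
## optionally mixed with the BCE term).

#' Training configuration
#'
#' @param lr Adam learning rate.
#' @param batch_size mini-batch size for pre-training.
#' @param epochs number of epochs.
#' @param seed master seed; every stochastic step derives its own seed
#'   from it.
#' @param margin triplet margin (> 0).
#' @param n_decoys decoys sampled per anchor pair (>= 1).
#' @param lambda_bce loss-mix weight in `[0, 1]` for fine-tuning:
#'   `total = (1 - lambda) * triplet + lambda * BCE`. 0 = pure triplet.
#' @param anchors_per_batch anchor pairs per fine-tuning mini-batch.
#' @param debug_checks assert the decoy-exclusion invariant inside the
#'   training loop.
#' @return a `training_config` list.
#' @export
training_config <- function(lr = 1e-3, batch_size = 32L, epochs = 10L,
                            seed = 1L, margin = 1, n_decoys = 50L,
                            lambda_bce = 0.5, anchors_per_batch = 4L,
                            debug_checks = FALSE) {
  stopifnot(n_decoys >= 1L, epochs >= 0L, margin > 0,
            lambda_bce >= 0, lambda_bce <= 1)
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 margin = margin, n_decoys = as.integer(n_decoys),
                 lambda_bce = lambda_bce,
                 anchors_per_batch = as.integer(anchors_per_batch),
                 debug_checks = isTRUE(debug_checks)),
            class = "training_config")
}

#' Assemble an interaction dataset
#'
#' Validates that every pair resolves to stored features and that no
#' (compound, target) pair is duplicated.
#'
#' @param pairs data.frame with columns `compound_id`, `target_id`,
#'   `label` (0/1).
#' @param compounds a `compound_set`. @param proteins a `protein_set`.
#' @return an `interaction_dataset`.
#' @export
interaction_dataset <- function(pairs, compounds, proteins) {
  need <- c("compound_id", "target_id", "label")
  stopifnot(all(need %in% names(pairs)))
  key <- paste(pairs$compound_id, pairs$target_id, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate (compound, target) pairs in dataset")
  if (!all(pairs$label %in% c(0, 1))) stop("labels must be 0/1")
  miss_c <- setdiff(unique(pairs$compound_id), compounds$ids)
  miss_t <- setdiff(unique(pairs$target_id), proteins$ids)
  if (length(miss_c)) stop("pairs reference unknown compounds: ",
                           paste(utils::head(miss_c, 3), collapse = ", "))
  if (length(miss_t)) stop("pairs reference unknown targets: ",
                           paste(utils::head(miss_t, 3), collapse = ", "))
  structure(list(pairs = pairs, compounds = compounds, proteins = proteins),
            class = "interaction_dataset")
}

#' Stratified train/validation split of an interaction pair table
#'
#' @param pairs pair data.frame with a `label` column.
#' @param train_fraction fraction assigned to training (default 0.85),
#'   stratified by label.
#' @param seed integer seed.
#' @return list with `train` and `validation` data.frames.
#' @export
split_pairs <- function(pairs, train_fraction = 0.85, seed = 1L) {
  withr::with_seed(seed, {
    idx <- unlist(lapply(split(seq_len(nrow(pairs)), pairs$label), function(i) {
      sample(i, round(length(i) * train_fraction))
    }))
  })
  list(train = pairs[sort(idx), , drop = FALSE],
       validation = pairs[setdiff(seq_len(nrow(pairs)), idx), , drop = FALSE])
}

#' Pre-train the interaction model on labelled pairs
#'
#' Minimises the sigmoid binary cross-entropy over shuffled mini-batches
#' with Adam. The run is bit-reproducible under a fixed config seed.
#'
#' @param model an [interaction_model()].
#' @param data an [interaction_dataset()].
#' @param config a [training_config()].
#' @return list with the updated `model` and a `trace` data.frame
#'   (epoch, mean BCE loss).
#' @export
pretrain <- function(model, data, config = training_config()) {
  stopifnot(inherits(data, "interaction_dataset"))
  pairs <- data$pairs
  if (length(unique(pairs$label)) < 2L) {
    warning("dataset contains a single class; proceeding (loss still defined)")
  }
  if (config$epochs == 0L) {
    return(list(model = model,
                trace = data.frame(epoch = integer(0), loss = numeric(0))))
  }
  E1_all <- data$proteins$features[pairs$target_id, , drop = FALSE]
  E2_all <- data$compounds$features[pairs$compound_id, , drop = FALSE]
  y <- pairs$label
  n <- nrow(pairs)
  state <- .adam_init(model$params)
  trace <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- withr::with_seed(derive_seed(config$seed, ep), sample.int(n))
    loss_sum <- 0
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      fw <- .model_forward(model, E1_all[idx, , drop = FALSE],
                           E2_all[idx, , drop = FALSE])
      yb <- y[idx]
      loss_sum <- loss_sum + bce_sigmoid_loss(fw$logit, yb) * length(idx)
      dlogit <- (sigmoid(fw$logit) - yb) / length(idx)
      grads <- .model_backward(model, fw, dlogit)
      st <- .adam_step(model$params, grads, state, lr = config$lr)
      model$params <- st$params
      state <- st$state
    }
    trace[ep] <- loss_sum / n
  }
  list(model = model, trace = data.frame(epoch = seq_len(config$epochs),
                                         loss = trace))
}

#' Sample non-interacting decoys for an anchor pair
#'
#' Draws `n` distinct compounds uniformly without replacement from the
#' pool, excluding the anchor's active compound and every compound that
#' forms a known positive with the anchor target.
#'
#' @param anchor list or character vector with `target_id` and
#'   `compound_id` of the active pair.
#' @param pool character vector of candidate compound ids.
#' @param positives data.frame of known positive pairs (`compound_id`,
#'   `target_id`).
#' @param n number of decoys.
#' @param seed integer seed.
#' @return a `decoy_set`: list with `target_id`, `compound_id`, `decoys`.
#' @export
sample_decoys <- function(anchor, pool, positives, n, seed = 1L) {
  target_id <- anchor$target_id %||% anchor[["target_id"]]
  compound_id <- anchor$compound_id %||% anchor[["compound_id"]]
  known <- positives$compound_id[positives$target_id == target_id]
  eligible <- setdiff(pool, c(compound_id, known))
  if (length(eligible) < n) {
    stop("decoy pool too small: need ", n, ", only ", length(eligible),
         " eligible compounds (short by ", n - length(eligible), ")")
  }
  decoys <- withr::with_seed(seed, sample(eligible, n))
  structure(list(target_id = target_id, compound_id = compound_id,
                 decoys = decoys),
            class = "decoy_set")
}

#' Contrastive fine-tuning with decoy augmentation
#'
#' For every positive anchor pair, decoys are re-sampled each epoch and
#' the triplet loss (averaged across each anchor's triplet set, with the
#' anchor target's projection as anchor and compound projections as
#' positive/negatives, Euclidean distance) is minimised, mixed with the
#' BCE term on the same rows by `lambda_bce`.
#'
#' @param model an [interaction_model()].
#' @param positives data.frame of positive pairs (`compound_id`,
#'   `target_id`).
#' @param pool character vector of decoy candidate compound ids.
#' @param compounds a `compound_set`. @param proteins a `protein_set`.
#' @param config a [training_config()].
#' @return list with the updated `model` and a `trace` data.frame
#'   (epoch, total loss, triplet and BCE components, and the mean
#'   anchor-positive minus anchor-decoy distance `separation`).
#' @export
contrastive_finetune <- function(model, positives, pool, compounds, proteins,
                                 config = training_config()) {
  if (nrow(positives) == 0L) stop("no positive anchor pairs")
  n_dec <- config$n_decoys
  lam <- config$lambda_bce
  state <- .adam_init(model$params)
  trace <- vector("list", config$epochs)
  for (ep in seq_len(config$epochs)) {
    ep_seed <- derive_seed(config$seed, 1000L + ep)
    anchors <- withr::with_seed(ep_seed, positives[sample.int(nrow(positives)), ,
                                                   drop = FALSE])
    decoy_sets <- lapply(seq_len(nrow(anchors)), function(i) {
      sample_decoys(anchors[i, ], pool, positives, n_dec,
                    seed = derive_seed(ep_seed, i))
    })
    if (config$debug_checks) {
      for (ds in decoy_sets) {
        bad <- ds$decoys %in%
          positives$compound_id[positives$target_id == ds$target_id]
        stopifnot(!any(bad), !ds$compound_id %in% ds$decoys,
                  !anyDuplicated(ds$decoys))
      }
    }
    ep_loss <- ep_trip <- ep_bce <- ep_dap <- ep_dan <- 0
    n_anchor_seen <- 0L
    for (start in seq(1L, nrow(anchors), by = config$anchors_per_batch)) {
      a_idx <- start:min(start + config$anchors_per_batch - 1L, nrow(anchors))
      batch <- .finetune_batch(anchors[a_idx, , drop = FALSE],
                               decoy_sets[a_idx], n_dec)
      E1 <- proteins$features[batch$target_id, , drop = FALSE]
      E2 <- compounds$features[batch$compound_id, , drop = FALSE]
      fw <- .model_forward(model, E1, E2)
      res <- .finetune_losses(model, fw, batch, config)
      dlogit <- if (lam > 0) {
        lam * (sigmoid(fw$logit) - batch$label) / nrow(batch)
      } else numeric(length(fw$logit))
      grads <- .model_backward(model, fw, dlogit,
                               dL3t_extra = (1 - lam) * res$dL3t,
                               dL3c_extra = (1 - lam) * res$dL3c)
      st <- .adam_step(model$params, grads, state, lr = config$lr)
      model$params <- st$params
      state <- st$state
      w <- length(a_idx)
      ep_loss <- ep_loss + ((1 - lam) * res$triplet + lam * res$bce) * w
      ep_trip <- ep_trip + res$triplet * w
      ep_bce <- ep_bce + res$bce * w
      ep_dap <- ep_dap + res$mean_dap * w
      ep_dan <- ep_dan + res$mean_dan * w
      n_anchor_seen <- n_anchor_seen + w
    }
    trace[[ep]] <- data.frame(
      epoch = ep, loss = ep_loss / n_anchor_seen,
      triplet = ep_trip / n_anchor_seen, bce = ep_bce / n_anchor_seen,
      separation = (ep_dap - ep_dan) / n_anchor_seen
    )
  }
  list(model = model, trace = do.call(rbind, trace) %||%
         data.frame(epoch = integer(0), loss = numeric(0),
                    triplet = numeric(0), bce = numeric(0),
                    separation = numeric(0)))
}

## rows of a fine-tuning batch: for each anchor, the positive pair first,
## then its decoy pairs (label 0)
.finetune_batch <- function(anchors, decoy_sets, n_dec) {
  rows <- lapply(seq_len(nrow(anchors)), function(i) {
    data.frame(
      target_id = anchors$target_id[i],
      compound_id = c(anchors$compound_id[i], decoy_sets[[i]]$decoys),
      label = c(1, rep(0, n_dec)),
      anchor = i
    )
  })
  do.call(rbind, rows)
}

## triplet loss and its gradient w.r.t. the projected embeddings, using
## the cached forward pass of the batch rows
.finetune_losses <- function(model, fw, batch, config) {
  L3t <- fw$m1$L3
  L3c <- fw$m2$L3
  n_rows <- nrow(batch)
  margin <- config$margin
  dL3t <- matrix(0, n_rows, ncol(L3t))
  dL3c <- matrix(0, n_rows, ncol(L3c))
  trip_sum <- 0
  dap_sum <- 0
  dan_sum <- 0
  anchors <- unique(batch$anchor)
  n_anchor <- length(anchors)
  for (a in anchors) {
    idx <- which(batch$anchor == a)
    pos_row <- idx[batch$label[idx] == 1]
    neg_rows <- idx[batch$label[idx] == 0]
    diff_ap <- L3t[pos_row, ] - L3c[pos_row, ]
    d_ap <- sqrt(sum(diff_ap^2))
    diff_an <- L3t[neg_rows, , drop = FALSE] - L3c[neg_rows, , drop = FALSE]
    d_an <- sqrt(rowSums(diff_an^2))
    terms <- pmax(0, d_ap - d_an + margin)
    active <- terms > 0
    n_neg <- length(neg_rows)
    trip_sum <- trip_sum + mean(terms)
    dap_sum <- dap_sum + d_ap
    dan_sum <- dan_sum + mean(d_an)
    w <- 1 / (n_neg * n_anchor)
    if (any(active) && d_ap > 1e-12) {
      u <- diff_ap / d_ap
      dL3t[pos_row, ] <- dL3t[pos_row, ] + w * sum(active) * u
      dL3c[pos_row, ] <- dL3c[pos_row, ] - w * sum(active) * u
    }
    for (j in which(active)) {
      if (d_an[j] <= 1e-12) next
      u <- diff_an[j, ] / d_an[j]
      dL3t[neg_rows[j], ] <- dL3t[neg_rows[j], ] - w * u
      dL3c[neg_rows[j], ] <- dL3c[neg_rows[j], ] + w * u
    }
  }
  bce <- bce_sigmoid_loss(fw$logit, batch$label)
  list(triplet = trip_sum / n_anchor, bce = bce,
       mean_dap = dap_sum / n_anchor, mean_dan = dan_sum / n_anchor,
       dL3t = dL3t, dL3c = dL3c)
}

#' Read / write interaction pair tables
#'
#' CSV or TSV with header `compound_id,target_id,label`.
#' @param path file path.
#' @export
read_pair_table <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "#")
  need <- c("compound_id", "target_id", "label")
  if (!all(need %in% names(df))) {
    stop("pair table ", path, " must have columns: ", paste(need, collapse = ", "))
  }
  df[, need]
}

#' Anchor-positive minus anchor-decoy latent separation
#'
#' Diagnostic for contrastive training: for every positive anchor pair,
#' the Euclidean distance between the target and compound projections
#' (latent width p) is compared with the mean distance to freshly
#' sampled decoys. Negative values mean actives sit closer to their
#' targets than decoys do.
#'
#' @param model an [interaction_model()].
#' @param positives data.frame of positive pairs.
#' @param pool decoy candidate compound ids.
#' @param compounds a `compound_set`. @param proteins a `protein_set`.
#' @param n_decoys decoys per anchor.
#' @param seed integer seed for the decoy draws.
#' @return scalar: mean d(anchor, positive) - mean d(anchor, decoy).
#' @export
latent_separation <- function(model, positives, pool, compounds, proteins,
                              n_decoys = 50L, seed = 1L) {
  L3t <- .as_row(project_modality(proteins$features, model, "target"))
  L3c <- .as_row(project_modality(compounds$features, model, "compound"))
  rownames(L3t) <- proteins$ids
  rownames(L3c) <- compounds$ids
  d_ap <- numeric(nrow(positives))
  d_an <- numeric(nrow(positives))
  for (i in seq_len(nrow(positives))) {
    t <- positives$target_id[i]; cpd <- positives$compound_id[i]
    ds <- sample_decoys(list(target_id = t, compound_id = cpd), pool,
                        positives, n_decoys, seed = derive_seed(seed, i))
    at <- L3t[t, ]
    d_ap[i] <- sqrt(sum((at - L3c[cpd, ])^2))
    d_an[i] <- mean(sqrt(rowSums(
      (L3c[ds$decoys, , drop = FALSE] -
         matrix(at, length(ds$decoys), length(at), byrow = TRUE))^2)))
  }
  mean(d_ap) - mean(d_an)
}
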