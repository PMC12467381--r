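## Latent-space screening: per-entity model embeddings, seeded 2-D
## manifold projection, Euclidean interaction distances, target ranking,
## control-proteome comparison and organ-level aggregation.

#' Extract per-entity latent embeddings from the model
#'
#' Each compound is mapped through the compound projection stack and
#' each protein through the target stack; the per-entity representation
#' is the third-layer projection output (width p). Entity kinds are
#' recorded for downstream grouping.
#'
#' @param model an [interaction_model()].
#' @param compounds a `compound_set` (or NULL).
#' @param proteins a `protein_set` (or NULL).
#' @param kinds optional named character vector mapping protein ids to a
#'   kind (`"ae_target"` or `"control_protein"`); unnamed proteins
#'   default to `"ae_target"`.
#' @return a `latent_embedding` object: list with `ids`, `kinds` and the
#'   embedding matrix `vectors` (entities in rows).
#' @export
extract_entity_embeddings <- function(model, compounds = NULL, proteins = NULL,
                                      kinds = NULL) {
  ids <- character(0); kind <- character(0); vecs <- NULL
  if (!is.null(compounds)) {
    v <- project_modality(compounds$features, model, "compound")
    ids <- c(ids, compounds$ids)
    kind <- c(kind, rep("compound", length(compounds$ids)))
    vecs <- rbind(vecs, .as_row(v))
  }
  if (!is.null(proteins)) {
    v <- project_modality(proteins$features, model, "target")
    k <- rep("ae_target", length(proteins$ids))
    if (!is.null(kinds)) {
      hit <- intersect(proteins$ids, names(kinds))
      k[match(hit, proteins$ids)] <- kinds[hit]
    }
    ids <- c(ids, proteins$ids)
    kind <- c(kind, k)
    vecs <- rbind(vecs, .as_row(v))
  }
  if (is.null(vecs) || nrow(vecs) == 0L) stop("no entities to embed")
  if (any(!is.finite(vecs))) stop("non-finite latent embedding")
  rownames(vecs) <- ids
  structure(list(ids = ids, kinds = stats::setNames(kind, ids), vectors = vecs),
            class = "latent_embedding")
}

#' Project latent embeddings to two dimensions
#'
#' Seeded neighbour-embedding projection (UMAP) that preserves local and
#' global structure; inputs with fewer than `umap_floor` points fall
#' back to a deterministic principal-axes (PCA) projection, since
#' neighbour graphs degenerate at small n. Identical inputs and seed
#' give identical coordinates.
#'
#' @param embeddings a `latent_embedding` (from
#'   [extract_entity_embeddings()]) or a numeric matrix with entity ids
#'   as row names.
#' @param seed integer projection seed.
#' @param umap_floor minimum number of points for the neighbour
#'   embedding (default 30).
#' @param n_neighbors UMAP neighbourhood size.
#' @return data.frame with columns `entity_id`, `entity_kind`, `x`, `y`,
#'   `projection_seed`.
#' @export
manifold_project_2d <- function(embeddings, seed = 1L, umap_floor = 30L,
                                n_neighbors = 15L) {
  if (inherits(embeddings, "latent_embedding")) {
    X <- embeddings$vectors
    kinds <- unname(embeddings$kinds)
  } else {
    X <- as.matrix(embeddings)
    kinds <- rep("unknown", nrow(X))
  }
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 points to project")
  if (n >= umap_floor) {
    xy <- withr::with_seed(seed, uwot::umap(
      X, n_components = 2L, n_neighbors = min(n_neighbors, n - 1L),
      n_threads = 1L, n_sgd_threads = 1L, batch = FALSE
    ))
  } else {
    xy <- .principal_axes_2d(X)
  }
  if (any(!is.finite(xy))) stop("projection produced non-finite coordinates")
  data.frame(
    entity_id = rownames(X) %||% as.character(seq_len(n)),
    entity_kind = kinds,
    x = xy[, 1], y = xy[, 2],
    projection_seed = as.integer(seed),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

## deterministic 2-D PCA with a sign convention (largest-magnitude
## loading positive) so results do not depend on LAPACK sign choices
.principal_axes_2d <- function(X) {
  Xc <- sweep(X, 2L, colMeans(X))
  sv <- svd(Xc, nu = 0L, nv = 2L)
  V <- sv$v
  if (ncol(V) < 2L) V <- cbind(V, 0)
  for (j in 1:2) {
    if (any(V[, j] != 0)) {
      i <- which.max(abs(V[, j]))
      if (V[i, j] < 0) V[, j] <- -V[, j]
    }
  }
  Xc %*% V
}

#' Euclidean interaction distance between two projected points
#'
#' Smaller distances indicate stronger predicted interaction. Points
#' must come from the same projection run: distances across different
#' projection seeds are meaningless and raise an error.
#'
#' @param a,b single rows of a [manifold_project_2d()] result.
#' @return non-negative scalar.
#' @export
interaction_distance <- function(a, b) {
  if (!identical(a$projection_seed, b$projection_seed)) {
    stop("points come from different projection runs (seeds ",
         a$projection_seed, " vs ", b$projection_seed, ")")
  }
  sqrt((a$x - b$x)^2 + (a$y - b$y)^2)
}

#' Rank targets by interaction distance to a compound
#'
#' Rank 1 is the smallest distance (strongest predicted interaction);
#' ties are broken by target id in lexicographic order.
#'
#' @param compound one projected point (single-row data.frame).
#' @param targets projected points of the candidate targets.
#' @return data.frame with `compound_id`, `target_id`, `entity_kind`,
#'   `distance`, `rank`, `projection_seed`.
#' @export
rank_targets <- function(compound, targets) {
  if (nrow(targets) == 0L) stop("empty target list")
  if (any(targets$projection_seed != compound$projection_seed)) {
    stop("compound and targets come from different projection runs")
  }
  d <- sqrt((targets$x - compound$x)^2 + (targets$y - compound$y)^2)
  ord <- order(d, targets$entity_id)
  out <- data.frame(
    compound_id = compound$entity_id,
    target_id = targets$entity_id[ord],
    entity_kind = targets$entity_kind[ord],
    distance = d[ord],
    rank = seq_along(ord),
    projection_seed = compound$projection_seed,
    stringsAsFactors = FALSE, row.names = NULL
  )
  out
}

#' Sample a control proteome
#'
#' Uniform sampling without replacement of `n` protein ids, excluding a
#' set of accessions together with their isoforms: an id whose base
#' accession (the part before any "-" suffix) appears in the exclusion
#' set is ineligible.
#'
#' @param proteome_ids candidate protein ids (accessions, possibly with
#'   isoform suffixes such as "-2").
#' @param exclude accessions to remove (base accessions).
#' @param n number of controls.
#' @param seed integer seed.
#' @return character vector of sampled ids.
#' @export
sample_control_proteins <- function(proteome_ids, exclude, n, seed = 1L) {
  base <- sub("-.*$", "", proteome_ids)
  exclude_base <- sub("-.*$", "", exclude)
  eligible <- proteome_ids[!(base %in% exclude_base)]
  if (length(eligible) < n) {
    stop("control pool too small: need ", n, ", have ", length(eligible))
  }
  withr::with_seed(seed, sample(eligible, n))
}

#' One-sided comparison of interaction distances against controls
#'
#' Welch two-sample t-test of the alternative that the mean distance to
#' the adverse-effect targets is smaller than to the control proteins
#' (closer = stronger predicted interaction).
#'
#' @param ae_distances distances to the adverse-effect-related targets.
#' @param control_distances distances to the control proteins.
#' @return list with `statistic` and `p_value`.
#' @export
compare_to_controls <- function(ae_distances, control_distances) {
  stopifnot(length(ae_distances) >= 2L, length(control_distances) >= 2L)
  res <- tryCatch(
    stats::t.test(ae_distances, control_distances,
                  alternative = "less", var.equal = FALSE),
    error = function(e) NULL
  )
  if (is.null(res)) {
    # both samples essentially constant: fall back to the sign of the
    # mean difference; equal means give p = 0.5 by convention
    dm <- mean(ae_distances) - mean(control_distances)
    p <- if (abs(dm) < .Machine$double.eps^0.5) 0.5 else if (dm < 0) 0 else 1
    return(list(statistic = NA_real_, p_value = p))
  }
  list(statistic = unname(res$statistic), p_value = unname(res$p.value))
}

#' Aggregate interaction distances by organ group over repeated projections
#'
#' Repeats the 2-D projection `n_repetitions` times with derived seeds
#' (`master_seed + repetition index`), recomputes all compound-target
#' distances in each repetition, and reports the per-(compound, target)
#' mean and standard error (sd / sqrt(n)), expanded by each target's
#' organ groups: a target annotated to two organ groups contributes the
#' same statistics to both.
#'
#' @param embeddings a `latent_embedding` containing compounds and
#'   targets.
#' @param organ_map named list mapping `target_id` to a character vector
#'   of organ groups; targets missing from the map are reported with a
#'   warning under `"unmapped"`.
#' @param n_repetitions number of projection repetitions (>= 2).
#' @param master_seed integer master seed.
#' @return data.frame with `compound_id`, `target_id`, `organ_group`,
#'   `mean_distance`, `se_distance`, `n_repetitions`.
#' @export
aggregate_by_organ <- function(embeddings, organ_map, n_repetitions = 5L,
                               master_seed = 1L) {
  stopifnot(n_repetitions >= 2L)
  kinds <- embeddings$kinds
  compound_ids <- names(kinds)[kinds == "compound"]
  target_ids <- names(kinds)[kinds != "compound"]
  if (length(compound_ids) == 0L || length(target_ids) == 0L) {
    stop("need at least one compound and one target")
  }
  dist_rep <- array(
    NA_real_, c(length(compound_ids), length(target_ids), n_repetitions),
    dimnames = list(compound_ids, target_ids, NULL)
  )
  for (r in seq_len(n_repetitions)) {
    pts <- manifold_project_2d(embeddings, seed = master_seed + r)
    xy <- as.matrix(pts[, c("x", "y")])
    rownames(xy) <- pts$entity_id
    for (ci in seq_along(compound_ids)) {
      dx <- xy[target_ids, 1] - xy[compound_ids[ci], 1]
      dy <- xy[target_ids, 2] - xy[compound_ids[ci], 2]
      dist_rep[ci, , r] <- sqrt(dx^2 + dy^2)
    }
  }
  mean_d <- apply(dist_rep, c(1, 2), mean)
  se_d <- apply(dist_rep, c(1, 2), stats::sd) / sqrt(n_repetitions)
  unmapped <- setdiff(target_ids, names(organ_map))
  if (length(unmapped)) {
    warning("targets missing from organ map, reported as 'unmapped': ",
            paste(utils::head(unmapped, 5), collapse = ", "))
  }
  rows <- list()
  for (t in target_ids) {
    organs <- organ_map[[t]] %||% "unmapped"
    for (org in organs) {
      rows[[length(rows) + 1L]] <- data.frame(
        compound_id = compound_ids,
        target_id = t,
        organ_group = org,
        mean_distance = mean_d[, t],
        se_distance = se_d[, t],
        n_repetitions = as.integer(n_repetitions),
        stringsAsFactors = FALSE, row.names = NULL
      )
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$compound_id, out$organ_group, out$target_id), , drop = FALSE]
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision: the mean of precision values at every
#' recall increment, scanning scores from highest to lowest (ties on the
#' score are processed as one block).
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels binary labels.
#' @return scalar in `[0, 1]`.
#' @export
pr_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1)
  if (n_pos == 0L) stop("no positive labels")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # process tied scores as blocks
  blocks <- rle(s)$lengths
  tp <- 0; fp <- 0; ap <- 0
  pos <- 0L
  for (b in blocks) {
    idx <- pos + seq_len(b)
    pos <- pos + b
    tp_new <- tp + sum(y[idx] == 1)
    fp_new <- fp + sum(y[idx] == 0)
    if (tp_new > tp) {
      prec <- tp_new / (tp_new + fp_new)
      ap <- ap + prec * (tp_new - tp) / n_pos
    }
    tp <- tp_new; fp <- fp_new
  }
  ap
}
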