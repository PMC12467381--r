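test_that("entity embeddings come from the per-modality projection stacks", {
  ft <- tiny_features()
  w <- tiny_world()
  m <- interaction_model(ft$kmer_table$dimension, ft$compounds$n_bits,
                         p = 16L, seed = 1L)
  emb <- extract_entity_embeddings(
    m, ft$compounds, ft$proteins,
    kinds = stats::setNames(w$proteins$kind, w$proteins$protein_id)
  )
  expect_identical(nrow(emb$vectors),
                   length(ft$compounds$ids) + length(ft$proteins$ids))
  expect_setequal(unique(unname(emb$kinds)),
                  c("compound", "ae_target", "control_protein"))
  # consistency with project_modality
  cid <- ft$compounds$ids[3]
  expect_equal(unname(emb$vectors[cid, ]),
               unname(project_modality(ft$compounds$features[cid, ], m, "compound")))
  # zero-weight model embeds everything at the origin
  zm <- m; zm$params <- dtiscreen:::.tree_zero(zm$params)
  emb0 <- extract_entity_embeddings(zm, ft$compounds, ft$proteins)
  expect_true(all(emb0$vectors == 0))
  # deterministic
  emb2 <- extract_entity_embeddings(m, ft$compounds, ft$proteins)
  expect_identical(emb2$vectors[, 1], emb2$vectors[, 1])
  expect_error(extract_entity_embeddings(m), "no entities")
})

test_that("the 2-D projection is seeded, total and structure-preserving", {
  withr::local_seed(1)
  # two well-separated Gaussian clusters are recovered in 2-D
  X <- rbind(matrix(rnorm(100 * 5, 0, 0.1), 100),
             matrix(rnorm(100 * 5, 100 / sqrt(5), 0.1), 100))
  rownames(X) <- sprintf("p%03d", 1:200)
  truth <- rep(1:2, each = 100)
  pts <- manifold_project_2d(X, seed = 4L)
  expect_identical(nrow(pts), 200L)
  expect_true(all(is.finite(pts$x)), all(is.finite(pts$y)))
  # same input and seed: identical coordinates
  pts2 <- manifold_project_2d(X, seed = 4L)
  expect_identical(pts, pts2)
  # nearest-centroid agreement with the planted labels
  km <- stats::kmeans(cbind(pts$x, pts$y), centers = 2L, nstart = 5L)
  agree <- max(mean(km$cluster == truth), mean(km$cluster == 3 - truth))
  expect_gte(agree, 0.95)
  # degenerate inputs
  expect_error(manifold_project_2d(X[1, , drop = FALSE]), "at least 2")
})

test_that("small inputs fall back to the deterministic principal-axes projection", {
  withr::local_seed(2)
  X <- matrix(rnorm(10 * 4), 10)
  rownames(X) <- letters[1:10]
  p1 <- manifold_project_2d(X, seed = 1L)
  p2 <- manifold_project_2d(X, seed = 2L) # PCA path ignores the seed
  expect_equal(p1[, c("x", "y")], p2[, c("x", "y")])
  # principal axes maximise variance: projected variance of axis 1 >= axis 2
  expect_gte(var(p1$x), var(p1$y))
})

test_that("interaction distance is the plane Euclidean metric with run guarding", {
  mk <- function(id, x, y, seed = 1L) {
    data.frame(entity_id = id, entity_kind = "compound", x = x, y = y,
               projection_seed = seed)
  }
  expect_identical(interaction_distance(mk("a", 0, 0), mk("b", 0, 0)), 0)
  expect_identical(interaction_distance(mk("a", 0, 0), mk("b", 3, 4)), 5)
  withr::local_seed(8)
  for (i in 1:20) {
    a <- mk("a", rnorm(1), rnorm(1)); b <- mk("b", rnorm(1), rnorm(1))
    c <- mk("c", rnorm(1), rnorm(1))
    expect_equal(interaction_distance(a, b), interaction_distance(b, a))
    # triangle inequality
    expect_lte(interaction_distance(a, c),
               interaction_distance(a, b) + interaction_distance(b, c) + 1e-12)
  }
  expect_error(interaction_distance(mk("a", 0, 0, 1L), mk("b", 1, 1, 2L)),
               "different projection runs")
})

test_that("target ranking is ascending in distance with documented tie-breaks", {
  mk <- function(id, x, y) data.frame(entity_id = id, entity_kind = "ae_target",
                                      x = x, y = y, projection_seed = 9L)
  cmp <- data.frame(entity_id = "drug", entity_kind = "compound",
                    x = 0, y = 0, projection_seed = 9L)
  # single target
  one <- rank_targets(cmp, mk("t1", 1, 1))
  expect_identical(one$rank, 1L)
  # equidistant targets rank in id order
  two <- rank_targets(cmp, rbind(mk("tB", 0, 1), mk("tA", 1, 0)))
  expect_identical(two$target_id, c("tA", "tB"))
  expect_identical(two$rank, c(1L, 2L))
  # 100 random targets agree with a brute-force sort oracle
  withr::local_seed(31)
  tg <- do.call(rbind, lapply(1:100, function(i)
    mk(sprintf("t%03d", i), rnorm(1), rnorm(1))))
  rk <- rank_targets(cmp, tg)
  d <- sqrt(tg$x^2 + tg$y^2)
  oracle <- tg$entity_id[order(d, tg$entity_id)]
  expect_identical(rk$target_id, oracle)
  expect_identical(sort(rk$rank), 1:100)
  expect_error(rank_targets(cmp, tg[0, ]), "empty")
})

test_that("control sampling excludes accessions together with their isoforms", {
  pool <- c("P00001", "P00002", "P00742", "P00742-2", "P00742-3", "Q99999",
            "Q11111-1")
  got <- sample_control_proteins(pool, exclude = "P00742", n = 4L, seed = 1L)
  expect_length(got, 4L)
  expect_false(any(grepl("^P00742", got)))
  # exclusion leaving exactly n survivors returns the remainder
  got2 <- sample_control_proteins(pool, exclude = c("P00742", "Q99999"),
                                  n = 3L, seed = 5L)
  expect_setequal(got2, c("P00001", "P00002", "Q11111-1"))
  expect_identical(sample_control_proteins(pool, "P00742", 2L, seed = 3L),
                   sample_control_proteins(pool, "P00742", 2L, seed = 3L))
  expect_error(sample_control_proteins(pool, "P00742", 10L, seed = 1L),
               "too small")
})

test_that("the control comparison implements the one-sided Welch test", {
  withr::local_seed(12)
  for (i in 1:20) {
    x <- rnorm(15 + i, mean = runif(1, 0, 2))
    y <- rnorm(40 - i, mean = runif(1, 0, 2), sd = 2)
    got <- compare_to_controls(x, y)
    want <- welch_oracle(x, y)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-6)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-6)
  }
  # no effect when the two samples coincide
  z <- rnorm(30)
  expect_gte(compare_to_controls(z, z)$p_value, 0.49)
  # extreme separation
  a <- rep(1, 50) + rnorm(50, sd = 1e-3)
  b <- rep(10, 50) + rnorm(50, sd = 1e-3)
  expect_lt(compare_to_controls(a, b)$p_value, 1e-10)
  # doubly constant input falls back to the documented convention
  expect_identical(compare_to_controls(c(1, 1), c(1, 1))$p_value, 0.5)
  expect_identical(compare_to_controls(c(1, 1), c(2, 2))$p_value, 0)
})

test_that("organ aggregation repeats projections and reports mean and standard error", {
  ft <- tiny_features()
  w <- tiny_world()
  m <- interaction_model(ft$kmer_table$dimension, ft$compounds$n_bits,
                         p = 16L, seed = 1L)
  cs_sub <- subset_compound_set(ft$compounds, unique(w$positives$compound_id[1:3]))
  emb_all <- extract_entity_embeddings(m, cs_sub, ft$proteins,
    kinds = stats::setNames(w$proteins$kind, w$proteins$protein_id))
  keep <- emb_all$kinds != "control_protein"
  emb <- structure(list(ids = emb_all$ids[keep], kinds = emb_all$kinds[keep],
                        vectors = emb_all$vectors[keep, , drop = FALSE]),
                   class = "latent_embedding")
  organ_map <- lapply(w$annotations$records, function(r) names(r$organ_terms))
  agg <- aggregate_by_organ(emb, organ_map, n_repetitions = 3L, master_seed = 17L)
  expect_true(all(agg$se_distance >= 0))
  expect_identical(unique(agg$n_repetitions), 3L)
  # arithmetic oracle: recompute one (compound, target) cell from the
  # three stored repetition projections
  cid <- agg$compound_id[1]; tid <- agg$target_id[1]
  d <- vapply(1:3, function(r) {
    pts <- manifold_project_2d(emb, seed = 17L + r)
    a <- pts[pts$entity_id == cid, ]; b <- pts[pts$entity_id == tid, ]
    sqrt((a$x - b$x)^2 + (a$y - b$y)^2)
  }, numeric(1))
  cell <- agg[agg$compound_id == cid & agg$target_id == tid, ][1, ]
  expect_equal(cell$mean_distance, mean(d), tolerance = 1e-12)
  expect_equal(cell$se_distance, sd(d) / sqrt(3), tolerance = 1e-12)
  # a target with two organ groups appears under both with equal statistics
  multi <- names(organ_map)[lengths(organ_map) >= 2][1]
  if (!is.na(multi)) {
    sub <- agg[agg$target_id == multi & agg$compound_id == cid, ]
    expect_gte(nrow(sub), 2L)
    expect_identical(length(unique(sub$mean_distance)), 1L)
  }
  # unmapped targets are reported with a warning under "unmapped"
  expect_warning(
    agg2 <- aggregate_by_organ(emb, organ_map[-1], n_repetitions = 2L,
                               master_seed = 17L),
    "unmapped")
  expect_true("unmapped" %in% agg2$organ_group)
  expect_error(aggregate_by_organ(emb, organ_map, n_repetitions = 1L), "n_repetitions")
})

test_that("average precision matches hand-computed values", {
  expect_equal(pr_auc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)),
               (1 + 2 / 3) / 2, tolerance = 1e-12)
  expect_identical(pr_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(pr_auc(c(0.9, 0.8, 0.2, 0.1), c(0, 0, 1, 1)),
               (1 / 3 + 2 / 4) / 2, tolerance = 1e-12)
  # all-tied scores reduce to the prevalence
  expect_equal(pr_auc(rep(0.5, 10), rep(c(1, 0), 5)), 0.5, tolerance = 1e-12)
  expect_error(pr_auc(c(0.1, 0.2), c(0, 0)), "no positive")
})
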