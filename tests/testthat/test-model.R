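zero_model <- function(m) {
  m$params <- dtiscreen:::.tree_zero(m$params)
  m
}

test_that("projection stacks are ReLU networks with the stated shape behaviour", {
  m <- interaction_model(6L, 9L, p = 8L, seed = 1L)
  e <- rnorm(6)
  out <- project_modality(e, m, "target")
  expect_length(out, 8L)
  expect_true(all(out >= 0))
  # zero parameters give the zero vector
  expect_identical(project_modality(e, zero_model(m), "target"), rep(0, 8L))
  # dimension mismatch is a shape error
  expect_error(project_modality(rnorm(5), m, "target"), "dimension mismatch")
  expect_error(project_modality(rnorm(6), m, "compound"), "dimension mismatch")
})

test_that("each forward component matches the straight-line oracle", {
  withr::local_seed(42)
  for (i in 1:25) {
    m <- interaction_model(5L, 7L, p = 8L, seed = i)
    e1 <- rnorm(5); e2 <- rnorm(7)
    or <- oracle_forward(m, e1, e2)
    L3t <- project_modality(e1, m, "target")
    L3c <- project_modality(e2, m, "compound")
    expect_equal(L3t, or$L3t, tolerance = 1e-6)
    expect_equal(L3c, or$L3c, tolerance = 1e-6)
    A <- dual_cross_attention(L3t, L3c, m)
    expect_equal(A, or$A, tolerance = 1e-6)
    cl <- classify_pair(L3t, L3c, A, m)
    expect_equal(cl$logit, or$logit, tolerance = 1e-6)
    expect_equal(cl$probability, or$prob, tolerance = 1e-6)
  }
})

test_that("gate attention reduces to 0.5 * V when queries are dead", {
  m <- interaction_model(4L, 4L, p = 8L, seed = 3L)
  m$params$att$Wq1[] <- 0 # Q1 = 0 so <q1, k2> = 0, gate = sigmoid(0)
  m$params$att$Wq2[] <- 0
  L3t <- abs(rnorm(8)); L3c <- abs(rnorm(8))
  a <- m$params$att
  h1 <- 0.5 * drop(L3c %*% a$Wv2)
  h2 <- 0.5 * drop(L3t %*% a$Wv1)
  expect_equal(dual_cross_attention(L3t, L3c, m),
               drop(c(h1, h2) %*% a$WG), tolerance = 1e-10)
})

test_that("with shared head parameters, swapping inputs permutes the heads", {
  m <- interaction_model(4L, 4L, p = 8L, seed = 5L)
  # share the query/key/value maps across the two streams
  m$params$att$Wq2 <- m$params$att$Wq1
  m$params$att$Wk2 <- m$params$att$Wk1
  m$params$att$Wv2 <- m$params$att$Wv1
  x <- abs(rnorm(8)); y <- abs(rnorm(8))
  fw_xy <- dtiscreen:::.attention_forward(matrix(x, 1), matrix(y, 1), m)
  fw_yx <- dtiscreen:::.attention_forward(matrix(y, 1), matrix(x, 1), m)
  expect_equal(unname(fw_xy$H[1, ]),
               unname(fw_yx$H[1, c(5:8, 1:4)]), tolerance = 1e-10)
})

test_that("token attention mode runs, is deterministic, and keeps dimensions", {
  m <- interaction_model(5L, 7L, p = 16L, n_tokens = 4L,
                         attention_mode = "token", seed = 2L)
  L3t <- project_modality(rnorm(5), m, "target")
  L3c <- project_modality(rnorm(7), m, "compound")
  A1 <- dual_cross_attention(L3t, L3c, m)
  expect_length(A1, 16L)
  expect_identical(A1, dual_cross_attention(L3t, L3c, m))
  expect_error(interaction_model(5L, 7L, p = 16L, n_tokens = 3L,
                                 attention_mode = "token"), "divisible")
})

test_that("the classifier head standardises and reads out as specified", {
  m <- interaction_model(4L, 4L, p = 8L, seed = 7L)
  # neutral affine + zero readout: logit 0, probability one half
  m0 <- m
  m0$params$head$alpha[] <- 1; m0$params$head$beta[] <- 0
  m0$params$head$W4[] <- 0; m0$params$head$b4 <- 0
  cl <- classify_pair(abs(rnorm(8)), abs(rnorm(8)), rnorm(8), m0)
  expect_identical(cl$logit, 0)
  expect_identical(cl$probability, 0.5)
  # layer-norm identity: standardised vector has mean ~0 and variance ~1
  hf <- dtiscreen:::.head_forward(matrix(abs(rnorm(8)), 1),
                                  matrix(abs(rnorm(8)), 1),
                                  matrix(rnorm(8), 1), m)
  expect_lt(abs(mean(hf$xhat)), 1e-6)
  expect_lt(abs(mean(hf$xhat^2) - 1), 10 * m$config$eps)
  expect_error(classify_pair(rnorm(4), rnorm(8), rnorm(8), m),
               "dimension mismatch")
})

test_that("checkpoints save and load to bit-identical predictions", {
  ft <- tiny_features()
  m <- interaction_model(ft$kmer_table$dimension, ft$compounds$n_bits,
                         p = 16L, seed = 13L)
  pairs <- tiny_world()$pairs[1:8, ]
  p1 <- predict_interaction(m, ft$compounds, ft$proteins, pairs)
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  expect_identical(predict_interaction(m2, ft$compounds, ft$proteins, pairs), p1)
  expect_identical(m2$config$p, m$config$p)
  # a corrupted tensor shape is rejected on load
  bad <- readRDS(f)
  bad$params$att$WG <- bad$params$att$WG[, -1]
  f2 <- withr::local_tempfile(fileext = ".rds")
  saveRDS(bad, f2)
  expect_error(load_model(f2), "shape")
})

test_that("backpropagation matches finite differences on a sampled subset of parameters", {
  withr::local_seed(99)
  m <- interaction_model(7L, 9L, p = 8L, seed = 31L)
  E1 <- matrix(rnorm(6 * 7), 6)
  E2 <- matrix(rnorm(6 * 9), 6)
  y <- c(1, 0, 1, 1, 0, 0)
  loss_at <- function(mm) {
    bce_sigmoid_loss(dtiscreen:::.model_forward(mm, E1, E2)$logit, y)
  }
  fw <- dtiscreen:::.model_forward(m, E1, E2)
  grads <- dtiscreen:::.model_backward(m, fw, (dtiscreen:::sigmoid(fw$logit) - y) / 6)
  eps <- 1e-6
  n_checked <- 0L
  for (grp in names(m$params)) {
    for (nm in names(m$params[[grp]])) {
      par <- m$params[[grp]][[nm]]
      take <- sample(length(par), max(1L, ceiling(length(par) * 0.01)))
      for (i in take) {
        mp <- m; mp$params[[grp]][[nm]][i] <- par[i] + eps
        mn <- m; mn$params[[grp]][[nm]][i] <- par[i] - eps
        fd <- (loss_at(mp) - loss_at(mn)) / (2 * eps)
        an <- grads[[grp]][[nm]][i]
        if (abs(fd) + abs(an) > 1e-8) {
          expect_lt(abs(fd - an) / (abs(fd) + abs(an)), 1e-3,
                    label = sprintf("grad %s$%s[%d]", grp, nm, i))
        }
        n_checked <- n_checked + 1L
      }
    }
  }
  expect_gte(n_checked, 20L)
})

test_that("fine-tuning gradients (triplet + BCE mix) match finite differences", {
  withr::local_seed(7)
  ft <- tiny_features()
  w <- tiny_world()
  m <- interaction_model(ft$kmer_table$dimension, ft$compounds$n_bits,
                         p = 8L, seed = 17L)
  anchors <- w$positives[1:2, ]
  ds <- lapply(1:2, function(i) {
    sample_decoys(anchors[i, ], w$decoy_pool, w$positives, 3L, seed = i)
  })
  batch <- dtiscreen:::.finetune_batch(anchors, ds, 3L)
  E1 <- ft$proteins$features[batch$target_id, , drop = FALSE]
  E2 <- ft$compounds$features[batch$compound_id, , drop = FALSE]
  cfg <- training_config(margin = 1, lambda_bce = 0.5, n_decoys = 3L)
  total_at <- function(mm) {
    fw <- dtiscreen:::.model_forward(mm, E1, E2)
    res <- dtiscreen:::.finetune_losses(mm, fw, batch, cfg)
    0.5 * res$triplet + 0.5 * res$bce
  }
  fw <- dtiscreen:::.model_forward(m, E1, E2)
  res <- dtiscreen:::.finetune_losses(m, fw, batch, cfg)
  dlogit <- 0.5 * (dtiscreen:::sigmoid(fw$logit) - batch$label) / nrow(batch)
  grads <- dtiscreen:::.model_backward(m, fw, dlogit,
                                       dL3t_extra = 0.5 * res$dL3t,
                                       dL3c_extra = 0.5 * res$dL3c)
  eps <- 1e-6
  for (probe in list(c("t", "W3"), c("c", "W3"), c("t", "b1"), c("head", "W4"))) {
    par <- m$params[[probe[1]]][[probe[2]]]
    for (i in sample(length(par), 4L)) {
      mp <- m; mp$params[[probe[1]]][[probe[2]]][i] <- par[i] + eps
      mn <- m; mn$params[[probe[1]]][[probe[2]]][i] <- par[i] - eps
      fd <- (total_at(mp) - total_at(mn)) / (2 * eps)
      an <- grads[[probe[1]]][[probe[2]]][i]
      if (abs(fd) + abs(an) > 1e-8) {
        expect_lt(abs(fd - an) / (abs(fd) + abs(an)), 1e-3,
                  label = sprintf("finetune grad %s$%s[%d]", probe[1], probe[2], i))
      }
    }
  }
})
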