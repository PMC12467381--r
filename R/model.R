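## The cross-modal interaction model: two 3-layer ReLU projection stacks
## (one per modality), a dual-headed cross-modal attention block, and a
## residual + layer-norm + linear classifier head. All operations are
## written against batches (samples in rows); the exported single-pair
## operations are thin wrappers.

.he_init <- function(n_in, n_out) {
  lim <- sqrt(6 / n_in)
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

#' Construct an interaction model
#'
#' Creates a seeded, randomly initialised model. `p` is the shared latent
#' width: the third projection layer of both modalities, the attention
#' output and the classifier head all live in R^p; each attention head
#' has width `p/2`.
#'
#' @param dim_target input dimension of the target (protein) embedding.
#' @param dim_compound input dimension of the compound fingerprint.
#' @param p latent width (even; 1024 in the full-scale configuration,
#'   64 in the fast test preset).
#' @param hidden widths of projection layers 1 and 2 (default `c(p, p)`).
#' @param attention_mode `"gate"` (scalar sigmoid gate per head, default)
#'   or `"token"` (latent vector reshaped into tokens with softmax
#'   attention). See the methods vignette for the two readings.
#' @param n_tokens tokens per head in `"token"` mode.
#' @param eps layer-norm stabiliser (> 0).
#' @param seed integer seed for parameter initialisation.
#' @return an object of class `interaction_model`.
#' @export
interaction_model <- function(dim_target, dim_compound, p = 64L,
                              hidden = c(p, p),
                              attention_mode = c("gate", "token"),
                              n_tokens = 32L, eps = 1e-5, seed = 1L) {
  attention_mode <- match.arg(attention_mode)
  stopifnot(p %% 2 == 0, eps > 0, length(hidden) == 2L)
  p2 <- p %/% 2L
  if (attention_mode == "token" && p2 %% n_tokens != 0)
    stop("head width p/2 must be divisible by n_tokens in token mode")
  params <- withr::with_seed(seed, list(
    t = list(W1 = .he_init(dim_target, hidden[1]), b1 = numeric(hidden[1]),
             W2 = .he_init(hidden[1], hidden[2]), b2 = numeric(hidden[2]),
             W3 = .he_init(hidden[2], p), b3 = numeric(p)),
    c = list(W1 = .he_init(dim_compound, hidden[1]), b1 = numeric(hidden[1]),
             W2 = .he_init(hidden[1], hidden[2]), b2 = numeric(hidden[2]),
             W3 = .he_init(hidden[2], p), b3 = numeric(p)),
    att = list(Wq1 = .he_init(p, p2), Wk1 = .he_init(p, p2), Wv1 = .he_init(p, p2),
               Wq2 = .he_init(p, p2), Wk2 = .he_init(p, p2), Wv2 = .he_init(p, p2),
               WG = .he_init(p, p)),
    head = list(alpha = rep(1, p), beta = numeric(p),
                W4 = .he_init(p, 1L)[, 1L], b4 = 0)
  ))
  structure(
    list(params = params,
         config = list(dim_target = as.integer(dim_target),
                       dim_compound = as.integer(dim_compound),
                       p = as.integer(p), hidden = as.integer(hidden),
                       attention_mode = attention_mode,
                       n_tokens = as.integer(n_tokens),
                       eps = eps, seed = as.integer(seed))),
    class = "interaction_model"
  )
}

.as_row <- function(x) if (is.matrix(x)) x else matrix(x, 1L)

.mlp_forward <- function(X, stack) {
  Z1 <- sweep(X %*% stack$W1, 2L, stack$b1, "+")
  L1 <- pmax(Z1, 0)
  Z2 <- sweep(L1 %*% stack$W2, 2L, stack$b2, "+")
  L2 <- pmax(Z2, 0)
  Z3 <- sweep(L2 %*% stack$W3, 2L, stack$b3, "+")
  L3 <- pmax(Z3, 0)
  list(X = X, Z1 = Z1, L1 = L1, Z2 = Z2, L2 = L2, Z3 = Z3, L3 = L3)
}

#' Project a modality embedding through its 3-layer ReLU stack
#'
#' `L3 = ReLU(W3' ReLU(W2' ReLU(W1' E + b1) + b2) + b3)`; every entry of
#' the output is non-negative and the output dimension is the latent
#' width p.
#'
#' @param E embedding vector (or matrix with samples in rows).
#' @param model an [interaction_model()].
#' @param modality `"target"` or `"compound"` (selects the stack).
#' @return numeric vector (or matrix) of width p.
#' @export
project_modality <- function(E, model, modality = c("target", "compound")) {
  modality <- match.arg(modality)
  stack <- if (modality == "target") model$params$t else model$params$c
  E <- .as_row(E)
  d_in <- nrow(stack$W1)
  if (ncol(E) != d_in) {
    stop("dimension mismatch: input has ", ncol(E), " features, stack expects ", d_in)
  }
  out <- .mlp_forward(E, stack)$L3
  if (nrow(out) == 1L) drop(out) else out
}

## batched attention; returns cache for backprop (gate mode)
.attention_forward <- function(L3t, L3c, model) {
  a <- model$params$att
  p <- model$config$p
  p2 <- p %/% 2L
  scl <- sqrt(p2)
  Q1 <- L3t %*% a$Wq1; K1 <- L3t %*% a$Wk1; V1 <- L3t %*% a$Wv1
  Q2 <- L3c %*% a$Wq2; K2 <- L3c %*% a$Wk2; V2 <- L3c %*% a$Wv2
  if (model$config$attention_mode == "gate") {
    s1 <- rowSums(Q1 * K2) / scl
    s2 <- rowSums(Q2 * K1) / scl
    g1 <- sigmoid(s1)
    g2 <- sigmoid(s2)
    h1 <- V2 * g1
    h2 <- V1 * g2
  } else {
    # token mode: each head vector is reshaped to n_tokens x (p2/n_tokens)
    # and standard softmax attention is applied across tokens
    Tn <- model$config$n_tokens
    dt <- p2 %/% Tn
    att_rows <- function(Q, K, V) {
      out <- matrix(0, nrow(Q), p2)
      for (i in seq_len(nrow(Q))) {
        Qi <- matrix(Q[i, ], Tn, dt, byrow = TRUE)
        Ki <- matrix(K[i, ], Tn, dt, byrow = TRUE)
        Vi <- matrix(V[i, ], Tn, dt, byrow = TRUE)
        S <- Qi %*% t(Ki) / sqrt(dt)
        S <- exp(S - apply(S, 1, max))
        S <- S / rowSums(S)
        out[i, ] <- as.vector(t(S %*% Vi))
      }
      out
    }
    h1 <- att_rows(Q1, K2, V2)
    h2 <- att_rows(Q2, K1, V1)
    s1 <- g1 <- s2 <- g2 <- NULL
  }
  H <- cbind(h1, h2)
  A <- H %*% a$WG
  list(Q1 = Q1, K1 = K1, V1 = V1, Q2 = Q2, K2 = K2, V2 = V2,
       s1 = s1, g1 = g1, s2 = s2, g2 = g2, H = H, A = A, scl = scl)
}

#' Dual-headed cross-modal attention
#'
#' Head 1 forms queries from the target stream and keys/values from the
#' compound stream; head 2 reverses the roles. The two head outputs
#' (each of width p/2) are concatenated and mixed by the global weight
#' `WG`. In `"gate"` mode each head output is
#' `sigmoid(<q, k> / sqrt(p/2)) * v`; in `"token"` mode the head vectors
#' are reshaped into tokens and standard softmax attention is applied.
#'
#' @param L3_target,L3_compound projected latent vectors (length p), or
#'   matrices with samples in rows.
#' @param model an [interaction_model()].
#' @return attention output of dimension p.
#' @export
dual_cross_attention <- function(L3_target, L3_compound, model) {
  L3t <- .as_row(L3_target); L3c <- .as_row(L3_compound)
  p <- model$config$p
  if (ncol(L3t) != p || ncol(L3c) != p) {
    stop("dimension mismatch: attention inputs must have width p = ", p)
  }
  A <- .attention_forward(L3t, L3c, model)$A
  if (nrow(A) == 1L) drop(A) else A
}

.head_forward <- function(L3t, L3c, A, model) {
  h <- model$params$head
  eps <- model$config$eps
  Ahat <- L3t + L3c + A
  mu <- rowMeans(Ahat)
  ctr <- Ahat - mu
  v <- rowMeans(ctr^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- ctr * inv
  lnout <- sweep(sweep(xhat, 2L, h$alpha, "*"), 2L, h$beta, "+")
  logit <- drop(lnout %*% h$W4) + h$b4
  list(Ahat = Ahat, mu = mu, v = v, inv = inv, xhat = xhat,
       lnout = lnout, logit = logit)
}

#' Residual + layer-norm + linear classifier head
#'
#' Forms the residual sum of the two projected embeddings and the
#' attention output, standardises it by its own empirical mean and
#' variance (with stabiliser eps), applies the learned gain/shift, and
#' reads out a single logit; the probability is its sigmoid.
#'
#' @param L3_target,L3_compound,A latent vectors of width p (or matrices).
#' @param model an [interaction_model()].
#' @return list with `logit` and `probability`.
#' @export
classify_pair <- function(L3_target, L3_compound, A, model) {
  L3t <- .as_row(L3_target); L3c <- .as_row(L3_compound); A <- .as_row(A)
  p <- model$config$p
  if (ncol(L3t) != p || ncol(L3c) != p || ncol(A) != p) {
    stop("dimension mismatch: classifier inputs must have width p = ", p)
  }
  hf <- .head_forward(L3t, L3c, A, model)
  list(logit = unname(hf$logit), probability = unname(sigmoid(hf$logit)))
}

## full forward pass with cache (used by training)
.model_forward <- function(model, E1, E2) {
  E1 <- .as_row(E1); E2 <- .as_row(E2)
  m1 <- .mlp_forward(E1, model$params$t)
  m2 <- .mlp_forward(E2, model$params$c)
  at <- .attention_forward(m1$L3, m2$L3, model)
  hd <- .head_forward(m1$L3, m2$L3, at$A, model)
  list(m1 = m1, m2 = m2, at = at, hd = hd,
       logit = hd$logit, prob = sigmoid(hd$logit))
}

#' Predict interaction probabilities for id pairs
#'
#' @param model trained [interaction_model()].
#' @param compounds a `compound_set`. @param proteins a `protein_set`.
#' @param pairs data.frame with columns `compound_id`, `target_id`.
#' @return numeric vector of probabilities.
#' @export
predict_interaction <- function(model, compounds, proteins, pairs) {
  E1 <- proteins$features[pairs$target_id, , drop = FALSE]
  E2 <- compounds$features[pairs$compound_id, , drop = FALSE]
  drop(.model_forward(model, E1, E2)$prob)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single archive holding every parameter tensor
#' plus a JSON configuration block; loading validates shape consistency
#' and reproduces bit-identical predictions.
#'
#' @param model an [interaction_model()].
#' @param path checkpoint path.
#' @export
save_model <- function(model, path) {
  obj <- list(
    config_json = as.character(jsonlite::toJSON(model$config, auto_unbox = TRUE,
                                                digits = NA)),
    params = model$params
  )
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  config <- jsonlite::fromJSON(obj$config_json)
  config$hidden <- as.integer(config$hidden)
  model <- structure(list(params = obj$params, config = config),
                     class = "interaction_model")
  .validate_model(model)
  model
}

.validate_model <- function(model) {
  cfg <- model$config
  p <- cfg$p; p2 <- p %/% 2L; h <- cfg$hidden
  pr <- model$params
  expect_dim <- function(x, d, what) {
    if (!identical(dim(x) %||% length(x), d)) {
      stop("checkpoint shape inconsistency in ", what)
    }
  }
  expect_dim(pr$t$W1, c(cfg$dim_target, h[1]), "target W1")
  expect_dim(pr$c$W1, c(cfg$dim_compound, h[1]), "compound W1")
  expect_dim(pr$t$W3, c(h[2], p), "target W3")
  expect_dim(pr$c$W3, c(h[2], p), "compound W3")
  expect_dim(pr$att$Wq1, c(p, p2), "Wq1")
  expect_dim(pr$att$WG, c(p, p), "WG")
  expect_dim(pr$head$alpha, as.integer(p), "alpha")
  expect_dim(pr$head$W4, as.integer(p), "W4")
  invisible(TRUE)
}

#' @export
print.interaction_model <- function(x, ...) {
  cfg <- x$config
  n_par <- sum(rapply(x$params, length, how = "unlist"))
  cat(sprintf(
    "interaction_model: p=%d, inputs %d (target) / %d (compound), %s attention, %d parameters\n",
    cfg$p, cfg$dim_target, cfg$dim_compound, cfg$attention_mode, n_par))
  invisible(x)
}
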