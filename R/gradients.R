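## Hand-derived backpropagation for the interaction model (gate attention
## mode) and a small Adam optimiser over the nested parameter list.

.mlp_backward <- function(stack, mf, dL3) {
  dZ3 <- dL3 * (mf$Z3 > 0)
  dW3 <- crossprod(mf$L2, dZ3)
  db3 <- colSums(dZ3)
  dL2 <- dZ3 %*% t(stack$W3)
  dZ2 <- dL2 * (mf$Z2 > 0)
  dW2 <- crossprod(mf$L1, dZ2)
  db2 <- colSums(dZ2)
  dL1 <- dZ2 %*% t(stack$W2)
  dZ1 <- dL1 * (mf$Z1 > 0)
  dW1 <- crossprod(mf$X, dZ1)
  db1 <- colSums(dZ1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, W3 = dW3, b3 = db3)
}

## dlogit: gradient of the loss w.r.t. each logit (length n).
## dL3t_extra/dL3c_extra: additional gradients flowing directly into the
## projected embeddings (used by the triplet term, which bypasses the
## attention block and classifier head).
.model_backward <- function(model, fw, dlogit,
                            dL3t_extra = NULL, dL3c_extra = NULL) {
  if (model$config$attention_mode != "gate") {
    stop("training backprop is implemented for the gate attention mode only")
  }
  pr <- model$params
  p <- model$config$p
  p2 <- p %/% 2L
  hd <- fw$hd; at <- fw$at
  L3t <- fw$m1$L3; L3c <- fw$m2$L3
  n <- nrow(L3t)
  dlogit <- as.numeric(dlogit)

  # classifier head
  dW4 <- drop(crossprod(hd$lnout, dlogit))
  db4 <- sum(dlogit)
  dlnout <- outer(dlogit, pr$head$W4)
  dalpha <- colSums(dlnout * hd$xhat)
  dbeta <- colSums(dlnout)
  dxhat <- sweep(dlnout, 2L, pr$head$alpha, "*")
  dAhat <- hd$inv * (dxhat - rowMeans(dxhat) - hd$xhat * rowMeans(dxhat * hd$xhat))

  dL3t <- dAhat
  dL3c <- dAhat
  dA <- dAhat

  # attention block
  dWG <- crossprod(at$H, dA)
  dH <- dA %*% t(pr$att$WG)
  dh1 <- dH[, seq_len(p2), drop = FALSE]
  dh2 <- dH[, p2 + seq_len(p2), drop = FALSE]

  dV2 <- dh1 * at$g1
  dg1 <- rowSums(dh1 * at$V2)
  ds1 <- dg1 * at$g1 * (1 - at$g1) / at$scl
  dQ1 <- ds1 * at$K2
  dK2 <- ds1 * at$Q1

  dV1 <- dh2 * at$g2
  dg2 <- rowSums(dh2 * at$V1)
  ds2 <- dg2 * at$g2 * (1 - at$g2) / at$scl
  dQ2 <- ds2 * at$K1
  dK1 <- ds2 * at$Q2

  datt <- list(
    Wq1 = crossprod(L3t, dQ1), Wk1 = crossprod(L3t, dK1), Wv1 = crossprod(L3t, dV1),
    Wq2 = crossprod(L3c, dQ2), Wk2 = crossprod(L3c, dK2), Wv2 = crossprod(L3c, dV2),
    WG = dWG
  )
  dL3t <- dL3t + dQ1 %*% t(pr$att$Wq1) + dK1 %*% t(pr$att$Wk1) + dV1 %*% t(pr$att$Wv1)
  dL3c <- dL3c + dQ2 %*% t(pr$att$Wq2) + dK2 %*% t(pr$att$Wk2) + dV2 %*% t(pr$att$Wv2)

  if (!is.null(dL3t_extra)) dL3t <- dL3t + dL3t_extra
  if (!is.null(dL3c_extra)) dL3c <- dL3c + dL3c_extra

  list(
    t = .mlp_backward(pr$t, fw$m1, dL3t),
    c = .mlp_backward(pr$c, fw$m2, dL3c),
    att = datt,
    head = list(alpha = dalpha, beta = dbeta, W4 = dW4, b4 = db4)
  )
}

## elementwise map over two/three parallel nested parameter lists
.tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- mapply(.tree_map2, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
    return(out)
  }
  f(a, b)
}

.tree_zero <- function(a) {
  if (is.list(a)) return(lapply(a, .tree_zero))
  a * 0
}

.adam_init <- function(params) {
  list(m = .tree_zero(params), v = .tree_zero(params), t = 0L)
}

.adam_step <- function(params, grads, state, lr = 1e-3,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- .tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- .tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  upd <- .tree_map2(function(m, v) lr * (m / c1) / (sqrt(v / c2) + eps),
                    state$m, state$v)
  params <- .tree_map2(`-`, params, upd)
  list(params = params, state = state)
}
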