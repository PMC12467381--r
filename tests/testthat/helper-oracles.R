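# Independent oracles used across tests. These deliberately avoid the
# package's own linear-algebra paths: everything is written as explicit
# scalar loops or textbook formulas.

# straight-line scalar implementation of the composed forward pass
# (projection stacks -> gated dual cross attention -> residual +
# layer-norm + linear readout) for a single pair
oracle_forward <- function(model, e1, e2) {
  relu <- function(x) ifelse(x > 0, x, 0)
  mlp <- function(e, st) {
    l1 <- relu(as.vector(t(st$W1) %*% e + st$b1))
    l2 <- relu(as.vector(t(st$W2) %*% l1 + st$b2))
    relu(as.vector(t(st$W3) %*% l2 + st$b3))
  }
  p <- model$config$p
  p2 <- p / 2
  a <- model$params$att
  l3t <- mlp(e1, model$params$t)
  l3c <- mlp(e2, model$params$c)
  q1 <- as.vector(t(a$Wq1) %*% l3t); k1 <- as.vector(t(a$Wk1) %*% l3t)
  v1 <- as.vector(t(a$Wv1) %*% l3t)
  q2 <- as.vector(t(a$Wq2) %*% l3c); k2 <- as.vector(t(a$Wk2) %*% l3c)
  v2 <- as.vector(t(a$Wv2) %*% l3c)
  g1 <- 1 / (1 + exp(-sum(q1 * k2) / sqrt(p2)))
  g2 <- 1 / (1 + exp(-sum(q2 * k1) / sqrt(p2)))
  A <- as.vector(t(a$WG) %*% c(g1 * v2, g2 * v1))
  ahat <- l3t + l3c + A
  mu <- mean(ahat)
  va <- mean((ahat - mu)^2)
  xhat <- (ahat - mu) / sqrt(va + model$config$eps)
  h <- model$params$head
  logit <- sum(h$W4 * (xhat * h$alpha + h$beta)) + h$b4
  list(L3t = l3t, L3c = l3c, A = A, logit = logit,
       prob = 1 / (1 + exp(-logit)))
}

# dynamic-programming Levenshtein distance
dp_levenshtein <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  D <- matrix(0L, n + 1, m + 1)
  D[, 1] <- 0:n
  D[1, ] <- 0:m
  if (n > 0 && m > 0) {
    for (i in 1:n) for (j in 1:m) {
      D[i + 1, j + 1] <- min(D[i, j + 1] + 1L, D[i + 1, j] + 1L,
                             D[i, j] + (ca[i] != cb[j]))
    }
  }
  D[n + 1, m + 1]
}

# naive agglomerative clustering oracle: repeatedly merge the closest
# pair of clusters under the given linkage, from a distance matrix
brute_agglom <- function(D, k, linkage = "average") {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  linkfun <- switch(linkage, average = mean, single = min, complete = max)
  while (length(clusters) > k) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      d <- linkfun(D[clusters[[i]], clusters[[j]]])
      if (d < best[1]) best <- c(d, i, j)
    }
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  lab <- integer(n)
  for (i in seq_along(clusters)) lab[clusters[[i]]] <- i
  lab
}

# Welch two-sample t statistic and one-sided p (H1: mean(x) < mean(y))
welch_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(statistic = t, p_value = pt(t, df))
}

random_word <- function(len) {
  paste(sample(letters[1:6], len, replace = TRUE), collapse = "")
}
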