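# Independent brute-force oracles: per-node loops and textbook formulas,
# deliberately sharing no code with the package's vectorised implementations.

neighbors_of <- function(g, i) {
  e <- g$edges
  c(e[e[, 1L] == i, 2L], e[e[, 2L] == i, 1L])
}

oracle_gcn_mp <- function(h, g, w) {
  n <- g$n_nodes
  deg <- sapply(seq_len(n), function(i) length(neighbors_of(g, i))) + 1
  out <- matrix(0, n, ncol(w))
  for (i in seq_len(n)) {
    for (j in c(i, neighbors_of(g, i))) {
      out[i, ] <- out[i, ] +
        as.vector(t(w) %*% h[j, ]) / (sqrt(deg[i]) * sqrt(deg[j]))
    }
  }
  out
}

oracle_sage <- function(h, g, w1, w2) {
  n <- g$n_nodes
  out <- matrix(0, n, ncol(w1))
  for (i in seq_len(n)) {
    nb <- c(i, neighbors_of(g, i))
    mean_h <- colMeans(h[nb, , drop = FALSE])
    out[i, ] <- as.vector(t(w1) %*% h[i, ]) + as.vector(t(w2) %*% mean_h)
  }
  out
}

oracle_graphconv <- function(h, g, w1, w2) {
  n <- g$n_nodes
  out <- matrix(0, n, ncol(w1))
  for (i in seq_len(n)) {
    out[i, ] <- as.vector(t(w1) %*% h[i, ])
    for (j in neighbors_of(g, i)) {
      out[i, ] <- out[i, ] + as.vector(t(w2) %*% h[j, ])
    }
  }
  out
}

oracle_featgraphconv <- function(h, g, w1, w2) {
  n <- g$n_nodes
  gmat <- matrix(0, n, ncol(w1))
  for (i in seq_len(n)) gmat[i, ] <- as.vector(t(w1) %*% h[i, ])
  out <- matrix(0, n, ncol(w2))
  for (i in seq_len(n)) {
    nb <- c(i, neighbors_of(g, i))
    mean_g <- colMeans(gmat[nb, , drop = FALSE])
    out[i, ] <- as.vector(t(w2) %*% c(gmat[i, ], mean_g))
  }
  out
}

# Dense evaluation of the normalised adjacency: D^{-1/2}(A+I)D^{-1/2}.
oracle_normalized_adjacency <- function(g) {
  n <- g$n_nodes
  a <- matrix(0, n, n)
  for (r in seq_len(nrow(g$edges))) {
    i <- g$edges[r, 1L]; j <- g$edges[r, 2L]
    a[i, j] <- 1; a[j, i] <- 1
  }
  a_hat <- a + diag(n)
  d <- rowSums(a_hat)
  diag(1 / sqrt(d)) %*% a_hat %*% diag(1 / sqrt(d))
}

# AUC by exhaustive pairwise comparison, ties counted one half.
oracle_auc <- function(pos, neg) {
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Average precision: mean of precision at the rank of each positive.
oracle_ap <- function(pos, neg) {
  scores <- c(pos, neg)
  lab <- c(rep(1, length(pos)), rep(0, length(neg)))
  lab <- lab[order(scores, decreasing = TRUE)]
  hits <- 0; total <- 0
  for (k in seq_along(lab)) {
    if (lab[k] == 1) {
      hits <- hits + 1
      total <- total + hits / k
    }
  }
  total / length(pos)
}

# Weighted full-matrix binary cross-entropy by explicit double loop.
oracle_reconstruction_loss <- function(z, g) {
  n <- g$n_nodes
  a <- matrix(0, n, n)
  for (r in seq_len(nrow(g$edges))) {
    a[g$edges[r, 1L], g$edges[r, 2L]] <- 1
    a[g$edges[r, 2L], g$edges[r, 1L]] <- 1
  }
  pw <- (n^2 - sum(a)) / sum(a)
  total <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- sum(z[i, ] * z[j, ])
    p <- 1 / (1 + exp(-s))
    total <- total + if (a[i, j] == 1) -pw * log(p) else -log(1 - p)
  }
  total / n^2
}

# R^2 via explicit normal equations with pseudo-inverse.
oracle_r_squared <- function(z, x) {
  d <- cbind(1, z)
  b <- MASS::ginv(t(d) %*% d) %*% t(d) %*% x
  resid <- x - d %*% b
  xc <- sweep(x, 2, colMeans(x))
  1 - sum(resid^2) / sum(xc^2)
}

random_test_graph <- function(n, p, seed) erdos_renyi_graph(n, p, seed = seed)

make_line_graph <- function(ids) {
  new_graph(ids, cbind(seq_len(length(ids) - 1L), seq(2L, length(ids))))
}
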