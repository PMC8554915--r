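# Dense/sparse matrix neural-network engine: Glorot initialisation, explicit
# forward/backward passes for each message-passing layer kind, and Adam.
# Full-batch training throughout -- the graphs here are desk-scale, so the
# whole propagation operator fits in memory as a sparse Matrix.

relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# log(1 + exp(x)) without overflow
softplus <- function(x) {
  out <- x
  pos <- x > 0
  out[pos] <- x[pos] + log1p(exp(-x[pos]))
  out[!pos] <- log1p(exp(x[!pos]))
  out
}

# Glorot/Xavier uniform initialisation; draws from the current RNG stream.
glorot_init <- function(fan_in, fan_out) {
  limit <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -limit, limit), fan_in, fan_out)
}

# Graph propagation operators, precomputed once per graph.
#   An : normalised adjacency D^{-1/2}(A+I)D^{-1/2}   (GCN message passing)
#   M  : row-stochastic closed-neighbourhood mean      (SAGE, FeatGraphConv)
#   A  : plain adjacency, no self-loops                (GraphConv)
graph_ops <- function(g) {
  list(An = normalize_adjacency(g),
       M  = mean_pool_operator(g),
       A  = adjacency_matrix(g, self_loops = FALSE))
}

# A layer is a list(kind, params = list(W1[, W2][, b])).
make_layer <- function(kind, input_dim, output_dim) {
  kind <- match.arg(kind, c("dense", "gcn", "sage", "graphconv",
                            "featgraphconv", "readout"))
  p <- switch(kind,
    dense         = list(W1 = glorot_init(input_dim, output_dim)),
    gcn           = list(W1 = glorot_init(input_dim, output_dim)),
    sage          = list(W1 = glorot_init(input_dim, output_dim),
                         W2 = glorot_init(input_dim, output_dim)),
    graphconv     = list(W1 = glorot_init(input_dim, output_dim),
                         W2 = glorot_init(input_dim, output_dim)),
    featgraphconv = list(W1 = glorot_init(input_dim, output_dim),
                         W2 = glorot_init(2L * output_dim, output_dim)),
    readout       = list(W1 = glorot_init(input_dim, output_dim),
                         b  = matrix(0, 1L, output_dim))
  )
  list(kind = kind, params = p)
}

layer_forward <- function(layer, h, ops) {
  p <- layer$params
  switch(layer$kind,
    dense = {
      out <- h %*% p$W1
      list(out = out, cache = list(h = h))
    },
    gcn = {
      hw <- h %*% p$W1
      out <- as.matrix(ops$An %*% hw)
      list(out = out, cache = list(h = h))
    },
    sage = {
      mh <- as.matrix(ops$M %*% h)
      out <- h %*% p$W1 + mh %*% p$W2
      list(out = out, cache = list(h = h, mh = mh))
    },
    graphconv = {
      ah <- as.matrix(ops$A %*% h)
      out <- h %*% p$W1 + ah %*% p$W2
      list(out = out, cache = list(h = h, ah = ah))
    },
    featgraphconv = {
      g1 <- h %*% p$W1
      mg <- as.matrix(ops$M %*% g1)
      cat_gm <- cbind(g1, mg)
      out <- cat_gm %*% p$W2
      list(out = out, cache = list(h = h, cat_gm = cat_gm))
    },
    readout = {
      out <- sweep(h %*% p$W1, 2L, p$b, "+")
      list(out = out, cache = list(h = h))
    },
    stop("unknown layer kind: ", layer$kind)
  )
}

# Returns list(dh = gradient w.r.t. the layer input, grads = named like params).
# All propagation operators except M are symmetric; M is transposed explicitly.
layer_backward <- function(layer, d_out, cache, ops) {
  p <- layer$params
  switch(layer$kind,
    dense = {
      list(dh = d_out %*% t(p$W1),
           grads = list(W1 = crossprod(cache$h, d_out)))
    },
    gcn = {
      da <- as.matrix(ops$An %*% d_out)  # An symmetric
      list(dh = da %*% t(p$W1),
           grads = list(W1 = crossprod(cache$h, da)))
    },
    sage = {
      dmh <- d_out %*% t(p$W2)
      dh <- d_out %*% t(p$W1) + as.matrix(Matrix::t(ops$M) %*% dmh)
      list(dh = dh,
           grads = list(W1 = crossprod(cache$h, d_out),
                        W2 = crossprod(cache$mh, d_out)))
    },
    graphconv = {
      dah <- d_out %*% t(p$W2)
      dh <- d_out %*% t(p$W1) + as.matrix(ops$A %*% dah)  # A symmetric
      list(dh = dh,
           grads = list(W1 = crossprod(cache$h, d_out),
                        W2 = crossprod(cache$ah, d_out)))
    },
    featgraphconv = {
      d_cat <- d_out %*% t(p$W2)
      d1 <- ncol(p$W1)
      dg <- d_cat[, seq_len(d1), drop = FALSE] +
        as.matrix(Matrix::t(ops$M) %*%
                    d_cat[, d1 + seq_len(d1), drop = FALSE])
      list(dh = dg %*% t(p$W1),
           grads = list(W1 = crossprod(cache$h, dg),
                        W2 = crossprod(cache$cat_gm, d_out)))
    },
    readout = {
      list(dh = d_out %*% t(p$W1),
           grads = list(W1 = crossprod(cache$h, d_out),
                        b = matrix(colSums(d_out), 1L)))
    },
    stop("unknown layer kind: ", layer$kind)
  )
}

# Forward through a whole stack; ReLU after every layer except the last.
network_forward <- function(layers, x, ops, keep_cache = FALSE) {
  n_layers <- length(layers)
  caches <- vector("list", n_layers)
  h <- x
  for (k in seq_len(n_layers)) {
    fw <- layer_forward(layers[[k]], h, ops)
    pre <- fw$out
    if (k < n_layers) {
      h <- relu(pre)
      if (keep_cache) caches[[k]] <- c(fw$cache, list(pre = pre))
    } else {
      h <- pre
      if (keep_cache) caches[[k]] <- fw$cache
    }
  }
  if (keep_cache) list(out = h, caches = caches) else h
}

network_backward <- function(layers, d_out, caches, ops) {
  n_layers <- length(layers)
  grads <- vector("list", n_layers)
  d <- d_out
  for (k in rev(seq_len(n_layers))) {
    if (k < n_layers) d <- d * (caches[[k]]$pre > 0)  # ReLU gate
    bw <- layer_backward(layers[[k]], d, caches[[k]], ops)
    grads[[k]] <- bw$grads
    d <- bw$dh
  }
  grads
}

adam_init <- function(layers) {
  lapply(layers, function(l) lapply(l$params, function(w) {
    list(m = w * 0, v = w * 0)
  }))
}

adam_step <- function(layers, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (k in seq_along(layers)) {
    for (nm in names(layers[[k]]$params)) {
      g <- grads[[k]][[nm]]
      s <- state[[k]][[nm]]
      s$m <- beta1 * s$m + (1 - beta1) * g
      s$v <- beta2 * s$v + (1 - beta2) * g * g
      m_hat <- s$m / (1 - beta1^t)
      v_hat <- s$v / (1 - beta2^t)
      layers[[k]]$params[[nm]] <- layers[[k]]$params[[nm]] -
        lr * m_hat / (sqrt(v_hat) + eps)
      state[[k]][[nm]] <- s
    }
  }
  list(layers = layers, state = state)
}

# Full-batch Adam training of a layer stack under masked MSE.
train_network_mse <- function(layers, x, target, mask, ops, epochs, lr) {
  state <- adam_init(layers)
  m <- mask != 0
  k <- sum(m)
  if (k == 0) stop("training mask selects no entries")
  losses <- numeric(epochs)
  for (t in seq_len(epochs)) {
    fw <- network_forward(layers, x, ops, keep_cache = TRUE)
    resid <- fw$out - target
    resid[!m] <- 0  # entries outside the mask never touch the loss
    loss <- sum(resid^2) / k
    if (!is.finite(loss)) stop("non-finite training loss at epoch ", t)
    losses[t] <- loss
    d_out <- 2 * resid / k
    grads <- network_backward(layers, d_out, fw$caches, ops)
    upd <- adam_step(layers, grads, state, lr, t)
    layers <- upd$layers
    state <- upd$state
  }
  list(layers = layers, losses = losses)
}

# Identity ops for graph-free stacks (MLP baselines).
no_graph_ops <- function() list(An = NULL, M = NULL, A = NULL)
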