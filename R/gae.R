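#' Graph auto-encoder configuration
#'
#' Hyper-parameters for the structural embedding: two GCN layers of sizes
#' \code{hidden1} and \code{hidden2}, trained with Adam.
#'
#' @param epochs number of full-batch gradient steps.
#' @param learning_rate Adam step size.
#' @param hidden1 first hidden layer width.
#' @param hidden2 embedding dimension (second layer width).
#' @param dropout dropout probability applied to the first hidden layer
#'   during training (0 disables it).
#' @param seed integer seed controlling weight initialisation (and dropout).
#' @return a list of class \code{gae_config}.
#' @export
gae_config <- function(epochs = 500L, learning_rate = 0.001,
                       hidden1 = 64L, hidden2 = 32L, dropout = 0,
                       seed = 1L) {
  stopifnot(epochs >= 1, learning_rate > 0, hidden1 >= 1, hidden2 >= 1,
            dropout >= 0, dropout < 1)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 hidden1 = as.integer(hidden1), hidden2 = as.integer(hidden2),
                 dropout = dropout, seed = as.integer(seed)),
            class = "gae_config")
}

#' One-hot (identity) node features
#'
#' The input used when the encoder should see only graph structure: each node
#' gets a distinct indicator feature carrying no functional information.
#'
#' @param n number of nodes.
#' @return a sparse identity matrix.
#' @export
identity_features <- function(n) Matrix::Diagonal(n)

#' Two-layer GCN encoder
#'
#' Computes the embedding
#' \eqn{Z = \tilde A \, \mathrm{ReLU}(\tilde A X W_0) W_1} — a graph
#' convolutional network with ReLU between the layers and identity output
#' activation.
#'
#' @param x node features (dense or sparse N x Q matrix, or the identity).
#' @param a_norm normalised adjacency from \code{\link{normalize_adjacency}}.
#' @param w list with weight matrices \code{W0} (Q x h1) and \code{W1}
#'   (h1 x d).
#' @return dense N x d embedding matrix.
#' @export
gcn_encode <- function(x, a_norm, w) {
  if (nrow(x) != nrow(a_norm)) stop("feature/adjacency row mismatch")
  if (ncol(x) != nrow(w$W0)) stop("W0 shape does not match input features")
  if (ncol(w$W0) != nrow(w$W1)) stop("W0/W1 shapes incompatible")
  h1 <- relu(as.matrix(a_norm %*% (x %*% w$W0)))
  as.matrix(a_norm %*% (h1 %*% w$W1))
}

#' Inner-product decoder
#'
#' Edge probability for a node pair is the logistic function of the dot
#' product of the two embedding rows: \eqn{\hat A_{ij} = \sigma(z_i^T z_j)}.
#' Symmetric in \eqn{(i, j)} by construction.
#'
#' @param z embedding matrix.
#' @param pairs two-column matrix of node indices.
#' @return numeric vector of probabilities, one per pair.
#' @export
decode_adjacency <- function(z, pairs) {
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  if (nrow(pairs) > 0L && (any(pairs < 1L) || any(pairs > nrow(z)))) {
    stop("pair index out of range")
  }
  sigmoid(rowSums(z[pairs[, 1L], , drop = FALSE] *
                    z[pairs[, 2L], , drop = FALSE]))
}

#' Weighted reconstruction loss of the adjacency matrix
#'
#' Binary cross-entropy between \eqn{\sigma(Z Z^T)} and the adjacency matrix
#' over all \eqn{N^2} entries. Because real networks are sparse, the positive
#' class is reweighted by \eqn{(N^2 - 2|E|) / (2|E|)} so present and absent
#' edges contribute comparably; the total is normalised by \eqn{N^2}.
#'
#' @param z embedding matrix (N x d).
#' @param g the target \code{gfae_graph} (must have at least one edge).
#' @return scalar loss.
#' @export
reconstruction_loss <- function(z, g) {
  n <- g$n_nodes
  if (nrow(z) != n) stop("embedding/graph row mismatch")
  m2 <- 2 * n_edges(g)  # number of 1-entries in A
  if (m2 == 0) stop("reconstruction loss undefined for an edgeless graph")
  pos_weight <- (n^2 - m2) / m2
  s <- z %*% t(z)
  a <- as.matrix(adjacency_matrix(g))
  sum(pos_weight * a * softplus(-s) + (1 - a) * softplus(s)) / n^2
}

#' Split edges into train/validation/test sets with sampled negatives
#'
#' Positive edges are partitioned uniformly at random; negative (absent)
#' pairs are sampled uniformly from the non-edges, matched in count to the
#' validation and test positives and disjoint from each other.
#'
#' @param g a \code{gfae_graph}.
#' @param val_frac,test_frac fractions of edges held out (sum < 1).
#' @param seed integer seed.
#' @return list with two-column index matrices \code{train_pos},
#'   \code{val_pos}, \code{test_pos}, \code{val_neg}, \code{test_neg}.
#' @export
split_edges <- function(g, val_frac = 0.05, test_frac = 0.10, seed = 1L) {
  stopifnot(val_frac >= 0, test_frac >= 0, val_frac + test_frac < 1)
  m <- n_edges(g)
  n_val <- floor(val_frac * m)
  n_test <- floor(test_frac * m)
  if (m - n_val - n_test < 1L) stop("too few edges to split")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  perm <- sample.int(m)
  e <- g$edges[perm, , drop = FALSE]
  val_pos <- e[seq_len(n_val), , drop = FALSE]
  test_pos <- e[n_val + seq_len(n_test), , drop = FALSE]
  held <- n_val + n_test
  train_pos <- if (held > 0L) e[-seq_len(held), , drop = FALSE] else e
  neg <- sample_negative_pairs(g, n_val + n_test)
  list(train_pos = train_pos, val_pos = val_pos, test_pos = test_pos,
       val_neg = neg[seq_len(n_val), , drop = FALSE],
       test_neg = neg[n_val + seq_len(n_test), , drop = FALSE])
}

# Uniform sample of k distinct unordered non-adjacent pairs (rejection).
sample_negative_pairs <- function(g, k) {
  if (k == 0L) return(matrix(integer(0), ncol = 2L))
  n <- g$n_nodes
  edge_key <- function(i, j) pmin(i, j) * (n + 1) + pmax(i, j)
  present <- edge_key(g$edges[, 1L], g$edges[, 2L])
  chosen <- numeric(0)
  out <- matrix(integer(0), ncol = 2L)
  max_tries <- 200L
  for (tries in seq_len(max_tries)) {
    need <- k - nrow(out)
    if (need <= 0L) break
    i <- sample.int(n, 2L * need + 10L, replace = TRUE)
    j <- sample.int(n, 2L * need + 10L, replace = TRUE)
    ok <- i != j
    i <- i[ok]; j <- j[ok]
    key <- edge_key(i, j)
    ok <- !(key %in% present) & !(key %in% chosen) & !duplicated(key)
    i <- i[ok]; j <- j[ok]; key <- key[ok]
    take <- seq_len(min(length(i), need))
    out <- rbind(out, cbind(pmin(i, j), pmax(i, j))[take, , drop = FALSE])
    chosen <- c(chosen, key[take])
  }
  if (nrow(out) < k) stop("could not sample enough negative pairs")
  storage.mode(out) <- "integer"
  out
}

#' Train the structural graph auto-encoder
#'
#' Minimises the weighted adjacency reconstruction loss of the training graph
#' (normalised adjacency and targets both built from \code{split$train_pos}
#' only) with Adam, full-batch. Deterministic under a fixed
#' \code{cfg$seed}.
#'
#' @param x_input node features: a dense/sparse matrix, or \code{NULL} for
#'   one-hot identity features (structure-only embedding).
#' @param g the \code{gfae_graph} being embedded.
#' @param split an edge split from \code{\link{split_edges}}; pass
#'   \code{NULL} to train on all edges.
#' @param cfg a \code{\link{gae_config}}.
#' @return list with \code{embedding} (N x hidden2 matrix), \code{weights}
#'   (list \code{W0}, \code{W1}), and \code{losses} (per-epoch loss curve).
#' @export
train_gae <- function(x_input, g, split = NULL, cfg = gae_config()) {
  n <- g$n_nodes
  if (is.null(x_input)) x_input <- identity_features(n)
  if (nrow(x_input) != n) stop("features and graph are not aligned")
  train_edges <- if (is.null(split)) g$edges else split$train_pos
  g_train <- new_graph(g$node_ids, train_edges)
  m2 <- 2 * n_edges(g_train)
  if (m2 == 0) stop("training graph has no edges")
  a_norm <- normalize_adjacency(g_train)
  a <- as.matrix(adjacency_matrix(g_train))
  pos_weight <- (n^2 - m2) / m2

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  w <- list(W0 = glorot_init(ncol(x_input), cfg$hidden1),
            W1 = glorot_init(cfg$hidden1, cfg$hidden2))
  state <- lapply(w, function(x) list(m = x * 0, v = x * 0))
  ax <- a_norm %*% x_input  # constant across epochs
  losses <- numeric(cfg$epochs)
  lr <- cfg$learning_rate
  for (t in seq_len(cfg$epochs)) {
    h1_pre <- as.matrix(ax %*% w$W0)
    h1 <- relu(h1_pre)
    if (cfg$dropout > 0) {
      keep <- (stats::runif(length(h1)) >= cfg$dropout) / (1 - cfg$dropout)
      h1 <- h1 * keep
    }
    z <- as.matrix(a_norm %*% (h1 %*% w$W1))
    s <- z %*% t(z)
    loss <- sum(pos_weight * a * softplus(-s) + (1 - a) * softplus(s)) / n^2
    if (!is.finite(loss)) stop("non-finite GAE loss at epoch ", t)
    losses[t] <- loss
    sig <- sigmoid(s)
    ds <- (pos_weight * a * (sig - 1) + (1 - a) * sig) / n^2
    dz <- 2 * ds %*% z                       # ds symmetric
    d_h1w1 <- as.matrix(a_norm %*% dz)       # a_norm symmetric
    g_w1 <- crossprod(h1, d_h1w1)
    dh1 <- d_h1w1 %*% t(w$W1)
    if (cfg$dropout > 0) dh1 <- dh1 * keep
    dh1 <- dh1 * (h1_pre > 0)
    g_w0 <- as.matrix(Matrix::crossprod(ax, dh1))
    grads <- list(W0 = g_w0, W1 = g_w1)
    for (nm in names(w)) {
      st <- state[[nm]]
      gg <- grads[[nm]]
      st$m <- 0.9 * st$m + 0.1 * gg
      st$v <- 0.999 * st$v + 0.001 * gg * gg
      w[[nm]] <- w[[nm]] - lr * (st$m / (1 - 0.9^t)) /
        (sqrt(st$v / (1 - 0.999^t)) + 1e-8)
      state[[nm]] <- st
    }
  }
  z_final <- gcn_encode(x_input, a_norm, list(W0 = w$W0, W1 = w$W1))
  list(embedding = z_final, weights = list(W0 = w$W0, W1 = w$W1),
       losses = losses)
}

#' Link-prediction metrics: AUC and average precision
#'
#' AUC is the probability that a positive pair scores above a negative pair,
#' ties counted one half (the Wilcoxon/Mann-Whitney statistic). Average
#' precision is the step-interpolated area under the precision-recall curve.
#'
#' @param scores_pos scores of held-out true edges.
#' @param scores_neg scores of sampled non-edges.
#' @return list with \code{auc} and \code{ap}.
#' @export
evaluate_link_prediction <- function(scores_pos, scores_neg) {
  np <- length(scores_pos); nn <- length(scores_neg)
  if (np == 0L || nn == 0L) stop("need nonempty positive and negative scores")
  r <- rank(c(scores_pos, scores_neg))
  auc <- (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
  labels <- c(rep(1L, np), rep(0L, nn))
  ord <- order(c(scores_pos, scores_neg), decreasing = TRUE)
  lab <- labels[ord]
  tp <- cumsum(lab)
  precision <- tp / seq_along(lab)
  ap <- sum(precision[lab == 1L]) / np
  list(auc = auc, ap = ap)
}

#' Variance of node features explained by an embedding
#'
#' Fits one joint ordinary-least-squares readout \eqn{X \approx [Z, 1] B}
#' across all feature columns and returns \eqn{R^2 = 1 - SS_{res}/SS_{tot}}
#' with the total sum of squares taken about column means. A rank-deficient
#' design is solved by the minimum-norm least-squares solution (SVD
#' pseudoinverse) with a message.
#'
#' @param z embedding matrix (N x d).
#' @param x feature matrix (N x Q).
#' @return scalar, at most 1.
#' @export
variance_explained <- function(z, x) {
  z <- as.matrix(z); x <- as.matrix(x)
  if (nrow(z) != nrow(x)) stop("embedding and features must have equal rows")
  design <- cbind(1, z)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    message("rank-deficient embedding design; using minimum-norm solution")
    sv <- svd(design)
    keep <- sv$d > max(sv$d) * 1e-10
    b <- sv$v[, keep, drop = FALSE] %*%
      ((crossprod(sv$u[, keep, drop = FALSE], x)) / sv$d[keep])
    fitted <- design %*% b
  } else {
    fitted <- design %*% qr.coef(qrd, x)
  }
  ss_res <- sum((x - fitted)^2)
  xc <- sweep(x, 2L, colMeans(x))
  ss_tot <- sum(xc^2)
  if (ss_tot == 0) return(0)
  1 - ss_res / ss_tot
}

#' Score candidate edges by expression correlation
#'
#' The feature-only alternative to a learned embedding: the score of a node
#' pair is the absolute Pearson correlation of the two feature rows, read
#' directly as the probability of an edge. Constant rows (zero variance) get
#' score 0 with a message.
#'
#' @param x feature matrix (N x Q, Q >= 2).
#' @param pairs two-column matrix of node indices.
#' @return numeric vector of scores in \eqn{[0, 1]}.
#' @export
correlation_edge_scores <- function(x, pairs) {
  if (ncol(x) < 2L) stop("need at least 2 experiments to correlate")
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  sds <- apply(x, 1L, stats::sd)
  const <- sds == 0
  if (any(const[unique(as.vector(pairs))])) {
    message("constant feature row(s) scored 0 in correlation_edge_scores")
  }
  vapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    if (const[i] || const[j]) return(0)
    abs(stats::cor(x[i, ], x[j, ]))
  }, numeric(1L))
}

#' Indirect prediction of node features from an embedding
#'
#' The two-stage route: the embedding is learned on the graph reconstruction
#' task, then a conventional regressor maps embedding rows to target values.
#'
#' @param z embedding matrix.
#' @param y_train target values for the training nodes.
#' @param train_nodes,test_nodes disjoint node index vectors.
#' @param regressor \code{"LR"} (ordinary least squares) or \code{"RF"}
#'   (100-tree random forest).
#' @param seed integer seed (used by the random forest).
#' @return numeric predictions for \code{test_nodes}.
#' @export
indirect_predict <- function(z, y_train, train_nodes, test_nodes,
                             regressor = c("LR", "RF"), seed = 1L) {
  regressor <- match.arg(regressor)
  if (length(intersect(train_nodes, test_nodes)) > 0L) {
    stop("train and test nodes must be disjoint")
  }
  z <- as.matrix(z)
  if (regressor == "LR") {
    fit <- stats::lm.fit(cbind(1, z[train_nodes, , drop = FALSE]), y_train)
    coefs <- fit$coefficients
    coefs[is.na(coefs)] <- 0
    as.vector(cbind(1, z[test_nodes, , drop = FALSE]) %*% coefs)
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    fit <- randomForest::randomForest(z[train_nodes, , drop = FALSE],
                                      y_train, ntree = 100L)
    as.vector(stats::predict(fit, z[test_nodes, , drop = FALSE]))
  }
}
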