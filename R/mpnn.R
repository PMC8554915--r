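#' GFAE training configuration
#'
#' @param epochs number of full-batch Adam steps. The reference profile is
#'   20000; \code{fast = TRUE} switches to the 500-epoch profile used for
#'   routine runs and continuous testing.
#' @param learning_rate Adam step size.
#' @param seed integer seed for weight initialisation.
#' @param fast use the 500-epoch profile.
#' @return a list of class \code{gfae_config}.
#' @export
gfae_config <- function(epochs = if (fast) 500L else 20000L,
                        learning_rate = 0.001, seed = 1L, fast = TRUE) {
  stopifnot(epochs >= 1, learning_rate > 0)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "gfae_config")
}

.layer_kinds <- c(GCN_MP = "gcn", GRAPHSAGE = "sage",
                  GRAPHCONV = "graphconv", FEATGRAPHCONV = "featgraphconv")

resolve_layer_kind <- function(layer_kind) {
  if (layer_kind %in% names(.layer_kinds)) return(.layer_kinds[[layer_kind]])
  if (layer_kind %in% .layer_kinds) return(layer_kind)
  stop("unknown layer kind: ", layer_kind,
       " (expected one of ", paste(names(.layer_kinds), collapse = ", "), ")")
}

#' Message-passing GCN layer
#'
#' \eqn{h'_i = \sum_{j \in N(i) \cup i} \frac{1}{\sqrt{\deg i}\sqrt{\deg j}}
#' W h_j}, with degrees counted on \eqn{A + I} (self-loops included, the
#' convention of the normalised adjacency operator). Equivalent to one dense
#' application \eqn{\tilde A H W}.
#'
#' @param h node feature matrix (N x d_in).
#' @param g a \code{gfae_graph}.
#' @param w weight matrix (d_in x d_out).
#' @return updated node matrix (N x d_out).
#' @export
gcn_mp_layer <- function(h, g, w) {
  h <- as.matrix(h)
  if (nrow(h) != g$n_nodes) stop("feature/graph row mismatch")
  if (ncol(h) != nrow(w)) stop("weight shape does not match features")
  as.matrix(normalize_adjacency(g) %*% (h %*% w))
}

#' GraphSAGE layer with closed-neighbourhood mean pooling
#'
#' \eqn{h'_i = W_1 h_i + W_2 \,\mathrm{mean}_{j \in N(i) \cup i} h_j}. The
#' node itself is included in the mean.
#'
#' @param h node feature matrix.
#' @param g a \code{gfae_graph}.
#' @param w1,w2 weight matrices (d_in x d_out).
#' @return updated node matrix.
#' @export
sage_layer <- function(h, g, w1, w2) {
  h <- as.matrix(h)
  if (nrow(h) != g$n_nodes) stop("feature/graph row mismatch")
  if (ncol(h) != nrow(w1) || ncol(h) != nrow(w2)) stop("weight shape mismatch")
  h %*% w1 + as.matrix(mean_pool_operator(g) %*% h) %*% w2
}

#' GraphConv layer (sum aggregation, self excluded)
#'
#' \eqn{h'_i = W_1 h_i + \sum_{j \in N(i)} W_2 h_j}; the neighbour sum does
#' not include the node itself and is not degree-normalised.
#'
#' @inheritParams sage_layer
#' @return updated node matrix.
#' @export
graphconv_layer <- function(h, g, w1, w2) {
  h <- as.matrix(h)
  if (nrow(h) != g$n_nodes) stop("feature/graph row mismatch")
  if (ncol(h) != nrow(w1) || ncol(h) != nrow(w2)) stop("weight shape mismatch")
  h %*% w1 + as.matrix(adjacency_matrix(g) %*% h) %*% w2
}

#' FeatGraphConv layer
#'
#' The feature-reconstruction layer: messages are first transformed by a
#' linear layer (\eqn{g_i = W_1 h_i}), aggregated by a mean over the closed
#' neighbourhood, then each node's own transformed state is concatenated with
#' the aggregate and passed through a shared linear update:
#' \eqn{h'_i = W_2 (g_i \,\|\, \mathrm{mean}_{j \in N(i) \cup i} g_j)}.
#' The concatenation lets the update weigh a node's own state against its
#' neighbourhood when reconstructing features.
#'
#' @param h node feature matrix.
#' @param g a \code{gfae_graph}.
#' @param w1 message transform (d_in x d_mid).
#' @param w2 update weights (2 d_mid x d_out).
#' @return updated node matrix.
#' @export
featgraphconv_layer <- function(h, g, w1, w2) {
  h <- as.matrix(h)
  if (nrow(h) != g$n_nodes) stop("feature/graph row mismatch")
  if (ncol(h) != nrow(w1)) stop("w1 shape does not match features")
  if (nrow(w2) != 2L * ncol(w1)) stop("w2 input dim must be 2 x w1 output dim")
  g1 <- h %*% w1
  mg <- as.matrix(mean_pool_operator(g) %*% g1)
  cbind(g1, mg) %*% w2
}

#' Linear readout
#'
#' \eqn{\tilde x_i = W h_i + b}: a fully connected linear layer mapping
#' hidden states to predicted feature values. No output nonlinearity.
#'
#' @param h node hidden-state matrix (N x d).
#' @param w weight matrix (d x q).
#' @param b bias (length-q vector or 1 x q matrix).
#' @return predicted feature matrix (N x q).
#' @export
readout <- function(h, w, b) {
  h <- as.matrix(h)
  if (ncol(h) != nrow(w)) stop("weight shape does not match hidden states")
  sweep(h %*% w, 2L, as.vector(b), "+")
}

#' Build an untrained graph feature auto-encoder
#'
#' Two convolution layers of the chosen kind (input -> \code{hidden[1]} ->
#' \code{hidden[2]}, ReLU after each) followed by a linear readout
#' (\code{hidden[2]} -> output). Weights use seeded Glorot initialisation.
#'
#' @param layer_kind one of \code{"GCN_MP"}, \code{"GRAPHSAGE"},
#'   \code{"GRAPHCONV"}, \code{"FEATGRAPHCONV"} (lower-case engine names also
#'   accepted).
#' @param input_dim,output_dim input/output feature dimensions.
#' @param seed integer seed.
#' @param hidden widths of the two hidden layers.
#' @return a list of class \code{gfae_network}.
#' @export
build_gfae <- function(layer_kind, input_dim, output_dim, seed = 1L,
                       hidden = c(64L, 32L)) {
  kind <- resolve_layer_kind(layer_kind)
  stopifnot(input_dim >= 1, output_dim >= 1, length(hidden) == 2L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  layers <- list(make_layer(kind, input_dim, hidden[1L]),
                 make_layer(kind, hidden[1L], hidden[2L]),
                 make_layer("readout", hidden[2L], output_dim))
  structure(list(layer_kind = kind, layers = layers,
                 input_dim = as.integer(input_dim),
                 output_dim = as.integer(output_dim),
                 hidden = as.integer(hidden)),
            class = "gfae_network")
}

#' @export
print.gfae_network <- function(x, ...) {
  cat(sprintf("<gfae_network> %s: %d -> %d -> %d -> %d\n", x$layer_kind,
              x$input_dim, x$hidden[1L], x$hidden[2L], x$output_dim))
  invisible(x)
}

#' Number of trainable parameters of a network
#' @param net a \code{gfae_network}.
#' @return integer count.
#' @export
n_parameters <- function(net) {
  sum(vapply(net$layers,
             function(l) sum(vapply(l$params, length, 1L)), 1L))
}

#' Train a graph feature auto-encoder end to end
#'
#' Minimises the mean squared error of predicted features over the entries
#' selected by \code{train_mask}, with message passing over the full graph at
#' every step (transductive: all nodes and edges are visible; only masked
#' target values are hidden). Full-batch Adam; deterministic for a fixed
#' network seed.
#'
#' @param net an untrained (or previously trained) \code{gfae_network}.
#' @param x_input input feature matrix (masked entries presented as 0).
#' @param target target feature matrix.
#' @param train_mask binary matrix selecting the entries that contribute to
#'   the loss.
#' @param g the \code{gfae_graph}.
#' @param cfg a \code{\link{gfae_config}}.
#' @return the trained network, with the per-epoch loss curve in
#'   \code{$losses}.
#' @export
train_gfae <- function(net, x_input, target, train_mask, g = NULL,
                       cfg = gfae_config()) {
  x_input <- as.matrix(x_input)
  target <- as.matrix(target)
  dense <- net$layer_kind == "dense"
  if (!dense && is.null(g)) stop("graph layers need a graph")
  if (!is.null(g) && nrow(x_input) != g$n_nodes) {
    stop("features and graph are not aligned")
  }
  if (ncol(x_input) != net$input_dim) stop("input dim mismatch with network")
  if (ncol(target) != net$output_dim) stop("target dim mismatch with network")
  ops <- if (dense) no_graph_ops() else graph_ops(g)
  fit <- train_network_mse(net$layers, x_input, target, train_mask, ops,
                           epochs = cfg$epochs, lr = cfg$learning_rate)
  net$layers <- fit$layers
  net$losses <- fit$losses
  net
}

#' Forward pass of a graph feature auto-encoder
#'
#' Deterministic prediction of all feature values for all nodes; no mask is
#' applied — the caller selects the entries of interest.
#'
#' @param net a \code{gfae_network}.
#' @param x_input input feature matrix.
#' @param g the \code{gfae_graph}.
#' @return predicted feature matrix (N x output_dim).
#' @export
predict_gfae <- function(net, x_input, g = NULL) {
  x_input <- as.matrix(x_input)
  dense <- net$layer_kind == "dense"
  if (!dense && is.null(g)) stop("graph layers need a graph")
  if (!is.null(g) && nrow(x_input) != g$n_nodes) {
    stop("features and graph are not aligned")
  }
  if (ncol(x_input) != net$input_dim) stop("input dim mismatch with network")
  network_forward(net$layers, x_input, if (dense) no_graph_ops() else graph_ops(g))
}
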