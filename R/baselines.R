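#' Build an untrained multilayer perceptron
#'
#' A graph-free network with the same trainer, widths and masking contract as
#' the graph feature auto-encoder: two dense hidden layers with ReLU, then a
#' linear readout. Used both as a feature-to-feature regressor and as the
#' auto-encoder baseline in the imputation experiment (input = masked matrix,
#' target = matrix, loss on observed entries) — the only difference from the
#' graph models is the absence of message passing.
#'
#' @param input_dim,output_dim input/output feature dimensions.
#' @param seed integer seed.
#' @param hidden widths of the two hidden layers.
#' @return a \code{gfae_network} with \code{layer_kind = "dense"}.
#' @export
build_mlp <- function(input_dim, output_dim, seed = 1L, hidden = c(64L, 32L)) {
  stopifnot(input_dim >= 1, output_dim >= 1, length(hidden) == 2L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  layers <- list(make_layer("dense", input_dim, hidden[1L]),
                 make_layer("dense", hidden[1L], hidden[2L]),
                 make_layer("readout", hidden[2L], output_dim))
  structure(list(layer_kind = "dense", layers = layers,
                 input_dim = as.integer(input_dim),
                 output_dim = as.integer(output_dim),
                 hidden = as.integer(hidden)),
            class = "gfae_network")
}

#' Fit a feature-only baseline regressor
#'
#' The comparison methods that predict expression from expression alone:
#' \describe{
#'   \item{MLP}{two hidden layers (64, 32) with ReLU, trained to MSE with
#'     Adam (500 epochs, learning rate 0.001), seeded.}
#'   \item{LR}{ordinary least squares with intercept (multi-output).}
#'   \item{RF}{random forest, 100 trees per target column, seeded.}
#' }
#'
#' @param kind \code{"MLP"}, \code{"LR"}, or \code{"RF"}.
#' @param features numeric matrix of training inputs (rows = genes).
#' @param targets numeric vector or matrix of training targets.
#' @param seed integer seed.
#' @param epochs,learning_rate MLP training profile.
#' @return a fitted model of class \code{gfae_baseline}.
#' @export
fit_baseline <- function(kind = c("MLP", "LR", "RF"), features, targets,
                         seed = 1L, epochs = 500L, learning_rate = 0.001) {
  kind <- match.arg(kind)
  features <- as.matrix(features)
  targets <- as.matrix(targets)
  if (nrow(features) < 2L) stop("need at least 2 training rows")
  if (nrow(features) != nrow(targets)) stop("feature/target row mismatch")
  model <- switch(kind,
    MLP = {
      net <- build_mlp(ncol(features), ncol(targets), seed = seed)
      fit <- train_network_mse(net$layers, features, targets,
                               matrix(1, nrow(targets), ncol(targets)),
                               no_graph_ops(), epochs = epochs,
                               lr = learning_rate)
      net$layers <- fit$layers
      list(net = net)
    },
    LR = {
      fit <- stats::lm.fit(cbind(1, features), targets)
      coefs <- as.matrix(fit$coefficients)
      coefs[is.na(coefs)] <- 0
      list(coef = coefs)
    },
    RF = {
      old <- .Random.seed_save()
      on.exit(.Random.seed_restore(old))
      set.seed(seed)
      forests <- lapply(seq_len(ncol(targets)), function(q) {
        randomForest::randomForest(features, targets[, q], ntree = 100L)
      })
      list(forests = forests)
    }
  )
  structure(c(list(kind = kind, p = ncol(features), q = ncol(targets)),
              model),
            class = "gfae_baseline")
}

#' Predict from a fitted baseline
#'
#' @param object a \code{gfae_baseline} from \code{\link{fit_baseline}}.
#' @param features numeric matrix of inputs with the training feature
#'   dimension.
#' @param ... unused.
#' @return numeric prediction matrix (rows x targets).
#' @export
predict.gfae_baseline <- function(object, features, ...) {
  features <- as.matrix(features)
  if (ncol(features) != object$p) stop("feature dimension mismatch")
  out <- switch(object$kind,
    MLP = network_forward(object$net$layers, features, no_graph_ops()),
    LR  = cbind(1, features) %*% object$coef,
    RF  = vapply(object$forests,
                 function(f) as.vector(stats::predict(f, features)),
                 numeric(nrow(features)))
  )
  matrix(out, nrow = nrow(features), ncol = object$q)
}

#' @rdname predict.gfae_baseline
#' @param model a \code{gfae_baseline}.
#' @export
predict_baseline <- function(model, features) predict(model, features)
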