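#' K-fold index partition
#'
#' Seeded shuffle of \code{1..n} split into \code{k} folds whose sizes differ
#' by at most one.
#'
#' @param n number of items.
#' @param k number of folds, \code{2 <= k <= n}.
#' @param seed integer seed.
#' @return list of \code{k} disjoint integer vectors covering \code{1..n}.
#' @export
kfold_indices <- function(n, k, seed = 1L) {
  if (k < 2L || k > n) stop("k must satisfy 2 <= k <= n")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  perm <- sample.int(n)
  sizes <- rep(floor(n / k), k) + (seq_len(k) <= n %% k)
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lapply(seq_len(k), function(f) sort(perm[starts[f]:ends[f]]))
}

#' Masks for the experiment-split protocol
#'
#' The first masking protocol: both experiments (columns) and genes (rows)
#' are split. Input features are the non-target columns of every gene; for
#' each target experiment and each gene fold, the target-column values of the
#' held-out genes are the test set and those of the remaining genes the
#' training set. One model is trained per target column.
#'
#' @param n_genes,n_experiments matrix dimensions.
#' @param gene_folds list of gene index sets (e.g. from
#'   \code{\link{kfold_indices}}).
#' @param target_experiments column indices to hold out as prediction
#'   targets; must be a nonempty proper subset of the columns.
#' @return list of mask-pair objects, one per (target experiment, fold),
#'   each with \code{train_mask}/\code{test_mask} (binary, genes x
#'   experiments, nonzero only in the target column), \code{target_col},
#'   \code{input_cols}, \code{train_genes}, \code{test_genes}, and
#'   \code{mode = "EXPERIMENT_SPLIT"}.
#' @export
make_experiment_masks <- function(n_genes, n_experiments, gene_folds,
                                  target_experiments) {
  target_experiments <- as.integer(target_experiments)
  if (length(target_experiments) == 0L) stop("need at least one target experiment")
  if (length(unique(target_experiments)) >= n_experiments) {
    stop("target experiments must be a proper subset of the columns")
  }
  if (any(target_experiments < 1L | target_experiments > n_experiments)) {
    stop("target experiment index out of range")
  }
  input_cols <- setdiff(seq_len(n_experiments), target_experiments)
  out <- list()
  for (q in target_experiments) {
    for (f in seq_along(gene_folds)) {
      test_genes <- gene_folds[[f]]
      train_genes <- setdiff(seq_len(n_genes), test_genes)
      train_mask <- matrix(0, n_genes, n_experiments)
      test_mask <- matrix(0, n_genes, n_experiments)
      train_mask[train_genes, q] <- 1
      test_mask[test_genes, q] <- 1
      out[[length(out) + 1L]] <- list(
        mode = "EXPERIMENT_SPLIT", target_col = q, input_cols = input_cols,
        train_genes = train_genes, test_genes = test_genes,
        train_mask = train_mask, test_mask = test_mask, fold = f)
    }
  }
  out
}

#' Masks for the imputation protocol
#'
#' The second masking protocol: matrix entries themselves are split at
#' random, and the test mask is the logical complement of the train mask
#' within the eligible entries. With \code{nonzero_only}, zero entries (the
#' technical dropouts of sparse single-cell matrices) stay train-visible and
#' never enter a test fold.
#'
#' @param x feature matrix.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @param nonzero_only restrict eligible (testable) entries to nonzero
#'   values.
#' @return list of \code{k} mask pairs, each with binary
#'   \code{train_mask}/\code{test_mask} matrices (\code{mode =
#'   "IMPUTATION"}).
#' @export
make_imputation_masks <- function(x, k, seed = 1L, nonzero_only = FALSE) {
  if (k < 2L) stop("k must be >= 2")
  eligible <- if (nonzero_only) which(x != 0) else seq_along(x)
  if (length(eligible) < k) stop("too few eligible entries for k folds")
  folds <- kfold_indices(length(eligible), k, seed = seed)
  lapply(seq_len(k), function(f) {
    test_idx <- eligible[folds[[f]]]
    test_mask <- matrix(0, nrow(x), ncol(x))
    test_mask[test_idx] <- 1
    train_mask <- matrix(0, nrow(x), ncol(x))
    train_mask[setdiff(eligible, test_idx)] <- 1
    if (nonzero_only) train_mask[x == 0] <- 1
    list(mode = "IMPUTATION", train_mask = train_mask, test_mask = test_mask,
         fold = f)
  })
}

.report_row <- function(method, setting, fold, metric, value, seed) {
  data.frame(method = method, setting = setting, fold = fold,
             metric = metric, value = value, seed = seed,
             stringsAsFactors = FALSE)
}

#' Structure-embedding experiment
#'
#' Measures how well a graph auto-encoder embedding reconstructs held-out
#' edges, and how much expression variance the embedding explains, under five
#' input settings: \code{RANDOM_GRAPH} (identity features, Erdős–Rényi graph
#' of matched density), \code{EXPR_RANDOM_GRAPH} (expression features, random
#' graph), \code{GRAPH} (identity features, real graph), \code{EXPR_GRAPH}
#' (expression features, real graph), and \code{EXPRESSION} (no training:
#' held-out pairs are scored by absolute expression correlation). For the
#' random-graph settings the random graph itself is split and evaluated —
#' an unlearnable null whose AUC sits near 0.5.
#'
#' @param setting one of the five input settings.
#' @param g the real \code{gfae_graph}.
#' @param x expression matrix aligned with \code{g}.
#' @param cfg a \code{\link{gae_config}}.
#' @param seed integer seed.
#' @param n_repeats number of independent edge splits ("folds").
#' @param val_frac,test_frac edge-split fractions.
#' @return a long-format \code{data.frame} report with metrics \code{auc},
#'   \code{ap}, and \code{variance_explained} per fold.
#' @export
run_structure_embedding_experiment <- function(
    setting = c("GRAPH", "RANDOM_GRAPH", "EXPR_RANDOM_GRAPH", "EXPR_GRAPH",
                "EXPRESSION"),
    g, x, cfg = gae_config(), seed = 1L, n_repeats = 3L,
    val_frac = 0.05, test_frac = 0.10) {
  setting <- match.arg(setting)
  if (setting == "EXPRESSION" && ncol(x) < 2L) {
    stop("EXPRESSION setting needs at least 2 experiments")
  }
  rows <- list()
  for (r in seq_len(n_repeats)) {
    split_seed <- seed + 1000L * r
    g_in <- g
    if (setting %in% c("RANDOM_GRAPH", "EXPR_RANDOM_GRAPH")) {
      p_match <- 2 * n_edges(g) / (g$n_nodes * (g$n_nodes - 1))
      g_in <- erdos_renyi_graph(g$n_nodes, p_match, seed = split_seed + 1L)
      g_in$node_ids <- g$node_ids
    }
    split <- split_edges(g_in, val_frac, test_frac, seed = split_seed)
    if (setting == "EXPRESSION") {
      sp <- correlation_edge_scores(x, split$test_pos)
      sn <- correlation_edge_scores(x, split$test_neg)
      metrics <- evaluate_link_prediction(sp, sn)
      ve <- NA_real_
    } else {
      x_in <- if (setting %in% c("EXPR_RANDOM_GRAPH", "EXPR_GRAPH")) x else NULL
      run_cfg <- cfg
      run_cfg$seed <- cfg$seed + r
      fit <- train_gae(x_in, g_in, split = split, cfg = run_cfg)
      sp <- decode_adjacency(fit$embedding, split$test_pos)
      sn <- decode_adjacency(fit$embedding, split$test_neg)
      metrics <- evaluate_link_prediction(sp, sn)
      ve <- variance_explained(fit$embedding, x)
    }
    rows[[length(rows) + 1L]] <- rbind(
      .report_row(setting, setting, r, "auc", metrics$auc, seed),
      .report_row(setting, setting, r, "ap", metrics$ap, seed),
      .report_row(setting, setting, r, "variance_explained", ve, seed))
  }
  do.call(rbind, rows)
}

.end_to_end_methods <- c("GCN_MP", "GRAPHSAGE", "GRAPHCONV", "FEATGRAPHCONV")
.indirect_methods <- c("LR_EMBEDDING", "RF_EMBEDDING")
.baseline_methods <- c("MLP", "LR", "RF")

#' Feature-prediction experiment (experiment-split masking)
#'
#' Compares end-to-end graph networks, indirect embedding-based regression,
#' and feature-only baselines at predicting held-out target-experiment values
#' under the experiment-split protocol: per target column and gene fold, a
#' model sees the non-target columns of all genes (or one-hot identity
#' features when \code{use_features = FALSE}) plus the full graph, and is
#' scored by test-gene MSE on the target column.
#'
#' @param g a \code{gfae_graph}.
#' @param x aligned expression matrix (>= 2 experiments).
#' @param methods subset of \code{GCN_MP, GRAPHSAGE, GRAPHCONV,
#'   FEATGRAPHCONV, LR_EMBEDDING, RF_EMBEDDING, MLP, LR, RF}.
#' @param use_features use expression input (\code{TRUE}) or graph-only
#'   one-hot input (\code{FALSE}; feature-only baselines are then skipped
#'   with a message).
#' @param k number of gene folds.
#' @param n_targets number of target experiments sampled per seed (default
#'   10\% of columns, at least 1).
#' @param gfae_cfg,gae_cfg training configurations.
#' @param seed integer seed.
#' @return long-format \code{data.frame} with one \code{mse} row per
#'   (method, target column, fold).
#' @export
run_feature_prediction_experiment <- function(
    g, x, methods = c(.end_to_end_methods, .baseline_methods),
    use_features = TRUE, k = 3L,
    n_targets = max(1L, round(0.1 * ncol(x))),
    gfae_cfg = gfae_config(), gae_cfg = gae_config(), seed = 1L) {
  if (ncol(x) < 2L) stop("need at least 2 experiments")
  n <- nrow(x)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  targets <- sort(sample.int(ncol(x), min(n_targets, ncol(x) - 1L)))
  folds <- kfold_indices(n, k, seed = seed)
  masks <- make_experiment_masks(n, ncol(x), folds, targets)
  input_cols <- masks[[1L]]$input_cols
  x_in <- if (use_features) x[, input_cols, drop = FALSE] else
    as.matrix(identity_features(n))
  setting <- if (use_features) "features" else "graph"

  needs_gae <- any(methods %in% .indirect_methods)
  z <- NULL
  if (needs_gae) {
    gae_cfg$seed <- gae_cfg$seed + seed
    z <- train_gae(if (use_features) x_in else NULL, g, split = NULL,
                   cfg = gae_cfg)$embedding
  }

  rows <- list()
  for (method in methods) {
    if (method %in% .baseline_methods && !use_features) {
      message("skipping ", method, ": feature-only baseline needs features")
      next
    }
    for (mp in masks) {
      q <- mp$target_col
      tr <- mp$train_genes
      te <- mp$test_genes
      y <- x[, q]
      mse <- if (method %in% .end_to_end_methods) {
        net <- build_gfae(method, ncol(x_in), 1L, seed = seed + mp$fold)
        net <- train_gfae(net, x_in, x[, q, drop = FALSE], mp$train_mask[, q,
                          drop = FALSE], g, cfg = gfae_cfg)
        pred <- predict_gfae(net, x_in, g)
        mean((pred[te, 1L] - y[te])^2)
      } else if (method %in% .indirect_methods) {
        reg <- if (method == "LR_EMBEDDING") "LR" else "RF"
        pred <- indirect_predict(z, y[tr], tr, te, regressor = reg,
                                 seed = seed + mp$fold)
        mean((pred - y[te])^2)
      } else {
        kind <- method
        fit <- fit_baseline(kind, x_in[tr, , drop = FALSE], y[tr],
                            seed = seed + mp$fold)
        pred <- predict_baseline(fit, x_in[te, , drop = FALSE])
        mean((pred[, 1L] - y[te])^2)
      }
      rows[[length(rows) + 1L]] <-
        .report_row(method, setting, mp$fold, "mse", mse, seed)
      rows[[length(rows)]]$target_col <- q
    }
  }
  do.call(rbind, rows)
}

#' Imputation experiment (entrywise masking)
#'
#' Trains one auto-encoder per method and fold with the loss restricted to
#' the train-visible entries and reports mean squared error on the held-out
#' (test) entries. Methods are the four graph convolution layers, the MLP
#' auto-encoder, a column-mean imputer (\code{COLMEAN}), and
#' \code{FEATGRAPHCONV_SHUFFLED}, which runs FeatGraphConv on a
#' degree-preserving edge-shuffled graph as a structure control.
#'
#' Two input conventions are supported. The default, \code{input = "full"},
#' is the auto-encoder reconstruction protocol: the complete matrix is the
#' model input at training and evaluation, and the entry split governs only
#' which entries the loss (train) and the metric (test) read — the
#' evaluation measures how well a model trained to reconstruct one random
#' subset of entries reconstructs the complementary subset. With
#' \code{input = "train_masked"} the test entries are zeroed in the model
#' input throughout (strict missing-value imputation); note that without an
#' information bottleneck this variant rewards memorising the observed
#' entries and generalises poorly.
#'
#' @param g a \code{gfae_graph}.
#' @param x aligned expression matrix.
#' @param methods methods to run (see above).
#' @param k number of entry folds the masks are built with (each test fold
#'   holds \code{1/k} of the eligible entries).
#' @param folds_per_seed how many of the \code{k} folds to evaluate.
#' @param nonzero_only restrict test entries to nonzero values.
#' @param input input convention, see Details.
#' @param cfg a \code{\link{gfae_config}}.
#' @param seed integer seed.
#' @return long-format \code{data.frame} with one \code{mse} row per
#'   (method, fold).
#' @export
run_imputation_experiment <- function(
    g, x, methods = c(.end_to_end_methods, "MLP", "COLMEAN"),
    k = 10L, folds_per_seed = 1L, nonzero_only = FALSE,
    input = c("full", "train_masked"),
    cfg = gfae_config(), seed = 1L) {
  input <- match.arg(input)
  masks <- make_imputation_masks(x, k, seed = seed,
                                 nonzero_only = nonzero_only)
  masks <- masks[seq_len(min(folds_per_seed, k))]
  q <- ncol(x)
  rows <- list()
  for (mp in masks) {
    x_in <- if (input == "full") x else x * mp$train_mask
    for (method in methods) {
      pred <- switch(method,
        COLMEAN = {
          cm <- colSums(x * mp$train_mask) / pmax(colSums(mp$train_mask), 1)
          matrix(cm, nrow(x), q, byrow = TRUE)
        },
        MLP = {
          net <- build_mlp(q, q, seed = seed + mp$fold)
          net <- train_gfae(net, x_in, x, mp$train_mask, g, cfg = cfg)
          predict_gfae(net, x_in, g)
        },
        FEATGRAPHCONV_SHUFFLED = {
          g_shuf <- shuffle_edges(g, seed = seed + mp$fold)
          net <- build_gfae("FEATGRAPHCONV", q, q, seed = seed + mp$fold)
          net <- train_gfae(net, x_in, x, mp$train_mask, g_shuf, cfg = cfg)
          predict_gfae(net, x_in, g_shuf)
        },
        {
          net <- build_gfae(method, q, q, seed = seed + mp$fold)
          net <- train_gfae(net, x_in, x, mp$train_mask, g, cfg = cfg)
          predict_gfae(net, x_in, g)
        })
      mse <- masked_mse(pred, x, mp$test_mask)
      rows[[length(rows) + 1L]] <-
        .report_row(method, "imputation", mp$fold, "mse", mse, seed)
    }
  }
  do.call(rbind, rows)
}

#' Summarise an experiment report
#'
#' Mean and standard deviation of each metric across folds (and seeds, if
#' the report concatenates several).
#'
#' @param report a long-format report \code{data.frame}.
#' @return \code{data.frame} with one row per (method, setting, metric).
#' @export
summarize_report <- function(report) {
  key <- interaction(report$method, report$setting, report$metric, drop = TRUE)
  out <- do.call(rbind, lapply(split(report, key), function(d) {
    data.frame(method = d$method[1L], setting = d$setting[1L],
               metric = d$metric[1L], mean = mean(d$value),
               sd = if (nrow(d) > 1L) stats::sd(d$value) else NA_real_,
               n = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
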