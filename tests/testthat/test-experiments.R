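test_that("kfold_indices partitions evenly and deterministically", {
  folds <- kfold_indices(100, 10, seed = 1)
  expect_length(folds, 10L)
  expect_true(all(lengths(folds) == 10L))
  expect_setequal(unlist(folds), 1:100)

  folds7 <- kfold_indices(23, 7, seed = 2)
  expect_true(max(lengths(folds7)) - min(lengths(folds7)) <= 1L)
  expect_setequal(unlist(folds7), 1:23)

  expect_identical(kfold_indices(50, 5, seed = 3), kfold_indices(50, 5, seed = 3))
  expect_error(kfold_indices(5, 6), "k must satisfy")
})

test_that("experiment-split masks separate genes and experiments correctly", {
  folds <- kfold_indices(10, 2, seed = 4)
  masks <- make_experiment_masks(10, 4, folds, target_experiments = 2L)
  expect_length(masks, 2L)
  for (mp in masks) {
    expect_equal(mp$input_cols, c(1L, 3L, 4L))
    expect_length(intersect(mp$input_cols, mp$target_col), 0L)
    expect_setequal(c(mp$train_genes, mp$test_genes), 1:10)
    expect_length(intersect(mp$train_genes, mp$test_genes), 0L)
    # masks live only in the target column
    expect_true(all(mp$train_mask[, -2] == 0))
    expect_true(all(mp$train_mask[, 2] + mp$test_mask[, 2] == 1))
    expect_equal(sum(mp$test_mask), length(folds[[mp$fold]]))
  }
  expect_error(make_experiment_masks(10, 4, folds, 1:4), "proper subset")
})

test_that("imputation masks are exact complements within the eligible set", {
  set.seed(5)
  for (r in 1:25) {
    n <- sample(3:12, 1); q <- sample(2:8, 1)
    x <- matrix(rnorm(n * q), n, q)
    k <- sample(2:min(4, n * q), 1)
    masks <- make_imputation_masks(x, k, seed = r)
    expect_length(masks, k)
    test_union <- matrix(0, n, q)
    for (mp in masks) {
      expect_true(all(mp$train_mask + mp$test_mask == 1))  # M_test = !M_train
      test_union <- test_union + mp$test_mask
    }
    expect_true(all(test_union == 1))  # folds partition the entries
  }

  x <- matrix(rnorm(1000), 50, 20)
  masks <- make_imputation_masks(x, 10, seed = 6)
  expect_true(all(vapply(masks, function(m) sum(m$test_mask), 1) == 100))
})

test_that("nonzero_only masking never tests a zero entry", {
  set.seed(7)
  x <- matrix(rnorm(200), 20, 10)
  x[sample(200, 60)] <- 0
  masks <- make_imputation_masks(x, 5, seed = 8, nonzero_only = TRUE)
  for (mp in masks) {
    expect_true(all(x[mp$test_mask == 1] != 0))
    expect_true(all(mp$train_mask[x == 0] == 1))  # zeros stay train-visible
    expect_true(all(mp$train_mask + mp$test_mask >= 1))
    expect_true(all(mp$train_mask * mp$test_mask == 0))
  }
})

test_that("experiment-split training never reads held-out target values", {
  g <- random_test_graph(20, 0.25, seed = 9)
  x <- smooth_features(g, 4, steps = 2, noise_sd = 0.2, seed = 10)
  folds <- kfold_indices(20, 4, seed = 11)
  mp <- make_experiment_masks(20, 4, folds, target_experiments = 4L)[[1]]
  target <- x[, 4, drop = FALSE]
  target[mp$test_genes, ] <- NaN  # poison: training must still be finite
  net <- build_gfae("FEATGRAPHCONV", 3, 1, seed = 12)
  trained <- train_gfae(net, x[, 1:3], target,
                        mp$train_mask[, 4, drop = FALSE], g,
                        gfae_config(epochs = 20))
  expect_true(all(is.finite(trained$losses)))
})

test_that("structure-embedding reports have the expected schema", {
  g <- two_block_graph(60, 0.4, 0.05, seed = 13)
  x <- smooth_features(g, 6, steps = 2, noise_sd = 0.3, seed = 14)
  rep <- run_structure_embedding_experiment("GRAPH", g, x,
                                            cfg = gae_config(epochs = 20),
                                            seed = 15, n_repeats = 2)
  expect_equal(nrow(rep), 3L * 2L)
  expect_setequal(unique(rep$metric), c("auc", "ap", "variance_explained"))

  rep_corr <- run_structure_embedding_experiment("EXPRESSION", g, x,
                                                 seed = 16, n_repeats = 2)
  expect_true(all(rep_corr$value[rep_corr$metric == "auc"] > 0))
})

test_that("correlation scoring gives AUC 1 when connected pairs share features", {
  g <- make_line_graph(paste0("g", 1:6))
  set.seed(17)
  base <- rnorm(8)
  x <- rbind(base, base, base, base, base, base)  # all rows identical
  x[5, ] <- rnorm(8); x[6, ] <- rnorm(8)          # break the tail apart
  sp_pos <- g$edges[1:3, , drop = FALSE]          # identical-row pairs
  sp_neg <- rbind(c(1L, 5L), c(2L, 6L))
  m <- evaluate_link_prediction(correlation_edge_scores(x, sp_pos),
                                correlation_edge_scores(x, sp_neg))
  expect_equal(m$auc, 1)
})

test_that("feature-prediction experiment: schema, copy task, and skips", {
  g <- random_test_graph(24, 0.25, seed = 18)
  v <- rnorm(24)
  x <- cbind(v, v, v, v)  # every column duplicates every other
  colnames(x) <- paste0("e", 1:4)
  rownames(x) <- g$node_ids
  rep <- run_feature_prediction_experiment(
    g, x, methods = "LR", k = 2, n_targets = 1, seed = 19)
  expect_equal(nrow(rep), 2L)  # 1 method x 1 target x 2 folds
  expect_true(all(rep$value < 1e-10))  # copy task is exact for LR

  expect_message(
    rep2 <- run_feature_prediction_experiment(
      g, x, methods = c("LR", "LR_EMBEDDING"), use_features = FALSE, k = 2,
      n_targets = 1, gae_cfg = gae_config(epochs = 10), seed = 20),
    "skipping LR")
  expect_true(all(rep2$method == "LR_EMBEDDING"))
  expect_equal(nrow(rep2), 2L)
})

test_that("imputation experiment reports are reproducible bit for bit", {
  g <- random_test_graph(30, 0.15, seed = 21)
  x <- smooth_features(g, 5, steps = 2, noise_sd = 0.2, seed = 22)
  args <- list(g = g, x = x, methods = c("FEATGRAPHCONV", "MLP", "COLMEAN"),
               k = 5, cfg = gfae_config(epochs = 30), seed = 23)
  r1 <- do.call(run_imputation_experiment, args)
  r2 <- do.call(run_imputation_experiment, args)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 3L)

  # strict imputation variant zeroes test entries in the model input
  r3 <- run_imputation_experiment(g, x, methods = "COLMEAN", k = 5,
                                  input = "train_masked", seed = 23)
  expect_equal(r3$value, r1$value[r1$method == "COLMEAN"])
})

test_that("a constant matrix is imputed almost perfectly by every method", {
  g <- random_test_graph(25, 0.2, seed = 24)
  x <- matrix(0.5, 25, 6)
  rep <- run_imputation_experiment(
    g, x, methods = c("GCN_MP", "GRAPHSAGE", "GRAPHCONV", "FEATGRAPHCONV",
                      "MLP", "COLMEAN"),
    k = 5, cfg = gfae_config(epochs = 800), seed = 25)
  expect_true(all(rep$value < 0.01))
})

test_that("reports summarise and round-trip through TSV", {
  g <- random_test_graph(20, 0.2, seed = 26)
  x <- smooth_features(g, 4, steps = 1, noise_sd = 0.2, seed = 27)
  rep <- run_imputation_experiment(g, x, methods = "COLMEAN", k = 4,
                                   folds_per_seed = 2, seed = 28)
  s <- summarize_report(rep)
  expect_equal(s$n, 2L)
  expect_equal(s$mean, mean(rep$value))

  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(rep, f, sep = "\t", row.names = FALSE, quote = FALSE)
  back <- utils::read.table(f, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  expect_equal(back$value, rep$value, tolerance = 1e-12)
  expect_equal(back$method, rep$method)
})
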