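test_that("the learning-rate schedule steps down by the drop factor", {
  cfg <- train_config()
  expect_equal(lr_at(0, cfg), 0.01)
  expect_equal(lr_at(39, cfg), 0.01)
  expect_equal(lr_at(40, cfg), 0.001)
  expect_equal(lr_at(45, cfg), 0.001)
  expect_equal(lr_at(49, cfg), 0.001)
  expect_error(lr_at(50, cfg), class = "gcnprio_range_error")
  expect_error(lr_at(-1, cfg), class = "gcnprio_range_error")
  expect_error(train_config(epochs = 30, lr_drop_epoch = 40),
               class = "gcnprio_config_error")
})

test_that("training is bitwise reproducible and follows the schedule", {
  bench <- small_benchmark(n = 30, seed = 2)
  g <- prune_isolated(bench$graph, bench$labels$gene)
  cfg <- fast_config(seed = 7, epochs = 6, drop = 4)
  m1 <- train_gcnn(g, bench$features, bench$labels, depth = 2, config = cfg,
                   hidden_dim = 8)
  m2 <- train_gcnn(g, bench$features, bench$labels, depth = 2, config = cfg,
                   hidden_dim = 8)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_identical(m1$predictions, m2$predictions)
  expect_equal(m1$lr_history, lr_at(0:5, cfg))
  expect_length(m1$loss_history, 6)

  m3 <- train_gcnn(g, bench$features, bench$labels, depth = 2,
                   config = fast_config(seed = 8, epochs = 6, drop = 4),
                   hidden_dim = 8)
  expect_false(identical(m1$loss_history, m3$loss_history))
})

test_that("training reduces the loss on a strong-signal benchmark", {
  bench <- small_benchmark(n = 60, seed = 3, effect_size = 2)
  g <- prune_isolated(bench$graph, bench$labels$gene)
  m <- train_gcnn(g, bench$features, bench$labels, depth = 3,
                  config = fast_config(seed = 1, epochs = 25, drop = 20),
                  hidden_dim = 8)
  expect_lt(m$loss_history[25], m$loss_history[1])
  expect_lt(m$loss_history[25], 0.3)
  # predictions separate the classes on the training data
  preds <- predict(m)
  preds$y_true <- bench$labels$label[match(preds$gene, bench$labels$gene)]
  expect_gt(auc_trapezoid(roc_points(preds)), 0.9)
})

test_that("single-class training labels are rejected", {
  bench <- small_benchmark(n = 20, seed = 4)
  g <- prune_isolated(bench$graph, bench$labels$gene)
  labs <- dplyr::filter(bench$labels, label == 1)
  expect_error(
    train_gcnn(g, bench$features, labs, config = fast_config()),
    class = "gcnprio_single_class_error"
  )
})

test_that("stratified folds partition the samples with near-equal sizes", {
  folds <- kfold_split(10, 10, labels = rep(0:1, 5), seed = 1)
  expect_length(folds, 10)
  expect_true(all(lengths(folds) == 1))

  y <- rep(c(0, 1), each = 142)
  folds <- kfold_split(284, 10, labels = y, seed = 3)
  sizes <- lengths(folds)
  expect_setequal(sort(unlist(folds)), 1:284)
  expect_equal(sum(sizes), 284)
  expect_lte(diff(range(sizes)), 1)
  expect_true(all(sizes %in% c(28, 29)))
  # stratification: each fold carries a near-balanced label mix
  pos_per_fold <- vapply(folds, function(f) sum(y[f]), numeric(1))
  expect_true(all(abs(pos_per_fold - sizes / 2) <= 1))

  expect_identical(folds, kfold_split(284, 10, labels = y, seed = 3))
  expect_false(identical(folds, kfold_split(284, 10, labels = y, seed = 4)))
  expect_error(kfold_split(5, 6), class = "gcnprio_fold_error")
})

test_that("cross-validation separates a perfectly informative fixture", {
  # features literally equal the labels: any fold must reach AUC 1
  withr::with_seed(5, {
    n <- 40
    ids <- sprintf("g%02d", 1:n)
    y <- rep(0:1, each = n / 2)
    adj <- matrix(0, n, n)
    for (i in 1:(n - 1)) adj[i, i + 1] <- adj[i + 1, i] <- 1
    g <- graph_from_adjacency(adj, ids)
    feats <- tibble::tibble(gene = ids, f1 = y, f2 = y, f3 = y, f4 = 0)
    labs <- tibble::tibble(gene = ids, label = y)
    rep <- run_cv(g, feats, labs, depth = 1, config = train_config(seed = 2),
                  k = 4, hidden_dim = 6)
  })
  expect_equal(rep$mean_auc, 1)
  expect_equal(rep$mean_aupr, 1)
})

test_that("evaluation reports have exact fold bookkeeping and default to 10 folds", {
  bench <- small_benchmark(n = 60, seed = 6)
  g <- prune_isolated(bench$graph, bench$labels$gene)
  rep <- run_cv(g, bench$features, bench$labels, method = "knn",
                config = train_config(seed = 9))
  expect_equal(rep$k, 10)
  expect_equal(nrow(rep$per_fold), 10)
  expect_equal(rep$mean_auc, mean(rep$per_fold$auc), tolerance = 1e-12)
  expect_equal(rep$mean_aupr, mean(rep$per_fold$aupr), tolerance = 1e-12)
  # every labelled gene scored exactly once across folds
  expect_setequal(rep$predictions$gene, rep$genes)
  expect_equal(nrow(rep$predictions), length(rep$genes))
  expect_s3_class(glance(rep), "tbl_df")
  expect_identical(tidy(rep), rep$per_fold)
  expect_s3_class(ggplot2::autoplot(rep), "ggplot")
})

test_that("held-out genes are masked from each fold's training labels", {
  bench <- small_benchmark(n = 30, seed = 8)
  g <- prune_isolated(bench$graph, bench$labels$gene)
  seen <- new.env(parent = emptyenv())
  seen$train_sets <- list()
  # intercept the per-fold training call to record which genes carry loss
  testthat::local_mocked_bindings(
    train_gcnn = function(graph, features, labels, ...) {
      seen$train_sets <- c(seen$train_sets, list(labels$gene))
      model <- list(predictions = tibble::tibble(
        gene = graph$node_ids, p_positive = stats::runif(length(graph$node_ids))
      ))
      class(model) <- "gcnn_model"
      model
    },
    .package = "gcnprio"
  )
  rep <- run_cv(g, bench$features, bench$labels, k = 5,
                config = fast_config(seed = 3))
  for (f in seq_len(5)) {
    test_genes <- rep$genes[rep$folds[[f]]]
    expect_length(intersect(seen$train_sets[[f]], test_genes), 0)
    expect_setequal(c(seen$train_sets[[f]], test_genes), rep$genes)
  }
})

test_that("rf and knn baseline folds are deterministic given the seed", {
  bench <- small_benchmark(n = 40, seed = 10)
  g <- prune_isolated(bench$graph, bench$labels$gene)
  for (m in c("rf", "knn")) {
    r1 <- run_cv(g, bench$features, bench$labels, method = m, k = 4,
                 config = train_config(seed = 11))
    r2 <- run_cv(g, bench$features, bench$labels, method = m, k = 4,
                 config = train_config(seed = 11))
    expect_identical(r1$per_fold, r2$per_fold)
  }
})

test_that("depth ablation emits one row per depth with shared folds", {
  bench <- small_benchmark(n = 30, seed = 12)
  g <- prune_isolated(bench$graph, bench$labels$gene)
  tab <- ablate_depth(g, bench$features, bench$labels, depths = c(1, 3),
                      config = fast_config(seed = 4, epochs = 4, drop = 3),
                      k = 3, hidden_dim = 6)
  expect_equal(nrow(tab), 2)
  expect_named(tab, c("depth", "mean_auc", "mean_aupr"))
  reports <- attr(tab, "reports")
  expect_identical(reports[[1]]$folds, reports[[2]]$folds)
  expect_error(ablate_depth(g, bench$features, bench$labels, depths = 0:2),
               class = "gcnprio_config_error")
  expect_s3_class(ggplot2::autoplot(tab), "ggplot")
})

test_that("the comparison harness evaluates all five methods on shared folds", {
  bench <- small_benchmark(n = 30, seed = 13)
  g <- prune_isolated(bench$graph, bench$labels$gene)
  tab <- run_baselines(g, bench$features, bench$labels,
                       config = fast_config(seed = 5, epochs = 4, drop = 3),
                       k = 3, depth = 1, hidden_dim = 6)
  expect_equal(nrow(tab), 5)
  expect_setequal(tab$method, c("gcn_cnn", "gcn", "cnn", "rf", "knn"))
  reports <- attr(tab, "reports")
  folds <- lapply(reports, `[[`, "folds")
  for (i in 2:5) expect_identical(folds[[1]], folds[[i]])
  expect_true(all(tab$mean_auc >= 0 & tab$mean_auc <= 1))
  expect_s3_class(ggplot2::autoplot(tab), "ggplot")
})

test_that("model tidiers expose the loss history and a one-row summary", {
  bench <- small_benchmark(n = 20, seed = 14)
  g <- prune_isolated(bench$graph, bench$labels$gene)
  m <- train_gcnn(g, bench$features, bench$labels, depth = 1,
                  config = fast_config(seed = 1, epochs = 5, drop = 4),
                  hidden_dim = 4)
  td <- tidy(m)
  expect_named(td, c("epoch", "loss", "lr"))
  expect_equal(nrow(td), 5)
  gl <- glance(m)
  expect_equal(gl$method, "gcn_cnn")
  expect_equal(gl$epochs, 5)
  expect_equal(gl$final_loss, m$loss_history[5])
})
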