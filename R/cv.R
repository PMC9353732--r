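#' Stratified k-fold partition
#'
#' Deals the indices of each label class round-robin into `k` folds after a
#' seeded shuffle, carrying the dealing position across classes so overall
#' fold sizes differ by at most one while each fold preserves the class
#' balance. Deterministic given `seed`.
#'
#' @param n Number of samples.
#' @param k Number of folds (default 10), `2 <= k <= n`.
#' @param labels Vector of length `n` of class labels used for stratification.
#' @param seed Integer seed.
#' @return List of `k` disjoint integer vectors whose union is `1:n`.
#' @export
kfold_split <- function(n, k = 10, labels = NULL, seed = 1) {
  n <- as.integer(n)
  k <- as.integer(k)
  if (k < 2L || k > n) {
    rlang::abort(sprintf("need 2 <= k <= n (got k = %d, n = %d)", k, n),
                 class = "gcnprio_fold_error")
  }
  if (is.null(labels)) labels <- rep(0L, n)
  if (length(labels) != n) {
    rlang::abort("`labels` must have length n", class = "gcnprio_fold_error")
  }
  folds <- vector("list", k)
  withr::with_seed(as.integer(seed), {
    pos <- 0L
    for (lev in sort(unique(as.character(labels)))) {
      idx <- sample(which(as.character(labels) == lev))
      assign_to <- ((pos + seq_along(idx) - 1L) %% k) + 1L
      for (f in seq_len(k)) {
        folds[[f]] <- c(folds[[f]], idx[assign_to == f])
      }
      pos <- (pos + length(idx)) %% k
    }
  })
  lapply(folds, sort)
}

score_ml_baseline <- function(method, x, y, train_idx, test_idx, seed) {
  xtr <- x[train_idx, , drop = FALSE]
  xte <- x[test_idx, , drop = FALSE]
  ytr <- factor(y[train_idx], levels = c(0L, 1L))
  if (method == "rf") {
    withr::with_seed(seed, {
      fit <- randomForest::randomForest(xtr, ytr, ntree = 500)
      as.numeric(stats::predict(fit, xte, type = "prob")[, "1"])
    })
  } else { # knn, k = 5, features standardized on the training fold
    mu <- colMeans(xtr)
    sd <- apply(xtr, 2L, stats::sd)
    sd[sd == 0] <- 1
    str <- sweep(sweep(xtr, 2L, mu), 2L, sd, `/`)
    ste <- sweep(sweep(xte, 2L, mu), 2L, sd, `/`)
    withr::with_seed(seed, {
      pred <- class::knn(str, ste, ytr, k = 5, prob = TRUE)
      pw <- attr(pred, "prob") # proportion of votes for the winning class
      ifelse(pred == "1", pw, 1 - pw)
    })
  }
}

#' Cross-validated evaluation
#'
#' Stratified k-fold cross-validation of a model variant on a labelled gene
#' set. Evaluation is transductive for the graph-based variants: every fold
#' trains on the full graph and feature matrix with the held-out genes' labels
#' masked, then scores the held-out genes. AUC and AUPR are computed per fold
#' and averaged; pooled-prediction variants are also reported.
#'
#' @inheritParams train_gcnn
#' @param k Number of folds (default 10).
#' @param method One of `"gcn_cnn"`, `"gcn"`, `"cnn"`, `"rf"`, `"knn"`.
#' @param folds Optional precomputed fold list (from [kfold_split()] over the
#'   labelled genes) to share folds across methods or depths.
#' @return An `eval_report`: per-fold tibble, `mean_auc`, `mean_aupr`,
#'   `pooled_auc`, `pooled_aupr`, pooled `predictions`, and the configuration
#'   snapshot (method, depth, k, seed, config).
#' @export
run_cv <- function(graph, features, labels, depth = 3, config = train_config(),
                   k = 10, method = c("gcn_cnn", "gcn", "cnn", "rf", "knn"),
                   hidden_dim = 32, folds = NULL) {
  method <- match.arg(method)
  inp <- align_pipeline_inputs(graph, features, labels)
  y <- inp$y
  labelled <- inp$labelled
  if (length(unique(y)) < 2L) {
    rlang::abort("labels must contain both classes", class = "gcnprio_single_class_error")
  }
  if (is.null(folds)) {
    folds <- kfold_split(length(labelled), k = k, labels = y, seed = config$seed)
  }
  k <- length(folds)
  fold_seeds <- derive_seeds(config$seed, k)

  per_fold <- vector("list", k)
  pooled <- vector("list", k)
  for (f in seq_len(k)) {
    test_genes <- labelled[folds[[f]]]
    train_genes <- labelled[-folds[[f]]]
    if (method %in% c("rf", "knn")) {
      tr_idx <- match(train_genes, rownames(inp$x))
      te_idx <- match(test_genes, rownames(inp$x))
      y_named <- stats::setNames(y, labelled)
      p <- score_ml_baseline(method, inp$x, y_named[rownames(inp$x)],
                             tr_idx, te_idx, fold_seeds[f])
    } else {
      cfg_f <- config
      cfg_f$seed <- fold_seeds[f]
      lab_tr <- tibble::tibble(gene = train_genes, label = y[match(train_genes, labelled)])
      model <- train_gcnn(inp$graph, inp$x, lab_tr, depth = depth, config = cfg_f,
                          hidden_dim = hidden_dim, method = method)
      p <- predict(model, genes = test_genes)$p_positive
    }
    preds <- tibble::tibble(
      gene = test_genes, fold = f,
      y_true = y[match(test_genes, labelled)], p_positive = p
    )
    m <- fold_metrics(preds)
    per_fold[[f]] <- tibble::tibble(fold = f, n_test = length(test_genes),
                                    auc = m[["auc"]], aupr = m[["aupr"]])
    pooled[[f]] <- preds
  }
  per_fold <- dplyr::bind_rows(per_fold)
  pooled <- dplyr::bind_rows(pooled)
  pooled_m <- fold_metrics(pooled)

  structure(
    list(
      per_fold = per_fold,
      mean_auc = mean(per_fold$auc),
      mean_aupr = mean(per_fold$aupr),
      pooled_auc = pooled_m[["auc"]],
      pooled_aupr = pooled_m[["aupr"]],
      predictions = pooled,
      method = method, depth = if (method %in% c("gcn_cnn", "gcn")) depth else NA_integer_,
      k = k, seed = config$seed, config = config, folds = folds,
      genes = labelled
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s | %d-fold CV | mean AUC %.4f | mean AUPR %.4f\n",
              x$method, x$k, x$mean_auc, x$mean_aupr))
  invisible(x)
}

#' @rdname eval_report_tidiers
#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) x$per_fold

#' Tidy and summarize a cross-validation report
#'
#' `tidy()` returns the per-fold AUC/AUPR tibble; `glance()` a one-row
#' summary with fold-averaged and pooled metrics.
#'
#' @param x An `eval_report` from [run_cv()].
#' @param ... Unused.
#' @name eval_report_tidiers
#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(
    method = x$method, depth = x$depth, k = x$k, seed = x$seed,
    mean_auc = x$mean_auc, mean_aupr = x$mean_aupr,
    pooled_auc = x$pooled_auc, pooled_aupr = x$pooled_aupr
  )
}

#' Plot per-fold cross-validation metrics
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_fold, c("auc", "aupr"),
                            names_to = "metric", values_to = "value")
  means <- tibble::tibble(metric = c("auc", "aupr"),
                          value = c(object$mean_auc, object$mean_aupr))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$fold), y = .data$value)) +
    ggplot2::geom_col(fill = "grey65") +
    ggplot2::geom_hline(data = means, ggplot2::aes(yintercept = .data$value),
                        linetype = 2) +
    ggplot2::facet_wrap(~metric, ncol = 1) +
    ggplot2::labs(x = "fold", y = NULL,
                  title = sprintf("%d-fold cross-validation (%s)", object$k, object$method)) +
    ggplot2::theme_minimal()
}

#' Depth ablation of the graph-convolutional encoder
#'
#' Re-runs the full cross-validation once per encoder depth with shared folds
#' and seed, so depth is the only varying factor.
#'
#' @inheritParams run_cv
#' @param depths Integer vector of depths within 1-4 (default `1:4`).
#' @return A tibble (class `depth_ablation`) with columns `depth`, `mean_auc`,
#'   `mean_aupr`; attribute `reports` holds the full `eval_report` per depth.
#' @export
ablate_depth <- function(graph, features, labels, depths = 1:4,
                         config = train_config(), k = 10, hidden_dim = 32) {
  if (any(depths < 1 | depths > 4)) {
    rlang::abort("depths must lie within 1-4", class = "gcnprio_config_error")
  }
  inp <- align_pipeline_inputs(graph, features, labels)
  folds <- kfold_split(length(inp$labelled), k = k, labels = inp$y,
                       seed = config$seed)
  reports <- purrr::map(depths, function(d) {
    run_cv(graph, features, labels, depth = d, config = config, k = k,
           method = "gcn_cnn", hidden_dim = hidden_dim, folds = folds)
  })
  out <- tibble::tibble(
    depth = as.integer(depths),
    mean_auc = purrr::map_dbl(reports, "mean_auc"),
    mean_aupr = purrr::map_dbl(reports, "mean_aupr")
  )
  attr(out, "reports") <- reports
  class(out) <- c("depth_ablation", class(out))
  out
}

#' Compare the full model against single-module and classical baselines
#'
#' Evaluates, with shared folds and seed: the full model (GCN encoder + CNN
#' head), the GCN-only variant (encoder + linear softmax head), the CNN-only
#' variant (convolutional head on raw features), a 500-tree random forest and
#' 5-nearest-neighbours on standardized raw features.
#'
#' @inheritParams run_cv
#' @param methods Character vector of variants to run.
#' @return A tibble (class `baseline_comparison`) with columns `method`,
#'   `mean_auc`, `mean_aupr`; attribute `reports` holds each `eval_report`.
#' @export
run_baselines <- function(graph, features, labels, config = train_config(),
                          k = 10, depth = 3, hidden_dim = 32,
                          methods = c("gcn_cnn", "gcn", "cnn", "rf", "knn")) {
  inp <- align_pipeline_inputs(graph, features, labels)
  folds <- kfold_split(length(inp$labelled), k = k, labels = inp$y,
                       seed = config$seed)
  reports <- purrr::map(methods, function(m) {
    run_cv(graph, features, labels, depth = depth, config = config, k = k,
           method = m, hidden_dim = hidden_dim, folds = folds)
  })
  out <- tibble::tibble(
    method = methods,
    mean_auc = purrr::map_dbl(reports, "mean_auc"),
    mean_aupr = purrr::map_dbl(reports, "mean_aupr")
  )
  attr(out, "reports") <- reports
  class(out) <- c("baseline_comparison", class(out))
  out
}

#' Plot a depth ablation or baseline comparison
#'
#' @param object A `depth_ablation` or `baseline_comparison` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot depth_ablation
#' @export
autoplot.depth_ablation <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object), c("mean_auc", "mean_aupr"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$depth, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "GCN depth", y = NULL, title = "Encoder depth ablation") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.depth_ablation
#' @method autoplot baseline_comparison
#' @export
autoplot.baseline_comparison <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object), c("mean_auc", "mean_aupr"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = NULL, title = "Method comparison (fold-averaged)") +
    ggplot2::theme_minimal()
}
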