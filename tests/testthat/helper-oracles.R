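# fixtures and independent brute-force oracles used across the suite

# gene_graph directly from a symmetric adjacency matrix
graph_from_adjacency <- function(adj, ids = paste0("g", seq_len(nrow(adj)))) {
  dimnames(adj) <- list(ids, ids)
  ut <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  edges <- tibble::tibble(
    gene_a = ids[ut[, 1]], gene_b = ids[ut[, 2]],
    weight = adj[ut]
  )
  structure(list(node_ids = ids, edges = edges, adjacency = adj),
            class = "gene_graph")
}

random_weighted_graph <- function(n, p = 0.4) {
  adj <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (stats::runif(1) < p) adj[i, j] <- adj[j, i] <- stats::runif(1, 0.1, 5)
    }
  }
  graph_from_adjacency(adj)
}

# entrywise D'^(-1/2) (A + I) D'^(-1/2) with explicit loops
naive_ahat <- function(adj) {
  n <- nrow(adj)
  ap <- adj + diag(n)
  d <- rowSums(ap)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      out[i, j] <- ap[i, j] / (sqrt(d[i]) * sqrt(d[j]))
    }
  }
  out
}

# entrywise triple product Ahat X W (W optional), explicit loops
naive_gcn_linear <- function(ahat, x, w = NULL) {
  xp <- matrix(0, nrow(x), ncol(x))
  for (i in seq_len(nrow(x))) {
    for (k in seq_len(ncol(x))) {
      acc <- 0
      for (j in seq_len(nrow(x))) acc <- acc + ahat[i, j] * x[j, k]
      xp[i, k] <- acc
    }
  }
  if (is.null(w)) return(xp)
  out <- matrix(0, nrow(x), ncol(w))
  for (i in seq_len(nrow(x))) {
    for (m in seq_len(ncol(w))) {
      acc <- 0
      for (k in seq_len(ncol(x))) acc <- acc + xp[i, k] * w[k, m]
      out[i, m] <- acc
    }
  }
  out
}

# tie-corrected pairwise Mann-Whitney statistic
mw_auc <- function(y, p) {
  pos <- p[y == 1]
  neg <- p[y == 0]
  total <- 0
  for (a in pos) {
    for (b in neg) {
      total <- total + (a > b) + 0.5 * (a == b)
    }
  }
  total / (length(pos) * length(neg))
}

# brute-force ROC/PR point sets: one confusion table per distinct threshold
naive_curve_points <- function(y, p, kind) {
  ths <- sort(unique(p), decreasing = TRUE)
  pts <- lapply(ths, function(t) {
    pred <- as.integer(p >= t)
    tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
    fn <- sum(pred == 0 & y == 1); tn <- sum(pred == 0 & y == 0)
    if (kind == "roc") c(x = fp / (fp + tn), y = tp / (tp + fn))
    else c(x = tp / (tp + fn), y = tp / (tp + fp))
  })
  do.call(rbind, pts)
}

# naive sliding-window forward pass of one conv block (same padding, stride 1)
# on a single embedding; kernel given as a (tap, c_in, c_out) array
naive_conv_block <- function(signal, karr) {
  len <- ncol(signal) # signal: c_in x len
  c_out <- dim(karr)[3]
  out <- matrix(0, c_out, len)
  for (f in seq_len(c_out)) {
    for (p in seq_len(len)) {
      acc <- 0
      for (t in 1:3) {
        q <- p + t - 2
        if (q >= 1 && q <= len) {
          for (c in seq_len(dim(karr)[2])) acc <- acc + karr[t, c, f] * signal[c, q]
        }
      }
      out[f, p] <- acc
    }
  }
  out
}

small_benchmark <- function(n = 60, seed = 1, effect_size = 2) {
  generate_benchmark(synthetic_config(
    n_genes = n, n_features = 8, effect_size = effect_size,
    p_within = 0.35, p_between = 0.08, seed = seed
  ))
}

fast_config <- function(seed = 1, epochs = 12, drop = 10) {
  train_config(epochs = epochs, lr_drop_epoch = drop, seed = seed)
}

# cross-validation runs on the default planted benchmark, memoised so the
# signal-recovery and combination-trend checks share the expensive fits
.cv_cache <- new.env(parent = emptyenv())

cached_benchmark_cv <- function(seed, method = "gcn_cnn", null = FALSE) {
  key <- paste(method, seed, null, sep = "_")
  if (is.null(.cv_cache[[key]])) {
    cfg <- if (null) {
      synthetic_config(effect_size = 0, p_within = 0.3, p_between = 0.3, seed = seed)
    } else {
      synthetic_config(seed = seed)
    }
    bench <- generate_benchmark(cfg)
    graph <- prune_isolated(bench$graph, bench$labels$gene)
    .cv_cache[[key]] <- run_cv(
      graph, bench$features, bench$labels,
      depth = 3, config = train_config(seed = seed), k = 10, method = method
    )
  }
  .cv_cache[[key]]
}
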