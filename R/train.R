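#' Training configuration
#'
#' Bundles the optimization schedule: 50 epochs of full-batch Adam (default
#' parameters beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8), initial learning
#' rate 0.01 reduced to one tenth after 40 epochs, and dropout rate 0.5 in the
#' decoder head.
#'
#' @param epochs Number of training epochs (default 50).
#' @param initial_lr Initial learning rate (default 0.01).
#' @param lr_drop_epoch Epoch (0-based) at which the rate drops (default 40).
#' @param lr_drop_factor Multiplicative drop (default 0.1).
#' @param dropout Dropout rate in `[0, 1)` (default 0.5).
#' @param seed Master integer seed driving weight initialization and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 50, initial_lr = 0.01, lr_drop_epoch = 40,
                         lr_drop_factor = 0.1, dropout = 0.5, seed = 1) {
  assert_scalar_number(epochs, "epochs", lower = 1)
  assert_scalar_number(initial_lr, "initial_lr", lower = 1e-12)
  assert_scalar_number(lr_drop_epoch, "lr_drop_epoch", lower = 1)
  assert_scalar_number(lr_drop_factor, "lr_drop_factor", lower = 1e-12)
  assert_scalar_number(dropout, "dropout", lower = 0, upper = 1 - 1e-9)
  if (epochs <= lr_drop_epoch) {
    rlang::abort("`epochs` must exceed `lr_drop_epoch`", class = "gcnprio_config_error")
  }
  structure(
    list(epochs = as.integer(epochs), initial_lr = initial_lr,
         lr_drop_epoch = as.integer(lr_drop_epoch),
         lr_drop_factor = lr_drop_factor, dropout = dropout,
         seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Learning rate at a given epoch
#'
#' Step schedule: `initial_lr` for epochs before `lr_drop_epoch`, then
#' `initial_lr * lr_drop_factor` for the remaining epochs.
#'
#' @param epoch 0-based epoch index, in `[0, config$epochs)`.
#' @param config A [train_config()].
#' @return Positive learning rate.
#' @export
lr_at <- function(epoch, config = train_config()) {
  if (any(epoch < 0 | epoch >= config$epochs)) {
    rlang::abort(sprintf("epoch must be in [0, %d)", config$epochs),
                 class = "gcnprio_range_error")
  }
  ifelse(epoch < config$lr_drop_epoch,
         config$initial_lr,
         config$initial_lr * config$lr_drop_factor)
}

# ---------------------------------------------------------------------------
# full-network forward/backward. `arch` fixes the variant:
#   gcn_cnn: GCN encoder -> CNN head (the full model)
#   gcn:     GCN encoder -> dropout -> linear softmax head
#   cnn:     raw features -> CNN head (graph unused)
# The convolutional head's fused forward/backward runs in compiled code; the
# encoder's matrix algebra stays in R (it is a handful of small gemms).

init_params <- function(arch) {
  par <- list()
  if (arch$use_graph) {
    dims_in <- c(arch$in_dim, rep(arch$hidden_dim, arch$depth - 1L))
    par$gcn <- lapply(seq_len(arch$depth), function(l) glorot(dims_in[l], arch$hidden_dim))
  }
  if (arch$head == "cnn") {
    par$head <- cnn_head(arch$emb_len, dropout_rate = arch$dropout, seed = NULL)$par
  } else {
    par$head <- list(fc_w = glorot(arch$emb_len, 2L), fc_b = rep(0, 2L))
  }
  par
}

init_running <- function(arch) {
  if (arch$head != "cnn") return(NULL)
  list(mean = lapply(CNN_CHANNELS, function(c) rep(0, c)),
       var = lapply(CNN_CHANNELS, function(c) rep(1, c)))
}

encoder_forward <- function(par, arch, a_hat, x, want_cache = FALSE) {
  h <- x
  cache <- NULL
  if (arch$use_graph) {
    cache <- vector("list", arch$depth)
    for (l in seq_len(arch$depth)) {
      ah <- a_hat %*% h
      z <- ah %*% par$gcn[[l]]
      if (want_cache) cache[[l]] <- list(ah = ah, mask = z > 0)
      h <- relu(z)
    }
  }
  list(h = h, cache = cache)
}

encoder_backward <- function(par, arch, a_hat, cache, demb) {
  g <- vector("list", arch$depth)
  dh <- demb
  for (l in rev(seq_len(arch$depth))) {
    dz <- dh * cache[[l]]$mask
    g[[l]] <- crossprod(cache[[l]]$ah, dz)
    # Ahat is symmetric, so the adjoint of h -> Ahat h is Ahat again
    if (l > 1L) dh <- a_hat %*% (dz %*% t(par$gcn[[l]]))
  }
  g
}

# one full-batch step evaluation: loss over the training genes and gradients
# for every parameter. `dmask` is the pre-scaled inverted-dropout mask for the
# flattened head input (NULL disables dropout); batch-norm batch statistics
# are computed over the training genes, the batch the loss sees.
train_step <- function(par, arch, a_hat, x, running, y, train_idx, dmask = NULL) {
  enc <- encoder_forward(par, arch, a_hat, x, want_cache = arch$use_graph)
  emb_t <- enc$h[train_idx, , drop = FALSE]
  grads <- list()
  if (arch$head == "cnn") {
    st <- .cpp_head_train_step(emb_t, par$head$kernels, par$head$gamma,
                               par$head$beta, running$mean, running$var,
                               par$head$fc_w, par$head$fc_b, y,
                               dmask %||% matrix(0, 0, 0), !is.null(dmask))
    grads$head <- list(
      kernels = st$dkernels,
      gamma = lapply(st$dgamma, as.numeric),
      beta = lapply(st$dbeta, as.numeric),
      fc_w = st$dfc_w, fc_b = as.numeric(st$dfc_b)
    )
    running <- list(mean = lapply(st$run_mean, as.numeric),
                    var = lapply(st$run_var, as.numeric))
    loss <- st$loss
    p_train <- st$probs[, 2L]
    demb_t <- st$demb
  } else {
    hd <- if (is.null(dmask)) emb_t else emb_t * dmask
    logits <- hd %*% par$head$fc_w + rep(par$head$fc_b, each = nrow(hd))
    probs <- softmax_rows(logits)
    p_train <- probs[, 2L]
    loss <- bce_loss(data.frame(y_true = y, p_positive = p_train))
    dlogits <- (probs - cbind(1 - y, y)) / length(y)
    grads$head <- list(fc_w = crossprod(hd, dlogits), fc_b = colSums(dlogits))
    demb_t <- dlogits %*% t(par$head$fc_w)
    if (!is.null(dmask)) demb_t <- demb_t * dmask
  }
  if (arch$use_graph) {
    demb <- matrix(0, nrow(x), arch$emb_len)
    demb[train_idx, ] <- demb_t
    grads$gcn <- encoder_backward(par, arch, a_hat, enc$cache, demb)
  }
  list(loss = loss, grads = grads, running = running, p_train = p_train)
}

# inference-mode probabilities for every node: running batch-norm statistics,
# no dropout; deterministic
infer_probs <- function(par, arch, a_hat, x, running) {
  h <- encoder_forward(par, arch, a_hat, x)$h
  if (arch$head == "cnn") {
    .cpp_head_infer(h, par$head$kernels, par$head$gamma, par$head$beta,
                    running$mean, running$var, par$head$fc_w, par$head$fc_b)
  } else {
    softmax_rows(h %*% par$head$fc_w + rep(par$head$fc_b, each = nrow(h)))
  }
}

align_pipeline_inputs <- function(graph, features, labels) {
  stopifnot(inherits(graph, "gene_graph"))
  fm <- features_to_matrix(features, graph$node_ids)
  if (length(fm$missing)) {
    message(sprintf("dropping %d graph gene(s) lacking feature rows: %s",
                    length(fm$missing), paste(fm$missing, collapse = ", ")))
    keep_edges <- graph$edges$gene_a %in% rownames(fm$x) &
      graph$edges$gene_b %in% rownames(fm$x)
    graph <- structure(
      list(node_ids = rownames(fm$x),
           edges = graph$edges[keep_edges, ],
           adjacency = graph$adjacency[rownames(fm$x), rownames(fm$x), drop = FALSE]),
      class = "gene_graph"
    )
  }
  y_all <- labels_to_vector(labels)
  labelled <- intersect(graph$node_ids, names(y_all))
  list(graph = graph, x = fm$x, y = y_all[labelled], labelled = labelled)
}

#' Train the graph-convolutional gene classifier end to end
#'
#' Optimizes the stacked GCN encoder and the convolutional decoder head
#' jointly by binary cross-entropy over the labelled training genes, using
#' full-batch Adam under the [train_config()] schedule. Training is
#' transductive: the whole graph and all node features take part in
#' propagation, and only the training genes contribute to the loss. The run is
#' fully reproducible from `config$seed`.
#'
#' @param graph A `gene_graph` (isolated genes pruned).
#' @param features Data frame with a `gene` column and numeric feature
#'   columns, or a matrix with gene rownames, covering the graph nodes.
#' @param labels Data frame with `gene` and `label` (0/1) columns; the
#'   training set. Must contain both classes.
#' @param depth Number of GCN layers, 1-4 (default 3).
#' @param config A [train_config()].
#' @param hidden_dim GCN layer width / embedding length (default 32,\n#'   matching the feature dimension of the default benchmark).
#' @param method Model variant: `"gcn_cnn"` (full model, default), `"gcn"`
#'   (encoder + linear softmax head) or `"cnn"` (convolutional head on raw
#'   features, graph ignored).
#' @param standardize Z-score feature columns over all nodes before training
#'   (default `TRUE`).
#' @return A `gcnn_model` with the trained `stack` and `head`, `loss_history`
#'   and `lr_history` (one entry per epoch), and inference-mode probabilities
#'   for every graph node (`predictions`).
#' @export
train_gcnn <- function(graph, features, labels, depth = 3,
                       config = train_config(), hidden_dim = 32,
                       method = c("gcn_cnn", "gcn", "cnn"),
                       standardize = TRUE) {
  method <- match.arg(method)
  stopifnot(inherits(config, "train_config"))
  if (depth < 1 || depth > 4) {
    rlang::abort("`depth` must be between 1 and 4", class = "gcnprio_config_error")
  }
  inp <- align_pipeline_inputs(graph, features, labels)
  if (length(unique(inp$y)) < 2L) {
    rlang::abort("training labels must contain both classes",
                 class = "gcnprio_single_class_error")
  }
  x <- inp$x
  if (standardize) {
    mu <- colMeans(x)
    sd <- apply(x, 2L, stats::sd)
    sd[sd == 0] <- 1
    x <- sweep(sweep(x, 2L, mu), 2L, sd, `/`)
  } else {
    mu <- rep(0, ncol(x)); sd <- rep(1, ncol(x))
  }

  use_graph <- method %in% c("gcn_cnn", "gcn")
  arch <- list(
    use_graph = use_graph, head = if (method == "gcn") "linear" else "cnn",
    depth = as.integer(depth), hidden_dim = as.integer(hidden_dim),
    in_dim = ncol(x),
    emb_len = if (use_graph) as.integer(hidden_dim) else ncol(x),
    dropout = config$dropout
  )
  if (arch$head == "cnn" && arch$emb_len < CNN_KERNEL) {
    rlang::abort("embedding length is shorter than the kernel span",
                 class = "gcnprio_input_size_error")
  }
  a_hat <- if (use_graph) normalized_operator(inp$graph)$a_hat else NULL

  train_idx <- match(inp$labelled, inp$graph$node_ids)
  y <- as.numeric(inp$y)
  b <- length(train_idx)
  flat_dim <- if (arch$head == "cnn") {
    arch$emb_len * CNN_CHANNELS[length(CNN_CHANNELS)]
  } else {
    arch$emb_len
  }
  keep <- 1 - config$dropout

  running <- init_running(arch)
  loss_history <- numeric(config$epochs)
  lr_history <- numeric(config$epochs)

  fit <- withr::with_seed(config$seed, {
    par <- init_params(arch)
    st <- adam_state(par)
    for (epoch in seq_len(config$epochs) - 1L) {
      lr <- lr_at(epoch, config)
      dmask <- if (config$dropout > 0) {
        matrix((stats::runif(b * flat_dim) < keep) / keep, b, flat_dim)
      } else {
        NULL
      }
      step <- train_step(par, arch, a_hat, x, running, y, train_idx, dmask)
      running <- step$running
      loss_history[epoch + 1L] <- step$loss
      lr_history[epoch + 1L] <- lr
      upd <- adam_step(par, step$grads, st, lr)
      par <- upd$par
      st <- upd$state
    }
    list(par = par, running = running)
  })
  par <- fit$par
  running <- fit$running

  probs <- infer_probs(par, arch, a_hat, x, running)
  predictions <- tibble::tibble(
    gene = inp$graph$node_ids,
    p_positive = as.numeric(probs[, 2L])
  )

  stack <- NULL
  if (use_graph) {
    stack <- structure(
      list(weights = par$gcn, depth = arch$depth,
           hidden_dim = arch$hidden_dim, in_dim = arch$in_dim),
      class = "gcn_stack"
    )
  }
  head_obj <- if (arch$head == "cnn") {
    structure(
      list(par = par$head,
           running = purrr::map2(running$mean, running$var,
                                 function(m, v) list(mean = m, var = v)),
           input_len = arch$emb_len,
           channels = CNN_CHANNELS, kernel_size = CNN_KERNEL,
           dropout_rate = arch$dropout),
      class = "cnn_head"
    )
  } else {
    structure(list(par = par$head, input_len = arch$emb_len), class = "linear_head")
  }

  structure(
    list(
      method = method, stack = stack, head = head_obj, arch = arch,
      config = config, node_ids = inp$graph$node_ids,
      train_genes = inp$labelled, y_train = y,
      loss_history = loss_history, lr_history = lr_history,
      predictions = predictions,
      standardization = list(mean = mu, sd = sd)
    ),
    class = "gcnn_model"
  )
}

#' @export
print.gcnn_model <- function(x, ...) {
  cat(sprintf("<gcnn_model> method %s | depth %s | %d nodes | final loss %.4f\n",
              x$method, if (is.null(x$stack)) "-" else x$stack$depth,
              length(x$node_ids), x$loss_history[length(x$loss_history)]))
  invisible(x)
}

#' Predict disease-relatedness probabilities
#'
#' Returns the inference-mode probability of the positive (disease-related)
#' class for every gene in the training graph. The model is transductive, so
#' predictions are read from the trained forward pass over the full graph.
#'
#' @param object A `gcnn_model`.
#' @param genes Optional character vector restricting the output.
#' @param ... Unused.
#' @return A tibble with columns `gene`, `p_positive`.
#' @export
predict.gcnn_model <- function(object, genes = NULL, ...) {
  out <- object$predictions
  if (!is.null(genes)) out <- out[match(genes, out$gene), , drop = FALSE]
  out
}

#' @rdname gcnn_model_tidiers
#' @method tidy gcnn_model
#' @export
tidy.gcnn_model <- function(x, ...) {
  tibble::tibble(
    epoch = seq_along(x$loss_history) - 1L,
    loss = x$loss_history,
    lr = x$lr_history
  )
}

#' Tidy and summarize a fitted gene classifier
#'
#' `tidy()` returns the per-epoch loss and learning-rate history; `glance()`
#' returns a one-row model summary.
#'
#' @param x A `gcnn_model`.
#' @param ... Unused.
#' @name gcnn_model_tidiers
#' @method glance gcnn_model
#' @export
glance.gcnn_model <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    depth = if (is.null(x$stack)) NA_integer_ else x$stack$depth,
    hidden_dim = if (is.null(x$stack)) NA_integer_ else x$stack$hidden_dim,
    epochs = x$config$epochs,
    initial_loss = x$loss_history[1L],
    final_loss = x$loss_history[length(x$loss_history)],
    n_nodes = length(x$node_ids),
    n_train = length(x$train_genes),
    seed = x$config$seed
  )
}
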