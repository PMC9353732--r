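#' Rectified linear unit
#'
#' Elementwise `max(x, 0)`; the activation used by every graph-convolution
#' layer and every convolutional block of the decoder.
#'
#' @param x Numeric vector, matrix or array with finite entries.
#' @return Object of the same shape.
#' @export
relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Glorot (Xavier) uniform initialization
glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

#' Create a stack of graph-convolution layers
#'
#' A depth-`depth` stack of layers `X <- ReLU(Ahat X W_l)` with trainable
#' weight matrices and no bias. Depth is restricted to 1-4, the range over
#' which stacking convolves information from correspondingly deeper
#' neighbourhoods without vanishing gradients on a network of a few hundred
#' genes; pass `force = TRUE` to exceed it deliberately.
#'
#' @param in_dim Number of input features per gene.
#' @param hidden_dim Output dimension of every layer (default 32).
#' @param depth Number of layers, in 1-4 (default 3).
#' @param seed Integer seed for Glorot-uniform weight initialization.
#' @param force Allow depth outside 1-4.
#' @return A `gcn_stack`: list with `weights` (list of matrices), `depth`,
#'   `hidden_dim`, `in_dim`.
#' @export
gcn_stack <- function(in_dim, hidden_dim = 32, depth = 3, seed = 1, force = FALSE) {
  assert_scalar_number(in_dim, "in_dim", lower = 1)
  assert_scalar_number(hidden_dim, "hidden_dim", lower = 1)
  if (!force && (depth < 1 || depth > 4)) {
    rlang::abort("`depth` must be between 1 and 4 (use force = TRUE to override)",
                 class = "gcnprio_config_error")
  }
  dims_in <- c(in_dim, rep(hidden_dim, depth - 1))
  weights <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(depth), function(l) glorot(dims_in[l], hidden_dim))
  })
  structure(
    list(weights = weights, depth = as.integer(depth),
         hidden_dim = as.integer(hidden_dim), in_dim = as.integer(in_dim)),
    class = "gcn_stack"
  )
}

#' @export
print.gcn_stack <- function(x, ...) {
  cat(sprintf("<gcn_stack> depth %d, %d -> %s\n", x$depth, x$in_dim,
              paste(rep(x$hidden_dim, x$depth), collapse = " -> ")))
  invisible(x)
}

#' Single graph-convolution layer
#'
#' Computes `ReLU(Ahat %*% X %*% W)` (or the linear part when
#' `activate = FALSE`): propagate features across the network, mix them with a
#' trainable weight matrix, rectify.
#'
#' @param op A `propagation_operator`.
#' @param x Numeric node-by-feature matrix (graph node order).
#' @param w Weight matrix with `ncol(x)` rows.
#' @param activate Apply ReLU (default `TRUE`).
#' @return Node-by-`ncol(w)` matrix.
#' @export
gcn_layer <- function(op, x, w, activate = TRUE) {
  x <- as.matrix(x)
  w <- as.matrix(w)
  if (ncol(x) != nrow(w)) {
    rlang::abort(
      sprintf("features have %d columns but the weight matrix has %d rows",
              ncol(x), nrow(w)),
      class = "gcnprio_shape_error"
    )
  }
  z <- propagate(op, x) %*% w
  if (activate) relu(z) else z
}

#' Encode node features with a stack of graph-convolution layers
#'
#' Applies [gcn_layer()] `depth` times, chaining outputs, so each gene's
#' embedding summarizes its features and those of its neighbourhood up to
#' `depth` hops away.
#'
#' @param op A `propagation_operator`.
#' @param x Numeric node-by-feature matrix, or a data frame with a `gene`
#'   column.
#' @param stack A `gcn_stack` whose `in_dim` matches `ncol(x)`.
#' @return Node-by-`hidden_dim` embedding matrix (rownames = node ids).
#' @export
encode <- function(op, x, stack) {
  stopifnot(inherits(stack, "gcn_stack"))
  if (is.data.frame(x)) x <- features_to_matrix(x, op$node_ids)$x
  h <- as.matrix(x)
  for (w in stack$weights) h <- gcn_layer(op, h, w, activate = TRUE)
  rownames(h) <- op$node_ids
  h
}

#' Write gene embeddings to a TSV file
#'
#' One row per gene: the gene identifier followed by its embedding vector.
#'
#' @param embedding Matrix with rownames = gene ids (e.g. from [encode()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(embedding, path) {
  df <- data.frame(gene = rownames(embedding), embedding, check.names = FALSE)
  colnames(df) <- c("gene", paste0("e", seq_len(ncol(embedding))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
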