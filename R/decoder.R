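CNN_CHANNELS <- c(32L, 64L, 32L, 16L)
CNN_KERNEL <- 3L
BCE_EPS <- 1e-7

#' Create the 1-D convolutional decoder head
#'
#' The decoder treats each gene's embedding as a one-channel 1-D signal and
#' applies four convolutional blocks — kernel size 3, filter counts 32, 64,
#' 32, 16, each followed by batch normalization and ReLU — with same-padding
#' and stride 1 so the signal length is preserved. The output is flattened,
#' passed through dropout (training mode only) and a fully connected layer to
#' two logits, and mapped to class probabilities by softmax.
#'
#' @param input_len Length of the embedding vector each gene presents to the
#'   head; must be at least the kernel size (3).
#' @param dropout_rate Dropout probability applied between flatten and the
#'   fully connected layer while training (default 0.5).
#' @param seed Integer seed for Glorot-uniform initialization, or `NULL` to
#'   draw from the current RNG state.
#' @return A `cnn_head` object holding the kernels (tap-major matrices),
#'   per-channel batch-norm scale/shift and running statistics, and the fully
#'   connected weights.
#' @export
cnn_head <- function(input_len, dropout_rate = 0.5, seed = 1) {
  assert_scalar_number(input_len, "input_len", lower = 1)
  if (input_len < CNN_KERNEL) {
    rlang::abort(
      sprintf("embedding length %d is shorter than the kernel span (%d)",
              input_len, CNN_KERNEL),
      class = "gcnprio_input_size_error"
    )
  }
  assert_scalar_number(dropout_rate, "dropout_rate", lower = 0, upper = 1 - 1e-9)
  build <- function() {
    chans <- c(1L, CNN_CHANNELS)
    kernels <- lapply(seq_along(CNN_CHANNELS), function(b) {
      glorot(CNN_KERNEL * chans[b], chans[b + 1L])
    })
    list(
      kernels = kernels,
      gamma = lapply(CNN_CHANNELS, function(c) rep(1, c)),
      beta = lapply(CNN_CHANNELS, function(c) rep(0, c)),
      fc_w = glorot(input_len * CNN_CHANNELS[length(CNN_CHANNELS)], 2L),
      fc_b = rep(0, 2L)
    )
  }
  par <- if (is.null(seed)) build() else withr::with_seed(as.integer(seed), build())
  structure(
    list(
      par = par,
      running = lapply(CNN_CHANNELS, function(c) list(mean = rep(0, c), var = rep(1, c))),
      input_len = as.integer(input_len),
      channels = CNN_CHANNELS,
      kernel_size = CNN_KERNEL,
      dropout_rate = dropout_rate
    ),
    class = "cnn_head"
  )
}

#' @export
print.cnn_head <- function(x, ...) {
  cat(sprintf("<cnn_head> input length %d | conv(k=%d): %s | fc: %d -> 2 (softmax)\n",
              x$input_len, x$kernel_size, paste(x$channels, collapse = ", "),
              x$input_len * x$channels[length(x$channels)]))
  invisible(x)
}

# reference (pure-R) forward pass over a batch: emb is an n x len matrix.
# Training here means batch statistics + sampled dropout; the compiled fused
# implementation used by the trainer is asserted equal to this path in tests.
head_forward_cnn <- function(head, emb, training = FALSE) {
  n <- nrow(emb)
  len <- ncol(emb)
  if (len != head$input_len) {
    rlang::abort(sprintf("embedding length %d does not match head input length %d",
                         len, head$input_len),
                 class = "gcnprio_input_size_error")
  }
  m <- matrix(as.vector(emb), ncol = 1L) # (n*len) x 1, node-fastest rows
  running <- head$running
  for (b in seq_along(head$channels)) {
    cv <- conv1d_forward(m, head$par$kernels[[b]], n)
    bn <- bn_forward(cv$z, head$par$gamma[[b]], head$par$beta[[b]],
                     running[[b]], training)
    if (training) running[[b]] <- bn$running
    m <- relu(bn$y)
  }
  # flatten (n*len) x c -> n x (len*c), channel blocks of len columns
  flat <- matrix(m, nrow = n)
  keep <- 1 - head$dropout_rate
  if (training && head$dropout_rate > 0) {
    dmask <- matrix(stats::runif(length(flat)) < keep, nrow = n) / keep
    flat_d <- flat * dmask
  } else {
    dmask <- NULL
    flat_d <- flat
  }
  logits <- flat_d %*% head$par$fc_w + rep(head$par$fc_b, each = n)
  probs <- softmax_rows(logits)
  list(probs = probs, logits = logits, running = running)
}

#' Decode one gene embedding into class probabilities
#'
#' Runs a single embedding vector through the convolutional head and returns
#' `(p_negative, p_positive)`. In training mode batch statistics are computed
#' from the single-vector batch and dropout is sampled; in inference mode
#' (default) the stored running statistics are used and the result is
#' deterministic.
#'
#' @param embedding Numeric vector of length `head$input_len` (>= 3).
#' @param head A [cnn_head()].
#' @param training_mode Logical; default `FALSE`.
#' @return Named numeric vector `c(p_negative = ..., p_positive = ...)`
#'   summing to 1.
#' @export
decode <- function(embedding, head, training_mode = FALSE) {
  stopifnot(inherits(head, "cnn_head"))
  embedding <- as.numeric(embedding)
  if (length(embedding) < CNN_KERNEL) {
    rlang::abort(
      sprintf("embedding of length %d is shorter than the kernel span (%d)",
              length(embedding), CNN_KERNEL),
      class = "gcnprio_input_size_error"
    )
  }
  fw <- head_forward_cnn(head, matrix(embedding, nrow = 1L), training = training_mode)
  stats::setNames(as.numeric(fw$probs), c("p_negative", "p_positive"))
}

#' Binary cross-entropy over labelled predictions
#'
#' Mean over samples of `-y * log(p) - (1 - y) * log(1 - p)`, with predicted
#' probabilities clipped into `[1e-7, 1 - 1e-7]` so the logarithms stay
#' finite.
#'
#' @param predictions Data frame with columns `y_true` (0/1) and `p_positive`
#'   (in `[0, 1]`).
#' @return Nonnegative scalar loss.
#' @export
bce_loss <- function(predictions) {
  predictions <- as.data.frame(predictions)
  if (nrow(predictions) == 0L) {
    rlang::abort("no predictions to score", class = "gcnprio_empty_input_error")
  }
  y <- as.numeric(predictions$y_true)
  p <- as.numeric(predictions$p_positive)
  if (!all(y %in% c(0, 1)) || any(p < 0 | p > 1 | !is.finite(p))) {
    rlang::abort("`y_true` must be 0/1 and `p_positive` in [0, 1]",
                 class = "gcnprio_shape_error")
  }
  p <- pmin(pmax(p, BCE_EPS), 1 - BCE_EPS)
  mean(-y * log(p) - (1 - y) * log(1 - p))
}

#' Write per-gene predictions to a TSV file
#'
#' @param predictions Data frame with columns `gene`, optionally `y_true`, and
#'   `p_positive`. Rows are written in decreasing `p_positive` order so the
#'   file doubles as a candidate-gene ranking.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  predictions <- as.data.frame(predictions)
  predictions <- predictions[order(-predictions$p_positive), , drop = FALSE]
  utils::write.table(predictions, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
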