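# Low-level neural-network primitives.
#
# 1-D signals over a batch of n nodes are stored as (n*len) x channels
# matrices with row r <-> (node i, position p), i varying fastest:
# r = (p-1)*n + i. With that layout, shifting every node's signal by one
# position is a single block row-shift, so same-padding convolution with
# kernel size 3 is one gemm on cbind(shift(-1), m, shift(+1)).

shift_rows <- function(m, o, n) {
  if (o == 0L) return(m)
  nr <- nrow(m)
  k <- abs(o) * n
  z <- matrix(0, nr, ncol(m))
  if (k >= nr) return(z)
  if (o < 0L) {
    z[(k + 1L):nr, ] <- m[1L:(nr - k), , drop = FALSE]
  } else {
    z[1L:(nr - k), ] <- m[(k + 1L):nr, , drop = FALSE]
  }
  z
}

# kernel matrices are (3*c_in) x c_out, rows ordered tap-major to match the
# cbind() block order below: tap 1 = position p-1, tap 2 = p, tap 3 = p+1
conv1d_forward <- function(m, kmat, n) {
  p <- cbind(shift_rows(m, -1L, n), m, shift_rows(m, 1L, n))
  list(z = p %*% kmat, p = p)
}

# convert between the tap-major kernel matrix and a (tap, c_in, c_out) array
# (the array form is what a sliding-window description of the kernel uses)
kernel_matrix_to_array <- function(kmat, c_in) {
  c_out <- ncol(kmat)
  aperm(array(kmat, dim = c(c_in, 3L, c_out)), c(2L, 1L, 3L))
}

kernel_array_to_matrix <- function(karr) {
  d <- dim(karr)
  matrix(aperm(karr, c(2L, 1L, 3L)), nrow = d[1L] * d[2L], ncol = d[3L])
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# batch normalization per channel (column). Training mode uses biased batch
# statistics and returns updated running statistics; inference uses the
# stored running statistics, making the forward pass deterministic.
bn_forward <- function(z, gamma, beta, running, training) {
  if (training) {
    mu <- colMeans(z)
    zc <- sweep(z, 2L, mu)
    v <- colMeans(zc * zc)
    inv <- 1 / sqrt(v + BN_EPS)
    xhat <- sweep(zc, 2L, inv, `*`)
    running <- list(
      mean = (1 - BN_MOMENTUM) * running$mean + BN_MOMENTUM * mu,
      var  = (1 - BN_MOMENTUM) * running$var + BN_MOMENTUM * v
    )
  } else {
    mu <- running$mean
    v <- running$var
    inv <- 1 / sqrt(v + BN_EPS)
    xhat <- sweep(sweep(z, 2L, mu), 2L, inv, `*`)
  }
  y <- sweep(sweep(xhat, 2L, gamma, `*`), 2L, beta, `+`)
  list(y = y, xhat = xhat, inv = inv, running = running)
}

softmax_rows <- function(logits) {
  z <- exp(logits - apply(logits, 1L, max))
  z / rowSums(z)
}

# Adam with bias correction; parameters, gradients and moments share one
# nested-list structure with numeric leaves
adam_state <- function(par) {
  zero <- function(x) if (is.list(x)) lapply(x, zero) else x * 0
  list(m = zero(par), v = zero(par), t = 0L)
}

adam_step <- function(par, grad, state, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - b1^state$t
  c2 <- 1 - b2^state$t
  rec <- function(p, g, m, v) {
    if (is.list(p)) {
      if (!is.null(names(p))) g <- g[names(p)] # align by name, not position
      out <- mapply(rec, p, g, m, v, SIMPLIFY = FALSE)
      list(
        p = lapply(out, `[[`, "p"),
        m = lapply(out, `[[`, "m"),
        v = lapply(out, `[[`, "v")
      )
    } else {
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g * g
      list(p = p - lr * (m / c1) / (sqrt(v / c2) + eps), m = m, v = v)
    }
  }
  out <- rec(par, grad, state$m, state$v)
  list(par = out$p, state = list(m = out$m, v = out$v, t = state$t))
}
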