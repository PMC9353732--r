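# double-precision R reference implementation of the decoder head's training
# step (forward with batch statistics, cross-entropy loss, full backward).
# It is verified against central finite differences and then serves as the
# oracle for the single-precision compiled step.

ref_shift_rows <- function(m, o, n) {
  if (o == 0) return(m)
  nr <- nrow(m)
  k <- abs(o) * n
  z <- matrix(0, nr, ncol(m))
  if (o < 0) z[(k + 1):nr, ] <- m[1:(nr - k), , drop = FALSE]
  else z[1:(nr - k), ] <- m[(k + 1):nr, , drop = FALSE]
  z
}

# head_par: list(kernels, gamma, beta, fc_w, fc_b) as built by cnn_head();
# emb: n x len batch; y: 0/1 labels; no dropout
ref_head_step <- function(head_par, emb, y) {
  n <- nrow(emb)
  len <- ncol(emb)
  eps <- 1e-5
  m <- matrix(as.vector(emb), ncol = 1L)
  nblk <- length(head_par$kernels)
  caches <- vector("list", nblk)
  for (b in seq_len(nblk)) {
    p <- cbind(ref_shift_rows(m, -1, n), m, ref_shift_rows(m, 1, n))
    z <- p %*% head_par$kernels[[b]]
    mu <- colMeans(z)
    v <- colMeans(z^2) - mu^2
    inv <- 1 / sqrt(v + eps)
    xhat <- sweep(sweep(z, 2, mu), 2, inv, `*`)
    act <- sweep(sweep(xhat, 2, head_par$gamma[[b]], `*`), 2,
                 head_par$beta[[b]], `+`)
    mask <- act > 0
    caches[[b]] <- list(p = p, xhat = xhat, inv = inv, mask = mask,
                        cin = ncol(m))
    m <- act * mask
  }
  flat <- matrix(m, nrow = n)
  logits <- flat %*% head_par$fc_w + rep(head_par$fc_b, each = n)
  pr <- exp(logits - apply(logits, 1, max))
  pr <- pr / rowSums(pr)
  p1 <- pmin(pmax(pr[, 2], 1e-7), 1 - 1e-7)
  loss <- mean(-y * log(p1) - (1 - y) * log(1 - p1))

  dlogits <- (pr - cbind(1 - y, y)) / n
  grads <- list(fc_w = crossprod(flat, dlogits), fc_b = colSums(dlogits),
                kernels = vector("list", nblk), gamma = vector("list", nblk),
                beta = vector("list", nblk))
  dflat <- dlogits %*% t(head_par$fc_w)
  dm <- matrix(as.vector(dflat), ncol = ncol(m))
  for (b in rev(seq_len(nblk))) {
    cc <- caches[[b]]
    dy <- dm * cc$mask
    grads$gamma[[b]] <- colSums(dy * cc$xhat)
    grads$beta[[b]] <- colSums(dy)
    dxhat <- sweep(dy, 2, head_par$gamma[[b]], `*`)
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * cc$xhat)
    dz <- sweep(sweep(dxhat, 2, m1) - sweep(cc$xhat, 2, m2, `*`), 2, cc$inv, `*`)
    grads$kernels[[b]] <- crossprod(cc$p, dz)
    dp <- dz %*% t(head_par$kernels[[b]])
    cin <- cc$cin
    dm <- ref_shift_rows(dp[, seq_len(cin), drop = FALSE], 1, n) +
      dp[, cin + seq_len(cin), drop = FALSE] +
      ref_shift_rows(dp[, 2 * cin + seq_len(cin), drop = FALSE], -1, n)
  }
  list(loss = loss, grads = grads, demb = matrix(dm, nrow = n), probs = pr)
}
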