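test_that("the decoder head has the fixed four-block convolutional structure", {
  head <- cnn_head(10, seed = 1)
  expect_identical(head$channels, c(32L, 64L, 32L, 16L))
  expect_identical(head$kernel_size, 3L)
  expect_length(head$par$kernels, 4)
  chans <- c(1L, head$channels)
  for (b in 1:4) {
    expect_equal(dim(head$par$kernels[[b]]), c(3L * chans[b], chans[b + 1]))
  }
  expect_equal(dim(head$par$fc_w), c(10L * 16L, 2L))
  expect_error(cnn_head(2), class = "gcnprio_input_size_error")
})

test_that("decode returns a valid two-class distribution for any input and weights", {
  withr::with_seed(8, {
    for (i in 1:10) {
      head <- cnn_head(sample(3:20, 1), seed = sample.int(1e6, 1))
      p <- decode(rnorm(head$input_len) * 10^runif(1, -2, 2), head)
      expect_length(p, 2)
      expect_true(all(p > 0 & p < 1))
      expect_equal(sum(p), 1, tolerance = 1e-9)
    }
  })
  expect_error(decode(c(1, 2), cnn_head(5)), class = "gcnprio_input_size_error")
})

test_that("zero fully-connected weights give (0.5, 0.5) regardless of input", {
  head <- cnn_head(6, seed = 3)
  head$par$fc_w[] <- 0
  head$par$fc_b[] <- 0
  expect_equal(unname(decode(rnorm(6), head)), c(0.5, 0.5))
})

test_that("decode matches a naive sliding-window convolution oracle", {
  len <- 6
  head <- cnn_head(len, seed = 42)
  withr::with_seed(7, emb <- rnorm(len))

  # naive chain: loop convolution, inference batch-norm (running stats:
  # mean 0, var 1), ReLU, then flatten/fc/softmax
  signal <- matrix(emb, nrow = 1)
  chans <- c(1L, head$channels)
  for (b in 1:4) {
    karr <- gcnprio:::kernel_matrix_to_array(head$par$kernels[[b]], chans[b])
    z <- naive_conv_block(signal, karr)
    xhat <- z / sqrt(1 + 1e-5)
    y <- xhat * head$par$gamma[[b]] + head$par$beta[[b]]
    signal <- pmax(y, 0)
  }
  flat <- as.vector(t(signal))
  logits <- as.vector(flat %*% head$par$fc_w) + head$par$fc_b
  oracle <- exp(logits - max(logits))
  oracle <- oracle / sum(oracle)

  expect_equal(unname(decode(emb, head)), oracle, tolerance = 1e-10)
})

test_that("the compiled inference path agrees with the reference R forward pass", {
  withr::with_seed(19, {
    head <- cnn_head(9, seed = 77)
    # make the running statistics nontrivial
    head$running <- lapply(head$channels, function(c) {
      list(mean = rnorm(c, sd = 0.2), var = runif(c, 0.5, 2))
    })
    emb <- matrix(rnorm(5 * 9), 5, 9)
    pr_r <- gcnprio:::head_forward_cnn(head, emb, training = FALSE)$probs
    pr_c <- gcnprio:::.cpp_head_infer(
      emb, head$par$kernels, head$par$gamma, head$par$beta,
      lapply(head$running, `[[`, "mean"), lapply(head$running, `[[`, "var"),
      head$par$fc_w, head$par$fc_b
    )
    # compiled path computes in single precision; R reference in double
    expect_equal(unname(pr_r), unname(pr_c), tolerance = 1e-5)
  })
})

test_that("the reference head backward matches central finite differences", {
  withr::with_seed(42, {
    n <- 7
    len <- 6
    head <- cnn_head(len, seed = 3)
    emb <- matrix(rnorm(n * len), n, len)
    y <- rep(c(1, 0), length.out = n)
    ref <- ref_head_step(head$par, emb, y)
    h <- 1e-6
    fd_check <- function(get, set, grad, n_coord = 5) {
      v <- get(head$par)
      for (i in sample(length(v), min(n_coord, length(v)))) {
        vp <- v; vp[i] <- vp[i] + h
        vm <- v; vm[i] <- vm[i] - h
        fd <- (ref_head_step(set(head$par, vp), emb, y)$loss -
                 ref_head_step(set(head$par, vm), emb, y)$loss) / (2 * h)
        expect_equal(as.numeric(grad[i]), as.numeric(fd), tolerance = 1e-4)
      }
    }
    for (b in 1:4) {
      fd_check(function(p) p$kernels[[b]],
               function(p, v) { p$kernels[[b]][] <- v; p },
               ref$grads$kernels[[b]])
      fd_check(function(p) p$gamma[[b]],
               function(p, v) { p$gamma[[b]] <- v; p },
               ref$grads$gamma[[b]], n_coord = 3)
      fd_check(function(p) p$beta[[b]],
               function(p, v) { p$beta[[b]] <- v; p },
               ref$grads$beta[[b]], n_coord = 3)
    }
    fd_check(function(p) p$fc_w, function(p, v) { p$fc_w[] <- v; p },
             ref$grads$fc_w)
    fd_check(function(p) p$fc_b, function(p, v) { p$fc_b <- v; p },
             ref$grads$fc_b)
    # and the gradient w.r.t. the embedding itself
    for (i in sample(length(emb), 5)) {
      ep <- emb; ep[i] <- ep[i] + h
      em <- emb; em[i] <- em[i] - h
      fd <- (ref_head_step(head$par, ep, y)$loss -
               ref_head_step(head$par, em, y)$loss) / (2 * h)
      expect_equal(ref$demb[i], fd, tolerance = 1e-4)
    }
  })
})

test_that("the compiled training step reproduces the double-precision reference", {
  withr::with_seed(43, {
    n <- 9
    len <- 8
    head <- cnn_head(len, seed = 5)
    emb <- matrix(rnorm(n * len), n, len)
    y <- rep(c(1, 0, 1), length.out = n)
    ref <- ref_head_step(head$par, emb, y)
    st <- gcnprio:::.cpp_head_train_step(
      emb, head$par$kernels, head$par$gamma, head$par$beta,
      lapply(head$running, `[[`, "mean"), lapply(head$running, `[[`, "var"),
      head$par$fc_w, head$par$fc_b, y, matrix(0, 0, 0), FALSE
    )
    expect_equal(st$loss, ref$loss, tolerance = 1e-5)
    expect_equal(unname(st$probs), unname(ref$probs), tolerance = 1e-5)
    for (b in 1:4) {
      expect_equal(st$dkernels[[b]], ref$grads$kernels[[b]],
                   ignore_attr = TRUE, tolerance = 1e-3)
      expect_equal(as.numeric(st$dgamma[[b]]), as.numeric(ref$grads$gamma[[b]]),
                   tolerance = 1e-3)
      expect_equal(as.numeric(st$dbeta[[b]]), as.numeric(ref$grads$beta[[b]]),
                   tolerance = 1e-3)
    }
    expect_equal(st$dfc_w, ref$grads$fc_w, ignore_attr = TRUE, tolerance = 1e-3)
    expect_equal(as.numeric(st$dfc_b), as.numeric(ref$grads$fc_b), tolerance = 1e-3)
    expect_equal(st$demb, ref$demb, ignore_attr = TRUE, tolerance = 1e-3)
  })
})

test_that("encoder gradients in the linear-head variant match finite differences", {
  ns <- asNamespace("gcnprio")
  withr::with_seed(44, {
    n <- 7
    g <- random_weighted_graph(n, p = 0.5)
    a_hat <- normalized_operator(g)$a_hat
    x <- matrix(rnorm(n * 4), n, 4)
    y <- rep(c(1, 0), length.out = n)
    arch <- list(use_graph = TRUE, head = "linear", depth = 2L, hidden_dim = 6L,
                 in_dim = 4L, emb_len = 6L, dropout = 0)
    par <- withr::with_seed(3, ns$init_params(arch))
    step <- ns$train_step(par, arch, a_hat, x, NULL, y, seq_len(n), NULL)
    loss_at <- function(p) ns$train_step(p, arch, a_hat, x, NULL, y, seq_len(n), NULL)$loss
    h <- 1e-6
    for (l in 1:2) {
      v <- par$gcn[[l]]
      for (i in sample(length(v), 6)) {
        pp <- par; pp$gcn[[l]][i] <- pp$gcn[[l]][i] + h
        pm <- par; pm$gcn[[l]][i] <- pm$gcn[[l]][i] - h
        fd <- (loss_at(pp) - loss_at(pm)) / (2 * h)
        expect_equal(step$grads$gcn[[l]][i], fd, tolerance = 1e-4)
      }
    }
    v <- par$head$fc_w
    for (i in sample(length(v), 4)) {
      pp <- par; pp$head$fc_w[i] <- pp$head$fc_w[i] + h
      pm <- par; pm$head$fc_w[i] <- pm$head$fc_w[i] - h
      fd <- (loss_at(pp) - loss_at(pm)) / (2 * h)
      expect_equal(step$grads$head$fc_w[i], fd, tolerance = 1e-4)
    }
  })
})

test_that("binary cross-entropy matches closed forms and is monotone", {
  expect_equal(bce_loss(data.frame(y_true = 1, p_positive = 0.5)), log(2),
               tolerance = 1e-12)
  expect_equal(bce_loss(data.frame(y_true = 0, p_positive = 0.5)), log(2),
               tolerance = 1e-12)
  expect_equal(
    bce_loss(data.frame(y_true = c(1, 0), p_positive = c(0.9, 0.2))),
    (-log(0.9) - log(0.8)) / 2,
    tolerance = 1e-12
  )
  # decreasing in p for a positive sample
  ps <- seq(0.05, 0.95, by = 0.1)
  losses <- vapply(ps, function(p) {
    bce_loss(data.frame(y_true = c(1, 0), p_positive = c(p, 0.3)))
  }, numeric(1))
  expect_true(all(diff(losses) < 0))
  # clipping keeps extreme probabilities finite
  expect_true(is.finite(bce_loss(data.frame(y_true = 1, p_positive = 0))))
  expect_error(bce_loss(data.frame(y_true = numeric(), p_positive = numeric())),
               class = "gcnprio_empty_input_error")
})

test_that("inference-mode decoding is deterministic, training mode is stochastic", {
  head <- cnn_head(8, seed = 10)
  emb <- seq(-1, 1, length.out = 8)
  expect_identical(decode(emb, head), decode(emb, head))
  withr::with_seed(1, a <- decode(emb, head, training_mode = TRUE))
  withr::with_seed(1, b <- decode(emb, head, training_mode = TRUE))
  withr::with_seed(2, c <- decode(emb, head, training_mode = TRUE))
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("prediction writer ranks genes by decreasing score", {
  preds <- tibble::tibble(gene = c("a", "b", "c"), y_true = c(0, 1, 1),
                          p_positive = c(0.2, 0.9, 0.5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_predictions(preds, path)
  back <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_identical(back$gene, c("b", "c", "a"))
})
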