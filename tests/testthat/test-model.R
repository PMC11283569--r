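test_that("scaled dot-product attention matches a scalar computation", {
  # independent scalar oracle on a fixed 3x2 instance
  Q <- matrix(c(0.5, -1, 2, 0.3, 1, -0.2), 3, 2)
  K <- matrix(c(1, 0, -1, 0.5, 2, 0), 3, 2)
  V <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2)
  expected_A <- matrix(0, 3, 3)
  for (i in 1:3) {
    s <- numeric(3)
    for (j in 1:3) {
      s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(2)
    }
    expected_A[i, ] <- exp(s) / sum(exp(s))
  }
  res <- attention_weights(Q, K, V)
  expect_equal(res$A, expected_A, tolerance = 1e-12)
  expect_equal(res$output, expected_A %*% V, tolerance = 1e-12)
})

test_that("attention degenerates to uniform rows for zero queries", {
  n <- 5
  Q <- matrix(0, n, 3)
  K <- matrix(rnorm(n * 3), n, 3)
  V <- diag(n)[, 1:3]
  A <- attention_weights(Q, K, V)$A
  expect_equal(A, matrix(1 / n, n, n))

  single <- attention_weights(matrix(1, 1, 2), matrix(2, 1, 2),
                              matrix(5, 1, 2))
  expect_equal(single$A, matrix(1, 1, 1))
  expect_error(attention_weights(matrix(0, 2, 2), matrix(0, 2, 3),
                                 matrix(0, 2, 2)),
               class = "endmotif_error_shape")
})

test_that("feed-forward implements max(0, xW1 + b1)W2 + b2", {
  d <- 4; f <- 6
  W1 <- matrix(rnorm(d * f), d, f); W2 <- matrix(rnorm(f * d), f, d)
  expect_equal(feed_forward(matrix(0, 2, d), W1, rep(0, f), W2, rep(0, d)),
               matrix(0, 2, d))
  # strongly negative b1 saturates the ReLU: output is b2 broadcast
  b2 <- rnorm(d)
  out <- feed_forward(matrix(rnorm(8), 2, d), W1, rep(-1e6, f), W2, b2)
  expect_equal(out, matrix(b2, 2, d, byrow = TRUE))
  # in the positive cone with b1 = 0 the map is linear: xW1W2 + b2
  x <- matrix(abs(rnorm(8)), 2, d)
  W1p <- abs(W1)
  expect_equal(feed_forward(x, W1p, rep(0, f), W2, b2),
               x %*% W1p %*% W2 + matrix(b2, 2, d, byrow = TRUE))
})

test_that("forward returns Z with embedding dimensions and normalized rows", {
  m <- tiny_model(seed = 2)
  s <- random_sequence(t = 10, seed = 3)
  fw <- transformer_forward(m, s)
  expect_equal(dim(fw$Z), c(12, m$config$hidden_size))   # t + 2 rows, d cols
  expect_equal(dim(fw$logits), c(12, 260))
  # row-softmax of logits sums to 1 at each position
  P <- exp(fw$logits - apply(fw$logits, 1, max))
  expect_equal(rowSums(P / rowSums(P)), rep(1, 12))
  # attention rows over non-PAD positions sum to 1 for every head
  for (A in fw$attentions[[1]]) {
    expect_equal(rowSums(A), rep(1, 12), tolerance = 1e-6)
  }
  # evaluation mode is deterministic
  fw2 <- transformer_forward(m, s)
  expect_identical(fw$logits, fw2$logits)
})

test_that("appending PAD positions never changes logits at real positions", {
  m <- tiny_model(seed = 4)
  s_short <- random_sequence(t = 8, seed = 5, pad_to = 8)
  s_padded <- random_sequence(t = 8, seed = 5, pad_to = 20)
  a <- transformer_forward(m, s_short)$logits
  b <- transformer_forward(m, s_padded)$logits
  expect_equal(b[1:10, ], a, tolerance = 1e-10)
})

test_that("forward rejects unknown tokens and over-long sequences", {
  m <- tiny_model(seed = 1, maxpos = 10)
  expect_error(transformer_forward(m, c("CLS", "NOPE", "SEP")),
               class = "endmotif_error_token")
  long <- random_sequence(t = 20, seed = 1)
  expect_error(transformer_forward(m, long), class = "endmotif_error_length")
})

test_that("analytic gradients match finite differences on a tiny model", {
  cfg <- transformer_config(hidden_size = 8, num_heads = 2, num_layers = 2,
                            ffn_dim = 12, vocab_size = 20, max_positions = 10,
                            dropout_rate = 0)
  m <- init_transformer(cfg, dict2, seed = 5)
  ids <- rbind(c(17L, 3L, 5L, 2L, 18L, 20L), c(17L, 8L, 9L, 10L, 18L, 20L))
  msk <- rbind(rep(1:0, c(5, 1)), rep(1:0, c(5, 1)))
  sel <- c(2L, 9L); tg <- c(3L, 9L)
  lg <- endmotif:::txf_loss_grads(ids, msk, sel, tg, m$params, cfg)
  num_grad <- function(nm, i, eps = 1e-5) {
    pp <- m$params; pp[[nm]][i] <- pp[[nm]][i] + eps
    lp <- endmotif:::txf_loss_grads(ids, msk, sel, tg, pp, cfg)$loss
    pp[[nm]][i] <- pp[[nm]][i] - 2 * eps
    lm <- endmotif:::txf_loss_grads(ids, msk, sel, tg, pp, cfg)$loss
    (lp - lm) / (2 * eps)
  }
  withr::with_seed(8, {
    for (nm in c("Wx", "Wp", "Wq_1", "Wk_2", "Wv_1", "W1_1", "W2_2", "g1_1",
                 "o2_2", "Hw1", "Hw2", "Hg", "Hb2")) {
      for (i in sample(length(m$params[[nm]]), 2)) {
        expect_equal(lg$grads[[nm]][i], num_grad(nm, i), tolerance = 1e-3)
      }
    }
  })
})

test_that("checkpoints reload to bit-identical forward outputs", {
  m <- tiny_model(seed = 6)
  s <- random_sequence(t = 12, seed = 7)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(transformer_forward(m, s)$logits,
                   transformer_forward(m2, s)$logits)
  expect_error(suppressWarnings(
    load_checkpoint(withr::local_tempfile(fileext = ".rds"))))
})
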