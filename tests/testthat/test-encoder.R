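test_that("class weights follow the inverse-frequency rule", {
  expect_equal(compute_class_weights(c(50, 50))$weights, c(1, 1))
  expect_equal(compute_class_weights(c(20, 100))$weights, c(3.0, 0.6))
  # corpus-scale counts: direct evaluation of S / (C * S_cj)
  cw <- compute_class_weights(c(34605, 516778))
  expect_equal(cw$S, 551383)
  expect_equal(cw$weights, 551383 / (2 * c(34605, 516778)))
  # a weighted class contributes loss mass S / C, equalizing the classes
  expect_equal(cw$weights * c(34605, 516778), rep(551383 / 2, 2))
  expect_error(compute_class_weights(c(10, 0)), "positive")
  expect_error(compute_class_weights(5), "two classes")
})

test_that("weight-count products conserve the sample total", {
  set.seed(31)
  for (i in 1:100) {
    counts <- sample.int(5000, sample(2:6, 1))
    cw <- compute_class_weights(counts)
    expect_lt(abs(sum(cw$weights * counts) - sum(counts)), 1e-9)
  }
})

test_that("encoder spec validates its architecture", {
  expect_equal(encoder_spec()$layer_widths, c(3072L, 1024L, 512L, 256L))
  expect_error(encoder_spec(layer_widths = c(100, 100, 50)), "decreasing")
  expect_error(encoder_spec(layer_widths = c(100)), "decreasing")
  expect_error(encoder_spec(dropout_rate = 1), "dropout")
})

test_that("pretraining reduces reconstruction loss across seeds", {
  st <- make_tiny_store(n = 400, d = 64, seed = 12, sep = 0)
  for (seed in 1:5) {
    sp <- encoder_spec(layer_widths = c(64, 32, 16), epochs = 5,
                       batch_size = 64, seed = seed)
    m <- pretrain_autoencoder(st, sp)
    h <- m$history
    expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  }
})

test_that("a linear encoder recovers an exact low-rank subspace", {
  # data on an 8-d linear subspace of 64-d space: a rank-16 bottleneck can
  # reconstruct it exactly, so trained MSE must be far below input variance
  set.seed(5)
  basis <- qr.Q(qr(matrix(rnorm(64 * 8), 64, 8)))
  z <- matrix(rnorm(300 * 8, sd = 2), 300, 8)
  x <- z %*% t(basis)
  st <- feature_store(x, sprintf("s%03d", 1:300), rep(c(0L, 1L), 150))
  sp <- encoder_spec(layer_widths = c(64, 16), dropout_rate = 0,
                     epochs = 150, batch_size = 64, learning_rate = 1e-2,
                     activation = "linear", validation_fraction = 0,
                     seed = 3)
  m <- pretrain_autoencoder(st, sp)
  mse <- mean((reconstruct(m, x) - x)^2)
  expect_lt(mse, 1e-3 * mean(x^2))
})

test_that("constant inputs are reconstructed almost perfectly", {
  x <- matrix(0.7, 80, 16)
  st <- feature_store(x, sprintf("s%02d", 1:80), rep(c(0L, 1L), 40))
  sp <- encoder_spec(layer_widths = c(16, 4), dropout_rate = 0,
                     epochs = 300, batch_size = 80, learning_rate = 5e-3,
                     activation = "linear", validation_fraction = 0,
                     seed = 2)
  m <- pretrain_autoencoder(st, sp)
  expect_lt(mean((reconstruct(m, x) - x)^2), 1e-6)
})

test_that("training is deterministic under a fixed seed", {
  st <- make_tiny_store(n = 120, d = 24, seed = 7)
  sp <- encoder_spec(layer_widths = c(24, 12, 6), epochs = 4,
                     batch_size = 32, seed = 99)
  a <- pretrain_autoencoder(st, sp)
  b <- pretrain_autoencoder(st, sp)
  expect_identical(a$history, b$history)
  expect_identical(a$encoder, b$encoder)
  fa <- finetune_with_labels(a, st)
  fb <- finetune_with_labels(b, st)
  expect_identical(fa$history, fb$history)
})

test_that("the two-step phase contract is enforced", {
  st <- make_tiny_store(n = 100, d = 16, seed = 4)
  sp <- encoder_spec(layer_widths = c(16, 8, 4), epochs = 2,
                     batch_size = 32, seed = 1)
  m <- pretrain_autoencoder(st, sp)
  expect_identical(m$phase, "pretrained")
  expect_error(strip_head(m), "finetuned")
  ft <- finetune_with_labels(m, st)
  expect_identical(ft$phase, "finetuned")
  expect_null(ft$decoder)
  expect_error(finetune_with_labels(ft, st), "pretrained")
  enc <- strip_head(ft)
  expect_identical(enc$phase, "encoder_only")
  expect_error(strip_head(enc), "finetuned")
  # encoding is a pure function with the bottleneck width
  codes <- encode_store(enc, st)
  expect_equal(ncol(codes$features), 4)
  expect_identical(codes$ids, st$ids)
  expect_identical(encode(enc, st$features), encode(enc, st$features))
  # empty store encodes to an empty store
  empty <- st[integer(0)]
  expect_equal(nrow(encode_store(enc, empty)$features), 0)
  expect_error(encode(enc, matrix(0, 2, 7)), "width")
})

test_that("fine-tuning fits separable clusters like a logistic oracle", {
  st <- make_tiny_store(n = 400, d = 32, seed = 21, sep = 8,
                        positive_fraction = 0.3)
  # logistic-regression oracle on the same data
  glm_fit <- suppressWarnings(
    glm(st$labels ~ st$features, family = binomial))
  oracle_acc <- mean((fitted(glm_fit) >= 0.5) == (st$labels == 1))
  expect_gte(oracle_acc, 0.99)
  sp <- encoder_spec(layer_widths = c(32, 16, 8), epochs = 10,
                     batch_size = 16, learning_rate = 3e-3, seed = 13)
  m <- finetune_with_labels(pretrain_autoencoder(st, sp), st)
  p <- 1 / (1 + exp(-(encode(m, st$features) %*% m$head$W +
                        m$head$b[1])))
  expect_gt(mean((p >= 0.5) == (st$labels == 1)), 0.95)
})

test_that("fine-tuning on label noise yields chance-level discrimination", {
  st <- make_tiny_store(n = 1000, d = 32, seed = 17, sep = 0,
                        positive_fraction = 0.3)
  sp <- encoder_spec(layer_widths = c(32, 16, 8), epochs = 5,
                     batch_size = 128, seed = 3)
  m <- finetune_with_labels(pretrain_autoencoder(st, sp), st)
  held <- make_tiny_store(n = 600, d = 32, seed = 18, sep = 0,
                          positive_fraction = 0.3)
  p <- as.vector(1 / (1 + exp(-(encode(m, held$features) %*% m$head$W +
                                  m$head$b[1]))))
  auc <- oracle_auc(p, held$labels)
  expect_gt(auc, 0.4)
  expect_lt(auc, 0.6)
})

test_that("PCA compression matches its eigendecomposition contract", {
  # plane embedded in 10-d: 2 components reconstruct exactly
  set.seed(9)
  z <- matrix(rnorm(40 * 2), 40, 2)
  emb <- matrix(rnorm(2 * 10), 2, 10)
  x <- z %*% emb
  st <- feature_store(x, sprintf("p%02d", 1:40), rep(c(0L, 1L), 20))
  fit <- pca_compress(st, 2)
  recon <- fit$codes$features %*% t(fit$rotation) +
    matrix(fit$center, 40, 10, byrow = TRUE)
  expect_lt(mean((recon - x)^2), 1e-10)
  # toy matrix: components match a brute-force eigensolver of the covariance
  toy <- matrix(c(2.1, 0.5, 3.3, 1.2, 2.2,
                  0.3, 1.9, 2.8, 0.7, 1.1,
                  1.5, 0.2, 2.5, 0.9, 1.8), 5, 3)
  st2 <- feature_store(toy, sprintf("t%d", 1:5), c(0L, 1L, 0L, 1L, 0L))
  fit2 <- pca_compress(st2, 2)
  ev <- eigen(cov(toy))
  for (j in 1:2) {
    align <- abs(sum(fit2$rotation[, j] * ev$vectors[, j]))
    expect_equal(align, 1, tolerance = 1e-8)
  }
  expect_equal(fit2$eigenvalues, ev$values, tolerance = 1e-8)
  # full basis: zero reconstruction error
  fit3 <- pca_compress(st2, 3)
  recon3 <- fit3$codes$features %*% t(fit3$rotation) +
    matrix(fit3$center, 5, 3, byrow = TRUE)
  expect_lt(max(abs(recon3 - toy)), 1e-10)
  expect_error(pca_compress(st2, 4), "dim")
})

test_that("a converged linear autoencoder approaches the PCA optimum", {
  set.seed(15)
  x <- matrix(rnorm(200 * 12), 200, 12) %*% diag(c(4:1, rep(0.3, 8)))
  st <- feature_store(x, sprintf("q%03d", 1:200), rep(c(0L, 1L), 100))
  fit <- pca_compress(st, 4)
  recon_pca <- fit$codes$features %*% t(fit$rotation) +
    matrix(fit$center, 200, 12, byrow = TRUE)
  mse_pca <- mean((recon_pca - x)^2)
  sp <- encoder_spec(layer_widths = c(12, 4), dropout_rate = 0,
                     epochs = 800, batch_size = 50, learning_rate = 1e-2,
                     activation = "linear", validation_fraction = 0,
                     seed = 8)
  m <- pretrain_autoencoder(st, sp)
  mse_ae <- mean((reconstruct(m, x) - x)^2)
  # PCA is the linear optimum: the network cannot beat it, and should
  # approach it within 5%
  expect_gte(mse_ae, mse_pca * (1 - 1e-6))
  expect_lte(mse_ae, mse_pca * 1.05)
})
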