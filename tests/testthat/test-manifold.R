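test_that("initialization chains the published layer shapes deterministically", {
  spec67 <- ae_spec(c(30, 10, 3, 10, 30, 67), 67, seed = 1)
  m <- init_autoencoder(spec67)
  dims <- lapply(m$layers, function(l) dim(l$W))
  expect_equal(dims, list(c(67L, 30L), c(30L, 10L), c(10L, 3L),
                          c(3L, 10L), c(10L, 30L), c(30L, 67L)))
  expect_equal(m$latent_dim, 3)
  m2 <- init_autoencoder(spec67)
  expect_identical(m$layers, m2$layers)
  spec11 <- ae_spec(c(8, 3, 8, 11), 11, seed = 2)
  m11 <- init_autoencoder(spec11)
  expect_equal(m11$latent_index, 2)
  expect_equal(ncol(m11$layers[[2]]$W), 3)
  spec204 <- ae_spec(c(16, 3, 16, 204), 204)
  expect_equal(vapply(init_autoencoder(spec204)$layers,
                      function(l) ncol(l$W), 0L), c(16L, 3L, 16L, 204L))
  expect_error(ae_spec(c(0, 3), 5), class = "vflatent_config_error")
})

test_that("supervised architectures chain through the class head", {
  for (cfg in list(list(sizes = c(16, 3, 10, 50), D = 204),
                   list(sizes = c(30, 10, 3, 10, 50), D = 67),
                   list(sizes = c(8, 3, 10, 50), D = 11))) {
    for (n_classes in c(4, 5)) {
      spec <- ae_spec(cfg$sizes, cfg$D, seed = 0)
      set.seed(1)
      X <- matrix(runif(20 * cfg$D), 20)
      y <- sample(letters[1:n_classes], 20, replace = TRUE)
      m <- fine_tune_supervised(spec, X, y, letters[1:n_classes],
                                epochs_pre = 2, epochs_ft = 2)
      widths <- vapply(m$layers, function(l) ncol(l$W), 0L)
      expect_equal(widths, c(cfg$sizes[seq_len(spec$latent_index)],
                             cfg$sizes[-seq_len(spec$latent_index)],
                             n_classes), ignore_attr = TRUE)
      expect_length(predict_labels(m, X), 20)
    }
  }
})

test_that("a linear bottleneck recovers the exact low-rank structure", {
  set.seed(42)
  X <- matrix(rnorm(200 * 3), 200, 3) %*% matrix(rnorm(3 * 11), 3, 11)
  spec <- ae_spec(c(3, 11), 11, latent_index = 1, activation = "linear", seed = 1)
  m <- train_autoencoder(init_autoencoder(spec), X, epochs = 4000, lr = 0.01)
  mse <- mean((decode(m, encode(m, X)$codes) - X)^2)
  expect_lt(mse / mean(X^2), 1e-6)
  # the projection is idempotent once converged
  H1 <- encode(m, X)$codes
  H2 <- encode(m, decode(m, H1))$codes
  expect_lt(max(abs(H1 - H2)), 1e-5)
})

test_that("converged linear autoencoders approach the optimal rank-d projection", {
  set.seed(13)
  X <- matrix(rnorm(80 * 8), 80, 8)       # full-rank data, lossy bottleneck
  spec <- ae_spec(c(3, 8), 8, latent_index = 1, activation = "linear", seed = 2)
  m <- train_autoencoder(init_autoencoder(spec), X, epochs = 6000, lr = 0.01)
  mse <- mean((decode(m, encode(m, X)$codes) - X)^2)
  best <- oracle_rank_d_mse(X, 3)
  expect_lt(mse, best * 1.01)
  expect_gte(mse, best - 1e-9)            # cannot beat the optimum
})

test_that("training reduces reconstruction loss and handles degenerate data", {
  set.seed(3)
  X <- matrix(runif(50 * 11), 50, 11)
  m <- train_autoencoder(init_autoencoder(ae_spec(c(8, 3, 8, 11), 11, seed = 4)),
                         X, epochs = 150)
  expect_true(all(is.finite(m$loss_log)))
  expect_lte(m$loss_log[length(m$loss_log)], m$loss_log[1])
  # constant rows converge toward that row
  C <- matrix(rep(runif(11), each = 40), 40, 11)
  mc <- train_autoencoder(init_autoencoder(ae_spec(c(3, 11), 11,
                                                   latent_index = 1, seed = 5)),
                          C, epochs = 3000, lr = 0.01)
  expect_lt(mean((decode(mc, encode(mc, C)$codes) - C)^2), 1e-4)
  expect_error(train_autoencoder(init_autoencoder(ae_spec(c(3, 4), 4,
                                                          latent_index = 1)),
                                 matrix(c(1, NA, 1, 1), 1)),
               class = "vflatent_input_error")
})

test_that("encode/decode respect shapes and the identity construction", {
  m <- init_autoencoder(ae_spec(c(4, 4), 4, latent_index = 1,
                                activation = "linear", seed = 0))
  m$layers[[1]]$W <- diag(4); m$layers[[1]]$b <- numeric(4)
  X <- matrix(rnorm(12), 3, 4)
  expect_equal(encode(m, X)$codes, X)
  # zero codes through zero-bias decoder with odd activation give zero
  m$layers[[2]]$b <- numeric(4)
  expect_equal(decode(m, matrix(0, 2, 4)), matrix(0, 2, 4))
  expect_error(encode(m, matrix(1, 2, 3)), class = "vflatent_input_error")
  expect_error(decode(m, matrix(1, 2, 3)), class = "vflatent_input_error")
})

test_that("softmax heads separate separable clusters and stay honest at chance", {
  set.seed(21)
  centers <- matrix(c(0, 0, 0, 6, 0, 0, 0, 6, 0), 3, byrow = TRUE)
  H <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(60 * 3, sd = 0.3), 60), 2, centers[k, ], `+`)))
  y <- rep(c("a", "b", "c"), each = 60)
  head <- train_softmax_head(H, y)
  expect_equal(mean(predict_labels(head, H) == y), 1)
  # uniform labels on random codes stay at chance on held-out data
  set.seed(22)
  Hr <- matrix(rnorm(10000 * 3), ncol = 3)
  yr <- sample(letters[1:5], 10000, replace = TRUE)
  head_r <- train_softmax_head(Hr[1:5000, ], yr[1:5000], letters[1:5])
  acc <- mean(predict_labels(head_r, Hr[5001:10000, ]) == yr[5001:10000])
  expect_lt(abs(acc - 0.2), 0.02)
  expect_warning(h1 <- train_softmax_head(H[1:10, ], rep("a", 10), c("a", "b")),
                 "single-class")
  expect_true(all(predict_labels(h1, H[1:10, ]) == "a"))
})

test_that("prediction breaks ties toward the lower class index and ignores row order", {
  head <- structure(list(W = matrix(0, 3, 5), b = numeric(5),
                         classes = letters[1:5]), class = "vf_softmax")
  expect_equal(predict_labels(head, matrix(rnorm(3), 1)), "a")
  set.seed(30)
  X <- matrix(runif(20 * 11), 20, 11)
  y <- sample(c("a", "b"), 20, replace = TRUE)
  m <- fine_tune_supervised(ae_spec(c(8, 3, 8, 11), 11, seed = 1), X, y,
                            c("a", "b"), epochs_pre = 30, epochs_ft = 30)
  perm <- sample(20)
  expect_equal(predict_labels(m, X)[perm], predict_labels(m, X[perm, ]))
  headless <- init_autoencoder(ae_spec(c(3, 11), 11, latent_index = 1))
  expect_error(predict_labels(headless, X), class = "vflatent_input_error")
})

test_that("fine-tuning never loses training accuracy and nails separable clusters", {
  set.seed(31)
  centers <- matrix(rnorm(4 * 11, sd = 4), 4, 11)
  X <- do.call(rbind, lapply(1:4, function(k)
    sweep(matrix(rnorm(40 * 11, sd = 0.3), 40), 2, centers[k, ], `+`)))
  y <- rep(letters[1:4], each = 40)
  m <- fine_tune_supervised(ae_spec(c(8, 3, 10, 50), 11, seed = 2), X, y,
                            letters[1:4], epochs_pre = 200, epochs_ft = 400,
                            lr = 3e-3)
  expect_gte(m$stage_accuracy[["fine_tuned"]], m$stage_accuracy[["head"]])
  expect_gte(mean(predict_labels(m, X) == y), 0.95)
  # single-class data is perfectly "classified" at every stage
  m1 <- fine_tune_supervised(ae_spec(c(3, 5), 5, latent_index = 1, seed = 3),
                             matrix(runif(40), 8, 5), rep("a", 8), c("a", "b"),
                             epochs_pre = 20, epochs_ft = 20)
  expect_equal(m1$stage_accuracy[["fine_tuned"]], 1)
})

test_that("full train-predict runs are reproducible under a fixed seed", {
  set.seed(40)
  X <- matrix(runif(30 * 11), 30, 11)
  y <- sample(c("a", "b"), 30, replace = TRUE)
  run <- function() {
    m <- fine_tune_supervised(ae_spec(c(8, 3, 8, 11), 11, seed = 9), X, y,
                              c("a", "b"), epochs_pre = 40, epochs_ft = 40)
    predict_labels(m, X)
  }
  expect_identical(run(), run())
})
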