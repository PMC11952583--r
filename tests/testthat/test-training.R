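test_that("standardization centers, scales, flags constants and inverts", {
  ds <- simulate_dataset(tiny_spec(seed = 12), n = 60)
  ds$x[[1]][, 2] <- 3.5  # constant column
  std <- standardize(ds)
  for (m in 1:2) {
    expect_lt(max(abs(colMeans(std$dataset$x[[m]]))), 1e-10)
  }
  tr <- std$transforms[[1]]
  expect_true(tr$constant[2])
  expect_equal(tr$scale[2], 1)  # centered, not divided
  sds <- apply(std$dataset$x[[1]], 2, sd)
  expect_equal(sds[-2], rep(1, 3), tolerance = 1e-12, ignore_attr = TRUE)
  back <- apply_standardizer(std$dataset$x, std$transforms, invert = TRUE)
  expect_equal(back[[1]], ds$x[[1]], tolerance = 1e-10)
  expect_equal(back[[2]], ds$x[[2]], tolerance = 1e-10)
  expect_error(standardize(list(x = list(matrix(1, 1, 2)))), "n >= 2")
})

test_that("training is bitwise reproducible under identical seeds", {
  ds <- simulate_dataset(tiny_spec(seed = 5), n = 300)
  cfg <- config_for_dataset(ds, enc_hidden = c(16, 16), dec_hidden = c(16, 16),
                            flow_hidden = 4, seed = 2)
  tc <- train_config(epochs = 4, batch_size = 64, seed = 3, patience = 10)
  f1 <- mmcrl_train(ds, cfg, tc)
  f2 <- mmcrl_train(ds, cfg, tc)
  drop_time <- function(h) h[, setdiff(names(h), "seconds")]
  expect_identical(drop_time(f1$history), drop_time(f2$history))
  expect_identical(f1$model$params, f2$model$params)
  expect_identical(f1$val_idx, f2$val_idx)
  # different seed changes the trajectory
  f3 <- mmcrl_train(ds, cfg, train_config(epochs = 4, batch_size = 64, seed = 4,
                                          patience = 10))
  expect_false(identical(f1$history$train_total, f3$history$train_total))
})

test_that("validation loss at the best epoch improves on epoch 1", {
  ds <- simulate_dataset(tiny_spec(seed = 6), n = 500)
  cfg <- config_for_dataset(ds, enc_hidden = c(16, 16), dec_hidden = c(16, 16),
                            flow_hidden = 4, seed = 1)
  fit <- mmcrl_train(ds, cfg, train_config(epochs = 12, batch_size = 128, seed = 1))
  h <- fit$history
  expect_lt(h$val_total[fit$best_epoch], h$val_total[1])
  expect_true(all(h$train_recon >= 0), all(h$train_sp >= 0))
  expect_identical(nrow(h), 12L)
  # fresh-model posterior-mean reconstruction on standardized data is
  # within 10x of the variance-only baseline (predicting column means)
  fresh <- init_model(cfg)
  xs <- standardize(ds)$dataset$x
  xhat <- lapply(1:2, function(m) {
    p <- encode(fresh, xs[[m]], m)
    decode(fresh, p$z$mean, p$eta$mean, m)
  })
  expect_lt(reconstruction_loss(xs, xhat),
            10 * sum(vapply(ds$x, ncol, 1L)))
  # validation rows are disjoint from the training pool and seed-stable
  expect_length(intersect(fit$val_idx, setdiff(seq_len(500), fit$val_idx)), 0)
})

test_that("with no independence or sparsity pressure, reconstruction approaches the PCA floor", {
  # linear rank-5 data, latent capacity 3 (= d_z + d_eta): the best linear
  # reconstruction keeps the top 3 principal components
  set.seed(14)
  n <- 1200
  zsrc <- matrix(rnorm(n * 5), n, 5)
  W <- matrix(rnorm(40), 5, 8)
  x <- zsrc %*% W
  ds <- structure(list(x = list(x), z = NULL,
                       meta = list(spec = list(d_z = 2L, d_eta = 1L, d_x = 8L))),
                  class = "mm_dataset")
  xs <- scale(x)
  sv <- svd(xs)$d
  floor_pca <- sum(sv[4:8]^2) / n
  cfg <- model_config(2L, 1L, 8L, enc_hidden = c(32, 32), dec_hidden = c(32, 32),
                      flow_hidden = 4,
                      alpha = c(recon = 1, ind = 0, sp = 0), seed = 2)
  fit <- mmcrl_train(ds, cfg, train_config(epochs = 60, batch_size = 256,
                                           lr = 3e-3, seed = 2, patience = 60))
  best <- fit$history$val_recon[fit$best_epoch]
  expect_lt(best, 1.6 * floor_pca)
  expect_gt(best, 0.4 * floor_pca)
})
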