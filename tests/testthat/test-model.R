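test_that("configuration validation catches bad weights and thresholds", {
  expect_error(model_config(2, 1, 4, alpha = c(recon = 1, ind = -1, sp = 0)),
               "nonnegative")
  expect_error(model_config(2, 1, 4, tau = 1.2), "tau")
  expect_error(model_config(2, 1, 4, alpha = c(a = 1, b = 2, c = 3)), "named")
})

test_that("encoder and decoder respect the configured widths", {
  model <- tiny_model(seed = 3)
  x1 <- matrix(rnorm(40), 10, 4)
  p <- encode(model, x1, 1)
  expect_identical(dim(p$z$mean), c(10L, 2L))
  expect_identical(dim(p$z$logvar), c(10L, 2L))
  expect_identical(dim(p$eta$mean), c(10L, 1L))
  # deterministic forward pass
  expect_identical(p, encode(model, x1, 1))
  expect_error(encode(model, matrix(0, 5, 3), 1), "expects 4")
  xr <- decode(model, p$z$mean, p$eta$mean, 1)
  expect_identical(dim(xr), c(10L, 4L))
  expect_identical(xr, decode(model, p$z$mean, p$eta$mean, 1))
  expect_error(decode(model, p$z$mean, cbind(p$eta$mean, 1), 1), "widths")
})

test_that("case-1 configuration yields per-modality latent width 2 and domain width 1", {
  ds <- simulate_dataset(case_spec(1), n = 30)
  cfg <- config_for_dataset(ds, eta_as_latent = FALSE)
  model <- init_model(cfg)
  p <- encode(model, matrix(rnorm(5 * 8), 5, 8), 1)
  expect_identical(ncol(p$z$mean), 2L)
  expect_identical(ncol(p$eta$mean), 1L)
  # default estimator: all three code dimensions are latent components
  cfg2 <- config_for_dataset(ds)
  p2 <- encode(init_model(cfg2), matrix(rnorm(5 * 8), 5, 8), 1)
  expect_identical(ncol(p2$z$mean), 3L)
  expect_identical(ncol(p2$eta$mean), 0L)
})

test_that("reconstruction loss matches hand arithmetic and is additive", {
  x <- matrix(c(1, 2), 1, 2)
  expect_equal(reconstruction_loss(x, matrix(0, 1, 2)), 5)
  expect_equal(reconstruction_loss(x, x), 0)
  x1 <- matrix(rnorm(12), 3); x2 <- matrix(rnorm(15), 3)
  h1 <- x1 + 1; h2 <- x2 * 2
  expect_equal(reconstruction_loss(list(x1, x2), list(h1, h2)),
               reconstruction_loss(x1, h1) + reconstruction_loss(x2, h2))
  expect_error(reconstruction_loss(x1, t(x1)), "shape")
})

test_that("Gaussian KL matches the closed forms", {
  expect_equal(gaussian_kl(0, 0), 0)
  mu <- 0.7
  expect_equal(gaussian_kl(mu, 0), mu^2 / 2, tolerance = 1e-9)
  s2 <- 2.3
  expect_equal(gaussian_kl(0, log(s2)), (s2 - 1 - log(s2)) / 2, tolerance = 1e-9)
  # matrices: mean over samples, sum over dimensions
  mu2 <- rbind(c(1, 0), c(0, 1))
  expect_equal(gaussian_kl(mu2, mu2 * 0), 0.5)
})

test_that("independence loss closed forms and estimators are consistent", {
  eta <- list(mean = matrix(c(0.5, -0.2), 2, 1), logvar = matrix(0, 2, 1))
  expect_equal(independence_loss(eta = eta),
               gaussian_kl(eta$mean, eta$logvar))
  expect_equal(independence_loss(), 0)
  # aggregate-moment KL: zero for exactly whitened samples
  set.seed(2)
  g <- matrix(rnorm(400 * 3), 400, 3)
  gw <- sweep(g, 2, colMeans(g), "-") %*%
    solve(chol(cov(g) * (399 / 399)))
  expect_lt(gaussian_moment_kl(gw), 1e-6)
  expect_gt(gaussian_moment_kl(2 * g), 0.5)
  expect_equal(independence_loss(gamma = gw), gaussian_moment_kl(gw))
  # cross-moment penalty: ~0 for independent columns, positive for
  # nonlinear (covariance-invisible) dependence
  x1 <- rnorm(4000)
  indep <- cbind(x1, rnorm(4000))
  dep <- cbind(x1, x1^2 - 1 + 0.3 * rnorm(4000))
  expect_lt(cross_moment_dependence(indep), 0.01)
  expect_gt(cross_moment_dependence(dep), 0.2)
  expect_lt(abs(cor(dep[, 1], dep[, 2])), 0.1)  # invisible to covariance

  # the training objective's independence term decomposes into the three
  # documented parts, recomputed here from exported functions
  model <- tiny_model(seed = 5)
  model$params$Alogit[] <- -50  # gates ~ 0, identity flows
  x <- lapply(1:2, function(m) matrix(rnorm(30 * 4), 30, 4))
  xi <- lapply(1:2, function(m) matrix(rnorm(30 * 3), 30, 3))
  res <- mmcrl_loss_grad(model, x, xi, want_grad = FALSE)
  posts <- lapply(1:2, function(m) encode(model, x[[m]], m))
  # identity flows + closed gates: eps-hat are the posterior means of z,
  # gamma = [eta means, z means]
  gam <- cbind(posts[[1]]$eta$mean, posts[[2]]$eta$mean,
               posts[[1]]$z$mean, posts[[2]]$z$mean)
  per_sample <- sum(vapply(1:2, function(m)
    gaussian_kl(cbind(posts[[m]]$z$mean, posts[[m]]$eta$mean),
                cbind(posts[[m]]$z$logvar, posts[[m]]$eta$logvar)), 0))
  cfg <- model$config
  expected <- gaussian_moment_kl(gam) +
    cfg$ind_cross_weight * cross_moment_dependence(gam) +
    cfg$ind_sample_weight * per_sample
  expect_equal(res$loss$ind, expected, tolerance = 1e-6)
})

test_that("sparsity loss is the L1 norm of the gated adjacency", {
  expect_equal(sparsity_loss(matrix(0, 3, 3)), 0)
  expect_equal(sparsity_loss(c(0.5, -0.25)), 0.75)
  A <- matrix(1, 6, 6); diag(A) <- 0
  expect_equal(sparsity_loss(A), 30)
})

test_that("total loss is the exact weighted sum", {
  alpha <- c(recon = 1, ind = 0.1, sp = 0.01)
  lb <- total_loss(2, 3, 4, alpha)
  expect_equal(lb$total, 2.34)
  expect_equal(total_loss(5, 7, 9, c(recon = 1, ind = 0, sp = 0))$total, 5)
  expect_equal(total_loss(0, 0, 0, alpha)$total, 0)
  # the identity holds on an actual training batch to machine precision
  model <- tiny_model(seed = 11)
  model$params$Alogit[lower.tri(diag(4))] <- rnorm(6)
  x <- lapply(1:2, function(m) matrix(rnorm(8 * 4), 8, 4))
  xi <- lapply(1:2, function(m) matrix(rnorm(8 * 3), 8, 3))
  res <- mmcrl_loss_grad(model, x, xi,
                         alpha = c(recon = 1, ind = 0.3, sp = 0.07),
                         want_grad = FALSE)
  expect_equal(res$loss$total,
               1 * res$loss$recon + 0.3 * res$loss$ind + 0.07 * res$loss$sp,
               tolerance = 1e-12)
})

test_that("flows are identity at initialization and invertible after perturbation", {
  model <- tiny_model(seed = 7)
  model$params$Alogit[] <- -50  # close all gates
  z <- matrix(rnorm(20 * 4), 20, 4)
  fl <- flow_to_exogenous(model, z)
  expect_equal(fl$eps_hat, z)
  expect_equal(fl$logdet, rep(0, 20))
  # randomize flows and open gates: round trip through the inverse
  set.seed(8)
  model$params$Alogit[lower.tri(diag(4))] <- rnorm(6)
  model$params$flow <- tree_map(function(p) p + rnorm(length(p), sd = 0.3),
                                model$params$flow)
  fl2 <- flow_to_exogenous(model, z)
  back <- flow_from_exogenous(model, fl2$eps_hat)
  expect_lt(max(abs(back - z)), 1e-5)
})

test_that("affine flow log-determinant matches the hand-computed form", {
  # depth-1 flow: eps = (z - mu(pa)) * exp(-s(pa)), so the per-sample
  # log|d eps / d z| is -sum_i s_i(pa_i)
  model <- tiny_model(seed = 9, flow_depth = 1L)
  set.seed(10)
  model$params$Alogit[lower.tri(diag(4))] <- rnorm(6, sd = 2)
  model$params$flow <- tree_map(function(p) p + rnorm(length(p), sd = 0.4),
                                model$params$flow)
  z <- matrix(rnorm(12 * 4), 12, 4)
  fl <- flow_to_exogenous(model, z)
  gates <- adjacency_gates(model)
  s_tot <- rep(0, 12)
  for (i in 1:4) {
    raw <- if (i == 1) matrix(model$params$flow[[1]]$bias, 12, 2, byrow = TRUE)
      else mlp_forward(model$params$flow[[i]],
                       z[, seq_len(i - 1), drop = FALSE] *
                         matrix(gates[i, seq_len(i - 1)], 12, i - 1, byrow = TRUE))$out
    s_tot <- s_tot + 3 * tanh(raw[, 2] / 3)
  }
  expect_equal(fl$logdet, -s_tot, tolerance = 1e-10)
})

test_that("gradients of the full objective match finite differences", {
  set.seed(42)
  spec <- tiny_spec(seed = 3)
  ds <- simulate_dataset(spec, n = 12)
  cfg <- model_config(spec$d_z, spec$d_eta, spec$d_x,
                      enc_hidden = c(6, 5), dec_hidden = c(6, 5),
                      flow_hidden = 4, flow_depth = 2,
                      alpha = c(recon = 1, ind = 0.37, sp = 0.11), seed = 9)
  model <- init_model(cfg)
  ml <- lower.tri(diag(4))
  model$params$Alogit[ml] <- rnorm(sum(ml), sd = 0.7)
  model$params$flow <- tree_map(function(p) p + rnorm(length(p), sd = 0.15),
                                model$params$flow)
  xi <- lapply(1:2, function(m) matrix(rnorm(12 * 3), 12, 3))
  res <- mmcrl_loss_grad(model, ds$x, xi)

  paths <- list()
  collect <- function(node, pre) {
    if (is.list(node)) for (k in seq_along(node)) collect(node[[k]], c(pre, k))
    else if (is.numeric(node)) paths[[length(paths) + 1]] <<- pre
  }
  collect(model$params, integer(0))
  get_at <- function(tree, path) { for (p in path) tree <- tree[[p]]; tree }
  set_at <- function(tree, path, val) {
    if (length(path) == 1) { tree[[path]] <- val; return(tree) }
    tree[[path[1]]] <- set_at(tree[[path[1]]], path[-1], val)
    tree
  }
  h <- 1e-5
  for (p in paths[seq(1, length(paths), by = 3)]) {
    arr <- get_at(model$params, p)
    g <- get_at(res$grads, p)
    j <- sample(length(arr), 1)
    m2 <- model
    a2 <- arr; a2[j] <- a2[j] + h
    m2$params <- set_at(m2$params, p, a2)
    lp <- mmcrl_loss_grad(m2, ds$x, xi, want_grad = FALSE)$loss$total
    a2[j] <- arr[j] - h
    m2$params <- set_at(m2$params, p, a2)
    lm <- mmcrl_loss_grad(m2, ds$x, xi, want_grad = FALSE)$loss$total
    fd <- (lp - lm) / (2 * h)
    expect_equal(g[j], fd, tolerance = 1e-4)
  }
})

test_that("masked adjacency entries stay exactly zero through optimizer steps", {
  model <- tiny_model(seed = 13)
  opt <- adam_init(model$params, lr = 5e-3)
  x <- lapply(1:2, function(m) matrix(rnorm(16 * 4), 16, 4))
  upper <- !lower.tri(diag(4))
  for (it in 1:5) {
    xi <- lapply(1:2, function(m) matrix(rnorm(16 * 3), 16, 3))
    res <- mmcrl_loss_grad(model, x, xi)
    st <- adam_step(opt, model$params, res$grads)
    opt <- st$state; model$params <- st$params
    expect_true(all(adjacency_gates(model)[upper] == 0))
    expect_true(all(res$grads$Alogit[upper] == 0))
  }
  g <- adjacency_gates(model)
  expect_true(all(g >= 0 & g <= 1))
})
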