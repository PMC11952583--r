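test_that("spec validation enforces the generative invariants", {
  expect_error(scm_spec(2, d_z = c(2, 2), d_eta = c(1, 1), d_x = c(2, 5)),
               "information preservation")
  expect_error(scm_spec(2, d_z = c(2, 0), d_eta = c(1, 1), d_x = c(5, 5)),
               ">= 1")
  expect_error(scm_spec(2, d_z = c(2, 2), d_eta = c(1, 1), d_x = c(5, 5),
                        sparsity_ratio = 1.2), "sparsity_ratio")
  expect_error(sample_scm(tiny_spec(sparsity_ratio = 1)), "coupled")
})

test_that("case presets reproduce the documented dimensions", {
  ds1 <- simulate_dataset(case_spec(1), n = 50)
  expect_length(ds1$x, 2L)
  expect_identical(sum(vapply(ds1$x, ncol, 1L)), 15L)
  expect_identical(ncol(ds1$z), 4L)
  ds2 <- simulate_dataset(case_spec(2), n = 20)
  expect_identical(sum(vapply(ds2$x, ncol, 1L)), 20L)
  ds3 <- simulate_dataset(case_spec(3), n = 20)
  expect_length(ds3$x, 4L)
  expect_identical(sum(vapply(ds3$x, ncol, 1L)), 30L)
  expect_identical(ncol(ds3$z), 8L)
})

test_that("identical spec and seed give bit-identical SCMs and datasets", {
  s1 <- sample_scm(tiny_spec(seed = 7))
  s2 <- sample_scm(tiny_spec(seed = 7))
  expect_identical(s1$A, s2$A)
  expect_identical(s1$f_params, s2$f_params)
  expect_identical(s1$mix_params, s2$mix_params)
  d1 <- simulate_dataset(tiny_spec(seed = 7), n = 40)
  d2 <- simulate_dataset(tiny_spec(seed = 7), n = 40)
  expect_identical(d1$x, d2$x)
  expect_identical(d1$z, d2$z)
  s3 <- sample_scm(tiny_spec(seed = 8))
  expect_false(identical(s1$mix_params, s3$mix_params))
})

test_that("adjacency is acyclic under the order and meets the edge quota", {
  for (seed in 1:5) {
    for (ratio in c(0, 0.25, 0.5, 0.75)) {
      spec <- tiny_spec(seed = seed, sparsity_ratio = ratio)
      scm <- sample_scm(spec)
      pos <- integer(length(scm$order)); pos[scm$order] <- seq_along(scm$order)
      idx <- which(scm$A == 1L, arr.ind = TRUE)
      expect_true(all(pos[idx[, 2L]] < pos[idx[, 1L]]))
      expect_true(all(diag(scm$A) == 0L))
      # cross-modal quota: round((1 - ratio) * P), modality coupling may
      # force extra edges at extreme sparsity
      got <- 1 - sparsity_ratio_of(scm$A, scm$partition, scm$order)
      quota <- floor((1 - ratio) * 4 + 0.5)
      expect_gte(got * 4, quota)
      if (quota >= 2) expect_equal(got * 4, quota)
      # every modality keeps at least one incident cross-modal edge
      modality <- rep(1:2, c(2, 2))
      cross <- scm$A * outer(modality, modality, "!=")
      for (m in 1:2) {
        ix <- scm$partition[[m]]
        expect_gt(sum(cross[ix, ]) + sum(cross[, ix]), 0)
      }
    }
  }
})

test_that("sparsity_ratio_of matches its definition and round-trips", {
  part <- list(1:2, 3:5)  # P = 6 admissible cross-modal pairs
  A <- matrix(0L, 5, 5)
  A[3, 1] <- A[4, 1] <- A[5, 2] <- 1L
  expect_equal(sparsity_ratio_of(A, part), 0.5)
  expect_equal(sparsity_ratio_of(matrix(0L, 5, 5), part), 1)
  full <- matrix(0L, 5, 5)
  for (i in 3:5) for (j in 1:2) full[i, j] <- 1L
  expect_equal(sparsity_ratio_of(full, part), 0)
  expect_error(sparsity_ratio_of(A, list()), "partition")
  B <- matrix(0L, 5, 5); B[1, 3] <- 1L  # parent later in the order
  expect_error(sparsity_ratio_of(B, part, order = 1:5), "acyclic")
  for (ratio in c(0, 1 / 3, 2 / 3)) {
    spec <- scm_spec(2, d_z = c(3, 3), d_eta = c(1, 1), d_x = c(8, 8),
                     sparsity_ratio = ratio, seed = 3)
    scm <- sample_scm(spec)
    expect_equal(sparsity_ratio_of(scm$A, scm$partition, scm$order), ratio,
                 tolerance = 1 / 9 + 1e-9)
  }
})

test_that("latents follow the structural equations by ancestral sampling", {
  spec <- tiny_spec(seed = 2, within_prob = 0)
  scm <- sample_scm(spec)
  expect_error(generate_latents(scm, 0), "positive")
  # no parents: z reduces to a componentwise transform of eps
  scm0 <- scm
  scm0$A[] <- 0L
  lat <- generate_latents(scm0, 30, seed = 5)
  expect_equal(lat$z, lat$eps)
  # linear structural function: corr(z1, z2) = c / sqrt(1 + c^2) for
  # z2 = c * z1 + eps2 with unit-variance z1 (closed form)
  spec2 <- scm_spec(2, d_z = c(1, 1), d_eta = c(1, 1), d_x = c(3, 3),
                    sparsity_ratio = 0, seed = 4)
  scm2 <- sample_scm(spec2)
  scm2$A <- matrix(c(0L, 0L, 1L, 0L), 2, 2, byrow = TRUE)
  scm2$order <- 1:2
  # tanh MLP arranged to act linearly: 800 * tanh(1e-3 * z) ~ 0.8 * z
  scm2$f_params[[2]] <- list(W1 = matrix(c(1e-3, rep(0, 7)), 1, 8),
                             b1 = rep(0, 8), w2 = c(800, rep(0, 7)), b2 = 0,
                             pnl_a = 0.5)
  lat2 <- generate_latents(scm2, 20000, seed = 11)
  expect_equal(cor(lat2$z[, 1], lat2$z[, 2]), 0.8 / sqrt(1.64),
               tolerance = 0.02)
  # non-finite structural output is reported with the component index
  scm_bad <- scm2
  scm_bad$f_params[[2]]$w2[1] <- Inf
  expect_error(generate_latents(scm_bad, 10), "component 2")
})

test_that("exogenous noise is mutually independent (distance-correlation null)", {
  ds <- simulate_dataset(case_spec(1, seed = 3), n = 400)
  set.seed(99)
  obs <- dcor(ds$eps[, 1], ds$eps[, 3])
  null <- replicate(40, dcor(ds$eps[, 1], ds$eps[sample(400), 3]))
  expect_lt(obs, quantile(null, 0.99) * 1.5)
  # and the causally linked latents are NOT independent
  idx <- which(cross_modal_part(ds$A_true, ds$partition) == 1L, arr.ind = TRUE)[1L, ]
  obs_z <- dcor(ds$z[, idx[1L]], ds$z[, idx[2L]])
  expect_gt(obs_z, quantile(null, 0.99))
})

test_that("mixing preserves information: full-column-rank Jacobians", {
  scm <- sample_scm(tiny_spec(seed = 6))
  for (m in 1:2) {
    k <- 3L  # d_z + d_eta per modality
    ranks <- mixing_jacobian_ranks(scm, m, n_points = 100, seed = 2)
    expect_gte(mean(ranks == k), 0.99)
  }
  # identity-initialized single-layer mixing passes [z, eta] through
  spec1 <- tiny_spec(seed = 6, mixing_depth = 1L, d_x = c(3L, 3L))
  scm1 <- sample_scm(spec1)
  scm1$mix_params[[1]] <- list(W = list(diag(3)), b = list(rep(0, 3)),
                               lift = diag(3), slope = 1)
  lat <- generate_latents(scm1, 25, seed = 1)
  x <- mix_observations(scm1, lat$z, lat$eta)
  expect_equal(x[[1]], cbind(lat$z[, 1:2], lat$eta[[1]]))
  expect_error(mix_observations(scm1, lat$z, lat$eta[1]), "per modality")
})

test_that("dataset archives round-trip bit-identically", {
  ds <- simulate_dataset(tiny_spec(seed = 9), n = 25)
  path <- file.path(tempdir(), "mmds-roundtrip")
  write_mmds(ds, path, overwrite = TRUE)
  back <- read_mmds(path)
  expect_identical(back$x[[1]], unname(ds$x[[1]]))
  expect_identical(back$x[[2]], unname(ds$x[[2]]))
  expect_identical(back$z, unname(ds$z))
  expect_identical(back$eps, unname(ds$eps))
  expect_identical(back$A_true, unname(ds$A_true))
  expect_identical(back$order, ds$order)
  expect_identical(back$partition, ds$partition)
  unlink(path, recursive = TRUE)
})
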