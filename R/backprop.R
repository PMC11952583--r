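# Training objective and exact gradient on one minibatch, by hand-written
# reverse mode.
#
# The independence term combines two complementary estimators of
# KL(q(gamma) || N(0, I)) for gamma = [eta-hat, eps-hat]:
#   1. the aggregate-moment KL: a full-covariance Gaussian fit to the
#      batch of sampled noise estimates — its off-diagonal covariance
#      penalizes linear dependence between components and gives the
#      encoder a direct disentangling (rotation) gradient;
#   2. the per-sample posterior KL, in closed form conditional on the
#      sampled parents (component i's posterior N(mu_i, sigma_i^2)
#      pushed through eps = a z + b is N(a mu + b, a^2 sigma^2)) — its
#      conditional-variance term rewards a flow for conditioning on
#      parents that genuinely shrink the component's residual variance,
#      which detects *nonlinear* parent dependence the moment term
#      cannot see and holds the corresponding gates open.
# The per-sample part enters with relative weight config$ind_sample_weight.
#
# x:  list of (standardized) observation matrices, nb rows each.
# xi: list of reparameterization draws, nb x (d_z[m] + d_eta[m]) each.
mmcrl_loss_grad <- function(model, x, xi, alpha = model$config$alpha,
                            want_grad = TRUE) {
  cfg <- model$config
  nb <- nrow(x[[1L]])
  aR <- alpha[["recon"]]; aI <- alpha[["ind"]]; aS <- alpha[["sp"]]
  part <- local({
    ends <- cumsum(cfg$d_z); starts <- c(1L, utils::head(ends, -1L) + 1L)
    lapply(seq_len(cfg$M), function(m) seq.int(starts[m], ends[m]))
  })

  wps <- if (is.null(cfg$ind_sample_weight)) 0 else cfg$ind_sample_weight
  enc_cache <- dec_cache <- post <- zeta <- vector("list", cfg$M)
  recon_m <- numeric(cfg$M)
  kl_eta_ps <- 0
  for (m in seq_len(cfg$M)) {
    enc_cache[[m]] <- mlp_forward(model$params$enc[[m]], x[[m]])
    p <- .split_posterior(cfg, m, enc_cache[[m]]$out)
    post[[m]] <- p
    zeta[[m]] <- p$mu + exp(0.5 * p$lv) * xi[[m]]
    dec_cache[[m]] <- mlp_forward(model$params$dec[[m]], zeta[[m]])
    recon_m[m] <- sum((x[[m]] - dec_cache[[m]]$out)^2) / nb
    ie <- cfg$d_z[m] + seq_len(cfg$d_eta[m])
    kl_eta_ps <- kl_eta_ps + sum(0.5 * (p$mu[, ie, drop = FALSE]^2 +
      exp(p$lv[, ie, drop = FALSE]) - 1 - p$lv[, ie, drop = FALSE])) / nb
  }
  use_mean <- is.null(cfg$gamma_source) || cfg$gamma_source == "mean"
  zhat_all <- do.call(cbind, lapply(seq_len(cfg$M), function(m)
    zeta[[m]][, seq_len(cfg$d_z[m]), drop = FALSE]))
  eta_all <- do.call(cbind, lapply(seq_len(cfg$M), function(m)
    zeta[[m]][, cfg$d_z[m] + seq_len(cfg$d_eta[m]), drop = FALSE]))
  mu_z <- do.call(cbind, lapply(seq_len(cfg$M), function(m)
    post[[m]]$mu[, seq_len(cfg$d_z[m]), drop = FALSE]))
  lv_z <- do.call(cbind, lapply(seq_len(cfg$M), function(m)
    post[[m]]$lv[, seq_len(cfg$d_z[m]), drop = FALSE]))
  mu_eta <- do.call(cbind, lapply(seq_len(cfg$M), function(m)
    post[[m]]$mu[, cfg$d_z[m] + seq_len(cfg$d_eta[m]), drop = FALSE]))
  Zflow <- if (use_mean) mu_z else zhat_all
  eta_gam <- if (use_mean) mu_eta else eta_all

  gates <- adjacency_gates(model)
  fc_list <- vector("list", cfg$D)
  eps_hat <- matrix(0, nb, cfg$D)
  mvec <- vvec <- vector("list", cfg$D)
  kl_eps_ps <- 0
  for (i in seq_len(cfg$D)) {
    fc <- .flow_coeffs_i(model, i, Zflow, gates)
    fc_list[[i]] <- fc
    eps_hat[, i] <- fc$a * Zflow[, i] + fc$b
    mi <- fc$a * mu_z[, i] + fc$b
    vi <- exp(lv_z[, i] - 2 * fc$S)
    mvec[[i]] <- mi; vvec[[i]] <- vi
    kl_eps_ps <- kl_eps_ps +
      sum(0.5 * (mi^2 + vi - 1 - (lv_z[, i] - 2 * fc$S))) / nb
  }
  d_eta_tot <- sum(cfg$d_eta)
  gamma <- cbind(eta_gam, eps_hat)
  dG <- ncol(gamma)
  if (nb <= dG)
    stop("batch size must exceed the noise dimensionality (", dG, ")")
  mu_g <- colMeans(gamma)
  Cg <- sweep(gamma, 2L, mu_g, "-")
  Sg <- crossprod(Cg) / (nb - 1) + 1e-8 * diag(dG)
  ch <- chol(Sg)
  ind_mom <- 0.5 * (sum(diag(Sg)) + sum(mu_g^2) - dG - 2 * sum(log(diag(ch))))

  # higher-order cross-moment dependence (Hermite features h1..h3)
  wx <- if (is.null(cfg$ind_cross_weight)) 0 else cfg$ind_cross_weight
  CLX <- 2.5
  gmc <- CLX * tanh(gamma / CLX)
  Fh <- cbind(gmc, (gmc^2 - 1) / sqrt(2), (gmc^3 - 3 * gmc) / sqrt(6))
  Fc <- sweep(Fh, 2L, colMeans(Fh), "-")
  Ch <- crossprod(Fc) / (nb - 1)
  compix <- rep(seq_len(dG), 3L)
  Mx <- outer(compix, compix, "!=")
  ind_x <- sum((Ch * Mx)^2)

  ind <- ind_mom + wx * ind_x + wps * (kl_eta_ps + kl_eps_ps)

  mask <- .model_mask(cfg)
  sp <- sum(gates[mask])
  breakdown <- total_loss(sum(recon_m), ind, sp, alpha, per_modality = recon_m)
  if (!is.finite(breakdown$total))
    stop("non-finite loss (recon = ", signif(sum(recon_m), 4),
         ", ind = ", signif(ind, 4), ", sp = ", signif(sp, 4), ")")
  if (!want_grad)
    return(list(loss = breakdown, zhat = zhat_all, eps_hat = eps_hat,
                gates = gates))

  gEnc <- gDec <- vector("list", cfg$M)
  gFlow <- vector("list", cfg$D)
  dzeta <- vector("list", cfg$M)
  for (m in seq_len(cfg$M))
    dzeta[[m]] <- matrix(0, nb, cfg$d_z[m] + cfg$d_eta[m])
  dZflow <- matrix(0, nb, cfg$D)
  dgates <- matrix(0, cfg$D, cfg$D)

  # reconstruction -> decoders -> sampled [z, eta]
  for (m in seq_len(cfg$M)) {
    dxhat <- aR * 2 * (dec_cache[[m]]$out - x[[m]]) / nb
    bw <- mlp_backward(model$params$dec[[m]], dec_cache[[m]], dxhat)
    gDec[[m]] <- bw$grad
    dzeta[[m]] <- dzeta[[m]] + bw$dX
  }

  # aggregate KL -> gamma samples
  Sinv <- chol2inv(ch)
  G_C <- Cg %*% (diag(dG) - Sinv) / (nb - 1)
  dGamma <- sweep(G_C, 2L, colSums(G_C) / nb, "-") +
    matrix(mu_g / nb, nb, dG, byrow = TRUE)

  # cross-moment penalty -> gamma samples
  if (wx > 0) {
    dFc <- 4 * (Fc %*% (Ch * Mx)) / (nb - 1)
    dFh <- sweep(dFc, 2L, colSums(dFc) / nb, "-")
    dgc <- dFh[, seq_len(dG), drop = FALSE] +
      dFh[, dG + seq_len(dG), drop = FALSE] * (sqrt(2) * gmc) +
      dFh[, 2L * dG + seq_len(dG), drop = FALSE] * ((3 * gmc^2 - 3) / sqrt(6))
    dGamma <- dGamma + wx * dgc * (1 - (gmc / CLX)^2)
  }
  dGamma <- aI * dGamma

  # per-sample posterior accumulators (mu / logvar of each modality block)
  dmu_post <- dlv_post <- vector("list", cfg$M)
  for (m in seq_len(cfg$M)) {
    dmu_post[[m]] <- matrix(0, nb, cfg$d_z[m] + cfg$d_eta[m])
    dlv_post[[m]] <- matrix(0, nb, cfg$d_z[m] + cfg$d_eta[m])
  }

  # eta columns: aggregate part -> eta source; per-sample part -> posterior
  cps <- aI * wps / nb
  off <- 0L
  for (m in seq_len(cfg$M)) {
    ie <- cfg$d_z[m] + seq_len(cfg$d_eta[m])
    dg_eta <- dGamma[, off + seq_len(cfg$d_eta[m]), drop = FALSE]
    if (use_mean) dmu_post[[m]][, ie] <- dmu_post[[m]][, ie] + dg_eta
    else dzeta[[m]][, ie] <- dzeta[[m]][, ie] + dg_eta
    dmu_post[[m]][, ie] <- dmu_post[[m]][, ie] +
      cps * post[[m]]$mu[, ie, drop = FALSE]
    dlv_post[[m]][, ie] <- dlv_post[[m]][, ie] +
      cps * 0.5 * (exp(post[[m]]$lv[, ie, drop = FALSE]) - 1)
    off <- off + cfg$d_eta[m]
  }

  # eps columns -> flows, gates, sampled latents, posterior parameters
  mod_of <- rep(seq_len(cfg$M), cfg$d_z)
  local_of <- unlist(lapply(cfg$d_z, seq_len))
  L <- cfg$flow_depth
  for (i in seq_len(cfg$D)) {
    fc <- fc_list[[i]]
    mi <- mvec[[i]]; vi <- vvec[[i]]
    m_idx <- mod_of[i]; lc <- local_of[i]
    deps <- dGamma[, d_eta_tot + i]
    # d(per-sample KL_i)/da = m mu + (v - 1)/a ; /db = m
    da <- deps * Zflow[, i] + cps * (mi * mu_z[, i] + (vi - 1) / fc$a)
    db <- deps + cps * mi
    dZflow[, i] <- dZflow[, i] + deps * fc$a
    dmu_post[[m_idx]][, lc] <- dmu_post[[m_idx]][, lc] + cps * mi * fc$a
    dlv_post[[m_idx]][, lc] <- dlv_post[[m_idx]][, lc] + cps * (0.5 * vi - 0.5)
    dS <- -fc$a * da
    ds <- matrix(dS, nb, L)
    dmu_l <- matrix(0, nb, L)
    for (k in rev(seq_len(L))) {
      ds[, k] <- ds[, k] - db * fc$bk[, k]
      dmu_l[, k] <- -db * fc$e[, k]
      db <- db * fc$e[, k]
    }
    dsraw <- ds * (1 - (fc$s / .S_CLAMP)^2)
    dOut <- cbind(dmu_l, dsraw)
    if (i == 1L) {
      gFlow[[1L]] <- list(bias = colSums(dOut))
    } else {
      bw <- mlp_backward(model$params$flow[[i]], fc$cache, dOut)
      gFlow[[i]] <- bw$grad
      jx <- seq_len(i - 1L)
      grow <- matrix(gates[i, jx], nb, i - 1L, byrow = TRUE)
      dZflow[, jx] <- dZflow[, jx] + bw$dX * grow
      dgates[i, jx] <- dgates[i, jx] +
        colSums(bw$dX * Zflow[, jx, drop = FALSE])
    }
  }

  # L1 sparsity on the gates
  dgates[mask] <- dgates[mask] + aS
  gsig <- gates * (1 - gates) / cfg$gate_temp
  dAlogit <- dgates * gsig
  dAlogit[!mask] <- 0

  # latent gradients from the flows back into the per-modality blocks
  for (m in seq_len(cfg$M)) {
    iz <- seq_len(cfg$d_z[m])
    if (use_mean)
      dmu_post[[m]][, iz] <- dmu_post[[m]][, iz] + dZflow[, part[[m]], drop = FALSE]
    else
      dzeta[[m]][, iz] <- dzeta[[m]][, iz] + dZflow[, part[[m]], drop = FALSE]
  }

  # reparameterization and log-variance clamp -> encoder outputs
  for (m in seq_len(cfg$M)) {
    p <- post[[m]]
    dmu <- dzeta[[m]] + dmu_post[[m]]
    dlv <- dzeta[[m]] * 0.5 * (zeta[[m]] - p$mu) + dlv_post[[m]]
    dlvraw <- dlv * (1 - (p$lv / .LV_CLAMP)^2)
    bw <- mlp_backward(model$params$enc[[m]], enc_cache[[m]],
                       cbind(dmu, dlvraw))
    gEnc[[m]] <- bw$grad
  }

  list(loss = breakdown,
       grads = list(enc = gEnc, dec = gDec, flow = gFlow, Alogit = dAlogit),
       zhat = zhat_all, eps_hat = eps_hat, gates = gates)
}
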