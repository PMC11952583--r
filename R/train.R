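#' Training configuration
#'
#' @param epochs maximum number of epochs (>= 1).
#' @param batch_size minibatch size.
#' @param lr Adam learning rate (> 0).
#' @param optimizer optimizer name; only `"adam"` is implemented.
#' @param seed seed controlling initialization noise draws, the
#'   validation split and data order.
#' @param val_frac fraction of samples held out for validation, in (0, 1).
#' @param patience early-stopping patience in epochs (no improvement of
#'   the validation total loss).
#' @param sp_start_frac,sp_anneal_frac the sparsity weight is 0 until
#'   `sp_start_frac` of the epoch budget, then ramps linearly to its
#'   target at `sp_anneal_frac`: the gates must stay open while the
#'   encoders and flow conditioners learn to explain the cross-modal
#'   dependence, and only then does the L1 pressure prune redundant
#'   parents (which is what pins down the within-block rotation).
#' @param ind_warmup_frac fraction of the epoch budget over which the
#'   independence weight is annealed from 0 to its target, letting the
#'   autoencoder form an information-preserving representation first.
#' @param lr_flow_mult,lr_gate_mult learning-rate multipliers for the flow
#'   conditioners and the adjacency logits relative to `lr`; the flows and
#'   gates receive much smaller raw gradients than the encoders.
#' @param lr_decay_frac,lr_decay_factor after `lr_decay_frac` of the epoch
#'   budget, all learning rates are multiplied by `lr_decay_factor`
#'   (set the factor to 1 to disable).
#' @param gate_temp_final the adjacency-gate temperature is annealed
#'   geometrically from the model's configured value to this value over
#'   training, sharpening soft gates into near-binary decisions; the
#'   fitted model keeps the final temperature.
#' @param cca_align_frac fractions of the epoch budget after which each
#'   modality's latent code is re-expressed in its canonical-correlation
#'   basis against the other modalities (strongest cross-modal direction
#'   first), the decoders are adjusted to keep reconstructions unchanged,
#'   and the flows and gates are reset. The independence-plus-sparsity
#'   landscape has many near-degenerate basins that differ by a
#'   within-block rotation; the CCA basis starts the sparse-conditioning
#'   phase inside the basin where cross-modal dependence is concentrated
#'   on few component pairs. May be a vector (a later pass re-concentrates
#'   the code after the flows have cleaned it); set to `NULL` to disable.
#' @param grad_clip global gradient-norm clip (`Inf` to disable).
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 500L, batch_size = 512L, lr = 2e-3,
                         optimizer = "adam", seed = 1L, val_frac = 0.1,
                         patience = 80L, sp_start_frac = 0.35,
                         sp_anneal_frac = 0.8,
                         ind_warmup_frac = 0.02,
                         lr_flow_mult = 3, lr_gate_mult = 5,
                         lr_decay_frac = 0.6, lr_decay_factor = 0.3,
                         gate_temp_final = 0.25,
                         cca_align_frac = c(0.25, 0.55),
                         grad_clip = 100) {
  if (epochs < 1L) stop("epochs must be >= 1")
  if (val_frac <= 0 || val_frac >= 1) stop("val_frac must lie in (0, 1)")
  if (lr <= 0) stop("learning rate must be positive")
  if (optimizer != "adam") stop("unsupported optimizer: ", optimizer)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, optimizer = optimizer, seed = as.integer(seed),
                 val_frac = val_frac, patience = as.integer(patience),
                 sp_start_frac = sp_start_frac,
                 sp_anneal_frac = sp_anneal_frac,
                 ind_warmup_frac = ind_warmup_frac,
                 lr_flow_mult = lr_flow_mult, lr_gate_mult = lr_gate_mult,
                 lr_decay_frac = lr_decay_frac,
                 lr_decay_factor = lr_decay_factor,
                 gate_temp_final = gate_temp_final,
                 cca_align_frac = cca_align_frac,
                 grad_clip = grad_clip),
            class = "train_config")
}

#' Standardize each observed dimension of a multimodal dataset
#'
#' Centers every observed column to mean zero and scales to unit standard
#' deviation. Columns with zero variance are centered only and flagged.
#' The returned transform supports exact inversion.
#'
#' @param ds an `mm_dataset` (or plain list of matrices in `$x`).
#' @return list with `dataset` (transformed copy) and `transforms` (per
#'   modality: `center`, `scale`, `constant` flags).
#' @export
standardize <- function(ds) {
  if (nrow(ds$x[[1L]]) < 2L) stop("standardization needs n >= 2")
  transforms <- vector("list", length(ds$x))
  for (m in seq_along(ds$x)) {
    mu <- colMeans(ds$x[[m]])
    sd <- apply(ds$x[[m]], 2L, stats::sd)
    const <- sd == 0
    sc <- ifelse(const, 1, sd)
    ds$x[[m]] <- sweep(sweep(ds$x[[m]], 2L, mu, "-"), 2L, sc, "/")
    transforms[[m]] <- list(center = mu, scale = sc, constant = const)
  }
  list(dataset = ds, transforms = transforms)
}

#' Apply or invert a stored standardization
#' @param x list of observation matrices.
#' @param transforms from [standardize()].
#' @param invert if `TRUE`, map standardized values back to the original
#'   scale.
#' @return list of transformed matrices.
#' @export
apply_standardizer <- function(x, transforms, invert = FALSE) {
  lapply(seq_along(x), function(m) {
    tr <- transforms[[m]]
    if (invert) sweep(sweep(x[[m]], 2L, tr$scale, "*"), 2L, tr$center, "+")
    else sweep(sweep(x[[m]], 2L, tr$center, "-"), 2L, tr$scale, "/")
  })
}

# Re-express each modality's latent code in its canonical-correlation
# basis against the other modalities (strongest cross-modal direction
# first, unit variance), with the exact counter-transform applied to the
# decoder input layer so reconstructions are unchanged. Flows are reset
# to the identity and gates reopened; optimizer states must be reset by
# the caller.
.cca_align <- function(model, xs, reset = TRUE) {
  cfg <- model$config
  n <- nrow(xs[[1L]])
  ix <- if (n > 4000L) sort(sample.int(n, 4000L)) else seq_len(n)
  kz <- cfg$d_z
  mus <- lapply(seq_len(cfg$M), function(m)
    mlp_forward(model$params$enc[[m]],
                xs[[m]][ix, , drop = FALSE])$out[, seq_len(kz[m]), drop = FALSE])
  for (m in seq_len(cfg$M)) {
    X <- mus[[m]]
    Y <- do.call(cbind, mus[-m])
    Tm <- tryCatch(stats::cancor(X, Y)$xcoef, error = function(e) NULL)
    if (is.null(Tm)) next
    if (ncol(Tm) < kz[m]) {
      Q <- qr.Q(qr(cbind(Tm, matrix(stats::rnorm(kz[m] * kz[m]), kz[m]))))
      Tm <- cbind(Tm, Q[, seq.int(ncol(Tm) + 1L, kz[m]), drop = FALSE])
    }
    sds <- apply(X %*% Tm, 2L, stats::sd)
    sds[sds < 1e-8] <- 1
    Tm <- sweep(Tm, 2L, sds, "/")
    Tinv <- solve(Tm)
    K <- length(model$params$enc[[m]]$W)
    W <- model$params$enc[[m]]$W[[K]]
    b <- model$params$enc[[m]]$b[[K]]
    zc <- seq_len(kz[m])
    W[, zc] <- W[, zc, drop = FALSE] %*% Tm
    b[zc] <- drop(rbind(b[zc]) %*% Tm)
    model$params$enc[[m]]$W[[K]] <- W
    model$params$enc[[m]]$b[[K]] <- b
    model$params$dec[[m]]$W[[1L]][zc, ] <-
      Tinv %*% model$params$dec[[m]]$W[[1L]][zc, , drop = FALSE]
  }
  # identity flows, reopened gates: the sparse-conditioning phase restarts
  # in the aligned basis. A light re-alignment (reset = FALSE) keeps the
  # learned flows and gates, appropriate when the basis change is small.
  if (reset) {
    for (i in seq_along(model$params$flow)) {
      if (i == 1L) {
        model$params$flow[[1L]]$bias[] <- 0
      } else {
        K <- length(model$params$flow[[i]]$W)
        model$params$flow[[i]]$W[[K]][] <- 0
        model$params$flow[[i]]$b[[K]][] <- 0
      }
    }
    model$params$Alogit[] <- 2
  }
  model
}

.tree_grad_norm <- function(g) {
  s <- 0
  walk <- function(node) {
    if (is.list(node)) lapply(node, walk)
    else if (is.numeric(node)) s <<- s + sum(node^2)
    invisible(NULL)
  }
  walk(g)
  sqrt(s)
}

#' Fit the estimation model to a multimodal dataset
#'
#' Standardizes the observations, splits off a validation set, and
#' minimizes the combined objective (reconstruction + independence KL +
#' L1 adjacency sparsity) with Adam. The sparsity weight is annealed from
#' zero over the first part of training; validation loss is always
#' computed at the full target weights. The returned model carries the
#' parameters of the best validation epoch and the standardization
#' transform.
#'
#' @param dataset an `mm_dataset`.
#' @param config an `mmcrl_config` (see [model_config()] /
#'   [config_for_dataset()]).
#' @param tconfig a [train_config()].
#' @param verbose print a line every `verbose` epochs (0 = silent).
#' @return an object of class `mmcrl_fit`: list with `model` (best
#'   checkpoint), `history` (per-epoch data frame), `best_epoch`,
#'   `val_idx`, `config`, `tconfig`.
#' @export
mmcrl_train <- function(dataset, config, tconfig = train_config(),
                        verbose = 0L) {
  stopifnot(inherits(config, "mmcrl_config"))
  mmcrl_train_from(dataset, init_model(config), tconfig, verbose = verbose)
}

#' Continue training from an existing model (warm start)
#'
#' Same optimization loop as [mmcrl_train()], but starting from the given
#' model's parameters instead of a fresh initialization.
#'
#' @param dataset an `mm_dataset`.
#' @param model an `mmcrl_model` (its `config` supplies dimensions and
#'   loss weights).
#' @param tconfig a [train_config()].
#' @param verbose print a line every `verbose` epochs (0 = silent).
#' @return an `mmcrl_fit`.
#' @export
mmcrl_train_from <- function(dataset, model, tconfig = train_config(),
                             verbose = 0L) {
  stopifnot(inherits(model, "mmcrl_model"), inherits(tconfig, "train_config"))
  config <- model$config
  n <- nrow(dataset$x[[1L]])
  if (!all(vapply(dataset$x, ncol, 1L) == config$d_x))
    stop("dataset observation widths do not match the model configuration")
  std <- standardize(dataset)
  xs <- std$dataset$x
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(tconfig$seed)

  # the aggregate-moment KL needs more rows than noise dimensions
  n_val <- max(sum(config$d_z) + sum(config$d_eta) + 2L,
               round(tconfig$val_frac * n))
  val_idx <- sort(sample.int(n, n_val))
  tr_idx <- setdiff(seq_len(n), val_idx)
  x_val <- lapply(xs, function(xm) xm[val_idx, , drop = FALSE])

  model$standardizer <- std$transforms
  # separate optimizer states so flows and gates can learn faster than the
  # (gradient-rich) encoders/decoders
  opt_ae <- adam_init(list(enc = model$params$enc, dec = model$params$dec),
                      lr = tconfig$lr)
  opt_flow <- adam_init(model$params$flow, lr = tconfig$lr * tconfig$lr_flow_mult)
  opt_gate <- adam_init(model$params$Alogit, lr = tconfig$lr * tconfig$lr_gate_mult)
  alpha_target <- config$alpha
  kdims <- config$d_z + config$d_eta

  draw_xi <- function(nb) lapply(seq_len(config$M), function(m)
    matrix(stats::rnorm(nb * kdims[m]), nb, kdims[m]))

  sp_lo <- tconfig$sp_start_frac * tconfig$epochs
  sp_hi <- max(sp_lo + 1, tconfig$sp_anneal_frac * tconfig$epochs)
  warmup_epochs <- max(1, ceiling(tconfig$ind_warmup_frac * tconfig$epochs))
  best <- list(total = Inf, epoch = 0L, params = NULL)
  hist_rows <- vector("list", tconfig$epochs)
  wait <- 0L

  temp0 <- config$gate_temp
  temp1 <- if (is.null(tconfig$gate_temp_final)) temp0 else tconfig$gate_temp_final
  decayed <- FALSE
  for (ep in seq_len(tconfig$epochs)) {
    t0 <- proc.time()[["elapsed"]]
    model$config$gate_temp <- temp0 * (temp1 / temp0)^(ep / tconfig$epochs)
    if (!decayed && ep > tconfig$lr_decay_frac * tconfig$epochs &&
        tconfig$lr_decay_factor != 1) {
      opt_ae$lr <- opt_ae$lr * tconfig$lr_decay_factor
      opt_flow$lr <- opt_flow$lr * tconfig$lr_decay_factor
      opt_gate$lr <- opt_gate$lr * tconfig$lr_decay_factor
      decayed <- TRUE
    }
    if (!is.null(tconfig$cca_align_frac) &&
        ep %in% pmax(2L, ceiling(tconfig$cca_align_frac * tconfig$epochs))) {
      first <- ep == pmax(2L, ceiling(tconfig$cca_align_frac[1L] * tconfig$epochs))
      x_tr <- lapply(xs, function(xm) xm[tr_idx, , drop = FALSE])
      model <- .cca_align(model, x_tr, reset = first)
      opt_ae <- adam_init(list(enc = model$params$enc, dec = model$params$dec),
                          lr = opt_ae$lr)
      opt_flow <- adam_init(model$params$flow, lr = opt_flow$lr)
      opt_gate <- adam_init(model$params$Alogit, lr = opt_gate$lr)
      if (first) best <- list(total = Inf, epoch = 0L, params = NULL)
    }
    alpha <- alpha_target
    alpha[["sp"]] <- alpha_target[["sp"]] *
      min(1, max(0, (ep - sp_lo) / (sp_hi - sp_lo)))
    alpha[["ind"]] <- alpha_target[["ind"]] * min(1, ep / warmup_epochs)
    ord <- sample(tr_idx)
    nb_tot <- ceiling(length(ord) / tconfig$batch_size)
    tr_sums <- c(recon = 0, ind = 0, sp = 0, total = 0)
    nb_done <- 0L
    last_ok <- NULL
    for (bi in seq_len(nb_tot)) {
      ix <- ord[seq.int((bi - 1L) * tconfig$batch_size + 1L,
                        min(bi * tconfig$batch_size, length(ord)))]
      # a trailing fragment smaller than the noise dimensionality cannot
      # support the covariance fit in the independence loss
      if (length(ix) <= sum(config$d_z) + sum(config$d_eta) + 1L) next
      xb <- lapply(xs, function(xm) xm[ix, , drop = FALSE])
      res <- tryCatch(
        mmcrl_loss_grad(model, xb, draw_xi(length(ix)), alpha = alpha),
        error = function(e) stop("training aborted at epoch ", ep, ", batch ",
                                 bi, ": ", conditionMessage(e),
                                 if (!is.null(last_ok)) paste0(
                                   "; last finite loss total = ",
                                   signif(last_ok, 6)) else "", call. = FALSE))
      last_ok <- res$loss$total
      g <- res$grads
      if (is.finite(tconfig$grad_clip)) {
        gn <- .tree_grad_norm(g)
        if (gn > tconfig$grad_clip)
          g <- tree_map(function(x) x * (tconfig$grad_clip / gn), g)
      }
      st <- adam_step(opt_ae, list(enc = model$params$enc, dec = model$params$dec),
                      list(enc = g$enc, dec = g$dec))
      opt_ae <- st$state
      model$params$enc <- st$params$enc
      model$params$dec <- st$params$dec
      st <- adam_step(opt_flow, model$params$flow, g$flow)
      opt_flow <- st$state
      model$params$flow <- st$params
      st <- adam_step(opt_gate, model$params$Alogit, g$Alogit)
      opt_gate <- st$state
      model$params$Alogit <- st$params
      tr_sums <- tr_sums + c(res$loss$recon, res$loss$ind, res$loss$sp,
                             res$loss$total)
      nb_done <- nb_done + 1L
    }
    tr_means <- tr_sums / max(1L, nb_done)
    val <- mmcrl_loss_grad(model, x_val, draw_xi(n_val),
                           alpha = alpha_target, want_grad = FALSE)$loss
    g <- adjacency_gates(model)
    row <- data.frame(epoch = ep,
                      train_recon = tr_means[["recon"]],
                      train_ind = tr_means[["ind"]],
                      train_sp = tr_means[["sp"]],
                      train_total = tr_means[["total"]],
                      val_recon = val$recon, val_ind = val$ind,
                      val_sp = val$sp, val_total = val$total,
                      gate_density = mean(g[.model_mask(config)]),
                      seconds = proc.time()[["elapsed"]] - t0)
    hist_rows[[ep]] <- row
    if (val$total < best$total) {
      best <- list(total = val$total, epoch = ep, params = model$params,
                   gate_temp = model$config$gate_temp)
      wait <- 0L
    } else {
      wait <- wait + 1L
    }
    if (verbose > 0L && ep %% verbose == 0L)
      message(sprintf("epoch %3d  train %.4f  val %.4f  gates %.3f",
                      ep, tr_means[["total"]], val$total, row$gate_density))
    if (wait >= tconfig$patience && ep > sp_hi) break
  }
  model$params <- best$params
  if (!is.null(best$gate_temp)) model$config$gate_temp <- best$gate_temp
  structure(list(model = model, history = do.call(rbind, hist_rows),
                 best_epoch = best$epoch, val_idx = val_idx,
                 config = config, tconfig = tconfig),
            class = "mmcrl_fit")
}

#' @export
print.mmcrl_fit <- function(x, ...) {
  h <- x$history
  cat("mmcrl fit:", nrow(h), "epochs (best at", x$best_epoch, ")\n")
  cat(sprintf("  best val total %.5g (recon %.5g, ind %.5g, sp %.5g)\n",
              h$val_total[x$best_epoch], h$val_recon[x$best_epoch],
              h$val_ind[x$best_epoch], h$val_sp[x$best_epoch]))
  invisible(x)
}

#' Posterior-mean latent estimates for a dataset
#'
#' Encodes each modality (standardizing with the fit's stored transform)
#' and returns the concatenated posterior means of the latent blocks, the
#' per-modality domain posteriors, and the exogenous estimates from the
#' gated flows.
#'
#' @param fit an `mmcrl_fit` (or a fitted `mmcrl_model`).
#' @param dataset an `mm_dataset` on the original observation scale.
#' @return list with `z_hat` (n x d(z)), `eta` (list of posteriors),
#'   `eps_hat`, `logdet`.
#' @export
estimate_latents <- function(fit, dataset) {
  model <- if (inherits(fit, "mmcrl_fit")) fit$model else fit
  x <- dataset$x
  if (!is.null(model$standardizer))
    x <- apply_standardizer(x, model$standardizer)
  cfg <- model$config
  posts <- lapply(seq_len(cfg$M), function(m) encode(model, x[[m]], m))
  z_hat <- do.call(cbind, lapply(posts, function(p) p$z$mean))
  fl <- flow_to_exogenous(model, z_hat)
  list(z_hat = z_hat, eta = lapply(posts, `[[`, "eta"),
       eps_hat = fl$eps_hat, logdet = fl$logdet)
}
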