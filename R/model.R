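#' Configuration of the multimodal estimation model
#'
#' The estimator has, per modality, a variational encoder producing a
#' diagonal-Gaussian posterior over `[z^(m), eta^(m)]` and a deterministic
#' decoder reconstructing `x^(m)` from a posterior sample. Across
#' modalities, per-component conditional affine flows map the estimated
#' latents to exogenous-noise estimates; each component's flow is
#' conditioned on its candidate parents, selected through a learnable
#' gated adjacency matrix masked to a fixed strict lower-triangular
#' component order (modality-block order). The training objective is the
#' weighted sum of a reconstruction loss, a KL independence loss on
#' `[eta-hat, eps-hat]`, and an L1 penalty on the gated adjacency.
#'
#' @param d_z,d_eta,d_x per-modality dimensions (must match the dataset).
#' @param enc_hidden,dec_hidden hidden-layer widths of encoders/decoders.
#' @param flow_depth number of affine layers per component flow.
#' @param flow_hidden hidden width of the flow conditioner networks.
#' @param gate_temp temperature of the sigmoid adjacency gates.
#' @param alpha named numeric vector of loss weights
#'   `c(recon = , ind = , sp = )`, all `>= 0`.
#' @param ind_sample_weight relative weight, inside the independence
#'   loss, of the per-sample posterior KL next to the aggregate-moment
#'   KL; see [independence_loss()] for the two estimators and the
#'   complementary dependence signals they carry.
#' @param ind_cross_weight relative weight, inside the independence loss,
#'   of the higher-order cross-moment penalty
#'   ([cross_moment_dependence()]), which blocks the encoder from hiding
#'   dependence between noise components in moments that a covariance fit
#'   cannot see.
#' @param gamma_source whether the flows and the aggregate-moment KL see
#'   the posterior `"mean"` (default; matches how latents are extracted
#'   at evaluation time and keeps the independence signal free of
#'   reparameterization noise) or a reparameterized `"sample"`.
#' @param mask_scope which entries of the (strict lower-triangular)
#'   adjacency are learnable: `"cross"` (default) admits only cross-modal
#'   parents, `"all"` also admits within-modality parents. Within-block
#'   coordinate changes are not identifiable and within-block dependence
#'   is the encoder's to absorb; admitting within-block gates offers the
#'   optimizer a shortcut that whitens an entangled block instead of
#'   disentangling it, so the cross-only mask is both the theoretically
#'   meaningful and the empirically stabler choice.
#' @param tau threshold in (0, 1) for extracting a binary graph from the
#'   gates.
#' @param seed seed for parameter initialization.
#' @return an object of class `mmcrl_config`.
#' @export
model_config <- function(d_z, d_eta, d_x,
                         enc_hidden = c(64L, 64L), dec_hidden = c(64L, 64L),
                         flow_depth = 3L, flow_hidden = 16L,
                         gate_temp = 1,
                         alpha = c(recon = 1, ind = 0.8, sp = 0.015),
                         ind_sample_weight = 0.05,
                         ind_cross_weight = 2,
                         gamma_source = c("mean", "sample"),
                         mask_scope = c("cross", "all"),
                         tau = 0.3, seed = 1L) {
  gamma_source <- match.arg(gamma_source)
  mask_scope <- match.arg(mask_scope)
  stopifnot(length(d_z) == length(d_eta), length(d_z) == length(d_x))
  if (any(c(d_z, d_x) < 1L) || any(d_eta < 0L))
    stop("latent/observation dimensions must be positive (d_eta may be 0)")
  if (any(alpha < 0)) stop("loss weights must be nonnegative")
  if (!all(c("recon", "ind", "sp") %in% names(alpha)))
    stop("alpha must have components named recon, ind, sp")
  if (tau <= 0 || tau >= 1) stop("tau must lie in (0, 1)")
  structure(list(
    M = length(d_z), d_z = as.integer(d_z), d_eta = as.integer(d_eta),
    d_x = as.integer(d_x), D = sum(d_z),
    enc_hidden = as.integer(enc_hidden), dec_hidden = as.integer(dec_hidden),
    flow_depth = as.integer(flow_depth), flow_hidden = as.integer(flow_hidden),
    gate_temp = gate_temp, alpha = alpha[c("recon", "ind", "sp")],
    ind_sample_weight = ind_sample_weight,
    ind_cross_weight = ind_cross_weight, gamma_source = gamma_source,
    mask_scope = mask_scope,
    tau = tau, seed = as.integer(seed)
  ), class = "mmcrl_config")
}

#' Model configuration matched to a dataset's generating specification
#'
#' @param ds an `mm_dataset` (its `meta$spec` supplies the dimensions).
#' @param eta_as_latent if `TRUE` (default), the estimator does not
#'   hard-wire a domain-specific slot: every per-modality code dimension
#'   (`d_z + d_eta` of them) is a latent component with its own flow and
#'   candidate cross-modal parents. A truly domain-specific factor then
#'   shows up as a component the sparsity penalty leaves without
#'   cross-modal edges — the distinction is learned, not imposed, which
#'   removes a whole class of misassignment failures (a causal latent
#'   trapped in the domain slot can never be conditioned on by another
#'   modality's flow). With `FALSE` the split follows the generating
#'   specification.
#' @param ... overrides passed to [model_config()].
#' @return an `mmcrl_config`.
#' @export
config_for_dataset <- function(ds, eta_as_latent = TRUE, ...) {
  sp <- ds$meta$spec
  if (eta_as_latent)
    model_config(d_z = sp$d_z + sp$d_eta, d_eta = rep(0L, length(sp$d_z)),
                 d_x = sp$d_x, ...)
  else
    model_config(d_z = sp$d_z, d_eta = sp$d_eta, d_x = sp$d_x, ...)
}

.LV_CLAMP <- 8    # soft bound on posterior log-variances
.S_CLAMP <- 3     # soft bound on per-layer flow log-scales

#' Initialize the estimation model
#'
#' Encoders and decoders are LeakyReLU MLPs; flow conditioners are tanh
#' MLPs with zero-initialized output layers so that every component flow
#' starts exactly at the identity. Adjacency logits start at +2 (gates
#' near 0.88): candidate parents must be visible to the flow conditioners
#' early in training — a closed gate zeroes the conditioner's input and
#' with it any gradient that could reopen it — and the annealed L1
#' penalty later prunes the gates whose conditioning buys no independence.
#' Entries outside the strict lower triangle are structurally masked to
#' zero and never receive gradient.
#'
#' @param config an `mmcrl_config`.
#' @return an object of class `mmcrl_model`.
#' @export
init_model <- function(config) {
  stopifnot(inherits(config, "mmcrl_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  D <- config$D
  enc <- dec <- vector("list", config$M)
  for (m in seq_len(config$M)) {
    k <- config$d_z[m] + config$d_eta[m]
    enc[[m]] <- mlp_init(config$d_x[m], config$enc_hidden, 2L * k)
    dec[[m]] <- mlp_init(k, config$dec_hidden, config$d_x[m])
  }
  flow <- vector("list", D)
  for (i in seq_len(D)) {
    flow[[i]] <- if (i == 1L) list(bias = numeric(2L * config$flow_depth))
      else mlp_init(i - 1L, config$flow_hidden, 2L * config$flow_depth,
                    act = "tanh", zero_out = TRUE)
  }
  structure(list(
    config = config,
    params = list(enc = enc, dec = dec, flow = flow,
                  Alogit = matrix(2, D, D)),
    standardizer = NULL
  ), class = "mmcrl_model")
}

#' @export
print.mmcrl_model <- function(x, ...) {
  cfg <- x$config
  cat("mmcrl estimation model:", cfg$M, "modalities, d(z) =",
      paste(cfg$d_z, collapse = "+"), "\n")
  g <- adjacency_gates(x)
  cat("  mean adjacency gate:", signif(mean(g[lower.tri(g)]), 3), "\n")
  cat("  fitted:", !is.null(x$standardizer), "\n")
  invisible(x)
}

# strict lower-triangular mask in the fixed (modality-block) component order
.adj_mask <- function(D) lower.tri(matrix(0, D, D))

# learnable-entry mask of a model configuration (lower triangle,
# optionally restricted to cross-modal pairs)
.model_mask <- function(cfg) {
  m <- .adj_mask(cfg$D)
  if (is.null(cfg$mask_scope) || cfg$mask_scope == "cross") {
    modality <- rep(seq_len(cfg$M), cfg$d_z)
    m <- m & outer(modality, modality, "!=")
  }
  m
}

#' Gated adjacency matrix of a model
#'
#' `sigmoid(logits / temperature)` on the learnable entries (strict lower
#' triangle, restricted to cross-modal pairs under the default mask
#' scope); masked entries are exactly zero.
#' @param model an `mmcrl_model`.
#' @return a d(z) x d(z) matrix with entries in `[0, 1]`.
#' @export
adjacency_gates <- function(model) {
  g <- stats::plogis(model$params$Alogit / model$config$gate_temp)
  g[!.model_mask(model$config)] <- 0
  g
}

.split_posterior <- function(config, m, out) {
  k <- config$d_z[m] + config$d_eta[m]
  mu <- out[, seq_len(k), drop = FALSE]
  lvraw <- out[, k + seq_len(k), drop = FALSE]
  lv <- .LV_CLAMP * tanh(lvraw / .LV_CLAMP)
  iz <- seq_len(config$d_z[m])
  list(mu = mu, lv = lv, lvraw = lvraw,
       z = list(mean = mu[, iz, drop = FALSE], logvar = lv[, iz, drop = FALSE]),
       eta = list(mean = mu[, -iz, drop = FALSE], logvar = lv[, -iz, drop = FALSE]))
}

#' Encode one modality into posterior parameters
#'
#' @param model an `mmcrl_model`.
#' @param x_m observation matrix (n x d(x^(m))), on the scale the model was
#'   trained on (standardized if the model carries a standardizer).
#' @param m modality index.
#' @return list with elements `z` and `eta`, each `list(mean, logvar)` of
#'   the diagonal-Gaussian posterior.
#' @export
encode <- function(model, x_m, m) {
  cfg <- model$config
  x_m <- as.matrix(x_m)
  if (ncol(x_m) != cfg$d_x[m])
    stop("x has ", ncol(x_m), " columns but modality ", m, " expects ", cfg$d_x[m])
  out <- mlp_forward(model$params$enc[[m]], x_m)$out
  if (any(!is.finite(out))) stop("encoder produced non-finite output")
  p <- .split_posterior(cfg, m, out)
  list(z = p$z, eta = p$eta)
}

#' Decode latent and domain-specific values into an observation
#'
#' @param model an `mmcrl_model`.
#' @param z_hat_m matrix (n x d(z^(m))).
#' @param eta_hat_m matrix (n x d(eta^(m))).
#' @param m modality index.
#' @return reconstruction matrix (n x d(x^(m))).
#' @export
decode <- function(model, z_hat_m, eta_hat_m, m) {
  cfg <- model$config
  z_hat_m <- as.matrix(z_hat_m); eta_hat_m <- as.matrix(eta_hat_m)
  if (ncol(z_hat_m) != cfg$d_z[m] || ncol(eta_hat_m) != cfg$d_eta[m])
    stop("latent/domain widths do not match modality ", m)
  mlp_forward(model$params$dec[[m]], cbind(z_hat_m, eta_hat_m))$out
}

# Conditional affine coefficients of component i's flow given all sampled
# latents. Composition of `flow_depth` layers u <- (u - mu_k) * exp(-s_k):
# overall eps = a * z_i + b. Returns per-sample a, b and backward caches.
.flow_coeffs_i <- function(model, i, zhat_all, gates) {
  cfg <- model$config
  L <- cfg$flow_depth
  nb <- nrow(zhat_all)
  if (i == 1L) {
    raw <- matrix(model$params$flow[[1L]]$bias, nb, 2L * L, byrow = TRUE)
    cache <- NULL; gp <- NULL
  } else {
    gp <- zhat_all[, seq_len(i - 1L), drop = FALSE] *
      matrix(gates[i, seq_len(i - 1L)], nb, i - 1L, byrow = TRUE)
    cache <- mlp_forward(model$params$flow[[i]], gp)
    raw <- cache$out
  }
  mu <- raw[, seq_len(L), drop = FALSE]
  sraw <- raw[, L + seq_len(L), drop = FALSE]
  s <- .S_CLAMP * tanh(sraw / .S_CLAMP)
  e <- exp(-s)
  bk <- matrix(0, nb, L)  # b after each layer
  b <- numeric(nb)
  for (k in seq_len(L)) {
    b <- (b - mu[, k]) * e[, k]
    bk[, k] <- b
  }
  S <- rowSums(s)
  list(a = exp(-S), b = b, S = S, mu = mu, s = s, sraw = sraw, e = e,
       bk = bk, cache = cache, gp = gp)
}

#' Map estimated latents to exogenous-noise estimates via the gated flows
#'
#' For each component `i` (in the model's fixed component order), applies
#' the conditional affine flow `eps_i = a_i(pa) * z_i + b_i(pa)` where the
#' coefficients are produced by a conditioner network fed the gated parent
#' values. With all gates closed and a freshly initialized flow this is the
#' identity map with zero log-determinant.
#'
#' @param model an `mmcrl_model`.
#' @param z_hat matrix (n x d(z)) of latent estimates (all modalities,
#'   block order).
#' @return list with `eps_hat` (n x d(z)) and `logdet` (length-n vector of
#'   per-sample log |d eps / d z|).
#' @export
flow_to_exogenous <- function(model, z_hat) {
  cfg <- model$config
  z_hat <- as.matrix(z_hat)
  if (ncol(z_hat) != cfg$D) stop("z_hat must have d(z) = ", cfg$D, " columns")
  gates <- adjacency_gates(model)
  eps <- matrix(0, nrow(z_hat), cfg$D)
  logdet <- numeric(nrow(z_hat))
  for (i in seq_len(cfg$D)) {
    fc <- .flow_coeffs_i(model, i, z_hat, gates)
    eps[, i] <- fc$a * z_hat[, i] + fc$b
    if (any(!is.finite(fc$S)))
      stop("non-finite flow log-determinant for component ", i)
    logdet <- logdet - fc$S
  }
  list(eps_hat = eps, logdet = logdet)
}

#' Invert the gated flows: reconstruct latents from exogenous estimates
#'
#' Components are reconstructed in the fixed order, so each component's
#' parents are available before it is inverted.
#'
#' @param model an `mmcrl_model`.
#' @param eps_hat matrix (n x d(z)).
#' @return latent matrix (n x d(z)).
#' @export
flow_from_exogenous <- function(model, eps_hat) {
  cfg <- model$config
  eps_hat <- as.matrix(eps_hat)
  gates <- adjacency_gates(model)
  z <- matrix(0, nrow(eps_hat), cfg$D)
  for (i in seq_len(cfg$D)) {
    fc <- .flow_coeffs_i(model, i, z, gates)
    z[, i] <- (eps_hat[, i] - fc$b) / fc$a
  }
  z
}

#' Reconstruction loss: summed squared error, averaged over samples
#'
#' `sum_m mean_n || x^(m) - xhat^(m) ||^2` — sum over modalities and
#' dimensions, mean over samples.
#'
#' @param x,x_hat lists of observation matrices (or single matrices).
#' @return nonnegative scalar; zero iff the reconstruction is exact.
#' @export
reconstruction_loss <- function(x, x_hat) {
  if (is.matrix(x)) x <- list(x)
  if (is.matrix(x_hat)) x_hat <- list(x_hat)
  if (length(x) != length(x_hat)) stop("modality counts differ")
  terms <- mapply(function(a, b) {
    if (!all(dim(a) == dim(b))) stop("shape mismatch in reconstruction loss")
    sum((a - b)^2) / nrow(a)
  }, x, x_hat)
  sum(terms)
}

#' Closed-form KL divergence of diagonal Gaussians from N(0, I)
#'
#' `KL(N(mu, diag(exp(logvar))) || N(0, I))`, summed over dimensions and
#' averaged over rows when matrices are supplied.
#'
#' @param mu,logvar numeric vectors (one sample) or matrices (samples in
#'   rows).
#' @return nonnegative scalar.
#' @export
gaussian_kl <- function(mu, logvar) {
  mu <- rbind(mu); logvar <- rbind(logvar)
  mean(rowSums(0.5 * (mu^2 + exp(logvar) - 1 - logvar)))
}

#' KL divergence of an empirical Gaussian fit from N(0, I)
#'
#' Fits a full-covariance Gaussian to the rows of `gamma` (sample mean and
#' covariance) and returns its closed-form KL divergence from the standard
#' normal: `0.5 (tr(S) + |m|^2 - d - log det S)`. Unlike a per-dimension
#' KL, this penalizes *cross-correlations* between the columns, which is
#' what makes it an operational independence measure for jointly Gaussian
#' noise estimates.
#'
#' @param gamma numeric matrix (samples x dimensions), at least d + 1
#'   rows.
#' @param jitter ridge added to the covariance diagonal for numerical
#'   stability.
#' @return nonnegative scalar.
#' @export
gaussian_moment_kl <- function(gamma, jitter = 1e-8) {
  gamma <- as.matrix(gamma)
  n <- nrow(gamma); d <- ncol(gamma)
  if (n <= d) stop("need more samples than dimensions for a covariance fit")
  mu <- colMeans(gamma)
  C <- sweep(gamma, 2L, mu, "-")
  S <- crossprod(C) / (n - 1) + jitter * diag(d)
  ch <- chol(S)
  0.5 * (sum(diag(S)) + sum(mu^2) - d - 2 * sum(log(diag(ch))))
}

#' Independence loss: KL of the noise posterior from a standard Gaussian
#'
#' Two complementary modes.
#'
#' With `gamma` (a matrix of sampled noise estimates
#' `[eta-hat (all modalities), eps-hat (all components)]`, one row per
#' sample) the loss is the *aggregate-posterior* divergence
#' [gaussian_moment_kl()]: the KL of the empirical Gaussian of the batch
#' from N(0, I). This is the form the trainer optimizes — its
#' off-diagonal covariance terms penalize dependence *between* noise
#' components, the property the identification theory requires, and it
#' carries no per-sample information penalty that would degrade
#' reconstruction.
#'
#' With `eta`/`eps` (Gaussian posterior parameters `list(mean, logvar)`)
#' the loss is the per-sample closed-form Gaussian KL, summed over the
#' supplied parts; with identity flows this equals [gaussian_kl()]
#' exactly.
#'
#' @param eta list(s) of `list(mean, logvar)` posteriors, or `NULL`.
#' @param eps `list(mean, logvar)` of the pushed-forward exogenous
#'   posterior, or `NULL`.
#' @param gamma optional matrix of sampled noise estimates; when given,
#'   `eta`/`eps` are ignored.
#' @return nonnegative scalar.
#' @export
independence_loss <- function(eta = NULL, eps = NULL, gamma = NULL) {
  if (!is.null(gamma)) return(gaussian_moment_kl(gamma))
  tot <- 0
  if (!is.null(eta)) {
    if (!is.null(eta$mean)) eta <- list(eta)
    tot <- tot + sum(vapply(eta, function(p) gaussian_kl(p$mean, p$logvar), 0))
  }
  if (!is.null(eps)) tot <- tot + gaussian_kl(eps$mean, eps$logvar)
  tot
}

#' Higher-order cross-moment dependence penalty
#'
#' Measures pairwise dependence between the columns of `gamma` beyond
#' second moments: each column is expanded in the first three normalized
#' Hermite polynomials (`h1 = g`, `h2 = (g^2 - 1)/sqrt(2)`,
#' `h3 = (g^3 - 3 g)/sqrt(6)`, after a soft clamp for numerical safety),
#' and the penalty is the sum of squared empirical covariances between
#' features of *different* columns. Under mutual independence every such
#' covariance vanishes, whatever the marginals; plain covariance (the
#' Gaussian-moment KL) can be blinded by componentwise nonlinear
#' transforms that push dependence into higher orders, which is exactly
#' what this term catches.
#'
#' @param gamma numeric matrix (samples x components).
#' @param clamp soft bound applied to `gamma` before the polynomial
#'   expansion.
#' @return nonnegative scalar.
#' @export
cross_moment_dependence <- function(gamma, clamp = 2.5) {
  gamma <- as.matrix(gamma)
  gc <- clamp * tanh(gamma / clamp)
  F <- cbind(gc, (gc^2 - 1) / sqrt(2), (gc^3 - 3 * gc) / sqrt(6))
  Fc <- sweep(F, 2L, colMeans(F), "-")
  C <- crossprod(Fc) / (nrow(F) - 1)
  d <- ncol(gamma)
  comp <- rep(seq_len(d), 3L)
  M <- outer(comp, comp, "!=")
  sum((C * M)^2)
}

#' L1 sparsity penalty on an adjacency matrix
#' @param A_hat a numeric matrix (typically the gated adjacency).
#' @return `sum(abs(A_hat))`.
#' @export
sparsity_loss <- function(A_hat) sum(abs(A_hat))

#' Combine loss components into the weighted training objective
#'
#' @param recon,ind,sp the three loss components.
#' @param alpha named weights `c(recon = , ind = , sp = )`.
#' @param per_modality optional vector of per-modality reconstruction
#'   terms.
#' @return an object of class `loss_breakdown` with fields `recon`, `ind`,
#'   `sp`, `total` satisfying
#'   `total = alpha["recon"] * recon + alpha["ind"] * ind + alpha["sp"] * sp`.
#' @export
total_loss <- function(recon, ind, sp, alpha, per_modality = NULL) {
  structure(list(
    recon = recon, ind = ind, sp = sp,
    total = alpha[["recon"]] * recon + alpha[["ind"]] * ind + alpha[["sp"]] * sp,
    per_modality = per_modality, alpha = alpha
  ), class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("loss: total %.5g = %g*recon(%.5g) + %g*ind(%.5g) + %g*sp(%.5g)\n",
              x$total, x$alpha[["recon"]], x$recon, x$alpha[["ind"]], x$ind,
              x$alpha[["sp"]], x$sp))
  invisible(x)
}
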