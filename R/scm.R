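#' Specification of a multimodal latent structural causal model
#'
#' An `scm_spec` fixes the dimensions and sparsity of the generative process:
#' `M` modalities, each with its own block of latent causal components
#' `z^(m)`, a domain-specific noise vector `eta^(m)`, and an observation
#' `x^(m)` produced by an invertible nonlinear mixing of `[z^(m), eta^(m)]`.
#' Latent components are causally related within and across modalities
#' through an acyclic graph; the fraction of *absent* cross-modal links is
#' controlled by `sparsity_ratio` (0 = fully connected across modalities,
#' values near 1 = very sparse).
#'
#' @param M number of modalities (>= 2 for cross-modal structure).
#' @param d_z integer vector of per-modality latent dimensions.
#' @param d_eta integer vector of per-modality domain-specific dimensions.
#' @param d_x integer vector of per-modality observation dimensions; must
#'   satisfy `d_x[m] >= d_z[m] + d_eta[m]` so the mixing can preserve
#'   information.
#' @param sparsity_ratio fraction in `[0, 1)` of admissible cross-modal
#'   ordered latent pairs that carry *no* causal edge.
#' @param mixing_depth number of square LeakyReLU layers in the mixing
#'   network (default 2).
#' @param within_prob probability of a within-modality causal edge between
#'   two latent components of the same block. The default is 0: the
#'   packaged numerical cases place all causal structure between
#'   modalities (within-modality blocks are internally independent), the
#'   regime the cross-modal sparsity theory addresses. Positive values
#'   are supported for stress-testing; note that with within-modality
#'   edges the independent-noise coordinates, not the raw latents, are
#'   the identifiable objects, so latent-recovery scores are structurally
#'   capped.
#' @param sf_type structural-function form: `"additive"` for
#'   `z_i = f(Pa(z_i)) + eps_i`, `"postnonlinear"` for
#'   `z_i = q(f(Pa(z_i)) + eps_i)` with `q` an invertible monotone map.
#' @param noise_law distribution of the exogenous variables; currently
#'   `"gaussian"` (standard normal).
#' @param ensure_coupling if `TRUE` (default), the cross-modal edge quota is
#'   spent first on covering every latent component with at least one
#'   incident cross-modal edge (when the quota allows), so that each
#'   component is in principle distinguishable from domain-specific noise.
#' @param coupling_strength scale of the structural functions relative to
#'   the unit-variance exogenous noise (default 1).
#' @param seed master seed; all randomness in SCM sampling and data
#'   generation is derived from it via fixed substreams.
#'
#' @return an object of class `scm_spec`.
#' @export
scm_spec <- function(M, d_z, d_eta, d_x, sparsity_ratio = 0.5,
                     mixing_depth = 2L, within_prob = 0,
                     sf_type = c("additive", "postnonlinear"),
                     noise_law = "gaussian",
                     ensure_coupling = TRUE, coupling_strength = 1,
                     seed = 1L) {
  sf_type <- match.arg(sf_type)
  M <- as.integer(M)
  d_z <- as.integer(d_z); d_eta <- as.integer(d_eta); d_x <- as.integer(d_x)
  if (length(d_z) != M || length(d_eta) != M || length(d_x) != M)
    stop("d_z, d_eta and d_x must each have length M = ", M)
  if (any(d_z < 1L) || any(d_eta < 1L) || any(d_x < 1L))
    stop("all dimensionalities must be >= 1")
  if (any(d_x < d_z + d_eta))
    stop("information preservation requires d_x[m] >= d_z[m] + d_eta[m] for every modality")
  if (!is.numeric(sparsity_ratio) || sparsity_ratio < 0 || sparsity_ratio > 1)
    stop("sparsity_ratio must lie in [0, 1]")
  if (noise_law != "gaussian") stop("unsupported noise_law: ", noise_law)
  structure(list(
    M = M, d_z = d_z, d_eta = d_eta, d_x = d_x,
    sparsity_ratio = sparsity_ratio, mixing_depth = as.integer(mixing_depth),
    within_prob = within_prob, sf_type = sf_type, noise_law = noise_law,
    ensure_coupling = isTRUE(ensure_coupling),
    coupling_strength = coupling_strength, seed = as.integer(seed)
  ), class = "scm_spec")
}

#' @export
print.scm_spec <- function(x, ...) {
  cat("Multimodal SCM specification\n")
  cat("  modalities:     ", x$M, "\n")
  cat("  d(z):           ", paste(x$d_z, collapse = ", "),
      " (total ", sum(x$d_z), ")\n", sep = "")
  cat("  d(eta):         ", paste(x$d_eta, collapse = ", "), "\n", sep = "")
  cat("  d(x):           ", paste(x$d_x, collapse = ", "),
      " (total ", sum(x$d_x), ")\n", sep = "")
  cat("  sparsity ratio: ", x$sparsity_ratio, "\n")
  cat("  structural form:", x$sf_type, "\n")
  invisible(x)
}

#' Preset specifications for the packaged numerical cases
#'
#' Three standard simulation settings: case 1 has two modalities with two
#' latent and one domain-specific variable each and 15 total observed
#' dimensions (split 8 + 7); case 2 has two modalities with three latent
#' and one domain-specific variable each and 20 total observed dimensions
#' (10 + 10); case 3 has four modalities with two latent and one
#' domain-specific variable each and 30 total observed dimensions
#' (8 + 8 + 7 + 7).
#'
#' @param case integer 1, 2 or 3.
#' @param sparsity_ratio fraction of absent cross-modal links; the default
#'   gives roughly one incident cross-modal edge per latent component
#'   (case 1: 2 of 4 possible links, case 2: 3 of 9, case 3: 6 of 24).
#' @param seed master seed.
#' @param ... further arguments passed to [scm_spec()].
#' @return an `scm_spec`.
#' @export
case_spec <- function(case, sparsity_ratio = NULL, seed = 1L, ...) {
  case <- as.integer(case)
  if (!case %in% 1:3) stop("case must be 1, 2 or 3")
  args <- switch(as.character(case),
    "1" = list(M = 2L, d_z = c(2L, 2L), d_eta = c(1L, 1L), d_x = c(8L, 7L),
               sparsity_ratio = 0.5),
    "2" = list(M = 2L, d_z = c(3L, 3L), d_eta = c(1L, 1L), d_x = c(10L, 10L),
               sparsity_ratio = 2 / 3),
    "3" = list(M = 4L, d_z = rep(2L, 4L), d_eta = rep(1L, 4L),
               d_x = c(8L, 8L, 7L, 7L), sparsity_ratio = 0.75))
  if (!is.null(sparsity_ratio)) args$sparsity_ratio <- sparsity_ratio
  do.call(scm_spec, c(args, list(seed = seed), list(...)))
}

# Named substreams of the master seed so that graph, function and noise
# randomness can be varied independently. Kept below 2^31 - 1.
.substream <- function(seed, name) {
  off <- c(graph = 11L, functions = 23L, noise = 37L, mixing = 53L)[[name]]
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483647)
}

# Global component indices are in modality-block order:
# modality 1 components first, then modality 2, etc.
.partition_of <- function(spec) {
  ends <- cumsum(spec$d_z)
  starts <- c(1L, head(ends, -1L) + 1L)
  lapply(seq_len(spec$M), function(m) seq.int(starts[m], ends[m]))
}

.modality_of <- function(spec) rep(seq_len(spec$M), spec$d_z)

# Count of admissible cross-modal ordered pairs: each unordered pair of
# components from different modalities can carry an edge in exactly one
# direction under any fixed topological order.
.cross_pair_count <- function(d_z) {
  s <- 0
  M <- length(d_z)
  for (m in seq_len(M - 1L)) for (n in seq.int(m + 1L, M))
    s <- s + d_z[m] * d_z[n]
  s
}

#' Sample a latent structural causal model from a specification
#'
#' Draws the causal graph, the structural-function parameters and the
#' mixing-network parameters. The topological order places modality blocks
#' in modality order with a random permutation inside each block, so
#' cross-modal edges always point from an earlier to a later modality.
#' The number of cross-modal edges equals `round((1 - sparsity_ratio) * P)`
#' (half away from zero), where `P` is the number of admissible cross-modal
#' component pairs; every modality is guaranteed at least one incident
#' cross-modal edge (forced beyond the quota if necessary).
#'
#' @param spec an [scm_spec()].
#' @return an object of class `latent_scm` with fields `spec`, `A` (binary
#'   adjacency, `A[i, j] = 1` means component `j` is a parent of component
#'   `i`), `order` (topological permutation), `partition`, `f_params`,
#'   `mix_params`.
#' @export
sample_scm <- function(spec) {
  stopifnot(inherits(spec, "scm_spec"))
  D <- sum(spec$d_z)
  P <- .cross_pair_count(spec$d_z)
  quota <- floor((1 - spec$sparsity_ratio) * P + 0.5)
  if (quota < 1L)
    stop("sparsity_ratio = ", spec$sparsity_ratio, " leaves no cross-modal ",
         "edges, conflicting with the requirement that every modality be ",
         "causally coupled to the others; lower the ratio.")
  part <- .partition_of(spec)
  modality <- .modality_of(spec)

  withr_seed <- function(s, expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(s); expr
  }

  graph <- withr_seed(.substream(spec$seed, "graph"), {
    order <- unlist(lapply(part, function(ix) if (length(ix) > 1L) sample(ix) else ix))
    pos <- integer(D); pos[order] <- seq_len(D)
    # admissible cross-modal (child, parent) pairs under the block order
    adm <- which(outer(modality, modality, ">"), arr.ind = TRUE)
    colnames(adm) <- c("child", "parent")
    A <- matrix(0L, D, D)
    chosen <- integer(0)  # row indices into adm
    if (spec$ensure_coupling) {
      covered <- rep(FALSE, D)
      avail <- rep(TRUE, nrow(adm))
      while (sum(chosen >= 0) < quota && any(!covered)) {
        if (length(chosen) >= quota) break
        unc <- which(!covered)
        c0 <- if (length(unc) > 1L) sample(unc, 1L) else unc
        cand <- which(avail & (adm[, 1L] == c0 | adm[, 2L] == c0))
        if (!length(cand)) { covered[c0] <- TRUE; next }
        other <- ifelse(adm[cand, 1L] == c0, adm[cand, 2L], adm[cand, 1L])
        pref <- cand[!covered[other]]
        pick <- if (length(pref)) pref else cand
        e <- if (length(pick) > 1L) sample(pick, 1L) else pick
        chosen <- c(chosen, e); avail[e] <- FALSE
        covered[adm[e, 1L]] <- TRUE; covered[adm[e, 2L]] <- TRUE
      }
      rest <- setdiff(which(avail), chosen)
      need <- quota - length(chosen)
      if (need > 0L)
        chosen <- c(chosen, if (length(rest) > 1L) sample(rest, need) else rest[seq_len(need)])
    } else {
      chosen <- sample(nrow(adm), quota)
    }
    for (e in chosen) A[adm[e, 1L], adm[e, 2L]] <- 1L
    # force >= 1 incident cross-modal edge per modality
    for (m in seq_len(spec$M)) {
      ix <- part[[m]]
      if (sum(A[ix, -ix, drop = FALSE]) + sum(A[-ix, ix, drop = FALSE]) == 0L) {
        cand <- which(avail_mod <- (adm[, 1L] %in% ix | adm[, 2L] %in% ix) &
                        !seq_len(nrow(adm)) %in% chosen)
        e <- if (length(cand) > 1L) sample(cand, 1L) else cand
        A[adm[e, 1L], adm[e, 2L]] <- 1L
      }
    }
    # within-modality edges, direction set by the topological order
    for (m in seq_len(spec$M)) {
      ix <- part[[m]]
      if (length(ix) < 2L) next
      for (i in ix) for (j in ix) {
        if (i != j && pos[j] < pos[i] && stats::runif(1) < spec$within_prob)
          A[i, j] <- 1L
      }
    }
    list(A = A, order = order, pos = pos)
  })

  f_params <- withr_seed(.substream(spec$seed, "functions"), {
    fp <- lapply(seq_len(D), function(i) {
      np <- sum(graph$A[i, ])
      if (np == 0L) return(NULL)
      h <- 8L
      list(
        W1 = matrix(stats::rnorm(np * h, sd = 1 / sqrt(np)), np, h),
        b1 = stats::rnorm(h, sd = 0.3),
        w2 = stats::rnorm(h, sd = 1 / sqrt(h)),
        b2 = 0,
        pnl_a = stats::runif(1, 0.3, 0.7)  # used only for post-nonlinear form
      )
    })
    # Calibrate each structural function on a pilot ancestral draw so the
    # parent contribution has standard deviation `coupling_strength`
    # relative to the unit-variance exogenous noise (a raw random tanh
    # network can be nearly saturated or nearly flat).
    n_pilot <- 2000L
    eps_p <- matrix(stats::rnorm(n_pilot * D), n_pilot, D)
    z_p <- matrix(0, n_pilot, D)
    for (i in graph$order) {
      pa <- which(graph$A[i, ] == 1L)
      if (!length(pa)) { z_p[, i] <- eps_p[, i]; next }
      f <- .apply_sf(fp[[i]], z_p[, pa, drop = FALSE])
      s <- stats::sd(f)
      if (s < 1e-8) s <- 1e-8
      fp[[i]]$w2 <- fp[[i]]$w2 * spec$coupling_strength / s
      fp[[i]]$b2 <- -mean(f) * spec$coupling_strength / s
      z_p[, i] <- .apply_sf(fp[[i]], z_p[, pa, drop = FALSE]) + eps_p[, i]
    }
    fp
  })

  mix_params <- withr_seed(.substream(spec$seed, "mixing"), {
    lapply(seq_len(spec$M), function(m) .draw_mixing(spec, m))
  })

  scm <- structure(list(spec = spec, A = graph$A, order = graph$order,
                        partition = part, f_params = f_params,
                        mix_params = mix_params), class = "latent_scm")
  .check_mixing_rank(scm)
}

.draw_mixing <- function(spec, m) {
  k <- spec$d_z[m] + spec$d_eta[m]
  rand_orth <- function(p) {
    q <- qr.Q(qr(matrix(stats::rnorm(p * p), p, p)))
    q * sign(diag(q))[col(q)]  # fix sign convention for reproducibility
  }
  W <- lapply(seq_len(spec$mixing_depth), function(l) rand_orth(k))
  b <- lapply(seq_len(spec$mixing_depth), function(l) stats::rnorm(k, sd = 0.2))
  lift <- qr.Q(qr(matrix(stats::rnorm(spec$d_x[m] * k), spec$d_x[m], k)))
  list(W = W, b = b, lift = lift, slope = 0.2)
}

# Numerical full-column-rank check of each mixing Jacobian at random points
# (finite differences); redraws the mixing parameters up to a retry budget.
.check_mixing_rank <- function(scm, n_points = 25L, retries = 5L) {
  spec <- scm$spec
  for (m in seq_len(spec$M)) {
    k <- spec$d_z[m] + spec$d_eta[m]
    for (r in seq_len(retries + 1L)) {
      ok <- mixing_jacobian_ranks(scm, m, n_points = n_points, seed = 1000L + r)
      if (mean(ok == k) >= 0.99) break
      if (r > retries)
        stop("mixing network for modality ", m,
             " failed the full-column-rank check after ", retries, " redraws")
      scm$mix_params[[m]] <- .draw_mixing(spec, m)
    }
  }
  invisible(scm)
}

#' Numerical column ranks of a modality's mixing Jacobian
#'
#' Finite-difference Jacobians of the mixing map at random input points;
#' used to verify that the mixing preserves all latent information
#' (full column rank, the information-preservation precondition for
#' identification).
#'
#' @param scm a `latent_scm`.
#' @param m modality index.
#' @param n_points number of random evaluation points.
#' @param seed seed for the evaluation points.
#' @param h finite-difference step.
#' @return integer vector of numerical ranks, one per point.
#' @export
mixing_jacobian_ranks <- function(scm, m, n_points = 100L, seed = 1L, h = 1e-5) {
  spec <- scm$spec
  k <- spec$d_z[m] + spec$d_eta[m]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  pts <- matrix(stats::rnorm(n_points * k), n_points, k)
  vapply(seq_len(n_points), function(p) {
    u <- pts[p, , drop = FALSE]
    J <- matrix(0, spec$d_x[m], k)
    f0 <- .apply_mixing(scm$mix_params[[m]], u)
    for (j in seq_len(k)) {
      up <- u; up[j] <- up[j] + h
      J[, j] <- (.apply_mixing(scm$mix_params[[m]], up) - f0) / h
    }
    qr(J, tol = 1e-7)$rank
  }, integer(1))
}

.lrelu <- function(a, slope) ifelse(a > 0, a, slope * a)

.apply_mixing <- function(mp, u) {
  H <- u
  for (l in seq_along(mp$W)) {
    H <- sweep(H %*% mp$W[[l]], 2L, -mp$b[[l]], "-")
    H <- .lrelu(H, mp$slope)
  }
  H %*% t(mp$lift)
}

#' Draw latent variables by ancestral sampling
#'
#' Draws the exogenous variables `eps` (one per latent component) and the
#' domain-specific variables `eta` (one block per modality) i.i.d. from the
#' standard normal, then evaluates the structural functions in topological
#' order: `z_i = f_i(Pa(z_i)) + eps_i` (additive form) or
#' `z_i = q(f_i(Pa(z_i)) + eps_i)` (post-nonlinear form). Components with
#' no parents reduce to `z_i = eps_i` (resp. `q(eps_i)`).
#'
#' @param scm a `latent_scm` from [sample_scm()].
#' @param n number of samples (>= 1).
#' @param seed seed for the noise draws.
#' @return a list with `z` (n x d(z)), `eps` (n x d(z)) and `eta` (list of
#'   n x d(eta^(m)) matrices).
#' @export
generate_latents <- function(scm, n, seed = .substream(scm$spec$seed, "noise")) {
  stopifnot(inherits(scm, "latent_scm"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer")
  spec <- scm$spec
  D <- sum(spec$d_z)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  eps <- matrix(stats::rnorm(n * D), n, D)
  eta <- lapply(seq_len(spec$M), function(m)
    matrix(stats::rnorm(n * spec$d_eta[m]), n, spec$d_eta[m]))
  z <- matrix(0, n, D)
  for (i in scm$order) {
    pa <- which(scm$A[i, ] == 1L)
    u <- if (length(pa)) .apply_sf(scm$f_params[[i]], z[, pa, drop = FALSE]) + eps[, i]
         else eps[, i]
    if (spec$sf_type == "postnonlinear") {
      a <- if (length(pa)) scm$f_params[[i]]$pnl_a else 0.5
      u <- u + a * tanh(u)
    }
    if (any(!is.finite(u)))
      stop("structural function for latent component ", i, " produced non-finite values")
    z[, i] <- u
  }
  list(z = z, eps = eps, eta = eta)
}

.apply_sf <- function(fp, pa_mat) {
  drop(tanh(sweep(pa_mat %*% fp$W1, 2L, -fp$b1, "-")) %*% fp$w2) + fp$b2
}

#' Mix latent and domain-specific variables into observations
#'
#' Applies each modality's mixing network `x^(m) = MLP_m([z^(m), eta^(m)])`:
#' square LeakyReLU layers with orthogonal weights followed by a fixed
#' full-column-rank linear lift to the observation dimension.
#'
#' @param scm a `latent_scm`.
#' @param z latent matrix (n x d(z), modality-block column order).
#' @param eta list of per-modality domain-specific matrices.
#' @return list of M observation matrices.
#' @export
mix_observations <- function(scm, z, eta) {
  stopifnot(inherits(scm, "latent_scm"))
  spec <- scm$spec
  if (length(eta) != spec$M) stop("eta must have one block per modality")
  n <- nrow(z)
  if (any(vapply(eta, nrow, 1L) != n)) stop("row counts of z and eta must agree")
  lapply(seq_len(spec$M), function(m) {
    u <- cbind(z[, scm$partition[[m]], drop = FALSE], eta[[m]])
    .apply_mixing(scm$mix_params[[m]], u)
  })
}

#' Simulate a complete multimodal dataset
#'
#' Composes [sample_scm()], [generate_latents()] and [mix_observations()]
#' and retains the ground truth (latents, exogenous noise, domain-specific
#' noise, true adjacency) alongside the observations.
#'
#' @param spec an [scm_spec()].
#' @param n number of samples (default 10000).
#' @param scm optionally, a pre-sampled `latent_scm` (so several datasets
#'   can share one ground-truth model).
#' @param noise_seed seed for the noise draws; defaults to the spec's noise
#'   substream.
#' @return an object of class `mm_dataset` with fields `x` (list of M
#'   matrices), `z`, `eps`, `eta`, `A_true`, `order`, `partition`, `meta`.
#' @export
simulate_dataset <- function(spec, n = 10000L, scm = NULL, noise_seed = NULL) {
  stopifnot(inherits(spec, "scm_spec"))
  if (is.null(scm)) scm <- sample_scm(spec)
  if (is.null(noise_seed)) noise_seed <- .substream(spec$seed, "noise")
  lat <- generate_latents(scm, n, seed = noise_seed)
  x <- mix_observations(scm, lat$z, lat$eta)
  structure(list(
    x = x, z = lat$z, eps = lat$eps, eta = lat$eta,
    A_true = scm$A, order = scm$order, partition = scm$partition,
    scm = scm,
    meta = list(spec = unclass(spec), n = n, noise_seed = noise_seed)
  ), class = "mm_dataset")
}

#' @export
print.mm_dataset <- function(x, ...) {
  cat("Multimodal dataset: n =", nrow(x$x[[1]]), "samples,",
      length(x$x), "modalities\n")
  cat("  observed dims: ", paste(vapply(x$x, ncol, 1L), collapse = ", "), "\n")
  if (!is.null(x$z))
    cat("  ground truth retained (z, eps, eta, adjacency)\n")
  invisible(x)
}

#' Cross-modal sparsity ratio of an adjacency matrix
#'
#' Returns the fraction of *absent* cross-modal links:
#' `1 - (cross-modal edge count) / P` where `P` is the number of admissible
#' cross-modal component pairs (each unordered pair of components from
#' different modalities admits exactly one edge direction under a fixed
#' topological order). 0 means fully connected across modalities, 1 means
#' no cross-modal edges.
#'
#' @param A binary adjacency matrix (`A[i, j] = 1`: j is a parent of i).
#' @param partition list of per-modality component index sets.
#' @param order topological permutation of the components; used to verify
#'   acyclicity.
#' @return the sparsity ratio in `[0, 1]`.
#' @export
sparsity_ratio_of <- function(A, partition, order = NULL) {
  if (!length(partition) || !all(lengths(partition) >= 1L))
    stop("partition must be a non-empty list of non-empty index sets")
  d_z <- lengths(partition)
  modality <- integer(sum(d_z))
  for (m in seq_along(partition)) modality[partition[[m]]] <- m
  if (!is.null(order)) {
    pos <- integer(length(order)); pos[order] <- seq_along(order)
    bad <- which(A != 0 & outer(pos, pos, "<="), arr.ind = TRUE)
    if (nrow(bad)) stop("adjacency is not acyclic under the given order")
  }
  cross <- sum(A[outer(modality, modality, "!=")] != 0)
  1 - cross / .cross_pair_count(d_z)
}
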