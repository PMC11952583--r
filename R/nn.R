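# Minimal dense-network toolkit: MLPs with LeakyReLU/tanh activations,
# hand-written reverse-mode gradients, and an Adam optimizer operating on
# nested parameter lists. All matrices are (batch x features).

# bitwise-equivalent to the naive indexed forms, but allocation-light
.nn_lrelu <- function(a, slope = 0.2) pmax(a, 0) + slope * pmin(a, 0)
.nn_lrelu_grad <- function(a, slope = 0.2) (a >= 0) + slope * (a < 0)

# He-style initialization for LeakyReLU hidden layers; the output layer can
# be zero-initialized (useful for flows that must start at the identity).
mlp_init <- function(d_in, hidden, d_out, act = "lrelu", zero_out = FALSE) {
  widths <- c(d_in, hidden, d_out)
  K <- length(widths) - 1L
  W <- vector("list", K); b <- vector("list", K)
  for (k in seq_len(K)) {
    fan_in <- widths[k]
    sd <- if (k == K && zero_out) 0 else sqrt(2 / max(1, fan_in))
    W[[k]] <- matrix(stats::rnorm(widths[k] * widths[k + 1L], sd = sd),
                     widths[k], widths[k + 1L])
    b[[k]] <- numeric(widths[k + 1L])
  }
  list(W = W, b = b, act = act)
}

# Forward pass; returns output and the cache needed for the backward pass.
# The final layer is linear.
mlp_forward <- function(p, X) {
  K <- length(p$W)
  H <- vector("list", K + 1L)  # H[[1]] = input, H[[k+1]] = post-activation
  A <- vector("list", K)       # pre-activations
  H[[1L]] <- X
  for (k in seq_len(K)) {
    Ak <- H[[k]] %*% p$W[[k]] + rep(p$b[[k]], each = nrow(X))
    A[[k]] <- Ak
    H[[k + 1L]] <- if (k == K) Ak
      else if (p$act == "tanh") tanh(Ak) else .nn_lrelu(Ak)
  }
  list(out = H[[K + 1L]], H = H, A = A)
}

# Backward pass: dY is the gradient at the output. Returns parameter
# gradients (same shape as p) and the gradient wrt the input matrix.
mlp_backward <- function(p, cache, dY) {
  K <- length(p$W)
  dW <- vector("list", K); db <- vector("list", K)
  dA <- dY
  for (k in rev(seq_len(K))) {
    if (k < K) {
      g <- if (p$act == "tanh") 1 - tanh(cache$A[[k]])^2
           else .nn_lrelu_grad(cache$A[[k]])
      dA <- dA * g
    }
    dW[[k]] <- crossprod(cache$H[[k]], dA)
    db[[k]] <- colSums(dA)
    dA <- dA %*% t(p$W[[k]])
  }
  list(grad = list(W = dW, b = db), dX = dA)
}

# ---- nested-list parameter utilities ------------------------------------

# Non-numeric leaves (e.g. an activation tag) pass through untouched.
tree_map <- function(f, a) {
  if (is.list(a)) lapply(a, function(ai) tree_map(f, ai))
  else if (is.numeric(a)) f(a) else a
}
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a)); names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else if (is.numeric(a)) f(a, b) else a
}
tree_zeros_like <- function(a) tree_map(function(x) x * 0, a)
tree_axpy <- function(a, x, y) tree_map2(function(xi, yi) a * xi + yi, x, y)

# ---- Adam ----------------------------------------------------------------

adam_init <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = tree_zeros_like(params), v = tree_zeros_like(params))
}

adam_step <- function(state, params, grads) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) state$beta1 * m + (1 - state$beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) state$beta2 * v + (1 - state$beta2) * g^2,
                       state$v, grads)
  bc1 <- 1 - state$beta1^state$t
  bc2 <- 1 - state$beta2^state$t
  mhat <- tree_map(function(m) m / bc1, state$m)
  vhat <- tree_map(function(v) v / bc2, state$v)
  params <- tree_map2(function(p, u) p - state$lr * u, params,
                      tree_map2(function(m, v) m / (sqrt(v) + state$eps), mhat, vhat))
  list(state = state, params = params)
}
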