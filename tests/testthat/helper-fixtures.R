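# Small shared fixtures and independent oracles for the test suite.

tiny_spec <- function(seed = 1L, ...) {
  args <- list(M = 2L, d_z = c(2L, 2L), d_eta = c(1L, 1L), d_x = c(4L, 4L),
               sparsity_ratio = 0.5, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(scm_spec, args)
}

tiny_model <- function(seed = 1L, ...) {
  args <- list(d_z = c(2L, 2L), d_eta = c(1L, 1L), d_x = c(4L, 4L),
               enc_hidden = c(8L, 8L), dec_hidden = c(8L, 8L),
               flow_hidden = 4L, flow_depth = 2L, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  init_model(do.call(model_config, args))
}

# Brute-force linear assignment oracle (cost minimization) by permutation
# enumeration; independent of the package's Hungarian implementation.
brute_lsap <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  best <- NULL; best_cost <- Inf
  for (p in perms(seq_len(n))) {
    cst <- sum(cost[cbind(seq_len(n), p)])
    if (cst < best_cost) { best_cost <- cst; best <- p }
  }
  list(assignment = best, cost = best_cost)
}

# Brute-force SHD oracle: per unordered pair, compare the joint edge
# pattern; a pure reversal counts one, any other difference counts the
# number of differing directed entries.
brute_shd <- function(G1, G2) {
  n <- nrow(G1)
  tot <- 0L
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    a <- c(G1[i, j], G1[j, i]); b <- c(G2[i, j], G2[j, i])
    if (all(a == b)) next
    tot <- tot + if (all(a == rev(b)) && sum(a) == 1L) 1L else sum(a != b)
  }
  tot
}

# Distance correlation (double-centered distance matrices), for modest n.
dcor <- function(x, y) {
  dc <- function(v) {
    d <- as.matrix(stats::dist(v))
    d - outer(rowMeans(d), colMeans(d), "+") + mean(d)
  }
  A <- dc(x); B <- dc(y)
  v <- sqrt(mean(A * A) * mean(B * B))
  if (v == 0) return(0)
  sqrt(max(0, mean(A * B))) / sqrt(v)
}

rand_dag <- function(n, p = 0.4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(0L, n, n)
  A[lower.tri(A)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
  perm <- sample(n)
  A[perm, perm]
}
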