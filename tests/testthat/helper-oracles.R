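# Independent oracles used across the test suite. These deliberately do not
# share code with the package implementations they check.

# Literal triple-loop affinity propagation, message updates written directly
# from the responsibility/availability update rules with the same damping
# and stopping schedule as the package solver.
naive_affinity_propagation <- function(s, damping = 0.9, max_iter = 1000L,
                                       conv_window = 50L) {
  N <- nrow(s)
  A <- matrix(0, N, N)
  R <- matrix(0, N, N)
  ex_prev <- integer(0)
  stable <- 0L
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    Rnew <- matrix(0, N, N)
    for (i in 1:N) {
      for (k in 1:N) {
        others <- setdiff(1:N, k)
        Rnew[i, k] <- s[i, k] - max(A[i, others] + s[i, others])
      }
    }
    R <- damping * R + (1 - damping) * Rnew
    Anew <- matrix(0, N, N)
    for (i in 1:N) {
      for (k in 1:N) {
        if (i == k) {
          Anew[k, k] <- sum(pmax(0, R[setdiff(1:N, k), k]))
        } else {
          others <- setdiff(1:N, c(i, k))
          Anew[i, k] <- min(0, R[k, k] + sum(pmax(0, R[others, k])))
        }
      }
    }
    A <- damping * A + (1 - damping) * Anew
    ex <- which(diag(R) + diag(A) > 0)
    if (identical(ex, ex_prev) && length(ex) > 0) {
      stable <- stable + 1L
      if (stable >= conv_window) break
    } else {
      stable <- 0L
      ex_prev <- ex
    }
  }
  ex <- which(diag(R) + diag(A) > 0)
  if (!length(ex)) ex <- which.max(diag(R) + diag(A))
  E <- A + R
  labels <- integer(N)
  for (i in 1:N) labels[i] <- ex[which.max(E[i, ex])]
  labels[ex] <- ex
  list(exemplars = ex, labels = labels)
}

# Net similarity of an exemplar set: every non-exemplar contributes its best
# similarity to an exemplar, every exemplar its preference.
net_similarity <- function(s, exemplars) {
  idx <- setdiff(seq_len(nrow(s)), exemplars)
  val <- sum(diag(s)[exemplars])
  if (length(idx)) {
    val <- val + sum(apply(s[idx, exemplars, drop = FALSE], 1, max))
  }
  val
}

# Exhaustive search over all non-empty exemplar subsets (feasible for
# N <= 12).
exhaustive_best_net_similarity <- function(s) {
  N <- nrow(s)
  stopifnot(N <= 12)
  best <- -Inf
  for (code in 1:(2^N - 1)) {
    ex <- which(bitwAnd(code, 2^(seq_len(N) - 1)) > 0)
    val <- net_similarity(s, ex)
    if (val > best) best <- val
  }
  best
}

# Literal step-up FDR rule: find the largest k with p_(k) <= k q / m and
# reject hypotheses with p <= p_(k).
brute_force_bh <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) * q / m)
  rejected <- logical(m)
  if (length(k)) rejected[p <= ps[max(k)]] <- TRUE
  rejected
}

# Small noisy mixture of planted sources for ICA tests.
make_mixture <- function(n_src, V, T_len, snr, seed) {
  maps <- gicadfc::generate_spatial_sources(n_src, V, seed = seed)
  set.seed(seed + 1)
  A <- matrix(rnorm(T_len * n_src), T_len, n_src)
  X <- A %*% maps
  X <- X + matrix(rnorm(length(X), sd = sqrt(var(as.vector(X)) / snr)),
                  nrow(X))
  list(X = X, A = A, maps = maps)
}
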