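# Subject ICA, intrinsic-reference extraction, constrained group ICA, and
# dual regression.
#
# Spatial ICA convention throughout: a data matrix X is T x V (rows are
# timepoint maps over voxels), components are rows of S (N x V, unit
# variance), and X ~ M S with M the T x N mixing matrix of time courses.

# E[log cosh v] for v ~ N(0, 1); Gaussian baseline of the negentropy
# contrast. Fixed constant (numerical integral, accurate to ~1e-10).
EG_GAUSS <- 0.3745672974

logcosh <- function(x) abs(x) + log1p(exp(-2 * abs(x))) - log(2)

# Whiten the row space of X (rows centered) to n dimensions.
# Returns Z (n x V) with Z %*% t(Z) / V = I, plus the PCA basis needed to
# map mixing vectors back. Picks the cheaper Gram matrix side.
whiten_rows <- function(X, n) {
  X <- X - rowMeans(X)
  V <- ncol(X)
  if (nrow(X) <= V) {
    eg <- eigen(tcrossprod(X), symmetric = TRUE)
    keep <- seq_len(n)
    d <- sqrt(pmax(eg$values[keep], .Machine$double.eps))
    # right singular vectors scaled to unit-variance rows
    Z <- sqrt(V) * (t(eg$vectors[, keep, drop = FALSE]) %*% X) / d
  } else {
    eg <- eigen(crossprod(X), symmetric = TRUE)
    keep <- seq_len(n)
    W <- eg$vectors[, keep, drop = FALSE]
    Z <- sqrt(V) * t(W)
  }
  list(Z = Z, Xc = X)
}

#' Estimate the number of latent components by minimum description length
#'
#' Applies the information-theoretic order-selection criterion (MDL) to the
#' eigenvalue spectrum of the temporal covariance of a T x V data matrix,
#' treating the V voxel time series as samples of a T-dimensional variable.
#' Returns the order k minimizing
#' \deqn{-V (T-k) \log(g_k / a_k) + \tfrac12 k (2T - k) \log V}
#' where \eqn{g_k} and \eqn{a_k} are the geometric and arithmetic means of
#' the smallest T-k eigenvalues.
#'
#' @param X T x V numeric matrix (T >= 3, V > T).
#' @return estimated component count (0 for white data).
#' @export
estimate_num_components <- function(X) {
  stop_if_not_matrix(X)
  T_len <- nrow(X)
  V <- ncol(X)
  if (T_len < 3 || V <= T_len) stop("need T >= 3 and V > T")
  ev <- eigen(stats::cov(t(X)), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  if (max(ev) - min(ev) <= 1e-12 * max(ev, 1e-300)) return(0L)
  ev <- pmax(ev, 1e-300)
  ks <- 0:(T_len - 1)
  mdl <- vapply(ks, function(k) {
    tail_ev <- ev[(k + 1):T_len]
    g <- mean(log(tail_ev))
    a <- log(mean(tail_ev))
    -V * (T_len - k) * (g - a) + 0.5 * k * (2 * T_len - k) * log(V)
  }, numeric(1))
  ks[which.min(mdl)]
}

#' Subject-level spatial ICA (FastICA)
#'
#' Whitens the data to `n_comp` dimensions by PCA and runs symmetric
#' fixed-point negentropy maximization with the log-cosh contrast. Component
#' maps are unit variance and sign-oriented so their skewness is positive;
#' the run is deterministic given `seed`.
#'
#' @param X T x V data matrix.
#' @param n_comp number of components (<= T).
#' @param seed integer seed for the random orthogonal start.
#' @param max_iter,tol fixed-point iteration controls.
#' @return object of class `subject_decomposition`: `M` (T x N mixing),
#'   `S` (N x V maps), `n_comp`, `converged`, `iterations`.
#' @export
fit_subject_ica <- function(X, n_comp, seed = 1L, max_iter = 200L,
                            tol = 1e-6) {
  stop_if_not_matrix(X)
  if (n_comp > nrow(X)) stop("n_comp must be <= T")
  wh <- whiten_rows(X, n_comp)
  Z <- wh$Z
  V <- ncol(Z)
  W <- with_seed(seed, {
    qr.Q(qr(matrix(stats::rnorm(n_comp^2), n_comp, n_comp)))
  })
  sym_orth <- function(W) {
    eg <- eigen(tcrossprod(W), symmetric = TRUE)
    K <- eg$vectors %*% diag(1 / sqrt(pmax(eg$values, 1e-15)),
                             n_comp) %*% t(eg$vectors)
    K %*% W
  }
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    S <- W %*% Z
    G1 <- tanh(S)
    W_new <- tcrossprod(G1, Z) / V - diag(rowMeans(1 - G1^2),
                                          n_comp) %*% W
    W_new <- sym_orth(W_new)
    delta <- max(abs(1 - abs(rowSums(W_new * W))))
    W <- W_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf("subject ICA did not converge in %d iterations", max_iter))
  }
  S <- W %*% Z
  flip <- sign(rowMeans(S^3))
  flip[flip == 0] <- 1
  S <- S * flip
  M <- tcrossprod(wh$Xc, S) / V
  structure(list(M = M, S = S, n_comp = n_comp, converged = converged,
                 iterations = it),
            class = "subject_decomposition")
}

#' Match a component of interest across subjects
#'
#' For each subject decomposition, selects the component whose spatial map
#' has the largest absolute Pearson correlation with a template map,
#' sign-flipping the selected map so the correlation is positive. Subjects
#' whose best correlation is below `floor` are flagged as unmatched.
#'
#' @param decomps list of `subject_decomposition` objects sharing V.
#' @param template_map length-V template (ground-truth map in synthetic
#'   runs, user-supplied map otherwise).
#' @param floor minimum acceptable |correlation|.
#' @return list with `index` (per-subject component index, NA if unmatched),
#'   `correlation`, `matched` (logical), and `matched_maps` (K x V matrix of
#'   sign-aligned selected maps; unmatched rows dropped).
#' @export
select_components_of_interest <- function(decomps, template_map,
                                          floor = 0.2) {
  template <- as.numeric(template_map)
  K <- length(decomps)
  idx <- integer(K)
  rho <- numeric(K)
  maps <- matrix(NA_real_, K, length(template))
  for (i in seq_len(K)) {
    S <- decomps[[i]]$S
    cors <- as.vector(stats::cor(t(S), template))
    j <- which.max(abs(cors))
    idx[i] <- j
    rho[i] <- cors[j]
    maps[i, ] <- S[j, ] * sign(cors[j])
  }
  matched <- abs(rho) >= floor
  idx[!matched] <- NA_integer_
  list(index = idx, correlation = rho, matched = matched,
       matched_maps = maps[matched, , drop = FALSE])
}

#' Extract the intrinsic reference from matched subject maps
#'
#' Stacks the K matched maps into R (K x V, rows centered internally), takes
#' the eigendecomposition of C = R R' and returns the first principal
#' component r = e1' R as the intrinsic spatial reference, sign-oriented so
#' its mean correlation with the rows of R is positive.
#'
#' @param matched_maps K x V matrix of sign-aligned subject maps.
#' @return object of class `reference_signal`: `reference` (length V),
#'   `values` (eigenvalues, non-increasing), `vectors`, `R` (centered rows).
#' @export
extract_intrinsic_reference <- function(matched_maps) {
  stop_if_not_matrix(matched_maps)
  R <- matched_maps - rowMeans(matched_maps)
  if (max(abs(R)) == 0) stop("matched maps are all zero; no direction")
  C <- tcrossprod(R)
  eg <- eigen(C, symmetric = TRUE)
  r <- as.vector(t(eg$vectors[, 1, drop = FALSE]) %*% R)
  mean_cor <- mean(stats::cor(r, t(R)))
  if (is.finite(mean_cor) && mean_cor < 0) r <- -r
  structure(list(reference = r, values = eg$values, vectors = eg$vectors,
                 R = R),
            class = "reference_signal")
}

#' Solver parameters for constrained group ICA
#'
#' The contrast is the negentropy proxy J(s) = (E\[G(s)\] - E\[G(v)\])^2 with
#' G = log cosh and v ~ N(0,1); the closeness measure is the correlation
#' distance eps(s, r) = 1 - cor(s, r), constrained by eps <= xi.
#'
#' @param xi closeness threshold on the correlation distance (> 0).
#' @param gamma augmented-Lagrangian penalty weight.
#' @param max_iter maximum outer iterations.
#' @param tol convergence tolerance on the map update.
#' @param seed seed for the fallback random start.
#' @return list of class `gica_params`.
#' @export
gica_params <- function(xi = 0.5, gamma = 10, max_iter = 500L, tol = 1e-6,
                        seed = 1L) {
  stopifnot(xi > 0, tol > 0, gamma > 0)
  structure(list(xi = xi, gamma = gamma, max_iter = as.integer(max_iter),
                 tol = tol, seed = as.integer(seed)),
            class = "gica_params")
}

# One constrained one-unit extraction in whitened space.
# Maximizes J(w' Z) subject to 1 - cor(s, r) - xi <= 0 and E[s^2] = 1 (held
# exactly by keeping ||w|| = 1 on the whitened sphere), via an augmented
# Lagrangian with projected-gradient inner ascent and backtracking.
constrained_one_unit <- function(Z, r, params) {
  V <- ncol(Z)
  r_std <- as.numeric(scale(r))
  c_vec <- as.vector(Z %*% r_std) / V
  if (sqrt(sum(c_vec^2)) < 1e-12) {
    w <- with_seed(params$seed, stats::rnorm(nrow(Z)))
  } else {
    w <- c_vec
  }
  w <- w / sqrt(sum(w^2))
  g_of <- function(w) 1 - sum(w * c_vec) - params$xi
  obj <- function(w, lambda) {
    s <- as.vector(crossprod(w, Z))
    delta <- mean(logcosh(s)) - EG_GAUSS
    g <- g_of(w)
    pen <- if (lambda + params$gamma * g > 0) {
      ((lambda + params$gamma * g)^2 - lambda^2) / (2 * params$gamma)
    } else {
      -lambda^2 / (2 * params$gamma)
    }
    delta^2 - pen
  }
  lambda <- 0
  converged <- FALSE
  it <- 0L
  while (it < params$max_iter) {
    it <- it + 1L
    s <- as.vector(crossprod(w, Z))
    delta <- mean(logcosh(s)) - EG_GAUSS
    grad <- 2 * delta * as.vector(Z %*% tanh(s)) / V
    g <- g_of(w)
    if (lambda + params$gamma * g > 0) {
      grad <- grad + (lambda + params$gamma * g) * c_vec
    }
    grad_t <- grad - sum(grad * w) * w
    f0 <- obj(w, lambda)
    step <- 1
    w_new <- w
    repeat {
      cand <- w + step * grad_t
      cand <- cand / sqrt(sum(cand^2))
      if (obj(cand, lambda) > f0 || step < 1e-12) {
        w_new <- cand
        break
      }
      step <- step / 2
    }
    lambda <- max(0, lambda + params$gamma * g_of(w_new))
    delta_w <- sqrt(min(sum((w_new - w)^2), sum((w_new + w)^2)))
    w <- w_new
    if (delta_w < params$tol && step >= 1e-12) {
      converged <- TRUE
      break
    }
  }
  s <- as.vector(crossprod(w, Z))
  g_final <- g_of(w)
  list(w = w, s = s, converged = converged, iterations = it,
       constraint = g_final, feasible = g_final <= 1e-9, lambda = lambda)
}

#' Constrained group ICA toward intrinsic references
#'
#' Temporally concatenates the (already stacked) group data, whitens it, and
#' extracts one group component per reference by maximizing the negentropy
#' contrast subject to the closeness constraint eps(s, r) - xi <= 0 and the
#' unit-variance constraint E\[s^2\] = 1. The equality constraint is enforced
#' exactly on the whitened sphere; the inequality is handled by an augmented
#' Lagrangian with multiplier updates.
#'
#' @param X_group KT x V stacked group data matrix.
#' @param references list of length-V reference maps (pairwise |cor| < 0.9).
#' @param params a [gica_params()].
#' @param n_whiten whitening dimension (default: number of references).
#' @return object of class `group_decomposition`: `S` (N x V group maps,
#'   unit variance), `M` (KT x N mixing), per-component `converged`,
#'   `feasible`, `constraint`.
#' @export
fit_constrained_group_ica <- function(X_group, references,
                                      params = gica_params(),
                                      n_whiten = length(references)) {
  stop_if_not_matrix(X_group)
  n_ref <- length(references)
  if (n_ref >= 2) {
    ref_mat <- do.call(rbind, lapply(references, as.numeric))
    cc <- stats::cor(t(ref_mat))
    if (max(abs(cc[upper.tri(cc)])) >= 0.9) {
      stop("references must be mutually distinct (pairwise |cor| < 0.9)")
    }
  }
  wh <- whiten_rows(X_group, n_whiten)
  Z <- wh$Z
  V <- ncol(Z)
  S <- matrix(0, n_ref, V)
  conv <- logical(n_ref)
  feas <- logical(n_ref)
  constr <- numeric(n_ref)
  for (k in seq_len(n_ref)) {
    fit <- constrained_one_unit(Z, as.numeric(references[[k]]), params)
    s <- fit$s
    if (stats::cor(s, as.numeric(references[[k]])) < 0) s <- -s
    S[k, ] <- s
    conv[k] <- fit$converged
    feas[k] <- fit$feasible
    constr[k] <- fit$constraint
    if (!fit$feasible) {
      warning(sprintf(
        "component %d: closeness constraint violated by %.3g at convergence",
        k, max(0, fit$constraint)))
    }
  }
  M <- tcrossprod(wh$Xc, S) / V
  structure(list(S = S, M = M, converged = conv, feasible = feas,
                 constraint = constr, n_components = n_ref),
            class = "group_decomposition")
}

#' Dual regression of group maps onto a subject's data
#'
#' Stage 1 regresses the subject data onto the group spatial maps (spatial
#' designs) to obtain subject time courses; stage 2 regresses the data onto
#' those time courses to obtain subject-specific maps. Both stages use
#' centered data.
#'
#' @param X_i T x V subject data matrix.
#' @param group_maps N x V group component maps.
#' @return list with `time_courses` (T x N) and `maps` (N x V).
#' @export
dual_regress <- function(X_i, group_maps) {
  stop_if_not_matrix(X_i)
  stop_if_not_matrix(group_maps)
  if (ncol(X_i) != ncol(group_maps)) stop("voxel dimensions do not match")
  D <- scale_cols(t(group_maps), scale = FALSE)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    cc <- stats::cor(t(group_maps))
    bad <- which(abs(cc) > 0.999 & upper.tri(cc), arr.ind = TRUE)
    pair <- if (nrow(bad)) sprintf(" (components %d and %d)",
                                   bad[1, 1], bad[1, 2]) else ""
    stop(sprintf("group maps are rank-deficient%s", pair))
  }
  Y <- scale_cols(t(X_i), scale = FALSE)
  tc <- t(qr.coef(qrD, Y))
  Tc <- scale_cols(tc, scale = FALSE)
  Xc <- scale_cols(X_i, scale = FALSE)
  maps <- qr.coef(qr(Tc), Xc)
  dimnames(maps) <- NULL
  dimnames(tc) <- NULL
  list(time_courses = tc, maps = maps)
}
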