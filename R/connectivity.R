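# Static and sliding-window dynamic functional connectivity.
#
# Time courses are T x n matrices (one column per network). Windowed
# correlation uses a rectangular (boxcar) window: window j (1-based) covers
# samples j .. j+W-1, and for step 1 there are T - W + 1 windows.

check_time_courses <- function(tcs) {
  stop_if_not_matrix(tcs)
  if (ncol(tcs) < 2) stop("need at least 2 network time courses")
  sds <- apply(tcs, 2, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("constant time course in column %s",
                 paste(which(sds == 0), collapse = ", ")))
  }
  invisible(tcs)
}

#' Static functional connectivity
#'
#' Full-length Pearson correlation matrix between network time courses.
#'
#' @param tcs T x n matrix of time courses (T >= 3, no constant column).
#' @return n x n correlation matrix.
#' @export
static_fc <- function(tcs) {
  check_time_courses(tcs)
  if (nrow(tcs) < 3) stop("need at least 3 timepoints")
  stats::cor(tcs)
}

#' Sliding-window dynamic functional connectivity
#'
#' Pearson correlation of contiguous windowed slices. A column that is
#' constant within some window gets zero correlations in that window (with a
#' warning) rather than NaN.
#'
#' @param tcs T x n matrix of time courses.
#' @param W window width in samples (3 <= W <= T).
#' @param step window step in samples (>= 1).
#' @return list of n x n correlation matrices, one per window; each carries
#'   a `window` attribute with its 1-based index.
#' @export
sliding_window_dfc <- function(tcs, W = 20L, step = 1L) {
  check_time_courses(tcs)
  T_len <- nrow(tcs)
  if (W > T_len) stop("window width W exceeds series length T")
  if (W < 3) stop("window width W must be >= 3")
  if (step < 1) stop("step must be >= 1")
  starts <- seq(1L, T_len - W + 1L, by = step)
  out <- vector("list", length(starts))
  warned <- FALSE
  for (k in seq_along(starts)) {
    slice <- tcs[starts[k]:(starts[k] + W - 1L), , drop = FALSE]
    sds <- apply(slice, 2, stats::sd)
    if (any(sds == 0)) {
      if (!warned) {
        warning(sprintf("constant column within window %d; entries set to 0",
                        k))
        warned <- TRUE
      }
      m <- diag(ncol(slice))
      ok <- sds > 0
      if (sum(ok) >= 2) {
        m[ok, ok] <- stats::cor(slice[, ok, drop = FALSE])
      }
    } else {
      m <- stats::cor(slice)
    }
    attr(m, "window") <- k
    out[[k]] <- m
  }
  out
}

#' Vectorize a connectivity matrix
#'
#' Strict upper triangle in row-major order: (1,2), (1,3), ..., (1,n),
#' (2,3), ..., (n-1,n).
#'
#' @param m symmetric n x n matrix (asymmetry beyond 1e-9 is an error).
#' @return numeric vector of length n(n-1)/2.
#' @export
vectorize_dfc <- function(m) {
  stop_if_not_matrix(m)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-9) {
    stop("input must be symmetric (within 1e-9)")
  }
  tm <- t(m)
  tm[lower.tri(tm)]
}

#' Rebuild a connectivity matrix from its vectorized upper triangle
#'
#' Inverse of [vectorize_dfc()]; the diagonal is set to 1.
#'
#' @param v vector of length n(n-1)/2.
#' @param n matrix dimension.
#' @return symmetric n x n matrix with unit diagonal.
#' @export
unvectorize_dfc <- function(v, n) {
  if (length(v) != n * (n - 1) / 2) stop("length(v) must be n(n-1)/2")
  m <- diag(n)
  tm <- t(m)
  tm[lower.tri(tm)] <- v
  m <- t(tm)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

#' Assemble the DFC vector set
#'
#' Stacks vectorized windowed connectivity matrices into a
#' (#windows) x n(n-1)/2 matrix, rows ordered by ascending window index.
#'
#' @param matrices list of same-dimension symmetric FC matrices.
#' @param W,step,TR optional metadata recorded as attributes.
#' @return matrix of class `dfc_vector_set` with attributes `W`, `step`,
#'   `TR`, `ordering`.
#' @export
assemble_dfc_vector_set <- function(matrices, W = NA_integer_,
                                    step = NA_integer_, TR = NA_real_) {
  if (!length(matrices)) stop("no matrices supplied")
  ns <- vapply(matrices, nrow, integer(1))
  if (length(unique(ns)) != 1) stop("matrices have mixed dimensions")
  out <- do.call(rbind, lapply(matrices, vectorize_dfc))
  n <- ns[1]
  pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  colnames(out) <- sprintf("%d-%d", pairs[, 1], pairs[, 2])
  structure(out, W = W, step = step, TR = TR,
            ordering = "upper-triangle row-major",
            class = c("dfc_vector_set", class(out)))
}
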