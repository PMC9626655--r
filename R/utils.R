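# Internal helpers shared across modules.

#' Evaluate code under a fixed RNG seed without disturbing the caller's stream
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seed for substream i of a master seed; kept < 2^31.
child_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(i)) %% 2147483629)
}

# FNV-1a hash of a character scalar; used for run manifests only.
fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (as.double(h) * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

stop_if_not_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric matrix", name), call. = FALSE)
  }
  invisible(x)
}

# Symmetric positive-definite check via eigenvalues.
is_spd <- function(m, tol = 1e-10) {
  if (!isSymmetric(m, tol = 1e-8)) return(FALSE)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  all(ev > tol * max(abs(ev)))
}

# Row-stochastic check within tolerance.
is_row_stochastic <- function(m, tol = 1e-12) {
  is.matrix(m) && all(m >= -tol) && all(abs(rowSums(m) - 1) <= tol * 10 + tol)
}

scale_cols <- function(x, center = TRUE, scale = TRUE) {
  x <- scale(x, center = center, scale = scale)
  attr(x, "scaled:center") <- NULL
  attr(x, "scaled:scale") <- NULL
  x
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items,
#' computed from the pair-counting contingency table. Used to score recovered
#' connectivity-state labels against planted ones.
#'
#' @param x,y integer or factor label vectors of equal length.
#' @return a number in \[-1, 1\]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(x, y) {
  if (length(x) != length(y)) stop("label vectors must have equal length")
  tab <- table(x, y)
  choose2 <- function(n) n * (n - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_i <- sum(choose2(rowSums(tab)))
  sum_j <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(x))
  expected <- sum_i * sum_j / n2
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
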