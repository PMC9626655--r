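# Paired before/after statistics with false discovery rate control.

#' Paired t test
#'
#' Two-sided paired t test on post - pre differences:
#' t = mean(d) / (sd(d) / sqrt(n)), df = n - 1. Zero-variance differences
#' are reported with p = 0 (if the mean difference is nonzero) or p = 1
#' (all-zero differences), flagged as degenerate.
#'
#' @param pre,post equal-length paired sample vectors (n >= 2).
#' @return list with `t`, `df`, `p`, `degenerate`.
#' @export
paired_t_test <- function(pre, post) {
  if (length(pre) != length(post)) stop("pre and post must be paired")
  n <- length(pre)
  if (n < 2) stop("need at least 2 pairs")
  d <- post - pre
  s <- stats::sd(d)
  if (s == 0) {
    if (mean(d) != 0) {
      return(list(t = sign(mean(d)) * Inf, df = n - 1, p = 0,
                  degenerate = TRUE))
    }
    return(list(t = 0, df = n - 1, p = 1, degenerate = TRUE))
  }
  t_stat <- mean(d) / (s / sqrt(n))
  list(t = t_stat, df = n - 1,
       p = 2 * stats::pt(abs(t_stat), df = n - 1, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up procedure at level `q_level`: with ordered p-values p_(1) <= ...
#' <= p_(m), rejects hypotheses 1..k* where k* is the largest k with
#' p_(k) <= k q / m. Adjusted values are the usual monotone-enforced
#' q-values.
#'
#' @param pvals p-values in \[0, 1\].
#' @param q_level FDR level (default 0.05).
#' @return list with `q` (adjusted values) and `rejected` (logical).
#' @export
fdr_correct <- function(pvals, q_level = 0.05) {
  p <- as.numeric(pvals)
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  q <- numeric(m)
  q[o] <- adj
  list(q = q, rejected = q <= q_level)
}

#' Edgewise paired comparison of connectivity between two conditions
#'
#' Runs a paired t test per network-pair edge across pairing units
#' (subjects at the individual level, windows at the group level), with
#' optional Fisher z transform of the correlations first, and
#' Benjamini-Hochberg correction across edges.
#'
#' @param pre_fc,post_fc units x edges matrices of FC values with matching
#'   dimensions (and column names, when present).
#' @param level `"individual"` (units are subjects) or `"group"` (units are
#'   windows); informational.
#' @param fisher_z apply atanh to the correlations before testing
#'   (default TRUE; values clamped away from +-1).
#' @param q_level FDR level for the significance flags.
#' @return data.frame with one row per edge: `edge`, `t`, `df`, `p`, `q`,
#'   `significant`.
#' @export
edgewise_group_comparison <- function(pre_fc, post_fc,
                                      level = c("individual", "group"),
                                      fisher_z = TRUE, q_level = 0.05) {
  level <- match.arg(level)
  pre_fc <- as.matrix(pre_fc)
  post_fc <- as.matrix(post_fc)
  if (!all(dim(pre_fc) == dim(post_fc))) {
    stop("pre and post must have matching pairing units and edges")
  }
  if (!is.null(colnames(pre_fc)) && !is.null(colnames(post_fc)) &&
      !identical(colnames(pre_fc), colnames(post_fc))) {
    stop("edge sets do not match")
  }
  if (fisher_z) {
    clamp <- function(x) pmin(pmax(x, -1 + 1e-12), 1 - 1e-12)
    pre_fc <- atanh(clamp(pre_fc))
    post_fc <- atanh(clamp(post_fc))
  }
  edges <- colnames(pre_fc)
  if (is.null(edges)) edges <- paste0("edge", seq_len(ncol(pre_fc)))
  res <- lapply(seq_len(ncol(pre_fc)), function(j) {
    paired_t_test(pre_fc[, j], post_fc[, j])
  })
  p <- vapply(res, `[[`, numeric(1), "p")
  fdr <- fdr_correct(p, q_level)
  data.frame(edge = edges,
             t = vapply(res, `[[`, numeric(1), "t"),
             df = vapply(res, `[[`, numeric(1), "df"),
             p = p, q = fdr$q, significant = fdr$rejected,
             row.names = NULL)
}
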