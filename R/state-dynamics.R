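# Markov state-transition estimation from per-window label sequences.

#' Estimate a state-transition probability matrix
#'
#' Counts transitions between consecutive windows within each label
#' sequence (never across sequence boundaries) and row-normalizes by each
#' state's total outgoing transitions. States that are never left yield an
#' all-zero row, flagged in `empty_rows`.
#'
#' @param labels integer vector of per-window state labels, or a list of
#'   such vectors (e.g. one per subject); each of length >= 2.
#' @param n_states number of states (default: maximum observed label).
#' @return object of class `transition_matrix`: `P` (row-stochastic where
#'   defined), `counts`, `visits`, `empty_rows`.
#' @export
estimate_transition_matrix <- function(labels, n_states = NULL) {
  if (!is.list(labels)) labels <- list(labels)
  labels <- lapply(labels, as.integer)
  if (any(vapply(labels, length, integer(1)) < 2)) {
    stop("each label sequence must have length >= 2")
  }
  maxlab <- max(vapply(labels, max, integer(1)))
  minlab <- min(vapply(labels, min, integer(1)))
  if (minlab < 1) stop("labels must be positive integers")
  if (is.null(n_states)) {
    n_states <- maxlab
  } else if (maxlab > n_states) {
    stop(sprintf("label %d exceeds n_states = %d", maxlab, n_states))
  }
  counts <- matrix(0, n_states, n_states)
  for (seq_i in labels) {
    from <- seq_i[-length(seq_i)]
    to <- seq_i[-1]
    for (k in seq_along(from)) {
      counts[from[k], to[k]] <- counts[from[k], to[k]] + 1
    }
  }
  out <- rowSums(counts)
  P <- counts / pmax(out, 1)
  empty <- which(out == 0)
  structure(list(P = P, counts = counts, visits = out,
                 empty_rows = empty,
                 n_states = n_states),
            class = "transition_matrix")
}

#' Window-level transition matrix implied by a planted segment chain
#'
#' The generator holds each sampled state for `segment_length` timepoints,
#' so per-window labels (majority vote over a width-W window, step 1) switch
#' only when a window majority crosses a segment boundary. For a session of
#' T timepoints there are B = ceiling(T / segment_length) - 1 boundaries and
#' T - W consecutive window pairs, giving (under a symmetric chain's uniform
#' stationary distribution) the closed form
#' P_w(a -> b) = B * P_seg(a -> b) / (T - W) for b != a, self-transitions by
#' complement. This is the planted quantity that window-label transition
#' estimates recover.
#'
#' @param P_seg planted segment-level transition matrix.
#' @param T_len session length in timepoints.
#' @param W window width in samples.
#' @param segment_length dwell length in timepoints.
#' @return row-stochastic matrix on the window-label scale.
#' @export
expected_window_transitions <- function(P_seg, T_len, W, segment_length) {
  if (!is_row_stochastic(P_seg, tol = 1e-9)) {
    stop("P_seg must be row-stochastic")
  }
  B <- ceiling(T_len / segment_length) - 1
  pairs <- T_len - W
  off <- B * P_seg / pairs
  diag(off) <- 0
  P <- off
  diag(P) <- 1 - rowSums(off)
  P
}
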