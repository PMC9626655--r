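# Recurring connectivity states by affinity propagation.
#
# Exemplar-based clustering by message passing: "responsibility" r(i,k)
# scores how well candidate exemplar k suits point i; "availability" a(i,k)
# scores how appropriate it is for i to choose k. The self-similarity
# ("preference") controls the emergent number of exemplars.

#' Build the similarity model for affinity propagation
#'
#' Similarity is negative squared Euclidean distance between rows;
#' self-similarities are set to the preference. `"median"` of the
#' off-diagonal similarities (the default) is the canonical
#' moderate-cluster-count choice; `"min"` is the standard conservative
#' choice when a small number of clusters is expected, and is what the
#' pipeline uses for connectivity-state extraction (see the vignette for
#' why windowed-correlation clouds over-partition under the median).
#'
#' @param vectors points-by-features matrix (e.g. DFC vector set rows).
#' @param preference numeric value, `"median"`, or `"min"`.
#' @param damping message damping factor in \[0.5, 1).
#' @param max_iter maximum message-passing iterations.
#' @param conv_window iterations of exemplar-set stability required to
#'   declare convergence.
#' @return list of class `similarity_model`.
#' @export
build_similarity <- function(vectors, preference = "median", damping = 0.9,
                             max_iter = 1000L, conv_window = 50L) {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) < 2) stop("need at least 2 points")
  if (damping < 0.5 || damping >= 1) stop("damping must be in [0.5, 1)")
  d2 <- as.matrix(stats::dist(vectors))^2
  s <- -d2
  off <- s[row(s) != col(s)]
  if (all(off == 0)) stop("all points identical; degenerate geometry")
  pref <- if (identical(preference, "median")) {
    stats::median(off)
  } else if (identical(preference, "min")) {
    min(off)
  } else {
    as.numeric(preference)
  }
  diag(s) <- pref
  structure(list(s = s, preference = pref, damping = damping,
                 max_iter = as.integer(max_iter),
                 conv_window = as.integer(conv_window)),
            class = "similarity_model")
}

#' Affinity propagation clustering
#'
#' Damped synchronous message passing. Availabilities start at zero;
#' responsibilities and availabilities are updated as
#' r(i,k) <- s(i,k) - max_{k' != k} (a(i,k') + s(i,k')),
#' a(i,k) <- min(0, r(k,k) + sum_{i' not in \{i,k\}} max(0, r(i',k))) and
#' a(k,k) <- sum_{i' != k} max(0, r(i',k)). Points with r(k,k) + a(k,k) > 0
#' become exemplars; every point is labeled by the exemplar maximizing
#' a(i,k) + r(i,k) (lowest index on ties), and exemplars label themselves.
#'
#' @param model a [build_similarity()] result.
#' @param seed optional seed; when given, a tiny similarity jitter breaks
#'   exact ties deterministically (and seeds the restart jitters).
#' @param restarts number of additional jittered runs; message passing has
#'   no optimality guarantee and can stall in a poor exemplar configuration
#'   on small or ambiguous instances, so (as with k-means starts) each
#'   restart perturbs the similarities by `jitter` x range and the candidate
#'   with the best net similarity on the unperturbed similarities is kept.
#'   0 runs the classic single deterministic pass.
#' @param jitter relative similarity perturbation used by restarts.
#' @return object of class `apc_result`: `exemplars`, `labels`,
#'   `responsibility`, `availability`, `iterations`, `converged`,
#'   `net_similarity`.
#' @export
affinity_propagation <- function(model, seed = NULL, restarts = 0L,
                                 jitter = 1e-2) {
  base <- ap_single(model, seed)
  base$net_similarity <- ap_net_similarity(model$s, base$exemplars,
                                           base$labels)
  if (restarts < 1) return(base)
  best <- base
  best_net <- base$net_similarity
  base_seed <- if (is.null(seed)) 0L else as.integer(seed)
  for (r in seq_len(restarts)) {
    jmod <- model
    rng <- diff(range(model$s))
    jit <- with_seed(child_seed(base_seed, r), {
      matrix(stats::rnorm(nrow(model$s)^2), nrow(model$s))
    })
    jmod$s <- model$s + jit * jitter * max(rng, .Machine$double.eps)
    cand <- ap_single(jmod, NULL)
    net <- ap_net_similarity(model$s, cand$exemplars, cand$labels)
    if (net > best_net) {
      best <- cand
      best_net <- net
    }
  }
  best$net_similarity <- best_net
  best
}

# Net similarity of a labeling on the original similarity matrix: each
# non-exemplar contributes its similarity to its exemplar, each exemplar its
# preference.
ap_net_similarity <- function(s, exemplars, labels) {
  idx <- setdiff(seq_len(nrow(s)), exemplars)
  val <- sum(diag(s)[exemplars])
  if (length(idx)) val <- val + sum(s[cbind(idx, labels[idx])])
  val
}

ap_single <- function(model, seed = NULL) {
  s <- model$s
  N <- nrow(s)
  if (!is.null(seed)) {
    rng <- diff(range(s))
    jit <- with_seed(seed, matrix(stats::rnorm(N * N), N, N))
    s <- s + jit * 1e-9 * max(rng, .Machine$double.eps)
  }
  if (N == 1) {
    return(structure(list(exemplars = 1L, labels = 1L,
                          responsibility = matrix(0, 1, 1),
                          availability = matrix(0, 1, 1),
                          iterations = 0L, converged = TRUE),
                     class = "apc_result"))
  }
  lam <- model$damping
  A <- matrix(0, N, N)
  R <- matrix(0, N, N)
  ex_prev <- integer(0)
  stable <- 0L
  it <- 0L
  converged <- FALSE
  while (it < model$max_iter) {
    it <- it + 1L
    # responsibilities
    AS <- A + s
    max1_idx <- max.col(AS, ties.method = "first")
    max1 <- AS[cbind(seq_len(N), max1_idx)]
    AS2 <- AS
    AS2[cbind(seq_len(N), max1_idx)] <- -Inf
    max2 <- apply(AS2, 1, max)
    Rnew <- s - max1
    Rnew[cbind(seq_len(N), max1_idx)] <- s[cbind(seq_len(N), max1_idx)] - max2
    R <- lam * R + (1 - lam) * Rnew
    # availabilities
    Rp <- pmax(R, 0)
    diag(Rp) <- 0
    cs <- colSums(Rp)
    Anew <- matrix(rep(diag(R) + cs, each = N), N, N) - Rp
    Anew <- pmin(Anew, 0)
    diag(Anew) <- cs
    A <- lam * A + (1 - lam) * Anew
    ex <- which(diag(R) + diag(A) > 0)
    if (identical(ex, ex_prev) && length(ex) > 0) {
      stable <- stable + 1L
      if (stable >= model$conv_window) {
        converged <- TRUE
        break
      }
    } else {
      stable <- 0L
      ex_prev <- ex
    }
  }
  ex <- which(diag(R) + diag(A) > 0)
  if (!length(ex)) ex <- which.max(diag(R) + diag(A))
  E <- A + R
  labels <- ex[max.col(E[, ex, drop = FALSE], ties.method = "first")]
  labels[ex] <- ex
  structure(list(exemplars = as.integer(ex), labels = as.integer(labels),
                 responsibility = R, availability = A,
                 iterations = it, converged = converged),
            class = "apc_result")
}

#' Summarize per-group state occupancy
#'
#' Counts, per state and group, how many windows were assigned to each
#' exemplar, and the within-group occupancy ratios (per group, ratios sum
#' to 1). State centroids are reported both as the exemplar vectors and as
#' per-state mean vectors.
#'
#' @param result an `apc_result`.
#' @param group_mask per-window group labels (length = points clustered).
#' @param vectors the clustered points (optional; enables centroids).
#' @return object of class `state_set`: `states` (exemplar indices),
#'   `counts` (state x group), `ratios`, `exemplar_vectors`, `centroids`.
#' @export
state_occupancy <- function(result, group_mask, vectors = NULL) {
  if (length(group_mask) != length(result$labels)) {
    stop("group mask length must equal the number of clustered windows")
  }
  states <- result$exemplars
  state_id <- match(result$labels, states)
  groups <- sort(unique(group_mask))
  counts <- table(factor(state_id, levels = seq_along(states)),
                  factor(group_mask, levels = groups))
  counts <- matrix(as.integer(counts), nrow = length(states),
                   dimnames = list(state = paste0("state", seq_along(states)),
                                   group = as.character(groups)))
  totals <- colSums(counts)
  ratios <- sweep(counts, 2, pmax(totals, 1L), "/")
  exemplar_vectors <- centroids <- NULL
  if (!is.null(vectors)) {
    vectors <- as.matrix(vectors)
    exemplar_vectors <- vectors[states, , drop = FALSE]
    centroids <- do.call(rbind, lapply(seq_along(states), function(k) {
      colMeans(vectors[state_id == k, , drop = FALSE])
    }))
    rownames(exemplar_vectors) <- rownames(centroids) <-
      paste0("state", seq_along(states))
  }
  structure(list(states = states, counts = counts, ratios = ratios,
                 exemplar_vectors = exemplar_vectors, centroids = centroids,
                 labels = state_id, n_states = length(states)),
            class = "state_set")
}

#' Match two state sets by centroid correlation
#'
#' Computes Pearson correlation between every pair of centroids and greedily
#' matches states one-to-one by descending correlation.
#'
#' @param a,b `state_set` objects (or plain centroid matrices).
#' @return list with `correlation` (full matrix), `pairs` (data.frame of
#'   matched a-state, b-state, correlation), `unmatched_a`, `unmatched_b`.
#' @export
match_state_sets <- function(a, b) {
  ca <- if (inherits(a, "state_set")) a$centroids else as.matrix(a)
  cb <- if (inherits(b, "state_set")) b$centroids else as.matrix(b)
  if (is.null(ca) || is.null(cb) || !nrow(ca) || !nrow(cb)) {
    stop("state sets must be non-empty with centroids")
  }
  cc <- stats::cor(t(ca), t(cb))
  avail_a <- seq_len(nrow(ca))
  avail_b <- seq_len(nrow(cb))
  pairs <- list()
  work <- cc
  while (length(avail_a) && length(avail_b)) {
    best <- which(work == max(work[avail_a, avail_b, drop = FALSE]),
                  arr.ind = TRUE)
    best <- best[best[, 1] %in% avail_a & best[, 2] %in% avail_b, ,
                 drop = FALSE][1, ]
    pairs[[length(pairs) + 1]] <- data.frame(
      a = best[1], b = best[2], correlation = cc[best[1], best[2]])
    avail_a <- setdiff(avail_a, best[1])
    avail_b <- setdiff(avail_b, best[2])
    work[best[1], ] <- -Inf
    work[, best[2]] <- -Inf
  }
  list(correlation = cc, pairs = do.call(rbind, pairs),
       unmatched_a = avail_a, unmatched_b = avail_b)
}
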