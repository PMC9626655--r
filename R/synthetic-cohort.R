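# Synthetic two-session cohort generator.
#
# Emulates the study design the pipeline targets: K subjects scanned twice
# (before/after), T timepoints per session at a fixed TR, a handful of spatial
# sources mixed into voxel data, and network time courses whose windowed
# covariance switches among a small set of planted connectivity states driven
# by a known Markov chain. Everything planted is recorded so downstream stages
# can be scored by parameter recovery.

#' Default planted connectivity states
#'
#' Four 6x6 correlation matrices with strongly distinct edge patterns over
#' two network triads ("front" = networks 1-3, "back" = networks 4-6):
#' front-coupled/back-anticoupled, the reverse, a cross-paired coupling
#' (network i with network i+3), and a doubly coupled state. All are
#' positive definite by construction (equicorrelation / permutation-coupling
#' blocks; minimum eigenvalue 0.2) and mutually well separated in vectorized
#' edge space (pairwise squared distance >= 4.3), which makes the windowed
#' correlation patterns identifiable at window widths of ~20 samples.
#'
#' @param n_sources number of sources; only 6 is supported for the defaults.
#' @return list of positive-definite correlation matrices with unit diagonal.
#' @export
default_state_covariances <- function(n_sources = 6) {
  if (n_sources != 6) {
    stop("default state covariances are defined for 6 sources; supply your own")
  }
  blk <- function(edges, r, m = diag(6)) {
    for (e in edges) {
      m[e[1], e[2]] <- r
      m[e[2], e[1]] <- r
    }
    m
  }
  front <- list(c(1, 2), c(1, 3), c(2, 3))
  back <- list(c(4, 5), c(4, 6), c(5, 6))
  paired <- list(c(1, 4), c(2, 5), c(3, 6))
  s1 <- blk(back, -0.4, blk(front, 0.8))
  s2 <- blk(back, 0.8, blk(front, -0.4))
  s3 <- blk(paired, 0.75, blk(back, -0.1, blk(front, -0.1)))
  s4 <- blk(back, 0.8, blk(front, 0.8))
  list(s1, s2, s3, s4)
}

#' Default session-1 state-transition matrix
#'
#' Moderately persistent symmetric chain over the planted states.
#'
#' @param n_states number of states.
#' @param self self-transition probability.
#' @return row-stochastic matrix.
#' @export
default_transition_matrix <- function(n_states = 4, self = 0.55) {
  off <- (1 - self) / (n_states - 1)
  m <- matrix(off, n_states, n_states)
  diag(m) <- self
  m
}

# Session-2 perturbation: one state's covariance is altered (the diffuse
# anti-correlated state becomes a globally integrated one) and the chain is
# re-weighted toward it, creating a true before/after difference.
session2_states <- function(states) {
  s4 <- matrix(0.35, 6, 6)
  diag(s4) <- 1
  states[[length(states)]] <- s4
  states
}

session2_transition <- function(n_states = 4) {
  m <- matrix(0, n_states, n_states)
  for (i in seq_len(n_states - 1)) {
    m[i, ] <- 0.2 / (n_states - 2)
    m[i, i] <- 0.5
    m[i, n_states] <- 0.3
  }
  m[n_states, ] <- 0.1
  m[n_states, n_states] <- 0.7
  m
}

#' Cohort configuration
#'
#' Collects the design parameters of a synthetic two-session cohort. Defaults
#' mirror the target study design: 33 subjects scanned before and after (66
#' sessions), 160 timepoints at TR 2 s, 6 spatial sources, and a sliding
#' window hint of 20 samples. States dwell for `segment_length` timepoints
#' (default 40, i.e. 80 s) so that most 20-sample windows cover a single
#' state.
#'
#' @param n_subjects number of subjects.
#' @param n_sessions sessions per subject (1 or 2).
#' @param T_len timepoints per session.
#' @param V voxel count of the synthetic grid.
#' @param n_sources number of planted spatial sources.
#' @param W_hint window width (samples) the dynamics should be identifiable at.
#' @param segment_length state dwell time in samples.
#' @param state_covariances list of positive-definite correlation matrices,
#'   one per planted state (session 1).
#' @param true_transition row-stochastic transition matrix (session 1).
#' @param state_covariances2,true_transition2 session-2 counterparts; defaults
#'   apply a built-in perturbation so the two sessions genuinely differ.
#' @param snr linear signal-to-noise variance ratio.
#' @param seed master integer seed.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 33, n_sessions = 2, T_len = 160,
                          V = 2000, n_sources = 6, W_hint = 20,
                          segment_length = 40,
                          state_covariances = default_state_covariances(),
                          true_transition = default_transition_matrix(
                            length(state_covariances)),
                          state_covariances2 = session2_states(
                            state_covariances),
                          true_transition2 = session2_transition(
                            length(state_covariances)),
                          snr = 10, seed = 1L) {
  cfg <- list(n_subjects = n_subjects, n_sessions = n_sessions,
              T_len = T_len, V = V, n_sources = n_sources, W_hint = W_hint,
              segment_length = segment_length,
              state_covariances = state_covariances,
              true_transition = true_transition,
              state_covariances2 = state_covariances2,
              true_transition2 = true_transition2,
              snr = snr, seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_subjects >= 1, cfg$n_sessions >= 1,
            cfg$n_sources >= 2, cfg$T_len > cfg$W_hint,
            cfg$snr > 0, cfg$segment_length >= cfg$W_hint / 2)
  for (s in c(cfg$state_covariances, cfg$state_covariances2)) {
    if (!is_spd(s)) stop("state covariance not symmetric positive-definite")
    if (max(abs(diag(s) - 1)) > 1e-12) {
      stop("state covariances must have unit diagonal")
    }
  }
  for (P in list(cfg$true_transition, cfg$true_transition2)) {
    if (!is_row_stochastic(P, tol = 1e-12)) {
      stop("transition matrix rows must sum to 1 (within 1e-12)")
    }
  }
  invisible(cfg)
}

#' Generate planted spatial source maps
#'
#' Places `n_sources` non-overlapping Gaussian blobs on a 1-D grid of V
#' voxels (a stand-in for localized resting-state network maps), adds a weak
#' two-sided Laplace background to each map, and standardizes each map to
#' zero mean and unit variance. The background makes the maps genuinely
#' independent across voxels (deterministic disjoint blobs are maximally
#' dependent — their pointwise product is zero — and blind separation then
#' legitimately prefers mixed directions), while the blob keeps each map
#' sparse / super-Gaussian and localized. Backgrounds are redrawn
#' (deterministically from the seed) until all pairwise |correlations| are
#' below 0.2, so the bound holds by construction.
#'
#' @param n_sources number of maps (>= 1).
#' @param V number of voxels (>= 10 * n_sources).
#' @param seed integer seed.
#' @return `n_sources` x `V` matrix, one standardized map per row.
#' @export
generate_spatial_sources <- function(n_sources, V, seed = 1L) {
  if (n_sources < 1) stop("n_sources must be >= 1")
  if (V < 10 * n_sources) {
    stop(sprintf("V = %d too small to place %d non-overlapping blobs",
                 V, n_sources))
  }
  grid <- seq_len(V)
  spacing <- V / n_sources
  for (attempt in seq_len(100L)) {
    maps <- with_seed(child_seed(seed, attempt - 1L), {
      centers <- (seq_len(n_sources) - 0.5) * spacing +
        stats::runif(n_sources, -0.05, 0.05) * spacing
      widths <- spacing / 10 * stats::runif(n_sources, 0.8, 1.2)
      m <- matrix(0, n_sources, V)
      for (k in seq_len(n_sources)) {
        blob <- exp(-0.5 * ((grid - centers[k]) / widths[k])^2)
        bg <- stats::rexp(V) * sign(stats::runif(V) - 0.5)
        row <- blob + 0.25 * bg
        row <- row - mean(row)
        m[k, ] <- row / stats::sd(row)
      }
      m
    })
    if (n_sources == 1) return(maps)
    cc <- stats::cor(t(maps))
    if (max(abs(cc[upper.tri(cc)])) < 0.2) return(maps)
  }
  stop(sprintf(
    "V = %d too small to generate %d sufficiently uncorrelated maps",
    V, n_sources))
}

#' Sample a segmented Markov state sequence
#'
#' Draws `n_segments` states from a first-order Markov chain (initial state
#' uniform) and holds each for `segment_length` timepoints, yielding
#' per-timepoint labels of length `n_segments * segment_length`.
#'
#' @param true_transition row-stochastic transition matrix.
#' @param n_segments number of dwell segments to sample.
#' @param segment_length dwell length in timepoints.
#' @param seed integer seed.
#' @return integer vector of per-timepoint state labels.
#' @export
generate_state_sequence <- function(true_transition, n_segments,
                                    segment_length, seed = 1L) {
  if (!is_row_stochastic(true_transition, tol = 1e-12)) {
    stop("transition matrix rows must sum to 1")
  }
  n_states <- nrow(true_transition)
  with_seed(seed, {
    states <- integer(n_segments)
    states[1] <- sample.int(n_states, 1)
    if (n_segments > 1) {
      for (g in 2:n_segments) {
        states[g] <- sample.int(n_states, 1,
                                prob = true_transition[states[g - 1], ])
      }
    }
    rep(states, each = segment_length)
  })
}

#' Generate state-switching network time courses
#'
#' Within each constant-state run of `state_labels`, rows are drawn from a
#' zero-mean multivariate normal with that state's covariance; columns are
#' then standardized to zero mean, unit variance over the whole session
#' (which leaves within-segment correlations untouched).
#'
#' @param state_labels per-timepoint integer labels of length T.
#' @param state_covariances list of covariance matrices indexed by label.
#' @param T_len number of timepoints (must equal `length(state_labels)`).
#' @param seed integer seed.
#' @return `T_len` x n matrix of time courses.
#' @export
generate_time_courses <- function(state_labels, state_covariances,
                                  T_len = length(state_labels), seed = 1L) {
  if (length(state_labels) != T_len) {
    stop("state_labels must have length T_len")
  }
  if (max(state_labels) > length(state_covariances) || min(state_labels) < 1) {
    stop("state label outside covariance index range")
  }
  chols <- lapply(state_covariances, function(s) {
    if (!is_spd(s)) stop("state covariance not positive-definite")
    chol(s)
  })
  n <- ncol(state_covariances[[1]])
  with_seed(seed, {
    runs <- rle(state_labels)
    out <- matrix(0, T_len, n)
    pos <- 1L
    for (k in seq_along(runs$lengths)) {
      len <- runs$lengths[k]
      st <- runs$values[k]
      z <- matrix(stats::rnorm(len * n), len, n)
      out[pos:(pos + len - 1L), ] <- z %*% chols[[st]]
      pos <- pos + len
    }
    scale_cols(out)
  })
}

#' Mix time courses into a noisy voxel-level session
#'
#' Forms X = time_courses %*% source_maps and adds white Gaussian noise
#' scaled so that var(signal) / var(noise) equals `snr`.
#'
#' @param source_maps n_sources x V matrix.
#' @param time_courses T x n_sources matrix.
#' @param snr linear signal-to-noise variance ratio (> 0).
#' @param seed integer seed.
#' @param subject,session identity tags carried on the result.
#' @return an object of class `subject_session`: list with `data` (T x V),
#'   `subject`, `session`.
#' @export
assemble_subject_session <- function(source_maps, time_courses, snr = 10,
                                     seed = 1L, subject = 1L, session = 1L) {
  if (snr <= 0) stop("snr must be > 0")
  stop_if_not_matrix(source_maps)
  stop_if_not_matrix(time_courses)
  if (ncol(time_courses) != nrow(source_maps)) {
    stop("time_courses and source_maps are not conformable")
  }
  signal <- time_courses %*% source_maps
  sd_noise <- sqrt(stats::var(as.vector(signal)) / snr)
  noise <- with_seed(seed, {
    matrix(stats::rnorm(length(signal), sd = sd_noise),
           nrow(signal), ncol(signal))
  })
  structure(list(data = signal + noise, subject = as.integer(subject),
                 session = as.integer(session), sd_noise = sd_noise),
            class = "subject_session")
}

#' Generate a full synthetic cohort with ground truth
#'
#' Produces `n_subjects * n_sessions` voxel-level sessions. All sessions
#' share the planted spatial maps; each subject-session has its own state
#' sequence drawn from that session's transition matrix and its own noise
#' realization. Session 2 (if present) uses the perturbed state set and
#' transition matrix from the configuration, creating a true before/after
#' contrast.
#'
#' @param config a [cohort_config()].
#' @return list with `sessions` (list of `subject_session`) and
#'   `ground_truth` (planted maps, mixings, label sequences, state sets,
#'   transition matrices, realized noise levels).
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  cfg <- config
  maps <- generate_spatial_sources(cfg$n_sources, cfg$V,
                                   seed = child_seed(cfg$seed, 1))
  n_seg <- ceiling(cfg$T_len / cfg$segment_length)
  sess_states <- list(cfg$state_covariances, cfg$state_covariances2)
  sess_trans <- list(cfg$true_transition, cfg$true_transition2)
  sessions <- vector("list", cfg$n_subjects * cfg$n_sessions)
  mixings <- vector("list", length(sessions))
  labels <- vector("list", length(sessions))
  noise_sd <- numeric(length(sessions))
  idx <- 0L
  for (i in seq_len(cfg$n_subjects)) {
    for (j in seq_len(cfg$n_sessions)) {
      idx <- idx + 1L
      base <- child_seed(cfg$seed, 1000L * i + 10L * j)
      lab <- generate_state_sequence(sess_trans[[min(j, 2)]], n_seg,
                                     cfg$segment_length,
                                     seed = child_seed(base, 1))
      lab <- lab[seq_len(cfg$T_len)]
      tc <- generate_time_courses(lab, sess_states[[min(j, 2)]],
                                  cfg$T_len, seed = child_seed(base, 2))
      ss <- assemble_subject_session(maps, tc, snr = cfg$snr,
                                     seed = child_seed(base, 3),
                                     subject = i, session = j)
      sessions[[idx]] <- ss
      mixings[[idx]] <- tc
      labels[[idx]] <- lab
      noise_sd[idx] <- ss$sd_noise
    }
  }
  ground_truth <- list(
    source_maps = maps,
    mixing_per_session = mixings,
    state_sequence_per_session = labels,
    noise_sd = noise_sd,
    state_covariances = sess_states[seq_len(min(cfg$n_sessions, 2))],
    transition_matrices = sess_trans[seq_len(min(cfg$n_sessions, 2))],
    subject = vapply(sessions, `[[`, integer(1), "subject"),
    session = vapply(sessions, `[[`, integer(1), "session"))
  list(sessions = sessions, ground_truth = ground_truth, config = cfg)
}

#' Per-window ground-truth state labels
#'
#' Labels each sliding window by the majority state among the timepoints it
#' covers (earliest state wins ties) and flags windows that straddle a state
#' switch. Used to score recovered window labels.
#'
#' @param state_labels per-timepoint labels.
#' @param W window width in samples.
#' @param step window step in samples.
#' @return data.frame with `window`, `label`, `pure` (no straddle).
#' @export
window_state_labels <- function(state_labels, W, step = 1L) {
  T_len <- length(state_labels)
  if (W > T_len) stop("W exceeds series length")
  starts <- seq(1L, T_len - W + 1L, by = step)
  lab <- integer(length(starts))
  pure <- logical(length(starts))
  for (k in seq_along(starts)) {
    seg <- state_labels[starts[k]:(starts[k] + W - 1L)]
    tab <- table(seg)
    best <- names(tab)[tab == max(tab)]
    first_best <- seg[seg %in% as.integer(best)][1]
    lab[k] <- as.integer(first_best)
    pure[k] <- length(tab) == 1L
  }
  data.frame(window = seq_along(starts), label = lab, pure = pure)
}
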