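test_that("spatial sources are standardized, sparse, and weakly correlated", {
  m1 <- generate_spatial_sources(1, 100, seed = 7)
  expect_equal(dim(m1), c(1, 100))
  expect_lt(abs(mean(m1[1, ])), 1e-9)
  expect_lt(abs(var(m1[1, ]) - 1), 1e-9)

  m6 <- generate_spatial_sources(6, 2000, seed = 1)
  cc <- cor(t(m6))
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.2)
  # super-Gaussian: positive excess kurtosis on every map
  kurt <- apply(m6, 1, function(x) mean(x^4) / mean(x^2)^2 - 3)
  expect_true(all(kurt > 1))

  expect_identical(generate_spatial_sources(3, 500, seed = 5),
                   generate_spatial_sources(3, 500, seed = 5))
  expect_error(generate_spatial_sources(6, 30, seed = 1), "too small")
})

test_that("state sequences follow the planted chain", {
  expect_equal(unique(generate_state_sequence(diag(2), 10, 5, seed = 1)),
               generate_state_sequence(diag(2), 10, 5, seed = 1)[1])
  alt <- generate_state_sequence(matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE),
                                 6, 10, seed = 2)
  seg <- alt[seq(1, length(alt), by = 10)]
  expect_true(all(abs(diff(seg)) == 1))
  expect_true(all(rle(alt)$lengths == 10))

  P <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE)
  lab <- generate_state_sequence(P, 10000, 1, seed = 3)
  est <- estimate_transition_matrix(lab, n_states = 2)
  expect_lt(max(abs(est$P - P)), 0.02)

  expect_error(generate_state_sequence(matrix(c(0.5, 0.2, 0.1, 0.9), 2, 2),
                                       5, 10),
               "sum to 1")
})

test_that("time courses realize the planted covariances", {
  id2 <- list(diag(2))
  tc <- generate_time_courses(rep(1L, 2000), id2, seed = 4)
  expect_equal(dim(tc), c(2000, 2))
  expect_lt(abs(cor(tc)[1, 2]), 0.08)

  s <- matrix(c(1, 0.8, 0.8, 1), 2, 2)
  tc2 <- generate_time_courses(rep(1L, 2000), list(s), seed = 5)
  expect_gt(cor(tc2)[1, 2], 0.75)
  expect_lt(cor(tc2)[1, 2], 0.85)

  bad <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(generate_time_courses(rep(1L, 50), list(bad)),
               "positive-definite")
  expect_error(generate_time_courses(rep(2L, 50), id2), "index range")
})

test_that("windowed correlation within a long segment converges to the state", {
  # at n = 500 the sampling sd of a near-zero correlation is ~0.045, so a
  # per-entry +-0.05 band is below noise for the 9 weak edges; the planted
  # strong couplings (sd <= 0.016) are held to +-0.05 per entry and the
  # whole matrix to +-0.05 on average
  states <- default_state_covariances()
  tc <- generate_time_courses(rep(2L, 500), states, seed = 6)
  err <- abs(cor(tc) - states[[2]])
  strong <- abs(states[[2]]) >= 0.75 & row(err) != col(err)
  expect_lt(max(err[strong]), 0.05)
  expect_lt(mean(err[upper.tri(err)]), 0.05)

  # convergence in segment length
  tc_long <- generate_time_courses(rep(2L, 5000), states, seed = 6)
  err_long <- abs(cor(tc_long) - states[[2]])
  expect_lt(mean(err_long[upper.tri(err_long)]),
            mean(err[upper.tri(err)]))
})

test_that("session assembly respects the signal-to-noise ratio", {
  maps <- generate_spatial_sources(3, 300, seed = 8)
  tc <- generate_time_courses(rep(1L, 100), list(diag(3)), seed = 9)
  clean <- tc %*% maps
  ss <- assemble_subject_session(maps, tc, snr = 1e9, seed = 10)
  expect_lt(norm(ss$data - clean, "F") / norm(clean, "F"), 1e-3)

  ss1 <- assemble_subject_session(maps, tc, snr = 1, seed = 11)
  ratio <- var(as.vector(clean)) / var(as.vector(ss1$data - clean))
  expect_gt(ratio, 0.9)
  expect_lt(ratio, 1.1)
  expect_error(assemble_subject_session(maps, tc, snr = 0), "snr")
})

test_that("default-shaped sessions are T x V", {
  cfg <- cohort_config(n_subjects = 1, n_sessions = 1, seed = 2)
  ch <- generate_cohort(cfg)
  expect_length(ch$sessions, 1)
  expect_equal(dim(ch$sessions[[1]]$data), c(160, 2000))
})

test_that("cohort generation is deterministic and well-formed", {
  cfg <- cohort_config(n_subjects = 3, n_sessions = 2, V = 120, seed = 13)
  ch <- generate_cohort(cfg)
  expect_length(ch$sessions, 6)
  expect_equal(ch$ground_truth$subject, rep(1:3, each = 2))
  expect_true(all(vapply(ch$ground_truth$state_sequence_per_session,
                         function(l) all(l >= 1 & l <= 4), logical(1))))
  ch2 <- generate_cohort(cfg)
  expect_identical(ch$sessions[[4]]$data, ch2$sessions[[4]]$data)
  ch3 <- generate_cohort(cohort_config(n_subjects = 3, n_sessions = 2,
                                       V = 120, seed = 14))
  expect_false(identical(ch$sessions[[1]]$data, ch3$sessions[[1]]$data))
})

test_that("cohort configuration is validated", {
  expect_error(cohort_config(snr = -1), "snr")
  expect_error(cohort_config(T_len = 10, W_hint = 20), "T_len > ")
  bad_states <- default_state_covariances()
  bad_states[[1]][1, 2] <- 0.99
  expect_error(cohort_config(state_covariances = bad_states), "symmetric")
  badP <- default_transition_matrix()
  badP[1, 1] <- 0.6
  expect_error(cohort_config(true_transition = badP), "sum to 1")
})

test_that("window labels flag straddling windows", {
  lab <- rep(c(1L, 2L), each = 40)
  wl <- window_state_labels(lab, 20)
  expect_equal(nrow(wl), 61)
  expect_true(all(wl$label[wl$window <= 21] == 1))
  expect_true(all(wl$label[wl$window >= 41] == 2))
  expect_false(any(wl$pure[wl$window > 21 & wl$window < 41]))
})
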