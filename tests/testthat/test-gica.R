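test_that("MDL order selection finds planted ranks", {
  mix1 <- make_mixture(1, 1000, 100, snr = 100, seed = 21)
  expect_equal(estimate_num_components(mix1$X), 1)

  mix5 <- make_mixture(5, 2000, 200, snr = 10, seed = 22)
  expect_equal(estimate_num_components(mix5$X), 5)

  set.seed(23)
  noise <- matrix(rnorm(100 * 1000), 100, 1000)
  expect_equal(estimate_num_components(noise), 0)

  expect_error(estimate_num_components(matrix(rnorm(20), 5, 4)), "V > T")
})

test_that("subject ICA recovers planted sources", {
  mix <- make_mixture(2, 500, 200, snr = 100, seed = 24)
  d <- fit_subject_ica(mix$X, 2, seed = 1)
  cc <- abs(cor(t(d$S), t(mix$maps)))
  expect_true(all(apply(cc, 2, max) > 0.99))
  expect_true(d$converged)
  # rows unit variance, positive skewness orientation
  expect_equal(unname(apply(d$S, 1, function(s) mean(s^2))), c(1, 1),
               tolerance = 1e-8)
  expect_true(all(rowMeans(d$S^3) > 0))
  # reconstruction within the whitened subspace
  Xc <- mix$X - rowMeans(mix$X)
  expect_lt(norm(Xc - d$M %*% d$S, "F") / norm(Xc, "F"), 0.2)
})

test_that("ICA of already-independent sources is a signed permutation", {
  # genuinely independent super-Gaussian sources: residual empirical
  # correlation is O(1/sqrt(V)), so recovery is near-exact
  set.seed(25)
  maps <- matrix(rexp(3 * 4000) * sign(runif(3 * 4000) - 0.5), 3, 4000)
  maps <- t(scale(t(maps)))
  d <- fit_subject_ica(maps, 3, seed = 2)
  cc <- abs(cor(t(d$S), t(maps)))
  expect_true(all(apply(cc, 2, max) > 0.999))
  expect_equal(sort(apply(cc, 2, which.max)), 1:3)
})

test_that("subject ICA is deterministic given the seed", {
  mix <- make_mixture(3, 400, 150, snr = 50, seed = 26)
  expect_identical(fit_subject_ica(mix$X, 3, seed = 7),
                   fit_subject_ica(mix$X, 3, seed = 7))
})

test_that("component matching selects and sign-aligns the right component", {
  mix <- make_mixture(4, 500, 150, snr = 50, seed = 27)
  d <- fit_subject_ica(mix$X, 4, seed = 1)
  template <- mix$maps[2, ]
  truth_idx <- which.max(abs(cor(t(d$S), template)))
  sel <- select_components_of_interest(list(d), template)
  expect_equal(sel$index, truth_idx)
  expect_gt(cor(sel$matched_maps[1, ], template), 0.95)

  exact <- select_components_of_interest(list(d), d$S[3, ])
  expect_equal(exact$index, 3)
  expect_equal(exact$correlation, 1, tolerance = 1e-12)

  set.seed(28)
  noise_dec <- structure(list(S = matrix(rnorm(4 * 500), 4, 500)),
                         class = "subject_decomposition")
  seln <- select_components_of_interest(list(noise_dec), template)
  expect_false(seln$matched[1])
  expect_true(is.na(seln$index[1]))
})

test_that("intrinsic reference extraction matches an SVD oracle", {
  set.seed(29)
  clean <- generate_spatial_sources(1, 400, seed = 30)[1, ]
  R <- do.call(rbind, lapply(1:50, function(i) {
    clean + rnorm(400, sd = sqrt(1 / 5))
  }))
  ref <- extract_intrinsic_reference(R)
  expect_gt(cor(ref$reference, clean), 0.99)
  expect_true(all(diff(ref$values) <= 1e-8))

  # independent oracle: first right singular vector of the centered matrix
  Rc <- R - rowMeans(R)
  v1 <- svd(Rc)$v[, 1]
  r_unit <- ref$reference / sqrt(sum(ref$reference^2))
  angle <- acos(min(1, abs(sum(r_unit * v1))))
  expect_lt(angle, 1e-8)

  one <- extract_intrinsic_reference(rbind(clean, clean, clean))
  expect_equal(abs(cor(one$reference, clean)), 1, tolerance = 1e-12)
  expect_error(extract_intrinsic_reference(matrix(0, 3, 10)), "zero")
})

test_that("constrained group ICA honors its constraints and recovers sources", {
  mix <- make_mixture(3, 600, 250, snr = 100, seed = 31)
  g <- fit_constrained_group_ica(mix$X, list(mix$maps[1, ]),
                                 params = gica_params(), n_whiten = 3)
  expect_gt(abs(cor(g$S[1, ], mix$maps[1, ])), 0.99)
  expect_lt(abs(mean(g$S[1, ]^2) - 1), 1e-6)
  expect_true(g$feasible[1])

  # inactive constraint reproduces the unconstrained solution
  d <- fit_subject_ica(mix$X, 3, seed = 1)
  g2 <- fit_constrained_group_ica(mix$X, list(mix$maps[1, ]),
                                  params = gica_params(xi = 10),
                                  n_whiten = 3)
  best <- which.max(abs(cor(t(d$S), mix$maps[1, ])))
  expect_gt(abs(cor(g2$S[1, ], d$S[best, ])), 0.99)

  # infeasible threshold is reported, not hidden
  set.seed(32)
  far_ref <- rnorm(600)
  expect_warning(
    g3 <- fit_constrained_group_ica(mix$X, list(far_ref),
                                    params = gica_params(xi = 1e-4),
                                    n_whiten = 3),
    "constraint")
  expect_false(g3$feasible[1])
  expect_gt(g3$constraint[1], 0)

  near_dup <- list(mix$maps[1, ], mix$maps[1, ] + 1e-6)
  expect_error(fit_constrained_group_ica(mix$X, near_dup), "distinct")
})

test_that("dual regression is exact on noiseless data and accurate at snr 10", {
  maps <- generate_spatial_sources(4, 500, seed = 33)
  set.seed(34)
  A <- matrix(rnorm(120 * 4), 120, 4)
  dr <- dual_regress(A %*% maps, maps)
  expect_lt(max(abs(dr$time_courses - A)), 1e-8)
  expect_equal(dim(dr$time_courses), c(120, 4))
  expect_equal(dim(dr$maps), c(4, 500))

  cfg <- cohort_config(n_subjects = 1, n_sessions = 1, V = 500, seed = 35)
  ch <- generate_cohort(cfg)
  drn <- dual_regress(ch$sessions[[1]]$data, ch$ground_truth$source_maps)
  cc <- abs(cor(drn$time_courses, ch$ground_truth$mixing_per_session[[1]]))
  expect_true(all(diag(cc) > 0.95))

  dup <- rbind(maps, maps[1, ])
  expect_error(dual_regress(A %*% maps, dup), "rank-deficient")
})

test_that("flipping a planted source's sign leaves recovery magnitudes alone", {
  mix <- make_mixture(2, 400, 150, snr = 100, seed = 36)
  flipped <- mix$maps
  flipped[1, ] <- -flipped[1, ]
  d <- fit_subject_ica(mix$X, 2, seed = 3)
  cc_orig <- abs(cor(t(d$S), t(mix$maps)))
  cc_flip <- abs(cor(t(d$S), t(flipped)))
  expect_equal(cc_orig, cc_flip, tolerance = 1e-12)
})
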