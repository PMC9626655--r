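test_that("similarity model uses negative squared distance and preferences", {
  two <- rbind(c(0, 0), c(2, 0))
  mod <- build_similarity(two, preference = -1)
  expect_equal(mod$s[1, 2], -4)

  dup <- rbind(c(1, 1), c(1, 1), c(3, 1))
  moddup <- build_similarity(dup)
  expect_equal(moddup$s[1, 2], 0)

  # points on a line at 0, 1, 3: pairwise similarities -1, -4, -9
  line <- cbind(c(0, 1, 3), 0)
  modl <- build_similarity(line, preference = "median")
  expect_equal(modl$preference, -4)
  expect_equal(unname(diag(modl$s)), rep(-4, 3))
  modm <- build_similarity(line, preference = "min")
  expect_equal(modm$preference, -9)

  expect_error(build_similarity(rbind(c(1, 1), c(1, 1))), "identical")
  expect_error(build_similarity(line, damping = 0.3), "damping")
})

test_that("affinity propagation handles degenerate and separable cases", {
  single <- structure(list(s = matrix(0, 1, 1), preference = 0,
                           damping = 0.9, max_iter = 10L,
                           conv_window = 2L),
                      class = "similarity_model")
  r1 <- affinity_propagation(single)
  expect_equal(r1$exemplars, 1L)
  expect_equal(r1$labels, 1L)

  set.seed(51)
  blobs <- rbind(matrix(rnorm(20, 0, 0.2), 10, 2),
                 matrix(rnorm(20, 10, 0.2), 10, 2))
  r2 <- affinity_propagation(build_similarity(blobs), seed = 1)
  expect_length(r2$exemplars, 2)
  expect_length(unique(r2$labels[1:10]), 1)
  expect_length(unique(r2$labels[11:20]), 1)
  expect_true(r2$converged)
  # every exemplar labels itself
  expect_equal(r2$labels[r2$exemplars], r2$exemplars)
})

test_that("affinity propagation matches the naive message-passing oracle", {
  set.seed(52)
  for (rep in 1:3) {
    pts <- matrix(rnorm(30 * 3), 30, 3) +
      matrix(sample(c(0, 4), 30 * 3, replace = TRUE), 30, 3)
    mod <- build_similarity(pts)
    mine <- affinity_propagation(mod)
    oracle <- naive_affinity_propagation(mod$s, damping = mod$damping,
                                         max_iter = mod$max_iter,
                                         conv_window = mod$conv_window)
    expect_identical(mine$labels, as.integer(oracle$labels))
    expect_identical(mine$exemplars, as.integer(oracle$exemplars))
  }
})

test_that("damping 0.5 and 0.9 agree on well-separated instances", {
  set.seed(53)
  pts <- rbind(cbind(rnorm(12, 0, 0.3), rnorm(12, 0, 0.3)),
               cbind(rnorm(12, 8, 0.3), rnorm(12, 8, 0.3)),
               cbind(rnorm(12, 0, 0.3), rnorm(12, 16, 0.3)))
  r_low <- affinity_propagation(build_similarity(pts, damping = 0.5))
  r_high <- affinity_propagation(build_similarity(pts, damping = 0.9))
  expect_equal(length(r_low$exemplars), length(r_high$exemplars))
  expect_equal(adjusted_rand_index(r_low$labels, r_high$labels), 1)
})

test_that("state occupancy counts and ratios are conserved", {
  set.seed(54)
  pts <- rbind(matrix(rnorm(30, 0, 0.2), 15, 2),
               matrix(rnorm(30, 6, 0.2), 15, 2))
  res <- affinity_propagation(build_similarity(pts))
  groups <- rep(c("pre", "post"), 15)
  occ <- state_occupancy(res, groups, vectors = pts)
  expect_equal(sum(occ$counts), 30)
  expect_equal(unname(colSums(occ$ratios)), c(1, 1))
  expect_equal(nrow(occ$centroids), occ$n_states)

  one_state <- structure(list(labels = rep(3L, 8), exemplars = 3L),
                         class = "apc_result")
  occ1 <- state_occupancy(one_state, rep(c("pre", "post"), 4))
  expect_equal(unname(occ1$ratios[1, ]), c(1, 1))
  expect_error(state_occupancy(one_state, rep("pre", 5)), "length")
})

test_that("occupancy of a planted 2-state run tracks dwell fractions", {
  states <- list(matrix(c(1, 0.8, 0.8, 1), 2, 2),
                 matrix(c(1, -0.8, -0.8, 1), 2, 2))
  lab <- rep(rep(1:2, 8), each = 60)[1:900]
  tc <- generate_time_courses(lab, states, seed = 55)
  wl <- window_state_labels(lab, 20)
  dv <- assemble_dfc_vector_set(sliding_window_dfc(tc, 20))
  keep <- which(wl$pure & wl$window %in% seq(1, nrow(dv), by = 20))
  res <- affinity_propagation(build_similarity(dv[keep, ],
                                               preference = "min"),
                              seed = 2)
  occ <- state_occupancy(res, rep("all", length(keep)), vectors = dv[keep, ])
  expect_equal(occ$n_states, 2)
  planted_frac <- mean(wl$label[keep] == 1)
  expect_lt(max(abs(sort(occ$ratios[, 1]) -
                    sort(c(planted_frac, 1 - planted_frac)))), 0.1)
})

test_that("state-set matching recovers permutations", {
  set.seed(56)
  a <- matrix(rnorm(4 * 15), 4, 15)
  perm <- c(3, 1, 4, 2)
  b <- a[perm, ] + matrix(rnorm(4 * 15, sd = 0.05), 4, 15)
  m <- match_state_sets(a, b)
  expect_true(all(m$correlation >= -1 & m$correlation <= 1))
  got <- m$pairs[order(m$pairs$a), "b"]
  expect_equal(got, order(perm))
  expect_true(all(m$pairs$correlation > 0.9))

  ident <- match_state_sets(a, a)
  expect_equal(ident$pairs$a, ident$pairs$b)
  expect_equal(ident$pairs$correlation, rep(1, 4), tolerance = 1e-12)
})

test_that("adjusted Rand index behaves at its anchors", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  set.seed(57)
  x <- sample(1:3, 300, replace = TRUE)
  y <- sample(1:3, 300, replace = TRUE)
  expect_lt(abs(adjusted_rand_index(x, y)), 0.1)
})
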