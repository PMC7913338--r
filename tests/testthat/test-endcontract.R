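test_that("obstruction-free contractions shortcut straight to the target", {
  P <- cbind(1:6, 0, 0)
  ec <- end_contraction_path(morph_chain(P), 4, "N")
  expect_equal(ec$cost, 3 + 2 + 1)
  expect_equal(ec$obstructions, 0L)
  # fractional target: only P1 moves
  ec2 <- end_contraction_path(morph_chain(P), 1.5, "N")
  expect_equal(ec2$cost, 0.5)
  # C-side mirror
  ec3 <- end_contraction_path(morph_chain(P), 3, "C")
  expect_equal(ec3$cost, 3 + 2 + 1)
  # a_j at the terminus: empty contraction
  expect_equal(end_contraction_path(morph_chain(P), 1, "N")$cost, 0)
})

test_that("a blocked tail inserts obstruction points with clearance", {
  # N-tail bent behind a crossing strand: pulling P1..P3 straight to the
  # target would sweep through the downstream hook
  P <- rbind(c(0, 6, 0), c(0, 2, 0), c(4, 0.5, 0), c(8, 0, 0),
             c(12, 0, 0), c(16, 0, 0), c(16, 4, 0), c(7, 2.5, 3),
             c(5, 1.5, -3), c(2, 5, -4))
  ec <- end_contraction_path(morph_chain(P), 5, "N")
  straight <- sum(sqrt(rowSums((P[1:5, ] -
                                matrix(P[5, ], 5, 3, byrow = TRUE))^2)))
  expect_gte(ec$obstructions, 1L)
  expect_gt(ec$cost, straight)
  # every route leg keeps clearance from the downstream curve
  route <- ec$route
  trimmed <- eval_curve(P, 5.05)[1, ]   # the path may touch the target itself
  down0 <- rbind(trimmed, P[6:9, ])
  down1 <- P[6:10, ]
  for (q in seq_len(nrow(route) - 1)) {
    for (s in seq_len(nrow(down0))) {
      d <- morphcheck:::seg_seg_distance(route[q, ], route[q + 1, ],
                                         down0[s, ], down1[s, ])
      expect_gt(d, 1e-6)
    }
  }
})

test_that("contraction cost is bounded below by straight-line distances", {
  set.seed(81)
  for (rep in 1:20) {
    P <- random_chain_points(12)
    a <- stats::runif(1, 2, 6)
    ec <- end_contraction_path(morph_chain(P), a, "N")
    target <- eval_curve(P, a)[1, ]
    lower <- sum(sqrt(rowSums((P[seq_len(ec$m), , drop = FALSE] -
                               matrix(target, ec$m, 3, byrow = TRUE))^2)))
    expect_gte(ec$cost + 1e-9, lower)
  }
})

test_that("the ramp estimator has the stated closed form", {
  expect_equal(estimate_contraction_cost(0), 0)
  expect_equal(estimate_contraction_cost(17), 225)
  expect_equal(estimate_contraction_cost(20), 300)
  expect_equal(estimate_contraction_cost(5), 25 * 15 / 17)
  expect_true(all(diff(estimate_contraction_cost(0:30)) >= 0))
})

test_that("the n+1 candidate pairs attain the constrained optimum", {
  pair <- make_crossing_change_pair(100)
  mo <- build_morph(pair$chain0$points, pair$chain1$points)
  si <- find_intersections(mo)$intersections[[1]]
  # no essentials: no contraction
  none <- optimize_end_contractions(list(), mo)
  expect_equal(none$cost, 0)
  best <- optimize_end_contractions(list(si), mo, use_estimates = TRUE)
  expect_true(is.finite(best$cost))
  # dense scan over feasible (a, b) with the same cost function
  grid_best <- Inf
  for (a in seq(1, mo$m - 1, by = 2.5)) {
    b <- if (si$a <= a) mo$m else min(si$b, mo$m)
    if (a >= b) next
    cn <- morphcheck:::.contraction_cost(mo, a, "N", TRUE)
    cc <- morphcheck:::.contraction_cost(mo, b, "C", TRUE)
    grid_best <- min(grid_best, cn$cost + cc$cost)
  }
  expect_lte(best$cost, grid_best + 1e-9)
})

test_that("multiple essentials are covered by the candidate enumeration", {
  set.seed(82)
  # smoothly varying displacement field, as in a rigid-ish domain motion
  c0 <- random_chain_points(30)
  c1 <- c0 + outer(2 + sin(seq(0, 3, length.out = 30)), c(2, 1, 0.5))
  mo <- build_morph(c0, c1)
  ess <- list(list(a = 4.3, b = 9.2), list(a = 11.5, b = 26.8),
              list(a = 17.2, b = 22.4))
  best <- optimize_end_contractions(ess, mo, use_estimates = TRUE)
  expect_true(is.finite(best$cost))
  # the chosen (a, b) satisfies every covering constraint
  for (e in ess)
    expect_true(e$a <= best$a + 1e-9 || best$b <= e$b + 1e-9)
  # dense feasible grid cannot beat the candidate set
  grid_best <- Inf
  av <- vapply(ess, `[[`, 0, "a")
  bv <- vapply(ess, `[[`, 0, "b")
  for (a in seq(1, mo$m - 1, by = 0.5)) {
    uncovered <- av > a
    b <- min(c(bv[uncovered], mo$m))
    if (a >= b) next
    cn <- morphcheck:::.contraction_cost(mo, a, "N", TRUE)
    cc <- morphcheck:::.contraction_cost(mo, b, "C", TRUE)
    grid_best <- min(grid_best, cn$cost + cc$cost)
  }
  expect_lte(best$cost, grid_best + 1e-9)
})

test_that("end-proximal intersections take the cheaper removal price", {
  pair <- make_loop_fixtures("removable_loop")
  mo <- build_morph(pair$chain0$points, pair$chain1$points)
  si <- find_intersections(mo)$intersections[[1]]
  o1 <- omega1_candidate(si, mo, max_length = 10)
  # mid-chain window: unchanged
  same <- terminal_omega1_price(si, mo, o1, window = 0.5)
  expect_identical(same, o1)
  # generous window: price can only improve
  upd <- terminal_omega1_price(si, mo, o1, window = 10, use_estimates = TRUE)
  expect_true(upd$feasible)
  expect_lte(upd$price, o1$price + 1e-9)
  # infeasible Omega_1 near a terminus becomes removable via contraction
  blocked <- omega1_candidate(si, mo, max_length = 0.5)
  upd2 <- terminal_omega1_price(si, mo, blocked, window = 10,
                                use_estimates = TRUE)
  expect_true(upd2$feasible)
  expect_true(upd2$via_end_contraction)
})
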