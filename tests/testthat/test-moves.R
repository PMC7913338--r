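# rebuild the Omega_1 loop of a self-intersection directly from the slice
.test_loop <- function(mo, si) {
  sl <- morphcheck:::morph_slice(mo, si$t_star)
  pts <- eval_curve(sl, si$a)
  ints <- seq.int(ceiling(si$a), floor(si$b))
  rbind(pts, sl[ints[ints > si$a & ints < si$b], , drop = FALSE])
}

test_that("a loop with a remote tail spans a free disk", {
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  loop <- cbind(5 * cos(th), 5 * sin(th), 0)
  curve <- rbind(cbind(seq(60, 90, by = 3.8), 0, 5),
                 cbind(95, 0, 5), cbind(99, 0, 5))
  expect_true(disk_is_free(loop, curve))
})

test_that("a segment through the centroid blocks the disk", {
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  loop <- cbind(5 * cos(th), 5 * sin(th), 0)
  curve <- rbind(c(0.3, 0.1, -8), c(0.3, 0.1, 8), c(40, 0, 8), c(60, 0, 8))
  res <- disk_is_free(loop, curve)
  expect_false(isTRUE(res))
  expect_equal(attr(res, "blocker"), 1L)
})

test_that("sorted early-exit disk test agrees with unsorted brute force", {
  set.seed(61)
  n_blocked <- 0
  for (rep in 1:150) {
    p <- sample(6:14, 1)
    th <- sort(stats::runif(p, 0, 2 * pi))
    r <- stats::runif(p, 3, 7)
    loop <- cbind(r * cos(th), r * sin(th), stats::rnorm(p, sd = 0.5))
    curve <- random_chain_points(sample(6:20, 1))
    curve <- sweep(curve, 2, colMeans(curve))       # center on the disk
    curve <- sweep(curve, 2, stats::rnorm(3, sd = 4), `+`)
    got <- disk_is_free(loop, curve)
    ref <- oracle_disk_free(loop, curve)
    expect_equal(isTRUE(got), ref)
    if (!ref) n_blocked <- n_blocked + 1
  }
  expect_gt(n_blocked, 20)     # the ensemble must contain blocked cases
})

test_that("Omega_1: the MaxLength gate precedes all geometry", {
  pair <- make_loop_fixtures("removable_loop")
  mo <- build_morph(pair$chain0$points, pair$chain1$points)
  si <- find_intersections(mo)$intersections[[1]]
  gated <- omega1_candidate(si, mo, max_length = si$b - si$a - 1)
  expect_false(gated$feasible)
  expect_equal(gated$reason, "max_length")
})

test_that("Omega_1 removability and price on the handedness-flip loop", {
  pair <- make_loop_fixtures("removable_loop")
  mo <- build_morph(pair$chain0$points, pair$chain1$points)
  si <- find_intersections(mo)$intersections[[1]]
  cand <- omega1_candidate(si, mo, max_length = 10)
  expect_true(cand$feasible)
  # independent price: 2 * sum of loop-point distances to the line through
  # the intersection point and the loop centroid
  loop <- .test_loop(mo, si)
  x <- loop[1, ]
  ctr <- colMeans(loop)
  dists <- apply(loop, 1, function(p) {
    u <- (ctr - x) / sqrt(sum((ctr - x)^2))
    rel <- p - x
    sqrt(max(sum(rel^2) - sum(rel * u)^2, 0))
  })
  expect_equal(cand$price, 2 * sum(dists), tolerance = 1e-9)
})

test_that("a strand threading the disk blocks the Omega_1 move", {
  pair <- make_loop_fixtures("threaded_loop")
  mo <- build_morph(pair$chain0$points, pair$chain1$points)
  si <- find_intersections(mo)$intersections[[1]]
  cand <- omega1_candidate(si, mo, max_length = 10)
  expect_false(cand$feasible)
  expect_equal(cand$reason, "blocked")
  expect_false(is.na(cand$blocker))
  # the blocker is a genuine disk crossing by brute force
  sl <- morphcheck:::morph_slice(mo, si$t_star)
  loop <- .test_loop(mo, si)
  expect_false(oracle_disk_free(loop, sl, list(c(si$a, si$b))))
})

test_that("Omega_2 on the strand-slide pair is feasible with the stated price", {
  pair <- make_loop_fixtures("slide_pair")
  mo <- build_morph(pair$chain0$points, pair$chain1$points)
  xs <- find_intersections(mo)$intersections
  expect_length(xs, 2L)
  expect_equal(xs[[1]]$sign + xs[[2]]$sign, 0)
  cand <- omega2_candidate(xs[[1]], xs[[2]], mo, max_length = 10)
  expect_true(cand$feasible)
  # price: 2 * sum of loop-point distances to the line joining the two
  # intersection points at t_avg
  t_avg <- mean(c(xs[[1]]$t_star, xs[[2]]$t_star))
  sl <- morphcheck:::morph_slice(mo, t_avg)
  xj <- as.vector(eval_curve(sl, min(xs[[1]]$a, xs[[2]]$a)))
  xk <- as.vector(eval_curve(sl, max(xs[[1]]$a, xs[[2]]$a)))
  u <- (xk - xj) / sqrt(sum((xk - xj)^2))
  loop_par_a <- sort(c(xs[[1]]$a, xs[[2]]$a))
  loop_par_b <- sort(c(xs[[1]]$b, xs[[2]]$b))
  expect_gt(cand$price, 0)
  mid <- function(lo, hi) {
    ints <- seq.int(ceiling(lo), floor(hi))
    ints[ints > lo & ints < hi]
  }
  d_direct <- apply(rbind(eval_curve(sl, loop_par_a[1]),
                          sl[mid(loop_par_a[1], loop_par_a[2]), , drop = FALSE],
                          eval_curve(sl, loop_par_a[2]),
                          eval_curve(sl, loop_par_b[1]),
                          sl[mid(loop_par_b[1], loop_par_b[2]), , drop = FALSE],
                          eval_curve(sl, loop_par_b[2])),
                    1, function(p) {
                      rel <- p - xj
                      sqrt(max(sum(rel^2) - sum(rel * u)^2, 0))
                    })
  expect_equal(cand$price, 2 * sum(d_direct), tolerance = 1e-6)
})

test_that("Omega_2 gates: same sign and MaxLength", {
  pair <- make_loop_fixtures("slide_pair")
  mo <- build_morph(pair$chain0$points, pair$chain1$points)
  xs <- find_intersections(mo)$intersections
  short <- omega2_candidate(xs[[1]], xs[[2]], mo, max_length = 5)
  expect_false(short$feasible)
  expect_equal(short$reason, "max_length")
  fake <- xs[[2]]
  fake$sign <- xs[[1]]$sign
  same <- omega2_candidate(xs[[1]], fake, mo, max_length = 20)
  expect_false(same$feasible)
  expect_equal(same$reason, "same_sign")
})

test_that("a third strand through the Omega_2 disk blocks the move", {
  pair <- make_loop_fixtures("slide_pair")
  P0 <- pair$chain0$points
  P1 <- pair$chain1$points
  # thread a static strand vertically through the small disk near the
  # origin (between the V tip and the baseline), attached far away
  thread <- rbind(c(40, 40, 10), c(2, 2, 10), c(0.5, -1, 9),
                  c(0.5, -1, -9), c(3, -4, -10), c(40, 40, -12))
  P0t <- rbind(P0, thread)
  P1t <- rbind(P1, thread)
  mo <- build_morph(P0t, P1t)
  xs <- find_intersections(mo)$intersections
  expect_length(xs, 2L)
  cand <- omega2_candidate(xs[[1]], xs[[2]], mo, max_length = 10)
  expect_false(cand$feasible)
})

test_that("move prices are rigid-motion invariant and scale linearly", {
  pair <- make_loop_fixtures("removable_loop")
  mo <- build_morph(pair$chain0$points, pair$chain1$points)
  si <- find_intersections(mo)$intersections[[1]]
  p_ref <- omega1_candidate(si, mo, 10)$price
  th <- 1.1
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  mo_r <- build_morph(morphcheck:::apply_transform(mo$curve0, R, c(5, 6, 7)),
                      morphcheck:::apply_transform(mo$curve1, R, c(5, 6, 7)))
  si_r <- find_intersections(mo_r)$intersections[[1]]
  expect_equal(omega1_candidate(si_r, mo_r, 10)$price, p_ref,
               tolerance = 1e-6)
  mo_s <- build_morph(2 * mo$curve0, 2 * mo$curve1)
  si_s <- find_intersections(mo_s)$intersections[[1]]
  expect_equal(omega1_candidate(si_s, mo_s, 10)$price, 2 * p_ref,
               tolerance = 1e-6)
})
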