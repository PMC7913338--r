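mk_o1 <- function(feasible, price = NA_real_, k = 1L, len = 3) {
  structure(list(kind = "omega1", members = k, backbone_length = len,
                 feasible = feasible, price = price),
            class = "move_candidate")
}

mk_o2 <- function(vi, vj, price, len = 5, feasible = TRUE) {
  structure(list(kind = "omega2", members = c(vi, vj),
                 backbone_length = len, feasible = feasible, price = price),
            class = "move_candidate")
}

mk_sis <- function(n) lapply(seq_len(n), function(k) list(k = k, t_star = k / (n + 1)))

test_that("move-graph weights follow the epsilon construction", {
  # no intersections: empty graph
  g0 <- build_move_graph(list(), list(), list())
  expect_equal(g0$K, 0L)
  expect_equal(nrow(g0$edges), 0L)
  # one Omega_1-feasible vertex of price 4: eps = 1/8, w_v = 1/2
  g1 <- build_move_graph(mk_sis(1), list(mk_o1(TRUE, 4)), list())
  expect_equal(g1$epsilon, 1 / 8)
  expect_equal(g1$w_v, 0.5)
  expect_equal(g1$K, 0L)
  # mixed 4-vertex instance checked against hand computation
  o1 <- list(mk_o1(TRUE, 10, 1), mk_o1(FALSE, k = 2), mk_o1(TRUE, 6, 3),
             mk_o1(FALSE, k = 4))
  o2 <- list(mk_o2(1, 2, 8), mk_o2(3, 4, 12))
  g <- build_move_graph(mk_sis(4), o1, o2)
  eps <- 1 / (2 * (10 + 6 + 8 + 12))
  expect_equal(g$epsilon, eps)
  expect_equal(g$w_v, c(eps * 10, 1, eps * 6, 1))
  expect_equal(g$K, 2L)
  expect_equal(g$p1_all, 16)
  w <- setNames(g$edges$weight, paste(g$edges$vi, g$edges$vj))
  expect_equal(unname(w["1 2"]), eps * 10 + 1 - eps * 8)
  expect_equal(unname(w["3 4"]), eps * 6 + 1 - eps * 12)
})

test_that("degenerate graphs: no moves means every vertex is essential", {
  g <- build_move_graph(mk_sis(3), list(mk_o1(FALSE, k = 1), mk_o1(FALSE, k = 2),
                                        mk_o1(FALSE, k = 3)), list())
  expect_equal(g$epsilon, 0)
  res <- solve_essential(g)
  expect_equal(res$n_essential, 3L)
  expect_equal(res$total_price, 0)
})

test_that("the matching prefers an Omega_2 over a blocking Omega_1", {
  # v4 is Omega_1-feasible and shares a feasible Omega_2 edge with the
  # non-removable v5: using the edge removes both, using Omega_1 leaves v5
  o1 <- list(mk_o1(TRUE, 5, 1), mk_o1(FALSE, k = 2))
  o2 <- list(mk_o2(1, 2, 9))
  g <- build_move_graph(mk_sis(2), o1, o2)
  res <- solve_essential(g, "optimal")
  expect_equal(res$n_essential, 0L)
  expect_equal(nrow(res$matching), 1L)
  expect_length(res$omega1_used, 0)
  expect_equal(res$total_price, 9)
})

test_that("optimal matching equals exhaustive enumeration on random graphs", {
  set.seed(71)
  for (rep in 1:50) {
    g <- random_move_graph(sample(2:9, 1), edge_prob = 0.45)
    if (nrow(g$edges) > 14) next
    res <- solve_essential(g, "optimal")
    ref <- oracle_best_matching(g)
    expect_equal(res$n_essential, ref$N)
    expect_equal(res$total_price, ref$price, tolerance = 1e-9)
    # the A(E') identity at the optimum
    expect_equal(res$objective,
                 g$K + g$epsilon * g$p1_all - sum(res$matching$weight),
                 tolerance = 1e-12)
  }
})

test_that("the A(E') identity holds for arbitrary matchings", {
  set.seed(72)
  for (rep in 1:40) {
    g <- random_move_graph(sample(3:8, 1), edge_prob = 0.5)
    ed <- g$edges
    if (nrow(ed) == 0) next
    # random greedy matching (not the optimum)
    sel <- integer(0)
    used <- rep(FALSE, g$n_vertices)
    for (k in sample(nrow(ed))) {
      if (!used[ed$vi[k]] && !used[ed$vj[k]]) {
        sel <- c(sel, k)
        used[c(ed$vi[k], ed$vj[k])] <- TRUE
      }
    }
    matched <- c(ed$vi[sel], ed$vj[sel])
    o1_used <- setdiff(which(g$omega1_feasible), matched)
    N <- g$n_vertices - length(matched) - length(o1_used)
    P <- sum(ed$price[sel]) + sum(g$p1[o1_used])
    expect_equal(N + g$epsilon * P,
                 g$K + g$epsilon * g$p1_all - sum(ed$weight[sel]),
                 tolerance = 1e-10)
    expect_gte(g$epsilon * P, 0)
    expect_lte(g$epsilon * P, 0.5 + 1e-12)
  }
})

test_that("optimal N is invariant under positive price rescaling", {
  set.seed(73)
  for (rep in 1:10) {
    nv <- sample(3:7, 1)
    sis <- mk_sis(nv)
    feas <- stats::runif(nv) < 0.5
    p1 <- ifelse(feas, stats::runif(nv, 1, 40), NA)
    mk <- function(scale) {
      o1 <- lapply(seq_len(nv), function(k) mk_o1(feas[k], scale * p1[k], k))
      o2 <- list(mk_o2(1, 2, scale * 7), mk_o2(2, 3, scale * 9))
      build_move_graph(sis, o1, o2)
    }
    n1 <- solve_essential(mk(1))$n_essential
    n2 <- solve_essential(mk(137.5))$n_essential
    expect_equal(n1, n2)
  }
})

test_that("greedy by backbone length can be strictly worse than optimal", {
  # path v1 - v2 - v3 - v4 where the middle edge is shortest: greedy takes
  # it and strands v1 and v4; optimal takes the two outer edges
  o1 <- lapply(1:4, function(k) mk_o1(FALSE, k = k))
  o2 <- list(mk_o2(1, 2, price = 5, len = 6),
             mk_o2(2, 3, price = 5, len = 2),
             mk_o2(3, 4, price = 5, len = 6))
  g <- build_move_graph(mk_sis(4), o1, o2)
  opt <- solve_essential(g, "optimal")
  grd <- solve_essential(g, "greedy")
  expect_equal(opt$n_essential, 0L)
  expect_equal(grd$n_essential, 2L)
  expect_gte(grd$n_essential, opt$n_essential)
})
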