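# Independent oracles used by the unit and acceptance tests.  Each oracle
# deliberately takes a route different from the package implementation:
# dense grids and bisection instead of closed forms, exhaustive enumeration
# instead of branch-and-bound, numerical optimization instead of SVD.

# dense-grid minimization of the pairwise distance over the interpolation
oracle_pair_min <- function(p0i, p0j, p1i, p1j, step = 1e-4) {
  v0 <- p0j - p0i
  v1 <- p1j - p1i
  dfun <- function(t) sqrt(((1 - t) * v0[1] + t * v1[1])^2 +
                           ((1 - t) * v0[2] + t * v1[2])^2 +
                           ((1 - t) * v0[3] + t * v1[3])^2)
  ts <- seq(0, 1, by = step)
  ds <- dfun(ts)
  i <- which.min(ds)
  # Brent refinement on the bracketing cell (the sqrt has unbounded
  # curvature at near-zero minima, so the bare grid is not enough)
  lo <- ts[max(i - 1L, 1L)]
  hi <- ts[min(i + 1L, length(ts))]
  if (lo >= hi) return(ds[i])
  min(ds[i], stats::optimize(dfun, c(lo, hi), tol = 1e-12)$objective)
}

# determinant of the segment-pair frame evaluated pointwise on a t grid
.oracle_dets <- function(morph, i, j, ts) {
  rows <- c(i, i + 1L, j, j + 1L)
  S0 <- morph$curve0[rows, , drop = FALSE]
  S1 <- morph$curve1[rows, , drop = FALSE]
  comp <- function(r) cbind((1 - ts) * S0[r, 1] + ts * S1[r, 1],
                            (1 - ts) * S0[r, 2] + ts * S1[r, 2],
                            (1 - ts) * S0[r, 3] + ts * S1[r, 3])
  P_i <- comp(1L); P_i1 <- comp(2L); P_j <- comp(3L); P_j1 <- comp(4L)
  u <- P_i1 - P_i
  v <- P_j1 - P_j
  w <- P_i - P_j
  u[, 1] * (v[, 2] * w[, 3] - v[, 3] * w[, 2]) -
    u[, 2] * (v[, 1] * w[, 3] - v[, 3] * w[, 1]) +
    u[, 3] * (v[, 1] * w[, 2] - v[, 2] * w[, 1])
}

# dense-time-sampling self-intersection detector: sign tracking of the
# pointwise determinant plus bisection, with a segment-distance containment
# test at the refined root
oracle_intersections <- function(morph, coarse = 1e-3, contain_tol = 1e-6) {
  m <- morph$m
  ts <- seq(0, 1, by = coarse)
  out <- list()
  for (i in seq_len(m - 3L)) {
    for (j in seq.int(i + 2L, m - 1L)) {
      dets <- .oracle_dets(morph, i, j, ts)
      sgn <- sign(dets)
      flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
      for (q in flips) {
        f <- function(t) .oracle_dets(morph, i, j, t)
        root <- stats::uniroot(f, c(ts[q], ts[q + 1L]), tol = 1e-13)$root
        sl <- (1 - root) * morph$curve0[c(i, i + 1L, j, j + 1L), ] +
              root * morph$curve1[c(i, i + 1L, j, j + 1L), ]
        cl <- morphcheck:::seg_seg_closest(sl[1, ], sl[2, ], sl[3, ], sl[4, ])
        if (cl$distance < contain_tol) {
          out[[length(out) + 1L]] <- list(
            a = i + cl$s, b = j + cl$t, t_star = root,
            sign = sign(dets[q + 1L] - dets[q]), i = i, j = j)
        }
      }
    }
  }
  if (length(out) > 1L) {
    ord <- order(vapply(out, `[[`, 0, "t_star"), vapply(out, `[[`, 0, "a"))
    out <- out[ord]
  }
  out
}

# unsorted all-pairs disk-freeness test (no early exit)
oracle_disk_free <- function(loop, curve, exclude = list()) {
  centroid <- colMeans(loop)
  p <- nrow(loop)
  nxt <- c(seq_len(p)[-1L], 1L)
  segs <- morphcheck:::.remainder_segments(nrow(curve), exclude)
  for (k in segs) {
    for (v in seq_len(p)) {
      if (morphcheck:::seg_triangle_intersect(curve[k, ], curve[k + 1L, ],
                                              loop[v, ], loop[nxt[v], ],
                                              centroid))
        return(FALSE)
    }
  }
  TRUE
}

# exhaustive enumeration of all matchings of a move graph: minimal N, then
# minimal price
oracle_best_matching <- function(graph) {
  ed <- graph$edges
  ne <- nrow(ed)
  stopifnot(ne <= 18L)
  best <- list(N = Inf, price = Inf)
  for (mask in 0:(2^ne - 1)) {
    sel <- which(bitwAnd(mask, bitwShiftL(1L, 0:(max(ne, 1) - 1L))) > 0)
    verts <- c(ed$vi[sel], ed$vj[sel])
    if (anyDuplicated(verts)) next
    o1_used <- setdiff(which(graph$omega1_feasible), verts)
    N <- graph$n_vertices - length(verts) - length(o1_used)
    price <- sum(ed$price[sel]) + sum(graph$p1[o1_used])
    if (N < best$N - 1e-12 ||
        (abs(N - best$N) < 1e-12 && price < best$price - 1e-9))
      best <- list(N = N, price = price)
  }
  best
}

# random-walk CA-like chain and a perturbed morph on it
random_chain_points <- function(n, step = 3.8) {
  dirs <- matrix(stats::rnorm(n * 3), n, 3)
  # bias successive steps forward to avoid immediate backtracking
  dirs[, 1] <- dirs[, 1] + 1.2
  dirs <- dirs / sqrt(rowSums(dirs^2))
  apply(dirs * step, 2, cumsum)
}

random_morph <- function(n = 12, noise = 3) {
  c0 <- random_chain_points(n)
  c1 <- c0 + matrix(stats::rnorm(n * 3), n, 3) * noise
  build_morph(c0, c1)
}

# synthetic move-graph ingredients for the matching tests
random_move_graph <- function(n_vertices, edge_prob = 0.4, o1_prob = 0.5) {
  fake_si <- lapply(seq_len(n_vertices), function(k)
    list(k = k, t_star = stats::runif(1)))
  o1 <- lapply(seq_len(n_vertices), function(k) {
    feas <- stats::runif(1) < o1_prob
    structure(list(kind = "omega1", members = k,
                   backbone_length = stats::runif(1, 1, 8),
                   feasible = feas,
                   price = if (feas) stats::runif(1, 1, 50) else NA_real_),
              class = "move_candidate")
  })
  o2 <- list()
  if (n_vertices >= 2L) {
    for (p in seq_len(n_vertices - 1L)) {
      for (q in seq.int(p + 1L, n_vertices)) {
        if (stats::runif(1) < edge_prob) {
          o2[[length(o2) + 1L]] <- structure(
            list(kind = "omega2", members = c(p, q),
                 backbone_length = stats::runif(1, 2, 10),
                 feasible = TRUE, price = stats::runif(1, 1, 60)),
            class = "move_candidate")
        }
      }
    }
  }
  build_move_graph(fake_si, o1, o2)
}

# brute-force rigid superposition via optimization over Euler angles
oracle_kabsch_rmsd <- function(X, Y) {
  rot_from <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
    Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
    Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
    Rz %*% Ry %*% Rx
  }
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  f <- function(ang) sqrt(mean(rowSums((Yc %*% t(rot_from(ang)) - Xc)^2)))
  best <- Inf
  for (start in list(c(0, 0, 0), c(pi / 2, 0, 0), c(0, pi / 2, 0),
                     c(pi, 0, 0), c(1, 1, 1))) {
    r <- stats::optim(start, f, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, r$value)
  }
  best
}

# reference crossing-change displacement multiset
crossing_displacements <- function(pair) {
  sqrt(rowSums((pair$chain1$points - pair$chain0$points)^2))
}
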