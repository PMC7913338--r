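# Candidate obstruction points inside a triangle: a barycentric grid plus
# points offset from each blocking intersection toward the current
# obstruction point Po.
.triangle_candidates <- function(Po, Pk1, Pk, blockers, grid = 15L,
                                 offset = 0.5) {
  cand <- list()
  for (u in seq_len(grid)) {
    for (v in seq_len(grid + 1L - u)) {
      l1 <- u / (grid + 2L)
      l2 <- v / (grid + 2L)
      cand[[length(cand) + 1L]] <- (1 - l1 - l2) * Po + l1 * Pk1 + l2 * Pk
    }
  }
  for (bp in blockers) {
    dir <- Po - bp
    nd <- vnorm(dir)
    if (nd > 1e-9) cand[[length(cand) + 1L]] <- bp + (offset / nd) * dir
  }
  cand
}

#' Greedy self-avoiding end-contraction of one structure
#'
#' Contracts all points upstream of parameter `a_j` (N-side; mirrored for
#' the C-side) onto the point P_{a_j}, shortcutting each point straight to
#' the current obstruction point when the connecting triangle is clear of
#' the curve downstream of `a_j`, and otherwise inserting a new obstruction
#' point inside the triangle that minimizes the two-leg path while avoiding
#' all downstream segments.  The algorithm is greedy: once accepted, a path
#' tail is reused by every further upstream point.
#'
#' @param chain a [morph_chain()] or n x 3 matrix (one structure at fixed
#'   interpolation time).
#' @param a_j real curve parameter of the obstruction (1 < a_j < n for the
#'   N side; for side "C" the contraction removes points downstream of a_j).
#' @param side `"N"` or `"C"`.
#' @param clearance minimum distance a path leg must keep from downstream
#'   segments.
#' @return list of class `end_contraction`: `side`, `a_j`, `m` (number of
#'   contracted points), `cost` (total distance traveled, Angstrom),
#'   `travel` (per-point distances), `route` (obstruction-point polyline
#'   from the last obstruction to P_{a_j}), `obstructions` (count).
#' @export
end_contraction_path <- function(chain, a_j, side = c("N", "C"),
                                 clearance = 1e-6) {
  side <- match.arg(side)
  P <- chain_points(chain)
  n <- nrow(P)
  if (side == "C") {
    res <- end_contraction_path(P[rev(seq_len(n)), , drop = FALSE],
                                n + 1 - a_j, side = "N",
                                clearance = clearance)
    res$side <- "C"
    res$a_j <- a_j
    return(res)
  }
  if (a_j <= 1 + 1e-12) {
    return(structure(list(side = side, a_j = a_j, m = 0L, cost = 0,
                          travel = numeric(0), route = NULL,
                          obstructions = 0L),
                     class = "end_contraction"))
  }
  if (a_j >= n) stop("a_j must be an interior parameter")
  target <- as.vector(eval_curve(P, a_j))
  m <- floor(a_j)
  # downstream polyline, starting just past the target so that paths ending
  # at the target are not flagged for touching it
  s0 <- min(a_j + 0.05, n)
  dn_lo <- ceiling(s0)
  verts <- rbind(eval_curve(P, s0), P[seq.int(dn_lo, n), , drop = FALSE])
  if (vnorm(verts[1L, ] - verts[2L, ]) < 1e-12)
    verts <- verts[-1L, , drop = FALSE]
  D0 <- verts[-nrow(verts), , drop = FALSE]
  D1 <- verts[-1L, , drop = FALSE]
  tri_blockers <- function(A, B, C) {
    pts <- list()
    hit <- FALSE
    for (q in seq_len(nrow(D0))) {
      res <- seg_triangle_intersect(D0[q, ], D1[q, ], A, B, C)
      if (isTRUE(as.logical(res))) {
        hit <- TRUE
        ip <- attr(res, "point")
        if (!is.null(ip)) pts[[length(pts) + 1L]] <- ip
      }
    }
    list(hit = hit, points = pts)
  }
  leg_clear <- function(A, B) {
    if (vnorm(B - A) < 1e-12) return(TRUE)
    for (q in seq_len(nrow(D0)))
      if (seg_seg_distance(A, B, D0[q, ], D1[q, ]) <= clearance) return(FALSE)
    TRUE
  }
  head <- target
  route <- matrix(target, 1L, 3L)
  route_len <- 0
  travel <- numeric(m)
  n_obst <- 0L
  travel[m] <- vnorm(P[m, ] - head) + route_len
  if (m > 1L) {
    for (k in seq.int(m - 1L, 1L)) {
      bl <- tri_blockers(head, P[k + 1L, ], P[k, ])
      if (bl$hit) {
        cands <- .triangle_candidates(head, P[k + 1L, ], P[k, ], bl$points)
        best <- NULL
        for (cnd in cands) {
          if (leg_clear(head, cnd) && leg_clear(cnd, P[k, ])) {
            len <- vnorm(head - cnd) + vnorm(cnd - P[k, ])
            if (is.null(best) || len < best$len)
              best <- list(pt = cnd, len = len)
          }
        }
        new_pt <- if (is.null(best)) P[k + 1L, ] else best$pt
        route_len <- route_len + vnorm(head - new_pt)
        head <- new_pt
        route <- rbind(new_pt, route)
        n_obst <- n_obst + 1L
      }
      travel[k] <- vnorm(P[k, ] - head) + route_len
    }
  }
  structure(list(side = side, a_j = a_j, m = m, cost = sum(travel),
                 travel = travel, route = route, obstructions = n_obst),
            class = "end_contraction")
}

#' @export
print.end_contraction <- function(x, ...) {
  cat(sprintf("<end_contraction> %s-side at a = %.2f: %d points, cost %.2f A (%d obstruction points)\n",
              x$side, x$a_j, x$m, x$cost, x$obstructions))
  invisible(x)
}

# Cost of contracting both end structures of the morph at parameter a
# (N side) or b (C side), plus m times the displacement of the contraction
# target under the original morph (all contracted points travel it).
.contraction_cost <- function(morph, par, side, use_estimate = FALSE) {
  m_vert <- morph$m
  if (side == "N" && par <= 1 + 1e-12) return(list(cost = 0, k = 0L))
  if (side == "C" && par >= m_vert - 1e-12) return(list(cost = 0, k = 0L))
  k <- if (side == "N") floor(par) else m_vert - ceiling(par) + 1L
  disp <- vnorm(as.vector(morph_point(morph, 1, par)) -
                as.vector(morph_point(morph, 0, par)))
  if (use_estimate) {
    path_cost <- 2 * estimate_contraction_cost(k)
  } else {
    e0 <- end_contraction_path(morph$curve0, par, side)
    e1 <- end_contraction_path(morph$curve1, par, side)
    path_cost <- e0$cost + e1$cost
  }
  list(cost = path_cost + k * disp, k = k)
}

#' Optimal N/C end-contraction pair removing all essential intersections
#'
#' Minimizes N-Contraction(a) + C-Contraction(b) over 1 <= a < b <= L
#' subject to (a_i <= a or b <= b_i) for every essential self-intersection
#' i.  Because the cost is non-decreasing in the contracted length, only
#' the n + 1 candidate pairs a = a_j, b = min(b_(j+1), ..., b_n, L)
#' (j = 0..n, with a_0 = 1) need to be checked.
#'
#' @param essentials list of essential self-intersections (with `a`, `b`).
#' @param morph the morph.
#' @param use_estimates replace exact path construction by
#'   [estimate_contraction_cost()].
#' @param max_contracted optional bound (residues) on the contracted length
#'   of each side; candidates exceeding it are infeasible.
#' @return list with `a`, `b`, `cost`, `cost_n`, `cost_c`, `k_n`, `k_c` and
#'   the candidate table; `cost` is `Inf` when no candidate is feasible.
#' @export
optimize_end_contractions <- function(essentials, morph,
                                      use_estimates = FALSE,
                                      max_contracted = Inf) {
  L <- morph$m
  if (length(essentials) == 0L)
    return(list(a = 1, b = L, cost = 0, cost_n = 0, cost_c = 0,
                k_n = 0L, k_c = 0L, candidates = NULL))
  av <- vapply(essentials, `[[`, 0, "a")
  bv <- vapply(essentials, `[[`, 0, "b")
  ord <- order(av)
  av <- av[ord]; bv <- bv[ord]
  nn <- length(av)
  cand <- data.frame(a = c(1, av),
                     b = vapply(0:nn, function(j)
                       min(c(bv[seq.int(j + 1L, length.out = nn - j)], L)),
                       numeric(1L)))
  best <- list(a = NA_real_, b = NA_real_, cost = Inf,
               cost_n = NA_real_, cost_c = NA_real_, k_n = NA, k_c = NA)
  cost_rows <- numeric(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    a <- cand$a[r]; b <- cand$b[r]
    if (a >= b) { cost_rows[r] <- Inf; next }
    if ((a - 1) > max_contracted || (L - b) > max_contracted) {
      cost_rows[r] <- Inf
      next
    }
    cn <- .contraction_cost(morph, a, "N", use_estimates)
    cc <- .contraction_cost(morph, b, "C", use_estimates)
    cost_rows[r] <- cn$cost + cc$cost
    if (cost_rows[r] < best$cost)
      best <- list(a = a, b = b, cost = cost_rows[r],
                   cost_n = cn$cost, cost_c = cc$cost,
                   k_n = cn$k, k_c = cc$k)
  }
  cand$cost <- cost_rows
  best$candidates <- cand
  best
}

#' Estimated end-contraction cost
#'
#' Distance traveled by contracted residues grows roughly linearly to 25 A
#' over the first 17 residues from the contraction point and fluctuates
#' around 25 A beyond, giving the per-structure estimate
#' sum_{r=1..k} d(r) with d(r) = 25 r / 17 for r <= 17 and 25 otherwise.
#'
#' @param k number of residues contracted (one structure).
#' @return Estimated cost in Angstrom.
#' @export
estimate_contraction_cost <- function(k) {
  vapply(k, function(ki) {
    if (ki <= 0) return(0)
    if (ki <= 17) 25 * ki * (ki + 1) / 2 / 17
    else 225 + 25 * (ki - 17)
  }, numeric(1L))
}

#' End-proximal Omega_1 pricing
#'
#' A self-intersection close to a terminus (within `window` residues,
#' default MaxLength / 2) may be treated as Omega_1-removable at the
#' minimum of its Omega_1 price (infinite when infeasible) and the cost of
#' the end-contraction that removes it.  Mid-chain intersections are
#' returned unchanged.
#'
#' @param si the self-intersection.
#' @param morph the morph.
#' @param omega1 the [omega1_candidate()] for `si`.
#' @param window residue window from either terminus.
#' @param use_estimates passed to the contraction costing.
#' @return An updated `move_candidate`: feasible at the minimum price when
#'   either route is available.
#' @export
terminal_omega1_price <- function(si, morph, omega1, window,
                                  use_estimates = FALSE) {
  d_n <- si$a - 1
  d_c <- morph$m - si$b
  if (min(d_n, d_c) > window) return(omega1)
  side <- if (d_n <= d_c) "N" else "C"
  par <- if (side == "N") si$a else si$b
  ec <- .contraction_cost(morph, par, side, use_estimates)
  p1 <- if (isTRUE(omega1$feasible)) omega1$price else Inf
  price <- min(p1, ec$cost)
  if (!is.finite(price)) return(omega1)
  omega1$feasible <- TRUE
  omega1$price <- price
  omega1$via_end_contraction <- ec$cost < p1
  omega1
}
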