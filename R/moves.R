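# Loop boundary for an Omega_1 move: the t*-slice points P_a, P_ceil(a), ...,
# P_floor(b) (the closing point P_b equals P_a at the self-intersection).
# Exact duplicates from integer a/b are dropped.
.loop_points <- function(slice, a, b) {
  pts <- eval_curve(slice, a)
  ints <- seq.int(ceiling(a), floor(b))
  if (length(ints)) pts <- rbind(pts, slice[ints, , drop = FALSE])
  keep <- c(TRUE, sqrt(rowSums((pts[-1L, , drop = FALSE] -
                                pts[-nrow(pts), , drop = FALSE])^2)) > 1e-9)
  pts[keep, , drop = FALSE]
}

# Segment index ranges of the slice lying outside the given parameter
# intervals (list of c(lo, hi)); the partial segments containing interval
# ends are excluded, as the loop boundary runs through them.
.remainder_segments <- function(m, exclude) {
  segs <- seq_len(m - 1L)
  keep <- rep(TRUE, m - 1L)
  for (iv in exclude) {
    lo <- floor(iv[1L])       # partial segment containing lo
    hi <- ceiling(iv[2L]) - 1 # partial segment containing hi
    keep[segs >= lo & segs <= hi] <- FALSE
  }
  segs[keep]
}

#' Is a spanning disk free of the rest of the curve?
#'
#' Builds the topological disk as the triangle fan from consecutive loop
#' boundary points to their centroid and tests it against every line segment
#' of the curve outside the excluded parameter range.  Segments are sorted
#' by center distance from the centroid; the scan stops early once the
#' triangle-inequality bound (loop radius + half segment length < center
#' distance) excludes all remaining segments.  Degenerate (zero-area)
#' triangles are skipped.
#'
#' @param loop p x 3 matrix of loop boundary points (closed implicitly).
#' @param curve the full t-slice of the morph (m x 3).
#' @param exclude list of parameter intervals `c(lo, hi)` whose segments
#'   belong to the loop and are not tested.
#' @return `TRUE` if no remaining segment intersects the disk; otherwise
#'   `FALSE` with the first blocking segment index attached as attribute
#'   `"blocker"`.
#' @export
disk_is_free <- function(loop, curve, exclude = list()) {
  centroid <- colMeans(loop)
  L <- sweep(loop, 2L, centroid)
  r_tri <- sqrt(max(rowSums(L^2)))
  segs <- .remainder_segments(nrow(curve), exclude)
  if (length(segs) == 0L) return(TRUE)
  S0 <- sweep(curve[segs, , drop = FALSE], 2L, centroid)
  S1 <- sweep(curve[segs + 1L, , drop = FALSE], 2L, centroid)
  ctr <- (S0 + S1) / 2
  half <- sqrt(rowSums((S1 - S0)^2)) / 2
  cd <- sqrt(rowSums(ctr^2))
  ord <- order(cd)
  p <- nrow(L)
  nxt <- c(seq_len(p)[-1L], 1L)
  for (q in seq_along(ord)) {
    k <- ord[q]
    if (cd[k] - half[k] > r_tri) {
      # by the triangle inequality no farther segment can reach the disk
      if (all(cd[ord[q:length(ord)]] - half[ord[q:length(ord)]] > r_tri))
        return(TRUE)
      next
    }
    for (v in seq_len(p)) {
      if (seg_triangle_intersect(S0[k, ], S1[k, ], L[v, ], L[nxt[v], ],
                                 c(0, 0, 0))) {
        out <- FALSE
        attr(out, "blocker") <- segs[k]
        return(out)
      }
    }
  }
  TRUE
}

#' Test a self-intersection for local Omega_1 removability
#'
#' The self-intersection is Omega_1-removable when its backbone span
#' b - a is at most `max_length` and the disk spanned by the loop at the
#' intersection time t* is free of the rest of that time slice.  The price
#' P1 is twice the sum of the distances from the loop points to the line
#' through the self-intersection point and the loop centroid (the axis a
#' simple loop rotation would use).
#'
#' @param si one self-intersection from [find_intersections()].
#' @param morph the morph it was found on.
#' @param max_length user bound on the backbone span (in segments) an
#'   Omega move may rearrange.
#' @return list of class `move_candidate`: kind `"omega1"`, `members`,
#'   `backbone_length`, `feasible`, `price` (NA when infeasible), `blocker`.
#' @export
omega1_candidate <- function(si, morph, max_length) {
  span <- si$b - si$a
  cand <- list(kind = "omega1", members = si$k, backbone_length = span,
               feasible = FALSE, price = NA_real_, blocker = NA_integer_)
  class(cand) <- "move_candidate"
  if (span > max_length) {
    cand$reason <- "max_length"
    return(cand)
  }
  slice <- morph_slice(morph, si$t_star)
  loop <- .loop_points(slice, si$a, si$b)
  free <- disk_is_free(loop, slice, exclude = list(c(si$a, si$b)))
  if (!isTRUE(free)) {
    cand$reason <- "blocked"
    cand$blocker <- attr(free, "blocker")
    return(cand)
  }
  x <- as.vector(eval_curve(slice, si$a))      # the self-intersection point
  centroid <- colMeans(loop)
  cand$feasible <- TRUE
  cand$price <- 2 * sum(point_line_distance(loop, x, centroid - x))
  cand
}

# Track of a self-intersection point over [t_lo, t_hi]: closest-approach
# midpoints of its two segments at `nsamp` uniform times.
.intersection_track <- function(morph, si, t_lo, t_hi, nsamp = 64L) {
  ts <- seq(t_lo, t_hi, length.out = nsamp)
  pts <- matrix(0, nsamp, 3L)
  for (q in seq_len(nsamp)) {
    sl <- (1 - ts[q]) * morph$curve0[c(si$i, si$i + 1L, si$j, si$j + 1L), ] +
          ts[q] * morph$curve1[c(si$i, si$i + 1L, si$j, si$j + 1L), ]
    cl <- seg_seg_closest(sl[1L, ], sl[2L, ], sl[3L, ], sl[4L, ])
    pts[q, ] <- (cl$p + cl$q) / 2
  }
  list(t = ts, pts = pts)
}

#' Test a self-intersection pair for local Omega_2 removability
#'
#' The two crossings of an Omega_2 move must have opposite signs.  With
#' t*_j <= t*_k, the pair is removable when the combined backbone length of
#' the two arcs is at most `max_length`, the disk spanned at
#' t_avg = (t*_j + t*_k)/2 by the closed loop through both intersection
#' points is free of the remainder of that slice, and the tracks swept by
#' the two self-intersection points over [t*_j, t*_k] stay clear of the
#' remainder of the moving curve.  The price P2 is twice the sum of loop
#' point distances to the line connecting the two intersection points.
#'
#' @param si_j,si_k self-intersections from the same morph.
#' @param morph the morph.
#' @param max_length user backbone-span bound.
#' @param track_samples time samples for the swept-track check.
#' @param track_clearance minimum allowed track/curve distance in Angstrom.
#' @return A `move_candidate` of kind `"omega2"`.
#' @export
omega2_candidate <- function(si_j, si_k, morph, max_length,
                             track_samples = 64L, track_clearance = 1e-6) {
  if (si_j$t_star > si_k$t_star) { tmp <- si_j; si_j <- si_k; si_k <- tmp }
  blen <- (si_j$b - si_j$a) + (si_k$b - si_k$a)
  cand <- list(kind = "omega2", members = c(si_j$k, si_k$k),
               backbone_length = blen, feasible = FALSE,
               price = NA_real_, blocker = NA_integer_)
  class(cand) <- "move_candidate"
  if (si_j$sign == si_k$sign) {
    cand$reason <- "same_sign"
    return(cand)
  }
  if (blen > max_length) {
    cand$reason <- "max_length"
    return(cand)
  }
  t_avg <- (si_j$t_star + si_k$t_star) / 2
  slice <- morph_slice(morph, t_avg)
  a_lo <- min(si_j$a, si_k$a); a_hi <- max(si_j$a, si_k$a)
  b_lo <- min(si_j$b, si_k$b); b_hi <- max(si_j$b, si_k$b)
  # closed loop: a-arc forward, then the b-arc continuing from the b-image
  # of the intersection at a_hi back to that of the intersection at a_lo
  # (the closing jumps between near-coincident images are short)
  arc_a <- .loop_arc(slice, a_lo, a_hi)
  arc_b <- .loop_arc(slice, b_lo, b_hi)
  b_at_ahi <- if (si_j$a > si_k$a) si_j$b else si_k$b
  if (abs(b_at_ahi - b_lo) < abs(b_at_ahi - b_hi)) {
    # antiparallel pairing: traverse the b-arc lo -> hi
  } else {
    arc_b <- arc_b[rev(seq_len(nrow(arc_b))), , drop = FALSE]
  }
  loop <- rbind(arc_a, arc_b)
  keep <- c(TRUE, sqrt(rowSums((loop[-1L, , drop = FALSE] -
                                loop[-nrow(loop), , drop = FALSE])^2)) > 1e-9)
  loop <- loop[keep, , drop = FALSE]
  exclude <- list(c(a_lo, a_hi), c(b_lo, b_hi))
  free <- disk_is_free(loop, slice, exclude = exclude)
  if (!isTRUE(free)) {
    cand$reason <- "blocked"
    cand$blocker <- attr(free, "blocker")
    return(cand)
  }
  # swept-track clearance over [t_j, t_k]
  if (si_k$t_star - si_j$t_star > 1e-12) {
    segs <- .remainder_segments(morph$m, exclude)
    for (si in list(si_j, si_k)) {
      tr <- .intersection_track(morph, si, si_j$t_star, si_k$t_star,
                                track_samples)
      for (q in seq_len(nrow(tr$pts) - 1L)) {
        tm <- (tr$t[q] + tr$t[q + 1L]) / 2
        sl <- morph_slice(morph, tm)
        for (r in segs) {
          dmin <- seg_seg_distance(tr$pts[q, ], tr$pts[q + 1L, ],
                                   sl[r, ], sl[r + 1L, ])
          if (dmin <= track_clearance) {
            cand$reason <- "track_blocked"
            cand$blocker <- r
            return(cand)
          }
        }
      }
    }
  }
  xj <- as.vector(eval_curve(slice, si_j$a))
  xk <- as.vector(eval_curve(slice, si_k$a))
  cand$feasible <- TRUE
  cand$price <- 2 * sum(point_line_distance(loop, xj, xk - xj))
  cand
}

# One arc of the Omega_2 loop: P_lo, integer vertices, P_hi.
.loop_arc <- function(slice, lo, hi) {
  pts <- eval_curve(slice, lo)
  ints <- seq.int(ceiling(lo), floor(hi))
  ints <- ints[ints > lo & ints < hi]
  if (length(ints)) pts <- rbind(pts, slice[ints, , drop = FALSE])
  rbind(pts, eval_curve(slice, hi))
}

#' @export
print.move_candidate <- function(x, ...) {
  cat(sprintf("<move_candidate> %s on {%s}: %s (backbone %.2f%s)\n",
              x$kind, paste(x$members, collapse = ","),
              if (x$feasible) sprintf("feasible, price %.2f A", x$price)
              else paste0("infeasible (", x$reason, ")"),
              x$backbone_length,
              if (!x$feasible && !is.na(x$blocker))
                paste0(", blocker seg ", x$blocker) else ""))
  invisible(x)
}
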