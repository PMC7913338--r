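#' Coefficients of the segment-pair determinant cubic
#'
#' For non-adjacent segments i and j of the morph, det_ij(t) =
#' det(P_{i+1}(t) - P_i(t), P_{j+1}(t) - P_j(t), P_i(t) - P_j(t)) is a
#' polynomial of degree at most 3 in the interpolation time t.  Its roots
#' are the times at which the two (moving) segments become coplanar; its
#' sign is the crossing sign of the pair.
#'
#' @param morph a [build_morph()] object.
#' @param i,j segment indices with |i - j| >= 2.
#' @return Numeric coefficients `c(c0, c1, c2, c3)` of c0 + c1 t + c2 t^2 +
#'   c3 t^3, computed exactly from the trilinear expansion.
#' @export
det_cubic <- function(morph, i, j) {
  if (abs(i - j) < 2L) stop("segments must be non-adjacent (|i - j| >= 2)")
  u0 <- morph$curve0[i + 1L, ] - morph$curve0[i, ]
  v0 <- morph$curve0[j + 1L, ] - morph$curve0[j, ]
  w0 <- morph$curve0[i, ] - morph$curve0[j, ]
  du <- (morph$curve1[i + 1L, ] - morph$curve1[i, ]) - u0
  dv <- (morph$curve1[j + 1L, ] - morph$curve1[j, ]) - v0
  dw <- (morph$curve1[i, ] - morph$curve1[j, ]) - w0
  unname(c(det3(u0, v0, w0),
           det3(du, v0, w0) + det3(u0, dv, w0) + det3(u0, v0, dw),
           det3(du, dv, w0) + det3(du, v0, dw) + det3(u0, dv, dw),
           det3(du, dv, dw)))
}

# Real roots of the cubic in [lo, hi] after normalization, polished by
# Newton steps.  Roots within `btol` of the interval ends are kept (flagged
# by the caller).  Returns numeric(0) for (near-)identically-zero input.
.cubic_roots01 <- function(coef, tol = 1e-9, btol = 1e-9) {
  scale <- max(abs(coef))
  if (scale < 1e-14) return(NULL)          # degenerate: coplanar throughout
  cf <- coef / scale
  deg <- max(which(abs(cf) > 1e-13)) - 1L
  if (deg == 0L) return(numeric(0))
  r <- polyroot(cf[seq_len(deg + 1L)])
  re <- Re(r)[abs(Im(r)) < 1e-7 * (1 + abs(Re(r)))]
  if (length(re) == 0L) return(numeric(0))
  f  <- function(t) cf[1L] + t * (cf[2L] + t * (cf[3L] + t * cf[4L]))
  fp <- function(t) cf[2L] + t * (2 * cf[3L] + t * 3 * cf[4L])
  for (k in seq_along(re)) {
    for (it in 1:3) {
      d <- fp(re[k])
      if (abs(d) < 1e-13) break
      re[k] <- re[k] - f(re[k]) / d
    }
  }
  re <- re[re >= -btol & re <= 1 + btol]
  if (length(re) > 1L) {
    re <- sort(re)
    re <- re[c(TRUE, diff(re) > 1e-9)]
  }
  pmin(pmax(re, 0), 1)
}

# Planar solve at the coplanar time: (1-s_i) P_i + s_i P_{i+1} =
# (1-s_j) P_j + s_j P_{j+1}.  Least squares on the 3 x 2 system; the
# residual must vanish (coplanarity) for a genuine candidate.
.planar_solve <- function(Pi, Pi1, Pj, Pj1) {
  u <- Pi1 - Pi
  v <- Pj1 - Pj
  A <- cbind(u, -v)
  rhs <- Pj - Pi
  sol <- tryCatch(qr.solve(A, rhs), error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  resid <- vnorm(A %*% sol - rhs)
  scale <- max(vnorm(u), vnorm(v), 1)
  list(s_i = sol[1L], s_j = sol[2L], resid = resid / scale)
}

#' Find all transversal self-intersections of a morph
#'
#' For every non-adjacent segment pair (optionally pre-filtered by
#' [needs_intersection_check()]) the determinant cubic's isolated real roots
#' t* in [0, 1] are found; at each root the planar 2-unknown system is
#' solved and an intersection is recorded iff both segment parameters lie in
#' [0, 1].  The crossing-sign change is the sign of the cubic's derivative
#' at t*; roots with derivative magnitude below tolerance (tangential
#' contacts, not transversal) are discarded and counted in the diagnostics.
#'
#' @param morph a [build_morph()] object.
#' @param filter an [overlap_analysis()] result to enable check-skipping, or
#'   `NULL` to test all pairs.
#' @param containment_tol slack on the [0, 1] containment of the segment
#'   parameters.
#' @param tangent_tol relative derivative threshold below which a root is
#'   treated as tangential.
#' @return list of class `intersection_set`: `intersections` (each with
#'   `a`, `b`, `sign`, `t_star`, segment indices `i`, `j`, `s_i`, `s_j`,
#'   `boundary` flag), sorted by (t*, a, b), plus `diagnostics` with counts
#'   of skipped pairs and tangential roots.
#' @export
find_intersections <- function(morph, filter = NULL,
                               containment_tol = 1e-9, tangent_tol = 1e-8) {
  m <- morph$m
  out <- list()
  skipped <- 0L
  tangential <- 0L
  degenerate <- 0L
  for (i in seq_len(m - 3L)) {
    for (j in seq.int(i + 2L, m - 1L)) {
      if (!is.null(filter) && !needs_intersection_check(i, j, filter, morph)) {
        skipped <- skipped + 1L
        next
      }
      coef <- det_cubic(morph, i, j)
      roots <- .cubic_roots01(coef)
      if (is.null(roots)) { degenerate <- degenerate + 1L; next }
      if (length(roots) == 0L) next
      scale <- max(abs(coef))
      for (t0 in roots) {
        slice_i <- (1 - t0) * morph$curve0[c(i, i + 1L, j, j + 1L), ] +
                   t0 * morph$curve1[c(i, i + 1L, j, j + 1L), ]
        ps <- .planar_solve(slice_i[1L, ], slice_i[2L, ],
                            slice_i[3L, ], slice_i[4L, ])
        if (is.null(ps) || ps$resid > 1e-6) next
        if (ps$s_i < -containment_tol || ps$s_i > 1 + containment_tol ||
            ps$s_j < -containment_tol || ps$s_j > 1 + containment_tol) next
        dcoef <- c(coef[2L], 2 * coef[3L], 3 * coef[4L])
        dval <- dcoef[1L] + t0 * (dcoef[2L] + t0 * dcoef[3L])
        if (abs(dval) < tangent_tol * scale) {
          tangential <- tangential + 1L
          next
        }
        s_i <- min(max(ps$s_i, 0), 1)
        s_j <- min(max(ps$s_j, 0), 1)
        out[[length(out) + 1L]] <- list(
          a = i + s_i, b = j + s_j,
          sign = sign(dval), t_star = t0,
          i = i, j = j, s_i = s_i, s_j = s_j,
          boundary = (t0 < 1e-9 || t0 > 1 - 1e-9))
      }
    }
  }
  if (length(out) > 1L) {
    ord <- order(vapply(out, `[[`, 0, "t_star"),
                 vapply(out, `[[`, 0, "a"),
                 vapply(out, `[[`, 0, "b"))
    out <- out[ord]
  }
  for (k in seq_along(out)) out[[k]]$k <- k
  structure(list(intersections = out,
                 diagnostics = list(skipped_pairs = skipped,
                                    tangential_roots = tangential,
                                    degenerate_pairs = degenerate)),
            class = "intersection_set")
}

#' @export
print.intersection_set <- function(x, ...) {
  n <- length(x$intersections)
  cat(sprintf("<intersection_set> %d transversal self-intersection%s\n",
              n, if (n == 1L) "" else "s"))
  for (si in x$intersections)
    cat(sprintf("  k=%d  a=%.3f b=%.3f sign=%+d t*=%.4f\n",
                si$k, si$a, si$b, si$sign, si$t_star))
  cat(sprintf("  (skipped %d pairs, %d tangential roots)\n",
              x$diagnostics$skipped_pairs, x$diagnostics$tangential_roots))
  invisible(x)
}
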