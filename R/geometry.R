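# Internal geometric primitives shared by the overlap, intersection, move and
# end-contraction code.  Points are numeric length-3 vectors; point sets are
# n x 3 matrices of coordinates in Angstrom.

cross3 <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

vnorm <- function(u) sqrt(sum(u * u))

det3 <- function(u, v, w) {
  u[1L] * (v[2L] * w[3L] - v[3L] * w[2L]) -
  u[2L] * (v[1L] * w[3L] - v[3L] * w[1L]) +
  u[3L] * (v[1L] * w[2L] - v[2L] * w[1L])
}

#' @noRd
clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Closest approach between segments p0-p1 and q0-q1.  Returns the minimum
# distance together with the segment parameters realizing it.
seg_seg_closest <- function(p0, p1, q0, q1) {
  d1 <- p1 - p0
  d2 <- q1 - q0
  r  <- p0 - q0
  a <- sum(d1 * d1)
  e <- sum(d2 * d2)
  f <- sum(d2 * r)
  tiny <- 1e-14
  if (a <= tiny && e <= tiny) {
    s <- 0; t <- 0
  } else if (a <= tiny) {
    s <- 0; t <- clamp01(f / e)
  } else {
    cc <- sum(d1 * r)
    if (e <= tiny) {
      t <- 0; s <- clamp01(-cc / a)
    } else {
      b <- sum(d1 * d2)
      denom <- a * e - b * b
      s <- if (denom > tiny) clamp01((b * f - cc * e) / denom) else 0
      t <- (b * s + f) / e
      if (t < 0) {
        t <- 0; s <- clamp01(-cc / a)
      } else if (t > 1) {
        t <- 1; s <- clamp01((b - cc) / a)
      }
    }
  }
  cp <- p0 + s * d1
  cq <- q0 + t * d2
  list(distance = vnorm(cp - cq), s = s, t = t, p = cp, q = cq)
}

seg_seg_distance <- function(p0, p1, q0, q1) {
  seg_seg_closest(p0, p1, q0, q1)$distance
}

# 2D helpers for the coplanar segment/triangle case ---------------------------

.orient2 <- function(a, b, c) {
  (b[1L] - a[1L]) * (c[2L] - a[2L]) - (b[2L] - a[2L]) * (c[1L] - a[1L])
}

.seg_seg_intersect2d <- function(p0, p1, q0, q1, tol) {
  o1 <- .orient2(p0, p1, q0)
  o2 <- .orient2(p0, p1, q1)
  o3 <- .orient2(q0, q1, p0)
  o4 <- .orient2(q0, q1, p1)
  if (((o1 > tol && o2 < -tol) || (o1 < -tol && o2 > tol)) &&
      ((o3 > tol && o4 < -tol) || (o3 < -tol && o4 > tol))) return(TRUE)
  on_seg <- function(a, b, p) {
    abs(.orient2(a, b, p)) <= tol &&
      p[1L] >= min(a[1L], b[1L]) - tol && p[1L] <= max(a[1L], b[1L]) + tol &&
      p[2L] >= min(a[2L], b[2L]) - tol && p[2L] <= max(a[2L], b[2L]) + tol
  }
  on_seg(p0, p1, q0) || on_seg(p0, p1, q1) ||
    on_seg(q0, q1, p0) || on_seg(q0, q1, p1)
}

.point_in_tri2d <- function(p, a, b, c, tol) {
  o1 <- .orient2(a, b, p)
  o2 <- .orient2(b, c, p)
  o3 <- .orient2(c, a, p)
  (o1 >= -tol && o2 >= -tol && o3 >= -tol) ||
    (o1 <= tol && o2 <= tol && o3 <= tol)
}

# Does segment s0-s1 intersect triangle (A, B, C)?  Touching within `tol`
# counts as an intersection (conservative for the disk-freeness test).
# Degenerate (zero area) triangles never intersect.  When an intersection is
# found in the transversal case, the intersection point is attached as an
# attribute (used to seed obstruction-point candidates).
seg_triangle_intersect <- function(s0, s1, A, B, C, tol = 1e-9) {
  e1 <- B - A
  e2 <- C - A
  n <- cross3(e1, e2)
  nn <- vnorm(n)
  scale <- max(vnorm(e1), vnorm(e2), vnorm(s1 - s0), 1)
  if (nn < 1e-12 * scale * scale) return(FALSE)   # degenerate triangle
  d <- s1 - s0
  den <- sum(d * n)
  if (abs(den) > 1e-10 * nn * scale) {
    # transversal: solve s0 + u d = A + v e1 + w e2
    rhs <- A - s0
    u <- sum(rhs * n) / den
    if (u < -tol || u > 1 + tol) return(FALSE)
    p <- s0 + u * d
    # barycentric coordinates of p
    v0 <- p - A
    d11 <- sum(e1 * e1); d12 <- sum(e1 * e2); d22 <- sum(e2 * e2)
    dv1 <- sum(v0 * e1); dv2 <- sum(v0 * e2)
    det <- d11 * d22 - d12 * d12
    if (abs(det) < 1e-14 * scale^4) return(FALSE)
    v <- (d22 * dv1 - d12 * dv2) / det
    w <- (d11 * dv2 - d12 * dv1) / det
    if (v >= -tol && w >= -tol && v + w <= 1 + tol) {
      out <- TRUE
      attr(out, "point") <- p
      return(out)
    }
    return(FALSE)
  }
  # segment parallel to the triangle plane
  nhat <- n / nn
  h0 <- sum(nhat * (s0 - A))
  if (abs(h0) > 1e-7 * scale) return(FALSE)
  # coplanar: work in the plane spanned by e1 and its orthogonal complement
  b1 <- e1 / vnorm(e1)
  b2 <- e2 - sum(e2 * b1) * b1
  nb2 <- vnorm(b2)
  if (nb2 < 1e-12 * scale) return(FALSE)
  b2 <- b2 / nb2
  proj <- function(p) c(sum((p - A) * b1), sum((p - A) * b2))
  P0 <- proj(s0); P1 <- proj(s1)
  A2 <- c(0, 0); B2 <- proj(B); C2 <- proj(C)
  t2 <- tol * scale
  if (.point_in_tri2d(P0, A2, B2, C2, t2) ||
      .point_in_tri2d(P1, A2, B2, C2, t2)) return(TRUE)
  .seg_seg_intersect2d(P0, P1, A2, B2, t2) ||
    .seg_seg_intersect2d(P0, P1, B2, C2, t2) ||
    .seg_seg_intersect2d(P0, P1, C2, A2, t2)
}

# Distance from points (rows of P) to the line through a with direction dir.
point_line_distance <- function(P, a, dir) {
  nd <- vnorm(dir)
  if (nd < 1e-12) return(sqrt(rowSums(sweep(P, 2L, a)^2)))
  u <- dir / nd
  rel <- sweep(P, 2L, a)
  along <- as.vector(rel %*% u)
  sqrt(pmax(rowSums(rel^2) - along^2, 0))
}

# Rigid transform helpers: rotation is a 3x3 proper rotation matrix applied to
# row-vector coordinates as  x' = x %*% t(rot) + trans.
apply_transform <- function(points, rotation, translation) {
  sweep(points %*% t(rotation), 2L, translation, `+`)
}
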