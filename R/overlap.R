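#' Minimum pairwise distance over the interpolation
#'
#' For the relative vectors p0 = p0j - p0i and p1 = p1j - p1i the squared
#' distance d^2(t) = ||(1-t) p0 + t p1||^2 is quadratic in t with
#' unconstrained minimizer t* = (a^2 - ab cos(theta)) / (a^2 + b^2 -
#' 2ab cos(theta)); the minimum over [0, 1] is attained at the clamp of t*.
#' If p1 - p0 vanishes the distance is constant.
#'
#' @param p0i,p0j,p1i,p1j 3D points: pair (i, j) in structures 0 and 1.
#' @return list with `a`, `b` (endpoint distances), `cos_theta`, `t_star`
#'   (unconstrained minimizer, 0 in the degenerate branch), `t_clamped`, and
#'   `d_interp` (minimum distance over the interpolation, Angstrom).
#' @export
pair_min_distance <- function(p0i, p0j, p1i, p1j) {
  v0 <- p0j - p0i
  v1 <- p1j - p1i
  a <- vnorm(v0)
  b <- vnorm(v1)
  D <- v1 - v0
  dd <- sum(D * D)
  ct <- if (a > 0 && b > 0) sum(v0 * v1) / (a * b) else 1
  if (dd < 1e-18) {
    return(list(a = a, b = b, cos_theta = ct, t_star = 0, t_clamped = 0,
                d_interp = a, degenerate = TRUE))
  }
  t_star <- -sum(v0 * D) / dd
  t_cl <- min(max(t_star, 0), 1)
  d <- vnorm((1 - t_cl) * v0 + t_cl * v1)
  list(a = a, b = b, cos_theta = ct, t_star = t_star, t_clamped = t_cl,
       d_interp = d, degenerate = FALSE)
}

#' Steric overlap of a linear morph
#'
#' For every vertex pair i < j of the morph, overlap_(i,j) =
#' max(d_min(separation) - d_interp(i,j), 0) where d_interp is the minimum
#' distance between the two interpolating points over t in [0, 1] and d_min
#' is the native minimum-distance table at the pair's backbone separation.
#' For reparameterized morphs the separation is fractional; the constraint
#' used is the weaker of the two chains' interpolated d_min values, which
#' reduces to the plain table in the gapless case.  MeanOverlap is the sum
#' over all pairs divided by the number of vertices; the local/nonlocal
#' split is at separation <= 4.
#'
#' @param morph a [build_morph()] object.
#' @param table d_min table; default chosen by the morph's representation.
#' @return An object of class `overlap_result` with the overlap matrix
#'   (upper triangle), `d_interp` matrix, `mean_overlap`, `local_overlap`,
#'   `nonlocal_overlap` and the table used.
#' @export
overlap_analysis <- function(morph, table = NULL) {
  if (is.null(table)) table <- dmin_table(morph$representation)
  P0 <- morph$curve0
  P1 <- morph$curve1
  m <- morph$m
  A2 <- as.matrix(stats::dist(P0))^2
  B2 <- as.matrix(stats::dist(P1))^2
  # C[i,j] = (p0j - p0i) . (p1j - p1i) expanded through the Gram matrix
  dot01 <- P0 %*% t(P1)
  C <- matrix(diag(dot01), m, m, byrow = TRUE) + matrix(diag(dot01), m, m) -
       dot01 - t(dot01)
  DD <- A2 + B2 - 2 * C            # ||v1 - v0||^2
  tstar <- ifelse(DD > 1e-18, (A2 - C) / DD, 0)
  tcl <- pmin(pmax(tstar, 0), 1)
  d2 <- (1 - tcl)^2 * A2 + tcl^2 * B2 + 2 * tcl * (1 - tcl) * C
  d_interp <- sqrt(pmax(d2, 0))
  sep0 <- abs(outer(morph$repar0, morph$repar0, `-`))
  sep1 <- abs(outer(morph$repar1, morph$repar1, `-`))
  dmin <- pmin(matrix(interpolated_dmin(pmax(sep0, 1e-9), table), m, m),
               matrix(interpolated_dmin(pmax(sep1, 1e-9), table), m, m))
  ov <- pmax(dmin - d_interp, 0)
  ov[lower.tri(ov, diag = TRUE)] <- 0
  sep <- pmin(sep0, sep1)
  upper <- upper.tri(ov)
  local <- sum(ov[upper & sep <= 4])
  total <- sum(ov[upper])
  structure(list(overlap = ov, d_interp = d_interp,
                 mean_overlap = total / m,
                 local_overlap = local,
                 nonlocal_overlap = total - local,
                 dmin_table = table,
                 representation = morph$representation),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap_result> mean overlap %.4f A (local %.3f, nonlocal %.3f)\n",
              x$mean_overlap, x$local_overlap, x$nonlocal_overlap))
  invisible(x)
}

#' Overlap-based filter for the self-intersection check
#'
#' The check for segments i and j (vertices i, i+1, j, j+1) may be skipped
#' when the involved alpha-carbon neighbor spacings are below 4 A in both
#' end structures and overlap_(i,j) + overlap_(i,j+1) + overlap_(i+1,j) +
#' overlap_(i+1,j+1) < 2.6 A; for the smooth representation the thresholds
#' are 3.5 A and 2.1 A.  Segment lengths are convex in t, so checking the two
#' end structures bounds all intermediate times.
#'
#' @param i,j segment indices (|i - j| >= 2).
#' @param overlap an [overlap_analysis()] result.
#' @param morph the morph the overlaps were computed on.
#' @return `TRUE` if the intersection check is needed, `FALSE` if it can be
#'   skipped.
#' @export
needs_intersection_check <- function(i, j, overlap, morph) {
  thr <- if (overlap$representation == "smooth") c(3.5, 2.1) else c(4.0, 2.6)
  len0 <- sqrt(rowSums((morph$curve0[c(i, j) + 1L, , drop = FALSE] -
                        morph$curve0[c(i, j), , drop = FALSE])^2))
  len1 <- sqrt(rowSums((morph$curve1[c(i, j) + 1L, , drop = FALSE] -
                        morph$curve1[c(i, j), , drop = FALSE])^2))
  if (any(c(len0, len1) >= thr[1L])) return(TRUE)
  ov <- overlap$overlap
  pick <- function(p, q) ov[min(p, q), max(p, q)]
  s <- pick(i, j) + pick(i, j + 1L) + pick(i + 1L, j) + pick(i + 1L, j + 1L)
  s >= thr[2L]
}
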