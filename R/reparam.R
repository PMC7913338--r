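#' Gap-filling reparameterization of an alignment
#'
#' Converts a (possibly gapped) residue alignment into two equal-length lists
#' of real curve parameters so that both curves reach consecutive aligned
#' pairs simultaneously.  Between aligned pairs spanning g0 intervals on
#' chain 0 and g1 on chain 1, max(g0, g1) uniform steps are inserted; on the
#' slower curve the parameter advances fractionally (e.g. a single unaligned
#' residue against no gap is paired with the opposing segment midpoint).
#'
#' @param alignment an [alignment_record()] with at least 2 pairs.
#' @return An object of class `reparam_pair` with fields `repar0`, `repar1`
#'   (strictly increasing, equal length m), `is_aligned` (0/1 at the m
#'   vertices: 1 exactly at aligned pairs), and `awf`, the aligned window
#'   fraction (shorter aligned window length over shorter chain length).
#' @export
build_reparam <- function(alignment) {
  p <- alignment$pairs
  K <- nrow(p)
  if (K < 2L) stop("need at least 2 aligned pairs to build a morph")
  repar0 <- p[1L, 1L]
  repar1 <- p[1L, 2L]
  aligned <- 1
  for (q in seq_len(K - 1L)) {
    g0 <- p[q + 1L, 1L] - p[q, 1L]
    g1 <- p[q + 1L, 2L] - p[q, 2L]
    G <- max(g0, g1)
    repar0 <- c(repar0, p[q, 1L] + (seq_len(G) / G) * g0)
    repar1 <- c(repar1, p[q, 2L] + (seq_len(G) / G) * g1)
    aligned <- c(aligned, rep(0, G - 1L), 1)
  }
  w0 <- p[K, 1L] - p[1L, 1L] + 1L
  w1 <- p[K, 2L] - p[1L, 2L] + 1L
  structure(list(repar0 = repar0, repar1 = repar1, is_aligned = aligned,
                 awf = min(w0, w1) / min(alignment$n0, alignment$n1)),
            class = "reparam_pair")
}

#' @export
print.reparam_pair <- function(x, ...) {
  cat(sprintf("<reparam_pair> m = %d vertices, %d aligned, AWF %.3f\n",
              length(x$repar0), sum(x$is_aligned == 1), x$awf))
  invisible(x)
}

#' Evaluate a piecewise-linear curve at a real parameter
#'
#' `P[i + f] = (1 - f) p_i + f p_(i+1)` for integer i and fractional f.
#'
#' @param chain a [morph_chain()] or n x 3 matrix.
#' @param s real parameter(s) in `[1, n]`.
#' @return A length(s) x 3 matrix of points.
#' @export
eval_curve <- function(chain, s) {
  P <- chain_points(chain)
  n <- nrow(P)
  if (any(s < 1 - 1e-9) || any(s > n + 1e-9))
    stop("curve parameter out of [1, n]")
  s <- pmin(pmax(s, 1), n)
  i <- pmin(floor(s), n - 1L)
  f <- s - i
  (1 - f) * P[i, , drop = FALSE] + f * P[i + 1L, , drop = FALSE]
}

#' Native minimum-distance tables
#'
#' Shortest alpha-carbon pair distances observed in native structures as a
#' function of backbone separation.  Alpha representation: 2.8, 4.5, 3.86,
#' 3.47, 3.52, 3.48, 3.6 A for separations 1..7 and 3.7 A beyond; smooth
#' representation: 1.0, 2.1, 3.0, 3.4, 3.6 A for 1..5 and 3.7 A beyond.
#' d_min(1) is deliberately small so that local deformations (helix
#' compression) do not dominate the overlap.
#'
#' @param representation `"alpha"` or `"smooth"`.
#' @return Numeric vector of d_min values; the last entry extends to all
#'   larger separations.
#' @export
dmin_table <- function(representation = c("alpha", "smooth")) {
  switch(match.arg(representation),
         alpha  = c(2.8, 4.5, 3.86, 3.47, 3.52, 3.48, 3.6, 3.7),
         smooth = c(1.0, 2.1, 3.0, 3.4, 3.6, 3.7))
}

#' Interpolated d_min at fractional backbone separation
#'
#' Linear interpolation of the discrete d_min table between the floor and
#' ceiling of the separation; constant beyond the table's last index (and at
#' the first value below separation 1).  Reparameterized (gapped) morphs have
#' fractional separations, e.g. d_min(4.80) = 3.51 A for the alpha table.
#'
#' @param separation positive backbone separation(s) in (reparameterized)
#'   line segments.
#' @param table a [dmin_table()] vector.
#' @return d_min in Angstrom, vectorized over `separation`.
#' @export
interpolated_dmin <- function(separation, table = dmin_table("alpha")) {
  L <- length(table)
  s <- pmin(pmax(separation, 1), L)
  i <- pmin(floor(s), L - 1L)
  f <- s - i
  (1 - f) * table[i] + f * table[i + 1L]
}

# IsAligned at a real reparameterized curve parameter: linear interpolation
# of the 0/1 vertex flags on each segment.
is_aligned_at <- function(rp, a) {
  v <- rp$is_aligned
  m <- length(v)
  a <- pmin(pmax(a, 1), m)
  i <- pmin(floor(a), m - 1L)
  f <- a - i
  (1 - f) * v[i] + f * v[i + 1L]
}

#' Classify a self-intersection by alignment involvement
#'
#' AlignedSum = IsAligned(a_k) + IsAligned(b_k), with IsAligned linearly
#' interpolated on segments.  Classes: `aligned_aligned` for AlignedSum >=
#' 1.5, `aligned_gap` in (0.5, 1.5), `gap_gap` for <= 0.5.
#'
#' @param si a self-intersection (from [find_intersections()]).
#' @param rp a [build_reparam()] result.
#' @return One of `"aligned_aligned"`, `"aligned_gap"`, `"gap_gap"`.
#' @export
classify_intersection_alignment <- function(si, rp) {
  s <- is_aligned_at(rp, si$a) + is_aligned_at(rp, si$b)
  if (s >= 1.5) "aligned_aligned" else if (s > 0.5) "aligned_gap" else "gap_gap"
}
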