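#' Linear morph between two superimposed curves
#'
#' A `morph` holds two equal-length (reparameterized) point lists `curve0`
#' and `curve1`; the interpolation is P(t, a) = (1 - t) P0_a + t P1_a for
#' t in [0, 1] and curve parameter a in [1, m].
#'
#' @param curve0,curve1 m x 3 matrices (m >= 3).
#' @param representation `"alpha"` or `"smooth"`.
#' @param repar0,repar1 optional original-curve parameters of the m vertices
#'   (from [build_reparam()]); default 1..m (gapless identity).
#' @param provenance free text (alignment method).
#' @return An object of class `morph`.
#' @export
build_morph <- function(curve0, curve1, representation = c("alpha", "smooth"),
                        repar0 = NULL, repar1 = NULL, provenance = "") {
  representation <- match.arg(representation)
  curve0 <- as.matrix(curve0); curve1 <- as.matrix(curve1)
  dimnames(curve0) <- NULL
  dimnames(curve1) <- NULL
  m <- nrow(curve0)
  if (nrow(curve1) != m) stop("curve0 and curve1 must have equal length")
  if (m < 3L) stop("a morph needs at least 3 vertices")
  if (is.null(repar0)) repar0 <- seq_len(m)
  if (is.null(repar1)) repar1 <- seq_len(m)
  structure(list(curve0 = curve0, curve1 = curve1, m = m,
                 representation = representation,
                 repar0 = repar0, repar1 = repar1,
                 provenance = provenance),
            class = "morph")
}

#' Assemble the morph of an aligned chain pair
#'
#' Applies the alignment's rigid transform to chain 1, optionally smoothens
#' both chains, reparameterizes per the alignment and evaluates both curves
#' at the common vertices.
#'
#' @param chain0,chain1 [morph_chain()] objects.
#' @param alignment an [alignment_record()].
#' @param representation `"alpha"` or `"smooth"` (smoothing is applied to the
#'   raw chains, after the transform, before reparameterization).
#' @return A [build_morph()] object.
#' @export
morph_from_alignment <- function(chain0, chain1, alignment,
                                 representation = c("alpha", "smooth")) {
  representation <- match.arg(representation)
  P0 <- chain_points(chain0)
  P1 <- apply_transform(chain_points(chain1), alignment$rotation,
                        alignment$translation)
  if (representation == "smooth") {
    P0 <- chain_points(smooth_chain(morph_chain(P0)))
    P1 <- chain_points(smooth_chain(morph_chain(P1)))
  }
  rp <- build_reparam(alignment)
  morph <- build_morph(eval_curve(P0, rp$repar0), eval_curve(P1, rp$repar1),
                       representation = representation,
                       repar0 = rp$repar0, repar1 = rp$repar1,
                       provenance = alignment$method)
  morph$reparam <- rp
  morph
}

#' @export
print.morph <- function(x, ...) {
  cat(sprintf("<morph> %d vertices (%s representation, %s)\n",
              x$m, x$representation,
              if (nzchar(x$provenance)) x$provenance else "unaligned"))
  invisible(x)
}

#' Five-point convex smoothening of a backbone curve
#'
#' Replaces each interior point (i in 3..n-2) by the fixed convex combination
#' (C[i-2] + a C[i-1] + b C[i] + a C[i+1] + C[i+2]) / (2 + 2a + b) with
#' a = 2.4 and b = 2.1; the first two and last two points are kept.  The
#' weights minimize total curvature over native structures; the result
#' straightens helices and strands the way cartoon renderings do.
#'
#' @param chain a [morph_chain()] of length >= 5.
#' @param a_w,b_w smoothing weights.
#' @return A [morph_chain()] with representation `"smooth"`.
#' @export
smooth_chain <- function(chain, a_w = 2.4, b_w = 2.1) {
  P <- chain_points(chain)
  n <- nrow(P)
  if (n < 5L) stop("smoothing needs a chain of length >= 5")
  S <- P
  i <- 3:(n - 2L)
  S[i, ] <- (P[i - 2L, ] + a_w * P[i - 1L, ] + b_w * P[i, ] +
             a_w * P[i + 1L, ] + P[i + 2L, ]) / (2 + 2 * a_w + b_w)
  labs <- if (inherits(chain, "morph_chain")) chain$residue_labels else NULL
  src <- if (inherits(chain, "morph_chain")) chain$source_id else ""
  morph_chain(S, residue_labels = labs, representation = "smooth",
              source_id = src)
}

#' Evaluate the morph at (t, a)
#'
#' Bilinear: piecewise-linear interpolation along each curve at parameter
#' `a`, then the convex combination (1 - t) curve0 + t curve1.
#'
#' @param morph a [build_morph()] object.
#' @param t interpolation time in [0, 1].
#' @param a curve parameter(s) in [1, m].
#' @return length(a) x 3 matrix of points.
#' @export
morph_point <- function(morph, t, a) {
  if (t < -1e-12 || t > 1 + 1e-12) stop("t must be in [0, 1]")
  (1 - t) * eval_curve(morph$curve0, a) + t * eval_curve(morph$curve1, a)
}

# Full t-slice of the morph (all m vertices).
morph_slice <- function(morph, t) {
  (1 - t) * morph$curve0 + t * morph$curve1
}
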