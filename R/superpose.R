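#' Optimal rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD of `Y`
#' superimposed onto `X` (equal point counts, paired by row).  Reflections
#' are disallowed, so a mirror image of a chiral set keeps a positive RMSD.
#'
#' @param X,Y n x 3 coordinate matrices, n >= 3.
#' @return list with `rotation` (3 x 3, det +1), `translation`, and `rmsd`
#'   such that `apply_transform(Y, rotation, translation)` minimizes RMSD
#'   to `X`.
#' @export
kabsch_superpose <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of points")
  if (nrow(X) < 3L) stop("need at least 3 points for superposition")
  cx <- colMeans(X)
  cy <- colMeans(Y)
  Xc <- sweep(X, 2L, cx)
  Yc <- sweep(Y, 2L, cy)
  H <- t(Yc) %*% Xc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  Yr <- Yc %*% t(R)
  rmsd <- sqrt(mean(rowSums((Yr - Xc)^2)))
  translation <- cx - as.vector(R %*% cy)
  list(rotation = R, translation = translation, rmsd = rmsd)
}

# All placements of the whole shorter chain onto the longer one using a start
# offset, one inner gap and an end offset.  Returns a list of index vectors
# into the longer chain (each of length s) plus the gap description.
.gap_placements <- function(s, L) {
  D <- L - s
  out <- list()
  for (dg in 0:D) {
    gpos <- if (dg == 0L) 0L else seq_len(s - 1L)   # gap after shorter res g
    for (g in gpos) {
      for (off in 0:(D - dg)) {
        idx <- seq_len(s) + off
        if (dg > 0L) idx[(g + 1L):s] <- idx[(g + 1L):s] + dg
        out[[length(out) + 1L]] <- list(idx = idx, gap_pos = g,
                                        gap_len = dg, offset = off)
      }
    }
  }
  out
}

#' Global minimal-RMSD alignment with one inner gap
#'
#' Exhaustively aligns the entire shorter chain onto the longer one over all
#' placements of a start offset, a single inner gap and an end offset, and
#' returns the placement with minimal Kabsch RMSD.
#'
#' @param chain0,chain1 [morph_chain()] objects.
#' @param max_ratio maximal allowed length ratio longer/shorter (default 1.1).
#' @param allow_ratio_override set `TRUE` to align anyway.
#' @return An [alignment_record()] (method `"global_rmsd"`) whose transform
#'   superimposes chain 1 onto chain 0; the minimal RMSD is attached as
#'   attribute `"rmsd"`.
#' @export
global_rmsd_align <- function(chain0, chain1, max_ratio = 1.1,
                              allow_ratio_override = FALSE) {
  P0 <- chain_points(chain0)
  P1 <- chain_points(chain1)
  n0 <- nrow(P0); n1 <- nrow(P1)
  lo <- min(n0, n1); hi <- max(n0, n1)
  if (hi > max_ratio * lo && !allow_ratio_override)
    stop("length ratio ", round(hi / lo, 3), " exceeds max_ratio ", max_ratio,
         "; set allow_ratio_override = TRUE to align anyway")
  swap <- n1 < n0            # shorter chain drives the placement
  S <- if (swap) P1 else P0
  Lg <- if (swap) P0 else P1
  best <- NULL
  for (pl in .gap_placements(nrow(S), nrow(Lg))) {
    fit <- if (swap) kabsch_superpose(Lg[pl$idx, , drop = FALSE], S)
           else      kabsch_superpose(S, Lg[pl$idx, , drop = FALSE])
    if (is.null(best) || fit$rmsd < best$fit$rmsd)
      best <- list(fit = fit, pl = pl)
  }
  idx <- best$pl$idx
  pairs <- if (swap) cbind(idx, seq_len(nrow(S))) else cbind(seq_len(nrow(S)), idx)
  rec <- alignment_record(pairs, n0 = n0, n1 = n1,
                          rotation = best$fit$rotation,
                          translation = best$fit$translation,
                          method = "global_rmsd")
  attr(rec, "rmsd") <- best$fit$rmsd
  attr(rec, "gap") <- best$pl[c("gap_pos", "gap_len", "offset")]
  rec
}

#' Alignment scores from per-residue distances
#'
#' Computes RMSD, GDT-TS and TM-score from the distances `d` traveled by the
#' n aligned residues between superimposed structures:
#' RMSD = sqrt(mean(d^2)); GDT-TS averages, over thresholds 1, 2, 4, 8 A, the
#' fraction of residues within the threshold (non-strict); TM-score is
#' mean(1 / (1 + (d/d0)^2)) with d0 = 1.24 (n - 15)^(1/3) - 1.8.
#'
#' @param d numeric vector of non-negative distances in Angstrom.
#' @param n residue count used for normalization (defaults to `length(d)`).
#' @return An object of class `score_set` with fields `rmsd`, `gdt_ts`, `tm`,
#'   `d0`, `n`, `d`.  For n <= 15 the TM normalization distance d0 is
#'   undefined and `tm` is `NA` (with a warning); `rmsd` and `gdt_ts` are
#'   still returned.
#' @export
alignment_scores <- function(d, n = length(d)) {
  if (length(d) != n) stop("d must have n entries")
  if (any(d < 0)) stop("distances must be non-negative")
  rmsd <- sqrt(mean(d^2))
  gdt <- mean(vapply(c(1, 2, 4, 8), function(m) mean(d <= m), numeric(1L)))
  if (n > 15) {
    d0 <- 1.24 * (n - 15)^(1 / 3) - 1.8
    tm <- mean(1 / (1 + (d / d0)^2))
  } else {
    warning("TM-score undefined for n <= 15 (d0 not positive)")
    d0 <- NA_real_
    tm <- NA_real_
  }
  structure(list(rmsd = rmsd, gdt_ts = gdt, tm = tm, d0 = d0,
                 n = as.integer(n), d = d),
            class = "score_set")
}

#' @export
print.score_set <- function(x, ...) {
  cat(sprintf("<score_set> n = %d: RMSD %.3f A, GDT-TS %.3f, TM %.3f\n",
              x$n, x$rmsd, x$gdt_ts, x$tm))
  invisible(x)
}
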