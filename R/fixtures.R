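# Deterministic synthetic fixtures.  Coordinates are laid out on a grid of
# CA-spacing units (3.8 A) in the xy-plane with crossing heights given
# directly in Angstrom on z; static scaffold points carry a small fixed
# out-of-plane wiggle so that no segment pair is exactly coplanar for all t.

.CA <- 3.8

.wiggle <- function(idx, amp = 0.35) amp * sin(1.7 * idx + 0.4)

#' Crossing-change chain pair
#'
#' Two n-residue chains identical except that a symmetric over/under
#' crossing is interchanged: the over-crossing strand has z-heights
#' 0, 0, 1.25, 2.5, 2.5, 1.25, 0, 0 A and the under-crossing strand the
#' negated profile; in the second structure the two are swapped.  The total
#' motion is 4 residues traveling 5 A and 4 traveling 2.5 A, so the pair's
#' RMSD is below 12/sqrt(n) A while the linear morph contains exactly one
#' transversal self-intersection (at t* = 1/2) that changes the threading.
#' The crossing is embedded in a clash-free serpentine scaffold with 3.8 A
#' spacing whose return route stays more than 12 A from the crossing.
#'
#' @param n total residue count (>= 70; the return route needs ~65 points).
#' @return list of two [morph_chain()] objects `chain0`, `chain1`.
#' @export
make_crossing_change_pair <- function(n = 100L) {
  if (n < 70L) stop("n too small for the crossing-change scaffold (need >= 70)")
  r <- 8.5                                 # return-arc radius, grid units
  over_x <- seq(-3.5, 3.5)                 # 8 points on the x-axis
  east_x <- seq(4.5, 8.5)                  # 5 points
  n_arc <- 40L                             # three-quarter circle, ~unit chords
  th <- pi / 2 - (3 * pi / 2) * seq_len(n_arc) / n_arc
  arc <- cbind(8.5 + r * cos(th), -8.5 + r * sin(th))
  appr_y <- seq(-7.5, -4.5)                # 4 points
  under_y <- seq(-3.5, 3.5)                # 8 points
  core <- 8L + 5L + n_arc + 4L + 8L
  spare <- n - core
  n_lead <- spare %/% 2L
  n_tail <- spare - n_lead
  lead_x <- if (n_lead > 0L) seq(-3.5 - n_lead, -4.5) else numeric(0)
  tail_y <- if (n_tail > 0L) seq(4.5, 3.5 + n_tail) else numeric(0)
  xy <- rbind(cbind(lead_x, 0), cbind(over_x, 0), cbind(east_x, 0), arc,
              cbind(0, appr_y), cbind(0, under_y), cbind(0, tail_y))
  m <- nrow(xy)
  z0 <- .wiggle(seq_len(m))
  over_idx <- n_lead + seq_len(8L)
  under_idx <- n_lead + 8L + 5L + n_arc + 4L + seq_len(8L)
  heights <- c(0, 0, 1.25, 2.5, 2.5, 1.25, 0, 0)
  z0[over_idx] <- heights
  z0[under_idx] <- -heights
  z1 <- z0
  z1[over_idx] <- -heights
  z1[under_idx] <- heights
  P0 <- cbind(xy * .CA, z0)
  P1 <- cbind(xy * .CA, z1)
  list(chain0 = morph_chain(P0, source_id = "crossing-change structure 0"),
       chain1 = morph_chain(P1, source_id = "crossing-change structure 1"))
}

# Shared scaffold of the loop fixtures: a backbone loop whose crossing
# strands swap z-sign between the structures, giving one self-intersection
# at t* = 1/2 whose Omega_1 loop spans ~6 segments.
.loop_base <- function() {
  xy <- rbind(c(-4, 0), c(-3, 0), c(-2, 0),
              c(-1, 0), c(1, 0),            # crossing baseline (moving)
              c(3, 0), c(4, 1.5), c(3, 3), c(1, 3), c(0, 1.5),
              c(0, -1.5),                   # crossing strand (moving)
              c(0, -3), c(-1, -4), c(-2, -4))
  m <- nrow(xy)
  z0 <- .wiggle(seq_len(m))
  h <- 2.1
  z0[c(4L, 5L)] <- h
  z0[c(10L, 11L)] <- -h
  z1 <- z0
  z1[c(4L, 5L)] <- -h
  z1[c(10L, 11L)] <- h
  list(xy = xy, z0 = z0, z1 = z1)
}

#' Loop fixtures for the Omega-move tests
#'
#' `removable_loop`: a backbone loop whose handedness flips between the two
#' structures, giving one self-intersection removable by an isolated-disk
#' Omega_1 move.  `threaded_loop`: the same loop with a chain segment
#' threading the spanning disk, so the Omega_1 move is blocked.
#' `slide_pair`: a V-shaped strand swept across a second strand, giving two
#' opposite-sign self-intersections at nearby times that form a feasible
#' Omega_2 pair.
#'
#' @param kind one of `"removable_loop"`, `"threaded_loop"`, `"slide_pair"`.
#' @return list of two [morph_chain()] objects `chain0`, `chain1`.
#' @export
make_loop_fixtures <- function(kind = c("removable_loop", "threaded_loop",
                                        "slide_pair")) {
  kind <- match.arg(kind)
  if (kind %in% c("removable_loop", "threaded_loop")) {
    base <- .loop_base()
    xy <- base$xy; z0 <- base$z0; z1 <- base$z1
    if (kind == "threaded_loop") {
      # climb above the loop and dive through its spanning disk near the
      # centroid of the Omega_1 loop (about (1.7, 1.3) grid units)
      thread_xy <- rbind(c(2, -4), c(4, -4), c(5, -2.5), c(4.5, -0.5),
                         c(3.2, 0.6), c(1.7, 1.3), c(1.7, 1.3),
                         c(2.4, -0.5), c(3.5, -2), c(5, -3.5))
      thread_z <- c(0.3, 2, 5, 8, 8.5, 8.5, -6, -8, -7, -5)
      xy <- rbind(xy, thread_xy)
      z0 <- c(z0, thread_z)
      z1 <- c(z1, thread_z)
    }
    P0 <- cbind(xy * .CA, z0)
    P1 <- cbind(xy * .CA, z1)
  } else {
    # hairpin: a V-strand descends while the baseline right below it rises,
    # with slightly asymmetric heights so the two crossings happen at
    # distinct times; the short turn keeps the combined backbone span of
    # the two intersections within a MaxLength of 10
    v_xy <- rbind(c(-2, 1), c(0, -1), c(2, 1))
    turn_xy <- rbind(c(3.5, 1.5))
    base_xy <- rbind(c(4, 0), c(2, 0), c(0, 0), c(-2, 0), c(-4, 0))
    xy <- rbind(v_xy, turn_xy, base_xy)
    m <- nrow(xy)
    zc <- .wiggle(seq_len(m))
    z0 <- zc; z1 <- zc
    z0[1:3] <- 2.2;  z1[1:3] <- -2.4                    # the moving V
    bi <- (m - 4L):m                                    # baseline rows
    z0[bi] <- -2.0 - 0.05 * base_xy[, 1L]
    z1[bi] <- 1.6 + 0.10 * base_xy[, 1L]
    P0 <- cbind(xy * .CA, z0)
    P1 <- cbind(xy * .CA, z1)
  }
  list(chain0 = morph_chain(P0, source_id = paste0(kind, " structure 0")),
       chain1 = morph_chain(P1, source_id = paste0(kind, " structure 1")))
}

#' The 12/10-residue gapped-alignment worked example
#'
#' The alignment of a 12-residue chain 0 with a 10-residue chain 1 whose
#' first aligned pairs are (3, 1), (4, 2), (6, 3): chain 0 residue 5 is
#' unaligned against the gap between chain 1 residues 2 and 3, and the
#' block between pairs (7, 4) and (10, 8) leaves 3 open intervals on
#' chain 0 against 4 on chain 1.
#'
#' @return An [alignment_record()] with method `"tm_align"`.
#' @export
make_worked_alignment <- function() {
  parse_tmalign_output(worked_alignment_text())
}

#' @rdname make_worked_alignment
#' @export
worked_alignment_text <- function() {
  c("AAAAAAAAA---AAA",
    "  :: ::     :: ",
    "--AA-AA--AAAAAA")
}
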