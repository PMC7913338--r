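#' Analysis configuration
#'
#' @param max_length maximal backbone span (in residues/segments) a single
#'   Omega move may rearrange; 0 disables local moves entirely.
#' @param representation `"alpha"` (raw CA trace) or `"smooth"`
#'   (five-point convex smoothening).
#' @param allow_end_contractions try terminus contractions when essential
#'   self-intersections remain.
#' @param end_contraction_limit maximal contracted length per terminus in
#'   residues (default `max_length / 2`).
#' @param end_proximal_omega1 treat intersections within
#'   `end_contraction_limit` of a terminus as Omega_1-removable at the
#'   cheaper of the loop-rotation and contraction prices.
#' @param torsion_penalty_weight weight on the net torsional effect (the
#'   absolute signed sum of Omega_1-removed crossing signs); default 0.
#' @param overlap_weight weight on the mean overlap in the morph length;
#'   default 0.
#' @param use_cost_estimates use the linear-ramp estimate instead of exact
#'   end-contraction paths.
#' @param solver `"optimal"` (exact matching) or `"greedy"`.
#' @param use_filter use the overlap-based intersection-check filter.
#' @return A list of class `morph_config`.
#' @export
morph_config <- function(max_length = 10,
                         representation = c("alpha", "smooth"),
                         allow_end_contractions = FALSE,
                         end_contraction_limit = max_length / 2,
                         end_proximal_omega1 = FALSE,
                         torsion_penalty_weight = 0,
                         overlap_weight = 0,
                         use_cost_estimates = FALSE,
                         solver = c("optimal", "greedy"),
                         use_filter = TRUE) {
  stopifnot(max_length >= 0, torsion_penalty_weight >= 0, overlap_weight >= 0)
  structure(list(max_length = max_length,
                 representation = match.arg(representation),
                 allow_end_contractions = allow_end_contractions,
                 end_contraction_limit = end_contraction_limit,
                 end_proximal_omega1 = end_proximal_omega1,
                 torsion_penalty_weight = torsion_penalty_weight,
                 overlap_weight = overlap_weight,
                 use_cost_estimates = use_cost_estimates,
                 solver = match.arg(solver),
                 use_filter = use_filter),
            class = "morph_config")
}

# Thickness penalty of the moves actually used: each backbone point crossing
# from over- to under-sliding has to travel half the circumference of a
# circle of radius d/2 at the minimal overlap-free distance d = 3.7 A.
.thickness_penalty <- function(result, intersections, d = 3.7) {
  pen <- 0
  half_circ <- pi * d / 2
  for (v in result$omega1_used) {
    si <- intersections[[v]]
    pen <- pen + half_circ * abs(si$b - si$a + 1)
  }
  if (nrow(result$matching)) {
    for (r in seq_len(nrow(result$matching))) {
      sj <- intersections[[result$matching$vi[r]]]
      sk <- intersections[[result$matching$vj[r]]]
      pen <- pen + half_circ * abs((sj$b - sj$a) + (sk$b - sk$a) + 2)
    }
  }
  pen
}

#' Full steric/topological analysis of an aligned chain pair
#'
#' Applies the alignment transform (and optional smoothening), builds the
#' gap-filled morph, quantifies overlap, detects all transversal
#' self-intersections, prices Omega_1/Omega_2 removals under the MaxLength
#' bound, solves the essential-set matching problem and, when essential
#' self-intersections remain and end-contractions are allowed, optimizes a
#' removing N/C contraction pair.  Assembles the morph-length decomposition
#' and alignment scores.
#'
#' @param chain0,chain1 [morph_chain()] objects.
#' @param alignment an [alignment_record()], or `NULL` to compute the global
#'   minimal-RMSD one-inner-gap alignment.
#' @param config a [morph_config()].
#' @return An object of class `morph_report`.
#' @export
analyze_pair <- function(chain0, chain1, alignment = NULL,
                         config = morph_config()) {
  if (is.null(alignment))
    alignment <- global_rmsd_align(chain0, chain1)
  morph <- morph_from_alignment(chain0, chain1, alignment,
                                representation = config$representation)
  rp <- morph$reparam
  ov <- overlap_analysis(morph)
  dets <- find_intersections(morph, filter = if (config$use_filter) ov)
  sis <- dets$intersections
  for (k in seq_along(sis))
    sis[[k]]$alignment_class <- classify_intersection_alignment(sis[[k]], rp)

  o1 <- lapply(sis, omega1_candidate, morph = morph,
               max_length = config$max_length)
  if (config$end_proximal_omega1 && length(sis)) {
    for (k in seq_along(sis))
      o1[[k]] <- terminal_omega1_price(sis[[k]], morph, o1[[k]],
                                       window = config$end_contraction_limit,
                                       use_estimates = config$use_cost_estimates)
  }
  o2 <- list()
  if (length(sis) >= 2L) {
    for (p in seq_len(length(sis) - 1L)) {
      for (q in seq.int(p + 1L, length(sis))) {
        if (sis[[p]]$sign == sis[[q]]$sign) next
        blen <- (sis[[p]]$b - sis[[p]]$a) + (sis[[q]]$b - sis[[q]]$a)
        if (blen > config$max_length) next
        o2[[length(o2) + 1L]] <- omega2_candidate(sis[[p]], sis[[q]], morph,
                                                  config$max_length)
      }
    }
  }
  graph <- build_move_graph(sis, o1, o2)
  res <- solve_essential(graph, method = config$solver)
  essentials <- sis[res$essential]

  end_con <- NULL
  resolved_by_contraction <- FALSE
  if (res$n_essential > 0L && config$allow_end_contractions) {
    end_con <- optimize_end_contractions(
      essentials, morph,
      use_estimates = config$use_cost_estimates,
      max_contracted = config$end_contraction_limit)
    resolved_by_contraction <- is.finite(end_con$cost)
  }
  end_cost <- if (resolved_by_contraction) end_con$cost else 0

  disp <- sqrt(rowSums((morph$curve1 - morph$curve0)^2))
  scores <- suppressWarnings(alignment_scores(disp))  # tm is NA for m <= 15
  l1 <- sum(disp)
  thick <- .thickness_penalty(res, sis)
  torsion <- if (length(res$omega1_used))
    abs(sum(vapply(sis[res$omega1_used], `[[`, 0, "sign"))) else 0
  total <- l1 + res$total_price + thick + end_cost +
    config$torsion_penalty_weight * torsion +
    config$overlap_weight * ov$mean_overlap

  structure(list(
    config = unclass(config),
    alignment_method = alignment$method,
    n_vertices = morph$m,
    awf = rp$awf,
    scores = unclass(scores)[c("rmsd", "gdt_ts", "tm", "d0", "n")],
    overlap = list(mean_overlap = ov$mean_overlap,
                   local_overlap = ov$local_overlap,
                   nonlocal_overlap = ov$nonlocal_overlap),
    intersections = lapply(sis, function(s)
      s[c("k", "a", "b", "sign", "t_star", "alignment_class")]),
    diagnostics = dets$diagnostics,
    candidates = list(
      omega1 = lapply(o1, unclass),
      omega2 = lapply(o2, unclass)),
    essential_result = list(
      method = res$method,
      n_essential = res$n_essential,
      essential = res$essential,
      omega1_used = res$omega1_used,
      matching = res$matching,
      total_price = res$total_price),
    end_contractions = if (!is.null(end_con))
      end_con[c("a", "b", "cost", "cost_n", "cost_c", "k_n", "k_c")],
    resolved_by_contraction = resolved_by_contraction,
    self_avoiding = (res$n_essential == 0L) || resolved_by_contraction,
    lengths = list(l1_length = l1,
                   move_price_total = res$total_price,
                   thickness_penalty = thick,
                   end_contraction_cost = end_cost,
                   torsion_effect = torsion,
                   total_morph_length = total)),
    class = "morph_report")
}

#' Morph-length decomposition
#'
#' Re-sums the components of the self-avoiding morph-length estimate:
#' the L1 length of the linear morph (sum of per-vertex displacements),
#' the prices of the Omega moves used, the chain-thickness penalties
#' (pi d / 2 per affected residue interval, d = 3.7 A), the end-contraction
#' cost, and the weighted torsion/overlap terms.
#'
#' @param report a [analyze_pair()] report.
#' @param config the [morph_config()] used (weights are re-read from the
#'   report when omitted).
#' @return list with `total` and the individual components.
#' @export
morph_length <- function(report, config = NULL) {
  cf <- if (is.null(config)) report$config else unclass(config)
  L <- report$lengths
  total <- L$l1_length + L$move_price_total + L$thickness_penalty +
    L$end_contraction_cost +
    cf$torsion_penalty_weight * L$torsion_effect +
    cf$overlap_weight * report$overlap$mean_overlap
  list(total = total,
       l1_length = L$l1_length,
       move_price_total = L$move_price_total,
       thickness_penalty = L$thickness_penalty,
       end_contraction_cost = L$end_contraction_cost,
       torsion_effect = L$torsion_effect,
       mean_overlap = report$overlap$mean_overlap)
}

#' @export
print.morph_report <- function(x, ...) {
  cat("<morph_report>\n")
  cat(sprintf("  %d vertices (%s, %s alignment), AWF %.3f\n",
              x$n_vertices, x$config$representation, x$alignment_method,
              x$awf))
  cat(sprintf("  RMSD %.3f A, GDT-TS %.3f, TM %s\n", x$scores$rmsd,
              x$scores$gdt_ts,
              if (is.na(x$scores$tm)) "NA" else sprintf("%.3f", x$scores$tm)))
  cat(sprintf("  mean overlap %.4f A; %d self-intersection(s); %d essential\n",
              x$overlap$mean_overlap, length(x$intersections),
              x$essential_result$n_essential))
  cat(sprintf("  morph length %.1f A (L1 %.1f + moves %.1f + thickness %.1f + contraction %.1f)\n",
              x$lengths$total_morph_length, x$lengths$l1_length,
              x$lengths$move_price_total, x$lengths$thickness_penalty,
              x$lengths$end_contraction_cost))
  cat(sprintf("  %s\n", if (x$self_avoiding)
    "self-avoiding morph found" else "essential self-intersections remain"))
  invisible(x)
}
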