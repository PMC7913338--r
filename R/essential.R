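#' Build the move graph for the essential-set problem
#'
#' Vertices are the self-intersections; edges are the feasible Omega_2
#' moves.  With epsilon = 1 / (2 * sum of all feasible move prices), vertex
#' weights are w_v = epsilon * P1 for Omega_1-removable vertices and 1
#' otherwise, and edge weights w(e) = w_v(v_i) + w_v(v_j) - epsilon * P2.
#' A maximum-weight matching then simultaneously minimizes the number N of
#' remaining (essential) self-intersections and, subject to minimal N, the
#' total move price, through the identity
#' N(E') + epsilon P(E') = K + epsilon P1_all - sum_{e in E'} w(e).
#'
#' @param intersections an `intersection_set` or its `$intersections` list.
#' @param omega1_results list of [omega1_candidate()] results, one per
#'   intersection (same order).
#' @param omega2_results list of [omega2_candidate()] results (any order;
#'   infeasible ones are ignored).
#' @return An object of class `move_graph` with fields `n_vertices`,
#'   `omega1_feasible`, `p1`, `edges` (data frame: vi, vj, price, length,
#'   weight), `epsilon`, `K`, `p1_all`, `w_v`.
#' @export
build_move_graph <- function(intersections, omega1_results, omega2_results) {
  if (inherits(intersections, "intersection_set"))
    intersections <- intersections$intersections
  nv <- length(intersections)
  o1_feas <- vapply(omega1_results, function(c) isTRUE(c$feasible), logical(1L))
  p1 <- vapply(omega1_results, function(c) if (isTRUE(c$feasible)) c$price else NA_real_,
               numeric(1L))
  feas2 <- Filter(function(c) isTRUE(c$feasible), omega2_results)
  ed <- data.frame(vi = integer(0), vj = integer(0), price = numeric(0),
                   length = numeric(0), t_star = numeric(0))
  for (c2 in feas2) {
    mm <- sort(c2$members)
    ed <- rbind(ed, data.frame(vi = mm[1L], vj = mm[2L], price = c2$price,
                               length = c2$backbone_length,
                               t_star = min(vapply(
                                 intersections[mm], `[[`, 0, "t_star"))))
  }
  total <- sum(p1[o1_feas]) + sum(ed$price)
  eps <- if (total > 0) 1 / (2 * total) else 0
  w_v <- ifelse(o1_feas, eps * p1, 1)
  if (nrow(ed)) {
    ed$weight <- w_v[ed$vi] + w_v[ed$vj] - eps * ed$price
    ed <- ed[order(ed$length, ed$t_star, ed$vi, ed$vj), , drop = FALSE]
    rownames(ed) <- NULL
  } else {
    ed$weight <- numeric(0)
  }
  structure(list(n_vertices = nv, omega1_feasible = o1_feas, p1 = p1,
                 edges = ed, epsilon = eps, K = sum(!o1_feas),
                 p1_all = sum(p1[o1_feas]), w_v = w_v),
            class = "move_graph")
}

# Exact maximum-weight matching by memoized branch-and-bound over the edge
# list (edges pre-sorted by backbone length for deterministic tie-breaking:
# on equal weight the earlier edge set is preferred).  Exponential worst
# case but the graphs here have one vertex per morph self-intersection.
.max_weight_matching <- function(edges, n_vertices) {
  ne <- nrow(edges)
  if (ne == 0L) return(integer(0))
  memo <- new.env(hash = TRUE, parent = emptyenv())
  rec <- function(k, used) {
    if (k > ne) return(list(w = 0, sel = integer(0)))
    key <- paste0(k, "|", paste(which(used), collapse = ","))
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- rec(k + 1L, used)                     # skip edge k
    vi <- edges$vi[k]; vj <- edges$vj[k]
    if (!used[vi] && !used[vj] && edges$weight[k] > 0) {
      used2 <- used
      used2[c(vi, vj)] <- TRUE
      take <- rec(k + 1L, used2)
      if (take$w + edges$weight[k] >= best$w - 1e-12)  # prefer taking on ties
        best <- list(w = take$w + edges$weight[k], sel = c(k, take$sel))
    }
    memo[[key]] <- best
    best
  }
  rec(1L, rep(FALSE, n_vertices))$sel
}

#' Solve the essential self-intersection problem
#'
#' `optimal` computes an exact maximum-weight matching on the move graph;
#' the unmatched Omega_1-removable vertices are removed by Omega_1 moves and
#' the remaining vertices are the essential set, with guaranteed minimal
#' count N and minimal total price among minimal-N solutions.  `greedy`
#' scans the feasible Omega_2 moves by increasing backbone length (ties by
#' t*), accepts an edge when both of its vertices are still unused, then
#' applies all remaining Omega_1 moves; it can leave more essential
#' self-intersections than the optimum.  Membership of the essential set
#' may be tie-sensitive; its cardinality N is the robust quantity.
#'
#' @param graph a [build_move_graph()] result.
#' @param method `"optimal"` or `"greedy"`.
#' @return An object of class `essential_result` with `matching` (edge rows
#'   of `graph$edges`), `omega1_used`, `essential`, `n_essential`,
#'   `total_price`, and the objective value `objective`
#'   (= N + epsilon * price).
#' @export
solve_essential <- function(graph, method = c("optimal", "greedy")) {
  method <- match.arg(method)
  ed <- graph$edges
  if (method == "optimal") {
    sel <- .max_weight_matching(ed, graph$n_vertices)
  } else {
    sel <- integer(0)
    used <- rep(FALSE, graph$n_vertices)
    for (k in seq_len(nrow(ed))) {          # edges sorted by backbone length
      if (!used[ed$vi[k]] && !used[ed$vj[k]]) {
        sel <- c(sel, k)
        used[c(ed$vi[k], ed$vj[k])] <- TRUE
      }
    }
  }
  matched <- unique(c(ed$vi[sel], ed$vj[sel]))
  o1_used <- setdiff(which(graph$omega1_feasible), matched)
  essential <- setdiff(seq_len(graph$n_vertices), c(matched, o1_used))
  price <- sum(ed$price[sel]) + sum(graph$p1[o1_used])
  structure(list(method = method,
                 matching = ed[sel, , drop = FALSE],
                 omega1_used = o1_used,
                 essential = essential,
                 n_essential = length(essential),
                 total_price = price,
                 objective = length(essential) + graph$epsilon * price),
            class = "essential_result")
}

#' @export
print.essential_result <- function(x, ...) {
  cat(sprintf("<essential_result> (%s) N = %d essential, %d Omega2 + %d Omega1 moves, price %.2f A\n",
              x$method, x$n_essential, nrow(x$matching),
              length(x$omega1_used), x$total_price))
  invisible(x)
}
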