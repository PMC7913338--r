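#' Backbone chain objects
#'
#' A `morph_chain` is an ordered alpha-carbon (or smoothened) trace: an
#' n x 3 coordinate matrix in Angstrom plus residue labels.  Indices along the
#' chain are 1-based positions in the extracted trace, not author residue
#' numbers; the residue labels keep the original numbering for reporting.
#'
#' @param points numeric n x 3 matrix of coordinates in Angstrom.
#' @param residue_labels character or integer vector of length n.
#' @param representation `"alpha"` (raw CA trace) or `"smooth"`.
#' @param source_id free-text provenance tag.
#' @return An object of class `morph_chain`.
#' @export
morph_chain <- function(points, residue_labels = NULL,
                        representation = c("alpha", "smooth"),
                        source_id = "") {
  representation <- match.arg(representation)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  dimnames(points) <- NULL
  if (ncol(points) != 3L) stop("chain points must be an n x 3 matrix")
  n <- nrow(points)
  if (n < 3L) stop("a chain needs at least 3 points, got ", n)
  if (anyNA(points)) stop("chain coordinates contain NA")
  step <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                        points[-n, , drop = FALSE])^2))
  if (any(step < 1e-9)) stop("consecutive chain points must be distinct")
  if (is.null(residue_labels)) residue_labels <- as.character(seq_len(n))
  if (length(residue_labels) != n) stop("residue_labels length mismatch")
  structure(list(points = points,
                 residue_labels = as.character(residue_labels),
                 representation = representation,
                 source_id = source_id),
            class = "morph_chain")
}

#' @export
print.morph_chain <- function(x, ...) {
  cat(sprintf("<morph_chain> %d residues (%s representation)%s\n",
              nrow(x$points), x$representation,
              if (nzchar(x$source_id)) paste0(" from ", x$source_id) else ""))
  invisible(x)
}

#' @export
length.morph_chain <- function(x) nrow(x$points)

chain_points <- function(chain) {
  if (inherits(chain, "morph_chain")) chain$points else as.matrix(chain)
}

#' Read alpha-carbon coordinates from PDB text
#'
#' Extracts one point per residue having a CA record, in file order.
#' Alternate locations are resolved by highest occupancy, ties by first seen.
#'
#' @param pdb_text PDB-format text (single string or character vector of lines).
#' @param chain_id single chain identifier to extract.
#' @param model_index which MODEL block to read (1-based; files without MODEL
#'   records are treated as a single model).
#' @return A [morph_chain()] whose residue labels are the author residue
#'   numbers (with insertion codes).
#' @export
read_ca_coordinates <- function(pdb_text, chain_id, model_index = 1L) {
  lines <- if (length(pdb_text) == 1L && grepl("\n", pdb_text, fixed = TRUE))
    strsplit(pdb_text, "\n", fixed = TRUE)[[1L]] else pdb_text
  rec <- substr(lines, 1L, 6L)
  model_starts <- which(trimws(rec) == "MODEL")
  if (length(model_starts) > 0L) {
    if (model_index > length(model_starts))
      stop("model_index ", model_index, " but file has ",
           length(model_starts), " models")
    from <- model_starts[model_index]
    ends <- which(trimws(rec) == "ENDMDL")
    to <- ends[ends > from][1L]
    if (is.na(to)) to <- length(lines)
    lines <- lines[from:to]
    rec <- substr(lines, 1L, 6L)
  } else if (model_index != 1L) {
    stop("file has no MODEL records; only model_index = 1 is available")
  }
  atom <- lines[rec == "ATOM  " | rec == "HETATM"]
  if (length(atom) == 0L) stop("no ATOM/HETATM records found")
  name <- trimws(substr(atom, 13L, 16L))
  ca <- atom[name == "CA"]
  if (length(ca) == 0L) stop("no CA records found")
  chains <- substr(ca, 22L, 22L)
  avail <- unique(chains)
  ca <- ca[chains == chain_id]
  if (length(ca) == 0L)
    stop("chain '", chain_id, "' not found; available chains: ",
         paste(avail, collapse = ", "))
  resid <- paste0(trimws(substr(ca, 23L, 26L)), trimws(substr(ca, 27L, 27L)))
  occ <- suppressWarnings(as.numeric(substr(ca, 55L, 60L)))
  occ[is.na(occ)] <- 1
  keep <- integer(0)
  for (r in unique(resid)) {
    idx <- which(resid == r)
    keep <- c(keep, idx[which.max(occ[idx])])   # which.max: first on ties
  }
  keep <- sort(keep)
  ca <- ca[keep]
  if (length(ca) < 3L)
    stop("chain '", chain_id, "' has only ", length(ca),
         " CA records; need at least 3")
  xyz <- cbind(as.numeric(substr(ca, 31L, 38L)),
               as.numeric(substr(ca, 39L, 46L)),
               as.numeric(substr(ca, 47L, 54L)))
  morph_chain(xyz, residue_labels = resid[keep],
              source_id = paste0("chain ", chain_id))
}

#' Write a chain as minimal PDB text
#'
#' Emits CA-only ATOM records, one per chain point.  Used for fixtures and
#' round-trip tests.
#'
#' @param chain a [morph_chain()].
#' @param chain_id one-letter chain identifier.
#' @return Character vector of PDB lines.
#' @export
write_chain_pdb <- function(chain, chain_id = "A") {
  P <- chain_points(chain)
  n <- nrow(P)
  labs <- suppressWarnings(as.integer(chain$residue_labels))
  if (anyNA(labs)) labs <- seq_len(n)
  c(sprintf("ATOM  %5d  CA  GLY %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            seq_len(n), chain_id, labs, P[, 1L], P[, 2L], P[, 3L]),
    "TER", "END")
}

#' Alignment records
#'
#' Holds an ordered residue-pair alignment between two chains together with
#' the rigid transform that superimposes chain 1 onto chain 0.
#'
#' @param pairs integer K x 2 matrix: 1-based positions (chain 0, chain 1),
#'   strictly increasing in both columns.
#' @param weak_flags logical length K; `TRUE` marks weakly aligned (".")
#'   pairs, which are treated as aligned.
#' @param n0,n1 chain lengths.
#' @param rotation 3 x 3 proper rotation applied to chain 1.
#' @param translation length-3 translation applied to chain 1.
#' @param method how the alignment was obtained.
#' @return An object of class `alignment_record`.
#' @export
alignment_record <- function(pairs, weak_flags = NULL, n0, n1,
                             rotation = diag(3), translation = c(0, 0, 0),
                             method = c("external", "global_rmsd", "tm_align")) {
  method <- match.arg(method)
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  K <- nrow(pairs)
  if (K < 1L) stop("alignment needs at least one pair")
  if (is.null(weak_flags)) weak_flags <- rep(FALSE, K)
  if (any(diff(pairs[, 1L]) <= 0) || any(diff(pairs[, 2L]) <= 0))
    stop("alignment pairs must be strictly increasing in both chains")
  if (any(pairs[, 1L] < 1L) || any(pairs[, 1L] > n0) ||
      any(pairs[, 2L] < 1L) || any(pairs[, 2L] > n1))
    stop("alignment pair index out of chain range")
  if (abs(det(rotation) - 1) > 1e-6)
    stop("rotation must be proper (determinant +1)")
  structure(list(pairs = pairs, weak_flags = as.logical(weak_flags),
                 n0 = as.integer(n0), n1 = as.integer(n1),
                 rotation = rotation, translation = as.numeric(translation),
                 method = method),
            class = "alignment_record")
}

#' @export
print.alignment_record <- function(x, ...) {
  cat(sprintf("<alignment_record> %d pairs (%d weak), chains %d/%d, method %s\n",
              nrow(x$pairs), sum(x$weak_flags), x$n0, x$n1, x$method))
  invisible(x)
}

#' Parse a TM-align alignment block
#'
#' Reads the standard three-line block (sequence 0, marker line with
#' `:`/`.`/spaces, sequence 1).  Columns marked `:` or `.` become aligned
#' pairs; `.` columns are flagged weak but treated as aligned.  Gap columns
#' (`-`) advance only the chain that has a residue.
#'
#' @param text character vector of lines or a single string.
#' @return An [alignment_record()] with method `"tm_align"` and identity
#'   transform (TM-align output coordinates are already superimposed).
#' @export
parse_tmalign_output <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    strsplit(text, "\n", fixed = TRUE)[[1L]] else text
  lines <- lines[nzchar(sub("\\s+$", "", lines))]
  is_marker <- grepl("^[:. ]*$", lines) & grepl("[:.]", lines)
  mk <- which(is_marker)
  mk <- mk[mk > 1L & mk < length(lines)]
  if (length(mk) == 0L) stop("no TM-align marker line found")
  m <- mk[1L]
  seq0 <- lines[m - 1L]
  seq1 <- lines[m + 1L]
  marker <- lines[m]
  # the marker line may have trailing spaces trimmed by extraction
  marker <- formatC(marker, width = nchar(seq0), flag = "-")
  if (nchar(seq0) != nchar(seq1) || nchar(seq0) != nchar(marker))
    stop("TM-align block lines have unequal lengths (",
         nchar(seq0), ", ", nchar(marker), ", ", nchar(seq1), ")")
  c0 <- strsplit(seq0, "")[[1L]]
  c1 <- strsplit(seq1, "")[[1L]]
  cm <- strsplit(marker, "")[[1L]]
  i0 <- cumsum(c0 != "-")
  i1 <- cumsum(c1 != "-")
  aligned <- cm %in% c(":", ".")
  if (any(aligned & (c0 == "-" | c1 == "-")))
    stop("aligned column against a gap in the TM-align block")
  pairs <- cbind(i0[aligned], i1[aligned])
  alignment_record(pairs, weak_flags = cm[aligned] == ".",
                   n0 = max(i0), n1 = max(i1), method = "tm_align")
}

#' Format an alignment record as a TM-align block
#'
#' Inverse of [parse_tmalign_output()] up to gap layout: unaligned residues
#' are emitted as gap columns, so `parse(format(x))` reproduces `x`.
#'
#' @param record an [alignment_record()].
#' @return Character vector of three lines.
#' @export
format_tmalign <- function(record) {
  p <- record$pairs
  s0 <- character(0); s1 <- character(0); mk <- character(0)
  prev0 <- 0L; prev1 <- 0L
  emit_gap <- function(k0, k1) {
    g0 <- k0 - prev0 - 1L
    g1 <- k1 - prev1 - 1L
    s0 <<- c(s0, rep("A", g0), rep("-", g1))
    s1 <<- c(s1, rep("-", g0), rep("A", g1))
    mk <<- c(mk, rep(" ", g0 + g1))
  }
  for (k in seq_len(nrow(p))) {
    emit_gap(p[k, 1L], p[k, 2L])
    s0 <- c(s0, "A"); s1 <- c(s1, "A")
    mk <- c(mk, if (record$weak_flags[k]) "." else ":")
    prev0 <- p[k, 1L]; prev1 <- p[k, 2L]
  }
  emit_gap(record$n0 + 1L, record$n1 + 1L)
  c(paste(s0, collapse = ""), paste(mk, collapse = ""),
    paste(s1, collapse = ""))
}

#' Write / read a morph report as JSON
#'
#' Serializes every field of a morph report to structured JSON; numeric
#' values round-trip to at least 12 significant digits.
#'
#' @param report a `morph_report` from [analyze_pair()].
#' @param path output file path.
#' @export
write_report <- function(report, path) {
  x <- unclass(report)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  class(x) <- "morph_report"
  x
}
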