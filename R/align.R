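# Reference-anchored pairwise alignment. Classification only needs pairwise
# anchoring of each candidate onto the two reference frames, so an exact
# global (Needleman-Wunsch, affine-gap) aligner is used instead of a
# progressive multiple alignment. Scoring convention: a gap run of length L
# costs gap_open + L * gap_extend.

#' Build an alignment result from two gapped strings
#'
#' Low-level constructor used by [global_align()] and directly useful in
#' tests or when importing alignments computed elsewhere. Both strings must
#' have equal length; columns where both are gaps are not allowed.
#'
#' @param aligned_query,aligned_ref equal-length strings with `-` for gaps.
#' @param score numeric alignment score (NA if unknown).
#' @return an object of class `c6_alignment` with the gapped strings, the
#'   score, and a per-column coordinate map (`query_pos`, `ref_pos`, NA at
#'   gaps).
#' @export
alignment_from_strings <- function(aligned_query, aligned_ref, score = NA_real_) {
  q <- strsplit(aligned_query, "")[[1]]
  r <- strsplit(aligned_ref, "")[[1]]
  if (length(q) != length(r)) {
    stop("aligned strings have different lengths")
  }
  if (any(q == "-" & r == "-")) stop("column with gaps in both rows")
  qpos <- ifelse(q == "-", NA_integer_, cumsum(q != "-"))
  rpos <- ifelse(r == "-", NA_integer_, cumsum(r != "-"))
  structure(
    list(aligned_query = aligned_query, aligned_ref = aligned_ref,
         score = score,
         column_map = data.frame(column = seq_along(q),
                                 query_pos = as.integer(qpos),
                                 ref_pos = as.integer(rpos))),
    class = "c6_alignment"
  )
}

#' @export
print.c6_alignment <- function(x, ...) {
  cat("Global pairwise alignment (score ", format(x$score), ")\n", sep = "")
  cat("  query: ", x$aligned_query, "\n  ref:   ", x$aligned_ref, "\n", sep = "")
  invisible(x)
}

default_submat <- function() {
  # BLOSUM62 as shipped with Biostrings; community default for protein
  # global alignment.
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Optimal global alignment of two protein sequences
#'
#' Needleman-Wunsch with affine gaps: a gap run of length L costs
#' `gap_open + L * gap_extend`, end gaps included. The score is the maximum
#' attainable; the traceback is deterministic.
#'
#' @param query,ref amino-acid strings (no gap characters).
#' @param matrix substitution matrix (square, dimnames = residue letters);
#'   default BLOSUM62.
#' @param gap_open,gap_extend non-negative gap penalties (subtracted).
#' @return a `c6_alignment` (see [alignment_from_strings()]).
#' @export
global_align <- function(query, ref, matrix = NULL, gap_open = 11,
                         gap_extend = 1) {
  if (grepl("-", query, fixed = TRUE) || grepl("-", ref, fixed = TRUE)) {
    stop("sequences must not contain gap characters")
  }
  if (!nzchar(query) || !nzchar(ref)) stop("sequences must be non-empty")
  if (is.null(matrix)) matrix <- default_submat()
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(ref),
    substitutionMatrix = matrix,
    gapOpening = gap_open, gapExtension = gap_extend, type = "global")
  alignment_from_strings(
    as.character(Biostrings::alignedPattern(aln)),
    as.character(Biostrings::alignedSubject(aln)),
    Biostrings::score(aln))
}

#' Map a reference coordinate onto the query through an alignment
#'
#' Returns the 1-based query position aligned to reference position
#' `ref_pos`, or `NA` (gap flag) if the query has a gap there. Used to read
#' the residue at the site equivalent to position 52 of the mature
#' A. thaliana cytochrome c6A reference.
#'
#' @param aln a `c6_alignment`.
#' @param ref_pos 1-based position on the ungapped reference.
#' @return integer query position, or `NA_integer_` if gapped.
#' @export
map_position <- function(aln, ref_pos) {
  cm <- aln$column_map
  n_ref <- max(cm$ref_pos, 0L, na.rm = TRUE)
  if (!is.numeric(ref_pos) || length(ref_pos) != 1 || is.na(ref_pos) ||
      ref_pos < 1 || ref_pos > n_ref) {
    stop("ref_pos out of range [1, ", n_ref, "]")
  }
  col <- which(!is.na(cm$ref_pos) & cm$ref_pos == as.integer(ref_pos))
  cm$query_pos[[col]]
}

#' List query insertions relative to the reference
#'
#' Maximal runs of reference-gap columns, reported left to right. Each span
#' gives the query start/end of the inserted residues and the reference
#' position after which the insertion opens (0 if it opens before the first
#' reference residue).
#'
#' @param aln a `c6_alignment`.
#' @return data frame with columns `query_start`, `query_end`, `length`,
#'   `ref_after`, `n_cys` (cysteines within the inserted query residues).
#' @export
find_insertions <- function(aln) {
  cm <- aln$column_map
  gap <- is.na(cm$ref_pos)
  out <- data.frame(query_start = integer(0), query_end = integer(0),
                    length = integer(0), ref_after = integer(0),
                    n_cys = integer(0))
  if (!any(gap)) return(out)
  r <- rle(gap)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  qchars <- strsplit(aln$aligned_query, "")[[1]]
  for (k in which(r$values)) {
    cols <- starts[[k]]:ends[[k]]
    qs <- cm$query_pos[cols]
    ref_after <- if (starts[[k]] == 1L) 0L else cm$ref_pos[[starts[[k]] - 1L]]
    out <- rbind(out, data.frame(
      query_start = min(qs), query_end = max(qs),
      length = length(cols), ref_after = ref_after,
      n_cys = sum(qchars[cols] == "C")))
  }
  out[order(out$query_start), , drop = FALSE]
}

#' Fraction of reference positions aligned to query residues
#' @param aln a `c6_alignment`.
#' @return numeric in [0, 1].
#' @export
alignment_coverage <- function(aln) {
  cm <- aln$column_map
  ref_cols <- !is.na(cm$ref_pos)
  sum(ref_cols & !is.na(cm$query_pos)) / sum(ref_cols)
}
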