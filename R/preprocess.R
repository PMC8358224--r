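# Validity filtering and maturation. Candidates are screened on the
# precursor length window [80, 200] (bounds inclusive: a sequence is removed
# only when shorter than 80 or longer than 200 residues), matured by
# trimming the N-terminal targeting-peptide overhang against a mature
# reference, and re-screened for an appropriately located CXXCH motif.

#' Filtering configuration
#'
#' @param min_len,max_len inclusive precursor length window (residues);
#'   sequences shorter than `min_len` or longer than `max_len` fail.
#' @param motif_window 1-based inclusive window on the mature sequence in
#'   which the first cysteine of the CXXCH motif must fall. The haem
#'   attachment site is N-proximal in all family members, hence the default
#'   N-terminal window.
#' @param post_trim_min_len minimum mature length after trimming, guarding
#'   against degenerate trims.
#' @return a list of class `c6_filter_config`.
#' @export
filter_config <- function(min_len = 80, max_len = 200,
                          motif_window = c(5, 40), post_trim_min_len = 60) {
  stopifnot(min_len > 0, min_len <= max_len,
            length(motif_window) == 2, motif_window[1] >= 1,
            motif_window[1] <= motif_window[2], motif_window[2] <= max_len,
            post_trim_min_len > 0)
  structure(list(min_len = min_len, max_len = max_len,
                 motif_window = as.integer(motif_window),
                 post_trim_min_len = post_trim_min_len),
            class = "c6_filter_config")
}

#' Precursor length filter
#'
#' Applied to the untrimmed (precursor) sequence: candidates shorter than
#' `min_len` or longer than `max_len` residues are removed as implausible
#' family members.
#'
#' @param record one sequence record (one row of [sequence_records()]), or a
#'   plain residue string.
#' @param cfg a [filter_config()].
#' @return list with `pass` (logical) and `reason` (string, `""` on pass).
#' @export
length_filter <- function(record, cfg = filter_config()) {
  res <- if (is.character(record)) record else record$residues[[1]]
  n <- nchar(res)
  if (n < cfg$min_len) {
    list(pass = FALSE, reason = sprintf("below %d", cfg$min_len))
  } else if (n > cfg$max_len) {
    list(pass = FALSE, reason = sprintf("above %d", cfg$max_len))
  } else {
    list(pass = TRUE, reason = "")
  }
}

#' Locate the haem-binding CXXCH motif
#'
#' Finds the left-most occurrence of C-x-x-C-H whose first cysteine lies
#' inside `cfg$motif_window` on the (mature) sequence. Overlapping
#' occurrences are all considered. Occurrences outside the window never
#' qualify but are returned as diagnostics.
#'
#' @param seq amino-acid string.
#' @param cfg a [filter_config()].
#' @return list with `position` (1-based start of the qualifying motif, or
#'   `NA_integer_` if none) and `outside_window` (integer vector of
#'   non-qualifying occurrence starts).
#' @export
find_haem_motif <- function(seq, cfg = filter_config()) {
  hits <- gregexpr("(?=C..CH)", seq, perl = TRUE)[[1]]
  hits <- as.integer(hits[hits > 0])
  inside <- hits[hits >= cfg$motif_window[1] & hits <= cfg$motif_window[2]]
  list(position = if (length(inside)) inside[[1]] else NA_integer_,
       outside_window = setdiff(hits, inside))
}

#' Trim the N-terminal targeting peptide by alignment overhang
#'
#' The precursor is aligned to a mature, class-agnostic reference with a
#' semi-global alignment (reference fully aligned, query ends free); every
#' query residue preceding the first reference-aligned column is treated as
#' targeting peptide and removed. The C-terminus is never trimmed.
#' Idempotent: trimming a matured sequence again removes nothing.
#'
#' @param record one sequence record (one row) or a residue string.
#' @param refs a [reference_profile()]; the c6 reference is the trimming
#'   anchor.
#' @param matrix,gap_open,gap_extend alignment scoring, as [global_align()].
#' @param min_coverage minimum fraction of reference positions that must be
#'   aligned to query residues; below it trimming is refused and the record
#'   flagged untrimmable.
#' @return list with `source_id`, `residues` (matured), `trim_offset`
#'   (residues removed), and `untrimmable` (logical).
#' @export
trim_signal_peptide <- function(record, refs, matrix = NULL, gap_open = 11,
                                gap_extend = 1, min_coverage = 0.5) {
  res <- if (is.character(record)) record else record$residues[[1]]
  id <- if (is.character(record)) NA_character_ else record$id[[1]]
  if (is.null(matrix)) matrix <- default_submat()
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(res), Biostrings::AAString(refs$ref_c6),
    substitutionMatrix = matrix, gapOpening = gap_open,
    gapExtension = gap_extend, type = "local-global")
  qs <- Biostrings::start(Biostrings::pattern(aln))
  ref_gapped <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  qry_gapped <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  covered <- sum(ref_gapped != "-" & qry_gapped != "-") / nchar(refs$ref_c6)
  if (covered < min_coverage) {
    return(list(source_id = id, residues = res, trim_offset = 0L,
                untrimmable = TRUE))
  }
  offset <- qs - 1L
  list(source_id = id,
       residues = substr(res, offset + 1L, nchar(res)),
       trim_offset = as.integer(offset), untrimmable = FALSE)
}

#' Filter and mature a collection of candidate sequences
#'
#' Applies, in order: the precursor length filter, targeting-peptide
#' trimming, the post-trim length guard, and the in-window CXXCH check on
#' the matured sequence. The surviving set is independent of input order.
#' Records failing the motif check are retained (classification routes them
#' to UNCLASSIFIED with the motif reason); records failing length or
#' trimming are dropped.
#'
#' @param records sequence records from [read_fasta()]/[sequence_records()].
#' @param refs a [reference_profile()].
#' @param cfg a [filter_config()].
#' @param ... passed to [trim_signal_peptide()].
#' @return list with `matured` (data frame: id, taxon, residues,
#'   trim_offset, motif_position, n_ambiguous) and `dropped` (data frame:
#'   id, reason).
#' @export
preprocess_sequences <- function(records, refs, cfg = filter_config(), ...) {
  kept <- list(); dropped <- list()
  for (i in seq_len(nrow(records))) {
    rec <- records[i, , drop = FALSE]
    lf <- length_filter(rec, cfg)
    if (!lf$pass) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(id = rec$id, reason = lf$reason)
      next
    }
    tr <- trim_signal_peptide(rec, refs, ...)
    if (tr$untrimmable) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(id = rec$id, reason = "untrimmable")
      next
    }
    if (nchar(tr$residues) < cfg$post_trim_min_len) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(id = rec$id,
                   reason = sprintf("below %d after trimming",
                                    cfg$post_trim_min_len))
      next
    }
    motif <- find_haem_motif(tr$residues, cfg)
    kept[[length(kept) + 1L]] <- data.frame(
      id = rec$id, taxon = rec$taxon, residues = tr$residues,
      trim_offset = tr$trim_offset, motif_position = motif$position,
      n_ambiguous = rec$n_ambiguous, stringsAsFactors = FALSE)
  }
  list(
    matured = if (length(kept)) do.call(rbind, kept) else
      data.frame(id = character(0), taxon = character(0),
                 residues = character(0), trim_offset = integer(0),
                 motif_position = integer(0), n_ambiguous = integer(0)),
    dropped = if (length(dropped)) do.call(rbind, dropped) else
      data.frame(id = character(0), reason = character(0))
  )
}
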