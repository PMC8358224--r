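# The classification rules. A candidate with an appropriately located
# CXXCH haem-binding motif is assigned by the residue at the site
# equivalent to position 52 of mature A. thaliana cytochrome c6A:
# glutamine -> c6; valine/leucine/isoleucine with a two-cysteine loop
# insertion peptide -> c6A; valine/leucine/isoleucine without it -> c6B.
# Everything else (other residues, X, or a gap at the diagnostic site) is
# refused rather than guessed. c6B and c6C are deliberately merged under
# the single label C6B: they are orthologs and no sequence rule separates
# them.

CLASS_LABELS <- c("C6", "C6A", "C6B", "UNCLASSIFIED")

#' Diagnostic-residue rule sets
#'
#' @param high_potential_set residues implying a high redox midpoint
#'   potential (conserved glutamine of cytochrome c6).
#' @param low_potential_set hydrophobic residues implying a low redox
#'   midpoint potential (c6A/c6B).
#' @return list of class `c6_class_rule`.
#' @export
class_rule <- function(high_potential_set = "Q",
                       low_potential_set = c("V", "L", "I")) {
  stopifnot(length(high_potential_set) > 0, length(low_potential_set) > 0,
            !length(intersect(high_potential_set, low_potential_set)))
  structure(list(high_potential_set = high_potential_set,
                 low_potential_set = low_potential_set),
            class = "c6_class_rule")
}

#' LIP detection parameters
#'
#' The canonical loop insertion peptide is 12 residues with two cysteines
#' that form a disulfide bridge; the length window admits indel noise
#' without accepting unrelated insertions. Disulfide formation is
#' operationalized as a cysteine count within the insertion.
#'
#' @param min_len,max_len accepted insertion length range (residues).
#' @param min_cys minimum cysteines within the insertion.
#' @return list of class `c6_lip_spec`.
#' @export
lip_spec <- function(min_len = 8, max_len = 20, min_cys = 2) {
  stopifnot(min_len <= max_len, min_cys >= 0)
  structure(list(min_len = min_len, max_len = max_len, min_cys = min_cys),
            class = "c6_lip_spec")
}

#' Detect a loop insertion peptide against the c6 reference
#'
#' Among query insertions that open inside the loop window and whose length
#' lies in the accepted range, returns the left-most one with at least
#' `min_cys` cysteines. An in-window, in-range insertion with too few
#' cysteines is reported as a candidate (`low_cys_candidate`) but not
#' accepted: such sequences are later labelled C6B with a warning flag.
#'
#' @param aln a `c6_alignment` of the matured query against the c6
#'   reference.
#' @param spec a [lip_spec()].
#' @param loop_window inclusive window on the c6 reference within which the
#'   insertion must open (after-position coordinates).
#' @return list: `present`, `query_start`, `query_end`, `length`, `n_cys`,
#'   `ref_after`, `low_cys_candidate`.
#' @export
detect_lip <- function(aln, spec = lip_spec(), loop_window = c(35, 50)) {
  ins <- find_insertions(aln)
  qual <- ins[ins$ref_after >= loop_window[1] & ins$ref_after <= loop_window[2] &
                ins$length >= spec$min_len & ins$length <= spec$max_len, ,
              drop = FALSE]
  absent <- list(present = FALSE, query_start = NA_integer_,
                 query_end = NA_integer_, length = NA_integer_,
                 n_cys = 0L, ref_after = NA_integer_,
                 low_cys_candidate = FALSE)
  if (!nrow(qual)) return(absent)
  ok <- qual[qual$n_cys >= spec$min_cys, , drop = FALSE]
  if (!nrow(ok)) {
    absent$low_cys_candidate <- TRUE
    return(absent)
  }
  hit <- ok[1, ]
  list(present = TRUE, query_start = hit$query_start,
       query_end = hit$query_end, length = hit$length, n_cys = hit$n_cys,
       ref_after = hit$ref_after, low_cys_candidate = FALSE)
}

#' Extract classification evidence for one matured sequence
#'
#' Gathers the three pieces of evidence the rules need: the in-window CXXCH
#' motif position, the residue at the diagnostic site (read through a
#' global alignment to the c6A reference), and the LIP (read through a
#' global alignment to the c6 reference). Missing evidence is encoded as
#' `NA`, never defaulted.
#'
#' @param m one row of the `matured` frame from [preprocess_sequences()],
#'   or a plain mature residue string.
#' @param refs a [reference_profile()].
#' @param lip a [lip_spec()].
#' @param cfg a [filter_config()] (motif window).
#' @param matrix,gap_open,gap_extend alignment scoring, as [global_align()].
#' @return a list of class `c6_features`.
#' @export
extract_features <- function(m, refs, lip = lip_spec(), cfg = filter_config(),
                             matrix = NULL, gap_open = 11, gap_extend = 1) {
  if (is.character(m)) {
    residues <- m
    id <- NA_character_
    motif_pos <- find_haem_motif(residues, cfg)$position
  } else {
    residues <- m$residues[[1]]
    id <- m$id[[1]]
    motif_pos <- if ("motif_position" %in% names(m)) m$motif_position[[1]] else
      find_haem_motif(residues, cfg)$position
  }
  if (is.null(matrix)) matrix <- default_submat()
  aln_a <- global_align(residues, refs$ref_c6a, matrix, gap_open, gap_extend)
  aln_b <- global_align(residues, refs$ref_c6, matrix, gap_open, gap_extend)
  dpos <- map_position(aln_a, refs$diagnostic_position)
  diag_res <- if (is.na(dpos)) NA_character_ else
    substr(residues, dpos, dpos)
  structure(list(
    id = id,
    motif_position = motif_pos,
    diagnostic_residue = diag_res,
    diagnostic_query_pos = dpos,
    lip = detect_lip(aln_b, lip, refs$loop_window),
    alignment_scores = c(c6a = aln_a$score, c6 = aln_b$score)),
    class = "c6_features")
}

#' Assign a family label from extracted features
#'
#' Pure function implementing the decision table. Precedence: a missing
#' motif dominates all other evidence (the motif is a validity criterion).
#' Then the diagnostic residue decides: glutamine gives C6; a hydrophobic
#' V/L/I gives C6A when a LIP is present and C6B otherwise; any other
#' residue, an ambiguous X, or a gap at the diagnostic site refuses
#' classification.
#'
#' @param f a `c6_features` object from [extract_features()], or any list
#'   with `motif_position`, `diagnostic_residue` and `lip$present`.
#' @param rule a [class_rule()].
#' @return list with `label` (one of C6, C6A, C6B, UNCLASSIFIED), `reason`
#'   (machine-readable rule trace) and `warn` (flag for the single-cysteine
#'   insertion ambiguity).
#' @export
assign_class <- function(f, rule = class_rule()) {
  warn <- isTRUE(f$lip$low_cys_candidate)
  if (is.na(f$motif_position)) {
    return(list(label = "UNCLASSIFIED", reason = "no haem motif",
                warn = warn))
  }
  d <- f$diagnostic_residue
  if (is.na(d)) {
    return(list(label = "UNCLASSIFIED", reason = "diagnostic site gapped",
                warn = warn))
  }
  if (d == "X") {
    return(list(label = "UNCLASSIFIED",
                reason = "ambiguous residue X at diagnostic site",
                warn = warn))
  }
  if (d %in% rule$high_potential_set) {
    return(list(label = "C6", reason = sprintf("diagnostic residue %s", d),
                warn = warn))
  }
  if (d %in% rule$low_potential_set) {
    if (isTRUE(f$lip$present)) {
      return(list(label = "C6A",
                  reason = sprintf("diagnostic residue %s + LIP", d),
                  warn = FALSE))
    }
    return(list(label = "C6B",
                reason = sprintf("diagnostic residue %s, no LIP", d),
                warn = warn))
  }
  list(label = "UNCLASSIFIED",
       reason = sprintf("diagnostic residue %s outside rule sets", d),
       warn = warn)
}

#' Classify a collection of matured sequences
#'
#' @param matured the `matured` frame from [preprocess_sequences()].
#' @param refs a [reference_profile()].
#' @param lip a [lip_spec()]; `rule` a [class_rule()].
#' @param rule a [class_rule()].
#' @param cfg a [filter_config()].
#' @param ... alignment scoring arguments for [extract_features()].
#' @return classification report: data frame with id, taxon, label,
#'   motif_position, diagnostic_residue, lip_length, lip_cys_count, reason,
#'   warn_low_cys.
#' @export
classify_matured <- function(matured, refs, lip = lip_spec(),
                             rule = class_rule(), cfg = filter_config(), ...) {
  rows <- lapply(seq_len(nrow(matured)), function(i) {
    m <- matured[i, , drop = FALSE]
    f <- extract_features(m, refs, lip = lip, cfg = cfg, ...)
    cl <- assign_class(f, rule)
    data.frame(
      id = m$id, taxon = m$taxon, label = cl$label,
      motif_position = f$motif_position,
      diagnostic_residue = ifelse(is.na(f$diagnostic_residue), "-",
                                  f$diagnostic_residue),
      lip_length = ifelse(f$lip$present, f$lip$length, NA_integer_),
      lip_cys_count = ifelse(f$lip$present, f$lip$n_cys, 0L),
      reason = cl$reason, warn_low_cys = cl$warn,
      stringsAsFactors = FALSE)
  })
  if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(0), taxon = character(0), label = character(0),
               motif_position = integer(0), diagnostic_residue = character(0),
               lip_length = integer(0), lip_cys_count = integer(0),
               reason = character(0), warn_low_cys = logical(0))
}

#' Preprocess and classify raw candidate records end to end
#'
#' @param records sequence records from [read_fasta()].
#' @param refs a [reference_profile()].
#' @param cfg,lip,rule configuration objects.
#' @param ... alignment scoring arguments.
#' @return list with `report` (classification report) and `dropped`
#'   (records removed by preprocessing, with reasons).
#' @export
classify_sequences <- function(records, refs = default_references(),
                               cfg = filter_config(), lip = lip_spec(),
                               rule = class_rule(), ...) {
  pre <- preprocess_sequences(records, refs, cfg, ...)
  report <- classify_matured(pre$matured, refs, lip = lip, rule = rule,
                             cfg = cfg, ...)
  stopifnot(nrow(report) + nrow(pre$dropped) == nrow(records))
  list(report = report, dropped = pre$dropped)
}
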