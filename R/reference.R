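#' Reference profile anchoring classification coordinates
#'
#' Holds the two mature reference sequences and the coordinates that anchor
#' the rules: the diagnostic position on the c6A reference (position 52 of
#' mature A. thaliana cytochrome c6A in the canonical frame; numbering is on
#' the mature protein, signal peptide excluded) and the loop window on the
#' c6 reference inside which a loop insertion peptide (LIP) must open.
#'
#' @param ref_c6a mature c6A reference residue string (canonical accession
#'   Q93VA3.1; the package bundles a synthetic stand-in).
#' @param ref_c6 mature c6 reference residue string (canonical accession
#'   O30881.1; synthetic stand-in bundled).
#' @param diagnostic_position 1-based site on the mature c6A reference whose
#'   residue separates high- (Gln) from low-potential (Val/Leu/Ile) family
#'   members.
#' @param loop_window 1-based inclusive interval on the c6 reference within
#'   which a LIP insertion must open.
#' @param cfg [filter_config()] used to check both references carry a
#'   qualifying CXXCH motif.
#' @return a list of class `c6_reference_profile`.
#' @export
reference_profile <- function(ref_c6a, ref_c6, diagnostic_position = 52,
                              loop_window = c(35, 50),
                              cfg = filter_config()) {
  ref_c6a <- toupper(ref_c6a); ref_c6 <- toupper(ref_c6)
  stopifnot(diagnostic_position >= 1,
            diagnostic_position <= nchar(ref_c6a),
            length(loop_window) == 2, loop_window[1] >= 1,
            loop_window[1] <= loop_window[2],
            loop_window[2] <= nchar(ref_c6))
  if (is.na(find_haem_motif(ref_c6a, cfg)$position)) {
    stop("c6A reference lacks an in-window CXXCH motif")
  }
  if (is.na(find_haem_motif(ref_c6, cfg)$position)) {
    stop("c6 reference lacks an in-window CXXCH motif")
  }
  structure(list(ref_c6a = ref_c6a, ref_c6 = ref_c6,
                 diagnostic_position = as.integer(diagnostic_position),
                 loop_window = as.integer(loop_window)),
            class = "c6_reference_profile")
}

#' Bundled synthetic reference profile
#'
#' Loads the synthetic stand-in reference pair shipped with the package.
#' These are not the canonical database sequences (which are deliberately
#' not redistributed); they are constructed so that the canonical
#' coordinates hold exactly: the diagnostic site is position 52 on the
#' mature c6A stand-in, and its 12-residue, two-cysteine LIP opens inside
#' the default loop window (after position 38) of the c6 stand-in. Users
#' analysing real data should supply the canonical accessions via
#' [reference_profile()].
#'
#' @return a `c6_reference_profile`.
#' @export
default_references <- function() {
  path <- system.file("extdata", "synthetic_references.fasta",
                      package = "cytc6", mustWork = TRUE)
  recs <- read_fasta(path)
  reference_profile(
    ref_c6a = recs$residues[recs$id == "c6A_synthetic_ref"],
    ref_c6 = recs$residues[recs$id == "c6_synthetic_ref"],
    diagnostic_position = 52, loop_window = c(35, 50))
}
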