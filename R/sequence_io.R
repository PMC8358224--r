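# 20 standard residues plus X (unknown); everything else is rejected on input.
AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_ALLOWED <- c(AA_LETTERS, "X")

#' Construct a collection of protein sequence records
#'
#' The unit flowing through the pipeline is a data frame with one row per
#' sequence and columns `id`, `taxon`, `description`, `residues` and
#' `n_ambiguous` (count of `X` residues). Residues are validated against the
#' 20 standard amino-acid letters plus `X`; anything else is an error.
#'
#' @param id character vector of unique identifiers.
#' @param residues character vector of upper-case residue strings.
#' @param taxon character vector of organism names (may be empty strings).
#' @param description character vector of free-text descriptions.
#' @return a `data.frame` of validated sequence records.
#' @export
sequence_records <- function(id, residues, taxon = "", description = "") {
  id <- as.character(id)
  residues <- toupper(as.character(residues))
  n <- length(id)
  stopifnot(length(residues) == n)
  taxon <- rep_len(as.character(taxon), n)
  description <- rep_len(as.character(description), n)
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])
    stop("duplicate sequence id(s): ", paste(dup, collapse = ", "))
  }
  if (any(!nzchar(residues))) {
    stop("empty residue string for record(s): ",
         paste(id[!nzchar(residues)], collapse = ", "))
  }
  for (i in seq_len(n)) {
    bad <- setdiff(unique(strsplit(residues[[i]], "")[[1]]), AA_ALLOWED)
    if (length(bad)) {
      stop("record '", id[[i]], "' contains disallowed residue character(s): ",
           paste(bad, collapse = ", "))
    }
  }
  data.frame(
    id = id, taxon = taxon, description = description, residues = residues,
    n_ambiguous = vapply(residues, function(r) {
      sum(strsplit(r, "")[[1]] == "X")
    }, integer(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Read a protein FASTA file into sequence records
#'
#' Headers are split at the first whitespace: the leading token becomes the
#' record `id`, the remainder the `description`. By default the taxon is
#' parsed from a bracketed organism name (`[...]`) in the description, the
#' dialect used by the major protein databases; records without one get an
#' empty taxon. Multi-line (wrapped) sequence bodies are accepted.
#'
#' @param path path to a FASTA file.
#' @param taxon_from `"brackets"` (default) to parse `[Organism name]` from
#'   the description, or `"none"` to leave taxa empty.
#' @return sequence records as from [sequence_records()], in file order.
#' @export
read_fasta <- function(path, taxon_from = c("brackets", "none")) {
  taxon_from <- match.arg(taxon_from)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(trimws(lines) != "")
  if (!length(nonblank)) {
    warning("empty FASTA file: ", path)
    return(sequence_records(character(0), character(0)))
  }
  first <- nonblank[[1]]
  if (!startsWith(trimws(lines[[first]]), ">")) {
    stop("malformed FASTA: sequence data before any header at line ", first,
         " of ", path)
  }
  set <- Biostrings::readAAStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  taxon <- rep("", length(ids))
  if (taxon_from == "brackets") {
    hit <- regmatches(desc, regexpr("\\[[^]]+\\]", desc))
    has <- grepl("\\[[^]]+\\]", desc)
    taxon[has] <- gsub("^\\[|\\]$", "", hit)
  }
  sequence_records(ids, as.character(set), taxon = taxon, description = desc)
}

#' Write sequence records to a FASTA file
#'
#' Bodies are wrapped at 60 columns. Writing is deterministic: identical
#' records give byte-identical files. Round trip with [read_fasta()]
#' reproduces ids and residues exactly.
#'
#' @param records sequence records as from [sequence_records()].
#' @param path output file path.
#' @param width line width for sequence bodies.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    header <- records$id[[i]]
    if (nzchar(records$description[[i]])) {
      header <- paste(header, records$description[[i]])
    }
    writeLines(paste0(">", header), con)
    body <- records$residues[[i]]
    starts <- seq(1, nchar(body), by = width)
    writeLines(substring(body, starts, pmin(starts + width - 1, nchar(body))),
               con)
  }
  invisible(path)
}

#' Read a taxon-to-clade mapping from a tab-separated file
#'
#' Two columns: taxon and clade. A header row named `taxon`/`clade` (any
#' case) is skipped if present. Duplicate rows that agree are collapsed with
#' a warning; duplicates that disagree are an error.
#'
#' @param path path to a two-column TSV file.
#' @return a named character vector mapping taxon to clade.
#' @export
read_clade_map <- function(path) {
  if (!file.exists(path)) stop("clade map file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[trimws(lines) != ""]
  if (!length(lines)) return(stats::setNames(character(0), character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  start <- 1L
  if (length(fields[[1]]) >= 2 &&
      tolower(trimws(fields[[1]][[1]])) == "taxon" &&
      tolower(trimws(fields[[1]][[2]])) == "clade") {
    start <- 2L
  }
  taxa <- character(0); clades <- character(0)
  for (i in seq(start, length.out = length(lines) - start + 1)) {
    f <- trimws(fields[[i]])
    if (length(f) < 2 || !nzchar(f[[1]]) || !nzchar(f[[2]])) {
      stop("clade map line ", i, " does not have two tab-separated columns")
    }
    taxa <- c(taxa, f[[1]]); clades <- c(clades, f[[2]])
  }
  if (anyDuplicated(taxa)) {
    for (t in unique(taxa[duplicated(taxa)])) {
      cl <- unique(clades[taxa == t])
      if (length(cl) > 1) {
        stop("taxon '", t, "' mapped to conflicting clades: ",
             paste(cl, collapse = ", "))
      }
    }
    warning("duplicate consistent clade-map rows collapsed")
    keep <- !duplicated(taxa)
    taxa <- taxa[keep]; clades <- clades[keep]
  }
  stats::setNames(clades, taxa)
}
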