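# Workflow drivers. These are the programmatic equivalents of the three
# pipeline stages: simulate a labelled dataset, classify a FASTA against a
# reference profile, and map classifications onto a species tree with event
# reconstruction. Each writes plain-text outputs (TSV/JSON/FASTA/Newick)
# into an output directory and returns its results invisibly. Every run is
# fully accounted: input count = classified + unclassified + filtered.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate and write a synthetic dataset bundle
#'
#' @param scfg a [scenario_config()].
#' @param out_dir output directory (created if needed).
#' @return the [simulate_scenario()] result, invisibly. Writes
#'   `sequences.fasta`, `tree.nwk`, `truth_sequences.tsv`,
#'   `truth_presence.tsv`, `truth_events.tsv`, `references.fasta` and
#'   `manifest.json`.
#' @export
run_simulate <- function(scfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_scenario(scfg, sequences = TRUE)
  write_fasta(sim$records, file.path(out_dir, "sequences.fasta"))
  ape::write.tree(sim$tree, file.path(out_dir, "tree.nwk"))
  write_tsv(sim$truth, file.path(out_dir, "truth_sequences.tsv"))
  write_tsv(sim$presence, file.path(out_dir, "truth_presence.tsv"))
  write_tsv(sim$events, file.path(out_dir, "truth_events.tsv"))
  write_fasta(sequence_records(
    id = c("c6A_synthetic_ref", "c6_synthetic_ref"),
    residues = c(sim$refs$ref_c6a, sim$refs$ref_c6)),
    file.path(out_dir, "references.fasta"))
  manifest <- list(
    seed = scfg$seed, n_taxa = scfg$n_taxa, root_genes = scfg$root_genes,
    loss_prob = scfg$loss_prob, insertion_node = sim$insertion_node,
    generator = unclass(scfg$gen),
    reference_coordinates = list(
      diagnostic_position = sim$refs$diagnostic_position,
      loop_window = sim$refs$loop_window))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(sim)
}

#' Classify a FASTA of candidate sequences and write reports
#'
#' Runs preprocessing (length filter, targeting-peptide trimming, motif
#' check) and classification, writing `classification.tsv` (the per-record
#' report), `filtered.tsv` (records dropped in preprocessing, with
#' reasons) and `classification.json` (full rule traces).
#'
#' @param fasta path to a protein FASTA, or a records data frame.
#' @param refs a [reference_profile()].
#' @param out_dir output directory.
#' @param cfg,lip,rule configuration objects.
#' @return list with `report` and `dropped`, invisibly.
#' @export
run_classify <- function(fasta, refs = default_references(), out_dir,
                         cfg = filter_config(), lip = lip_spec(),
                         rule = class_rule()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  records <- if (is.character(fasta)) read_fasta(fasta) else fasta
  res <- classify_sequences(records, refs, cfg = cfg, lip = lip, rule = rule)
  stopifnot(nrow(res$report) + nrow(res$dropped) == nrow(records))
  write_tsv(res$report, file.path(out_dir, "classification.tsv"))
  write_tsv(res$dropped, file.path(out_dir, "filtered.tsv"))
  jsonlite::write_json(
    list(n_input = nrow(records),
         n_classified = sum(res$report$label != "UNCLASSIFIED"),
         n_unclassified = sum(res$report$label == "UNCLASSIFIED"),
         n_filtered = nrow(res$dropped),
         labels = as.list(table(res$report$label)),
         records = res$report),
    file.path(out_dir, "classification.json"),
    auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}

#' Map classifications onto a species tree and reconstruct events
#'
#' Builds the per-taxon presence matrix, the clade summary, and the Dollo
#' reconstructions: gain/loss for the c6 family and gain/loss plus LIP
#' insertion(s) for the c6B/c6A family. Taxa present in the report but
#' absent from the tree are listed with a warning and ignored in
#' reconstruction.
#'
#' @param report classification report (data frame or path to
#'   `classification.tsv`).
#' @param tree a `phylo` tree, or path/string for [read_newick()].
#' @param clade_map named vector from [read_clade_map()], or `NULL` to
#'   skip the clade summary.
#' @param out_dir output directory.
#' @return list with `presence`, `clade_summary`, `events` (table),
#'   `rec_c6`, `rec_c6b` (reconstruction objects), invisibly. Writes
#'   `presence_matrix.tsv`, `clade_summary.tsv`, `clade_summary.md`,
#'   `events.tsv` and `annotated_tree.nwk`.
#' @export
run_map <- function(report, tree, clade_map = NULL, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(report)) {
    report <- utils::read.delim(report, stringsAsFactors = FALSE)
  }
  if (is.character(tree)) tree <- read_newick(tree)
  tree <- prepare_tree(tree)
  presence <- build_presence_matrix(report)
  missing <- setdiff(presence$taxon, tree$tip.label)
  if (length(missing)) {
    warning("taxa in report absent from tree (ignored in reconstruction): ",
            paste(missing, collapse = ", "))
  }
  tips <- tree$tip.label
  row_of <- match(tips, presence$taxon)
  count_of <- function(cl) {
    v <- ifelse(is.na(row_of), 0L, presence[[cl]][row_of])
    stats::setNames(as.integer(v), tips)
  }
  c6 <- count_of("C6"); c6a <- count_of("C6A"); c6b <- count_of("C6B")
  rec_c6 <- dollo_reconstruct(tree, stats::setNames(as.integer(c6 >= 1), tips),
                              family = "C6")
  states <- ifelse(c6a >= 1 & c6b >= 1, "both",
                   ifelse(c6a >= 1, "C6A", ifelse(c6b >= 1, "C6B", "none")))
  rec_c6b <- reconstruct_c6a_transition(tree, stats::setNames(states, tips))
  ev <- events_table(rec_c6, rec_c6b)
  write_tsv(as.data.frame(presence), file.path(out_dir, "presence_matrix.tsv"))
  write_tsv(ev, file.path(out_dir, "events.tsv"))
  summary <- NULL
  if (!is.null(clade_map)) {
    summary <- summarize_by_clade(presence, clade_map)
    write_tsv(summary, file.path(out_dir, "clade_summary.tsv"))
    writeLines(clade_summary_markdown(summary),
               file.path(out_dir, "clade_summary.md"))
  }
  ann <- tree
  tags <- stats::setNames(rep("", length(node_labels(tree))), node_labels(tree))
  for (i in seq_len(nrow(ev))) {
    b <- ev$branch[[i]]
    tags[b] <- paste0(tags[b], sprintf(".%s_%s", ev$event[[i]], ev$family[[i]]))
  }
  tags <- gsub("/", "", tags, fixed = TRUE)
  all_labs <- paste0(node_labels(tree), tags)
  ann$tip.label <- all_labs[seq_along(tree$tip.label)]
  ann$node.label <- all_labs[-seq_along(tree$tip.label)]
  ape::write.tree(ann, file.path(out_dir, "annotated_tree.nwk"))
  invisible(list(presence = presence, clade_summary = summary, events = ev,
                 rec_c6 = rec_c6, rec_c6b = rec_c6b))
}

# Table-1-style Markdown rendering of the clade summary.
clade_summary_markdown <- function(summary) {
  cell <- function(taxa, total) {
    if (taxa == 0) "O" else sprintf("✓ (%d)", total)
  }
  lines <- c("| Clade | n | c6 | c6A | c6B |",
             "|---|---|---|---|---|")
  for (i in seq_len(nrow(summary))) {
    s <- summary[i, ]
    lines <- c(lines, sprintf(
      "| %s | %d | %s | %s | %s |", s$clade, s$n,
      cell(s$C6_taxa, s$C6_total), cell(s$C6A_taxa, s$C6A_total),
      cell(s$C6B_taxa, s$C6B_total)))
  }
  lines
}
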