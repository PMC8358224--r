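# Independent oracles used to cross-check the implementation: an
# exhaustive alignment-path enumerator, an exhaustive single-origin Dollo
# enumerator, a brute-force transition-placement search, and enumeration of
# all rooted binary labelled tree shapes for small leaf sets.

# Maximum affine-gap global alignment score by enumerating every alignment
# path. A gap run of length L costs open + L * ext (same convention as
# global_align), end gaps included. Exponential; for sequences <= 6 only.
brute_force_align_score <- function(q, r, mat, open, ext) {
  qc <- strsplit(q, "")[[1]]
  rc <- strsplit(r, "")[[1]]
  rec <- function(i, j, last) {
    if (i == length(qc) && j == length(rc)) return(0)
    best <- -Inf
    if (i < length(qc) && j < length(rc)) {
      best <- max(best, mat[qc[i + 1], rc[j + 1]] + rec(i + 1, j + 1, "m"))
    }
    if (i < length(qc)) {
      cost <- ext + if (last == "u") 0 else open
      best <- max(best, rec(i + 1, j, "u") - cost)
    }
    if (j < length(rc)) {
      cost <- ext + if (last == "l") 0 else open
      best <- max(best, rec(i, j + 1, "l") - cost)
    }
    best
  }
  rec(0L, 0L, "")
}

# Simple match/mismatch substitution matrix over a small alphabet.
simple_matrix <- function(letters, match = 1, mismatch = -1) {
  m <- matrix(mismatch, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- match
  m
}

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# All rooted binary leaf-labelled tree shapes on a label set, as Newick
# strings (without trailing semicolon). Each topology appears exactly once:
# the partition containing the first label is taken as the left child.
all_rooted_newick <- function(labels) {
  if (length(labels) == 1) return(labels)
  rest <- labels[-1]
  out <- character(0)
  for (k in 0:(length(rest) - 1)) {
    for (idx in if (k == 0) list(integer(0)) else
         asplit(utils::combn(length(rest), k), 2)) {
      left <- c(labels[1], rest[idx])
      right <- setdiff(labels, left)
      if (!length(right)) next
      for (lt in all_rooted_newick(left)) {
        for (rt in all_rooted_newick(right)) {
          out <- c(out, paste0("(", lt, ",", rt, ")"))
        }
      }
    }
  }
  out
}

tree_nodes <- function(tree) seq_len(length(tree$tip.label) + tree$Nnode)

oracle_clade_tips <- function(tree, v) {
  n_tip <- length(tree$tip.label)
  if (v <= n_tip) return(v)
  kids <- tree$edge[tree$edge[, 1] == v, 2]
  unlist(lapply(kids, oracle_clade_tips, tree = tree))
}

oracle_parent <- function(tree, v) {
  p <- tree$edge[tree$edge[, 2] == v, 1]
  if (length(p)) p else NA_integer_
}

# Minimal single-origin (Dollo) event count by enumerating every origin
# placement; for a fixed origin the minimal losses are the edges from a
# not-all-absent parent to an all-absent child within the origin's clade.
dollo_oracle_count <- function(tree, pres) {
  # pres: logical over tips in tip order
  if (!any(pres)) return(0L)
  n_tip <- length(tree$tip.label)
  best <- Inf
  for (origin in tree_nodes(tree)) {
    cl <- oracle_clade_tips(tree, origin)
    if (!all(which(pres) %in% cl)) next
    losses <- 0L
    for (v in tree_nodes(tree)) {
      if (v == origin) next
      p <- oracle_parent(tree, v)
      if (is.na(p)) next
      anc <- v; below <- FALSE
      while (!is.na(anc)) {
        if (anc == origin) { below <- TRUE; break }
        anc <- oracle_parent(tree, anc)
      }
      if (!below) next
      v_absent <- !any(pres[oracle_clade_tips(tree, v)])
      p_absent <- !any(pres[oracle_clade_tips(tree, p)])
      if (v_absent && !p_absent) losses <- losses + 1L
    }
    best <- min(best, 1L + losses)
  }
  as.integer(best)
}

# Brute-force transition placement: enumerate origin, every loss subset and
# every insertion subset, keep combinations whose forward replay equals the
# observed leaf states, and return the minimal total event count. Small
# trees only.
transition_oracle_count <- function(tree, states) {
  n_tip <- length(tree$tip.label)
  tips <- tree$tip.label
  st <- states[tips]
  if (all(st == "none")) return(0L)
  nodes <- tree_nodes(tree)
  anc_of <- function(a, v) {
    while (!is.na(v)) {
      if (v == a) return(TRUE)
      v <- oracle_parent(tree, v)
    }
    FALSE
  }
  replay <- function(origin, losses, ins) {
    out <- rep("none", n_tip)
    for (i in seq_len(n_tip)) {
      if (!anc_of(origin, i)) next
      if (any(vapply(losses, anc_of, logical(1), v = i))) next
      out[i] <- if (any(vapply(ins, anc_of, logical(1), v = i))) "C6A" else "C6B"
    }
    stats::setNames(out, tips)
  }
  subsets <- function(x) {
    do.call(c, lapply(0:length(x), function(k) {
      if (k == 0) list(integer(0)) else
        asplit(utils::combn(x, k), 2)
    }))
  }
  best <- Inf
  for (origin in nodes) {
    below <- nodes[vapply(nodes, function(v) anc_of(origin, v), logical(1))]
    cand <- setdiff(below, origin)
    for (losses in subsets(cand)) {
      for (ins in subsets(below)) {
        n_ev <- 1L + length(losses) + length(ins)
        if (n_ev >= best) next
        if (identical(replay(origin, losses, ins), st)) best <- n_ev
      }
    }
  }
  as.integer(best)
}

# Random rooted tree on n leaves, optionally with polytomies (collapsing
# random internal edges of a binary tree).
random_tree <- function(n, polytomy_prob = 0.25) {
  tr <- ape::rtree(n, tip.label = paste0("L", seq_len(n)))
  tr$edge.length <- rep(1, nrow(tr$edge))
  internal <- which(tr$edge[, 2] > length(tr$tip.label))
  collapse <- internal[stats::runif(length(internal)) < polytomy_prob]
  if (length(collapse)) {
    tr$edge.length[collapse] <- 0
    tr <- ape::di2multi(tr, tol = 1e-8)
  }
  tr
}

random_residues <- function(n, letters = c("A", "C", "D", "E", "F", "G", "H",
                                           "I", "K", "L", "M", "N", "P", "Q",
                                           "R", "S", "T", "V", "W", "Y")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# The published decision table, restated independently of assign_class.
expected_label <- function(motif_ok, diag, lip) {
  if (!motif_ok) return("UNCLASSIFIED")
  if (is.na(diag)) return("UNCLASSIFIED")
  if (diag == "Q") return("C6")
  if (diag %in% c("V", "L", "I")) return(if (lip) "C6A" else "C6B")
  "UNCLASSIFIED"
}

make_features <- function(motif_ok, diag, lip) {
  list(motif_position = if (motif_ok) 10L else NA_integer_,
       diagnostic_residue = diag,
       lip = list(present = lip, low_cys_candidate = FALSE))
}

# Plain data-frame view of a presence matrix (drops S3 attributes) for
# exact comparison against simulated truth tables.
presence_df <- function(pm) {
  data.frame(taxon = pm$taxon, C6 = pm$C6, C6A = pm$C6A, C6B = pm$C6B,
             stringsAsFactors = FALSE)
}
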