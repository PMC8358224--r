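# Presence/absence aggregation and event reconstruction. The ancestry model
# is formalized as Dollo parsimony: each gene family is gained exactly once
# (origin at the most recent common ancestor of the taxa carrying it) and
# lost any number of times (losses at the maximal all-absent subtrees below
# the origin). The c6A family is modelled as c6B-with-LIP: a single family
# origin plus one or more irreversible LIP-insertion transitions, each
# converting c6B to c6A in a subtree. More than one required insertion is
# reported as evidence the user must interpret (e.g. an independent LIP
# insertion in peridinin dinoflagellates).

#' Build a per-taxon presence matrix from a classification report
#'
#' Cell (taxon, class) counts the records of that taxon assigned that
#' label. A count above 1 marks a potential paralog. UNCLASSIFIED records
#' are excluded from the matrix but tallied in the `unclassified`
#' attribute.
#'
#' @param report classification report from [classify_matured()].
#' @return data frame of class `c6_presence` with columns `taxon`, `C6`,
#'   `C6A`, `C6B`; attributes `unclassified` (taxon, n) and `paralogs`
#'   (taxon, class rows with count > 1).
#' @export
build_presence_matrix <- function(report) {
  if (nrow(report) && any(!nzchar(report$taxon))) {
    stop("records without a taxon: ",
         paste(report$id[!nzchar(report$taxon)], collapse = ", "))
  }
  classified <- report[report$label != "UNCLASSIFIED", , drop = FALSE]
  taxa <- sort(unique(report$taxon))
  mat <- data.frame(taxon = taxa, C6 = integer(length(taxa)),
                    C6A = integer(length(taxa)), C6B = integer(length(taxa)),
                    stringsAsFactors = FALSE)
  for (cl in c("C6", "C6A", "C6B")) {
    tb <- table(classified$taxon[classified$label == cl])
    mat[[cl]][match(names(tb), mat$taxon)] <- as.integer(tb)
  }
  un <- report[report$label == "UNCLASSIFIED", , drop = FALSE]
  if (nrow(un)) {
    un_tab <- as.data.frame(table(taxon = un$taxon), stringsAsFactors = FALSE)
    names(un_tab) <- c("taxon", "n")
  } else {
    un_tab <- data.frame(taxon = character(0), n = integer(0))
  }
  par_rows <- do.call(rbind, lapply(c("C6", "C6A", "C6B"), function(cl) {
    hit <- mat$taxon[mat[[cl]] > 1]
    if (length(hit)) data.frame(taxon = hit, class = cl, count = mat[[cl]][mat[[cl]] > 1]) else NULL
  }))
  structure(mat, class = c("c6_presence", "data.frame"),
            unclassified = un_tab,
            paralogs = if (is.null(par_rows))
              data.frame(taxon = character(0), class = character(0),
                         count = integer(0)) else par_rows)
}

#' Read a species tree from a Newick file
#'
#' The basal node of the Newick string is always treated as the root
#' (including basal polytomies, which are accepted); no rerooting is ever
#' applied, so the rooting of the input is the user's scientific decision.
#' Internal nodes without labels receive stable generated labels.
#'
#' @param path path to a Newick file containing a single tree, or a Newick
#'   string ending in `;`.
#' @return an `ape` `phylo` tree with unique tip and node labels.
#' @export
read_newick <- function(path) {
  tr <- if (grepl(";", path, fixed = TRUE)) ape::read.tree(text = path)
        else ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick input")
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1) stop("expected a single tree, found ", length(tr))
    tr <- tr[[1]]
  }
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate leaf label(s): ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  }
  prepare_tree(tr)
}

# Ensure every node carries a unique label; tips keep theirs.
prepare_tree <- function(tree) {
  n_node <- tree$Nnode
  lab <- tree$node.label
  if (is.null(lab)) lab <- rep("", n_node)
  lab[is.na(lab)] <- ""
  need <- !nzchar(lab) | duplicated(lab) | lab %in% tree$tip.label
  lab[need] <- paste0("node", which(need))
  while (anyDuplicated(c(tree$tip.label, lab))) {
    dup <- duplicated(c(tree$tip.label, lab))[length(tree$tip.label) + seq_along(lab)]
    lab[dup] <- paste0(lab[dup], "_")
  }
  tree$node.label <- lab
  tree
}

node_labels <- function(tree) c(tree$tip.label, tree$node.label)

node_children <- function(tree) {
  ch <- vector("list", length(tree$tip.label) + tree$Nnode)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]
    ch[[p]] <- c(ch[[p]], tree$edge[i, 2])
  }
  ch
}

node_parents <- function(tree) {
  par <- rep(NA_integer_, length(tree$tip.label) + tree$Nnode)
  par[tree$edge[, 2]] <- tree$edge[, 1]
  par
}

clade_tips <- function(tree, node, ch = node_children(tree)) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(node)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    if (v <= n_tip) out <- c(out, v) else stack <- c(ch[[v]], stack)
  }
  out
}

is_ancestor <- function(tree, anc, node, par = node_parents(tree)) {
  while (!is.na(node)) {
    if (node == anc) return(TRUE)
    node <- par[node]
  }
  FALSE
}

#' Dollo reconstruction of one gene family on a species tree
#'
#' Single-gain reconstruction: the origin is placed at the most recent
#' common ancestor of all taxa carrying the family; losses at the maximal
#' all-absent subtrees below the origin. This placement is minimal among
#' all single-origin placements. An all-absent leaf vector yields an empty
#' reconstruction (no origin), not an error.
#'
#' @param tree a `phylo` tree (see [read_newick()]).
#' @param presence named 0/1 (or logical) vector over the tree's leaves.
#' @param family family name carried through to the event table.
#' @return list of class `c6_events`: `family`, `origin` (node label or
#'   NA), `losses` (labels of branches, named by child node), `n_events`
#'   (1 + number of losses, 0 if no origin).
#' @export
dollo_reconstruct <- function(tree, presence, family = "gene") {
  tree <- prepare_tree(tree)
  tips <- tree$tip.label
  if (!all(tips %in% names(presence))) {
    stop("presence vector missing leaves: ",
         paste(setdiff(tips, names(presence)), collapse = ", "))
  }
  pres <- as.logical(as.numeric(presence[tips]))
  n_tip <- length(tips)
  empty <- structure(list(family = family, origin = NA_character_,
                          origin_node = NA_integer_, losses = character(0),
                          loss_nodes = integer(0), n_events = 0L),
                     class = "c6_events")
  if (!any(pres)) return(empty)
  present_tips <- which(pres)
  origin <- if (length(present_tips) == 1) present_tips else
    ape::getMRCA(tree, tips[present_tips])
  ch <- node_children(tree)
  par <- node_parents(tree)
  n_all <- n_tip + tree$Nnode
  all_absent <- logical(n_all)
  for (v in seq_len(n_all)) {
    all_absent[v] <- !any(pres[clade_tips(tree, v, ch)])
  }
  losses <- integer(0)
  for (v in seq_len(n_all)) {
    if (v == origin || !all_absent[v]) next
    p <- par[v]
    if (!is.na(p) && !all_absent[p] && is_ancestor(tree, origin, v, par)) {
      losses <- c(losses, v)
    }
  }
  labs <- node_labels(tree)
  structure(list(family = family, origin = labs[origin],
                 origin_node = as.integer(origin),
                 losses = labs[losses], loss_nodes = as.integer(losses),
                 n_events = 1L + length(losses)),
            class = "c6_events")
}

#' Replay a reconstruction forward to leaf states
#'
#' Simulates the reconstructed events down the tree: present below the
#' origin except within lost subtrees. Used to verify that a
#' reconstruction implies exactly the observed leaf states.
#'
#' @param tree a `phylo` tree.
#' @param rec a `c6_events` reconstruction.
#' @return named 0/1 vector over leaves.
#' @export
replay_events <- function(tree, rec) {
  tree <- prepare_tree(tree)
  tips <- tree$tip.label
  out <- stats::setNames(rep(0L, length(tips)), tips)
  if (is.na(rec$origin_node)) return(out)
  par <- node_parents(tree)
  for (i in seq_along(tips)) {
    if (!is_ancestor(tree, rec$origin_node, i, par)) next
    lost <- any(vapply(rec$loss_nodes, function(l)
      is_ancestor(tree, l, i, par), logical(1)))
    if (!lost) out[[i]] <- 1L
  }
  out
}

#' Place LIP-insertion transitions for the c6B/c6A family
#'
#' Treats c6A as c6B-with-LIP: one Dollo origin for the whole family, plus
#' a minimal set of irreversible insertion branches each converting c6B to
#' c6A in its subtree. Insertions are placed at the maximal subtrees whose
#' present leaves are all c6A; distinct maximal subtrees cannot share an
#' insertion, so the count is minimal. More than one required insertion is
#' flagged (`multiple_insertions`).
#'
#' @param tree a `phylo` tree.
#' @param states named character vector over leaves with values `"none"`,
#'   `"C6B"`, `"C6A"`, or `"both"`; `"both"` raises a warning and is
#'   treated as c6A for placement (flagged in the result).
#' @return list of class `c6_transition`: the family `c6_events` fields
#'   plus `insertions` (branch labels), `insertion_nodes`,
#'   `multiple_insertions` flag, `flagged_leaves`, and total `n_events`
#'   (origin + losses + insertions).
#' @export
reconstruct_c6a_transition <- function(tree, states) {
  tree <- prepare_tree(tree)
  tips <- tree$tip.label
  if (!all(tips %in% names(states))) {
    stop("state vector missing leaves: ",
         paste(setdiff(tips, names(states)), collapse = ", "))
  }
  st <- as.character(states[tips])
  bad <- setdiff(unique(st), c("none", "C6B", "C6A", "both"))
  if (length(bad)) stop("invalid state(s): ", paste(bad, collapse = ", "))
  flagged <- tips[st == "both"]
  if (length(flagged)) {
    warning("leaf/leaves with both c6A and c6B treated as c6A: ",
            paste(flagged, collapse = ", "))
    st[st == "both"] <- "C6A"
  }
  presence <- stats::setNames(as.integer(st != "none"), tips)
  fam <- dollo_reconstruct(tree, presence, family = "C6B/C6A")
  if (is.na(fam$origin_node)) {
    return(structure(c(fam, list(insertions = character(0),
                                 insertion_nodes = integer(0),
                                 multiple_insertions = FALSE,
                                 flagged_leaves = flagged)),
                     class = c("c6_transition", "c6_events")))
  }
  ch <- node_children(tree)
  par <- node_parents(tree)
  n_tip <- length(tips)
  n_all <- n_tip + tree$Nnode
  qualifies <- logical(n_all)
  for (v in seq_len(n_all)) {
    if (!is_ancestor(tree, fam$origin_node, v, par)) next
    cl <- clade_tips(tree, v, ch)
    present <- cl[st[cl] != "none"]
    qualifies[v] <- length(present) > 0 && all(st[present] == "C6A")
  }
  ins <- integer(0)
  for (v in which(qualifies)) {
    p <- par[v]
    if (v == fam$origin_node || is.na(p) || !qualifies[p] ||
        !is_ancestor(tree, fam$origin_node, p, par)) {
      ins <- c(ins, v)
    }
  }
  labs <- node_labels(tree)
  structure(c(fam[setdiff(names(fam), "n_events")],
              list(insertions = labs[ins], insertion_nodes = as.integer(ins),
                   multiple_insertions = length(ins) > 1,
                   flagged_leaves = flagged,
                   n_events = fam$n_events + length(ins))),
            class = c("c6_transition", "c6_events"))
}

#' Replay a c6B/c6A transition reconstruction to leaf states
#'
#' @param tree a `phylo` tree.
#' @param rec a `c6_transition` reconstruction.
#' @return named character vector over leaves in `"none"`/`"C6B"`/`"C6A"`.
#' @export
replay_transition <- function(tree, rec) {
  tree <- prepare_tree(tree)
  tips <- tree$tip.label
  pres <- replay_events(tree, rec)
  par <- node_parents(tree)
  out <- stats::setNames(rep("none", length(tips)), tips)
  for (i in seq_along(tips)) {
    if (!pres[[i]]) next
    inserted <- any(vapply(rec$insertion_nodes, function(v)
      is_ancestor(tree, v, i, par), logical(1)))
    out[[i]] <- if (inserted) "C6A" else "C6B"
  }
  out
}

#' Convert reconstructions to an event table
#'
#' @param ... `c6_events` / `c6_transition` objects.
#' @return data frame with columns `family`, `event`, `branch` (child-node
#'   label of the branch carrying the event).
#' @export
events_table <- function(...) {
  recs <- list(...)
  rows <- lapply(recs, function(r) {
    out <- NULL
    if (!is.na(r$origin)) {
      out <- data.frame(family = r$family, event = "origin", branch = r$origin)
    }
    if (length(r$losses)) {
      out <- rbind(out, data.frame(family = r$family, event = "loss",
                                   branch = r$losses))
    }
    if (!is.null(r$insertions) && length(r$insertions)) {
      out <- rbind(out, data.frame(family = r$family, event = "lip_insertion",
                                   branch = r$insertions))
    }
    out
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) data.frame(family = character(0), event = character(0),
                               branch = character(0)) else out
}

#' Summarize a presence matrix by clade
#'
#' For each clade: the number of taxa (`n`), and per class the number of
#' taxa with at least one sequence and the total sequence count. Taxa
#' missing from the clade map are listed under clade `"unassigned"` with a
#' warning.
#'
#' @param matrix a `c6_presence` matrix from [build_presence_matrix()].
#' @param clade_map named character vector from [read_clade_map()].
#' @return data frame with columns `clade`, `n`, `C6_taxa`, `C6_total`,
#'   `C6A_taxa`, `C6A_total`, `C6B_taxa`, `C6B_total`.
#' @export
summarize_by_clade <- function(matrix, clade_map) {
  clade <- unname(clade_map[matrix$taxon])
  if (any(is.na(clade))) {
    warning("taxa missing from clade map listed as 'unassigned': ",
            paste(matrix$taxon[is.na(clade)], collapse = ", "))
    clade[is.na(clade)] <- "unassigned"
  }
  out <- lapply(split(seq_len(nrow(matrix)), clade), function(idx) {
    row <- data.frame(clade = clade[idx[[1]]], n = length(idx))
    for (cl in c("C6", "C6A", "C6B")) {
      row[[paste0(cl, "_taxa")]] <- sum(matrix[[cl]][idx] >= 1)
      row[[paste0(cl, "_total")]] <- sum(matrix[[cl]][idx])
    }
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$clade), , drop = FALSE]
}
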