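# Seeded synthetic data. A run draws one uniformly random scaffold (the
# shared backbone all sequences in the run derive from), plants the family
# anatomy on it (one in-window CXXCH motif, a diagnostic site, a loop
# opening point), and emits per-class sequences: the class residue at the
# diagnostic site, a two-cysteine LIP for c6A, an optional random targeting
# peptide, and i.i.d. substitution noise that never touches the motif, the
# diagnostic site or the LIP cysteines unless the adversarial flag is set.
# Per-sequence randomness is derived by stable hashing of the record id, so
# outputs are independent of generation order.

#' Generator configuration
#'
#' Defaults mirror the canonical family anatomy: mature sequences of
#' roughly one hundred residues, an N-proximal CXXCH motif, a LIP length
#' distribution centred on the canonical 12 residues with exactly two
#' cysteines, and cleavable targeting peptides of up to 40 residues.
#'
#' @param seed integer seed (mandatory: all outputs are reproducible).
#' @param mature_len_range scaffold length range (residues).
#' @param motif_pos_range range for the motif's first cysteine (1-based,
#'   within the default motif window).
#' @param lip_len_range LIP length range (uniform; canonical length 12).
#' @param lip_cys cysteines planted in each generated LIP.
#' @param signal_len_range targeting-peptide length range (residues).
#' @param noise per-residue substitution probability.
#' @param adversarial if TRUE, noise may also hit the planted motif,
#'   diagnostic site and LIP cysteines (used to exercise UNCLASSIFIED
#'   routing).
#' @return list of class `c6_generator_config`.
#' @export
generator_config <- function(seed, mature_len_range = c(85, 120),
                             motif_pos_range = c(10, 25),
                             lip_len_range = c(10, 16), lip_cys = 2,
                             signal_len_range = c(0, 40), noise = 0.02,
                             adversarial = FALSE) {
  stopifnot(is.numeric(seed), length(seed) == 1,
            mature_len_range[1] >= 80,
            mature_len_range[1] <= mature_len_range[2],
            motif_pos_range[1] >= 5, motif_pos_range[2] <= 35,
            motif_pos_range[1] <= motif_pos_range[2],
            lip_len_range[1] >= 4, lip_len_range[1] <= lip_len_range[2],
            lip_cys >= 0, lip_cys <= lip_len_range[1] - 3,
            signal_len_range[1] >= 0,
            signal_len_range[1] <= signal_len_range[2],
            noise >= 0, noise <= 1)
  structure(list(seed = as.integer(seed),
                 mature_len_range = as.integer(mature_len_range),
                 motif_pos_range = as.integer(motif_pos_range),
                 lip_len_range = as.integer(lip_len_range),
                 lip_cys = as.integer(lip_cys),
                 signal_len_range = as.integer(signal_len_range),
                 noise = noise, adversarial = isTRUE(adversarial)),
            class = "c6_generator_config")
}

# Run code under a given seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Stable 31-bit hash of a string, combined with the run seed; keeps
# per-sequence substreams independent of generation order.
stable_hash <- function(seed, id) {
  h <- as.numeric(seed) %% 2147483647
  for (code in utf8ToInt(id)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

sample_range <- function(range) {
  if (range[1] == range[2]) range[1] else sample(range[1]:range[2], 1)
}

# Letters safe for LIP interiors and sanitization replacements: anything
# that cannot create or complete a CXXCH pattern.
AA_SAFE <- setdiff(AA_LETTERS, c("C", "H"))

# Mutate the histidine of any stray in-window CXXCH occurrence that is not
# the planted one; replacement letters cannot re-create a motif.
sanitize_motifs <- function(chars, planted_start, window) {
  repeat {
    seq <- paste(chars, collapse = "")
    hits <- gregexpr("(?=C..CH)", seq, perl = TRUE)[[1]]
    hits <- as.integer(hits[hits > 0])
    stray <- hits[hits != planted_start & hits >= window[1] & hits <= window[2]]
    if (!length(stray)) return(chars)
    chars[stray[[1]] + 4L] <- sample(AA_SAFE, 1)
  }
}

#' Initialize a generator run (scaffold and planted coordinates)
#'
#' Draws the run scaffold and the anatomy coordinates. The matching
#' reference pair for classifying this run's output is given by
#' [generator_references()].
#'
#' @param cfg a [generator_config()].
#' @return list of class `c6_generator`: the config plus `scaffold`
#'   (residue string), `motif_start`, `diag_pos` (scaffold coordinate),
#'   `loop_after` (scaffold position after which LIPs open), and `ref_lip`
#'   (the 12-residue reference LIP).
#' @export
new_generator <- function(cfg) {
  stopifnot(inherits(cfg, "c6_generator_config"))
  with_seed(cfg$seed, {
    len <- sample_range(cfg$mature_len_range)
    chars <- sample(AA_LETTERS, len, replace = TRUE)
    m <- sample_range(cfg$motif_pos_range)
    chars[m] <- "C"
    chars[m + 1L] <- sample(AA_SAFE, 1)
    chars[m + 2L] <- sample(AA_SAFE, 1)
    chars[m + 3L] <- "C"
    chars[m + 4L] <- "H"
    d <- sample(45:min(60, len - 20), 1)
    p <- d - sample(2:6, 1)
    chars[d] <- "Q"
    chars <- sanitize_motifs(chars, m, filter_config()$motif_window)
    ref_lip <- sample(AA_SAFE, 12, replace = TRUE)
    ref_lip[c(3, 10)] <- "C"
    # pin the insertion boundaries: if a boundary residue equalled its
    # flanking scaffold residue the gap placement would be ambiguous and
    # planted coordinates would not be recoverable even at zero noise
    ref_lip[1] <- sample(setdiff(AA_SAFE, chars[p + 1L]), 1)
    ref_lip[12] <- sample(setdiff(AA_SAFE, chars[p]), 1)
    structure(c(unclass(cfg),
                list(scaffold = paste(chars, collapse = ""),
                     motif_start = as.integer(m), diag_pos = as.integer(d),
                     loop_after = as.integer(p),
                     ref_lip = paste(ref_lip, collapse = ""))),
              class = "c6_generator")
  })
}

#' Reference profile matching a generator run
#'
#' The c6 reference is the run scaffold with glutamine at the diagnostic
#' site; the c6A reference additionally carries a valine there and the
#' 12-residue reference LIP. The diagnostic position and loop window are
#' expressed in the respective reference coordinates.
#'
#' @param gen a `c6_generator` from [new_generator()].
#' @return a [reference_profile()].
#' @export
generator_references <- function(gen) {
  sc <- strsplit(gen$scaffold, "")[[1]]
  ref_c6 <- paste(sc, collapse = "")
  sc_a <- sc
  sc_a[gen$diag_pos] <- "V"
  ref_c6a <- paste(c(sc_a[seq_len(gen$loop_after)],
                     strsplit(gen$ref_lip, "")[[1]],
                     sc_a[(gen$loop_after + 1L):length(sc_a)]),
                   collapse = "")
  reference_profile(ref_c6a = ref_c6a, ref_c6 = ref_c6,
                    diagnostic_position = gen$diag_pos + nchar(gen$ref_lip),
                    loop_window = c(max(gen$motif_start + 5L, gen$loop_after - 5L),
                                    gen$loop_after + 5L))
}

#' Generate one labelled synthetic sequence with ground truth
#'
#' @param class_label one of `"C6"`, `"C6A"`, `"C6B"`.
#' @param gen a `c6_generator`.
#' @param id record identifier (also seeds the per-sequence substream).
#' @param taxon taxon name recorded on the output.
#' @return list with `record` (one-row sequence record, precursor
#'   residues) and `truth` (one-row data frame of every planted feature:
#'   class, signal length, motif start, diagnostic position, LIP
#'   coordinates and cysteine positions, all in mature coordinates).
#' @export
generate_sequence <- function(class_label, gen, id, taxon = "") {
  stopifnot(class_label %in% c("C6", "C6A", "C6B"))
  with_seed(stable_hash(gen$seed, paste0(id, "|", class_label)), {
    chars <- strsplit(gen$scaffold, "")[[1]]
    d <- gen$diag_pos
    chars[d] <- if (class_label == "C6") "Q" else sample(c("V", "L", "I"), 1)
    lip_len <- NA_integer_; lip_cys_at <- integer(0)
    if (class_label == "C6A") {
      lip_len <- sample_range(gen$lip_len_range)
      lip <- sample(AA_SAFE, lip_len, replace = TRUE)
      if (gen$lip_cys > 0) {
        lip_cys_at <- sort(sample(3:(lip_len - 1L), gen$lip_cys))
        lip[lip_cys_at] <- "C"
      }
      # unambiguous gap placement: boundary residues must differ from the
      # flanking scaffold residues (cysteines are never at the boundaries)
      lip[1] <- sample(setdiff(AA_SAFE, chars[gen$loop_after + 1L]), 1)
      lip[lip_len] <- sample(setdiff(AA_SAFE, chars[gen$loop_after]), 1)
      chars <- c(chars[seq_len(gen$loop_after)], lip,
                 chars[(gen$loop_after + 1L):length(chars)])
      d <- d + lip_len
    }
    diag_mature <- d
    protected <- c(gen$motif_start:(gen$motif_start + 4L), diag_mature,
                   if (length(lip_cys_at)) gen$loop_after + lip_cys_at)
    if (gen$adversarial) protected <- integer(0)
    hit <- which(runif(length(chars)) < gen$noise)
    hit <- setdiff(hit, protected)
    for (i in hit) chars[i] <- sample(setdiff(AA_LETTERS, chars[i]), 1)
    sp_len <- sample_range(gen$signal_len_range)
    sp <- if (sp_len > 0) sample(AA_LETTERS, sp_len, replace = TRUE) else character(0)
    record <- sequence_records(
      id = id, residues = paste(c(sp, chars), collapse = ""),
      taxon = taxon,
      description = sprintf("synthetic %s [%s]", class_label,
                            if (nzchar(taxon)) taxon else "unknown"))
    truth <- data.frame(
      id = id, class = class_label, signal_len = as.integer(sp_len),
      mature_len = length(chars),
      motif_start = gen$motif_start, diag_pos = as.integer(diag_mature),
      lip_start = if (class_label == "C6A") gen$loop_after + 1L else NA_integer_,
      lip_end = if (class_label == "C6A") gen$loop_after + lip_len else NA_integer_,
      lip_len = as.integer(lip_len),
      lip_cys = if (length(lip_cys_at))
        paste(gen$loop_after + lip_cys_at, collapse = ",") else "",
      stringsAsFactors = FALSE)
    list(record = record, truth = truth)
  })
}

#' Generate a labelled synthetic dataset
#'
#' @param labels character vector of class labels (one sequence each).
#' @param gen a `c6_generator`.
#' @param ids optional record ids (default `seq0001_<label>` style).
#' @param taxa optional taxon names per sequence.
#' @return list with `records` (sequence records) and `truth` (data frame).
#' @export
generate_dataset <- function(labels, gen, ids = NULL, taxa = "") {
  if (is.null(ids)) {
    ids <- sprintf("seq%04d_%s", seq_along(labels), tolower(labels))
  }
  taxa <- rep_len(taxa, length(labels))
  out <- Map(function(l, i, t) generate_sequence(l, gen, i, t),
             labels, ids, taxa)
  list(records = do.call(rbind, lapply(out, `[[`, "record")),
       truth = do.call(rbind, lapply(out, `[[`, "truth")))
}

#' Scenario configuration for simulated family evolution
#'
#' @param seed integer seed.
#' @param n_taxa number of leaves on the simulated species tree.
#' @param root_genes families present at the root (`"C6"` and/or `"C6B"`).
#' @param loss_prob per-branch loss probability, a scalar or a named
#'   vector over families.
#' @param insertion_node label of the branch (child node) where the
#'   c6B-to-c6A LIP insertion occurs; `NULL` picks a random internal
#'   branch whose clade holds between 2 and `n_taxa - 2` leaves.
#' @param gen a [generator_config()] for leaf sequence emission (default:
#'   derived from `seed`).
#' @return list of class `c6_scenario_config`.
#' @export
scenario_config <- function(seed, n_taxa = 24, root_genes = c("C6", "C6B"),
                            loss_prob = 0.1, insertion_node = NULL,
                            gen = NULL) {
  stopifnot(n_taxa >= 3, all(root_genes %in% c("C6", "C6B")),
            all(loss_prob >= 0), all(loss_prob <= 1))
  if (is.null(gen)) gen <- generator_config(seed = seed + 7919L)
  structure(list(seed = as.integer(seed), n_taxa = as.integer(n_taxa),
                 root_genes = root_genes, loss_prob = loss_prob,
                 insertion_node = insertion_node, gen = gen),
            class = "c6_scenario_config")
}

family_loss_prob <- function(loss_prob, family) {
  if (!is.null(names(loss_prob)) && family %in% names(loss_prob)) {
    loss_prob[[family]]
  } else {
    unname(loss_prob[[1]])
  }
}

#' Simulate a species tree and gene-family evolution scenario
#'
#' Genes propagate from the root; each family is lost on a branch with the
#' configured probability; on the designated insertion branch a surviving
#' c6B becomes c6A (irreversibly). Leaves emit one synthetic sequence per
#' surviving gene. The true event history records every realized event
#' with its branch.
#'
#' @param scfg a [scenario_config()].
#' @param sequences emit leaf sequences (set `FALSE` for state-only
#'   simulations, e.g. large replicate studies).
#' @return list: `tree` (phylo), `records`, `truth` (per-sequence ground
#'   truth), `presence` (true per-taxon count matrix), `states` (per-leaf
#'   `none`/`C6B`/`C6A` for the low-potential family), `events` (realized
#'   event table), `insertion_node` (designated branch label), `refs`
#'   (matching [reference_profile()], when sequences are emitted).
#' @export
simulate_scenario <- function(scfg, sequences = TRUE) {
  stopifnot(inherits(scfg, "c6_scenario_config"))
  sim <- with_seed(scfg$seed, {
    tree <- ape::rtree(scfg$n_taxa,
                       tip.label = sprintf("t%03d", seq_len(scfg$n_taxa)))
    tree <- prepare_tree(tree)
    n_tip <- length(tree$tip.label)
    labs <- node_labels(tree)
    ch <- node_children(tree)
    ins_node <- NA_integer_
    if ("C6B" %in% scfg$root_genes) {
      if (is.null(scfg$insertion_node)) {
        sizes <- vapply(seq_len(n_tip + tree$Nnode), function(v)
          length(clade_tips(tree, v, ch)), integer(1))
        eligible <- which(sizes >= 2 & sizes <= n_tip - 2 &
                            seq_along(sizes) > n_tip)
        ins_node <- if (!length(eligible)) NA_integer_ else
          if (length(eligible) == 1) eligible else sample(eligible, 1)
      } else {
        ins_node <- match(scfg$insertion_node, labs)
        if (is.na(ins_node)) {
          stop("insertion node '", scfg$insertion_node, "' not in tree")
        }
      }
    }
    root <- n_tip + 1L
    families <- scfg$root_genes
    # state per node per family: "" absent, "P" present (C6), "B"/"A" (C6B)
    state <- matrix("", nrow = n_tip + tree$Nnode, ncol = length(families),
                    dimnames = list(NULL, families))
    state[root, ] <- ifelse(families == "C6", "P", "B")
    events <- data.frame(family = families, event = "origin",
                         branch = labs[root], stringsAsFactors = FALSE)
    # preorder walk
    stack <- root
    order_nodes <- integer(0)
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      order_nodes <- c(order_nodes, v)
      if (v > n_tip) stack <- c(ch[[v]], stack)
    }
    # walk edges parent->child in preorder
    par <- node_parents(tree)
    for (v in order_nodes[-1]) {
      p <- par[v]
      for (fam in families) {
        s <- state[p, fam]
        if (s == "") next
        if (runif(1) < family_loss_prob(scfg$loss_prob, fam)) {
          events <- rbind(events, data.frame(family = fam, event = "loss",
                                             branch = labs[v]))
          next
        }
        if (fam == "C6B" && !is.na(ins_node) && v == ins_node && s == "B") {
          s <- "A"
          events <- rbind(events, data.frame(family = fam,
                                             event = "lip_insertion",
                                             branch = labs[v]))
        }
        state[v, fam] <- s
      }
    }
    list(tree = tree, state = state, events = events, ins_node = ins_node,
         labs = labs, n_tip = n_tip)
  })
  tree <- sim$tree
  tips <- tree$tip.label
  has_c6 <- "C6" %in% scfg$root_genes
  has_b <- "C6B" %in% scfg$root_genes
  presence <- data.frame(
    taxon = tips,
    C6 = if (has_c6) as.integer(sim$state[seq_along(tips), "C6"] == "P") else 0L,
    C6A = if (has_b) as.integer(sim$state[seq_along(tips), "C6B"] == "A") else 0L,
    C6B = if (has_b) as.integer(sim$state[seq_along(tips), "C6B"] == "B") else 0L,
    stringsAsFactors = FALSE)
  states <- stats::setNames(
    ifelse(presence$C6A == 1, "C6A", ifelse(presence$C6B == 1, "C6B", "none")),
    tips)
  out <- list(tree = tree, presence = presence, states = states,
              events = sim$events,
              insertion_node = if (is.na(sim$ins_node)) NA_character_ else
                sim$labs[sim$ins_node],
              config = scfg)
  if (sequences) {
    gen <- new_generator(scfg$gen)
    recs <- NULL; truth <- NULL
    for (i in seq_along(tips)) {
      for (cl in c("C6", "C6A", "C6B")) {
        if (presence[[cl]][i] >= 1) {
          g <- generate_sequence(cl, gen, sprintf("%s_%s", tips[i], tolower(cl)),
                                 taxon = tips[i])
          recs <- rbind(recs, g$record)
          truth <- rbind(truth, g$truth)
        }
      }
    }
    out$records <- if (is.null(recs)) sequence_records(character(0), character(0)) else recs
    out$truth <- truth
    out$refs <- generator_references(gen)
    out$generator <- gen
  }
  out
}
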