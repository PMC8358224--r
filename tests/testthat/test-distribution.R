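mk_report <- function(taxon, label) {
  data.frame(id = sprintf("r%02d", seq_along(taxon)), taxon = taxon,
             label = label, stringsAsFactors = FALSE)
}

test_that("presence matrix counts copies per taxon and flags paralogs", {
  pm <- build_presence_matrix(mk_report(c("T", "T"), c("C6", "C6B")))
  expect_identical(pm$C6[pm$taxon == "T"], 1L)
  expect_identical(pm$C6A[pm$taxon == "T"], 0L)
  expect_identical(pm$C6B[pm$taxon == "T"], 1L)

  pm2 <- build_presence_matrix(mk_report(c("W", "W"), c("C6B", "C6B")))
  expect_identical(pm2$C6B, 2L)
  expect_identical(attr(pm2, "paralogs")$taxon, "W")

  empty <- build_presence_matrix(mk_report(character(0), character(0)))
  expect_identical(nrow(empty), 0L)

  expect_error(build_presence_matrix(mk_report(c("T", ""), c("C6", "C6"))),
               "without a taxon.*r02")

  un <- build_presence_matrix(mk_report(c("T", "T"), c("C6", "UNCLASSIFIED")))
  expect_identical(attr(un, "unclassified")$n, 1L)
  expect_identical(un$C6[un$taxon == "T"], 1L)
})

test_that("newick reading keeps leaves, accepts polytomies, rejects duplicates", {
  tr <- read_newick("((A,B),C);")
  expect_identical(sort(tr$tip.label), c("A", "B", "C"))
  expect_identical(length(cytc6:::node_children(tr)[[4]]), 2L)

  poly <- read_newick("((A,B),(C,D),E);")
  root <- length(poly$tip.label) + 1L
  expect_identical(length(cytc6:::node_children(poly)[[root]]), 3L)

  expect_error(read_newick("((A,B),A);"), "duplicate")
})

test_that("Dollo reconstruction places the origin at the MRCA and minimal losses", {
  tr <- read_newick("((A,B),C);")
  r1 <- dollo_reconstruct(tr, c(A = 1, B = 1, C = 0))
  expect_identical(r1$origin_node,
                   ape::getMRCA(tr, c("A", "B")))
  expect_identical(length(r1$losses), 0L)
  expect_identical(r1$n_events, 1L)

  r2 <- dollo_reconstruct(tr, c(A = 1, B = 0, C = 1))
  expect_identical(r2$origin_node, 4L)  # root
  expect_identical(r2$losses, "B")
  expect_identical(r2$n_events, 2L)
  expect_identical(r2$n_events, dollo_oracle_count(tr, c(TRUE, FALSE, TRUE)))

  r3 <- dollo_reconstruct(tr, c(A = 1, B = 1, C = 1))
  expect_identical(r3$origin_node, 4L)
  expect_identical(r3$n_events, 1L)

  r0 <- dollo_reconstruct(tr, c(A = 0, B = 0, C = 0))
  expect_true(is.na(r0$origin))
  expect_identical(r0$n_events, 0L)
})

test_that("reconstruction equals the exhaustive single-origin oracle and replays", {
  set.seed(61)
  for (i in 1:30) {
    n <- sample(4:7, 1)
    tr <- random_tree(n)
    pres <- stats::setNames(sample(0:1, n, replace = TRUE), tr$tip.label)
    rec <- dollo_reconstruct(tr, pres)
    expect_identical(rec$n_events,
                     dollo_oracle_count(tr, as.logical(pres[tr$tip.label])))
    expect_identical(replay_events(tr, rec),
                     stats::setNames(as.integer(pres[tr$tip.label]),
                                     tr$tip.label))
  }
})

test_that("the c6B-to-c6A transition is placed minimally on the tree", {
  tr <- read_newick("((Green1,Green2),Red);")
  rec <- reconstruct_c6a_transition(
    tr, c(Green1 = "C6A", Green2 = "C6A", Red = "C6B"))
  expect_identical(rec$origin_node, 4L)
  expect_identical(rec$insertions,
                   cytc6:::node_labels(tr)[ape::getMRCA(tr, c("Green1", "Green2"))])
  expect_false(rec$multiple_insertions)
  expect_identical(rec$n_events, 2L)

  # independent insertion in a distant lineage forces two events
  tr2 <- read_newick("((G1,G2),(R1,Dino));")
  st2 <- c(G1 = "C6A", G2 = "C6A", R1 = "C6B", Dino = "C6A")
  rec2 <- reconstruct_c6a_transition(tr2, st2)
  expect_identical(length(rec2$insertions), 2L)
  expect_true(rec2$multiple_insertions)
  expect_identical(rec2$n_events, transition_oracle_count(tr2, st2))

  all_b <- reconstruct_c6a_transition(
    tr, c(Green1 = "C6B", Green2 = "C6B", Red = "C6B"))
  expect_identical(length(all_b$insertions), 0L)

  expect_warning(
    both <- reconstruct_c6a_transition(
      tr, c(Green1 = "both", Green2 = "C6A", Red = "C6B")),
    "both")
  expect_identical(both$flagged_leaves, "Green1")
})

test_that("transition event counts match brute-force placement on random trees", {
  set.seed(62)
  for (i in 1:8) {
    n <- sample(4:5, 1)
    tr <- random_tree(n, polytomy_prob = 0)
    st <- stats::setNames(sample(c("none", "C6B", "C6A"), n, replace = TRUE),
                          tr$tip.label)
    rec <- suppressWarnings(reconstruct_c6a_transition(tr, st))
    oracle <- if (all(st == "none")) 0L else transition_oracle_count(tr, st)
    expect_identical(rec$n_events, oracle, info = paste(st, collapse = ","))
    expect_identical(replay_transition(tr, rec), st[tr$tip.label])
  }
})

test_that("clade summaries aggregate and conserve presence-matrix totals", {
  pm <- build_presence_matrix(mk_report(c("t1", "t2"), c("C6", "C6")))
  cm <- c(t1 = "X", t2 = "X")
  s <- summarize_by_clade(pm, cm)
  expect_identical(s$n, 2L)
  expect_identical(s$C6_taxa, 2L)

  one <- summarize_by_clade(
    build_presence_matrix(mk_report("t1", "C6")), c(t1 = "X", t2 = "X"))
  expect_identical(one$n, 1L)

  expect_warning(
    unas <- summarize_by_clade(
      build_presence_matrix(mk_report("t9", "C6B")), c(t1 = "X")),
    "unassigned")
  expect_identical(unas$clade, "unassigned")

  # random scenario: totals conserved and identical to an independent groupby
  sim <- simulate_scenario(scenario_config(seed = 63), sequences = FALSE)
  rep_df <- do.call(rbind, lapply(seq_len(nrow(sim$presence)), function(i) {
    p <- sim$presence[i, ]
    lab <- c(rep("C6", p$C6), rep("C6A", p$C6A), rep("C6B", p$C6B))
    if (!length(lab)) return(NULL)
    data.frame(id = paste0(p$taxon, "_", seq_along(lab)), taxon = p$taxon,
               label = lab)
  }))
  pm2 <- build_presence_matrix(rep_df)
  clades <- stats::setNames(rep(c("cladeA", "cladeB"),
                                length.out = nrow(pm2)), pm2$taxon)
  s2 <- summarize_by_clade(pm2, clades)
  for (cl in c("C6", "C6A", "C6B")) {
    expect_identical(sum(s2[[paste0(cl, "_total")]]), sum(pm2[[cl]]))
    ind <- tapply(pm2[[cl]], unname(clades[pm2$taxon]), sum)
    expect_identical(as.integer(ind[s2$clade]),
                     s2[[paste0(cl, "_total")]])
    ind_taxa <- tapply(pm2[[cl]] >= 1, unname(clades[pm2$taxon]), sum)
    expect_identical(as.integer(ind_taxa[s2$clade]),
                     s2[[paste0(cl, "_taxa")]])
  }
})
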