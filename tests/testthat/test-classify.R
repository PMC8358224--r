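test_that("the decision table matches the published rules exhaustively", {
  residues <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                "P", "Q", "R", "S", "T", "V", "W", "Y", "X", NA)
  for (motif_ok in c(TRUE, FALSE)) {
    for (lip in c(TRUE, FALSE)) {
      for (d in residues) {
        got <- assign_class(make_features(motif_ok, d, lip))
        expect_identical(got$label, expected_label(motif_ok, d, lip),
                         info = sprintf("motif=%s diag=%s lip=%s",
                                        motif_ok, d, lip))
      }
    }
  }
})

test_that("rule traces explain every refusal and the motif dominates", {
  expect_match(assign_class(make_features(TRUE, "K", FALSE))$reason,
               "outside rule sets")
  expect_match(assign_class(make_features(TRUE, "K", FALSE))$reason, "K")
  # precedence: motif failure dominates even a perfect c6A signature
  got <- assign_class(make_features(FALSE, "V", TRUE))
  expect_identical(got$label, "UNCLASSIFIED")
  expect_identical(got$reason, "no haem motif")
  expect_match(assign_class(make_features(TRUE, NA, FALSE))$reason, "gapped")
  expect_match(assign_class(make_features(TRUE, "X", FALSE))$reason, "X")
})

test_that("LIP detection applies the length, cysteine and window rules", {
  spec <- lip_spec()
  mk <- function(len, n_cys, after) {
    ins <- c(rep("A", len))
    if (n_cys > 0) ins[seq_len(n_cys) + 1] <- "C"
    alignment_from_strings(
      paste0(strrep("G", after), paste(ins, collapse = ""), strrep("G", 40)),
      paste0(strrep("G", after), strrep("-", len), strrep("G", 40)))
  }
  hit <- detect_lip(mk(12, 2, 44), spec, c(35, 50))
  expect_true(hit$present)
  expect_identical(hit$length, 12L)
  expect_identical(hit$n_cys, 2L)
  expect_identical(hit$ref_after, 44L)

  # two cysteines are required; a lone one is only a flagged candidate
  none <- detect_lip(mk(12, 0, 44), spec, c(35, 50))
  expect_false(none$present)
  expect_true(none$low_cys_candidate)
  one <- detect_lip(mk(12, 1, 44), spec, c(35, 50))
  expect_false(one$present)
  expect_true(one$low_cys_candidate)

  # length window and loop window both gate acceptance
  expect_false(detect_lip(mk(7, 2, 44), spec, c(35, 50))$present)
  expect_false(detect_lip(mk(21, 2, 44), spec, c(35, 50))$present)
  expect_false(detect_lip(mk(12, 2, 60), spec, c(35, 50))$present)
  expect_false(detect_lip(alignment_from_strings("ACDEF", "ACDEF"),
                          spec, c(35, 50))$present)
})

test_that("features extracted from clean synthetic sequences match their class", {
  gen <- new_generator(generator_config(seed = 501, noise = 0,
                                        signal_len_range = c(0, 0),
                                        lip_len_range = c(12, 12)))
  refs <- generator_references(gen)

  c6 <- generate_sequence("C6", gen, "s1")
  f6 <- extract_features(c6$record$residues, refs)
  expect_identical(f6$diagnostic_residue, "Q")
  expect_false(f6$lip$present)
  expect_identical(assign_class(f6)$label, "C6")

  c6a <- generate_sequence("C6A", gen, "s2")
  fa <- extract_features(c6a$record$residues, refs)
  expect_true(fa$diagnostic_residue %in% c("V", "L", "I"))
  expect_true(fa$lip$present)
  expect_identical(fa$lip$length, 12L)
  expect_identical(fa$lip$n_cys, 2L)
  expect_identical(assign_class(fa)$label, "C6A")

  c6b <- generate_sequence("C6B", gen, "s3")
  fb <- extract_features(c6b$record$residues, refs)
  expect_false(fb$lip$present)
  expect_identical(assign_class(fb)$label, "C6B")
})

test_that("a deletion spanning the diagnostic site refuses classification", {
  refs <- default_references()
  chars <- strsplit(refs$ref_c6a, "")[[1]]
  gapped <- paste(chars[-(48:56)], collapse = "")
  f <- extract_features(gapped, refs)
  expect_true(is.na(f$diagnostic_residue))
  expect_identical(assign_class(f)$label, "UNCLASSIFIED")
})

test_that("hydrophobic residue with a one-cysteine insertion falls back to C6B with a warning flag", {
  gen <- new_generator(generator_config(seed = 502, noise = 0,
                                        lip_cys = 1,
                                        signal_len_range = c(0, 0)))
  refs <- generator_references(gen)
  s <- generate_sequence("C6A", gen, "amb1")
  f <- extract_features(s$record$residues, refs)
  cl <- assign_class(f)
  expect_identical(cl$label, "C6B")
  expect_true(cl$warn)
})

test_that("classification is deterministic and order-independent", {
  gen <- new_generator(generator_config(seed = 503))
  refs <- generator_references(gen)
  ds <- generate_dataset(rep(c("C6", "C6A", "C6B"), 5), gen)
  r1 <- classify_sequences(ds$records, refs)$report
  set.seed(42)
  perm <- sample(nrow(ds$records))
  r2 <- classify_sequences(ds$records[perm, ], refs)$report
  r2 <- r2[match(r1$id, r2$id), ]
  rownames(r2) <- NULL
  expect_identical(r1, r2)
})

test_that("all labels are recovered from zero-noise synthetic sequences", {
  gen <- new_generator(generator_config(seed = 504, noise = 0))
  refs <- generator_references(gen)
  set.seed(504)
  labels <- sample(c("C6", "C6A", "C6B"), 60, replace = TRUE)
  ds <- generate_dataset(labels, gen)
  res <- classify_sequences(ds$records, refs)
  expect_identical(res$report$label, ds$truth$class)
})
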