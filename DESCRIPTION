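Package: cytc6
Title: Rule-Based Classification and Ancestry Mapping of the Cytochrome c6 Family
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies cytochrome c6-family protein sequences (c6, c6A, c6B)
    from sequence evidence alone: an appropriately located CXXCH haem-binding
    motif, the residue at the site equivalent to position 52 of mature
    Arabidopsis thaliana cytochrome c6A (glutamine versus valine/leucine/
    isoleucine), and the presence of a two-cysteine loop insertion peptide
    (LIP) detected by reference-anchored global alignment. Downstream tools
    aggregate class labels into per-taxon presence/absence matrices, summarize
    them by clade, and reconstruct gain, loss and LIP-insertion events on a
    species tree under Dollo parsimony. A seeded synthetic-sequence and
    scenario generator provides labelled test data so the whole pipeline is
    verifiable without database access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
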