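---
title: "Classifying the cytochrome c6 family and reconstructing its history"
author: "cytc6"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying the cytochrome c6 family and reconstructing its history}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytc6)
```

## The biological problem

Cytochrome c6 carries electrons between the cytochrome b6f complex and
photosystem I in cyanobacteria and many algae. Its family has three further
members with a markedly lower redox midpoint potential and unknown
function: cytochrome c6A in plants and green algae, and cytochromes
c6B/c6C in cyanobacteria (treated throughout this package as a single
family, c6B, since they are orthologs and no sequence feature separates
them). Two sequence features carry essentially all of the classification
signal:

* the residue at the site equivalent to **position 52 of mature
  *Arabidopsis thaliana* cytochrome c6A** — a conserved glutamine in c6,
  a hydrophobic valine, leucine or isoleucine in the low-potential
  members; and
* the **loop insertion peptide (LIP)** — a roughly 12-residue insertion in
  a loop region, containing two cysteines that form a disulfide bridge —
  which distinguishes c6A from c6B.

In addition, any genuine family member must carry the covalent
haem-attachment motif CXXCH near its N terminus. `cytc6` turns these
observations into an explicit, tested decision procedure, maps the
resulting per-taxon presence patterns onto species trees, and reconstructs
gain/loss/insertion histories under Dollo parsimony. A seeded synthetic
generator provides labelled data so that every stage is verifiable without
live database searches.

Coordinates are 1-based and refer to **mature** sequences (targeting
peptide removed) throughout; this matters for "position 52", which is
counted on the mature c6A reference frame.

## The classification procedure

Candidates pass through four stages.

**1. Validity filtering.** Precursor sequences shorter than 80 or longer
than 200 residues are removed (bounds inclusive: 80 and 200 both pass —
the filter removes only what is strictly outside the window). The filter
is applied before trimming, because the plausibility argument concerns the
database entry as retrieved.

**2. Targeting-peptide trimming.** Many entries are precursors with a
cleavable N-terminal targeting peptide. The package trims by alignment
overhang: the precursor is aligned to the mature c6 reference with a
semi-global alignment (reference fully aligned, query ends free) and every
query residue before the first reference-aligned column is removed. A pure
global alignment is deliberately not used here: with end-gap penalties, a
long random N-terminal overhang is absorbed into mismatched columns
(random residue pairs score about −1 per column under BLOSUM62, cheaper
than an affine gap run), which would defeat trimming. The C terminus is
never trimmed, trimming is idempotent, and an alignment covering less than
half of the reference refuses to trim (the record is flagged
untrimmable). A post-trim length guard (default 60 residues) catches
degenerate trims.

**3. Motif check.** The left-most CXXCH occurrence whose first cysteine
falls inside a configurable window on the mature sequence (default
positions 5–40; the haem site is N-proximal in all four family members)
qualifies. Occurrences outside the window are reported as diagnostics but
never qualify. Overlapping occurrences are all considered. A failed motif
check dominates all other evidence — the motif is a validity criterion,
not a class feature — so such records are routed to UNCLASSIFIED rather
than dropped silently.

**4. Diagnostic rules.** Each matured sequence is globally aligned
(Needleman–Wunsch, affine gaps, BLOSUM62, gap open 11, gap extend 1; a gap
of length L costs `gap_open + L * gap_extend`) to the two references. The
residue aligned to the diagnostic position of the c6A reference and the
insertions relative to the c6 reference give the decision table:

| motif | residue at diagnostic site | LIP | label |
|---|---|---|---|
| absent | — | — | UNCLASSIFIED |
| present | Q | any | C6 |
| present | V/L/I | present | C6A |
| present | V/L/I | absent | C6B |
| present | other / X / gap | — | UNCLASSIFIED |

A LIP is an insertion that opens inside the loop window of the c6
reference (default positions 35–50), is 8–20 residues long (a window
around the canonical 12, admitting indel noise without accepting unrelated
insertions), and contains at least two cysteines. Disulfide formation is
operationalized purely as that cysteine count — only sequence data are
available. Two deliberate refusals: residues other than Q/V/L/I at the
diagnostic site (e.g. M, F) are UNCLASSIFIED rather than extrapolated to
"low potential", and a gap or an ambiguous X at the site is likewise
refused — guessing would silently corrupt downstream presence counts. One
ambiguous case gets a softer treatment: a hydrophobic diagnostic residue
with an in-window, in-range insertion carrying only **one** cysteine is
labelled C6B with a warning flag (`warn_low_cys`), since no published rule
adjudicates it.

### References

The two anchoring references are, canonically, mature *A. thaliana*
cytochrome c6A (accession Q93VA3.1) and mature *Synechococcus* sp. PCC
7002 cytochrome c6 (accession O30881.1). The package does not redistribute
these database sequences; `default_references()` loads a **synthetic
stand-in pair** (so named in the file and documentation) constructed on a
shared random backbone so that the canonical coordinates hold exactly: the
c6A stand-in carries V at mature position 52 and a 12-residue two-cysteine
LIP opening after position 38 of the c6 stand-in (inside the default loop
window), and the c6 stand-in carries Q at the equivalent backbone site
(position 40). Users analysing real data should fetch the canonical
accessions and build a profile with `reference_profile()`.

## Presence mapping and event reconstruction

Labels are aggregated into a taxon × {C6, C6A, C6B} count matrix
(`build_presence_matrix()`); counts above one flag potential paralogs, and
UNCLASSIFIED records are tallied separately, never mixed into family
counts. `summarize_by_clade()` produces the per-clade survey table (n taxa
searched, taxa with at least one sequence, total sequences per family).

The narrative history of the family — single origin of c6B by duplication
of c6, later conversion to c6A by LIP insertion in the green lineage,
losses scattered across taxa — is formalized as **Dollo parsimony**: each
family is gained exactly once and lost any number of times. This is a
modelling choice of the package, matching the single-origin reasoning the
distribution supports. `dollo_reconstruct()` places the origin at the most
recent common ancestor of the taxa carrying the family and losses at the
maximal all-absent subtrees below it; this placement is provably minimal
among single-origin placements, and the test suite checks it exhaustively
against a brute-force enumeration on all small tree shapes.

`reconstruct_c6a_transition()` treats c6A as c6B-with-LIP: one family
origin plus a minimal set of irreversible insertion branches, each
converting c6B to c6A in its subtree. Insertions are placed at the maximal
subtrees whose present members are all c6A; two distinct such subtrees can
never share an insertion (their join would contain a c6B taxon), so the
count is minimal. When more than one insertion is required the result is
flagged (`multiple_insertions`) — this is exactly the signature of an
independent LIP gain, as in the peridinin dinoflagellates — and
interpretation (e.g. lateral transfer, which is not modelled) is left to
the user. A taxon reported to carry both c6A and c6B would contradict the
model's irreversibility; it raises a warning, is treated as c6A for
placement, and is listed in `flagged_leaves`.

Trees are read from Newick with `read_newick()`. The basal node of the
Newick string is always treated as the root — including basal polytomies,
which are accepted — and no rerooting is ever applied: a Newick file
cannot reliably encode "unrootedness", so the rooting of the input is the
user's scientific decision and is taken at face value.

## The synthetic generator

`generator_config()` / `new_generator()` define one **run**: a scaffold of
85–120 uniformly random residues with the anatomy planted on it — a single
in-window CXXCH (first cysteine at positions 10–25), a diagnostic site
(drawn between positions 45 and 60), and a loop opening point 2–6 residues
before it. Every sequence of the run derives from that scaffold: the class
residue at the diagnostic site (Q, or uniform over V/L/I), for c6A a LIP
of uniform length 10–16 with exactly two cysteines inserted at the loop
point, an optional random targeting peptide of 0–40 residues, and i.i.d.
substitution noise (default 2%). `generator_references()` returns the
matching reference pair (the clean Q- and V-bearing scaffold variants), so
classification of a run's output is anchored in the same frame.

Design points worth knowing:

* **Shared scaffold, not independent backgrounds.** Classification is
  alignment-anchored, so recovering planted labels requires the query and
  the references to be alignable; sequences with mutually independent
  random backgrounds would make position mapping meaningless. The uniform
  randomness therefore lives at the run level (the scaffold), and
  per-sequence variation is noise plus features. Consequently the
  generator tests the *rules*, not remote-homology detection — passing
  tests say nothing about BLAST-stage sensitivity on real data, which is
  outside the package's scope.
* **Protected positions.** Noise never touches the motif, the diagnostic
  site, or the LIP cysteines unless `adversarial = TRUE` (used to test
  UNCLASSIFIED routing). This separates clean-recovery tests from
  robustness tests.
* **Unambiguous insertion boundaries.** The first and last LIP residues
  are constrained to differ from their flanking scaffold residues;
  otherwise the optimal alignment could slide the gap run by one column
  and the planted coordinates would not be recoverable even at zero noise.
* **Order-independent determinism.** One run-level stream is seeded from
  the config; each sequence draws from a substream keyed by a stable hash
  of its id, so regenerating in any order gives byte-identical output.
* Stray in-window CXXCH occurrences arising from the random background are
  removed by mutating the offending histidine; occurrences outside the
  motif window are harmless and left alone.

`scenario_config()` / `simulate_scenario()` add the evolutionary layer: a
random 24-taxon species tree (birth-only shape via `ape::rtree`), root
gene set {c6, c6B}, per-branch loss probability 0.1 per family, and one
designated internal insertion branch (clade size between 2 and n−2) on
which a surviving c6B becomes c6A. Leaves emit one sequence per surviving
gene; the realized event history is recorded with its branches.

## What the tests establish — and their limits

* The decision table is checked exhaustively over every diagnostic residue
  × LIP state × motif state.
* Alignment scores are checked against an independent exhaustive
  enumeration of alignment paths (all pairs up to length 2 over a 4-letter
  alphabet, plus seeded random pairs covering every length combination up
  to 6×6 — full enumeration of all ~3×10⁷ length-≤6 pairs adds nothing at
  far greater cost).
* Dollo event counts are checked against brute-force single-origin
  enumeration on **all** rooted binary labelled topologies with up to 5
  leaves under **all** leaf-state vectors, plus seeded random topologies
  (including polytomies) with 6–8 leaves under all vectors.
* Label recovery: 100% at zero noise and ≥ 99% at 5% substitution noise
  over 1,000 seeded sequences. The residual failures at 5% noise are
  honest refusals (noise shifts the alignment so the diagnostic site falls
  in a gap → UNCLASSIFIED), not wrong labels.
* Scenario identifiability: at zero substitution noise the pipeline
  reproduces the true presence matrix exactly, and the reconstructed
  events always replay to the observed leaf states. The *realized* event
  history is provably identifiable only when it is canonical — losses near
  the root move the inferred origin to the surviving clade's MRCA, and two
  independent sibling losses are indistinguishable from one parental loss;
  both are correct minimal-event behavior. Exact history recovery is
  therefore asserted in the no-loss, single-insertion limit, and under
  loss probability 0.1 the designated insertion branch is recovered in
  ≥ 90% of 500 seeded replicates (the failures are dominated by histories
  where losses erase or blur the insertion subtree's boundary).

Problem sizes throughout (1,000-sequence recovery runs, 500 scenario
replicates, trees to 8 leaves for exhaustive enumeration, 24-taxon demo
scenarios) were chosen as the smallest sizes at which the binomial
tolerances above are meaningful.

## Known limitations

* No homology search: the package classifies candidate sets, it does not
  find them. BLAST-stage sensitivity, multiple alignment, tree inference
  and network analyses are delegated to external tools (alignments and
  trees are exported in standard formats).
* No lateral gene transfer in the event model; multiple required
  insertions are reported as evidence, not adjudicated.
* c6B vs c6C cannot be separated by any sequence rule; the merged label is
  a considered position, not a loss of information.
* The generator's i.i.d. substitution noise is not a phylogenetic
  substitution model; recovery rates under it do not translate directly to
  real divergence levels.
* Redox midpoint potentials are never predicted; the diagnostic residue is
  used strictly as a sequence feature.

## A worked miniature

```{r mini}
tree <- read_newick("((Green1,Green2),(Red1,Red2));")
states <- c(Green1 = "C6A", Green2 = "C6A", Red1 = "C6B", Red2 = "C6B")
rec <- reconstruct_c6a_transition(tree, states)
rec$origin       # family origin (root: all four carry the family)
rec$insertions   # single LIP insertion on the green stem
rec$n_events     # origin + insertion
```

The three numbered scripts under `analysis/` run the full workflow on a
simulated survey (simulate → classify → map/reconstruct) and print the
agreement between reconstruction and simulated truth;
`scripts/acceptance.R` recomputes the package's headline quantities from
scratch.
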