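---
title: "Trio-free ancestry painting: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trio-free ancestry painting: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplorigin)
```

## The problem

A phased assembly of an interspecific hybrid reports two haplotype sets
("phases"), but which chromosome copy descends from which parental lineage
is unknown. The classical answer — trio binning — requires sequencing both
parents. `haplorigin` implements a trio-free alternative that leverages
subtle divergence in the repetitive fraction of the genome: satellite
families private to one lineage mark its chromosomes, and high-copy k-mers
enriched in one lineage's repeat neighborhoods extend those marks into a
dense genome-wide painting.

## The procedure

1. **Tandem-repeat canonicalization.** Tandem-repeat annotations (from
   TandemRepeatFinder `.dat` files, or the built-in exact detector for
   synthetic data) are made comparable by mapping each consensus unit to
   its *canonical unit*: the lexicographically first string among all
   cyclic rotations of the unit and of its reverse complement. This removes
   the arbitrary phase of the annotation start (TGC-TGC-... can be reported
   as TGC, GCT or CTG, and on the other strand as GCA, CAG or AGC; all six
   canonicalize to AGC). Overlapping annotations — the annotator re-reports
   arrays at multiple unit sizes — are resolved by keeping longer intervals
   whole and trimming shorter ones to the uncovered remainder.

2. **Family clustering and phase specificity.** Canonical units are grouped
   into families (exact grouping; optionally single-linkage clustering at a
   configurable global-identity threshold, default 0.9, with gaps counted
   as mismatches over the longer unit's length). Each family's member base
   pairs are profiled in genome bins and split by phase; a family is
   *parent-specific* when one phase holds at least `s_min` (default 0.9) of
   its bp and the family totals at least `b_min` (default 50 kb). The
   original analysis selected these families by inspecting distribution
   plots; the thresholds automate that judgement and are deliberately
   exposed. Centromere-specific families need no special handling — they
   simply fail the specificity flag.

3. **Provisional partition and marker selection.** Member intervals of
   flagged families, extended by `merge_distance` (default: the painting
   bin size) and with doubly-claimed stretches dropped, form each parent's
   k-mer source bins. Canonical k-mers of sizes 20, 30, 40 and 50 are
   counted inside each side's bins; a k-mer enters the a1 library iff its
   a1 count is at least 400 and log2(count a1 / count a2) is at least 4.25
   (a zero opposite count passes as an infinite fold change), symmetrically
   for a2 with the 250 threshold. The asymmetric frequency defaults
   reflect unequal repeat content of the two source-bin sets and are kept
   as published; no normalization for unequal bin totals is applied.
   Counts are taken within the provisional bins (not genome-wide), and the
   per-k libraries are kept separate — painting unions their hits.

4. **Painting.** Every perfect match of a library k-mer (either strand,
   canonical comparison) tags the interval it covers; per-parent tag
   unions are intersected with near-equal bins (`binGenome` chooses
   n = round(length/target) bins whose lengths differ by at most 1 bp, so
   no ragged terminal bin distorts edge ratios). Each bin's log2(a1 bp /
   a2 bp) is an extended real: +Inf when a2 = 0 < a1, −Inf when a1 = 0 <
   a2, 0 on equality, undefined when both are 0 (observed only at small
   bin sizes). For display, ±Inf map to trunc(max finite + 0.5) + 0.1 and
   trunc(min finite − 0.5) − 0.1 per sequence; this transform is
   visualization-only and segmentation never reads it. Note the printed
   transform can place the +Inf display *below* the finite maximum (a
   finite maximum of 3.4 displays infinity at 3.1); we implement the
   formula as stated rather than silently "fixing" it, and flag the
   discrepancy here.

5. **Segmentation.** Bins get signs (+/−/neutral); neutral bins inherit
   the previous signed bin's sign (leading neutrals inherit the first
   signed sign — a choice, since 0-valued bins are not discussed in the
   source procedure). A sign change between adjacent bins is accepted as a
   block boundary only when both flanking bins carry at least
   `min_tag_bp` (default 50 bp) of tagged sequence, filtering crossings
   driven by near-empty bins. Accepted crossings cut each sequence into
   alternating a1/a2 blocks with boundary accuracy on the order of one
   bin. The "corresponding bins" of the tag filter are read as the two
   bins flanking the crossing.

## Introgression genotyping

For a focal region (e.g. a donor introgression), the diagnostic set is the
region's canonical 31-mers minus every 31-mer occurring anywhere else in
the assembly (both phases; the region is excised and its flanks treated as
separate pieces so no artificial junction k-mers arise). Reads of each
individual are scanned; a read carrying at least `min_hits` (default 1)
diagnostic k-mers counts as a carrier, and the carrier proportion over all
scanned reads estimates dosage. Individuals are clustered into 0/1/2-copy
classes by one-dimensional k-means (k = 3) with deterministic centers
initialized at (min, median, max) — an automated stand-in for the original
visual clustering; with exactly three individuals each defines its own
class. Class counts are tested against 1:2:1 with a Pearson chi-square
(df = 2). Whether a read should be counted once or per contained k-mer is
not specified in the source; counting once is the implemented reading, and
the proportion denominator is all scanned reads.

## Coverage-based origin verification

Windowed read counts (default 5 Mb windows) are normalized first to each
sample's sequencing coverage (library size — per-base coverage differs
only by the constant read length, which cancels in the next step) and then
to the reference individual's rate in the same window. Log base 2 is used
throughout (the source leaves the base of the per-sample logarithm
unstated; base 2 keeps it consistent with the group contrast). The group
contrast is log2 of the ratio of *unlogged* group means — averaging on the
ratio scale before taking logs, the other undocumented choice we fixed.
Zero sample counts flag −Inf; windows where the reference has no reads are
undefined and excluded pairwise.

## Closed-form utilities

* Per-alignment identity: the printed formula is mismatches/length × 100 —
  a mismatch percentage despite its "identity" label. Both the as-printed
  value and its complement are exposed; results quoting 75–78% identity
  correspond to the complement.
* LTR insertion age: Age = (1 − LTR identity) / (2 µ) × 10⁻⁶ Myr with
  µ = 1.3 × 10⁻⁸ substitutions/site/year; the factor 2 reflects
  independent divergence of the two terminal repeats.
* Switch error: 100 · switched/total phased SNPs, reported half-to-even at
  3 decimals (122,753 of 5,886,045 gives 2.085).

## The synthetic-data generator

The generator defines the validation conditions; it is not a tuning knob.
The `desk` preset simulates 2 chromosomes of 3 Mb per phase: a shared
ancestral background mutated independently into each parent at 2% per
branch (substitutions only — exact k-mer matching is the mechanism under
test, so indels would only dilute it without changing the logic), then
each parent receives one private 9-bp satellite unit planted as three
30 kb arrays at fixed anchors plus dispersed 300 bp mini-arrays every
~20 kb. The mini-arrays matter: real lineage-enriched k-mers come from
repeats spread along chromosomes, and without dispersed copies the painting
would have no signal between the large arrays. The default hybrid keeps
chr1 parent-pure per phase and plants a parent-2 introgression on chr2
phase 1 at fractions 0.4–0.6, emulating the mostly-unmixed haplotypes with
occasional introgressions that motivate the method. Painting uses 50 kb
bins; all bp-denominated thresholds (50 bp tag filter, 50 kb family floor)
keep their published values, while the count-denominated k-mer frequency
filters are rescaled to 100/60 — preserving the published 400:250
asymmetry — because planted copy numbers are proportionally smaller at
desk scale. The `paper` preset carries the full-scale values (500 kb bins,
400/250, 5 Mb coverage windows) for real-sized data.

The population generator draws 128 offspring whose introgression copy
number follows 1:2:1, on a 150 kb chromosome pair with a 30 kb donor
region, and error-free 100 bp reads at 2× per copy. Problem sizes were
chosen so the full 20-seed validation suites complete in minutes on one
CPU while leaving clear separation between dosage classes.

What the generator does *not* emulate: transposon landscapes, segmental
duplications, assembly errors, indel divergence, sequencing-error-induced
singleton k-mer hits, and centromeric satellite gradients. Passing the
synthetic suites therefore demonstrates the correctness of the algorithmic
chain under its stated assumptions, not robustness to every artifact of
real assemblies; on real data the exposed thresholds (`s_min`, `b_min`,
frequency and fold-change filters, `min_hits`) are the instruments for
handling those artifacts.

## Numerical and representation choices

* Intervals live in `GRanges` (1-based closed) inside the package; every
  file interface converts (TRF `.dat` is 1-based inclusive; BED/TSV
  outputs are 0-based half-open; CLI region strings are 1-based
  inclusive). This differs from a 0-based internal convention only in
  representation, not in any emitted coordinate.
* "int" in the display transform is truncation toward zero (`trunc`).
* The bin count of `binGenome` uses R's round (half-to-even); both worked
  bin examples are unaffected.
* Canonical k-mers are held 2-bit packed (k ≤ 64); since A<C<G<T maps to
  0<1<2<3, integer order equals lexicographic order and the packed
  canonical form agrees with the string definition. Counting sorts the
  packed windows and run-length encodes, which keeps memory proportional
  to the window count and is deterministic.
* Unit-pair identity for clustering is 1 − Levenshtein/max(length):
  matching columns over the longer unit's length with gaps as mismatches.
* k-means degeneracy (fewer than three distinct proportions) yields
  "unassigned" individuals with a warning rather than an arbitrary split.
* Tie-breaks in overlap resolution (equal lengths): smaller start, then
  higher score, then input order — the published rule only says
  longer-first. A smaller interval split in two by an accepted larger one
  keeps both flanks; its copy number is rescaled to the trimmed width.
* Mate pairs are treated as independent reads; read order never matters.

## Known limitations

* Exact matching only: a single substitution in a marker k-mer erases the
  hit. At the published k sizes and filter stringency this is the intended
  behavior (specificity over sensitivity), but heavily diverged or
  error-rich assemblies will paint sparsely.
* Families are flagged by *phase* specificity, so a hybrid whose phases
  are already heavily intermixed weakens the seed partition; the method's
  premise is that recombination between lineages is rare.
* The naive tandem detector reports only perfect arrays; it substitutes
  for a full annotator in synthetic pipelines, not on real genomes.
* `cluster_units` computes all pairwise unit distances; catalogs with
  more than a few thousand distinct canonical units should raise the
  identity threshold to 1 (exact grouping) first.
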