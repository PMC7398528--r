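---
title: "Scanning and cross-species analysis of p53 response elements"
author: "p53re authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning and cross-species analysis of p53 response elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p53re)
```

## The problem

p53 is a sequence-specific transcription factor that binds a palindromic
consensus: two copies of the degenerate decamer `RRRCWWGYYY` (R = purine,
Y = pyrimidine, W = A/T) separated by a spacer of 0–13 bp. Whether a given
gene responds to p53 in a given species depends, to first order, on whether
such a response element (RE) sits in its promoter. Orthologous promoters can
gain or lose REs: a gene that is a robust p53 target in mouse may be
entirely p53-independent in human because the mouse sites are simply not
there in the human sequence. The mouse-specific p53 target *Pierce1*
(*C9orf116*), whose two proximal binding sites (BS1, BS2) have no human
counterpart, is the motivating example.

`p53re` implements the desk-scale side of that comparison as a reusable,
tested pipeline:

1. **Scan** promoters for REs by degenerate half-site matching and pairing
   (`scan_response_elements()`).
2. **Project** reference-species sites into other species' promoters through
   a global alignment and re-scan the projected window
   (`conservation_table()`).
3. **Classify** species by site presence/absence and render a UPGMA
   dendrogram (`categorize_species()`, `cluster_species()`).
4. **Design** site-swap constructs that move one species' site into another
   species' promoter (`swap_site()`), the in-silico counterpart of
   promoter-mutagenesis reporter assays.
5. **Summarise** provided ChIP-seq coverage over promoter windows,
   normalised to a common read depth (`normalize_to_10M()`,
   `occupancy_report()`).
6. **Simulate** all of the above with exact ground truth
   (`synth_cohort()`, `synth_coverage()`).

## The matching model

A *half-site hit* is any decamer window whose mismatch count against the
degenerate consensus is at most `max_mm_per_half` (default 2). Position `i`
mismatches iff the observed base is outside the allowed set of consensus
symbol `i`; an `N` in the sequence mismatches every symbol, so a site is
never called on ambiguous sequence. Both strands are scanned; because the
consensus is self-reverse-complementary, a window can match identically on
both strands (same physical mismatch columns), in which case it is reported
once with strand `+`.

A *full element* is an ordered pair of half-site hits whose spacer (gap
between the decamers) lies in `[spacer_min, spacer_max]` (default 0–13 bp)
and whose summed mismatches are at most `max_mm_total` (default 3). All
admissible pairings are reported, ranked by (total mismatches, spacer
length, leftmost start); `non_overlapping = TRUE` applies a greedy pass in
that order. The defaults are deliberately permissive single-digit budgets:
tight enough that random decamer pairs are rare in kilobase-scale promoters,
loose enough that a functional site carrying one or two degenerate-position
substitutions is still called. Functional REs are routinely imperfect, so a
mismatch *ceiling* — rather than an exact mismatch count — is the only
internally consistent reading: a perfect match is the strongest site, not a
non-site. All budgets are `p53_pattern()` parameters.

This is deliberately a counting model, not a position-weight matrix: no
per-position energies, no background model, no p-values. The scientific
claim the pipeline supports is presence/absence of a consensus-conforming
site, and the counting model makes every call exactly reproducible and
exhaustively checkable against literal enumeration (the test suite does
this on thousands of random sequences).

## Cross-species projection

Promoter windows of the compared species are globally aligned
(Needleman–Wunsch; match +1, mismatch −1, gap −2, linear gaps). The
traceback tie-break is fixed (diagonal, then gap-in-query, then
gap-in-reference) so the same input pair always yields the same alignment
and hence the same projection. A reference site's interval is mapped to the
query positions aligned to its columns; if every column lands in a query
gap the site is *deleted* in that species.

The projected interval, widened by `slack` bases on each side (default 5),
is re-scanned with the same pattern. The slack absorbs small indels that
shift the site without destroying it; 5 bp covers the indel lengths the
synthetic cohort generator emits (1–3 bp) with margin. A site is **present**
in a species iff the re-scan finds a full element within budget.
Divergence from the reference is reported as two separate numbers —
substitution columns (`mm_to_reference`) and indel columns — because a
per-base highlight of substitutions is only meaningful over aligned,
ungapped columns.

Two limitations follow from this design. Whole-window global alignment
assumes the provided promoter windows are orthologous and roughly
comparable in extent; it is not a substitute for whole-genome alignment
chains, and grossly rearranged promoters will project badly. And the
substitution-column count is a lower bound on per-base difference whenever
the aligner absorbs a diverged stretch as indels.

## Species classification

Presence calls collapse to a species × site logical matrix. For the site
pair {BS1, BS2} each species falls in exactly one of four categories —
`both`, `BS1_only`, `BS2_only`, `none` — with the conventional display
colours (red, yellow, light blue, deep blue). Species are clustered with
UPGMA on simple-matching distance (fraction of differing cells). Ties are
broken lexicographically so output is deterministic. The result is written
as ultrametric Newick. Two binary characters cannot resolve a phylogeny;
the tree is a classification dendrogram of promoter structure, nothing
more.

## ChIP coverage summaries

The module consumes per-interval coverage (bedGraph) plus a declared total
mapped-read count; it never touches reads or calls peaks. Depths are
rescaled by `1e7 / total_reads` so libraries are comparable at a read depth
of 10 million; the operation is linear, a fixed point at exactly 10 M
reads, and guarded against double application. Promoter occupancy is the
window maximum (and length-weighted mean, with uncovered bases as zero),
expressed as a ratio to a positive-control locus — a constitutive p53
target such as *CDKN1A* — whose peak certifies that p53 was active in the
experiment at all. The `enriched` flag defaults to ratio ≥ 0.1 of the
control maximum; no published numeric criterion exists for this call, so
the threshold is a declared, configurable default rather than an inferred
one.

## The synthetic-data generator

The generator exists to test plumbing with known answers, not to model
molecular evolution.

* `generate_background(length, gc)` draws i.i.d. bases at a target GC
  fraction. Defaults used throughout the tests: 0.8–1.2 kb windows at GC
  0.45, typical of mammalian promoter neighbourhoods.
* `plant_sites()` writes `realize_half_site(mm1) + spacer + realize_half_site(mm2)`
  at stated positions; `realize_half_site()` places *exactly* the requested
  number of mismatches, so planted truth is exact by construction.
* `diverge_species()` applies per-base substitution (uniform over the three
  alternatives) and per-base indel initiation (insertion or deletion with
  equal probability, length 1–3 uniform, insertions after the initiating
  base) and can ablate named sites by overwriting them with
  background-composition sequence. Test cohorts use substitution rates of
  0.02–0.05 — the low-divergence regime where projection through a global
  alignment is expected to work — and indel rates of 0–0.002. The truth
  table tracks every site's coordinates through the indels and re-derives
  its present/absent verdict by direct re-scanning.
* `synth_coverage()` lays triangular peaks over Poisson-jittered background.
  Simulated peak apexes (60 over the promoter, 100 over the control, on
  background 1) are roughly two orders of magnitude above background, as in
  strong ChIP-seq peaks, which places the enriched/not-enriched
  configurations decisively on either side of the 0.1 ratio threshold — a
  borderline simulation would test the noise, not the logic.

A cohort spec's `seed` fixes every byte of output, so golden tests are
exactly reproducible.

One definitional boundary is worth knowing: the generator's truth table
re-scans each site's *exact* projected interval, whereas the conservation
module re-scans that interval widened by the `slack` (±5 bp by default).
For sites diverged in place the two windows agree. For *ablated* sites —
fully replaced by random sequence — the wider window occasionally (about
1% of ablated cells under the default budgets) contains a weak element
assembled from the random replacement plus flanking bases, so the pipeline
calls "present" where the truth says "absent". End-to-end agreement with
generator truth is therefore ~98–100% rather than exactly 100% on cohorts
with ablation; with `slack = 0` the two definitions coincide.

What passing these tests shows — and does not show. i.i.d. background has
no repeats, no CpG islands, no compositional heterogeneity; the divergence
model has no rate variation, no transition/transversion bias, no large
rearrangements. Tests on this material verify that the scanner,
projection, classification and coverage arithmetic are *correct*, not that
the biological defaults are *optimal* for any particular genome. Real
promoter analyses should treat the mismatch budgets and the promoter
window choice as study parameters.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally (BED-compatible); every
  human-readable report prints 1-based inclusive.
* The promoter window to scan is the caller's choice; nothing is inferred
  from annotation.
* Empty sequences scan to empty results; alignment of an empty sequence is
  an error (there is nothing to project through).
* UPGMA tie comparisons use an absolute tolerance of 1e−12 on distances;
  dendrogram ultrametricity holds to better than 1e−9.
* Greedy non-overlap keeps the first element in (total mismatches, spacer,
  start) order; overlapping alternative pairings of the same half-site are
  otherwise all reported, since no published exclusion rule exists.
* Problem sizes in the test suite and acceptance script — 1000 random
  sequences up to 200 bp for oracle equivalence, 200 synthetic 1.2 kb
  promoters for recovery, 100 random matrices for UPGMA, 10 cohorts for the
  end-to-end conservation check — are chosen so the whole battery runs in
  about a minute on a laptop while still exercising every budget and
  spacer combination.

## Scope

The package makes no claim about *PIERCE1* biology and performs no wet-lab
statistics, read alignment, or peak calling. Public ChIP-seq inputs are
optional; every stage is testable from the synthetic generator alone.
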