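---
title: "Designing family-exclusive COI barcode primers in flanking tRNA genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing family-exclusive COI barcode primers in flanking tRNA genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trnabarcode)
```

## The problem

The mitochondrial *cytochrome c oxidase subunit I* (COI) gene is the standard
animal DNA barcode: conserved within a species, variable between species.
Amplifying the *whole* barcode region by PCR requires primers outside COI
itself, and the transfer-RNA genes that flank COI in the vertebrate
mitogenome (upstream `tRNA-Cys`, `tRNA-Tyr`; downstream `tRNA-Ser`,
`tRNA-Asp`) are short, conserved, and close enough to serve as primer
landing sites. `trnabarcode` automates the discovery of primer pairs placed
in those flanks that are **exclusive to a taxonomic family**: across a whole
collection of annotated fish mitogenomes, a family's pair must amplify every
member of that family and nothing else. Such a catalog lets a lab identify a
processed fish sample to family level with one family-specific PCR plus a
COI sequence read.

## The two-stage model

Species are grouped by family. For each genome, the k-th nearest flanking
tRNA segments around COI are extracted (`extract_flanks()`), primer pairs
are enumerated inside the nearest segments (`design_pairs()`), and each pair
is screened *in silico* against every genome in the universe
(`classify_exclusivity()`). Groups whose members cannot all be covered by
exclusive pairs escalate through a fixed sequence:

1. **Candidate cycling** — up to `top_n` ranked pairs per species are tried,
   not just the best one.
2. **Flank extension** — primers are redesigned in the second-nearest tRNA
   segments (`resolve_by_extension()`). Extension is capped at `max_k = 2`:
   each step moves the primers further from COI, and unlimited extension
   degrades both amplicon interpretability and within-family conservation.
3. **Re-grouping** — when a family is inseparable from its closest relative
   (by representative-to-representative COI similarity), the two are merged
   into a multi-family group and re-screened (`resolve_by_regroup()`).
4. **Stage 2** — species that still lack an exclusive pair are re-screened
   with *their own mitogenomes as the reference set*: each residual species
   contributes candidate pairs, and a pair is assigned to the residual
   subset it amplifies within that restricted reference (`run_stage2()`).

Each step runs only on groups the previous step left unresolved, and
species counts are conserved throughout: every input genome receives exactly
one catalog entry, possibly flagged `unresolved` with a reason
(missing flank, no further tRNA, no unique primer).

### Why stage 2 screens against the residual reference

Stage 1 already gives every species the chance to cover itself with its own
universe-exclusive pairs. A species reaches stage 2 precisely because no
such pair exists — its flanks collide with sequences outside its family. A
second pass against the full universe would therefore fail for the same
reason it failed the first time. Restricting the reference to the residual
set changes the question from "unique in the world" to "sufficient to
discriminate among the unresolved species", which is what a follow-up assay
needs once the family-level screen has narrowed the candidates. Catalog
entries carry `stage = 2` so users know the pair's exclusivity holds within
that restricted scope.

### Why a failed merge is reverted

A merge is accepted when the mean intra-group COI similarity drops by at
most `delta` and stays above the `theta` floor. The mean is insensitive for
large groups: absorbing one 15%-divergent genome into a 12-member family
moves the group mean by only ~20 points, so the criterion alone would let an
oversized family swallow unrelated neighbours without gaining anything.
`resolve_by_regroup()` therefore keeps a merge only when the re-screen fully
resolves the merged group; otherwise the original grouping is restored and
the residuals escalate to stage 2. Merges that do help — two families whose
COI sets are nearly identical and whose shared flanks made both
non-exclusive — are kept and re-screened as a multi-family group.

## Similarity scoring

Pairwise similarity is reported on a 0–1000 scale: the identity fraction
over the columns of one optimal global alignment (match +1, mismatch −1,
gap open 2, gap extend 1), scaled so identical sequences score 1000.
Scores ≥ 700 are read as high similarity, 400–699 moderate, below 400 low.
Two technical choices matter:

* Co-optimal global alignments can differ in match count depending on
  argument order, so the pair is aligned in canonical (sorted) order —
  this makes the score exactly symmetric.
* A singleton group has intra-group mean 1000 by convention, and the group
  representative is the member with the highest mean similarity to the
  rest, ties broken by smallest accession, so representative selection is
  deterministic.

Merging a group with itself is a no-op (`delta = 0`): the union is
deduplicated by accession before scoring.

## Primer model

Candidates are all substring windows of a flank segment between `min_len`
(18 nt) and `max_len` (26 nt), the length regime appropriate for COI-flank
primers, with a 21-nt optimum. Hard filters reject windows containing `N`,
homopolymer runs longer than 4, GC fraction outside 0.30–0.70, or a
self-complementary run longer than 8 nt (a deterministic primer-dimer
proxy, not a thermodynamic fold). Surviving windows are ranked by

```
penalty = w_len * |len − 21| + w_tm * |Tm − 57.5|
        + w_gc * dist(gc, [0.30, 0.70]) + w_clamp * [no 3' G/C]
```

with Tm from the Wallace rule below 14 nt and
`64.9 + 41 (GC − 16.4) / len` otherwise. The defaults
(`w_len = 1, w_tm = 1, w_gc = 2, w_clamp = 3`) are fixed, documented
weights: only the relative ranking feeds the pipeline, and all weights are
configurable through `primer_constraints()`. Pairs combine a forward window
of the upstream segment with a reverse-complement window of the downstream
segment; `pair_penalty` adds a Tm-difference term (`w_pair_tm = 1`). All
orderings break ties on (offset, length) and are fully deterministic.

In-silico PCR (`find_matches()`, `predict_amplicons()`) requires end-to-end
alignment with at most `max_mm` mismatches (default 0 — the strictest
reading of "uniquely found" — configurable up to 3) and an exactly matching
3-base 3'-terminal window; circular genomes are scanned across the origin.
An amplicon is a plus-strand forward site followed by a minus-strand
reverse site with product length in 200–3000 nt, bounds that admit the full
~1.5 kb COI gene plus flanks. A pair that amplifies nothing is classified
non-exclusive, never vacuously exclusive.

On circular genomes every tRNA is both "upstream" and "downstream" of COI
in the wrap-around sense, so flank extraction assigns each tRNA to the side
to which it is closer (ties go upstream). A genome whose tRNAs all sit on
one side of COI thus reports a genuinely missing flank instead of borrowing
genes across the origin.

## The synthetic universe

`simulate_universe()` generates annotated circular mitogenomes with the
vertebrate cassette `tRNA-Cys, tRNA-Tyr, COI, tRNA-Ser, tRNA-Asp` embedded
in neutral spacers. Family ancestors derive from one global ancestral
cassette under a star phylogeny at `inter_family_divergence / 2` per
branch, so *pairwise* inter-family divergence matches the configured value
(default 15%); species mutate from their family ancestor at
`intra_family_sub_rate` (default 1%). Mutations are substitutions only:
keeping lengths fixed makes planted mismatch counts exact, which the
scenario tests rely on. A single seed fixes every draw, and the GenBank
output is byte-identical across runs with the same seed.

Three failure scenarios can be planted:

* **Confusable pair** — two single-species families whose nearest flanks
  are identical except one base per side. The differing base is flanked by
  5-base homopolymer runs, so every admissible primer window (homopolymer
  filter ≤ 4) provably avoids it: the pair is non-exclusive at the nearest
  flank by construction, and resolves after extension because the second
  flanks diverge normally. This makes the escalation path deterministic
  instead of dependent on ranking accidents.
* **Missing flank** — a species with no tRNA downstream of COI at all
  (omitting only the nearest would silently heal by the nearest-neighbour
  rule). Such species surface as `unresolved` / `missing-flank`.
* **Megafamily** — one oversized family whose last five species form a
  known residual set: four share flank haplotype A, one carries haplotype
  B (both divergent from the family core), and their k = 1 / k = 2 flanks
  are exact copies of three single-species decoy families' flanks. The
  residuals are therefore non-exclusive at both extension depths, the
  merge criterion rejects re-grouping (COI is 15% divergent), and stage 2
  resolves them with exactly two shared pairs — one for the four-species
  haplotype, one for the singleton — while the decoys resolve by extension
  or at stage 1.

What the simulator does **not** emulate: indels, codon structure and
strand-asymmetric mutation, rearranged gene orders, within-family
phylogenetic structure (star trees only), or heterogeneous tRNA lengths.
Passing the simulated checks therefore demonstrates the pipeline's logic
and its escalation behaviour, not its performance on real annotation noise
(mis-annotated or absent tRNAs, partial genomes) — on real data the
extraction step inherits whatever the annotations claim.

## Problem sizes and runtime choices

The test suite and the acceptance script use universes of 10 families × 5
species (plus planted scenarios, up to ~65 genomes of ~2 kb) and 20
simulation seeds for the recovery checks; property suites use 200 random
match-search instances up to 5 kb and 500 random similarity pairs. These
sizes make every check reproducible on a laptop in minutes while keeping
each estimate comfortably away from its decision boundary. The full-scale
application — thousands of complete mitogenomes — runs through exactly the
same code path via `read_genomes()`; the screening index and the caches in
`run_pipeline()` scale linearly in total genome length.

## Known limitations

* Exclusivity at `max_mm = 0` is the strictest possible reading; real PCR
  tolerates some mismatches away from the 3' end, so a pair reported
  exclusive here may still cross-amplify in the lab. The `max_mm` knob (with
  the 3-base 3' exact window) exists to probe that sensitivity.
* The dimer/hairpin screen is a run-length proxy, not a thermodynamic
  model; borderline primers should be checked with a dedicated tool before
  ordering oligos.
* Re-grouping considers only the single most similar related group per
  unresolved group, mirroring the one-neighbour merge bookkeeping of the
  escalation design; chains of merges across several families are out of
  scope.
* GenBank parsing covers the LOCUS/FEATURES/ORIGIN subset this package
  writes and the simple location forms (`a..b`, `complement()`, a
  two-segment origin-wrapping `join()`); exotic location strings are
  rejected with a format error rather than guessed at.
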