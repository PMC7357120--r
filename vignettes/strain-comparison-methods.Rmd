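---
title: "Methods: reconciling and comparing bacterial strain assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reconciling and comparing bacterial strain assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainlift)
```

## The problem

Closely related bacterial strains — the motivating case is *Streptomyces
venezuelae* strains differing in chloramphenicol and jadomycin
production — are often represented unevenly in the archives: one strain
by a completed, closed genome, another by an older draft containing
thousands of undetermined bases (`N`) and a handful of other IUPAC
ambiguity codes (`M`, `S`, `K`). Comparing such assemblies requires (i)
reconciling the draft against the completed sequence, (ii) re-examining
gene annotations across the two coordinate systems, (iii) asking which
secondary-metabolite biosynthetic gene clusters (BGCs) are conserved,
and (iv) pinpointing the sequence-level changes — frameshifts, amino-acid
differences, tandem-repeat copy changes in regulatory regions — that can
explain phenotype differences. `strainlift` implements each step as a
plain function over explicit data structures, with a synthetic-data
module that generates every input with known truth.

All internal coordinates are 0-based half-open, so the length of any
feature is `end - start` with no ±1 adjustments anywhere downstream; GFF3
and GenBank convert at the file boundary. Lowercase (soft-masked) input is
uppercased rather than rejected, since deposited assemblies commonly mix
case; the ambiguity census is therefore case-insensitive by construction.

## Assembly reconciliation

The draft is fragmented at every *maximal run of N* — only `N` triggers a
break; isolated `M`/`S`/`K` positions stay inside fragments and behave as
mismatches to every base during alignment. Fragments plus their recorded
N-runs reconstruct the draft exactly (a tested invariant), so the
fragmentation is lossless.

Each fragment is placed on the completed genome by seed-and-extend:

* **Seeding.** Exact 31-mers taken every 15 bp along the fragment (capped
  at ~48 seeds for long fragments), matched on both strands of the
  reference via a single `PDict` pass for all queries. Matching diagonals
  within 30 bp are clustered into candidate loci, ranked by seed support
  (at most 8 evaluated).
* **Extension.** The cost model is match +1, mismatch −2, and −3 per
  inserted or deleted base (linear); "similarity" is matches over aligned
  columns. Queries up to `dp_limit` (3 kb) are extended by a local
  dynamic-programming alignment under this model; longer queries are
  extended *ungapped* along the seeded diagonal by a maximum-subarray
  scan over per-position scores. The two are equivalent whenever the
  optimal alignment is gap-free, which holds by construction for
  N-run-delimited fragments of a draft that is collinear with the
  completed genome between gaps; the hybrid exists because full DP over
  multi-kilobase fragments is needlessly quadratic. Real drafts with
  internal indels inside a >3 kb fragment would be scored slightly
  pessimistically; the limit is a parameter.
* **Acceptance.** A placement must align at least `length_fraction`
  (default 0.2) of the fragment at identity at least
  `similarity_fraction` (default 0.5). Equal-scoring loci are resolved by
  the non-specific policy: random placement under a recorded integer
  seed (reproducible), or drop. Raising the similarity threshold can only
  shrink the mapped set (tested monotonicity).

The unaligned flanks of a placed fragment (`left_clip_bp`,
`right_clip_bp`, in draft orientation) quantify misassembled sequence at
either side. Between consecutive fragments of the draft, the placements'
separation on the reference classifies the junction: positive separation
is a **gap** (sequence the completed assembly resolved), negative an
**overlap** (sequence duplicated across the draft junction), zero
abutting. Junctions with an unmapped side, or sides on different
replicons or strands, are *unresolved* and excluded from the summaries —
a signed distance across strands is not defined. On a draft built by
replacing k disjoint segments with equal-length N-runs, the accounting
provably returns exactly k gaps whose lengths equal the replaced
lengths, and the suite asserts this closed loop at 200 kb scale.

## Annotation diffing

Draft CDSs are lifted by placing each gene's genomic extent with the same
engine (a gene interrupted by an N-run is lifted by its longest
determined part; a fully undetermined gene is unmapped). Every reference
gene is then classified against its best-matching lifted gene — maximum
overlap, same strand by default, each draft gene usable by at most one
reference gene (greedy by descending overlap, ties to the smaller start):

1. both ends equal → **Identical**;
2. any overlap with different total length → **Long** (reference longer)
   or **Short** (reference shorter);
3. equal length, neither end equal, overlap > `moved_overlap_fraction`
   (default 0.5) of the reference gene's length → **Moved**;
4. otherwise → **New**; an equal-length pair failing the overlap test
   also releases its draft partner.
5. Draft genes never retained as a partner → **Missing**.

Two invariants follow and are tested: Identical+Long+Short+Moved+New
always equals the reference gene count, and partners+Missing equals the
draft gene count. The overlap denominator is switchable to the shorter
gene; 5′/3′ end-match evidence is strand-aware. Pseudogenes are kept by
default with a reader switch to drop them, since annotation pipelines
differ on their inclusion.

## BGC conservation

Clusters are tables of genes with roles (core biosynthetic, additional
biosynthetic, regulatory, transport, other) and protein sequences —
either a simple TSV or antiSMASH-style region GenBank (`gene_kind`
qualifiers map onto the roles). "Aligned" genes are operationalised as
protein matches at ≥70% identity over aligned residue pairs and ≥70%
query coverage (both configurable; they are package choices, not
literature values). Queries are aligned global-locally (query fully
covered, free target ends) under BLOSUM62; a target shorter than the
coverage floor is skipped exactly, and a shared-5-mer prefilter skips
hopeless pairs cheaply.

The decision procedure per query cluster: all core genes matching inside
a single target cluster gives **Conserved**, unless the matched region
carries two distinct cluster product types (**Partially conserved**, the
hybrid-region case) or the two clusters sit in different chromosome
zones with at least one in a terminal arm (**Conserved in other
regions**; terminal means the outermost 10% of the chromosome,
configurable, and the zone pair is recorded as evidence). Any other
non-empty match pattern — accessory-only conservation, as when only the
regulatory genes of a cluster survive inside another strain's cluster, or
an incomplete core — is **Partially conserved**. No match at all emits
the **strain-specific / Missing** verdict pair. Lowering the identity
threshold can only move labels toward Conserved (tested monotonicity),
and self-comparison is all-Conserved.

## Variant effects

CDS pairs are aligned globally under the same DNA cost model. Runs of
same-kind edit columns merge into single variants; indels are
left-aligned to their leftmost equivalent placement, making positions
like "the base at CDS position 505" well defined in repeat contexts. A
0.01 gap-opening term acts purely as a tie-break so that one multi-base
indel is preferred over the same bases split around a coincidental
match — it cannot reorder alignments that differ in total gap bases.
Applying the called variants to the reference reconstructs the alternate
CDS exactly (round-trip invariant, tested on every synthetic pair).

Frameshift arithmetic: walking indels left to right, the first indel at
which the cumulative indel length is not divisible by 3 disrupts the
frame; the first affected codon is `⌈p/3⌉` for a disruption starting at
nucleotide p (for an insertion after p, at p+1). A premature stop is the
first stop codon in the translated edited sequence before the reference
stop, under bacterial genetic code 11 with ambiguity codons as `X`. The
test suite checks 500 random single-indel cases against an independent
translate-and-compare oracle (different translation library, no variant
calls): the frameshift flag, the invariance of all codons before the
first affected one, and the premature-stop position must all agree.

Difference-site counting across 2–3 strains aligns each protein against
the longest and threads the pairwise alignments into one column-consistent
alignment; a column counts once if any two strains disagree there, a gap
counting as a difference. This union-of-disagreements rule is a package
definition — other counting conventions exist — and the count is
invariant under strain relabeling.

Tandem repeats are exact-only: every maximal array of ≥2 contiguous
copies of a unit in the requested length range, reported once at its
leftmost phase with a primitive motif (an array of "CCCGTTTC" repeated
four times is not additionally reported as two copies of the doubled
16-mer). Intergenic extraction returns the half-open sequence strictly
between two gene extents; overlapping genes give length 0 with the
negative raw separation recorded.

## Fragment ANI and fold changes

The ANI estimator tiles the query genome into non-overlapping 1020 bp
fragments, places each with the engine, and accepts fragments at ≥30%
identity and ≥70% coverage — the conventional fragment-ANI acceptance
rule; ANI is the mean identity of accepted fragments. It is deliberately
*not* a MUMmer-based ANIm reimplementation and is not expected to
reproduce ANIm values to the decimal; what it preserves, and what the
tests assert, are the properties that matter for the species question:
self-ANI is exactly 100, ANI decreases monotonically with substitution
rate, a ~1%-substituted pair sits near 99%, and unrelated random genomes
fail the 95% same-species threshold outright (no fragment is accepted).
Titer fold changes are rounded half away from zero to one decimal —
half-even rounding would print 16.4 where the conventional report of
20.60/1.25 is 16.5.

## The synthetic-data module

`simulate_strain_pair()` is the package's study-conditions generator, at
a desk scale that runs the full pipeline in seconds: a 200 kb completed
genome at GC 0.725 (the organisms' GC content) with 200 non-overlapping
genes; a draft carrying 10 N-gaps of 50–500 bp (equal-length mode by
default; a jitter switch decouples run length from true gap length),
5 duplicated overlaps of 50–200 bp, and isolated ambiguity singletons
M=2, S=3, K=1 — the gap/overlap counts scale the motivating study's
147 gaps and 46 overlaps on an 8.2 Mb genome down to 200 kb, and the
singleton mix mirrors its draft. The annotation mix perturbs 40 genes
per category; the BGC pair plants one cluster per conservation class
plus controls and a target-only decoy; the CDS pair carries 50
substitutions and 3 indels in a ~1 kb CDS; ten repeat arrays (units
8–16 bp, 2–5 copies) are planted with guarded flanks so they are exactly
maximal. Planted events keep ≥1 kb apart so placements cannot interact.
Every generator is bit-deterministic under its seed (one master seed
fans out through a modular hash), and each output comes with a truth
table that the corresponding analysis stage must recover — that closed
loop *is* the module's acceptance surface.

What the simulator does not emulate — and hence what passing tests do
not show about real data: repeat-rich and biased-composition genomes
(placements here are never ambiguous except by explicit construction),
structural rearrangements beyond duplicated junctions, sequencing error
inside fragments beyond point ambiguity, overlapping genes and operonic
structure, and drafts whose N-run length misstates the true gap (covered
only by the jitter switch). Accession-scale inputs behave the same
mechanically but their published values depend on the exact mapper the
original study used; this package's aligner is faithful to the stated
cost model, not bit-compatible with any commercial tool.

## Numerical and design choices

* GC% counts `S` (G-or-C) in the numerator and every ambiguity code in
  the denominator; at realistic ambiguity densities the choice moves GC
  by under 0.001%.
* Compound (join) gene locations collapse to their outer span with a
  flag; the comparison procedures operate on gene extents only.
* Placement tie-breaks are seeded and the seed is echoed in every JSON
  report header, so any run is reproducible from its header alone.
* Test and acceptance problem sizes (200 kb genomes, 60 kb ANI pairs,
  500 oracle cases) were chosen once as the smallest sizes that exercise
  every rule branch with comfortable statistical margin.
* Known limitations: the ungapped fast path for >3 kb fragments assumes
  collinearity within a fragment; the protein 5-mer prefilter could in
  principle skip a borderline homolog near the 70% identity floor;
  multi-strain difference counting is defined for the 2–3 strain case,
  not a general MSA.
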