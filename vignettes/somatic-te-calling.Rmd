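---
title: "Calling somatic TE insertions from short and long reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling somatic TE insertions from short and long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teclone)
library(data.table)
```

## The problem

A transposable element (TE) that mobilizes in a somatic cell leaves a
non-reference insertion carried by that cell's descendants. In a renewing
tissue such as the *Drosophila* intestine, a single mutant stem cell can
expand clonally — for example after inactivation of the X-linked tumor
suppressor *Notch* in males, where one hit suffices — and amplify its
somatic variants to detectable allele frequencies. `teclone` detects such
insertions from two complementary assays:

* **Short-read, clonal samples.** Paired-end whole-genome sequencing of a
  clonally amplified tissue sample and a matched control tissue from the
  same individual. Evidence takes two forms: *split reads* whose terminal
  soft-clipped bases align to a TE consensus, and *discordant pairs*
  where one mate maps near the insertion and the other maps to a
  consensus.
* **Long-read, pooled samples.** Single-molecule reads long enough to
  contain an entire non-reference insertion, with both genomic flanks,
  inside one read. Without clonal expansion a somatic insertion is
  expected in only a fraction of cells in a pooled library, so the
  detection unit is the *singleton*: an insertion supported by exactly
  one read, restricted to one tissue pool.

In both arms, a **target-site duplication (TSD)** — the short identical
sequence duplicated on both sides of the insert by the staggered
endonuclease cut at integration — serves as the footprint that separates
genuine transposition from artifacts.

## Short-read pipeline

### Evidence tagging

`tag_reads()` joins genome alignments with alignments of the same reads
against a TE consensus library. A read contributes *self* evidence when
a soft clip of at least `min_clip` (default 10) bases overlaps its TE
alignment, and *mate* evidence when its mate aligns to a consensus. Hits
from multiple consensus copies of one family collapse to the best score
per family; across families the best score wins, ties breaking
lexicographically and flagged ambiguous. The 10-base floor discards
clips dominated by base-call noise; it is exposed as a parameter because
no principled universal value exists.

### Clustering and junctions

`find_clusters()` performs single-linkage clustering of tagged reads:
two reads join when their junction anchors lie within the upper bound of
the sample's insert-size interval (`estimate_insert_interval()`, the
empirical central 95% of proper-pair template lengths, inverse-ECDF
definition) and their same-side clip sequences do not conflict. Clip
compatibility is anchored identity: the shorter clip must be at least 10
bases and match the longer at 90% or better from the junction outward.
The implementation is a sorted sweep with union-find; it is exactly the
connected components of the full pairwise compatibility graph, and the
test suite verifies this equivalence against an exhaustive
adjacency-matrix oracle.

Each cluster's 5' junction is the modal alignment end of right-clipped
split reads; the 3' junction the modal start of left-clipped ones.
Mate-only clusters fall back to the midpoint between the innermost mate
anchors — and, carrying no clip and no junction resolution, can never
yield a valid TSD, so they are removed by the TSD filter downstream.

### TSD inference

At a TSD-bearing insertion the reference resumes `t` bases *before* the
5' junction. `call_tsd()` therefore requires the 3' junction `p2` to lie
strictly left of the 5' junction `p1` with `1 <= p1 - p2 <= max_tsd`,
and returns `reference[p2, p1)`. `max_tsd` defaults to 60: reported
family medians reach ~26 bases, so 60 is a generous ceiling that still
excludes artifactual overlaps.

### Somatic filtering

`prefilter_support()` keeps candidates with at least one split read
*and* one mate pair. `confirm_somatic()` then removes any candidate that
links to a panel-of-normals call — linking means same chromosome and
family, junctions within `slop` (default 50 bases, chosen to exceed the
junction jitter of mate-only evidence), and clip sequences not
conflicting under the same 90% rule — and requires a valid TSD. The
panel for a clonal (case) sample is every control-tissue sample;
detecting somatic events in controls uses the inverse panel. Manual
screenshot review is replaced by a machine-readable `needs_review` flag
raised when linked case calls disagree on the junction by more than
`slop/2`.

`classify_germline()` labels sites evidenced in both tissues of an
individual as germline, discards germline sites with median coverage
below 10, and splits them into `germline_shared` (all individuals),
`germline_private` (exactly one) — plus `germline_multi` for the
intermediate case and `ambiguous` for individuals lacking a second
tissue; the intermediate labels are deliberate extensions, since folding
them into either end of the scale would misstate the evidence.
`per_family_germline_mode()` re-runs confirmation with the panel set to
all *other* families' calls (ignoring family identity in the link key,
which is what makes an other-family panel able to exclude anything),
retaining calls private to the family under analysis.

## Long-read pipeline

### Read-size normalization

Detection power for fully-contained insertions depends on read length,
so libraries are first equalized: reads are binned on a **fixed**
log-spaced grid (100 bp to 1 Mb, five bins per decade) and each library
is subsampled, seeded and without replacement, to the per-bin minimum.
A fixed grid — rather than breaks derived from the pooled data — makes
normalization idempotent (renormalizing keeps every read) and results
comparable across runs; the grid is a parameter.

### Variant extraction and singletons

`extract_long_variants()` walks each alignment's CIGAR (alignments below
mapping quality 40 are discarded) and tests every insertion segment and
terminal soft clip of at least `min_insert = 100` bases for TE homology.
Homology search is `local_align_te()`: a k-mer-seeded (k = 11), banded
Smith–Waterman with linear gap penalty (match 2, mismatch −3, gap −4,
band 50). Consensi sharing no 11-mer with the segment are rejected in
linear time; the band covers the seeded diagonals, which suffices for
the substitution-dominated divergence this tool targets. The test suite
checks the seeded aligner against an independent full local-alignment
implementation.

Because an aligner folds the duplicated copy into the inserted block,
the TSD of an insert segment is found by comparing the segment's tail
with the reference immediately left of the junction (or its head with
the reference to the right): the longest *exact* match wins, with a
90%-identity rescan only if no exact match exists. A pure
identity-threshold rule systematically overcalls long TSDs (at length 9
and above, one tolerated mismatch always extends the call by one base).

`call_singletons()` groups variants into keys (chromosome, family,
position within 50 bases), requires exactly one supporting read in the
key's own tissue, no support in any other tissue (population germline
variants appear in both pools and are eliminated), both flanks at least
`min_flank = 200` bases, TE coverage of at least 80% of the segment, and
a valid TSD. The flank and coverage floors are set so that moderately 5'
truncated elements still qualify while random clips do not.

## Downstream statistics

* **Allele frequency and timing.** `estimate_af()` counts supporting
  molecules per junction side and averages the sides; opposing molecules
  are proper, fully-aligned pairs spanning the insertion point with no
  TE tag and no junction clip (clipped-but-untagged reads are treated as
  uninformative). The per-side average matters: an insert longer than
  the fragment size recruits distinct molecules on each flank, while an
  opposing molecule spans the locus once, so the naive total
  double-counts carrier molecules and inflates the expected AF from `q`
  to `2q/(1+q)`. `cell_fraction()` doubles autosomal AFs (capped at 1)
  and uses hemizygous-X AFs directly; `classify_timing()` labels an
  insertion pre-clonal when its cell fraction is at least that of the
  clonal driver event, which is an external input (from
  structural-variant calls) rather than something this package computes.
* **Summaries.** `tsd_summary()` reports per-family TSD medians and
  quartiles for families with at least six insertions;
  `family_counts()` tallies catalogs with a family-to-class map.
* **Flanks.** `extract_flanks()` takes the 10 bases on each side of the
  TSD span (the TSD itself excluded by default; a flag includes it,
  since either reading of "±10 around the site" is defensible), writes
  FASTA for external motif tools, and computes per-position base
  frequencies and information content.
* **Enrichment.** `enrichment()` builds, per annotation track, a 2×2
  table of call sites in/out of the track against background units
  in/out, tests it with a two-sided Fisher exact test, and adjusts
  across tracks with Benjamini–Hochberg. The default background unit is
  a seeded sample of random sites within the mappable intervals (100 per
  call) — insertion sites are points, so point sampling is the matched
  null — with base-pair accounting available for parity with
  interval-overlap tools. Enrichment is the observed/expected fraction
  ratio `r`, reported as `r` when `r >= 1` and `-1/r` otherwise; a row
  is significant when the adjusted p is below 0.001 **and** the signed
  magnitude exceeds 1.5. Both thresholds are exposed; the
  BH-at-0.05-then-p<0.001 pairing is redundant but kept as the
  documented convention.

## The simulator and what passing tests mean

`simkit` builds a random genome and a six-family consensus library
(0.6–2.8 kb, covering LTR, LINE-like, TIR and foldback classes),
implants elements with TSDs (optionally 5'-truncated, stranded, at a
given cell fraction and zygosity), and emits paired-end or long reads
together with *gold* alignments derived from the known read origins —
no external aligner is involved, and the truth manifest doubles as the
test oracle. Short-read fragments switch to the carrier haplotype with
probability `cell_fraction x dosage` (heterozygous ½, hemizygous and
homozygous 1) when they cross an insertion point, with carrier coverage
over the inserted block replenished at matched density, so junction
allele fractions are binomial by construction.

Simulated sequencing error is uniform substitution only. The simulator
therefore does **not** emulate: indel or homopolymer error profiles,
PCR duplicates, chimeric reads, mapping ambiguity in repeats (gold
alignments are placed at the true origin; clip anchors shorter than 15
bases are emitted unmapped as a coarse mappability proxy), or reference
TE copies that attract spurious homology. Passing the end-to-end tests
shows the logic of evidence tagging, clustering, TSD inference,
filtering and counting is correct under ideal alignment; it does not
certify recall on real repetitive genomes, where aligner behavior
dominates.

Two generator details are identifiability conditions rather than
conveniences. `random_implant_specs()` rejects sites where the
element's terminal base equals the reference base immediately 5' of the
TSD — at such sites (a quarter of random ones) the duplication length is
ambiguous from sequence alone, and no caller could recover the recorded
value. And in the controlled singleton regime (`reads_per_implant`),
spanning reads are confined between neighboring implant blocks so each
key receives exactly the requested support.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; SAM POS, GFF3 spans and
  catalog positions convert at the file boundary. The reported insertion
  point is the 1-based first duplicated base.
* Ties break lexicographically everywhere (family names, clip consensus
  by count then length then sequence, modal junctions by smallest
  coordinate), so all outputs are deterministic given sorted inputs.
* `estimate_insert_interval()` errors below 2 proper pairs; empty inputs
  yield typed empty tables throughout rather than NULL.
* All stochastic steps take an explicit seed and restore the caller's
  RNG state; identical seeds give identical outputs.

## Problem sizes used in the checks

The end-to-end verification uses a 1 Mb two-chromosome genome with 20
implants (TSDs 3–12 bases) at 50x paired-end coverage; subclonal
sensitivity uses 0.3 cell fraction over repeated 200 kb simulations;
the long-read arm uses ten 0.5–3 kb implants in single reads over two
libraries with different length distributions at 85x-style budgets
scaled to a 0.5 Mb genome; the enrichment null uses 20 random tracks
and 1000 random call sets. These sizes are the package's verification
conditions, chosen to exercise every code path at depths where the
expected evidence counts match the short-read design (tens of reads per
junction).

## Known limitations

* The clip-compatibility and cross-sample linking rules (90% anchored
  identity, 50-base slop) are heuristics; the original analysis did not
  publish exact values, so both are parameters.
* Allele frequencies assume diploid autosomes and a hemizygous male X;
  other karyotypes require a custom `karyotype` table.
* CRAM input, aligner invocation and reference liftover are out of
  scope; alignments come from any standard aligner as SAM (or tables).
* Assembly of full insert sequences from short reads is not attempted;
  full-length insert recovery is the long-read arm's job.
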