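---
title: "Comparing annotation versions: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing annotation versions: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(annotcompare)
```

This vignette explains the models and procedures the package implements, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the places where the design was genuinely open and a choice had
to be made.

## The comparison problem

When a genome is reannotated — typically because new expression evidence
such as RNA-Seq has become available — the practical question is whether the
new gene set is an improvement. Whole-dataset metrics (gene counts, mean
lengths) say little on their own, so the package follows the established
locus-level strategy: put both gene sets on the same coordinates, group
genes into shared loci by coding overlap, classify what happened at each
locus, and then adjudicate the disagreements with independent evidence
(protein homology, domains, intron-level evidence support).

Coordinates are 1-based inclusive genome coordinates throughout, the GFF3
convention. Intron identity is exact coordinate equality of
`(seq_id, strand, first, last)`: the notion of an intron being "fully
supported" by evidence only makes sense with exact boundary agreement, so no
slack window is offered anywhere.

## Locus clustering and classification

Two genes occupy the same locus iff the per-base unions of their CDS
segments share at least one base pair. Using the per-base union across
isoforms (rather than any single isoform) makes locus membership independent
of isoform choice; using CDS rather than exons makes the comparison robust
to the fact that only one of the two versions may annotate UTRs. Loci are
the connected components of the overlap graph over both versions jointly —
within-version overlaps also link, which is what lets redundant gene copies
mapping to one locus end up in one cluster.

Clustering is stranded by default. Merged/split events and structural
identity are inherently strand-specific notions; an overlap between genes on
opposite strands is a different biological situation (and can be examined
with `stranded = FALSE`).

Classification is purely combinatorial: counts of members per side, plus CDS
chain equality for 1-to-1 loci. Two details are deliberate:

* a gene pair is *identical* if **any** isoform of one shares an exact
  ordered CDS chain with **any** isoform of the other — only genes differing
  in *all* alternative isoforms count as structurally different;
* loci with two or more genes on *both* sides are reported as `complex`
  rather than forced into merged or split, because no consistency rule below
  applies cleanly to them. They are rare (absent by construction in the
  simulation) and surface separately so the analyst can look at them.

Ordering everywhere (clusters, members, GFF3 output) is by
`(seq_id, start, id)` with lexicographic id tie-breaks, so all outputs are
deterministic.

## Adjudication rules

For a merged/split event the "merged side" holds the single fused gene and
the "split side" its two or more counterparts. The rule order is:

1. no member of the group has any homology hit → the whole group is a
   **false positive**;
2. at least `min_shared` split-side genes share the merged gene's best hit →
   the **merged** structure is optimal (the fragments look like pieces of
   one protein);
3. the split-side genes have ≥ 2 distinct best hits → the **split**
   structure is optimal (the fusion glued different proteins together);
4. exactly one split-side gene has a hit → **ambiguous**: one hit cannot
   separate a truncated merge from a spurious split;
5. anything else → **ambiguous**.

`min_shared` defaults to 2, i.e. "two or more counterparts agree". A merged
gene usually has exactly two counterparts, so requiring three or more
agreeing counterparts would make the common case undecidable; the parameter
is exposed for users who want the stricter reading.

Best hits come from a 12-column tabular hit file filtered at E ≤ 1e-5 and
ranked by ascending E-value, then descending bitscore. Best-hit identity is
subject-accession string equality.

Modified 1-to-1 pairs are compared only when both proteins have the same
best hit, by aligning each to that subject sequence and comparing identity,
similarity, score and gap count. The four metrics are reported *per metric*
(four tallies) rather than collapsed into a single winner, because the
metrics can disagree and the disagreement is informative; a composite
verdict (lexicographic score > identity > similarity > fewer gaps) is
available behind the `composite` flag.

## The global aligner

`global_align()` is a standard three-state (match / gap-in-one /
gap-in-other) Needleman–Wunsch dynamic program with affine gap penalties: a
gap run of length L costs `gap_open + (L - 1) * gap_extend`, terminal gaps
included. Defaults are BLOSUM62 with open 12 / extend 2, the conventional
defaults of global protein alignment tools. Numerical choices:

* ties in the dynamic program and traceback prefer the diagonal state, then
  the gap consuming the first sequence, then the gap consuming the second —
  making the reported alignment (not just its score) deterministic;
* identity and similarity denominators are the full alignment length
  including all gap columns (terminal ones too): gap columns count toward
  length, never toward identity or similarity; `gaps` counts gap positions
  in both rows;
* adjacent gaps in opposite sequences are allowed and charged as two runs.

The tests verify the implementation three independent ways: the traceback
rescored from its explicit gap runs equals the DP optimum; scores equal an
exhaustive enumeration over all global alignments for short peptides; and
scores agree with an independently implemented aligner under the equivalent
gap parameterization.

## Evidence support

Each evidence track is reduced to the set of introns implied by its
multi-segment features; single-segment features contribute nothing. Tracks
carry one of three class labels — transcript, protein, de novo — and a
gene's intron is supported by a class iff its exact key appears in the union
of that class's tracks. A multi-exon gene is *supported* by a class when at
least one intron is, and *full-length supported* when every intron is; Venn
partitions over classes (or over individual tracks, e.g. RNA-Seq vs EST)
are computed from those flags. Which prediction tracks belong in the
de-novo class is configuration, not hard-coded: predictors trained on the
very evidence being scored should simply not be passed in as tracks.

Support is evaluated on one representative isoform per gene — the isoform
with the longest total CDS, ties broken by transcript id — using the introns
of its full exon chain (CDS plus UTR exons). Most genes have a single
isoform, so this choice rarely matters, but it has to be fixed for the
analysis to be well defined. Single-exon genes have no introns and are
excluded from this analysis, with a notice.

## The synthetic-data generator

The generator exists so that every stage of the pipeline can be validated
against a machine-readable truth, end to end, without any external data. Its
defaults describe the study conditions used throughout the package's own
analyses: 2,000 genes on five sequences, genome GC 0.32 (coding codons drawn
at GC 0.42), exon counts uniform on 1–8, exons of 25–100 codons, introns of
60–600 bp, 8% of unperturbed genes given an exon-skipping second isoform,
UTRs only in the truth version — mirroring a comparison in which only the
newer annotation has UTR evidence. Planted events: 30 merges, 30 splits, 100
boundary shifts, 50 + 50 version-specific genes. Per-class intron-support
probabilities default to 0.90 (transcript), 0.76 (protein) and 0.84
(de novo); with the simulated intron-count distribution these reproduce
full-length-support rates of roughly 72%, 40% and 57% — the ballpark
reported for RNA-Seq-era plant reannotations, where transcript evidence
fully supports the most genes and protein homology the fewest. Planted hit
rates for version-specific genes (26.4% / 59.3%) mirror the same setting.

Construction principles, and what they buy:

* **Planted events sit on disjoint gene sets and genes never overlap**, so
  every expected count is exact, not approximate: the recovery tests can
  demand equality rather than tolerance.
* **All CDS segment lengths are multiples of 3** (codon-aligned exon
  boundaries). This is a simplification relative to real genes, but it makes
  frame-preserving perturbations pure coordinate arithmetic: a boundary
  shift of ±3k bp deletes whole internal codons, and merge/split
  constructions keep reading frame across fragments.
* **Every gene in both versions translates with a start and a stop codon and
  no internal stops.** For a planted merge (one truth gene emitted as two
  v1 fragments) the missing stop of the left fragment and the missing start
  of the right one are planted as in-frame triplets inside the truth gene's
  intron, at its first and last three bases. For a planted split (two
  adjacent same-strand truth genes fused into one v1 gene) the internal stop
  codon is dropped from the fused CDS. Both versions therefore pass the
  ≥ 50-aa start/stop filter and differences are purely structural.
* **The background GC is solved analytically**: given the target genome GC,
  the codon-sampling distribution and all planted triplets, the non-coding
  base probability is chosen so the genome-wide expectation hits the target
  exactly; the empirical GC then lands within binomial noise of it
  (checked at 3 sigma).
* **The EST track is a subset of the RNA-Seq track** (no EST-only introns),
  so the transcript-class support probability stays exactly `p_transcript`
  and the two-set track-level Venn reproduces the situation where RNA-Seq
  covers essentially everything ESTs do.
* **Hit tables are constructed backwards from the planted verdict labels**
  (shared accessions for merge-optimal events, distinct accessions for
  split-optimal ones, one-hit patterns for ambiguous, silence for false
  positives), with decoy lower-ranked rows and sub-threshold rows mixed in
  to exercise ranking and filtering. Reference protein sequences for
  modified pairs are the translation of the planted better side, so the
  per-metric comparison must favor that side.
* **Identical seeds give byte-identical output files**; all file writers
  order their records canonically.

What the generator does **not** emulate: alignment noise and soft intron
boundaries (real spliced aligners misplace edges; support here is exact by
design), overlapping or nested genes, non-canonical splicing,
frame-breaking structural errors, expression levels, assembly gaps, or
`complex` many-to-many loci. Passing tests therefore demonstrate that the
pipeline's logic is correct under clean conditions — they do not measure
robustness to noisy evidence, which on real data should be handled upstream
(by the aligners and combiners producing the inputs).

## Filters, ORFs, rounding and degenerate inputs

The gene-model filter removes a gene only when *every* isoform fails
(protein < 50 aa, or missing start, or missing stop); it is idempotent. The
boundary is inclusive: exactly 50 aa is kept, exactly 150 bp transcripts are
kept. The ORF scanner reports, per transcript, complete ORFs only (ATG
through in-frame stop, length including the stop codon); within a frame,
nested starts resolve to the first ATG after the previous stop, and the
per-transcript flag asks whether any complete ORF reaches `min_nt`
(default 30 nt).

Report rounding is half-up, with percentages and Kb densities at 1 decimal
and per-transcript means at 2 — but published tables are not always
internally consistent about rounding mode (some entries are visibly
truncated), so `report_round()` exposes `truncate` as an alternative and
recomputed values are best compared at printed precision.

Degenerate inputs are handled explicitly rather than silently: empty
annotation sets summarize to zero counts with `NA` means; empty hit files
yield hit tables with no queries; a CDS whose length is not a multiple of 3
translates its complete codons with a warning flag; genes spanning multiple
sequences or strands are rejected at construction; single-exon genes are
skipped (with a notice) by the support analysis; a shared best hit whose
sequence is missing from the reference FASTA flags the pair as not
comparable instead of failing the run.

## Problem sizes

The packaged analyses and tests run the generator at 2,000 genes (about a
7 Mb genome), the clustering oracle-equivalence check at 200 genes over 100
random replicates, and the exhaustive alignment enumeration at peptide
lengths up to 6 over a 4-letter alphabet — sizes chosen so each suite
exercises its component thoroughly while the whole build remains quick on a
single CPU.

## Known limitations

* Many-to-many (`complex`) loci are reported but not adjudicated.
* The evidence-support analysis uses one representative isoform per gene;
  per-isoform support profiles are not produced.
* The aligner is pure R and quadratic; it is comfortable at protein scale
  (hundreds of residues) but not meant for genomic-length alignments.
* GTF input is not supported, only GFF3; cross-assembly coordinate mapping
  is out of scope — both annotations must already be on one assembly.
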