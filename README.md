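# annotcompare

Tools for asking, quantitatively, whether a new version of a genome's
protein-coding gene annotation is better than the old one. The package grew
out of the kind of reannotation study in which RNA-Seq evidence is added to a
gene-prediction pipeline and the resulting gene set is compared, locus by
locus, with the previously published set on the same assembly.

It is aimed at genome-annotation practitioners who have two GFF3 gene sets on
common coordinates plus the usual side products of an annotation pipeline —
spliced evidence alignments, BLASTP tabular hits against a protein database,
and domain-scan results — and who want the comparison itself to be
reproducible and testable.

## What it computes

**Summary statistics.** `summarize_annotation()` produces the standard
annotation panel (gene/transcript/exon/intron/UTR counts and lengths, GC,
gene density in Kb/gene, percent coding as the per-base union of CDS), and
`derive_ratios()` recomputes the derived entries of such a panel from its
totals, e.g. mean exons per transcript e/t and the implied intron count
e − t. `find_complete_orfs()` scans all six frames for complete ORFs
(ATG … in-frame stop); `filter_gene_models()` and
`filter_short_transcripts()` apply the conventional ≥ 50-aa start+stop gene
filter and the ≥ 150-bp transcript filter.

**Structural comparison.** Two genes occupy the same locus iff their per-base
CDS unions share ≥ 1 bp (stranded by default); loci are connected components
of that overlap graph (`cluster_loci()`). Each locus is classified by
`classify_clusters()`:

| members (v1, v2) | kind |
|---|---|
| 1, 0 / 0, 1 | specific_v1 / specific_v2 |
| 1, 1 equal CDS chains | identical |
| 1, 1 different chains | modified_1to1 |
| ≥2, 1 | merged |
| 1, ≥2 | split |
| ≥2, ≥2 | complex |

Structure equality is exact coordinate identity of some isoform's ordered CDS
chain (UTRs ignored); a single shared isoform means same structure.

**Adjudication.** For merged/split events, `adjudicate_merge_split()` applies
best-hit consistency rules to a BLAST-style hit table (E ≤ 1e-5): no hits in
the group ⇒ false positive; ≥ 2 split-side genes sharing the merged gene's
best hit ⇒ the merged structure is optimal; ≥ 2 distinct split-side best hits
⇒ the split structure is optimal; a single split-side hit is ambiguous. For
modified 1-to-1 pairs sharing a best hit, `compare_pair()` aligns both
proteins to the subject with a built-in affine-gap global aligner
(`global_align()`, BLOSUM62, gap open 12 / extend 2) and compares identity,
similarity, score and gap count per metric; `domain_summary()` tallies domain
content per version.

**Evidence support.** Evidence tracks (`build_track()`) are class-labeled
sets of intron keys — exact (seq, strand, first, last) coordinates — derived
from spliced alignments or ab initio predictions. `profile_genes()` marks
each multi-exon gene as supported (≥ 1 intron matched) or full-length
supported (all introns matched) per class, and `venn_counts()` partitions the
genes into disjoint Venn regions over the evidence classes.

**Synthetic data.** `generate(sim_config(...))` builds a seeded toy genome
with a truth annotation, a perturbed annotation with planted merge / split /
boundary-shift / version-specific events, evidence tracks with per-intron
Bernoulli support, hit and domain tables consistent with planted verdict
labels, and a truth ledger (`expected_outputs()`) against which every
pipeline stage is checked exactly.

## Worked example

```r
library(annotcompare)

cfg <- sim_config(seed = 101, n_genes = 300, n_seqs = 2,
                  n_merge = 10, n_split = 10, n_shift = 20,
                  n_specific_v1 = 10, n_specific_v2 = 10)
sim <- generate(cfg)

res <- classify_clusters(cluster_loci(sim$v1, sim$v2), sim$v1, sim$v2)
res$report
#> <comparison_report> 300 loci (280 shared)
#>           kind events genes_v1 genes_v2
#>      identical    240      240      240
#>  modified_1to1     20       20       20
#>         merged     10       20       10
#>          split     10       10       20
#>    specific_v1     10       10        0
#>    specific_v2     10        0       10
#>        complex      0        0        0
```

Every planted event is recovered: 10 merged loci (two v1 genes, one v2
gene), 10 split loci, 20 modified pairs, 10 + 10 version-specific genes; the
remaining 240 loci are structurally identical. Adjudicating the merge/split
events with the simulated hit table reproduces the planted labels:

```r
verdicts <- adjudicate_events(res$events, hit_table(sim$hits))
table(verdicts$kind, verdicts$verdict)
#>          ambiguous false_positive optimal_v1 optimal_v2
#>   merged         2              2          1          5
#>   split          1              1          5          3
```

Full-length evidence support of the 280-odd multi-exon truth genes, as a
three-set Venn over evidence classes:

```r
prof <- profile_genes(sim$v2, sim$tracks, quiet = TRUE)
venn_counts(prof, mode = "full_length")
#>                transcript                   protein                    denovo
#>                        57                        15                        23
#>        transcript&protein         transcript&denovo            protein&denovo
#>                        23                        45                        15
#> transcript&protein&denovo                      none
#>                        51                        42
```

And the aligner underlying pair comparison:

```r
global_align("MKVLLAGRRWE", "MKVLAGRRWE")
#> <alignment_stats> length 11, score 42, identity 90.9%, similarity 90.9%, gaps 1
```

## Analysis workflow

The `analysis/` scripts run the whole study in order on a 2,000-gene
simulated dataset (written under `scratch/sim/`, tables under `results/`):

```sh
Rscript analysis/01_simulate.R           # genome + annotations + ledger
Rscript analysis/02_summary_stats.R      # summary panels, published ratios
Rscript analysis/03_structural_compare.R # loci, events, recovery check
Rscript analysis/04_adjudication.R       # verdicts, pair metrics, domains
Rscript analysis/05_evidence_support.R   # support profiles, Venn, binomial check
```

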