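#!/usr/bin/env Rscript
# Step 1 — generate the synthetic study dataset.
#
# Builds the default 2,000-gene dataset: a toy genome, the truth annotation
# ("annotVer 2.0"), a perturbed annotation ("annotVer 1.0") with 30 planted
# merges, 30 splits, 100 boundary shifts and 50+50 version-specific genes,
# four evidence tracks, hit/domain tables and the truth ledger. Files land
# under scratch/sim/ (they are large); downstream steps read them from there.

suppressPackageStartupMessages(library(annotcompare))

cfg <- sim_config(seed = 20111102)
print(cfg)
sim <- generate(cfg, outdir = "scratch/sim")
cat(
  "wrote scratch/sim: genome", sum(Biostrings::width(sim$genome)), "bp,",
  n_genes(sim$v1), "v1 genes,", n_genes(sim$v2), "v2 genes,",
  nrow(sim$hits), "hit rows\n"
)
cat("genome GC:", round(gc_content(sim$genome), 4), "(target", cfg$gc, ")\n")
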