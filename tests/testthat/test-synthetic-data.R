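# the seeded generator: determinism, validity of the emitted annotation,
# and exact recovery of everything planted

test_that("infeasible configurations fail before any output", {
  expect_error(
    sim_config(n_genes = 20, n_merge = 10, n_split = 10, n_shift = 10),
    "infeasible"
  )
  expect_error(sim_config(p_transcript = 1.2), "probabilities")
  expect_error(
    sim_config(label_mix = c(
      optimal_merged = 0.9, optimal_split = 0.3,
      false_positive = 0, ambiguous = 0
    )),
    "sum to 1"
  )
})

test_that("the same seed reproduces byte-identical output files", {
  cfg <- sim_config(
    seed = 99, n_genes = 40, n_seqs = 1, n_merge = 2, n_split = 2,
    n_shift = 4, n_specific_v1 = 3, n_specific_v2 = 3,
    frac_multi_isoform = 0.1
  )
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate(cfg, d1)
  generate(cfg, d2)
  files <- list.files(d1, recursive = TRUE)
  expect_true(length(files) >= 9)
  for (f in files) {
    expect_identical(
      readLines(file.path(d1, f)), readLines(file.path(d2, f)),
      info = f
    )
  }
})

test_that("written files parse back into the generated objects", {
  cfg <- sim_config(
    seed = 17, n_genes = 30, n_seqs = 1, n_merge = 2, n_split = 2,
    n_shift = 3, n_specific_v1 = 2, n_specific_v2 = 2
  )
  d <- withr::local_tempdir()
  sim <- generate(cfg, d)
  v1 <- parse_gff3(file.path(d, "v1.gff3"), version_label = "annotVer 1.0")
  v2 <- parse_gff3(file.path(d, "v2.gff3"), version_label = "annotVer 2.0")
  expect_identical(v1, sim$v1)
  expect_identical(v2, sim$v2)
  genome <- read_genome(file.path(d, "genome.fa"))
  expect_equal(as.character(genome), as.character(sim$genome))
  tr <- build_track(file.path(d, "tracks", "rnaseq.gff3"), "rnaseq", "transcript")
  expect_equal(tr$keys, sim$tracks$rnaseq$keys)
  h <- load_hits(file.path(d, "hits.tsv"))
  expect_equal(sort(unique(h$qseqid)), sort(unique(hit_table(sim$hits)$qseqid)))
})

test_that("every truth gene translates with start and stop; perturbed genes too", {
  sim <- small_sim()
  check_set <- function(set) {
    for (g in set$genes) {
      for (t in g$transcripts) {
        tr <- translate_cds(t, sim$genome)
        expect_true(tr$has_start, info = t$id)
        expect_true(tr$has_stop, info = t$id)
        expect_false(tr$partial_codon, info = t$id)
        expect_false(grepl("*", tr$protein, fixed = TRUE), info = t$id)
      }
    }
  }
  check_set(sim$v2)
  check_set(sim$v1)
})

test_that("planted structural events are recovered exactly", {
  sim <- small_sim()
  res <- classify_clusters(cluster_loci(sim$v1, sim$v2), sim$v1, sim$v2)
  exp <- expected_outputs(sim$truth)$event_counts
  expect_equal(res$report$event_counts[names(exp)], exp, ignore_attr = TRUE)
  # the planted ledger also matches event-by-event
  got <- events_df(res$events)
  truth <- sim$truth$structural
  truth_key <- sort(paste(truth$kind, truth$v1_ids, truth$v2_ids))
  got_key <- sort(paste(got$kind, got$v1_ids, got$v2_ids))
  expect_equal(got_key, truth_key)
})

test_that("planted adjudication labels are recovered for all plantings", {
  sim <- small_sim()
  res <- classify_clusters(cluster_loci(sim$v1, sim$v2), sim$v1, sim$v2)
  verd <- adjudicate_events(res$events, hit_table(sim$hits))
  ev_by_id <- stats::setNames(
    res$events, vapply(res$events, `[[`, "", "cluster_id")
  )
  verd$merged_gene <- vapply(verd$event_id, function(eid) {
    e <- ev_by_id[[eid]]
    if (e$kind == "merged") e$v2_gene_ids else e$v1_gene_ids
  }, "")
  m <- merge(verd, sim$truth$adjudication, by = "merged_gene")
  expect_equal(nrow(m), nrow(sim$truth$adjudication))
  expect_equal(m$verdict, m$expected_verdict)
})

test_that("support profiles equal the ledger emissions exactly", {
  sim <- small_sim()
  prof <- profile_genes(sim$v2, sim$tracks, quiet = TRUE)
  exp <- expected_outputs(sim$truth)$support
  m <- merge(prof, exp, by = "gene_id", suffixes = c("", ".exp"))
  expect_equal(nrow(m), nrow(prof))
  expect_equal(m$n_introns, m$n_introns.exp)
  for (cl in c("transcript", "protein", "denovo")) {
    expect_equal(
      m[[paste0("supported_", cl)]], m[[paste0("supported_", cl, ".exp")]],
      info = cl
    )
    expect_equal(
      m[[paste0("full_", cl)]], m[[paste0("full_", cl, ".exp")]],
      info = cl
    )
  }
  expect_equal(m$sup_n_transcript, sim$truth$evidence$sup_transcript[
    match(m$gene_id, sim$truth$evidence$gene_id)
  ])
})

test_that("modified pairs align better on the planted side", {
  sim <- small_sim()
  res <- classify_clusters(cluster_loci(sim$v1, sim$v2), sim$v1, sim$v2)
  kept <- exclude_multi_isoform(res$events, sim$v1, sim$v2)$kept
  pairs <- compare_modified_pairs(
    kept, sim$v1, sim$v2, sim$genome,
    hit_table(sim$hits), sim$ref_proteins
  )
  expect_true(all(pairs$comparable))
  truth <- sim$truth$pairs
  m <- merge(pairs, truth, by = "v1_id")
  expect_equal(nrow(m), nrow(truth))
  exp_outcome <- ifelse(m$better_side == "v1", "v1_better", "v2_better")
  expect_equal(m$score, exp_outcome)
  expect_equal(m$identity, exp_outcome)
  expect_equal(m$gaps, exp_outcome)
})

test_that("p_transcript = 1 makes every multi-exon gene full-length supported", {
  cfg <- sim_config(
    seed = 5, n_genes = 60, n_seqs = 1, n_merge = 0, n_split = 0,
    n_shift = 0, n_specific_v1 = 0, n_specific_v2 = 0,
    p_transcript = 1
  )
  sim <- generate(cfg)
  prof <- profile_genes(sim$v2, sim$tracks, quiet = TRUE)
  expect_true(all(prof$full_transcript))
})

test_that("the genome-wide GC lands within three binomial sigma of the target", {
  sim <- small_sim()
  gc <- gc_content(sim$genome)
  L <- sum(Biostrings::width(sim$genome))
  target <- sim$config$gc
  sigma <- sqrt(target * (1 - target) / L)
  expect_lt(abs(gc - target), 3 * sigma)
})

test_that("domain tables are consistent with the planted extra-domain flags", {
  sim <- small_sim()
  truth <- sim$truth$pairs
  ds <- domain_summary(sim$domains, truth$v1_id, truth$v2_id)
  expect_equal(ds$v1$n_genes_with_domain, nrow(truth))
  expect_equal(ds$v2$n_genes_with_domain, nrow(truth))
  expect_equal(ds$v2$n_domain_kinds, nrow(truth) + sum(truth$extra_domain_v2))
  expect_equal(ds$v1$n_domain_kinds, nrow(truth))
})
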