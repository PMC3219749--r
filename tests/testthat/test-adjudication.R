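# hit tables, the merge/split verdict rules, and modified-pair comparison

write_hits <- function(rows, path) {
  write.table(rows, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  path
}

hit_row <- function(q, s, evalue, bitscore = 100) {
  data.frame(
    q = q, s = s, pid = 90, len = 100, mm = 10, go = 0,
    qs = 1, qe = 100, ss = 1, se = 100, ev = evalue, bs = bitscore
  )
}

mk_event <- function(kind, v1, v2, id = "locus_000001") {
  structure(
    list(cluster_id = id, kind = kind, v1_gene_ids = v1, v2_gene_ids = v2),
    class = "comparison_event"
  )
}

test_that("hit loading applies the E-value cutoff and ranks by E-value then bitscore", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_hits(rbind(
    hit_row("q1", "keep", 1e-6),
    hit_row("q1", "drop", 1e-4), # fails the 1e-5 cutoff
    hit_row("q2", "second", 1e-8, bitscore = 50),
    hit_row("q2", "first", 1e-10, bitscore = 40),
    hit_row("q3", "tieB", 1e-9, bitscore = 60),
    hit_row("q3", "tieA", 1e-9, bitscore = 80)
  ), f)
  h <- load_hits(f, evalue_cutoff = 1e-5)
  expect_equal(nrow(h), 5L)
  expect_false("drop" %in% h$sseqid)
  expect_equal(best_hit(h, "q1"), "keep")
  expect_equal(best_hit(h, "q2"), "first") # smaller E-value wins
  expect_equal(best_hit(h, "q3"), "tieA") # bitscore breaks E-value ties
  expect_true(is.na(best_hit(h, "missing")))
})

test_that("an empty hit file yields a table with no queries", {
  f <- withr::local_tempfile(fileext = ".tsv")
  file.create(f)
  h <- load_hits(f)
  expect_s3_class(h, "hit_table")
  expect_equal(nrow(h), 0L)
})

test_that("malformed hit rows are reported with their row number", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "q1\ts1\t90\t100\t10\t0\t1\t100\t1\t100\t1e-20\t100",
    "q2\ts2\t90\t100\t10\t0\t1\t100\t1\t100\tnot_a_number\t100"
  ), f)
  expect_error(load_hits(f), "2")
})

test_that("the verdict rule table is applied in order, on both event kinds", {
  merged_ev <- mk_event("merged", c("a1", "a2"), "b1")
  split_ev <- mk_event("split", "a1", c("b1", "b2"))

  run <- function(event, rows, ...) {
    adjudicate_merge_split(event, hit_table(do.call(rbind, rows)), ...)
  }

  # rule 1: no hits anywhere -> false positive
  v <- adjudicate_merge_split(merged_ev, hit_table(hit_row("zz", "s", 1e-20)[0, ]))
  expect_equal(v$verdict, "false_positive")
  expect_match(v$rationale, "rule 1")

  # rule 2: both split-side genes share the merged gene's best hit
  v2 <- run(merged_ev, list(
    hit_row("b1", "P", 1e-50), hit_row("a1", "P", 1e-40), hit_row("a2", "P", 1e-30)
  ))
  expect_equal(v2$verdict, "optimal_v2") # merged side of a "merged" event is v2
  expect_match(v2$rationale, "rule 2")

  # the same hit pattern on a "split" event favors v1 (its merged side)
  v2s <- run(split_ev, list(
    hit_row("a1", "P", 1e-50), hit_row("b1", "P", 1e-40), hit_row("b2", "P", 1e-30)
  ))
  expect_equal(v2s$verdict, "optimal_v1")

  # rule 3: split-side genes have two distinct best hits
  v3 <- run(split_ev, list(
    hit_row("a1", "P", 1e-50), hit_row("b1", "P", 1e-40), hit_row("b2", "Q", 1e-30)
  ))
  expect_equal(v3$verdict, "optimal_v2") # split side of a "split" event is v2
  expect_match(v3$rationale, "rule 3")

  # rule 4: exactly one split-side gene has a hit
  v4 <- run(merged_ev, list(hit_row("b1", "P", 1e-50), hit_row("a1", "P", 1e-40)))
  expect_equal(v4$verdict, "ambiguous")
  expect_match(v4$rationale, "rule 4")

  # rule 5: both split genes share one best hit but the merged gene has none
  v5 <- run(merged_ev, list(hit_row("a1", "P", 1e-40), hit_row("a2", "P", 1e-30)))
  expect_equal(v5$verdict, "ambiguous")
  expect_match(v5$rationale, "rule 5")

  # min_shared is configurable: requiring 3 shared turns rule 2 into rule 5
  v6 <- run(merged_ev, list(
    hit_row("b1", "P", 1e-50), hit_row("a1", "P", 1e-40), hit_row("a2", "P", 1e-30)
  ), min_shared = 3)
  expect_equal(v6$verdict, "ambiguous")

  # wrong kind is a usage error
  expect_error(
    adjudicate_merge_split(
      mk_event("identical", "a1", "b1"),
      hit_table(hit_row("a1", "P", 1e-40))
    ),
    "merged/split"
  )
})

test_that("every merged/split event receives exactly one verdict", {
  sim <- small_sim()
  res <- classify_clusters(cluster_loci(sim$v1, sim$v2), sim$v1, sim$v2)
  verd <- adjudicate_events(res$events, hit_table(sim$hits))
  n_ms <- sum(vapply(res$events, `[[`, "", "kind") %in% c("merged", "split"))
  expect_equal(nrow(verd), n_ms)
  expect_false(anyDuplicated(verd$event_id) > 0)
  expect_true(all(verd$verdict %in% c(
    "optimal_v1", "optimal_v2", "false_positive", "ambiguous"
  )))
})

test_that("identical proteins compare equal; a deletion makes the intact gene better", {
  ref <- Biostrings::AAStringSet(c(P1 = "MKVLLAGRRWE"))
  hits <- hit_table(rbind(hit_row("g1", "P1", 1e-30), hit_row("g2", "P1", 1e-30)))
  same <- compare_pair("MKVLLAGRRWE", "MKVLLAGRRWE", "g1", "g2", hits, ref)
  expect_true(same$comparable)
  expect_equal(unname(same$metrics), rep("equal", 4))

  worse <- compare_pair("MKVLAGRRWE", "MKVLLAGRRWE", "g1", "g2", hits, ref)
  expect_equal(unname(worse$metrics[c("identity", "score", "gaps")]),
    rep("v2_better", 3))

  comp <- compare_pair("MKVLAGRRWE", "MKVLLAGRRWE", "g1", "g2", hits, ref,
    composite = TRUE)
  expect_equal(comp$composite, "v2_better")
})

test_that("pairs without a shared best hit or reference sequence are flagged, not fatal", {
  ref <- Biostrings::AAStringSet(c(P1 = "MKV"))
  hits <- hit_table(rbind(hit_row("g1", "P1", 1e-30), hit_row("g2", "P2", 1e-30)))
  pv <- compare_pair("MKV", "MKV", "g1", "g2", hits, ref)
  expect_false(pv$comparable)
  expect_match(pv$reason, "differ")

  hits2 <- hit_table(rbind(hit_row("g1", "PX", 1e-30), hit_row("g2", "PX", 1e-30)))
  pv2 <- compare_pair("MKV", "MKV", "g1", "g2", hits2, ref)
  expect_false(pv2$comparable)
  expect_match(pv2$reason, "PX")

  hits3 <- hit_table(hit_row("g1", "P1", 1e-30))
  expect_false(compare_pair("MKV", "MKV", "g1", "g2", hits3, ref)$comparable)
})

test_that("domain tallies count genes with domains and distinct accessions per version", {
  domains <- data.frame(
    gene_id = c("g1", "g2", "g2"),
    domain_accession = c("D1", "D1", "D2")
  )
  ds <- domain_summary(domains, v1_ids = "g1", v2_ids = "g2")
  expect_equal(ds$v1$n_genes_with_domain, 1L)
  expect_equal(ds$v1$n_domain_kinds, 1L)
  expect_equal(ds$v2$n_genes_with_domain, 1L)
  expect_equal(ds$v2$n_domain_kinds, 2L)
})
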