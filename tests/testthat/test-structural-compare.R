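# locus clustering, structure equality and event classification

test_that("coding overlap of one base pair joins a locus; disjoint genes do not", {
  a <- annotation_set(list(make_gene("a1", exons = seg(100, 200))), "v1")
  b <- annotation_set(list(make_gene("b1", exons = seg(150, 250))), "v2")
  cl <- cluster_loci(a, b)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$members_v1, "a1")
  expect_equal(cl[[1]]$members_v2, "b1")

  b2 <- annotation_set(list(make_gene("b1", exons = seg(300, 400))), "v2")
  cl2 <- cluster_loci(a, b2)
  expect_length(cl2, 2L)
  expect_equal(lengths(lapply(cl2, `[[`, "members_v1")), c(1L, 0L), ignore_attr = TRUE)

  # exactly one shared base pair still links
  b3 <- annotation_set(list(make_gene("b1", exons = seg(200, 300))), "v2")
  expect_length(cluster_loci(a, b3), 1L)
})

test_that("transitive chains form one cluster", {
  a <- annotation_set(list(
    make_gene("A", exons = seg(100, 200)),
    make_gene("C", exons = seg(300, 400))
  ), "v1")
  b <- annotation_set(list(make_gene("B", exons = seg(180, 320))), "v2")
  cl <- cluster_loci(a, b)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$members_v1, c("A", "C"))
  expect_equal(cl[[1]]$members_v2, "B")
})

test_that("stranded clustering separates opposite-strand overlaps; unstranded joins them", {
  a <- annotation_set(list(make_gene("a1", strand = "+", exons = seg(100, 200))), "v1")
  b <- annotation_set(list(make_gene("b1", strand = "-", exons = seg(150, 250))), "v2")
  expect_length(cluster_loci(a, b, stranded = TRUE), 2L)
  expect_length(cluster_loci(a, b, stranded = FALSE), 1L)
})

test_that("clustering matches a brute-force union-find oracle on random sets", {
  set.seed(77)
  for (rep in 1:15) {
    pair <- random_annotation_pair(n_per_version = 60, max_pos = 8000)
    got <- partition_of_clusters(cluster_loci(pair$a, pair$b))
    expect_equal(got, unname(oracle_partition(pair$a, pair$b)))
    got_un <- partition_of_clusters(cluster_loci(pair$a, pair$b, stranded = FALSE))
    expect_equal(got_un, unname(oracle_partition(pair$a, pair$b, stranded = FALSE)))
  }
})

test_that("structure equality compares ordered CDS chains over isoforms", {
  g1 <- make_gene("g1", exons = seg(1, 90, 201, 290))
  g2 <- make_gene("g2", exons = seg(1, 90, 201, 290))
  expect_true(structures_equal(g1, g2))

  shifted <- make_gene("g3", exons = seg(1, 90, 204, 290))
  expect_false(structures_equal(g1, shifted))

  # a single shared isoform means same structure
  multi <- gene_model("g4", list(
    make_tx("g4.1", "g4", exons = seg(1, 90, 201, 290)),
    make_tx("g4.2", "g4", exons = seg(1, 90))
  ))
  expect_true(structures_equal(multi, g1))

  # different strand is never equal
  minus <- make_gene("g5", strand = "-", exons = seg(1, 90, 201, 290))
  expect_false(structures_equal(g1, minus))
})

test_that("classification follows the member-count rule table", {
  a <- annotation_set(list(
    make_gene("a_ident", exons = seg(100, 190)),
    make_gene("a_mod", exons = seg(1100, 1190)),
    make_gene("a_m1", exons = seg(2100, 2190)),
    make_gene("a_m2", exons = seg(2300, 2390)),
    make_gene("a_split", exons = seg(3100, 3490)),
    make_gene("a_only", exons = seg(5100, 5190))
  ), "v1")
  b <- annotation_set(list(
    make_gene("b_ident", exons = seg(100, 190)),
    make_gene("b_mod", exons = seg(1100, 1193)),
    make_gene("b_merged", exons = seg(2100, 2390)),
    make_gene("b_s1", exons = seg(3100, 3190)),
    make_gene("b_s2", exons = seg(3400, 3490)),
    make_gene("b_only", exons = seg(6100, 6190))
  ), "v2")
  res <- classify_clusters(cluster_loci(a, b), a, b)
  kinds <- stats::setNames(
    vapply(res$events, `[[`, "", "kind"),
    vapply(res$events, function(e) paste(c(e$v1_gene_ids, e$v2_gene_ids), collapse = "+"), "")
  )
  expect_equal(unname(kinds[["a_ident+b_ident"]]), "identical")
  expect_equal(unname(kinds[["a_mod+b_mod"]]), "modified_1to1")
  expect_equal(unname(kinds[["a_m1+a_m2+b_merged"]]), "merged")
  expect_equal(unname(kinds[["a_split+b_s1+b_s2"]]), "split")
  expect_equal(unname(kinds[["a_only"]]), "specific_v1")
  expect_equal(unname(kinds[["b_only"]]), "specific_v2")
  expect_equal(res$report$n_shared_loci, 4L)
  # every gene appears in exactly one event
  all_ids <- unname(unlist(lapply(res$events, function(e) c(e$v1_gene_ids, e$v2_gene_ids))))
  expect_equal(sort(all_ids), sort(unname(c(names(a$genes), names(b$genes)))))
})

test_that("swapping the versions swaps merged/split and the specific counts", {
  sim <- small_sim()
  fwd <- classify_clusters(cluster_loci(sim$v1, sim$v2), sim$v1, sim$v2)$report
  rev <- classify_clusters(cluster_loci(sim$v2, sim$v1), sim$v2, sim$v1)$report
  expect_equal(fwd$event_counts[["merged"]], rev$event_counts[["split"]])
  expect_equal(fwd$event_counts[["split"]], rev$event_counts[["merged"]])
  expect_equal(fwd$event_counts[["specific_v1"]], rev$event_counts[["specific_v2"]])
  expect_equal(fwd$event_counts[["specific_v2"]], rev$event_counts[["specific_v1"]])
  expect_equal(fwd$event_counts[["identical"]], rev$event_counts[["identical"]])
  expect_equal(fwd$event_counts[["modified_1to1"]], rev$event_counts[["modified_1to1"]])
})

test_that("the partition property holds on simulated data", {
  sim <- small_sim()
  res <- classify_clusters(cluster_loci(sim$v1, sim$v2), sim$v1, sim$v2)
  ids <- unlist(lapply(res$events, function(e) c(
    paste0("1|", e$v1_gene_ids, recycle0 = TRUE),
    paste0("2|", e$v2_gene_ids, recycle0 = TRUE)
  )))
  expect_equal(length(ids), n_genes(sim$v1) + n_genes(sim$v2))
  expect_false(anyDuplicated(ids) > 0)
})

test_that("multi-isoform genes are excluded from downstream adjudication", {
  multi <- gene_model("gm", list(
    make_tx("gm.1", "gm", exons = seg(100, 190, 301, 390)),
    make_tx("gm.2", "gm", exons = seg(100, 190))
  ))
  a <- annotation_set(list(make_gene("ga", exons = seg(100, 190))), "v1")
  b <- annotation_set(list(multi), "v2")
  res <- classify_clusters(cluster_loci(a, b), a, b)
  filt <- exclude_multi_isoform(res$events, a, b)
  expect_length(filt$kept, 0L)
  expect_equal(filt$excluded$gene_id, "gm")
  expect_equal(filt$excluded$n_isoforms, 2L)

  # all-single-isoform events are retained; empty input stays empty
  res2 <- classify_clusters(cluster_loci(a, a), a, a)
  expect_length(exclude_multi_isoform(res2$events, a, a)$kept, length(res2$events))
  expect_length(exclude_multi_isoform(list(), a, b)$kept, 0L)
})
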