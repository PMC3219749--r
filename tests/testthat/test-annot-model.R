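# gene-model types, intron derivation, translation, GC content,
# and the CDS interval index

test_that("transcript and gene constructors validate their invariants", {
  t <- make_tx(exons = seg(101, 200, 301, 400), cds = seg(151, 200, 301, 350))
  expect_s3_class(t, "transcript_model")
  expect_equal(t$exons$start, c(101, 301))

  # exons sorted on construction
  t2 <- make_tx(exons = seg(301, 400, 101, 200))
  expect_equal(t2$exons$start, c(101, 301))

  expect_error(make_tx(exons = seg(101, 200, 150, 300)), "overlap")
  expect_error(make_tx(exons = seg(200, 101)), "end must be >= start")
  expect_error(
    make_tx(exons = seg(100, 200), cds = seg(500, 600)),
    "not contained in any exon"
  )
  # seq-id-spanning genes rejected
  expect_error(
    gene_model("g", list(
      make_tx("t1", "g", "chr1", "+", seg(1, 30)),
      make_tx("t2", "g", "chr2", "+", seg(1, 30))
    )),
    "multiple sequences or strands"
  )
})

test_that("introns_of derives the gaps between consecutive segments", {
  t <- make_tx(exons = seg(101, 200, 301, 400))
  i <- introns_of(t)
  expect_equal(i$first, 201)
  expect_equal(i$last, 300)

  expect_equal(nrow(introns_of(make_tx(exons = seg(101, 200)))), 0)

  t3 <- make_tx(exons = seg(101, 200, 301, 400, 501, 700))
  i3 <- introns_of(t3)
  expect_equal(i3$first, c(201, 401))
  expect_equal(i3$last, c(300, 500))

  # cds basis uses the CDS chain
  t4 <- make_tx(
    exons = seg(101, 200, 301, 400),
    cds = seg(150, 200, 301, 350)
  )
  expect_equal(introns_of(t4, basis = "cds")$first, 201)
})

test_that("intron count equals segment count minus one on random transcripts", {
  set.seed(11)
  for (rep in 1:25) {
    k <- sample(1:9, 1)
    starts <- cumsum(sample(50:200, k)) + (0:(k - 1)) * 100
    ends <- starts + sample(20:80, k, replace = TRUE)
    t <- make_tx(exons = data.frame(start = starts, end = ends))
    expect_equal(nrow(introns_of(t)), k - 1)
    # genomic ascending order regardless of strand
    tm <- make_tx(strand = "-", exons = data.frame(start = starts, end = ends))
    expect_equal(introns_of(tm)$first, introns_of(t)$first)
  }
})

test_that("translate_cds handles both strands, flags and partial codons", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "TTATGAAATAGTT"))
  t <- make_tx(exons = seg(3, 11))
  tr <- translate_cds(t, genome)
  expect_equal(tr$protein, "MK")
  expect_equal(tr$aa_length, 2L)
  expect_true(tr$has_start)
  expect_true(tr$has_stop)

  # no ATG at the first codon
  genome2 <- Biostrings::DNAStringSet(c(chr1 = "AAAAAATAG"))
  tr2 <- translate_cds(make_tx(exons = seg(1, 9)), genome2)
  expect_false(tr2$has_start)
  expect_true(tr2$has_stop)

  # minus strand: genome holds the reverse complement of ATGAAATAG
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString("ATGAAATAG")))
  genome3 <- Biostrings::DNAStringSet(stats::setNames(paste0("CC", rc, "CC"), "chr1"))
  tr3 <- translate_cds(make_tx(strand = "-", exons = seg(3, 11)), genome3)
  expect_equal(tr3$protein, "MK")
  expect_true(tr3$has_start && tr3$has_stop)

  # spliced CDS across an intron
  genome4 <- Biostrings::DNAStringSet(c(chr1 = "ATGAAATTTTTTTAG"))
  t4 <- make_tx(exons = seg(1, 6, 13, 15))
  expect_equal(translate_cds(t4, genome4)$protein, "MK")

  # CDS length not divisible by 3: warns, translates the floor
  genome5 <- Biostrings::DNAStringSet(c(chr1 = "ATGAAATAGG"))
  t5 <- make_tx(exons = seg(1, 10))
  expect_warning(tr5 <- translate_cds(t5, genome5), "not divisible by 3")
  expect_true(tr5$partial_codon)
  expect_equal(tr5$protein, "MK")
})

test_that("gc_content excludes ambiguity codes and matches the definition", {
  expect_equal(gc_content("ATGC"), 0.5)
  expect_equal(gc_content("AAAA"), 0)
  expect_equal(gc_content("GGCC"), 1)
  expect_equal(gc_content("GGNNAA"), 0.5) # N excluded from the denominator
  expect_true(is.na(gc_content("NNNN")))
  expect_true(is.na(gc_content(character(0))))
})

test_that("gc_content is invariant under reverse complement", {
  set.seed(5)
  for (rep in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 200, replace = TRUE), collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_equal(gc_content(s), gc_content(rc))
  }
})

test_that("UTRs are derived as exon minus CDS, oriented by strand", {
  t <- make_tx(
    exons = seg(100, 250, 300, 500),
    cds = seg(200, 250, 300, 420)
  )
  u <- utr_segments(t)
  expect_equal(u$utr5, data.frame(start = 100L, end = 199L))
  expect_equal(u$utr3, data.frame(start = 421L, end = 500L))
  tm <- make_tx(
    strand = "-",
    exons = seg(100, 250, 300, 500),
    cds = seg(200, 250, 300, 420)
  )
  um <- utr_segments(tm)
  expect_equal(um$utr5, data.frame(start = 421L, end = 500L))
  expect_equal(um$utr3, data.frame(start = 100L, end = 199L))
})

test_that("the interval index agrees with a brute-force overlap scan", {
  set.seed(21)
  for (rep in 1:5) {
    genes <- lapply(1:60, function(i) {
      start <- sample.int(5000, 1)
      make_gene(sprintf("g%03d", i),
        seq_id = sample(c("chr1", "chr2"), 1),
        strand = sample(c("+", "-"), 1),
        exons = seg(start, start + sample(20:300, 1))
      )
    })
    set <- annotation_set(genes)
    for (q in 1:20) {
      qs <- sample.int(5000, 1)
      qe <- qs + sample(10:400, 1)
      qseq <- sample(c("chr1", "chr2"), 1)
      hits <- overlapping_genes(set, qseq, qs, qe)
      brute <- sort(vapply(
        Filter(function(g) {
          u <- cds_union(g)
          g$seq_id == qseq && min(u$start) <= qe && qs <= max(u$end)
        }, genes),
        `[[`, "", "id"
      ))
      expect_equal(hits, unname(brute))
    }
  }
})

test_that("representative isoform is the longest CDS with id tie-break", {
  g <- gene_model("g", list(
    make_tx("t.b", "g", exons = seg(1, 30)),
    make_tx("t.a", "g", exons = seg(1, 60))
  ))
  expect_equal(representative_isoform(g)$id, "t.a")
  tie <- gene_model("g2", list(
    make_tx("t.z", "g2", exons = seg(1, 30)),
    make_tx("t.y", "g2", exons = seg(101, 130))
  ))
  expect_equal(representative_isoform(tie)$id, "t.y")
})
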