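# Builders and independent oracles shared by the test files. The oracles
# deliberately use naive algorithms (pairwise scans, union-find, exhaustive
# enumeration) so they stay independent of the implementation they check.

seg <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  data.frame(start = m[, 1], end = m[, 2])
}

make_tx <- function(id = "t1", gene_id = "g1", seq_id = "chr1", strand = "+",
                    exons, cds = exons) {
  transcript_model(id, gene_id, seq_id, strand, exons, cds)
}

make_gene <- function(id = "g1", seq_id = "chr1", strand = "+",
                      exons, cds = exons, tx_id = paste0(id, ".t1")) {
  gene_model(id, list(make_tx(tx_id, id, seq_id, strand, exons, cds)))
}

# a single-exon gene whose protein has exactly aa_len residues (start+stop),
# plus the genome holding it
make_gene_with_protein <- function(aa_len, id = "g1", pad = 12L,
                                   strand = "+", seq_id = "chr1") {
  cds_nt <- paste0("ATG", strings_rep("GCA", aa_len - 1), "TAA")
  len <- nchar(cds_nt)
  if (strand == "-") {
    cds_nt <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds_nt)))
  }
  chrom <- paste0(strings_rep("A", pad), cds_nt, strings_rep("A", pad))
  genome <- Biostrings::DNAStringSet(chrom)
  names(genome) <- seq_id
  g <- make_gene(id,
    seq_id = seq_id, strand = strand,
    exons = seg(pad + 1L, pad + len)
  )
  list(gene = g, genome = genome)
}

strings_rep <- function(x, n) paste(rep(x, n), collapse = "")

# random annotation pair with single-exon, single-CDS genes at random
# positions (overlaps allowed); used for clustering-oracle equivalence
random_annotation_pair <- function(n_per_version = 100, max_pos = 20000,
                                   n_seqs = 2, stranded_mix = TRUE) {
  mk <- function(version, n) {
    lapply(seq_len(n), function(i) {
      start <- sample.int(max_pos, 1)
      len <- sample(30:400, 1)
      make_gene(
        id = sprintf("v%d_g%03d", version, i),
        seq_id = sprintf("chr%d", sample.int(n_seqs, 1)),
        strand = if (stranded_mix) sample(c("+", "-"), 1) else "+",
        exons = seg(start, start + len)
      )
    })
  }
  list(
    a = annotation_set(mk(1, n_per_version), "v1"),
    b = annotation_set(mk(2, n_per_version), "v2")
  )
}

# --- union-find clustering oracle (O(n^2) pairwise overlap scan) ----------

oracle_partition <- function(a, b, stranded = TRUE) {
  info <- do.call(rbind, lapply(list(c(1, "a"), c(2, "b")), function(vv) {
    set <- if (vv[2] == "a") a else b
    do.call(rbind, lapply(set$genes, function(g) {
      u <- cds_union(g)
      data.frame(
        node = paste0(vv[1], "|", g$id), seq_id = g$seq_id,
        strand = g$strand, start = min(u$start), end = max(u$end)
      )
    }))
  }))
  n <- nrow(info)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same_seq <- info$seq_id[i] == info$seq_id[j]
      same_str <- !stranded || info$strand[i] == info$strand[j]
      over <- info$start[i] <= info$end[j] && info$start[j] <= info$end[i]
      if (same_seq && same_str && over) {
        ri <- find(i)
        rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  groups <- split(info$node, roots)
  sort(vapply(groups, function(g) paste(sort(g), collapse = ","), ""))
}

partition_of_clusters <- function(clusters) {
  unname(sort(vapply(clusters, function(cl) {
    mem <- c(
      paste0("1|", cl$members_v1, recycle0 = TRUE),
      paste0("2|", cl$members_v2, recycle0 = TRUE)
    )
    paste(sort(mem), collapse = ",")
  }, "")))
}

# --- exhaustive global-alignment oracle -----------------------------------

# enumerate every global alignment as a move string (D = aligned pair,
# U = gap in second sequence, L = gap in first) and score it with the
# affine run model; returns the maximum score
enum_align_score <- function(p1, p2, mat, gap_open = 12, gap_extend = 2) {
  a <- strsplit(p1, "")[[1]]
  b <- strsplit(p2, "")[[1]]
  n <- length(a)
  m <- length(b)
  best <- -Inf
  score_moves <- function(moves) {
    i <- 0L
    j <- 0L
    s <- 0
    for (mv in moves) {
      if (mv == "D") {
        i <- i + 1L
        j <- j + 1L
        s <- s + mat[a[i], b[j]]
      } else if (mv == "U") i <- i + 1L else j <- j + 1L
    }
    r <- rle(moves)
    runs <- r$lengths[r$values != "D"]
    s - sum(gap_open + (runs - 1) * gap_extend)
  }
  rec <- function(i, j, moves) {
    if (i == n && j == m) {
      best <<- max(best, score_moves(moves))
      return(invisible())
    }
    if (i < n && j < m) rec(i + 1L, j + 1L, c(moves, "D"))
    if (i < n) rec(i + 1L, j, c(moves, "U"))
    if (j < m) rec(i, j + 1L, c(moves, "L"))
  }
  rec(0L, 0L, character(0))
  best
}

# --- naive six-frame complete-ORF flag ------------------------------------

oracle_has_complete_orf <- function(s, min_nt = 30) {
  check_strand <- function(x) {
    L <- nchar(x)
    for (p in seq_len(max(L - 5, 0))) {
      if (substr(x, p, p + 2) != "ATG") next
      q <- p + 3
      while (q + 2 <= L) {
        cod <- substr(x, q, q + 2)
        if (cod %in% c("TAA", "TAG", "TGA")) {
          if (q + 2 - p + 1 >= min_nt) return(TRUE)
          break
        }
        q <- q + 3
      }
    }
    FALSE
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  check_strand(s) || check_strand(rc)
}

# small shared simulation for module tests (kept modest for speed)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(
        seed = 424242, n_genes = 220, n_seqs = 2,
        n_merge = 8, n_split = 8, n_shift = 16,
        n_specific_v1 = 12, n_specific_v2 = 12
      )
      cache <<- generate(cfg)
    }
    cache
  }
})
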