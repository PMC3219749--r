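# Seeded synthetic-data generator: a toy genome, a truth annotation ("v2"),
# a perturbed annotation ("v1") with planted merge / split / boundary-shift /
# version-specific events, class-labeled evidence tracks with controlled
# per-intron support probabilities, hit and domain tables consistent with
# planted adjudication labels, and a machine-readable truth ledger.
#
# Construction conventions that make planted events exact rather than
# approximate: genes never overlap; every CDS segment length is a multiple
# of 3 (codon-aligned exon boundaries), so frame-preserving perturbations
# are simple coordinate arithmetic; planted events sit on disjoint gene
# sets. A planted merge event means two v1 genes merged into one v2 gene
# (constructed by splitting one truth gene into two v1 fragments, with the
# missing stop/start codons planted in-frame inside the truth gene's
# intron); a planted split event means one v1 gene split into two v2 genes
# (constructed by fusing two adjacent same-strand truth genes into one v1
# gene, dropping the internal stop codon from its CDS).

#' Simulation configuration
#'
#' Defaults describe a 2,000-gene study on five sequences with 30 planted
#' merges, 30 splits, 100 frame-preserving boundary shifts (+-3 bp) and
#' 50 + 50 version-specific genes; genome GC 0.32, exon counts uniform on
#' 1..8, and per-class intron support probabilities 0.90 (transcript),
#' 0.76 (protein) and 0.84 (de novo).
#'
#' @param seed integer RNG seed; identical seeds give byte-identical output.
#' @param n_seqs number of genome sequences.
#' @param n_genes number of truth (v2) genes.
#' @param gc target genome-wide GC fraction; the non-coding background is
#'   solved analytically so the expectation hits this value exactly.
#' @param gc_coding GC fraction targeted inside coding codons.
#' @param intergenic range (bp) of intergenic gaps.
#' @param exon_range range of exon counts per gene.
#' @param exon_codons range of codons per coding exon.
#' @param min_gene_codons minimal total codons per gene (deficits are added
#'   to the first exon) so every truth protein comfortably passes a
#'   50-amino-acid completeness filter.
#' @param intron_range range (bp) of intron lengths.
#' @param utr5_range,utr3_range ranges (bp) of UTR lengths on truth genes
#'   (the perturbed v1 annotation carries no UTRs).
#' @param frac_multi_isoform fraction of unperturbed genes given a second,
#'   exon-skipping isoform.
#' @param n_merge planted merge events (two v1 genes, one v2 gene).
#' @param n_split planted split events (one v1 gene, two v2 genes).
#' @param n_shift planted 1-to-1 modified pairs (internal CDS boundary moved
#'   by `3 * shift_codons` bp, frame preserved).
#' @param shift_codons codons removed by each boundary shift.
#' @param n_specific_v1,n_specific_v2 version-specific genes.
#' @param p_transcript,p_protein,p_denovo per-class probability that a given
#'   intron of a multi-exon truth gene is emitted into that class's evidence.
#' @param p_est probability that a transcript-supported intron is also in the
#'   EST track (the EST track is a subset of the RNA-Seq track; no
#'   EST-only introns).
#' @param label_mix fractions of planted adjudication labels over merge/split
#'   events: `optimal_merged`, `optimal_split`, `false_positive`,
#'   `ambiguous`; must sum to 1.
#' @param frac_pair_v1_better fraction of modified pairs planted so that the
#'   v1 structure aligns better to the shared best hit.
#' @param frac_pair_extra_domain_v2 fraction of modified pairs whose v2 gene
#'   carries an extra domain kind.
#' @param p_hit_specific_v1,p_hit_specific_v2 fraction of version-specific
#'   genes planted with a homology hit (counts are exact, not sampled).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_seqs = 5L,
                       n_genes = 2000L,
                       gc = 0.32,
                       gc_coding = 0.42,
                       intergenic = c(300L, 1500L),
                       exon_range = c(1L, 8L),
                       exon_codons = c(25L, 100L),
                       min_gene_codons = 60L,
                       intron_range = c(60L, 600L),
                       utr5_range = c(30L, 320L),
                       utr3_range = c(80L, 500L),
                       frac_multi_isoform = 0.08,
                       n_merge = 30L,
                       n_split = 30L,
                       n_shift = 100L,
                       shift_codons = 1L,
                       n_specific_v1 = 50L,
                       n_specific_v2 = 50L,
                       p_transcript = 0.90,
                       p_protein = 0.76,
                       p_denovo = 0.84,
                       p_est = 0.35,
                       label_mix = c(
                         optimal_merged = 0.5, optimal_split = 0.2,
                         false_positive = 0.15, ambiguous = 0.15
                       ),
                       frac_pair_v1_better = 0.2,
                       frac_pair_extra_domain_v2 = 0.3,
                       p_hit_specific_v1 = 0.264,
                       p_hit_specific_v2 = 0.593) {
  cfg <- list(
    seed = as.integer(seed), n_seqs = as.integer(n_seqs),
    n_genes = as.integer(n_genes), gc = gc, gc_coding = gc_coding,
    intergenic = as.integer(intergenic), exon_range = as.integer(exon_range),
    exon_codons = as.integer(exon_codons),
    min_gene_codons = as.integer(min_gene_codons),
    intron_range = as.integer(intron_range),
    utr5_range = as.integer(utr5_range), utr3_range = as.integer(utr3_range),
    frac_multi_isoform = frac_multi_isoform,
    n_merge = as.integer(n_merge), n_split = as.integer(n_split),
    n_shift = as.integer(n_shift), shift_codons = as.integer(shift_codons),
    n_specific_v1 = as.integer(n_specific_v1),
    n_specific_v2 = as.integer(n_specific_v2),
    p_transcript = p_transcript, p_protein = p_protein, p_denovo = p_denovo,
    p_est = p_est, label_mix = label_mix,
    frac_pair_v1_better = frac_pair_v1_better,
    frac_pair_extra_domain_v2 = frac_pair_extra_domain_v2,
    p_hit_specific_v1 = p_hit_specific_v1,
    p_hit_specific_v2 = p_hit_specific_v2
  )
  probs <- c(
    gc, gc_coding, p_transcript, p_protein, p_denovo, p_est,
    frac_multi_isoform, frac_pair_v1_better, frac_pair_extra_domain_v2,
    p_hit_specific_v1, p_hit_specific_v2
  )
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(sum(label_mix) - 1) > 1e-8) stop("label_mix must sum to 1")
  needed <- cfg$n_merge + 2L * cfg$n_split + cfg$n_shift + cfg$n_specific_v2
  if (needed > cfg$n_genes) {
    stop(
      "infeasible configuration: planted events need ", needed,
      " truth genes but n_genes = ", cfg$n_genes
    )
  }
  if (cfg$intron_range[1] < 12L) stop("introns must be at least 12 bp")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(
    "<sim_config> seed ", x$seed, ": ", x$n_genes, " genes on ", x$n_seqs,
    " sequence(s); planted events merge=", x$n_merge, " split=", x$n_split,
    " shift=", x$n_shift, " specific=", x$n_specific_v1, "+", x$n_specific_v2,
    "\n",
    sep = ""
  )
  invisible(x)
}

# codon tables -----------------------------------------------------------

sim_codon_setup <- function(gc_coding) {
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  stops <- c("TAA", "TAG", "TGA")
  sense <- setdiff(codons, stops)
  pb <- stats::setNames(
    c((1 - gc_coding) / 2, gc_coding / 2, gc_coding / 2, (1 - gc_coding) / 2),
    bases
  )
  gc_count <- function(cod) {
    vapply(strsplit(cod, ""), function(b) sum(b %in% c("G", "C")), numeric(1))
  }
  w <- vapply(strsplit(sense, ""), function(b) prod(pb[b]), numeric(1))
  w <- w / sum(w)
  list(
    sense = sense, weights = w,
    e_gc_per_mid_base = sum(w * gc_count(sense)) / 3,
    stops = c("TAA", "TAG", "TGA")
  )
}

# GFF3 writer for evidence tracks (match/match_part chains)
write_track_gff3 <- function(df, path, source = "annotcompare") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(df) > 0) {
    df <- df[order(df$group, df$start), , drop = FALSE]
    grp <- split(df, df$group)
    grp <- grp[order(names(grp))]
    lines <- unlist(lapply(grp, function(g) {
      c(
        paste(g$seq_id[1], source, "match", min(g$start), max(g$end), ".",
          g$strand[1], ".", paste0("ID=", g$group[1]),
          sep = "\t"
        ),
        paste(g$seq_id, source, "match_part", g$start, g$end, ".",
          g$strand, ".", paste0("Parent=", g$group),
          sep = "\t"
        )
      )
    }), use.names = FALSE)
    writeLines(lines, con)
  }
  invisible(path)
}

# deterministic integer counts from fractions (largest-remainder rounding)
apportion <- function(n, fractions) {
  raw <- fractions * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}

#' Generate a synthetic annotation-comparison dataset
#'
#' Builds, from a seeded configuration, all the inputs of the
#' annotation-comparison pipeline plus the truth ledger needed to verify its
#' outputs exactly. With `outdir` set, everything is also written to disk
#' (genome.fa, v1.gff3, v2.gff3, tracks/*.gff3, hits.tsv, domains.tsv,
#' ref_proteins.fa, truth.json); the files are byte-identical across runs
#' with the same configuration.
#'
#' @param config a [sim_config()].
#' @param outdir output directory, or `NULL` (default) for in-memory use
#'   only.
#' @return (invisibly when writing) a list with `config`, `genome`
#'   (`DNAStringSet`), `v1` and `v2` ([annotation_set()]s), `tracks` (list of
#'   `evidence_track`s), `track_segments` (the raw segment data.frames),
#'   `hits` (12-column data.frame), `domains`, `ref_proteins`
#'   (`AAStringSet`) and `truth` (the ledger).
#' @export
generate <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  codon <- sim_codon_setup(cfg$gc_coding)

  n2 <- cfg$n_genes
  nsp1 <- cfg$n_specific_v1
  n_slots <- n2 + nsp1
  seq_ids <- sprintf("chr%02d", seq_len(cfg$n_seqs))
  bounds <- round(seq(0, n_slots, length.out = cfg$n_seqs + 1))
  seq_of_slot <- rep(seq_len(cfg$n_seqs), times = diff(bounds))

  # --- role assignment ---------------------------------------------------
  v1only_slots <- sort(sample.int(n_slots, nsp1))
  v2_slots <- setdiff(seq_len(n_slots), v1only_slots)

  # split events need two consecutive truth genes on the same sequence
  cand <- which(
    seq_of_slot[v2_slots[-length(v2_slots)]] == seq_of_slot[v2_slots[-1]]
  )
  cand <- sample(cand)
  pair_first <- integer(0)
  used <- logical(length(v2_slots))
  for (i in cand) {
    if (length(pair_first) >= cfg$n_split) break
    if (!used[i] && !used[i + 1]) {
      pair_first <- c(pair_first, i)
      used[i] <- used[i + 1] <- TRUE
    }
  }
  if (length(pair_first) < cfg$n_split) {
    stop("could not place ", cfg$n_split, " split events; increase n_genes or n_seqs")
  }
  pair_second <- pair_first + 1L

  roles <- rep("identical", n2) # indexed over v2 gene order
  roles[pair_first] <- "split_first"
  roles[pair_second] <- "split_second"
  free <- which(roles == "identical")
  picks <- sample(free, cfg$n_merge + cfg$n_shift + cfg$n_specific_v2)
  roles[picks[seq_len(cfg$n_merge)]] <- "merge"
  roles[picks[cfg$n_merge + seq_len(cfg$n_shift)]] <- "shift"
  roles[picks[cfg$n_merge + cfg$n_shift + seq_len(cfg$n_specific_v2)]] <- "specific_v2"

  # --- per-slot structure draws -------------------------------------------
  rint <- function(lo, hi, n = 1L) {
    if (lo >= hi) rep(lo, n) else lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
  }
  slot_role <- character(n_slots)
  slot_role[v1only_slots] <- "specific_v1"
  slot_role[v2_slots] <- roles

  slots <- vector("list", n_slots)
  pair_strand <- NA_character_ # carries strand from split_first to split_second
  for (s in seq_len(n_slots)) {
    role <- slot_role[s]
    strand <- if (role == "split_second") pair_strand else sample(c("+", "-"), 1)
    if (role == "split_first") pair_strand <- strand
    lo_ex <- if (role %in% c("merge", "shift")) max(2L, cfg$exon_range[1]) else cfg$exon_range[1]
    k <- rint(lo_ex, cfg$exon_range[2])
    codons_per_exon <- rint(cfg$exon_codons[1], cfg$exon_codons[2], k)
    deficit <- cfg$min_gene_codons - sum(codons_per_exon)
    if (deficit > 0) codons_per_exon[1] <- codons_per_exon[1] + deficit
    introns <- if (k >= 2) rint(cfg$intron_range[1], cfg$intron_range[2], k - 1L) else integer(0)
    has_utr <- role != "specific_v1" # v1-only genes carry no UTR either way
    slots[[s]] <- list(
      role = role, strand = strand, k = k,
      codons = codons_per_exon, introns = introns,
      utr5 = if (has_utr) rint(cfg$utr5_range[1], cfg$utr5_range[2]) else 0L,
      utr3 = if (has_utr) rint(cfg$utr3_range[1], cfg$utr3_range[2]) else 0L,
      gap = rint(cfg$intergenic[1], cfg$intergenic[2]),
      split_at = if (role %in% c("merge", "shift")) rint(1L, k - 1L) else NA_integer_,
      skip_seg = NA_integer_
    )
  }

  # second isoforms: exon-skipping, only on unperturbed genes with >= 3 exons
  ident_idx <- which(roles == "identical")
  k_of <- vapply(slots[v2_slots], `[[`, integer(1), "k")
  eligible <- ident_idx[k_of[ident_idx] >= 3]
  n_multi <- min(length(eligible), round(cfg$frac_multi_isoform * n2))
  multi_idx <- sort(sample(eligible, n_multi))
  for (i in multi_idx) {
    s <- v2_slots[i]
    slots[[s]]$skip_seg <- rint(2L, slots[[s]]$k - 1L)
  }

  # --- layout --------------------------------------------------------------
  cursor <- integer(cfg$n_seqs)
  for (s in seq_len(n_slots)) {
    sl <- slots[[s]]
    sq <- seq_of_slot[s]
    left_ext <- if (sl$strand == "+") sl$utr5 else sl$utr3
    right_ext <- if (sl$strand == "+") sl$utr3 else sl$utr5
    start <- cursor[sq] + sl$gap + 1L
    cds_start <- integer(sl$k)
    cds_end <- integer(sl$k)
    pos <- start + left_ext
    for (e in seq_len(sl$k)) {
      cds_start[e] <- pos
      cds_end[e] <- pos + 3L * sl$codons[e] - 1L
      pos <- cds_end[e] + 1L + (if (e < sl$k) sl$introns[e] else 0L)
    }
    exon_start <- cds_start
    exon_end <- cds_end
    exon_start[1] <- exon_start[1] - left_ext
    exon_end[sl$k] <- exon_end[sl$k] + right_ext
    slots[[s]]$seq_id <- seq_ids[sq]
    slots[[s]]$cds <- data.frame(start = cds_start, end = cds_end)
    slots[[s]]$exons <- data.frame(start = exon_start, end = exon_end)
    cursor[sq] <- exon_end[sl$k]
  }
  seq_len_bp <- cursor + cfg$intergenic[2]

  # --- solve background GC so the genome-wide expectation hits cfg$gc ------
  total_bp <- sum(seq_len_bp)
  n_codons_total <- sum(vapply(slots, function(sl) sum(sl$codons), integer(1)))
  n_coding_genes <- n_slots
  n_mid <- n_codons_total - 2L * n_coding_genes
  coding_bp <- 3L * n_codons_total
  planted_bp <- 6L * cfg$n_merge
  bg_bp <- total_bp - coding_bp - planted_bp
  exp_coding_gc <- codon$e_gc_per_mid_base * 3 * n_mid + # middle codons
    1 * n_coding_genes + # ATG has one G
    (2 / 3) * n_coding_genes # stop codons average 2/3 GC
  exp_planted_gc <- 1 * cfg$n_merge # TAA+ATG (or revcomp) = 1 GC per event
  p_bg <- (cfg$gc * total_bp - exp_coding_gc - exp_planted_gc) / bg_bp
  if (p_bg <= 0 || p_bg >= 1) {
    stop("background GC solution ", round(p_bg, 3), " out of range; adjust gc/gc_coding")
  }

  # --- sample coding sequence --------------------------------------------
  # genome base writes are accumulated per sequence and applied in one pass
  # (planted merge codons are added below, in the v1 derivation loop)
  write_pos <- stats::setNames(
    replicate(cfg$n_seqs, list(), simplify = FALSE), seq_ids
  )
  write_chars <- write_pos
  queue_write <- function(seq_id, positions, chars) {
    n <- length(write_pos[[seq_id]]) + 1L
    write_pos[[seq_id]][[n]] <<- positions
    write_chars[[seq_id]][[n]] <<- chars
  }
  revcomp_chars <- function(x) {
    rev(chartr("ACGT", "TGCA", x))
  }
  for (s in seq_len(n_slots)) {
    sl <- slots[[s]]
    n_cod <- sum(sl$codons)
    spliced <- c(
      "ATG",
      sample(codon$sense, n_cod - 2L, replace = TRUE, prob = codon$weights),
      sample(codon$stops, 1L)
    )
    chars <- unlist(strsplit(spliced, ""), use.names = FALSE)
    if (sl$strand == "-") chars <- revcomp_chars(chars)
    positions <- unlist(Map(seq.int, sl$cds$start, sl$cds$end), use.names = FALSE)
    queue_write(sl$seq_id, positions, chars)
  }

  # --- truth (v2) gene models ---------------------------------------------
  v2_genes <- vector("list", length(v2_slots))
  v2_ids <- sprintf("Csa2G%06d", seq_along(v2_slots) * 10L)
  for (i in seq_along(v2_slots)) {
    sl <- slots[[v2_slots[i]]]
    gid <- v2_ids[i]
    iso <- list(transcript_model(
      paste0(gid, ".1"), gid, sl$seq_id, sl$strand, sl$exons, sl$cds
    ))
    if (!is.na(sl$skip_seg)) {
      keep <- setdiff(seq_len(sl$k), sl$skip_seg)
      iso <- c(iso, list(transcript_model(
        paste0(gid, ".2"), gid, sl$seq_id, sl$strand,
        sl$exons[keep, , drop = FALSE], sl$cds[keep, , drop = FALSE]
      )))
    }
    v2_genes[[i]] <- gene_model(gid, iso)
  }
  names(v2_genes) <- v2_ids
  role_of_v2 <- roles

  # --- perturbed (v1) gene models and planted stop/start codons -----------
  v1_genes <- list()
  v1_counter <- 0L
  new_v1_id <- function() {
    v1_counter <<- v1_counter + 1L
    sprintf("Csa1G%06d", v1_counter * 10L)
  }
  structural <- list() # truth per locus
  merge_events <- list()
  split_events <- list()
  pair_events <- list()
  skip_next <- FALSE

  for (i in seq_along(v2_slots)) {
    if (skip_next) {
      skip_next <- FALSE
      next
    }
    sl <- slots[[v2_slots[i]]]
    gid2 <- v2_ids[i]
    role <- role_of_v2[i]
    if (role == "identical") {
      gid1 <- new_v1_id()
      v1_genes[[gid1]] <- gene_model(gid1, list(transcript_model(
        paste0(gid1, ".1"), gid1, sl$seq_id, sl$strand, sl$cds, sl$cds
      )))
      structural[[length(structural) + 1L]] <- data.frame(
        kind = "identical", v1_ids = gid1, v2_ids = gid2
      )
    } else if (role == "shift") {
      j <- sl$split_at
      cds1 <- sl$cds
      cds1$end[j] <- cds1$end[j] - 3L * cfg$shift_codons
      gid1 <- new_v1_id()
      v1_genes[[gid1]] <- gene_model(gid1, list(transcript_model(
        paste0(gid1, ".1"), gid1, sl$seq_id, sl$strand, cds1, cds1
      )))
      structural[[length(structural) + 1L]] <- data.frame(
        kind = "modified_1to1", v1_ids = gid1, v2_ids = gid2
      )
      pair_events[[length(pair_events) + 1L]] <- list(v1 = gid1, v2 = gid2)
    } else if (role == "merge") {
      j <- sl$split_at
      # left fragment: segments 1..j, extended 3 bp into intron j
      left <- sl$cds[seq_len(j), , drop = FALSE]
      ext_left <- c(left$end[j] + 1L, left$end[j] + 3L)
      left$end[j] <- left$end[j] + 3L
      # right fragment: segments j+1..k, extended 3 bp left
      right <- sl$cds[(j + 1L):sl$k, , drop = FALSE]
      ext_right <- c(right$start[1] - 3L, right$start[1] - 1L)
      right$start[1] <- right$start[1] - 3L
      plant_left <- if (sl$strand == "+") c("T", "A", "A") else c("C", "A", "T")
      plant_right <- if (sl$strand == "+") c("A", "T", "G") else c("T", "T", "A")
      queue_write(sl$seq_id, ext_left[1]:ext_left[2], plant_left)
      queue_write(sl$seq_id, ext_right[1]:ext_right[2], plant_right)
      gidA <- new_v1_id()
      gidB <- new_v1_id()
      v1_genes[[gidA]] <- gene_model(gidA, list(transcript_model(
        paste0(gidA, ".1"), gidA, sl$seq_id, sl$strand, left, left
      )))
      v1_genes[[gidB]] <- gene_model(gidB, list(transcript_model(
        paste0(gidB, ".1"), gidB, sl$seq_id, sl$strand, right, right
      )))
      structural[[length(structural) + 1L]] <- data.frame(
        kind = "merged", v1_ids = paste(gidA, gidB, sep = ","), v2_ids = gid2
      )
      merge_events[[length(merge_events) + 1L]] <- list(
        kind = "merged", merged_gene = gid2, split_genes = c(gidA, gidB)
      )
    } else if (role == "split_first") {
      sl2 <- slots[[v2_slots[i + 1L]]]
      gid2b <- v2_ids[i + 1L]
      if (sl$strand == "+") {
        a <- sl$cds
        a$end[sl$k] <- a$end[sl$k] - 3L # drop stop of the left gene
        fused <- rbind(a, sl2$cds)
      } else {
        b <- sl2$cds
        b$start[1] <- b$start[1] + 3L # drop stop of the right (upstream) gene
        fused <- rbind(sl$cds, b)
      }
      gid1 <- new_v1_id()
      v1_genes[[gid1]] <- gene_model(gid1, list(transcript_model(
        paste0(gid1, ".1"), gid1, sl$seq_id, sl$strand, fused, fused
      )))
      structural[[length(structural) + 1L]] <- data.frame(
        kind = "split", v1_ids = gid1, v2_ids = paste(gid2, gid2b, sep = ",")
      )
      split_events[[length(split_events) + 1L]] <- list(
        kind = "split", merged_gene = gid1, split_genes = c(gid2, gid2b)
      )
      skip_next <- TRUE
    } else if (role == "specific_v2") {
      structural[[length(structural) + 1L]] <- data.frame(
        kind = "specific_v2", v1_ids = "", v2_ids = gid2
      )
    }
  }
  # v1-only genes
  spec1_ids <- character(0)
  for (s in v1only_slots) {
    sl <- slots[[s]]
    gid1 <- new_v1_id()
    spec1_ids <- c(spec1_ids, gid1)
    v1_genes[[gid1]] <- gene_model(gid1, list(transcript_model(
      paste0(gid1, ".1"), gid1, sl$seq_id, sl$strand, sl$cds, sl$cds
    )))
    structural[[length(structural) + 1L]] <- data.frame(
      kind = "specific_v1", v1_ids = gid1, v2_ids = ""
    )
  }
  structural <- do.call(rbind, structural)

  # --- assemble the genome -------------------------------------------------
  bases <- c("A", "C", "G", "T")
  bg_prob <- c((1 - p_bg) / 2, p_bg / 2, p_bg / 2, (1 - p_bg) / 2)
  genome <- Biostrings::DNAStringSet(vapply(seq_len(cfg$n_seqs), function(sq) {
    v <- sample(bases, seq_len_bp[sq], replace = TRUE, prob = bg_prob)
    sid <- seq_ids[sq]
    if (length(write_pos[[sid]])) {
      v[unlist(write_pos[[sid]], use.names = FALSE)] <-
        unlist(write_chars[[sid]], use.names = FALSE)
    }
    paste(v, collapse = "")
  }, ""))
  names(genome) <- seq_ids
  v2 <- annotation_set(v2_genes, version_label = "annotVer 2.0")
  v1 <- annotation_set(v1_genes, version_label = "annotVer 1.0")

  # --- evidence tracks -----------------------------------------------------
  flank <- 20L
  track_defs <- list(
    rnaseq = "transcript", est = "transcript",
    genewise = "protein", snap = "denovo"
  )
  seg_rows <- stats::setNames(
    replicate(length(track_defs), list(), simplify = FALSE), names(track_defs)
  )
  evid_rows <- list()
  for (i in seq_along(v2_slots)) {
    sl <- slots[[v2_slots[i]]]
    if (sl$k < 2) next
    gid <- v2_ids[i]
    k <- sl$k - 1L
    first <- sl$cds$end[-sl$k] + 1L
    last <- sl$cds$start[-1] - 1L
    emit_tr <- stats::runif(k) < cfg$p_transcript
    emit_est <- emit_tr & (stats::runif(k) < cfg$p_est)
    emit_pr <- stats::runif(k) < cfg$p_protein
    emit_dn <- stats::runif(k) < cfg$p_denovo
    add_segments <- function(track, which_introns) {
      idx <- which(which_introns)
      if (length(idx) == 0) return()
      df <- data.frame(
        group = sprintf("%s_%s_i%d", track, gid, idx),
        seq_id = sl$seq_id, strand = sl$strand,
        start = c(first[idx] - flank, last[idx] + 1L),
        end = c(first[idx] - 1L, last[idx] + flank)
      )
      seg_rows[[track]][[length(seg_rows[[track]]) + 1L]] <<- df
    }
    add_segments("rnaseq", emit_tr)
    add_segments("est", emit_est)
    add_segments("genewise", emit_pr)
    add_segments("snap", emit_dn)
    evid_rows[[length(evid_rows) + 1L]] <- data.frame(
      gene_id = gid, n_introns = k,
      sup_transcript = sum(emit_tr), sup_est = sum(emit_est),
      sup_protein = sum(emit_pr), sup_denovo = sum(emit_dn),
      full_transcript = all(emit_tr), full_protein = all(emit_pr),
      full_denovo = all(emit_dn)
    )
  }
  track_segments <- lapply(seg_rows, function(rows) {
    if (length(rows)) do.call(rbind, rows) else data.frame(
      group = character(0), seq_id = character(0), strand = character(0),
      start = integer(0), end = integer(0)
    )
  })
  tracks <- Map(
    function(df, nm) build_track(df, nm, track_defs[[nm]]),
    track_segments, names(track_segments)
  )
  evidence <- if (length(evid_rows)) do.call(rbind, evid_rows) else NULL

  # --- planted adjudication labels and hit table ---------------------------
  hit_rows <- list()
  add_hit <- function(q, s, evalue, bitscore, len = 200L) {
    hit_rows[[length(hit_rows) + 1L]] <<- data.frame(
      qseqid = q, sseqid = s, pident = 95.0, length = len, mismatch = 5L,
      gapopen = 0L, qstart = 1L, qend = len, sstart = 1L, send = len,
      evalue = evalue, bitscore = bitscore
    )
  }
  ms_events <- c(merge_events, split_events)
  labels <- sample(rep(
    names(cfg$label_mix),
    times = apportion(length(ms_events), cfg$label_mix)
  ))
  adjudication <- NULL
  if (length(ms_events) > 0) {
    adj_rows <- list()
    for (e in seq_along(ms_events)) {
      ev <- ms_events[[e]]
      lab <- labels[e]
      acc_a <- sprintf("UPMS%04dA", e)
      acc_b <- sprintf("UPMS%04dB", e)
      mg <- ev$merged_gene
      sg <- ev$split_genes
      if (lab == "optimal_merged") {
        add_hit(mg, acc_a, 1e-80, 300)
        add_hit(sg[1], acc_a, 1e-70, 250)
        add_hit(sg[2], acc_a, 1e-60, 220)
      } else if (lab == "optimal_split") {
        add_hit(mg, acc_a, 1e-40, 150)
        add_hit(sg[1], acc_a, 1e-75, 260)
        add_hit(sg[2], acc_b, 1e-72, 255)
      } else if (lab == "ambiguous") {
        add_hit(mg, acc_a, 1e-35, 140)
        add_hit(sg[1], acc_a, 1e-50, 180)
      } # false_positive: no hits at all
      if (lab != "false_positive") {
        # decoy secondary hit (worse rank) and a sub-threshold row
        add_hit(sg[1], sprintf("UPDECOY%04d", e), 1e-8, 60)
        add_hit(mg, sprintf("UPWEAK%04d", e), 1e-3, 30)
      }
      merged_version <- if (ev$kind == "merged") "v2" else "v1"
      expected <- switch(lab,
        optimal_merged = if (merged_version == "v2") "optimal_v2" else "optimal_v1",
        optimal_split = if (merged_version == "v2") "optimal_v1" else "optimal_v2",
        false_positive = "false_positive",
        ambiguous = "ambiguous"
      )
      adj_rows[[e]] <- data.frame(
        kind = ev$kind, merged_gene = mg,
        split_genes = paste(sg, collapse = ","),
        label = lab, expected_verdict = expected
      )
    }
    adjudication <- do.call(rbind, adj_rows)
  }

  # --- modified pairs: shared best hit, reference protein, domains ---------
  ref_list <- character(0)
  domain_rows <- list()
  pairs <- NULL
  if (length(pair_events) > 0) {
    n_pairs <- length(pair_events)
    n_v1_better <- round(cfg$frac_pair_v1_better * n_pairs)
    better <- sample(c(
      rep("v1", n_v1_better), rep("v2", n_pairs - n_v1_better)
    ))
    extra_dom <- sample(c(
      rep(TRUE, round(cfg$frac_pair_extra_domain_v2 * n_pairs)),
      rep(FALSE, n_pairs - round(cfg$frac_pair_extra_domain_v2 * n_pairs))
    ))
    pair_rows <- list()
    for (e in seq_len(n_pairs)) {
      pe <- pair_events[[e]]
      acc <- sprintf("UPPAIR%05d", e)
      src <- if (better[e] == "v1") v1$genes[[pe$v1]] else v2$genes[[pe$v2]]
      prot <- translate_cds(representative_isoform(src), genome)$protein
      ref_list[acc] <- prot
      add_hit(pe$v1, acc, 1e-100, 400)
      add_hit(pe$v2, acc, 1e-100, 400)
      dom <- sprintf("PF%05d", e)
      domain_rows[[length(domain_rows) + 1L]] <- data.frame(
        gene_id = c(pe$v1, pe$v2), domain_accession = dom
      )
      if (extra_dom[e]) {
        domain_rows[[length(domain_rows) + 1L]] <- data.frame(
          gene_id = pe$v2, domain_accession = sprintf("PF9%04d", e)
        )
      }
      pair_rows[[e]] <- data.frame(
        v1_id = pe$v1, v2_id = pe$v2, better_side = better[e],
        ref_acc = acc, extra_domain_v2 = extra_dom[e]
      )
    }
    pairs <- do.call(rbind, pair_rows)
  }

  # --- hits for version-specific genes -------------------------------------
  spec2_ids <- v2_ids[role_of_v2 == "specific_v2"]
  plant_spec_hits <- function(ids, p, tag) {
    n_hit <- round(p * length(ids))
    with_hit <- sort(sample(ids, n_hit))
    for (i in seq_along(with_hit)) {
      add_hit(with_hit[i], sprintf("UPSPEC%s%04d", tag, i), 1e-20, 120)
    }
    data.frame(gene_id = ids, has_hit = ids %in% with_hit)
  }
  spec_hits_v1 <- if (length(spec1_ids)) plant_spec_hits(spec1_ids, cfg$p_hit_specific_v1, "A") else NULL
  spec_hits_v2 <- if (length(spec2_ids)) plant_spec_hits(spec2_ids, cfg$p_hit_specific_v2, "B") else NULL

  hits <- if (length(hit_rows)) do.call(rbind, hit_rows) else data.frame(
    qseqid = character(0), sseqid = character(0), pident = numeric(0),
    length = integer(0), mismatch = integer(0), gapopen = integer(0),
    qstart = integer(0), qend = integer(0), sstart = integer(0),
    send = integer(0), evalue = numeric(0), bitscore = numeric(0)
  )
  domains <- if (length(domain_rows)) do.call(rbind, domain_rows) else data.frame(
    gene_id = character(0), domain_accession = character(0)
  )
  ref_proteins <- Biostrings::AAStringSet(ref_list)

  # --- bookkeeping summary (generator's own tally) -------------------------
  txs <- all_transcripts(v2)
  n_ex_tx <- vapply(txs, function(t) nrow(t$exons), integer(1))
  truth <- list(
    config = unclass(cfg),
    counts = list(
      n_genes_v1 = length(v1$genes),
      n_genes_v2 = length(v2$genes),
      n_identical = sum(structural$kind == "identical"),
      n_modified = sum(structural$kind == "modified_1to1"),
      n_merged_events = sum(structural$kind == "merged"),
      n_split_events = sum(structural$kind == "split"),
      n_specific_v1 = sum(structural$kind == "specific_v1"),
      n_specific_v2 = sum(structural$kind == "specific_v2"),
      n_multi_isoform = n_multi,
      n_multi_exon_v2 = sum(vapply(v2$genes, is_multi_exon, logical(1)))
    ),
    summary_v2 = list(
      genome_size = sum(Biostrings::width(genome)),
      n_genes = length(v2$genes),
      n_transcripts = length(txs),
      n_exons = sum(n_ex_tx),
      n_introns = sum(n_ex_tx - 1L)
    ),
    structural = structural,
    adjudication = adjudication,
    pairs = pairs,
    evidence = evidence,
    specific_hits_v1 = spec_hits_v1,
    specific_hits_v2 = spec_hits_v2
  )

  out <- list(
    config = cfg, genome = genome, v1 = v1, v2 = v2,
    tracks = tracks, track_segments = track_segments,
    hits = hits, domains = domains, ref_proteins = ref_proteins,
    truth = truth
  )
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(outdir, "tracks"), showWarnings = FALSE)
    Biostrings::writeXStringSet(genome, file.path(outdir, "genome.fa"))
    write_gff3(v2, file.path(outdir, "v2.gff3"), write_utrs = TRUE)
    write_gff3(v1, file.path(outdir, "v1.gff3"))
    for (nm in names(track_segments)) {
      write_track_gff3(
        track_segments[[nm]],
        file.path(outdir, "tracks", paste0(nm, ".gff3"))
      )
    }
    utils::write.table(hits, file.path(outdir, "hits.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
    )
    utils::write.table(domains, file.path(outdir, "domains.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE
    )
    Biostrings::writeXStringSet(ref_proteins, file.path(outdir, "ref_proteins.fa"))
    jsonlite::write_json(truth, file.path(outdir, "truth.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    return(invisible(out))
  }
  out
}

#' Expected pipeline outputs implied by a truth ledger
#'
#' Closed-form expectations used as oracles: the event counts
#' [classify_clusters()] must report, the verdict counts
#' [adjudicate_events()] must reproduce, and per-gene per-class evidence
#' support flags [profile_genes()] must match.
#'
#' @param truth the `truth` element of a [generate()] result (or parsed
#'   truth.json).
#' @return list with `event_counts`, `verdict_counts`, and
#'   `support` (data.frame of expected per-gene class support).
#' @export
expected_outputs <- function(truth) {
  counts <- truth$counts
  event_counts <- c(
    identical = counts$n_identical,
    modified_1to1 = counts$n_modified,
    merged = counts$n_merged_events,
    split = counts$n_split_events,
    specific_v1 = counts$n_specific_v1,
    specific_v2 = counts$n_specific_v2,
    complex = 0L
  )
  verdict_counts <- if (is.null(truth$adjudication)) NULL else {
    table(truth$adjudication$expected_verdict)
  }
  support <- if (is.null(truth$evidence)) NULL else {
    ev <- truth$evidence
    data.frame(
      gene_id = ev$gene_id, n_introns = ev$n_introns,
      supported_transcript = ev$sup_transcript >= 1,
      supported_protein = ev$sup_protein >= 1,
      supported_denovo = ev$sup_denovo >= 1,
      full_transcript = ev$sup_transcript == ev$n_introns,
      full_protein = ev$sup_protein == ev$n_introns,
      full_denovo = ev$sup_denovo == ev$n_introns
    )
  }
  list(
    event_counts = event_counts,
    verdict_counts = verdict_counts,
    support = support
  )
}
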