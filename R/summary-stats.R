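# Annotation summary panel (genes / transcripts / exons / introns / UTRs),
# headline ratios, the complete-ORF statistic and the gene-model filters.

#' Summarize an annotation set against its genome
#'
#' Computes the full summary panel of an annotation version: genome size and
#' GC, gene counts by strand, mean lengths, gene density, transcript counts,
#' the fraction of transcripts with introns, per-feature exon/intron/UTR
#' counts and lengths with GC content, and the coding fraction of the genome.
#' The coding fraction uses the per-base union of all CDS segments, so
#' overlapping isoforms are never double-counted and the value cannot exceed
#' 100%. Exon/intron tallies are per transcript (features shared between
#' isoforms count once per isoform), so `n_introns = n_exons - n_transcripts`
#' holds by construction. Means are arithmetic; empty denominators are
#' reported as `NA`.
#'
#' @param set an [annotation_set()].
#' @param genome named `DNAStringSet` covering every seq_id in `set`.
#' @return an object of class `annotation_summary` (a named list; see
#'   [as.data.frame.annotation_summary()]).
#' @export
summarize_annotation <- function(set, genome) {
  stopifnot(inherits(set, "annotation_set"))
  used <- unique(vapply(set$genes, `[[`, "", "seq_id"))
  missing <- setdiff(used, names(genome))
  if (length(missing)) {
    stop("seq_id(s) absent from genome: ", paste(missing, collapse = ", "))
  }
  genome_size <- sum(Biostrings::width(genome))
  gc_genome <- gc_content(genome)

  mean_or_na <- function(x) if (length(x) == 0) NA_real_ else mean(x)

  genes <- set$genes
  ng <- length(genes)
  if (ng == 0) {
    gene_len <- integer(0)
    strands <- character(0)
  } else {
    sp <- vapply(genes, model_span, integer(2))
    gene_len <- sp["end", ] - sp["start", ] + 1L
    strands <- vapply(genes, `[[`, "", "strand")
  }

  txs <- all_transcripts(set)
  nt <- length(txs)
  tx_len <- vapply(txs, function(t) {
    s <- model_span(t)
    s[["end"]] - s[["start"]] + 1L
  }, integer(1))
  cds_len <- vapply(txs, function(t) sum(t$cds$end - t$cds$start + 1L), integer(1))
  n_ex_tx <- vapply(txs, function(t) nrow(t$exons), integer(1))

  # per-transcript exon and intron features
  seg_df <- function(kind) {
    do.call(rbind, c(list(data.frame(
      seq_id = character(0), start = integer(0), end = integer(0)
    )), lapply(txs, function(t) {
      s <- if (kind == "exon") t$exons else {
        i <- introns_of(t, basis = "exon")
        data.frame(start = i$first, end = i$last)
      }
      if (nrow(s) == 0) return(NULL)
      data.frame(seq_id = t$seq_id, start = s$start, end = s$end)
    })))
  }
  exons <- seg_df("exon")
  introns <- seg_df("intron")

  gc_of_features <- function(df) {
    if (nrow(df) == 0) return(NA_real_)
    counts <- c(A = 0, C = 0, G = 0, T = 0)
    for (sid in unique(df$seq_id)) {
      sub <- df[df$seq_id == sid, , drop = FALSE]
      seqs <- Biostrings::extractAt(
        genome[[sid]], IRanges::IRanges(sub$start, sub$end)
      )
      counts <- counts + Biostrings::alphabetFrequency(
        seqs, collapse = TRUE
      )[c("A", "C", "G", "T")]
    }
    if (sum(counts) == 0) return(NA_real_)
    unname((counts["G"] + counts["C"]) / sum(counts))
  }

  # per-base union of CDS over the whole set
  all_cds <- do.call(rbind, c(list(data.frame(
    seq_id = character(0), start = integer(0), end = integer(0)
  )), lapply(txs, function(t) {
    if (nrow(t$cds) == 0) return(NULL)
    data.frame(seq_id = t$seq_id, start = t$cds$start, end = t$cds$end)
  })))
  coding_bp <- if (nrow(all_cds) == 0) 0L else {
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      all_cds$seq_id, IRanges::IRanges(all_cds$start, all_cds$end)
    ))
    sum(GenomicRanges::width(gr))
  }

  # derived UTRs
  utrs <- lapply(txs, utr_segments)
  u5 <- do.call(rbind, lapply(utrs, `[[`, "utr5"))
  u3 <- do.call(rbind, lapply(utrs, `[[`, "utr3"))
  u5_len <- if (is.null(u5)) integer(0) else u5$end - u5$start + 1L
  u3_len <- if (is.null(u3)) integer(0) else u3$end - u3$start + 1L
  gene_has_utr <- vapply(genes, function(g) {
    any(vapply(g$transcripts, function(t) {
      u <- utr_segments(t)
      nrow(u$utr5) + nrow(u$utr3) > 0
    }, logical(1)))
  }, logical(1))

  exon_len <- if (nrow(exons)) exons$end - exons$start + 1L else integer(0)
  intron_len <- if (nrow(introns)) introns$end - introns$start + 1L else integer(0)

  structure(list(
    genome_size = genome_size,
    gc_genome = gc_genome,
    n_genes = ng,
    n_genes_plus = sum(strands == "+"),
    n_genes_minus = sum(strands == "-"),
    mean_gene_length = mean_or_na(gene_len),
    gene_density = if (ng > 0) genome_size / ng / 1000 else NA_real_,
    n_transcripts = nt,
    pct_transcripts_with_introns =
      if (nt > 0) 100 * mean(n_ex_tx >= 2) else NA_real_,
    mean_transcript_length = mean_or_na(tx_len),
    mean_cds_length = mean_or_na(cds_len[cds_len > 0]),
    pct_coding = if (genome_size > 0) 100 * coding_bp / genome_size else NA_real_,
    n_exons = nrow(exons),
    mean_exons_per_transcript = if (nt > 0) nrow(exons) / nt else NA_real_,
    gc_exons = gc_of_features(exons),
    mean_exon_length = mean_or_na(exon_len),
    total_exon_length = sum(exon_len),
    n_introns = nrow(introns),
    mean_introns_per_transcript = if (nt > 0) nrow(introns) / nt else NA_real_,
    gc_introns = gc_of_features(introns),
    mean_intron_length = mean_or_na(intron_len),
    total_intron_length = sum(intron_len),
    n_genes_with_utr = sum(gene_has_utr),
    mean_utr_length = mean_or_na(c(u5_len, u3_len)),
    n_utr5 = length(u5_len),
    mean_utr5_length = mean_or_na(u5_len),
    n_utr3 = length(u3_len),
    mean_utr3_length = mean_or_na(u3_len)
  ), class = "annotation_summary")
}

#' @export
print.annotation_summary <- function(x, ...) {
  df <- as.data.frame(x)
  cat("<annotation_summary>\n")
  print(df, row.names = FALSE)
  invisible(x)
}

#' Flatten an annotation summary to a two-column data.frame
#'
#' @param x an `annotation_summary`.
#' @param ... unused.
#' @return data.frame with columns `field` and `value`.
#' @export
as.data.frame.annotation_summary <- function(x, ...) {
  data.frame(
    field = names(unclass(x)),
    value = vapply(unclass(x), function(v) as.numeric(v)[1], numeric(1)),
    row.names = NULL
  )
}

#' Headline ratios from annotation totals
#'
#' Recomputes the derived quantities of a summary table from its printed
#' totals: gene density in Kb per gene, mean exons and introns per
#' transcript, and the intron count implied by the exon and transcript
#' counts (every transcript with e exons has e - 1 introns).
#'
#' @param totals named list or vector with (any of) `genome_size`, `n_genes`,
#'   `n_transcripts`, `n_exons`, `n_introns`.
#' @return list with `gene_density` (Kb/gene), `mean_exons_per_transcript`,
#'   `mean_introns_per_transcript`, `implied_introns`; unavailable or
#'   zero-denominator entries are `NA`.
#' @export
derive_ratios <- function(totals) {
  totals <- as.list(totals)
  num <- function(k) {
    v <- totals[[k]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }
  gs <- num("genome_size"); ng <- num("n_genes")
  nt <- num("n_transcripts"); ne <- num("n_exons"); ni <- num("n_introns")
  if (any(c(gs, ng, nt, ne, ni) < 0, na.rm = TRUE)) {
    stop("totals must be nonnegative")
  }
  implied <- if (!is.na(ne) && !is.na(nt)) ne - nt else NA_real_
  if (is.na(ni)) ni <- implied
  list(
    gene_density = if (!is.na(gs) && !is.na(ng) && ng > 0) gs / ng / 1000 else NA_real_,
    mean_exons_per_transcript = if (!is.na(ne) && !is.na(nt) && nt > 0) ne / nt else NA_real_,
    mean_introns_per_transcript = if (!is.na(ni) && !is.na(nt) && nt > 0) ni / nt else NA_real_,
    implied_introns = implied
  )
}

#' Filter gene models on protein length and completeness
#'
#' A gene is removed iff every transcript fails the completeness test:
#' protein shorter than `min_aa` amino acids, or missing a start codon, or
#' missing a stop codon. The operation is idempotent.
#'
#' @param set an [annotation_set()].
#' @param genome named `DNAStringSet`.
#' @param min_aa minimum protein length in amino acids (default 50; a protein
#'   of exactly `min_aa` residues is kept).
#' @return list with `kept` (filtered `annotation_set`) and `report`
#'   (data.frame `gene_id`, `reason` for each removed gene).
#' @export
filter_gene_models <- function(set, genome, min_aa = 50) {
  stopifnot(inherits(set, "annotation_set"))
  keep <- logical(length(set$genes))
  reasons <- character(length(set$genes))
  for (i in seq_along(set$genes)) {
    g <- set$genes[[i]]
    fails <- character(0)
    ok <- FALSE
    for (t in g$transcripts) {
      if (nrow(t$cds) == 0) {
        fails <- union(fails, "no_cds")
        next
      }
      tr <- suppressWarnings(translate_cds(t, genome))
      f <- character(0)
      if (tr$aa_length < min_aa) f <- c(f, "short_protein")
      if (!tr$has_start) f <- c(f, "missing_start")
      if (!tr$has_stop) f <- c(f, "missing_stop")
      if (length(f) == 0) {
        ok <- TRUE
        break
      }
      fails <- union(fails, f)
    }
    keep[i] <- ok
    reasons[i] <- paste(fails, collapse = ",")
  }
  list(
    kept = annotation_set(set$genes[keep], version_label = set$version_label),
    report = data.frame(
      gene_id = names(set$genes)[!keep],
      reason = reasons[!keep],
      row.names = NULL
    )
  )
}

#' Remove short transcript sequences
#'
#' Reconstructed transcripts shorter than a threshold are treated as false
#' positives and removed (default 150 bp; a 150 bp transcript is kept).
#'
#' @param seqs named `DNAStringSet` (or character vector) of transcript
#'   sequences.
#' @param min_len minimum length in bp.
#' @return list with `kept` (same type as input) and `report` (data.frame
#'   `id`, `length` of removed sequences).
#' @export
filter_short_transcripts <- function(seqs, min_len = 150) {
  was_char <- is.character(seqs)
  if (was_char) seqs <- Biostrings::DNAStringSet(seqs)
  w <- Biostrings::width(seqs)
  keep <- w >= min_len
  report <- data.frame(
    id = if (is.null(names(seqs))) as.character(which(!keep)) else names(seqs)[!keep],
    length = w[!keep],
    row.names = NULL
  )
  kept <- seqs[keep]
  if (was_char) kept <- as.character(kept)
  list(kept = kept, report = report)
}
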