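# Core gene-model data types. Coordinates are 1-based inclusive genome
# coordinates throughout, matching GFF3.

#' Construct a transcript model
#'
#' A transcript is an ordered set of exons plus an ordered set of CDS
#' segments, all on one sequence and strand. Exons must be disjoint and every
#' CDS segment must lie within an exon. UTRs are not stored; they are derived
#' as exon minus CDS (see [utr_segments()]), which also covers annotations
#' that carry no explicit UTR features.
#'
#' @param id transcript identifier.
#' @param gene_id identifier of the parent gene.
#' @param seq_id sequence (chromosome/scaffold) identifier.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with `start`, `end` columns (1-based inclusive).
#' @param cds data.frame with `start`, `end` columns; may be empty.
#' @return an object of class `transcript_model`.
#' @export
transcript_model <- function(id, gene_id, seq_id, strand, exons, cds) {
  if (!strand %in% c("+", "-")) {
    stop("transcript ", id, ": strand must be '+' or '-'")
  }
  exons <- tryCatch(as_segment_df(exons, "exon"),
    error = function(e) stop("transcript ", id, ": ", conditionMessage(e))
  )
  cds <- tryCatch(as_segment_df(cds, "CDS segment"),
    error = function(e) stop("transcript ", id, ": ", conditionMessage(e))
  )
  if (nrow(exons) == 0) stop("transcript ", id, " has no exons")
  # every CDS segment contained in some exon
  if (nrow(cds) > 0) {
    ok <- vapply(seq_len(nrow(cds)), function(i) {
      any(exons$start <= cds$start[i] & cds$end[i] <= exons$end)
    }, logical(1))
    if (!all(ok)) {
      stop(
        "transcript ", id, ": CDS segment(s) ",
        paste(which(!ok), collapse = ","), " not contained in any exon"
      )
    }
  }
  structure(
    list(
      id = as.character(id), gene_id = as.character(gene_id),
      seq_id = as.character(seq_id), strand = strand,
      exons = exons, cds = cds
    ),
    class = "transcript_model"
  )
}

#' Construct a gene model
#'
#' A gene holds one or more transcript isoforms that must share sequence and
#' strand; seq-id-spanning (trans-spliced) genes are rejected.
#'
#' @param id gene identifier.
#' @param transcripts list of [transcript_model()] objects.
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(id, transcripts) {
  if (length(transcripts) < 1) stop("gene ", id, " has no transcripts")
  seqs <- vapply(transcripts, `[[`, "", "seq_id")
  strands <- vapply(transcripts, `[[`, "", "strand")
  if (length(unique(seqs)) != 1 || length(unique(strands)) != 1) {
    stop(
      "gene ", id, ": transcripts span multiple sequences or strands; ",
      "such gene models are rejected"
    )
  }
  transcripts <- transcripts[order(vapply(transcripts, `[[`, "", "id"))]
  names(transcripts) <- vapply(transcripts, `[[`, "", "id")
  structure(
    list(
      id = as.character(id), seq_id = seqs[1], strand = strands[1],
      transcripts = transcripts
    ),
    class = "gene_model"
  )
}

#' Genomic span of a gene or transcript
#'
#' @param x a `gene_model` or `transcript_model`.
#' @return integer vector `c(start, end)` over all exons.
#' @export
model_span <- function(x) {
  if (inherits(x, "transcript_model")) {
    return(c(start = min(x$exons$start), end = max(x$exons$end)))
  }
  sp <- vapply(x$transcripts, model_span, integer(2))
  c(start = min(sp["start", ]), end = max(sp["end", ]))
}

#' Per-base union of the CDS of a gene across isoforms
#'
#' @param g a `gene_model`.
#' @return data.frame with `start`, `end` of the reduced (merged) CDS ranges.
#' @export
cds_union <- function(g) {
  segs <- do.call(rbind, lapply(g$transcripts, `[[`, "cds"))
  if (is.null(segs) || nrow(segs) == 0) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  r <- IRanges::reduce(IRanges::IRanges(segs$start, segs$end))
  data.frame(start = IRanges::start(r), end = IRanges::end(r))
}

#' Is a gene multi-exon?
#'
#' @param g a `gene_model`.
#' @return `TRUE` iff some transcript has at least two exons.
#' @export
is_multi_exon <- function(g) {
  any(vapply(g$transcripts, function(t) nrow(t$exons) >= 2, logical(1)))
}

#' Representative isoform of a gene
#'
#' The isoform with the longest total CDS (ties broken by transcript id) is
#' used wherever a single structure per gene is needed, e.g. in the
#' evidence-support analysis.
#'
#' @param g a `gene_model`.
#' @return a `transcript_model`.
#' @export
representative_isoform <- function(g) {
  len <- vapply(g$transcripts, function(t) sum(t$cds$end - t$cds$start + 1L), integer(1))
  ids <- vapply(g$transcripts, `[[`, "", "id")
  g$transcripts[[order(-len, ids)[1]]]
}

#' Introns of a transcript
#'
#' Intron i spans `(segment_i end + 1) .. (segment_{i+1} start - 1)` between
#' consecutive exons (or consecutive CDS segments when `basis = "cds"`), in
#' ascending genomic order regardless of strand. Intron identity is exact
#' coordinate equality of (seq_id, strand, first, last).
#'
#' @param t a `transcript_model`.
#' @param basis derive introns from the exon chain (`"exon"`, default) or the
#'   CDS chain (`"cds"`).
#' @return data.frame with `seq_id`, `strand`, `first`, `last`, `key`.
#' @export
introns_of <- function(t, basis = c("exon", "cds")) {
  basis <- match.arg(basis)
  segs <- if (basis == "exon") t$exons else t$cds
  n <- nrow(segs)
  if (n < 2) {
    return(data.frame(
      seq_id = character(0), strand = character(0),
      first = integer(0), last = integer(0), key = character(0)
    ))
  }
  first <- segs$end[-n] + 1L
  last <- segs$start[-1] - 1L
  data.frame(
    seq_id = t$seq_id, strand = t$strand, first = first, last = last,
    key = make_intron_key(t$seq_id, t$strand, first, last)
  )
}

#' Derived UTR segments of a transcript
#'
#' UTRs are the exonic regions outside the CDS span, split into 5' and 3'
#' parts by strand. Annotations without explicit UTR features are handled the
#' same way as those with them.
#'
#' @param t a `transcript_model`.
#' @return list with data.frames `utr5` and `utr3` (`start`, `end`).
#' @export
utr_segments <- function(t) {
  empty <- data.frame(start = integer(0), end = integer(0))
  if (nrow(t$cds) == 0) {
    return(list(utr5 = empty, utr3 = empty))
  }
  cds_lo <- min(t$cds$start)
  cds_hi <- max(t$cds$end)
  ex <- IRanges::IRanges(t$exons$start, t$exons$end)
  left <- IRanges::restrict(ex, end = cds_lo - 1L)
  right <- IRanges::restrict(ex, start = cds_hi + 1L)
  left <- left[IRanges::width(left) > 0L]
  right <- right[IRanges::width(right) > 0L]
  left <- data.frame(start = IRanges::start(left), end = IRanges::end(left))
  right <- data.frame(start = IRanges::start(right), end = IRanges::end(right))
  if (t$strand == "+") list(utr5 = left, utr3 = right) else list(utr5 = right, utr3 = left)
}

#' Translate the CDS of a transcript
#'
#' CDS segments are concatenated in transcript order (reverse-complemented on
#' the minus strand) and translated with the standard genetic code. A trailing
#' stop codon is not included in the reported protein or amino-acid count.
#'
#' @param t a `transcript_model` with a non-empty CDS.
#' @param genome a named [Biostrings::DNAStringSet] containing `t$seq_id`.
#' @return list with `protein` (string, trailing stop stripped), `aa_length`,
#'   `has_start` (first codon ATG), `has_stop` (last codon TAA/TAG/TGA) and
#'   `partial_codon` (`TRUE` when CDS length is not divisible by 3, in which
#'   case only complete codons are translated).
#' @export
translate_cds <- function(t, genome) {
  if (nrow(t$cds) == 0) stop("transcript ", t$id, " has no CDS")
  if (!t$seq_id %in% names(genome)) {
    stop("sequence ", t$seq_id, " not present in genome")
  }
  chrom <- genome[[t$seq_id]]
  parts <- Biostrings::extractAt(
    chrom, IRanges::IRanges(t$cds$start, t$cds$end)
  )
  s <- unlist(parts)
  if (t$strand == "-") s <- Biostrings::reverseComplement(s)
  len <- length(s)
  partial <- (len %% 3L) != 0L
  if (partial) {
    warning("transcript ", t$id, ": CDS length ", len,
      " not divisible by 3; translating complete codons only",
      call. = FALSE
    )
    s <- Biostrings::subseq(s, 1L, len - (len %% 3L))
  }
  n_codon <- length(s) %/% 3L
  if (n_codon == 0L) {
    return(list(
      protein = "", aa_length = 0L, has_start = FALSE,
      has_stop = FALSE, partial_codon = partial
    ))
  }
  first_codon <- as.character(Biostrings::subseq(s, 1L, 3L))
  last_codon <- as.character(Biostrings::subseq(s, length(s) - 2L, length(s)))
  aa <- as.character(Biostrings::translate(s, no.init.codon = TRUE))
  has_stop <- last_codon %in% c("TAA", "TAG", "TGA")
  if (has_stop) aa <- substr(aa, 1L, nchar(aa) - 1L)
  list(
    protein = aa, aa_length = nchar(aa),
    has_start = first_codon == "ATG", has_stop = has_stop,
    partial_codon = partial
  )
}

#' GC content of nucleotide sequences
#'
#' Computed as (#G + #C) / (#A + #C + #G + #T); `N` (and any other ambiguity
#' code) is excluded from the denominator. An empty or all-N input is
#' undefined and reported as `NA`.
#'
#' @param x a character vector, `DNAString` or `DNAStringSet`; the fraction is
#'   computed over all sequences pooled.
#' @return a fraction in `[0, 1]`, or `NA_real_`.
#' @export
gc_content <- function(x) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  if (inherits(x, "DNAString")) x <- Biostrings::DNAStringSet(x)
  if (length(x) == 0) return(NA_real_)
  af <- colSums(Biostrings::alphabetFrequency(x)[, c("A", "C", "G", "T"), drop = FALSE])
  denom <- sum(af)
  if (denom == 0) return(NA_real_)
  unname((af["G"] + af["C"]) / denom)
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(
    "<transcript_model> ", x$id, " (gene ", x$gene_id, ") ", x$seq_id, ":",
    min(x$exons$start), "-", max(x$exons$end), "(", x$strand, ") ",
    nrow(x$exons), " exon(s), ", nrow(x$cds), " CDS segment(s)\n",
    sep = ""
  )
  invisible(x)
}

#' @export
print.gene_model <- function(x, ...) {
  sp <- model_span(x)
  cat(
    "<gene_model> ", x$id, " ", x$seq_id, ":", sp["start"], "-", sp["end"],
    "(", x$strand, ") ", length(x$transcripts), " isoform(s)\n",
    sep = ""
  )
  invisible(x)
}
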