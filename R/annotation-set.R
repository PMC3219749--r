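# One annotation version: a collection of gene models plus an interval index
# over the per-gene CDS union, used for all overlap queries.

#' Construct an annotation set
#'
#' @param genes list of [gene_model()] objects with unique ids.
#' @param version_label free-text label of the annotation version, e.g.
#'   `"annotVer 2.0"`.
#' @return an object of class `annotation_set` with a prebuilt
#'   [GenomicRanges::GRanges] index of per-gene reduced CDS ranges.
#' @export
annotation_set <- function(genes, version_label = "") {
  ids <- vapply(genes, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop(
      "duplicated gene ids: ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    )
  }
  if (length(genes) > 0) {
    # canonical gene order: (seq_id, span start, id); makes iteration and
    # GFF3 round-trips deterministic
    sp <- vapply(genes, function(g) model_span(g)["start"], integer(1))
    genes <- genes[order(vapply(genes, `[[`, "", "seq_id"), sp, ids)]
    ids <- vapply(genes, `[[`, "", "id")
  }
  names(genes) <- ids
  structure(
    list(
      version_label = version_label, genes = genes,
      cds_index = build_cds_index(genes)
    ),
    class = "annotation_set"
  )
}

# GRanges of reduced per-gene CDS ranges (one or more ranges per gene),
# with a gene_id metadata column
build_cds_index <- function(genes) {
  if (length(genes) == 0) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$gene_id <- character(0)
    return(gr)
  }
  per_gene <- lapply(genes, function(g) {
    segs <- do.call(rbind, lapply(g$transcripts, `[[`, "cds"))
    if (is.null(segs) || nrow(segs) == 0) return(NULL)
    list(n = nrow(segs), start = segs$start, end = segs$end)
  })
  keep <- !vapply(per_gene, is.null, logical(1))
  if (!any(keep)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$gene_id <- character(0)
    return(gr)
  }
  per_gene <- per_gene[keep]
  gsub <- genes[keep]
  nseg <- vapply(per_gene, `[[`, integer(1), "n")
  gid <- vapply(gsub, `[[`, "", "id")
  gr <- GenomicRanges::GRanges(
    seqnames = rep(vapply(gsub, `[[`, "", "seq_id"), nseg),
    ranges = IRanges::IRanges(
      unlist(lapply(per_gene, `[[`, "start"), use.names = FALSE),
      unlist(lapply(per_gene, `[[`, "end"), use.names = FALSE)
    ),
    strand = rep(vapply(gsub, `[[`, "", "strand"), nseg)
  )
  # one reduce over all genes at once: per-gene per-base CDS union
  grl <- GenomicRanges::reduce(S4Vectors::split(
    gr, factor(rep(gid, nseg), levels = gid)
  ))
  flat <- unlist(grl, use.names = FALSE)
  S4Vectors::mcols(flat)$gene_id <- rep(gid, S4Vectors::elementNROWS(grl))
  flat
}

#' Genes whose CDS union overlaps a query interval
#'
#' @param set an `annotation_set`.
#' @param seq_id sequence identifier of the query.
#' @param start,end 1-based inclusive query coordinates.
#' @param strand `"+"`, `"-"`, or `NULL` (default) for strand-blind queries.
#' @return character vector of gene ids, sorted.
#' @export
overlapping_genes <- function(set, seq_id, start, end, strand = NULL) {
  stopifnot(inherits(set, "annotation_set"))
  q <- GenomicRanges::GRanges(
    seqnames = seq_id, ranges = IRanges::IRanges(start, end),
    strand = if (is.null(strand)) "*" else strand
  )
  hits <- GenomicRanges::findOverlaps(q, set$cds_index,
    ignore.strand = is.null(strand)
  )
  sort(unique(S4Vectors::mcols(set$cds_index)$gene_id[S4Vectors::subjectHits(hits)]))
}

#' Number of genes in an annotation set
#'
#' @param x an `annotation_set`.
#' @return integer gene count.
#' @export
n_genes <- function(x) length(x$genes)

#' All transcripts of an annotation set
#'
#' @param set an `annotation_set`.
#' @return flat named list of `transcript_model`s.
#' @export
all_transcripts <- function(set) {
  out <- unlist(lapply(set$genes, `[[`, "transcripts"), recursive = FALSE, use.names = FALSE)
  if (is.null(out)) return(list())
  names(out) <- vapply(out, `[[`, "", "id")
  out
}

#' @export
print.annotation_set <- function(x, ...) {
  nt <- sum(vapply(x$genes, function(g) length(g$transcripts), integer(1)))
  cat(
    "<annotation_set> ", if (nzchar(x$version_label)) paste0(x$version_label, ": "),
    length(x$genes), " genes, ", nt, " transcripts on ",
    length(unique(vapply(x$genes, `[[`, "", "seq_id"))), " sequence(s)\n",
    sep = ""
  )
  invisible(x)
}
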