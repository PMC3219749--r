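# GFF3 reading and writing. Parsing goes through rtracklayer; writing is
# formatted here so that output ordering is canonical and byte-stable
# (required for reproducible simulation output).

#' Parse a GFF3 file into an annotation set
#'
#' Expects a gene/mRNA/exon/CDS hierarchy linked via `ID`/`Parent`
#' (`transcript` is accepted as a synonym of `mRNA`; explicit UTR features are
#' ignored because UTRs are derived as exon minus CDS). All structural
#' invariants are validated: exons disjoint, CDS within exons, one sequence
#' and strand per gene.
#'
#' @param path path to a GFF3 file.
#' @param version_label label stored on the returned set; defaults to the
#'   file name.
#' @return an [annotation_set()].
#' @export
parse_gff3 <- function(path, version_label = basename(path)) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) stop("failed to parse GFF3 '", path, "': ", conditionMessage(e))
  )
  type <- as.character(gr$type)
  ids <- as.character(gr$ID)
  parent <- as.list(gr$Parent)

  seq_ids <- as.character(GenomicRanges::seqnames(gr))
  starts <- GenomicRanges::start(gr)
  ends <- GenomicRanges::end(gr)
  strands <- as.character(GenomicRanges::strand(gr))

  is_child <- type %in% c("exon", "CDS")
  child_rows <- which(is_child)
  child_parents <- parent[child_rows]
  np <- lengths(child_parents)
  if (any(np == 0)) {
    stop("GFF3 '", path, "': exon/CDS feature without a Parent attribute")
  }
  crow <- rep(child_rows, np)
  cparent <- unlist(child_parents)

  mrna_rows <- which(type %in% c("mRNA", "transcript"))
  if (length(mrna_rows) == 0 && any(is_child)) {
    stop("GFF3 '", path, "': no mRNA features found")
  }
  mrna_ids <- ids[mrna_rows]
  if (anyNA(mrna_ids)) stop("GFF3 '", path, "': mRNA feature without an ID")
  mrna_parent <- vapply(
    parent[mrna_rows],
    function(p) if (length(p)) p[[1]] else NA_character_, ""
  )
  if (anyNA(mrna_parent)) {
    stop("GFF3 '", path, "': mRNA feature without a gene Parent")
  }

  gene_rows <- which(type == "gene")
  gene_ids <- ids[gene_rows]
  if (anyNA(gene_ids)) stop("GFF3 '", path, "': gene feature without an ID")

  exon_by_tx <- split(crow[type[crow] == "exon"], cparent[type[crow] == "exon"])
  cds_by_tx <- split(crow[type[crow] == "CDS"], cparent[type[crow] == "CDS"])

  transcripts <- lapply(seq_along(mrna_rows), function(i) {
    tid <- mrna_ids[i]
    r <- mrna_rows[i]
    ex <- exon_by_tx[[tid]]
    cd <- cds_by_tx[[tid]]
    if (is.null(ex)) stop("GFF3 '", path, "': transcript ", tid, " has no exons")
    transcript_model(
      id = tid, gene_id = mrna_parent[i],
      seq_id = seq_ids[r], strand = strands[r],
      exons = data.frame(start = starts[ex], end = ends[ex]),
      cds = if (is.null(cd)) NULL else data.frame(start = starts[cd], end = ends[cd])
    )
  })
  tx_gene <- vapply(transcripts, `[[`, "", "gene_id")
  unknown <- setdiff(unique(tx_gene), gene_ids)
  if (length(unknown)) {
    stop("GFF3 '", path, "': mRNA Parent(s) not defined as genes: ",
      paste(unknown, collapse = ", "))
  }
  genes <- lapply(gene_ids, function(gid) {
    tx <- transcripts[tx_gene == gid]
    if (length(tx) == 0) stop("GFF3 '", path, "': gene ", gid, " has no mRNA")
    gene_model(gid, tx)
  })
  annotation_set(genes, version_label = version_label)
}

#' Write an annotation set as GFF3
#'
#' Output is deterministic: genes ordered by (seq_id, start, id), then per
#' transcript an mRNA line, exons, CDS segments (with phase), and optionally
#' the derived UTR features. The file is parseable by [parse_gff3()] and
#' round-trips to an identical object graph.
#'
#' @param set an [annotation_set()].
#' @param path output file path.
#' @param write_utrs also emit derived `five_prime_UTR`/`three_prime_UTR`
#'   features (default `FALSE`; they are derivable either way).
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(set, path, write_utrs = FALSE) {
  stopifnot(inherits(set, "annotation_set"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (length(set$genes) == 0) return(invisible(path))

  sp <- vapply(set$genes, model_span, integer(2))
  ord <- order(
    vapply(set$genes, `[[`, "", "seq_id"), sp["start", ],
    vapply(set$genes, `[[`, "", "id")
  )
  fmt <- function(seqid, src, type, start, end, strand, phase, attrs) {
    paste(seqid, src, type, start, end, ".", strand, phase, attrs, sep = "\t")
  }
  for (g in set$genes[ord]) {
    gs <- model_span(g)
    lines <- fmt(
      g$seq_id, "annotcompare", "gene", gs["start"], gs["end"], g$strand, ".",
      paste0("ID=", g$id)
    )
    tx_ids <- sort(names(g$transcripts))
    for (tid in tx_ids) {
      t <- g$transcripts[[tid]]
      ts <- model_span(t)
      lines <- c(lines, fmt(
        t$seq_id, "annotcompare", "mRNA", ts["start"], ts["end"], t$strand, ".",
        paste0("ID=", t$id, ";Parent=", g$id)
      ))
      ex <- t$exons
      lines <- c(lines, fmt(
        t$seq_id, "annotcompare", "exon", ex$start, ex$end, t$strand, ".",
        paste0("ID=", t$id, ".exon", seq_len(nrow(ex)), ";Parent=", t$id)
      ))
      cd <- t$cds
      if (nrow(cd) > 0) {
        # phase in transcript order: bases to skip to reach the next codon start
        tx_order <- if (t$strand == "+") seq_len(nrow(cd)) else rev(seq_len(nrow(cd)))
        lens <- cd$end - cd$start + 1L
        before <- cumsum(c(0L, lens[tx_order]))[seq_len(nrow(cd))]
        phase <- integer(nrow(cd))
        phase[tx_order] <- (3L - (before %% 3L)) %% 3L
        lines <- c(lines, fmt(
          t$seq_id, "annotcompare", "CDS", cd$start, cd$end, t$strand, phase,
          paste0("ID=", t$id, ".cds;Parent=", t$id)
        ))
      }
      if (write_utrs) {
        u <- utr_segments(t)
        if (nrow(u$utr5) > 0) {
          lines <- c(lines, fmt(
            t$seq_id, "annotcompare", "five_prime_UTR", u$utr5$start, u$utr5$end,
            t$strand, ".", paste0("Parent=", t$id)
          ))
        }
        if (nrow(u$utr3) > 0) {
          lines <- c(lines, fmt(
            t$seq_id, "annotcompare", "three_prime_UTR", u$utr3$start, u$utr3$end,
            t$strand, ".", paste0("Parent=", t$id)
          ))
        }
      }
    }
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a genome FASTA
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that truncates
#' sequence names at the first whitespace, matching how GFF3 seq_ids are
#' usually written.
#'
#' @param path FASTA file.
#' @return a named `DNAStringSet`.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}
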