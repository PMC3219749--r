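# Intron-level evidence support of multi-exon genes: each evidence track is
# a class-labeled set of intron keys derived from spliced alignments or ab
# initio predictions; a gene's intron is supported by a class iff its exact
# coordinates occur in that class's key union (no slack window).

EVIDENCE_CLASSES <- c("transcript", "protein", "denovo")

#' Build an evidence track from multi-segment features
#'
#' Every multi-segment feature chain contributes the introns (gaps) between
#' its consecutive segments; single-segment features contribute nothing, and
#' duplicate introns are kept once (set semantics).
#'
#' @param x a GFF3 file of segment features grouped by `Parent` (e.g.
#'   `match`/`match_part` alignments or gene/mRNA/exon predictions), or a
#'   data.frame with columns `group`, `seq_id`, `strand`, `start`, `end`.
#' @param name track name, e.g. `"rnaseq_pasa"`.
#' @param class evidence class: `"transcript"`, `"protein"` or `"denovo"`.
#' @return object of class `evidence_track` with the set of intron `keys`.
#' @export
build_track <- function(x, name, class) {
  if (!class %in% EVIDENCE_CLASSES) {
    stop(
      "unknown evidence class '", class, "'; expected one of ",
      paste(EVIDENCE_CLASSES, collapse = ", ")
    )
  }
  if (is.character(x) && length(x) == 1) {
    gr <- rtracklayer::import(x, format = "gff3")
    parent <- as.list(gr$Parent)
    np <- lengths(parent)
    has_parent <- np > 0
    df <- data.frame(
      group = vapply(parent[has_parent], `[[`, "", 1),
      seq_id = as.character(GenomicRanges::seqnames(gr))[has_parent],
      strand = as.character(GenomicRanges::strand(gr))[has_parent],
      start = GenomicRanges::start(gr)[has_parent],
      end = GenomicRanges::end(gr)[has_parent]
    )
  } else {
    df <- as.data.frame(x)
    stopifnot(all(c("group", "seq_id", "strand", "start", "end") %in% names(df)))
  }
  keys <- character(0)
  if (nrow(df) > 0) {
    df <- df[order(df$group, df$start), , drop = FALSE]
    grp <- split(df, df$group)
    keys <- unlist(lapply(grp, function(g) {
      n <- nrow(g)
      if (n < 2) return(character(0))
      make_intron_key(
        g$seq_id[1], g$strand[1],
        g$end[-n] + 1L, g$start[-1] - 1L
      )
    }), use.names = FALSE)
    keys <- unique(keys)
  }
  structure(list(name = name, class = class, keys = sort(keys)),
    class = "evidence_track"
  )
}

#' @export
print.evidence_track <- function(x, ...) {
  cat("<evidence_track> ", x$name, " (", x$class, "): ",
    length(x$keys), " intron keys\n",
    sep = ""
  )
  invisible(x)
}

#' Intron support profile of one multi-exon gene
#'
#' Introns are taken from the exon chain (CDS plus UTR exons) of the gene's
#' representative isoform (longest CDS). An intron is supported by a class
#' iff its exact key occurs in the union of that class's tracks; a gene is
#' `supported` by a class when at least one intron is, and `full_length`
#' when all of its introns are.
#'
#' @param g a multi-exon `gene_model`; single-exon genes are excluded from
#'   this analysis and raise an error (use [profile_genes()] to skip them
#'   with a notice).
#' @param tracks list of `evidence_track` objects.
#' @return one-row data.frame: `gene_id`, `n_introns`, then per class
#'   `sup_n_<class>`, `supported_<class>`, `full_<class>`, and the same three
#'   per track as `*_track_<name>`.
#' @export
profile_gene <- function(g, tracks) {
  rep_iso <- representative_isoform(g)
  ii <- introns_of(rep_iso, basis = "exon")
  if (nrow(ii) == 0) {
    stop("gene ", g$id, " is single-exon; the intron-support analysis covers multi-exon genes only")
  }
  keys <- ii$key
  row <- data.frame(gene_id = g$id, n_introns = length(keys))
  class_of <- vapply(tracks, `[[`, "", "class")
  for (cl in EVIDENCE_CLASSES) {
    union_keys <- unique(unlist(lapply(tracks[class_of == cl], `[[`, "keys")))
    n_sup <- sum(keys %in% union_keys)
    row[[paste0("sup_n_", cl)]] <- n_sup
    row[[paste0("supported_", cl)]] <- n_sup >= 1
    row[[paste0("full_", cl)]] <- n_sup == length(keys)
  }
  for (tr in tracks) {
    n_sup <- sum(keys %in% tr$keys)
    row[[paste0("sup_n_track_", tr$name)]] <- n_sup
    row[[paste0("supported_track_", tr$name)]] <- n_sup >= 1
    row[[paste0("full_track_", tr$name)]] <- n_sup == length(keys)
  }
  row
}

#' Intron support profiles for all multi-exon genes of a set
#'
#' @param set an [annotation_set()].
#' @param tracks list of `evidence_track` objects.
#' @param quiet suppress the skip notice (default `FALSE`).
#' @return data.frame with one row per multi-exon gene (see
#'   [profile_gene()]); skipped single-exon gene ids are attached as
#'   attribute `"skipped"`.
#' @export
profile_genes <- function(set, tracks, quiet = FALSE) {
  stopifnot(inherits(set, "annotation_set"))
  multi <- vapply(set$genes, function(g) {
    nrow(representative_isoform(g)$exons) >= 2
  }, logical(1))
  skipped <- names(set$genes)[!multi]
  if (length(skipped) && !quiet) {
    message(
      length(skipped),
      " single-exon gene(s) skipped; intron support is defined for multi-exon genes"
    )
  }
  genes <- set$genes[multi]
  key_list <- lapply(genes, function(g) {
    introns_of(representative_isoform(g), basis = "exon")$key
  })
  n_introns <- lengths(key_list)
  flat <- unlist(key_list, use.names = FALSE)
  gidx <- rep(seq_along(genes), n_introns)
  out <- data.frame(
    gene_id = names(genes) %||% character(0),
    n_introns = as.integer(n_introns),
    row.names = NULL
  )
  count_sup <- function(union_keys) {
    hit <- flat %in% union_keys
    as.integer(rowsum(as.integer(hit), gidx, reorder = TRUE))
  }
  class_of <- vapply(tracks, `[[`, "", "class")
  for (cl in EVIDENCE_CLASSES) {
    union_keys <- unique(unlist(lapply(tracks[class_of == cl], `[[`, "keys")))
    n_sup <- if (nrow(out)) count_sup(union_keys) else integer(0)
    out[[paste0("sup_n_", cl)]] <- n_sup
    out[[paste0("supported_", cl)]] <- n_sup >= 1L
    out[[paste0("full_", cl)]] <- n_sup == out$n_introns
  }
  for (tr in tracks) {
    n_sup <- if (nrow(out)) count_sup(tr$keys) else integer(0)
    out[[paste0("sup_n_track_", tr$name)]] <- n_sup
    out[[paste0("supported_track_", tr$name)]] <- n_sup >= 1L
    out[[paste0("full_track_", tr$name)]] <- n_sup == out$n_introns
  }
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Venn region counts of evidence support
#'
#' Partitions the profiled genes into the disjoint regions of the n-set Venn
#' diagram over the chosen evidence classes (or tracks): a gene falls into
#' the region named by the `&`-joined sets that support it. Genes supported
#' by no set are counted under `"none"`, so the region counts plus `"none"`
#' always sum to the number of genes profiled.
#'
#' @param profiles data.frame from [profile_genes()].
#' @param sets class names (default the three evidence classes) or, with
#'   `level = "track"`, track names.
#' @param mode `"supported"` (at least one intron supported) or
#'   `"full_length"` (all introns supported).
#' @param level look up class columns (default) or per-track columns.
#' @return named integer vector: one count per non-empty subset region
#'   (names like `"transcript&protein"`) plus `"none"`.
#' @export
venn_counts <- function(profiles, sets = EVIDENCE_CLASSES,
                        mode = c("supported", "full_length"),
                        level = c("class", "track")) {
  mode <- match.arg(mode)
  level <- match.arg(level)
  prefix <- if (mode == "supported") "supported_" else "full_"
  if (level == "track") prefix <- paste0(prefix, "track_")
  cols <- paste0(prefix, sets)
  missing <- setdiff(cols, names(profiles))
  if (length(missing)) {
    stop("profiles lack column(s): ", paste(missing, collapse = ", "),
      "; were the profiles computed against these sets?")
  }
  memb <- as.matrix(profiles[, cols, drop = FALSE])
  colnames(memb) <- sets
  region <- apply(memb, 1, function(r) {
    if (!any(r)) "none" else paste(sets[r], collapse = "&")
  })
  # all possible regions, in subset-size order, plus none
  region_names <- unlist(lapply(seq_along(sets), function(k) {
    apply(utils::combn(sets, k), 2, paste, collapse = "&")
  }))
  out <- stats::setNames(integer(length(region_names) + 1L), c(region_names, "none"))
  tab <- table(region)
  out[names(tab)] <- as.integer(tab)
  out
}
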