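# Deciding which annotation version is better: best-hit consistency rules
# for merge/split events; domain tallies and global-alignment statistics for
# modified 1-to-1 gene pairs. Homology hits arrive as 12-column blast-style
# tables; no search is executed here.

HIT_COLUMNS <- c(
  "qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
  "qstart", "qend", "sstart", "send", "evalue", "bitscore"
)

#' Build a hit table from a blast-style data.frame
#'
#' Entries failing the E-value cutoff are dropped; surviving entries are
#' ranked per query by ascending E-value then descending bitscore, so the
#' best hit of a query is its first row.
#'
#' @param df data.frame with (at least) the 12 standard tabular columns,
#'   named or in standard order.
#' @param evalue_cutoff maximal E-value retained (default `1e-5`).
#' @return data.frame of class `hit_table`.
#' @export
hit_table <- function(df, evalue_cutoff = 1e-5) {
  if (ncol(df) < 12) stop("hit table needs 12 columns, got ", ncol(df))
  df <- df[, 1:12]
  names(df) <- HIT_COLUMNS
  num_cols <- setdiff(HIT_COLUMNS, c("qseqid", "sseqid"))
  for (cn in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    if (anyNA(v) && !anyNA(df[[cn]])) {
      stop(
        "malformed hit row(s) ",
        paste(which(is.na(v))[1:min(3, sum(is.na(v)))], collapse = ","),
        ": non-numeric '", cn, "'"
      )
    }
    df[[cn]] <- v
  }
  df$qseqid <- as.character(df$qseqid)
  df$sseqid <- as.character(df$sseqid)
  df <- df[df$evalue <= evalue_cutoff, , drop = FALSE]
  df <- df[order(df$qseqid, df$evalue, -df$bitscore), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "evalue_cutoff") <- evalue_cutoff
  class(df) <- c("hit_table", "data.frame")
  df
}

#' Load a tabular homology-hit file
#'
#' Reads a 12-column blast-style TSV (query, subject, percent identity,
#' alignment length, mismatches, gap opens, query/subject spans, E-value,
#' bitscore) and applies the E-value cutoff.
#'
#' @param path TSV file without header; an empty file yields a table with no
#'   queries.
#' @inheritParams hit_table
#' @return data.frame of class `hit_table`.
#' @export
load_hits <- function(path, evalue_cutoff = 1e-5) {
  if (file.size(path) == 0) {
    df <- as.data.frame(
      stats::setNames(rep(list(character(0)), 12), HIT_COLUMNS)
    )
    return(hit_table(df, evalue_cutoff))
  }
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  hit_table(df, evalue_cutoff)
}

#' Best hit of a query
#'
#' @param hits a `hit_table`.
#' @param query query id.
#' @return subject accession of the top-ranked hit, or `NA_character_` when
#'   the query has no hit passing the cutoff.
#' @export
best_hit <- function(hits, query) {
  i <- which(hits$qseqid == query)
  if (length(i) == 0) return(NA_character_)
  hits$sseqid[i[1]]
}

#' Adjudicate a merged or split event with best-hit consistency rules
#'
#' Every merged/split event has one gene on its "merged side" (the version
#' holding the single fused gene) and two or more counterpart genes on its
#' "split side". The rules are applied in order:
#' \enumerate{
#'   \item no member of the group has any hit: the whole group is a
#'     \strong{false_positive};
#'   \item at least `min_shared` split-side genes share the merged gene's
#'     best hit: the merged structure is optimal;
#'   \item the split-side genes have two or more distinct best hits: the
#'     split structure is optimal;
#'   \item exactly one split-side gene has a hit: \strong{ambiguous} (one
#'     hit cannot distinguish the two structures);
#'   \item otherwise \strong{ambiguous}.
#' }
#' For an event of kind `"merged"` the merged side is version 2, so
#' "merged optimal" maps to `optimal_v2`; for kind `"split"` it is version 1.
#'
#' @param event a `comparison_event` of kind `"merged"` or `"split"`.
#' @param hits a `hit_table` whose query ids are gene ids.
#' @param min_shared split-side genes that must share the merged gene's best
#'   hit for rule 2 (default 2, i.e. "two or more"; configurable).
#' @return object of class `adjudication_verdict`: `event_id`, `kind`,
#'   `verdict` in `{optimal_v1, optimal_v2, false_positive, ambiguous}`, and
#'   a `rationale` string citing the triggering rule.
#' @export
adjudicate_merge_split <- function(event, hits, min_shared = 2) {
  if (!event$kind %in% c("merged", "split")) {
    stop("event ", event$cluster_id, " has kind '", event$kind,
      "'; only merged/split events can be adjudicated")
  }
  if (event$kind == "merged") {
    merged_gene <- event$v2_gene_ids
    split_genes <- event$v1_gene_ids
    merged_version <- "v2"
  } else {
    merged_gene <- event$v1_gene_ids
    split_genes <- event$v2_gene_ids
    merged_version <- "v1"
  }
  optimal_merged <- if (merged_version == "v2") "optimal_v2" else "optimal_v1"
  optimal_split <- if (merged_version == "v2") "optimal_v1" else "optimal_v2"

  all_members <- c(merged_gene, split_genes)
  bh <- vapply(all_members, function(g) best_hit(hits, g), "")
  names(bh) <- all_members
  if (all(is.na(bh))) {
    return(verdict_obj(event, "false_positive", "rule 1: no member of the group has any hit"))
  }
  merged_bh <- bh[merged_gene]
  split_bh <- bh[split_genes]
  if (!is.na(merged_bh)) {
    n_shared <- sum(!is.na(split_bh) & split_bh == merged_bh)
    if (n_shared >= min_shared) {
      return(verdict_obj(
        event, optimal_merged,
        sprintf(
          "rule 2: %d split-side gene(s) share the merged gene's best hit %s",
          n_shared, merged_bh
        )
      ))
    }
  }
  distinct <- unique(split_bh[!is.na(split_bh)])
  if (length(distinct) >= 2) {
    return(verdict_obj(
      event, optimal_split,
      sprintf("rule 3: split-side genes have %d distinct best hits", length(distinct))
    ))
  }
  if (sum(!is.na(split_bh)) == 1) {
    return(verdict_obj(
      event, "ambiguous",
      "rule 4: exactly one split-side gene has a hit"
    ))
  }
  verdict_obj(event, "ambiguous", "rule 5: hit pattern matches no decisive rule")
}

verdict_obj <- function(event, verdict, rationale) {
  structure(list(
    event_id = event$cluster_id, kind = event$kind,
    verdict = verdict, rationale = rationale
  ), class = "adjudication_verdict")
}

#' Adjudicate all merged/split events of a comparison
#'
#' @param events list of `comparison_event` objects (non-merge/split events
#'   are ignored).
#' @inheritParams adjudicate_merge_split
#' @return data.frame with `event_id`, `kind`, `verdict`, `rationale`.
#' @export
adjudicate_events <- function(events, hits, min_shared = 2) {
  ms <- Filter(function(e) e$kind %in% c("merged", "split"), events)
  out <- lapply(ms, adjudicate_merge_split, hits = hits, min_shared = min_shared)
  data.frame(
    event_id = vapply(out, `[[`, "", "event_id"),
    kind = vapply(out, `[[`, "", "kind"),
    verdict = vapply(out, `[[`, "", "verdict"),
    rationale = vapply(out, `[[`, "", "rationale"),
    row.names = NULL
  )
}

#' Load a domain table
#'
#' @param path TSV with header columns `gene_id`, `domain_accession`.
#' @return data.frame.
#' @export
load_domains <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "domain_accession") %in% names(df))) {
    stop("domain table needs columns gene_id, domain_accession")
  }
  df
}

#' Domain tallies for two gene lists
#'
#' @param domains data.frame with `gene_id`, `domain_accession`.
#' @param v1_ids,v2_ids gene ids of the two versions.
#' @return list with, per version, `n_genes_with_domain` and
#'   `n_domain_kinds` (distinct accessions).
#' @export
domain_summary <- function(domains, v1_ids, v2_ids) {
  tally <- function(ids) {
    sub <- domains[domains$gene_id %in% ids, , drop = FALSE]
    list(
      n_genes_with_domain = length(unique(sub$gene_id)),
      n_domain_kinds = length(unique(sub$domain_accession))
    )
  }
  list(v1 = tally(v1_ids), v2 = tally(v2_ids))
}

#' Compare a modified 1-to-1 gene pair by alignment to a shared best hit
#'
#' When the two proteins share a best hit, each is globally aligned to that
#' subject's sequence and the four alignment statistics are compared
#' per metric: higher identity, similarity and score are better, fewer gaps
#' are better. Pairs without a shared best hit are reported not comparable;
#' a shared best hit whose sequence is missing from the reference FASTA
#' flags the pair rather than failing.
#'
#' @param p1,p2 protein strings of the v1 and v2 gene.
#' @param id1,id2 the gene ids (hit-table query ids).
#' @param hits a `hit_table`.
#' @param ref_proteins named `AAStringSet` of subject sequences.
#' @param composite also report a single composite winner by lexicographic
#'   score > identity > similarity > fewer gaps (default `FALSE`).
#' @param ... passed to [global_align()].
#' @return object of class `pair_verdict`: `comparable`, `reason` (when not
#'   comparable), `shared_hit`, `metrics` (named character vector over
#'   identity/similarity/score/gaps with values `v1_better`/`v2_better`/
#'   `equal`), `stats_v1`, `stats_v2`, and `composite` when requested.
#' @export
compare_pair <- function(p1, p2, id1, id2, hits, ref_proteins,
                         composite = FALSE, ...) {
  bh1 <- best_hit(hits, id1)
  bh2 <- best_hit(hits, id2)
  not_comparable <- function(reason) {
    structure(list(
      pair = c(v1 = id1, v2 = id2), comparable = FALSE, reason = reason,
      shared_hit = NA_character_, metrics = NULL,
      stats_v1 = NULL, stats_v2 = NULL
    ), class = "pair_verdict")
  }
  if (is.na(bh1) || is.na(bh2)) return(not_comparable("missing best hit"))
  if (bh1 != bh2) return(not_comparable("best hits differ"))
  if (!bh1 %in% names(ref_proteins)) {
    return(not_comparable(paste0("subject ", bh1, " absent from reference FASTA")))
  }
  ref <- as.character(ref_proteins[[bh1]])
  s1 <- global_align(p1, ref, ...)
  s2 <- global_align(p2, ref, ...)
  cmp <- function(x1, x2, higher_better = TRUE) {
    if (x1 == x2) return("equal")
    better1 <- if (higher_better) x1 > x2 else x1 < x2
    if (better1) "v1_better" else "v2_better"
  }
  metrics <- c(
    identity = cmp(s1$identity, s2$identity),
    similarity = cmp(s1$similarity, s2$similarity),
    score = cmp(s1$score, s2$score),
    gaps = cmp(s1$gaps, s2$gaps, higher_better = FALSE)
  )
  out <- structure(list(
    pair = c(v1 = id1, v2 = id2), comparable = TRUE, reason = NA_character_,
    shared_hit = bh1, metrics = metrics, stats_v1 = s1, stats_v2 = s2
  ), class = "pair_verdict")
  if (composite) {
    key1 <- c(s1$score, s1$identity, s1$similarity, -s1$gaps)
    key2 <- c(s2$score, s2$identity, s2$similarity, -s2$gaps)
    d <- key1 - key2
    nz <- which(d != 0)
    out$composite <- if (length(nz) == 0) {
      "equal"
    } else if (d[nz[1]] > 0) {
      "v1_better"
    } else {
      "v2_better"
    }
  }
  out
}

#' Compare all modified 1-to-1 pairs of a comparison
#'
#' Translates the representative isoform of each gene of every
#' `modified_1to1` event and runs [compare_pair()].
#'
#' @param events list of `comparison_event`s (only `modified_1to1` used);
#'   normally pre-filtered with [exclude_multi_isoform()].
#' @param a,b the annotation sets.
#' @param genome named `DNAStringSet`.
#' @inheritParams compare_pair
#' @return data.frame with one row per pair: ids, `comparable`, the four
#'   per-metric outcomes, and the raw statistics of both alignments.
#' @export
compare_modified_pairs <- function(events, a, b, genome, hits, ref_proteins, ...) {
  mods <- Filter(function(e) e$kind == "modified_1to1", events)
  rows <- lapply(mods, function(e) {
    id1 <- e$v1_gene_ids
    id2 <- e$v2_gene_ids
    p1 <- suppressWarnings(translate_cds(representative_isoform(a$genes[[id1]]), genome))
    p2 <- suppressWarnings(translate_cds(representative_isoform(b$genes[[id2]]), genome))
    pv <- compare_pair(p1$protein, p2$protein, id1, id2, hits, ref_proteins, ...)
    data.frame(
      cluster_id = e$cluster_id, v1_id = id1, v2_id = id2,
      comparable = pv$comparable,
      reason = pv$reason,
      identity = if (pv$comparable) pv$metrics[["identity"]] else NA_character_,
      similarity = if (pv$comparable) pv$metrics[["similarity"]] else NA_character_,
      score = if (pv$comparable) pv$metrics[["score"]] else NA_character_,
      gaps = if (pv$comparable) pv$metrics[["gaps"]] else NA_character_,
      identity_v1 = if (pv$comparable) pv$stats_v1$identity else NA_real_,
      identity_v2 = if (pv$comparable) pv$stats_v2$identity else NA_real_,
      score_v1 = if (pv$comparable) pv$stats_v1$score else NA_real_,
      score_v2 = if (pv$comparable) pv$stats_v2$score else NA_real_,
      gaps_v1 = if (pv$comparable) pv$stats_v1$gaps else NA_integer_,
      gaps_v2 = if (pv$comparable) pv$stats_v2$gaps else NA_integer_,
      row.names = NULL
    )
  })
  if (length(rows) == 0) {
    return(data.frame(
      cluster_id = character(0), v1_id = character(0), v2_id = character(0),
      comparable = logical(0)
    ))
  }
  do.call(rbind, rows)
}

#' @export
print.adjudication_verdict <- function(x, ...) {
  cat("<adjudication_verdict> ", x$event_id, " (", x$kind, "): ", x$verdict,
    " [", x$rationale, "]\n",
    sep = ""
  )
  invisible(x)
}

#' @export
print.pair_verdict <- function(x, ...) {
  if (!x$comparable) {
    cat("<pair_verdict> ", x$pair[["v1"]], " vs ", x$pair[["v2"]],
      ": not comparable (", x$reason, ")\n",
      sep = ""
    )
  } else {
    cat("<pair_verdict> ", x$pair[["v1"]], " vs ", x$pair[["v2"]],
      " via ", x$shared_hit, ": ",
      paste(names(x$metrics), x$metrics, sep = "=", collapse = ", "), "\n",
      sep = ""
    )
  }
  invisible(x)
}
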