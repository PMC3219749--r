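# Locus clustering across two annotation versions and classification of
# every gene as identical / modified / merged / split / version-specific.

#' Cluster genes from two annotation versions into shared loci
#'
#' Two genes occupy the same locus iff their per-base CDS unions share at
#' least one base pair on the same sequence (and the same strand when
#' `stranded = TRUE`, the default). Loci are the connected components of the
#' resulting overlap graph, taken over genes of both versions (within-version
#' overlaps also link). Because the overlap test uses the per-base union of
#' CDS across isoforms, isoform choice cannot change locus membership.
#'
#' @param a annotation set, version 1.
#' @param b annotation set, version 2, on the same assembly coordinates.
#' @param stranded require equal strand for overlap (default `TRUE`;
#'   merged/split analysis and structural comparison are strand-specific).
#' @return list of `locus_cluster` objects ordered by (seq_id, span start,
#'   first member id); each has `id`, `seq_id`, `start`, `end`, `members_v1`,
#'   `members_v2` (gene ids sorted by position then id).
#' @export
cluster_loci <- function(a, b, stranded = TRUE) {
  stopifnot(inherits(a, "annotation_set"), inherits(b, "annotation_set"))
  ia <- a$cds_index
  ib <- b$cds_index
  node_a <- paste0("1|", S4Vectors::mcols(ia)$gene_id)
  node_b <- paste0("2|", S4Vectors::mcols(ib)$gene_id)
  gr <- suppressWarnings(c(GenomicRanges::granges(ia), GenomicRanges::granges(ib)))
  nodes_per_range <- c(node_a, node_b)
  # all genes are vertices, including CDS-less ones (isolated)
  vertices <- c(paste0("1|", names(a$genes)), paste0("2|", names(b$genes)))

  hits <- GenomicRanges::findOverlaps(gr, gr, ignore.strand = !stranded)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  edge_from <- nodes_per_range[qh]
  edge_to <- nodes_per_range[sh]
  keep <- edge_from != edge_to
  edges <- unique(data.frame(from = edge_from[keep], to = edge_to[keep]))

  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
  comp <- igraph::components(g)
  membership <- comp$membership[vertices]

  # per-gene position for ordering
  pos_of <- function(set) {
    if (length(set$genes) == 0) {
      return(data.frame(seq_id = character(0), start = integer(0)))
    }
    sp <- vapply(set$genes, model_span, integer(2))
    data.frame(
      seq_id = vapply(set$genes, `[[`, "", "seq_id"),
      start = sp["start", ], end = sp["end", ], row.names = NULL
    )
  }
  pa <- pos_of(a)
  pb <- pos_of(b)
  info <- data.frame(
    node = vertices,
    version = c(
      rep(1L, length(a$genes)), rep(2L, length(b$genes))
    ),
    gene_id = c(names(a$genes), names(b$genes)),
    seq_id = c(pa$seq_id, pb$seq_id),
    start = c(pa$start, pb$start),
    end = c(pa$end, pb$end),
    comp = unname(membership),
    row.names = NULL
  )
  groups <- split(info, info$comp)
  clusters <- lapply(groups, function(m) {
    m <- m[order(m$start, m$gene_id), , drop = FALSE]
    structure(list(
      id = NA_character_,
      seq_id = m$seq_id[1],
      start = min(m$start), end = max(m$end),
      members_v1 = m$gene_id[m$version == 1L],
      members_v2 = m$gene_id[m$version == 2L]
    ), class = "locus_cluster")
  })
  first_id <- vapply(clusters, function(cl) {
    c(cl$members_v1, cl$members_v2)[1]
  }, "")
  ord <- order(
    vapply(clusters, `[[`, "", "seq_id"),
    vapply(clusters, function(cl) cl$start, numeric(1)),
    first_id
  )
  clusters <- clusters[ord]
  for (i in seq_along(clusters)) {
    clusters[[i]]$id <- sprintf("locus_%06d", i)
  }
  names(clusters) <- vapply(clusters, `[[`, "", "id")
  clusters
}

#' Do two gene models have the same coding structure?
#'
#' Only coding regions are considered (UTRs are ignored). Two genes are
#' structurally equal iff some isoform of one and some isoform of the other
#' have identical ordered CDS segment coordinate lists: genes differing in
#' all alternative spliced isoforms are the ones viewed as structurally
#' different, so a single shared isoform means equal structure. Genes on
#' different sequences or strands are never equal.
#'
#' @param g1,g2 `gene_model` objects.
#' @return logical.
#' @export
structures_equal <- function(g1, g2) {
  if (g1$seq_id != g2$seq_id || g1$strand != g2$strand) return(FALSE)
  chain <- function(t) paste(t$cds$start, t$cds$end, sep = "-", collapse = ";")
  c1 <- vapply(g1$transcripts, chain, "")
  c2 <- vapply(g2$transcripts, chain, "")
  c1 <- c1[nzchar(c1)]
  c2 <- c2[nzchar(c2)]
  length(intersect(c1, c2)) > 0
}

#' Classify locus clusters into comparison events
#'
#' Each cluster is classified purely by member counts and structure equality:
#' \describe{
#'   \item{specific_v1 / specific_v2}{one gene, only in one version}
#'   \item{identical}{one gene in each version, equal coding structures}
#'   \item{modified_1to1}{one gene in each version, different structures}
#'   \item{merged}{two or more v1 genes vs one v2 gene (the v1 genes are
#'     merged into one v2 gene)}
#'   \item{split}{one v1 gene vs two or more v2 genes}
#'   \item{complex}{two or more genes on both sides; reported separately and
#'     never forced into merged or split}
#' }
#'
#' @param clusters result of [cluster_loci()].
#' @param a,b the annotation sets the clusters were built from.
#' @return list with `events` (list of `comparison_event`: `cluster_id`,
#'   `kind`, `v1_gene_ids`, `v2_gene_ids`) and `report` (class
#'   `comparison_report`: event counts, per-version gene counts per kind,
#'   and the number of shared loci).
#' @export
classify_clusters <- function(clusters, a, b) {
  kinds <- c(
    "identical", "modified_1to1", "merged", "split",
    "specific_v1", "specific_v2", "complex"
  )
  events <- lapply(clusters, function(cl) {
    m <- length(cl$members_v1)
    n <- length(cl$members_v2)
    kind <- if (m == 1 && n == 0) {
      "specific_v1"
    } else if (m == 0 && n == 1) {
      "specific_v2"
    } else if (m == 1 && n == 1) {
      if (structures_equal(a$genes[[cl$members_v1]], b$genes[[cl$members_v2]])) {
        "identical"
      } else {
        "modified_1to1"
      }
    } else if (m >= 2 && n == 1) {
      "merged"
    } else if (m == 1 && n >= 2) {
      "split"
    } else {
      "complex"
    }
    structure(list(
      cluster_id = cl$id, kind = kind,
      v1_gene_ids = cl$members_v1, v2_gene_ids = cl$members_v2
    ), class = "comparison_event")
  })
  kind_of <- vapply(events, `[[`, "", "kind")
  nv1 <- vapply(events, function(e) length(e$v1_gene_ids), integer(1))
  nv2 <- vapply(events, function(e) length(e$v2_gene_ids), integer(1))
  count_by <- function(x) {
    out <- vapply(kinds, function(k) sum(x[kind_of == k]), numeric(1))
    stats::setNames(as.integer(out), kinds)
  }
  report <- structure(list(
    n_clusters = length(events),
    n_shared_loci = sum(nv1 > 0 & nv2 > 0),
    event_counts = count_by(rep(1L, length(events))),
    genes_v1 = count_by(nv1),
    genes_v2 = count_by(nv2)
  ), class = "comparison_report")
  list(events = events, report = report)
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report> ", x$n_clusters, " loci (",
    x$n_shared_loci, " shared)\n",
    sep = ""
  )
  df <- data.frame(
    kind = names(x$event_counts),
    events = unname(x$event_counts),
    genes_v1 = unname(x$genes_v1),
    genes_v2 = unname(x$genes_v2)
  )
  print(df, row.names = FALSE)
  invisible(x)
}

#' Flatten comparison events to a data.frame
#'
#' @param events list of `comparison_event` objects.
#' @return data.frame with `cluster_id`, `kind`, comma-joined `v1_ids` and
#'   `v2_ids`.
#' @export
events_df <- function(events) {
  data.frame(
    cluster_id = vapply(events, `[[`, "", "cluster_id"),
    kind = vapply(events, `[[`, "", "kind"),
    v1_ids = vapply(events, function(e) paste(e$v1_gene_ids, collapse = ","), ""),
    v2_ids = vapply(events, function(e) paste(e$v2_gene_ids, collapse = ","), ""),
    row.names = NULL
  )
}

#' Exclude events involving multi-isoform genes
#'
#' Genes with alternative spliced isoforms are filtered out before the
#' downstream adjudication analyses to keep those analyses one-structure-per
#' -gene.
#'
#' @param events list of `comparison_event` objects.
#' @param a,b the annotation sets.
#' @return list with `kept` (events whose genes are all single-isoform) and
#'   `excluded` (data.frame `cluster_id`, `gene_id`, `version`,
#'   `n_isoforms`, one row per offending gene).
#' @export
exclude_multi_isoform <- function(events, a, b) {
  n_iso <- function(set, ids) {
    vapply(ids, function(id) length(set$genes[[id]]$transcripts), integer(1))
  }
  rows <- list()
  keep <- logical(length(events))
  for (i in seq_along(events)) {
    e <- events[[i]]
    i1 <- n_iso(a, e$v1_gene_ids)
    i2 <- n_iso(b, e$v2_gene_ids)
    bad1 <- e$v1_gene_ids[i1 >= 2]
    bad2 <- e$v2_gene_ids[i2 >= 2]
    keep[i] <- length(bad1) + length(bad2) == 0
    if (!keep[i]) {
      rows[[length(rows) + 1L]] <- data.frame(
        cluster_id = e$cluster_id,
        gene_id = c(bad1, bad2),
        version = c(rep("v1", length(bad1)), rep("v2", length(bad2))),
        n_isoforms = c(i1[i1 >= 2], i2[i2 >= 2]),
        row.names = NULL
      )
    }
  }
  list(
    kept = events[keep],
    excluded = if (length(rows)) do.call(rbind, rows) else data.frame(
      cluster_id = character(0), gene_id = character(0),
      version = character(0), n_isoforms = integer(0)
    )
  )
}
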