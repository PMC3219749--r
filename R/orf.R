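# Six-frame scan for complete open reading frames (start codon through
# in-frame stop codon) in transcript sequences.

STOP_CODONS <- c("TAA", "TAG", "TGA")

# complete ORFs in one frame of one sequence string; returns start/end
# positions on that string (1-based, forward orientation of the string)
orfs_in_frame <- function(s, offset) {
  L <- nchar(s)
  n_codon <- (L - offset) %/% 3L
  if (n_codon < 2L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  pos <- offset + 1L + 3L * (seq_len(n_codon) - 1L)
  codons <- substring(s, pos, pos + 2L)
  is_stop <- codons %in% STOP_CODONS
  is_atg <- codons == "ATG"
  stops <- which(is_stop)
  atgs <- which(is_atg)
  if (length(stops) == 0 || length(atgs) == 0) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  starts <- integer(0)
  ends <- integer(0)
  prev_stop <- 0L
  for (st in stops) {
    a <- atgs[atgs > prev_stop & atgs < st]
    if (length(a)) {
      starts <- c(starts, a[1])
      ends <- c(ends, st)
    }
    prev_stop <- st
  }
  data.frame(start = pos[starts], end = pos[ends] + 2L)
}

#' Find complete ORFs in transcript sequences
#'
#' Scans all six reading frames of each sequence for complete open reading
#' frames: an ATG followed by an in-frame stop codon with no earlier in-frame
#' stop. The reported length includes the stop codon (so the minimal complete
#' ORF, ATG + stop, has length 6). Within one frame, nested ORFs are resolved
#' to the first ATG after the previous stop. Coordinates are reported on the
#' input sequence with `start < end`; for minus-strand ORFs `start` is the
#' position of the stop-codon end.
#'
#' @param seqs named `DNAStringSet` or character vector of transcript
#'   sequences.
#' @param min_nt minimal ORF length (nt, including the stop codon) for the
#'   per-transcript `complete` flag; default 30.
#' @return list with `orfs` (data.frame `transcript_id`, `strand`, `frame`
#'   (0..2), `start`, `end`, `length`, one row per complete ORF) and
#'   `per_transcript` (data.frame `transcript_id`, `n_complete`,
#'   `longest_complete`, `complete` = any complete ORF of at least `min_nt`).
#' @export
find_complete_orfs <- function(seqs, min_nt = 30) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  ids <- names(seqs) %||% as.character(seq_along(seqs))
  if (is.null(names(seqs))) names(seqs) <- ids
  rows <- list()
  for (i in seq_along(seqs)) {
    s_fwd <- as.character(seqs[[i]])
    s_rev <- as.character(Biostrings::reverseComplement(seqs[[i]]))
    L <- nchar(s_fwd)
    for (fr in 0:2) {
      fw <- orfs_in_frame(s_fwd, fr)
      if (nrow(fw)) {
        rows[[length(rows) + 1L]] <- data.frame(
          transcript_id = ids[i], strand = "+", frame = fr,
          start = fw$start, end = fw$end, length = fw$end - fw$start + 1L
        )
      }
      rv <- orfs_in_frame(s_rev, fr)
      if (nrow(rv)) {
        # map back to forward coordinates of the input sequence
        rows[[length(rows) + 1L]] <- data.frame(
          transcript_id = ids[i], strand = "-", frame = fr,
          start = L - rv$end + 1L, end = L - rv$start + 1L,
          length = rv$end - rv$start + 1L
        )
      }
    }
  }
  orfs <- if (length(rows)) do.call(rbind, rows) else data.frame(
    transcript_id = character(0), strand = character(0), frame = integer(0),
    start = integer(0), end = integer(0), length = integer(0)
  )
  per <- do.call(rbind, lapply(ids, function(id) {
    sub <- orfs[orfs$transcript_id == id, , drop = FALSE]
    data.frame(
      transcript_id = id,
      n_complete = nrow(sub),
      longest_complete = if (nrow(sub)) max(sub$length) else NA_integer_,
      complete = any(sub$length >= min_nt)
    )
  }))
  rownames(orfs) <- NULL
  rownames(per) <- NULL
  list(orfs = orfs, per_transcript = per)
}
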