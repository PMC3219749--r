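# small shared helpers

#' Round half away from zero
#'
#' Base `round()` rounds half to even; annotation reports conventionally round
#' half up, so 87.55 becomes 87.6.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Truncate to a number of decimal places
#'
#' @param x numeric vector.
#' @param digits number of decimal places kept.
#' @return truncated numeric vector.
#' @export
truncate_digits <- function(x, digits = 0) {
  p <- 10^digits
  trunc(x * p) / p
}

#' Format a value for a report
#'
#' Percentages and Kb densities are reported to 1 decimal, per-transcript
#' means to 2 decimals; the rounding mode is configurable because published
#' tables are not always consistent about it.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @param mode `"half_up"` (default) or `"truncate"`.
#' @return rounded numeric vector.
#' @export
report_round <- function(x, digits = 1, mode = c("half_up", "truncate")) {
  mode <- match.arg(mode)
  if (mode == "half_up") round_half_up(x, digits) else truncate_digits(x, digits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# canonical string identity of an intron: exact coordinate equality of
# (seq_id, strand, first, last)
make_intron_key <- function(seq_id, strand, first, last) {
  paste(seq_id, strand, first, last, sep = ":")
}

# coerce anything interval-like to a validated, sorted segment data.frame
as_segment_df <- function(x, what = "segment") {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  if (is.matrix(x)) x <- as.data.frame(x)
  stopifnot(is.data.frame(x), all(c("start", "end") %in% names(x)))
  df <- data.frame(start = as.integer(x$start), end = as.integer(x$end))
  if (anyNA(df$start) || anyNA(df$end)) {
    stop(what, " coordinates contain missing values")
  }
  if (any(df$start < 1L)) stop(what, " start coordinates must be >= 1")
  if (any(df$end < df$start)) stop(what, " end must be >= start")
  df <- df[order(df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  if (nrow(df) > 1 && any(df$start[-1] <= df$end[-nrow(df)])) {
    stop(what, "s overlap: segments must be disjoint")
  }
  df
}
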