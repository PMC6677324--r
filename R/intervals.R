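#' Construct a table of genomic intervals
#'
#' All interval coordinates in this package are 0-based, half-open
#' (`start` inclusive, `end` exclusive), the native BED convention.
#' Conversions happen only at format boundaries (GTF is 1-based inclusive).
#'
#' @param scaffold character vector of scaffold/chromosome names.
#' @param start,end integer vectors, 0-based half-open; `end > start`.
#' @param name optional feature names (recycled).
#' @param score optional numeric scores (recycled).
#' @param strand strand characters in `+`, `-`, `.` (recycled).
#' @return A `data.frame` with columns `scaffold`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @export
genomic_intervals <- function(scaffold, start, end, name = ".",
                              score = 0, strand = ".") {
  n <- length(start)
  df <- data.frame(
    scaffold = rep_len(as.character(scaffold), n),
    start    = as.integer(start),
    end      = as.integer(end),
    name     = rep_len(as.character(name), n),
    score    = rep_len(as.numeric(score), n),
    strand   = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  validate_intervals(df)
  df
}

validate_intervals <- function(df) {
  if (nrow(df) == 0L) return(invisible(df))
  if (any(is.na(df$start) | is.na(df$end)))
    stop("interval coordinates must be non-missing integers")
  bad <- which(df$start < 0L | df$end <= df$start)
  if (length(bad))
    stop("invalid interval(s) at row(s) ", paste(bad, collapse = ", "),
         ": need 0 <= start < end")
  if (any(!nzchar(df$scaffold)))
    stop("scaffold names must be non-empty")
  if (any(!df$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  invisible(df)
}

#' Test pairwise interval overlap
#'
#' Two half-open intervals overlap iff `a.start < b.end && b.start < a.end`
#' and they lie on the same scaffold.
#'
#' @param a,b single-row interval data frames (or lists with `scaffold`,
#'   `start`, `end`).
#' @return logical.
#' @export
intervals_overlap <- function(a, b) {
  a$scaffold == b$scaffold && a$start < b$end && b$start < a$end
}

# Internal: intervals data.frame -> GRanges (shifts to 1-based closed).
as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$scaffold,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = ifelse(df$strand %in% c("+", "-"), df$strand, "*")
  )
}

# Internal: GRanges -> intervals data.frame (back to 0-based half-open).
from_granges <- function(gr, name = ".", score = 0) {
  st <- as.character(GenomicRanges::strand(gr))
  st[st == "*"] <- "."
  genomic_intervals(
    scaffold = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = name, score = score, strand = st
  )
}
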