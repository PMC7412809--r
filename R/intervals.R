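#' Construct a table of genomic intervals
#'
#' Intervals are stored throughout the package as plain data frames in
#' 0-based half-open coordinates (the BED convention): a peak covering the
#' first 100 bases of a chromosome has `start = 0`, `end = 100`.
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer vector, 0-based inclusive start positions.
#' @param end Integer vector, exclusive end positions (`end > start`).
#' @param strand Strand, one of `"+"`, `"-"`, `"."` (recycled).
#' @return A data frame with columns `chrom`, `start`, `end`, `strand`.
#' @examples
#' genomic_intervals("chr1", 100, 300)
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".") {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- max(length(chrom), length(start), length(end))
  if (n > 0) {
    chrom <- rep_len(chrom, n)
    start <- rep_len(start, n)
    end <- rep_len(end, n)
    strand <- rep_len(as.character(strand), n)
  } else {
    strand <- character(0)
  }
  if (any(!nzchar(chrom))) stop("chrom names must be non-empty")
  if (any(start < 0)) stop("interval start must be >= 0")
  if (any(start >= end)) {
    bad <- which(start >= end)[1]
    stop(sprintf("interval %d has start >= end (%d >= %d)",
                 bad, start[bad], end[bad]))
  }
  if (any(!strand %in% c("+", "-", "."))) stop("strand must be one of +, -, .")
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             stringsAsFactors = FALSE)
}

#' Midpoints of intervals
#' @param intervals Interval data frame from [genomic_intervals()].
#' @return Numeric vector of interval centers (may be half-integers).
#' @export
interval_centers <- function(intervals) {
  (intervals$start + intervals$end) / 2
}

#' Canonical "chrom:start-end" identifiers for intervals
#' @inheritParams interval_centers
#' @return Character vector of identifiers.
#' @export
interval_ids <- function(intervals) {
  sprintf("%s:%d-%d", intervals$chrom,
          as.integer(intervals$start), as.integer(intervals$end))
}

# Convert a 0-based half-open interval table to a GRanges (1-based closed)
# for overlap arithmetic. Strand is dropped: overlaps here are unstranded.
as_granges <- function(intervals) {
  GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start + 1L,
                              end = as.integer(intervals$end))
  )
}

# Hits between two 0-based interval tables (any base overlap).
interval_overlaps <- function(query, subject) {
  hits <- GenomicRanges::findOverlaps(as_granges(query), as_granges(subject))
  data.frame(query = S4Vectors::queryHits(hits),
             subject = S4Vectors::subjectHits(hits))
}

# Merge overlapping/adjacent intervals per group; returns summed widths by
# group id (used for total exon length).
merged_widths_by_group <- function(intervals, group) {
  gr <- as_granges(intervals)
  grl <- S4Vectors::split(gr, factor(group, levels = unique(group)))
  red <- GenomicRanges::reduce(grl)
  sums <- sum(IRanges::width(red))
  stats::setNames(as.numeric(sums), names(sums))
}
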