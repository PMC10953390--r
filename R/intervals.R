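# Genomic interval helpers.
#
# Every interval inside the package is 0-based half-open [start, end), the BED
# convention. Tables that arrive in 1-based inclusive coordinates (ibed-style
# interaction tables, SNP positions) are converted once at the I/O boundary.
# Strand is ignored throughout.

#' Construct and validate a table of genomic intervals
#'
#' @param chrom character vector of chromosome names.
#' @param start integer vector, 0-based inclusive starts.
#' @param end integer vector, 0-based exclusive ends.
#' @param ... further equal-length columns carried along (e.g. `name`,
#'   `cell_type`).
#'
#' @return a `data.frame` with columns `chrom`, `start`, `end` plus any extras.
#' @export
#' @examples
#' genomic_intervals("chr1", 99, 100)  # covers 1-based position 100
genomic_intervals <- function(chrom, start, end, ...) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   ...,
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

#' Validate interval invariants
#'
#' Checks `chrom` non-empty, `start >= 0`, `end > start`. Called by every
#' loader and constructor; errors identify the first offending row.
#'
#' @param df data.frame with `chrom`, `start`, `end` (or prefixed variants).
#' @param prefix optional column prefix, e.g. `"bait_"`.
#' @param what label used in error messages.
#' @return `df`, invisibly.
#' @export
validate_intervals <- function(df, prefix = "", what = "interval") {
  cn <- paste0(prefix, c("chrom", "start", "end"))
  missing_cols <- setdiff(cn, names(df))
  if (length(missing_cols) > 0)
    stop("missing interval columns: ", paste(missing_cols, collapse = ", "))
  chrom <- df[[cn[1]]]; start <- df[[cn[2]]]; end <- df[[cn[3]]]
  bad <- which(is.na(chrom) | !nzchar(chrom))
  if (length(bad) > 0)
    stop(sprintf("%s row %d: empty chromosome name", what, bad[1]))
  bad <- which(!is.finite(start) | !is.finite(end))
  if (length(bad) > 0)
    stop(sprintf("%s row %d: non-numeric coordinates", what, bad[1]))
  bad <- which(start < 0)
  if (length(bad) > 0)
    stop(sprintf("%s row %d: start < 0", what, bad[1]))
  bad <- which(end <= start)
  if (length(bad) > 0)
    stop(sprintf("%s row %d: end <= start (coordinate error)", what, bad[1]))
  invisible(df)
}

# data.frame of 0-based half-open intervals -> GRanges (1-based closed)
.as_granges <- function(df, prefix = "") {
  cn <- paste0(prefix, c("chrom", "start", "end"))
  GenomicRanges::GRanges(
    seqnames = df[[cn[1]]],
    ranges = IRanges::IRanges(start = df[[cn[2]]] + 1, end = df[[cn[3]]])
  )
}

# 1-based SNP positions -> width-1 GRanges
.points_granges <- function(chrom, pos) {
  GenomicRanges::GRanges(seqnames = chrom,
                         ranges = IRanges::IRanges(start = pos, end = pos))
}

#' Merge (union) a set of intervals
#'
#' Overlapping or bookended intervals are collapsed per chromosome. A positive
#' `gap` additionally merges intervals separated by at most `gap` bp.
#'
#' @param df interval data.frame (`chrom`, `start`, `end`).
#' @param gap maximum separation (bp) still merged; default 0 merges only
#'   overlapping/adjacent intervals.
#' @return interval data.frame sorted by (chrom, start).
#' @export
merge_intervals <- function(df, gap = 0) {
  validate_intervals(df)
  if (nrow(df) == 0)
    return(df[, c("chrom", "start", "end")])
  gr <- GenomicRanges::reduce(.as_granges(df), min.gapwidth = gap + 1)
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1,
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Which 1-based positions fall inside a set of intervals?
#'
#' A SNP at 1-based position `p` overlaps a 0-based half-open interval
#' `[s, e)` iff `s <= p - 1 < e`.
#'
#' @param chrom,pos vectors of chromosome names and 1-based positions.
#' @param intervals interval data.frame.
#' @return logical vector, one flag per position.
#' @export
points_in_intervals <- function(chrom, pos, intervals) {
  if (length(chrom) == 0) return(logical(0))
  if (nrow(intervals) == 0) return(rep(FALSE, length(chrom)))
  validate_intervals(intervals)
  # differing seqlevel sets between points and intervals are expected
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(.points_granges(chrom, pos),
                                .as_granges(intervals)))
  out <- rep(FALSE, length(chrom))
  out[unique(S4Vectors::queryHits(hits))] <- TRUE
  out
}

# All (point, interval) containment pairs; returns data.frame(point_idx, interval_idx)
.point_interval_hits <- function(chrom, pos, intervals) {
  if (length(chrom) == 0 || nrow(intervals) == 0)
    return(data.frame(point_idx = integer(0), interval_idx = integer(0)))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(.points_granges(chrom, pos),
                                .as_granges(intervals)))
  data.frame(point_idx = S4Vectors::queryHits(hits),
             interval_idx = S4Vectors::subjectHits(hits))
}

# Coordinate conversions at the I/O boundary --------------------------------

#' Convert 1-based inclusive coordinates to 0-based half-open (and back)
#'
#' `coords_1based_to_0based(s1, e1)` maps a 1-based inclusive pair to the
#' internal convention; `coords_0based_to_1based()` is its inverse.
#'
#' @param start,end coordinate vectors.
#' @return list with `start` and `end`.
#' @export
coords_1based_to_0based <- function(start, end) {
  list(start = start - 1, end = end)
}

#' @rdname coords_1based_to_0based
#' @export
coords_0based_to_1based <- function(start, end) {
  list(start = start + 1, end = end)
}
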