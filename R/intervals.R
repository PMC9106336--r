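# Genomic interval primitives. All coordinates are 0-based, half-open
# ([start, end), BED convention) throughout the package; any 1-based dialect
# must be converted at the reader boundary. Strand is ignored everywhere.

#' Construct a table of genomic intervals
#'
#' @param chrom character chromosome names.
#' @param start,end numeric 0-based half-open coordinates; `end > start`,
#'   `start >= 0` are enforced.
#' @param ... further equal-length columns (e.g. `label`).
#' @return a `data.frame` with columns `chrom`, `start`, `end`, `...`.
#' @examples
#' genomic_intervals("chr1", 100, 200)
#' @export
genomic_intervals <- function(chrom, start, end, ...) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), ..., stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df, what = "interval") {
  bad <- which(!(df$end > df$start) | df$start < 0 | is.na(df$start) | is.na(df$end))
  if (length(bad) > 0L) {
    ls_stop(sprintf("invalid %s at row %d: start=%s end=%s (need 0 <= start < end)",
                    what, bad[1L], format(df$start[bad[1L]]), format(df$end[bad[1L]])),
            "loopscore_validation_error")
  }
  invisible(df)
}

#' Half-open interval overlap predicate
#'
#' True iff the intervals share a chromosome and `a.start < b.end` and
#' `b.start < a.end`. Touching intervals (`[0,10)` vs `[10,20)`) do not
#' overlap. Vectorized with recycling; symmetric and reflexive.
#'
#' @param a,b interval tables as built by [genomic_intervals()].
#' @return logical vector.
#' @export
overlaps <- function(a, b) {
  a$chrom == b$chrom & a$start < b$end & b$start < a$end
}

#' Interval midpoint
#'
#' `floor((start + end) / 2)`; the floor matters for odd-width anchors and is
#' the convention used for loop spans.
#'
#' @param a interval table.
#' @return numeric base positions.
#' @export
midpoint <- function(a) {
  floor((a$start + a$end) / 2)
}

# Convert an interval data.frame to GRanges for bulk overlap queries.
# Internal: IRanges are 1-based closed, hence start + 1.
as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end)
  )
}

# For each query interval, whether any subject interval overlaps it
# (half-open semantics preserved by the +1 closed-coordinate conversion).
any_overlap <- function(query, subject) {
  if (nrow(subject) == 0L || nrow(query) == 0L) {
    return(rep(FALSE, nrow(query)))
  }
  IRanges::overlapsAny(as_granges(query), as_granges(subject))
}
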