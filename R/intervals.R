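#' Genomic intervals
#'
#' All coordinates in this package are 0-based, half-open `[start, end)`,
#' the BED convention. A set of intervals is represented as a plain
#' `data.frame` with columns `chrom`, `start`, `end`, `strand`; helper
#' constructors validate the invariants (`0 <= start < end`, strand is
#' `"+"` or `"-"`).
#'
#' @param chrom character vector of sequence names.
#' @param start,end integer vectors, 0-based half-open.
#' @param strand character vector of `"+"` / `"-"`.
#' @return A validated `data.frame` with one row per interval.
#' @export
genomic_interval <- function(chrom, start, end, strand = "+") {
  gi <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   strand = as.character(strand),
                   stringsAsFactors = FALSE)
  validate_intervals(gi)
  gi
}

#' Validate an interval data.frame
#'
#' @param gi data.frame with columns `chrom`, `start`, `end`, `strand`.
#' @return Invisibly `gi`; stops on invariant violation.
#' @export
validate_intervals <- function(gi) {
  stopifnot(is.data.frame(gi),
            all(c("chrom", "start", "end", "strand") %in% names(gi)))
  if (any(gi$start < 0L)) {
    stop("interval start must be >= 0")
  }
  if (any(gi$start >= gi$end)) {
    stop("interval start must be < end (0-based half-open)")
  }
  if (!all(gi$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  invisible(gi)
}

#' Length of the intersection of two half-open intervals
#'
#' Vectorised; returns 0 for disjoint pairs.
#'
#' @param s1,e1,s2,e2 numeric vectors of interval bounds.
#' @return Numeric vector of overlap lengths (>= 0).
#' @export
interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}

#' Do intervals in one set hit any interval in another?
#'
#' For each interval in `(s1, e1)` reports whether it intersects at least
#' one interval of `(s2, e2)`. Quadratic scan; the site/motif/event sets
#' this package handles per transcript are small.
#'
#' @param s1,e1 query interval bounds (vectors).
#' @param s2,e2 subject interval bounds (vectors).
#' @return Logical vector along the query.
#' @export
overlaps_any <- function(s1, e1, s2, e2) {
  if (length(s2) == 0L) {
    return(rep(FALSE, length(s1)))
  }
  vapply(seq_along(s1), function(i) {
    any(s1[i] < e2 & s2 < e1[i])
  }, logical(1))
}
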