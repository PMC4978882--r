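# Interval sets: sorted, disjoint, half-open [start, end) bp intervals,
# represented user-side as data.frames with integer `start` and `end`
# columns (0-based, BED-like).  IRanges does the set arithmetic internally
# (converted to 1-based closed coordinates).

#' Construct an interval set
#'
#' @param start,end integer vectors of half-open interval bounds (0-based).
#' @param ... further equal-length columns carried along (e.g. `fold`).
#' @return A data.frame of class `interval_set`, sorted by start.
#' @export
interval_set <- function(start = integer(), end = integer(), ...) {
  df <- data.frame(start = as.numeric(start), end = as.numeric(end), ...)
  if (any(df$end <= df$start)) stop("intervals must satisfy start < end")
  df <- df[order(df$start), , drop = FALSE]
  if (nrow(df) > 1 && any(df$start[-1] < df$end[-nrow(df)]))
    stop("intervals must be pairwise disjoint")
  rownames(df) <- NULL
  class(df) <- c("interval_set", "data.frame")
  df
}

as_iranges0 <- function(x) {
  if (nrow(x) == 0) return(IRanges::IRanges())
  IRanges::IRanges(start = as.integer(x$start) + 1L, end = as.integer(x$end))
}

from_iranges0 <- function(ir) {
  interval_set(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

#' Merge overlapping or abutting intervals
#'
#' @param x an `interval_set` or data.frame with `start`/`end` columns.
#' @return A merged `interval_set` (idempotent).
#' @export
interval_merge <- function(x) {
  if (nrow(x) == 0) return(interval_set())
  from_iranges0(IRanges::reduce(as_iranges0(x)))
}

#' Total bp covered by an interval set
#' @param x an `interval_set`.
#' @return Numeric bp count.
#' @export
interval_total_bp <- function(x) {
  if (nrow(x) == 0) return(0)
  sum(IRanges::width(IRanges::reduce(as_iranges0(x))))
}

#' Intersection of two interval sets
#' @param x,y `interval_set`s.
#' @return The `interval_set` of bp covered by both.
#' @export
interval_intersect <- function(x, y) {
  if (nrow(x) == 0 || nrow(y) == 0) return(interval_set())
  ir <- IRanges::intersect(IRanges::reduce(as_iranges0(x)),
                           IRanges::reduce(as_iranges0(y)))
  if (length(ir) == 0) return(interval_set())
  from_iranges0(ir)
}

#' bp of overlap between two interval sets
#' @param x,y `interval_set`s.
#' @return Numeric bp count of the intersection.
#' @export
interval_overlap_bp <- function(x, y) {
  interval_total_bp(interval_intersect(x, y))
}
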