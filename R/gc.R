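#' Cumulative GC profile of a DNA sequence
#'
#' One linear pass over the bases builds cumulative G+C counts, after which
#' any interval's GC content is an O(1) lookup. Non-ACGT characters count as
#' non-GC; if they exceed 10% of the sequence a warning is raised.
#'
#' @param x A DNA character string, a `sim_seq`, or a
#'   `Biostrings::DNAString`.
#' @return An object of class `gc_profile`: list with `cum` (integer vector
#'   of length n+1), `length`, `ambiguous` (non-ACGT count) and `id`.
#' @examples
#' p <- gc_profile("ACGTGGCC")
#' gc_fraction(p, 0, 4)
#' @export
gc_profile <- function(x) {
  id <- "seq"
  if (inherits(x, "sim_seq")) { id <- x$id; x <- x$bases }
  if (inherits(x, "gc_profile")) return(x)
  if (!is.character(x)) x <- as.character(x)   # DNAString etc.
  stopifnot(length(x) == 1, nchar(x) >= 1)
  p <- cpp_gc_profile(x)
  p$id <- id
  class(p) <- "gc_profile"
  if (p$ambiguous > 0.1 * p$length)
    warning(sprintf("%d of %d bases (%.1f%%) are not A/C/G/T; counted as non-GC",
                    p$ambiguous, p$length, 100 * p$ambiguous / p$length))
  p
}

#' @export
print.gc_profile <- function(x, ...) {
  cat(sprintf("GC profile of %s: %s bp, overall GC %.4f (%d ambiguous)\n",
              x$id, format(x$length, big.mark = ","),
              x$cum[x$length + 1] / x$length, x$ambiguous))
  invisible(x)
}

#' GC fraction of an interval
#'
#' Returns `(#G + #C) / (end - start)` over the 0-based half-open interval
#' `[start, end)`. Pass a [gc_profile()] to make repeated queries O(1).
#'
#' @param x A DNA string, `sim_seq`, or `gc_profile`.
#' @param start,end Interval bounds, 0-based half-open. Defaults to the whole
#'   sequence.
#' @return GC fraction in \[0, 1\].
#' @examples
#' gc_fraction("GGCC")
#' gc_fraction("ATAT")
#' @export
gc_fraction <- function(x, start = 0, end = NULL) {
  p <- gc_profile(x)
  if (is.null(end)) end <- p$length
  if (start < 0 || end > p$length || start >= end)
    stop("need 0 <= start < end <= sequence length")
  (p$cum[end + 1] - p$cum[start + 1]) / (end - start)
}
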