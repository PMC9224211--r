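#' Window-classify-merge segmentation
#'
#' The fixed-window segmenter: partition the sequence into non-overlapping
#' windows (100 kb by default; the trailing window may be shorter), compute
#' each window's GC content, classify it into one of the five isochore
#' families ([classify_family()]), and merge maximal runs of same-family
#' windows into single segments whose `mean_gc` is the GC of the merged
#' interval. Compositional variation *within* a window is ignored by
#' construction, and no predicted segment can be shorter than one window.
#'
#' @param x A DNA character string, `sim_seq`, `Biostrings::DNAString`, or
#'   [gc_profile()].
#' @param window Window size in bp (default 100,000).
#' @return A [new_segmentation()] object with family labels; consecutive
#'   segments never share a family.
#' @examples
#' set.seed(1)
#' d <- make_equal_length_domains(3e5, 3)
#' segment_windowmerge(synthesize_sequence(d), window = 1e5)
#' @export
segment_windowmerge <- function(x, window = 1e5) {
  stopifnot(window >= 1)
  p <- gc_profile(x)
  L <- p$length
  starts <- seq(0, L - 1, by = window)
  ends <- pmin(starts + window, L)
  wgc <- (p$cum[ends + 1] - p$cum[starts + 1]) / (ends - starts)
  fam <- classify_family(wgc)
  r <- rle(fam)
  last <- cumsum(r$lengths)
  first <- c(1, head(last, -1) + 1)
  seg_start <- starts[first]
  seg_end <- ends[last]
  seg_gc <- (p$cum[seg_end + 1] - p$cum[seg_start + 1]) / (seg_end - seg_start)
  new_segmentation(p$id, L,
                   data.frame(start = seg_start, end = seg_end,
                              mean_gc = seg_gc, family = r$values,
                              stringsAsFactors = FALSE),
                   algorithm = "windowmerge")
}
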