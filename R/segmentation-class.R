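#' Construct a segmentation object
#'
#' A segmentation is an algorithm's output on one sequence: an ordered set of
#' segments tiling `[0, sequence_length)`, each carrying its observed mean GC
#' and, for the window-merge algorithm, an isochore family label.
#'
#' @param sequence_id Sequence identifier.
#' @param sequence_length Sequence length in bp.
#' @param segments Data frame with columns `start`, `end`, `mean_gc` and
#'   optionally `family` (NA where the algorithm assigns none).
#' @param algorithm Label of the producing algorithm.
#' @return An object of class `segmentation`.
#' @export
new_segmentation <- function(sequence_id, sequence_length, segments, algorithm) {
  if (is.null(segments$family)) segments$family <- NA_character_
  segments <- segments[c("start", "end", "mean_gc", "family")]
  stopifnot(nrow(segments) >= 1, segments$start[1] == 0,
            segments$end[nrow(segments)] == sequence_length,
            all(segments$end > segments$start))
  if (nrow(segments) > 1)
    stopifnot(all(segments$start[-1] == segments$end[-nrow(segments)]))
  structure(list(sequence_id = sequence_id,
                 sequence_length = sequence_length,
                 segments = segments, algorithm = algorithm),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("Segmentation of %s (%s bp) by '%s': %d segment(s)\n",
              x$sequence_id, format(x$sequence_length, big.mark = ","),
              x$algorithm, nrow(x$segments)))
  print(head(x$segments, 10), row.names = FALSE)
  if (nrow(x$segments) > 10) cat("  ...", nrow(x$segments) - 10, "more\n")
  invisible(x)
}

#' @export
summary.segmentation <- function(object, ...) {
  len <- object$segments$end - object$segments$start
  out <- list(sequence_id = object$sequence_id, algorithm = object$algorithm,
              n_segments = nrow(object$segments),
              mean_length = mean(len), median_length = median(len),
              gc_range = range(object$segments$mean_gc))
  class(out) <- "summary.segmentation"
  out
}

#' @export
print.summary.segmentation <- function(x, ...) {
  cat(sprintf("%s on %s: %d segments, mean length %s bp, GC %.3f-%.3f\n",
              x$algorithm, x$sequence_id, x$n_segments,
              format(round(x$mean_length), big.mark = ","),
              x$gc_range[1], x$gc_range[2]))
  invisible(x)
}

#' @export
as.data.frame.segmentation <- function(x, ...) {
  cbind(sequence_id = x$sequence_id, x$segments,
        algorithm = x$algorithm, stringsAsFactors = FALSE)
}

#' Plot a segmentation's GC profile
#'
#' Step plot of each segment's mean GC against position, with the classical
#' family band boundaries as dashed lines.
#'
#' @param x A `segmentation`.
#' @param truth Optional ground-truth domain data frame to overlay (drawn in
#'   grey at its target GC).
#' @param ... Ignored.
#' @export
plot.segmentation <- function(x, truth = NULL, ...) {
  plot.new()
  plot.window(xlim = c(0, x$sequence_length), ylim = c(0.25, 0.7))
  axis(1); axis(2)
  title(main = sprintf("%s: %s", x$algorithm, x$sequence_id),
        xlab = "position (bp)", ylab = "GC fraction")
  abline(h = c(0.37, 0.41, 0.46, 0.53), lty = 3, col = "grey70")
  if (!is.null(truth))
    segments(truth$start, truth$target_gc, truth$end, truth$target_gc,
             col = "grey60", lwd = 4)
  segments(x$segments$start, x$segments$mean_gc,
           x$segments$end, x$segments$mean_gc, col = "firebrick", lwd = 2)
  invisible(x)
}
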