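#' Match predicted domains to ground truth under the boundary rule
#'
#' A truth domain is a candidate match for a predicted segment `p` of length
#' `Lp` iff both `|p.start - t.start|` and `|p.end - t.end|` are at most
#' `tolerance * Lp` (the tolerance is anchored to the *predicted* domain
#' size). Matching is one-to-one: predictions are processed in ascending
#' start order, each greedily taking the unmatched candidate with the
#' smallest total boundary discrepancy. Unmatched predictions are false
#' positives, unmatched truths false negatives.
#'
#' @param predicted A [new_segmentation()] object or a data frame with
#'   `start`/`end` columns.
#' @param truth Ground-truth domains: a data frame with `start`/`end` (e.g.
#'   a `sim_seq$domains`) or a `sim_seq`.
#' @param tolerance Boundary tolerance as a fraction of the predicted
#'   domain's length (default 0.05, the ±5% rule).
#' @return An object of class `match_outcome`: list with counts `tp`, `fp`,
#'   `fn` and `pairs`, a data frame of (pred_index, truth_index) matches.
#' @examples
#' truth <- data.frame(start = c(0, 500), end = c(500, 1000))
#' match_domains(truth, truth)   # identity: all matched
#' @export
match_domains <- function(predicted, truth, tolerance = 0.05) {
  stopifnot(tolerance > 0)
  pr <- as_intervals(predicted)
  tr <- as_intervals(truth)
  plen <- attr(pr, "seq_length"); tlen <- attr(tr, "seq_length")
  if (!is.null(plen) && !is.null(tlen) && plen != tlen)
    stop("predicted and truth refer to different sequence lengths (",
         plen, " vs ", tlen, ")")
  matched <- logical(nrow(tr))
  pi <- integer(0); ti <- integer(0)
  for (i in order(pr$start)) {
    tol <- tolerance * (pr$end[i] - pr$start[i])
    ds <- abs(tr$start - pr$start[i])
    de <- abs(tr$end - pr$end[i])
    cand <- which(!matched & ds <= tol & de <= tol)
    if (length(cand)) {
      j <- cand[which.min(ds[cand] + de[cand])]
      matched[j] <- TRUE
      pi <- c(pi, i); ti <- c(ti, j)
    }
  }
  structure(list(tp = length(pi), fp = nrow(pr) - length(pi),
                 fn = nrow(tr) - length(pi),
                 pairs = data.frame(pred_index = pi, truth_index = ti)),
            class = "match_outcome")
}

# normalize the accepted input shapes to a start/end data frame
as_intervals <- function(x) {
  if (inherits(x, "segmentation")) {
    out <- x$segments[c("start", "end")]
    attr(out, "seq_length") <- x$sequence_length
    return(out)
  }
  if (inherits(x, "sim_seq")) {
    out <- x$domains[c("start", "end")]
    attr(out, "seq_length") <- x$length
    return(out)
  }
  stopifnot(is.data.frame(x), all(c("start", "end") %in% names(x)))
  out <- x[c("start", "end")]
  if (x$start[1] == 0 && all(x$start[-1] == x$end[-nrow(x)]))
    attr(out, "seq_length") <- x$end[nrow(x)]
  out
}

#' @export
print.match_outcome <- function(x, ...) {
  cat(sprintf("Domain matching: TP %d, FP %d, FN %d\n", x$tp, x$fp, x$fn))
  invisible(x)
}

#' Sensitivity, precision and Jaccard index from match counts
#'
#' `sensitivity = TP/(TP+FN)`, `precision = TP/(TP+FP)` (defined as 0 when
#' there are no predictions) and `jaccard = TP/(TP+FP+FN)`.
#'
#' @param outcome A [match_domains()] result, or any list with `tp`, `fp`,
#'   `fn` counts.
#' @return Named list with `sensitivity`, `precision`, `jaccard`.
#' @examples
#' compute_metrics(list(tp = 2, fp = 5, fn = 4))
#' @export
compute_metrics <- function(outcome) {
  tp <- outcome$tp; fp <- outcome$fp; fn <- outcome$fn
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  if (tp + fn < 1) stop("no truth domains: metrics are undefined")
  list(sensitivity = tp / (tp + fn),
       precision = if (tp + fp == 0) 0 else tp / (tp + fp),
       jaccard = tp / (tp + fp + fn))
}

#' Score a segmentation against ground truth
#'
#' Convenience wrapper combining [match_domains()] and [compute_metrics()].
#'
#' @inheritParams match_domains
#' @return An object of class `score_report`: counts, metrics and the
#'   tolerance used.
#' @examples
#' s <- simulate_sequence("equal", 10, 1, sim_config(seed = 3))
#' score_segmentation(segment_windowmerge(s), s)
#' @export
score_segmentation <- function(predicted, truth, tolerance = 0.05) {
  m <- match_domains(predicted, truth, tolerance)
  out <- c(m[c("tp", "fp", "fn")], compute_metrics(m),
           list(pairs = m$pairs, tolerance = tolerance))
  class(out) <- "score_report"
  out
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d  (boundary tolerance %.0f%% of predicted length)\n",
              x$tp, x$fp, x$fn, 100 * x$tolerance))
  cat(sprintf("sensitivity %.4f  precision %.4f  Jaccard %.4f\n",
              x$sensitivity, x$precision, x$jaccard))
  invisible(x)
}
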