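#' Run the full segmentation benchmark
#'
#' Streams over the simulated corpus: each sequence is generated from its
#' seed substream, segmented with the requested algorithms, scored against
#' its ground truth with the ±5% boundary rule, and summarized as one row per
#' (sequence, algorithm). Sequences are discarded after scoring, so memory
#' stays flat at any corpus size.
#'
#' @param config A [sim_config()]. Use `replicates` (or `reduced`) to scale
#'   the corpus.
#' @param params [recursive_params()] for the recursive segmenter; defaults
#'   to the config's seed so one seed drives the whole study.
#' @param algorithms Which segmenters to run.
#' @param reduced Optional replicate count overriding `config$replicates`
#'   (desk-scale reproduction of the full study).
#' @param window Window size for the window-merge segmenter.
#' @param tolerance Boundary tolerance for scoring.
#' @param corpus_dir Optional directory; when given, every simulated sequence
#'   is also written to per-arm FASTA and ground-truth BED files as the run
#'   streams.
#' @param verbose Print one line per sequence.
#' @return Data frame with columns `sequence_id`, `arm`, `n_domains`,
#'   `true_mean_domain_length`, `algorithm`, `tp`, `fp`, `fn`,
#'   `sensitivity`, `precision`, `jaccard`, `n_predicted`,
#'   `mean_predicted_length`.
#' @examples
#' rows <- run_benchmark(sim_config(equal_divisions = 10,
#'                                  variable_partitions = 4, seed = 2),
#'                       reduced = 2, algorithms = "windowmerge")
#' rows[c("sequence_id", "tp", "fp", "fn", "sensitivity")]
#' @export
run_benchmark <- function(config = sim_config(),
                          params = recursive_params(seed = config$seed),
                          algorithms = c("windowmerge", "recursive"),
                          reduced = NULL, window = 1e5, tolerance = 0.05,
                          corpus_dir = NULL, verbose = FALSE) {
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  if (!is.null(reduced)) {
    stopifnot(reduced >= 1)
    config$replicates <- as.integer(reduced)
  }
  man <- benchmark_manifest(config)
  if (!is.null(corpus_dir)) {
    dir.create(corpus_dir, showWarnings = FALSE, recursive = TRUE)
    unlink(file.path(corpus_dir,
                     c("sequences_equal.fasta", "ground_truth_equal.bed",
                       "sequences_variable.fasta", "ground_truth_variable.bed")))
  }
  rows <- vector("list", nrow(man) * length(algorithms))
  k <- 0
  for (i in seq_len(nrow(man))) {
    s <- tryCatch(
      simulate_sequence(man$arm[i], man$n_domains[i], man$replicate[i], config),
      error = function(e) stop("while simulating ", man$id[i], ": ",
                               conditionMessage(e), call. = FALSE))
    if (!is.null(corpus_dir)) {
      write_fasta(s, file.path(corpus_dir,
                               sprintf("sequences_%s.fasta", man$arm[i])),
                  append = TRUE)
      write_bed(s, file.path(corpus_dir,
                             sprintf("ground_truth_%s.bed", man$arm[i])),
                append = TRUE)
    }
    p <- gc_profile(s)
    for (alg in algorithms) {
      seg <- tryCatch(
        if (alg == "windowmerge") segment_windowmerge(p, window = window)
        else segment_recursive(p, params = params),
        error = function(e) stop("while segmenting ", man$id[i], " with ",
                                 alg, ": ", conditionMessage(e), call. = FALSE))
      sc <- score_segmentation(seg, s$domains, tolerance)
      n_pred <- nrow(seg$segments)
      k <- k + 1
      rows[[k]] <- data.frame(
        sequence_id = s$id, arm = man$arm[i], n_domains = man$n_domains[i],
        true_mean_domain_length = man$length[i] / man$n_domains[i],
        algorithm = alg, tp = sc$tp, fp = sc$fp, fn = sc$fn,
        sensitivity = sc$sensitivity, precision = sc$precision,
        jaccard = sc$jaccard, n_predicted = n_pred,
        mean_predicted_length = man$length[i] / n_pred,
        stringsAsFactors = FALSE)
      if (verbose)
        message(sprintf("%s %s: %d segments, sens %.3f", s$id, alg, n_pred,
                        sc$sensitivity))
    }
  }
  do.call(rbind, rows[seq_len(k)])
}

#' Pooled benchmark summary with rank-sum comparisons
#'
#' Pools all per-sequence metric values of both arms and reports, per
#' algorithm, the mean and median of sensitivity, precision and Jaccard
#' index, plus -- when both algorithms are present -- the two-sample Wilcoxon
#' rank-sum p-value per metric (unpaired, normal approximation with
#' continuity correction).
#'
#' @param rows Output of [run_benchmark()].
#' @return An object of class `benchmark_summary`: a data frame `table` with
#'   one row per metric and the per-algorithm mean/median columns plus
#'   `p_value`.
#' @export
summarize_benchmark <- function(rows) {
  stopifnot(nrow(rows) >= 1)
  algs <- unique(rows$algorithm)
  metrics <- c("sensitivity", "precision", "jaccard")
  tab <- data.frame(metric = metrics, stringsAsFactors = FALSE)
  for (a in algs) {
    v <- rows[rows$algorithm == a, metrics, drop = FALSE]
    tab[[paste0("mean_", a)]] <- vapply(v, mean, numeric(1))
    tab[[paste0("median_", a)]] <- vapply(v, median, numeric(1))
  }
  if (length(algs) == 2) {
    tab$p_value <- vapply(metrics, function(m) {
      x <- rows[rows$algorithm == algs[1], m]
      y <- rows[rows$algorithm == algs[2], m]
      if (length(unique(c(x, y))) == 1) return(1)  # all tied: no difference
      suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    }, numeric(1))
  }
  structure(list(table = tab, algorithms = algs,
                 n = c(table(rows$algorithm))),
            class = "benchmark_summary")
}

#' @export
print.benchmark_summary <- function(x, ...) {
  cat("Pooled benchmark summary (", paste(x$n, names(x$n), collapse = ", "),
      " rows)\n", sep = "")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Predicted versus true domain lengths (equal-length arm)
#'
#' For every (domain count, algorithm) pair of the equal-length arm, the mean
#' over replicates of the per-sequence mean predicted domain length, next to
#' the true domain length. The window-merge segmenter can never emit a
#' segment shorter than one window, so its column is bounded below by the
#' window size however small the true domains are.
#'
#' @param rows Output of [run_benchmark()].
#' @return Data frame with `n_domains`, `true_length`, `algorithm`,
#'   `mean_predicted_length`.
#' @export
length_comparison <- function(rows) {
  eq <- rows[rows$arm == "equal", ]
  if (!nrow(eq)) stop("no equal-arm rows in input")
  out <- aggregate(mean_predicted_length ~ n_domains + algorithm, eq, mean)
  tl <- aggregate(true_mean_domain_length ~ n_domains + algorithm, eq, mean)
  out$true_length <- tl$true_mean_domain_length
  out[order(out$algorithm, out$n_domains),
      c("n_domains", "true_length", "algorithm", "mean_predicted_length")]
}
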