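#' Write sequences to FASTA
#'
#' One record per sequence, 60-column line wrap (via Biostrings).
#'
#' @param x Named character vector of DNA strings, or a `sim_seq`.
#' @param path Output file.
#' @param append Append to an existing file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, append = FALSE) {
  if (inherits(x, "sim_seq")) x <- setNames(x$bases, x$id)
  stopifnot(is.character(x), !is.null(names(x)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path,
                              append = append, width = 60L)
  invisible(path)
}

#' Read a FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write domains or a segmentation to BED
#'
#' Five columns, tab-separated, 0-based half-open: `chrom start end name
#' score`. For ground-truth domains `name` is the isochore family and
#' `score` the target GC; for a segmentation `name` is the family label (or
#' `.` where the algorithm assigns none) and `score` the observed mean GC.
#'
#' @param x A domain data frame (columns `start`, `end`, and `family` +
#'   `target_gc` or `mean_gc`), a `sim_seq`, or a `segmentation`.
#' @param path Output file.
#' @param chrom Chromosome/sequence name for plain data frames.
#' @param append Append to an existing file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, chrom = NULL, append = FALSE) {
  if (inherits(x, "sim_seq")) {
    chrom <- x$id; x <- x$domains
  } else if (inherits(x, "segmentation")) {
    chrom <- x$sequence_id; x <- x$segments
  }
  if (is.null(chrom)) chrom <- "seq"
  name <- if (!is.null(x$family)) ifelse(is.na(x$family), ".", x$family) else "."
  score <- if (!is.null(x$target_gc)) x$target_gc else x$mean_gc
  df <- data.frame(chrom = chrom,
                   start = format(x$start, scientific = FALSE, trim = TRUE),
                   end = format(x$end, scientific = FALSE, trim = TRUE),
                   name = name, score = sprintf("%.6f", score))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE, append = append)
  invisible(path)
}

#' Read a 5-column BED file
#'
#' @param path BED file as written by [write_bed()].
#' @return Data frame with `chrom`, `start`, `end`, `name`, `score`.
#' @export
read_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "name", "score"),
                   colClasses = c("character", "numeric", "numeric",
                                  "character", "numeric"))
  df
}
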