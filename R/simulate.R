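#' Power-law quantile function
#'
#' Inverse CDF of the continuous power law with density proportional to
#' `x^-alpha` for `x >= xmin`: `Q(u) = xmin * (1 - u)^(-1/(alpha - 1))`.
#'
#' @param u Probabilities in \[0, 1).
#' @param alpha Exponent magnitude (> 1).
#' @param xmin Lower cutoff (>= 1).
#' @return Numeric vector of quantiles (continuous, not rounded).
#' @export
qpowerlaw <- function(u, alpha = 2.55, xmin = 10000) {
  if (alpha <= 1) stop("alpha must exceed 1 (the power law is not normalizable)")
  if (xmin < 1) stop("xmin must be >= 1")
  if (any(u < 0 | u >= 1)) stop("u must lie in [0, 1)")
  xmin * (1 - u)^(-1 / (alpha - 1))
}

#' Sample power-law distributed domain lengths
#'
#' Draws `n` lengths by inverse-CDF sampling from the power law with exponent
#' magnitude `alpha` and cutoff `xmin`, rounded to integer base pairs. Every
#' draw is at least `xmin`.
#'
#' @inheritParams qpowerlaw
#' @param n Number of draws.
#' @return Numeric vector of `n` integer lengths (bp).
#' @examples
#' set.seed(1)
#' summary(sample_powerlaw_lengths(1000))
#' @export
sample_powerlaw_lengths <- function(n, alpha = 2.55, xmin = 10000) {
  stopifnot(n >= 1)
  round(qpowerlaw(runif(n), alpha, xmin))
}

#' Build equal-length ground-truth domains
#'
#' Tiles `[0, total_length)` with `n_domains` equal-length domains (the last
#' domain absorbs any rounding residual). Each domain is assigned an isochore
#' family by weight, adjacent domains always to different families, and a
#' target GC drawn uniformly within the family's band.
#'
#' @param total_length Sequence length in bp.
#' @param n_domains Number of domains (>= 1).
#' @param families Family table from [isochore_families()].
#' @return Data frame with columns `start`, `end`, `family`, `target_gc`
#'   (0-based, half-open coordinates).
#' @examples
#' set.seed(1)
#' make_equal_length_domains(1e6, 10)
#' @export
make_equal_length_domains <- function(total_length, n_domains,
                                      families = isochore_families()) {
  stopifnot(n_domains >= 1)
  if (n_domains > total_length) stop("n_domains exceeds total_length")
  len <- floor(total_length / n_domains)
  starts <- (seq_len(n_domains) - 1) * len
  ends <- starts + len
  ends[n_domains] <- total_length
  finish_domains(starts, ends, families)
}

#' Build variable-length ground-truth domains from a power law
#'
#' Draws `n_domains` power-law lengths, rescales them to sum to
#' `total_length`, rounds, and pushes the rounding residual into the longest
#' domain. If normalization leaves any domain below `floor_len` the whole
#' length vector is resampled (up to `max_retries` times). Family assignment
#' and target GC as in [make_equal_length_domains()].
#'
#' @inheritParams make_equal_length_domains
#' @param alpha,xmin Power-law parameters (see [qpowerlaw()]).
#' @param floor_len Minimum post-normalization domain length in bp.
#' @param max_retries Resampling attempts before giving up.
#' @return Data frame with columns `start`, `end`, `family`, `target_gc`.
#' @examples
#' set.seed(1)
#' d <- make_variable_length_domains(5e6, 10)
#' sum(d$end - d$start)
#' @export
make_variable_length_domains <- function(total_length, n_domains,
                                         alpha = 2.55, xmin = 10000,
                                         families = isochore_families(),
                                         floor_len = 1000, max_retries = 100) {
  stopifnot(n_domains >= 2)
  if (total_length < n_domains * floor_len)
    stop("total_length too small for n_domains domains of >= floor_len bp")
  for (try in seq_len(max_retries)) {
    raw <- sample_powerlaw_lengths(n_domains, alpha, xmin)
    len <- normalize_lengths(raw, total_length)
    if (all(len >= floor_len)) {
      ends <- cumsum(len)
      starts <- c(0, ends[-n_domains])
      return(finish_domains(starts, ends, families))
    }
  }
  stop("could not draw a length vector with all domains >= ", floor_len,
       " bp in ", max_retries, " attempts")
}

# rescale raw lengths to sum exactly to total; residual to the longest domain
normalize_lengths <- function(raw, total) {
  len <- round(raw * total / sum(raw))
  len[which.max(len)] <- len[which.max(len)] + (total - sum(len))
  len
}

# attach family + target GC to a set of tiling intervals
finish_domains <- function(starts, ends, families) {
  k <- length(starts)
  fam <- sample_family_run(k, families)
  idx <- match(fam, families$name)
  lo <- families$gc_low[idx]
  hi <- families$gc_high[idx]
  data.frame(start = starts, end = ends, family = fam,
             target_gc = lo + runif(k) * (hi - lo),
             stringsAsFactors = FALSE)
}

#' Synthesize DNA bases for a set of domains
#'
#' In `exact` mode (default) each domain receives exactly
#' `round(target_gc * length)` G+C bases, split as evenly as possible between
#' G and C (remainder to G), the remainder between A and T (remainder to A),
#' with positions uniformly shuffled -- so the realized domain GC equals the
#' target up to rounding. In `iid` mode each base is independently G or C
#' with probability `target_gc / 2` each.
#'
#' @param domains Domain data frame as from [make_equal_length_domains()]
#'   (must tile an interval starting at 0).
#' @param mode `"exact"` or `"iid"`.
#' @return A single character string of A/C/G/T of the domains' total length.
#' @examples
#' set.seed(1)
#' d <- data.frame(start = 0, end = 10, family = "H3", target_gc = 0.8)
#' synthesize_sequence(d)
#' @export
synthesize_sequence <- function(domains, mode = c("exact", "iid")) {
  mode <- match.arg(mode)
  check_tiling(domains)
  total <- domains$end[nrow(domains)]
  codes <- integer(total)                  # 1=A, 2=C, 3=G, 4=T
  for (i in seq_len(nrow(domains))) {
    len <- domains$end[i] - domains$start[i]
    t <- domains$target_gc[i]
    if (mode == "exact") {
      gc <- round(t * len)
      at <- len - gc
      v <- cpp_domain_codes(at - at %/% 2, gc %/% 2, gc - gc %/% 2, at %/% 2)
    } else {
      v <- sample.int(4L, len, replace = TRUE,
                      prob = c((1 - t) / 2, t / 2, t / 2, (1 - t) / 2))
    }
    codes[(domains$start[i] + 1):domains$end[i]] <- v
  }
  cpp_codes_to_dna(codes)
}

check_tiling <- function(domains) {
  stopifnot(nrow(domains) >= 1)
  if (domains$start[1] != 0) stop("domains must start at 0")
  if (any(domains$end <= domains$start)) stop("empty domain interval")
  if (nrow(domains) > 1 &&
      any(domains$start[-1] != domains$end[-nrow(domains)]))
    stop("domains must tile the sequence without gaps or overlaps")
  invisible(TRUE)
}

#' Simulation configuration
#'
#' Bundles the study conditions for the simulated benchmark: a 1 Mb
#' equal-length arm (domain counts 1, 2, 4, 5, 10, 20, 25, 40, 50, 80, 100)
#' and a 5 Mb variable-length arm (domain counts 2, 4, 6, 8, 10, 20, 30, 40,
#' 100; power-law lengths with exponent magnitude 2.55 and xmin 10,000 bp,
#' normalized to the sequence length), 100 replicates per setting.
#'
#' @param equal_length,variable_length Sequence lengths (bp) of the two arms.
#' @param equal_divisions,variable_partitions Domain counts per arm.
#' @param replicates Replicates per setting.
#' @param alpha,xmin Power-law parameters for the variable arm.
#' @param mode Base-synthesis mode, see [synthesize_sequence()].
#' @param seed Top-level seed; each sequence gets a substream derived from
#'   (seed, arm, n_domains, replicate) and is regenerable in isolation.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(equal_length = 1e6, variable_length = 5e6,
                       equal_divisions = c(1, 2, 4, 5, 10, 20, 25, 40, 50, 80, 100),
                       variable_partitions = c(2, 4, 6, 8, 10, 20, 30, 40, 100),
                       replicates = 100, alpha = 2.55, xmin = 10000,
                       mode = c("exact", "iid"), seed = 1) {
  mode <- match.arg(mode)
  stopifnot(replicates >= 1, alpha > 1, xmin >= 1,
            all(equal_divisions >= 1), all(variable_partitions >= 2))
  structure(list(equal_length = equal_length, variable_length = variable_length,
                 equal_divisions = as.numeric(equal_divisions),
                 variable_partitions = as.numeric(variable_partitions),
                 replicates = as.integer(replicates), alpha = alpha,
                 xmin = xmin, mode = mode, seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  equal arm:    %s bp x {%s} domains\n",
              format(x$equal_length, big.mark = ","),
              paste(x$equal_divisions, collapse = ", ")))
  cat(sprintf("  variable arm: %s bp x {%s} domains (alpha %.2f, xmin %s)\n",
              format(x$variable_length, big.mark = ","),
              paste(x$variable_partitions, collapse = ", "),
              x$alpha, format(x$xmin, big.mark = ",")))
  cat(sprintf("  replicates %d, mode %s, seed %d\n",
              x$replicates, x$mode, x$seed))
  invisible(x)
}

#' Enumerate the benchmark corpus without generating it
#'
#' @param config A [sim_config()].
#' @return Data frame with one row per planned sequence: `id`, `arm`,
#'   `n_domains`, `replicate`, `length`.
#' @examples
#' nrow(benchmark_manifest(sim_config()))
#' @export
benchmark_manifest <- function(config = sim_config()) {
  arm_grid <- function(arm, settings, len) {
    g <- expand.grid(replicate = seq_len(config$replicates),
                     n_domains = settings)
    data.frame(id = sprintf("sim_%s_%ddom_r%d", arm, g$n_domains, g$replicate),
               arm = rep_len(arm, nrow(g)), n_domains = g$n_domains,
               replicate = g$replicate, length = rep_len(len, nrow(g)),
               stringsAsFactors = FALSE)
  }
  rbind(arm_grid("equal", config$equal_divisions, config$equal_length),
        arm_grid("variable", config$variable_partitions, config$variable_length))
}

#' Simulate one benchmark sequence
#'
#' Regenerates any single sequence of the corpus from its coordinates
#' (arm, domain count, replicate) under the configuration's seed; the
#' caller's RNG state is left untouched.
#'
#' @param arm `"equal"` or `"variable"`.
#' @param n_domains Number of ground-truth domains.
#' @param replicate Replicate index (1-based).
#' @param config A [sim_config()].
#' @param families Family table from [isochore_families()].
#' @return An object of class `sim_seq`: list with `id`, `length`, `bases`
#'   (one character string) and `domains` (ground-truth data frame).
#' @examples
#' s <- simulate_sequence("equal", 10, 1, sim_config(seed = 7))
#' s
#' @export
simulate_sequence <- function(arm = c("equal", "variable"), n_domains,
                              replicate = 1, config = sim_config(),
                              families = isochore_families()) {
  arm <- match.arg(arm)
  seed <- mix_seed(config$seed, match(arm, c("equal", "variable")),
                   n_domains, replicate)
  with_seed(seed, {
    if (arm == "equal") {
      len <- config$equal_length
      domains <- make_equal_length_domains(len, n_domains, families)
    } else {
      len <- config$variable_length
      domains <- make_variable_length_domains(len, n_domains, config$alpha,
                                              config$xmin, families)
    }
    bases <- synthesize_sequence(domains, config$mode)
    structure(list(id = sprintf("sim_%s_%ddom_r%d", arm, n_domains, replicate),
                   length = len, bases = bases, domains = domains),
              class = "sim_seq")
  })
}

#' @export
print.sim_seq <- function(x, ...) {
  cat(sprintf("Simulated sequence %s: %s bp, %d domain(s)\n", x$id,
              format(x$length, big.mark = ","), nrow(x$domains)))
  cat(sprintf("  families: %s\n", paste(x$domains$family, collapse = " ")))
  invisible(x)
}

#' Generate the benchmark corpus
#'
#' Emits `replicates x |equal_divisions|` equal-arm sequences and
#' `replicates x |variable_partitions|` variable-arm sequences (1,100 and 900
#' at the default configuration). With `out_dir` the corpus is streamed to
#' disk as one FASTA and one ground-truth BED per arm; without it a list of
#' [simulate_sequence()] objects is returned (refused above ~200 Mb of bases
#' to avoid exhausting memory -- the full default corpus is ~5.6 Gb).
#'
#' @param config A [sim_config()].
#' @param out_dir Optional output directory.
#' @param families Family table from [isochore_families()].
#' @param verbose Print progress.
#' @return The manifest data frame (invisibly when writing to disk), or a
#'   named list of `sim_seq` objects.
#' @export
generate_benchmark <- function(config = sim_config(), out_dir = NULL,
                               families = isochore_families(), verbose = FALSE) {
  man <- benchmark_manifest(config)
  if (is.null(out_dir)) {
    if (sum(man$length) > 2e8)
      stop("corpus of ", format(sum(man$length), big.mark = ","),
           " bases is too large to hold in memory; supply out_dir")
    out <- vector("list", nrow(man))
    for (i in seq_len(nrow(man))) {
      out[[i]] <- simulate_sequence(man$arm[i], man$n_domains[i],
                                    man$replicate[i], config, families)
      if (verbose) message(man$id[i])
    }
    names(out) <- man$id
    return(out)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (arm in unique(man$arm)) {
    fa <- file.path(out_dir, paste0("sequences_", arm, ".fasta"))
    bed <- file.path(out_dir, paste0("ground_truth_", arm, ".bed"))
    unlink(c(fa, bed))
    rows <- which(man$arm == arm)
    for (i in rows) {
      s <- simulate_sequence(man$arm[i], man$n_domains[i], man$replicate[i],
                             config, families)
      write_fasta(setNames(s$bases, s$id), fa, append = TRUE)
      write_bed(s$domains, bed, chrom = s$id, append = TRUE)
      if (verbose) message(s$id)
    }
  }
  invisible(man)
}
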