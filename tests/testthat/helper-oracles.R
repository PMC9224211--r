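# Independent oracles used by the unit and property tests.

# window-classify-merge by direct string chopping + run-length encoding,
# independent of the cumulative-count implementation
bf_windowmerge <- function(bases, window) {
  L <- nchar(bases)
  starts <- seq(0, L - 1, by = window)
  ends <- pmin(starts + window, L)
  wgc <- mapply(function(s, e) {
    chars <- strsplit(substr(bases, s + 1, e), "")[[1]]
    mean(chars %in% c("G", "C", "g", "c"))
  }, starts, ends)
  fam <- classify_family(wgc)
  r <- rle(fam)
  last <- cumsum(r$lengths)
  first <- c(1, head(last, -1) + 1)
  data.frame(start = starts[first], end = ends[last], family = r$values,
             stringsAsFactors = FALSE)
}

# exhaustive maximum one-to-one boundary matching (count only)
bf_best_matching <- function(pred, truth, tol_frac = 0.05) {
  np <- nrow(pred)
  cand <- lapply(seq_len(np), function(i) {
    tol <- tol_frac * (pred$end[i] - pred$start[i])
    which(abs(truth$start - pred$start[i]) <= tol &
          abs(truth$end - pred$end[i]) <= tol)
  })
  rec <- function(i, used) {
    if (i > np) return(0L)
    m <- rec(i + 1L, used)
    for (j in cand[[i]])
      if (!(j %in% used)) m <- max(m, 1L + rec(i + 1L, c(used, j)))
    m
  }
  rec(1L, integer(0))
}

# random partition of [0, len) into k intervals
random_tiling <- function(len, k) {
  cuts <- if (k > 1) sort(sample(seq_len(len - 1), k - 1)) else integer(0)
  data.frame(start = c(0, cuts), end = c(cuts, len))
}

# constructed coordinates reproducing the schematic scoring example:
# six truth domains, seven predictions of which exactly two (D and E) have
# both boundaries inside the 5%-of-predicted-length tolerance
fig6_fixture <- function() {
  list(truth = data.frame(start = c(0, 200, 400, 500, 700, 900),
                          end = c(200, 400, 500, 700, 900, 1200)),
       pred = data.frame(start = c(0, 150, 330, 500, 700, 900, 1000),
                         end = c(150, 330, 500, 700, 900, 1000, 1200)))
}

# brute-force argmax of the Jensen-Shannon statistic over all admissible
# split offsets, via the exported vectorized divergence (independent of the
# compiled scan)
bf_best_split <- function(bases, min_len) {
  p <- gc_profile(bases)
  n <- p$length
  s <- min_len:(n - min_len)
  c1 <- p$cum[s + 1]
  c <- p$cum[n + 1]
  d <- js_divergence(c1, s, c - c1, n - s)
  list(position = s[which.max(d)], d_js = max(d))
}

# random DNA string with given GC probability
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
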