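test_that("Jensen-Shannon divergence matches hand-computed entropy values", {
  expect_equal(js_divergence(2, 4, 2, 4), 0)          # identical flanks
  expect_equal(js_divergence(4, 4, 0, 4), 1)          # all-GC vs all-AT
  # n = 8, c1 = 3/4, c2 = 1/4: H(1/2) - 1/2 H(3/4) - 1/2 H(1/4) = 1 - H(1/4)
  h14 <- -(1 / 4) * log2(1 / 4) - (3 / 4) * log2(3 / 4)
  expect_equal(js_divergence(3, 4, 1, 4), 1 - h14)
  # bounded in [0, 1]
  set.seed(31)
  for (i in 1:20) {
    n1 <- sample(1:50, 1); n2 <- sample(1:50, 1)
    v <- js_divergence(sample(0:n1, 1), n1, sample(0:n2, 1), n2)
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("best_split finds a hard change point and matches the brute-force argmax", {
  s <- paste0(strrep("GC", 5000), strrep("AT", 5000))  # 10 kb GC | 10 kb AT
  bs <- best_split(s, min_len = 1000)
  expect_equal(bs$position, 10000)

  set.seed(32)
  for (i in 1:6) {
    s <- random_dna(sample(4000:20000, 1), runif(1, 0.3, 0.6))
    bs <- best_split(s, min_len = 500)
    oracle <- bf_best_split(s, 500)
    expect_equal(bs$position, oracle$position)
    expect_equal(bs$d_js, oracle$d_js)
  }

  expect_null(best_split(random_dna(5000), min_len = 3000))  # < 2*min_len
})

test_that("the dynamic threshold is positive and shrinks with segment length", {
  p <- recursive_params(seed = 33)
  t1 <- dynamic_threshold(1e4, 0.5, p)
  t2 <- dynamic_threshold(1e6, 0.5, p)
  expect_gt(t1, 0)
  expect_gt(t2, 0)
  expect_lt(t2, t1)
  # cached: second call is exact-identical
  expect_identical(dynamic_threshold(1e4, 0.5, p), t1)
})

test_that("threshold calibration is self-consistent: false-split rate near q", {
  p <- recursive_params(seed = 34)
  thr <- dynamic_threshold(1e5, 0.45, p)
  set.seed(99)
  fresh <- isobench:::cpp_null_max_js(100000L, 0.45, 500L, p$min_len,
                                      isobench:::get_xlog2x(1e5))
  rate <- mean(fresh > thr)
  expect_lt(abs(rate - p$q), 3 * sqrt(p$q * (1 - p$q) / 500))
})

test_that("homogeneous sequences are rarely split; a strong boundary is localized", {
  p <- recursive_params(seed = 35)
  cfg_dom <- function(gc) data.frame(start = 0, end = 1e6, family = "H2",
                                     target_gc = gc)
  set.seed(36)
  single <- 0L
  runs <- 40
  for (i in seq_len(runs)) {
    seg <- segment_recursive(synthesize_sequence(cfg_dom(0.5)), p)
    if (nrow(seg$segments) == 1) single <- single + 1L
  }
  # per-sequence false-split rate <= q + 3 * MC sigma
  expect_gte(single / runs, 1 - p$q - 3 * sqrt(p$q * (1 - p$q) / runs))

  # two 500-kb domains at GC 0.35 / 0.55: boundary within 5% of 500 kb
  d2 <- data.frame(start = c(0, 5e5), end = c(5e5, 1e6),
                   family = c("L1", "H3"), target_gc = c(0.35, 0.55))
  set.seed(37)
  for (i in 1:3) {
    seg <- segment_recursive(synthesize_sequence(d2), p)
    expect_gte(nrow(seg$segments), 2)
    inner <- seg$segments$end[-nrow(seg$segments)]
    expect_lte(min(abs(inner - 5e5)), 0.05 * 5e5)
  }
})

test_that("recursive output always tiles the input exactly", {
  p <- recursive_params(seed = 38)
  set.seed(39)
  for (i in 1:5) {
    k <- sample(1:6, 1)
    d <- random_tiling(sample(c(2e4, 5e4, 1e5), 1), k)
    d$family <- "L2"; d$target_gc <- runif(k, 0.3, 0.6)
    s <- synthesize_sequence(d)
    seg <- segment_recursive(s, p)
    expect_equal(seg$segments$start[1], 0)
    expect_equal(seg$segments$end[nrow(seg$segments)], nchar(s))
    if (nrow(seg$segments) > 1)
      expect_equal(seg$segments$start[-1],
                   seg$segments$end[-nrow(seg$segments)])
    expect_true(all(seg$segments$end - seg$segments$start >= p$min_len))
  }

  # shorter than 2*min_len: emitted whole
  short <- segment_recursive(random_dna(4000), p)
  expect_equal(nrow(short$segments), 1)
})
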