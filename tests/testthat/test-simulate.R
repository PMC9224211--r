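test_that("equal-length domains tile the sequence with distinct adjacent families", {
  set.seed(1)
  d <- make_equal_length_domains(1e6, 10)
  expect_equal(nrow(d), 10)
  expect_equal(unique(d$end - d$start), 1e5)   # ten 100-kb domains
  expect_equal(d$start[1], 0)
  expect_equal(d$end[10], 1e6)

  d1 <- make_equal_length_domains(1e6, 1)
  expect_equal(nrow(d1), 1)
  expect_equal(c(d1$start, d1$end), c(0, 1e6))

  d100 <- make_equal_length_domains(1e6, 100)
  expect_equal(unique(d100$end - d100$start), 1e4)
  expect_true(all(d100$family[-1] != d100$family[-100]))  # all 99 junctions
  expect_true(all(d100$start[-1] == d100$end[-100]))

  # target GC always inside the assigned family's band
  fam <- isochore_families()
  idx <- match(d100$family, fam$name)
  expect_true(all(d100$target_gc >= fam$gc_low[idx] &
                  d100$target_gc < fam$gc_high[idx]))

  expect_error(make_equal_length_domains(5, 10), "exceeds")
})

test_that("power-law sampling matches the inverse CDF and recovers the exponent", {
  expect_equal(qpowerlaw(0, 2.55, 1e4), 1e4)                 # CDF inverse at 0
  expect_equal(qpowerlaw(0.5, 2.55, 1e4), 1e4 * 2^(1 / 1.55))
  expect_error(qpowerlaw(0.5, alpha = 1), "alpha")

  set.seed(7)
  x <- sample_powerlaw_lengths(1e4, 2.55, 1e4)
  expect_true(all(x >= 1e4))
  # Hill / maximum-likelihood exponent estimate
  ahat <- 1 + length(x) / sum(log(x / 1e4))
  expect_lt(abs(ahat - 2.55), 0.05)
})

test_that("variable-length domains are normalized to the exact total with a length floor", {
  expect_equal(isobench:::normalize_lengths(c(1e4, 3e4), 5e6),
               c(1250000, 3750000))                          # proportional scaling
  set.seed(11)
  for (k in c(2, 10, 100)) {
    d <- make_variable_length_domains(5e6, k)
    expect_equal(nrow(d), k)
    expect_equal(sum(d$end - d$start), 5e6)                  # exactly 5 Mb
    expect_true(all(d$end - d$start >= 1000))
    expect_equal(d$start[1], 0)
    expect_true(all(d$start[-1] == d$end[-k]))
    if (k > 1) expect_true(all(d$family[-1] != d$family[-k]))
  }
})

test_that("exact synthesis forces per-domain GC counts; iid mode is approximate", {
  d <- data.frame(start = 0, end = 10, family = "H3", target_gc = 0.8)
  set.seed(3)
  s <- synthesize_sequence(d)
  expect_equal(nchar(s), 10)
  expect_equal(sum(strsplit(s, "")[[1]] %in% c("G", "C")), 8)

  d0 <- data.frame(start = 0, end = 50, family = "L1", target_gc = 0)
  s0 <- synthesize_sequence(d0)
  expect_false(grepl("[GC]", s0))

  # multi-domain: each domain's realized GC equals round(target * len) / len
  set.seed(5)
  dm <- make_equal_length_domains(5e4, 5)
  sm <- synthesize_sequence(dm)
  p <- gc_profile(sm)
  for (i in 1:5) {
    len <- dm$end[i] - dm$start[i]
    expect_equal(gc_fraction(p, dm$start[i], dm$end[i]),
                 round(dm$target_gc[i] * len) / len)
  }

  set.seed(6)
  si <- synthesize_sequence(dm, mode = "iid")
  expect_equal(nchar(si), 5e4)
  expect_lt(abs(gc_fraction(si) - mean(dm$target_gc)), 0.05)

  expect_error(synthesize_sequence(data.frame(start = c(0, 20), end = c(10, 30),
                                              family = "L1", target_gc = 0.3)),
               "tile")
})

test_that("a window of varying sub-domains averages to the window-level GC", {
  # ten 10-kb sub-domains whose target GCs average 0.8: the 100-kb window
  # reads GC 0.8 even though no sub-domain has that composition
  gcs <- rep(c(0.75, 0.85), 5)
  d <- data.frame(start = seq(0, 9e4, 1e4), end = seq(1e4, 1e5, 1e4),
                  family = rep(c("H3", "H3"), 5), target_gc = gcs)
  set.seed(8)
  s <- synthesize_sequence(d)
  expect_equal(gc_fraction(s), 0.8)
})

test_that("the corpus manifest enumerates both arms and tiny corpora generate in memory", {
  man <- benchmark_manifest(sim_config())
  expect_equal(sum(man$arm == "equal"), 1100)
  expect_equal(sum(man$arm == "variable"), 900)
  expect_false(any(duplicated(man$id)))

  cfg <- sim_config(replicates = 2, equal_divisions = 1,
                    variable_partitions = numeric(0), seed = 4)
  seqs <- generate_benchmark(cfg)
  expect_length(seqs, 2)
  expect_named(seqs, c("sim_equal_1dom_r1", "sim_equal_1dom_r2"))
  expect_equal(nchar(seqs[[1]]$bases), 1e6)
})

test_that("sequences are reproducible from the seed and leave the caller's RNG alone", {
  cfg <- sim_config(seed = 9)
  a <- simulate_sequence("equal", 4, 2, cfg)
  b <- simulate_sequence("equal", 4, 2, cfg)
  expect_identical(a, b)
  expect_false(identical(a$bases,
                         simulate_sequence("equal", 4, 3, cfg)$bases))

  set.seed(123); r1 <- runif(3)
  set.seed(123); invisible(simulate_sequence("equal", 4, 2, cfg)); r2 <- runif(3)
  expect_identical(r1, r2)
})

test_that("FASTA and BED outputs are byte-identical across runs with the same seed", {
  cfg <- sim_config(replicates = 1, equal_divisions = 5,
                    variable_partitions = numeric(0), equal_length = 5e4,
                    seed = 13)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_benchmark(cfg, out_dir = d1)
  generate_benchmark(cfg, out_dir = d2)
  for (f in c("sequences_equal.fasta", "ground_truth_equal.bed")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # round trip
  fa <- read_fasta(file.path(d1, "sequences_equal.fasta"))
  expect_equal(unname(nchar(fa)), 5e4)
  expect_identical(names(fa), "sim_equal_5dom_r1")
  s <- simulate_sequence("equal", 5, 1, cfg)
  expect_identical(unname(fa), s$bases)
  bed <- read_bed(file.path(d1, "ground_truth_equal.bed"))
  expect_equal(bed$start, s$domains$start)
  expect_equal(bed$end, s$domains$end)
  expect_equal(bed$name, s$domains$family)
  expect_equal(bed$score, s$domains$target_gc, tolerance = 1e-5)
  # 60-column wrap
  lines <- readLines(file.path(d1, "sequences_equal.fasta"))
  expect_true(all(nchar(lines[!startsWith(lines, ">")]) <= 60))
})
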