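# Shared benchmark runs for the acceptance tests, computed once per session.
# Seed 20 fixed for the whole acceptance corpus; replicate counts are the
# desk-scale study sizes (20 per setting for the window-merge corpus, 10 for
# the recursive corpus).
acc_env <- new.env()

acc_wm_rows <- function() {
  if (is.null(acc_env$wm))
    acc_env$wm <- run_benchmark(sim_config(replicates = 20, seed = 20),
                                algorithms = "windowmerge")
  acc_env$wm
}

acc_rc_rows <- function() {
  if (is.null(acc_env$rc))
    acc_env$rc <- run_benchmark(sim_config(replicates = 10, seed = 20),
                                params = recursive_params(seed = 20),
                                algorithms = "recursive")
  acc_env$rc
}

# percentile bootstrap CI for a sample median
boot_median_ci <- function(x, n_boot = 2000, level = 0.99) {
  meds <- replicate(n_boot, median(sample(x, replace = TRUE)))
  quantile(meds, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
}
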