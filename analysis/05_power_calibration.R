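#!/usr/bin/env Rscript
# Stage 5: operating characteristics of the causal test.
#
# Monte-Carlo power and false-positive rates of the two-criterion rule on
# two-gene benchmarks (20 panels per condition, bootstrap depth 200):
#  - unidirectional coupling 0.32 at the 3-tree x 24-point design and the
#    6-tree x 36-point design (true and reverse direction), and
#  - no coupling with shared seasonal forcing (the seasonal-surrogate null).

library(seasonccm)

dir.create("results", showWarnings = FALSE)
two_gene <- function(s, coupling = 0.32, amp = 0, ni = 3, ny = 2) {
  cpl <- matrix(0, 2, 2, dimnames = list(c("X", "Y"), c("X", "Y")))
  cpl["Y", "X"] <- coupling
  simulate_panel(network_spec(c("X", "Y"), cpl, growth_rates = c(3.8, 3.7),
                              seasonal_amplitude = amp, noise_sd = 0.05,
                              n_individuals = ni, n_years = ny, seed = s))
}
cfg <- ccm_config(n_boot = 200, n_surrogates = 200, seed = 0)

run_condition <- function(label, seeds, ...) {
  calls <- t(vapply(seeds, function(s) {
    sim <- two_gene(s, ...)
    cfg$seed <- 5000L + s
    c(test_causality(sim$panel, "Y", "X", cfg)$causal,
      test_causality(sim$panel, "X", "Y", cfg)$causal)
  }, logical(2)))
  message(sprintf("%-38s true-direction calls %2.0f%%, reverse %2.0f%%",
                  label, 100 * mean(calls[, 1]), 100 * mean(calls[, 2])))
  list(true_pct = 100 * mean(calls[, 1]), reverse_pct = 100 * mean(calls[, 2]),
       n_seeds = length(seeds))
}

out <- list(
  coupled_3trees_24pts = run_condition("coupling 0.32, 3 trees x 24 pts:", 1:20),
  coupled_6trees_36pts = run_condition("coupling 0.32, 6 trees x 36 pts:", 1:20,
                                       ni = 6, ny = 3),
  seasonal_null_3trees = run_condition("coupling 0, shared seasonality:", 21:40,
                                       coupling = 0, amp = 0.5))
jsonlite::write_json(out, "results/power_calibration.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
message("wrote results/power_calibration.json")
message("note: at 24 points per tree the two-criterion rule is conservative;")
message("power rises with series length (see the methods vignette).")
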