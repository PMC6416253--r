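masked_series <- function(seed, n_years = 3) {
  sim <- two_gene_panel(seed, n_years = n_years)
  panel_series(sim$panel, "Y")
}

test_that("phase randomization preserves the amplitude spectrum exactly", {
  set.seed(4)
  x <- rnorm(36)
  s <- phase_randomize(x, 20)
  a0 <- Mod(fft(x))
  for (j in 1:20) {
    expect_equal(Mod(fft(s[, j])), a0, tolerance = 1e-9)
  }
  expect_equal(colMeans(s), rep(mean(x), 20), tolerance = 1e-9)
})

test_that("a purely seasonal series is its own surrogate", {
  ser <- masked_series(1)
  # replace values by a function of calendar month only
  v <- sin(2 * pi * ser$month / 12)
  v[ser$month %in% c(11, 12, 1:5)] <- 0
  s <- seasonal_surrogate(v, ser$month, ser$segment, n = 10, seed = 1)
  for (j in 1:10) expect_equal(s[, j], v, tolerance = 1e-12)
})

test_that("surrogates preserve per-month means and the residual spectrum", {
  ser <- masked_series(2)
  s <- seasonal_surrogate(ser$values, ser$month, ser$segment, n = 50, seed = 7)
  for (seg in unique(ser$segment)) {
    idx <- which(ser$segment == seg & ser$month %in% 6:10)
    profile <- ave(ser$values[idx], ser$month[idx])
    amp0 <- Mod(fft(ser$values[idx] - profile))
    for (j in c(1, 17, 50)) {
      prof_j <- ave(s[idx, j], ser$month[idx])
      expect_equal(prof_j, profile, tolerance = 1e-9)
      expect_equal(Mod(fft(s[idx, j] - prof_j)), amp0, tolerance = 1e-9)
    }
  }
})

test_that("masked positions stay exactly zero in every surrogate", {
  ser <- masked_series(3)
  s <- seasonal_surrogate(ser$values, ser$month, ser$segment, n = 30, seed = 2)
  winter <- ser$month %in% c(11, 12, 1:5)
  expect_true(all(s[winter, ] == 0))
})

test_that("surrogates destroy dependence on the coupled partner", {
  sim <- two_gene_panel(5, coupling = 0.5, noise_sd = 0)
  cs <- panel_series(sim$panel, "Y")
  es <- panel_series(sim$panel, "X")
  grow <- cs$month %in% 6:10
  # residualize the effect on its own monthly profile: the surrogate keeps
  # the cause's profile by construction, so only the residual dependence
  # can and must be destroyed
  eff_resid <- es$values[grow] -
    ave(es$values[grow], paste(es$segment[grow], es$month[grow]))
  orig_cor <- abs(cor(cs$values[grow], eff_resid))
  s <- seasonal_surrogate(cs$values, cs$month, cs$segment, n = 200, seed = 3)
  cors <- apply(s[grow, ], 2, cor, y = eff_resid)
  expect_lt(abs(mean(cors)), 0.1)
  expect_lt(mean(abs(cors)), max(orig_cor, 0.25))
})

test_that("surrogate generation is reproducible and validated", {
  ser <- masked_series(6)
  a <- seasonal_surrogate(ser$values, ser$month, ser$segment, n = 5, seed = 9)
  b <- seasonal_surrogate(ser$values, ser$month, ser$segment, n = 5, seed = 9)
  expect_identical(a, b)
  drop <- which(ser$month == 6)[1]  # lose one growing-season June
  expect_error(
    seasonal_surrogate(ser$values[-drop], ser$month[-drop],
                       ser$segment[-drop], n = 2, seed = 1),
    "whole years|unbalanced")
})

test_that("surrogate skill distribution has the requested size and calibration", {
  sim <- two_gene_panel(4)
  ens <- surrogate_rho_distribution(sim$panel, "Y", "X", E = 2,
                                    n_surrogates = 40, seed = 5,
                                    n_boot_per_surrogate = 20)
  expect_length(ens$rho_surr_samples, 40)
  expect_true(all(abs(ens$rho_surr_samples) <= 1))
  # full-library mode also works and is deterministic
  e2 <- surrogate_rho_distribution(sim$panel, "Y", "X", E = 2,
                                   n_surrogates = 40, seed = 5,
                                   library = "full")
  e3 <- surrogate_rho_distribution(sim$panel, "Y", "X", E = 2,
                                   n_surrogates = 40, seed = 5,
                                   library = "full")
  expect_identical(e2$rho_surr_samples, e3$rho_surr_samples)
})

test_that("independent seasonal genes sit inside the surrogate null", {
  hits <- vapply(1:10, function(s) {
    sim <- two_gene_panel(s, coupling = 0, seasonal_amplitude = 0.5)
    ens <- surrogate_rho_distribution(sim$panel, "Y", "X", E = 2,
                                      n_surrogates = 60, seed = 100 + s,
                                      n_boot_per_surrogate = 30)
    obs <- ens$rho_observed
    q <- quantile(ens$rho_surr_samples, c(0.025, 0.975))
    obs >= q[1] && obs <= q[2]
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
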