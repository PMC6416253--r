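test_that("delay embedding matches its definition and counts", {
  emb <- embed_series(c(1, 2, 3, 4, 5), E = 2, tau = 1)
  expect_equal(nrow(emb$vectors), 4)
  expect_equal(emb$vectors, cbind(c(2, 3, 4, 5), c(1, 2, 3, 4)))
  # E = 1 reproduces the series
  emb1 <- embed_series(c(3, 1, 4), E = 1)
  expect_equal(drop(emb1$vectors), c(3, 1, 4))
  # two segments never mix
  seg <- rep(1:2, each = 5)
  emb2 <- embed_series(rep(1:5, 2), seg, E = 3)
  expect_equal(nrow(emb2$vectors), 6)
  expect_true(all(table(emb2$segment) == 3))
  expect_error(embed_series(1:3, E = 5), "too short")
})

test_that("vector counts match the closed form on a property grid", {
  set.seed(11)
  for (case in 1:25) {
    n_seg <- sample(1:4, 1)
    lens <- sample(3:30, n_seg, replace = TRUE)
    E <- sample(1:5, 1)
    tau <- sample(1:3, 1)
    expected <- brute_embed_count(lens, E, tau)
    expect_equal(embedding_vector_count(lens, E, tau), expected)
    if (expected > 0) {
      values <- rnorm(sum(lens))
      seg <- rep(seq_len(n_seg), lens)
      emb <- embed_series(values, seg, E = E, tau = tau)
      expect_equal(nrow(emb$vectors), expected)
    }
  }
})

test_that("simplex projection equals an exhaustive brute-force oracle", {
  for (s in 1:5) {
    set.seed(s)
    x <- rnorm(30 + s)
    for (E in c(2, 3)) {
      fc <- simplex_forecast(x, E = E)
      oracle <- brute_simplex(x, E = E)
      expect_equal(fc$predictions$predicted, oracle$predicted,
                   tolerance = 1e-12)
      expect_equal(fc$rho, oracle$rho, tolerance = 1e-12)
    }
  }
  # also across a segment boundary
  set.seed(99)
  x <- rnorm(40)
  seg <- rep(1:2, each = 20)
  fc <- simplex_forecast(x, seg, E = 2)
  oracle <- brute_simplex(x, seg, E = 2)
  expect_equal(fc$rho, oracle$rho, tolerance = 1e-12)
})

test_that("deterministic chaos is one-step predictable, noise is not", {
  x <- logistic_series(100)
  expect_gt(simplex_forecast(x, E = 2)$rho, 0.95)
  rhos <- vapply(1:20, function(s) {
    set.seed(s)
    simplex_forecast(rnorm(100), E = 2)$rho
  }, numeric(1))
  expect_lt(abs(median(rhos)), 0.3)
})

test_that("forecast skill is invariant to affine rescaling", {
  set.seed(3)
  x <- rnorm(60)
  r1 <- simplex_forecast(x, E = 3)$rho
  r2 <- simplex_forecast(5 - 2.7 * x, E = 3)$rho
  expect_equal(r1, r2, tolerance = 1e-9)
})

test_that("embedding dimension selection behaves on known systems", {
  expect_equal(as.integer(select_embedding_dimension(rnorm(30), E_range = 3)), 3)
  # planar limit cycle: monthly-sampled sine
  sine <- sin(2 * pi * (1:200) / 12)  + 0.01 * sin(1:200)
  E_sine <- as.integer(select_embedding_dimension(sine, E_range = 1:6))
  expect_true(E_sine %in% 2:3)
  # 2-species coupled logistic attractor is ~2-dimensional
  set.seed(8)
  n <- 200
  x <- numeric(n); y <- numeric(n); x[1] <- 0.4; y[1] <- 0.6
  for (t in 1:(n - 1)) {
    y[t + 1] <- y[t] * (3.7 - 3.7 * y[t])
    x[t + 1] <- x[t] * (3.8 - 3.8 * x[t] - 0.32 * y[t])
  }
  E_cl <- as.integer(select_embedding_dimension(x, E_range = 1:6))
  expect_true(E_cl %in% 2:3)
  expect_error(select_embedding_dimension(rnorm(30), E_range = 11), "1, 10")
})

test_that("S-map with theta grid {0} has zero skill gain by definition", {
  set.seed(2)
  res <- smap_nonlinearity_test(rnorm(50), E = 2, theta_grid = 0,
                                n_surrogate = 5, seed = 1)
  expect_identical(res$delta_rho, 0)
  expect_false(res$nonlinear)
})

test_that("S-map nonlinearity test separates linear from chaotic series", {
  grid <- c(0, 0.3, 1, 3)
  verdict <- function(x, seed) {
    smap_nonlinearity_test(x, E = 2, theta_grid = grid, n_surrogate = 30,
                           seed = seed)$nonlinear
  }
  linear_calls <- vapply(1:10, function(s) {
    set.seed(s)
    verdict(as.numeric(arima.sim(list(ar = 0.6), 200)), seed = 100 + s)
  }, logical(1))
  expect_gte(sum(!linear_calls), 9)
  chaotic_calls <- vapply(1:10, function(s) {
    verdict(logistic_series(200, x0 = 0.1 + 0.03 * s), seed = 200 + s)
  }, logical(1))
  expect_gte(sum(chaotic_calls), 9)
})
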