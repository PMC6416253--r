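# Independent brute-force oracles and small simulation helpers.
# These deliberately re-derive everything from definitions with plain loops,
# sharing no code path with the package internals they check.

# Exhaustive simplex projection: for each target time build the lag vector by
# hand, scan every candidate neighbor, sort all distances, take the E+1
# nearest, weight exp(-d/d1), predict the future tp steps ahead.
brute_simplex <- function(values, segment = NULL, E, tau = 1, tp = 1,
                          theiler = 1) {
  if (is.null(segment)) segment <- rep(1, length(values))
  lagvec <- function(i) {
    idx <- i - (0:(E - 1)) * tau
    if (any(idx < 1) || length(unique(segment[idx])) > 1) return(NULL)
    values[idx]
  }
  n <- length(values)
  heads <- which(vapply(seq_len(n), function(i) !is.null(lagvec(i)), logical(1)))
  # within-segment time index of each point
  tin <- stats::ave(seq_len(n), segment, FUN = seq_along)
  pred <- obs <- c()
  for (i in heads) {
    if (i + tp > n || segment[i + tp] != segment[i]) next
    vi <- lagvec(i)
    cand <- c(); d <- c()
    for (j in heads) {
      if (j + tp > n || segment[j + tp] != segment[j]) next
      if (segment[j] == segment[i] && abs(tin[j] - tin[i]) <= theiler) next
      cand <- c(cand, j)
      d <- c(d, sqrt(sum((lagvec(j) - vi)^2)))
    }
    if (length(cand) < E + 1) next
    o <- order(d)
    nn <- cand[o[1:(E + 1)]]
    dn <- d[o[1:(E + 1)]]
    p <- if (dn[1] == 0) {
      mean(values[nn[dn == 0] + tp])
    } else {
      w <- exp(-dn / dn[1])
      sum(w * values[nn + tp]) / sum(w)
    }
    pred <- c(pred, p)
    obs <- c(obs, values[i + tp])
  }
  list(rho = stats::cor(pred, obs), predicted = pred, observed = obs)
}

# Direct count of valid delay vectors by enumeration.
brute_embed_count <- function(segment_lengths, E, tau = 1) {
  total <- 0L
  for (L in segment_lengths) {
    for (t in seq_len(L)) {
      if (t - (E - 1) * tau >= 1) total <- total + 1L
    }
  }
  total
}

# Two coupled logistic maps, Y driving X, in the chaotic regime (the
# standard cross-mapping benchmark), as a masked 2-gene panel.
two_gene_panel <- function(seed, coupling = 0.32, noise_sd = 0.05,
                           seasonal_amplitude = 0, n_individuals = 3,
                           n_years = 2) {
  cpl <- matrix(0, 2, 2, dimnames = list(c("X", "Y"), c("X", "Y")))
  cpl["Y", "X"] <- coupling
  spec <- network_spec(c("X", "Y"), cpl, growth_rates = c(3.8, 3.7),
                       seasonal_amplitude = seasonal_amplitude,
                       noise_sd = noise_sd,
                       n_individuals = n_individuals, n_years = n_years,
                       seed = seed)
  simulate_panel(spec)
}

# A long unmasked single-individual panel from an arbitrary pair of series
# (calendar months assigned cyclically; no winter mask).
series_panel <- function(x, y = NULL, normalize = TRUE) {
  n <- length(x)
  mi <- seq_len(n)
  recs <- data.frame(gene_id = "X", individual_id = "i1",
                     year = 2000 + (mi - 1) %/% 12,
                     month = (mi - 1) %% 12 + 1, value = x)
  if (!is.null(y)) {
    recs <- rbind(recs, data.frame(gene_id = "Y", individual_id = "i1",
                                   year = 2000 + (mi - 1) %/% 12,
                                   month = (mi - 1) %% 12 + 1, value = y))
  }
  p <- expression_panel(recs)
  if (normalize) p <- normalize_panel(p)
  p
}

logistic_series <- function(n, r = 3.8, x0 = 0.41, burn = 100) {
  x <- x0
  for (i in seq_len(burn)) x <- r * x * (1 - x)
  out <- numeric(n)
  for (i in seq_len(n)) { out[i] <- x; x <- r * x * (1 - x) }
  out
}
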