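#' Phase-randomized surrogates
#'
#' Ebisuzaki-style surrogates: the Fourier amplitude spectrum of the series
#' is kept exactly while phases of the non-DC frequencies are drawn uniformly
#' (the Nyquist coefficient, when present, gets a random sign), so every
#' surrogate is a real series with the original power spectrum and mean but
#' randomized temporal structure.  Uses the current RNG stream.
#'
#' @param x numeric series.
#' @param n number of surrogates.
#' @return a `length(x) x n` matrix, one surrogate per column.
#' @export
phase_randomize <- function(x, n) {
  N <- length(x)
  f <- stats::fft(x)
  out <- matrix(NA_real_, N, n)
  half <- if (N %% 2L == 0L) N / 2L - 1L else (N - 1L) / 2L
  for (j in seq_len(n)) {
    g <- f
    if (half >= 1L) {
      ph <- stats::runif(half, 0, 2 * pi)
      k <- 2:(half + 1L)
      g[k] <- Mod(f[k]) * exp(1i * ph)
      g[N + 2L - k] <- Conj(g[k])
    }
    if (N %% 2L == 0L) {
      g[N / 2L + 1L] <- f[N / 2L + 1L] * sample(c(-1, 1), 1L)
    }
    out[, j] <- Re(stats::fft(g, inverse = TRUE)) / N
  }
  out
}

#' Seasonal surrogates of a monthly series
#'
#' Null series that preserve both the calendar-month mean profile and the
#' residual power spectrum of the original, destroying any cross-series
#' causal signal.  Per segment (individual): the monthly mean profile is
#' subtracted, the residual is phase-randomized ([phase_randomize()]), and
#' the profile is added back.  Because subtracting the monthly profile zeroes
#' the Fourier coefficients at all annual harmonics, and phase randomization
#' preserves amplitudes, every surrogate reproduces the original per-month
#' means exactly.
#'
#' For winter-masked series (`mask_months` non-`NULL`) the decomposition and
#' randomization act on the growing-season subsequence only, and the masked
#' positions stay exactly zero: randomizing the full calendar series would
#' leak residual variance into the dormant months, where re-masking deletes
#' it, leaving surrogates with systematically less growing-season variance
#' than the original -- a biased (anticonservative) null.
#'
#' @param values numeric series, whole years per segment (each calendar
#'   month equally represented).
#' @param month calendar month (1-12) per value.
#' @param segment segment id per value; default single segment.
#' @param n number of surrogates (default 1000).
#' @param seed RNG seed (`NULL` = use current stream).
#' @param mask_months dormant months held fixed at zero; `NULL` randomizes
#'   the whole series.
#' @return a `length(values) x n` matrix of surrogate series.
#' @export
seasonal_surrogate <- function(values, month, segment = NULL, n = 1000L,
                               seed = NULL,
                               mask_months = c(11L, 12L, 1L, 2L, 3L, 4L, 5L)) {
  if (is.null(segment)) segment <- rep(1L, length(values))
  stopifnot(length(month) == length(values),
            length(segment) == length(values))
  if (!is.null(seed)) set.seed(seed)
  out <- matrix(NA_real_, length(values), n)
  masked <- month %in% (mask_months %||% integer(0))
  out[masked, ] <- 0
  for (s in unique(segment)) {
    idx <- which(segment == s & !masked)
    cnt <- table(month[idx])
    if (length(unique(cnt)) != 1L) {
      stop("segment '", s,
           "' does not cover whole years (unbalanced calendar months)",
           call. = FALSE)
    }
    m <- month[idx]
    profile <- stats::ave(values[idx], m)  # per-calendar-month mean
    resid <- values[idx] - profile
    out[idx, ] <- profile + phase_randomize(resid, n)
  }
  out
}

#' Surrogate cross-map skill distribution
#'
#' The null distribution of cross-map skill for a putative cause: the
#' (real) effect gene's pooled delay embedding cross-maps each seasonal
#' surrogate of the cause gene.  With `library = "bootstrap"` (default)
#' every surrogate's skill is the mean over `n_boot_per_surrogate`
#' bootstrap library draws -- the same resampling design used for the
#' observed maximum-library skill, so the two quantities are directly
#' comparable (the bootstrap draws are shared across surrogates, a paired
#' design).  With `library = "full"` each surrogate gets one deterministic
#' full-library evaluation.  The observed series' own skill under the same
#' scheme is returned for reference.
#'
#' @param panel a normalized, winter-masked [expression_panel()].
#' @param cause,effect gene ids (the tested direction is cause -> effect).
#' @param E embedding dimension of the effect (library) variable.
#' @param n_surrogates number of surrogates (default 1000).
#' @param seed RNG seed.
#' @param tau lag.
#' @param exclusion_radius temporal neighbor-exclusion radius within a
#'   segment (0 = exclude only the target vector itself, the cross-mapping
#'   default).
#' @param library `"bootstrap"` (default) or `"full"`.
#' @param n_boot_per_surrogate bootstrap draws averaged per surrogate when
#'   `library = "bootstrap"` (default 100).
#' @return A `surrogate_ensemble` list: `rho_surr_samples`, `rho_observed`,
#'   `n_surrogates`, `cause`, `effect`, `E`, and `surrogates` (the series
#'   matrix).
#' @export
surrogate_rho_distribution <- function(panel, cause, effect, E,
                                       n_surrogates = 1000L, seed = 1L,
                                       tau = 1L, exclusion_radius = 0L,
                                       library = c("bootstrap", "full"),
                                       n_boot_per_surrogate = 100L) {
  library <- match.arg(library)
  lib <- pool_individuals(panel, effect, E = E, tau = tau)
  cs <- panel_series(panel, cause)
  emb <- lib$embedding
  mask_months <- attr(panel, "mask_months") %||% c(11L, 12L, 1:5)
  surr <- seasonal_surrogate(cs$values, cs$month, cs$segment,
                             n = n_surrogates, seed = seed,
                             mask_months = mask_months)
  D <- as.matrix(stats::dist(emb$vectors))
  if (library == "full") {
    W <- ccm_weight_matrix(D, emb$segment, emb$time,
                           E + 1L, as.integer(exclusion_radius))
    ok <- !is.na(W[, 1L])
    if (sum(ok) < 3L) stop("too few cross-map targets", call. = FALSE)
    pred <- W[ok, , drop = FALSE] %*% surr[emb$row, , drop = FALSE]
    obs <- surr[emb$row[ok], , drop = FALSE]
    rho_surr <- colwise_cor(pred, obs)
    pred0 <- drop(W[ok, , drop = FALSE] %*% cs$values[emb$row])
    rho_obs <- safe_cor(pred0, cs$values[emb$row[ok]])
  } else {
    n_vec <- nrow(emb$vectors)
    boot <- matrix(sample.int(n_vec, n_boot_per_surrogate * n_vec,
                              replace = TRUE),
                   nrow = n_boot_per_surrogate)
    vals <- cbind(surr[emb$row, , drop = FALSE], cs$values[emb$row])
    rho_mat <- ccm_boot_rho_matrix(D, vals, as.integer(emb$segment),
                                   as.integer(emb$time), boot,
                                   as.integer(E + 1L),
                                   as.integer(exclusion_radius))
    m <- colMeans(rho_mat)
    rho_surr <- m[seq_len(n_surrogates)]
    rho_obs <- m[n_surrogates + 1L]
  }
  structure(list(rho_surr_samples = rho_surr,
                 rho_observed = rho_obs,
                 n_surrogates = n_surrogates,
                 cause = cause, effect = effect, E = E,
                 surrogates = surr),
            class = "surrogate_ensemble")
}

# Pearson correlation of matching columns of two matrices; degenerate
# columns give 0 (no skill) rather than NA.
colwise_cor <- function(a, b) {
  ca <- sweep(a, 2L, colMeans(a))
  cb <- sweep(b, 2L, colMeans(b))
  num <- colSums(ca * cb)
  den <- sqrt(colSums(ca^2) * colSums(cb^2))
  r <- ifelse(den > 0, num / den, 0)
  pmin(1, pmax(-1, r))
}
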