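#' S-map (sequentially locally weighted global linear) forecasting
#'
#' Locally weighted linear prediction in delay-embedding space.  For each
#' target vector, all eligible library vectors are weighted by
#' `w_i = exp(-theta * d_i / dbar)` (`dbar` = mean distance to the target)
#' and a ridge-regularized weighted least-squares map is solved to predict
#' the value `tp` steps ahead.  `theta = 0` reduces to a global linear
#' (autoregressive) model; forecast improvement at `theta > 0` indicates
#' state dependence, i.e. nonlinearity.
#'
#' @param values,segment series layout as in [embed_series()].
#' @param E embedding dimension.
#' @param theta local weighting parameter (>= 0).
#' @param tau,tp,theiler as in [simplex_forecast()].
#' @param lambda ridge penalty for the local solve (default 1e-6; keeps
#'   near-singular local designs solvable, never hard-fails).
#' @return A `forecast_result` list (see [simplex_forecast()]).
#' @export
smap_forecast <- function(values, segment = NULL, E, theta = 0, tau = 1L,
                          tp = 1L, theiler = 1L, lambda = 1e-6) {
  if (theta < 0) stop("theta must be >= 0", call. = FALSE)
  emb <- embed_series(values, segment, E = E, tau = tau)
  if (is.null(segment)) segment <- rep(1L, length(values))
  n <- nrow(emb$vectors)
  fut <- future_values(values, segment, emb, tp)
  has_fut <- !is.na(fut)
  if (sum(has_fut) < E + 2L) stop("too few vectors for S-map", call. = FALSE)
  D <- as.matrix(stats::dist(emb$vectors))
  pred <- rep(NA_real_, n)
  p <- E + 1L  # intercept + E coordinates
  ridge <- diag(sqrt(lambda), p)
  for (i in seq_len(n)) {
    if (!has_fut[i]) next
    elig <- has_fut &
      !(emb$segment == emb$segment[i] & abs(emb$time - emb$time[i]) <= theiler)
    elig[i] <- FALSE
    idx <- which(elig)
    if (length(idx) < p + 1L) next
    d <- D[i, idx]
    dbar <- mean(d)
    w <- if (theta == 0 || dbar == 0) rep(1, length(idx)) else exp(-theta * d / dbar)
    sw <- sqrt(w)
    X <- cbind(1, emb$vectors[idx, , drop = FALSE]) * sw
    y <- fut[idx] * sw
    fit <- stats::.lm.fit(rbind(X, ridge), c(y, numeric(p)))
    pred[i] <- sum(c(1, emb$vectors[i, ]) * fit$coefficients)
  }
  ok <- !is.na(pred) & has_fut
  rho <- safe_cor(pred[ok], fut[ok])
  structure(list(rho = rho,
                 predictions = tibble::tibble(segment = emb$segment[ok],
                                              time = emb$time[ok],
                                              predicted = pred[ok],
                                              observed = fut[ok]),
                 n_pred = sum(ok),
                 n_skipped = sum(has_fut & is.na(pred)),
                 E = E),
            class = "forecast_result")
}

#' S-map nonlinearity test
#'
#' Computes the gain in S-map forecast skill from state-dependent weighting,
#' `delta_rho = max_theta rho(theta) - rho(0)`, and assesses its significance
#' against phase-randomized surrogates of the series (which preserve the
#' power spectrum, hence all linear autocorrelation structure, but destroy
#' state dependence).  `p_value = (1 + #{surrogate delta >= observed}) /
#' (n_surrogate + 1)`.
#'
#' @param values,segment series layout as in [embed_series()].
#' @param E embedding dimension.
#' @param theta_grid grid of weighting parameters; must contain 0.
#' @param n_surrogate number of phase-randomized null series (default 100).
#' @param seed RNG seed for the surrogates.
#' @param alpha significance level (default 0.05).
#' @param tau,tp,theiler,lambda forwarded to [smap_forecast()].
#' @return list with `delta_rho`, `p_value`, `nonlinear`, `rho_by_theta`
#'   (named numeric) and `delta_rho_surr`.
#' @export
smap_nonlinearity_test <- function(values, segment = NULL, E,
                                   theta_grid = c(0, 0.1, 0.3, 0.75, 1.5, 3, 6),
                                   n_surrogate = 100L, seed = 1L,
                                   alpha = 0.05, tau = 1L, tp = 1L,
                                   theiler = 1L, lambda = 1e-6) {
  if (!any(theta_grid == 0)) stop("theta_grid must include 0", call. = FALSE)
  if (is.null(segment)) segment <- rep(1L, length(values))
  if (stats::sd(values) == 0) stop("degenerate (constant) series", call. = FALSE)
  delta_of <- function(x) {
    rho <- vapply(theta_grid, function(th) {
      smap_forecast(x, segment, E = E, theta = th, tau = tau, tp = tp,
                    theiler = theiler, lambda = lambda)$rho
    }, numeric(1L))
    list(delta = max(rho, na.rm = TRUE) - rho[which(theta_grid == 0)[1L]],
         rho = rho)
  }
  obs <- delta_of(values)
  if (length(theta_grid) == 1L) {
    return(list(delta_rho = 0, p_value = 1, nonlinear = FALSE,
                rho_by_theta = stats::setNames(obs$rho, theta_grid),
                delta_rho_surr = numeric(0)))
  }
  set.seed(seed)
  surr <- matrix(NA_real_, length(values), n_surrogate)
  for (s in unique(segment)) {
    idx <- which(segment == s)
    surr[idx, ] <- phase_randomize(values[idx], n_surrogate)
  }
  delta_surr <- vapply(seq_len(n_surrogate),
                       function(j) delta_of(surr[, j])$delta, numeric(1L))
  p <- (1 + sum(delta_surr >= obs$delta)) / (n_surrogate + 1)
  list(delta_rho = obs$delta, p_value = p, nonlinear = p < alpha,
       rho_by_theta = stats::setNames(obs$rho, theta_grid),
       delta_rho_surr = delta_surr)
}
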