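#' Simplex-projection forecasting
#'
#' Nearest-neighbor forecasting in delay-embedding space.  For each target
#' vector the E + 1 nearest library vectors (Euclidean distance; the target
#' itself and temporal neighbors within the Theiler window are excluded, as
#' are vectors without a future `tp` steps ahead in their own segment) are
#' combined with exponential weights `w_i = exp(-d_i / d_1)` to predict the
#' value `tp` steps ahead.  If the nearest distance is zero the exact-match
#' neighbors are weighted uniformly.  Forecast skill is the Pearson
#' correlation between predictions and observations.
#'
#' @param values,segment series and segment layout as in [embed_series()].
#' @param E,tau embedding parameters.
#' @param tp prediction horizon in steps (default 1).
#' @param theiler temporal exclusion radius within a segment (default 1);
#'   the target vector itself is always excluded.
#' @return A `forecast_result` list: `rho`, `predictions` (tibble with
#'   `segment`, `time`, `predicted`, `observed`), `n_pred`, `n_skipped`
#'   (targets with fewer than E + 1 eligible neighbors), and `E`.
#' @export
simplex_forecast <- function(values, segment = NULL, E, tau = 1L, tp = 1L,
                             theiler = 1L) {
  emb <- embed_series(values, segment, E = E, tau = tau)
  if (is.null(segment)) segment <- rep(1L, length(values))
  n <- nrow(emb$vectors)
  if (n < E + 2L) stop("too few embedding vectors for simplex forecast", call. = FALSE)
  # future value tp steps ahead of each vector head, within its own segment
  fut <- future_values(values, segment, emb, tp)
  has_fut <- !is.na(fut)
  D <- as.matrix(stats::dist(emb$vectors))
  k <- E + 1L
  pred <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!has_fut[i]) next
    elig <- has_fut &
      !(emb$segment == emb$segment[i] & abs(emb$time - emb$time[i]) <= theiler)
    elig[i] <- FALSE
    idx <- which(elig)
    if (length(idx) < k) next
    d <- D[i, idx]
    ord <- order(d)[seq_len(k)]
    nn <- idx[ord]
    dn <- d[ord]
    if (dn[1L] == 0) {
      zmatch <- nn[dn == 0]
      pred[i] <- mean(fut[zmatch])
    } else {
      w <- exp(-dn / dn[1L])
      pred[i] <- sum(w * fut[nn]) / sum(w)
    }
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

# value tp steps ahead of each embedding-vector head, NA when it leaves the
# segment
future_values <- function(values, segment, emb, tp) {
  n <- nrow(emb$vectors)
  fut <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    j <- emb$row[i] + tp
    if (j >= 1L && j <= length(values) && segment[j] == emb$segment[i]) {
      fut[i] <- values[j]
    }
  }
  fut
}

safe_cor <- function(x, y) {
  if (length(x) < 3L) return(NA_real_)
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Select the optimal embedding dimension
#'
#' Leave-one-out simplex forecast skill is computed for every `E` in
#' `E_range`; the `E` maximizing Pearson rho is returned, ties broken toward
#' the smaller dimension.  Dimensions for which the series is too short are
#' skipped.
#'
#' @param values,segment series layout as in [embed_series()].
#' @param E_range candidate dimensions (default 1:10).
#' @param tau,tp,theiler forwarded to [simplex_forecast()].
#' @return integer `E*`, with the per-dimension skills attached as attribute
#'   `rho_by_E` (named numeric).
#' @export
select_embedding_dimension <- function(values, segment = NULL, E_range = 1:10,
                                       tau = 1L, tp = 1L, theiler = 1L) {
  E_range <- sort(unique(as.integer(E_range)))
  if (any(E_range < 1L) || any(E_range > 10L)) {
    stop("E_range must lie within [1, 10]", call. = FALSE)
  }
  rho <- rep(NA_real_, length(E_range))
  names(rho) <- E_range
  for (i in seq_along(E_range)) {
    fc <- tryCatch(simplex_forecast(values, segment, E = E_range[i],
                                    tau = tau, tp = tp, theiler = theiler),
                   error = function(e) NULL)
    if (!is.null(fc)) rho[i] <- fc$rho
  }
  if (all(is.na(rho))) {
    stop("forecast skill undefined for every E in E_range", call. = FALSE)
  }
  best <- which.max(ifelse(is.na(rho), -Inf, rho))  # first max: smallest E wins ties
  structure(E_range[best], rho_by_E = rho)
}
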