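#' Takens delay embedding with segment bookkeeping
#'
#' Builds lagged state vectors `(x_t, x_{t-tau}, ..., x_{t-(E-1)tau})` from a
#' series that may be the concatenation of several individuals' segments.  No
#' vector ever spans a segment boundary, so each segment of length `L`
#' contributes `max(0, L - (E - 1) * tau)` vectors.
#'
#' @param values numeric series, ordered by (segment, time).
#' @param segment segment id per value (one id per individual); defaults to a
#'   single segment.
#' @param E embedding dimension (>= 1).
#' @param tau lag in time steps (>= 1, default 1 = monthly).
#' @return A `delay_embedding` list: `E`, `tau`, `vectors` (matrix, one row
#'   per state vector, lag 0 first), `time` (time index within segment of the
#'   vector head), `segment`, and `row` (index of the head into `values`).
#' @export
embed_series <- function(values, segment = NULL, E, tau = 1L) {
  E <- as.integer(E); tau <- as.integer(tau)
  if (E < 1L || tau < 1L) stop("E and tau must be >= 1", call. = FALSE)
  if (is.null(segment)) segment <- rep(1L, length(values))
  if (length(segment) != length(values)) {
    stop("segment must have one entry per value", call. = FALSE)
  }
  seg_ids <- unique(segment)
  span <- (E - 1L) * tau
  rows <- list(); times <- list(); segs <- list(); heads <- list()
  for (s in seg_ids) {
    idx <- which(segment == s)
    n <- length(idx)
    if (n < span + 1L) next
    t_head <- (span + 1L):n
    lagmat <- vapply(0:(E - 1L),
                     function(l) values[idx[t_head - l * tau]],
                     numeric(length(t_head)))
    rows[[length(rows) + 1L]] <- matrix(lagmat, ncol = E)
    times[[length(times) + 1L]] <- t_head
    segs[[length(segs) + 1L]] <- rep(s, length(t_head))
    heads[[length(heads) + 1L]] <- idx[t_head]
  }
  if (length(rows) == 0L) {
    stop("series too short for E = ", E, " (tau = ", tau, ")", call. = FALSE)
  }
  structure(list(E = E, tau = tau,
                 vectors = do.call(rbind, rows),
                 time = unlist(times, use.names = FALSE),
                 segment = unlist(segs, use.names = FALSE),
                 row = unlist(heads, use.names = FALSE)),
            class = "delay_embedding")
}

#' Number of embedding vectors for given segment lengths
#'
#' Closed-form count `sum(max(0, L_s - (E - 1) * tau))`.
#'
#' @param segment_lengths integer vector of per-segment lengths.
#' @param E,tau embedding parameters.
#' @return integer vector count.
#' @export
embedding_vector_count <- function(segment_lengths, E, tau = 1L) {
  sum(pmax(0L, as.integer(segment_lengths) - (as.integer(E) - 1L) * as.integer(tau)))
}

#' Pool individuals into one composite embedding library
#'
#' Dew-drop-style pooling: each individual's (independently normalized)
#' series is embedded separately and the vectors are concatenated into one
#' library, so neighbors for a target in one tree may come from any tree,
#' but no lag vector ever mixes two trees.
#'
#' @param panel a winter-masked [expression_panel()].
#' @param gene gene id.
#' @param E,tau embedding parameters.
#' @return A `composite_library` list: `embedding` (a [embed_series()]
#'   result), `individuals`, `total_points`, `gene`, and `series` (the
#'   pooled series layout from [panel_series()]).
#' @export
pool_individuals <- function(panel, gene, E, tau = 1L) {
  ser <- panel_series(panel, gene)
  emb <- embed_series(ser$values, ser$segment, E = E, tau = tau)
  structure(list(embedding = emb,
                 individuals = ser$individuals,
                 total_points = length(ser$values),
                 gene = gene,
                 series = ser),
            class = "composite_library")
}
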