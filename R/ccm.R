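#' Convergent cross mapping with bootstrap libraries
#'
#' Tests the direction cause -> effect by embedding the *effect* gene (the
#' library variable, pooled across individuals) and using its nearest
#' neighbors to predict the contemporaneous cause values: only if the cause
#' leaves its signature in the effect's dynamics can the effect's attractor
#' recover it.  Each bootstrap replicate draws `library_size` embedding
#' vectors with replacement from the pooled library and returns the Pearson
#' correlation between cross-mapped and observed cause values over all
#' target times.
#'
#' @param panel a normalized, winter-masked [expression_panel()].
#' @param cause,effect gene ids.
#' @param E embedding dimension of the effect (library) variable.
#' @param library_size vectors drawn per replicate; `NULL` (default) = all
#'   available vectors (the "maximum library").
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @param tau lag.
#' @param replace draw with replacement (default `TRUE`, a bootstrap); set
#'   `FALSE` for a subsample sensitivity check.
#' @param exclusion_radius Theiler radius within a segment (default 0:
#'   exclude only the target vector itself).
#' @return numeric vector of `n_boot` cross-map skills in [-1, 1].
#' @export
cross_map <- function(panel, cause, effect, E, library_size = NULL,
                      n_boot = 1000L, seed = 1L, tau = 1L, replace = TRUE,
                      exclusion_radius = 0L) {
  lib <- pool_individuals(panel, effect, E = E, tau = tau)
  emb <- lib$embedding
  n_vec <- nrow(emb$vectors)
  if (is.null(library_size)) library_size <- n_vec
  if (library_size < E + 1L) {
    stop("library_size must be at least E + 1 = ", E + 1L, call. = FALSE)
  }
  if (!replace && library_size > n_vec) {
    stop("library_size exceeds available vectors (", n_vec,
         ") and replace = FALSE", call. = FALSE)
  }
  cs <- panel_series(panel, cause)
  if (!identical(cs$month_index, lib$series$month_index)) {
    stop("cause and effect series have different time coverage", call. = FALSE)
  }
  xvals <- cs$values[emb$row]  # cause value at each vector head (tp = 0)
  D <- as.matrix(stats::dist(emb$vectors))
  set.seed(seed)
  boot <- matrix(sample.int(n_vec, n_boot * library_size, replace = replace),
                 nrow = n_boot)
  ccm_boot_rho(D, xvals, xvals, as.integer(emb$segment),
               as.integer(emb$time), boot, as.integer(E + 1L),
               as.integer(exclusion_radius))
}

#' Cross-map convergence over library size
#'
#' Computes the bootstrap cross-map skill distribution at a grid of library
#' sizes, including the minimum library (E + 1 vectors) and the maximum
#' library (all vectors), the two lengths entering the causal decision rule.
#'
#' @inheritParams cross_map
#' @param sizes ascending library sizes; `NULL` = 8 sizes from E + 1 to the
#'   maximum.
#' @return A `ccm_rho` list: `cause`, `effect`, `E`, `library_sizes`,
#'   `rho_curve` (mean skill per size), `rho_min_samples` and
#'   `rho_max_samples` (full bootstrap samples at the extreme sizes).
#' @export
convergence_curve <- function(panel, cause, effect, E, sizes = NULL,
                              n_boot = 1000L, seed = 1L, tau = 1L,
                              exclusion_radius = 0L) {
  lib <- pool_individuals(panel, effect, E = E, tau = tau)
  n_vec <- nrow(lib$embedding$vectors)
  if (is.null(sizes)) {
    sizes <- unique(round(seq(E + 1L, n_vec, length.out = 8L)))
  }
  sizes <- sort(unique(as.integer(sizes)))
  if (sizes[1L] < E + 1L) stop("minimum library size is E + 1", call. = FALSE)
  samples <- vector("list", length(sizes))
  for (i in seq_along(sizes)) {
    samples[[i]] <- cross_map(panel, cause, effect, E,
                              library_size = sizes[i], n_boot = n_boot,
                              seed = seed + i - 1L, tau = tau,
                              exclusion_radius = exclusion_radius)
  }
  structure(list(cause = cause, effect = effect, E = E,
                 library_sizes = sizes,
                 rho_curve = vapply(samples, mean, numeric(1L)),
                 rho_min_samples = samples[[1L]],
                 rho_max_samples = samples[[length(samples)]]),
            class = "ccm_rho")
}
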