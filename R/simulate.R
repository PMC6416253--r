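#' Specify a synthetic regulatory network
#'
#' Defines a set of genes evolving as coupled logistic maps in the chaotic
#' regime, the canonical benchmark family for cross-mapping causality tests.
#' `coupling[i, j]` is the strength with which gene `i` suppresses the
#' per-capita growth of gene `j` (0 = no edge); the map update for gene `j`
#' is `x_j(t+1) = x_j(t) * (r_j - r_j * x_j(t) - sum_i coupling[i, j] * x_i(t))`.
#'
#' @param genes character vector of unique gene ids.
#' @param coupling square numeric matrix with zero diagonal, rows = causes,
#'   columns = effects.
#' @param growth_rates per-gene logistic growth rates; values in 3.6-4.0
#'   keep the dynamics chaotic.
#' @param seasonal_amplitude per-gene amplitude of the multiplicative
#'   seasonal modulation of the observation (0 = none).
#' @param noise_sd observation noise as a fraction of each series' own
#'   standard deviation (0.05 = 5% relative noise, typical of replicated
#'   relative-expression measurements); the panel is z-scored downstream, so
#'   noise is naturally parameterized on the signal scale.
#' @param n_individuals number of trees simulated (independent initial
#'   conditions on the same attractor).
#' @param n_years number of observation years (>= 2).
#' @param seed integer RNG seed.
#' @return A `network_spec` list.
#' @export
network_spec <- function(genes, coupling, growth_rates = 3.8,
                         seasonal_amplitude = 0, noise_sd = 0.05,
                         n_individuals = 3L, n_years = 2L, seed = 1L) {
  genes <- as.character(genes)
  if (anyDuplicated(genes) > 0L) stop("gene ids must be unique", call. = FALSE)
  g <- length(genes)
  coupling <- as.matrix(coupling)
  if (!all(dim(coupling) == c(g, g))) {
    stop("coupling must be a ", g, " x ", g, " matrix", call. = FALSE)
  }
  if (any(diag(coupling) != 0)) {
    stop("coupling must have a zero diagonal (no self edges)", call. = FALSE)
  }
  growth_rates <- rep_len(growth_rates, g)
  seasonal_amplitude <- rep_len(seasonal_amplitude, g)
  if (n_years < 2L) {
    stop("n_years must be >= 2 (cross mapping needs at least E + 2 growing-season points)",
         call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(genes = genes, coupling = coupling,
                 growth_rates = growth_rates,
                 seasonal_amplitude = seasonal_amplitude,
                 noise_sd = noise_sd,
                 n_individuals = as.integer(n_individuals),
                 n_years = as.integer(n_years),
                 seed = as.integer(seed)),
            class = "network_spec")
}

# One coupled-logistic trajectory: burn-in, then n_steps recorded states.
# Returns a n_steps x G matrix.  Dormant months carry no update, so one map
# iteration joins October to the following June.
iterate_network <- function(x0, r, coupling, n_steps, burn_in = 200L) {
  g <- length(x0)
  x <- x0
  out <- matrix(NA_real_, n_steps, g)
  total <- burn_in + n_steps
  for (t in seq_len(total)) {
    if (t > burn_in) out[t - burn_in, ] <- x
    xn <- x * (r - r * x - drop(crossprod(coupling, x)))
    if (any(!is.finite(xn)) || any(abs(xn) > 10)) {
      stop("trajectory diverged; coupling/growth rates leave the unit interval",
           call. = FALSE)
    }
    x <- xn
  }
  out
}

#' Simulate a masting-like expression panel with known causal structure
#'
#' Latent gene states follow coupled logistic maps iterated once per month
#' during the growing season (June-October); dormant months carry no update.
#' Observations are the latent state times a seasonal multiplier
#' `s(m) = 1 + amplitude * cos(2 * pi * (m - 7) / 12)` (peaking in July) plus
#' Gaussian noise.  Each individual starts from independent random initial
#' conditions and a burn-in of 200 iterations.  The returned panel is, by
#' default, normalized per series and winter-masked, matching the analysis
#' conventions of the rest of the pipeline.
#'
#' @param spec a [network_spec()].
#' @param normalize,mask apply per-series z-scoring and the winter zero mask
#'   (defaults `TRUE`).
#' @param start_year first calendar year of the panel (cosmetic).
#' @return list with `panel` (an [expression_panel()]), `truth` (tibble
#'   `cause`, `effect`, `strength` of the nonzero couplings) and `spec`.
#' @export
simulate_panel <- function(spec, normalize = TRUE, mask = TRUE,
                           start_year = 2015L) {
  stopifnot(inherits(spec, "network_spec"))
  g <- length(spec$genes)
  months <- 6:10
  n_steps <- spec$n_years * length(months)
  recs <- vector("list", spec$n_individuals)
  for (i in seq_len(spec$n_individuals)) {
    # one RNG stream per panel, split across individuals by fixed offsets
    set.seed(spec$seed + 104729L * (i - 1L))
    x0 <- stats::runif(g, 0.2, 0.8)
    lat <- iterate_network(x0, spec$growth_rates, spec$coupling, n_steps)
    mon <- rep(months, times = spec$n_years)
    yr <- rep(start_year + seq_len(spec$n_years) - 1L, each = length(months))
    sm <- 1 + outer(cos(2 * pi * (mon - 7) / 12), spec$seasonal_amplitude)
    obs <- lat * sm
    if (spec$noise_sd > 0) {
      sds <- apply(obs, 2L, stats::sd)
      noise <- matrix(stats::rnorm(length(obs)), nrow(obs), ncol(obs))
      obs <- obs + sweep(noise, 2L, spec$noise_sd * sds, "*")
    }
    recs[[i]] <- tibble::tibble(
      gene_id = rep(spec$genes, each = n_steps),
      individual_id = sprintf("ind%02d", i),
      year = rep(yr, times = g),
      month = rep(mon, times = g),
      value = as.vector(obs))
  }
  panel <- expression_panel(dplyr::bind_rows(recs))
  if (normalize) panel <- normalize_panel(panel)
  if (mask) panel <- apply_winter_mask(panel)
  edge_idx <- which(spec$coupling != 0, arr.ind = TRUE)
  truth <- tibble::tibble(
    cause = spec$genes[edge_idx[, 1L]],
    effect = spec$genes[edge_idx[, 2L]],
    strength = spec$coupling[edge_idx])
  truth <- truth[order(truth$cause, truth$effect), ]
  list(panel = panel, truth = truth, spec = spec)
}

#' Simulate the florigen-activation motif
#'
#' A seven-gene benchmark motif emulating the regulatory cascade inferred in
#' masting beech: an upstream flowering-time regulator (`FE`) drives four
#' nitrate transporters (`NPF1`-`NPF4`), which in turn drive the florigen
#' gene (`FT`); `FE` additionally drives `FT` directly and its export partner
#' `FTIP1`.  Ten true directed edges in total; all other ordered pairs are
#' non-edges.  Per-edge strengths are scaled by the in-degree of the target
#' so that multi-parent genes stay on a bounded chaotic attractor.
#'
#' @param n_individuals number of trees (default 6).
#' @param n_years observation years (default 3, i.e. 36 monthly points after
#'   masking).
#' @param seed RNG seed.
#' @param noise_sd observation noise (default 0.05).
#' @param coupling_strength total forcing on a single-parent target
#'   (default 0.32).
#' @param seasonal_amplitude seasonal observation modulation (default 0).
#' @return As [simulate_panel()].
#' @export
simulate_motif_fe_npf_ft <- function(n_individuals = 6L, n_years = 3L,
                                     seed = 1L, noise_sd = 0.05,
                                     coupling_strength = 0.32,
                                     seasonal_amplitude = 0) {
  genes <- c("FE", "NPF1", "NPF2", "NPF3", "NPF4", "FT", "FTIP1")
  g <- length(genes)
  cpl <- matrix(0, g, g, dimnames = list(genes, genes))
  cpl["FE", c("NPF1", "NPF2", "NPF3", "NPF4")] <- coupling_strength
  cpl[c("NPF1", "NPF2", "NPF3", "NPF4"), "FT"] <- coupling_strength / 5
  cpl["FE", "FT"] <- coupling_strength / 5
  cpl["FE", "FTIP1"] <- coupling_strength
  r <- c(FE = 3.9, NPF1 = 3.7, NPF2 = 3.8, NPF3 = 3.75, NPF4 = 3.85,
         FT = 3.8, FTIP1 = 3.7)
  spec <- network_spec(genes, cpl, growth_rates = r,
                       seasonal_amplitude = seasonal_amplitude,
                       noise_sd = noise_sd,
                       n_individuals = n_individuals,
                       n_years = n_years, seed = seed)
  simulate_panel(spec)
}
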