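#' Length-dependent causal margin
#'
#' The margin epsilon that the mean maximum-library skill must clear above
#' the surrogate null's 95% upper confidence limit.  Shorter series are more
#' prone to type-one error, so the margin is stricter: 0.02 for series of at
#' most 24 points per individual, 0.01 for 36 or more, linearly interpolated
#' in between.
#'
#' @param n_points_per_individual series length per individual (>= 12).
#' @return numeric epsilon.
#' @export
epsilon_for_length <- function(n_points_per_individual) {
  n <- n_points_per_individual
  if (any(n < 12)) stop("series shorter than 12 points per individual", call. = FALSE)
  ifelse(n <= 24, 0.02,
         ifelse(n >= 36, 0.01, 0.02 - 0.01 * (n - 24) / 12))
}

#' Configuration for the causal test
#'
#' @param E_range candidate embedding dimensions for the library (effect)
#'   variable (default 2:5: cross-mapping a driver requires at least one
#'   coordinate beyond the driven map's own dimension, and 24-36-point
#'   monthly series cannot support E > 5).
#' @param tau embedding lag (default 1 month).
#' @param n_boot bootstrap replicates for the rho_min / rho_max
#'   distributions (default 1000).
#' @param n_surrogates seasonal surrogates for the null skill distribution
#'   (default 1000).
#' @param epsilon `"auto"` (length-dependent, [epsilon_for_length()]) or a
#'   fixed numeric margin.
#' @param conf one-sided confidence level of the upper confidence limits
#'   (default 0.95, i.e. the 95th percentile).
#' @param exclusion_radius Theiler radius for cross-map neighbor search
#'   (default 0).
#' @param theiler_univariate Theiler radius for the univariate simplex used
#'   in embedding-dimension selection (default 1).
#' @param surrogate_library `"bootstrap"` (default) or `"full"`; see
#'   [surrogate_rho_distribution()].
#' @param n_boot_per_surrogate bootstrap draws averaged per surrogate
#'   (default 100).
#' @param seed integer seed controlling all randomness.
#' @return a `ccm_config` list.
#' @export
ccm_config <- function(E_range = 2:5, tau = 1L, n_boot = 1000L,
                       n_surrogates = 1000L, epsilon = "auto",
                       conf = 0.95, exclusion_radius = 0L,
                       theiler_univariate = 1L,
                       surrogate_library = "bootstrap",
                       n_boot_per_surrogate = 100L, seed = 1L) {
  structure(list(E_range = as.integer(E_range), tau = as.integer(tau),
                 n_boot = as.integer(n_boot),
                 n_surrogates = as.integer(n_surrogates),
                 epsilon = epsilon, conf = conf,
                 exclusion_radius = as.integer(exclusion_radius),
                 theiler_univariate = as.integer(theiler_univariate),
                 surrogate_library = surrogate_library,
                 n_boot_per_surrogate = as.integer(n_boot_per_surrogate),
                 seed = as.integer(seed)),
            class = "ccm_config")
}

#' The two-criterion causal decision rule
#'
#' Pure function of the summary statistics.  Criterion 1 (convergence):
#' the mean maximum-library skill is above zero and above the 95% upper
#' confidence limit of the minimum-library skill.  Criterion 2 (seasonal
#' null): the mean maximum-library skill exceeds the 95% upper confidence
#' limit of the surrogate skill by more than epsilon.  The pair is called
#' causal when both hold.
#'
#' @param mean_rho_max mean cross-map skill at maximum library length.
#' @param ucl95_rho_min upper confidence limit of the minimum-library skill.
#' @param ucl95_rho_surr upper confidence limit of the surrogate skill.
#' @param epsilon margin (see [epsilon_for_length()]).
#' @return list with `criterion1`, `criterion2`, `causal`.
#' @export
causal_decision <- function(mean_rho_max, ucl95_rho_min, ucl95_rho_surr,
                            epsilon) {
  criterion1 <- (mean_rho_max > 0) & (mean_rho_max > ucl95_rho_min)
  criterion2 <- (mean_rho_max - ucl95_rho_surr) > epsilon
  list(criterion1 = criterion1, criterion2 = criterion2,
       causal = criterion1 & criterion2)
}

#' Test one ordered gene pair for causal influence
#'
#' Runs the full measurement machinery for the direction cause -> effect:
#' optimal embedding dimension of the effect (library) variable by pooled
#' leave-one-out simplex projection, bootstrap cross-map skill at minimum
#' (E + 1) and maximum library lengths, the seasonal-surrogate null skill,
#' and the two-criterion decision ([causal_decision()]).
#'
#' @param panel a normalized, winter-masked [expression_panel()].
#' @param cause,effect gene ids.
#' @param config a [ccm_config()].
#' @param E embedding dimension override; `NULL` (default) selects it from
#'   the effect series.
#' @return A `causal_verdict` list with the decision booleans, all summary
#'   statistics, and the underlying samples (`rho_min_samples`,
#'   `rho_max_samples`, `rho_surr_samples`).
#' @export
test_causality <- function(panel, cause, effect, config = ccm_config(),
                           E = NULL) {
  flags <- panel_flags(panel)
  if (!flags$winter_masked) {
    stop("panel must be winter-masked before causality testing", call. = FALSE)
  }
  es <- panel_series(panel, effect)
  n_per_ind <- length(es$values) / length(es$individuals)
  if (is.null(E)) {
    E <- as.integer(select_embedding_dimension(
      es$values, es$segment, E_range = config$E_range, tau = config$tau,
      theiler = config$theiler_univariate))
  }
  rho_min <- cross_map(panel, cause, effect, E, library_size = E + 1L,
                       n_boot = config$n_boot, seed = config$seed,
                       tau = config$tau,
                       exclusion_radius = config$exclusion_radius)
  rho_max <- cross_map(panel, cause, effect, E, library_size = NULL,
                       n_boot = config$n_boot, seed = config$seed + 1L,
                       tau = config$tau,
                       exclusion_radius = config$exclusion_radius)
  surr <- surrogate_rho_distribution(panel, cause, effect, E,
                                     n_surrogates = config$n_surrogates,
                                     seed = config$seed + 2L,
                                     tau = config$tau,
                                     exclusion_radius = config$exclusion_radius,
                                     library = config$surrogate_library %||% "bootstrap",
                                     n_boot_per_surrogate = config$n_boot_per_surrogate %||% 100L)
  eps <- if (identical(config$epsilon, "auto")) {
    epsilon_for_length(n_per_ind)
  } else {
    as.numeric(config$epsilon)
  }
  mean_rho_max <- mean(rho_max)
  ucl_min <- stats::quantile(rho_min, config$conf, names = FALSE)
  ucl_surr <- stats::quantile(surr$rho_surr_samples, config$conf, names = FALSE)
  dec <- causal_decision(mean_rho_max, ucl_min, ucl_surr, eps)
  structure(list(cause = cause, effect = effect, E = E,
                 n_points_per_individual = n_per_ind,
                 mean_rho_max = mean_rho_max,
                 mean_rho_min = mean(rho_min),
                 ucl95_rho_min = ucl_min,
                 ucl95_rho_surr = ucl_surr,
                 rho_observed_full_library = surr$rho_observed,
                 epsilon = eps,
                 criterion1 = dec$criterion1,
                 criterion2 = dec$criterion2,
                 causal = dec$causal,
                 rho_min_samples = rho_min,
                 rho_max_samples = rho_max,
                 rho_surr_samples = surr$rho_surr_samples),
            class = "causal_verdict")
}

#' @export
print.causal_verdict <- function(x, ...) {
  cat(sprintf("Causal test %s -> %s (E = %d)\n", x$cause, x$effect, x$E))
  cat(sprintf("  mean rho_max = %.3f | UCL95 rho_min = %.3f | UCL95 rho_surr = %.3f | eps = %.3f\n",
              x$mean_rho_max, x$ucl95_rho_min, x$ucl95_rho_surr, x$epsilon))
  cat(sprintf("  criterion1 (convergence) = %s, criterion2 (surrogate) = %s => causal = %s\n",
              x$criterion1, x$criterion2, x$causal))
  invisible(x)
}

#' Pairwise causal network over a gene set
#'
#' Runs [test_causality()] for every ordered gene pair (n * (n - 1) tests)
#' and assembles the directed edge list.  A failing pair is flagged in the
#' `status` column rather than aborting the network.  No multiplicity
#' correction is applied across pairs; the length-dependent epsilon is the
#' only tightening.
#'
#' @param panel a normalized, winter-masked [expression_panel()].
#' @param genes gene ids to test (default: all genes in the panel).
#' @param config a [ccm_config()]; per-pair seeds are derived from
#'   `config$seed` deterministically.
#' @return tibble with one row per ordered pair: verdict statistics,
#'   decision booleans, and `status` (`"ok"` or the error message).
#' @export
build_network <- function(panel, genes = NULL, config = ccm_config()) {
  if (is.null(genes)) genes <- unique(tibble::as_tibble(panel)$gene_id)
  genes <- as.character(genes)
  if (length(genes) < 2L) stop("need at least 2 genes", call. = FALSE)
  pairs <- expand.grid(effect = genes, cause = genes,
                       stringsAsFactors = FALSE)[, c("cause", "effect")]
  pairs <- pairs[pairs$cause != pairs$effect, ]
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    cfg <- config
    cfg$seed <- config$seed + 101L * i
    v <- tryCatch(test_causality(panel, pairs$cause[i], pairs$effect[i], cfg),
                  error = function(e) e)
    if (inherits(v, "error")) {
      rows[[i]] <- tibble::tibble(
        cause = pairs$cause[i], effect = pairs$effect[i], E = NA_integer_,
        mean_rho_max = NA_real_, ucl95_rho_min = NA_real_,
        ucl95_rho_surr = NA_real_, epsilon = NA_real_,
        criterion1 = NA, criterion2 = NA, causal = NA,
        status = conditionMessage(v))
    } else {
      rows[[i]] <- tibble::tibble(
        cause = v$cause, effect = v$effect, E = v$E,
        mean_rho_max = v$mean_rho_max, ucl95_rho_min = v$ucl95_rho_min,
        ucl95_rho_surr = v$ucl95_rho_surr, epsilon = v$epsilon,
        criterion1 = v$criterion1, criterion2 = v$criterion2,
        causal = v$causal, status = "ok")
    }
  }
  dplyr::bind_rows(rows)
}

#' Precision and recall of a recovered network
#'
#' @param network edge table from [build_network()] (rows with
#'   `causal == TRUE` are the predicted edges).
#' @param truth tibble of true edges with columns `cause`, `effect`.
#' @return list with `precision`, `recall`, `n_predicted`, `n_true`,
#'   `n_correct`.
#' @export
edge_precision_recall <- function(network, truth) {
  pred <- network[!is.na(network$causal) & network$causal, c("cause", "effect")]
  pkey <- paste(pred$cause, pred$effect, sep = "->")
  tkey <- paste(truth$cause, truth$effect, sep = "->")
  n_correct <- length(intersect(pkey, tkey))
  list(precision = if (length(pkey) > 0L) n_correct / length(pkey) else NA_real_,
       recall = if (length(tkey) > 0L) n_correct / length(tkey) else NA_real_,
       n_predicted = length(pkey), n_true = length(tkey),
       n_correct = n_correct)
}

#' Write a network as a Graphviz DOT file
#'
#' @param network edge table from [build_network()].
#' @param path output path.
#' @param name graph name.
#' @return `path`, invisibly.
#' @export
write_network_dot <- function(network, path, name = "ccm_network") {
  edges <- network[!is.na(network$causal) & network$causal, ]
  lines <- c(sprintf("digraph %s {", name),
             sprintf('  "%s" -> "%s" [label="%.2f"];',
                     edges$cause, edges$effect, edges$mean_rho_max),
             "}")
  writeLines(lines, path)
  invisible(path)
}
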