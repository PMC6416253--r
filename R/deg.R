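#' Label floral-induction years from flowering intensity
#'
#' Floral induction precedes anthesis by one year, so a year is labeled as an
#' induction year when the proportion of reproductive buds observed the
#' *following* spring exceeds 0.4 (strictly).  Years without a following
#' observation remain unlabeled and are dropped.
#'
#' @param flowering data frame with columns `individual_id`, `year`,
#'   `flowering_proportion` (in [0, 1]; the proportion of buds that are
#'   reproductive at that year's anthesis).
#' @return tibble with `individual_id`, `year`, `induced`, and
#'   `flowering_proportion_next_spring` (the value the label is based on).
#' @export
label_induction_years <- function(flowering) {
  required <- c("individual_id", "year", "flowering_proportion")
  missing_cols <- setdiff(required, names(flowering))
  if (length(missing_cols) > 0L) {
    stop("flowering table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  p <- flowering$flowering_proportion
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop("flowering_proportion must lie in [0, 1]", call. = FALSE)
  }
  fl <- tibble::as_tibble(flowering)
  fl$year <- as.integer(fl$year)
  nxt <- fl
  nxt$year <- nxt$year - 1L  # spring observation labels the preceding year
  nxt <- nxt[c("individual_id", "year", "flowering_proportion")]
  names(nxt)[3L] <- "flowering_proportion_next_spring"
  out <- dplyr::inner_join(fl[c("individual_id", "year")], nxt,
                           by = c("individual_id", "year"))
  out$induced <- out$flowering_proportion_next_spring > 0.4
  out[order(out$individual_id, out$year),
      c("individual_id", "year", "induced",
        "flowering_proportion_next_spring")]
}

#' Differential-expression screen by induction status and season
#'
#' For each gene, fits the randomized-block two-way ANOVA
#' `value ~ tree + induction + season` on growing-season observations
#' (tree ID as a fixed blocking term absorbing between-individual level
#' differences) and reports the F-test p-values of the induction and season
#' factors.  Seasons follow the field convention: summer = June-August,
#' fall = September-October.  Genes are screened at a raw p < alpha
#' (default 0.01); no multiplicity correction is applied.
#'
#' @param panel an [expression_panel()] (growing-season observations; masked
#'   winter zeros are excluded automatically).
#' @param labels induction labels, as from [label_induction_years()] or a
#'   data frame with `individual_id`, `year`, `induced`.
#' @param alpha significance threshold (default 0.01).
#' @param seasons named list mapping season names to month vectors.
#' @return tibble with `gene_id`, `p_induction`, `p_season`,
#'   `sig_induction`, `sig_season`.
#' @export
anova_screen <- function(panel, labels, alpha = 0.01,
                         seasons = list(summer = 6:8, fall = 9:10)) {
  df <- tibble::as_tibble(panel)
  season_months <- unlist(seasons, use.names = FALSE)
  df <- df[df$month %in% season_months, ]
  season_of <- rep(names(seasons), lengths(seasons))
  names(season_of) <- as.character(season_months)
  df$season <- factor(season_of[as.character(df$month)], levels = names(seasons))
  lab <- tibble::as_tibble(labels)[c("individual_id", "year", "induced")]
  df <- dplyr::left_join(df, lab, by = c("individual_id", "year"))
  if (anyNA(df$induced)) {
    bad <- df[is.na(df$induced), ][1L, ]
    stop(sprintf("no induction label for individual '%s', year %d",
                 bad$individual_id, bad$year), call. = FALSE)
  }
  if (length(unique(df$individual_id)) < 2L) {
    stop("anova_screen needs at least 2 individuals (tree blocking term)",
         call. = FALSE)
  }
  if (length(unique(df$induced)) < 2L) {
    stop("induction factor has a single level; design is rank-deficient",
         call. = FALSE)
  }
  df$tree <- factor(df$individual_id)
  df$induction <- factor(df$induced, levels = c(FALSE, TRUE))
  genes <- unique(df$gene_id)
  res <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    d <- df[df$gene_id == genes[i], ]
    fit <- stats::lm(value ~ tree + induction + season, data = d)
    av <- stats::anova(fit)
    res[[i]] <- tibble::tibble(
      gene_id = genes[i],
      p_induction = av["induction", "Pr(>F)"],
      p_season = av["season", "Pr(>F)"])
  }
  out <- dplyr::bind_rows(res)
  out$sig_induction <- out$p_induction < alpha
  out$sig_season <- out$p_season < alpha
  out
}

#' Venn counts of a DEG screen
#'
#' @param results table from [anova_screen()].
#' @return named list: `n_induction`, `n_season`, `n_both`.
#' @export
overlap_counts <- function(results) {
  if (nrow(results) == 0L) stop("empty results table", call. = FALSE)
  list(n_induction = sum(results$sig_induction),
       n_season = sum(results$sig_season),
       n_both = sum(results$sig_induction & results$sig_season))
}
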