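# growing-season panel for the ANOVA screen: 3 trees x 2 years x Jun-Oct
deg_panel <- function(values_fun, genes, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(individual_id = c("t1", "t2", "t3"),
                      year = 2015:2016, month = 6:10,
                      stringsAsFactors = FALSE)
  labels <- tibble::tibble(
    individual_id = rep(c("t1", "t2", "t3"), each = 2),
    year = rep(2015:2016, 3),
    induced = c(FALSE, TRUE, FALSE, TRUE, FALSE, FALSE))
  recs <- do.call(rbind, lapply(genes, function(g) {
    d <- grid
    d$gene_id <- g
    d <- dplyr::left_join(d, labels, by = c("individual_id", "year"))
    d$value <- values_fun(d)
    d[c("gene_id", "individual_id", "year", "month", "value")]
  }))
  list(panel = expression_panel(recs), labels = labels)
}

test_that("induction years are labeled from the following spring", {
  fl <- tibble::tibble(
    individual_id = rep("t1", 4), year = 2014:2017,
    flowering_proportion = c(0, 0.45, 0.40, 0.9))
  lab <- label_induction_years(fl)
  # 2017 has no following observation -> 3 labeled years
  expect_equal(lab$year, 2014:2016)
  expect_identical(lab$induced, c(TRUE, FALSE, TRUE))  # 0.40 is NOT induced
  none <- label_induction_years(tibble::tibble(
    individual_id = "a", year = 2014:2016, flowering_proportion = 0))
  expect_true(all(!none$induced))
  expect_error(label_induction_years(tibble::tibble(
    individual_id = "a", year = 2014, flowering_proportion = 1.2)),
    "\\[0, 1\\]")
})

test_that("a planted induction effect is detected with high power", {
  d <- deg_panel(function(d) rnorm(nrow(d)) + 2 * d$induced,
                 genes = sprintf("g%03d", 1:100), seed = 5)
  res <- anova_screen(d$panel, d$labels)
  expect_gte(mean(res$sig_induction), 0.9)
})

test_that("null genes are flagged at close to the nominal rate", {
  d <- deg_panel(function(d) rnorm(nrow(d)),
                 genes = sprintf("n%04d", 1:1000), seed = 6)
  res <- anova_screen(d$panel, d$labels)
  hits <- sum(res$p_induction < 0.01)
  ci <- qbinom(c(0.0005, 0.9995), 1000, 0.01)
  expect_gte(hits, ci[1])
  expect_lte(hits, ci[2])
})

test_that("an October spike is a season effect, not an induction effect", {
  d <- deg_panel(function(d) rnorm(nrow(d), sd = 0.5) + 3 * (d$month == 10),
                 genes = sprintf("s%02d", 1:50), seed = 7)
  res <- anova_screen(d$panel, d$labels)
  expect_gte(mean(res$sig_season & !res$sig_induction), 0.9)
})

test_that("p-values are invariant to affine rescaling of expression", {
  d <- deg_panel(function(d) rnorm(nrow(d)) + d$induced, genes = "g1",
                 seed = 8)
  res1 <- anova_screen(d$panel, d$labels)
  scaled <- tibble::as_tibble(d$panel)
  scaled$value <- 100 - 3.5 * scaled$value
  res2 <- anova_screen(expression_panel(scaled), d$labels)
  expect_equal(res1$p_induction, res2$p_induction, tolerance = 1e-9)
  expect_equal(res1$p_season, res2$p_season, tolerance = 1e-9)
})

test_that("rank-deficient designs are rejected with a reason", {
  d <- deg_panel(function(d) rnorm(nrow(d)), genes = "g1", seed = 9)
  one_ind <- tibble::as_tibble(d$panel)
  one_ind <- one_ind[one_ind$individual_id == "t1", ]
  expect_error(anova_screen(expression_panel(one_ind), d$labels),
               "2 individuals")
  never <- d$labels
  never$induced <- FALSE
  expect_error(anova_screen(d$panel, never), "single level")
  missing_lab <- d$labels[-1, ]
  expect_error(anova_screen(d$panel, missing_lab), "no induction label")
})

test_that("overlap counts are simple tallies with the expected bound", {
  res <- tibble::tibble(gene_id = c("a", "b", "c"),
                        p_induction = c(0.001, 0.5, 0.005),
                        p_season = c(0.5, 0.004, 0.002),
                        sig_induction = c(TRUE, FALSE, TRUE),
                        sig_season = c(FALSE, TRUE, TRUE))
  oc <- overlap_counts(res)
  expect_equal(oc, list(n_induction = 2L, n_season = 2L, n_both = 1L))
  expect_lte(oc$n_both, min(oc$n_induction, oc$n_season))
  all_false <- res
  all_false$sig_induction <- all_false$sig_season <- FALSE
  expect_equal(overlap_counts(all_false)$n_both, 0L)
  expect_error(overlap_counts(res[0, ]), "empty")
})

test_that("planted Venn structure is recovered by the screen", {
  genes <- c(sprintf("ind%02d", 1:10), sprintf("sea%02d", 1:20),
             sprintf("bot%02d", 1:5), sprintf("nul%02d", 1:50))
  d <- deg_panel(function(d) {
    g <- d$gene_id[1]
    base <- rnorm(nrow(d), sd = 0.5)
    if (startsWith(g, "ind")) base <- base + 1.5 * d$induced
    if (startsWith(g, "sea")) base <- base + 1.5 * (d$month >= 9)
    if (startsWith(g, "bot")) base <- base + 1.5 * d$induced + 1.5 * (d$month >= 9)
    base
  }, genes = genes, seed = 10)
  res <- anova_screen(d$panel, d$labels)
  oc <- overlap_counts(res)
  expect_gte(oc$n_induction, 13)  # 10 planted + 5 'both'  (+/- noise)
  expect_gte(oc$n_season, 23)
  expect_gte(oc$n_both, 3)
  expect_lte(sum(res$sig_induction[startsWith(res$gene_id, "nul")]), 5)
})
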