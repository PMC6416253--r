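Package: seasonccm
Title: Convergent Cross Mapping with Seasonal Surrogates for Short
    Multi-Individual Expression Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Empirical dynamic modeling tools for inferring directed
    regulatory influence between genes from short, strongly seasonal,
    multi-individual monthly expression time series, of the kind collected
    in field studies of masting trees.  Implements Takens delay embedding,
    simplex projection, S-map nonlinearity testing, and convergent cross
    mapping with bootstrap libraries pooled across individuals (dew-drop
    style), a seasonal surrogate null model that preserves calendar-month
    means and the residual power spectrum, and a two-criterion causal
    decision rule with a series-length-dependent margin.  Includes a
    synthetic-data generator of masting-like coupled gene dynamics with
    known causal structure, and a differential-expression screen
    (two-way randomized-block ANOVA on floral-induction status and
    season) for candidate-gene selection.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    Rcpp,
    readr,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
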