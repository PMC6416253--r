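#!/usr/bin/env Rscript
# Stage 1: generate the benchmark expression panel.
#
# Seven genes on the florigen-activation motif (FE -> NPF1..4 -> FT, plus
# FE -> FT and FE -> FTIP1), six trees, three years of monthly observations
# (36 points per series after winter masking), 5% observation noise.
# The panel and the ground-truth edge list are written under results/.

library(seasonccm)

dir.create("results", showWarnings = FALSE)
sim <- simulate_motif_fe_npf_ft(n_individuals = 6, n_years = 3, seed = 101)

write_panel(sim$panel, "results/panel.tsv")
readr::write_tsv(sim$truth, "results/truth.tsv")

df <- tibble::as_tibble(sim$panel)
message(sprintf("panel: %d genes x %d trees x %d months = %d records",
                length(unique(df$gene_id)),
                length(unique(df$individual_id)),
                length(unique(df$month_index)), nrow(df)))
message(sprintf("true network: %d directed edges among %d ordered pairs",
                nrow(sim$truth), 7 * 6))
message("wrote results/panel.tsv and results/truth.tsv")
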