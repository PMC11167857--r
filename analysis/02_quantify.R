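#!/usr/bin/env Rscript
# Quantifies the 221-site panel from the simulated quant table written by
# analysis/01_simulate.R: per-digest relative abundances, their mean, and
# beta/M-values for every (site, sample). Writes the occupancy matrix and
# prints the completeness report plus the recovered group means of the
# planted sites.
#
#   Rscript analysis/02_quantify.R [seed]

suppressMessages({ library(histodiff); library(data.table) })

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L
run <- file.path("results", sprintf("run_seed%d", seed))

cfg <- study_replay_config()
qt <- read_quant_table(file.path(run, "simulation", "quant_table.tsv"),
                       samples = file.path(run, "simulation", "design.tsv"))
mat <- build_ptm_matrix(cfg$panel, qt, quantifier = pipeline_quantifier(cfg))
write_ptm_matrix(mat, file.path(run, "ptm_matrix.tsv"))
comp <- attr(mat, "completeness")
cat(sprintf("Occupancy matrix: %d profiles (%d missing) -> %s\n",
            comp$n_profiles, comp$n_missing,
            file.path(run, "ptm_matrix.tsv")))

d <- merge(as.data.table(mat), qt$samples, by = "sample_id")
planted <- c("H1K16ub", "H1S1ac", "H3K14ac", "H3K18ub")
show <- d[d$site_id %in% planted,
          .(mean_ra = round(mean(relative_abundance), 2)),
          by = .(site_id, tissue, group)]
cat("Recovered group means (percent) of the planted sites:\n")
print(show[(site_id == "H1K16ub" & tissue == "gills" &
              group %in% c("FW", "SW", "SW_FW")) |
             (site_id == "H1S1ac" & tissue == "gills" &
                group %in% c("S0", "S1", "S3")) |
             (site_id %in% c("H3K14ac", "H3K18ub") & tissue == "testes" &
                group %in% c("S0", "S1", "S3"))])
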