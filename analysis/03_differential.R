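#!/usr/bin/env Rscript
# Runs every tissue x group-pair comparison on the occupancy matrix from
# analysis/02_quantify.R: Welch t-tests on M-values, fold changes on the
# percent scale, covariate-conditioned q-values (modification class as the
# covariate), volcano classification and the q < 0.1 responsiveness call.
# Writes one results file per correction family plus the responsive
# summary under results/run_seed<seed>/comparisons/.
#
#   Rscript analysis/03_differential.R [seed]

suppressMessages({ library(histodiff); library(data.table) })

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L
run <- file.path("results", sprintf("run_seed%d", seed))

cfg <- study_replay_config()
qt <- read_quant_table(file.path(run, "simulation", "quant_table.tsv"),
                       samples = file.path(run, "simulation", "design.tsv"))
mat <- build_ptm_matrix(cfg$panel, qt, quantifier = pipeline_quantifier(cfg))
res <- run_comparisons(mat, qt$samples, cfg$panel)
write_comparison_results(res, file.path(run, "comparisons"), seed = seed)

r <- as.data.table(res)
cat(sprintf("%d comparisons across %d families; %d responsive calls\n",
            nrow(r), length(unique(r$comparison)), sum(r$responsive)))
if (sum(r$responsive) > 0) {
  cat("Responsive sites (conditioned q < 0.1):\n")
  print(r[responsive == TRUE,
          .(comparison, site_id, mean_ra_a = round(mean_ra_a, 2),
            mean_ra_b = round(mean_ra_b, 2),
            p_value = signif(p_value, 3),
            conditioned_q = signif(conditioned_q, 2))])
}
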