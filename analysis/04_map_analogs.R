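#!/usr/bin/env Rscript
# Maps the four salinity-responsive sites onto the human histone stand-ins
# by global pairwise alignment and writes the analog report. The K16
# ubiquitylation site of the H1 isoform projects onto an arginine in the
# human H1 stand-in, so it gets no human analog (ubiquitylation cannot
# occur on arginine); the other three sites are conserved.
#
#   Rscript analysis/04_map_analogs.R

suppressMessages(library(histodiff))

pro <- read_protein_fasta(system.file("extdata",
                                      "synthetic_histones.fasta",
                                      package = "histodiff"))
hum <- read_protein_fasta(system.file("extdata",
                                      "synthetic_human_histones.fasta",
                                      package = "histodiff"))
tab <- default_mass_table()
panel <- ptm_panel(list(
  ptm_site("H1x1", 16L, "K", tab$defs[["gly-gly"]], protein_name = "H1",
           abbreviated_name = "H1K16ub"),
  ptm_site("H1like", 1L, "S", tab$defs[["acetyl"]], protein_name = "H1",
           abbreviated_name = "H1S1ac"),
  ptm_site("H3", 14L, "K", tab$defs[["acetyl"]], protein_name = "H3",
           abbreviated_name = "H3K14ac"),
  ptm_site("H3", 18L, "K", tab$defs[["gly-gly"]], protein_name = "H3",
           abbreviated_name = "H3K18ub")))

dir.create("results", showWarnings = FALSE)
rep_ <- analog_report(panel, pro, hum,
                      protein_map = c(H1x1 = "human_H1",
                                      H1like = "human_H1",
                                      H3 = "human_H3"),
                      path = file.path("results", "human_analogs.tsv"))
print(rep_[, c("site_id", "target_protein", "target_position",
               "target_residue", "verdict", "conserved")])
cat("-> results/human_analogs.tsv\n")
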