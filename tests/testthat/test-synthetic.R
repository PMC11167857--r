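test_that("the same seed reproduces a bit-identical table", {
  cfg <- small_sim_config(sigma_bio = 0.2, sigma_tech = 0.15)
  s1 <- simulate_quant_table(cfg, 13L, tissues = "gills",
                             experiments = "short_term")
  s2 <- simulate_quant_table(cfg, 13L, tissues = "gills",
                             experiments = "short_term")
  expect_identical(s1$table$records, s2$table$records)
  s3 <- simulate_quant_table(cfg, 14L, tissues = "gills",
                             experiments = "short_term")
  expect_false(identical(s1$table$records$normalized_area,
                         s3$table$records$normalized_area))
})

test_that("noise-free closure: pipeline recovers true occupancy exactly", {
  cfg <- small_sim_config(sigma_bio = 0, sigma_tech = 0,
                          baseline = c(T1K10ac = 0.2, T1K40ub = 0.05,
                                       T2R10me1 = 0.5, T2K40ac = 0.8))
  sim <- simulate_quant_table(cfg, 1L, tissues = "gills",
                              experiments = "short_term")
  mat <- as.data.frame(build_ptm_matrix(cfg$panel, sim$table,
                                        cfg$proteins))
  ra1 <- mat$relative_abundance[mat$site_id == "T1K10ac"]
  expect_equal(ra1, rep(20, length(ra1)))
  ra2 <- mat$relative_abundance[mat$site_id == "T2K40ac"]
  expect_equal(ra2, rep(80, length(ra2)))
  # per-digest values agree too (three-digest averaging is trivial here)
  expect_equal(mat$ra_trypsin_propionyl, mat$relative_abundance)
})

test_that("tiny noise converges to the true occupancy within 0.1 points", {
  cfg <- small_sim_config(sigma_bio = 1e-3, sigma_tech = 1e-3)
  sim <- simulate_quant_table(cfg, 2L, tissues = "gills",
                              experiments = "short_term")
  mat <- merge(as.data.frame(build_ptm_matrix(cfg$panel, sim$table,
                                              cfg$proteins)),
               as.data.frame(sim$samples), by = "sample_id")
  truth <- as.data.frame(sim$truth)
  got <- merge(aggregate(relative_abundance ~ site_id + group, mat, mean),
               truth, by = c("site_id", "group"))
  expect_true(all(abs(got$relative_abundance - 100 * got$theta) < 0.1))
})

test_that("simulated per-fish occupancies stay strictly inside (0,1)", {
  cfg <- small_sim_config(sigma_bio = 2, sigma_tech = 0.5,
                          baseline = c(T1K10ac = 0.001, T1K40ub = 0.999,
                                       T2R10me1 = 0.5, T2K40ac = 0.9))
  sim <- simulate_quant_table(cfg, 21L, tissues = "gills",
                              experiments = "short_term")
  rec <- sim$table$records
  expect_true(all(rec$normalized_area >= 0))
  agg <- aggregate(normalized_area ~ sample_id + digest, rec, sum)
  expect_true(all(agg$normalized_area > 0))
})

test_that("the replay preset plants the four reported effects in a 221-site panel", {
  cfg <- study_replay_config()
  expect_length(cfg$panel, 221L)
  occ <- as.data.frame(cfg$occupancy)
  spread <- aggregate(theta ~ site_id + experiment + tissue, occ,
                      function(x) max(x) - min(x))
  planted <- unique(spread$site_id[spread$theta > 0])
  expect_setequal(planted, c("H1K16ub", "H1S1ac", "H3K14ac", "H3K18ub"))
  # printed group means are the planted occupancies
  g <- function(s, t, gr) occ$theta[occ$site_id == s & occ$tissue == t &
                                      occ$group == gr][1]
  expect_equal(g("H1K16ub", "gills", "FW"), 0.0203)
  expect_equal(g("H1K16ub", "gills", "SW"), 0.0378)
  expect_equal(g("H1K16ub", "gills", "SW_FW"), 0.0333)
  expect_equal(g("H1S1ac", "gills", "S0"), 0.0559)
  expect_equal(g("H1S1ac", "gills", "S1"), 0.0333)
  expect_equal(g("H3K14ac", "testes", "S0"), 0.275)
  expect_equal(g("H3K14ac", "testes", "S1"), 0.153)
  expect_equal(g("H3K18ub", "testes", "S0"), 0.050)
  expect_equal(g("H3K18ub", "testes", "S1"), 0.022)
  # design: the study's sample sizes
  des <- as.data.frame(cfg$design)
  n_of <- function(e, t) unique(des$n[des$experiment == e & des$tissue == t])
  expect_equal(n_of("short_term", "gills"), 6L)
  expect_equal(n_of("short_term", "testes"), 3L)
  expect_equal(n_of("long_term", "gills"), 8L)
  expect_equal(n_of("long_term", "testes"), 6L)
})

test_that("a planted effect at reported size dominates its family for a fixed seed", {
  cfg <- study_replay_config()
  out <- run_pipeline(cfg, 7L, quantifier = pipeline_quantifier(cfg),
                      tissues = "testes", experiments = "long_term")
  fam <- as.data.frame(out$results)
  fam <- fam[fam$comparison == "testes:S1_vs_S0", ]
  fam <- fam[order(fam$p_value), ]
  expect_true(all(c("H3K14ac", "H3K18ub") %in% fam$site_id[1:3]))
})

test_that("the global-null variant removes every group effect", {
  cfg <- small_sim_config(
    overrides = data.frame(site_id = "T1K10ac", tissue = "gills",
                           group = c("FW", "SW"), theta = c(0.2, 0.5)))
  null <- global_null_config(cfg)
  occ <- as.data.frame(null$occupancy)
  spread <- aggregate(theta ~ site_id + experiment + tissue, occ,
                      function(x) max(x) - min(x))
  expect_true(all(spread$theta == 0))
  # structural pieces are untouched so quantifier caches stay valid
  expect_identical(null$alloc, cfg$alloc)
})

test_that("run directories round-trip through the delimited writers", {
  cfg <- small_sim_config(sigma_bio = 0.1, sigma_tech = 0.1)
  sim <- simulate_quant_table(cfg, 31L, tissues = "gills",
                              experiments = "short_term")
  dir <- withr::local_tempdir()
  write_simulation_run(sim, dir)
  expect_true(all(file.exists(file.path(
    dir, c("quant_table.tsv", "design.tsv", "ground_truth.tsv",
           "manifest.json")))))
  back <- read_quant_table(file.path(dir, "quant_table.tsv"),
                           samples = file.path(dir, "design.tsv"))
  expect_equal(nrow(back$records), nrow(sim$table$records))
  m1 <- build_ptm_matrix(cfg$panel, back, cfg$proteins)
  m2 <- build_ptm_matrix(cfg$panel, sim$table, cfg$proteins)
  expect_equal(as.data.frame(m1)$relative_abundance,
               as.data.frame(m2)$relative_abundance, tolerance = 1e-10)
})
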