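pro <- fixture_proteins()

test_that("covering forms partition into modified and unmodified at the target residue", {
  site <- toy_site("H1K16ub")
  qt <- quant_table(data.frame(
    modified_sequence = c(
      "SEEAPAPAPAPAKAAK[+114]KKTTASKPKKVGPSVGE",
      "S[+42]EEAPAPAPAPAK[+57]AAKKKTTASKPKKVGPSVGE"),
    digest = "v8_ambic", sample_id = "s1", normalized_area = c(1, 1)))
  cf <- covering_forms(site, qt, pro, "v8_ambic")
  expect_equal(cf$modified, "SEEAPAPAPAPAKAAK[+114]KKTTASKPKKVGPSVGE")
  # the second form carries other marks but lacks K16ub: unmodified
  expect_equal(cf$unmodified,
               "S[+42]EEAPAPAPAPAK[+57]AAKKKTTASKPKKVGPSVGE")

  # the site's modification mass at a different residue is still unmodified
  qt2 <- quant_table(data.frame(
    modified_sequence = "SEEAPAPAPAPAKAAKK[+114]KTTASKPKKVGPSVGE",
    digest = "v8_ambic", sample_id = "s1", normalized_area = 1))
  cf2 <- covering_forms(site, qt2, pro, "v8_ambic")
  expect_length(cf2$modified, 0L)
  expect_length(cf2$unmodified, 1L)

  # a site covered by no form yields empty partitions
  cf3 <- covering_forms(toy_site("H3K14ac"), qt, pro, "v8_ambic")
  expect_length(cf3$modified, 0L)
  expect_length(cf3$unmodified, 0L)
})

test_that("relative abundance is the modified share of covering signal, in percent", {
  site <- toy_site("H3K14ac")
  qt <- k14_quant_table(mod_area = 200, unmod_area = 800)
  expect_equal(
    relative_abundance_per_digest(site, qt, pro, "s1", "trypsin_propionyl"),
    20)
  # no modified signal detected: 0, not missing
  qt0 <- k14_quant_table(mod_area = 0, unmod_area = 500)
  expect_equal(
    relative_abundance_per_digest(site, qt0, pro, "s1", "trypsin_propionyl"),
    0)
  # no covering signal at all in the digest: missing
  expect_true(is.na(
    relative_abundance_per_digest(site, qt, pro, "s1", "v8_ambic")))
})

test_that("profiles average non-missing digests and derive beta/M-values", {
  site <- toy_site("H3K14ac")
  mk <- function(ra, digest) quant_table(data.frame(
    modified_sequence = c("K[+112]STGGK[+42]APR", "K[+112]STGGK[+56]APR"),
    digest = rep(digest, each = 2), sample_id = "s1",
    normalized_area = as.vector(rbind(ra, 100 - ra))))
  qt <- mk(c(20, 30, 10), digest_levels())
  prof <- mean_relative_abundance(site, qt, pro, "s1")
  expect_equal(prof$relative_abundance, 20)
  expect_equal(prof$beta, 0.2)
  expect_equal(prof$m_value, log2(0.25))

  # one digest missing: mean over the available two
  qt2 <- mk(c(20, 10), c("trypsin_propionyl", "v8_naphos"))
  prof2 <- mean_relative_abundance(site, qt2, pro, "s1")
  expect_equal(prof2$relative_abundance, 15)
  expect_true(is.na(prof2$per_digest_ra[["v8_ambic"]]))

  # beta = 0.5 is the M-value symmetry point
  expect_equal(m_value(0.5), 0)
  # clamping keeps M finite at 0% and 100%
  expect_true(is.finite(m_value(beta_value(0))))
  expect_true(is.finite(m_value(beta_value(100))))
  expect_equal(m_value(beta_value(0), logit_base = exp(1)) /
                 m_value(beta_value(0)), log(2), tolerance = 1e-12)
})

test_that("occupancy is invariant to rescaling one (sample, digest) and monotone in modified signal", {
  site <- toy_site("H3K14ac")
  base <- relative_abundance_per_digest(
    site, k14_quant_table(150, 600), pro, "s1", "trypsin_propionyl")
  for (c_ in c(0.01, 3, 1e4)) {
    scaled <- relative_abundance_per_digest(
      site, k14_quant_table(150 * c_, 600 * c_), pro, "s1",
      "trypsin_propionyl")
    expect_equal(scaled, base)
  }
  ras <- vapply(c(150, 200, 400, 1000), function(a)
    relative_abundance_per_digest(site, k14_quant_table(a, 600), pro,
                                  "s1", "trypsin_propionyl"), 0)
  expect_true(all(diff(ras) > 0))
})

test_that("complementary marks at a two-state residue sum to 100 percent", {
  tab <- default_mass_table()
  # K14 acetyl vs K14 GG on the same covering forms
  site_ac <- toy_site("H3K14ac")
  site_ub <- ptm_site("H3", 14L, "K", tab$defs[["gly-gly"]],
                      abbreviated_name = "H3K14ub")
  qt <- quant_table(data.frame(
    modified_sequence = c("K[+112]STGGK[+42]APR", "K[+112]STGGK[+114]APR"),
    digest = "trypsin_propionyl", sample_id = "s1",
    normalized_area = c(320, 680)))
  ra_ac <- relative_abundance_per_digest(site_ac, qt, pro, "s1",
                                         "trypsin_propionyl")
  ra_ub <- relative_abundance_per_digest(site_ub, qt, pro, "s1",
                                         "trypsin_propionyl")
  expect_equal(ra_ac + ra_ub, 100)
})

test_that("panel matrices cover every (site, sample) and log missing profiles", {
  cfg <- small_sim_config()
  sim <- simulate_quant_table(cfg, 3L, tissues = "gills",
                              experiments = "short_term")
  mat <- build_ptm_matrix(cfg$panel, sim$table, cfg$proteins)
  expect_s3_class(mat, "ptm_matrix")
  expect_equal(nrow(mat), length(cfg$panel) * nrow(sim$samples))
  expect_equal(attr(mat, "completeness")$n_missing, 0L)

  # dropping one site's records entirely makes its profiles missing
  rec <- sim$table$records
  q <- pipeline_quantifier(cfg)
  gone <- unique(q$map[q$map$site_id == names(cfg$panel)[1], ]$modified_sequence)
  rec2 <- rec[!rec$modified_sequence %in% gone, ]
  qt2 <- quant_table(rec2[, c("modified_sequence", "digest", "sample_id",
                              "normalized_area")],
                     samples = sim$samples)
  expect_message(
    mat2 <- build_ptm_matrix(cfg$panel, qt2, cfg$proteins),
    "profiles missing")
  expect_equal(attr(mat2, "completeness")$n_missing, nrow(sim$samples))
})

test_that("zero-noise synthetic occupancies are recovered exactly", {
  cfg <- small_sim_config(sigma_bio = 0, sigma_tech = 0)
  sim <- simulate_quant_table(cfg, 11L, tissues = "kidney",
                              experiments = "long_term")
  mat <- build_ptm_matrix(cfg$panel, sim$table, cfg$proteins)
  dt <- merge(as.data.frame(mat), as.data.frame(sim$samples),
              by = "sample_id")
  truth <- as.data.frame(sim$truth)
  for (k in seq_len(nrow(dt))) {
    th <- truth$theta[truth$site_id == dt$site_id[k] &
                        truth$group == dt$group[k]]
    expect_equal(dt$relative_abundance[k], 100 * th, tolerance = 1e-12)
  }
})
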