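test_that("Welch t-test matches stats::t.test and handles degenerate groups", {
  a <- c(1, 2, 3, 4); b <- c(3, 4, 5, 6)
  mine <- welch_t_test(a, b)
  ref <- t.test(a, b)
  expect_equal(mine$t_statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(mine$t_statistic, -2.19, tolerance = 1e-2)
  expect_equal(mine$df, 6)
  expect_equal(mine$p_value, 0.071, tolerance = 1e-2)

  # identical groups are a perfect null
  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)

  # zero variance in both groups, different means: finite and extreme
  deg <- welch_t_test(c(0, 0), c(1, 1))
  expect_true(is.finite(deg$t_statistic))
  expect_lt(deg$p_value, 1e-6)
  # zero variance, equal means
  eq <- welch_t_test(c(2, 2), c(2, 2))
  expect_equal(eq$p_value, 1)

  expect_error(welch_t_test(1, c(1, 2)), ">= 2")

  # Student variant matches the pooled t.test
  refs <- t.test(a, b, var.equal = TRUE)
  mines <- welch_t_test(a, b, var_equal = TRUE)
  expect_equal(mines$p_value, refs$p.value, tolerance = 1e-12)
})

test_that("fold change uses the percent scale with clamping", {
  # the reported H1K16ub group means
  expect_equal(fold_change(3.78, 2.03), log2(3.78 / 2.03))
  expect_equal(fold_change(3.78, 2.03), 0.897, tolerance = 1e-2)
  expect_equal(fold_change(5, 5), 0)
  fc0 <- fold_change(0, 10)
  expect_true(is.finite(fc0))
  expect_equal(fc0, log2(0.01 / 10))
})

test_that("pi0 regression clips, reduces to Storey, and is near 1 under the uniform", {
  # clipping rule at a single lambda with an intercept-only design
  p_hi <- seq(0.51, 0.99, length.out = 25)
  pi0 <- estimate_pi0_regression(p_hi, covariate = NULL, lambda_grid = 0.5)
  expect_equal(unique(pi0), 1)  # 1/(1-0.5) = 2 clipped to 1

  set.seed(401)
  p <- runif(2000)
  cov_un <- sample(c("u", "v"), 2000, replace = TRUE)
  pi0u <- estimate_pi0_regression(p, cov_un)
  storey <- mean(p > 0.5) / 0.5
  expect_lt(abs(mean(pi0u) - 1), 0.05)
  expect_lt(abs(mean(pi0u) - storey), 0.1)
})

test_that("an informative covariate orders class-wise pi0 like class-wise Storey", {
  set.seed(402)
  cls <- rep(c("null", "mix"), each = 1000)
  p <- c(runif(1000),
         ifelse(runif(1000) < 0.5, rbeta(1000, 0.1, 1), runif(1000)))
  p <- pmin(pmax(p, 1e-12), 1)
  pi0 <- estimate_pi0_regression(p, cls)
  m_null <- mean(pi0[cls == "null"]); m_mix <- mean(pi0[cls == "mix"])
  expect_gt(m_null, m_mix)
  st <- vapply(split(p, cls), function(x) mean(x > 0.5) / 0.5, 0)
  expect_equal(st[["null"]] > st[["mix"]], m_null > m_mix)
})

test_that("sparse covariate levels merge and single-lambda skips smoothing", {
  set.seed(403)
  p <- runif(50)
  cov_sparse <- c(rep("big", 49), "lonely")
  expect_message(estimate_pi0_regression(p, cov_sparse), "merging")
  pi0 <- suppressMessages(estimate_pi0_regression(p, cov_sparse,
                                                  lambda_grid = 0.5))
  expect_length(unique(pi0), 1L)
})

test_that("conditioned q-values reduce to BH when pi0 is 1 and scale with pi0", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(conditioned_q_values(p, 1), rep(0.04, 4))
  set.seed(404)
  for (k in 1:5) {
    pv <- runif(80)^2
    expect_equal(conditioned_q_values(pv, 1), p.adjust(pv, "BH"))
    expect_equal(conditioned_q_values(pv, 0.5),
                 pmin(0.5 * p.adjust(pv, "BH"), 1))
  }
  # monotone non-decreasing in the order of increasing p
  pv <- runif(60)
  pi0 <- runif(60, 0.2, 1)
  q <- conditioned_q_values(pv, pi0)
  expect_true(all(diff(q[order(pv)]) >= 0))
  expect_true(all(q <= 1))
})

test_that("volcano classes follow the q/fold-change quadrants", {
  q <- c(0.05, 0.05, 0.5, 0.5)
  fc <- c(2, 0.3, -1.5, 0.2)
  expect_equal(volcano_class(q, fc), c("red", "blue", "green", "gray"))
  # thresholds: q strictly below 0.1, |fc| strictly above 1
  expect_equal(volcano_class(0.1, 0), "gray")
  expect_equal(volcano_class(0.07, 1), "blue")
})

test_that("group-pair comparisons respect the q < 0.1 responsiveness rule and ordering", {
  cfg <- small_sim_config(
    sigma_bio = 0.15, sigma_tech = 0.1,
    overrides = data.frame(site_id = "T1K10ac", tissue = "kidney",
                           group = c("S0", "S1", "S3"),
                           theta = c(0.275, 0.153, 0.16)))
  out <- run_pipeline(cfg, 55L, tissues = "kidney",
                      experiments = "long_term")
  res <- as.data.frame(out$results)
  expect_setequal(unique(res$comparison),
                  c("kidney:S1_vs_S0", "kidney:S3_vs_S0",
                    "kidney:S3_vs_S1"))
  expect_true(all(res$responsive == (res$conditioned_q < 0.1)))
  fam <- res[res$comparison == "kidney:S1_vs_S0", ]
  expect_equal(fam$conditioned_q, sort(fam$conditioned_q))
  # the planted effect leads its family
  expect_equal(fam$site_id[1], "T1K10ac")
  expect_equal(fam$n_a[1], 6L)
  expect_equal(fam$n_b[1], 6L)
})

test_that("swapping group labels negates t and fold change, keeping p", {
  cfg <- small_sim_config(sigma_bio = 0.2, sigma_tech = 0.1)
  sim <- simulate_quant_table(cfg, 77L, tissues = "gills",
                              experiments = "short_term")
  mat <- build_ptm_matrix(cfg$panel, sim$table, cfg$proteins)
  res <- as.data.frame(run_comparisons(mat, sim$samples, cfg$panel))
  # swap SW and FW labels in the design
  sw <- as.data.frame(sim$samples)
  sw$group <- c(FW = "SW", SW = "FW", SW_FW = "SW_FW")[sw$group]
  res2 <- as.data.frame(run_comparisons(mat, sw, cfg$panel))
  a <- res[res$comparison == "gills:SW_vs_FW", ]
  b <- res2[res2$comparison == "gills:SW_vs_FW", ]
  b <- b[match(a$site_id, b$site_id), ]
  expect_equal(b$t_statistic, -a$t_statistic)
  expect_equal(b$log2_fold_change, -a$log2_fold_change)
  expect_equal(b$p_value, a$p_value)
})

test_that("families with too few samples are skipped with a reason", {
  cfg <- small_sim_config(sigma_bio = 0.1, sigma_tech = 0.1)
  sim <- simulate_quant_table(cfg, 9L, tissues = "gills",
                              experiments = "short_term")
  mat <- build_ptm_matrix(cfg$panel, sim$table, cfg$proteins)
  # drop all but one SW sample
  keep <- as.data.frame(sim$samples)
  sw_ids <- keep$sample_id[keep$group == "SW"]
  keep <- keep[!(keep$sample_id %in% sw_ids[-1]), ]
  res <- suppressMessages(run_comparisons(mat, keep, cfg$panel))
  skipped <- attr(res, "skipped")
  expect_true(any(grepl("SW", names(skipped))))
  expect_false("gills:SW_vs_FW" %in% unique(as.data.frame(res)$comparison))
})
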