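#' Welch t-test on M-values
#'
#' Unequal-variance two-sample t-test with Welch--Satterthwaite degrees of
#' freedom, the default for group comparisons of M-values (occupancy
#' variance differs visibly between treatment groups in this kind of data;
#' Student's pooled-variance variant is available). A variance floor keeps
#' degenerate groups testable: when both groups are constant and equal the
#' test is a perfect null (t = 0, p = 1); when constant but different, the
#' floor yields a finite, extreme statistic instead of an error.
#'
#' @param a,b numeric vectors of M-values, each with >= 2 non-missing
#'   values.
#' @param var_equal use the pooled-variance (Student) form.
#' @param var_floor variance floor applied per group (default `1e-12`).
#' @return list with `t_statistic`, `df`, `p_value`.
#' @export
welch_t_test <- function(a, b, var_equal = FALSE, var_floor = 1e-12) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("welch_t_test: each group needs >= 2 non-missing values")
  r <- t_from_stats(length(a), length(b), mean(a), mean(b),
                    var(a), var(b), var_equal, var_floor)
  list(t_statistic = r$t[1], df = r$df[1], p_value = r$p[1])
}

# vectorized t-test from per-group summary statistics
t_from_stats <- function(na, nb, ma, mb, va, vb,
                         var_equal = FALSE, var_floor = 1e-12) {
  va <- pmax(va, var_floor); vb <- pmax(vb, var_floor)
  d <- ma - mb
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- ifelse(d == 0, 0, d / se)
  list(t = t, df = df, p = pmin(1, 2 * pt(-abs(t), df)))
}

#' Log2 fold change of mean relative abundances
#'
#' Computed on the percent (relative-abundance) scale, group A = treatment,
#' group B = reference. Means are clamped below at `eps_ra` percent so a
#' zero mean yields a large finite fold change rather than infinity.
#'
#' @param mean_ra_a,mean_ra_b group mean relative abundances in percent.
#' @param eps_ra clamping floor in percent (default `0.01`).
#' @return log2 ratio.
#' @export
fold_change <- function(mean_ra_a, mean_ra_b, eps_ra = 0.01) {
  log2(pmax(mean_ra_a, eps_ra) / pmax(mean_ra_b, eps_ra))
}

#' Covariate-conditioned null-proportion estimate (FDR regression)
#'
#' Estimates, per test, the probability that its null hypothesis is true,
#' conditioned on a per-test covariate (here: the modification class, by
#' Unimod accession). For each threshold lambda, the indicator
#' `1(p > lambda)` is regressed on the covariate (logistic link by default,
#' one-hot with intercept); the fitted probability divided by `1 - lambda`
#' estimates `pi0(x; lambda)`. The lambda profile of each covariate level
#' is then smoothed with a cubic smoothing spline and read off at the
#' largest lambda, and the result clipped into `[0, 1]`. Covariate levels
#' with fewer than 2 tests are merged into the largest level; a separated
#' or otherwise failing regression at some lambda falls back to the
#' intercept-only fit for that lambda (both logged as messages).
#'
#' @param p_values p-values in `(0, 1]`.
#' @param covariate per-test categorical covariate (factor/character), or
#'   `NULL` for an intercept-only fit.
#' @param lambda_grid strictly increasing thresholds inside `(0, 1)`;
#'   default `seq(0.05, 0.95, by = 0.05)`. With a single lambda the spline
#'   smoothing is skipped.
#' @param link `"logistic"` (default) or `"linear"` (linear-probability
#'   regression, the reference implementation's default).
#' @param spline_df degrees of freedom of the smoothing spline.
#' @return numeric vector of per-test `pi0_hat` in `[0, 1]`, with the
#'   per-level lambda profile attached as attribute `"profile"`.
#' @export
estimate_pi0_regression <- function(p_values,
                                    covariate = NULL,
                                    lambda_grid = seq(0.05, 0.95, by = 0.05),
                                    link = c("logistic", "linear"),
                                    spline_df = 3) {
  link <- match.arg(link)
  m <- length(p_values)
  stopifnot(m >= 1L, all(p_values > 0 & p_values <= 1),
            all(lambda_grid > 0 & lambda_grid < 1),
            !is.unsorted(lambda_grid, strictly = TRUE))
  if (is.null(covariate)) {
    x <- factor(rep("all", m))
  } else {
    stopifnot(length(covariate) == m)
    x <- factor(as.character(covariate))
    small <- names(which(table(x) < 2L))
    if (length(small) > 0L) {
      ref <- names(which.max(table(x)))
      message("pi0 regression: merging sparse covariate level(s) ",
              paste(small, collapse = ", "), " into '", ref, "'")
      levels(x)[levels(x) %in% small] <- ref
    }
  }
  x <- droplevels(x)
  one_level <- nlevels(x) == 1L
  # fitted P(p > lambda | level) for each lambda, by covariate level
  fit_level <- matrix(NA_real_, nrow = nlevels(x),
                      ncol = length(lambda_grid),
                      dimnames = list(levels(x), NULL))
  for (j in seq_along(lambda_grid)) {
    lam <- lambda_grid[j]
    y <- as.integer(p_values > lam)
    fitted_lvl <- NULL
    if (!one_level) {
      fitted_lvl <- tryCatch({
        sep <- FALSE
        fit <- withCallingHandlers(
          if (link == "logistic")
            glm(y ~ x, family = binomial())
          else lm(y ~ x),
          warning = function(w) {
            if (grepl("fitted probabilities numerically 0 or 1",
                      conditionMessage(w)))
              sep <<- TRUE
            invokeRestart("muffleWarning")
          })
        if (sep) {
          message(sprintf(
            "pi0 regression: separation at lambda=%.2f; intercept-only fallback",
            lam))
          NULL
        } else {
          nd <- data.frame(x = factor(levels(x), levels = levels(x)))
          pr <- predict(fit, newdata = nd,
                        type = if (link == "logistic") "response" else NULL)
          as.numeric(pr)
        }
      }, error = function(e) NULL)
    }
    if (is.null(fitted_lvl))
      fitted_lvl <- rep(mean(y), nlevels(x))
    fit_level[, j] <- pmin(pmax(fitted_lvl, 0), 1) / (1 - lam)
  }
  # smooth each level's lambda profile; evaluate at the largest lambda
  pi0_level <- apply(fit_level, 1L, function(prof) {
    if (length(lambda_grid) == 1L) return(prof[1L])
    sp <- smooth.spline(lambda_grid, prof, df = spline_df)
    predict(sp, x = max(lambda_grid))$y
  })
  pi0_level <- pmin(pmax(pi0_level, 0), 1)
  out <- unname(pi0_level[as.integer(x)])
  attr(out, "profile") <- fit_level
  attr(out, "pi0_by_level") <- pi0_level
  out
}

#' Conditioned q-values
#'
#' `q_i = pi0_hat_i * BH(p)_i`, then enforcement of monotone non-decreasing
#' q along increasing p (a cumulative maximum from the smallest p upward,
#' which raises later values and never lowers the q of a smaller p -- with
#' covariate-varying pi0 the step-up direction would instead propagate one
#' optimistic pi0 across the whole family) and capping at 1. With
#' `pi0_hat` identically 1 this reduces exactly to Benjamini--Hochberg.
#'
#' @param p_values p-values.
#' @param pi0_hat per-test null-proportion estimates (recycled if scalar).
#' @return numeric vector of q-values in `[0, 1]`.
#' @export
conditioned_q_values <- function(p_values, pi0_hat = 1) {
  m <- length(p_values)
  if (length(pi0_hat) == 1L) pi0_hat <- rep(pi0_hat, m)
  stopifnot(length(pi0_hat) == m)
  q <- pi0_hat * p.adjust(p_values, method = "BH")
  ord <- order(p_values)
  q[ord] <- cummax(q[ord])
  pmin(q, 1)
}

#' Volcano classification
#'
#' @param q conditioned q-values.
#' @param log2_fc log2 fold changes.
#' @param q_threshold q significance cutoff (default 0.1).
#' @param lfc_threshold absolute log2-fold-change cutoff (default 1).
#' @return character vector: `red` (both significant), `blue` (q only),
#'   `green` (fold change only), `gray` (neither).
#' @export
volcano_class <- function(q, log2_fc, q_threshold = 0.1,
                          lfc_threshold = 1) {
  qs <- q < q_threshold
  fs <- abs(log2_fc) > lfc_threshold
  out <- rep("gray", length(q))
  out[qs & !fs] <- "blue"
  out[!qs & fs] <- "green"
  out[qs & fs] <- "red"
  out
}

#' Default statistical settings for group comparisons
#'
#' @param q_threshold responsiveness cutoff on the conditioned q-value.
#' @param lfc_threshold volcano fold-change cutoff (|log2 FC|).
#' @param lambda_grid,link,spline_df see [estimate_pi0_regression()].
#' @param var_equal Student instead of Welch t-test.
#' @param eps_ra fold-change clamping floor in percent.
#' @param min_n minimum per-group sample count for a testable site.
#' @return list of settings for [run_comparisons()].
#' @export
comparison_config <- function(q_threshold = 0.1, lfc_threshold = 1,
                              lambda_grid = seq(0.05, 0.95, by = 0.05),
                              link = "logistic", spline_df = 3,
                              var_equal = FALSE, eps_ra = 0.01,
                              min_n = 2L) {
  list(q_threshold = q_threshold, lfc_threshold = lfc_threshold,
       lambda_grid = lambda_grid, link = link, spline_df = spline_df,
       var_equal = var_equal, eps_ra = eps_ra, min_n = as.integer(min_n))
}

#' Group-pair treatment comparisons per tissue
#'
#' For every tissue and every treatment-group pair of each experiment
#' (short-term: SW vs FW, SW/FW vs FW, SW vs SW/FW; long-term: S1 vs S0,
#' S3 vs S0, S3 vs S1), tests each panel site's M-values between groups,
#' computes fold changes on the percent scale, fits the covariate-
#' conditioned null proportion with the modification class (Unimod
#' accession) as covariate, derives conditioned q-values, and calls a site
#' salinity-responsive when q < the threshold. Each (tissue, group pair) is
#' its own correction family; untestable sites (fewer than `min_n`
#' non-missing samples in either group) are excluded and the realized
#' family size reported. A family whose tissue/group has no samples is
#' skipped with a message.
#'
#' @param mat a [build_ptm_matrix()] result.
#' @param samples sample design table (see [quant_table()]); defaults to
#'   the one stored in the quant table used to build `mat`.
#' @param panel the [ptm_panel()] the matrix was built from.
#' @param config a [comparison_config()].
#' @return data.table of class `comparison_results`: one row per
#'   (tissue, comparison, site), columns `tissue`, `experiment`,
#'   `comparison`, `group_a`, `group_b`, `site_id`, `unimod`, `n_a`, `n_b`,
#'   `mean_ra_a`, `mean_ra_b`, `log2_fold_change`, `t_statistic`, `df`,
#'   `p_value`, `pi0_hat`, `conditioned_q`, `responsive`, `volcano_class`,
#'   sorted by family then conditioned q then p. Skipped families and
#'   per-family sizes are attached as attributes.
#' @export
run_comparisons <- function(mat, samples, panel,
                            config = comparison_config()) {
  stopifnot(inherits(mat, "ptm_matrix"), inherits(panel, "ptm_panel"))
  samples <- as.data.table(samples)
  validate_sample_meta(samples)
  panel_df <- as.data.table(as.data.frame(panel))
  dat <- merge(as.data.table(mat), samples, by = "sample_id")
  pairs <- list(
    short_term = list(c("SW", "FW"), c("SW_FW", "FW"), c("SW", "SW_FW")),
    long_term = list(c("S1", "S0"), c("S3", "S0"), c("S3", "S1")))
  results <- list()
  skipped <- list()
  fam_sizes <- list()
  for (exp_ in intersect(names(pairs), unique(samples$experiment))) {
    for (tis in sort(unique(samples$tissue[samples$experiment == exp_]))) {
      for (pr in pairs[[exp_]]) {
        ga <- pr[1]; gb <- pr[2]
        lab <- sprintf("%s:%s_vs_%s", tis, ga, gb)
        sub <- dat[dat$tissue == tis & dat$experiment == exp_ &
                     dat$group %in% pr & dat$missing == FALSE, ]
        ids_a <- unique(samples$sample_id[samples$tissue == tis &
                                            samples$group == ga])
        ids_b <- unique(samples$sample_id[samples$tissue == tis &
                                            samples$group == gb])
        if (length(ids_a) < config$min_n || length(ids_b) < config$min_n) {
          skipped[[lab]] <- sprintf(
            "fewer than %d samples in a group (%s n=%d, %s n=%d)",
            config$min_n, ga, length(ids_a), gb, length(ids_b))
          message("skipping family ", lab, ": ", skipped[[lab]])
          next
        }
        agg <- sub[, .(
          n_a = sum(group == ga), n_b = sum(group == gb),
          mean_m_a = mean(m_value[group == ga]),
          mean_m_b = mean(m_value[group == gb]),
          var_a = var(m_value[group == ga]),
          var_b = var(m_value[group == gb]),
          mean_ra_a = mean(relative_abundance[group == ga]),
          mean_ra_b = mean(relative_abundance[group == gb])),
          by = site_id]
        agg <- agg[agg$n_a >= config$min_n & agg$n_b >= config$min_n, ]
        if (nrow(agg) > 0L) {
          tt <- t_from_stats(agg$n_a, agg$n_b, agg$mean_m_a, agg$mean_m_b,
                             agg$var_a, agg$var_b,
                             var_equal = config$var_equal)
          fam <- data.table(
            tissue = tis, experiment = exp_, comparison = lab,
            group_a = ga, group_b = gb, site_id = agg$site_id,
            unimod = panel_df$unimod[match(agg$site_id, panel_df$site_id)],
            n_a = agg$n_a, n_b = agg$n_b,
            mean_ra_a = agg$mean_ra_a, mean_ra_b = agg$mean_ra_b,
            log2_fold_change = fold_change(agg$mean_ra_a, agg$mean_ra_b,
                                           config$eps_ra),
            t_statistic = tt$t, df = tt$df, p_value = tt$p)
        } else fam <- data.table()
        if (nrow(fam) == 0L) {
          skipped[[lab]] <- "no testable sites"
          message("skipping family ", lab, ": no testable sites")
          next
        }
        n_drop <- length(panel) - nrow(fam)
        if (n_drop > 0L)
          message(sprintf("family %s: %d untestable site(s) excluded (m = %d)",
                          lab, n_drop, nrow(fam)))
        pi0 <- estimate_pi0_regression(
          fam$p_value, covariate = fam$unimod,
          lambda_grid = config$lambda_grid, link = config$link,
          spline_df = config$spline_df)
        fam[, pi0_hat := as.numeric(pi0)]
        fam[, conditioned_q := conditioned_q_values(p_value, pi0_hat)]
        fam[, responsive := conditioned_q < config$q_threshold]
        fam[, volcano_class := volcano_class(conditioned_q,
                                             log2_fold_change,
                                             config$q_threshold,
                                             config$lfc_threshold)]
        setorder(fam, conditioned_q, p_value)
        fam_sizes[[lab]] <- nrow(fam)
        results[[lab]] <- fam
      }
    }
  }
  out <- rbindlist(results)
  structure(out, class = c("comparison_results", class(out)),
            skipped = skipped, family_sizes = fam_sizes, config = config)
}

#' Write comparison results and a machine-readable run manifest
#'
#' One delimited file per correction family plus a `responsive_summary.tsv`
#' of all responsive sites and a `manifest.json` recording the settings,
#' their hash, the seed (if any) and realized family sizes.
#'
#' @param results a [run_comparisons()] output.
#' @param dir output directory (created if needed).
#' @param seed optional integer recorded in the manifest.
#' @param sep field separator.
#' @return `dir`, invisibly.
#' @export
write_comparison_results <- function(results, dir, seed = NULL,
                                     sep = "\t") {
  stopifnot(inherits(results, "comparison_results"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  res <- as.data.table(results)
  for (lab in unique(res$comparison)) {
    f <- file.path(dir, paste0(gsub("[:/]", "_", lab), ".tsv"))
    fwrite(res[res$comparison == lab, ], f, sep = sep)
  }
  fwrite(res[res$responsive == TRUE,
             .(comparison, site_id, mean_ra_a, mean_ra_b,
               log2_fold_change, p_value, conditioned_q)],
         file.path(dir, "responsive_summary.tsv"), sep = sep)
  cfg <- attr(results, "config")
  cfg_file <- file.path(dir, "config.json")
  jsonlite::write_json(cfg, cfg_file, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package_version = as.character(packageVersion("histodiff")),
    seed = seed,
    config_md5 = unname(md5sum(cfg_file)),
    family_sizes = attr(results, "family_sizes"),
    skipped_families = attr(results, "skipped"),
    n_responsive = sum(res$responsive))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
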