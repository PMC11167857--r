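#' Simulate, quantify and test in one call
#'
#' End-to-end convenience wrapper: draws a synthetic quant table from the
#' configuration, quantifies the site panel, runs every tissue/group-pair
#' comparison, and (optionally) writes the run directory -- simulation
#' inputs, occupancy matrix, per-family results, responsive summary and
#' manifests. A fixed `(config, seed)` reproduces every output
#' byte-for-byte.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed for the simulation.
#' @param out_dir optional run directory.
#' @param comparison a [comparison_config()].
#' @param quantifier optional prebuilt [ptm_quantifier()] for the
#'   configuration's form set (see [pipeline_quantifier()]).
#' @param tissues,experiments optional design subsets.
#' @return list with `sim`, `matrix`, `results`.
#' @export
run_pipeline <- function(config, seed, out_dir = NULL,
                         comparison = comparison_config(),
                         quantifier = NULL,
                         tissues = NULL, experiments = NULL) {
  sim <- simulate_quant_table(config, seed, tissues = tissues,
                              experiments = experiments)
  if (is.null(quantifier)) quantifier <- pipeline_quantifier(config)
  mat <- build_ptm_matrix(config$panel, sim$table, quantifier = quantifier)
  res <- run_comparisons(mat, sim$samples, config$panel, comparison)
  if (!is.null(out_dir)) {
    write_simulation_run(sim, file.path(out_dir, "simulation"))
    write_ptm_matrix(mat, file.path(out_dir, "ptm_matrix.tsv"))
    write_comparison_results(res, file.path(out_dir, "comparisons"),
                             seed = seed)
  }
  list(sim = sim, matrix = mat, results = res)
}

#' Covering map for a simulation configuration's peptide forms
#'
#' The covering map depends only on the configuration's peptide forms and
#' proteins, not on the noise draws, so it can be computed once and shared
#' across many simulated tables (e.g. seed sweeps).
#'
#' @param config a [simulation_config()].
#' @param ... passed to [ptm_quantifier()].
#' @return a [ptm_quantifier()].
#' @export
pipeline_quantifier <- function(config, ...) {
  stopifnot(inherits(config, "simulation_config"))
  key <- sprintf("quantifier_%s", paste(
    config$structure_seed, nrow(config$alloc), length(config$panel),
    sep = "_"))
  if (!is.null(.histodiff_cache[[key]]))
    return(.histodiff_cache[[key]])
  forms <- unique(config$alloc[, .(modified_sequence, digest)])
  q <- ptm_quantifier(config$panel, forms, config$proteins, ...)
  .histodiff_cache[[key]] <- q
  q
}
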