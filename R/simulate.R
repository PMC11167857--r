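# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

#' Default study design: fish per treatment group per tissue
#'
#' Short-term exposures (FW control, SW, SW/FW recovery): 6 gill and 6
#' kidney samples but only 3 testes samples per group (sexes of the fish
#' were random). Long-term exposures (S0 control, S1 one pulse, S3 three
#' pulses): 8 gill, 6 kidney and 6 testes samples per group.
#'
#' @return data.table with columns `experiment`, `tissue`, `group`, `n`.
#' @export
default_design <- function() {
  rbindlist(list(
    data.table(experiment = "short_term",
               tissue = rep(c("gills", "kidney", "testes"), each = 3L),
               group = rep(c("FW", "SW", "SW_FW"), 3L),
               n = rep(c(6L, 6L, 3L), each = 3L)),
    data.table(experiment = "long_term",
               tissue = rep(c("gills", "kidney", "testes"), each = 3L),
               group = rep(c("S0", "S1", "S3"), 3L),
               n = rep(c(8L, 6L, 6L), each = 3L))))
}

#' Expand a per-site occupancy specification to the full design grid
#'
#' @param panel a [ptm_panel()].
#' @param baseline named numeric: true occupancy theta in (0,1) per site,
#'   used for every (tissue, group) not overridden.
#' @param overrides optional data.frame with columns `site_id`, `tissue`,
#'   `group`, `theta` planting group effects in specific tissues.
#' @param design a [default_design()]-shaped table.
#' @return data.table `site_id`, `experiment`, `tissue`, `group`, `theta`.
#' @export
occupancy_table <- function(panel, baseline, overrides = NULL,
                            design = default_design()) {
  stopifnot(inherits(panel, "ptm_panel"),
            setequal(names(baseline), names(panel)),
            all(baseline > 0 & baseline < 1))
  cells <- unique(as.data.table(design)[, .(experiment, tissue, group)])
  occ <- cells[, .(site_id = names(panel),
                   theta = unname(baseline[names(panel)])),
               by = .(experiment, tissue, group)]
  if (!is.null(overrides)) {
    ov <- as.data.table(overrides)
    stopifnot(all(c("site_id", "tissue", "group", "theta") %in% names(ov)),
              all(ov$theta > 0 & ov$theta < 1))
    occ[ov, on = c("site_id", "tissue", "group"), theta := i.theta]
  }
  setorder(occ, site_id, experiment, tissue, group)
  occ[]
}

# candidate peptide windows for a site: contain the residue, stay inside
# the protein, avoid every other panel site of the same protein, and occur
# exactly once in the whole protein collection
site_windows <- function(site, proteins, other_positions,
                         len_range = c(7L, 24L), max_candidates = 40L) {
  seq_ <- proteins[[site$protein_id]]
  L <- nchar(seq_)
  pos <- site$residue_position
  cand <- list()
  for (len in seq(len_range[1], len_range[2])) {
    lo <- max(1L, pos - len + 1L)
    hi <- min(pos, L - len + 1L)
    if (hi < lo) next
    for (start in seq(lo, hi)) {
      end <- start + len - 1L
      if (any(other_positions >= start & other_positions <= end)) next
      w <- substr(seq_, start, end)
      if (nrow(substring_hits(w, proteins)) != 1L) next
      cand[[length(cand) + 1L]] <- list(start = start, len = len, window = w)
      if (length(cand) >= max_candidates) return(cand)
    }
  }
  cand
}

# render a window into modified / unmodified sequence strings for a digest.
# Propionylation chemistry applies only to the trypsin digest: free
# (non-site-modified) lysines gain +56, and a lysine at the peptide
# N-terminus gains +112 (N-terminal + side-chain propionyl) unless it is
# the site residue itself.
render_form <- function(window, start, site, digest, modified) {
  chars <- strsplit(window, "", fixed = TRUE)[[1]]
  off <- site$residue_position - start + 1L
  ann <- rep("", length(chars))
  if (modified) ann[off] <- sprintf("[+%d]", site$mass)
  if (digest == "trypsin_propionyl") {
    for (k in seq_along(chars)) {
      if (chars[k] != "K") next
      if (k == off) {
        if (!modified) ann[k] <- "[+56]"
      } else {
        ann[k] <- if (k == 1L) "[+112]" else "[+56]"
      }
    }
  }
  paste(paste0(chars, ann), collapse = "")
}

#' Assemble a synthetic-study simulation configuration
#'
#' Fixes everything structural about a simulated study -- the site panel,
#' the protein sequences, the peptide forms covering each site in each of
#' the three digests, the design (fish per group per tissue) and the true
#' occupancies -- so that repeated noise draws (see
#' [simulate_quant_table()]) share one fixed quantification target. Form
#' windows are drawn deterministically from `structure_seed`.
#'
#' @param panel a [ptm_panel()].
#' @param proteins named sequences covering every panel site.
#' @param occupancy an [occupancy_table()].
#' @param design a [default_design()]-shaped table.
#' @param n_modified_range,n_unmodified_range inclusive ranges for the
#'   number of peptide forms carrying / lacking the mark, per site and
#'   digest (counts echo the worked examples of real histone data, where a
#'   site is quantified from a handful of modified and up to dozens of
#'   unmodified species; capped by the available distinct windows).
#' @param sigma_bio between-fish SD of occupancy on the natural-logit
#'   scale.
#' @param sigma_tech multiplicative technical noise SD on the log scale.
#' @param base_meanlog,base_sdlog log-normal parameters of the total
#'   covering abundance per (site, sample, digest), arbitrary
#'   normalized-intensity units.
#' @param structure_seed seed for the deterministic structural draws.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(panel, proteins, occupancy,
                              design = default_design(),
                              n_modified_range = c(1L, 6L),
                              n_unmodified_range = c(3L, 12L),
                              sigma_bio = 0.23, sigma_tech = 0.15,
                              base_meanlog = log(1e5), base_sdlog = 0.5,
                              structure_seed = 104729L) {
  stopifnot(inherits(panel, "ptm_panel"), all(as.data.table(design)$n >= 1L),
            sigma_bio >= 0, sigma_tech >= 0)
  panel_df <- as.data.table(as.data.frame(panel))
  alloc <- with_seed(structure_seed, {
    out <- vector("list", nrow(panel_df))
    for (s in seq_len(nrow(panel_df))) {
      site <- as.list(panel_df[s])
      others <- panel_df$residue_position[
        panel_df$protein_id == site$protein_id &
          panel_df$site_id != site$site_id]
      cand <- site_windows(site, proteins, others)
      if (length(cand) == 0L)
        stop("no usable peptide windows for site ", site$site_id)
      rows <- list()
      for (dg in digest_levels()) {
        n_mod <- sample(seq(n_modified_range[1], n_modified_range[2]), 1L)
        n_unm <- sample(seq(n_unmodified_range[1], n_unmodified_range[2]),
                        1L)
        pick_mod <- sample(length(cand), min(n_mod, length(cand)))
        pick_unm <- sample(length(cand), min(n_unm, length(cand)))
        for (w in cand[pick_mod])
          rows[[length(rows) + 1L]] <- data.table(
            site_id = site$site_id, digest = dg,
            modified_sequence = render_form(w$window, w$start, site, dg,
                                            TRUE),
            modified = TRUE)
        for (w in cand[pick_unm])
          rows[[length(rows) + 1L]] <- data.table(
            site_id = site$site_id, digest = dg,
            modified_sequence = render_form(w$window, w$start, site, dg,
                                            FALSE),
            modified = FALSE)
      }
      out[[s]] <- rbindlist(rows)
    }
    rbindlist(out)
  })
  structure(
    list(panel = panel, proteins = proteins,
         occupancy = as.data.table(occupancy),
         design = as.data.table(design), alloc = alloc,
         sigma_bio = sigma_bio, sigma_tech = sigma_tech,
         base_meanlog = base_meanlog, base_sdlog = base_sdlog,
         structure_seed = structure_seed),
    class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "<simulation_config> %d sites, %d proteins, %d peptide forms; sigma_bio=%.3g, sigma_tech=%.3g\n",
    length(x$panel), length(x$proteins), nrow(x$alloc), x$sigma_bio,
    x$sigma_tech))
  invisible(x)
}

# sample sheet for a (possibly subset) design
design_samples <- function(design) {
  design <- as.data.table(design)
  out <- design[, .(fish = seq_len(n)), by = .(experiment, tissue, group)]
  out[, fish_id := sprintf("%s_%s_f%d",
                           ifelse(experiment == "short_term", "ST", "LT"),
                           group, fish)]
  out[, sample_id := sprintf("%s_%s", fish_id, tissue)]
  out[, .(sample_id, fish_id, tissue, experiment, group)]
}

#' Simulate a peptide-level quant table with known ground truth
#'
#' For each fish, its occupancy of each site is the configured true
#' occupancy perturbed on the logit scale by `Normal(0, sigma_bio)`
#' (biological replicate noise; skipped exactly when `sigma_bio = 0`).
#' Per digest, the total covering abundance of each (site, sample) is
#' log-normal; modified forms share `theta_i` of it and unmodified forms
#' the rest, partitioned by symmetric Dirichlet weights re-drawn per fish
#' and digest, and every individual area is finally perturbed by
#' multiplicative log-normal technical noise. The same seed yields a
#' bit-identical table.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed for all noise draws.
#' @param tissues,experiments optional subsets of the design.
#' @return list with `table` (a [quant_table()]), `samples`, `truth`
#'   (occupancies with a per-site `responsive` flag), and `seed`.
#' @export
simulate_quant_table <- function(config, seed, tissues = NULL,
                                 experiments = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  des <- config$design
  if (!is.null(tissues)) des <- des[des$tissue %in% tissues, ]
  if (!is.null(experiments)) des <- des[des$experiment %in% experiments, ]
  if (nrow(des) == 0L) stop("design subset is empty")
  samples <- design_samples(des)
  occ <- config$occupancy
  set.seed(seed)
  # per-fish occupancy
  th <- samples[, .(sample_id, tissue, experiment, group)][
    , .(site_id = unique(config$alloc$site_id)),
    by = .(sample_id, tissue, experiment, group)]
  th <- occ[th, on = c("site_id", "experiment", "tissue", "group"),
            nomatch = NA]
  if (anyNA(th$theta))
    stop("occupancy table does not cover every (site, tissue, group)")
  setorder(th, site_id, sample_id)
  if (config$sigma_bio > 0) {
    th[, theta_i := plogis(qlogis(theta) +
                             rnorm(.N, 0, config$sigma_bio))]
  } else th[, theta_i := theta]
  # per (site, sample, digest) total covering abundance
  tot <- th[, .(digest = digest_levels()), by = .(site_id, sample_id)]
  setorder(tot, site_id, sample_id, digest)
  tot[, total := rlnorm(.N, config$base_meanlog, config$base_sdlog)]
  # expand forms x samples
  alloc <- copy(config$alloc)[, form_ord := .I]
  sid <- sort(unique(samples$sample_id))
  rows <- alloc[rep(seq_len(nrow(alloc)), each = length(sid))]
  rows[, sample_id := rep(sid, times = nrow(alloc))]
  setorder(rows, form_ord, sample_id)
  rows <- th[, .(site_id, sample_id, theta_i)][rows,
                                               on = c("site_id", "sample_id")]
  rows <- tot[rows, on = c("site_id", "sample_id", "digest")]
  setorder(rows, form_ord, sample_id)
  rows[, gamma_w := rgamma(.N, shape = 1, rate = 1)]
  rows[, w := gamma_w / sum(gamma_w),
       by = .(site_id, sample_id, digest, modified)]
  if (config$sigma_tech > 0) {
    rows[, tech := exp(rnorm(.N, 0, config$sigma_tech))]
  } else rows[, tech := 1]
  rows[, normalized_area := total *
         ifelse(modified, theta_i, 1 - theta_i) * w * tech]
  qt <- quant_table(
    rows[, .(modified_sequence, digest, sample_id, normalized_area)],
    samples = samples)
  truth <- occ[unique(samples[, .(experiment, tissue)]),
               on = c("experiment", "tissue")]
  flags <- truth[, .(responsive = max(theta) - min(theta) > 0),
                 by = .(site_id, experiment, tissue)]
  truth <- flags[truth, on = c("site_id", "experiment", "tissue")]
  list(table = qt, samples = samples, truth = truth, seed = seed)
}

#' Write a simulation run directory
#'
#' Emits the quant table, design and ground truth as tab-separated text
#' plus a `manifest.json` carrying the seed and structural settings.
#'
#' @param sim a [simulate_quant_table()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_simulation_run <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_quant_table(sim$table, file.path(dir, "quant_table.tsv"))
  fwrite(sim$samples, file.path(dir, "design.tsv"), sep = "\t")
  fwrite(sim$truth, file.path(dir, "ground_truth.tsv"), sep = "\t")
  jsonlite::write_json(
    list(seed = sim$seed,
         package_version = as.character(packageVersion("histodiff")),
         n_records = nrow(sim$table$records),
         n_samples = nrow(sim$samples)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

# deterministic synthetic protein: fixed residues at site positions,
# filler free of K/R/S/T so marks only occur where planted
synth_protein <- function(length, fixed = integer(0), residues = character(0)) {
  filler <- c("A", "C", "D", "E", "F", "G", "H", "I", "L", "M", "N", "P",
              "Q", "V", "W", "Y")
  chars <- sample(filler, length, replace = TRUE)
  if (length(fixed) > 0L) chars[fixed] <- residues
  paste(chars, collapse = "")
}

#' Shipped preset replaying the study's reported effects
#'
#' A 221-site panel with four planted group effects at the reported group
#' mean occupancies -- H1K16ub in the gills under short-term seawater
#' transfer (2.03% in FW, 3.78% in SW, 3.33% in SW/FW), H1S1ac in the
#' gills under long-term stress (5.59% in S0, 3.33% in S1), and H3K14ac
#' (27.5% to 15.3%, 16.0% after three pulses) and H3K18ub (5.0% to 2.2%,
#' 2.6%) in the testes under long-term stress -- among 217 null sites
#' whose occupancies span roughly 0.5% to 60% and are identical across
#' groups. Sample sizes follow [default_design()]. The four real sites sit
#' on the synthetic stand-in histone sequences shipped with the package;
#' null sites live on deterministically generated carrier proteins.
#'
#' @param sigma_bio,sigma_tech noise levels passed to
#'   [simulation_config()].
#' @param structure_seed structural seed passed through.
#' @return a [simulation_config()].
#' @export
study_replay_config <- function(sigma_bio = 0.23, sigma_tech = 0.15,
                                structure_seed = 104729L) {
  key <- sprintf("replay_%g_%g_%d", sigma_bio, sigma_tech, structure_seed)
  if (!is.null(.histodiff_cache[[key]])) return(.histodiff_cache[[key]])
  tab <- default_mass_table()
  fixtures <- read_protein_fasta(
    system.file("extdata", "synthetic_histones.fasta",
                package = "histodiff"))
  n_null <- 217L
  per_protein <- 10L
  n_prot <- ceiling(n_null / per_protein)
  spacing <- 30L
  null_mods <- list(
    list(mod = "acetyl", res = "K"), list(mod = "methyl", res = "K"),
    list(mod = "dimethyl", res = "K"), list(mod = "gly-gly", res = "K"),
    list(mod = "methyl", res = "R"), list(mod = "dimethyl", res = "R"))
  built <- with_seed(structure_seed + 1L, {
    prot <- list(); sites <- list()
    k <- 0L
    for (p in seq_len(n_prot)) {
      n_here <- min(per_protein, n_null - (p - 1L) * per_protein)
      pos <- 10L + spacing * (seq_len(n_here) - 1L)
      res <- character(n_here)
      for (i in seq_len(n_here)) {
        mspec <- null_mods[[(k + i - 1L) %% length(null_mods) + 1L]]
        res[i] <- mspec$res
      }
      pid <- sprintf("HVAR%02d", p)
      prot[[pid]] <- synth_protein(max(pos) + 20L, pos, res)
      for (i in seq_len(n_here)) {
        mspec <- null_mods[[(k + i - 1L) %% length(null_mods) + 1L]]
        sites[[k + i]] <- ptm_site(pid, pos[i], res[i],
                                   tab$defs[[mspec$mod]])
      }
      k <- k + n_here
    }
    list(proteins = unlist(prot), sites = sites)
  })
  real_sites <- list(
    ptm_site("H1x1", 16L, "K", tab$defs[["gly-gly"]],
             protein_name = "H1", abbreviated_name = "H1K16ub"),
    ptm_site("H1like", 1L, "S", tab$defs[["acetyl"]],
             protein_name = "H1", abbreviated_name = "H1S1ac"),
    ptm_site("H3", 14L, "K", tab$defs[["acetyl"]],
             protein_name = "H3", abbreviated_name = "H3K14ac"),
    ptm_site("H3", 18L, "K", tab$defs[["gly-gly"]],
             protein_name = "H3", abbreviated_name = "H3K18ub"))
  panel <- ptm_panel(c(real_sites, built$sites))
  proteins <- c(fixtures, built$proteins)
  baseline <- c(
    H1K16ub = 0.0203, H1S1ac = 0.0559, H3K14ac = 0.275, H3K18ub = 0.050,
    setNames(plogis(seq(-5.3, 0.5, length.out = n_null)),
             vapply(built$sites, `[[`, "", "abbreviated_name")))
  overrides <- rbindlist(list(
    data.table(site_id = "H1K16ub", tissue = "gills",
               group = c("FW", "SW", "SW_FW"),
               theta = c(0.0203, 0.0378, 0.0333)),
    data.table(site_id = "H1S1ac", tissue = "gills",
               group = c("S0", "S1", "S3"),
               theta = c(0.0559, 0.0333, 0.0450)),
    data.table(site_id = "H3K14ac", tissue = "testes",
               group = c("S0", "S1", "S3"),
               theta = c(0.275, 0.153, 0.160)),
    data.table(site_id = "H3K18ub", tissue = "testes",
               group = c("S0", "S1", "S3"),
               theta = c(0.050, 0.022, 0.026))))
  occ <- occupancy_table(panel, baseline, overrides)
  cfg <- simulation_config(panel, proteins, occ,
                           sigma_bio = sigma_bio, sigma_tech = sigma_tech,
                           structure_seed = structure_seed)
  .histodiff_cache[[key]] <- cfg
  cfg
}

# session cache for expensive deterministic builds
.histodiff_cache <- new.env(parent = emptyenv())

#' Global-null variant of a simulation configuration
#'
#' Returns the same configuration (same panel, proteins, peptide forms and
#' noise) with every planted group effect removed: within each
#' (site, experiment, tissue) cell, all groups get the first group's
#' occupancy. Useful for false-discovery calibration runs, since the
#' covering map of the original configuration still applies.
#'
#' @param config a [simulation_config()].
#' @return a [simulation_config()] under the global null.
#' @export
global_null_config <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  occ <- copy(config$occupancy)
  occ[, theta := theta[1L], by = .(site_id, experiment, tissue)]
  out <- config
  out$occupancy <- occ
  out
}
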