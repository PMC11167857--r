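#' Construct a peptide-level quant table
#'
#' The pipeline's raw input: one normalized-area value per (peptide form,
#' sample, digest). Areas come pre-normalized from upstream chromatographic
#' integration; no between-sample normalization happens here.
#'
#' @param records data.frame/data.table with columns `modified_sequence`,
#'   `digest`, `sample_id`, `normalized_area` (an optional `protein` column
#'   is carried through as a hint but localization is always recomputed).
#' @param samples optional sample design table with columns `sample_id`,
#'   `fish_id`, `tissue` (`gills`/`kidney`/`testes`), `experiment`
#'   (`short_term`/`long_term`), `group` (`FW`/`SW`/`SW_FW`/`S0`/`S1`/`S3`).
#' @return An object of class `quant_table` with elements `records`
#'   (keyed by `form_id`), `forms` (unique `(modified_sequence, digest)`
#'   pairs) and `samples`.
#' @export
quant_table <- function(records, samples = NULL) {
  rec <- as.data.table(records)
  need <- c("modified_sequence", "digest", "sample_id", "normalized_area")
  miss <- setdiff(need, names(rec))
  if (length(miss) > 0L)
    stop("quant table is missing required columns: ",
         paste(miss, collapse = ", "))
  rec[, normalized_area := as.numeric(normalized_area)]
  if (anyNA(rec$normalized_area) || any(rec$normalized_area < 0))
    stop("normalized_area must be nonnegative and numeric")
  bad <- setdiff(unique(rec$digest), digest_levels())
  if (length(bad) > 0L)
    stop("unknown digest condition(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(digest_levels(), collapse = "/"), ")")
  forms <- unique(rec[, .(modified_sequence, digest)])
  forms[, form_id := sprintf("F%05d", .I)]
  rec <- forms[rec, on = c("modified_sequence", "digest")]
  dup <- rec[, .N, by = .(form_id, sample_id, digest)][N > 1L]
  if (nrow(dup) > 0L) {
    k <- forms[dup[1L], on = "form_id"]
    stop(sprintf(
      "duplicate quant record(s): first offender (sequence=%s, sample=%s, digest=%s); %d duplicated keys in total",
      k$modified_sequence[1], dup$sample_id[1], dup$digest[1], nrow(dup)))
  }
  if (!is.null(samples)) {
    samples <- as.data.table(samples)
    validate_sample_meta(samples)
  }
  structure(list(records = rec, forms = forms, samples = samples),
            class = "quant_table")
}

#' @export
print.quant_table <- function(x, ...) {
  cat(sprintf(
    "<quant_table> %d records, %d peptide forms, %d samples, digests: %s\n",
    nrow(x$records), nrow(x$forms), length(unique(x$records$sample_id)),
    paste(sort(unique(x$forms$digest)), collapse = ", ")))
  invisible(x)
}

#' The three parallel digest conditions
#'
#' Propionylation followed by trypsin, V8 protease in ammonium bicarbonate,
#' and V8 protease in sodium phosphate; each yields a distinct peptide set
#' covering the same sites.
#'
#' @return character vector of digest labels.
#' @export
digest_levels <- function() c("trypsin_propionyl", "v8_ambic", "v8_naphos")

sample_groups <- function(experiment) {
  switch(experiment,
         short_term = c("FW", "SW", "SW_FW"),
         long_term = c("S0", "S1", "S3"),
         stop("unknown experiment: ", experiment))
}

validate_sample_meta <- function(samples) {
  need <- c("sample_id", "fish_id", "tissue", "experiment", "group")
  miss <- setdiff(need, names(samples))
  if (length(miss) > 0L)
    stop("sample table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in sample table")
  stopifnot(all(samples$tissue %in% c("gills", "kidney", "testes")),
            all(samples$experiment %in% c("short_term", "long_term")))
  ok <- mapply(function(g, e) g %in% sample_groups(e),
               samples$group, samples$experiment)
  if (!all(ok))
    stop("sample group inconsistent with experiment for sample(s): ",
         paste(samples$sample_id[!ok], collapse = ", "))
  invisible(samples)
}

#' Read / write quant tables as delimited text
#'
#' Long format, delimiter auto-detected between comma and tab. Rows that
#' fail validation individually (negative area, unknown digest) are
#' collected into a row-level error report; the read aborts only when the
#' unparseable fraction exceeds `max_bad_fraction`.
#'
#' @param path delimited file with the columns of [quant_table()].
#' @param samples optional design table (or path to one).
#' @param max_bad_fraction abort threshold for the fraction of bad rows.
#' @return A [quant_table()]; bad rows (if any) are attached as attribute
#'   `"row_errors"`.
#' @export
read_quant_table <- function(path, samples = NULL, max_bad_fraction = 0.05) {
  raw <- fread(path, sep = "auto", header = TRUE)
  need <- c("modified_sequence", "digest", "sample_id", "normalized_area")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0L)
    stop("quant table ", path, " missing columns: ",
         paste(miss, collapse = ", "))
  for (cc in c("modified_sequence", "digest", "sample_id"))
    raw[, (cc) := as.character(.SD[[1L]]), .SDcols = cc]
  if (is.character(samples) && length(samples) == 1L)
    samples <- fread(samples)
  raw[, normalized_area := suppressWarnings(as.numeric(normalized_area))]
  bad <- is.na(raw$normalized_area) | raw$normalized_area < 0 |
    !(raw$digest %in% digest_levels())
  if (any(bad)) {
    frac <- mean(bad)
    if (frac > max_bad_fraction)
      stop(sprintf("%d/%d rows (%.1f%%) unparseable, above the %.1f%% limit",
                   sum(bad), nrow(raw), 100 * frac, 100 * max_bad_fraction))
    warning(sprintf("dropping %d unparseable row(s)", sum(bad)))
  }
  qt <- quant_table(raw[!bad], samples = samples)
  attr(qt, "row_errors") <- raw[bad]
  qt
}

#' @rdname read_quant_table
#' @param qt a [quant_table()].
#' @param sep field separator (`"\t"` or `","`).
#' @export
write_quant_table <- function(qt, path, sep = "\t") {
  stopifnot(inherits(qt, "quant_table"))
  out <- qt$records[, .(modified_sequence, digest, sample_id,
                        normalized_area)]
  fwrite(out, path, sep = sep)
  invisible(path)
}

#' Precompute the site-to-peptide covering map
#'
#' Parses, localizes and classifies every unique peptide form once, then
#' records for every (site, digest) which forms cover the site's residue and
#' which of those carry the site's modification at exactly that residue.
#' "Unmodified" means lacking the mark of interest at the target residue --
#' a covering form may carry any other marks elsewhere. Ambiguously
#' localized forms are excluded from quantification by default (they would
#' be double-counted across histone variants); set
#' `ambiguous = "count_all"` to count them in every hit.
#'
#' @param panel a [ptm_panel()].
#' @param qt a [quant_table()] (or its `forms` table).
#' @param proteins named character vector of protein sequences.
#' @param table a [mass_table()].
#' @param ambiguous `"exclude"` (default) or `"count_all"`.
#' @return An object of class `ptm_quantifier`: list with `map` (data.table
#'   `site_id`, `digest`, `form_id`, `modified`), `form_info` (per-form
#'   localization status) and `errors` (forms that failed classification).
#' @export
ptm_quantifier <- function(panel, qt, proteins,
                           table = default_mass_table(),
                           ambiguous = c("exclude", "count_all")) {
  ambiguous <- match.arg(ambiguous)
  stopifnot(inherits(panel, "ptm_panel"))
  forms <- if (inherits(qt, "quant_table")) qt$forms else as.data.table(qt)
  seqs <- unique(forms$modified_sequence)
  info <- vector("list", length(seqs))
  marks <- vector("list", length(seqs))
  errors <- list()
  for (k in seq_along(seqs)) {
    sq <- seqs[k]
    pf <- tryCatch(parse_modified_sequence(sq), error = function(e) e)
    if (inherits(pf, "error")) {
      errors[[length(errors) + 1L]] <-
        data.table(modified_sequence = sq, stage = "parse",
                   message = conditionMessage(pf))
      next
    }
    pf <- localize_peptide(pf, proteins)
    cls <- tryCatch(classify_modifications(pf, table),
                    error = function(e) e)
    if (inherits(cls, "error")) {
      errors[[length(errors) + 1L]] <-
        data.table(modified_sequence = sq, stage = "classify",
                   message = conditionMessage(cls))
      next
    }
    hits <- switch(pf$status,
                   localized = pf$hits,
                   ambiguous = if (ambiguous == "count_all") pf$hits else
                     pf$hits[0L],
                   unlocalized = pf$hits)
    info[[k]] <- data.table(modified_sequence = sq, status = pf$status,
                            length = nchar(pf$stripped),
                            protein_id = if (nrow(hits) > 0L)
                              hits$protein_id[1] else NA_character_,
                            start = if (nrow(hits) > 0L) hits$start[1]
                            else NA_integer_)
    if (nrow(hits) > 0L && nrow(cls) > 0L)
      marks[[k]] <- rbindlist(lapply(seq_len(nrow(hits)), function(h)
        data.table(modified_sequence = sq,
                   protein_id = hits$protein_id[h],
                   abs_pos = hits$start[h] + cls$position - 1L,
                   residue = cls$residue, name = cls$name)))
    if (pf$status == "ambiguous" && ambiguous == "count_all") {
      # one info row per hit so every hit's span is counted
      info[[k]] <- data.table(modified_sequence = sq, status = pf$status,
                              length = nchar(pf$stripped),
                              protein_id = hits$protein_id,
                              start = hits$start)
    }
  }
  form_info <- rbindlist(info, fill = TRUE)
  mark_tab <- rbindlist(marks)
  panel_df <- as.data.table(as.data.frame(panel))
  usable <- form_info[form_info$status == "localized" |
                        (form_info$status == "ambiguous" &
                           ambiguous == "count_all"), ]
  map <- list()
  for (s in seq_len(nrow(panel_df))) {
    site <- panel_df[s]
    cov <- usable[usable$protein_id == site$protein_id &
                    usable$start <= site$residue_position &
                    usable$start + usable$length - 1L >=
                      site$residue_position, ]
    if (nrow(cov) == 0L) next
    if (nrow(mark_tab) > 0L) {
      mod_seqs <- unique(mark_tab[
        mark_tab$modified_sequence %in% cov$modified_sequence &
          mark_tab$protein_id == site$protein_id &
          mark_tab$abs_pos == site$residue_position &
          mark_tab$residue != "Nterm" &
          mark_tab$name == site$mod_name, ]$modified_sequence)
    } else mod_seqs <- character(0)
    # expand to (digest, sequence) pairs present in the form table
    fm <- forms[forms$modified_sequence %in% cov$modified_sequence,
                c("modified_sequence", "digest")]
    map[[length(map) + 1L]] <-
      data.table(site_id = site$site_id, digest = fm$digest,
                 modified_sequence = fm$modified_sequence,
                 modified = fm$modified_sequence %in% mod_seqs)
  }
  structure(list(map = unique(rbindlist(map)), form_info = form_info,
                 errors = rbindlist(errors), ambiguous = ambiguous),
            class = "ptm_quantifier")
}

#' @export
print.ptm_quantifier <- function(x, ...) {
  cat(sprintf(
    "<ptm_quantifier> %d (site, digest, form) links; %d forms (%d localized, %d ambiguous, %d unlocalized); %d form errors\n",
    nrow(x$map), nrow(x$form_info), sum(x$form_info$status == "localized"),
    sum(x$form_info$status == "ambiguous"),
    sum(x$form_info$status == "unlocalized"), nrow(x$errors)))
  invisible(x)
}

#' Partition covering peptide forms for one site and digest
#'
#' @param site a [ptm_site()].
#' @param qt a [quant_table()].
#' @param proteins protein sequences.
#' @param digest one of [digest_levels()].
#' @param ... passed to [ptm_quantifier()].
#' @return list with `modified` and `unmodified` character vectors of
#'   modified-sequence strings; empty partitions are legal.
#' @export
covering_forms <- function(site, qt, proteins, digest, ...) {
  q <- ptm_quantifier(ptm_panel(list(site)), qt, proteins, ...)
  if (nrow(q$map) == 0L)
    return(list(modified = character(0), unmodified = character(0)))
  m <- q$map[q$map$digest == digest, ]
  list(modified = m$modified_sequence[m$modified],
       unmodified = m$modified_sequence[!m$modified])
}

# per (site, sample, digest) sums -> long RA table; internal workhorse
ra_long <- function(quantifier, qt, digests = digest_levels()) {
  map <- quantifier$map
  if (nrow(map) == 0L)
    return(data.table(site_id = character(0), sample_id = character(0),
                      digest = character(0), ra = numeric(0)))
  rec <- qt$records[, .(modified_sequence, digest, sample_id,
                        normalized_area)]
  j <- map[rec, on = c("modified_sequence", "digest"), nomatch = NULL,
           allow.cartesian = TRUE]
  sums <- j[, .(area_mod = sum(normalized_area[modified]),
                area_all = sum(normalized_area)),
            by = .(site_id, sample_id, digest)]
  sums <- sums[digest %in% digests]
  sums[, ra := ifelse(area_all > 0, 100 * area_mod / area_all, NA_real_)]
  sums[!is.na(ra), .(site_id, sample_id, digest, ra)]
}

#' Relative abundance of a site in one sample and digest
#'
#' 100 x (summed area of covering forms carrying the mark) / (summed area of
#' all covering forms), or `NA` when the denominator is zero (no covering
#' signal in that digest).
#'
#' @inheritParams covering_forms
#' @param sample_id sample to evaluate.
#' @return percent in `[0, 100]`, or `NA_real_`.
#' @export
relative_abundance_per_digest <- function(site, qt, proteins, sample_id,
                                          digest, ...) {
  q <- ptm_quantifier(ptm_panel(list(site)), qt, proteins, ...)
  long <- ra_long(q, qt, digests = digest)
  v <- long$ra[long$sample_id == sample_id]
  if (length(v) == 0L) NA_real_ else v
}

#' Beta- and M-value transforms of relative abundance
#'
#' Beta is occupancy as a proportion, clamped into `[eps, 1 - eps]` so the
#' logit stays finite at 0% and 100%; the M-value is its logit. Base-2
#' logarithm by default (the beta/M convention of the DNA-methylation
#' literature these terms come from); natural log available, which rescales
#' every M-value by a constant and changes no test decision.
#'
#' @param ra relative abundance in percent.
#' @param eps clamping constant for beta (default `1e-4`).
#' @param logit_base 2 (default) or `exp(1)`.
#' @return numeric vector.
#' @export
beta_value <- function(ra, eps = 1e-4) pmin(pmax(ra / 100, eps), 1 - eps)

#' @rdname beta_value
#' @param beta proportion in `(0, 1)`.
#' @export
m_value <- function(beta, logit_base = 2) {
  log(beta / (1 - beta), base = logit_base)
}

#' Per-sample occupancy profile for one site
#'
#' Averages the per-digest relative abundances (unweighted mean over
#' non-missing digests -- each digest is one independent estimate of the
#' same occupancy regardless of how many peptide forms it contributes) and
#' derives beta and M-values. The profile is missing only when all digests
#' are.
#'
#' @inheritParams relative_abundance_per_digest
#' @param eps,logit_base see [beta_value()].
#' @return list with `site`, `sample_id`, `per_digest_ra` (named numeric),
#'   `relative_abundance`, `beta`, `m_value`, `missing`.
#' @export
mean_relative_abundance <- function(site, qt, proteins, sample_id,
                                    eps = 1e-4, logit_base = 2, ...) {
  q <- ptm_quantifier(ptm_panel(list(site)), qt, proteins, ...)
  long <- ra_long(q, qt)
  per <- setNames(rep(NA_real_, length(digest_levels())), digest_levels())
  rows <- long[long$sample_id == sample_id, ]
  per[rows$digest] <- rows$ra
  if (all(is.na(per))) {
    return(list(site = site, sample_id = sample_id, per_digest_ra = per,
                relative_abundance = NA_real_, beta = NA_real_,
                m_value = NA_real_, missing = TRUE))
  }
  ra <- mean(per, na.rm = TRUE)
  b <- beta_value(ra, eps)
  list(site = site, sample_id = sample_id, per_digest_ra = per,
       relative_abundance = ra, beta = b,
       m_value = m_value(b, logit_base), missing = FALSE)
}

#' Occupancy matrix for a whole panel
#'
#' One profile per (site, sample): per-digest relative abundances, their
#' mean, beta and M-value. Profiles with no covering signal in any digest
#' are reported missing and excluded from statistics downstream; a
#' completeness report is attached.
#'
#' @param panel a [ptm_panel()].
#' @param qt a [quant_table()].
#' @param proteins protein sequences; ignored when `quantifier` is given.
#' @param quantifier optional prebuilt [ptm_quantifier()] (reuse it when
#'   quantifying many tables that share one form set).
#' @param eps,logit_base see [beta_value()].
#' @param ... passed to [ptm_quantifier()].
#' @return An object of class `ptm_matrix`: data.table with columns
#'   `site_id`, `sample_id`, `ra_<digest>` per digest, `relative_abundance`,
#'   `beta`, `m_value`, `missing`; attributes `completeness` and
#'   `quantifier`.
#' @export
build_ptm_matrix <- function(panel, qt, proteins = NULL, quantifier = NULL,
                             eps = 1e-4, logit_base = 2, ...) {
  stopifnot(inherits(panel, "ptm_panel"), inherits(qt, "quant_table"))
  if (is.null(quantifier)) {
    stopifnot(!is.null(proteins))
    quantifier <- ptm_quantifier(panel, qt, proteins, ...)
  }
  long <- ra_long(quantifier, qt)
  samples <- sort(unique(qt$records$sample_id))
  grid <- data.table(expand.grid(site_id = names(panel),
                                 sample_id = samples,
                                 stringsAsFactors = FALSE))
  wide <- dcast(long, site_id + sample_id ~ digest, value.var = "ra")
  for (d in digest_levels())
    if (!d %in% names(wide)) wide[, (d) := NA_real_]
  out <- merge(grid, wide, by = c("site_id", "sample_id"), all.x = TRUE)
  setnames(out, digest_levels(), paste0("ra_", digest_levels()))
  racols <- paste0("ra_", digest_levels())
  out[, relative_abundance := rowMeans(.SD, na.rm = TRUE), .SDcols = racols]
  out[, missing := is.nan(relative_abundance)]
  out[missing == TRUE, relative_abundance := NA_real_]
  out[, beta := beta_value(relative_abundance, eps)]
  out[, m_value := m_value(beta, logit_base)]
  setorder(out, site_id, sample_id)
  n_missing <- sum(out$missing)
  if (n_missing > 0L)
    message(sprintf("ptm matrix: %d of %d (site, sample) profiles missing",
                    n_missing, nrow(out)))
  structure(out,
            class = c("ptm_matrix", class(out)),
            completeness = list(n_profiles = nrow(out) - n_missing,
                                n_missing = n_missing),
            quantifier = quantifier,
            logit_base = logit_base, eps = eps)
}

#' @rdname build_ptm_matrix
#' @param mat a `ptm_matrix`.
#' @param path output file.
#' @param sep field separator.
#' @export
write_ptm_matrix <- function(mat, path, sep = "\t") {
  fwrite(as.data.table(mat), path, sep = sep)
  invisible(path)
}
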