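#' Read protein sequences from FASTA
#'
#' Standard FASTA via Biostrings; the protein identifier is the first
#' whitespace-delimited token of the description line.
#'
#' @param path FASTA file.
#' @return named character vector of amino-acid sequences.
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- vapply(strsplit(names(aa), "[[:space:]]+"), `[[`, "", 1L)
  if (anyDuplicated(names(seqs)))
    stop("duplicate protein identifiers in ", path)
  seqs
}

# all (protein, start) exact-substring hits of `pattern` in `proteins`
substring_hits <- function(pattern, proteins) {
  hits <- lapply(names(proteins), function(id) {
    m <- gregexpr(pattern, proteins[[id]], fixed = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    data.table(protein_id = id, start = as.integer(m))
  })
  rbindlist(Filter(Negate(is.null), hits))
}

#' Localize a peptide form onto a protein collection
#'
#' Exact substring search of the stripped sequence against every protein.
#' A unique hit sets `source_protein` and `protein_start` so each annotation
#' gains an absolute residue position (`protein_start + peptide_position - 1`);
#' multiple hits flag the form `ambiguous` (all hits retained), zero hits
#' flag it `unlocalized`. Neither is an error: ambiguity and absence are
#' statuses the caller filters on.
#'
#' @param form a `peptide_form`.
#' @param proteins named character vector (see [read_protein_fasta()]).
#' @return the form, with `status` one of `localized` / `ambiguous` /
#'   `unlocalized`, and `hits` a data.table of all matches.
#' @export
localize_peptide <- function(form, proteins) {
  stopifnot(inherits(form, "peptide_form"), length(proteins) > 0L)
  hits <- substring_hits(form$stripped, proteins)
  form$hits <- hits
  if (nrow(hits) == 0L) {
    form$status <- "unlocalized"
  } else if (nrow(hits) == 1L) {
    form$status <- "localized"
    form$source_protein <- hits$protein_id[1]
    form$protein_start <- hits$start[1]
  } else {
    form$status <- "ambiguous"
  }
  form
}

#' Define a biological PTM site
#'
#' The unit of all downstream statistics: one modification on one residue of
#' one histone protein, e.g. H3 lysine-14 acetylation (`H3K14ac`).
#' Lab-introduced chemistry (propionylation) can never define a site, and
#' the residue must be able to carry the mark.
#'
#' @param protein_id identifier matching the FASTA.
#' @param residue_position 1-based residue position on the protein.
#' @param residue one-letter residue code at that position.
#' @param mod a [mod_def()] with `lab_introduced = FALSE`.
#' @param protein_name short display name (e.g. `"H3"`); default the id.
#' @param abbreviated_name site label; default
#'   `<protein_name><residue><position><mod abbrev>` (e.g. `H3K14ac`).
#' @return An object of class `ptm_site`.
#' @export
ptm_site <- function(protein_id, residue_position, residue, mod,
                     protein_name = protein_id,
                     abbreviated_name = NULL) {
  stopifnot(inherits(mod, "mod_def"))
  if (mod$lab_introduced)
    stop("ptm_site: '", mod$name,
         "' is lab-introduced chemistry and cannot define a PTM site")
  if (!residue %in% mod$residues)
    stop(sprintf("ptm_site: residue %s cannot carry %s (allowed: %s)",
                 residue, mod$name, paste(mod$residues, collapse = ",")))
  residue_position <- as.integer(residue_position)
  stopifnot(residue_position >= 1L)
  if (is.null(abbreviated_name))
    abbreviated_name <- paste0(protein_name, residue, residue_position,
                               mod$abbrev)
  structure(
    list(protein_id = protein_id, protein_name = protein_name,
         residue_position = residue_position, residue = residue,
         mod = mod, abbreviated_name = abbreviated_name),
    class = "ptm_site")
}

#' @export
print.ptm_site <- function(x, ...) {
  cat(sprintf("<ptm_site> %s: %s %s%d %s (Unimod %d)\n", x$abbreviated_name,
              x$protein_id, x$residue, x$residue_position, x$mod$name,
              x$mod$unimod))
  invisible(x)
}

#' Assemble a panel of PTM sites
#'
#' @param sites list of [ptm_site()] objects; abbreviated names must be
#'   unique within the panel.
#' @return An object of class `ptm_panel` (a named list of sites).
#' @export
ptm_panel <- function(sites) {
  stopifnot(length(sites) > 0L,
            all(vapply(sites, inherits, TRUE, "ptm_site")))
  nm <- vapply(sites, `[[`, "", "abbreviated_name")
  if (anyDuplicated(nm))
    stop("duplicate abbreviated site names in panel: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  names(sites) <- nm
  structure(sites, class = "ptm_panel")
}

#' @export
print.ptm_panel <- function(x, ...) {
  cat(sprintf("<ptm_panel> %d sites: %s%s\n", length(x),
              paste(head(names(x), 6L), collapse = ", "),
              if (length(x) > 6L) ", ..." else ""))
  invisible(x)
}

#' @export
as.data.frame.ptm_panel <- function(x, ...) {
  do.call(rbind, lapply(unname(x), function(s)
    data.frame(site_id = s$abbreviated_name, protein_id = s$protein_id,
               protein_name = s$protein_name,
               residue_position = s$residue_position, residue = s$residue,
               mod_name = s$mod$name, unimod = s$mod$unimod,
               mass = s$mod$mass, stringsAsFactors = FALSE)))
}
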