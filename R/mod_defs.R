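#' Modification definitions and the nominal mass table
#'
#' Peptide export strings annotate modifications as bracketed nominal
#' (integer) mass shifts, e.g. `K[+42]`. A [mod_def()] resolves one such
#' shift on one residue class to a modification identity carrying its Unimod
#' accession. Derivatization chemistry (propionylation of free lysines and
#' peptide N-termini) is part of sample preparation, not biology, and is
#' flagged `lab_introduced` so it can never define a biological PTM site.
#'
#' @param name modification name, e.g. `"acetyl"`.
#' @param unimod integer Unimod accession of the modification class.
#' @param mass nonzero integer nominal mass shift in Da.
#' @param residues character vector of one-letter residue codes that can
#'   carry the mark; the special code `"Nterm"` means the peptide N-terminus.
#' @param lab_introduced logical; `TRUE` for sample-preparation chemistry.
#' @param abbrev short suffix used in site names (e.g. `"ac"` in `H3K14ac`).
#' @return An object of class `mod_def`.
#' @export
mod_def <- function(name, unimod, mass, residues, lab_introduced = FALSE,
                    abbrev = name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  mass <- as.integer(mass)
  if (is.na(mass) || mass == 0L)
    stop("mod_def '", name, "': nominal mass must be a nonzero integer")
  if (length(residues) == 0L)
    stop("mod_def '", name, "': allowed_residues must be non-empty")
  structure(
    list(name = name, unimod = as.integer(unimod), mass = mass,
         residues = unique(as.character(residues)),
         lab_introduced = isTRUE(lab_introduced),
         abbrev = as.character(abbrev)),
    class = "mod_def")
}

#' @export
print.mod_def <- function(x, ...) {
  cat(sprintf("<mod_def> %s (Unimod %d): %+d Da on %s%s\n", x$name,
              x$unimod, x$mass, paste(x$residues, collapse = ","),
              if (x$lab_introduced) " [lab-introduced]" else ""))
  invisible(x)
}

#' Build a mass table from modification definitions
#'
#' A mass table is the configuration that resolves `(nominal mass, residue)`
#' pairs to modification identities. Ambiguity -- two definitions claiming
#' the same `(mass, residue)` pair -- is a configuration error, rejected at
#' construction rather than tie-broken silently.
#'
#' @param defs list of [mod_def()] objects.
#' @return An object of class `mass_table`.
#' @export
mass_table <- function(defs) {
  stopifnot(length(defs) > 0L, all(vapply(defs, inherits, TRUE, "mod_def")))
  names(defs) <- vapply(defs, `[[`, "", "name")
  if (anyDuplicated(names(defs)))
    stop("duplicate modification names in mass table")
  pairs <- rbindlist(lapply(defs, function(d)
    data.table(name = d$name, mass = d$mass, residue = d$residues)))
  dup <- pairs[, .N, by = .(mass, residue)][N > 1L]
  if (nrow(dup) > 0L)
    stop("ambiguous mass table: (",
         paste(sprintf("%+d on %s", dup$mass, dup$residue), collapse = "; "),
         ") each resolve to more than one modification")
  structure(list(defs = defs, pairs = pairs), class = "mass_table")
}

#' @export
print.mass_table <- function(x, ...) {
  cat(sprintf("<mass_table> %d modifications\n", length(x$defs)))
  for (d in x$defs) print(d)
  invisible(x)
}

#' Default nominal mass table for propionylated histone peptides
#'
#' Ships the shifts seen in histone DIA exports: +42 acetyl (ambiguous with
#' trimethyl at nominal resolution; resolved to acetyl by default, override
#' via configuration), +56 propionyl (lab-introduced), +114 GG / ubiquityl
#' remnant, +14/+28 mono/dimethyl, +32 dioxidation, +156 4-hydroxynonenal.
#' A +57 entry is carried as an explicitly unassigned lab-flagged shift:
#' it occurs in real exports on lysine but matches no biological histone
#' mark at nominal mass, so it must parse and classify without ever
#' defining a PTM site.
#'
#' @return A [mass_table()].
#' @export
default_mass_table <- function() {
  mass_table(list(
    mod_def("acetyl",      1L,  42L, c("K", "S", "T", "Nterm"), abbrev = "ac"),
    mod_def("propionyl",  58L,  56L, c("K", "Nterm"), lab_introduced = TRUE,
            abbrev = "pr"),
    mod_def("gly-gly",   121L, 114L, "K", abbrev = "ub"),
    mod_def("methyl",     34L,  14L, c("K", "R"), abbrev = "me1"),
    mod_def("dimethyl",   36L,  28L, c("K", "R"), abbrev = "me2"),
    mod_def("dioxidation", 425L, 32L, c("M", "W"), abbrev = "ox2"),
    mod_def("hne",        53L, 156L, c("C", "H", "K"), abbrev = "hne"),
    mod_def("unassigned57", -1L, 57L, c("K", "S", "T"), lab_introduced = TRUE,
            abbrev = "x57")
  ))
}

#' Read / write a mass table as YAML
#'
#' The on-disk form is a list of entries keyed by modification name, each
#' with `unimod`, `mass`, `residues`, `lab_introduced` and `abbrev` fields;
#' `write_mass_table()` followed by `read_mass_table()` is the identity.
#'
#' @param path file path.
#' @return `read_mass_table()` returns a [mass_table()];
#'   `write_mass_table()` returns `path` invisibly.
#' @export
read_mass_table <- function(path) {
  raw <- yaml::read_yaml(path)
  mass_table(lapply(names(raw), function(nm) {
    e <- raw[[nm]]
    mod_def(nm, unimod = e$unimod, mass = e$mass, residues = e$residues,
            lab_introduced = isTRUE(e$lab_introduced),
            abbrev = if (is.null(e$abbrev)) nm else e$abbrev)
  }))
}

#' @rdname read_mass_table
#' @param table a [mass_table()].
#' @export
write_mass_table <- function(table, path) {
  stopifnot(inherits(table, "mass_table"))
  out <- lapply(table$defs, function(d)
    list(unimod = d$unimod, mass = d$mass, residues = as.list(d$residues),
         lab_introduced = d$lab_introduced, abbrev = d$abbrev))
  yaml::write_yaml(out, path)
  invisible(path)
}

# definitions matching (mass, residue); residue may be "Nterm"
mods_for <- function(table, mass, residue) {
  keep <- table$pairs$mass == as.integer(mass) &
    table$pairs$residue == residue
  table$defs[table$pairs$name[keep]]
}
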