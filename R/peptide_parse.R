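#' Parse a modified-peptide sequence string
#'
#' Quant exports annotate modifications inline as bracketed integer mass
#' shifts following the modified residue, e.g. `"K[+112]STGGK[+42]APR"`.
#' Whitespace inside brackets (as some reports print, `"[+ 42]"`) is
#' tolerated and dropped. A bracket group before any residue letter is an
#' N-terminal annotation assigned to peptide position 1. Several groups on
#' the same residue are summed into one nominal shift; decomposition back
#' into individual marks is [classify_modifications()]'s job.
#'
#' @param raw non-empty sequence string.
#' @return A `peptide_form`: list with `stripped` (plain sequence),
#'   `annotations` (data.table with columns `position`, `mass`, `nterm`),
#'   and localization fields (`source_protein`, `protein_start`, `status`)
#'   filled by [localize_peptide()].
#' @seealso [serialize_peptide_form()] for the canonical inverse.
#' @export
parse_modified_sequence <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || !nzchar(raw))
    stop("parse error: input must be a single non-empty string")
  chars <- strsplit(raw, "", fixed = TRUE)[[1]]
  n <- length(chars)
  residues <- character(0)
  ann <- list()   # each: c(position, mass, nterm)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (grepl("^[A-Za-z]$", ch)) {
      residues <- c(residues, toupper(ch))
      i <- i + 1L
    } else if (ch == "[") {
      close <- i
      repeat {
        close <- close + 1L
        if (close > n)
          stop(sprintf("parse error at offset %d: unbalanced '['", i))
        if (chars[close] == "]") break
      }
      body <- gsub("[[:space:]]", "", paste(chars[(i + 1L):(close - 1L)],
                                            collapse = ""))
      if (!grepl("^[+-][0-9]+$", body))
        stop(sprintf(
          "parse error at offset %d: bracket group '[%s]' is not [+N]/[-N]",
          i, paste(chars[(i + 1L):(close - 1L)], collapse = "")))
      mass <- as.integer(body)
      if (mass == 0L)
        stop(sprintf("parse error at offset %d: zero mass shift", i))
      if (length(residues) == 0L) {
        ann[[length(ann) + 1L]] <- c(1L, mass, 1L)   # N-terminal group
      } else {
        ann[[length(ann) + 1L]] <- c(length(residues), mass, 0L)
      }
      i <- close + 1L
    } else if (ch == "]") {
      stop(sprintf("parse error at offset %d: ']' without '['", i))
    } else {
      stop(sprintf("parse error at offset %d: unexpected character '%s'",
                   i, ch))
    }
  }
  if (length(residues) == 0L)
    stop("parse error: no residues in sequence")
  if (length(ann) > 0L) {
    a <- as.data.table(do.call(rbind, ann))
    setnames(a, c("position", "mass", "nterm"))
    # sum repeated groups on the same residue (same N-terminal status)
    a <- a[, .(mass = sum(mass)), by = .(position, nterm)]
    a[, nterm := as.logical(nterm)]
    setorder(a, position, -nterm)
  } else {
    a <- data.table(position = integer(0), mass = integer(0),
                    nterm = logical(0))
  }
  structure(
    list(stripped = paste(residues, collapse = ""), annotations = a,
         digest = NA_character_, source_protein = NA_character_,
         protein_start = NA_integer_, status = "unlocalized",
         hits = NULL),
    class = "peptide_form")
}

#' Canonical serialization of a peptide form
#'
#' Writes the bracket notation with no whitespace; an N-terminal annotation
#' is printed before the first residue. Parsing then re-serializing a
#' canonical string is the identity.
#'
#' @param form a `peptide_form`.
#' @return character scalar.
#' @export
serialize_peptide_form <- function(form) {
  stopifnot(inherits(form, "peptide_form"))
  res <- strsplit(form$stripped, "", fixed = TRUE)[[1]]
  a <- form$annotations
  out <- character(0)
  nt <- a[a$nterm == TRUE, ]
  if (nrow(nt) > 0L)
    out <- sprintf("[%+d]", nt$mass)
  for (k in seq_along(res)) {
    out <- c(out, res[k])
    side <- a[a$position == k & a$nterm == FALSE, ]
    if (nrow(side) > 0L)
      out <- c(out, sprintf("[%+d]", side$mass))
  }
  paste(out, collapse = "")
}

#' @export
print.peptide_form <- function(x, ...) {
  cat("<peptide_form>", serialize_peptide_form(x), "\n")
  cat("  status:", x$status)
  if (x$status == "localized")
    cat(sprintf(" (%s @ %d)", x$source_protein, x$protein_start))
  cat("\n")
  invisible(x)
}

#' Resolve annotated mass shifts to modification identities
#'
#' Each `(position, mass)` annotation must resolve to exactly one
#' modification definition for the residue at that position, with one
#' decomposition rule: a shift at peptide position 1 equal to the sum of an
#' N-terminus-allowed mass and a residue-allowed mass is split into both
#' marks (the classic case is +112 on an N-terminal lysine = N-terminal
#' propionyl +56 plus side-chain propionyl +56). Unresolvable shifts raise
#' an error naming every candidate considered -- they are never dropped.
#'
#' @param form a `peptide_form`.
#' @param table a [mass_table()]; default [default_mass_table()].
#' @return data.table with one row per resolved mark: `position`, `residue`
#'   (`"Nterm"` for the N-terminal component), `mass`, `name`, `unimod`,
#'   `lab_introduced`, `abbrev`.
#' @export
classify_modifications <- function(form, table = default_mass_table()) {
  stopifnot(inherits(form, "peptide_form"), inherits(table, "mass_table"))
  a <- form$annotations
  if (nrow(a) == 0L)
    return(data.table(position = integer(0), residue = character(0),
                      mass = integer(0), name = character(0),
                      unimod = integer(0), lab_introduced = logical(0),
                      abbrev = character(0)))
  out <- vector("list", nrow(a))
  for (k in seq_len(nrow(a))) {
    pos <- a$position[k]; m <- a$mass[k]; nterm <- a$nterm[k]
    res <- substr(form$stripped, pos, pos)
    target_res <- if (nterm) "Nterm" else res
    direct <- mods_for(table, m, target_res)
    if (length(direct) == 1L) {
      d <- direct[[1]]
      out[[k]] <- data.table(position = pos, residue = target_res, mass = m,
                             name = d$name, unimod = d$unimod,
                             lab_introduced = d$lab_introduced,
                             abbrev = d$abbrev)
      next
    }
    if (pos == 1L) {
      # subset-sum over (N-term-allowed, residue-allowed) definition pairs
      nterm_defs <- Filter(function(d) "Nterm" %in% d$residues, table$defs)
      side_defs <- Filter(function(d) res %in% d$residues, table$defs)
      combos <- list()
      for (d1 in nterm_defs) for (d2 in side_defs)
        if (d1$mass + d2$mass == m)
          combos[[length(combos) + 1L]] <- list(d1, d2)
      if (length(combos) == 1L) {
        d1 <- combos[[1]][[1]]; d2 <- combos[[1]][[2]]
        out[[k]] <- data.table(
          position = c(1L, 1L), residue = c("Nterm", res),
          mass = c(d1$mass, d2$mass), name = c(d1$name, d2$name),
          unimod = c(d1$unimod, d2$unimod),
          lab_introduced = c(d1$lab_introduced, d2$lab_introduced),
          abbrev = c(d1$abbrev, d2$abbrev))
        next
      }
      if (length(combos) > 1L)
        stop(sprintf(
          "classification error: %+d at N-terminal %s decomposes ambiguously: %s",
          m, res,
          paste(vapply(combos, function(cc)
            paste0(cc[[1]]$name, "+", cc[[2]]$name), ""), collapse = "; ")))
    }
    cand <- table$pairs[table$pairs$residue %in% c(res, if (pos == 1L) "Nterm"), ]
    stop(sprintf(
      "classification error: %+d on %s at position %d matches no definition (candidates considered for %s: %s)",
      m, res, pos, res,
      if (nrow(cand) > 0L)
        paste(sprintf("%s %+d", cand$name, cand$mass), collapse = ", ")
      else "none"))
  }
  rbindlist(out)
}
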