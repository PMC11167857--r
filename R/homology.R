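#' BLOSUM62 substitution matrix
#'
#' Loaded from Biostrings' shipped data; unknown residues score through the
#' `X` row/column.
#'
#' @return integer matrix.
#' @export
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

aa_indices <- function(seq, mat) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  chars[!chars %in% rownames(mat)] <- "X"
  match(chars, rownames(mat))
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman--Wunsch/Gotoh alignment: a gap of length L costs
#' `gap_open + L * gap_extend` (both penalties positive). Traceback
#' tie-breaking is deterministic: a substitution column is preferred over a
#' gap in `a`, which is preferred over a gap in `b`. Non-standard residues
#' are scored as `X`.
#'
#' @param a,b non-empty amino-acid sequences (character scalars).
#' @param substitution_matrix scoring matrix; default [blosum62()].
#' @param gap_open,gap_extend positive gap penalties (defaults 10 and 1).
#' @return An object of class `residue_map`: list with `query_protein`,
#'   `target_protein` (names, if `a`/`b` are named), `pairs` (data.table
#'   `query_position`, `target_position`, `NA` marking a gap on either
#'   side), `alignment_score`, and the two aligned strings.
#' @export
global_align <- function(a, b, substitution_matrix = blosum62(),
                         gap_open = 10, gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) stop("global_align: empty sequence")
  qname <- if (!is.null(names(a))) names(a) else NA_character_
  tname <- if (!is.null(names(b))) names(b) else NA_character_
  S <- substitution_matrix
  ia <- aa_indices(a, S); ib <- aa_indices(b, S)
  n <- length(ia); m <- length(ib)
  NEG <- -1e9
  # M: a[i] aligned to b[j]; X: gap in b (a[i] unmatched); Y: gap in a
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)
  Y <- matrix(NEG, n + 1L, m + 1L)
  M[1, 1] <- 0
  if (n >= 1L) X[2:(n + 1L), 1] <- -(gap_open + gap_extend * seq_len(n))
  if (m >= 1L) Y[1, 2:(m + 1L)] <- -(gap_open + gap_extend * seq_len(m))
  for (i in seq_len(n)) {
    Srow <- S[ia[i], ]
    for (j in seq_len(m)) {
      sc <- Srow[ib[j]]
      M[i + 1L, j + 1L] <- sc + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1L, j + 1L] <- max(
        M[i, j + 1L] - gap_open - gap_extend,
        X[i, j + 1L] - gap_extend)
      Y[i + 1L, j + 1L] <- max(
        M[i + 1L, j] - gap_open - gap_extend,
        Y[i + 1L, j] - gap_extend)
    }
  }
  score <- max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
  # traceback; preference: substitution > gap in a (consume b) > gap in b
  i <- n; j <- m
  state <- c("M", "Y", "X")[which.max(
    c(M[n + 1L, m + 1L], Y[n + 1L, m + 1L], X[n + 1L, m + 1L]))]
  qpos <- integer(0); tpos <- integer(0)
  while (i > 0L || j > 0L) {
    if (state == "M") {
      qpos <- c(i, qpos); tpos <- c(j, tpos)
      sc <- S[ia[i], ib[j]]
      prev <- c(M[i, j], Y[i, j], X[i, j])
      state <- c("M", "Y", "X")[which.max(prev)]
      i <- i - 1L; j <- j - 1L
    } else if (state == "Y") {        # gap in a: consumes b[j]
      qpos <- c(NA_integer_, qpos); tpos <- c(j, tpos)
      from_m <- M[i + 1L, j] - gap_open - gap_extend
      from_y <- Y[i + 1L, j] - gap_extend
      state <- if (from_m >= from_y) "M" else "Y"
      j <- j - 1L
    } else {                          # X: gap in b: consumes a[i]
      qpos <- c(i, qpos); tpos <- c(NA_integer_, tpos)
      from_m <- M[i, j + 1L] - gap_open - gap_extend
      from_x <- X[i, j + 1L] - gap_extend
      state <- if (from_m >= from_x) "M" else "X"
      i <- i - 1L
    }
    if (i == 0L && j > 0L) state <- "Y"
    if (j == 0L && i > 0L) state <- "X"
  }
  achars <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  bchars <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  aligned_a <- paste(ifelse(is.na(qpos), "-", achars[qpos]), collapse = "")
  aligned_b <- paste(ifelse(is.na(tpos), "-", bchars[tpos]), collapse = "")
  structure(
    list(query_protein = qname, target_protein = tname,
         pairs = data.table(query_position = qpos, target_position = tpos),
         alignment_score = unname(score),
         aligned_query = aligned_a, aligned_target = aligned_b),
    class = "residue_map")
}

#' @export
print.residue_map <- function(x, ...) {
  cat(sprintf("<residue_map> score %.1f\n  %s\n  %s\n",
              x$alignment_score, x$aligned_query, x$aligned_target))
  invisible(x)
}

#' Cross-species analog call for one PTM site
#'
#' Projects the site's residue position through a global alignment of its
#' protein against a target-species homolog. The aligned target residue
#' must be chemically able to carry the modification (per the
#' modification's allowed residues) for an analog to exist: e.g. a
#' lysine-ubiquitylation site whose aligned target residue is arginine has
#' no analog, because ubiquitylation does not occur on arginine. A site
#' falling in a target deletion has no analog either.
#'
#' @param site a [ptm_site()].
#' @param query_sequence sequence of the site's own protein.
#' @param target_sequence homologous protein of the other species.
#' @param substitution_matrix,gap_open,gap_extend see [global_align()].
#' @return list of class `analog_call`: `site`, `target_position`,
#'   `target_residue`, `verdict` (`analog` /
#'   `no_analog_incompatible_residue` / `no_analog_gap`), `conserved`
#'   (target residue letter equals the site's), `alignment_score`.
#' @export
analog_for_site <- function(site, query_sequence, target_sequence,
                            substitution_matrix = blosum62(),
                            gap_open = 10, gap_extend = 1) {
  stopifnot(inherits(site, "ptm_site"))
  qres <- substr(query_sequence, site$residue_position,
                 site$residue_position)
  if (!nzchar(qres) || qres != site$residue)
    stop(sprintf(
      "site %s does not localize on the query sequence (expected %s at %d, found '%s')",
      site$abbreviated_name, site$residue, site$residue_position, qres))
  al <- global_align(query_sequence, target_sequence,
                     substitution_matrix, gap_open, gap_extend)
  row <- al$pairs[which(al$pairs$query_position == site$residue_position), ]
  tpos <- row$target_position[1]
  if (is.na(tpos)) {
    verdict <- "no_analog_gap"; tres <- NA_character_; conserved <- FALSE
  } else {
    tres <- substr(target_sequence, tpos, tpos)
    if (tres %in% site$mod$residues) {
      verdict <- "analog"; conserved <- tres == site$residue
    } else {
      verdict <- "no_analog_incompatible_residue"; conserved <- FALSE
    }
  }
  structure(list(site = site, target_position = tpos,
                 target_residue = tres, verdict = verdict,
                 conserved = conserved,
                 alignment_score = al$alignment_score,
                 residue_map = al),
            class = "analog_call")
}

#' @export
print.analog_call <- function(x, ...) {
  cat(sprintf("<analog_call> %s -> %s\n", x$site$abbreviated_name,
              if (x$verdict == "analog")
                sprintf("%s%d (%s)", x$target_residue, x$target_position,
                        if (x$conserved) "conserved" else "substituted")
              else x$verdict))
  invisible(x)
}

#' Analog report for a site panel
#'
#' Runs [analog_for_site()] for every panel site against the target
#' homolog named by `protein_map`, and returns (optionally writes) a
#' delimited report. Sites whose protein has no mapped target, or that do
#' not localize on their query sequence, get a per-site error entry rather
#' than aborting the report.
#'
#' @param panel a [ptm_panel()].
#' @param query_proteins,target_proteins named sequence vectors (see
#'   [read_protein_fasta()]).
#' @param protein_map named character vector: query protein id -> target
#'   protein id.
#' @param path optional output file (tab-separated).
#' @param ... passed to [analog_for_site()].
#' @return data.table with one row per site: `site_id`, `query_protein`,
#'   `target_protein`, `target_position`, `target_residue`, `verdict`,
#'   `conserved`, `alignment_score`, `error`.
#' @export
analog_report <- function(panel, query_proteins, target_proteins,
                          protein_map, path = NULL, ...) {
  stopifnot(inherits(panel, "ptm_panel"))
  rows <- lapply(unname(panel), function(site) {
    tgt <- if (site$protein_id %in% names(protein_map))
      protein_map[[site$protein_id]] else NULL
    base <- data.table(site_id = site$abbreviated_name,
                       query_protein = site$protein_id,
                       target_protein = if (is.null(tgt)) NA_character_
                       else tgt,
                       target_position = NA_integer_,
                       target_residue = NA_character_,
                       verdict = NA_character_, conserved = NA,
                       alignment_score = NA_real_, error = NA_character_)
    if (is.null(tgt) || !tgt %in% names(target_proteins) ||
        !site$protein_id %in% names(query_proteins)) {
      base$error <- "no target homolog mapped for this protein"
      return(base)
    }
    call <- tryCatch(
      analog_for_site(site, query_proteins[[site$protein_id]],
                      target_proteins[[tgt]], ...),
      error = function(e) e)
    if (inherits(call, "error")) {
      base$error <- conditionMessage(call)
      return(base)
    }
    base$target_position <- call$target_position
    base$target_residue <- call$target_residue
    base$verdict <- call$verdict
    base$conserved <- call$conserved
    base$alignment_score <- call$alignment_score
    base
  })
  out <- rbindlist(rows)
  if (!is.null(path)) fwrite(out, path, sep = "\t")
  out
}
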