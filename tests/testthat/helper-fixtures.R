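# Shared fixtures, all built in code.

h3_tail <- "ARTKQTARKSTGGKAPRKQLATKAARKSAPAT"

fixture_fasta <- function() {
  system.file("extdata", "synthetic_histones.fasta", package = "histodiff")
}

fixture_proteins <- function() read_protein_fasta(fixture_fasta())

human_proteins <- function() {
  read_protein_fasta(system.file("extdata",
                                 "synthetic_human_histones.fasta",
                                 package = "histodiff"))
}

toy_site <- function(id = c("H3K14ac", "H3K18ub", "H1K16ub", "H1S1ac")) {
  id <- match.arg(id)
  tab <- default_mass_table()
  switch(id,
    H3K14ac = ptm_site("H3", 14L, "K", tab$defs[["acetyl"]],
                       protein_name = "H3", abbreviated_name = "H3K14ac"),
    H3K18ub = ptm_site("H3", 18L, "K", tab$defs[["gly-gly"]],
                       protein_name = "H3", abbreviated_name = "H3K18ub"),
    H1K16ub = ptm_site("H1x1", 16L, "K", tab$defs[["gly-gly"]],
                       protein_name = "H1", abbreviated_name = "H1K16ub"),
    H1S1ac = ptm_site("H1like", 1L, "S", tab$defs[["acetyl"]],
                      protein_name = "H1", abbreviated_name = "H1S1ac"))
}

# minimal quant table: one site (H3 K14 acetyl), configurable areas
k14_quant_table <- function(mod_area = 200, unmod_area = 800,
                            sample_id = "s1",
                            digest = "trypsin_propionyl") {
  quant_table(data.frame(
    modified_sequence = c("K[+112]STGGK[+42]APR", "K[+112]STGGK[+56]APR"),
    digest = digest, sample_id = sample_id,
    normalized_area = c(mod_area, unmod_area)))
}

# small 4-site simulation config on deterministic carrier proteins
small_sim_config <- function(sigma_bio = 0, sigma_tech = 0,
                             baseline = c(T1K10ac = 0.2, `T1K40ub` = 0.05,
                                          T2R10me1 = 0.5, T2K40ac = 0.8),
                             overrides = NULL, structure_seed = 7L) {
  tab <- default_mass_table()
  prot <- histodiff:::with_seed(structure_seed, c(
    T1 = histodiff:::synth_protein(60L, c(10L, 40L), c("K", "K")),
    T2 = histodiff:::synth_protein(60L, c(10L, 40L), c("R", "K"))))
  panel <- ptm_panel(list(
    ptm_site("T1", 10L, "K", tab$defs[["acetyl"]]),
    ptm_site("T1", 40L, "K", tab$defs[["gly-gly"]]),
    ptm_site("T2", 10L, "R", tab$defs[["methyl"]]),
    ptm_site("T2", 40L, "K", tab$defs[["acetyl"]])))
  occ <- occupancy_table(panel, baseline[names(panel)],
                         overrides = overrides)
  simulation_config(panel, prot, occ,
                    n_modified_range = c(1L, 2L),
                    n_unmodified_range = c(2L, 4L),
                    sigma_bio = sigma_bio, sigma_tech = sigma_tech,
                    structure_seed = structure_seed)
}

# independent alignment oracles ----------------------------------------

# exhaustive enumeration of every global alignment (lengths <= ~5);
# adjacent opposite-direction gap runs are scored as two separate gaps
enum_align_score <- function(a, b, S, gap_open, gap_extend) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, moves) {
    if (i == length(ca) && j == length(cb)) {
      best <<- max(best, score_moves(moves, ca, cb, S, gap_open,
                                     gap_extend))
      return(invisible())
    }
    if (i < length(ca) && j < length(cb)) rec(i + 1, j + 1, c(moves, "M"))
    if (i < length(ca)) rec(i + 1, j, c(moves, "X"))
    if (j < length(cb)) rec(i, j + 1, c(moves, "Y"))
  }
  rec(0L, 0L, character(0))
  best
}

score_moves <- function(moves, ca, cb, S, gap_open, gap_extend) {
  i <- 0L; j <- 0L; sc <- 0; prev <- ""
  for (mv in moves) {
    if (mv == "M") {
      i <- i + 1L; j <- j + 1L
      sc <- sc + S[ca[i], cb[j]]
    } else if (mv == "X") {
      i <- i + 1L
      sc <- sc - gap_extend - if (prev == "X") 0 else gap_open
    } else {
      j <- j + 1L
      sc <- sc - gap_extend - if (prev == "Y") 0 else gap_open
    }
    prev <- mv
  }
  sc
}

# memoized best-score recursion over (i, j, previous move); permits every
# move sequence (including adjacent opposite gaps as separate gaps)
recursive_align_score <- function(a, b, S, gap_open, gap_extend) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  na <- length(ca); nb <- length(cb)
  memo <- array(NA_real_, dim = c(na + 1L, nb + 1L, 3L))
  prevs <- c("M", "X", "Y")
  f <- function(i, j, prev) {
    if (i == na && j == nb) return(0)
    key <- c(i + 1L, j + 1L, match(prev, prevs))
    if (!is.na(memo[key[1], key[2], key[3]]))
      return(memo[key[1], key[2], key[3]])
    best <- -Inf
    if (i < na && j < nb)
      best <- max(best, S[ca[i + 1L], cb[j + 1L]] + f(i + 1L, j + 1L, "M"))
    if (i < na)
      best <- max(best, -gap_extend - (if (prev == "X") 0 else gap_open) +
                    f(i + 1L, j, "X"))
    if (j < nb)
      best <- max(best, -gap_extend - (if (prev == "Y") 0 else gap_open) +
                    f(i, j + 1L, "Y"))
    memo[key[1], key[2], key[3]] <<- best
    best
  }
  f(0L, 0L, "M")
}

# simple match/mismatch matrix over a reduced alphabet
simple_matrix <- function(alphabet = c("A", "C", "G", "T"),
                          match = 2, mismatch = -1) {
  m <- matrix(mismatch, length(alphabet), length(alphabet),
              dimnames = list(alphabet, alphabet))
  diag(m) <- match
  m
}

random_seq <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
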