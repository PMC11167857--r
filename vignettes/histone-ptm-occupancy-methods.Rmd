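---
title: "Quantifying histone PTM occupancy and testing salinity responsiveness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying histone PTM occupancy and testing salinity responsiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histodiff)
```

## The measurement model

Bottom-up histone proteomics never observes a modification site directly.
After acid extraction, histones are digested three parallel ways
(propionylation followed by trypsin; V8 protease in ammonium bicarbonate;
V8 in sodium phosphate), and a data-independent-acquisition workflow
reports a *normalized area* for every quantifiable peptide species — a
stripped sequence plus its set of mass shifts, written
`K[+112]STGGK[+42]APR`. Each digest yields a different peptide set covering
the same residues, so one site (say H3 lysine 14 acetylation, `H3K14ac`)
is covered by a handful of peptide forms that carry the mark and a larger
collection that do not.

The *relative abundance* (occupancy) of a site in a sample is computed per
digest as

$$\mathrm{RA}_d \;=\; 100 \times
  \frac{\sum_{\text{covering forms with the mark}} \text{area}}
       {\sum_{\text{all covering forms}} \text{area}},$$

and the per-digest values are averaged with equal weight. Equal weighting
(rather than weighting by the number of contributing forms) treats each
digest as one independent estimate of the same underlying occupancy; a
digest with no covering signal is simply absent from the mean, and a
profile is missing only when all three digests are. "Covering" means the
localized peptide span includes the site's residue; "carrying the mark"
means the classified modification sits at exactly that residue —
a peptide acetylated at a *different* lysine counts as unmodified for this
site.

Downstream statistics use the logit scale: `beta = RA/100` clamped into
`[1e-4, 1 - 1e-4]` so that fully unmodified or fully modified sites remain
testable, and the M-value `M = log2(beta / (1 - beta))`. Base-2 logarithms
follow the beta/M convention of the DNA-methylation literature these terms
are borrowed from; a natural-log option rescales every M-value by a
constant and cannot change any test decision.

## Parsing, classification, localization

The parser accepts bracketed integer shifts after a residue (whitespace
inside brackets, as figure captions print them, is ignored), assigns a
leading bracket group to position 1 with an N-terminal flag, and sums
repeated groups on one residue. Re-serialization to the canonical
no-space form is the identity, which the tests exercise on the worked
peptides.

Shifts resolve against a configurable nominal mass table
(`default_mass_table()`, YAML round-trip via `read_mass_table()`):
+42 acetyl (K/S/T/N-terminus), +56 propionyl (lab-introduced), +114
GG/ubiquityl remnant, +14/+28 mono- and dimethyl (K/R), +32 dioxidation,
+156 4-hydroxynonenal. Three deliberate choices live here:

* **+42 is nominally ambiguous** between acetyl and trimethyl
  (42.011 vs 42.047 Da). The default resolves to acetyl; a configuration
  can re-point the pair per residue, and configuring *both* on the same
  residue is rejected as an error rather than silently tie-broken.
* **+112 on an N-terminal lysine** matches no single definition; it is
  decomposed by an exhaustive pair search over (N-terminus-allowed,
  residue-allowed) masses into N-terminal + side-chain propionyl. Any
  other unresolvable shift is an error that names the candidates
  considered — shifts are never dropped.
* **+57 on lysine** occurs in real exports but matches no biological
  histone mark at nominal mass; the shipped entry is explicitly
  unassigned and flagged lab-introduced, so such peptides parse, classify
  and count as covering forms while the shift can never define a site.

Localization is exact substring search against the protein FASTA.
Ambiguous peptides (multiple hits — common for the N-terminal stretch
shared by H1 isoforms) are excluded from quantification by default to
avoid double counting across histone variants; `ambiguous = "count_all"`
counts them in every hit. Coordinates are 1-based on both peptide and
protein, so K14 is the fourteenth residue.

## Differential testing

Within each tissue, every pair of treatment groups of an experiment
(short-term: SW vs FW, SW/FW vs FW, SW vs SW/FW; long-term: S1 vs S0,
S3 vs S0, S3 vs S1) is one correction family. Per site:

* **Welch t-test on M-values** (Student's available by configuration).
  Welch is the default because occupancy variance differs visibly between
  groups in this kind of data. A `1e-12` variance floor per group keeps
  constant groups testable: equal constants give t = 0, p = 1; different
  constants give a finite, extreme statistic. Sites with fewer than two
  usable samples in either group are excluded and the realized family
  size is reported.
* **Fold change on the percent scale**, `log2(mean RA_A / mean RA_B)`
  with group A the treatment and B the reference, means clamped at 0.01
  percent. The volcano fold-change cutoff is `|log2 FC| > 1`; the study
  design this emulates never states its cutoff, so it is exposed in
  `comparison_config()` and recorded in the run manifest.
* **Conditioned q-values.** The null proportion is estimated by FDR
  regression on a per-site covariate — the modification class, keyed by
  Unimod accession. For each lambda in `0.05, 0.10, ..., 0.95` the
  indicator `1(p > lambda)` is regressed on the covariate (logistic link;
  a linear-probability option mirrors the reference implementation's
  default), the fitted probability is divided by `1 - lambda`, each
  covariate level's lambda-profile is smoothed with a cubic smoothing
  spline (df = 3) and read off at lambda = 0.95, then clipped into
  `[0, 1]`. Covariate levels with fewer than two tests merge into the
  largest level; a separated fit falls back to intercept-only for that
  lambda. Both events are logged. With a single configured lambda the
  smoothing is skipped. Finally `q_i = pi0_i x BH_i`.
* **Monotonicity.** q-values are made non-decreasing along increasing p
  by a cumulative maximum from the smallest p upward. The step-up
  direction used by single-pi0 q-value software (cumulative minimum from
  the largest p downward) is wrong here: with covariate-varying pi0 it
  propagates one optimistic level estimate across the entire family. The
  cumulative maximum never lowers the q of a smaller p, preserves the
  exact reduction to Benjamini–Hochberg when pi0 = 1, and is
  conservative.

A site is called *salinity-responsive* when its conditioned q-value is
below 0.1. Volcano classes follow the two significance axes: red (both),
blue (q only), green (fold change only), gray (neither).

The read-off at the largest lambda makes the pi0 estimate noisy at
realistic family sizes: on a uniform p-vector of length 2000 its sampling
SD is about 0.03 (mean about 0.97), and at m = 221 per-level estimates
can dip well below 1 by chance. The global-null simulations in the test
suite measure the practical consequence: the per-family probability of at
least one q < 0.1 call sits slightly above the nominal 0.1, within the
binomial band the tests check. This finite-sample behaviour is a property
of the estimator itself, not of this implementation.

## Cross-species analog mapping

Analog calls project a site's residue through a global pairwise alignment
(Needleman–Wunsch with affine gaps; BLOSUM62, gap open 10, extend 1, a
gap of length L costing `open + L x extend`). Only pairwise projection is
needed, so a self-contained aligner replaces a multiple-alignment tool; a
three-sequence comparison is handled as two pairwise alignments against
the target. Traceback ties break deterministically: substitution over gap
in the query, over gap in the target. Unknown residues score as `X`.

The modification's allowed-residue set is the sole arbiter of chemistry:
a lysine-ubiquitylation site whose aligned human residue is arginine has
**no analog**, because ubiquitylation does not occur on arginine; a site
opposite a gap has no analog either. Analog calls also report whether the
residue letter is conserved. The shipped FASTA fixtures are synthetic
stand-ins (named so in file and headers) built to reproduce the
structural situations of interest — the H1-isoform K16 lysine aligning
onto an arginine eight residues deeper into the human sequence, a shared
serine 1, and identical H3 tails — not the real accessions, which are
accepted as pre-downloaded inputs when available.

Position numbering of N-terminal residues follows the input FASTA as
given; whether a sequence includes its initiator methionine is the
caller's convention and is deliberately not second-guessed.

## The synthetic-data generator

`simulation_config()` fixes everything structural — panel, carrier
proteins, and the peptide windows covering each site in each digest,
drawn deterministically from a `structure_seed` — so that repeated noise
draws (`simulate_quant_table(config, seed)`) share one quantification
target, and a fixed seed reproduces a table bit for bit. Per fish, the
site occupancy is the configured truth perturbed on the natural-logit
scale by `Normal(0, sigma_bio)` (skipped exactly at `sigma_bio = 0`, so
noise-free closure is exact to machine precision). Per digest, the total
covering abundance is log-normal (`meanlog = log(1e5)`, `sdlog = 0.5`,
arbitrary units); the modified forms share `theta_i` of it and the
unmodified forms the rest, split by symmetric Dirichlet(1) weights
re-drawn per fish and digest; each area then receives multiplicative
log-normal technical noise `exp(Normal(0, sigma_tech))`.

Forms per site and digest are drawn from ranges (1–6 modified, 3–12
unmodified), echoing the worked examples of real histone data where a
site is quantified from a few modified and up to dozens of unmodified
species; window lengths span 7–24 residues, must localize uniquely, and
avoid covering any *other* panel site. That last constraint is a
deliberate simplification: real peptides do span neighbouring sites
(H3 K14 and K18 are four residues apart), which couples their
denominators; the generator keeps sites independent so ground truth is
exactly recoverable. Trypsin-digest forms carry the propionylation
chemistry (+56 on free lysines, +112 on an unmodified N-terminal lysine),
so every simulated table exercises the decomposition and
lab-vs-biological classification paths.

`study_replay_config()` is the shipped study preset: 221 sites — four
planted effects at the reported group-mean occupancies (H1K16ub gills
2.03 → 3.78% with recovery 3.33%; H1S1ac gills 5.59 → 3.33%; H3K14ac
testes 27.5 → 15.3%, 16.0% after three pulses; H3K18ub testes
5.0 → 2.2%, 2.6%) and 217 null sites whose occupancies span ~0.5–62%
(logit-uniform) and are identical across groups — at the study's sample
sizes (short-term: 6 gills, 6 kidney, 3 testes per group; long-term: 8
gills, 6 kidney, 6 testes). The S3 group mean of H1S1ac is not reported
anywhere; the preset plants 4.5%, between the two reported means, to
match the qualitative account. Null modification classes cycle through
acetyl, methyl, dimethyl and GG on K plus methyl/dimethyl on R so the
FDR-regression covariate has realistic levels.

**Noise calibration.** The reported effects come with p-values, and
inverting the Welch statistic at the printed (effect, n, p) triples gives
the per-fish natural-logit SD each effect must have had: 0.209, 0.242,
0.246, 0.269 (mean 0.241). Fixing technical noise at a 15% area CV and
measuring (by simulation at `sigma_bio = 0`) that it contributes 0.073 to
the M-value SD leaves `sigma_bio = sqrt(0.241^2 - 0.073^2) ≈ 0.23`. The
derivation is `analysis/00_calibrate_noise.R`; the defaults are
`sigma_bio = 0.23`, `sigma_tech = 0.15`. Between-fish occupancy variance
is not printed anywhere, so these are declared, calibrated assumptions —
not estimates of the real tissues.

What passing tests on this generator do **not** show about real data:
no shared peptides across sites, no retention-time or spectral artifacts,
no missingness mechanism beyond zero-coverage digests, independent
tissues within a fish, and log-normal noise by construction.

## Problem sizes in the tests and acceptance script

The test suite verifies noise-free closure, scale invariance,
complementarity and monotonicity exactly; pi0 calibration on m = 2000
uniform draws (the 0.05 band is checked on the mean over five fixed
draws, matching the estimator's ~0.03 single-draw SD); family-wise
false-call behaviour over 100 global-null simulations of the long-term
gill design (binomial consistency bound at the 99.5th percentile of
Binomial(100, 0.1)); and recovery of all four planted effects into their
families' top 10 by p-value in at least 90% of 50 simulations. The
aligner is checked against full enumeration of alignment space on tiny
pairs, a memoized move-sequence oracle up to length 8, and
`Biostrings::pairwiseAlignment` on longer random pairs.
`scripts/acceptance.R` recomputes the same quantities at smaller seed
counts (40 null, 25 replay) chosen to keep a full run under two minutes.

## Known limitations

* The FDR-regression estimator is anti-conservative in finite samples;
  with 221 tests, expect the realized family-wise call rate under the
  null to run a few points above the nominal q threshold.
* `RA` ratios are slightly biased when a digest contributes very few
  modified forms (Jensen effect of technical noise on the ratio); at the
  calibrated noise this is well under a relative percent.
* The aligner is O(nm) dynamic programming in plain R — fine for histone
  lengths, not for proteome scans.
* Quantification trusts upstream normalization; no between-sample
  normalization or peptide-intensity imputation is attempted, by design.
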