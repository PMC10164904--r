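---
title: "From K-OPL screen signal to proteome-wide substrate prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From K-OPL screen signal to proteome-wide substrate prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(koplr)
library(dplyr)
```

## The experiment this package models

A lysine-oriented peptide library (K-OPL) probes the sequence selectivity of a
lysine methyltransferase with degenerate 7-mer peptide mixtures. Every peptide
has lysine at the central position (P0, the methyl acceptor); each *set*
additionally fixes one residue at one of the six flanking positions P-3..P+3,
with the remaining five positions fully degenerate. With the 19-letter
fixed-residue alphabet (the 20 standard amino acids minus cysteine, which is
conventionally excluded from synthesized libraries because its thiol
cross-links) there are 6 × 19 = 114 sets, and the degenerate positions over
the full 20-letter alphabet give 20^6 = 64 million distinct 7-mers:

```{r}
nrow(kopl_sets())
sequence_space_size()
```

A curiosity of these two alphabet choices, worth knowing when reasoning about
coverage: a 7-mer whose six flank residues are *all* cysteine belongs to no
set, so the union of set memberships covers 20^6 − 1 sequences, not 20^6.
`sequence_space_size()` reports |alphabet|^6 by definition. Both alphabets are
arguments, not constants, so libraries with other exclusions are supported.

Each set is assayed in replicate (typically triplicate) by a scintillation
surface proximity assay; the readout is counts per minute (cpm) of transferred
tritiated methyl groups. The screen table is therefore 114 rows × a ragged
number of replicate columns — the package accepts n ≥ 1 replicates per set
because real screens occasionally carry a duplicate cell among triplicates.

## From cpm to a scoring matrix

The pipeline is deliberately simple and follows the assay's own arithmetic,
in this order:

1. **Average** replicates per set (arithmetic mean).
2. **Normalize**. *Global* mode divides every cell by the single highest mean
   cpm — this is the matrix used for scoring. *Position* mode divides each
   position's cells by that position's maximum and exists for per-position
   selectivity heatmaps; `scan_proteome()` refuses position-mode matrices
   because their columns are not on a common scale.
3. **Transform**: x → ln(1 + x), the natural log after a +1 pseudocount *on
   the normalized scale*, mapping [0, 1] to [0, ln 2]. The transform is
   strictly monotone, so it preserves every within- and across-position
   ordering while compressing the dynamic range that the additive score sums
   over.

No background subtraction is applied before normalization: the assay's
background is part of the signal model and the normalization is scale-free. A
constant-subtraction option was considered and rejected as a default because
the appropriate constant is assay-specific and unknown in general; users can
subtract from the mean-signal table themselves before `normalize_screen()`.

The PSSM score of a lysine-centered 7-mer is the sum over its six flanking
positions of the matrix entry for the residue observed there. The central K is
fixed in every library peptide and carries no information, so it contributes
0. Scores therefore live in [0, 6·ln 2 ≈ 4.159], and score differences between
single-residue variants equal single matrix-entry differences (additivity) —
which is what makes variant rank prediction with
`predict_variant_order()` exact rather than approximate.

**Cysteine-containing motifs.** Under the default 19-letter fixed alphabet the
matrix has no Cys row. The default policy (`unmatched = "skip"`) leaves such
motifs unscored and counts them in the run log, so no reported score is ever
built from an imputed cell; `unmatched = "zero"` is available when a complete
ranking matters more than strict provenance.

**Terminal lysines.** Lysines within three residues of a protein terminus are
skipped, not padded: the library contains only complete 7-mers, so the matrix
has no model of what a missing flank residue "costs". A padding mode is
deliberately not provided.

**Phospho rows.** Screens may include sets with fixed phosphorylated Ser, Thr
or Tyr (lowercase `s`/`t`/`y` codes). They are parsed, normalized and stored in
the matrix — they are informative about modification cross-talk — but excluded
from grid-completeness checks and from proteome scanning, which operates on
unmodified sequence.

## Ranking and thresholding

`scan_proteome()` deduplicates identical 7-mers by default ("sequence motifs"),
carrying every site per motif; per-site ranking is a flag away. Ordering is
deterministic: score descending, then motif alphabetically. `rank` is dense and
1-based; `percentile` is 100 × the fraction of unique motifs scoring at or
below the row, so ties share a percentile and the top score sits at 100.

`top_candidates()` implements the "top fraction" rule as
`ceiling(fraction × N)` rows of the ordered table, with the alphabetical
tie-break deciding equal-score blocks that straddle the cutoff. A score-range
mode (`score ≥ max − fraction × (max − min)`) is provided behind a flag because
"top X%" is genuinely ambiguous between the two readings for published screens;
the package makes no attempt to decide which one any particular published count
used. Candidate curation (tissue expression, pathway links, domain context) is
modeled as declarative boolean filters over a user-supplied annotation table —
it is judgment applied to external resources, not an algorithm, so the package
stores and filters it rather than pretending to reproduce it.

## What the synthetic generator emulates — and what it does not

`simulate_screen()` draws each set's replicates as
`cpm = (baseline + amplitude × weight) × exp(ε)`, `ε ~ N(0, σ²)`:

* **Linear signal in the fixed cell's weight.** The degenerate positions of a
  set contribute an average activity factor that is the same for every set and
  is absorbed into `amplitude`. This is the simplest model under which
  single-cell preferences are readable from set-level signals; it ignores
  real couplings between positions (a set's degenerate mixture is scored by
  the enzyme, not by one residue at a time).
* **Multiplicative log-normal noise** rather than additive Gaussian: cpm data
  are positive and heteroskedastic, and the multiplicative model keeps
  replicates positive without truncation. The defaults — `baseline_cpm = 500`,
  `amplitude_cpm = 5000` (a 10:1 dynamic range over background), `σ = 0.1`,
  triplicates — are a choice of plausible assay conditions: the true noise
  magnitude of any given screen is not identifiable from published figures, so
  σ here is illustrative, not fitted.
* **Not modeled:** plate-layout artifacts, bead-binding kinetics, tritium
  decay, reaction-rate saturation, phospho-set chemistry. Passing recovery
  tests therefore demonstrate that the *arithmetic* of the pipeline inverts
  the generative model; they do not certify performance on a real screen whose
  noise structure violates these assumptions.

The default planted truth, `prdm9_like_profile()`, is a synthetic stylization
of a PRDM9-class selectivity pattern — weight 1 at (P-1, I), 0.9 at (P+1, K),
0.6 at (P-3, S) and (P+2, T), floor 0.05 elsewhere. It is used only as test
ground truth and is not a measured matrix.

`simulate_proteome()` writes known lysine-centered 7-mers over non-overlapping
interior windows of uniformly random proteins and returns the truth table of
planted sites, so scan results can be checked against ground truth end to end.

## Measuring recovery, and a caution about Spearman with tied truth

`recovery_report()` compares a recovered matrix with the planted weights:
per-position and overall Spearman rank correlation, a concordance index, and
whether the argmax cell matches. One property deserves emphasis because it is
easy to misread as a pipeline failure:

With a floor-style truth profile, each position's truth vector holds ≥ 18
*tied* values. Any noise at all breaks those ties in the recovered matrix, and
Spearman computed on average ranks is then bounded far below 1 — for one
elevated cell among 19 the ceiling is ≈ 0.387 — *even when the recovery is as
good as it can possibly be*. The bound is a property of the statistic under
ties, not of the estimator: at σ = 0 the ties survive the (strictly monotone)
pipeline and Spearman is exactly 1, while for any σ > 0 it collapses to the
ceiling. For this reason `recovery_report()` also reports a concordance index
computed only over pairs whose truth weights differ (+1 when every such pair
is ordered correctly, −1 when every one is inverted); it is immune to floor
ties and is the number to read when the truth contains them. Positions whose
truth (or estimate) is constant have no defined rank correlation and are
flagged not-applicable rather than given a value.

## Numerical and design choices

* Ties anywhere a single winner is needed (validation-set picks, equal-score
  candidate blocks) break alphabetically by residue or motif — deterministic
  and documented, with a `degenerate` flag where a tie collapses the
  high/medium/low triple.
* "Approximately half the signal" and "near background" in validation-set
  selection are operationalized as closest-to-half-of-high and
  closest-to-background; background defaults to the position's minimum mean
  signal, since assays rarely publish their no-enzyme baseline.
* Matrix files carry `# mode:` and `# transformed:` headers and 15 significant
  digits, so write→read→write is byte-stable and entries round-trip well below
  1e-12.
* All generators take an integer seed that fully determines output.
* Coordinates are 1-based and inclusive; a motif's span is
  [center − 3, center + 3].

Problem sizes used by the test suite — full 114-set screens, proteomes of
50 proteins of 100–300 residues, 20 simulation seeds, 100-protein oracle
comparisons — were chosen so the whole suite exercises every pipeline stage at
realistic density while remaining quick enough to run on every change.

## Worked chain

```{r, message = FALSE}
truth <- prdm9_like_profile()
pssm <- simulate_screen(truth, sigma = 0.1, seed = 7) |>
  average_replicates() |>
  normalize_screen("global") |>
  log_transform()
glance(pssm)

sim <- simulate_proteome(50, c(100, 300),
                         planted = tibble::tibble(motif = "SAIKKTA", copies = 5),
                         seed = 7)
hits <- scan_proteome(sim$proteins, pssm, quiet = TRUE) |>
  top_candidates(0.01)
hits
glance(recovery_report(pssm, truth))
```

The planted optimal motif tops the candidate table with all five planted
sites, and the recovery glance shows the tied-truth Spearman ceiling alongside
a concordance of 1 — the behaviour discussed above.

## Known limitations

* The selectivity model is strictly additive across positions; cooperative or
  anti-cooperative flanking effects are invisible to it by construction.
* Structural context (surface accessibility of the candidate lysine) is out of
  scope; candidate tables should be filtered by such knowledge via the
  annotation mechanism.
* Methylation state (mono/di/tri) is not predicted.
* The scan treats the proteome as linear sequence; splice isoforms and
  modified residues are whatever the input FASTA says they are.
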