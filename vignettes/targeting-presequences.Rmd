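---
title: "Scoring bipartite targeting presequences: models, parameters and design choices"
author: "BTScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring bipartite targeting presequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BTScan)
```

## The biological model

Proteins imported into rhodophyte-derived secondary plastids carry a
bipartite targeting signal: a cleavable ER signal peptide immediately
followed by a chloroplast-type transit peptide. Signal peptidase removes
the signal peptide; the residue exposed at the new N-terminus — position
+1 in the convention used throughout this package — is frequently an
invariant phenylalanine in these lineages, and the strength of that
conservation is species-specific. Mitochondrial presequences are
shorter, positively charged and arginine-rich; secretory proteins carry
the signal peptide alone; cytosolic proteins have no presequence.

BTScan operationalizes this picture in four layers: cleavage-site
prediction and consensus, bit-score matrix training, sliding-window
scanning with a classification cascade, and threshold calibration by
sensitivity/precision sweeps.

## Cleavage sites and consensus

A cleavage site is stored as the 1-based index of the *last* signal
peptide residue, so the mature protein starts at `position + 1`. The
internal predictor is a log-odds position weight matrix over offsets
−13..+2 (the classic signal-peptidase footprint: the hydrophobic h-region
tail, the c-region with its (−3, −1) small-residue constraint, and the
first two mature residues). Cell values are

```
cell(o, a) = log2( (count(a at o) + q) / (n_eff(o) + 20 q) / background(a) )
```

with pseudocount `q` (default 1) and a uniform 0.05 background by
default; a background estimated from cytosolic references can be
supplied instead. `X` never enters the counts: `n_eff` is per-offset, so
single ambiguous residues do not discard whole training rows — a
deliberate choice for the small curated reference sets this tool
targets. Candidate positions 10..45 are scanned (N-terminal extensions
of plastid references run roughly 40–80 residues with the signal peptide
in the first half; mitochondrial extensions are shorter), each scored by
the sum of its window cells (`X` contributes 0), and the best position is
reported when it reaches `minScore` (default 4 bits, i.e. a 16-fold
enrichment over background across the window). Ties go to the smallest
position, making the scan fully deterministic.

Consensus over several predictors is a *strict majority of the
predictors that returned any site*, requiring exact positional identity.
Both choices were genuinely open: "majority" could mean ≥ 2 of 4, and
near-identical positions (±1) could plausibly count as agreement. We
default to the strict reading because it is the only one that is
unambiguous and order-independent, and expose `tolerance` for the
relaxed variant; with tolerance on, the supported position with maximal
support wins, ties to the smallest position. The returned consensus
carries the number of supporting predictors as its score.

## Bit-score matrices

Training windows (default offsets −10..+15, covering the signal-peptide
C-region and the early transit peptide; the span is configurable since
no canonical value exists) are stacked over the consensus sites and
converted to sequence-logo weights:

* `freq(o, a) = (count + q) / (n_eff + 20 q)`, default `q = 0`;
* `info(o) = log2(20) − H(o) − e(n_eff)` with
  `H(o) = −Σ_a freq log2 freq` and the Schneider small-sample correction
  `e(n) = 19 / (2 ln 2 · n)`, on by default for training;
* `cell(o, a) = freq(o, a) · info(o)`.

Negative post-correction information is clamped to zero. The rationale
is structural, not cosmetic: the cells feed a *cumulative* scorer, and a
column that carries no information must contribute nothing rather than
subtract noise. Unit tests that check analytic identities (uniform
column → 0 bits, invariant column → log2 20, the two-residue closed
form) run with the correction off, since the identities hold exactly
only for the uncorrected entropy.

The conservation identity `Σ_a cell(o, a) = info(o)` holds at machine
precision by construction and is enforced by the class validity check,
as are `Σ_a freq = 1` and `0 ≤ info ≤ log2 20`.

`exportLogo()` renders the matrix as a logo (bits or frequency mode),
letters drawn as stacked coloured tiles with heights equal to the cells;
the cleavage boundary is marked between offsets 0 and +1, where the
scissile bond lies.

## Scanning and classification

For a protein with a consensus site, the cumulative score is the sum of
`cell(o, residue at site + o)` over the full matrix span. Separately, a
window of length 5 over matrix offsets +1..+5 is slid across shifts
−5..+5 (the window at shift `d` starts at residue `site + 1 + d`), and
the best-scoring shift — ties resolved to the smallest |d|, then the
smallest d — must fall within ±2 of the anchor for the scan to "agree".
The window length and tolerance reflect that the Phe motif occupies +1
and that the scan's purpose is to *localize* it around the predicted
site, not to re-find the site.

Two compositions of the plastid score were conceivable: the full-span
sum at the anchor, or the best window's score. We define the cumulative
score as the full-span sum and keep window agreement as a separate
boolean, and document it here precisely because published cumulative
scores of similar scanners are not decomposable from the outside;
results are self-consistent within this package but not numerically
comparable to other tools.

The classification cascade is: no consensus site → mitochondrion if an
external mitochondrial score passes its threshold, else other; site
present → plastid iff cumulative ≥ threshold AND the window agrees;
site present but not plastid → secretory. Species presets ship at 1.4
(cvelia profile) and 1.0 (vbrassicaformis profile); both are overridable
and, on synthetic cohorts, better operating points are obtained by
sweeping (below). Mitochondrial calling is intentionally delegated to
external predictor scores — presequence-based mitochondrial prediction
is a different modelling problem, and the package's adapters parse those
tools' outputs instead.

## Threshold calibration

`sensitivity = TP/(TP+FN)` and `precision = TP/(TP+FP)` are computed
with an *inclusive* comparison (score ≥ threshold); inclusivity is a
convention choice that matters at tied scores and is therefore fixed and
documented. Undefined ratios (no positives; nothing passing) return
`NA` markers and are kept in curves, never coerced to 0 or 1 — silently
treating an empty denominator as a number inflates curves at their ends.

`selectThreshold()` makes the dual-threshold scheme explicit and
deterministic: the "s" point is the *largest* threshold whose
sensitivity still reaches the floor (0.75 by default), which maximizes
precision subject to that floor because sensitivity is weakly decreasing
in the threshold; the "p" point is the *smallest* threshold reaching the
precision floor (0.85), maximizing sensitivity subject to it. Whether a
published table's thresholds were chosen this way or by inspection is
generally unknowable; an explicit rule at least makes the selection
reproducible. Unattainable floors return the closest point flagged
`attained = FALSE` rather than failing.

## The synthetic-data generator

`generateFixture()` emulates exactly the architecture the method
assumes, with all enrichment parameters exposed in `fixtureSpec`:

* **Plastid**: Met + n-region (1–5 charged/neutral residues) +
  h-region (7–13 hydrophobic) + c-region; the signal length is drawn
  from 16..28 and the whole bipartite extension from 40..80 residues.
  Position +1 is Phe with probability 0.8 (`cvelia_like`) or 0.5
  (`vbrassicaformis_like`) — when the draw fails, +1 is sampled from the
  non-Phe background so the probability is exact. The rest of the
  transit peptide is enriched in S/T/R (combined frequency 0.45, an
  invented default motivated by the general hydroxylated-residue
  enrichment of transit peptides — a parameter, not a claim about any
  real species). Mature domains are background-sampled, 150–400
  residues.
* **Secretory**: the same signal peptide, then background mature domain.
* **Mitochondrion**: Met + presequence of 15–40 residues with Arg
  frequency 0.25 and no Asp/Glu.
* **Cytosol**: Met + background.

The c-region follows the von Heijne (−3, −1) rule: Ala at −1 with
probability 0.85 (else Gly/Ser), Ala at −3 with probability 0.7 (else
Val), and an Ala-free interior drawn from small residues. This is what
makes the cleavage site positionally well-defined — with a diffuse
c-region the "true" site of a synthetic secretory protein is genuinely
ambiguous to ±2 residues, which no scorer could resolve; the sharpened
signature reflects the real signal-peptidase specificity the generator
is meant to emulate.

What the generator does **not** emulate: genuine length/composition
correlations, homology and redundancy between reference proteins,
assembly truncation and frame errors, signal anchors, dual-targeted
proteins, and lineage-specific background frequencies. Passing the
seeded end-to-end tests therefore demonstrates the pipeline's internal
correctness and its behaviour under the assumed architecture — not
performance on real proteomes, where curated references and external
predictors are required.

The generator draws all randomness from its own seed and restores the
caller's RNG state, so fixtures are byte-reproducible and cannot
interact with surrounding code.

## Numerical choices and degenerate inputs

* All tie-breaks (PWM position, window shift, consensus position) are
  deterministic and documented above.
* Score comparisons at thresholds are inclusive; floating-point ties in
  argmax scans use a 1e−12 guard so equal-score candidates resolve by
  the tie-break rather than rounding noise.
* Records whose sequence cannot cover a training window are skipped with
  a warning and counted; an offset whose residues are all `X` is a hard
  error naming the offset.
* Proteins too short for any scan degrade to an "other" call with a
  warning — classification over a valid record never crashes.
* `-Inf` is used as the score of records with no detected cleavage site
  in prediction tables, so score sweeps handle them naturally (they
  never pass a finite threshold).
* N-terminus extension requires an exact match of the target's first 30
  residues (configurable) inside a candidate; "almost identical"
  transcript overlap is a curation judgement we deliberately replace
  with an exact, testable criterion, choosing the candidate with the
  longest upstream extension and breaking ties lexicographically by id.

## Problem sizes

The shipped tests and the acceptance script train on 200 proteins per
class and evaluate on held-out cohorts of 300 (100 plastid + 100
cytosol + 100 secretory), with oracle-equivalence properties checked on
100 random instances per operation; the full suite runs in well under a
minute. These sizes put binomial noise on recovered rates at a few
percent, which is the regime the default thresholds and test bands are
stated for.

## Known limitations

* The internal PWM predictor stands in for a stack of external
  signal-peptide predictors; when external outputs are available they
  should be parsed via the adapters and fed to the consensus caller,
  which then takes precedence.
* Cumulative scores are comparable only between matrices of the same
  offset span and training convention.
* No redundancy weighting of training sequences is applied; highly
  similar references will bias the matrix toward their family.
* Signal-anchor (uncleaved) proteins and dual-targeted proteins are out
  of scope and will surface as secretory/other calls.
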