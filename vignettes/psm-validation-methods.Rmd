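---
title: "Validating peptide-spectrum matches with an alternating decision tree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating peptide-spectrum matches with an alternating decision tree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

A database search engine such as Sequest assigns every MS/MS spectrum a
ranked list of tentative peptide matches (PSMs). Most of these are wrong:
in a typical MALDI search result only about 5% of instances are correct
identifications, and roughly a third of the correct ones do not sit at rank
1. Threshold rules on the search scores (the classic "XCorr > 2.2 and
deltaCn < 0.1, fully tryptic" expert filter) discard many correct borderline
matches. `psmval` implements a supervised alternative: represent every
candidate (all ten ranks, not just the top hit) as a feature vector, learn an
interpretable boosted tree on labelled data, calibrate its scores into
probabilities, and aggregate those into protein presence probabilities.

```{r}
library(psmval)
ds <- simulate_dataset(sim_config(n_spectra = 300, seed = 7))
res <- run_pipeline(ds, seed = 7)
res$evaluation$metrics
```

## The feature model

Features come in three groups (`psm_feature_names()` fixes their order).

**Search-engine pass-throughs.** `xcorr`, `deltacn`, `sp`, `sprank`, the
matched-ion fraction, and `delta_mh`, the gap between the observed precursor
MH+ and the candidate's theoretical MH+ (monoisotopic; MH+ = neutral mass +
1.00728 Da).

**Sequence context.** Tryptic-terminus count (NTT, conventional encoding:
2 = fully tryptic — note some discussions of tree paths in the literature
conflate NTT with missed cleavages or invert the encoding; this package does
not re-map), peptide length, C-terminal residue code (Arg = 1, Lys = 2,
other = 3), proline and arginine counts, a mobile-proton class (1 = mobile
when the charge exceeds the count of R/K/H, 3 = non-mobile when arginines
alone cover the charge, 2 = partial; an artifact convention, since proton
mobility is reported under varying definitions), and the number of database
peptides within ±3 Da (configurable) of the candidate mass.

**Dataset-level evidence.** The two load-bearing novel features exploit the
fact that a present protein sheds many peptides:

* **Protein Hit Count (PHC).** With `D` observable peptides in the digested
  database, `n` of them from the candidate's parent protein, and `P`
  instances in the search result, random sampling would hit the protein
  `Poisson(lambda = P n / D)` times. PHC is the `-log10` tail probability of
  the observed count `k`. The default is the upper tail `P(X >= k)`, so a
  large PHC means "more hits than chance" — the direction in which a learned
  tree treats PHC as positive evidence. A `lower` mode preserves the literal
  "k or fewer" formulation. Base 10 is a documented choice; it affects
  thresholds, not ranking. Both tails are evaluated with `ppois(log.p =
  TRUE)`, so deep tails never underflow. Because `D` and `P` normalise the
  rate, models transfer between databases and dataset sizes. The Poisson
  approximation to the exact binomial tail is excellent in the regime real
  databases occupy (`n/D` around 1e-4): the literal lower-tail form stays
  within 0.05 log10 units of the exact binomial sum throughout `n/D <= 0.01`,
  while the upper-tail form degrades in the far tail as `n/D` approaches
  0.01 — a property of the approximation itself, quantified in the test
  suite.
* **Potential Coverage Ratio (PCR).** The fraction of a protein's
  observable residues covered by the peptides actually observed, computed as
  a residue union on protein coordinates so overlapping peptides are not
  double-counted (summing peptide lengths would overstate coverage).

PHC and PCR are *global dataset features*: `k` counts every instance of the
protein across all ranks of the dataset being featurised and `P` is that
dataset's instance count, so each side of a train/test split is featurised
against its own search result.

Also included: PTM percentage (share of modifiable residues the search had
to modify to make the match — a high value is suspicious) and
spectral-quality statistics (summed/mean/sd intensity, peak count, and the
intensity histogram in five 20% bins normalised by the spectrum's maximum
intensity — the normalisation is a documented choice).

The observable-peptide universe behind `D`, `n`, and PCR comes from
`build_digest_index()`: fully tryptic peptides (cleave after K/R except
before P; protein termini count as boundaries), up to 2 missed cleavages by
default, whose mass in at least one searched-modification state (at most 3
simultaneous modifications are enumerated, for tractability) falls in the
instrument window. The window default of [600, 4000] Da reflects a typical
MALDI-TOF/TOF acquisition range; the missed-cleavage default is a common
search setting. Peptides containing `X` have no defined mass and are
excluded. A sequence shared by two proteins counts toward both proteins'
`n` and twice toward `D`, because every PSM is attributable to one specific
parent protein. Missing search-score fields reject the instance outright —
imputation would silently distort training.

## The classifier

The alternating decision tree is an additive rule model. The root carries
the prior log-odds `0.5 ln(W+/W-)`. Each boosting iteration adds one base
rule — a splitter `feature <= threshold` hanging under an existing
prediction node — chosen to minimise

```
Z = 2 [ sqrt(W+(c & s) W-(c & s)) + sqrt(W+(c & not s) W-(c & not s)) ] + W(not c)
```

over every (prediction node `c`, feature, threshold) triple, with thresholds
at midpoints between consecutive distinct feature values under `c`. The two
new prediction values are smoothed log-odds `0.5 ln((W+ + eps)/(W- + eps))`
and weights update multiplicatively, `w <- w exp(-y r(x))`. An instance's
margin is the sum of the values on *all* paths it reaches, and the class is
positive exactly when the margin exceeds zero. Numerical choices:

* `epsilon = 1` (Laplace-style smoothing; prevents infinite values on pure
  branches).
* Ties in `Z` break to the earliest prediction node, then the lowest feature
  index, then the lowest threshold — training is bit-reproducible.
* All prediction nodes are eligible preconditions (full tree search, not
  boosting by stumps).
* The categorical C-terminal code (1/2/3) is treated as ordered — a
  documented caveat of using threshold splitters on a nominal code.
* `iterations = 9` by default: each iteration adds one splitter and two
  prediction nodes, so models stay under 20 prediction nodes and remain
  readable (`export_tree()` renders text, DOT, and lossless JSON; rule
  numbers give the discovery order, a rough importance ranking).
* Class-weighted initialisation is available but off by default, matching
  vanilla boosting.

```{r}
cat(export_tree(res$model, "text"))
```

Margins become probabilities by logistic (Platt-family) calibration,
`p = 1/(1 + exp(-(A m + B)))`, fitted by maximum likelihood (an ordinary
binomial GLM). The pipeline fits the calibration on a held-out half of the
training spectra, never on the tree's own training instances, whose margins
are optimistically large. Under complete separation the slope is bounded by
the iteration cap; Platt's smoothed targets are available as an option. The
map is strictly monotone, so AUC is identical before and after calibration.

Protein presence probabilities follow the conservative noisy-OR: `P = 1 -
prod_i (1 - max_j p_ij)` over the protein's *distinct* peptides, taking the
best probability within each peptide because repeated identifications of the
same molecule are not independent evidence. The default distinct-peptide key
is the bare sequence (modification states of one sequence pool together);
charge state never enters the key, since MALDI precursors are predominantly
singly charged. The product is accumulated in `log1p` space. A peptide
shared by two accessions contributes to both — no parsimony or minimal-set
step is attempted, which is a different (EM-based) family of methods.

## Evaluation

`psm_metrics()` reports accuracy, sensitivity, specificity, precision, and
net prediction = (sensitivity + specificity)/2; a zero denominator yields an
explicit `NA`, never a silent 0. ROC and precision-recall curves sweep one
threshold per distinct score with tied scores collapsed into a single step,
so the trapezoidal AUC equals the Mann-Whitney statistic with half credit
for ties. The decision rule for threshold metrics is margin > 0 (strictly),
or probability > 0.5 in calibrated mode.

## What the simulator emulates — and what it does not

`simulate_dataset()` generates a protein database (K/R frequencies tuned so
tryptic fragments average 8–15 residues), picks a "present" subset, and
emits ranked candidate lists with the structure the protocol assumes: 10
candidates per spectrum; about 47% of spectra contain one true candidate
(so ~4.7% of instances are positive); true candidates sit at rank 1 with
probability 0.66; rank-1 deltaCn is 0 and lower ranks carry the relative
XCorr gap; decoy candidates are database peptides within the precursor
tolerance (±2 Da; nearest-by-mass fallback when the neighbourhood is
sparse), because a search engine only reports candidates inside its
tolerance. True-class XCorr is Normal(3.0, 0.7) truncated at zero against
Normal(1.5, 0.5) for decoys; ion fractions are Beta(8, 12) against
Beta(6, 14). These spreads were set so that the benchmark's held-out AUC
lands in the high-0.9s — the difficulty regime reported for the reference
MALDI data — rather than saturating at 1, and they are claims about test
difficulty, not about MALDI physics. Per-protein loads are exponential, so
true hits cluster on few proteins; that clustering is exactly what gives
PHC and PCR their signal, and the `cluster_hits = FALSE` switch removes it
to show the hit-count features are inert without it.

Peak lists are Poisson-count peaks with lognormal intensities — enough to
exercise the spectral-quality features, which carry no planted signal here
(and were found non-instrumental on real data too). The simulator does not
model fragment-ion physics, instrument noise, homologous proteins, or
charge-state mixtures; a passing benchmark therefore demonstrates that the
pipeline recovers a planted clustered signal under realistic score overlap,
not that it reproduces the numbers obtainable on any particular real
dataset (which would require the original proprietary search output).

Benchmark problem sizes used by the test suite: 1000 spectra × 10
candidates per dataset; the headline recovery check runs 10 simulation
seeds and the clustering ablation 5 seeds per arm, which is ample for its
direction-only comparison of medians.

## Known limitations

* The observable-peptide index is fully tryptic; semi-tryptic matches are
  handled at the PSM level (NTT feature, PCR exclusion with a warning) but
  do not enter `D` or `n`.
* PHC/PCR make instances non-exchangeable across datasets: a model
  transfers, but features must be recomputed per search result.
* `P` counts PSM instances, not spectra ("samples" is read as instances); a
  rank-1-only hit-count mode exists for sensitivity analysis.
* The upper-tail Poisson PHC is an approximation whose far-tail accuracy
  degrades for proteins contributing more than ~0.3% of the observable
  database — negligible for realistic databases, visible in stress tests.
* No protein grouping: homologous accessions sharing all their peptides
  each receive the full shared evidence.
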