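---
title: "Predicting RNA m5C sites with pseudo dinucleotide composition"
author: "rnam5c authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting RNA m5C sites with pseudo dinucleotide composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnam5c)
```

## The problem and the model

5-methylcytosine (m5C) is a post-transcriptional RNA modification;
given a transcript, only some of its cytosines carry it. `rnam5c`
treats site identification as binary classification of fixed-width
sequence windows: the candidate C sits at the center of a
(2&xi;+1)-nt window, and the model must decide whether that center is
a modified site. The design rests on three assumptions worth stating
explicitly:

* **locality** — the signal distinguishing modified from unmodified
  cytosines is carried by the ±&xi; nt around the site;
* **composition over position** — the encoding used here summarizes a
  window by lagged covariances of dinucleotide physical-chemical
  profiles, so it responds to compositional and short-range
  correlation structure, not to the literal identity of each
  position;
* **exchangeable windows** — windows are treated as i.i.d. samples;
  no transcript-level or positional covariates enter the model.

### Window extraction

For each annotated position the window is the literal substring when
it fits; where it overruns a sequence end, missing flank positions
are filled with the nearest existing residue (the terminal base), so
every sample has exactly 2&xi;+1 nt. Exact duplicate windows are
removed *within* each class subset (first occurrence kept); a window
string occurring in both classes is kept in both, since removing it
from either would silently change a class's composition. Windows
containing non-ACGU symbols (N and other IUPAC codes survive the
T→U conversion) are excluded and counted, because the property table
is defined only over the 16 plain dinucleotides.

### The encoding

Each of the window's L−1 overlapping dinucleotides D_i is looked up
in a table of 10 physical-chemical properties, standardized
per property to zero mean and unit *population* standard deviation
over the 16 dinucleotides. For property m with window profile
P_m(D_1..D_{L−1}) and window mean P̄_m, the features are

$$AC(m, g) = \frac{1}{L-1-g} \sum_{i=1}^{L-1-g}
  (P_m(D_i) - \bar P_m)(P_m(D_{i+g}) - \bar P_m)$$

$$CC(\mu_1, \mu_2, g) = \frac{1}{L-1-g} \sum_{i=1}^{L-1-g}
  (P_{\mu_1}(D_i) - \bar P_{\mu_1})(P_{\mu_2}(D_{i+g}) - \bar P_{\mu_2}),
  \qquad \mu_1 \ne \mu_2$$

for lags g = 1..&lambda;. The layout is fixed and versioned
(`acc-lagmajor-1`): the 10&lambda; auto-covariances first (lag-major:
g outer, property inner), then the cross-covariances over all 90
ordered property pairs in lexicographic (&mu;₁, &mu;₂) order, also
lag-major — &Omega; = 100&lambda; components, 500 at the default
&lambda; = 5. The deviations are taken from the *window* mean of each
property profile and the sum is divided by the number of summands
L−1−g; this window-centered, per-summand-normalized form is adopted
as the single normative definition and is pinned in the tests by a
brute-force loop oracle. An optional k-mer frequency block
(alphabetical order, each count divided by L−k+1) can be appended,
but is off by default because the default predictor is defined purely
by the covariance components.

Choosing &lambda; trades off reach against stability: lag g has
L−1−g summands, so large lags average fewer terms and are noisier.
&lambda; must satisfy &lambda; ≤ L−2 so every lag has at least one
summand; the default &lambda; = 5 on 41-nt windows leaves ≥ 34
summands per lag.

### The property table

The shipped default (`inst/extdata/rna_dinucleotide_properties.tsv`)
combines six A-form helical step parameters (shift, slide, rise,
tilt, roll, twist; representative values compiled from the structural
literature, with reverse-complement symmetry) and four thermodynamic
nearest-neighbor sets (stacking free energy; enthalpy, entropy and
free energy of Watson–Crick stacks). Because every property is
standardized before use, only the *relative* pattern across the 16
dinucleotides matters. The table is an input, not a constant: any TSV
with a `property` column and the 16 dinucleotide columns can be
supplied, and trained models carry an MD5 checksum of the table so a
model/encoder mismatch is an explicit error rather than a silent
mis-scoring.

### The classifier

A random forest of `ntree = 100` trees. Each tree is grown on a
bootstrap resample of the training windows, and at every split
`mtry = 22` randomly drawn features are considered — the
random-subspace dimension, close to the √500 ≈ 22 convention for a
500-dimensional encoding. Trees are grown to purity (the classical
default, no depth limit), and the ensemble score of a window is the
fraction of trees voting "site", so scores are multiples of 1/ntree.
The decision threshold defaults to 0.5 with ties called positive
(documented, since a vote fraction can land exactly on the
threshold). An alternative `subspace = "per_tree"` mode confines each
tree to its own 22 features — useful for fidelity experiments, since
"random subspace" in the ensemble literature sometimes means
per-tree rather than per-split sampling; the per-split forest is the
default. The 1:3 class imbalance is deliberately left unweighted: an
unweighted forest on imbalanced data favors specificity over
sensitivity, which is the operating profile reported for predictors
of this family.

Training is deterministic given (data, seed): the seed is set once
before growing the forest (per-split mode) or per tree (per-tree
mode).

### Evaluation

The four metrics are computed from the misclassification counts
N₋⁺ (true sites predicted negative) and N₊⁻ (non-sites predicted
positive); the MCC expression in this parameterization is
algebraically identical to the classical Matthews correlation, which
the tests verify on 1,000 random count tuples. When every prediction
falls in one class the MCC denominator vanishes; the package reports
0 with a warning, a documented convention.

The jackknife (leave-one-out) test is the reference protocol because
it is deterministic given the benchmark; each fold trains a fresh
forest with seed `master seed + fold index`, so the full procedure is
reproducible while the per-fold forests differ. Stratified k-fold is
the cheaper proxy (its fold assignment is seeded, hence arbitrary in
a way the jackknife is not); `k = N` reduces exactly to the
jackknife, fold i holding out sample i. ROC curves threshold the
pooled out-of-fold vote fractions at every distinct value; AUC is
the trapezoid area, which under tie-grouping equals the rank
statistic P(random positive outranks random negative, ties ½).
Pooled out-of-fold scores are the normative input for the ROC —
a refit on the full data would leak training information into the
curve.

## The synthetic benchmark generator

`simulate_benchmark()` emulates the *structure* of real m5C
benchmarks so every stage is testable without downloads: C-centered
windows of 2&xi;+1 nt, positives and negatives at a configurable
ratio, and a class signal of configurable strength. Defaults mirror
the benchmark this pipeline targets — 475 positives vs 1,425
negatives (1:3), &xi; = 20 — with a uniform background composition.
A positive window carries the signal with probability
`signal_strength` (default 0.9): its flanks are drawn from a
GC-shifted composition (A 0.15, C 0.35, G 0.35, U 0.15) and, if a
`motif` is supplied, that subsequence is planted (by default
immediately upstream of the center). At `signal_strength = 0` the
classes are exchangeable, which the null-calibration tests exploit.
Collisions are resampled so all windows are globally distinct,
keeping the deduplication invariants trivially true and making label
shuffling safe.

What the generator does *not* emulate: real m5C determinants
(enzyme-specific motifs such as NSUN2's, secondary structure,
transcript context), linkage between windows from the same
transcript, or sequencing noise in the annotations. Passing tests on
synthetic data therefore demonstrate that the pipeline recovers a
planted compositional signal at the benchmark's geometry and
imbalance — not that it attains any particular accuracy on real
benchmarks, which additionally depends on the property table and on
how the real negatives were sampled.

One property of the encoding shapes the test fixtures: because the
features are lagged covariances of dinucleotide properties, a planted
motif is visible roughly in proportion to the dinucleotide-property
contrast it creates, not to its length. An alternating motif such as
`GCGCG` produces a strong periodic covariance signature and is
recovered almost perfectly at full strength; a low-contrast motif of
the same length can be much harder. The "strong-signal" fixtures in
the tests therefore use alternating motifs.

## Numerical and design choices

* Coordinates are 1-based and inclusive everywhere; the window center
  is index &xi;+1.
* Standardization uses the population (divisor-16) standard
  deviation; a constant property row is a zero-variance error.
* Covariance identities are tested to 1e−12 against loop oracles;
  standardization to 1e−9.
* Degenerate inputs fail loudly: empty FASTA records, annotations
  pointing at non-C residues or beyond the sequence end, lags with no
  summands (g > L−2), equal property indices in CC, single-class
  training labels, thresholds outside [0, 1].
* Problem sizes in the tests and the acceptance script are scaled to
  keep runs brisk: oracle equivalences use 30–60-window sets with
  &lambda; = 2 and 20–60 trees; the pipeline-recovery check uses 400
  windows at the full encoder configuration (&lambda; = 5, 100 trees,
  subspace 22) under 10-fold CV; the acceptance script runs 10-fold
  CV on the full 1,900-window synthetic benchmark. These sizes are
  the package's own choices for routine verification; the full
  jackknife at N = 1,900 is supported but is an overnight-scale job.

## A compact run

```{r example, eval = FALSE}
bm <- simulate_benchmark(n_pos = 100, n_neg = 300, xi = 20,
                         signal_strength = 1, motif = "GCGCG", seed = 7)
cv <- m5c_kfold(bm, k = 10, seed = 7)
cv
plot(cv)   # ROC of the pooled out-of-fold vote fractions
```

## Known limitations

* The ten default property values are a documented, swappable
  compilation; numerical agreement with any particular published
  predictor additionally depends on its (often unpublished) table,
  forest variant and seeds.
* Deduplication is exact-match only; near-duplicate windows (e.g.
  from homologous transcripts) are not collapsed, so cross-validation
  on real data can be optimistic unless the input is pre-filtered.
* No probability calibration: vote fractions are ranks, not
  calibrated probabilities.
* The jackknife's cost grows linearly in N with a full forest per
  fold; for large benchmarks stratified k-fold is the practical
  protocol.
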