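---
title: "Methods: the 188D GPCR classification pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the 188D GPCR classification pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpcr188)
```

## The model

`gpcr188` frames GPCR recognition as binary classification of fixed-length
summaries of variable-length protein sequences. The working assumption is
compositional: a seven-transmembrane receptor devotes a large, positionally
structured share of its residues to hydrophobic membrane-spanning helices,
and that signature survives in global composition, class-transition and
class-distribution statistics even without any alignment or motif model.

Each sequence of length $L$ over the 20 standard amino acids becomes a
188-vector:

1. **Amino-acid composition** (positions 1–20): $f(a) = n_a/L$, alphabetical
   by one-letter code. Sums to 1.
2. **CTD blocks** (positions 21–188): for each of eight properties, the
   alphabet is partitioned into three classes and the sequence rewritten as a
   class string $c_1 c_2 \ldots c_L$ over $\{1,2,3\}$. Then
   - composition $C_j = n_j/L$ (3 values, sum 1),
   - transition $T_{jk} = \#\{i : \{c_i, c_{i+1}\} = \{j,k\}\}/(L-1)$ for
     $(j,k) \in \{(1,2),(1,3),(2,3)\}$ (3 values; their sum is at most 1),
   - distribution (15 values): for each class $j$ with occurrences at
     positions $p_1 < \dots < p_{n_j}$, the five anchors
     $100\,p_{m(q)}/L$ for $q \in \{\text{first}, 25, 50, 75, 100\}$ with
     $m(\text{first}) = 1$ and $m(q) = \max(1, \lceil q\,n_j/100 \rceil)$.

The block layout per property is C1,C2,C3,T12,T13,T23 followed by the five
anchors of class 1, class 2, class 3 — so $20 + 8 \times 21 = 188$, always.

## Numerical and convention choices

These were genuinely open and are fixed here once:

* **Distribution anchor rule.** CTD implementations disagree on whether the
  occurrence index uses floor, round or ceiling. We use
  $m(q) = \max(1, \lceil q\,n_j/100\rceil)$: it guarantees $m(100\%) = n_j$
  and $m(q) \ge 1$ with no special cases. The choice is isolated in
  `ctd_distribution()` and checked against an independent scanning oracle in
  the tests; absent classes yield five zeros, and the first-occurrence anchor
  is always emitted even when it coincides with the 25% anchor.
* **Degenerate sequences.** A length-1 sequence has no adjacent pairs;
  transitions are defined as (0,0,0) rather than an error so batch encoding
  survives fragment records.
* **Feature order.** No canonical AAC order exists; alphabetical is
  reproducible without reference output. Property order and within-property
  class order follow the shipped table (`inst/extdata/property_groupings.txt`)
  and are part of the public contract, since feature positions depend on them.
* **Property partitions.** The three-class partitions follow the established
  SVM-Prot/PROFEAT tables. Because single-residue assignments vary between
  published variants, the partitions live in a plain-text config and can be
  replaced per run (`read_property_table()`, CLI `--property-table`) — a
  discrepancy is a one-file fix, not a code change.
* **Residue policy.** UniProt entries may contain B, Z, U, O, J, X, gaps or
  stops. Default policy `map` resolves B→D, Z→E, U→C, O→K, J→L and removes
  the rest; `strict` refuses them; `drop` removes them all. Cleaning is
  idempotent and validated by round-trip tests.

## Dataset handling

* **Stratified k-fold splits.** Positives and negatives are shuffled
  independently under the run seed and each split into $k$ near-equal parts;
  part $i$ is fold $i$'s test set. With $P$ positives, every part receives
  $\lfloor P/k \rfloor$ and the remainder goes to the highest-indexed parts.
  Separate stratified shuffling (rather than a joint shuffle) is what makes
  per-fold class counts deterministic functions of $P$, $N$ and $k$ — e.g.
  2495 positives and 10386 negatives at $k=5$ give test folds of 499
  positives each and 2077/2077/2077/2077/2078 negatives.
* **SMOTE** (`smote()`): each minority vector contributes
  $\mathrm{percent}/100$ synthetic points $x + u\,(x_{nn} - x)$,
  $u \sim U(0,1)$, with $x_{nn}$ among its $k=5$ nearest minority neighbours
  (exact brute-force Euclidean search; distance ties break to the lower input
  index for determinism). The default percent, 300, quadruples the minority
  class — at the 1:4 imbalance this pipeline targets, that brings the two
  classes to near parity (e.g. 1996 → 7984 positives against 8309
  negatives). Rebalancing happens strictly inside each training partition,
  after splitting: synthetic points never enter a test set, which is the
  leakage-safe ordering.
* **ARFF.** Datasets round-trip through Weka's ARFF with 188 numeric
  attributes plus a nominal class in {1, −1}, label last. Feature values are
  written with 6 significant digits — far beyond the precision the forest is
  sensitive to.

## The classifier and its evaluation

The ensemble is `randomForest`: bootstrap sample per tree, default 100 trees,
$\lfloor\sqrt{188}\rfloor = 13$ candidate features per split, fully grown
leaves. Tree count is a convention default, configurable; the pipeline's
contract is what the tests pin down: seeded determinism, scores equal to the
fraction of trees voting +1 (hence multiples of $1/\text{n\_trees}$), and
label +1 exactly when score ≥ 0.5 (ties to +1, fixed and documented).
Per-stage seeds (split, per-fold SMOTE, per-fold forest) are derived from the
single run seed, so one integer reproduces a whole run byte-for-byte.

Both accuracy conventions are always reported because published per-fold
tables in this area mix them: *weighted* accuracy $(TP+TN)/\text{total}$
tracks the overall correct-classification rate, while *balanced* accuracy
$(Sn+Sp)/2$ is what some per-fold "Acc" columns actually contain. Reporting
both makes either comparison possible. Aggregation uses the arithmetic mean
and the sample (n−1) standard deviation. Metrics with an empty denominator
are `NA` plus a flag — never silently 0 — except MCC, which takes the
standard 0-on-zero-marginal convention, flagged. The ROC sweeps thresholds
from high to low, ties advancing the curve in one step; the trapezoidal AUC
then equals the Mann–Whitney statistic with ties counted ½, which the tests
verify against exhaustive pairwise counting.

## What the synthetic generator does and does not show

`generate_positive()` emits sequences alternating seven hydrophobic-biased
stretches (18–25 residues, 80% of residue mass on {C,L,V,I,M,F,W}) with
loops drawn from Swiss-Prot-like globular frequencies; `generate_negative()`
draws whole sequences from those background frequencies. Defaults: 1:4
positive:negative imbalance (the realistic proteome-scale ratio for this
problem), total lengths 250–420 residues — enough room for seven helices
plus realistic loop mass. Generation is fully seeded.

This emulates *compositional* 7TM structure only: no real topology, signal
peptides, motifs or homology. The two populations are therefore separated by
a wide compositional margin (the hydrophobic class fraction differs by ≈0.2
on average), and the pipeline classifies them essentially perfectly. Passing
tests consequently demonstrate that the machinery — encoding, splitting,
rebalancing, training, scoring — is correct and leak-free; they do not
demonstrate field performance on real proteomes, where negatives include
membrane proteins that genuinely resemble receptors and published accuracies
sit near the low 90s (percent) rather than 100.

The greedy redundancy filter is likewise an estimator, not an aligner: it
clusters by shared distinct 5-mer fraction relative to the shorter sequence,
processing records longest-first. It reproduces identity-threshold behaviour
for near-duplicates (one point mutation in 100 residues destroys at most 5
of 96 5-mers, keeping estimated identity above 0.94) but is not a CD-HIT
replacement for borderline cases.

## Problem sizes

The shipped tests and the acceptance script run at desk scale by choice: 100
positive + 400 negative synthetic sequences for the end-to-end recovery runs
(repeated across 5 seeds), exhaustive oracle checks over all class strings
of length ≤ 6 and score sets of ≤ 12 samples, and split arithmetic exercised
at the full 2495/10386 size with one-dimensional placeholder vectors. The
complete suite runs in about a minute on one CPU.

## Known limitations

* Only the categorical 3-class CTD encoding is supported — no continuous
  hydrophobicity scales, PseAAC, autocorrelation or profile features.
* No hyperparameter search; forest depth/tree count are user-set.
* The SMOTE neighbourhood is exact brute force, fine to a few thousand
  minority points, quadratic beyond.
* Undersampling and SMOTE variants (Borderline, ADASYN) are out of scope.
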