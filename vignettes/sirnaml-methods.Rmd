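---
title: "Methods: trichotomous threshold models for siRNA efficacy"
author: "sirnaml"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trichotomous threshold models for siRNA efficacy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sirnaml)
```

This vignette is the package's own account of the statistical procedure it
implements: the model, its assumptions, the tunable parameters and their
defaults, the numerical conventions that were genuinely open choices, what
the synthetic-data generator does and does not emulate, and the known
limitations.

## Problem and data model

Fully chemically modified siRNAs are screened in panels of a few hundred
compounds; efficacy is read out as percent reporter expression remaining
relative to untreated cells (lower = stronger silencing), typically averaged
over about three replicate measurements whose spread can rival the distance
between biologically distinct compounds. The package treats each compound as
a record `(id, gene, target_site, efficacy_pct, rep*)`, where `target_site`
is the 20-nt mRNA window complementary to the guide strand, positions t1–t20
in the register pairing with guide positions g1–g20. Sequence is the only
feature source: with a uniform chemical scaffold across a panel, strand-
loading asymmetry is carried by the chemistry, not the sequence, so the
model deliberately excludes thermodynamic-asymmetry terms, target structure
and flanking context.

Encoding is one-hot with the fixed base order A, U, C, G per position, 80
features in all (`one_hot_encode()`). DNA-alphabet input is accepted and T
mapped to U, because published external siRNA sets use DNA overhang
conventions. Whether t1 is the 5' or 3' end of the window relative to
genomic coordinates is left to the caller; all internal conventions are
consistent with sequences supplied in t1→t20 order, and transcript scanning
emits windows 5'→3' into that register in a single place
(`scan_transcript()`) should the convention ever need to change.

## Trichotomous labeling and the threshold sweep

A threshold pair (h₁, h₂), h₁ ≤ h₂, labels a record effective when
`efficacy_pct <= h1`, ineffective when `efficacy_pct > h2`, undefined
otherwise; undefined records are excluded from model development. With
h₁ = h₂ the labeling is exhaustive. The strict/non-strict boundary
assignment matters at the cutoffs and is pinned by tests.

Candidate thresholds are the nine interior equal-count boundaries of the
empirical efficacy distribution (`select_equal_count_thresholds()`, default
`n_groups = 10`). The lower empirical quantile is used — threshold *k* is
the largest observed value with at most *kn*/10 values at or below it — so
thresholds always sit at observed data values; rounding is display-only and
never used for classification. All 45 ordered pairs are evaluated
(`enumerate_threshold_pairs()`, *n*(*n*+1)/2 pairs for *n* thresholds):
the sweep replaces a single ad hoc cutoff with a systematic comparison, and
no automatic threshold optimization is layered on top.

## Assessment protocol

Per pair (`run_threshold_sweep()`):

1. **Stratified split.** The labeled records are split
   `round(0.75 n)` / remainder into training and holdout, per-class
   proportions preserved within one record (largest-remainder allocation),
   sampling without replacement under a seeded generator. A 356-record
   exhaustive labeling gives 267/89.
2. **Class-balanced K-fold.** Training records are partitioned into K = 10
   folds differing by at most one in size and at most one from per-class
   balance; each class is shuffled and chunked independently, remainder
   chunks placed at opposite ends of the fold list. Each round trains on
   K−1 folds and produces a precision-recall curve on the held fold; the K
   curves are vertically averaged on a fixed 101-point recall grid.
3. **Final model and holdout evaluation.** The model is refit on the full
   training set and evaluated on the untouched holdout set.

Pairs whose labeling leaves a split or fold without both classes are marked
degenerate, skipped with a recorded reason, and excluded from
normalization — on small datasets stringent pairs can legitimately empty a
cell, and aborting the sweep would discard the informative pairs with it.

All seeds (split, folds, forest construction, per pair) derive
deterministically from one master seed, so two sweeps with the same
configuration serialize to byte-identical summaries.

## Model families

**Random forest** (`train_random_forest()`, via `ranger`): 200 trees,
maximum depth 3, minimum one sample per leaf, single-threaded with a fixed
seed. These hyperparameters are deliberately frozen — the framework's
subject is labeling and evaluation, not architecture search — and shallow
trees on 80 sparse binary features resist overfitting panels of tens of
records. Confidence is the fraction of trees voting effective. Records are
pre-sorted by id before fitting so results do not depend on input row
order.

**Linear base-frequency difference** (`train_linear_freqdiff()`): weight
w(p, b) = freq(b at p | effective) − freq(b at p | ineffective); a
sequence's raw score is the sum of its observed-base weights, identically
the inner product of its one-hot vector with the flattened weight matrix.
Raw scores are mapped to [0, 1] by min–max over the training scores (probes
clipped). The mapping is strictly monotone, so every ranking-based metric is
unaffected by it; only the position of the 0.5 margin depends on this
choice, which is recorded as a convention rather than inherited from the
linear method itself. A degenerate training set whose scores are all equal
maps to 0.5 (uninformative).

Binary calls use a fixed 0.5 confidence margin; ties classify negative — the
conservative direction for design, where a false positive costs a synthesis.
Margin tuning is explicitly out of scope.

## Evaluation: AUCPR_adj

The precision-recall curve (`precision_recall_curve()`) has one point per
distinct score used as margin (predict positive iff score > margin, matching
`classify()`), plus the full-recall endpoint where everything is predicted
positive and precision equals the prevalence. Precision with zero predicted
positives is defined as 1, the standard left-endpoint convention.

The area (`aucpr()`) is the step sum Σ (rᵢ − rᵢ₋₁) pᵢ over points in
non-decreasing recall order — the average-precision rule. Two properties pin
this choice: a ranker with all-equal scores must score exactly the
prevalence (so the adjusted metric below is exactly zero for it), and linear
PR interpolation is known to be optimistic. Brute-force margin-enumeration
oracles in the test suite hold the implementation to this convention at
1e−12 over hundreds of random instances.

Because P_R=1 equals the positive prevalence, raw AUCPR has a floor that
rises with permissive h₁ thresholds. The package therefore reports

`aucpr_adj()` = AUCPR − P_R=1,

which is 0 for no discrimination, 1 − prevalence for a perfect ranker, and
negative for worse-than-baseline rankers. A perfect ranker's curve touches
recall 1 at two precisions (1 and the prevalence); the prevalence endpoint
is the one subtracted, which is what makes the no-discrimination case land
exactly at zero. For cross-model display, AUCPR_adj values are min–max
normalized to 0–100 *within* each evaluation stage (all cross-validation
results together, all holdout results together, per family); a constant
collection maps to all-zero. ROC AUC (ties counted half) and the margin-0.5
contingency table are reported alongside, since no single metric is reliable
when an evaluation cell can hold fewer than twenty records.

## Proxy feature extraction

`classification_groups()` splits evaluated records into TP/TN/FP/FN at the
margin; `proxy_feature_weights()` computes
mean(TP) + mean(TN) − mean(FP) − mean(FN) over one-hot vectors, an empty
group contributing zero (the sum's neutral element), and reshapes to 20 x 4.
Group means are unweighted by default (`weighted = TRUE` is a sensitivity
variant). `normalize_weight_matrix()` scales sign-preservingly to a maximum
magnitude of 100 and zeroes entries below 20; it is idempotent and leaves an
all-zero matrix untouched.

Two genuinely open choices are worth stating plainly:

* **Which records feed the groups.** "Records used in model development" is
  read as the training set; the functions accept any record set, so
  training+holdout extraction is a caller-side switch.
* **The sign of the TN term.** The formula as stated adds the true-negative
  composition positively. For a model with no errors the matrix then reduces
  to mean(TP) + mean(TN), a sum of base compositions that is non-negative
  everywhere — informative about importance, silent about direction. The
  `flip_tn = TRUE` variant enters TN negatively, reducing in the error-free
  case to exactly freqE − freqI, i.e. the direct linear weights, and thus
  aligning sign with "positive = favored in effective". The literal formula
  stays the default and is the behavior the formula-level tests pin;
  direction-dependent analyses in this package (planted-sign recovery,
  proxy-versus-direct comparison) use the sign-aligned variant, and say so.
  A zeroed entry carries no direction, so sign comparisons are made at
  entries both matrices retain.

`direct_linear_weights()` normalizes the linear model's own matrix for
comparison, and `au_gc_trend()` reports (A+U) − (G+C) per position as a
local duplex-stability proxy.

## Synthetic-data generator

`generate_sirna_dataset()` emulates the statistical regime the framework
targets, with every default chosen once as that regime's description:

* 356 records over 17 genes (totals take precedence over the inconsistent
  "about 15 per gene" average; 356/17 ≈ 21).
* A planted sparse weight matrix W\* (25% of entries nonzero, magnitudes
  0.5–1.5, random signs) oriented as *effectiveness* weights: positive
  entries lower reporter expression. Optional pairwise base-conjunction
  interactions (5 terms, coefficients 1–2) provide signal only a non-linear
  model can fully exploit. `effect_strength = 0` yields an identically zero
  W\* (pure noise).
* Latent efficacy = standardized planted signal (weight `effect_strength`,
  default 1.5, about two-thirds of latent variance), per-gene random effect
  (weight `gene_sd = 0.3` — the per-gene efficacy breakdown of real panels
  is not documented, so this scale is a convention), and unit Gaussian
  noise; affinely calibrated to mean 44, sd 25, clipped to [4, 120].
  Clipping at the lower bound induces the mild right skew (median below
  mean) seen in reporter data; clipping rather than resampling matches a
  bounded readout.
* Three replicates per record with per-record noise sd drawn from an
  exponential (mean 3.75, capped at 16), giving a mean absolute percent
  error near 3; replicates are clipped to the bounds and their mean is
  stored as `efficacy_pct`, so generated records satisfy the same
  replicate-consistency invariant enforced on read data.
* Sequences are i.i.d. with expected GC fraction 0.4 (design panels favor
  low GC).

What the generator does **not** emulate: positional composition biases of
real transcripts, off-target landscapes, correlated sequence features within
genes, or assay-specific error structure. Tests passing on this generator
demonstrate that the machinery behaves as specified under known ground
truth — not that any particular biological weight pattern is correct.

## Problem sizes and numerical conventions

The test suite and the acceptance script run the production-scale
configuration where it matters — full 45-pair sweeps on 356-record datasets
with 200-tree forests and K = 10 — and scale down elsewhere (80-record
fixtures with 4 groups and K = 5 for orchestration mechanics; 25-record
datasets across hundreds of seeds for bound properties; oracle suites at
n ≤ 30, where brute force is exact). Tie handling is explicit throughout:
score ties at the margin classify negative, ROC ties count half, candidate
ranking breaks confidence ties by ascending window start, split sizes use
round-half-up. Degenerate inputs (all-equal scores, all-zero weight
matrices, empty contingency groups, constant normalization input,
transcripts shorter than 20 nt) have defined, tested behavior rather than
incidental outcomes.

## Limitations

* AUCPR_adj compares rankers; it does not calibrate probabilities, and no
  confidence intervals are attached — with holdout cells this small,
  interval estimates would be decoration.
* The proxy matrices describe *the model*, not biology; correlated features
  are not disentangled, and per-record attributions are out of scope by
  design.
* The linear family's confidence scale (min–max) is a convention; only its
  0.5-margin intercept, and hence its contingency tables, depend on it.
* The generator's gene effects and noise scales are field-plausible
  conventions, not measured quantities; conclusions about real panels
  require real panels.
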