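---
title: "Rank-percentile decision-tree ensembles for hypoxia classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-percentile decision-tree ensembles for hypoxia classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypotrees)
```

## The problem and the representation

Classifying a transcriptome as hypoxic usually requires comparing it to
something: a matched normoxic control, a reference cohort, or at least a
normalization scheme that makes expression values commensurable across
samples. None of those are available when the unit of analysis is a single
sample — one patient biopsy, one public RNA-seq run, one spatial
transcriptomics spot.

`hypotrees` sidesteps the comparison entirely. Cells responding to low
oxygen induce a stereotyped HIF-dependent program, so hypoxia-inducible
genes move *up within the sample's own expression ranking*. The package
therefore represents sample `s` by the rank percentile of each gene:
average competition ranks `r` within the sample (ties get the mean of the
ranks they cover), rescaled as `100 * (r - 1) / (G - 1)` over the `G` genes
present, so the most expressed gene is at 100 and the least at 0.

Two consequences drive the whole design:

* **Normalization-freeness.** Any strictly increasing per-sample transform
  (depth scaling, CPM, log, VST) leaves ranks — and therefore percentiles,
  and therefore every downstream prediction — bitwise unchanged. This is
  asserted as a test invariant, not just assumed.
* **Ranking universe.** Percentiles are computed over *all* genes in the
  supplied matrix, before any signature restriction; `subset_genes()`
  never re-ranks. Thresholds learned on full-transcriptome ranks are only
  meaningful against full-transcriptome ranks. Whether one ranks the full
  annotation or only detected genes shifts the percentile scale slightly;
  the package ranks whatever matrix it is given, and this is a documented
  sensitivity caveat for cross-dataset use.

Tied values share one percentile (the average-rank convention), which
matters in RNA-seq where many genes tie at zero. A consequence worth
stating: the 0 anchor of a column is only attained when the column minimum
is untied — a block of zero-count genes sits at the tie block's average
percentile, strictly above 0. An all-equal column (e.g. a blank spatial
spot) carries no ranking information; it is set to percentile 50 with a
warning rather than failing, so spatial runs survive empty spots, and spot
classification reports such spots with an `NA` label and a `blank` flag.

## Decision trees

The central objects are small CART classification trees on percentile
data. Induction is greedy recursive partitioning:

* at each node, every candidate (gene, threshold) pair is scored by the
  weighted Gini impurity `(n_L * g_L + n_R * g_R) / n` with
  `g = 2 p (1 - p)`; thresholds are midpoints between consecutive distinct
  observed percentiles;
* samples with `percentile >= threshold` take the high branch — samples
  exactly at the threshold go high, a convention that has to be fixed
  somewhere and is asserted in tests;
* ties in the split search go to the lexicographically smallest gene ID,
  then the lowest threshold, making training fully deterministic;
* recursion stops on depth, node size (`min_samples_split`), child size
  (`min_leaf`), purity, or when the impurity decrease falls below
  `complexity` times the root impurity (an rpart-style `cp`);
* each leaf stores the fraction of hypoxic training samples as its hypoxia
  probability, so summing `fraction x probability` over leaves recovers
  the training class balance exactly.

Defaults (`min_samples_split = 20`, `min_leaf = 7`, `max_depth = 5`,
`complexity = 0.01`) mirror common CART practice and yield the shallow
3–5-gene trees that make interpretable single-sample classifiers; all are
exposed in `tree_params()`. Split optimality is verified against an
exhaustive brute-force Gini search on small random instances at every
internal node, not only the root.

Trees serialize to a versioned JSON schema in which the only threshold
unit is the rank percentile; unknown top-level document fields are
preserved across a load/save cycle, and `render_tree()` output is a pure
function of the node table, so rendering is identical before and after a
round trip. Importing externally published tree collections is a matter of
writing documents in this schema; no third-party trees are bundled.

## Random-forest feature selection

Forests here are a *selection* device, never the final classifier. A
forest grows `n_trees` unpruned CART trees (node size 2, no complexity
penalty, depth cap 12) on bootstrap resamples, drawing a fresh random
subset of `features_per_split` genes at every split; out-of-bag (OOB)
indices are recorded per tree and prediction is by majority vote.
`tune_hyperparameters()` picks `(features_per_split, n_trees)` by mean
holdout accuracy over repeated random 70/30 splits, ties going to the
smaller model; the workflow's operating point is 200 trees with 10
features per split.

Importance is permutation-based mean decrease in accuracy (MDA): at each
of `n_iterations` iterations a forest is grown on a fresh 70% subsample
(without replacement; bootstrap applies inside the forest), and for every
gene each tree's OOB accuracy is compared before and after permuting that
gene's values among the tree's OOB samples. Per-tree decreases are
averaged over **all** trees of the forest — a tree that never splits on
the gene contributes exactly zero, since permuting an unused gene cannot
change routing (this also makes a constant gene's MDA exactly 0). Class
balance is not enforced in the resampling; a degenerate single-class
resample contributes a zero row, which at the recommended iteration counts
is negligible but is a documented caveat for tiny cohorts.

### Raw points versus the scaled statistic

`permutation_importance()` reports **raw accuracy percentage points** by
default: that is the natural axis for importance bar plots and for the
null/signal contract tested in the suite (a lone informative gene scores
tens of points; label-independent genes stay within ±2 points). But an
*absolute selection threshold* behaves very differently under redundancy.
When `k` interchangeable informative genes share the signal, each is
consulted by roughly `1/k` of the trees, so raw MDA dilutes
proportionally: with 25 redundant genes and 200-tree forests the
theoretical ceiling is about `8% x 0.5 ~ 4` points and observed values sit
near 3 — a fixed raw cutoff of 4 points would select nothing even though
every one of those genes is individually a perfect separator. The
selection pipeline therefore thresholds the **scaled** statistic
(`scale = TRUE`: mean decrease divided by its standard error over
iterations, the randomForest display convention), on which informative
genes and noise genes separate by an order of magnitude and the selection
default of 4 reads as a z-score-style cutoff. `select_features()` applies
the threshold strictly (`mean_mda > threshold`) and returns genes in
decreasing importance order.

## Ensembles and consensus

`generate_tree_population()` trains each of `n_candidates` (default
10000; scaled down where noted) trees on its own independent random 70/30
split restricted to the selected genes, scoring accuracy and F1 (hypoxic
positive) on the tree's own holdout. Splits that leave a single class in
training are redrawn. `filter_by_accuracy()` keeps trees with holdout
accuracy **strictly** above the cutoff (default 0.95) — "over" is read as
a strict inequality everywhere in the package, including the consensus
call: a sample is hypoxic iff its mean per-tree leaf probability is
strictly greater than the threshold (default 0.5), so a mean of exactly
0.5 is normoxic.

Consensus uses leaf *probabilities*, not hard votes, so the ensemble score
is a continuous quantity bounded by the per-tree extremes, and sweeping
the threshold from 0 to 1 gives a monotone non-increasing count of hypoxic
calls — both asserted as properties. `select_top_k_by_f1()` averages each
tree's F1 across validation sets without size weighting (a deliberate
choice; weighting by set size would let one large cohort dominate), skips
a set that lacks a gene the tree needs (with a warning), and breaks ties
by holdout accuracy then tree ID. When no positive calls exist, precision
is undefined; it is reported as 0 with an explicit `precision_defined =
FALSE` flag, and F1 is 0.

Missing features are an ensemble-level concern, not a tree-level one:
rather than imputing or using surrogate splits, `filter_by_available_features()`
retains exactly the trees whose gene sets are covered by the target data —
the practical answer to applying human-trained trees to, say, mouse data
lacking an annotated ortholog of a lncRNA signature gene. If nothing
survives, the error names the genes whose presence would unblock the most
trees.

ROC curves sweep every distinct score; AUC is the trapezoid area, which
with tied scores grouped equals the Mann–Whitney concordance probability
(ties counted 1/2) — cross-checked in the tests against an explicit
pair-counting oracle and against an independent ROC implementation.

## The synthetic-data generator

`generate_cohort()` emulates a two-condition (normoxic/hypoxic) bulk
transcriptome cohort with known ground truth, so every pipeline stage can
be scored. The model:

* per-gene baseline log2-abundances `mu_g ~ N(6, 2)`, drawn once;
* a configured number of **responsive genes**, drawn from genes with
  enough headroom (baseline percentile no higher than `100 - effect/2`;
  inducible genes must be able to rise). If the feasible pool is smaller
  than `de_genes` the requested effect is infeasible and the call errors;
* each responsive gene receives a gene-specific target percentile shift —
  the requested `effect` jittered by ±25% so no single gene is always the
  best marker and trees cannot collapse onto one feature by design. At
  `effect = 100` the jitter is suspended and every responsive gene is
  promoted strictly above the whole baseline ranking (the documented
  meaning of full effect);
* the percentile shift is converted to a log2-abundance offset through the
  empirical quantile function of the baselines — a calibration, not a
  guess. Because dropout both zeroes a gene (probability `dropout_p`) and
  compresses the nonzero percentile range, a nominal shift realizes as
  `(1 - dropout_p)^2` of itself on average; the calibration divides by
  this factor so the *delivered* shift matches the request. The
  Monte-Carlo suite verifies the realized hypoxic-minus-normoxic
  percentile difference stays within ±5 points of the request at the
  reference condition;
* per-sample noise (`noise_sd` on the log2 scale), dropout applied
  *before* ranking (so the tie-at-zero regime of real counts is
  exercised), and a multiplicative library-size factor that is
  deliberately irrelevant to ranks but keeps raw values realistic.

Defaults — 1000 genes, 25 responsive, effect 20 percentile points, 60
samples per condition, `noise_sd = 0.3`, `dropout_p = 0.1`, depth factors
in [0.5, 2] — describe a realistic desk-scale analogue of a multi-study
hypoxia compendium and are used as-is by the acceptance workflow.

Everything is a deterministic function of the config seed. The optional
`sample_seed` argument redraws the samples under a second seed while
keeping the gene model (baselines, responsive-gene identities, calibrated
shifts) tied to the config seed — this is how matched independent
train/validation/test cohorts and spatial grids are produced.

`generate_spatial()` lays spots on a grid and labels those inside a disc
hypoxic; each spot is one sample from the same generative model. It
emulates a hypoxic core in a tissue section, *not* realistic spatial
autocorrelation, cell-type mixtures, or morphology: passing the spatial
recovery test shows the consensus transfers from bulk-style training to
per-spot application, and nothing more.

What the generator does **not** emulate — batch structure between
studies, platform differences, correlated co-regulation beyond the shared
condition label, compositional effects, cell-type-specific response
heterogeneity — bounds what green tests mean: they validate the
machinery, and deliberately not the biology of any external cohort.

## Problem sizes and numerical conventions

The test suite and `scripts/acceptance.R` run the workflow at sizes chosen
to exercise every stage in a few minutes on one core: 100 iterations of
200-tree forests for gene selection, 500 candidate trees, two validation
cohorts for the top-20 selection, one independent test cohort, and a
12x12 spot grid with a radius-3 core. These are the package's scaled-down
reference conditions; the same code runs the 1000-iteration / 10000-tree
operating point unchanged.

Numerical conventions collected in one place: split-search ties resolved
by gene ID then threshold (with a 1e-12 guard against floating-point
near-ties); `>=` at node thresholds goes high; "over" thresholds
(accuracy 0.95, probability 0.5, MDA 4) are strict; leaf probabilities are
exact class fractions; AUC is trapezoid with ties at 1/2; gene-ID matching
is exact and case-sensitive throughout.

## Known limitations

* The absolute MDA threshold is only portable on the scaled statistic;
  raw-point thresholds must be recalibrated whenever signature redundancy
  or forest size changes.
* Percentiles depend mildly on the ranking universe (full annotation vs
  detected genes); apply trees to matrices ranked the same way they were
  trained.
* Blank or near-blank spots carry no signal; they are flagged, not
  rescued.
* The generator's cohorts are easier than heterogeneous public data;
  holdout accuracies and AUCs reported on synthetic cohorts characterize
  the machinery, not expected field performance.
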