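# hypotrees

Reference-free classification of individual transcriptomes as **hypoxic**
or **normoxic**, for anyone who needs to score single samples — a bulk
RNA-seq library, a tumor profile, or one spatial-transcriptomics spot —
without a matched control, a reference cohort, or any between-sample
normalization.

## The idea

Oxygen-starved cells mount a stereotyped HIF-driven transcriptional program:
a modest set of hypoxia-inducible genes climbs toward the top of the cell's
own expression ranking. `hypotrees` exploits this with a representation that
needs nothing but the sample itself: every gene *g* in sample *s* is mapped
to its **rank percentile**

```
pct(g, s) = 100 * (r_gs - 1) / (G - 1)
```

where `r_gs` is the average competition rank of `g` among the `G` genes of
sample `s` (most expressed gene = 100, least = 0). Rank percentiles are
invariant under any strictly increasing per-sample transform, so raw
counts, pseudocounts, CPM, FPKM, or VST values all give the identical
representation, and sequencing depth cancels by construction.

On this representation the package builds the full classifier-construction
workflow:

1. **Feature selection** — random forests (default 200 trees, 10 features
   per split) grown on repeated 70% resamples; genes ranked by permutation
   importance (mean decrease in out-of-bag accuracy, MDA) and selected by
   an MDA threshold.
2. **Mass tree generation** — thousands of small CART trees (Gini
   impurity, midpoint thresholds, `percentile >= threshold` takes the high
   branch), each trained on its own random 70/30 split and scored on its
   own holdout.
3. **Accuracy filtering** — trees with holdout accuracy strictly above
   0.95 form the working ensemble; the top 20 by mean F1 across validation
   cohorts form a compact one.
4. **Consensus classification** — a sample's score is the mean of the
   per-tree leaf probabilities; it is called hypoxic when the mean is
   strictly over the threshold (default 0.5). Datasets missing a signature
   gene (e.g. a lncRNA with no ortholog in mouse) are handled by keeping
   only the trees that never consult that gene.
5. **Evaluation** — confusion metrics, F1, ROC curves and trapezoid AUC
   (equivalently the Mann–Whitney concordance probability).

A synthetic-cohort generator with known hypoxia-responsive genes makes the
whole pipeline testable end to end, including spatial grids with a hypoxic
disc core.

## Worked example

```r
library(hypotrees)

cfg    <- synthetic_config(seed = 101)   # 1000 genes, 25 responsive, 60+60 samples
cohort <- generate_cohort(cfg)
rpm    <- rank_percentile(cohort$matrix)

# a 178-gene candidate panel containing the truly responsive genes
set.seed(1)
panel <- sort(union(cohort$truth,
                    sample(setdiff(rownames(rpm), cohort$truth), 153)))

imp   <- permutation_importance(subset_genes(rpm, panel), cohort$labels,
                                forest_params(seed = 1),
                                n_iterations = 30, scale = TRUE)
genes <- select_features(imp, 4)

pop   <- generate_tree_population(rpm, cohort$labels, genes,
                                  n_candidates = 300, seed = 2)
ens   <- filter_by_accuracy(pop, 0.95)
glance(ens)
#> # A tibble: 1 × 4
#>   n_trees n_genes min_holdout_accuracy mean_holdout_accuracy
#>     <int>   <int>                <dbl>                 <dbl>
#> 1      56       4                0.972                 0.972

val   <- generate_cohort(cfg, sample_seed = 7)
top20 <- select_top_k_by_f1(ens, 20,
                            list(list(matrix = rank_percentile(val$matrix),
                                      labels = val$labels)))

test  <- generate_cohort(cfg, sample_seed = 99)   # independent cohort
res   <- ensemble_predict(top20, rank_percentile(test$matrix))
evaluate(test$labels, res)
#> # A tibble: 1 × 9
#>      tp    fp    fn    tn accuracy precision recall    f1 precision_defined
#> 1    53     0     7    60    0.942         1  0.883 0.938 TRUE
roc_auc(test$labels, res$samples$mean_prob)
#> <roc_curve> AUC = 0.9732 (7 thresholds)

print(top20$trees[[1]])
#> <hypoxia_tree 11>
#> g0171 >= 84.6346? H p=0.51 n=100%
#>   no:  g0051 >= 24.4244? N p=0.05 n=51%
#>     no:  N p=0.00 n=43%
#>     yes: N p=0.29 n=8%
#>   yes: H p=1.00 n=49%
#> holdout accuracy 0.972, F1 0.970
```

Reading the numbers: the 30-iteration importance scan selected exactly the
25 truly responsive genes; 56 of 300 candidate trees survived the strict
0.95 holdout filter, together consulting 4 genes; on a fully independent
cohort the 20-tree consensus calls 53 of 60 hypoxic samples with no false
positives (accuracy 0.942, AUC 0.973). Each tree is a human-readable rule:
the printed one calls a sample hypoxic when gene `g0171` sits in the top
~15% of that sample's own expression ranking.

Results are tibbles throughout, fitted objects support `tidy()` /
`glance()`, and `autoplot()` / `plot_importance()` / `plot_spatial()`
provide ggplot2 graphics.

## Command line

A thin wrapper over the same functions (see `exec/hypotrees`):

```sh
hypotrees simulate --out cohort --seed 1
hypotrees rank     --counts cohort/counts.tsv --out ranks.tsv
hypotrees select   --ranks ranks.tsv --labels cohort/labels.tsv \
                   --out importance.tsv --genes-out selected.txt
hypotrees train    --ranks ranks.tsv --labels cohort/labels.tsv \
                   --genes selected.txt --out trees.json
hypotrees classify --ranks ranks.tsv --trees trees.json --out result.tsv
hypotrees evaluate --result result.tsv --labels cohort/labels.tsv --out report.tsv
hypotrees spatial  --mtx visium_dir/ --trees trees.json --out spots.tsv
```

Trees are exchanged as a versioned JSON schema (`save_trees()` /
`load_trees()`); spatial data is read from 10x-style Matrix Market
directories (`read_mtx_dir()`, gzip-tolerant).

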