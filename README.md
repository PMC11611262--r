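# phosphoseed

Sequence-based prediction of protein phosphorylation sites (S/T/Y) for
fungal proteomes, built around an offspring-competition genetic algorithm
for feature-subset selection.

## What it does

Most phosphosite predictors target model organisms; fungal proteomes are
poorly covered. `phosphoseed` implements a complete fragment-based
predictor:

1. **Fragments** — every candidate site becomes a 41-residue window with
   the S/T/Y at position 21 (`X`-padded at protein termini). Proteins and
   fragments are de-redunded by greedy clustering on global-alignment
   identity (thresholds 0.3 and 0.4), negatives are down-sampled to a
   balanced set, and an 80/20 stratified split is made.
2. **Features** — six physicochemical blocks (AAC, EAAC, CTDC, PAAC,
   QSOrder, positional one-hot BINARY) and a distributed representation:
   overlapping k-mers embedded by a seeded subword skip-gram model, the
   fragment vector being the concatenation of its k-mer vectors
   ((41 − k + 1) × 20 components; 700 for k = 7).
3. **Selection** — EAAC and BINARY are pre-filtered to their top 250
   columns by gradient-boosting importance; each feature family is then
   reduced by AUC-driven sequential forward selection (SFS); finally an
   **offspring-competition genetic algorithm** picks a fixed 100-feature
   subset from the combined space: per parent pair, 10 candidate offspring
   are produced by two-point crossover + mutation and only the fittest
   survives. Fitness is 5-fold cross-validated AUC of an RBF-SVM
   (population 60, mutation 3e-4 per gene, mutation passes escalating every
   5 generations, elitist carry-over).
4. **Model & evaluation** — an RBF-SVM with a small cost/gamma grid search;
   reported metrics are ACC, SN, SP, MCC = (TP·TN − FP·FN)/√((FP+TP)(FN+TP)(FP+TN)(FN+TN)),
   trapezoidal AUC, and the prediction-bias indicator |SN − SP|%.

A synthetic-data module generates proteins with planted positional motifs
(arginine at fragment position 18, proline at 22, serine-rich 17–21), so
every stage is testable offline; it defines the conditions the test suite
and acceptance script run under.

## Worked example

```r
library(phosphoseed)

cfg <- pipeline_config(
  seed      = 101,
  embedding = embedding_config(k = 7, w = 1, epochs = 20),
  sfs_max   = 25, sfs_min_keep = 60,
  ga        = ga_config(generations = 3, seed = 101))

model <- run_pipeline(cfg,
  synth = list(n = 180, length_range = c(150, 250),
               n_sites = c(positive = 60, negative = 600)),
  out_dir = "run1", verbose = TRUE)
#> [phosphoseed] balanced dataset: 120 fragments (96 train)
#> [phosphoseed] physchem block: 625 features
#> [phosphoseed] physchem SFS: best prefix 16, keeping 60 (AUC 0.9562)
#> [phosphoseed] embedding SFS: best prefix 23, keeping 60 (AUC 0.8524)
#> [phosphoseed] combined selected features: 120
#> [phosphoseed] training final classifier on 100 features
#> [phosphoseed] held-out: ACC 0.7917 SN 0.7500 SP 0.8333 MCC 0.5854 AUC 0.9167

model$report
#> <eval_report: ACC 0.7917  SN 0.7500  SP 0.8333  |SN-SP|% 8.33  MCC 0.5854  AUC 0.9167>
length(model$selected_features)
#> [1] 100

binary_feature_index(18, "R")   # arginine at fragment position 18
#> [1] 342
embed_feature_info(282, k = 7)$span  # fragment positions covered
#> [1] 15 21
```

The held-out report says the model separates planted-motif positives from
background negatives (AUC 0.92 on 24 held-out fragments here); the GA subset
always has exactly 100 features. `run1/` contains per-stage artifacts
(fragments, SFS curves, GA history, selected subset, ROC) as plain TSV/JSON.

A thin CLI wraps the same functions
(`inst/cli/phosphoseed.R synth|extract|run|predict`).

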