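---
title: "Predicting fungal phosphorylation sites: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting fungal phosphorylation sites: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Protein phosphorylation occurs on serine, threonine and tyrosine residues,
and only a small fraction of the S/T/Y residues in a proteome are ever
phosphorylated. Predicting which candidate sites are phosphorylatable from
sequence alone is a standard binary classification task: the unit of
classification is the **fragment**, a 41-residue window centered on the
candidate site (the site sits at position 21; windows running past a protein
terminus are padded with `X`). `phosphoseed` implements a complete
fragment-based predictor aimed at fungal proteomes, where tool coverage is
thin: feature encoding, two rounds of feature selection, a support-vector
machine, and a synthetic-data generator that makes the whole pipeline
testable without any external database.

## Data preparation

Proteins are first reduced for redundancy (greedy incremental clustering:
a sequence is kept iff its global-alignment identity to every previously
kept sequence is below 0.3), fragments are extracted, fragments are reduced
again at 0.4, negatives are down-sampled to the number of positives, and the
balanced set is split 80/20 stratified by label — in that order. Identity is
computed by Needleman–Wunsch global alignment with affine gaps (BLOSUM62,
gap opening 10, extension 0.5) as matches / alignment length, with gaps in
the denominator. Common clustering tools do not go below 40% identity, which
is why the package carries its own deterministic greedy filter; the
alignment itself is a small C++ routine whose identities are checked against
`Biostrings::pairwiseAlignment` in the test suite. Because the greedy pass
is order-dependent, results are deterministic for a fixed input order.
Whether negatives should be sampled before or after fragment-level
redundancy reduction is genuinely open; the pipeline samples **after**, so
the negative pool is already non-redundant.

## Feature encoding

Six physicochemical blocks, all indexed 1-based from the fragment start:

* **AAC** — the 20 residue frequencies.
* **EAAC** — AAC inside every sliding window of 5 (`SW.<window>.<residue>`;
  window 17 covers positions 17–21, i.e. the site and the four residues to
  its left). 37 windows × 20 = 740 features.
* **CTDC** — for 13 physicochemical properties (seven hydrophobicity
  scales, van der Waals volume, polarity, polarizability, charge, secondary
  structure, solvent accessibility), each splitting the alphabet into three
  groups, the fraction of residues in each group (39 features). The group
  tables ship in the package source, so results are reproducible
  bit-for-bit.
* **PAAC** — Chou's pseudo-amino-acid composition: 20 composition terms
  plus λ sequence-order correlation factors built from normalized
  hydrophobicity, hydrophilicity and side-chain mass.
* **QSOrder** — quasi-sequence-order terms built from two residue-pair
  distance matrices (40 + 2·nlag features).
* **BINARY** — a 20-slot one-hot per position (820 features), named
  `BINARY.F<n>` with `n = (position − 1)·20 + rank(residue)` over the
  alphabet `ARNDCQEGHILKMFPSTWYV`; arginine at position 18 is F342, proline
  at position 22 is F435. One-hot encodings pay off on larger datasets;
  `use_binary` in `encoder_config()` turns the block off.

`X` positions are excluded from both numerator and denominator of every
composition-type feature, so slices remain probability simplices over real
residues; BINARY emits all zeros at an `X`.

Two table-level choices deserve a note. The Grantham distance matrix is
recomputed from Grantham's published formula and property table (α = 1.833,
β = 0.1018, γ = 0.000399, ρ = 50.723); recomputed values match the published
rounded table to within about one unit. The second QSOrder matrix in the
literature is the Schneider–Wrede physicochemical distance, whose numeric
table is not reproducible from public sources; the package instead uses a
documented substitute (`hphys_matrix()`): the root-mean-square difference of
the same three normalized scales PAAC uses. It plays the same structural
role — a symmetric physicochemical residue distance — and is labelled by
what it is, not as Schneider–Wrede.

PAAC's λ and QSOrder's nlag default to 2 with weights 0.05 and 0.1
(conventional values; the optimal settings for real fungal data are a
dataset property, and both are exposed in `encoder_config()`). With these
defaults the combined physicochemical space is 20 + 39 + 250 + 22 + 44 +
250 = 625 columns after pre-filtering (below); the exact total moves with λ
and nlag, so tests assert the dimension formulas rather than any single
total.

## Distributed k-mer embeddings

Each fragment is tokenized into overlapping k-mers (stride 1, `41 − k + 1`
tokens) and treated as a sentence. A skip-gram model with negative sampling
embeds every k-mer into 20 dimensions; in the fastText manner each word is
represented as the mean of its own vector and its character n-gram (3–6)
vectors, the n-grams hashed into 2^16 shared buckets, so k-mers unseen in
training still compose a vector from their subwords. The fragment feature is
the concatenation of its token vectors — 700 components for k = 7 — named
`EmbedFea<n>` with `n = (token − 1)·20 + component`, so components 281–300
describe the 15th k-mer (fragment positions 15–21 at k = 7).

The trainer is a small single-threaded C++ routine with its own seeded
xorshift RNG: for a fixed seed, training is bit-reproducible, which the
determinism contract requires and which multithreaded embedding libraries
cannot offer. Defaults: 100 epochs (small corpora need many passes), 5
negatives per positive pair, linear learning-rate decay 0.05 → 1e-4, minimum
word count 1. The embedding is trained on training fragments only, to keep
the held-out evaluation leak-free.

`grid_search_kw()` scans k = 2..10 and window w = 1..10, scoring each cell
by 5-fold cross-validated accuracy of the downstream SVM on the training
split, and prefers smaller k, then smaller w, on ties (simpler models win
when accuracy does not distinguish them). Whether such a grid should be
scored by cross-validation or a held-out set is open; cross-validation on
the training split avoids consuming the test set.

## Feature selection

Two stages operate on the encoded blocks:

1. **Pre-filter**: the two high-dimensional blocks (EAAC 740, BINARY 820)
   are cut to their top 250 columns by gradient-boosted-tree gain
   importance, keeping original column order.
2. **Sequential forward selection (SFS)**: given an importance ranking
   (F-score, gradient boosting, random forest, or
   Max-Relevance-Max-Distance), features are added one at a time; at every
   step the five metrics of a 5-fold cross-validated RBF-SVM are recorded,
   and the selected subset is the prefix with the highest AUC (first
   maximizer on ties). Forward only, step size 1.

The four importance methods are deliberately heterogeneous: a univariate
statistic, two tree ensembles (gain and impurity decrease), and MRMD, which
adds a redundancy penalty — relevance is |Pearson correlation| with the
label and the distance term is the mean Euclidean distance to the other
z-scored columns; the two terms enter with equal weight (the original
weighting is under-documented, so the weights are exposed as arguments).
Ranking ties break by original column index, which keeps every ranking a
deterministic permutation.

## The offspring-competition genetic algorithm

SFS scores features one at a time and cannot see interactions; the final
reduction therefore runs a genetic algorithm over fixed-size feature
subsets. A **chromosome** is a set of exactly 100 distinct column indices;
its **fitness** is the mean 5-fold cross-validated AUC of the RBF-SVM on
those columns (fold assignment fixed once per run; fitness values cached per
gene-set so identical subsets are never re-evaluated).

Per generation, with the default configuration (population 60, 150
generations, per-gene mutation probability 3e-4, 10 crossover repeats):

1. **Selection** — the top third (20) of the population by fitness become
   parents.
2. **Offspring competition** — parents are shuffled into pairs; each pair
   produces 10 candidate offspring by two-point crossover on the sorted gene
   arrays (the segment between two random cuts is swapped in), duplicate
   genes are repaired by uniform resampling from unused features, mutation
   is applied, and only the fittest candidate survives. Pairing rounds
   repeat until 60 offspring exist.
3. **Mutation escalation** — mutation runs in `1 + floor(generation / 5)`
   passes; each pass independently replaces each gene with probability
   3e-4 by an unused feature. Escalation combats late-stage premature
   convergence.
4. **Elitism** — the best individual ever seen replaces the worst
   offspring, making the best-fitness trajectory non-decreasing.

Three readings in this design were genuinely open and are all
config-exposed: "10 crossover repeats" is read as 10 competing candidates
per pair (the natural meaning of offspring competition); "selection three
times to refill the population" is implemented as pairing rounds repeating
until the population is refilled (three rounds of 10 survivors from 20
parents yield 30; the loop continues to 60); and elitism is not stated by
the source framework but is required for a monotone best-fitness trajectory,
so it is included. With `crossover_repeats = 1` and mutation off the
algorithm degenerates to a plain elitist GA, which the tests exercise as a
sanity limit.

## Classifier and evaluation

The final model is an RBF-kernel SVM with a small grid search over cost and
gamma (selected by 5-fold cross-validated AUC). Scores are logistic
transforms of the SVM decision value: Platt's probability fitting inside
libsvm consumes an RNG that cannot be seeded from R, which would break
bit-reproducibility, and any strictly monotone transform leaves ranking
metrics untouched. The decision threshold for the confusion-based metrics
is 0.5 on that score, i.e. the sign of the margin.

Reported metrics: ACC, sensitivity SN = TP/(TP+FN), specificity
SP = TN/(TN+FP), Matthews correlation
MCC = (TP·TN − FP·FN) / √((FP+TP)(FN+TP)(FP+TN)(FN+TN)), and trapezoidal
AUC over all score thresholds, plus |SN − SP| in percent as a
prediction-bias indicator. Degenerate denominators: SN/SP with an empty
class are `NA`; an MCC denominator of zero yields 0 with a warning.

## The synthetic-data generator

`generate_proteins()` emulates the input data: i.i.d. uniform background
residues (an empirical residue distribution can be supplied), with planted
positional motifs around positive sites. The default motif set mirrors the
positional biases reported around fungal serine phosphosites — arginine
enriched at fragment position 18 (probability 0.40), proline at 22 (0.40),
and a serine-rich stretch at 17–20 (0.30 each; position 21 is the site
itself). Sites are placed at least 43 residues apart so windows never
overlap. Default scale: 400 positives and 4000 negatives before balancing.
`generate_feature_matrix()` plants class-shifted normal columns among
standard-normal noise for selector-level tests.

What the generator does **not** emulate: kinase-family substrate
specificity beyond single-position enrichment, realistic residue
composition, homology structure between proteins (synthetic proteins are
nearly never redundant, so the redundancy filters pass almost everything
through), or class imbalance beyond the 1:10 default. A pipeline that
passes on these fixtures is verified in its mechanics — encodings, index
arithmetic, selection dynamics, reproducibility — not certified to reach
any particular accuracy on real fungal data.

## Numerical choices and problem sizes

* All stochastic steps take explicit integer seeds; the full pipeline is
  bit-reproducible for a fixed seed (asserted in the tests by comparing
  artifact checksums across two runs).
* Fold assignment is stratified and seeded; the same folds are reused for
  every fitness evaluation within a GA run so chromosomes are compared on
  identical partitions.
* SFS can be capped (`sfs_max`) and floored (`sfs_min_keep`): the cap
  bounds the curve length, the floor keeps the combined selected space at
  least as wide as the GA chromosome. The vignette-scale and test-scale
  runs use fixtures of 60–400 positives, SFS caps of 25–50 steps and GA
  runs of 1–10 generations at the default population of 60 — chosen so the
  whole suite runs on a laptop-class single core; the algorithmic constants
  (population 60, chromosome 100, mutation 3e-4, 10 crossover repeats, top
  third selection, escalation every 5 generations) are never scaled.
* Ties: ranking ties break by column index, SFS and grid-search ties by the
  earlier/simpler candidate, fitness ties in parent selection by insertion
  order. All three rules exist for determinism.

## Known limitations

* The redundancy filter is greedy and order-dependent by design; it is not
  a globally optimal clustering.
* The Schneider–Wrede matrix is substituted as described above; QSOrder
  values are therefore not numerically comparable with implementations that
  ship the original table, though their structure and behavior are.
* The skip-gram trainer is deliberately minimal (no hierarchical softmax,
  no subsampling of frequent words); on the small corpora fragments
  produce, these refinements matter little, but the embedding is not a
  drop-in replica of large-scale text embeddings.
* Score calibration is a logistic squash of the margin, not a fitted
  probability; scores order sites correctly but are not calibrated
  posterior probabilities.
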