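# lpiforest

Sequence-based prediction of interactions between long noncoding RNAs
(lncRNAs) and RNA-binding proteins with a cascade deep forest.

Most lncRNAs act by binding proteins, but the experimentally mapped
lncRNA–protein interaction (LPI) network is sparse: for a typical curated
dataset of hundreds of lncRNAs and tens of proteins, the vast majority of
pairs have unknown status. `lpiforest` scores those unknown pairs from
sequence alone, and evaluates predictions honestly in the three regimes that
matter: pairs between known entities, entirely new lncRNAs, and entirely new
proteins.

## Method

Given lncRNA sequences, protein sequences, and a binary interaction matrix
*Y* (*Y<sub>ij</sub>* = 1 for a known interaction, 0 for unknown):

* **lncRNA features** — 4-mer nucleotide composition: the relative frequency
  of every length-4 word over all overlapping windows, 256 features in
  lexicographic A < C < G < T order.
* **Protein features** — each protein is segmented with a sliding window
  (*K* = 3), segments are hashed with a fixed polynomial
  *h(s)* = (Σ<sub>i</sub> code(s<sub>i</sub>)·31<sup>i</sup>) mod 8191,
  and the padded, scaled hash sequence is compressed by a seeded
  feed-forward autoencoder whose 544-unit bottleneck is the feature vector.
* **Classifier** — pair features (256 + 544 = 800 dimensions) enter a
  cascade deep forest: each layer holds logistic regression, gradient-boosted
  trees, a random forest, and extremely randomized trees; their four
  (p<sub>pos</sub>, p<sub>neg</sub>) pairs form an 8-dimensional class
  vector that is concatenated with the original 800 features (808 columns)
  as input to the next layer. Class vectors for training rows are produced
  out-of-fold, depth is chosen automatically on a held-out validation split,
  zero-importance features are pruned, and the final score is the mean of
  the last layer's positive-class probabilities.
* **Evaluation** — balanced negatives sampled from unknown pairs; five-fold
  cross-validation masking lncRNA rows (CV1), protein columns (CV2), or
  pairs (CV3); precision, recall, accuracy, F1, AUC and AUPR averaged over
  folds and repeats. AUC/AUPR implementations are tested against brute-force
  oracles.
* **Synthetic data** — a seeded generator plants latent compatibility
  classes via sequence motifs, giving self-contained fixtures with known,
  recoverable signal.

## Worked example

Generate a synthetic dataset with planted signal, featurize it, and run the
pairwise (CV3) protocol — about five minutes on one CPU at these sizes:

```r
library(lpiforest)

ds <- generate_dataset(synthetic_spec(seed = 11))   # 150 lncRNAs x 20 proteins
ds
#> lpi_dataset: 150 lncRNAs x 20 proteins, 497 known interactions (2503 unknown pairs)

feats <- featurize_dataset(ds, seed = 11)           # 256 + 544 feature blocks
report <- run_cv_experiment(ds, "CV3", n_folds = 5, repeats = 2,
                            features = feats, seed = 11)
report
#> lpi_cv_report: CV3, 5 folds x 2 repeat(s), base seed 11
#>   precision 0.8046 +/- 0.0055
#>   recall    0.7813 +/- 0.0071
#>   accuracy  0.7947 +/- 0.0056
#>   f1        0.7917 +/- 0.0055
#>   auc       0.8462 +/- 0.0032
#>   aupr      0.8447 +/- 0.0050
```

The fixture plants four latent compatibility classes: matching
lncRNA–protein class pairs interact with probability 0.6, mismatching ones
with 0.02. Because the signal is probabilistic, even a perfect
class-recovering model tops out near AUC 0.89 here, so 0.85 means the
cascade has recovered most of the planted rule; the same experiment with the
match boost removed calibrates near 0.5. Cold-start evaluation over lncRNAs
(`"CV1"`) and ranking of unknown pairs work the same way:

```r
pos <- which(ds$Y == 1L, arr.ind = TRUE)
neg <- sample_negatives(ds$Y, sum(ds$Y), seed = 11)
X <- pair_features(feats, c(pos[, 1], neg$row), c(pos[, 2], neg$col))
model <- fit_cascade(X, rep(1:0, c(nrow(pos), nrow(neg))),
                     cascade_config(seed = 11))
ranked <- rank_unknown_pairs(model, ds, feats)      # 2503 scored pairs
head(ranked, 3)
```

A thin command-line wrapper with `simulate`, `featurize`, `evaluate` and
`rank` subcommands lives at `inst/cli/lpiforest.R`:

```sh
Rscript inst/cli/lpiforest.R simulate --seed 11 --out data/
Rscript inst/cli/lpiforest.R evaluate --config run.yaml --seed 11 --out results/
```

## Package layout

| Path | Contents |
| --- | --- |
| `R/io_data.R` | FASTA/edge-list readers, interaction matrix, dataset container |
| `R/features_lncrna.R` | k-mer composition |
| `R/features_protein.R` | segmentation, hashing, autoencoder embedding |
| `R/cascade.R` | cascade deep forest (fit, predict, prune, serialize) |
| `R/evaluation.R` | negative sampling, CV schemes, metrics, ranking |
| `R/synthetic_data.R` | seeded fixture generator, worked-example fixtures |
| `R/cli.R` + `inst/cli/` | workflow commands and shell wrapper |
| `vignettes/lpiforest-methods.Rmd` | model, assumptions, design choices |
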