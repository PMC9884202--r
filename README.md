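# sarcloc

Machine-learning segmentation of sarcomeric double-line structures in
single-molecule localization microscopy (SMLM) point clouds.

dSTORM measurements of sarcomeric proteins in isolated myofibrils yield
localization tables, not images. Many of these proteins sit in disc pairs
perpendicular to the myofibril axis, so their 2D projection is a
*double line*: two parallel ~1.5 µm lines separated by d ≈ 120 nm,
repeating every L ≈ 3.4 µm along the strand. Measuring a protein's axial
position by structure averaging requires selecting those objects and the
localizations that belong to them — tedious by hand, and ill-suited to
pixel-based detectors alone. sarcloc automates the whole chain for people
analysing such data:

1. **simulate** — a localization-level generator produces labelled
   double-line fields (epitopes → labels → blinks → localizations) plus
   clustered (vesicle) and uniform background noise, with noise within
   50 nm of the structures removed so the labels stay clean.
2. **featurize** — every localization gets a fixed 380-element descriptor
   computed inside density-normalized random subsets (~300 object
   localizations per structure per subset): the 350 sorted
   nearest-neighbour distances concatenated with a 30-bin (12°),
   3-bin-smoothed neighbour-direction histogram circularly aligned so its
   global maximum sits at −π/6.
3. **classify** — a one-hidden-layer network (32 ReLU units, sigmoid
   output, binary cross-entropy, Adam, 10 epochs, batch 32) maps feature
   vectors to object/noise, with TP/TN evaluation and a
   distances-only / directions-only / combined ablation.
4. **roi** — measurement files are rendered at 100 nm/pixel, candidate
   boxes are detected over several contrast settings (classical
   blur/Otsu/morphology backend, pluggable), each box is expanded by 1 µm
   (growing in 0.5 µm steps until ≥351 localizations) and partitioned into
   subsets; features are computed only inside those regions.
5. **postfilter** — classifier positives pass a 10-NN / 5×-median outlier
   rule, DBSCAN (ε = 50 nm, minPts = 5) largest-cluster selection, and a
   quality gate (sigma within [112, 160] nm, Thompson precision ≤ 20 nm),
   with per-stage discard accounting and convex-hull summaries.
6. **analyze** — each object's long axis (principal component) and line
   separation d̂ (symmetric two-Gaussian mixture on the perpendicular
   offsets) close the loop on parameter recovery.

Everything is tidyverse-shaped: localization tables in, tibbles out,
`tidy()`/`glance()` on fitted models, `autoplot()`/`plot_*()` for the main
result types. The heavy kernels (kNN features, DBSCAN, the MLP training
loop) are compiled via Rcpp and checked against brute-force oracles in the
test suite.

## Worked example

```r
library(sarcloc)

# labelled corpus: two 27-pair fields spanning epitope densities 30-50 /um^2
# and line separations 120-128 nm, ~110k localizations
corpus <- simulate_training_corpus(seed = 1)
feats  <- featurize_corpus(corpus, seed = 11)
labels <- corpus$label[feats$.row]
split  <- split_train_val_test(tibble::tibble(label = labels), seed = 21)

tab <- run_ablation(feats, labels, split, seed = 31)
tab[, c("feature_set", "tp_rate", "tn_rate")]
#> # A tibble: 3 × 3
#>   feature_set tp_rate tn_rate
#>   <chr>         <dbl>   <dbl>
#> 1 distances     1.000   0.984
#> 2 directions    0.966   0.851
#> 3 combined      0.998   0.986
```

`tp_rate` is the fraction of true double-line localizations the model
recognises on the held-out 10% test split; `tn_rate` the fraction of noise
it rejects. Distances-only features are strong on this clean synthetic
corpus, directions-only clearly weaker; the combined 380-wide vector keeps
both rates high at once.

The full measurement-style pipeline (detect → featurize → classify →
filter → analyze) and the separation estimate:

```r
cfg <- pipeline_config(
  seed = 11,
  simulate = list(densities = c(40), d = c(120), n_pairs = 6)
)
res <- run_pipeline(cfg, out_dir = "out")
res$separations
#> # A tibble: 6 × 5
#>   object_id d_hat axis_angle width n_locs
#>       <int> <dbl>      <dbl> <dbl>  <int>
#> 1         1  119.       1.55  23.5    811
#> 2         2  113.      -1.53  26.2    774
#> 3         3  120.      -1.57  21.9    843
#> 4         4  113.       1.53  27.7    806
#> 5         5  120.       1.56  21.7    760
#> 6         6  115.      -1.56  21.8    892
```

All six simulated objects are found and their line separation is recovered
within a few nanometres of the simulated 120 nm (`axis_angle ≈ ±π/2`: the
lines run perpendicular to the horizontal strand). `res$report` holds the
per-stage discard table, `out/` the CSV/JSON artifacts and a manifest with
the config hash and seed.

A thin command-line front end wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "sarcloc.R", package = "sarcloc"))') \
  simulate --seed 1 --out locs.csv
```

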