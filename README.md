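# translucid

Statistics and image transforms for two-condition (color vs. grayscale)
psychophysics of translucent-material perception.

People disagree far more about whether wax, jelly or fruit flesh is
"translucent" than they do about glass or metal, and removing color makes
the disagreement worse. Studies of this effect collect, per condition, a
binary translucent/opaque classification of each image by every observer,
6-point Likert ratings of five semantic attributes (see-throughness,
glossiness, softness, glow, density), and an 18-way material
categorization. `translucid` implements the full analysis pipeline for
such data:

* **Agreement** — percent agreement `P_i = max(N_o, N_t)/N`,
  translucent/opaque/unsure labeling at a ≥60% vote threshold, label-flip
  typology between conditions, image- and person-level representational
  dissimilarity matrices (normalized Hamming distance), pairwise Cohen's
  `κ = (P_a − P_e)/(1 − P_e)` with agreement-level binning, and one-sided
  Mann–Whitney region comparisons (exact for small samples).
* **Rating distributions** — add-one-smoothed 6-bin distributions,
  `D_KL(G‖C) = Σ G(x) log(G(x)/C(x))` in nats with the `D_KL > 1` flag,
  skewness shifts `D_s = s_color − s_gray`, Kendall τ-b correlations of
  mean ratings with opacity votes, and the Bonferroni-corrected (α =
  0.05/10 = 0.005) attribute correlation matrix.
* **Perceptual space** — PCA of mean ratings, per-observer PCA on
  polychoric correlations (estimator implemented in-package), stratified
  3-fold cross-validated logistic prediction of each observer's own binary
  labels with Wald-significant attribute counting, and seeded t-SNE
  embeddings (perplexity 15).
* **Categorization** — the closed 18-name vocabulary, regrouping to 8
  major categories, misjudgment counts against ground truth, food vs.
  non-food tables, and person-by-person categorical RDMs.
* **Colorimetry** — CIELab-lightness decolorization under D65, CIELCh
  lightness/chroma extraction, CIE u′v′ saturation–luminance statistics,
  and the correlation-blending transform that modulates saturation toward
  luminance while preserving the saturation mean and SD.
* **Synthetic data** — a seeded generator of full observer panels (latent
  translucency continuum, criterion-varying observers, grayscale signal
  attenuation + noise inflation, food/non-food confusion) and of
  Beer–Lambert cube stimuli, so the entire pipeline is testable with no
  data download.

## Worked example

```r
library(translucid)

pair <- generate_panel(synthetic_config(seed = 1))

votes    <- vote_counts(pair$color)
labels_c <- assign_label(votes)                       # >= 60% rule
labels_g <- assign_label(vote_counts(pair$grayscale))
table(labels_c$label)
#>   T   U   O
#> 109  40 151

flip_table(labels_c, labels_g)$counts
#> T->O O->T T->U U->T O->U U->O
#>    5   10   26   15   45    7

km_c <- kappa_matrix(pair$color)
km_g <- kappa_matrix(pair$grayscale)
c(color = km_c$mean_kappa, grayscale = km_g$mean_kappa)
#>     color grayscale
#> 0.2759...  0.0721...

mr  <- mean_ratings(pair$color)
tau_vs_opacity(mr$see_throughness,
               votes$n_opaque[match(mr$image_id, votes$image_id)])$tau
#> -0.826...

pca <- pca_mean_ratings(mr)
sum(pca$explained_variance_ratio[1:2])
#> 0.9516...

acc <- sapply(panel_predictions(pair$color, seed = 1), `[[`,
              "mean_accuracy")
c(median = median(acc), above_0.7 = mean(acc > 0.7))
#>    median above_0.7
#> 0.8783...         1
```

Reading the numbers: grayscale observers agree far less than color
observers (mean κ drops from 0.28 to 0.07) and 108 of 300 images change
their T/U/O label; mean see-throughness falls steeply as images are voted
opaque (τ ≈ −0.83); two principal components carry ~95% of the
mean-rating variance, with see-throughness/glow/glossiness on one axis and
softness/density on the other; and each simulated observer's own ratings
predict their binary labels well above the 0.5 chance line. These are
properties of the documented synthetic world, not reproductions of any
published dataset.

The end-to-end pipeline with one JSON report:

```r
report <- run_all(run_config(synthetic_config(seed = 1), seed = 1))
write_report(report, "report.json")
```

A command-line interface is installed at `inst/cli/translucid`
(subcommands `validate`, `agreement`, `ratings`, `space`, `categories`,
`image`, `simulate`, `run`).

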