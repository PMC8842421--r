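Package: translucid
Title: Analysis Toolkit for Translucency-Perception Psychophysics
Version: 0.1.0
Authors@R:
    person("Translucid", "Maintainers", email = "maintainers@translucid.invalid",
           role = c("aut", "cre"))
Description: Statistics and image transforms for psychophysical studies of
    translucent-material perception with color and grayscale stimuli.
    Implements inter-observer agreement analysis (percent agreement,
    translucent/opaque/unsure labeling, label-flip typology, normalized
    Hamming representational dissimilarity matrices, pairwise Cohen's kappa,
    one-sided Mann-Whitney comparisons), Likert rating-distribution
    statistics (Kullback-Leibler divergence, skewness shifts, Kendall tau-b
    correlations), perceptual-space analyses (PCA of mean ratings,
    per-observer polychoric PCA, cross-validated logistic prediction of
    binary classification, t-SNE embeddings), material-categorization
    analyses (category regrouping, misjudgment counts, food versus non-food
    tables, person-by-person categorical RDMs), and CIE colorimetry
    (CIELab-lightness decolorization, CIELCh channel extraction, CIE u'v'
    saturation-luminance statistics and correlation blending). A seeded
    synthetic observer and stimulus generator emulates the statistical
    structure such studies assume, so the whole pipeline is testable without
    access to observer data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    Rtsne,
    png
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    withr
Config/testthat/edition: 3
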