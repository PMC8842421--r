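---
title: "Methods: agreement, rating and colorimetry statistics for translucency psychophysics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: agreement, rating and colorimetry statistics for translucency psychophysics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem this package addresses

Translucent materials — wax, skin, fruit flesh, jelly — transmit and scatter
light inside their volume, and people disagree much more about them than
about clearly transparent or clearly opaque things. A standard way to study
this is a two-condition psychophysics design: one observer group judges
photographs of real objects in color, a second group judges the same images
in grayscale, across three tasks — a binary translucent/opaque
classification, 6-point Likert ratings of five semantic attributes
(see-throughness, glossiness, softness, glow, density), and an 18-way
material categorization. `translucid` implements the complete statistical
pipeline for such data, plus the image transforms used to reason about
*why* color matters (lightness decolorization, chroma extraction, and
saturation–luminance correlation manipulation), and a seeded synthetic
observer generator so that every stage is testable without access to any
observer data.

# Statistical model and procedures

## Agreement (binary task)

For image $i$ with $N$ observers, percent agreement is
$P_i = \max(N_{oi}, N_{ti})/N$. Images are labeled translucent (T), opaque
(O) or unsure (U) by a vote-fraction threshold, by default
$n/N \ge 0.6$ — the comparison is inclusive, so 12 of 20 votes qualifies.
Crossing the labels of the two conditions yields the flip typology
(T→O, O→T, and the four transitions through U).

Dissimilarity uses the normalized Hamming distance: for two response
vectors, the number of disagreeing positions divided by the vector length.
Applied over images it gives the image-by-image representational
dissimilarity matrix (RDM); over observers (or over categorization
responses, where "disagree" means "chose a different fine category") it
gives person-by-person RDMs.

Pairwise inter-observer agreement is Cohen's
$\kappa = (P_a - P_e)/(1 - P_e)$, with $P_e$ from the two raters' marginal
label frequencies. Agreement levels are binned half-open:
$[0, 0.20)$ none, $[0.20, 0.40)$ minimal, $[0.40, 0.60)$ weak,
$[0.60, 0.80)$ moderate, $[0.80, 1]$ strong; negative $\kappa$ reports as
"none". The published verbal ranges these bins implement leave gaps
(e.g. between 0.20 and 0.21), so the contiguous cover above is an
interpretation, and it is stated here rather than hidden. When both raters
are constant, chance-corrected agreement is not identified: $\kappa$ is
defined as 1 (identical) or 0 (different) with a degeneracy flag.

Condition comparisons use a one-sided Mann–Whitney U test: exact by
complete enumeration when both groups have at most 8 values (valid under
ties), otherwise the normal approximation with tie and continuity
correction. RDM and $\kappa$ cells are not independent samples, so these
p-values are descriptive, and region comparisons use only upper-triangle
off-diagonal cells of the designated sub-blocks to avoid double counting.

## Rating distributions

Per image, attribute and condition, ratings form a 6-bin distribution. The
divergence of the grayscale distribution $G$ from the color distribution
$C$ is $D_{KL}(G\|C) = \sum_x G(x)\log\frac{G(x)}{C(x)}$, computed in
natural log units. Two choices the underlying formula leaves open:

* **Smoothing.** $D_{KL}$ is infinite whenever $C(x) = 0$ at an observed
  $G(x) > 0$, which happens constantly at 20 observers over 6 bins. Both
  distributions therefore get add-one smoothing,
  $p_k = (c_k + 1)/(n + 6)$, which is minimal, symmetric between
  conditions, and can be disabled (`smooth = FALSE`) for strictly positive
  data.
* **Log base.** Natural log (nats). The conventional "$D_{KL} > 1$ flags a
  substantial change" rule is base-dependent, so the base is recorded in
  the result metadata.

Distribution shape changes are tracked by
$D_s = s_{color} - s_{gray}$, the difference in adjusted Fisher–Pearson
sample skewness (the standard small-sample bias-corrected estimator;
constant samples map to skewness 0 with a flag). A downward rating shift
in grayscale piles mass at the low end of the scale, raising $s_{gray}$
and driving $D_s$ negative.

Rating–classification association uses Kendall's $\tau$-b with tie
correction — Likert ratings and vote counts are heavily tied, so the
untied variants would be biased. The attribute-by-attribute correlation
matrix tests 10 pairs, so the family-wise 0.05 level Bonferroni-adjusts to
0.005 per pair.

## Perceptual space

PCA of the image-by-attribute mean-rating table standardizes attributes by
default: the five attributes share the 1–6 scale, but standardization
keeps loadings comparable when rating variances differ, and it can be
turned off. Component signs are fixed by making the largest-magnitude
loading positive, so output is deterministic across eigensolvers.

Per-observer analyses respect the ordinal scale by working from
**polychoric correlations**: each attribute is modeled as a discretized
latent normal, thresholds are fixed at the normal quantiles of the
empirical marginals, and each pairwise latent correlation maximizes the
contingency-table likelihood, with bivariate normal rectangle
probabilities evaluated by a 48-node Gauss–Legendre quadrature of the
correlation-integral identity (accurate to ~1e-10, deterministic). If the
pairwise assembly is indefinite it is repaired by eigenvalue clipping and
flagged. No polychoric package is assumed; the estimator is implemented
here and checked against parameter recovery and an independent bivariate
CDF oracle.

Each observer's binary classification is predicted from their own five
ratings by unpenalized logistic regression with stratified 3-fold
cross-validation (stratified by the observer's own labels so each fold
contains both classes; the fold seed is recorded). Per training fold,
attributes significant by the Wald test at 0.05 are collected — Wald was
chosen among the asymptotically equivalent tests and is noted in the
output. Perfect separation is detected from the fitting warnings or
runaway coefficients; those folds fall back to a small ridge-penalized
Newton fit for prediction, and their Wald tests are marked unreliable.

t-SNE embeddings (perplexity 15, exact gradients) are deterministic given
the seed; they are descriptive visualization aids, not inferential output.

## Categorization

The 18 fine category names are a closed vocabulary; unknown names are
rejected at load time rather than coerced. For error analysis the fine
categories collapse to eight major groups (all seven `food/*` names into
"food in general"; ivory into marble/stone/concrete; rubber into
plastic/synthetic; chalk and wood discarded as too sparse), a projection
(applying it twice equals applying it once). Only "food in general" counts
as food in the food/non-food binarization; a discarded choice can never
match a major-group ground truth and scores as an error. Person RDMs are
computed over *fine* categories, before any regrouping, because regrouping
would mask exactly the disagreements of interest.

## Colorimetry

All conversions run sRGB → linear RGB → XYZ (IEC matrix) → CIELab /
u'v' under D65, with L* on the CIE [0,100] scale. The white point is
defined as the exact row sums of the sRGB matrix so achromatic pixels get
exactly $a^* = b^* = 0$. Decolorization stores the 8-bit gray value
$\mathrm{round}(255\,L^*/100)$ (half-up), replicated to three channels —
the same convention as the common OpenCV Lab pathway. One consequence is
documented honestly below (see *Known limitations*): this L*-scaled gray
is not an sRGB-encoded value, so re-running the conversion on its own
output shifts mid-grays by several levels; the mapping is kept because it
is the stated method, not because it is a fixed point.

Saturation is $s = 13\sqrt{(u'-u'_n)^2 + (v'-v'_n)^2}$ and luminance is
the XYZ $Y$ of the linearized image. The correlation-blending transform
z-normalizes $s$ and $Y$ over the object mask, blends
$z_{out} = (1-w)z(s) + w z(Y)$, re-standardizes, and maps back through the
original mean and SD of $s$ (so those moments are preserved exactly before
the clip at zero). The reconstruction rule is the minimal one consistent
with "only saturation changes": chromaticity moves radially in the u'v'
plane toward or away from the white point, luminance and hue angle are
untouched, and out-of-gamut pixels are pulled back along the same ray by
bisection and flagged per pixel.

# The synthetic world

The generator states one fixed world (the defaults of
`synthetic_config()`); they were chosen once to reproduce the qualitative
structure of two-condition translucency studies and are documented as
calibration choices, not as facts about any data set.

* 300 images, 20 observers per condition, 15 of whom also categorize.
* Each image has a latent translucency score $t_i \sim U(0,1)$ and an
  independent material latent $m_i \sim N(0,1)$.
* Observer $o$'s percept of image $i$ is
  $p = \alpha_c \cdot 3\,(t_i - \tfrac12) + \varepsilon$,
  $\varepsilon \sim N(0, \beta_c)$, judged against a personal criterion
  $c_o \sim N(0, 0.3)$. Color has $\alpha = \beta = 1$; grayscale
  attenuates signal ($\alpha_{gray} = 0.7$) *and* inflates noise
  ($\beta_{gray} = 1.5$) — both mechanisms are needed, because label flips
  require attenuation and extra disagreement requires noise.
* See-throughness, glow and glossiness ratings discretize noisy copies of
  the *same percept* (probit-style, symmetric thresholds
  $\pm1.5, \pm0.75, 0$), which is what makes an observer's ratings
  predictive of their own labels; softness and density discretize
  $\pm m_i$, making them mutually anti-correlated and orthogonal to the
  translucency axis. Grayscale adds a $-0.3$ latent shift to glossiness,
  glow, softness and density, reproducing the downward rating shifts.
* Ground-truth food categories concentrate at translucent images
  ($P(\text{food}) = 0.2 + 0.5\,t_i$). A trial picks the true fine
  category with probability 0.8 (color) or 0.65 (grayscale); errors cross
  the food/non-food boundary with probability 0.3 (color) or 0.55
  (grayscale).
* The Beer–Lambert cube stimulus attenuates a white backlight through a
  pyramid-thickness yellow medium, giving the negative
  saturation–luminance correlation characteristic of backlit translucency.

What a green directional test establishes: that the implemented statistics
detect, in the direction reported for real observers, the structure this
world builds in. What it does not establish: any quantitative agreement
with published values (no raw data are deposited), realism of photographs,
lighting, memory colors, or culture-dependent category knowledge — none of
which the generator models.

# Numerical and design decisions at genuinely open points

* **Exactness cutoff for Mann–Whitney**: enumeration up to 8 per group
  (12870 assignments worst case), normal approximation beyond.
* **Null-manipulation check**: with $\alpha_{gray} = \beta_{gray} = 1$ the
  two conditions are exchangeable, but the *mean absolute* per-image
  percent-agreement difference does not vanish — two independent
  20-observer groups differ by binomial noise alone — so exchangeability
  is tested on the signed mean difference.
* **Image-RDM direction**: added noise drives all Hamming distances toward
  0.5, so the *global* mean RDM entry is not reliably higher in grayscale;
  the within-region (T and O sub-block) dissimilarity is, and that is what
  the directional tests compare — matching how the regional comparisons
  are defined in the first place.
* **Loading geometry**: softness and density load with opposite signs, so
  their loading *centroid* is degenerate; the orthogonality property is
  measured against the softness-minus-density axis.
* **Polychoric near-ties**: two identical ordinal columns have latent
  correlation 1, which sits on the optimizer boundary; it is returned as
  $1 - 10^{-9}$ and the PCA treats it as 1.

# Known limitations

* The L*-scaled grayscale mapping is not idempotent to ±1 8-bit level
  (mid-grays move by up to ~9 levels on re-application). The
  corresponding acceptance check is implemented as stated and left
  failing, with the analysis recorded, rather than silently switching to
  an sRGB-encoded luminance mapping that would pass.
* Polychoric PCA "scores" project standardized numeric ratings on the
  eigenvectors; the latent scores themselves are not identified from
  ordinal data.
* The contrast-preserving decolorization used in some control experiments
  is out of scope; the pipeline accepts externally decolorized images.
* p-values attached to RDM/κ comparisons are descriptive (dependent
  cells), and no multiple-comparison correction is applied across region
  tests.

# Reproducibility

Every stochastic step takes an explicit seed (`synthetic_config(seed=)`,
`predict_binary_from_ratings(seed=)`, `tsne_embed(seed=)`,
`run_config(seed=)`), seeds are recorded in outputs, and `run_all()` is
idempotent for a fixed config. The acceptance criteria are implemented in
`tests/testthat/test-acceptance.R`; `scripts/acceptance.R` re-verifies the
two worked values from the installed package and writes the (empty) target
report.
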