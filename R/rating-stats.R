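#' Rating distribution for one image/attribute/condition
#'
#' Tallies observer ratings over the six Likert bins and converts counts to
#' probabilities. Because the divergence between two empirical rating
#' distributions is undefined whenever a bin is empty in the comparison
#' distribution, probabilities default to add-one (Laplace) smoothing over
#' the 6 bins: `p = (count + 1) / (n + 6)`. Set `smooth = FALSE` for raw
#' relative frequencies.
#'
#' @param ratings integer vector of ratings in 1..6 (one per observer), or a
#'   panel ratings data frame together with `image`, `attribute`.
#' @param image,attribute optional keys used when `ratings` is a data frame.
#' @param smooth apply add-one smoothing (default `TRUE`).
#' @return list of class `rating_distribution` with `counts` (length-6
#'   integer), `probs` (length-6, sums to 1), `n`, `smoothed`.
#' @export
rating_distribution <- function(ratings, image = NULL, attribute = NULL,
                                smooth = TRUE) {
  if (is.data.frame(ratings)) {
    stopifnot(!is.null(image), !is.null(attribute),
              attribute %in% TLC_ATTRIBUTES)
    ratings <- ratings[[attribute]][ratings$image_id == image]
  }
  if (length(ratings) == 0) stop("no ratings for the requested key")
  if (!all(ratings %in% TLC_RATING_LEVELS)) stop("ratings must lie in 1..6")
  counts <- tabulate(ratings, nbins = 6)
  probs <- if (smooth) (counts + 1) / (sum(counts) + 6) else
    counts / sum(counts)
  structure(list(counts = as.integer(counts), probs = probs,
                 n = length(ratings), smoothed = smooth),
            class = "rating_distribution")
}

#' Kullback-Leibler divergence between rating distributions
#'
#' `D_KL(G || C) = sum_x G(x) log(G(x) / C(x))` in natural log units (nats),
#' with `G` the grayscale-condition and `C` the color-condition rating
#' distribution. With the default add-one smoothing all probabilities are
#' strictly positive, so the sum is always finite. Divergence above 1 nat is
#' flagged as indicating a substantial distribution change.
#'
#' @param g,c_ `rating_distribution` objects (or bare probability vectors)
#'   for the grayscale and color conditions.
#' @param threshold flag level in nats (default 1).
#' @return list with `d_kl`, `exceeds_threshold`, `log_base` (`"e"`).
#' @export
kl_divergence <- function(g, c_, threshold = 1) {
  pg <- if (inherits(g, "rating_distribution")) g$probs else g
  pc <- if (inherits(c_, "rating_distribution")) c_$probs else c_
  stopifnot(length(pg) == length(pc))
  if (any(pg <= 0) || any(pc <= 0)) {
    stop("probabilities must be strictly positive; use smoothing")
  }
  stopifnot(abs(sum(pg) - 1) < 1e-9, abs(sum(pc) - 1) < 1e-9)
  d <- sum(pg * log(pg / pc))
  d <- max(d, 0) # guard tiny negative rounding
  list(d_kl = d, exceeds_threshold = d > threshold, log_base = "e")
}

#' KL divergences for every image and attribute of a panel pair
#'
#' @param panel_color,panel_gray [response_panel()] objects with ratings for
#'   the same images.
#' @param threshold flag level in nats.
#' @return data frame with columns `image_id`, `attribute`, `d_kl`,
#'   `exceeds_threshold`.
#' @export
kl_table <- function(panel_color, panel_gray, threshold = 1) {
  imgs <- intersect(unique(panel_color$ratings$image_id),
                    unique(panel_gray$ratings$image_id))
  rows <- lapply(imgs, function(im) {
    rc <- panel_color$ratings[panel_color$ratings$image_id == im, ]
    rg <- panel_gray$ratings[panel_gray$ratings$image_id == im, ]
    data.frame(
      image_id = im, attribute = TLC_ATTRIBUTES,
      d_kl = vapply(TLC_ATTRIBUTES, function(a) {
        kl_divergence(rating_distribution(rg[[a]]),
                      rating_distribution(rc[[a]]),
                      threshold)$d_kl
      }, numeric(1)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$exceeds_threshold <- out$d_kl > threshold
  rownames(out) <- NULL
  out
}

#' Summarize KL divergences per attribute
#'
#' Empirical CDF support and the fraction of images whose divergence exceeds
#' the threshold, per attribute.
#'
#' @param results a [kl_table()] data frame.
#' @param threshold flag level in nats.
#' @return named list per attribute: `ecdf_x` (sorted divergences),
#'   `ecdf_p` (cumulative fractions), `fraction_above`.
#' @export
kl_summary <- function(results, threshold = 1) {
  out <- lapply(split(results$d_kl, results$attribute), function(d) {
    xs <- sort(d)
    list(ecdf_x = xs,
         ecdf_p = seq_along(xs) / length(xs),
         fraction_above = mean(d > threshold))
  })
  out[intersect(TLC_ATTRIBUTES, names(out))]
}

#' Adjusted Fisher-Pearson sample skewness
#'
#' `g1 * sqrt(n (n - 1)) / (n - 2)` with `g1 = m3 / m2^(3/2)`. Constant
#' samples (zero variance) return 0 with a degeneracy flag; samples of size
#' below 3 are degenerate as well.
#'
#' @param x numeric sample.
#' @return list with `skewness` and `degenerate`.
#' @export
sample_skewness <- function(x) {
  if (length(x) == 0) stop("sample must be non-empty")
  n <- length(x)
  m2 <- mean((x - mean(x))^2)
  if (n < 3 || m2 < 1e-24) {
    return(list(skewness = 0, degenerate = TRUE))
  }
  g1 <- mean((x - mean(x))^3) / m2^1.5
  list(skewness = g1 * sqrt(n * (n - 1)) / (n - 2), degenerate = FALSE)
}

#' Skewness shift between conditions
#'
#' `D_s = s_color - s_gray`: the change in the skewness of an image's rating
#' distribution when color is removed. Positive `D_s` means ratings skew
#' higher (pile at the top of the scale less) in grayscale than in color.
#'
#' @param ratings_color,ratings_gray numeric rating samples for one
#'   image/attribute in each condition.
#' @return list with `s_color`, `s_gray`, `d_s`, `degenerate`.
#' @export
skewness_shift <- function(ratings_color, ratings_gray) {
  sc <- sample_skewness(ratings_color)
  sg <- sample_skewness(ratings_gray)
  list(s_color = sc$skewness, s_gray = sg$skewness,
       d_s = sc$skewness - sg$skewness,
       degenerate = sc$degenerate || sg$degenerate)
}

#' Skewness shifts for every image and attribute of a panel pair
#'
#' @inheritParams kl_table
#' @return data frame with columns `image_id`, `attribute`, `s_color`,
#'   `s_gray`, `d_s`.
#' @export
skewness_table <- function(panel_color, panel_gray) {
  imgs <- intersect(unique(panel_color$ratings$image_id),
                    unique(panel_gray$ratings$image_id))
  rows <- lapply(imgs, function(im) {
    rc <- panel_color$ratings[panel_color$ratings$image_id == im, ]
    rg <- panel_gray$ratings[panel_gray$ratings$image_id == im, ]
    res <- lapply(TLC_ATTRIBUTES, function(a) skewness_shift(rc[[a]], rg[[a]]))
    data.frame(image_id = im, attribute = TLC_ATTRIBUTES,
               s_color = vapply(res, `[[`, numeric(1), "s_color"),
               s_gray = vapply(res, `[[`, numeric(1), "s_gray"),
               d_s = vapply(res, `[[`, numeric(1), "d_s"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Kendall correlation between mean ratings and opacity votes
#'
#' Kendall tau-b (tie-corrected) rank correlation between per-image mean
#' attribute ratings and the number of observers voting the image opaque,
#' with a two-sided p-value. A negative tau means the attribute decreases as
#' images are more uniformly judged opaque.
#'
#' @param mean_rating numeric vector of per-image mean ratings.
#' @param opaque_votes integer vector of per-image opaque-vote counts,
#'   aligned with `mean_rating`.
#' @param alpha significance level (default 0.05).
#' @return list with `tau`, `p_value`, `significant`, `degenerate` (constant
#'   input on either side).
#' @export
tau_vs_opacity <- function(mean_rating, opaque_votes, alpha = 0.05) {
  stopifnot(length(mean_rating) == length(opaque_votes))
  if (length(mean_rating) < 3) stop("need at least 3 images")
  if (sd(mean_rating) == 0 || sd(opaque_votes) == 0) {
    return(list(tau = NA_real_, p_value = NA_real_, significant = FALSE,
                degenerate = TRUE))
  }
  ct <- suppressWarnings(
    cor.test(mean_rating, opaque_votes, method = "kendall",
             alternative = "two.sided", exact = FALSE))
  list(tau = unname(ct$estimate), p_value = ct$p.value,
       significant = ct$p.value < alpha, degenerate = FALSE)
}

#' Kendall correlation matrix between attributes
#'
#' Pairwise Kendall tau-b between the five mean-rating columns, with
#' significance at a Bonferroni-adjusted alpha: 5 attributes give 10 pairs,
#' so the default family-wise 0.05 becomes 0.005 per pair.
#'
#' @param ratings_table data frame or matrix of per-image mean ratings with
#'   the five attribute columns.
#' @param alpha per-pair adjusted significance level (default
#'   `bonferroni_alpha()`).
#' @return list with `tau` (symmetric 5x5 matrix, unit diagonal), `p_value`
#'   matrix, `significant` logical matrix, and `alpha`.
#' @export
attribute_correlation_matrix <- function(ratings_table,
                                         alpha = bonferroni_alpha()) {
  m <- as.matrix(as.data.frame(ratings_table)[, TLC_ATTRIBUTES])
  if (nrow(m) < 3) stop("need at least 3 images")
  k <- ncol(m)
  tau <- diag(1, k)
  pv <- matrix(NA_real_, k, k)
  dimnames(tau) <- dimnames(pv) <- list(TLC_ATTRIBUTES, TLC_ATTRIBUTES)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (sd(m[, i]) == 0 || sd(m[, j]) == 0) next
      ct <- suppressWarnings(
        cor.test(m[, i], m[, j], method = "kendall", exact = FALSE))
      tau[i, j] <- tau[j, i] <- unname(ct$estimate)
      pv[i, j] <- pv[j, i] <- ct$p.value
    }
  }
  list(tau = tau, p_value = pv,
       significant = !is.na(pv) & pv < alpha, alpha = alpha)
}

#' Bonferroni-adjusted alpha for attribute pairs
#'
#' @param family_alpha family-wise level (default 0.05).
#' @param n_attributes number of attributes (default 5, giving
#'   `choose(5, 2) = 10` pairs and an adjusted level of 0.005).
#' @return the per-comparison alpha.
#' @export
bonferroni_alpha <- function(family_alpha = 0.05, n_attributes = 5) {
  family_alpha / choose(n_attributes, 2)
}
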