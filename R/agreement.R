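#' Percent agreement of binary classification
#'
#' The majority fraction `max(N_o, N_t) / N` of observers giving the modal
#' binary label for each image. Always in \[0.5, 1\]; 1 iff unanimous.
#'
#' @param votes data frame with columns `n_translucent`, `n_opaque`,
#'   `n_total` (see [vote_counts()]).
#' @return numeric vector of per-image percent agreement.
#' @export
percent_agreement <- function(votes) {
  stopifnot(all(c("n_translucent", "n_opaque", "n_total") %in% names(votes)))
  if (any(votes$n_total <= 0)) stop("n_total must be positive")
  if (any(votes$n_translucent + votes$n_opaque != votes$n_total)) {
    stop("n_translucent + n_opaque must equal n_total")
  }
  pmax(votes$n_opaque, votes$n_translucent) / votes$n_total
}

#' Assign translucent/opaque/unsure labels
#'
#' An image is labeled `T` if at least `threshold` of observers classify it
#' as translucent, `O` if at least `threshold` classify it as opaque, and
#' `U` otherwise. The comparison is `n/N >= threshold`, so with the default
#' 0.6 threshold 12 of 20 votes qualifies.
#'
#' @inheritParams percent_agreement
#' @param threshold vote fraction needed for a definite label; must exceed
#'   0.5 so the two definite labels cannot both fire.
#' @return data frame with columns `image_id` (if present in `votes`) and
#'   `label` (factor with levels `T`, `U`, `O`).
#' @export
assign_label <- function(votes, threshold = 0.6) {
  if (length(threshold) != 1 || threshold <= 0.5 || threshold > 1) {
    stop("threshold must lie in (0.5, 1]")
  }
  if (any(votes$n_total <= 0)) stop("n_total must be positive")
  ft <- votes$n_translucent / votes$n_total
  fo <- votes$n_opaque / votes$n_total
  lab <- ifelse(ft >= threshold, "T", ifelse(fo >= threshold, "O", "U"))
  out <- data.frame(label = factor(lab, levels = c("T", "U", "O")))
  if ("image_id" %in% names(votes)) {
    out <- cbind(data.frame(image_id = votes$image_id,
                            stringsAsFactors = FALSE), out)
  }
  out
}

FLIP_TYPES <- c("T->O", "O->T", "T->U", "U->T", "O->U", "U->O", "none")

#' Label flips between conditions
#'
#' Crosses per-image labels from the color and grayscale conditions and
#' classifies each image's label transition.
#'
#' @param labels_color,labels_gray [assign_label()] outputs (must include
#'   `image_id`) over the same image set.
#' @return list with `records` (data frame `image_id`, `label_color`,
#'   `label_gray`, `flip_type`), `counts` (named integer vector over the six
#'   flip types), and `n_flipped`.
#' @export
flip_table <- function(labels_color, labels_gray) {
  if (!setequal(labels_color$image_id, labels_gray$image_id)) {
    stop("label sets cover different images")
  }
  g <- labels_gray[match(labels_color$image_id, labels_gray$image_id), ]
  lc <- as.character(labels_color$label)
  lg <- as.character(g$label)
  ft <- ifelse(lc == lg, "none", paste0(lc, "->", lg))
  records <- data.frame(image_id = labels_color$image_id,
                        label_color = lc, label_gray = lg,
                        flip_type = factor(ft, levels = FLIP_TYPES),
                        stringsAsFactors = FALSE)
  counts <- table(records$flip_type)[setdiff(FLIP_TYPES, "none")]
  list(records = records,
       counts = setNames(as.integer(counts), names(counts)),
       n_flipped = sum(records$flip_type != "none"))
}

new_rdm <- function(values, axis) {
  stopifnot(isSymmetric(unname(values)), all(diag(values) == 0),
            all(values >= 0 & values <= 1))
  structure(list(axis = axis, ids = rownames(values), values = values),
            class = "rdm")
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("<rdm> %d x %d over %ss; mean off-diagonal %.3f\n",
              nrow(x$values), ncol(x$values), x$axis,
              mean(x$values[upper.tri(x$values)])))
  invisible(x)
}

#' Mean of the off-diagonal upper triangle of an RDM
#' @param rdm an `rdm` object.
#' @return scalar mean dissimilarity.
#' @export
rdm_mean <- function(rdm) mean(rdm$values[upper.tri(rdm$values)])

#' Normalized-Hamming representational dissimilarity matrix
#'
#' For `axis = "image"`, entry (i, j) is the number of observers whose
#' binary labels differ between images i and j, divided by the number of
#' observers; for `axis = "observer"` the response matrix is transposed
#' first, giving pairwise observer dissimilarity over images.
#'
#' @param binary 0/1 matrix, rows = images, columns = observers (e.g.
#'   `panel$binary`).
#' @param axis `"image"` or `"observer"`.
#' @return an `rdm` object: list with `axis`, `ids`, and the symmetric
#'   `values` matrix with zero diagonal, entries in \[0, 1\].
#' @export
hamming_rdm <- function(binary, axis = c("image", "observer")) {
  axis <- match.arg(axis)
  stopifnot(is.matrix(binary), all(binary %in% c(0, 1)))
  x <- if (axis == "image") binary else t(binary)
  if (ncol(x) == 0) stop("vectors must have positive length")
  # pairwise disagreements via cross products of the 0/1 matrix
  ones <- x %*% t(x)
  zeros <- (1 - x) %*% t(1 - x)
  d <- (ncol(x) - ones - zeros) / ncol(x)
  diag(d) <- 0
  dimnames(d) <- list(rownames(x), rownames(x))
  new_rdm(d, axis)
}

KAPPA_LEVELS <- c("none", "minimal", "weak", "moderate", "strong")

#' Agreement level of a kappa value
#'
#' Half-open contiguous bins: \[0, 0.20) none, \[0.20, 0.40) minimal,
#' \[0.40, 0.60) weak, \[0.60, 0.80) moderate, \[0.80, 1\] strong. Negative
#' kappa (below-chance agreement) is reported as "none".
#'
#' @param kappa numeric vector of kappa values.
#' @return factor with levels none/minimal/weak/moderate/strong.
#' @export
kappa_level <- function(kappa) {
  cut(pmax(kappa, 0), breaks = c(-Inf, 0.2, 0.4, 0.6, 0.8, Inf),
      labels = KAPPA_LEVELS, right = FALSE)
}

#' Cohen's kappa between two raters
#'
#' Chance-corrected agreement `(P_a - P_e) / (1 - P_e)` on binary responses,
#' with `P_a` the observed agreement rate and `P_e` the chance agreement from
#' the two raters' marginal label frequencies. Degenerate cases (both raters
#' constant, so `P_e = 1`): kappa is 1 if the constant labels agree, 0
#' otherwise, with `degenerate = TRUE`.
#'
#' @param a,b equal-length 0/1 vectors of the two raters' responses.
#' @return list with `kappa`, `p_observed`, `p_chance`, `level`, and
#'   `degenerate`.
#' @export
cohen_kappa <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2,
            all(a %in% c(0, 1)), all(b %in% c(0, 1)))
  pa <- mean(a == b)
  ma <- mean(a)
  mb <- mean(b)
  pe <- ma * mb + (1 - ma) * (1 - mb)
  if (sd(a) == 0 && sd(b) == 0) {
    # both raters constant: chance-corrected agreement is not identified
    k <- if (pa >= 1 - 1e-12) 1 else 0
    degenerate <- TRUE
  } else {
    k <- (pa - pe) / (1 - pe)
    degenerate <- FALSE
  }
  list(kappa = k, p_observed = pa, p_chance = pe,
       level = kappa_level(k), degenerate = degenerate)
}

#' Pairwise kappa matrix of a panel
#'
#' Cohen's kappa between every pair of observers on the binary task, plus a
#' summary of the fraction of observer pairs falling in each agreement level.
#'
#' @param panel a [response_panel()], or a 0/1 matrix images x observers.
#' @return list with `values` (symmetric observer matrix, unit diagonal),
#'   `level_fractions` (named, sums to 1 over upper-triangle pairs),
#'   `mean_kappa` (mean over upper-triangle pairs), and `degenerate_pairs`.
#' @export
kappa_matrix <- function(panel) {
  binary <- if (inherits(panel, "response_panel")) panel$binary else panel
  n <- ncol(binary)
  if (n < 2) stop("need at least 2 observers")
  obs <- colnames(binary)
  k <- matrix(1, n, n, dimnames = list(obs, obs))
  degenerate <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      res <- cohen_kappa(binary[, i], binary[, j])
      k[i, j] <- k[j, i] <- res$kappa
      if (res$degenerate) {
        degenerate <- c(degenerate, paste(obs[i], obs[j], sep = ":"))
      }
    }
  }
  up <- k[upper.tri(k)]
  fr <- table(kappa_level(up)) / length(up)
  list(values = k,
       level_fractions = setNames(as.numeric(fr), names(fr)),
       mean_kappa = mean(up),
       degenerate_pairs = degenerate)
}

#' One-sided Mann-Whitney U test
#'
#' Rank-sum comparison of two samples. With both groups of size at most 8
#' the p-value is exact by complete enumeration of group assignments (valid
#' under ties); larger samples use the normal approximation with tie
#' correction and continuity correction. Used descriptively for RDM-region
#' and kappa comparisons, where matrix cells are not independent.
#'
#' @param x,y numeric samples.
#' @param alternative `"less"` (x stochastically smaller than y),
#'   `"greater"`, or `"two.sided"`.
#' @param exact_max largest per-group size for which the exact enumeration is
#'   used.
#' @return list with `U` (the U statistic for `x`), `p_value`, `method`, and
#'   `all_tied` flag (all values identical across both samples, p = 1).
#' @export
mwu_test <- function(x, y, alternative = c("less", "greater", "two.sided"),
                     exact_max = 8) {
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1) {
    return(list(U = n1 * n2 / 2, p_value = 1, method = "degenerate",
                all_tied = TRUE))
  }
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - length(idx) * (length(idx) + 1) / 2
  U <- u_of(seq_len(n1))
  if (n1 <= exact_max && n2 <= exact_max) {
    sets <- combn(n1 + n2, n1)
    us <- apply(sets, 2, u_of)
    p <- switch(alternative,
      less = mean(us <= U + 1e-9),
      greater = mean(us >= U - 1e-9),
      two.sided = min(1, 2 * min(mean(us <= U + 1e-9),
                                 mean(us >= U - 1e-9))))
    method <- "exact enumeration"
  } else {
    n <- n1 + n2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(n1 * n2 / 12 * (n + 1 - tie_term))
    mu <- n1 * n2 / 2
    p <- switch(alternative,
      less = pnorm(U - mu + 0.5, sd = sigma),
      greater = pnorm(U - mu - 0.5, sd = sigma, lower.tail = FALSE),
      two.sided = {
        z <- U - mu
        corr <- sign(z) * 0.5
        min(1, 2 * pnorm(abs(z) - corr, sd = sigma, lower.tail = FALSE))
      })
    method <- "normal approximation with tie correction"
  }
  list(U = U, p_value = p, method = method, all_tied = FALSE)
}

#' Compare RDM regions between conditions
#'
#' Extracts the upper-triangle, off-diagonal cells of a labeled sub-block of
#' two RDMs and compares them with a one-sided Mann-Whitney test (is the
#' first condition's dissimilarity lower than the second's?). p-values are
#' descriptive: cells of an RDM are not independent.
#'
#' @param rdm_a,rdm_b `rdm` objects on the same axis.
#' @param ids_a,ids_b identifiers delimiting the sub-block in each RDM
#'   (default: all shared ids).
#' @return the [mwu_test()] result (alternative `"less"`).
#' @export
compare_rdm_regions <- function(rdm_a, rdm_b, ids_a = NULL, ids_b = NULL) {
  pick <- function(rdm, ids) {
    if (is.null(ids)) ids <- rdm$ids
    v <- rdm$values[ids, ids, drop = FALSE]
    v[upper.tri(v)]
  }
  mwu_test(pick(rdm_a, ids_a), pick(rdm_b, ids_b), alternative = "less")
}
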