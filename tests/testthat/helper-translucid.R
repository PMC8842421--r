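# Shared fixtures and independent oracles. Oracles are deliberately naive
# (double loops, term-by-term sums) so they stay independent of the
# vectorized implementation paths they check.

make_binary <- function(mat, images = NULL, observers = NULL) {
  if (is.null(images)) images <- sprintf("img%02d", seq_len(nrow(mat)))
  if (is.null(observers)) observers <- sprintf("obs%02d", seq_len(ncol(mat)))
  dimnames(mat) <- list(images, observers)
  mat
}

# brute-force normalized Hamming distance matrix over rows
oracle_hamming_rows <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) {
        diffs <- 0
        for (k in seq_len(ncol(m))) if (m[i, k] != m[j, k]) diffs <- diffs + 1
        d[i, j] <- diffs / ncol(m)
      }
    }
  }
  d
}

# Cohen's kappa from the 2x2 contingency table, non-degenerate case
oracle_kappa <- function(a, b) {
  n <- length(a)
  p11 <- sum(a == 1 & b == 1) / n
  p00 <- sum(a == 0 & b == 0) / n
  pa <- p11 + p00
  pe <- mean(a) * mean(b) + (1 - mean(a)) * (1 - mean(b))
  (pa - pe) / (1 - pe)
}

# term-by-term KL sum
oracle_kl <- function(p, q) {
  acc <- 0
  for (i in seq_along(p)) acc <- acc + p[i] * log(p[i] / q[i])
  acc
}

# direct-moment adjusted Fisher-Pearson skewness
oracle_skewness <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- sum((x - m)^2) / n
  m3 <- sum((x - m)^3) / n
  (m3 / m2^1.5) * sqrt(n * (n - 1)) / (n - 2)
}

# brute-force person RDM over fine categories
oracle_person_rdm <- function(records) {
  obs <- sort(unique(records$observer_id))
  imgs <- sort(unique(records$image_id))
  d <- matrix(0, length(obs), length(obs), dimnames = list(obs, obs))
  for (i in seq_along(obs)) {
    for (j in seq_along(obs)) {
      if (i != j) {
        diffs <- 0
        for (im in imgs) {
          ci <- records$category[records$observer_id == obs[i] &
                                   records$image_id == im]
          cj <- records$category[records$observer_id == obs[j] &
                                   records$image_id == im]
          if (ci != cj) diffs <- diffs + 1
        }
        d[i, j] <- diffs / length(imgs)
      }
    }
  }
  d
}

# small fast config for non-acceptance tests
small_config <- function(seed = 1, ...) {
  synthetic_config(n_images = 60, n_observers_binary = 8,
                   n_observers_category = 6, seed = seed, ...)
}

# deterministic toy panel: 4 images x 3 observers with ratings
tiny_panel <- function(condition = "color") {
  bin <- make_binary(matrix(c(1, 1, 1,
                              1, 1, 0,
                              0, 0, 1,
                              0, 0, 0), 4, 3, byrow = TRUE))
  ratings <- expand.grid(observer_id = colnames(bin),
                         image_id = rownames(bin),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  set.seed(42)
  for (a in tlc_attributes()) {
    ratings[[a]] <- sample(1:6, nrow(ratings), replace = TRUE)
  }
  cats <- data.frame(observer_id = rep(colnames(bin), each = 4),
                     image_id = rep(rownames(bin), 3),
                     category = rep(c("glass", "wax", "metal",
                                      "food/cheese"), 3),
                     stringsAsFactors = FALSE)
  gt <- setNames(c("glass", "wax", "metal", "food/cheese"), rownames(bin))
  response_panel(condition, bin, ratings, cats, gt)
}

# random sRGB test image
random_image <- function(h = 8, w = 8, seed = 1) {
  set.seed(seed)
  array(runif(h * w * 3), dim = c(h, w, 3))
}
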