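test_that("pca_mean_ratings handles rank-1 tables and sign conventions", {
  tab <- data.frame(see_throughness = seq(1, 6, length.out = 10),
                    glossiness = 3, softness = 3, glow = 3, density = 3)
  p <- pca_mean_ratings(tab, standardize = FALSE)
  expect_equal(p$explained_variance_ratio[1], 1)
  expect_equal(sum(p$explained_variance_ratio), 1)
  # largest-magnitude loading is positive on every component
  for (j in seq_len(ncol(p$loadings))) {
    expect_gte(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  }
  expect_error(pca_mean_ratings(tab, standardize = TRUE), "zero-variance")
})

test_that("anti-correlated attributes load oppositely on PC1 (eigen oracle)", {
  set.seed(2)
  soft <- runif(50, 1, 6)
  tab <- data.frame(see_throughness = 3, glossiness = 3,
                    softness = soft, glow = 3, density = 7 - soft)
  p <- pca_mean_ratings(tab, standardize = FALSE)
  l1 <- p$loadings[, 1]
  expect_equal(unname(abs(l1["softness"])), unname(abs(l1["density"])),
               tolerance = 1e-8)
  expect_lt(l1["softness"] * l1["density"], 0)
  # independent eigendecomposition of the 5x5 covariance as oracle
  ev <- eigen(cov(as.matrix(tab)))
  expect_equal(p$explained_variance_ratio,
               ev$values / sum(ev$values), tolerance = 1e-8)
})

test_that("standardized PCA is invariant to per-attribute affine rescaling", {
  set.seed(3)
  tab <- as.data.frame(matrix(runif(40 * 5, 1, 6), 40, 5))
  names(tab) <- tlc_attributes()
  p1 <- pca_mean_ratings(tab)
  tab2 <- tab
  tab2$glow <- 10 * tab$glow - 4
  tab2$density <- 0.2 * tab$density + 1
  p2 <- pca_mean_ratings(tab2)
  expect_equal(p1$loadings, p2$loadings, tolerance = 1e-8)
  expect_equal(p1$explained_variance_ratio, p2$explained_variance_ratio,
               tolerance = 1e-8)
})

test_that("bivariate normal CDF matches the mvtnorm oracle", {
  skip_if_not_installed("mvtnorm")
  set.seed(8)
  for (rep in 1:40) {
    h <- rnorm(1)
    k <- rnorm(1)
    r <- runif(1, -0.98, 0.98)
    oracle <- mvtnorm::pmvnorm(upper = c(h, k),
                               corr = matrix(c(1, r, r, 1), 2))[1]
    expect_equal(pbvnorm(h, k, r), oracle, tolerance = 1e-8)
  }
  expect_equal(pbvnorm(Inf, 0.3, 0.5), pnorm(0.3))
  expect_equal(pbvnorm(-Inf, 0.3, 0.5), 0)
})

test_that("polychoric correlation recovers the generating rho", {
  discretize <- function(z) {
    cuts <- c(-1.5, -0.75, 0, 0.75, 1.5)
    1L + rowSums(outer(z, cuts, `>`))
  }
  set.seed(12)
  z1 <- rnorm(500)
  z2 <- 0.8 * z1 + sqrt(1 - 0.64) * rnorm(500)
  est <- polychoric_corr(discretize(z1), discretize(z2))
  expect_lt(abs(est - 0.8), 0.1)
  # identical ordinal columns -> rho = 1 and PC1 carries both
  x <- discretize(z1)
  pm <- polychoric_matrix(cbind(a = x, b = x, c = discretize(rnorm(500))))
  expect_equal(pm$rho["a", "b"], 1, tolerance = 1e-6)
  pp <- polychoric_pca(cbind(see_throughness = x, glossiness = x,
                             softness = discretize(rnorm(500)),
                             glow = discretize(rnorm(500)),
                             density = discretize(rnorm(500))))
  expect_gt(abs(pp$loadings["see_throughness", 1] *
                  pp$loadings["glossiness", 1]), 0.2)
  # independence: |rho| < 0.15 in >= 95% of replicates
  set.seed(13)
  est0 <- replicate(40, {
    abs(polychoric_corr(discretize(rnorm(500)), discretize(rnorm(500))))
  })
  expect_gte(mean(est0 < 0.15), 0.95)
})

test_that("polychoric_matrix excludes single-level columns and repairs PSD", {
  set.seed(30)
  x <- sample(1:6, 100, replace = TRUE)
  expect_warning(
    pm <- polychoric_matrix(cbind(a = x, b = rep(3L, 100),
                                  c = sample(1:6, 100, TRUE))),
    "single-level")
  expect_equal(colnames(pm$rho), c("a", "c"))
  expect_error(polychoric_matrix(cbind(a = 1:2, b = 2:1)), "at least 3")
})

test_that("logistic prediction is perfect on a separable rule and chance on noise", {
  set.seed(17)
  X <- matrix(sample(1:6, 300 * 5, replace = TRUE), 300, 5,
              dimnames = list(NULL, tlc_attributes()))
  y <- as.integer(X[, "see_throughness"] >= 4)
  r <- predict_binary_from_ratings(X, y, seed = 2)
  expect_equal(r$mean_accuracy, 1.0)
  expect_true(all(vapply(seq_len(3), function(f)
    "see_throughness" %in% r$significant_attributes[[f]] ||
      !r$wald_reliable[f], logical(1))))
  expect_true(all(r$fold_accuracies >= 0 & r$fold_accuracies <= 1))
  # folds partition the images and are stratified
  expect_equal(sort(unique(r$folds)), 1:3)
  expect_equal(length(r$folds), 300)
  for (f in 1:3) expect_gt(length(unique(y[r$folds == f])), 1)
  # permuted labels: chance-level accuracy (Monte Carlo)
  accs <- replicate(50, {
    yp <- sample(y)
    predict_binary_from_ratings(X, yp, seed = 3)$mean_accuracy
  })
  expect_lt(abs(mean(accs) - 0.5), 0.1)
  # single-class observer is skipped with a flag
  expect_true(predict_binary_from_ratings(X, rep(1L, 300))$skipped)
  expect_error(predict_binary_from_ratings(X[1:10, ], y[1:10]), "at least 30")
})

test_that("significant-attribute counts report per-fold medians and ranges", {
  fake <- function(sig) {
    structure(list(skipped = FALSE,
                   significant_attributes = sig),
              class = "prediction_result")
  }
  res <- list(fake(list("see_throughness", "see_throughness",
                        "see_throughness")),
              fake(list("see_throughness", character(0),
                        "see_throughness")))
  sc <- significant_attribute_counts(res)
  st <- sc[sc$attribute == "see_throughness", ]
  expect_equal(st$median_count, 2)
  expect_equal(st$fold_range, 1)
  expect_equal(sc$median_count[sc$attribute == "density"], 0)
  # median invariant to fold reordering
  res2 <- lapply(res, function(r) {
    r$significant_attributes <- rev(r$significant_attributes)
    r
  })
  expect_equal(significant_attribute_counts(res2)$median_count,
               sc$median_count)
})

test_that("t-SNE embeddings are seeded, separate clusters, and keep duplicates close", {
  set.seed(18)
  cl1 <- matrix(rnorm(60 * 5, 2, 0.3), 60, 5)
  cl2 <- matrix(rnorm(60 * 5, 5, 0.3), 60, 5)
  feats <- rbind(cl1, cl2)
  colnames(feats) <- tlc_attributes()
  e1 <- tsne_embed(feats, seed = 4)
  e2 <- tsne_embed(feats, seed = 4)
  expect_identical(e1$coordinates, e2$coordinates)
  # silhouette of the true clusters in the embedding
  lab <- rep(1:2, each = 60)
  d <- as.matrix(dist(e1$coordinates))
  sil <- vapply(seq_len(nrow(d)), function(i) {
    a <- mean(d[i, lab == lab[i]][-which(which(lab == lab[i]) == i)])
    b <- mean(d[i, lab != lab[i]])
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)
  # duplicated rows land nearly coincident relative to cluster spread
  featd <- rbind(feats, feats[1, , drop = FALSE])
  e3 <- tsne_embed(featd, seed = 5)
  dup_dist <- sqrt(sum((e3$coordinates[1, ] - e3$coordinates[121, ])^2))
  spread <- mean(dist(e3$coordinates[lab == 1, ]))
  expect_lt(dup_dist, spread)
  expect_error(tsne_embed(feats[1:20, ]), "perplexity")
})

test_that("transmission and softness/density loadings stay well separated", {
  # angle between the two loading-group centroids in PC1-2 exceeds 60
  # degrees for most seeds (scaled-down directional property)
  angles <- vapply(1:10, function(s) {
    pair <- generate_panel(small_config(seed = 100 + s))
    p <- pca_mean_ratings(mean_ratings(pair$color))
    l <- p$loadings[, 1:2]
    g1 <- colMeans(l[c("see_throughness", "glow", "glossiness"), ])
    # softness and density load with opposite signs, so their centroid is
    # degenerate; the spanned direction is their difference axis
    g2 <- l["softness", ] - l["density", ]
    acos(abs(sum(g1 * g2)) /
           (sqrt(sum(g1^2)) * sqrt(sum(g2^2)))) * 180 / pi
  }, numeric(1))
  expect_gte(mean(angles > 60), 0.9)
})
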