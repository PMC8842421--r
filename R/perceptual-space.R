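# Deterministic loading signs: flip each component so its largest-magnitude
# loading is positive. Scores (if given) are flipped to match.
fix_loading_signs <- function(loadings, scores = NULL) {
  for (j in seq_len(ncol(loadings))) {
    peak <- which.max(abs(loadings[, j]))
    if (loadings[peak, j] < 0) {
      loadings[, j] <- -loadings[, j]
      if (!is.null(scores)) scores[, j] <- -scores[, j]
    }
  }
  list(loadings = loadings, scores = scores)
}

#' PCA of per-image mean attribute ratings
#'
#' Principal component analysis of the image-by-attribute mean-rating table.
#' Attributes share the 1-6 scale but are standardized by default so loadings
#' are comparable; components are sign-fixed so the largest-magnitude loading
#' on each is positive.
#'
#' @param ratings_table data frame or matrix with the five attribute columns
#'   (rows = images).
#' @param standardize scale each attribute to unit variance (default `TRUE`).
#' @return list of class `tlc_pca` with `loadings` (attribute x component),
#'   `scores` (image x component), `explained_variance_ratio` (sums to 1),
#'   `sdev`, `standardized`.
#' @export
pca_mean_ratings <- function(ratings_table, standardize = TRUE) {
  df <- as.data.frame(ratings_table)
  m <- as.matrix(df[, intersect(TLC_ATTRIBUTES, names(df)), drop = FALSE])
  if (ncol(m) == 0) m <- as.matrix(df)
  if (nrow(m) < 5) stop("need at least 5 images")
  if (anyNA(m)) stop("missing cells in rating table")
  if (standardize) {
    zero_var <- colnames(m)[apply(m, 2, sd) == 0]
    if (length(zero_var) > 0) {
      stop("zero-variance attribute(s) cannot be standardized: ",
           paste(zero_var, collapse = ", "))
    }
  }
  p <- prcomp(m, center = TRUE, scale. = standardize)
  fixed <- fix_loading_signs(p$rotation, p$x)
  structure(
    list(loadings = fixed$loadings, scores = fixed$scores,
         explained_variance_ratio = p$sdev^2 / sum(p$sdev^2),
         sdev = p$sdev, standardized = standardize),
    class = "tlc_pca")
}

#' Polychoric PCA of one observer's ordinal ratings
#'
#' Eigendecomposition of the 5x5 polychoric correlation matrix of an
#' observer's raw ordinal ratings (see [polychoric_matrix()]); appropriate
#' for Likert data where Pearson correlations of raw scores understate the
#' latent association. Scores are the standardized numeric ratings projected
#' on the eigenvectors (a pragmatic surrogate; the latent scores themselves
#' are not identified).
#'
#' @param ratings integer matrix/data frame, images x attributes, values 1-6.
#' @return list of class `tlc_pca` with `loadings`, `scores`,
#'   `explained_variance_ratio`, plus `rho` and `psd_repaired`.
#' @export
polychoric_pca <- function(ratings) {
  pm <- polychoric_matrix(ratings)
  ev <- eigen(pm$rho, symmetric = TRUE)
  loadings <- ev$vectors
  dimnames(loadings) <- list(colnames(pm$rho),
                             paste0("PC", seq_len(ncol(loadings))))
  m <- as.matrix(as.data.frame(ratings))[, colnames(pm$rho), drop = FALSE]
  z <- scale(m)
  z[, apply(m, 2, sd) == 0] <- 0
  scores <- z %*% loadings
  fixed <- fix_loading_signs(loadings, scores)
  structure(
    list(loadings = fixed$loadings, scores = fixed$scores,
         explained_variance_ratio = pmax(ev$values, 0) /
           sum(pmax(ev$values, 0)),
         sdev = sqrt(pmax(ev$values, 0)),
         rho = pm$rho, psd_repaired = pm$psd_repaired,
         excluded = pm$excluded),
    class = "tlc_pca")
}

#' @export
print.tlc_pca <- function(x, ...) {
  cat("<tlc_pca> explained variance ratio:",
      paste(sprintf("%.3f", x$explained_variance_ratio), collapse = " "),
      "\n")
  invisible(x)
}

# Stratified fold assignment: within each class, observations are permuted
# and dealt to folds round-robin, so every fold contains both classes.
stratified_folds <- function(labels, k = 3, seed = 1) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Ridge-penalized logistic regression by Newton iteration; penalty excludes
# the intercept. Used only as the separation fallback.
ridge_logistic <- function(X, y, lambda = 1e-2, maxit = 50) {
  X1 <- cbind(1, X)
  beta <- numeric(ncol(X1))
  pen <- diag(c(0, rep(lambda, ncol(X))))
  for (it in seq_len(maxit)) {
    eta <- drop(X1 %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- t(X1) %*% (X1 * w) + 2 * pen
    g <- t(X1) %*% (y - mu) - 2 * pen %*% beta
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < 1e-8) break
  }
  drop(beta)
}

#' Predict an observer's binary classification from their ratings
#'
#' Fits an unpenalized logistic regression of the observer's own binary
#' translucent/opaque labels on their five attribute ratings with stratified
#' 3-fold cross-validation. For each fold the model is fit on the training
#' split, held-out accuracy is recorded, and the attributes whose Wald test
#' is significant at `alpha` in the training fit are collected. If the
#' training fit shows (quasi-)separation the fold falls back to a small
#' ridge penalty and its Wald tests are marked unreliable.
#'
#' @param ratings numeric matrix, images x 5 attributes, one observer.
#' @param labels 0/1 vector of the same observer's binary classifications.
#' @param k number of folds (default 3).
#' @param seed fold-assignment seed.
#' @param alpha Wald significance level (default 0.05).
#' @return list of class `prediction_result`: `fold_accuracies`,
#'   `mean_accuracy`, `significant_attributes` (list of character vectors,
#'   one per fold), `coefficients` (per fold), `wald_reliable` (per fold),
#'   `skipped` (TRUE when the observer used a single class), `folds`.
#' @export
predict_binary_from_ratings <- function(ratings, labels, k = 3, seed = 1,
                                        alpha = 0.05) {
  X <- as.matrix(as.data.frame(ratings)[, TLC_ATTRIBUTES])
  y <- as.integer(labels)
  stopifnot(nrow(X) == length(y))
  if (nrow(X) < 30) stop("need ratings and labels for at least 30 images")
  if (length(unique(y)) < 2) {
    return(structure(list(skipped = TRUE,
                          reason = "observer used a single class"),
                     class = "prediction_result"))
  }
  fold <- stratified_folds(y, k = k, seed = seed)
  acc <- numeric(k)
  sig <- vector("list", k)
  coefs <- vector("list", k)
  reliable <- logical(k)
  for (f in seq_len(k)) {
    tr <- fold != f
    dtr <- data.frame(y = y[tr], X[tr, , drop = FALSE])
    separated <- FALSE
    fit <- withCallingHandlers(
      glm(y ~ ., data = dtr, family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1|algorithm did not converge",
                  conditionMessage(w))) {
          separated <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    if (!separated && max(abs(coef(fit)[-1]), na.rm = TRUE) > 20) {
      separated <- TRUE
    }
    if (separated) {
      beta <- ridge_logistic(scale_cols(X[tr, , drop = FALSE]), y[tr])
      # map back to raw-scale coefficients for prediction
      ctr <- attr(scale_cols(X[tr, , drop = FALSE]), "center")
      scl <- attr(scale_cols(X[tr, , drop = FALSE]), "scale")
      b_raw <- beta[-1] / scl
      b0 <- beta[1] - sum(ctr * b_raw)
      eta <- b0 + X[!tr, , drop = FALSE] %*% b_raw
      coefs[[f]] <- c(`(Intercept)` = b0, setNames(b_raw, colnames(X)))
      sig[[f]] <- character(0)
      reliable[f] <- FALSE
    } else {
      eta <- predict(fit, newdata = data.frame(X[!tr, , drop = FALSE]))
      sm <- summary(fit)$coefficients
      pv <- sm[-1, "Pr(>|z|)"]
      sig[[f]] <- names(pv)[pv < alpha]
      coefs[[f]] <- coef(fit)
      reliable[f] <- TRUE
    }
    acc[f] <- mean((eta > 0) == (y[!tr] == 1))
  }
  structure(
    list(skipped = FALSE, fold_accuracies = acc, mean_accuracy = mean(acc),
         significant_attributes = sig, coefficients = coefs,
         wald_reliable = reliable, folds = fold, alpha = alpha, seed = seed),
    class = "prediction_result")
}

scale_cols <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0] <- 1
  out <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}

#' Prediction results for every observer of a panel
#'
#' @param panel a [response_panel()] with ratings.
#' @param seed fold-assignment seed (per-observer seeds derive from it).
#' @param ... passed to [predict_binary_from_ratings()].
#' @return named list of `prediction_result` objects, one per observer with
#'   ratings.
#' @export
panel_predictions <- function(panel, seed = 1, ...) {
  obs <- sort(unique(panel$ratings$observer_id))
  out <- lapply(seq_along(obs), function(i) {
    o <- obs[i]
    m <- observer_rating_matrix(panel, o)
    y <- panel$binary[rownames(m), o]
    predict_binary_from_ratings(m, y, seed = seed + i, ...)
  })
  names(out) <- obs
  out
}

#' Count observers with significant attributes per fold
#'
#' For each attribute and fold index, counts the observers for whom the
#' attribute was a significant predictor in that training fold, then reports
#' the median and range (max - min) of the three per-fold counts.
#'
#' @param results list of `prediction_result` objects (see
#'   [panel_predictions()]); skipped observers are ignored.
#' @return data frame with columns `attribute`, `median_count`, `fold_range`,
#'   plus one `fold_<i>` count column per fold.
#' @export
significant_attribute_counts <- function(results) {
  results <- Filter(function(r) !isTRUE(r$skipped), results)
  if (length(results) == 0) stop("no usable prediction results")
  k <- length(results[[1]]$significant_attributes)
  counts <- sapply(seq_len(k), function(f) {
    vapply(TLC_ATTRIBUTES, function(a) {
      sum(vapply(results,
                 function(r) a %in% r$significant_attributes[[f]],
                 logical(1)))
    }, numeric(1))
  })
  out <- data.frame(attribute = TLC_ATTRIBUTES,
                    median_count = apply(counts, 1, median),
                    fold_range = apply(counts, 1, function(v)
                      max(v) - min(v)),
                    stringsAsFactors = FALSE)
  colnames(counts) <- paste0("fold_", seq_len(k))
  cbind(out, counts)
}

#' t-SNE embedding of a rating table
#'
#' Two-dimensional t-distributed stochastic neighbor embedding of an
#' image-by-attribute feature table (exact gradients, deterministic given
#' the seed). Duplicate rows are permitted.
#'
#' @param features numeric matrix/data frame, rows = images.
#' @param perplexity t-SNE perplexity (default 15); requires more than
#'   `3 * perplexity` rows.
#' @param seed random seed for the embedding initialization.
#' @param max_iter optimization iterations.
#' @return list of class `tlc_embedding` with `coordinates` (n x 2),
#'   `perplexity`, `seed`.
#' @export
tsne_embed <- function(features, perplexity = 15, seed = 1,
                       max_iter = 500) {
  m <- as.matrix(as.data.frame(features))
  if (nrow(m) - 1 < 3 * perplexity) {
    stop("need more than 3 * perplexity rows (have ", nrow(m), ")")
  }
  set.seed(seed)
  fit <- Rtsne::Rtsne(m, dims = 2, perplexity = perplexity,
                      theta = 0, check_duplicates = FALSE, pca = FALSE,
                      max_iter = max_iter, verbose = FALSE)
  coords <- fit$Y
  rownames(coords) <- rownames(m)
  structure(list(coordinates = coords, perplexity = perplexity,
                 seed = seed),
            class = "tlc_embedding")
}
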