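# Gauss-Legendre nodes/weights on [0,1], 48 points, computed once at load
# via the Golub-Welsch eigendecomposition of the Jacobi matrix.
gauss_legendre_01 <- function(n = 48) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  ord <- order(x)
  list(x = (x[ord] + 1) / 2, w = w[ord] / 2)
}
.gl48 <- gauss_legendre_01(48)

#' Bivariate standard normal CDF
#'
#' `P(X <= h, Y <= k)` for standard normal `(X, Y)` with correlation `rho`,
#' via the single-integral identity
#' `Phi2(h, k; rho) = Phi(h) Phi(k) + (1/2pi) int_0^rho phi2(h, k; r) dr`
#' evaluated with 48-point Gauss-Legendre quadrature. Accurate to about 1e-10
#' for `|rho| <= 0.999`; handles infinite limits.
#'
#' @param h,k upper limits (vectors recycle).
#' @param rho scalar correlation in (-1, 1).
#' @return vector of probabilities.
#' @export
pbvnorm <- function(h, k, rho) {
  stopifnot(length(rho) == 1, abs(rho) < 1)
  n <- max(length(h), length(k))
  h <- rep_len(h, n)
  k <- rep_len(k, n)
  base <- pnorm(h) * pnorm(k)
  if (rho == 0) return(base)
  fin <- is.finite(h) & is.finite(k)
  out <- base
  # infinite limits reduce to univariate or zero regardless of rho
  out[h == -Inf | k == -Inf] <- 0
  out[h == Inf & is.finite(k)] <- pnorm(k[h == Inf & is.finite(k)])
  out[k == Inf & is.finite(h)] <- pnorm(h[k == Inf & is.finite(h)])
  out[h == Inf & k == Inf] <- 1
  if (any(fin)) {
    hh <- h[fin]
    kk <- k[fin]
    r <- rho * .gl48$x           # nodes on [0, rho]
    w <- rho * .gl48$w
    acc <- numeric(length(hh))
    for (m in seq_along(r)) {
      rm <- r[m]
      om <- 1 - rm^2
      acc <- acc + w[m] *
        exp(-(hh^2 - 2 * rm * hh * kk + kk^2) / (2 * om)) / sqrt(om)
    }
    out[fin] <- pnorm(hh) * pnorm(kk) + acc / (2 * pi)
  }
  pmin(pmax(out, 0), 1)
}

# Thresholds from empirical marginals of an ordinal variable with the given
# level set; returns c(-Inf, qnorm(cumulative), Inf).
ordinal_thresholds <- function(x, levels = TLC_RATING_LEVELS) {
  p <- cumsum(tabulate(match(x, levels), length(levels))) / length(x)
  c(-Inf, qnorm(p[-length(p)]), Inf)
}

#' Polychoric correlation of two ordinal variables
#'
#' Two-step estimate: thresholds are fixed at the normal quantiles of the
#' empirical marginal distributions, then the latent correlation is found by
#' maximizing the bivariate-normal contingency likelihood over `rho` with
#' cell probabilities from [pbvnorm()].
#'
#' @param x,y equal-length ordinal vectors.
#' @param levels ordered level set (default 1..6).
#' @return the estimated latent correlation (scalar).
#' @export
polychoric_corr <- function(x, y, levels = TLC_RATING_LEVELS) {
  stopifnot(length(x) == length(y))
  tab <- table(factor(x, levels = levels), factor(y, levels = levels))
  tx <- ordinal_thresholds(x, levels)
  ty <- ordinal_thresholds(y, levels)
  used_x <- which(rowSums(tab) > 0)
  used_y <- which(colSums(tab) > 0)
  if (length(used_x) < 2 || length(used_y) < 2) {
    stop("each variable needs at least 2 observed levels")
  }
  nonzero <- which(tab > 0, arr.ind = TRUE)
  counts <- tab[nonzero]
  hi_x <- tx[nonzero[, 1] + 1]; lo_x <- tx[nonzero[, 1]]
  hi_y <- ty[nonzero[, 2] + 1]; lo_y <- ty[nonzero[, 2]]
  negll <- function(rho) {
    p <- pbvnorm(hi_x, hi_y, rho) - pbvnorm(lo_x, hi_y, rho) -
      pbvnorm(hi_x, lo_y, rho) + pbvnorm(lo_x, lo_y, rho)
    -sum(counts * log(pmax(p, 1e-12)))
  }
  optimize(negll, interval = c(-0.999, 0.999), tol = 1e-6)$minimum
}

#' Polychoric correlation matrix of an ordinal rating table
#'
#' Pairwise two-step polychoric correlations between the attribute columns.
#' Columns observed at a single level are excluded with a warning. If the
#' pairwise assembly is indefinite, it is repaired to the nearest positive
#' semidefinite correlation matrix by eigenvalue clipping (flagged).
#'
#' @param ratings integer matrix/data frame (images x attributes), values in
#'   `levels`.
#' @param levels ordered level set (default 1..6).
#' @return list with `rho` (correlation matrix), `excluded` (column names),
#'   `psd_repaired` flag.
#' @export
polychoric_matrix <- function(ratings, levels = TLC_RATING_LEVELS) {
  m <- as.matrix(as.data.frame(ratings))
  if (nrow(m) < 3) stop("need at least 3 rows")
  nlev <- apply(m, 2, function(v) length(unique(v)))
  excluded <- colnames(m)[nlev < 2]
  if (length(excluded) > 0) {
    warning("excluding single-level attribute(s): ",
            paste(excluded, collapse = ", "))
    m <- m[, nlev >= 2, drop = FALSE]
  }
  k <- ncol(m)
  rho <- diag(1, k)
  dimnames(rho) <- list(colnames(m), colnames(m))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      r <- if (identical(m[, i], m[, j])) 1 - 1e-9 else
        polychoric_corr(m[, i], m[, j], levels)
      rho[i, j] <- rho[j, i] <- r
    }
  }
  repaired <- FALSE
  ev <- eigen(rho, symmetric = TRUE)
  if (min(ev$values) < 0) {
    repaired <- TRUE
    vals <- pmax(ev$values, 1e-8)
    rho <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    d <- sqrt(diag(rho))
    rho <- rho / outer(d, d)
    dimnames(rho) <- list(colnames(m), colnames(m))
  }
  list(rho = rho, excluded = excluded, psd_repaired = repaired)
}
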