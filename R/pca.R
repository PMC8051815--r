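#' Genotype principal component analysis
#'
#' Standard genotype PCA: the dosage matrix is mean-imputed per variant,
#' centered by twice the estimated allele frequency and scaled by
#' `sqrt(2 p (1 - p))` (so common variants do not dominate), and the
#' sample-space covariance of the standardized matrix is
#' eigendecomposed. Variants with zero variance after imputation are
#' dropped (with a message). Eigenvector signs follow a fixed convention:
#' each component's largest-magnitude variant loading is made positive, so
#' coordinates are reproducible rather than reproducible-up-to-sign.
#'
#' @param x a [call_set()] or an integer/numeric dosage matrix
#'   (variants x samples, `NA` = missing).
#' @param variants optional variant index (rows) to restrict to.
#' @param samples optional sample index (columns) to restrict to.
#' @return object of class `pca_result`: `vectors` (samples x components,
#'   orthonormal), `values` (nonincreasing, >= 0), `loadings`
#'   (variants x components), `m_used`, `n_dropped`.
#' @export
genotype_pca <- function(x, variants = NULL, samples = NULL) {
  g <- if (inherits(x, "call_set")) x$gt else x
  if (!is.null(variants)) g <- g[variants, , drop = FALSE]
  if (!is.null(samples)) g <- g[, samples, drop = FALSE]
  if (nrow(g) < 2 || ncol(g) < 2) stop("PCA needs >= 2 variants and >= 2 samples")

  g <- impute_row_means(g)
  p_hat <- rowMeans(g) / 2
  scale2 <- 2 * p_hat * (1 - p_hat)
  keep <- scale2 > 0 & rowSums((g - rowMeans(g))^2) > 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(n_dropped, " zero-variance variant(s) dropped before PCA")
  }
  if (sum(keep) < 2) stop("fewer than 2 informative variants for PCA")
  z <- (g[keep, , drop = FALSE] - 2 * p_hat[keep]) / sqrt(scale2[keep])
  m <- nrow(z)

  n <- ncol(z)
  if (m < n) {
    # variant-side decomposition: same nonzero spectrum, much smaller
    # eigenproblem when the subset has fewer variants than samples
    eg <- eigen(tcrossprod(z) / (m - 1), symmetric = TRUE)
    values <- pmax(eg$values, 0)
    pos <- values > 1e-12
    u <- eg$vectors[, pos, drop = FALSE]
    values <- values[pos]
    vectors <- crossprod(z, u) /
      rep(sqrt(values * (m - 1)), each = n)
    loadings <- u * rep(sqrt(values * (m - 1)), each = m)
  } else {
    eg <- eigen(crossprod(z) / (m - 1), symmetric = TRUE)
    values <- pmax(eg$values, 0)
    vectors <- eg$vectors
    loadings <- z %*% vectors
  }
  for (j in seq_len(ncol(vectors))) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      vectors[, j] <- -vectors[, j]
      loadings[, j] <- -loadings[, j]
    }
  }
  structure(list(
    vectors = vectors, values = values, loadings = loadings,
    m_used = m, n_dropped = n_dropped
  ), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("pca_result:", nrow(x$vectors), "samples,", x$m_used,
      "variants; leading eigenvalues:",
      paste(sprintf("%.3g", utils::head(x$values, 5)), collapse = ", "), "\n")
  invisible(x)
}

#' Number of principal components to retain as covariates
#'
#' Counts the leading eigenvalues above 1 (the eigenvalue-above-one rule),
#' capped at `max_pcs` since under the sample-covariance scaling a long
#' bulk of null eigenvalues can sit just above 1. Warns when no component
#' qualifies (the pipeline then uses no PC covariates).
#'
#' @param pca a `pca_result`.
#' @param max_pcs cap on the retained count (default 10).
#' @return integer number of retained components.
#' @export
retain_pcs <- function(pca, max_pcs = 10L) {
  stopifnot(inherits(pca, "pca_result"))
  above <- pca$values > 1
  k <- if (!above[1]) 0L else {
    first_below <- which(!above)
    if (length(first_below) == 0) length(above) else first_below[1] - 1L
  }
  k <- min(as.integer(k), as.integer(max_pcs))
  if (k == 0L) warning("no eigenvalue above 1; retaining 0 PC covariates")
  k
}

#' Projection scores (eigenvectors scaled by singular values)
#' @param pca a `pca_result`.
#' @param k number of components.
#' @return samples x k matrix.
#' @export
pc_scores <- function(pca, k = NULL) {
  k <- k %||% length(pca$values)
  pca$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pca$values[seq_len(k)]), nrow = k)
}

#' Cluster samples into subpopulations on retained PCs
#'
#' Model-free surrogate for model-based admixture estimation: k-means over
#' the retained principal component scores for each candidate `k`, with the
#' number of clusters chosen by maximum mean silhouette width (`k = 1`
#' scores 0, so it wins only when no split produces positive silhouette;
#' degenerate inputs where k-means cannot split fall back to `k = 1`).
#'
#' @param pca a `pca_result`.
#' @param k_range candidate cluster counts.
#' @param n_pcs how many leading PCs to cluster on (default: the
#'   [retain_pcs()] count, minimum 1).
#' @param seed integer seed for the k-means restarts.
#' @param nstart k-means restarts per candidate `k`.
#' @return list: `labels` (integer vector), `k` (chosen), `silhouette`
#'   (named vector of mean silhouette per candidate `k`).
#' @export
cluster_subpops <- function(pca, k_range = 1:6, n_pcs = NULL, seed = 1L,
                            nstart = 10L) {
  stopifnot(inherits(pca, "pca_result"))
  n <- nrow(pca$vectors)
  if (any(k_range < 1L) || any(k_range > n)) {
    stop("k_range must lie within [1, n_samples]")
  }
  n_pcs <- n_pcs %||% max(1L, suppressWarnings(retain_pcs(pca)))
  xs <- pc_scores(pca, n_pcs)
  d <- stats::dist(xs)
  set.seed(stage_seed(seed, "kmeans"))
  sil <- stats::setNames(rep(NA_real_, length(k_range)), k_range)
  fits <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    if (k == 1L) {
      sil[i] <- 0
      fits[[i]] <- rep(1L, n)
      next
    }
    fit <- tryCatch(
      stats::kmeans(xs, centers = k, nstart = nstart, iter.max = 50),
      error = function(e) NULL
    )
    if (is.null(fit) || length(unique(fit$cluster)) < 2L) next
    sil[i] <- mean(cluster::silhouette(fit$cluster, d)[, "sil_width"])
    fits[[i]] <- fit$cluster
  }
  if (all(is.na(sil))) stop("no candidate k could be evaluated")
  best <- which.max(sil)          # ties resolve to the smaller k
  list(labels = fits[[best]], k = k_range[best], silhouette = sil)
}
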