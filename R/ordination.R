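# Distance-based ordination, implemented from first principles: Bray-Curtis
# dissimilarity on (square-root) standardized abundances, principal
# coordinates analysis by eigendecomposition of the Gower-centred matrix,
# and group centroids with standard errors for ordination plots.

#' Pairwise sample dissimilarities
#'
#' `d(i,j) = sum_k |x_ki - x_kj| / sum_k (x_ki + x_kj)` for Bray-Curtis
#' (on non-negative, typically sqrt-transformed relative abundances);
#' Euclidean and Jaccard (presence/absence Bray-Curtis) are selectable.
#'
#' @param x Numeric OTU x sample matrix, values >= 0; samples are columns.
#' @param method `"bray"`, `"euclidean"` or `"jaccard"`.
#' @return A `dist_matrix`: list with `sample_ids` and symmetric matrix `d`
#'   (zero diagonal; Bray-Curtis values in \[0, 1\]).
#' @export
bray_curtis <- function(x, method = c("bray", "euclidean", "jaccard")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("S", seq_len(ncol(x)))
  if (method != "euclidean" && any(x < 0)) .stopf("negative abundances")
  n <- ncol(x)
  if (method == "jaccard") x <- (x > 0) * 1
  d <- matrix(0, n, n, dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(n - 1L)) {
    xi <- x[, i]
    for (j in (i + 1L):n) {
      xj <- x[, j]
      if (method == "euclidean") {
        dij <- sqrt(sum((xi - xj)^2))
      } else {
        denom <- sum(xi + xj)
        if (denom == 0)
          .stopf("dissimilarity undefined for all-zero sample pair: %s, %s",
                 colnames(x)[i], colnames(x)[j])
        dij <- sum(abs(xi - xj)) / denom
        if (method == "jaccard") dij <- 2 * dij / (1 + dij)
      }
      d[i, j] <- d[j, i] <- dij
    }
  }
  dist_matrix(d)
}

#' Construct/validate a distance matrix object
#'
#' @param d Symmetric non-negative matrix with zero diagonal and sample
#'   dimnames (or a `stats::dist`).
#' @return A `dist_matrix`.
#' @export
dist_matrix <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("S", seq_len(nrow(d)))
  }
  if (!isSymmetric(unname(d), tol = 1e-10)) .stopf("distance matrix is not symmetric")
  if (any(diag(d) != 0)) .stopf("distance matrix diagonal must be zero")
  if (any(d < 0)) .stopf("negative distances")
  structure(list(sample_ids = rownames(d), d = 0.5 * (d + t(d))),
            class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("dist_matrix: %d samples, range [%.4g, %.4g]\n",
              length(x$sample_ids), min(x$d[upper.tri(x$d)]), max(x$d)))
  invisible(x)
}

# Gower-centred matrix G = -1/2 J D^2 J with J = I - 11'/n.
gower_center <- function(d) {
  dm <- if (inherits(d, "dist_matrix")) d$d else as.matrix(d)
  n <- nrow(dm)
  a <- -0.5 * dm^2
  rm <- rowMeans(a); gm <- mean(a)
  sweep(sweep(a, 1L, rm), 2L, rm) + gm
}

#' Principal coordinates analysis
#'
#' Eigendecomposition of the Gower-centred matrix. Coordinates are the
#' eigenvectors scaled by the square root of their (positive) eigenvalues;
#' negative eigenvalues are reported but contribute no axes (no Lingoes or
#' Cailliez correction is applied). Proportion explained is relative to the
#' sum of positive eigenvalues.
#'
#' @param d A `dist_matrix` (or symmetric matrix / `dist`).
#' @return An `ordination` object: `coordinates` (sample x axis),
#'   `eigenvalues` (positive, decreasing), `negative_eigenvalues`,
#'   `prop_explained`, `vectors` (orthonormal eigenvectors of the retained
#'   axes), `trace`.
#' @export
pcoa <- function(d) {
  if (!inherits(d, "dist_matrix")) d <- dist_matrix(d)
  n <- length(d$sample_ids)
  if (n < 3L) .stopf("PCoA needs at least 3 samples")
  G <- gower_center(d)
  eig <- eigen(G, symmetric = TRUE)
  tol <- max(abs(eig$values)) * 1e-9
  pos <- which(eig$values > tol)
  neg <- eig$values[eig$values < -tol]
  lam <- eig$values[pos]
  vec <- eig$vectors[, pos, drop = FALSE]
  coords <- sweep(vec, 2L, sqrt(lam), "*")
  rownames(coords) <- rownames(vec) <- d$sample_ids
  colnames(coords) <- colnames(vec) <- paste0("PCo", seq_along(pos))
  structure(list(coordinates = coords, eigenvalues = lam,
                 negative_eigenvalues = neg,
                 prop_explained = lam / sum(lam),
                 vectors = vec, trace = sum(diag(G))),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("ordination: %d samples, %d axes; first axes explain %s\n",
              nrow(x$coordinates), ncol(x$coordinates),
              paste(sprintf("%.1f%%", 100 * utils::head(x$prop_explained, 3L)),
                    collapse = ", ")))
  if (length(x$negative_eigenvalues))
    cat(sprintf("  %d negative eigenvalues (min %.4g) reported, not embedded\n",
                length(x$negative_eigenvalues), min(x$negative_eigenvalues)))
  invisible(x)
}

#' Group centroids on ordination axes
#'
#' Mean coordinate per factor level with per-axis standard error
#' (sd/sqrt(n)); the standard presentation of crowded ordinations (points =
#' group means, error bars = SE). Singleton levels get `NA` standard errors.
#'
#' @param ord An `ordination`.
#' @param groups Factor/character vector, one level per sample (in
#'   coordinate row order), or named by sample.
#' @param axes Axes to report (default first two).
#' @return Data frame: level, n, axis, mean, se.
#' @export
group_centroids <- function(ord, groups, axes = 1:2) {
  coords <- ord$coordinates
  axes <- axes[axes <= ncol(coords)]
  if (!is.null(names(groups))) groups <- groups[rownames(coords)]
  if (length(groups) != nrow(coords) || anyNA(groups))
    .stopf("every sample needs a factor level")
  g <- as.character(groups)
  rows <- list()
  for (lev in unique(g)) {
    idx <- which(g == lev)
    for (ax in axes) {
      v <- coords[idx, ax]
      rows[[length(rows) + 1L]] <- data.frame(
        level = lev, n = length(idx), axis = colnames(coords)[ax],
        mean = mean(v),
        se = if (length(idx) > 1L) stats::sd(v) / sqrt(length(idx)) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Principal component analysis of a taxa table
#'
#' Covariance-based PCA of standardized percent abundances (taxa as
#' variables), via the same eigen machinery: an ordination of samples with
#' taxon loadings, used for taxa-driven biplots.
#'
#' @param taxa Taxa x sample matrix of percents.
#' @return List with `scores` (sample x PC), `loadings` (taxon x PC),
#'   `eigenvalues`, `prop_explained`.
#' @export
taxa_pca <- function(taxa) {
  x <- t(as.matrix(taxa))           # samples x taxa
  x <- sweep(x, 2L, colMeans(x))
  sv <- svd(x)
  lam <- sv$d^2 / (nrow(x) - 1L)
  keep <- lam > max(lam) * 1e-12
  scores <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], sum(keep))
  rownames(scores) <- rownames(x)
  loadings <- sv$v[, keep, drop = FALSE]
  rownames(loadings) <- colnames(x)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(sum(keep)))
  list(scores = scores, loadings = loadings, eigenvalues = lam[keep],
       prop_explained = lam[keep] / sum(lam[keep]))
}
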