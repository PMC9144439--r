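#' Principal component analysis of a genotype matrix
#'
#' PCA of the column-centered genotype matrix via singular value
#' decomposition. Centering only — no per-marker variance scaling — so the
#' principal-component geometry tracks allele-frequency divergence, the
#' population-genetics default; in a cohort with two diverged gene pools the
#' leading component separates them. Missing calls are mean-imputed before
#' centering. The decomposition is deterministic up to component sign; the
#' sign is fixed by forcing the largest-magnitude marker loading of each
#' component to be positive, so scores are reproducible across runs and
#' platforms.
#'
#' @param G a [genotype_matrix()], or an already-encoded (centered) numeric
#'   matrix.
#' @param n_components number of components to return,
#'   `<= min(accessions - 1, markers)`.
#' @return An object of class `genotype_pca`: list with `scores`
#'   (accessions x `n_components`, zero column means), `explained_fraction`
#'   (per-component fraction of total variance, over all components of the
#'   decomposition), `loadings` (markers x `n_components`), and
#'   `n_components`.
#' @export
genotype_pca <- function(G, n_components = 3) {
  if (inherits(G, "genotype_matrix")) {
    enc <- genotype_encoder(G)
    M <- encode_genotypes(enc, G)
  } else {
    M <- as.matrix(G)
    M <- sweep(M, 2L, colMeans(M), "-")
  }
  n <- nrow(M)
  if (n < 2L) stop("PCA requires at least 2 accessions")
  rank_max <- min(n - 1L, ncol(M))
  if (n_components > rank_max) {
    stop("n_components must be <= min(accessions - 1, markers)")
  }
  sv <- svd(M)
  d2 <- sv$d^2
  explained <- d2 / sum(d2)
  k <- n_components
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    pivot <- which.max(abs(loadings[, j]))
    if (loadings[pivot, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- rownames(M)
  colnames(scores) <- paste0("PC", seq_len(k))
  colnames(loadings) <- paste0("PC", seq_len(k))
  structure(list(scores = scores,
                 explained_fraction = explained[seq_len(rank_max)],
                 loadings = loadings,
                 n_components = k),
            class = "genotype_pca")
}

#' @export
print.genotype_pca <- function(x, ...) {
  k <- x$n_components
  cat(sprintf("genotype_pca: %d accessions, %d components\n",
              nrow(x$scores), k))
  cat(sprintf("  variance explained (first %d): %s\n", k,
              paste(sprintf("%.1f%%", 100 * x$explained_fraction[seq_len(k)]),
                    collapse = ", ")))
  invisible(x)
}

#' Plot genotype PCA scores colored by group
#'
#' @param x a [genotype_pca()] result.
#' @param groups optional factor (e.g. gene pool or class) used for colors.
#' @param components length-2 integer vector of components to plot.
#' @param ... further arguments passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.genotype_pca <- function(x, groups = NULL, components = c(1, 2), ...) {
  i <- components[1]; j <- components[2]
  col <- if (is.null(groups)) 1L else as.integer(factor(groups))
  lab <- function(k) sprintf("PC%d (%.1f%%)", k,
                             100 * x$explained_fraction[k])
  graphics::plot(x$scores[, i], x$scores[, j], col = col, pch = 19,
                 xlab = lab(i), ylab = lab(j), ...)
  if (!is.null(groups)) {
    graphics::legend("topright", legend = levels(factor(groups)),
                     col = seq_along(levels(factor(groups))), pch = 19)
  }
  invisible(x)
}

#' Quantify gene-pool separation in PCA space
#'
#' Mean silhouette coefficient of a grouping (typically the gene-pool
#' labels) computed on the leading principal-component scores. Values near
#' 1 indicate tight, well-separated clusters; values near 0 indicate no
#' separation beyond chance — calibrate against a permutation null by
#' shuffling the labels.
#'
#' @param scores numeric score matrix (accessions x components), e.g.
#'   `genotype_pca(G)$scores`.
#' @param groups vector of group labels aligned with the score rows; at
#'   least two groups must be present.
#' @param k number of leading score columns to use (default 3, capped at
#'   the available columns).
#' @return The mean silhouette width, in `[-1, 1]`.
#' @export
pool_separation <- function(scores, groups, k = 3) {
  scores <- as.matrix(scores)
  groups <- factor(groups)
  if (nrow(scores) != length(groups)) {
    stop("scores and groups must be aligned")
  }
  if (nlevels(groups) < 2L) stop("at least two groups are required")
  k <- min(k, ncol(scores))
  sil <- cluster::silhouette(as.integer(groups),
                             dist(scores[, seq_len(k), drop = FALSE]))
  mean(sil[, "sil_width"])
}
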