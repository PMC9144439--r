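# Independent oracles used to cross-check the implementation. These follow
# different algebraic routes than the package code on purpose.

# Hudson Fst estimator (ratio of averages) for two inbred populations coded
# 0/1; each accession contributes one allele draw.
hudson_fst <- function(g1, g2) {
  p1 <- colMeans(g1, na.rm = TRUE)
  p2 <- colMeans(g2, na.rm = TRUE)
  n1 <- colSums(!is.na(g1))
  n2 <- colSums(!is.na(g2))
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

# Brute-force restricted log-likelihood at a fixed variance ratio lambda,
# computed from determinants of the full covariance (no spectral shortcut).
reml_ll_direct <- function(log_lambda, y, Z, X = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  p <- ncol(X)
  K <- tcrossprod(Z)
  H <- K + diag(exp(log_lambda), n)
  Hi <- solve(H)
  XtHiX <- crossprod(X, Hi %*% X)
  beta <- solve(XtHiX, crossprod(X, Hi %*% y))
  r <- y - X %*% beta
  s2 <- drop(crossprod(r, Hi %*% r)) / (n - p)
  -0.5 * ((n - p) * log(2 * pi * s2) +
            determinant(H, logarithm = TRUE)$modulus +
            determinant(XtHiX, logarithm = TRUE)$modulus +
            (n - p))
}

# argmax of the direct restricted likelihood over a fixed grid
reml_grid_argmax <- function(y, Z, grid) {
  ll <- vapply(grid, reml_ll_direct, numeric(1), y = y, Z = Z)
  grid[which.max(ll)]
}

# Kernel (GBLUP) prediction: K_test,train (K_train + lambda I)^-1 (y - Xb)
gblup_predict <- function(y, Z_train, Z_test, lambda, beta) {
  K_tt <- Z_test %*% t(Z_train)
  K <- tcrossprod(Z_train)
  r <- y - beta
  drop(K_tt %*% solve(K + diag(lambda, nrow(K)), r))
}

# random centered regression instance for solver tests
random_instance <- function(n, m, h2 = 0.5, seed = 1) {
  set.seed(seed)
  Z <- matrix(rbinom(n * m, 1, runif(m, 0.1, 0.9)[rep(seq_len(m), each = n)]),
              n, m)
  Z <- sweep(Z, 2, colMeans(Z), "-")
  u <- rnorm(m)
  g <- drop(Z %*% u)
  vg <- var(g)
  y <- if (vg > 0) g + rnorm(n, sd = sqrt(vg * (1 - h2) / h2)) else rnorm(n)
  list(y = y, Z = Z)
}

# small deterministic genotype_matrix builder for IO/filter tests
toy_genotypes <- function(values, chrom = NULL) {
  values <- as.matrix(values)
  m <- ncol(values)
  if (is.null(chrom)) chrom <- rep("Chr01", m)
  pos <- stats::ave(seq_len(m), chrom, FUN = seq_along) * 100L
  map <- data.frame(chrom = chrom, pos = pos,
                    id = sprintf("mk%03d", seq_len(m)),
                    ref = rep("A", m), alt = rep("T", m),
                    stringsAsFactors = FALSE)
  genotype_matrix(values, map, sprintf("s%02d", seq_len(nrow(values))))
}
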