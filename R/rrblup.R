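#' Fit an RR-BLUP mixed model by exact REML
#'
#' Fits the single-random-effect genomic prediction model
#' \deqn{y = X\beta + Zu + \varepsilon, \quad u \sim N(0, I\sigma_u^2),
#'   \quad \varepsilon \sim N(0, I\sigma_e^2),}
#' where `y` are training-set phenotypes, `X` a fixed-effects design
#' (intercept-only by default) and `Z` the centered genotype matrix. All
#' marker effects share a common variance — ridge regression with the
#' penalty chosen by restricted maximum likelihood.
#'
#' Variance components are estimated by profiling the restricted likelihood
#' over the single ratio \eqn{\lambda = \sigma_e^2/\sigma_u^2}: after one
#' spectral decomposition of the genomic kernel \eqn{ZZ^\top} projected onto
#' the orthogonal complement of the column space of `X`, each likelihood
#' evaluation costs O(N). The optimum over \eqn{\log\lambda} is located by a
#' coarse bracketing grid followed by Brent's method to tolerance `tol`
#' within `log_lambda_bounds`; an optimum pinned to the bracket boundary is
#' clamped there and flagged (`boundary = TRUE`). At the optimum,
#' \eqn{\beta} is the generalized least-squares estimate and the marker
#' effects are the BLUP
#' \eqn{\hat u = Z^\top (ZZ^\top + \lambda I)^{-1}(y - X\hat\beta)},
#' identical to the ridge solution with penalty \eqn{\lambda}.
#'
#' Genotype entries may be inbred-coded \{0,1\} (the common-bean case, a
#' highly self-pollinated crop) or heterozygote dosages; either way `Z`
#' must be column-centered on the training scale — see
#' [genotype_encoder()].
#'
#' @param y numeric phenotype vector, length N >= 3, no missing values.
#' @param Z numeric N x M centered genotype matrix, no missing values.
#' @param X fixed-effects design matrix (N x p, full column rank); default
#'   an intercept column.
#' @param log_lambda_bounds search bracket for \eqn{\log\lambda}.
#' @param tol convergence tolerance of the one-dimensional optimization on
#'   \eqn{\log\lambda}.
#' @param keep_z keep `Z` inside the fit (needed by [simulate.rrblup()]).
#'
#' @return An object of class `rrblup`: a list with components `beta`
#'   (fixed effects), `u` (marker-effect BLUPs), `var_u`, `var_e` (REML
#'   variance components), `lambda`, `log_lambda`, `loglik` (restricted
#'   log-likelihood at the optimum), `h2_hat` (genomic heritability
#'   estimate \eqn{\sigma_u^2 \mathrm{tr}(ZZ^\top)/N} over total variance),
#'   `fitted`, `residuals`, `boundary`, and bookkeeping fields.
#'
#' @examples
#' set.seed(42)
#' Z <- scale(matrix(rbinom(50 * 20, 1, 0.5), 50, 20), scale = FALSE)
#' u <- rnorm(20)
#' y <- drop(Z %*% u) + rnorm(50)
#' fit <- rrblup(y, Z)
#' summary(fit)
#' @seealso [predict.rrblup()] for GEBVs, [summary.rrblup()],
#'   [simulate.rrblup()]
#' @export
rrblup <- function(y, Z, X = NULL, log_lambda_bounds = c(-10, 10),
                   tol = 1e-8, keep_z = TRUE) {
  y <- as.numeric(y)
  Z <- as.matrix(Z)
  n <- length(y)
  if (n < 3L) stop("at least 3 training observations are required")
  if (nrow(Z) != n) stop("nrow(Z) must equal length(y)")
  if (ncol(Z) < 1L) stop("Z must have at least one marker column")
  if (anyNA(y) || anyNA(Z)) stop("y and Z must not contain missing values")
  if (!all(is.finite(y)) || !all(is.finite(Z))) {
    stop("y and Z must be finite")
  }
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (nrow(X) != n) stop("nrow(X) must equal length(y)")
  p <- ncol(X)
  qrx <- qr(X)
  if (qrx$rank < p) stop("X is rank deficient")
  if (n - p < 2L) stop("too few residual degrees of freedom")
  cl <- match.call()

  ols <- function() qr.coef(qrx, y)

  if (stats::var(y) == 0) {
    warning("phenotype has zero variance; returning boundary fit")
    beta <- ols()
    fit <- build_rrblup(beta, rep(0, ncol(Z)), 0, 0, NA_real_, NA_real_,
                        -Inf, X, Z, y, boundary = TRUE, keep_z, cl)
    return(fit)
  }

  K <- tcrossprod(Z)
  # restricted likelihood on error contrasts: Q spans the orthogonal
  # complement of col(X), so Q'y ~ N(0, sigma_u^2 Q'KQ + sigma_e^2 I)
  Q <- qr.Q(qrx, complete = TRUE)[, (p + 1L):n, drop = FALSE]
  KQ <- crossprod(Q, K %*% Q)
  eig <- eigen((KQ + t(KQ)) / 2, symmetric = TRUE)
  xi <- pmax(eig$values, 0)
  w <- drop(crossprod(eig$vectors, crossprod(Q, y)))
  np <- n - p

  if (max(xi) <= 1e-12 * max(1, sum(abs(diag(K))) / n)) {
    # Z carries no usable signal (e.g. all-zero matrix): likelihood is flat
    # in lambda; fall back to ordinary least squares
    beta <- ols()
    var_e <- sum(w^2) / np
    ll <- -0.5 * (np * log(2 * pi * var_e) + np)
    fit <- build_rrblup(beta, rep(0, ncol(Z)), 0, var_e, NA_real_, NA_real_,
                        ll, X, Z, y, boundary = TRUE, keep_z, cl)
    return(fit)
  }

  reml_ll <- function(log_lambda) {
    d <- xi + exp(log_lambda)
    s <- sum(w^2 / d)
    0.5 * (np * log(np / (2 * pi)) - np - np * log(s) - sum(log(d)))
  }

  grid <- seq(log_lambda_bounds[1], log_lambda_bounds[2], length.out = 41L)
  ll_grid <- vapply(grid, reml_ll, numeric(1))
  i <- which.max(ll_grid)
  lower <- grid[max(1L, i - 1L)]
  upper <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(reml_ll, c(lower, upper), maximum = TRUE, tol = tol)
  log_lambda <- opt$maximum
  boundary <- FALSE
  span <- diff(log_lambda_bounds)
  if (log_lambda <= log_lambda_bounds[1] + 1e-4 * span ||
      log_lambda >= log_lambda_bounds[2] - 1e-4 * span) {
    boundary <- TRUE
    log_lambda <- min(max(log_lambda, log_lambda_bounds[1]),
                      log_lambda_bounds[2])
  }
  lambda <- exp(log_lambda)
  var_u <- sum(w^2 / (xi + lambda)) / np
  var_e <- lambda * var_u
  loglik <- reml_ll(log_lambda)

  H_inv <- chol2inv(chol(K + diag(lambda, n)))
  HiX <- H_inv %*% X
  beta <- drop(solve(crossprod(X, HiX), crossprod(HiX, y)))
  names(beta) <- colnames(X)
  r <- y - drop(X %*% beta)
  u <- drop(crossprod(Z, H_inv %*% r))
  names(u) <- colnames(Z)

  build_rrblup(beta, u, var_u, var_e, lambda, log_lambda, loglik,
               X, Z, y, boundary, keep_z, cl)
}

build_rrblup <- function(beta, u, var_u, var_e, lambda, log_lambda, loglik,
                         X, Z, y, boundary, keep_z, call) {
  fitted <- drop(X %*% beta) + drop(Z %*% u)
  tr_K <- sum(Z^2)
  n <- length(y)
  genic_var <- var_u * tr_K / n
  h2_hat <- if (genic_var + var_e > 0) genic_var / (genic_var + var_e)
            else NA_real_
  structure(list(
    beta = beta, u = u, var_u = var_u, var_e = var_e,
    lambda = lambda, log_lambda = log_lambda, loglik = loglik,
    h2_hat = h2_hat, fitted = fitted, residuals = y - fitted,
    y = y, X = X, Z = if (keep_z) Z else NULL,
    n = n, m = length(u), tr_K = tr_K,
    boundary = boundary, call = call
  ), class = "rrblup")
}

#' @export
print.rrblup <- function(x, digits = 4, ...) {
  cat("RR-BLUP mixed model (REML)\n")
  cat(sprintf("  N = %d training accessions, M = %d markers\n", x$n, x$m))
  cat(sprintf("  var_u = %.*g, var_e = %.*g, lambda = %.*g%s\n",
              digits, x$var_u, digits, x$var_e, digits, x$lambda,
              if (x$boundary) " (boundary)" else ""))
  cat(sprintf("  restricted log-likelihood = %.*g\n", digits, x$loglik))
  invisible(x)
}

#' Summary of an RR-BLUP fit
#'
#' @param object an [rrblup()] fit.
#' @param ... ignored.
#' @return An object of class `summary.rrblup` with variance components,
#'   the variance ratio, the genomic heritability estimate and fit metadata.
#' @export
summary.rrblup <- function(object, ...) {
  structure(list(
    call = object$call, n = object$n, m = object$m,
    beta = object$beta, var_u = object$var_u, var_e = object$var_e,
    lambda = object$lambda, h2_hat = object$h2_hat,
    loglik = object$loglik, boundary = object$boundary
  ), class = "summary.rrblup")
}

#' @export
print.summary.rrblup <- function(x, digits = 4, ...) {
  cat("RR-BLUP mixed model (REML)\n\n")
  cat(sprintf("Training set: N = %d accessions, M = %d markers\n", x$n, x$m))
  cat("\nFixed effects:\n")
  print(round(x$beta, digits))
  cat(sprintf("\nVariance components:\n  marker-effect var_u: %.*g\n  residual      var_e: %.*g\n  ratio lambda = var_e/var_u: %.*g\n",
              digits, x$var_u, digits, x$var_e, digits, x$lambda))
  cat(sprintf("Genomic heritability estimate: %.*g\n", digits, x$h2_hat))
  cat(sprintf("Restricted log-likelihood: %.*g\n", digits, x$loglik))
  if (x$boundary) cat("Note: variance ratio at the search boundary.\n")
  invisible(x)
}

#' Extract coefficients from an RR-BLUP fit
#'
#' @param object an [rrblup()] fit.
#' @param type `"fixed"` for the fixed effects \eqn{\hat\beta} or
#'   `"markers"` for the marker-effect BLUPs \eqn{\hat u}.
#' @param ... ignored.
#' @return A named numeric vector.
#' @export
coef.rrblup <- function(object, type = c("fixed", "markers"), ...) {
  type <- match.arg(type)
  if (type == "fixed") object$beta else object$u
}

#' Predict genomic estimated breeding values
#'
#' Computes GEBVs for new accessions as `newdata %*% u` — the additive
#' genetic value on the centered training scale. `newdata` must be encoded
#' with the same training-set constants as the fit's `Z` matrix (see
#' [encode_genotypes()]). With `include_fixed = TRUE` the intercept is
#' added, giving a phenotype-scale prediction; predictive ability is
#' invariant to this shift.
#'
#' @param object an [rrblup()] fit.
#' @param newdata numeric matrix with `M` columns, rows encoded on the
#'   training scale. Defaults to the training `Z`.
#' @param include_fixed add the fixed-effect intercept (requires an
#'   intercept-only design).
#' @param ... ignored.
#' @return A numeric vector of GEBVs, named by `rownames(newdata)`.
#' @export
predict.rrblup <- function(object, newdata = NULL, include_fixed = FALSE,
                           ...) {
  if (is.null(newdata)) {
    if (is.null(object$Z)) stop("fit was built with keep_z = FALSE; supply newdata")
    newdata <- object$Z
  }
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$m) {
    stop("newdata must have ", object$m, " marker columns")
  }
  if (anyNA(newdata)) stop("newdata must be encoded (no missing values)")
  gebv <- drop(newdata %*% object$u)
  if (include_fixed) {
    if (ncol(object$X) != 1L || any(object$X != 1)) {
      stop("include_fixed is only defined for intercept-only designs")
    }
    gebv <- gebv + object$beta[[1L]]
  }
  names(gebv) <- rownames(newdata)
  gebv
}

#' @export
fitted.rrblup <- function(object, ...) object$fitted

#' @export
residuals.rrblup <- function(object, ...) object$residuals

#' @export
logLik.rrblup <- function(object, ...) {
  structure(object$loglik, df = length(object$beta) + 2L,
            nobs = object$n, class = "logLik")
}

#' Simulate phenotypes from a fitted RR-BLUP model
#'
#' Draws new phenotype vectors from the fitted generative model:
#' fresh marker effects \eqn{u^* \sim N(0, I\hat\sigma_u^2)} and residuals
#' \eqn{\varepsilon^* \sim N(0, I\hat\sigma_e^2)} around the estimated
#' fixed-effect mean.
#'
#' @param object an [rrblup()] fit built with `keep_z = TRUE`.
#' @param nsim number of simulated phenotype vectors.
#' @param seed optional integer seed.
#' @param ... ignored.
#' @return A data.frame with `nsim` columns of length N.
#' @export
simulate.rrblup <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(object$Z)) stop("fit was built with keep_z = FALSE")
  if (!is.null(seed)) set.seed(seed)
  mu <- drop(object$X %*% object$beta)
  out <- vapply(seq_len(nsim), function(i) {
    u_star <- stats::rnorm(object$m, sd = sqrt(object$var_u))
    mu + drop(object$Z %*% u_star) +
      stats::rnorm(object$n, sd = sqrt(object$var_e))
  }, numeric(object$n))
  out <- as.data.frame(out)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

# Multi-trait solver sharing the training-set decompositions: one genomic
# kernel, one restricted-likelihood eigenbasis and one kernel eigenbasis per
# training set, then O(N^2) work per trait. Intercept-only fixed effects.
# Used by the experiment designs, where the same training set is fitted for
# many traits; agrees with rrblup() + predict() trait by trait.
rrblup_engine <- function(Y, Ztr, Zte, log_lambda_bounds = c(-10, 10),
                          tol = 1e-8) {
  Y <- as.matrix(Y)
  n <- nrow(Ztr)
  stopifnot(nrow(Y) == n, ncol(Zte) == ncol(Ztr))
  K <- tcrossprod(Ztr)
  Ktt <- tcrossprod(Zte, Ztr)
  qrx <- qr(matrix(1, n, 1))
  Q <- qr.Q(qrx, complete = TRUE)[, -1L, drop = FALSE]
  KQ <- crossprod(Q, K %*% Q)
  eq <- eigen((KQ + t(KQ)) / 2, symmetric = TRUE)
  xi <- pmax(eq$values, 0)
  np <- n - 1L
  ek <- eigen((K + t(K)) / 2, symmetric = TRUE)
  dk <- pmax(ek$values, 0)
  Uk <- ek$vectors
  b1 <- drop(crossprod(Uk, rep(1, n)))
  W <- crossprod(eq$vectors, crossprod(Q, Y))
  grid <- seq(log_lambda_bounds[1], log_lambda_bounds[2], length.out = 41L)
  n_traits <- ncol(Y)
  gebv <- matrix(NA_real_, nrow(Zte), n_traits,
                 dimnames = list(rownames(Zte), colnames(Y)))
  lambda <- var_u <- var_e <- numeric(n_traits)
  no_signal <- max(xi) <= 1e-12 * max(1, sum(dk) / n)
  for (t in seq_len(n_traits)) {
    w <- W[, t]
    if (no_signal || stats::var(Y[, t]) == 0) {
      gebv[, t] <- 0
      lambda[t] <- NA_real_; var_u[t] <- 0; var_e[t] <- sum(w^2) / np
      next
    }
    ll <- function(l) {
      d <- xi + exp(l)
      s <- sum(w^2 / d)
      0.5 * (np * log(np / (2 * pi)) - np - np * log(s) - sum(log(d)))
    }
    ll_grid <- vapply(grid, ll, numeric(1))
    i <- which.max(ll_grid)
    opt <- stats::optimize(ll, c(grid[max(1L, i - 1L)],
                                 grid[min(length(grid), i + 1L)]),
                           maximum = TRUE, tol = tol)
    lam <- exp(opt$maximum)
    a <- drop(crossprod(Uk, Y[, t]))
    denom <- dk + lam
    beta <- sum(b1 * a / denom) / sum(b1^2 / denom)
    h_inv_r <- Uk %*% ((a - beta * b1) / denom)
    gebv[, t] <- drop(Ktt %*% h_inv_r)
    lambda[t] <- lam
    var_u[t] <- sum(w^2 / (xi + lam)) / np
    var_e[t] <- lam * var_u[t]
  }
  list(gebv = gebv, lambda = lambda, var_u = var_u, var_e = var_e)
}

#' Plot observed against fitted values of an RR-BLUP fit
#'
#' @param x an [rrblup()] fit.
#' @param ... further arguments passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.rrblup <- function(x, ...) {
  graphics::plot(x$fitted, x$y,
                 xlab = "Fitted value (Xb + Zu)",
                 ylab = "Observed phenotype", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
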