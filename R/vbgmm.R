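## Variational Bayesian Gaussian mixture for strict clustering of sparse
## (radius, velocity, moment) data: full-covariance Gaussians with a
## Dirichlet prior on the weights whose small concentration prunes
## superfluous components (effective components are those keeping
## non-negligible weight).

## One VB-GMM run (Gaussian-Wishart conjugate updates).
.vbgmmFit <- function(X, K, alpha0, maxIter, tol, seed) {
  n <- nrow(X); D <- ncol(X)
  beta0 <- 1
  m0 <- colMeans(X)
  nu0 <- D + 2
  W0inv <- diag(apply(X, 2, stats::var), D) * nu0
  W0 <- solve(W0inv)

  ## init responsibilities from kmeans
  km <- .withSeed(seed, stats::kmeans(X, centers = K, nstart = 5,
                                      iter.max = 50))
  r <- matrix(1e-8, n, K)
  r[cbind(seq_len(n), km$cluster)] <- 1
  r <- r / rowSums(r)

  logLik <- -Inf
  for (it in seq_len(maxIter)) {
    ## M-like step: update variational parameters
    Nk <- colSums(r) + 1e-10
    ak <- alpha0 + Nk
    bk <- beta0 + Nk
    nuk <- nu0 + Nk
    xbar <- t(r) %*% X / Nk
    mk <- (beta0 * matrix(m0, K, D, byrow = TRUE) + Nk * xbar) / bk
    Winv <- vector("list", K)
    for (k in seq_len(K)) {
      Xc <- sweep(X, 2, xbar[k, ])
      Sk <- t(Xc * r[, k]) %*% Xc
      dm <- xbar[k, ] - m0
      Winv[[k]] <- W0inv + Sk + (beta0 * Nk[k] / (beta0 + Nk[k])) *
        tcrossprod(dm)
    }
    ## E step: expected log responsibilities
    ElnPi <- digamma(ak) - digamma(sum(ak))
    lr <- matrix(0, n, K)
    for (k in seq_len(K)) {
      Wk <- solve(Winv[[k]])
      ElnLam <- sum(digamma((nuk[k] + 1 - seq_len(D)) / 2)) + D * log(2) +
        determinant(Wk, logarithm = TRUE)$modulus
      Xc <- sweep(X, 2, mk[k, ])
      mah <- D / bk[k] + nuk[k] * rowSums((Xc %*% Wk) * Xc)
      lr[, k] <- ElnPi[k] + 0.5 * ElnLam - 0.5 * mah - D / 2 * log(2 * pi)
    }
    mx <- apply(lr, 1, max)
    r <- exp(lr - mx)
    norm <- rowSums(r)
    r <- r / norm
    ll <- sum(mx + log(norm))
    if (is.finite(logLik) && abs(ll - logLik) < tol * abs(ll)) break
    logLik <- ll
  }
  weights <- as.numeric(ak / sum(ak))
  list(resp = r, weights = weights, means = xbar, logBound = logLik,
       iterations = it)
}

#' Cluster cells in (radius, velocity, moment) space
#'
#' Variational Bayesian Gaussian mixture (full covariance, Dirichlet weight
#' prior with small concentration) on standardized coordinates. The prior
#' empties superfluous components; effective clusters are the components
#' whose posterior weight exceeds \code{weightThreshold}.
#'
#' @param points n x 3 matrix of (R um, v um/s, m A m^2); columns are
#'   standardized internally, results are reported in original units.
#' @param maxComponents upper bound on the number of components (requires
#'   n >= 10 * maxComponents).
#' @param seed RNG seed (initialisation is by k-means).
#' @param weightThreshold minimum posterior weight for an effective cluster
#'   (default 0.01).
#' @param alpha0 Dirichlet concentration per component (small values prune
#'   harder).
#' @param maxIter,tol VB iteration controls.
#' @return list(labels, nEffective, weights, means, responsibilities);
#'   means has one row per effective cluster, in original units.
#' @export
clusterRVM <- function(points, maxComponents = 8L, seed = 1,
                       weightThreshold = 0.01, alpha0 = NULL,
                       maxIter = 300L, tol = 1e-8) {
  X <- as.matrix(points)
  .stopIfNot(ncol(X) == 3L, "points must have 3 columns (R, v, m)")
  n <- nrow(X)
  .stopIfNot(n >= 10L * maxComponents,
             "need at least 10 points per candidate component")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (any(scl == 0)) stop("singular data: a coordinate is constant")
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  if (is.null(alpha0)) alpha0 <- 1 / maxComponents
  fit <- .vbgmmFit(Z, as.integer(maxComponents), alpha0, maxIter, tol, seed)
  eff <- which(fit$weights > weightThreshold)
  labAll <- apply(fit$resp, 1, which.max)
  ## snap labels of emptied components onto the nearest effective one
  labels <- vapply(seq_len(n), function(i) {
    k <- labAll[i]
    if (k %in% eff) match(k, eff)
    else which.max(fit$resp[i, eff, drop = FALSE])
  }, integer(1))
  means <- sweep(sweep(fit$means[eff, , drop = FALSE], 2, scl, "*"), 2, ctr,
                 "+")
  colnames(means) <- colnames(X) %||% c("R", "v", "m")
  list(labels = labels, nEffective = length(eff),
       weights = fit$weights[eff], means = means,
       responsibilities = fit$resp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
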