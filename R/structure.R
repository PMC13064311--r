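#' PCA on a (LD-pruned) genotype matrix
#'
#' Genotypes are standardised per SNP as \code{(g - 2p) / sqrt(2p(1-p))} with
#' p the alt-allele frequency over called genotypes; missing entries become 0
#' after centring. The sample-by-sample covariance is eigendecomposed;
#' explained variance is each eigenvalue over the sum of positive eigenvalues.
#' Component signs are fixed so the largest-magnitude sample coordinate of
#' each component is positive.
#'
#' @param gm a [geno_matrix()] (typically after [ld_prune()]).
#' @param n_components number of components to return (default 10).
#' @return list with \code{coords} (samples x components, scaled by
#'   sqrt(eigenvalue)), \code{explained} (variance fractions) and
#'   \code{eigenvalues}.
#' @export
pca_genotypes <- function(gm, n_components = 10) {
  if (length(gm$samples) < 2) stop("PCA needs >= 2 samples")
  G <- gm$calls
  p <- colMeans(G, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic SNPs")
  G <- G[, poly, drop = FALSE]
  p <- p[poly]
  Z <- sweep(G, 2, 2 * p, "-")
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
  Z[is.na(Z)] <- 0
  K <- tcrossprod(Z) / ncol(Z)
  eg <- eigen(K, symmetric = TRUE)
  pos <- pmax(eg$values, 0)
  n_components <- min(n_components, length(eg$values))
  coords <- eg$vectors[, seq_len(n_components), drop = FALSE] %*%
    diag(sqrt(pos[seq_len(n_components)]), n_components)
  for (k in seq_len(n_components)) {
    j <- which.max(abs(coords[, k]))
    if (coords[j, k] < 0) coords[, k] <- -coords[, k]
  }
  rownames(coords) <- gm$samples
  colnames(coords) <- paste0("PC", seq_len(n_components))
  list(coords = coords,
       explained = pos[seq_len(n_components)] / sum(pos),
       eigenvalues = eg$values[seq_len(n_components)])
}

# binomial log-likelihood of dosages G given Theta = Q F, missing entries skipped
admix_ll <- function(G, Theta) {
  ok <- !is.na(G)
  sum(G[ok] * log(Theta[ok]) + (2 - G[ok]) * log(1 - Theta[ok]))
}

admix_em_once <- function(G, k, max_iter, tol, eps = 1e-6) {
  n <- nrow(G); m <- ncol(G)
  Gz <- G; Gz[is.na(G)] <- 0          # masked entries contribute nothing
  G2 <- 2 - G; G2[is.na(G)] <- 0
  m_i <- rowSums(!is.na(G))
  p0 <- colMeans(G, na.rm = TRUE) / 2
  p0[is.na(p0)] <- 0.5
  F <- pmin(pmax(matrix(p0, k, m, byrow = TRUE) +
                   matrix(runif(k * m, -0.1, 0.1), k, m), eps), 1 - eps)
  Q <- matrix(rgamma(n * k, 1), n, k)
  Q <- Q / rowSums(Q)
  ll_prev <- -Inf
  ll_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Theta <- Q %*% F
    Theta <- pmin(pmax(Theta, eps), 1 - eps)
    P1 <- Gz / Theta          # g / theta        (0 where missing)
    P2 <- G2 / (1 - Theta)    # (2-g) / (1-theta)
    Fnum <- F * (t(Q) %*% P1)
    Fden <- Fnum + (1 - F) * (t(Q) %*% P2)
    Fnew <- pmin(pmax(Fnum / pmax(Fden, .Machine$double.xmin), eps), 1 - eps)
    Qnew <- Q * (P1 %*% t(F) + P2 %*% t(1 - F)) / (2 * pmax(m_i, 1))
    Qnew <- Qnew / rowSums(Qnew)
    Q <- Qnew; F <- Fnew
    ll <- admix_ll(G, pmin(pmax(Q %*% F, eps), 1 - eps))
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_prev) && ll - ll_prev < tol && ll >= ll_prev - 1e-8) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
  }
  list(Q = Q, F = F, loglik = ll, iterations = length(ll_trace),
       converged = converged, ll_trace = ll_trace)
}

#' Fit the binomial-likelihood admixture model by EM
#'
#' Maximises \code{sum(g log(theta) + (2 - g) log(1 - theta))} with
#' \code{theta = Q F}, Q the n x k ancestry fractions (rows sum to 1) and F
#' the k x m ancestral allele frequencies (clipped to [1e-6, 1 - 1e-6]).
#' Missing genotypes contribute nothing. Plain EM with multiple random
#' restarts, keeping the best likelihood; the log-likelihood is
#' non-decreasing across iterations within a run.
#'
#' @param gm a [geno_matrix()] (typically LD-pruned).
#' @param k number of ancestral components (1 <= k <= n samples).
#' @param seed optional RNG seed.
#' @param max_iter maximum EM iterations per restart (default 500).
#' @param tol stop when the log-likelihood gain falls below this (default 1e-4).
#' @param n_restarts random restarts (default 5).
#' @return list with \code{k}, \code{Q}, \code{F}, \code{loglik},
#'   \code{iterations}, \code{converged}, \code{ll_trace}.
#' @export
admixture_fit <- function(gm, k, seed = NULL, max_iter = 500, tol = 1e-4,
                          n_restarts = 5) {
  if (!is.null(seed)) set.seed(seed)
  G <- gm$calls
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(G)) stop("k exceeds the number of samples")
  if (k == 1) {
    p <- colMeans(G, na.rm = TRUE) / 2
    p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
    Q <- matrix(1, nrow(G), 1)
    F <- matrix(p, 1)
    ll <- admix_ll(G, Q %*% F)
    return(list(k = 1, Q = Q, F = F, loglik = ll, iterations = 0L,
                converged = TRUE, ll_trace = ll))
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- admix_em_once(G, k, max_iter, tol)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  c(list(k = k), best)
}

#' Choose k by masked-entry cross-validation
#'
#' Non-missing genotype entries are partitioned into \code{folds} random
#' folds. Each fold is masked in turn, the model refit, and the masked
#' entries scored by binomial deviance between the held-out dosage g and the
#' fitted 2*theta. The best k minimises the mean deviance over folds.
#'
#' @param gm a [geno_matrix()].
#' @param k_range candidate k values (default 1:10).
#' @param folds number of folds (default 20, must be >= 2).
#' @param seed optional RNG seed.
#' @param max_iter,tol,n_restarts passed to the EM fits (restarts default to 1
#'   for speed during CV).
#' @return list with \code{cv} (data.frame k, mean_error) and \code{best_k}.
#' @export
admixture_cv <- function(gm, k_range = 1:10, folds = 20, seed = NULL,
                         max_iter = 200, tol = 1e-2, n_restarts = 1) {
  if (folds < 2) stop("folds must be >= 2 (no held-out data otherwise)")
  if (!is.null(seed)) set.seed(seed)
  G <- gm$calls
  obs <- which(!is.na(G))
  if (length(obs) < folds) stop("not enough non-missing entries for the folds")
  fold_of <- sample(rep(seq_len(folds), length.out = length(obs)))
  err <- matrix(NA_real_, length(k_range), folds)
  for (f in seq_len(folds)) {
    Gf <- G
    held <- obs[fold_of == f]
    Gf[held] <- NA_integer_
    gmf <- gm
    gmf$calls <- Gf
    for (ki in seq_along(k_range)) {
      fit <- admixture_fit(gmf, k_range[ki], max_iter = max_iter, tol = tol,
                           n_restarts = n_restarts)
      Theta <- pmin(pmax(fit$Q %*% fit$F, 1e-6), 1 - 1e-6)
      g <- G[held]
      th <- Theta[held]
      d1 <- ifelse(g > 0, g * log(g / (2 * th)), 0)
      d2 <- ifelse(g < 2, (2 - g) * log((2 - g) / (2 - 2 * th)), 0)
      err[ki, f] <- mean(2 * (d1 + d2))
    }
  }
  cv <- data.frame(k = k_range, mean_error = rowMeans(err))
  list(cv = cv, best_k = k_range[which.min(cv$mean_error)])
}
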