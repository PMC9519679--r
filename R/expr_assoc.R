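#' Principal component analysis of an expression matrix
#'
#' Genes (rows) are centered, not standardized, and the samples are
#' projected onto the principal axes.
#'
#' @param expr genes x samples matrix of non-negative expression values
#' @param k number of components to return (`k < ncol(expr)`)
#' @return a list with `loadings` (samples x k matrix of sample scores)
#'   and `var_explained` (length-k fractions of total variance)
#' @export
expression_pca <- function(expr, k = 3L) {
  if (ncol(expr) < 2L) stop("need at least 2 samples")
  if (k >= ncol(expr)) stop("k must be smaller than the sample count")
  if (any(expr < 0)) stop("expression values must be non-negative")
  xc <- expr - rowMeans(expr)
  if (all(abs(xc) < .Machine$double.eps * 100))
    stop("degenerate input: expression matrix is constant across samples")
  pc <- stats::prcomp(t(xc), center = FALSE, scale. = FALSE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  list(loadings = pc$x[, seq_len(k), drop = FALSE],
       var_explained = vf[seq_len(k)])
}

#' Permutation test of SV-cluster association with expression PCs
#'
#' The observed statistic per principal component is the mean over
#' clusters of the absolute Pearson correlation between the cluster's
#' presence/absence vector (used as a metric character) and the sample
#' loadings. The null distribution is built by independently permuting
#' each cluster's presence vector across samples in every iteration;
#' `p = (1 + #{null >= observed}) / (n_perm + 1)`. Per-cluster permutation
#' p-values (against each cluster's own null `|r|`) are also returned.
#'
#' @param presence clusters x samples 0/1 matrix; rows with MAF at or
#'   below `maf_min` are dropped, constant rows are dropped with a warning
#' @param loadings samples x k matrix of PC sample scores
#' @param n_perm number of permutations (default 1000); must be >= 1
#' @param maf_min minor-allele-frequency filter (default 0.15; over 23
#'   samples this requires a minor count of at least 4)
#' @param seed integer seed
#' @return a list with `stats` (data frame `pc`, `observed`, `q95`, `p`),
#'   `per_cluster` (data frame `id`, `pc`, `r`, `p`), `n_clusters`
#' @export
pc_correlation_permutation <- function(presence, loadings, n_perm = 1000L,
                                       maf_min = 0.15, seed = 1L) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  n <- ncol(presence)
  if (nrow(loadings) != n)
    stop("loadings must have one row per sample")
  f <- rowMeans(presence)
  maf <- pmin(f, 1 - f)
  keep <- maf > maf_min
  if (any(keep & (f %in% c(0, 1)))) {
    warning("constant presence vectors excluded")
    keep <- keep & !(f %in% c(0, 1))
  }
  if (!any(keep)) stop("no cluster passes the MAF filter")
  x <- presence[keep, , drop = FALSE]
  ids <- rownames(x)
  if (is.null(ids)) ids <- sprintf("cluster%d", which(keep))
  set.seed(seed)
  obs_r <- stats::cor(t(x), loadings)        # clusters x k
  obs <- colMeans(abs(obs_r))
  k <- ncol(loadings)
  null_mean <- matrix(NA_real_, n_perm, k)
  exceed <- matrix(0L, nrow(x), k)           # per-cluster null >= |r|
  for (b in seq_len(n_perm)) {
    xp <- t(apply(x, 1L, sample))
    nr <- abs(stats::cor(t(xp), loadings))
    null_mean[b, ] <- colMeans(nr)
    exceed <- exceed + (nr >= abs(obs_r))
  }
  p <- (1 + colSums(null_mean >= rep(obs, each = n_perm))) / (n_perm + 1)
  q95 <- apply(null_mean, 2L, stats::quantile, probs = 0.95, names = FALSE)
  pcs <- colnames(loadings)
  if (is.null(pcs)) pcs <- paste0("PC", seq_len(k))
  per_cluster <- data.frame(
    id = rep(ids, k), pc = rep(pcs, each = nrow(x)),
    r = as.vector(obs_r),
    p = as.vector((1 + exceed) / (n_perm + 1)),
    stringsAsFactors = FALSE)
  list(stats = data.frame(pc = pcs, observed = obs, q95 = q95, p = p,
                          stringsAsFactors = FALSE),
       per_cluster = per_cluster, n_clusters = nrow(x))
}

#' Additive kinship matrix from a marker matrix
#'
#' Markers (columns) are centered by their allele frequency and the
#' cross-product is normalized by the summed marker variances,
#' `K = Z Z^T / sum(p (1 - p))`, so that the mean diagonal is comparable
#' to 1 under haploid 0/1 coding. Monomorphic markers are dropped.
#'
#' @param markers samples x markers matrix coded 0/1 (`NA` mean-imputed)
#' @return symmetric positive semi-definite kinship matrix
#' @export
compute_kinship <- function(markers) {
  m <- as.matrix(markers)
  if (anyNA(m)) {
    mu <- colMeans(m, na.rm = TRUE)
    idx <- which(is.na(m), arr.ind = TRUE)
    m[idx] <- mu[idx[, 2]]
  }
  p <- colMeans(m)
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic markers")
  m <- m[, poly, drop = FALSE]
  p <- p[poly]
  z <- sweep(m, 2L, p)
  (z %*% t(z)) / sum(p * (1 - p))
}

#' REML fit of a single-kernel linear mixed model
#'
#' Fits `y = X beta + u + e` with `u ~ N(0, sg^2 K)` and
#' `e ~ N(0, se^2 I)` by restricted maximum likelihood, profiling the
#' variance ratio `lambda = sg^2 / se^2` on the spectral decomposition of
#' `K` and optimizing `log(lambda)` in one dimension.
#'
#' @param y response vector
#' @param X fixed-effects design matrix (must have full column rank)
#' @param K symmetric PSD kernel over the samples
#' @param lambda_bounds search interval for `log(lambda)`
#' @param tol optimizer tolerance
#' @return a list with `beta`, `se_beta` (Wald standard errors), `df`
#'   (residual degrees of freedom), `sigma_g2`, `sigma_e2`, `lambda`,
#'   `loglik`, and `fitted_u` components for BLUP construction:
#'   `V_inv_resid = V^{-1}(y - X beta)` (on the original scale) scaled
#'   such that `u_hat = sigma_g2 * K %*% V_inv_resid`
#' @export
reml_kernel <- function(y, X, K, lambda_bounds = c(-18, 18), tol = 1e-8) {
  n <- length(y)
  X <- as.matrix(X)
  p <- ncol(X)
  if (qr(X)$rank < p) stop("fixed-effects design is singular (collinear)")
  eig <- eigen(K, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  ys <- crossprod(U, y)
  Xs <- crossprod(U, X)
  prof <- function(loglam) {
    lam <- exp(loglam)
    w <- lam * d + 1
    Xw <- Xs / w
    xtx <- crossprod(Xs, Xw)
    xty <- crossprod(Xw, ys)
    beta <- solve(xtx, xty)
    r <- ys - Xs %*% beta
    rss <- sum(r^2 / w)
    se2 <- rss / (n - p)
    ll <- -0.5 * ((n - p) * log(2 * pi * se2) + sum(log(w)) +
                    determinant(xtx, logarithm = TRUE)$modulus + (n - p))
    list(ll = as.numeric(ll), beta = beta, se2 = se2, lam = lam, xtx = xtx,
         w = w)
  }
  opt <- stats::optimize(function(l) prof(l)$ll, lambda_bounds,
                         maximum = TRUE, tol = tol)
  fit <- prof(opt$maximum)
  cov_beta <- fit$se2 * solve(fit$xtx)
  resid <- y - X %*% fit$beta
  ## V^{-1} r on the original scale: U diag(1/(se2 * w)) U^T r
  vinv_r <- U %*% (crossprod(U, resid) / (fit$se2 * fit$w))
  list(beta = as.numeric(fit$beta), se_beta = sqrt(diag(cov_beta)),
       df = n - p, sigma_g2 = fit$lam * fit$se2, sigma_e2 = fit$se2,
       lambda = fit$lam, loglik = fit$ll, V_inv_resid = as.numeric(vinv_r))
}

#' PK mixed-model association of an SV cluster with gene expression
#'
#' Fits `y = mu + Q beta_q + x beta_sv + u + e` with `u ~ N(0, sg^2 K)`
#' (the "PK" model: population-structure covariates plus a kinship random
#' effect), estimating variance components per gene by exact REML and
#' testing the SV presence effect with a Wald t-test on `df = n - p`.
#'
#' @param presence 0/1 presence vector of the cluster over samples
#' @param y expression vector of the gene over the same samples
#' @param structure samples x q matrix of structure covariates (e.g. the
#'   first two marker PCs); may be `NULL`
#' @param K kinship matrix
#' @return a list with `beta_sv`, `se`, `statistic`, `p_value`,
#'   `sigma_g2`, `sigma_e2`
#' @export
pk_association <- function(presence, y, structure = NULL, K) {
  n <- length(y)
  X <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(structure)) X <- cbind(X, as.matrix(structure))
  X <- cbind(X, sv = presence)
  if (qr(X)$rank < ncol(X))
    stop("SV presence is collinear with the structure covariates")
  fit <- reml_kernel(y, X, K)
  j <- ncol(X)
  tstat <- fit$beta[j] / fit$se_beta[j]
  p <- 2 * stats::pt(-abs(tstat), df = fit$df)
  list(beta_sv = fit$beta[j], se = fit$se_beta[j], statistic = tstat,
       p_value = p, sigma_g2 = fit$sigma_g2, sigma_e2 = fit$sigma_e2)
}
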