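#' Adjusted entry means from replicated multi-environment phenotypes
#'
#' Fits genotype and environment effects to the genotype-by-environment
#' cell means (replicates and genotype-by-environment deviations are
#' absorbed into the cell-mean error) and returns each genotype's
#' predicted value at the average environment. For a balanced complete
#' design this equals the simple genotype mean.
#'
#' @param table long data frame with columns `genotype`, `environment`,
#'   `value` (one row per replicate observation)
#' @return named numeric vector of adjusted entry means per genotype
#' @export
adjusted_entry_means <- function(table) {
  stopifnot(all(c("genotype", "environment", "value") %in% names(table)))
  if (length(unique(table$genotype)) < 2L)
    stop("need at least 2 genotypes")
  cm <- stats::aggregate(value ~ genotype + environment, data = table,
                         FUN = mean)
  ## estimability: the genotype-environment incidence graph must connect
  ## all genotypes
  gl <- unique(cm$genotype); el <- unique(cm$environment)
  parent <- seq_along(gl); names(parent) <- gl
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (e in el) {
    gs <- match(cm$genotype[cm$environment == e], gl)
    if (length(gs) > 1L)
      for (g in gs[-1]) parent[find(g)] <- find(gs[1])
  }
  if (length(unique(vapply(seq_along(gl), find, numeric(1)))) > 1L)
    stop("disconnected genotype x environment design; ",
         "adjusted means not estimable")
  cm$genotype <- factor(cm$genotype, levels = gl)
  cm$environment <- factor(cm$environment, levels = el)
  fit <- stats::lm(value ~ genotype + environment, data = cm)
  grid <- expand.grid(genotype = factor(gl, levels = gl),
                      environment = factor(el, levels = el))
  grid$pred <- stats::predict(fit, newdata = grid)
  out <- tapply(grid$pred, grid$genotype, mean)
  stats::setNames(as.numeric(out), names(out))
}

#' Additive relationship matrix from a feature matrix
#'
#' Drops monomorphic features, features with a missing-value fraction
#' above `missing_max`, and exact duplicate columns (after mean
#' imputation of the remaining missing values); the surviving columns are
#' centered and scaled to unit variance (`W*`), and
#' `G = W* W*^T / m` with `m` the number of surviving features.
#'
#' @param features samples x features numeric matrix
#' @param missing_max maximum tolerated per-feature missing fraction
#'   (default 0.2)
#' @param label predictor label attached to the result
#' @return a list of class `g_matrix` with `G` (n x n), `m` (feature
#'   count used) and `label`
#' @export
build_G <- function(features, missing_max = 0.2, label = "predictor") {
  W <- as.matrix(features)
  if (nrow(W) < 2L) stop("need at least 2 samples")
  miss <- colMeans(is.na(W))
  W <- W[, miss <= missing_max, drop = FALSE]
  if (anyNA(W)) {
    mu <- colMeans(W, na.rm = TRUE)
    idx <- which(is.na(W), arr.ind = TRUE)
    W[idx] <- mu[idx[, 2]]
  }
  sds <- apply(W, 2L, stats::sd)
  W <- W[, sds > 0, drop = FALSE]
  W <- W[, !duplicated(t(W)), drop = FALSE]
  m <- ncol(W)
  if (m == 0L) stop("no informative features survive filtering")
  Ws <- scale(W)
  G <- tcrossprod(Ws) / m
  structure(list(G = G, m = m, label = label), class = "g_matrix")
}

#' GBLUP prediction of test-set genotypic values
#'
#' Estimates variance components by REML on the training samples
#' (spectral decomposition of the training block of `G`), then predicts
#' the test genomic values from the train/test blocks:
#' `u_test = G_ts (G_tt + (se^2/sg^2) I)^{-1} (y_train - mu)`.
#'
#' @param G n x n relationship matrix (a `g_matrix` or plain matrix)
#' @param y phenotype vector (adjusted entry means) over all n samples
#' @param train_idx,test_idx disjoint index vectors into `y`
#' @return numeric vector of predictions for `test_idx`
#' @export
gblup_predict <- function(G, y, train_idx, test_idx) {
  if (inherits(G, "g_matrix")) G <- G$G
  if (length(intersect(train_idx, test_idx)) > 0L)
    stop("train and test sets must be disjoint")
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-6 * max(abs(ev)))
    stop("relationship matrix is not positive semi-definite")
  ytr <- y[train_idx]
  if (stats::sd(ytr) == 0) stop("zero phenotypic variance in training set")
  Gtt <- G[train_idx, train_idx, drop = FALSE]
  fit <- reml_kernel(ytr, matrix(1, length(ytr), 1L), Gtt)
  mu <- fit$beta[1]
  if (fit$sigma_g2 <= 0 || fit$lambda < 1e-12)
    return(rep(mu, length(test_idx)))
  shrink <- fit$sigma_e2 / fit$sigma_g2
  u <- G[test_idx, train_idx, drop = FALSE] %*%
    solve(Gtt + shrink * diag(length(train_idx)), ytr - mu)
  as.numeric(mu + u)
}

#' Enumerate kernel weight triples on a grid
#'
#' All triples `(w1, w2, w3)` with entries on `seq(0, 1, step)` summing
#' to 1. At step 0.1 this yields 66 combinations.
#'
#' @param step grid step in `(0, 1]`; must divide 1
#' @return data frame `w1`, `w2`, `w3`
#' @export
enumerate_weight_grid <- function(step = 0.1) {
  if (step <= 0 || step > 1) stop("step must lie in (0, 1]")
  k <- round(1 / step)
  if (abs(k * step - 1) > 1e-8) stop("step must divide 1")
  rows <- list()
  for (i in 0:k) for (j in 0:(k - i))
    rows[[length(rows) + 1L]] <- c(i, j, k - i - j) / k
  m <- do.call(rbind, rows)
  data.frame(w1 = m[, 1], w2 = m[, 2], w3 = m[, 3])
}

#' Weighted sum of relationship matrices
#'
#' @param Gs list of `g_matrix` objects (or plain matrices) over the same
#'   samples
#' @param w numeric weight vector, same length as `Gs`, summing to 1
#' @return a `g_matrix` with the weighted kernel
#' @export
build_weighted_G <- function(Gs, w) {
  if (length(Gs) != length(w)) stop("one weight per matrix required")
  if (abs(sum(w) - 1) > 1e-8) stop("weights must sum to 1")
  mats <- lapply(Gs, function(g) if (inherits(g, "g_matrix")) g$G else g)
  G <- Reduce(`+`, Map(`*`, mats, w))
  labs <- vapply(Gs, function(g)
    if (inherits(g, "g_matrix")) g$label else "G", character(1))
  structure(list(G = G,
                 m = sum(vapply(Gs, function(g)
                   if (inherits(g, "g_matrix")) g$m else NA_integer_,
                   numeric(1))),
                 label = paste(sprintf("%.1f*%s", w, labs),
                               collapse = " + ")),
            class = "g_matrix")
}

#' Replicated k-fold cross-validation of GBLUP prediction ability
#'
#' Per replicate, samples are partitioned into `k` folds whose sizes
#' differ by at most one; the prediction ability is the Pearson
#' correlation between observed and predicted values within each
#' validation fold. The per-replicate summary is the median over folds
#' and the overall summary the median of the per-replicate medians.
#' Replicate `r` uses seed `seed + r`, so results are reproducible and
#' replicates are independent of `n_rep`.
#'
#' @param G relationship matrix (`g_matrix` or plain matrix)
#' @param y phenotype vector
#' @param k number of folds (default 5)
#' @param n_rep number of replicates (default 200)
#' @param seed base seed
#' @param predictor prediction function with the signature of
#'   [gblup_predict()]
#' @return a list of class `cv_result` with `ability` (overall median of
#'   medians), `replicate_medians`, and `folds` (data frame `replicate`,
#'   `fold`, `ability`)
#' @export
cross_validate <- function(G, y, k = 5L, n_rep = 200L, seed = 1L,
                           predictor = gblup_predict) {
  n <- length(y)
  if (n < k) stop("sample count must be at least k")
  sizes <- rep(floor(n / k), k)
  extra <- n - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  if (min(sizes) < 3L)
    stop("configuration yields folds with fewer than 3 samples")
  rows <- list()
  med <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    set.seed(seed + r)
    perm <- sample.int(n)
    stops <- cumsum(sizes)
    starts <- c(1L, utils::head(stops, -1L) + 1L)
    ab <- numeric(k)
    for (f in seq_len(k)) {
      test <- perm[starts[f]:stops[f]]
      train <- setdiff(seq_len(n), test)
      pred <- predictor(G, y, train, test)
      ab[f] <- if (stats::sd(pred) == 0 || stats::sd(y[test]) == 0)
        0 else stats::cor(y[test], pred)
      rows[[length(rows) + 1L]] <-
        data.frame(replicate = r, fold = f, ability = ab[f])
    }
    med[r] <- stats::median(ab)
  }
  structure(list(ability = stats::median(med), replicate_medians = med,
                 folds = do.call(rbind, rows)),
            class = "cv_result")
}

#' Grid search over joined weighted relationship matrices
#'
#' Evaluates every weight triple on the grid by replicated k-fold
#' cross-validation and returns the triple with the highest overall
#' ability. Ties are resolved towards the larger weight for the
#' first-listed kernel (then the second).
#'
#' @param Gs list of exactly 3 `g_matrix` objects
#' @param y phenotype vector
#' @param step weight grid step (default 0.1)
#' @param ... passed to [cross_validate()] (`k`, `n_rep`, `seed`)
#' @return a list with `best` (row of the grid plus ability) and
#'   `surface` (grid with the ability per triple)
#' @export
grid_search_weights <- function(Gs, y, step = 0.1, ...) {
  if (length(Gs) != 3L) stop("exactly 3 kernels required")
  grid <- enumerate_weight_grid(step)
  grid$ability <- vapply(seq_len(nrow(grid)), function(i) {
    Gw <- build_weighted_G(Gs, as.numeric(grid[i, c("w1", "w2", "w3")]))
    cross_validate(Gw, y, ...)$ability
  }, numeric(1))
  ord <- order(-grid$ability, -grid$w1, -grid$w2)
  list(best = grid[ord[1], ], surface = grid)
}
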