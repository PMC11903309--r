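# Post-hoc analysis: classical MDS, hierarchical clustering of condition
# distances, and generic decoders (optimal linear estimation, k-NN).

#' Classical MDS of a condition distance matrix
#'
#' Treats the optimal-transport costs as squared dissimilarities
#' (consistent with the squared-Euclidean ground cost), double-centres
#' \eqn{-D/2} and returns the leading eigenvector coordinates. Warns when
#' the negative eigenvalue mass exceeds 20% of the spectrum's l1 norm
#' (strongly non-Euclidean input).
#'
#' @param D symmetric matrix with zero diagonal ([condition_distances]
#'   output or similar).
#' @param dims embedding dimension.
#' @return `C x dims` coordinate matrix (rows named as `D`).
#' @export
mds_embed <- function(D, dims = 2) {
  D <- unclass(as.matrix(D))
  stopifnot(isSymmetric(unname(D), tol = 1e-6), all(abs(diag(D)) < 1e-8))
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% D %*% J
  ev <- eigen((B + t(B)) / 2, symmetric = TRUE)
  neg_mass <- sum(pmax(-ev$values, 0))
  if (neg_mass > 0.2 * sum(abs(ev$values)))
    warning("distance matrix strongly non-Euclidean (negative eigenvalue ",
            "mass ", round(100 * neg_mass / sum(abs(ev$values))), "%)")
  lam <- pmax(ev$values[seq_len(dims)], 0)
  coords <- ev$vectors[, seq_len(dims), drop = FALSE] %*%
    diag(sqrt(lam), dims)
  rownames(coords) <- rownames(D)
  coords
}

#' Hierarchical clustering of conditions
#'
#' Agglomerative clustering on the condition distance matrix (average
#' linkage by default), cut at `k` clusters.
#'
#' @param D symmetric distance matrix over conditions.
#' @param k number of clusters (`1 <= k <= C`).
#' @param linkage linkage criterion passed to [stats::hclust].
#' @return List of class `cluster_result`: `labels` (1..k per condition),
#'   `tree` (the `hclust` object), `k`.
#' @export
cluster_conditions <- function(D, k, linkage = "average") {
  D <- unclass(as.matrix(D))
  if (k < 1) stop("k must be at least 1")
  if (k > nrow(D)) stop("k exceeds the number of conditions")
  tree <- stats::hclust(stats::as.dist(D), method = linkage)
  labels <- stats::cutree(tree, k = k)
  structure(list(labels = labels, tree = tree, k = k),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Hierarchical clustering: %d conditions cut at k = %d\n",
              length(x$labels), x$k))
  print(x$labels)
  invisible(x)
}

#' Boundary of a two-way split along an ordered condition sweep
#'
#' Cuts the hierarchical clustering of a condition distance matrix into two
#' clusters, reduces the labels to the best contiguous split along the
#' supplied parameter ordering (maximising agreement with the cluster
#' labels), and reports the midpoint between the two parameter values at
#' the split. Used to locate abrupt dynamical changes (bifurcations) along
#' a parameter sweep.
#'
#' @param D condition distance matrix, rows ordered or orderable by
#'   `values`.
#' @param values numeric parameter value per condition.
#' @param linkage linkage criterion for [cluster_conditions].
#' @return List: `boundary` (parameter midpoint at the split), `split`
#'   (index of the last condition in the first block), `agreement`
#'   (fraction of conditions consistent with the contiguous split), and
#'   `labels`.
#' @export
split_boundary <- function(D, values, linkage = "average") {
  stopifnot(length(values) == nrow(as.matrix(D)))
  ord <- order(values)
  Dm <- unclass(as.matrix(D))[ord, ord]
  vals <- values[ord]
  cl <- cluster_conditions(Dm, 2, linkage = linkage)$labels
  C <- length(vals)
  agree <- vapply(seq_len(C - 1), function(s) {
    lab <- c(rep(1, s), rep(2, C - s))
    max(mean(lab == cl), mean(lab == (3 - cl)))
  }, numeric(1))
  s <- which.max(agree)
  list(boundary = (vals[s] + vals[s + 1]) / 2, split = s,
       agreement = agree[s], labels = cl)
}

#' Optimal linear estimation decoder
#'
#' Least-squares affine map from latent vectors to continuous targets,
#' with a ridge fallback (`lambda = 1e-6`) if the design is
#' rank-deficient. `cv_r2` reports k-fold cross-validated goodness of fit.
#'
#' @param Z `n x E` latent matrix.
#' @param targets `n x q` matrix (or vector) of decoding targets.
#' @return Object of class `linear_decoder` with a `predict` method.
#' @export
fit_linear_decoder <- function(Z, targets) {
  Z <- as.matrix(Z); targets <- as.matrix(targets)
  n <- nrow(Z)
  if (n < ncol(Z) + 1) stop("need at least E + 1 samples")
  X <- cbind(1, Z)
  XtX <- crossprod(X)
  B <- tryCatch({
    if (rcond(XtX) < 1e-12) stop("rank deficient")
    solve(XtX, crossprod(X, targets))
  }, error = function(e) {
    warning("rank-deficient design; ridge fallback (lambda = 1e-6)")
    solve(XtX + 1e-6 * diag(ncol(X)), crossprod(X, targets))
  })
  structure(list(coefficients = B), class = "linear_decoder")
}

#' @export
predict.linear_decoder <- function(object, newdata, ...) {
  cbind(1, as.matrix(newdata)) %*% object$coefficients
}

#' Cross-validated decoding accuracy
#'
#' Fits the linear decoder on `folds - 1` folds and evaluates R-squared
#' (variance-weighted across target columns) on the held-out fold,
#' repeating for every fold; reports the mean.
#'
#' @param Z latent matrix; `targets` decoding targets.
#' @param folds number of folds (default 10).
#' @param seed seed for the fold split.
#' @return Mean cross-validated R-squared.
#' @export
cv_r2 <- function(Z, targets, folds = 10, seed = 1) {
  Z <- as.matrix(Z); targets <- as.matrix(targets)
  n <- nrow(Z)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(folds), n))
  r2 <- vapply(seq_len(folds), function(f) {
    tr <- fold != f
    dec <- suppressWarnings(fit_linear_decoder(Z[tr, , drop = FALSE],
                                               targets[tr, , drop = FALSE]))
    pred <- predict(dec, Z[!tr, , drop = FALSE])
    obs <- targets[!tr, , drop = FALSE]
    1 - sum((obs - pred)^2) /
      sum(sweep(obs, 2, colMeans(obs))^2)
  }, numeric(1))
  mean(r2)
}

#' k-nearest-neighbour decoder
#'
#' Predicts continuous labels as the mean label of the `k` nearest
#' training embeddings under a cosine or Euclidean metric.
#'
#' @param Z_train,y_train training embeddings and labels.
#' @param Z_test query embeddings.
#' @param k neighbour count (`1 <= k <= n_train`).
#' @param metric `"cosine"` or `"euclidean"`.
#' @return Matrix (or vector) of predictions, one row per query.
#' @export
knn_decoder <- function(Z_train, y_train, Z_test, k = 36,
                        metric = c("cosine", "euclidean")) {
  metric <- match.arg(metric)
  Z_train <- as.matrix(Z_train); Z_test <- as.matrix(Z_test)
  y_train <- as.matrix(y_train)
  if (k < 1) stop("k must be at least 1")
  if (k > nrow(Z_train)) stop("k exceeds the training size")
  if (metric == "cosine") {
    nr <- sqrt(rowSums(Z_train^2)); nr[nr == 0] <- 1
    nq <- sqrt(rowSums(Z_test^2)); nq[nq == 0] <- 1
    S <- tcrossprod(Z_test / nq, Z_train / nr)
    D <- 1 - S
  } else {
    D <- outer(rowSums(Z_test^2), rep(1, nrow(Z_train))) +
      outer(rep(1, nrow(Z_test)), rowSums(Z_train^2)) -
      2 * tcrossprod(Z_test, Z_train)
  }
  pred <- t(apply(D, 1, function(dr) {
    nb <- order(dr)[seq_len(k)]
    colMeans(y_train[nb, , drop = FALSE])
  }))
  if (ncol(y_train) == 1) pred <- drop(pred)
  pred
}

#' Mean absolute error
#'
#' @param pred,obs predictions and observations.
#' @return Scalar MAE.
#' @export
mae <- function(pred, obs) mean(abs(as.matrix(pred) - as.matrix(obs)))
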