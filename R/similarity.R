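# Optimal-transport similarity between latent empirical distributions.

#' Optimal-transport distance between two latent point clouds
#'
#' Treats the rows of `Z1`, `Z2` as empirical distributions with uniform
#' weights and computes the minimum transport cost
#' \eqn{\min_\gamma \sum_{uv} \gamma_{uv} \|z_u - z_v\|_2^2} subject to
#' uniform marginals. The reported value is the transport cost itself
#' (squared-Euclidean ground cost), not its square root.
#'
#' The exact solver requires equal cloud sizes (the optimum is then a
#' permutation, found by a shortest-augmenting-path assignment algorithm);
#' unequal or oversized clouds are uniformly subsampled to
#' `min(n1, n2, max_n)` points under the recorded seed. An entropic
#' (Sinkhorn) solver is available as an opt-in approximation.
#'
#' @param Z1,Z2 numeric matrices with matching column count `E`.
#' @param method `"exact"` (default) or `"sinkhorn"`.
#' @param epsilon entropic regularisation strength (Sinkhorn only).
#' @param max_n exact-solver size cap; larger clouds are subsampled.
#' @param seed seed used for any subsampling (recorded in attributes).
#' @return Non-negative scalar with attributes `n` (cloud size used),
#'   `method`, and `seed` when subsampling occurred.
#' @export
ot_distance <- function(Z1, Z2, method = c("exact", "sinkhorn"),
                        epsilon = 0.01, max_n = 2000, seed = 1) {
  method <- match.arg(method)
  Z1 <- as.matrix(Z1); Z2 <- as.matrix(Z2)
  if (nrow(Z1) < 1 || nrow(Z2) < 1) stop("empty point cloud")
  if (ncol(Z1) != ncol(Z2)) stop("latent dimensions differ")
  n <- min(nrow(Z1), nrow(Z2), max_n)
  sub <- (nrow(Z1) != n) || (nrow(Z2) != n)
  if (sub) {
    set.seed(seed)
    if (nrow(Z1) > n) Z1 <- Z1[sample.int(nrow(Z1), n), , drop = FALSE]
    if (nrow(Z2) > n) Z2 <- Z2[sample.int(nrow(Z2), n), , drop = FALSE]
  }
  C <- outer(rowSums(Z1^2), rep(1, n)) + outer(rep(1, n), rowSums(Z2^2)) -
    2 * tcrossprod(Z1, Z2)
  C[C < 0] <- 0
  if (method == "exact") {
    match <- solve_assignment_cpp(C)
    val <- mean(C[cbind(seq_len(n), match)])
  } else {
    val <- .sinkhorn_cost(C, epsilon)
  }
  structure(val, n = n, method = method,
            seed = if (sub) seed else NULL, epsilon =
              if (method == "sinkhorn") epsilon else NULL)
}

# log-domain Sinkhorn on uniform marginals; returns transport cost of the
# (entropically) optimal plan
.sinkhorn_cost <- function(C, epsilon, max_iter = 2000, tol = 1e-9) {
  n1 <- nrow(C); n2 <- ncol(C)
  loga <- -log(n1); logb <- -log(n2)
  f <- numeric(n1); g <- numeric(n2)
  K <- -C / epsilon
  lse <- function(M) {  # row-wise log-sum-exp
    mx <- apply(M, 1, max)
    mx + log(rowSums(exp(M - mx)))
  }
  for (it in seq_len(max_iter)) {
    f_new <- epsilon * (loga - lse(sweep(K, 2, g / epsilon, `+`)))
    g_new <- epsilon * (logb - lse(t(sweep(K, 1, f_new / epsilon, `+`))))
    if (max(abs(f_new - f)) < tol && max(abs(g_new - g)) < tol) {
      f <- f_new; g <- g_new; break
    }
    f <- f_new; g <- g_new
  }
  P <- exp(sweep(sweep(K, 1, f / epsilon, `+`), 2, g / epsilon, `+`))
  sum(P * C)
}

#' Pairwise optimal-transport distances between conditions
#'
#' @param x a [flowrep] fit or a named list of latent matrices.
#' @param ... passed to [ot_distance].
#' @return Symmetric `C x C` matrix of class `flow_dist` with condition
#'   labels as dimnames, zero diagonal, and solver metadata attributes.
#' @export
condition_distances <- function(x, ...) {
  Zs <- if (inherits(x, "flowrep")) x$embeddings else x
  stopifnot(is.list(Zs), length(Zs) >= 2)
  labs <- names(Zs)
  if (is.null(labs)) labs <- paste0("c", seq_along(Zs))
  C <- length(Zs)
  D <- matrix(0, C, C, dimnames = list(labs, labs))
  failed <- matrix(FALSE, C, C)
  for (a in seq_len(C - 1)) for (b in (a + 1):C) {
    v <- tryCatch(ot_distance(Zs[[a]], Zs[[b]], ...),
                  error = function(e) NA_real_)
    if (is.na(v)) failed[a, b] <- failed[b, a] <- TRUE
    D[a, b] <- D[b, a] <- as.numeric(v)
  }
  structure(D, class = c("flow_dist", "matrix"), failed = failed)
}

#' @export
print.flow_dist <- function(x, digits = 4, ...) {
  cat("Optimal-transport distance matrix (squared-Euclidean ground cost)\n")
  m <- unclass(x)
  attr(m, "failed") <- NULL
  print(round(m, digits))
  if (any(attr(x, "failed")))
    cat("(entries flagged as failed solver runs are reported as NA)\n")
  invisible(x)
}
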