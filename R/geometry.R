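# Manifold scaffold: farthest-point subsampling, continuous k-NN proximity
# graph, tangent frames, parallel-transport connections, connection Laplacian.

#' Farthest-point subsampling of a point cloud
#'
#' Greedy farthest-point ordering from a deterministic start (the first
#' point). Points are retained until every remaining candidate lies within
#' `alpha * diam` of the kept set, so `alpha` sets the spacing relative to
#' the diameter of the cloud; `alpha = 0` performs no subsampling and
#' returns all indices in their original order.
#'
#' @param X numeric matrix of points (rows).
#' @param alpha spacing parameter in `[0, 1]`.
#' @return Integer vector of retained row indices.
#' @export
subsample_farthest_point <- function(X, alpha) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= 1)
  if (length(alpha) != 1 || !is.finite(alpha) || alpha < 0 || alpha > 1)
    stop("alpha must lie in [0, 1]")
  if (alpha == 0 || n == 1L) return(seq_len(n))
  # diameter: exact for small n, double-sweep estimate otherwise
  diam <- if (n <= 3000) {
    max(dist(X))
  } else {
    ctr <- colMeans(X)
    i1 <- which.max(rowSums(sweep(X, 2, ctr)^2))
    max(sqrt(rowSums(sweep(X, 2, X[i1, ])^2)))
  }
  thr <- alpha * diam
  kept <- 1L
  d2 <- rowSums(sweep(X, 2, X[1L, ])^2)  # squared dist to kept set
  repeat {
    i <- which.max(d2)
    if (sqrt(d2[i]) <= thr) break
    kept <- c(kept, i)
    d2 <- pmin(d2, rowSums(sweep(X, 2, X[i, ])^2))
  }
  kept
}

#' Continuous k-nearest-neighbour proximity graph
#'
#' Connects points `i` and `j` whenever
#' \eqn{\|x_i - x_j\|^2 < \delta \|x_i - x_u\| \|x_j - x_v\|}, where `u`, `v`
#' are the k-th nearest neighbours of `i` and `j`. Unlike a plain k-NN graph
#' this rule adapts to local sampling density. A warning is issued if the
#' graph is disconnected or has isolated nodes; downstream steps proceed per
#' connected component.
#'
#' @param X numeric matrix of points.
#' @param k neighbour count for the local scale (`n > k >= 1`).
#' @param delta scale parameter, `delta >= 1` typically.
#' @return Object of class `proximity_graph` with components `edges`
#'   (two-column matrix, `i < j`), `adj` (sparse adjacency), `graph`
#'   (igraph), `component` (per-node membership), and the points `X`.
#' @export
build_proximity_graph <- function(X, k = 15, delta = 1.0) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n > k, k >= 1, delta > 0)
  D <- as.matrix(dist(X))
  # distance to the k-th nearest neighbour (self excluded)
  rk <- apply(D, 1L, function(r) sort(r)[k + 1L])
  thr <- delta * outer(rk, rk)
  A <- (D^2 < thr)
  diag(A) <- FALSE
  A <- A | t(A)  # the rule is symmetric already; guard numerics
  edges <- which(A & upper.tri(A), arr.ind = TRUE)
  colnames(edges) <- c("i", "j")
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  comp <- igraph::components(g)
  deg <- igraph::degree(g)
  if (any(deg == 0))
    warning(sum(deg == 0), " isolated node(s) in proximity graph")
  if (comp$no > 1L)
    warning("proximity graph has ", comp$no,
            " connected components; processing per component")
  nbrs <- lapply(seq_len(n), function(i) which(A[i, ]))
  structure(list(X = X, edges = edges,
    adj = Matrix::Matrix(A, sparse = TRUE), nbrs = nbrs,
    graph = g, component = comp$membership, degree = deg,
    k = k, delta = delta, n = n),
    class = "proximity_graph")
}

#' @export
print.proximity_graph <- function(x, ...) {
  cat(sprintf(
    "Proximity graph: %d nodes, %d edges (ck-NN, k = %d, delta = %g)\n",
    x$n, nrow(x$edges), x$k, x$delta))
  invisible(x)
}

# neighbours of i ordered by (hop distance, Euclidean distance, index)
.ordered_neighbourhood <- function(graph, i, K) {
  n <- graph$n
  hops <- as.numeric(igraph::distances(graph$graph, v = i, mode = "all"))
  cand <- setdiff(which(is.finite(hops)), i)
  if (!length(cand)) return(integer(0))
  eu <- sqrt(rowSums(sweep(graph$X[cand, , drop = FALSE], 2, graph$X[i, ])^2))
  cand <- cand[order(hops[cand], eu, cand)]
  head(cand, K)
}

#' Fit orthonormal tangent frames at every node
#'
#' The tangent space at node `i` is estimated from the `K` nearest nodes on
#' the graph (ordered by hop distance, then Euclidean distance, then index):
#' edge vectors are column-stacked and the top `m` left singular vectors
#' span the frame. `K` defaults per node to `ceiling(1.5 * degree)`, a
#' compromise between locality and robustness.
#' When `m == d` the tangent space is the whole ambient space and the
#' identity basis is used at every node (the same span as the SVD basis,
#' but globally consistent, so all connections become the identity).
#'
#' The within-subspace basis of an SVD is an arbitrary gauge — near-equal
#' singular values make it numerically unstable, and the raw LAPACK basis
#' is not equivariant under rotations of the data. When `orient_field` is
#' supplied, the basis is re-anchored to the data: the first direction is
#' the tangent projection of the locally averaged field, subsequent
#' directions are fixed against the neighbourhood's mean edge vector (both
#' rotate with the data, so the whole construction is
#' rotation-equivariant); without it, a deterministic sign convention
#' (largest-magnitude entry of each column positive) is applied.
#'
#' @param graph a [build_proximity_graph] result.
#' @param m intrinsic manifold dimension (`1 <= m <= d`).
#' @param K neighbour count for the fit; `NULL` for the per-node default.
#' @param orient_field optional `n x d` matrix of anchored vectors used to
#'   fix the in-plane gauge equivariantly (typically the vector field that
#'   will be analysed on the bundle).
#' @return Object of class `tangent_bundle`: list of `d x m` frames plus
#'   bookkeeping (`m`, `degenerate` flags).
#' @export
fit_tangent_frames <- function(graph, m = 2, K = NULL, orient_field = NULL) {
  stopifnot(inherits(graph, "proximity_graph"))
  d <- ncol(graph$X)
  stopifnot(m >= 1, m <= d)
  n <- graph$n
  frames <- vector("list", n)
  degenerate <- logical(n)
  shrunk <- FALSE
  if (m == d && is.null(orient_field)) {
    # the tangent space is the whole ambient space; any orthonormal basis
    # spans it, so use the identity gauge everywhere (deterministic and
    # globally consistent, so connections are exactly the identity)
    frames <- replicate(n, diag(d), simplify = FALSE)
    return(structure(list(frames = frames, m = m, K = K,
                          degenerate = degenerate),
                     class = "tangent_bundle"))
  }
  for (i in seq_len(n)) {
    Ki <- if (is.null(K)) max(m, ceiling(1.5 * graph$degree[i])) else K
    nb <- .ordered_neighbourhood(graph, i, Ki)
    if (length(nb) < Ki) shrunk <- TRUE
    if (length(nb) == 0L) {
      frames[[i]] <- matrix(0, d, m); degenerate[i] <- TRUE; next
    }
    if (m == d) {
      Ti <- diag(d)
      take <- m
    } else {
      E <- t(graph$X[nb, , drop = FALSE]) - graph$X[i, ]  # d x |nb|
      sv <- svd(E, nu = min(d, length(nb)))
      r <- sum(sv$d > max(sv$d[1], 1e-300) * 1e-10)
      if (r < m) degenerate[i] <- TRUE
      Ti <- matrix(0, d, m)
      take <- min(m, ncol(sv$u))
      Ti[, seq_len(take)] <- sv$u[, seq_len(take)]
    }
    if (!is.null(orient_field) && take == m) {
      # data-derived anchor directions, all rotation-equivariant: position
      # relative to the cloud centroid, then the locally averaged field,
      # then the neighbourhood's mean edge vector
      anchors <- rbind(graph$X[i, ] - colMeans(graph$X),
                       colMeans(orient_field[c(i, nb), , drop = FALSE]),
                       colMeans(graph$X[nb, , drop = FALSE]) - graph$X[i, ])
      # m < d: keep the principal axes, orient their signs equivariantly;
      # m == d: the axes themselves must rotate with the data
      Ti <- if (m == d) .orient_frame(Ti, anchors)
            else .orient_signs(Ti, anchors)
    } else {
      Ti <- .sign_fix(Ti)
    }
    frames[[i]] <- Ti
  }
  if (shrunk)
    warning("neighbourhood smaller than K for some nodes; frames fitted on ",
            "available neighbours")
  if (any(degenerate))
    warning(sum(degenerate), " node(s) with rank-deficient tangent fit")
  structure(list(frames = frames, m = m, K = K, degenerate = degenerate),
            class = "tangent_bundle")
}

#' @export
print.tangent_bundle <- function(x, ...) {
  d <- nrow(x$frames[[1]])
  cat(sprintf("Tangent bundle: %d frames (%d x %d), %d degenerate\n",
              length(x$frames), d, x$m, sum(x$degenerate)))
  invisible(x)
}

#' Parallel-transport connections between adjacent frames
#'
#' For every edge, the orthogonal matrix (rotation or reflection) best
#' aligning the two frames in the Frobenius sense,
#' \eqn{O_{ji} = \arg\min_{O \in O(m)} \|T_i - T_j O\|_F}, computed by the
#' Kabsch algorithm (SVD of \eqn{T_j^\top T_i}). The stored matrix per edge
#' `(i, j)` (with `i < j`) is \eqn{O_{ij} = O_{ji}^\top}, which transports
#' tangent coordinates from frame `j` into frame `i`.
#'
#' @param bundle a [fit_tangent_frames] result.
#' @param graph the matching proximity graph.
#' @return Object of class `connections`: list of `m x m` orthogonal
#'   matrices aligned with `graph$edges`, plus a `flagged` logical for edges
#'   with near-orthogonal tangent spaces (identity fallback).
#' @export
# neighbourhood averaging of an ambient vector field (used to stabilise
# the orientation anchors near fixed points; rotation-equivariant)
.smooth_field <- function(graph, V, rounds = 3) {
  V <- as.matrix(V)
  for (r in seq_len(rounds)) {
    V2 <- V
    for (i in seq_len(graph$n)) {
      nb <- graph$nbrs[[i]]
      if (length(nb))
        V2[i, ] <- colMeans(V[c(i, nb), , drop = FALSE])
    }
    V <- V2
  }
  V
}

# deterministic sign convention: largest-|entry| element of each column
# made positive
.sign_fix <- function(Ti) {
  for (q in seq_len(ncol(Ti))) {
    col <- Ti[, q]
    if (any(col != 0)) {
      piv <- which.max(abs(col))
      if (col[piv] < 0) Ti[, q] <- -col
    }
  }
  Ti
}

# equivariant sign convention: orient each basis column by the first
# anchor direction it is not orthogonal to (anchors rotate with the data,
# so the signed basis does too when the principal axes are non-degenerate)
.orient_signs <- function(U, anchors) {
  for (q in seq_len(ncol(U))) {
    for (k in seq_len(nrow(anchors))) {
      dp <- sum(U[, q] * anchors[k, ])
      if (abs(dp) > 1e-8 * max(sqrt(sum(anchors[k, ]^2)), 1e-300)) {
        if (dp < 0) U[, q] <- -U[, q]
        break
      }
    }
  }
  U
}

# re-anchor the within-subspace basis to data-derived directions (rows of
# `anchors`, in priority order): Gram-Schmidt of their tangent projections.
# Directions the anchors cannot fix are completed from the SVD basis with
# the sign convention.
.orient_frame <- function(U, anchors) {
  m <- ncol(U)
  G <- matrix(0, m, 0)
  for (k in seq_len(nrow(anchors))) {
    if (ncol(G) == m) break
    a <- crossprod(U, anchors[k, ])
    if (ncol(G) > 0) a <- a - G %*% crossprod(G, a)
    na <- sqrt(sum(a^2))
    if (na > 1e-10 * max(sqrt(sum(anchors[k, ]^2)), 1e-300))
      G <- cbind(G, a / na)
  }
  if (ncol(G) < m) {
    # complete with the remaining subspace directions, sign-fixed
    for (q in seq_len(m)) {
      if (ncol(G) == m) break
      e <- diag(m)[, q]
      if (ncol(G) > 0) e <- e - G %*% crossprod(G, e)
      ne <- sqrt(sum(e^2))
      if (ne > 1e-8) G <- cbind(G, e / ne)
    }
    return(.sign_fix(U %*% G))
  }
  U %*% G
}

# Kabsch solution of argmin_{O in O(m)} ||Ti - Tj O||_F
.kabsch <- function(Ti, Tj) {
  sv <- svd(crossprod(Tj, Ti))
  sv$u %*% t(sv$v)
}

compute_connections <- function(bundle, graph) {
  stopifnot(inherits(bundle, "tangent_bundle"),
            inherits(graph, "proximity_graph"))
  m <- bundle$m
  ne <- nrow(graph$edges)
  O <- vector("list", ne)
  flagged <- logical(ne)
  for (e in seq_len(ne)) {
    i <- graph$edges[e, 1L]; j <- graph$edges[e, 2L]
    C <- crossprod(bundle$frames[[j]], bundle$frames[[i]])  # T_j' T_i
    if (min(svd(C)$d) < 1e-12) {
      flagged[e] <- TRUE
      O[[e]] <- diag(m)
    } else {
      Oji <- .kabsch(bundle$frames[[i]], bundle$frames[[j]])
      O[[e]] <- t(Oji)            # O_ij: frame-j coords -> frame-i coords
    }
  }
  if (any(flagged))
    warning(sum(flagged), " edge(s) with ill-conditioned alignment; ",
            "identity connection used")
  structure(list(O = O, edges = graph$edges, m = m, flagged = flagged),
            class = "connections")
}

# transport matrix taking frame-`from` coordinates into frame-`to`
# coordinates, for adjacent nodes
.transport <- function(conn, to, from) {
  if (to == from) return(diag(conn$m))
  e <- which((conn$edges[, 1L] == min(to, from)) &
               (conn$edges[, 2L] == max(to, from)))
  if (!length(e)) stop("nodes ", to, " and ", from, " are not adjacent")
  Oij <- conn$O[[e[1L]]]
  if (to < from) Oij else t(Oij)
}

#' Random-walk normalised connection Laplacian
#'
#' Block-sparse `nm x nm` operator with identity diagonal blocks and
#' off-diagonal blocks \eqn{-\mathrm{deg}(i)^{-1} O_{ij}} for each neighbour
#' `j` of `i`. It generates vector diffusion: smoothing of tangent vector
#' fields that respects parallel transport (and hence preserves fixed-point
#' structure). Node `i` occupies rows `(i-1)*m + 1:m`.
#'
#' @param graph a proximity graph.
#' @param conn matching [compute_connections] result.
#' @return A sparse `Matrix::dgCMatrix` of class also `connection_laplacian`.
#' @export
connection_laplacian <- function(graph, conn) {
  stopifnot(inherits(graph, "proximity_graph"), inherits(conn, "connections"))
  if (nrow(conn$edges) != nrow(graph$edges))
    stop("connections do not match graph edges")
  m <- conn$m; n <- graph$n
  deg <- graph$degree
  ii <- jj <- xx <- vector("list", 2L * nrow(graph$edges) + 1L)
  blk <- function(i) ((i - 1L) * m + 1L):(i * m)
  # identity diagonal
  ii[[1L]] <- seq_len(n * m); jj[[1L]] <- seq_len(n * m)
  xx[[1L]] <- rep(1, n * m)
  idx <- 2L
  grid <- as.matrix(expand.grid(r = seq_len(m), c = seq_len(m)))
  for (e in seq_len(nrow(graph$edges))) {
    i <- graph$edges[e, 1L]; j <- graph$edges[e, 2L]
    Oij <- conn$O[[e]]          # j -> i
    ii[[idx]] <- (i - 1L) * m + grid[, "r"]
    jj[[idx]] <- (j - 1L) * m + grid[, "c"]
    xx[[idx]] <- -Oij[grid] / deg[i]
    idx <- idx + 1L
    Oji <- t(Oij)
    ii[[idx]] <- (j - 1L) * m + grid[, "r"]
    jj[[idx]] <- (i - 1L) * m + grid[, "c"]
    xx[[idx]] <- -Oji[grid] / deg[j]
    idx <- idx + 1L
  }
  L <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n * m, n * m))
  attr(L, "m") <- m
  attr(L, "n") <- n
  L
}
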