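# Local flow field features: tangent projection, vector diffusion,
# directional-derivative (gradient) filters and rotation-invariant
# inner products.

#' Project an ambient vector field into local tangent coordinates
#'
#' \eqn{f'_i = T_i^\top f_i}: the \eqn{\ell_2}-optimal projection of each
#' anchored vector onto the tangent frame at its node.
#'
#' @param field a [vector_field] (its `vectors` are used) or an `n x d`
#'   matrix of vectors.
#' @param bundle a [fit_tangent_frames] result with matching `n`.
#' @return `n x m` matrix of tangent coordinates.
#' @export
project_to_tangent <- function(field, bundle) {
  V <- if (inherits(field, "vector_field")) field$vectors else as.matrix(field)
  stopifnot(inherits(bundle, "tangent_bundle"),
            nrow(V) == length(bundle$frames))
  out <- matrix(0, nrow(V), bundle$m)
  for (i in seq_len(nrow(V)))
    out[i, ] <- crossprod(bundle$frames[[i]], V[i, ])
  out
}

#' Vector diffusion under the connection Laplacian
#'
#' Computes \eqn{\mathrm{vec}(F(\tau)) = e^{-\tau L} \mathrm{vec}(F)} where
#' `L` is the random-walk normalised connection Laplacian. The matrix
#' exponential is never formed: its action is evaluated by scaling plus
#' truncated Taylor series on sparse matrix-vector products (relative
#' tolerance `1e-8`). Unlike scalar heat diffusion, vector diffusion aligns
#' neighbouring vectors through parallel transport, preserving the
#' fixed-point structure of the field.
#'
#' @param Fl `n x m` matrix of tangent-coordinate vectors.
#' @param L connection Laplacian from [connection_laplacian].
#' @param tau diffusion time, `tau >= 0`.
#' @return Diffused `n x m` matrix.
#' @export
vector_diffusion <- function(Fl, L, tau) {
  Fl <- as.matrix(Fl)
  if (length(tau) != 1 || !is.finite(tau) || tau < 0)
    stop("tau must be a non-negative scalar")
  m <- attr(L, "m"); n <- attr(L, "n")
  stopifnot(nrow(Fl) == n, ncol(Fl) == m)
  if (tau == 0) return(Fl)
  v <- as.numeric(t(Fl))  # row-wise concatenation: node blocks of length m
  # ||L||_1 <= 2 for the random-walk normalisation; scale so the per-stage
  # exponent is small, then apply truncated Taylor stages
  s <- max(1L, ceiling(tau * 2))
  h <- tau / s
  for (stage in seq_len(s)) {
    term <- v; acc <- v
    for (k in 1:60) {
      term <- as.numeric(L %*% term) * (-h / k)
      acc <- acc + term
      if (sqrt(sum(term^2)) <= 1e-10 * max(sqrt(sum(acc^2)), 1e-300)) break
    }
    v <- acc
  }
  matrix(v, nrow = n, ncol = m, byrow = TRUE)
}

#' Build directional-derivative filters
#'
#' For each node `i` and each tangent direction `q`, a sparse weight row
#' over the 1-hop neighbourhood implementing the directional derivative
#' along \eqn{t_i^{(q)}}. Weights come from a Gaussian-weighted local linear
#' least-squares fit in tangent coordinates, so the filters are exact on
#' affine fields over flat regions and annihilate constant (parallel)
#' fields. Neighbour values are parallel-transported into frame `i` before
#' the filter is applied, making the result insensitive to local curvature.
#'
#' @param graph proximity graph.
#' @param bundle tangent bundle.
#' @param conn connections for the graph edges.
#' @return Object of class `gradient_kernels`: per node, the neighbour
#'   index set (`i` first) and an `m x |set|` weight matrix; nodes with
#'   under-determined neighbourhoods are flagged and given zero kernels.
#' @export
build_gradient_kernels <- function(graph, bundle, conn) {
  stopifnot(inherits(graph, "proximity_graph"),
            inherits(bundle, "tangent_bundle"),
            inherits(conn, "connections"))
  n <- graph$n; m <- bundle$m
  adj <- lapply(seq_len(n), function(i) which(graph$adj[i, ]))
  kernels <- vector("list", n)
  flagged <- logical(n)
  for (i in seq_len(n)) {
    nb <- adj[[i]]
    idx <- c(i, nb)
    if (length(nb) < m) {
      flagged[i] <- TRUE
      kernels[[i]] <- list(idx = idx,
                           W = matrix(0, m, length(idx)))
      next
    }
    # local coordinates of the neighbourhood in frame i
    B <- sweep(graph$X[nb, , drop = FALSE], 2, graph$X[i, ]) %*%
      bundle$frames[[i]]                       # |nb| x m
    Bc <- rbind(0, B)                          # include the centre point
    r2 <- rowSums(Bc^2)
    eps <- mean(sqrt(r2[-1L]))^2
    w <- exp(-r2 / max(eps, 1e-300))
    Dsg <- cbind(1, Bc)                        # intercept + linear model
    WD <- Dsg * w
    M <- crossprod(Dsg, WD)
    hat <- tryCatch(solve(M, t(WD)), error = function(e) NULL)
    if (is.null(hat)) {
      flagged[i] <- TRUE
      kernels[[i]] <- list(idx = idx, W = matrix(0, m, length(idx)))
      next
    }
    kernels[[i]] <- list(idx = idx, W = hat[-1L, , drop = FALSE])
  }
  if (any(flagged))
    warning(sum(flagged), " node(s) with under-determined derivative fit; ",
            "zero kernels used")
  structure(list(kernels = kernels, m = m, flagged = flagged),
            class = "gradient_kernels")
}

# transported neighbour gather: columns are the channel vectors of idx
# nodes expressed in frame i
.gather_transported <- function(ch, i, idx, conn) {
  m <- ncol(ch)
  out <- matrix(0, m, length(idx))
  for (s in seq_along(idx)) {
    j <- idx[s]
    out[, s] <- if (j == i) ch[i, ] else .transport(conn, i, j) %*% ch[j, ]
  }
  out
}

# one application of the m directional derivatives to a single vector
# channel (n x m): returns a list of m new channels
.apply_gradient <- function(ch, kernels, conn) {
  n <- nrow(ch); m <- ncol(ch)
  new <- lapply(seq_len(m), function(q) matrix(0, n, m))
  for (i in seq_len(n)) {
    kr <- kernels$kernels[[i]]
    TC <- .gather_transported(ch, i, kr$idx, conn)   # m x |idx|
    D <- TC %*% t(kr$W)                              # m x m: col q = D^(q)
    for (q in seq_len(m)) new[[q]][i, ] <- D[, q]
  }
  new
}

#' Number of gradient-augmented channels
#'
#' Closed form \eqn{c = \sum_{k=0}^{p} m^k = (1 - m^{p+1})/(1 - m)} (equal
#' to `p + 1` when `m = 1`).
#'
#' @param m manifold dimension.
#' @param p filter order.
#' @return Integer channel count.
#' @export
channel_count <- function(m, p) {
  stopifnot(m >= 1, p >= 0)
  sum(m^(0:p))
}

#' Gradient feature stack
#'
#' Iterated application of the `m` directional-derivative filters to the
#' tangent field produces channels \eqn{(f, \nabla f_\cdot,
#' \nabla(\nabla f_\cdot)_\cdot, \ldots)} up to order `p`: the coefficients
#' of the best local polynomial approximation of the flow field around each
#' node. All channels at node `i` live in the tangent frame at `i`.
#'
#' @param Fl `n x m` tangent-coordinate field.
#' @param kernels a [build_gradient_kernels] result.
#' @param conn connections.
#' @param p filter order (`p > 3` warns; cost grows as `m^p`).
#' @return `n x m x c` array with `c = channel_count(m, p)`.
#' @export
gradient_feature_stack <- function(Fl, kernels, conn, p = 2) {
  stopifnot(p >= 0)
  if (p > 3) warning("p > 3: channel count grows as m^p")
  Fl <- as.matrix(Fl)
  n <- nrow(Fl); m <- ncol(Fl)
  stopifnot(m == kernels$m)
  channels <- list(Fl)
  frontier <- list(Fl)
  if (p > 0) for (ord in seq_len(p)) {
    frontier <- unlist(lapply(frontier, .apply_gradient,
                              kernels = kernels, conn = conn),
                       recursive = FALSE)
    channels <- c(channels, frontier)
  }
  out <- array(0, dim = c(n, m, length(channels)))
  for (r in seq_along(channels)) out[, , r] <- channels[[r]]
  out
}

#' Rotation-invariant inner-product features
#'
#' Collapses the `m x c` per-node stack to a length-`c` vector by taking,
#' for each channel `r`, the sum of inner products against all channels,
#' weighted by a learnable matrix:
#' \eqn{E^{(r)} = \sum_s \langle f^D(\cdot,r),\, A^{(r)} f^D(\cdot,s)\rangle}.
#' Because all channels at a node share one tangent frame, the result is
#' invariant to any simultaneous rotation of the channels when
#' `A = identity`; learning `A` captures rotation/scaling relationships
#' between channel pairs.
#'
#' @param stack `n x m x c` array from [gradient_feature_stack].
#' @param A list of `c` matrices (`m x m`), or `NULL` for identities.
#' @return `n x c` matrix of invariant features.
#' @export
inner_product_features <- function(stack, A = NULL) {
  dm <- dim(stack)
  stopifnot(length(dm) == 3)
  n <- dm[1]; m <- dm[2]; cc <- dm[3]
  if (is.null(A)) A <- replicate(cc, diag(m), simplify = FALSE)
  if (length(A) != cc || any(vapply(A, function(a) !all(dim(a) == m),
                                    logical(1))))
    stop("A must be a list of c matrices of size m x m")
  out <- matrix(0, n, cc)
  for (i in seq_len(n)) {
    Fd <- matrix(stack[i, , ], m, cc)
    S <- rowSums(Fd)
    for (r in seq_len(cc))
      out[i, r] <- sum(Fd[, r] * (A[[r]] %*% S))
  }
  out
}
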