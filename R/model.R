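# Contrastive embedding model: MLP forward/backward, negative-sampling
# loss, pair sampling and the shared-across-conditions training loop.
# All gradients are hand-derived; the optimiser is Adam.

.sigmoid <- function(x) 1 / (1 + exp(-x))

# numerically safe -log(sigmoid(x)) = log(1 + exp(-x))
.softplus_neg <- function(x) ifelse(x > -30, log1p(exp(-x)), -x)

#' Initialise MLP weights (Kaiming)
#'
#' Fully connected layers with ReLU between them (none after the last).
#' Weights are drawn \eqn{N(0, \sqrt{2/\mathrm{fan_in}})}, biases zero.
#'
#' @param dims integer vector of layer sizes, e.g. `c(in, hidden, out)`.
#' @return List of layers, each `list(W, b)`.
#' @export
mlp_init <- function(dims) {
  stopifnot(length(dims) >= 2)
  lapply(seq_len(length(dims) - 1L), function(l) {
    list(W = matrix(rnorm(dims[l + 1L] * dims[l], sd = sqrt(2 / dims[l])),
                    dims[l + 1L], dims[l]),
         b = numeric(dims[l + 1L]))
  })
}

#' Forward pass of the embedding MLP
#'
#' \eqn{z_i = \mathrm{MLP}(f_i;\ \omega)} with ReLU nonlinearities between
#' linear layers.
#'
#' @param features `n x in` matrix of per-node features.
#' @param weights list of layers (`list(W, b)`), as from [mlp_init].
#' @return `n x out` matrix of latent vectors.
#' @export
mlp_embed <- function(features, weights) {
  X <- as.matrix(features)
  L <- length(weights)
  for (l in seq_len(L)) {
    if (ncol(X) != ncol(weights[[l]]$W))
      stop("feature/weight shape mismatch at layer ", l)
    X <- X %*% t(weights[[l]]$W) + rep(weights[[l]]$b, each = nrow(X))
    if (l < L) X <- pmax(X, 0)
  }
  X
}

# forward keeping pre-activations for backprop
.mlp_forward_cache <- function(X, weights) {
  L <- length(weights)
  acts <- vector("list", L + 1L)
  acts[[1L]] <- X
  for (l in seq_len(L)) {
    A <- acts[[l]] %*% t(weights[[l]]$W) + rep(weights[[l]]$b, each = nrow(X))
    acts[[l + 1L]] <- if (l < L) pmax(A, 0) else A
  }
  acts
}

# gradients of all layers (and of the input) given dZ; acts[[l]] for l >= 2
# are post-ReLU activations, acts[[1]] is the input
.mlp_backward <- function(weights, acts, dZ) {
  L <- length(weights)
  grads <- vector("list", L)
  delta <- dZ
  for (l in rev(seq_len(L))) {
    grads[[l]] <- list(W = crossprod(delta, acts[[l]]),
                       b = colSums(delta))
    delta <- delta %*% weights[[l]]$W
    if (l > 1L) delta <- delta * (acts[[l]] > 0)
  }
  list(grads = grads, dX = delta)
}

#' Sample positive and negative contrastive pairs
#'
#' For every non-isolated anchor node, one positive (a uniform one-step
#' random-walk neighbour on the same manifold) and one negative (uniform
#' over all nodes of all manifolds). Reproducible under the current RNG
#' state (or a supplied seed).
#'
#' @param graphs list of [build_proximity_graph] objects, one per condition.
#' @param seed optional integer seed.
#' @param anchors optional integer vector of pooled node indices to use as
#'   anchors (defaults to all non-isolated nodes).
#' @return List with `anchor`, `positive`, `negative` integer vectors in
#'   pooled node indexing (conditions concatenated in order).
#' @export
sample_contrastive_pairs <- function(graphs, seed = NULL, anchors = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ns <- vapply(graphs, function(g) g$n, integer(1))
  offset <- cumsum(c(0L, ns[-length(ns)]))
  ntot <- sum(ns)
  skipped <- 0L
  anc_l <- pos_l <- vector("list", length(graphs))
  for (ci in seq_along(graphs)) {
    g <- graphs[[ci]]
    nbs <- if (!is.null(g$nbrs)) g$nbrs else
      lapply(seq_len(g$n), function(i) which(g$adj[i, ]))
    loc <- seq_len(g$n)
    if (!is.null(anchors))
      loc <- loc[(offset[ci] + loc) %in% anchors]
    degs <- lengths(nbs[loc])
    skipped <- skipped + sum(degs == 0L)
    loc <- loc[degs > 0L]
    anc_l[[ci]] <- offset[ci] + loc
    pos_l[[ci]] <- offset[ci] + vapply(nbs[loc], function(nb)
      nb[sample.int(length(nb), 1L)], integer(1))
  }
  anchor <- unlist(anc_l); positive <- unlist(pos_l)
  if (skipped > 0L) warning(skipped, " isolated node(s) skipped as anchors")
  negative <- sample.int(ntot, length(anchor), replace = TRUE)
  list(anchor = anchor, positive = positive, negative = negative)
}

#' Negative-sampling contrastive loss
#'
#' \eqn{J = -\log\sigma(z_i^\top z_j) - Q\,E_k[\log\sigma(-z_i^\top z_k)]}
#' averaged over anchors; positives `j` are graph neighbours, negatives `k`
#' uniform nodes.
#'
#' @param Z `n x E` matrix of latent vectors.
#' @param pairs list with `anchor`, `positive`, `negative`.
#' @param Q weight of the negative term (default 1).
#' @return Scalar loss.
#' @export
contrastive_loss <- function(Z, pairs, Q = 1) {
  stopifnot(Q > 0)
  if (!all(is.finite(Z))) stop("non-finite embeddings")
  s_pos <- rowSums(Z[pairs$anchor, , drop = FALSE] *
                     Z[pairs$positive, , drop = FALSE])
  s_neg <- rowSums(Z[pairs$anchor, , drop = FALSE] *
                     Z[pairs$negative, , drop = FALSE])
  mean(.softplus_neg(s_pos)) + Q * mean(.softplus_neg(-s_neg))
}

# dJ/dZ for the loss above
.contrastive_loss_grad <- function(Z, pairs, Q = 1) {
  n <- nrow(Z)
  na <- length(pairs$anchor)
  Za <- Z[pairs$anchor, , drop = FALSE]
  Zp <- Z[pairs$positive, , drop = FALSE]
  Zn <- Z[pairs$negative, , drop = FALSE]
  s_pos <- rowSums(Za * Zp)
  s_neg <- rowSums(Za * Zn)
  J <- mean(.softplus_neg(s_pos)) + Q * mean(.softplus_neg(-s_neg))
  dsp <- (.sigmoid(s_pos) - 1) / na
  dsn <- Q * .sigmoid(s_neg) / na
  dZ <- matrix(0, n, ncol(Z))
  add <- function(dZ, idx, contrib) {
    agg <- rowsum(contrib, idx)
    rows <- as.integer(rownames(agg))
    dZ[rows, ] <- dZ[rows, , drop = FALSE] + agg
    dZ
  }
  dZ <- add(dZ, pairs$anchor, dsp * Zp + dsn * Zn)
  dZ <- add(dZ, pairs$positive, dsp * Za)
  dZ <- add(dZ, pairs$negative, dsn * Za)
  list(J = J, dZ = dZ)
}

# Adam update; state holds first/second moments per parameter vector
.adam_step <- function(par, grad, state, lr, b1 = 0.9, b2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- b1 * state$m + (1 - b1) * grad
  state$v <- b2 * state$v + (1 - b2) * grad^2
  mh <- state$m / (1 - b1^state$t)
  vh <- state$v / (1 - b2^state$t)
  list(par = par - lr * mh / (sqrt(vh) + eps), state = state)
}

.adam_new <- function(par) list(t = 0L, m = par * 0, v = par * 0)

# Shared training loop. `stacks` is a list (per condition) of n_c x m x c
# arrays; mode decides the MLP input (flattened stacks or inner-product
# features with learnable A). Minibatch Adam with early stopping on the
# validation loss. Returns weights, A, losses and embeddings.
.train_embedding <- function(stacks, graphs, mode, E, Q = 1, hidden = NULL,
                             lr = 1e-2, epochs = 300, patience = 20,
                             batch = 256, min_delta = 1e-4, clip = NULL,
                             seed = 1, verbose = FALSE) {
  set.seed(seed)
  ns <- vapply(stacks, function(s) dim(s)[1], integer(1))
  m <- dim(stacks[[1]])[2]; cc <- dim(stacks[[1]])[3]
  ntot <- sum(ns)
  aware <- identical(mode, "embedding-aware")

  # pooled channel matrices: for each channel r an ntot x m matrix, plus the
  # channel sum (used by the inner-product features and their gradient)
  Fr <- lapply(seq_len(cc), function(r)
    do.call(rbind, lapply(stacks, function(s) s[, , r, drop = TRUE])))
  Fr <- lapply(Fr, function(M) matrix(M, ntot, m))
  Smat <- Reduce(`+`, Fr)

  flat <- if (aware) do.call(cbind, Fr) else NULL  # ntot x (m*c)
  A <- if (!aware) replicate(cc, diag(m), simplify = FALSE) else NULL

  input_features <- function(A, rows = NULL) {
    if (is.null(rows)) rows <- seq_len(ntot)
    if (aware) return(flat[rows, , drop = FALSE])
    out <- matrix(0, length(rows), cc)
    Sm <- Smat[rows, , drop = FALSE]
    for (r in seq_len(cc))
      out[, r] <- rowSums((Fr[[r]][rows, , drop = FALSE] %*% A[[r]]) * Sm)
    out
  }

  # per-column scale normalisation of the MLP input (conditioning only;
  # invariances are per-column properties and are preserved), with an
  # optional winsorisation at a pooled per-column |value| quantile to stop
  # heavy-tailed channels (e.g. gradients near fixed points) from
  # dominating the loss
  X0 <- input_features(A)
  fscale <- apply(X0, 2, function(v) sqrt(mean(v^2)))
  fscale[!is.finite(fscale) | fscale == 0] <- 1
  fclip <- if (is.null(clip)) NULL else
    pmax(apply(abs(sweep(X0, 2, fscale, "/")), 2, stats::quantile,
               probs = clip), 1e-12)
  prep_input <- function(A, rows = NULL) {
    Xi <- sweep(input_features(A, rows), 2, fscale, "/")
    if (!is.null(fclip))
      Xi <- pmin(pmax(Xi, rep(-fclip, each = nrow(Xi))),
                 rep(fclip, each = nrow(Xi)))
    Xi
  }
  din <- length(fscale)
  if (is.null(hidden)) hidden <- 2L * din
  weights <- mlp_init(c(din, hidden, E))

  # 80/10/10 split of pooled nodes
  perm <- sample.int(ntot)
  n_tr <- floor(0.8 * ntot); n_va <- floor(0.1 * ntot)
  if (n_va < 1L) stop("too few nodes for a validation split")
  idx_tr <- perm[seq_len(n_tr)]
  idx_va <- perm[(n_tr + 1L):(n_tr + n_va)]
  idx_te <- perm[(n_tr + n_va + 1L):ntot]

  val_pairs <- sample_contrastive_pairs(graphs, anchors = idx_va)

  # flatten parameters for Adam bookkeeping
  pack <- function() {
    ps <- unlist(lapply(weights, function(l) c(l$W, l$b)))
    if (!aware) ps <- c(ps, unlist(A))
    ps
  }
  unpack <- function(ps) {
    pos <- 0L
    for (l in seq_along(weights)) {
      nw <- length(weights[[l]]$W); nb <- length(weights[[l]]$b)
      weights[[l]]$W[] <<- ps[pos + seq_len(nw)]; pos <- pos + nw
      weights[[l]]$b <<- ps[pos + seq_len(nb)]; pos <- pos + nb
    }
    if (!aware) for (r in seq_len(cc)) {
      A[[r]][] <<- ps[pos + seq_len(m * m)]; pos <- pos + m * m
    }
  }
  par <- pack()
  st <- .adam_new(par)

  best <- list(val = Inf, par = par, epoch = 0L)
  wait <- 0L
  tr_hist <- va_hist <- numeric(0)

  for (ep in seq_len(epochs)) {
    pairs <- sample_contrastive_pairs(graphs, anchors = idx_tr)
    ord <- sample.int(length(pairs$anchor))
    nb <- max(1L, ceiling(length(ord) / batch))
    ep_loss <- 0
    for (bi in seq_len(nb)) {
      sel <- ord[((bi - 1L) * batch + 1L):min(bi * batch, length(ord))]
      a <- pairs$anchor[sel]; p <- pairs$positive[sel]
      ng <- pairs$negative[sel]
      rows <- unique(c(a, p, ng))
      bpairs <- list(anchor = match(a, rows), positive = match(p, rows),
                     negative = match(ng, rows))
      Xin <- prep_input(A, rows)
      acts <- .mlp_forward_cache(Xin, weights)
      Z <- acts[[length(acts)]]
      lg <- .contrastive_loss_grad(Z, bpairs, Q = Q)
      bp <- .mlp_backward(weights, acts, lg$dZ)
      grad <- unlist(lapply(bp$grads, function(l) c(l$W, l$b)))
      if (!aware) {
        dXin <- sweep(bp$dX, 2, fscale, "/")
        if (!is.null(fclip))  # zero subgradient on winsorised entries
          dXin[abs(Xin) >= rep(fclip, each = nrow(Xin))] <- 0
        Sm <- Smat[rows, , drop = FALSE]
        gA <- lapply(seq_len(cc), function(r)
          crossprod(Fr[[r]][rows, , drop = FALSE] * dXin[, r], Sm))
        grad <- c(grad, unlist(gA))
      }
      if (!all(is.finite(grad)) || !is.finite(lg$J))
        stop("training diverged (non-finite loss or gradient)")
      gn <- sqrt(sum(grad^2))   # global norm clip guards rare blow-ups
      if (gn > 10) grad <- grad * (10 / gn)
      upd <- .adam_step(par, grad, st, lr)
      par <- upd$par; st <- upd$state
      unpack(par)
      ep_loss <- ep_loss + lg$J * length(sel) / length(ord)
    }

    # validation
    Zv <- mlp_embed(prep_input(A), weights)
    val <- contrastive_loss(Zv, val_pairs, Q = Q)
    tr_hist <- c(tr_hist, ep_loss); va_hist <- c(va_hist, val)
    if (val < best$val - min_delta) {
      best <- list(val = val, par = par, epoch = ep)
      wait <- 0L
    } else wait <- wait + 1L
    if (verbose && ep %% 10 == 0)
      message(sprintf("epoch %4d  train %.4f  val %.4f", ep, ep_loss, val))
    if (wait >= patience) break
  }
  unpack(best$par)
  Z <- mlp_embed(prep_input(A), weights)
  test_loss <- contrastive_loss(Z, sample_contrastive_pairs(
    graphs, anchors = idx_te), Q = Q)

  list(weights = weights, A = A, fscale = fscale, fclip = fclip, Z = Z,
       split = list(train = idx_tr, val = idx_va, test = idx_te),
       history = list(train = tr_hist, val = va_hist),
       best_epoch = best$epoch, val_loss = best$val, test_loss = test_loss,
       mode = mode, E = E, Q = Q, hidden = hidden, ns = ns)
}
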