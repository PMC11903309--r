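# The user-facing model: flowrep() runs the full pipeline over a list of
# per-condition vector fields and returns a classed fit object.

# preprocessing of one condition: subsample, graph, frames, connections,
# (optional) diffusion, tangent projection, gradient features
.preprocess_condition <- function(vf, m, p, k, delta, alpha, tau, K,
                                  orient = TRUE) {
  idx <- subsample_farthest_point(vf$points, alpha)
  X <- vf$points[idx, , drop = FALSE]
  V <- vf$vectors[idx, , drop = FALSE]
  graph <- build_proximity_graph(X, k = k, delta = delta)
  bundle <- fit_tangent_frames(graph, m = m, K = K,
                               orient_field = if (orient)
                                 .smooth_field(graph, V) else NULL)
  conn <- compute_connections(bundle, graph)
  Fl <- project_to_tangent(V, bundle)
  if (tau > 0) {
    L <- connection_laplacian(graph, conn)
    Fl <- vector_diffusion(Fl, L, tau)
  }
  kernels <- build_gradient_kernels(graph, bundle, conn)
  stack <- gradient_feature_stack(Fl, kernels, conn, p = p)
  list(condition = vf$condition, keep = idx, graph = graph, bundle = bundle,
       conn = conn, kernels = kernels, field = Fl, stack = stack)
}

#' Fit an unsupervised representation of dynamics over latent manifolds
#'
#' Runs the full pipeline on one or more per-condition vector fields:
#' farthest-point subsampling, continuous k-NN proximity graph, tangent
#' frames and parallel-transport connections, optional vector diffusion,
#' gradient (directional-derivative) feature extraction, optional
#' rotation-invariant inner products, and a two-layer MLP trained jointly
#' across all conditions with a negative-sampling contrastive loss.
#' Condition labels are used only to organise feature extraction, never for
#' supervision.
#'
#' @param data a [vector_field], a [trajectory_set], or a list of either
#'   (trajectory sets are differenced with [vectors_from_trajectories]).
#' @param m intrinsic manifold dimension (default 2).
#' @param p gradient filter order (default 2; second order suffices for
#'   most flow fields).
#' @param mode `"embedding-agnostic"` uses rotation-invariant inner-product
#'   features, so representations can be compared across differently
#'   embedded manifolds; `"embedding-aware"` uses the raw gradient channels
#'   and is sensitive to the orientation of the flow.
#' @param E latent dimension.
#' @param k,delta continuous k-NN graph parameters.
#' @param alpha farthest-point spacing in `[0, 1]` (0 = keep every point).
#' @param tau vector-diffusion time (0 disables diffusion).
#' @param K tangent-frame neighbour count (`NULL`: `ceiling(1.5 * degree)`
#'   per node).
#' @param Q negative-sampling weight.
#' @param hidden hidden-layer width (`NULL`: twice the feature dimension).
#' @param lr,epochs,patience Adam learning rate, maximum epochs and
#'   early-stopping patience (validation loss, `min_delta = 1e-4`).
#' @param batch minibatch size (anchors per Adam step).
#' @param clip optional per-column winsorisation quantile in (0, 1) applied
#'   to the scale-normalised features (e.g. `0.98`); tames heavy-tailed
#'   gradient channels near fixed points. `NULL` disables.
#' @param seed integer seed controlling subsampling ties, splits, pair
#'   sampling and initialisation.
#' @param verbose print training progress.
#' @return An object of class `flowrep` with, among others, `embeddings`
#'   (per-condition latent matrices), `conditions`, `model` (weights,
#'   inner-product matrices, feature scale), `prep` (per-condition
#'   geometry), and `history` (loss curves). Methods: `print`, `summary`,
#'   `coef`, `fitted`, `predict`, `plot`.
#' @examples
#' \donttest{
#' fs <- lapply(c(0, pi / 2), function(th)
#'   sample_toy_fields("constant", params = list(vector = c(cos(th), sin(th))),
#'                     n_points = 100, seed = 1, condition = sprintf("%.2f", th)))
#' fit <- flowrep(fs, mode = "embedding-aware", E = 3, epochs = 60, seed = 1)
#' condition_distances(fit)
#' }
#' @export
flowrep <- function(data, m = 2, p = 2,
                    mode = c("embedding-agnostic", "embedding-aware"),
                    E = 5, k = 15, delta = 1.0, alpha = 0, tau = 0,
                    K = NULL, Q = 1, hidden = NULL, lr = 1e-2,
                    epochs = 100, patience = 20, batch = 256, clip = NULL,
                    seed = 1, verbose = FALSE) {
  mode <- match.arg(mode)
  cl <- match.call()
  if (inherits(data, "vector_field") || inherits(data, "trajectory_set"))
    data <- list(data)
  data <- lapply(data, function(d) {
    if (inherits(d, "trajectory_set")) vectors_from_trajectories(d) else d
  })
  stopifnot(length(data) >= 1,
            all(vapply(data, inherits, logical(1), "vector_field")))
  set.seed(seed)
  # field-aligned (rotation-equivariant) frame gauge in agnostic mode;
  # fixed gauge in aware mode, which is deliberately orientation-sensitive
  prep <- lapply(data, .preprocess_condition, m = m, p = p, k = k,
                 delta = delta, alpha = alpha, tau = tau, K = K,
                 orient = (mode == "embedding-agnostic"))
  conds <- vapply(prep, `[[`, character(1), "condition")
  if (anyDuplicated(conds))
    conds <- make.unique(conds)
  stacks <- lapply(prep, `[[`, "stack")
  graphs <- lapply(prep, `[[`, "graph")
  # a run that cannot beat the trivial all-zero embedding (loss 2 log 2)
  # has not converged; retry from a different initialisation
  tr <- NULL
  for (attempt in 0:2) {
    cand <- .train_embedding(stacks, graphs, mode = mode, E = E, Q = Q,
                             hidden = hidden, lr = lr, epochs = epochs,
                             patience = patience, batch = batch,
                             clip = clip, seed = seed + 1000L * attempt,
                             verbose = verbose)
    if (is.null(tr) || cand$val_loss < tr$val_loss) tr <- cand
    if (tr$val_loss <= 2 * log(2) + 0.05) break
    if (verbose && attempt < 2)
      message(sprintf("validation loss %.3f above the trivial bound; ",
                      tr$val_loss), "restarting")
  }
  ns <- vapply(stacks, function(s) dim(s)[1], integer(1))
  grp <- rep(seq_along(ns), ns)
  embeddings <- split.data.frame(tr$Z, grp)
  embeddings <- lapply(embeddings, as.matrix)
  names(embeddings) <- conds
  structure(list(
    conditions = conds, embeddings = embeddings, prep = prep,
    model = list(weights = tr$weights, A = tr$A, fscale = tr$fscale,
                 fclip = tr$fclip, mode = mode, m = m, p = p, E = E,
                 tau = tau, Q = Q, hidden = tr$hidden),
    hyper = list(k = k, delta = delta, alpha = alpha, K = K, lr = lr,
                 epochs = epochs, patience = patience),
    history = tr$history, best_epoch = tr$best_epoch,
    val_loss = tr$val_loss, test_loss = tr$test_loss,
    split = tr$split, seed = seed, call = cl), class = "flowrep")
}

#' @export
print.flowrep <- function(x, ...) {
  ns <- vapply(x$embeddings, nrow, integer(1))
  cat("Flow-field representation fit\n")
  cat(sprintf("  mode: %s  (m = %d, p = %d, E = %d, tau = %g)\n",
              x$model$mode, x$model$m, x$model$p, x$model$E, x$model$tau))
  cat(sprintf("  conditions: %d  |  nodes: %s (total %d)\n",
              length(x$conditions), paste(ns, collapse = ", "), sum(ns)))
  cat(sprintf("  validation loss %.4f (epoch %d), test loss %.4f\n",
              x$val_loss, x$best_epoch, x$test_loss))
  invisible(x)
}

#' @export
summary.flowrep <- function(object, ...) {
  ns <- vapply(object$embeddings, nrow, integer(1))
  edges <- vapply(object$prep, function(p) nrow(p$graph$edges), integer(1))
  out <- list(
    conditions = data.frame(condition = object$conditions, nodes = ns,
                            edges = edges, row.names = NULL),
    mode = object$model$mode, m = object$model$m, p = object$model$p,
    E = object$model$E, tau = object$model$tau,
    channels = channel_count(object$model$m, object$model$p),
    epochs_run = length(object$history$train),
    best_epoch = object$best_epoch,
    val_loss = object$val_loss, test_loss = object$test_loss,
    seed = object$seed)
  class(out) <- "summary.flowrep"
  out
}

#' @export
print.summary.flowrep <- function(x, ...) {
  cat("Flow-field representation fit\n")
  cat(sprintf("  mode %s, m = %d, p = %d (%d channels), E = %d, tau = %g\n",
              x$mode, x$m, x$p, x$channels, x$E, x$tau))
  cat(sprintf("  %d epochs run, best validation %.4f at epoch %d; test %.4f\n",
              x$epochs_run, x$val_loss, x$best_epoch, x$test_loss))
  cat("  per-condition geometry:\n")
  print(x$conditions, row.names = FALSE)
  invisible(x)
}

#' @export
coef.flowrep <- function(object, ...) {
  list(weights = object$model$weights, A = object$model$A)
}

#' @export
fitted.flowrep <- function(object, ...) {
  Z <- do.call(rbind, object$embeddings)
  data.frame(condition = rep(object$conditions,
                             vapply(object$embeddings, nrow, integer(1))),
             Z, row.names = NULL)
}

#' Embed new vector fields with a trained model
#'
#' Runs the geometric preprocessing on `newdata` with the hyperparameters
#' stored in the fit and maps the resulting features through the trained
#' network. With `newdata = NULL`, returns the stored per-condition
#' embeddings.
#'
#' @param object a [flowrep] fit.
#' @param newdata a [vector_field] / [trajectory_set] or list of them.
#' @param ... unused.
#' @return Named list of `n_c x E` latent matrices.
#' @export
predict.flowrep <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$embeddings)
  if (inherits(newdata, "vector_field") || inherits(newdata, "trajectory_set"))
    newdata <- list(newdata)
  newdata <- lapply(newdata, function(d)
    if (inherits(d, "trajectory_set")) vectors_from_trajectories(d) else d)
  mdl <- object$model; hp <- object$hyper
  prep <- lapply(newdata, .preprocess_condition, m = mdl$m, p = mdl$p,
                 k = hp$k, delta = hp$delta, alpha = hp$alpha,
                 tau = mdl$tau, K = hp$K,
                 orient = (mdl$mode == "embedding-agnostic"))
  out <- lapply(prep, function(pr) {
    feats <- if (mdl$mode == "embedding-aware") {
      cc <- dim(pr$stack)[3]
      do.call(cbind, lapply(seq_len(cc), function(r)
        matrix(pr$stack[, , r], dim(pr$stack)[1], mdl$m)))
    } else {
      inner_product_features(pr$stack, mdl$A)
    }
    Xi <- sweep(feats, 2, mdl$fscale, "/")
    if (!is.null(mdl$fclip))
      Xi <- pmin(pmax(Xi, rep(-mdl$fclip, each = nrow(Xi))),
                 rep(mdl$fclip, each = nrow(Xi)))
    mlp_embed(Xi, mdl$weights)
  })
  names(out) <- vapply(prep, `[[`, character(1), "condition")
  out
}

#' Plot a fitted representation
#'
#' `type = "embedding"` scatters the first two latent dimensions coloured
#' by condition; `type = "loss"` shows training/validation loss curves.
#'
#' @param x a [flowrep] fit.
#' @param type what to plot.
#' @param ... passed to [graphics::plot].
#' @export
plot.flowrep <- function(x, type = c("embedding", "loss"), ...) {
  type <- match.arg(type)
  if (type == "loss") {
    h <- x$history
    graphics::plot(h$train, type = "l", xlab = "epoch", ylab = "loss",
                   ylim = range(c(h$train, h$val)), ...)
    graphics::lines(h$val, lty = 2)
    graphics::legend("topright", c("train", "validation"), lty = 1:2,
                     bty = "n")
  } else {
    Z <- do.call(rbind, x$embeddings)
    grp <- rep(seq_along(x$embeddings),
               vapply(x$embeddings, nrow, integer(1)))
    graphics::plot(Z[, 1], Z[, 2], col = grp, pch = 16, cex = 0.5,
                   xlab = "z1", ylab = "z2", ...)
    graphics::legend("topright", legend = x$conditions,
                     col = seq_along(x$conditions), pch = 16, bty = "n")
  }
  invisible(x)
}
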