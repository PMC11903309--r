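# Shared fixtures: all built in code, deterministic under explicit seeds.

# random orthogonal d x d matrix (Haar via QR)
random_rotation <- function(d, seed = 1) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(d * d), d))
  Q <- qr.Q(qr_)
  Q %*% diag(sign(diag(qr.R(qr_))), d)
}

# jittered flat grid in 2-D (full-rank neighbourhoods for the kernels)
flat_grid <- function(nside = 15, jitter = 0.002, seed = 1) {
  set.seed(seed)
  g <- as.matrix(expand.grid(x = seq(0, 1, length.out = nside),
                             y = seq(0, 1, length.out = nside)))
  g + matrix(rnorm(nrow(g) * 2, sd = jitter), ncol = 2)
}

# full geometric preprocessing for a planar point set
flat_geometry <- function(X, k = 8, delta = 1.0, m = 2) {
  graph <- build_proximity_graph(X, k = k, delta = delta)
  bundle <- fit_tangent_frames(graph, m = m)
  conn <- compute_connections(bundle, graph)
  list(graph = graph, bundle = bundle, conn = conn,
       kernels = build_gradient_kernels(graph, bundle, conn))
}

# brute-force optimal transport between equal-size uniform clouds by
# enumerating all permutation plans (Birkhoff vertices); n <= 6
ot_enumerate <- function(Z1, Z2) {
  n <- nrow(Z1)
  stopifnot(n == nrow(Z2), n <= 6)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  C <- as.matrix(stats::dist(rbind(Z1, Z2)))[seq_len(n), n + seq_len(n),
                                             drop = FALSE]^2
  min(vapply(perms(seq_len(n)),
             function(p) mean(C[cbind(seq_len(n), p)]), numeric(1)))
}

# tiny multi-condition toy suite for fast end-to-end fits
toy_suite <- function(n = 80, seed = 1) {
  list(
    sample_toy_fields("constant", list(vector = c(1, 0)), n,
                      seed = seed + 1, condition = "c-right"),
    sample_toy_fields("constant", list(vector = c(0, 1)), n,
                      seed = seed + 2, condition = "c-up"),
    sample_toy_fields("rotational", list(omega = 1), n,
                      seed = seed + 3, condition = "rot"))
}
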