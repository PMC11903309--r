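test_that("farthest-point subsampling follows the greedy spacing rule", {
  X <- cbind(c(0, 1, 2, 10), 0)
  expect_equal(subsample_farthest_point(X, 0), 1:4)  # alpha = 0: keep all
  # diam = 10, threshold 5: greedy keeps 0 then 10, drops 1 and 2
  expect_equal(sort(subsample_farthest_point(X, 0.5)), c(1, 4))
  # duplicated points collapse to one representative for any alpha > 0
  Xd <- rbind(c(0, 0), c(0, 0), c(1, 0), c(1, 0))
  keep <- subsample_farthest_point(Xd, 0.01)
  expect_equal(nrow(unique(Xd[keep, , drop = FALSE])), length(keep))
  expect_error(subsample_farthest_point(X, 1.5), "alpha")
})

test_that("greedy subsampling matches brute force on a small instance", {
  set.seed(21)
  X <- matrix(runif(16), 8, 2)
  alpha <- 0.4
  # independent re-implementation of the greedy rule
  diam <- max(dist(X))
  kept <- 1L
  repeat {
    d2k <- apply(X, 1, function(p)
      min(colSums((t(X[kept, , drop = FALSE]) - p)^2)))
    i <- which.max(d2k)
    if (sqrt(d2k[i]) <= alpha * diam) break
    kept <- c(kept, i)
  }
  expect_equal(subsample_farthest_point(X, alpha), kept)
})

test_that("continuous k-NN rule connects and separates as the inequality says", {
  # equilateral triangle, k = 1, delta = 1.5: all pairwise inequalities hold
  tri <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  g <- build_proximity_graph(tri, k = 1, delta = 1.5)
  expect_equal(nrow(g$edges), 3)
  # two distant dense clusters: no cross edges at moderate delta
  set.seed(22)
  cl1 <- matrix(rnorm(40, sd = 0.05), 20, 2)
  cl2 <- matrix(rnorm(40, sd = 0.05), 20, 2) + 10
  g2 <- suppressWarnings(build_proximity_graph(rbind(cl1, cl2), k = 3,
                                               delta = 1.5))
  side <- g2$edges <= 20
  expect_true(all(side[, 1] == side[, 2]))
  # delta -> infinity: complete graph
  g3 <- build_proximity_graph(tri, k = 1, delta = 1e9)
  expect_equal(nrow(g3$edges), 3)
  X <- rbind(tri, c(5, 5))
  g4 <- build_proximity_graph(X, k = 1, delta = 1e9)
  expect_equal(nrow(g4$edges), choose(4, 2))
})

test_that("ck-NN graph is invariant under rigid motion", {
  set.seed(23)
  X <- matrix(rnorm(60), 30, 2)
  R <- random_rotation(2, seed = 5)
  Xr <- X %*% t(R) + rep(c(3, -7), each = 30)
  g1 <- suppressWarnings(build_proximity_graph(X, k = 4, delta = 1.2))
  g2 <- suppressWarnings(build_proximity_graph(Xr, k = 4, delta = 1.2))
  expect_equal(g1$edges, g2$edges)
})

test_that("tangent frames recover planes, spheres and lines", {
  set.seed(24)
  # plane z = 0 in 3-space: projector ~ diag(1, 1, 0)
  Xp <- cbind(matrix(runif(200), 100, 2), 0)
  gp <- build_proximity_graph(Xp, k = 6, delta = 1.2)
  bp <- fit_tangent_frames(gp, m = 2)
  for (i in c(1, 25, 60)) {
    P <- tcrossprod(bp$frames[[i]])
    expect_equal(P, diag(c(1, 1, 0)), tolerance = 1e-6)
  }
  # unit sphere: frames orthogonal to the radius
  th <- acos(runif(300, -1, 1)); ph <- runif(300, 0, 2 * pi)
  Xs <- cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  gs <- build_proximity_graph(Xs, k = 8, delta = 1.2)
  bs <- fit_tangent_frames(gs, m = 2)
  rad <- vapply(seq_len(300), function(i)
    max(abs(crossprod(bs$frames[[i]], Xs[i, ]))), numeric(1))
  expect_lt(stats::median(rad), 0.2)  # discretisation tolerance
  # collinear points, m = 1: frame is the line direction up to sign
  Xl <- cbind(seq(0, 1, length.out = 20) * 3, seq(0, 1, length.out = 20) * 4) / 5
  gl <- build_proximity_graph(Xl, k = 2, delta = 1.1)
  bl <- fit_tangent_frames(gl, m = 1)
  expect_equal(abs(sum(bl$frames[[10]] * c(3, 4) / 5)), 1, tolerance = 1e-8)
})

test_that("frames are orthonormal and connections orthogonal to 1e-8", {
  set.seed(25)
  th <- acos(runif(150, -1, 1)); ph <- runif(150, 0, 2 * pi)
  Xs <- cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  g <- build_proximity_graph(Xs, k = 6, delta = 1.2)
  b <- fit_tangent_frames(g, m = 2)
  co <- compute_connections(b, g)
  for (i in sample(150, 20))
    expect_equal(crossprod(b$frames[[i]]), diag(2), tolerance = 1e-8)
  for (e in sample(nrow(g$edges), 20)) {
    O <- co$O[[e]]
    expect_equal(crossprod(O), diag(2), tolerance = 1e-8)
  }
})

test_that("Kabsch alignment matches a brute-force grid oracle", {
  base <- qr.Q(qr(matrix(c(1, 0, 0, 0, 1, 0), 3, 2)))
  rot2 <- function(th) matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  # identical frames: identity connection
  expect_equal(flowrep:::.kabsch(base, base), diag(2), tolerance = 1e-12)
  grid <- seq(0, 2 * pi, length.out = 1e4)
  for (th in c(0.3, 2.5)) {
    Tj <- base %*% rot2(th)
    O <- flowrep:::.kabsch(base, Tj)      # argmin ||T_i - T_j O||
    costs <- vapply(grid, function(a)
      norm(base - Tj %*% rot2(a), "F"), numeric(1))
    best <- grid[which.min(costs)]
    # the Kabsch optimum can only beat the finite grid
    expect_lte(norm(base - Tj %*% O, "F"), min(costs) + 1e-12)
    expect_equal(O, rot2(best), tolerance = 1e-3)
    expect_equal(det(O), 1, tolerance = 1e-12)
  }
  # reflection-related frames: optimal O has determinant -1
  Tj <- base %*% diag(c(1, -1))
  O <- flowrep:::.kabsch(base, Tj)
  expect_equal(det(O), -1, tolerance = 1e-12)
  refl_grid <- vapply(grid, function(a)
    norm(base - Tj %*% (rot2(a) %*% diag(c(1, -1))), "F"), numeric(1))
  expect_lte(norm(base - Tj %*% O, "F"), min(refl_grid) + 1e-9)
})

test_that("connection Laplacian has the stated block structure", {
  # 2-node path, m = 1: [[1, -O], [-O, 1]] with eigenvalues {0, 2} for O = 1
  X <- cbind(c(0, 1), 0)
  g <- build_proximity_graph(X, k = 1, delta = 2)
  b <- suppressWarnings(fit_tangent_frames(g, m = 1))  # tiny K by design
  co <- compute_connections(b, g)
  L <- as.matrix(connection_laplacian(g, co))
  O <- co$O[[1]][1, 1]
  expect_equal(L, rbind(c(1, -O), c(-O, 1)), tolerance = 1e-12)
  expect_equal(sort(eigen(rbind(c(1, -1), c(-1, 1)))$values), c(0, 2))
})

test_that("flat aligned bundle reduces to scalar Laplacian tensor identity", {
  X <- flat_grid(8, jitter = 0, seed = 1)
  geo <- flat_geometry(X, k = 4, delta = 1.05)
  L <- as.matrix(connection_laplacian(geo$graph, geo$conn))
  A <- as.matrix(geo$graph$adj) * 1
  Lrw <- diag(nrow(X)) - diag(1 / rowSums(A)) %*% A
  expect_equal(L, kronecker(Lrw, diag(2)), tolerance = 1e-10)
  # a globally parallel field is in the kernel
  par_field <- matrix(rep(c(0.3, -0.7), nrow(X)), ncol = 1)
  expect_lt(max(abs(L %*% par_field)), 1e-12)
  # the degree-similarity transform symmetrises the random-walk operator;
  # its spectrum is real and non-negative
  S <- kronecker(diag(sqrt(rowSums(A))), diag(2))
  Lsym <- S %*% L %*% solve(S)
  expect_equal(Lsym, t(Lsym), tolerance = 1e-10)
  ev <- eigen((Lsym + t(Lsym)) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  expect_gt(min(ev), -1e-10)
})
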