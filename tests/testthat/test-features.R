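test_that("tangent projection is the l2-optimal restriction", {
  set.seed(30)
  X <- cbind(matrix(runif(60), 30, 2), 0)
  g <- suppressWarnings(build_proximity_graph(X, k = 5, delta = 1.4))
  b <- fit_tangent_frames(g, m = 2)
  # in-plane vectors are reproduced exactly, normal components vanish
  V <- cbind(matrix(rnorm(60), 30, 2), 0)
  Fl <- project_to_tangent(V, b)
  back <- t(vapply(seq_len(30), function(i)
    as.numeric(b$frames[[i]] %*% Fl[i, ]), numeric(3)))
  expect_equal(back, V, tolerance = 1e-10)
  Vn <- cbind(0 * V[, 1:2], rnorm(30))
  expect_lt(max(abs(project_to_tangent(Vn, b))), 1e-10)
  # planar identity frames: (a, b, c) -> (a, b)
  Xp <- matrix(runif(40), 20, 2)
  gp <- suppressWarnings(build_proximity_graph(Xp, k = 3, delta = 1.2))
  bp <- fit_tangent_frames(gp, m = 2)
  Vp <- matrix(rnorm(40), 20, 2)
  expect_equal(project_to_tangent(Vp, bp), Vp)
})

test_that("vector diffusion matches a dense matrix-exponential oracle", {
  set.seed(31)
  # 30-node connected jittered grid
  X <- as.matrix(expand.grid(x = seq(0, 1, length.out = 5),
                             y = seq(0, 1, length.out = 6))) +
    matrix(rnorm(60, sd = 0.01), 30, 2)
  geo <- flat_geometry(X, k = 4, delta = 1.2)
  L <- connection_laplacian(geo$graph, geo$conn)
  Fl <- matrix(rnorm(60), 30, 2)
  expect_identical(vector_diffusion(Fl, L, 0), Fl)     # tau = 0 identity
  expect_error(vector_diffusion(Fl, L, -1), "tau")
  for (tau in c(0.3, 1.7)) {
    got <- vector_diffusion(Fl, L, tau)
    # dense eigen-based expm on the 60 x 60 operator
    Ld <- as.matrix(L)
    ee <- eigen(Ld)
    Ex <- Re(ee$vectors %*% diag(exp(-tau * ee$values)) %*% solve(ee$vectors))
    want <- matrix(Ex %*% as.numeric(t(Fl)), 30, 2, byrow = TRUE)
    expect_equal(got, want, tolerance = 1e-6)
    # flat aligned bundle: equals per-channel scalar heat diffusion
    A <- as.matrix(geo$graph$adj) * 1
    Lrw <- diag(30) - diag(1 / rowSums(A)) %*% A
    es <- eigen(Lrw)
    Es <- Re(es$vectors %*% diag(exp(-tau * es$values)) %*% solve(es$vectors))
    expect_equal(got, Es %*% Fl, tolerance = 1e-6)
  }
})

test_that("long-time diffusion approaches the degree-weighted stationary blend", {
  set.seed(32)
  X <- as.matrix(expand.grid(x = seq(0, 1, length.out = 5),
                             y = seq(0, 1, length.out = 5))) +
    matrix(rnorm(50, sd = 0.01), 25, 2)
  geo <- flat_geometry(X, k = 4, delta = 1.3)
  L <- connection_laplacian(geo$graph, geo$conn)
  Fl <- matrix(rnorm(50), 25, 2)
  got <- vector_diffusion(Fl, L, 500)
  # left stationary vector of the random walk is proportional to degree
  deg <- geo$graph$degree
  blend <- colSums(Fl * deg) / sum(deg)
  expect_equal(got, matrix(blend, 25, 2, byrow = TRUE), tolerance = 1e-6)
})

test_that("gradient filters annihilate constants and are exact on affine fields", {
  X <- flat_grid(15, jitter = 0.002, seed = 33)
  geo <- flat_geometry(X, k = 8, delta = 1.0)
  # parallel (constant) field: all directional derivatives vanish
  const <- matrix(rep(c(0.4, -1.1), each = nrow(X)), ncol = 2)
  st0 <- gradient_feature_stack(const, geo$kernels, geo$conn, p = 1)
  expect_lt(max(abs(st0[, , 2:3])), 1e-10)
  # linear field f(x) = A x: first-order channels recover A columns
  A <- matrix(c(0.3, -1, 1, 0.5), 2, 2, byrow = TRUE)
  st1 <- gradient_feature_stack(X %*% t(A), geo$kernels, geo$conn, p = 1)
  interior <- which(apply(X, 1, function(p)
    all(p > 0.1) && all(p < 0.9)))
  for (q in 1:2) {
    est <- colMeans(st1[interior, , q + 1])
    expect_equal(est, A[, q], tolerance = 1e-3)
  }
  # rotational field: Jacobian [[0, -1], [1, 0]]
  st2 <- gradient_feature_stack(cbind(-X[, 2], X[, 1]),
                                geo$kernels, geo$conn, p = 1)
  expect_equal(colMeans(st2[interior, , 2]), c(0, 1), tolerance = 1e-3)
  expect_equal(colMeans(st2[interior, , 3]), c(-1, 0), tolerance = 1e-3)
})

test_that("second-order channels track the analytic Hessian on a quadratic field", {
  X <- flat_grid(20, jitter = 0.001, seed = 34)
  geo <- flat_geometry(X, k = 8, delta = 1.0)
  # f_1 = x^2/2 (Hessian d2f1/dx2 = 1), f_2 = x y
  Fl <- cbind(X[, 1]^2 / 2, X[, 1] * X[, 2])
  st <- gradient_feature_stack(Fl, geo$kernels, geo$conn, p = 2)
  interior <- which(apply(X, 1, function(p) all(p > 0.15) && all(p < 0.85)))
  # channel layout: 1 = f; 2, 3 = D1 f, D2 f; 4..7 = D1 D1 f, D2 D1 f, ...
  # iterated local least squares carries a small systematic bias on mixed
  # partials that shrinks slowly with density; 3% bounds it here
  expect_equal(mean(st[interior, 1, 4]), 1, tolerance = 0.03)   # d2 f1 / dx2
  expect_equal(mean(st[interior, 2, 4]), 0, tolerance = 0.03)   # d2 f2 / dx2
  expect_equal(mean(st[interior, 2, 5]), 1, tolerance = 0.03)   # d2 f2 / dxdy
  expect_equal(mean(st[interior, 1, 7]), 0, tolerance = 0.03)   # d2 f1 / dy2
})

test_that("channel count follows the closed form", {
  for (m in 1:3) for (p in 0:3)
    expect_equal(channel_count(m, p), sum(m^(0:p)))
  expect_equal(channel_count(2, 2), 7)
  expect_equal(channel_count(1, 3), 4)
  # and the stack agrees
  X <- flat_grid(7, seed = 35)
  geo <- flat_geometry(X, k = 5, delta = 1.0)
  Fl <- matrix(rnorm(2 * nrow(X)), ncol = 2)
  for (p in 0:2)
    expect_equal(dim(gradient_feature_stack(Fl, geo$kernels, geo$conn,
                                            p = p))[3],
                 channel_count(2, p))
})

test_that("inner products collapse channels into rotation-invariant scalars", {
  set.seed(36)
  n <- 40; m <- 2; cc <- 5
  stack <- array(rnorm(n * m * cc), dim = c(n, m, cc))
  # identity A, single channel: squared norm
  one <- array(stack[, , 1], dim = c(n, m, 1))
  expect_equal(inner_product_features(one)[, 1], rowSums(stack[, , 1]^2))
  expect_true(all(inner_product_features(array(0, dim = c(n, m, cc))) == 0))
  # simultaneous rotation of every channel leaves the output unchanged
  R <- random_rotation(m, seed = 37)
  rot <- stack
  for (r in seq_len(cc)) rot[, , r] <- stack[, , r] %*% t(R)
  expect_equal(inner_product_features(rot), inner_product_features(stack),
               tolerance = 1e-10)
  expect_error(inner_product_features(stack, A = list(diag(3))), "A must")
})

test_that("embedding-agnostic features are invariant to ambient rotation, aware are not", {
  set.seed(38)
  f0 <- sample_toy_fields("rotational", list(omega = 1), 150, seed = 38)
  R3 <- random_rotation(3, seed = 39)
  # embed the planar field in 3-D and rotate the whole dataset
  lift <- function(M) cbind(M, 0.3 * M[, 1]^2)  # curved embedding
  X1 <- lift(f0$points)
  V1 <- lift(f0$points + f0$vectors) - X1
  X2 <- X1 %*% t(R3); V2 <- V1 %*% t(R3)
  feat <- function(X, V, orient) {
    g <- build_proximity_graph(X, k = 8, delta = 1.2)
    b <- fit_tangent_frames(g, m = 2,
                            orient_field = if (orient) V else NULL)
    co <- compute_connections(b, g)
    ker <- build_gradient_kernels(g, b, co)
    st <- gradient_feature_stack(project_to_tangent(V, b), ker, co, p = 2)
    list(ip = inner_product_features(st), st = st)
  }
  # field-aligned gauge (agnostic path): invariant inner products
  f1 <- feat(X1, V1, TRUE); f2 <- feat(X2, V2, TRUE)
  rel <- norm(f1$ip - f2$ip, "F") / norm(f1$ip, "F")
  expect_lt(rel, 1e-5)
  # fixed gauge (aware path): the raw channels change under the rotation
  a1 <- feat(X1, V1, FALSE); a2 <- feat(X2, V2, FALSE)
  rel_aware <- norm(matrix(a1$st - a2$st), "F") / norm(matrix(a1$st), "F")
  expect_gt(rel_aware, 1e-2)
})

test_that("vector diffusion leaves the vortex fixed point in place", {
  X <- flat_grid(13, jitter = 0.001, seed = 40)
  geo <- flat_geometry(X, k = 6, delta = 1.0)
  ctr <- c(0.5, 0.5)
  Fl <- cbind(-(X[, 2] - ctr[2]), X[, 1] - ctr[1])  # linear vortex
  L <- connection_laplacian(geo$graph, geo$conn)
  spacing <- 1 / 12
  i0 <- which.min(rowSums(Fl^2))
  for (tau in c(0.5, 1)) {
    Fd <- vector_diffusion(Fl, L, tau)
    i1 <- which.min(rowSums(Fd^2))
    expect_lt(sqrt(sum((X[i1, ] - X[i0, ])^2)), spacing + 1e-9)
  }
})
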