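test_that("toy fields realise their vector-calculus identities", {
  cst <- sample_toy_fields("constant", list(vector = c(2, -1)), 50, seed = 81)
  expect_true(all(cst$vectors[, 1] == 2 & cst$vectors[, 2] == -1))
  rot <- sample_toy_fields("rotational", list(center = c(0.5, 0.5),
                                              omega = 1.5), 400, seed = 82)
  # the field vanishes at the centre and is linear: fit f = A (x - c)
  fitA <- coef(lm(rot$vectors ~ rot$points))
  A <- unname(t(fitA[-1, ]))
  expect_equal(A[1, 1] + A[2, 2], 0, tolerance = 1e-10)        # divergence
  expect_equal(A[2, 1] - A[1, 2], 2 * 1.5, tolerance = 1e-10)  # curl = 2w
  # fixed point at the centre: predicted vector there is zero
  expect_lt(max(abs(fitA[1, ] + A %*% c(0.5, 0.5))), 1e-10)
  # radial term adds divergence
  exp_ <- sample_toy_fields("rotational", list(omega = 1, radial = 0.3),
                            400, seed = 83)
  Ae <- unname(t(coef(lm(exp_$vectors ~ exp_$points))[-1, ]))
  expect_equal(Ae[1, 1] + Ae[2, 2], 0.6, tolerance = 1e-10)
  expect_warning(sample_toy_fields("rotational", list(omega = 0), 20,
                                   seed = 84), "zero")
})

test_that("the oscillator conserves energy at zero damping and finds its cycle", {
  # fixed point at the origin stays put
  still <- simulate_vdp(0.5, n_traj = 1, T = 1, dt = 0.01, ic_range = 1e-12,
                        seed = 85, lift = FALSE)
  expect_lt(max(abs(still$trials[[1]]$state)), 1e-9)
  # mu = 0: harmonic oscillator; RK4 energy drift < 1e-6 per period
  ho <- simulate_vdp(0, n_traj = 3, T = 2 * pi, dt = 1e-3, ic_range = 0.5,
                     seed = 86, lift = FALSE)
  for (tr in ho$trials) {
    en <- rowSums(tr$state^2) / 2
    expect_lt(abs(en[length(en)] - en[1]) / en[1], 1e-6)
  }
  # mu = 0.5: convergence to a closed orbit (successive upward zero
  # crossings of y converge in position)
  lc <- simulate_vdp(0.5, n_traj = 1, T = 80, dt = 0.005, ic_range = 0.8,
                     seed = 87, lift = FALSE)
  st <- lc$trials[[1]]$state
  y <- st[, 2]
  up <- which(y[-length(y)] < 0 & y[-1] >= 0)
  xs <- st[up, 1]
  k <- length(xs)
  expect_gt(k, 5)
  expect_lt(abs(xs[k] - xs[k - 1]), 1e-3)
})

test_that("the paraboloid lift is z-consistent by construction", {
  ts <- simulate_vdp(0.3, alpha = 0.5, n_traj = 4, T = 3, dt = 0.01,
                     seed = 88)
  for (tr in ts$trials) {
    z <- tr$state[, 3]
    expect_equal(z, -(0.5 * tr$state[, 1])^2 - (0.5 * tr$state[, 2])^2,
                 tolerance = 1e-12)
  }
  # first differences of the lifted states equal the stated velocity lift
  vf <- vectors_from_trajectories(ts)
  parab <- function(x, y) -(0.5 * x)^2 - (0.5 * y)^2
  dz <- parab(vf$points[, 1] + vf$vectors[, 1],
              vf$points[, 2] + vf$vectors[, 2]) -
    parab(vf$points[, 1], vf$points[, 2])
  expect_equal(vf$vectors[, 3], dz, tolerance = 1e-12)
})

test_that("task trials respect the epoch protocol and target rule", {
  trials <- make_dms_trials(gain = 0.7, n_trials = 400, seed = 89, dt = 50)
  fix <- vapply(trials, function(tr) tr$epochs[["fixation"]], numeric(1))
  del <- vapply(trials, function(tr) tr$epochs[["delay"]], numeric(1))
  expect_true(all(fix >= 100 & fix <= 500))
  expect_true(all(del >= 500 & del <= 3000))
  # the uniform bounds are approached empirically
  expect_lt(min(fix), 150); expect_gt(max(fix), 450)
  expect_lt(min(del), 700); expect_gt(max(del), 2800)
  expect_equal(vapply(trials, function(tr) tr$epochs[["stim1"]], numeric(1)),
               rep(500, 400))
  # target +1 iff the two stimulus identities match; inputs only in epochs
  for (tr in trials[1:30]) {
    expect_equal(tr$target, if (tr$stimuli[1] == tr$stimuli[2]) 1 else -1)
    on <- tr$onsets
    u <- tr$u
    expect_true(all(u[1:(on[2] - 1), ] == 0))                 # fixation
    expect_true(all(u[on[2]:(on[3] - 1), tr$stimuli[1]] == 0.7))
    expect_true(all(u[on[2]:(on[3] - 1), 3 - tr$stimuli[1]] == 0))
    expect_true(all(u[on[3]:(on[4] - 1), ] == 0))             # delay
    expect_true(all(u[on[5]:nrow(u), ] == 0))                 # decision
  }
  # the four combinations are balanced: match probability 0.5
  match_frac <- mean(vapply(trials, function(tr) tr$target == 1, logical(1)))
  expect_lt(abs(match_frac - 0.5), 3 * sqrt(0.25 / 400))
  # gain 0: identically zero inputs
  z <- make_dms_trials(0, n_trials = 5, seed = 90, dt = 50)
  expect_true(all(vapply(z, function(tr) all(tr$u == 0), logical(1))))
})

test_that("rate network integrates its linear and low-rank limits correctly", {
  # zero connectivity, zero input, zero noise: exponential decay from x0
  p <- rnn_params(N = 20, R = 2, seed = 91, sigma_noise = 0)
  p$M[] <- 0; p$Nm[] <- 0; p$Win[] <- 0
  x0 <- rnorm(20)
  sim <- simulate_rnn(p, list(u = matrix(0, 500, 2), dt = 1), dt = 1,
                      x0 = x0)
  expect_equal(sim$X[301, ], x0 * (1 - 1 / 100)^300, tolerance = 1e-10)
  expect_error(simulate_rnn(p, list(u = matrix(0, 5, 2), dt = 200),
                            dt = 200), "dt must")
  # rank-2 connectivity, zero noise: off-plane component decays as exp(-t/tau)
  p2 <- rnn_params(N = 40, R = 2, seed = 92, sigma_noise = 0)
  p2$Win[] <- 0
  set.seed(93)
  x0 <- rnorm(40)
  sim2 <- simulate_rnn(p2, list(u = matrix(0, 1200, 2), dt = 1), dt = 1,
                       x0 = x0)
  B <- qr.Q(qr(p2$M))           # trajectory plane spanned by m_1, m_2
  X <- sim2$X
  resid <- X - X %*% B %*% t(B)
  r0 <- sqrt(sum(resid[1, ]^2))
  r10 <- sqrt(sum(resid[1001, ]^2))  # t = 10 tau
  expect_lt(r10, max(1e-6, r0 * exp(-10) * 1.05))
  # stationary noise variance matches the Ornstein-Uhlenbeck closed form
  p3 <- rnn_params(N = 200, R = 2, seed = 94, sigma_noise = 0.03)
  p3$M[] <- 0; p3$Nm[] <- 0; p3$Win[] <- 0
  set.seed(95)
  sim3 <- simulate_rnn(p3, list(u = matrix(0, 3000, 2), dt = 1), dt = 1)
  v <- var(as.numeric(sim3$X[1500:3001, ]))
  expect_equal(v, 0.03^2 / 2, tolerance = 0.1)
})

test_that("rank-2 trajectories are planar after the input transient", {
  p <- rnn_params(N = 64, R = 2, seed = 96, sigma_noise = 0)
  tr <- make_dms_trials(1, n_trials = 1, seed = 97, dt = 2)[[1]]
  sim <- simulate_rnn(p, tr, dt = 2)
  # states from 3 tau after the last stimulus to trial end
  from <- tr$onsets[5] + 150
  X <- sim$X[from:nrow(sim$X), ]
  pc <- prcomp(X, center = FALSE)
  resid <- sum(pc$sdev[-(1:2)]^2) / sum(pc$sdev^2)
  expect_lt(resid, 1e-4)
})

test_that("task accuracy behaves at chance and at ceiling", {
  # deterministic correct outputs: accuracy 1 (readout aligned with target)
  p <- rnn_params(N = 16, R = 2, seed = 98, sigma_noise = 0)
  # an untrained network is at chance over balanced targets
  acc <- rnn_task_performance(p, gain = 1, n_trials = 300, seed = 99, dt = 5)
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / 300) + 0.15)
})
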