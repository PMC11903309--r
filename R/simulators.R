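# Self-contained dynamical simulators: planar toy fields, the Van der Pol
# oscillator lifted to a paraboloid, and rank-R rate RNNs performing a
# delayed-match-to-sample (DMS) working-memory task.

#' Sample planar toy vector fields
#'
#' Points uniform on the unit square with either a constant field
#' `f = vector` or a rotational field
#' \eqn{f(x) = \omega R_{90}(x - center) + radial\,(x - center)} (positive
#' `radial` gives expansion, negative contraction).
#'
#' @param kind `"constant"` or `"rotational"`.
#' @param params list: `vector` (constant), or `center`, `omega`, `radial`
#'   (rotational; defaults `c(0.5, 0.5)`, `1`, `0`).
#' @param n_points number of sampled points (at least 10).
#' @param seed integer seed.
#' @param condition label for the output field.
#' @return A [vector_field].
#' @export
sample_toy_fields <- function(kind = c("constant", "rotational"),
                              params = list(), n_points = 200, seed = 1,
                              condition = kind) {
  kind <- match.arg(kind)
  stopifnot(n_points >= 10)
  set.seed(seed)
  X <- cbind(runif(n_points), runif(n_points))
  if (kind == "constant") {
    v <- params$vector
    if (is.null(v)) v <- c(1, 0)
    V <- matrix(v, n_points, 2, byrow = TRUE)
  } else {
    ctr <- if (is.null(params$center)) c(0.5, 0.5) else params$center
    om <- if (is.null(params$omega)) 1 else params$omega
    rad <- if (is.null(params$radial)) 0 else params$radial
    if (om == 0 && rad == 0)
      warning("rotational field with omega = 0 and no radial term is ",
              "identically zero")
    R <- sweep(X, 2, ctr)
    V <- om * cbind(-R[, 2], R[, 1]) + rad * R
  }
  vector_field(X, V, condition = condition[1])
}

#' Simulate the Van der Pol oscillator, lifted to a paraboloid
#'
#' Integrates \eqn{\dot x = y,\ \dot y = \mu(1 - x^2) y - x} by classical
#' RK4 from random initial conditions uniform in
#' \eqn{[-ic, ic]^2}. For \eqn{\mu < 0} the origin is stable inside an
#' unstable limit cycle, so initial conditions outside its basin diverge in
#' finite time; the default `ic_range = 1` keeps the whole damping sweep
#' \eqn{\mu \in [-1, 1]} bounded. At \eqn{\mu = 0}
#' the system is the harmonic oscillator; for \eqn{\mu > 0} trajectories
#' converge to a limit cycle (Hopf bifurcation at \eqn{\mu = 0}). When
#' `lift = TRUE` each planar trajectory is mapped onto the paraboloid
#' \eqn{z = \mathrm{parab}(x, y) = -(\alpha x)^2 - (\alpha y)^2}, so that
#' first differences of the lifted states realise the velocity lift
#' \eqn{\dot z = \mathrm{parab}(x + \dot x, y + \dot y) -
#' \mathrm{parab}(x, y)} exactly.
#'
#' @param mu damping parameter.
#' @param alpha paraboloid curvature (not the subsampling spacing).
#' @param n_traj number of trajectories.
#' @param T total integration time per trajectory (time units).
#' @param dt RK4 step.
#' @param ic_range half-width of the initial-condition box.
#' @param ic optional `n_traj x 2` matrix of initial conditions overriding
#'   the uniform draw (e.g. a stratified design).
#' @param seed integer seed for the initial conditions.
#' @param lift map trajectories onto the paraboloid (3-D output).
#' @param condition label; defaults to `mu` formatted.
#' @return A [trajectory_set] (d = 3 when lifted, d = 2 otherwise).
#'   Trajectories exceeding |state| = 1e3 are truncated with a warning.
#' @export
simulate_vdp <- function(mu, alpha = 1, n_traj = 50, T = 2, dt = 0.01,
                         ic_range = 1, ic = NULL, seed = 1, lift = TRUE,
                         condition = sprintf("mu=%.3f", mu)) {
  stopifnot(dt > 0, T >= dt, n_traj >= 1, ic_range > 0)
  set.seed(seed)
  nstep <- round(T / dt)
  if (is.null(ic)) {
    x <- runif(n_traj, -ic_range, ic_range)
    y <- runif(n_traj, -ic_range, ic_range)
  } else {
    ic <- as.matrix(ic)
    stopifnot(nrow(ic) == n_traj, ncol(ic) == 2)
    x <- ic[, 1]; y <- ic[, 2]
  }
  deriv <- function(x, y) list(dx = y, dy = mu * (1 - x^2) * y - x)
  states <- array(NA_real_, dim = c(nstep + 1L, n_traj, 2L))
  states[1L, , ] <- cbind(x, y)
  for (s in seq_len(nstep)) {
    k1 <- deriv(x, y)
    k2 <- deriv(x + dt / 2 * k1$dx, y + dt / 2 * k1$dy)
    k3 <- deriv(x + dt / 2 * k2$dx, y + dt / 2 * k2$dy)
    k4 <- deriv(x + dt * k3$dx, y + dt * k3$dy)
    x <- x + dt / 6 * (k1$dx + 2 * k2$dx + 2 * k3$dx + k4$dx)
    y <- y + dt / 6 * (k1$dy + 2 * k2$dy + 2 * k3$dy + k4$dy)
    states[s + 1L, , ] <- cbind(x, y)
  }
  times <- seq(0, by = dt, length.out = nstep + 1L)
  blew <- FALSE
  trials <- lapply(seq_len(n_traj), function(tr) {
    st <- states[, tr, ]
    bad <- which(apply(abs(st), 1, max) > 1e3)
    tt <- times
    if (length(bad)) {
      blew <<- TRUE
      keep <- seq_len(max(2L, min(bad) - 1L))
      st <- st[keep, , drop = FALSE]; tt <- tt[keep]
    }
    if (lift) st <- cbind(st, -(alpha * st[, 1])^2 - (alpha * st[, 2])^2)
    list(time = tt, state = st)
  })
  if (blew) warning("trajectory blow-up (|state| > 1e3); truncated")
  trajectory_set(trials, condition = condition)
}

#' Random rank-R RNN parameters
#'
#' Connectivity \eqn{J = (1/N) \sum_r m_r n_r^\top}; all coefficient
#' vectors drawn i.i.d. standard normal. Time constant in milliseconds.
#'
#' @param N number of rate units.
#' @param R connectivity rank.
#' @param n_in number of input channels.
#' @param tau_rnn membrane time constant, ms.
#' @param sigma_noise white-noise standard deviation.
#' @param seed integer seed.
#' @return Object of class `rnn_params`: `M`, `Nm` (`N x R`), `Win`
#'   (`N x n_in`), `wout` (`N`), `tau_rnn`, `sigma`.
#' @export
rnn_params <- function(N = 128, R = 2, n_in = 2, tau_rnn = 100,
                       sigma_noise = 3e-2, seed = 1) {
  stopifnot(N >= 1, R >= 1, tau_rnn > 0)
  set.seed(seed)
  structure(list(M = matrix(rnorm(N * R), N, R),
                 Nm = matrix(rnorm(N * R), N, R),
                 Win = matrix(rnorm(N * n_in), N, n_in),
                 wout = rnorm(N),
                 N = N, R = R, n_in = n_in,
                 tau_rnn = tau_rnn, sigma = sigma_noise),
            class = "rnn_params")
}

#' @export
print.rnn_params <- function(x, ...) {
  cat(sprintf(
    "Rank-%d rate RNN: N = %d units, %d input(s), tau = %g ms, noise sd %g\n",
    x$R, x$N, x$n_in, x$tau_rnn, x$sigma))
  invisible(x)
}

#' Generate delayed-match-to-sample trials
#'
#' Five epochs: fixation (100-500 ms, uniform), stimulus 1 (500 ms), delay
#' (500-3,000 ms, uniform), stimulus 2 (500 ms), decision (1,000 ms). In
#' each stimulus epoch one of two stimuli is shown, encoded by which input
#' channel carries the amplitude `gain` during that epoch (inputs are zero
#' at all other times). The target is +1 when the two stimuli match and
#' -1 otherwise; the four stimulus combinations are balanced, so match and
#' non-match trials are equiprobable and chance performance is 0.5. Note
#' the network dynamics are odd-symmetric (`tanh` rates, linear readout),
#' so a task variant in which non-match trials can carry no input at all
#' is not solvable above ~0.9 — the two-alternative encoding used here is
#' the one under which the task trains to criterion.
#'
#' @param gain stimulus amplitude (>= 0; 0 gives identically zero inputs).
#' @param n_trials number of trials.
#' @param seed integer seed.
#' @param dt sampling step of the input traces, ms.
#' @return List of trials; each has `u` (T x 2 input trace), `target`,
#'   `stimuli` (length-2 integer, which channel was shown in each epoch),
#'   `epochs` (durations, ms), `onsets` (epoch start indices) and `gain`.
#' @export
make_dms_trials <- function(gain, n_trials = 1, seed = 1, dt = 1) {
  stopifnot(gain >= 0, n_trials >= 1, dt > 0)
  set.seed(seed)
  lapply(seq_len(n_trials), function(i) {
    fix <- runif(1, 100, 500)
    del <- runif(1, 500, 3000)
    durs <- c(fixation = fix, stim1 = 500, delay = del,
              stim2 = 500, decision = 1000)
    steps <- pmax(1L, round(durs / dt))
    bounds <- cumsum(c(0L, steps))
    Tn <- bounds[length(bounds)]
    stimuli <- c(sample.int(2L, 1L), sample.int(2L, 1L))
    u <- matrix(0, Tn, 2L)
    u[(bounds[2] + 1L):bounds[3], stimuli[1]] <- gain
    u[(bounds[4] + 1L):bounds[5], stimuli[2]] <- gain
    list(u = u, target = if (stimuli[1] == stimuli[2]) 1 else -1,
         stimuli = stimuli,
         epochs = durs, onsets = bounds[-length(bounds)] + 1L,
         gain = gain, dt = dt)
  })
}

#' Simulate a rate RNN on one trial
#'
#' Euler-Maruyama integration of
#' \eqn{\tau \dot x_i = -x_i + \sum_j J_{ij}\phi(x_j) + \tilde u_i(t) +
#' \eta_i(t)} with \eqn{\phi = \tanh}, \eqn{x(0) = 0} and readout
#' \eqn{o(t) = \sum_i w^{out}_i \phi(x_i)}.
#'
#' @param params an [rnn_params] object.
#' @param trial a trial from [make_dms_trials] (or any list with a `u`
#'   matrix of per-step inputs).
#' @param dt integration step, ms; must satisfy `dt < tau_rnn` (the trial's
#'   input trace is resampled if its `dt` differs).
#' @param seed optional integer seed for the noise.
#' @param x0 optional initial state (defaults to zeros, the task protocol).
#' @return List: `X` ((T+1) x N states), `rates` (tanh of `X`), `o`
#'   (readout trace), `time` (ms).
#' @export
simulate_rnn <- function(params, trial, dt = 1, seed = NULL, x0 = NULL) {
  stopifnot(inherits(params, "rnn_params"))
  if (dt >= params$tau_rnn) stop("dt must be smaller than tau_rnn")
  if (!is.null(seed)) set.seed(seed)
  u <- trial$u
  if (!is.null(trial$dt) && trial$dt != dt) {
    tend <- nrow(u) * trial$dt
    idx <- pmin(nrow(u), floor(seq(0, tend - dt, by = dt) / trial$dt) + 1L)
    u <- u[idx, , drop = FALSE]
  }
  out <- rnn_forward_cpp(params$M, params$Nm, params$Win, params$wout,
                         u, dt, params$tau_rnn, params$sigma, x0)
  list(X = out$X, rates = tanh(out$X), o = as.numeric(out$o),
       time = seq(0, by = dt, length.out = nrow(out$X)))
}

# curriculum trial builder: like make_dms_trials but with a configurable
# delay range and decision duration, and optional precursor tasks
# ("discriminate": no delay/second stimulus, report stimulus-1 identity;
# "remember": full structure, report stimulus-1 identity). Loss windows
# start at `dec0` (0-based step index).
.dms_stage_trials <- function(gain, n, dt, task, del_rng, dec_dur = 500) {
  lapply(seq_len(n), function(i) {
    durs <- c(runif(1, 100, 500), 500, runif(1, del_rng[1], del_rng[2]),
              500, dec_dur)
    steps <- pmax(1L, round(durs / dt))
    b <- cumsum(c(0L, steps))
    s <- c(sample.int(2L, 1L), sample.int(2L, 1L))
    u <- matrix(0, b[length(b)], 2L)
    u[(b[2] + 1L):b[3], s[1]] <- gain
    if (task != "hold") u[(b[4] + 1L):b[5], s[2]] <- gain
    target <- if (task == "match") {
      if (s[1] == s[2]) 1 else -1
    } else {
      if (s[1] == 1L) 1 else -1
    }
    # "hold": no second stimulus, loss runs from stimulus-1 offset so the
    # identity must be expressed continuously; others: decision epoch only
    list(u = u, target = target,
         dec0 = if (task == "hold") b[3] else b[5])
  })
}

# accuracy on a list of stage trials
.stage_accuracy <- function(params, trials, dt) {
  mean(vapply(trials, function(tr) {
    oT <- rnn_final_output_cpp(params$M, params$Nm, params$Win, params$wout,
                               tr$u, dt, params$tau_rnn, params$sigma)
    sign(oT) == tr$target
  }, logical(1)))
}

#' Train a rank-R RNN on the delayed-match-to-sample task
#'
#' Optimises the decision-epoch loss \eqn{|o(t) - \hat o(T)|} (averaged
#' over the decision window; at convergence this coincides with the
#' final-time loss) over random trials at the given gain, with Adam and
#' backpropagation through time of the Euler-Maruyama recurrence.
#'
#' Training from a cold start uses a shaping curriculum, which is what
#' makes the task reachable at desk scale: express the identity of
#' stimulus 1 continuously from its offset (near-zero delay, no second
#' stimulus), then hold it across realistic delays, then across the
#' second stimulus as a distractor (building a robust persistent memory),
#' then learn the match rule (retried from the memory checkpoint under
#' fresh sampling streams if it stalls), and finally fine-tune on the
#' full task protocol. Stages anneal their learning rate on validation
#' plateaus, rewinding to the best parameters seen. Each stage
#' tracks a validation accuracy, keeps the best parameters seen, reverts
#' to them (halving the learning rate) after a catastrophic drop, and
#' advances once its criterion or iteration budget is reached. Direct
#' training on the full protocol without shaping stalls at chance: the
#' match computation has no first-order gradient signal at a symmetric
#' initialisation.
#'
#' @param N,R network size and connectivity rank (R >= 2 for this task).
#' @param gain training stimulus gain.
#' @param dt integration step, ms.
#' @param batch trials per Adam update.
#' @param max_iter iteration budget for the final (full-protocol) stage.
#' @param lr base Adam learning rate (stages scale it).
#' @param curriculum use the shaping curriculum (recommended).
#' @param val_every validation cadence, iterations.
#' @param target_acc stop once full-protocol validation accuracy reaches
#'   this.
#' @param restarts maximum curriculum restarts from fresh initialisations
#'   when the match stage stays stuck.
#' @param seed integer seed (initialisation, trials, noise).
#' @param verbose print progress.
#' @return The trained [rnn_params], with attributes `history` (per-batch
#'   mean loss), `val_acc` (validation accuracy trace) and `converged`.
#' @export
train_rnn <- function(N = 128, R = 2, gain = 1, dt = 5, batch = 32,
                      max_iter = 400, lr = 0.02, curriculum = TRUE,
                      val_every = 25, target_acc = 0.99, restarts = 1,
                      seed = 1, verbose = FALSE) {
  stopifnot(R >= 2)
  set.seed(seed)
  params <- rnn_params(N = N, R = R, seed = seed)
  th <- c(params$M, params$Nm, params$Win, params$wout)
  np <- c(M = N * R, Nm = N * R, Win = N * params$n_in, wout = N)
  st <- .adam_new(th)
  unpack <- function(th) {
    pos <- 0L
    params$M[] <<- th[pos + seq_len(np[1])]; pos <- pos + np[1]
    params$Nm[] <<- th[pos + seq_len(np[2])]; pos <- pos + np[2]
    params$Win[] <<- th[pos + seq_len(np[3])]; pos <- pos + np[3]
    params$wout <<- th[pos + seq_len(np[4])]
  }
  history <- numeric(0); val_acc <- numeric(0)

  run_stage <- function(task, del_rng, iters, stage_lr, stop_acc,
                        full = FALSE, tag = task, abort_below = NULL,
                        abort_at = Inf, min_iter = 0L, anneal = FALSE) {
    best <- list(acc = -Inf, th = th, st = st)
    cur_lr <- stage_lr
    hits <- 0L; stale <- 0L
    for (it in seq_len(iters)) {
      trials <- if (full) {
        make_dms_trials(gain, n_trials = batch,
                        seed = sample.int(2^31 - 1, 1), dt = dt)
      } else {
        .dms_stage_trials(gain, batch, dt, task, del_rng)
      }
      g <- 0 * th; loss <- 0
      for (tr in trials) {
        dec0 <- if (full) tr$onsets[5] - 1L else tr$dec0
        r <- rnn_loss_grad_cpp(params$M, params$Nm, params$Win,
                               params$wout, tr$u, tr$target, dt,
                               params$tau_rnn, params$sigma, dec0)
        g <- g + c(r$gM, r$gNm, r$gWin, r$gwout) / batch
        loss <- loss + r$loss / batch
      }
      if (!all(is.finite(g))) stop("RNN training diverged (non-finite)")
      upd <- .adam_step(th, g, st, cur_lr)
      th <<- upd$par; st <<- upd$state
      unpack(th)
      history <<- c(history, loss)
      if (it %% val_every == 0 || it == iters) {
        vt <- if (full) {
          make_dms_trials(gain, n_trials = 100,
                          seed = sample.int(2^31 - 1, 1), dt = dt)
        } else .dms_stage_trials(gain, 100, dt, task, del_rng)
        acc <- .stage_accuracy(params, vt, dt)
        val_acc <<- c(val_acc, acc)
        if (verbose)
          message(sprintf("[%s] iter %4d  loss %.3f  val acc %.3f",
                          tag, it, loss, acc))
        if (acc > best$acc) {
          best <- list(acc = acc, th = th, st = st); stale <- 0L
        } else stale <- stale + 1L
        if (anneal && stale >= 8L) {
          # plateau: rewind to the best point and take finer steps
          th <<- best$th; st <<- best$st
          unpack(th)
          cur_lr <- cur_lr / 2
          stale <- 0L
          if (verbose) message(sprintf("[%s] annealed; lr -> %g", tag, cur_lr))
        }
        if (acc >= stop_acc && it >= min_iter) break
        # a stuck stage will not unstick: hand control back for a restart
        if (!is.null(abort_below) && best$acc < abort_below &&
            (it >= abort_at || (anneal && cur_lr < stage_lr / 16))) break
      }
    }
    th <<- best$th; st <<- best$st
    unpack(th)
    best$acc
  }

  # the hold/remember stages are reliable; escaping the match plateau is
  # stochastic. Retry the match stage from the post-remember checkpoint
  # under fresh sampling streams, keeping the best outcome.
  overall <- list(acc = -Inf, th = th)
  if (curriculum) {
    run_stage("hold", c(0, 1), 150, 2.5 * lr, 0.99)
    run_stage("hold", c(100, 1000), 200, 2.5 * lr, 0.97, anneal = TRUE,
              tag = "hold-delay")
    # the distractor (remember) stage must produce a robust memory before
    # the match rule is learnable; gate it and retry on a stalled draw
    ck0 <- list(th = th, st = st)
    for (rt in 0:2) {
      if (rt > 0) {
        if (verbose) message(sprintf("remember retry %d", rt))
        th <- ck0$th; st <- ck0$st
        unpack(th)
        set.seed(seed + 3331L * rt)
      }
      racc <- run_stage("remember", c(100, 1000), 300, 2.5 * lr, 0.95,
                        anneal = TRUE)
      if (racc >= 0.9) break
    }
    ckpt <- list(th = th, st = st)
    for (try in 0:(restarts + 1L)) {
      if (try > 0) {
        if (verbose) message(sprintf("match retry %d", try))
        th <- ckpt$th; st <- ckpt$st
        unpack(th)
        set.seed(seed + 7777L * try + 13L)
      }
      macc <- run_stage("match", c(100, 1500), 1500, 0.5 * lr, 0.99,
                        abort_below = 0.85, anneal = TRUE)
      if (macc > overall$acc) overall <- list(acc = macc, th = th)
      if (macc >= 0.9) break
    }
    th <- overall$th; st <- .adam_new(th)
    unpack(th)
  }
  final_acc <- run_stage("match", NULL, max_iter, 0.4 * lr, target_acc,
                         full = TRUE, tag = "full")
  converged <- final_acc >= target_acc
  if (!converged)
    warning(sprintf("validation accuracy %.3f below target %.2f; ",
                    final_acc, target_acc),
            "returning best parameters")
  attr(params, "history") <- history
  attr(params, "val_acc") <- val_acc
  attr(params, "converged") <- converged
  params
}

#' Task accuracy of an RNN over random trials
#'
#' Fraction of trials on which the sign of the final readout matches the
#' target.
#'
#' @param params an [rnn_params].
#' @param gain stimulus gain of the evaluation trials.
#' @param n_trials number of trials.
#' @param seed integer seed.
#' @param dt integration step, ms.
#' @return Accuracy in `[0, 1]`.
#' @export
rnn_task_performance <- function(params, gain, n_trials = 200, seed = 1,
                                 dt = 2) {
  stopifnot(n_trials >= 1)
  trials <- make_dms_trials(gain, n_trials = n_trials, seed = seed, dt = dt)
  correct <- vapply(trials, function(tr) {
    oT <- rnn_final_output_cpp(params$M, params$Nm, params$Win, params$wout,
                               tr$u, dt, params$tau_rnn, params$sigma)
    sign(oT) == tr$target
  }, logical(1))
  mean(correct)
}
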