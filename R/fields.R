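# Ingestion: multi-trial time series -> anchored discrete vector fields.

#' Construct a set of trials under one experimental condition
#'
#' A trajectory set holds multiple trials of a \eqn{d}-dimensional continuous
#' state variable (for example, smoothed firing rates), all recorded under the
#' same condition. Trials are never averaged; each contributes its own states.
#'
#' @param trials list; each element is a list with components `time` (numeric,
#'   strictly increasing, seconds) and `state` (numeric matrix, one row per
#'   time point, `d` columns). A plain matrix is accepted for `state` with
#'   `time` defaulting to `0:(nrow-1)`.
#' @param condition character scalar labelling the condition.
#' @return An object of class `trajectory_set`.
#' @examples
#' tr <- trajectory_set(list(list(time = 0:2, state = cbind(0:2, c(0, 0, 1)))))
#' vectors_from_trajectories(tr)
#' @export
trajectory_set <- function(trials, condition = "c1") {
  stopifnot(is.list(trials), length(trials) >= 1L)
  trials <- lapply(seq_along(trials), function(i) {
    tr <- trials[[i]]
    if (is.matrix(tr) || is.data.frame(tr)) tr <- list(state = as.matrix(tr))
    state <- as.matrix(tr$state)
    storage.mode(state) <- "double"
    time <- if (is.null(tr$time)) seq_len(nrow(state)) - 1 else as.numeric(tr$time)
    if (nrow(state) < 2L)
      stop("trial ", i, " has fewer than 2 samples")
    if (length(time) != nrow(state))
      stop("trial ", i, ": time and state lengths differ")
    if (any(diff(time) <= 0))
      stop("trial ", i, ": times must strictly increase")
    if (!all(is.finite(state)))
      stop("trial ", i, ": non-finite state values")
    list(time = time, state = state)
  })
  d <- unique(vapply(trials, function(tr) ncol(tr$state), integer(1)))
  if (length(d) != 1L) stop("all trials must share the same dimension d")
  structure(list(condition = as.character(condition), trials = trials, d = d),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  lens <- vapply(x$trials, function(tr) length(tr$time), integer(1))
  cat(sprintf("Trajectory set '%s': %d trial(s), d = %d, %d samples total\n",
              x$condition, length(x$trials), x$d, sum(lens)))
  invisible(x)
}

#' Construct an anchored discrete vector field
#'
#' The basic input unit of the representation pipeline: a point cloud
#' \eqn{X} (sampled states) with a vector \eqn{f_i} anchored at every point.
#'
#' @param points numeric matrix, `n x d` anchor points.
#' @param vectors numeric matrix, `n x d` vectors, same shape as `points`.
#' @param condition character condition label.
#' @param source_index optional data frame (`trial`, `step`) recording where
#'   each point came from.
#' @return Object of class `vector_field`.
#' @export
vector_field <- function(points, vectors, condition = "c1", source_index = NULL) {
  points <- as.matrix(points); vectors <- as.matrix(vectors)
  storage.mode(points) <- "double"; storage.mode(vectors) <- "double"
  if (!identical(dim(points), dim(vectors)))
    stop("points and vectors must have identical shape")
  if (nrow(points) < 1L) stop("need at least one point")
  if (!all(is.finite(points)) || !all(is.finite(vectors)))
    stop("non-finite entries in points or vectors")
  if (!is.null(source_index)) {
    source_index <- as.data.frame(source_index)
    stopifnot(nrow(source_index) == nrow(points))
  }
  structure(list(condition = as.character(condition),
                 points = points, vectors = vectors,
                 source_index = source_index),
            class = "vector_field")
}

#' @export
print.vector_field <- function(x, ...) {
  cat(sprintf("Vector field '%s': n = %d points in R^%d\n",
              x$condition, nrow(x$points), ncol(x$points)))
  invisible(x)
}

#' First-order finite differences of trials
#'
#' Converts each trial \eqn{x(t)} into anchored vectors
#' \eqn{f(t) = x(t+1) - x(t)} at points \eqn{x(t)}, dropping the terminal
#' sample of every trial. With `normalize_dt = TRUE` the differences are
#' divided by the local time step (velocity convention), useful for
#' irregularly sampled trials; the default keeps raw differences.
#'
#' @param traj a [trajectory_set].
#' @param normalize_dt logical; divide differences by \eqn{\Delta t}.
#' @return A [vector_field] with `n = sum(trial lengths - 1)` rows and
#'   per-point provenance in `source_index`.
#' @export
vectors_from_trajectories <- function(traj, normalize_dt = FALSE) {
  stopifnot(inherits(traj, "trajectory_set"))
  pts <- vecs <- vector("list", length(traj$trials))
  src <- vector("list", length(traj$trials))
  for (i in seq_along(traj$trials)) {
    tr <- traj$trials[[i]]
    nt <- nrow(tr$state)
    dif <- tr$state[-1L, , drop = FALSE] - tr$state[-nt, , drop = FALSE]
    if (normalize_dt) dif <- dif / diff(tr$time)
    pts[[i]] <- tr$state[-nt, , drop = FALSE]
    vecs[[i]] <- dif
    src[[i]] <- data.frame(trial = i, step = seq_len(nt - 1L))
  }
  vector_field(do.call(rbind, pts), do.call(rbind, vecs),
               condition = traj$condition,
               source_index = do.call(rbind, src))
}

#' Smooth spike trains into firing rates
#'
#' Convolves each unit's spike times with a Gaussian kernel (truncated at
#' four standard deviations) and samples the result on a regular grid,
#' yielding rates in events per second. An empty spike list gives an
#' all-zero trace.
#'
#' @param spike_times list with one numeric vector of event times (seconds)
#'   per unit.
#' @param kernel_sd Gaussian kernel standard deviation, seconds.
#' @param bin sampling interval of the output grid, seconds.
#' @param t_range optional length-2 window; defaults to
#'   `c(0, max spike time)` padded by `4 * kernel_sd`.
#' @param condition condition label for the output.
#' @return A [trajectory_set] with a single trial whose state has one column
#'   per unit.
#' @export
rates_from_spikes <- function(spike_times, kernel_sd, bin, t_range = NULL,
                              condition = "c1") {
  stopifnot(kernel_sd > 0, bin > 0, is.list(spike_times))
  all_t <- unlist(spike_times, use.names = FALSE)
  if (length(all_t) && any(all_t < 0)) stop("negative spike times")
  if (is.null(t_range)) {
    hi <- if (length(all_t)) max(all_t) else 1
    t_range <- c(0, hi + 4 * kernel_sd)
  }
  grid <- seq(t_range[1], t_range[2], by = bin)
  trunc <- 4 * kernel_sd
  rates <- vapply(spike_times, function(sp) {
    r <- numeric(length(grid))
    for (s in sp) {
      w <- which(abs(grid - s) <= trunc)
      r[w] <- r[w] + stats::dnorm(grid[w], mean = s, sd = kernel_sd)
    }
    r
  }, numeric(length(grid)))
  rates <- matrix(rates, nrow = length(grid))
  trajectory_set(list(list(time = grid, state = rates)), condition = condition)
}

#' Read per-condition trials from a delimited table
#'
#' Expects columns `trial`, `time`, then the `d` state channels.
#'
#' @param path CSV file path.
#' @param condition condition label (defaults to the file name).
#' @return A [trajectory_set].
#' @export
read_trajectories <- function(path, condition = NULL) {
  if (is.null(condition))
    condition <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.csv(path)
  if (!all(c("trial", "time") %in% names(df)))
    stop("expected columns 'trial' and 'time'")
  ycols <- setdiff(names(df), c("trial", "time"))
  trials <- lapply(split(df, df$trial), function(tr) {
    tr <- tr[order(tr$time), , drop = FALSE]
    list(time = tr$time, state = as.matrix(tr[, ycols, drop = FALSE]))
  })
  trajectory_set(unname(trials), condition = condition)
}

#' Write a trajectory set to a delimited table
#'
#' @param traj a [trajectory_set].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory_set"))
  rows <- lapply(seq_along(traj$trials), function(i) {
    tr <- traj$trials[[i]]
    st <- as.data.frame(tr$state)
    names(st) <- paste0("y", seq_len(ncol(st)))
    cbind(data.frame(trial = i, time = tr$time), st)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Normalise the speed scale of a vector field
#'
#' Dynamical systems are often compared by the geometry of their flow
#' rather than its raw speed (which may be in arbitrary units or differ by
#' orders of magnitude across conditions). `"mean"` divides all vectors by
#' their mean norm; `"unit"` rescales every vector to unit length, keeping
#' only the direction field.
#'
#' @param field a [vector_field].
#' @param method `"mean"` or `"unit"`.
#' @return A [vector_field] with rescaled vectors.
#' @export
normalize_vectors <- function(field, method = c("mean", "unit")) {
  method <- match.arg(method)
  stopifnot(inherits(field, "vector_field"))
  nr <- sqrt(rowSums(field$vectors^2))
  V <- if (method == "unit") field$vectors / pmax(nr, 1e-12)
       else field$vectors / max(mean(nr), 1e-12)
  vector_field(field$points, V, condition = field$condition,
               source_index = field$source_index)
}

#' Project states onto leading principal components
#'
#' Optional generic projection utility for high-dimensional recordings; fits
#' a single PCA across all trials of all supplied trajectory sets and
#' projects each trial into the leading subspace.
#'
#' @param trajs a [trajectory_set] or list of them.
#' @param ncomp number of components to retain.
#' @return Same structure as the input, with `d = ncomp`.
#' @export
project_pca <- function(trajs, ncomp) {
  single <- inherits(trajs, "trajectory_set")
  if (single) trajs <- list(trajs)
  allx <- do.call(rbind, lapply(trajs, function(ts)
    do.call(rbind, lapply(ts$trials, `[[`, "state"))))
  pc <- stats::prcomp(allx, center = TRUE, rank. = ncomp)
  out <- lapply(trajs, function(ts) {
    trials <- lapply(ts$trials, function(tr) {
      proj <- scale(tr$state, center = pc$center, scale = FALSE) %*%
        pc$rotation[, seq_len(ncomp), drop = FALSE]
      list(time = tr$time, state = proj)
    })
    trajectory_set(trials, condition = ts$condition)
  })
  if (single) out[[1]] else out
}
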