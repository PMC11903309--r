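# Orchestration: validated run configurations, presets for the three
# built-in experiments, and an end-to-end pipeline writing artifacts to
# disk (embeddings, distance matrix, post-analysis, manifest).

.config_defaults <- function() {
  list(
    preset = "toy",            # toy | vdp | rnn-gain
    seed = NULL,               # mandatory
    outdir = "flowrep-run",
    mode = NULL,               # resolved per preset when NULL
    m = 2, p = NULL, E = NULL, k = 15, delta = 1.0, alpha = 0, tau = NULL,
    K = NULL, Q = 1, lr = 1e-2, epochs = 120, patience = 20,
    clip = NULL, unit_vectors = NULL,
    # toy preset
    toy_n_points = 300,
    # Van der Pol preset
    vdp_mus = seq(-1, 1, length.out = 20), vdp_alpha = 0.5,
    vdp_n_traj = 50, vdp_T = 10, vdp_dt = 0.01, vdp_subsample = 200,
    vdp_reps = 5,
    # RNN gain-sweep preset
    rnn_N = 128, rnn_gains = seq(0.05, 1, length.out = 20),
    rnn_zero_controls = 20, rnn_trials_per_cond = 20, rnn_dt = 5,
    rnn_train_iter = 400, rnn_pca = 5, rnn_subsample = 200)
}

# preset-specific defaults for entries the user left NULL
.preset_resolve <- function(cfg) {
  fill <- function(key, val) {
    if (is.null(cfg[[key]])) cfg[[key]] <<- val
  }
  switch(cfg$preset,
    "toy" = {
      fill("mode", "embedding-aware"); fill("p", 2); fill("E", 3)
      fill("unit_vectors", FALSE); fill("tau", 0)
    },
    "vdp" = {
      # tau = 2: vector diffusion denoises the sparse per-condition fields
      fill("mode", "embedding-agnostic"); fill("p", 2); fill("E", 5)
      fill("clip", 0.95); fill("unit_vectors", TRUE); fill("tau", 2)
    },
    "rnn-gain" = {
      # gain modulation is a magnitude effect: vectors stay unnormalised
      fill("mode", "embedding-agnostic"); fill("p", 2); fill("E", 5)
      fill("clip", 0.95); fill("unit_vectors", FALSE); fill("tau", 0)
    })
  cfg
}

#' Build a validated run configuration
#'
#' Unknown keys are rejected; `seed` is mandatory. Defaults encode the
#' three built-in experiments (`toy`, `vdp`, `rnn-gain`).
#'
#' @param ... configuration entries overriding the defaults (see
#'   [run_pipeline] for their meaning), or a single named list.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(...) {
  over <- list(...)
  if (length(over) == 1L && is.null(names(over)) && is.list(over[[1L]]))
    over <- over[[1L]]
  defs <- .config_defaults()
  unknown <- setdiff(names(over), names(defs))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defs, over, keep.null = TRUE)
  if (is.null(cfg$seed)) stop("config must set a seed")
  cfg$seed <- as.integer(cfg$seed)
  if (!cfg$preset %in% c("toy", "vdp", "rnn-gain"))
    stop("preset must be one of toy, vdp, rnn-gain")
  structure(.preset_resolve(cfg), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file of configuration entries.
#' @return A [run_config].
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read YAML configs")
  run_config(yaml::read_yaml(path))
}

# condition builders for each preset ----------------------------------

.preset_toy_fields <- function(cfg) {
  n <- cfg$toy_n_points
  list(
    sample_toy_fields("constant", list(vector = c(1, 0)), n,
                      seed = cfg$seed + 11L, condition = "const-right"),
    sample_toy_fields("constant", list(vector = c(0, 1)), n,
                      seed = cfg$seed + 12L, condition = "const-up"),
    sample_toy_fields("rotational", list(omega = 1), n,
                      seed = cfg$seed + 13L, condition = "rot-ccw"),
    sample_toy_fields("rotational", list(omega = -1), n,
                      seed = cfg$seed + 14L, condition = "rot-cw"))
}

# matched (paired) initial conditions across the damping sweep remove
# trajectory-sampling variance from the condition comparison; a Latin
# hypercube draw stratifies the coverage of the initial box
.preset_vdp_fields <- function(cfg) {
  set.seed(cfg$seed)
  ic <- if (requireNamespace("lhs", quietly = TRUE)) {
    2 * lhs::randomLHS(cfg$vdp_n_traj, 2) - 1
  } else {
    matrix(runif(2 * cfg$vdp_n_traj, -1, 1), ncol = 2)
  }
  lapply(seq_along(cfg$vdp_mus), function(i) {
    mu <- cfg$vdp_mus[i]
    ts <- simulate_vdp(mu, alpha = cfg$vdp_alpha, n_traj = cfg$vdp_n_traj,
                       T = cfg$vdp_T, dt = cfg$vdp_dt, ic = ic,
                       seed = cfg$seed)
    vf <- vectors_from_trajectories(ts)
    keep <- .fps_fixed_size(vf$points, cfg$vdp_subsample)
    vf <- vector_field(vf$points[keep, , drop = FALSE],
                       vf$vectors[keep, , drop = FALSE],
                       condition = vf$condition)
    if (isTRUE(cfg$unit_vectors)) vf <- normalize_vectors(vf, "unit")
    vf
  })
}

# farthest-point order truncated at a fixed size (spacing chosen by count
# rather than by alpha; deterministic start at the first point)
.fps_fixed_size <- function(X, size) {
  n <- nrow(X)
  if (n <= size) return(seq_len(n))
  kept <- integer(size)
  kept[1L] <- 1L
  d2 <- rowSums(sweep(X, 2, X[1L, ])^2)
  for (s in 2:size) {
    i <- which.max(d2)
    kept[s] <- i
    d2 <- pmin(d2, rowSums(sweep(X, 2, X[i, ])^2))
  }
  sort(kept)
}

# stimulated-epoch rate trajectories of a trained RNN at each gain,
# PCA-projected, differenced and subsampled into vector fields
.preset_rnn_fields <- function(cfg, params) {
  gains <- c(cfg$rnn_gains, rep(0, cfg$rnn_zero_controls))
  labs <- c(sprintf("gain=%.3f", cfg$rnn_gains),
            sprintf("control-%02d", seq_len(cfg$rnn_zero_controls)))
  trajs <- lapply(seq_along(gains), function(ci) {
    trials <- make_dms_trials(gains[ci], n_trials = cfg$rnn_trials_per_cond,
                              seed = cfg$seed + 500L + ci, dt = cfg$rnn_dt)
    tr_list <- lapply(trials, function(tr) {
      sim <- simulate_rnn(params, tr, dt = cfg$rnn_dt)
      # stimulus-1 epoch (stimulated vs unstimulated depending on gain and
      # presence), plus the early delay: where gain modulation acts
      a <- tr$onsets[2]; b <- min(tr$onsets[3] + 50L, nrow(sim$rates))
      list(time = sim$time[a:b], state = sim$rates[a:b, , drop = FALSE])
    })
    trajectory_set(tr_list, condition = labs[ci])
  })
  trajs <- project_pca(trajs, cfg$rnn_pca)
  lapply(trajs, function(ts) {
    vf <- vectors_from_trajectories(ts)
    keep <- .fps_fixed_size(vf$points, cfg$rnn_subsample)
    vf <- vector_field(vf$points[keep, , drop = FALSE],
                       vf$vectors[keep, , drop = FALSE],
                       condition = ts$condition)
    if (isTRUE(cfg$unit_vectors)) vf <- normalize_vectors(vf, "unit")
    vf
  })
}

#' Run an end-to-end experiment
#'
#' Simulates the preset's conditions, fits the representation, computes
#' the pairwise optimal-transport distance matrix, MDS coordinates and a
#' two-way clustering, and writes all artifacts (CSV embeddings, CSV
#' distance matrix, JSON metrics and manifest) under `cfg$outdir`.
#' Deterministic under the config seed.
#'
#' @param cfg a [run_config].
#' @return Invisibly, a list with the fit, distance matrix, MDS
#'   coordinates, clustering and (for the RNN preset) the trained network
#'   and its accuracy curve.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  extra <- list()
  if (cfg$preset == "toy") {
    fields <- .preset_toy_fields(cfg)
  } else if (cfg$preset == "vdp") {
    fields <- .preset_vdp_fields(cfg)
  } else {
    params <- train_rnn(N = cfg$rnn_N, gain = 1, dt = cfg$rnn_dt,
                        max_iter = cfg$rnn_train_iter, seed = cfg$seed)
    extra$rnn <- params
    extra$accuracy <- vapply(cfg$rnn_gains, function(g)
      rnn_task_performance(params, g, n_trials = 100,
                           seed = cfg$seed + 7L, dt = cfg$rnn_dt),
      numeric(1))
    fields <- .preset_rnn_fields(cfg, params)
  }
  # repeat training and average the distance matrices: the contrastive
  # optimum is degenerate, and single-run latent geometry carries run-to-run
  # variability that averaging over independent fits removes
  reps <- if (cfg$preset == "vdp") cfg$vdp_reps else 1L
  fit <- NULL
  Dsum <- NULL
  for (r in seq_len(reps)) {
    fit <- flowrep(fields, m = cfg$m, p = cfg$p, mode = cfg$mode,
                   E = cfg$E, k = cfg$k, delta = cfg$delta,
                   alpha = cfg$alpha, tau = cfg$tau, K = cfg$K, Q = cfg$Q,
                   lr = cfg$lr, epochs = cfg$epochs,
                   patience = cfg$patience, clip = cfg$clip,
                   seed = cfg$seed + 7919L * (r - 1L))
    Dr <- condition_distances(fit, seed = cfg$seed)
    Dsum <- if (is.null(Dsum)) Dr else Dsum + unclass(Dr)
  }
  D <- structure(unclass(Dsum) / reps, class = c("flow_dist", "matrix"))
  mds <- mds_embed(D, dims = 2)
  clus <- cluster_conditions(D, k = 2)

  # artifacts
  emb <- fitted(fit)
  utils::write.csv(emb, file.path(cfg$outdir, "embeddings.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(unclass(D)),
                   file.path(cfg$outdir, "distances.csv"))
  utils::write.csv(data.frame(condition = rownames(mds), mds,
                              cluster = clus$labels),
                   file.path(cfg$outdir, "analysis.csv"), row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    manifest <- list(
      preset = cfg$preset, seed = cfg$seed,
      config = cfg[setdiff(names(cfg), "outdir")],
      n_conditions = length(fit$conditions),
      val_loss = fit$val_loss, test_loss = fit$test_loss,
      elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    if (!is.null(extra$accuracy)) manifest$rnn_accuracy <- extra$accuracy
    jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(c(list(fit = fit, distances = D, mds = mds, clusters = clus),
              extra))
}
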