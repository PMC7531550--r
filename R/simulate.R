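## Synthetic-data generator: condition-mean patterns with a planted
## representational geometry, forward-simulated BOLD runs, behavioural
## trial tables, and on-disk datasets.

#' Planted pattern geometry model
#'
#' Parameterizes the representational geometry planted in simulated
#' condition-mean patterns. Components (room, task, step position, item,
#' display/visual) live along mutually orthonormal voxel-space directions,
#' so every component magnitude translates into a known contribution to
#' pairwise squared pattern distance (see [expected_decomposition()]).
#'
#' @param g_room,g_task,g_step,g_item,g_vis Component magnitudes in
#'   pattern units (>= 0).
#' @param n_voxels Number of voxels carrying the patterns (>= 41, the size
#'   of the orthonormal component basis).
#' @param noise_sd SD of run-specific pattern noise added to the condition
#'   means of each run (independent between runs).
#' @param ar_rho,ar_sd AR(1) temporal noise: autocorrelation coefficient
#'   and innovation SD.
#' @param drift_amplitude SD of the random low-frequency (discrete-cosine,
#'   slower than 1/128 Hz) drift added to each voxel.
#' @return Object of class \code{pattern_model}.
#' @export
pattern_model <- function(g_room = 0.25, g_task = 0.5, g_step = 1,
                          g_item = 0.75, g_vis = 0.5, n_voxels = 160L,
                          noise_sd = 0.3, ar_rho = 0.3, ar_sd = 1,
                          drift_amplitude = 1) {
  mags <- c(g_room, g_task, g_step, g_item, g_vis)
  if (any(mags < 0)) stop("component magnitudes must be >= 0")
  structure(list(g_room = g_room, g_task = g_task, g_step = g_step,
                 g_item = g_item, g_vis = g_vis,
                 n_voxels = as.integer(n_voxels), noise_sd = noise_sd,
                 ar_rho = ar_rho, ar_sd = ar_sd,
                 drift_amplitude = drift_amplitude),
            class = "pattern_model")
}

# number of orthonormal basis vectors the geometry needs
n_basis_required <- function(structure) {
  n_items <- nrow(structure$items)
  n_tasks <- nrow(structure$tasks)
  n_items + n_tasks + length(structure$rooms) + 3L + n_tasks
}

#' Plant condition-mean patterns
#'
#' Builds the 72 condition-mean voxel patterns implied by a
#' [pattern_model()]: for condition (task t, step k, distractor d),
#' \deqn{\mu = g_{item} v_{item}(t,k) + g_{task} v_{task}(t) +
#'   g_{room} v_{room}(t) + g_{step} w(k) + g_{vis} v_{disp}(t,d)}
#' with all basis vectors mutually orthonormal. The step code
#' \eqn{w(k)} is a cumulative sum of orthonormal increments, so squared
#' distance between steps i and j is exactly \eqn{g_{step}^2 |i-j|};
#' the display component is the normalized sum of per-task display
#' vectors of the two tasks whose items appear in the search arrays, so
#' shared display tasks reduce squared distance by \eqn{g_{vis}^2} each.
#'
#' @param model A [pattern_model()].
#' @param structure A [task_structure()].
#' @param seed Integer seed for the random orthonormal basis.
#' @return A \code{condition_patterns} object (72 x voxels matrix plus
#'   condition table).
#' @export
plant_condition_patterns <- function(model, structure, seed) {
  nb <- n_basis_required(structure)
  if (model$n_voxels < nb)
    stop("n_voxels must be at least ", nb,
         " to hold the orthonormal component basis")
  rng <- local_rng(seed)
  G <- matrix(rng$norm(model$n_voxels * nb), model$n_voxels, nb)
  Q <- qr.Q(qr(G))  # orthonormal columns

  n_items <- nrow(structure$items)
  n_tasks <- nrow(structure$tasks)
  i0 <- 0L
  V_item <- Q[, i0 + seq_len(n_items), drop = FALSE]; i0 <- i0 + n_items
  V_task <- Q[, i0 + seq_len(n_tasks), drop = FALSE]; i0 <- i0 + n_tasks
  V_room <- Q[, i0 + seq_len(2L), drop = FALSE]; i0 <- i0 + 2L
  V_inc <- Q[, i0 + seq_len(3L), drop = FALSE]; i0 <- i0 + 3L
  V_disp <- Q[, i0 + seq_len(n_tasks), drop = FALSE]

  # cumulative step code: w(1) = 0, w(k) = sum of increments < k
  W <- matrix(0, 4L, model$n_voxels)
  for (k in 2:4) W[k, ] <- W[k - 1L, ] + V_inc[, k - 1L]

  conds <- condition_table(structure)
  tasks <- structure$tasks$task
  P <- matrix(0, nrow(conds), model$n_voxels)
  for (i in seq_len(nrow(conds))) {
    tk <- conds$task[i]; d <- conds$distractor[i]; k <- conds$step[i]
    ti <- match(tk, tasks); di <- match(d, tasks)
    ri <- match(structure_room(structure, tk), structure$rooms)
    item_idx <- which(structure$items$task == tk & structure$items$step == k)
    P[i, ] <- model$g_item * V_item[, item_idx] +
      model$g_task * V_task[, ti] +
      model$g_room * V_room[, ri] +
      model$g_step * W[k, ] +
      model$g_vis * (V_disp[, ti] + V_disp[, di]) / sqrt(2)
  }
  rownames(P) <- conds$label
  structure(list(patterns = P, conditions = conds, model = model),
            class = "condition_patterns")
}

#' Expected decomposition coefficients of a planted geometry
#'
#' Closed-form coefficients that [fit_decomposition()] recovers from the
#' noiseless squared-distance RDM of patterns planted by
#' [plant_condition_patterns()]: item intercept \eqn{2 g_{item}^2}, room
#' \eqn{2 g_{room}^2}, task \eqn{2 g_{task}^2}, step slope
#' \eqn{g_{step}^2}, visual \eqn{2 g_{vis}^2}; divided by the voxel count
#' when the RDM is voxel-normalized.
#'
#' When the RDM is computed with multivariate noise normalization, the
#' LDC is a squared Mahalanobis distance: under the generator's
#' spatially iid temporal noise the planted geometry is divided by the
#' marginal noise variance \code{ar_sd^2 / (1 - ar_rho^2)}. Set
#' \code{noise_normalized = TRUE} to express the expectation in those
#' units.
#'
#' @param model A [pattern_model()].
#' @param normalized Whether the RDM entries are divided by voxel count.
#' @param noise_normalized Whether the RDM was computed with the noise
#'   covariance estimated from GLM residuals (as opposed to an identity
#'   noise model).
#' @return Named numeric vector (item, room, task, step, visual).
#' @export
expected_decomposition <- function(model, normalized = TRUE,
                                   noise_normalized = FALSE) {
  out <- c(item = 2 * model$g_item^2, room = 2 * model$g_room^2,
           task = 2 * model$g_task^2, step = model$g_step^2,
           visual = 2 * model$g_vis^2)
  if (normalized) out <- out / model$n_voxels
  if (noise_normalized) {
    if (model$ar_sd <= 0)
      stop("noise-normalized expectation undefined without temporal noise")
    out <- out / (model$ar_sd^2 / (1 - model$ar_rho^2))
  }
  out
}

#' Forward-simulate one BOLD run
#'
#' Voxel time series are the sum over conditions of the condition's
#' HRF-convolved onset-plus-epoch regressor times its (run-perturbed) mean
#' pattern, plus low-frequency drift and AR(1) temporal noise. The
#' run-specific pattern perturbation (\code{noise_sd}) and the temporal
#' noise are independent between runs.
#'
#' @param design A \code{run_design}.
#' @param means A \code{condition_patterns} object of true condition means.
#' @param model A [pattern_model()].
#' @param TR Repetition time in seconds.
#' @param seed Integer seed for this run's noise.
#' @return List with \code{bold} (scans x voxels), \code{n_scans},
#'   \code{design_matrix} (the noiseless event design used as forward
#'   model) and \code{run_means} (the perturbed means).
#' @export
simulate_run_bold <- function(design, means, model, TR = 1.373, seed = 1) {
  stopifnot(TR > 0)
  rng <- local_rng(seed)
  dm <- build_event_design(design, behavior = NULL, TR = TR)
  n_scans <- nrow(dm$values)
  conds <- means$conditions
  M <- means$patterns
  V <- ncol(M)

  # run-specific pattern perturbation, independent between runs
  if (model$noise_sd > 0)
    M <- M + matrix(rng$norm(length(M), sd = model$noise_sd), nrow(M))

  # condition regressor = onset + epoch columns
  Xc <- vapply(conds$label, function(lb)
    dm$values[, paste0(lb, ".onset")] + dm$values[, paste0(lb, ".epoch")],
    numeric(n_scans))
  bold <- Xc %*% M

  if (model$drift_amplitude > 0) {
    K <- max(1L, floor(2 * (n_scans * TR) / 128))
    B <- dct_basis(n_scans, K)
    bold <- bold + model$drift_amplitude * sqrt(n_scans) / sqrt(K) *
      (B %*% matrix(rng$norm(K * V), K, V))
  }
  if (model$ar_sd > 0) {
    innov <- matrix(rng$norm(n_scans * V, sd = model$ar_sd), n_scans, V)
    noise <- if (model$ar_rho != 0)
      apply(innov, 2L, function(e)
        stats::filter(e, model$ar_rho, method = "recursive"))
    else innov
    bold <- bold + noise
  }
  list(bold = unname(as.matrix(bold)), n_scans = n_scans,
       design_matrix = dm, run_means = M)
}

#' Behavioural response model
#'
#' @param base_rt Mean reaction time (s) for non-first arrays at step 1.
#' @param first_array_slowing Additional mean RT (s) on the first search
#'   array of each step.
#' @param step_trend Additive RT change (s) per step position.
#' @param rt_sd SD of Gaussian RT noise (s).
#' @param step_error_rates Error probability per step (length 4,
#'   increasing across steps by default).
#' @param first_array_error_boost Additional error probability on the
#'   first array of a step.
#' @param high_error_rate Probability that an episode is a lapse episode
#'   with elevated error probability.
#' @param high_error_p Error probability within a lapse episode.
#' @return Object of class \code{behavior_model}.
#' @export
behavior_model <- function(base_rt = 0.77, first_array_slowing = 0.25,
                           step_trend = 0.02, rt_sd = 0.12,
                           step_error_rates = c(0.010, 0.015, 0.020, 0.025),
                           first_array_error_boost = 0.02,
                           high_error_rate = 0.0132, high_error_p = 0.8) {
  structure(as.list(environment()), class = "behavior_model")
}

#' Simulate a behavioural trial table
#'
#' One response per search array of every non-dummy episode (36 episodes x
#' 12 responses). RTs carry first-array slowing and a per-step trend;
#' error probability grows across steps; a small fraction of episodes are
#' lapse episodes with high error rates (these are the episodes the
#' > 25\% rule flags).
#'
#' @param design A \code{run_design}.
#' @param rt_model A [behavior_model()].
#' @param seed Integer seed.
#' @return Data frame with columns \code{episode}, \code{cued_task},
#'   \code{distractor_task}, \code{step}, \code{search}, \code{rt},
#'   \code{correct}, \code{error_type}.
#' @export
simulate_behavior <- function(design, rt_model = behavior_model(),
                              seed = 1) {
  rng <- local_rng(seed)
  ep <- design$episodes[!design$episodes$is_dummy, ]
  m <- rt_model
  rows <- vector("list", nrow(ep))
  err_types <- c("wrong_step", "wrong_task", "wrong_both", "missed")
  for (i in seq_len(nrow(ep))) {
    lapse <- m$high_error_rate > 0 &&
      rng$unif(1) < m$high_error_rate
    g <- expand.grid(search = 1:3, step = 1:4)
    p_err <- if (lapse) rep(m$high_error_p, 12L)
    else m$step_error_rates[g$step] +
      m$first_array_error_boost * (g$search == 1L)
    err <- rng$unif(12L) < p_err
    rt <- m$base_rt + m$first_array_slowing * (g$search == 1L) +
      m$step_trend * (g$step - 1L) + rng$norm(12L, sd = m$rt_sd)
    rt <- pmax(rt, 0.1)
    type <- rep(NA_character_, 12L)
    if (any(err))
      type[err] <- err_types[ceiling(rng$unif(sum(err)) * 4)]
    missed <- !is.na(type) & type == "missed"
    rt[missed] <- NA_real_
    rows[[i]] <- data.frame(
      episode = ep$index[i], cued_task = ep$cued_task[i],
      distractor_task = ep$distractor_task[i],
      step = g$step, search = g$search, rt = rt,
      correct = !err, error_type = type, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Simulate a complete subject
#'
#' Two runs of the paradigm: each run gets its own transition-balanced,
#' efficiency-selected design, behavioural table, and BOLD matrix over the
#' voxels of a compact ROI mask embedded in a 3D grid. Condition means are
#' shared between runs; all noise sources are run-independent.
#'
#' @param model A [pattern_model()].
#' @param structure A [task_structure()].
#' @param seed Integer seed.
#' @param n_candidates Candidate orders per run for efficiency selection.
#' @param TR Repetition time (s).
#' @param grid_dim 3D grid dimensions (default \code{c(20, 20, 20)}).
#' @param voxel_size_mm Isotropic voxel size in mm (default 2).
#' @param rt_model A [behavior_model()].
#' @return Object of class \code{simulated_subject}: \code{runs} (list of
#'   two, each with \code{design}, \code{bold}, \code{behavior}),
#'   \code{mask} (logical 3D array; \code{sum(mask) == n_voxels}),
#'   \code{affine}, \code{truth} (model and planted means), \code{TR}.
#' @export
simulate_subject <- function(model = pattern_model(),
                             structure = task_structure(), seed = 1,
                             n_candidates = 10L, TR = 1.373,
                             grid_dim = c(20L, 20L, 20L),
                             voxel_size_mm = 2,
                             rt_model = behavior_model()) {
  mask <- compact_roi_mask(grid_dim, model$n_voxels)
  affine <- diag(c(rep(voxel_size_mm, 3), 1))
  means <- plant_condition_patterns(model, structure,
                                    seed = derive_seed(seed, 3L))
  runs <- lapply(1:2, function(r) {
    des <- select_efficient_order(structure, n_candidates = n_candidates,
                                  seed = derive_seed(seed, 100L + r),
                                  TR = TR)
    beh <- simulate_behavior(des, rt_model, seed = derive_seed(seed, 200L + r))
    sim <- simulate_run_bold(des, means, model, TR = TR,
                             seed = derive_seed(seed, 300L + r))
    list(design = des, behavior = beh, bold = sim$bold,
         n_scans = sim$n_scans)
  })
  structure(list(runs = runs, mask = mask, affine = affine,
                 truth = list(model = model, means = means),
                 structure = structure, TR = TR, seed = seed),
            class = "simulated_subject")
}

# Logical 3D mask of exactly n_voxels voxels, grown as a ball around the
# grid center.
compact_roi_mask <- function(grid_dim, n_voxels) {
  if (prod(grid_dim) < n_voxels)
    stop("grid too small for ", n_voxels, " ROI voxels")
  ctr <- (grid_dim + 1) / 2
  co <- as.matrix(expand.grid(x = seq_len(grid_dim[1]),
                              y = seq_len(grid_dim[2]),
                              z = seq_len(grid_dim[3])))
  d2 <- colSums((t(co) - ctr)^2)
  keep <- order(d2)[seq_len(n_voxels)]
  mask <- array(FALSE, grid_dim)
  mask[co[keep, , drop = FALSE]] <- TRUE
  mask
}

#' Write a simulated subject to disk
#'
#' Writes per-run 4D NIfTI volumes (masked voxels carry the simulated
#' series; out-of-mask voxels are zero), BIDS-style events TSVs, a
#' behaviour TSV, the ROI mask NIfTI, and a truth JSON with the model
#' parameters and seed.
#'
#' @param subject A \code{simulated_subject}.
#' @param dir Existing output directory.
#' @return Named character vector of the files written.
#' @export
write_synthetic_dataset <- function(subject, dir) {
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  idx <- which(subject$mask)
  files <- c()
  for (r in 1:2) {
    run <- subject$runs[[r]]
    vol <- array(0, c(dim(subject$mask), run$n_scans))
    nvox <- prod(dim(subject$mask))
    for (s in seq_len(run$n_scans))
      vol[idx + (s - 1L) * nvox] <- run$bold[s, ]
    bold_path <- file.path(dir, sprintf("run-%d_bold.nii.gz", r))
    img <- RNifti::asNifti(vol)
    RNifti::pixdim(img) <- c(diag(subject$affine)[1:3], subject$TR)
    RNifti::writeNifti(img, bold_path)
    ev_path <- file.path(dir, sprintf("run-%d_events.tsv", r))
    write_design(run$design, ev_path)
    beh_path <- file.path(dir, sprintf("run-%d_behavior.tsv", r))
    utils::write.table(run$behavior, beh_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, bold = bold_path, events = ev_path,
               behavior = beh_path)
  }
  mask_path <- file.path(dir, "mask_roi.nii.gz")
  mimg <- RNifti::asNifti(array(as.numeric(subject$mask),
                                dim(subject$mask)))
  RNifti::pixdim(mimg) <- diag(subject$affine)[1:3]
  RNifti::writeNifti(mimg, mask_path)
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(seed = subject$seed, model = unclass(subject$truth$model),
         expected = as.list(expected_decomposition(subject$truth$model))),
    truth_path, auto_unbox = TRUE, digits = NA)
  c(files, mask = mask_path, truth = truth_path)
}
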