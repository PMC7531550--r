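test_that("planted geometry has the closed-form pairwise distances", {
  ts <- fixture_structure()
  # step-only model: squared distance between same-task same-distractor
  # steps i, j equals |i - j|
  pm <- pattern_model(g_room = 0, g_task = 0, g_step = 1, g_item = 0,
                      g_vis = 0, n_voxels = 50, noise_sd = 0, ar_sd = 0,
                      drift_amplitude = 0)
  means <- plant_condition_patterns(pm, ts, seed = 4)
  co <- means$conditions
  same <- which(co$task == co$task[1] & co$distractor == co$distractor[1])
  for (i in same) for (j in same) {
    d2 <- sum((means$patterns[i, ] - means$patterns[j, ])^2)
    expect_equal(d2, abs(co$step[i] - co$step[j]), tolerance = 1e-10)
  }

  # all magnitudes zero: all 72 means identical
  pm0 <- pattern_model(g_room = 0, g_task = 0, g_step = 0, g_item = 0,
                       g_vis = 0, n_voxels = 50, noise_sd = 0, ar_sd = 0,
                       drift_amplitude = 0)
  m0 <- plant_condition_patterns(pm0, ts, seed = 4)
  expect_lt(max(abs(sweep(m0$patterns, 2, m0$patterns[1, ]))), 1e-12)

  # too few voxels for the basis
  expect_error(plant_condition_patterns(
    pattern_model(n_voxels = 10), ts, seed = 1), "n_voxels")
})

test_that("every planted model satisfies the linear decomposition exactly", {
  ts <- fixture_structure()
  mod <- fixture_model_rdms()
  for (seed in 1:3) {
    g <- abs(sin(seed + 1:5))  # arbitrary deterministic magnitudes
    pm <- pattern_model(g_room = g[1], g_task = g[2], g_step = g[3],
                        g_item = g[4], g_vis = g[5], n_voxels = 48,
                        noise_sd = 0, ar_sd = 0, drift_amplitude = 0)
    means <- plant_condition_patterns(pm, ts, seed = 30 + seed)
    # brute-force pairwise squared distances
    D <- as.matrix(stats::dist(means$patterns))^2
    rdm <- rdm_from_matrix(D, means$conditions, n_voxels = pm$n_voxels,
                           normalized = FALSE)
    fit <- fit_decomposition(rdm, mod)
    expected <- expected_decomposition(pm, normalized = FALSE)
    expect_equal(unname(fit$coefficients[names(expected)]),
                 unname(expected), tolerance = 1e-10)
    # residual of the included cells is numerically zero
    expect_lt(fit$residual_variance, 1e-20)
  }
})

test_that("noiseless BOLD is the convolved forward model", {
  ts <- fixture_structure()
  des <- fixture_design()
  pm <- pattern_model(g_room = 0, g_task = 0, g_step = 0, g_item = 1,
                      g_vis = 0, n_voxels = 45, noise_sd = 0, ar_sd = 0,
                      drift_amplitude = 0)
  means <- plant_condition_patterns(pm, ts, seed = 6)
  sim <- simulate_run_bold(des, means, pm, seed = 7)
  dm <- sim$design_matrix
  lb <- means$conditions$label
  Xc <- sapply(lb, function(l)
    dm$values[, paste0(l, ".onset")] + dm$values[, paste0(l, ".epoch")])
  expect_equal(sim$bold, unname(Xc %*% means$patterns), tolerance = 1e-12)

  # two seeds: identical signal expectation, independent noise
  pm2 <- pattern_model(g_item = 1, n_voxels = 45, noise_sd = 0,
                       ar_sd = 0.5, drift_amplitude = 0,
                       g_room = 0, g_task = 0, g_step = 0, g_vis = 0)
  s1 <- simulate_run_bold(des, means, pm2, seed = 11)
  s2 <- simulate_run_bold(des, means, pm2, seed = 12)
  n1 <- s1$bold - sim$bold
  n2 <- s2$bold - sim$bold
  expect_gt(stats::sd(n1), 0)
  expect_lt(abs(stats::cor(as.vector(n1), as.vector(n2))), 0.05)
})

test_that("GLM recovers planted condition means as noise vanishes", {
  ts <- fixture_structure()
  des <- fixture_design()
  pm <- fixture_noiseless_model()
  means <- plant_condition_patterns(pm, ts, seed = 9)
  sim <- simulate_run_bold(des, means, pm, seed = 10)
  fit <- fit_ols(sim$bold, sim$design_matrix)
  pat <- average_condition_patterns(fit)
  expect_lt(sqrt(mean((pat$patterns - means$patterns)^2)), 1e-8)
})

test_that("behavioural RTs carry the configured effects", {
  des <- fixture_design()
  # degenerate model: all RTs equal the base
  bm0 <- behavior_model(base_rt = 0.8, first_array_slowing = 0,
                        step_trend = 0, rt_sd = 0,
                        step_error_rates = rep(0, 4),
                        first_array_error_boost = 0,
                        high_error_rate = 0)
  beh0 <- simulate_behavior(des, bm0, seed = 1)
  expect_equal(nrow(beh0), 36L * 12L)
  expect_true(all(beh0$rt == 0.8))
  expect_true(all(beh0$correct))

  # first-array slowing of 200 ms appears in the mean over many episodes
  bm <- behavior_model(base_rt = 0.8, first_array_slowing = 0.2,
                       step_trend = 0, rt_sd = 0.1,
                       step_error_rates = rep(0, 4),
                       first_array_error_boost = 0, high_error_rate = 0)
  beh <- do.call(rbind, lapply(1:8, function(s)
    simulate_behavior(des, bm, seed = s)))
  slow <- mean(beh$rt[beh$search == 1]) - mean(beh$rt[beh$search != 1])
  n1 <- sum(beh$search == 1)
  se <- 0.1 * sqrt(1 / n1 + 1 / (2 * n1))
  expect_lt(abs(slow - 0.2), 4 * se)
})

test_that("injected lapse episodes match the binomial flagging rate", {
  des <- fixture_design()
  bm <- behavior_model(step_error_rates = rep(0, 4),
                       first_array_error_boost = 0,
                       high_error_rate = 0.05, high_error_p = 0.9)
  flagged <- vapply(1:60, function(s) {
    beh <- simulate_behavior(des, bm, seed = 400 + s)
    sum(flag_error_episodes(beh))
  }, 0)
  # expected ~ 36 * 0.05 = 1.8 per run (lapse episodes are flagged with
  # probability ~ 1 at error rate 0.9)
  m <- mean(flagged)
  se <- stats::sd(flagged) / sqrt(length(flagged))
  expect_lt(abs(m - 1.8), 4 * se + 0.1)
})

test_that("a simulated subject round-trips through the on-disk format", {
  pm <- pattern_model(n_voxels = 45, g_room = 0.2, g_task = 0.3,
                      g_step = 0.5, g_item = 0.4, g_vis = 0.2)
  subj <- simulate_subject(pm, fixture_structure(), seed = 77,
                           n_candidates = 1, grid_dim = c(8L, 8L, 8L))
  expect_equal(sum(subj$mask), 45L)
  dir <- file.path(tempdir(), "synthsubj")
  expect_error(write_synthetic_dataset(subj, dir), "does not exist")
  dir.create(dir)
  files <- write_synthetic_dataset(subj, dir)
  expect_true(all(file.exists(files)))
  # events table round trip is exact
  ev <- read_events(files[["events"]])
  expect_equal(ev, design_events(subj$runs[[1]]$design),
               ignore_attr = TRUE, tolerance = 1e-9)
  # volume carries the bold series at mask voxels
  vol <- read_volume(files[["bold"]])
  idx <- which(subj$mask)
  s1 <- as.vector(vol$data[, , , 1])[idx]
  expect_equal(s1, unname(subj$runs[[1]]$bold[1, ]), tolerance = 1e-5)
  truth <- jsonlite::read_json(files[["truth"]])
  expect_equal(truth$seed, 77L)
  unlink(dir, recursive = TRUE)
})
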