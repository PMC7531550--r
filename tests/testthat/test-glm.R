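test_that("event design has the expected interest structure", {
  dm <- fixture_event_dm()
  expect_equal(sum(dm$interest), 162L)
  nm <- dm$names[dm$interest]
  # 9 interest regressors per cued x distractor combination
  combo <- sub("\\.(s[1-4]\\.(onset|epoch)|offset)$", "", nm)
  expect_equal(length(unique(combo)), 18L)
  expect_true(all(table(combo) == 9L))
  # each combination: 4 onsets + 4 epochs + 1 offset
  expect_equal(sum(grepl("\\.onset$", nm)), 72L)
  expect_equal(sum(grepl("\\.epoch$", nm)), 72L)
  expect_equal(sum(grepl("\\.offset$", nm)), 18L)
})

test_that("noiseless onset/epoch amplitudes are recovered by OLS", {
  des <- fixture_design()
  dm <- fixture_event_dm()
  nm <- dm$names
  set.seed(5)
  b_true <- numeric(ncol(dm$values))
  b_true[dm$interest] <- rnorm(sum(dm$interest))
  y <- dm$values %*% b_true
  fit <- fit_ols(y, dm)
  expect_equal(unname(drop(fit$betas)), b_true, tolerance = 1e-6)
})

test_that("condition patterns average the onset and epoch betas", {
  dm <- fixture_event_dm()
  p <- ncol(dm$values)
  betas <- matrix(0, p, 3)
  rownames(betas) <- dm$names
  conds <- condition_table(fixture_structure())
  a <- c(1, -2, 0.5); b <- c(3, 0, 1)
  betas[paste0(conds$label[10], ".onset"), ] <- a
  betas[paste0(conds$label[10], ".epoch"), ] <- b
  bs <- structure(list(betas = betas, names = dm$names, kind = "event",
                       conditions = conds), class = "beta_set")
  pat <- average_condition_patterns(bs)
  expect_equal(nrow(pat$patterns), 72L)
  expect_equal(unname(pat$patterns[10, ]), (a + b) / 2)
  expect_true(all(pat$patterns[-10, ] == 0))
  # missing regressor -> error
  bs2 <- bs
  rownames(bs2$betas)[1] <- "gone"
  bs2$names[1] <- "gone"
  expect_error(average_condition_patterns(bs2), "missing regressor")
})

test_that("FIR design tiles windows with per-task bin sets", {
  des <- fixture_design()
  dm <- suppressWarnings(build_fir_design(des, TR = 1.373))
  expect_s3_class(dm, "design_matrix")
  nm <- dm$names[dm$interest]
  # 60 bins for each of the six per-task window sets
  expect_equal(length(nm), 6L * 60L)
  sets <- unique(sub("\\.bin\\d+$", "", nm))
  expect_length(sets, 6L)
  # boxcar definition: bin 1 of a window is 1 exactly within
  # [anchor, anchor + 1.5)
  ep <- des$episodes
  anchors <- ep$step1_onset[!ep$is_dummy & ep$index %% 2 == 0]
  scan_t <- seq(0, by = dm$TR, length.out = nrow(dm$values))
  task1 <- episodeRSA:::task_codes(fixture_structure())[[
    ep$cued_task[!ep$is_dummy & ep$index %% 2 == 0][1]]]
  col <- dm$values[, paste0(task1, ".bin01")]
  a1 <- anchors[1]
  inside <- scan_t >= a1 & scan_t < a1 + 1.5
  expect_true(all(col[inside] == 1))
})

test_that("a planted FIR response is recovered without noise", {
  des <- fixture_design()
  dm <- suppressWarnings(build_fir_design(des, TR = 1.373))
  set.seed(8)
  b_true <- numeric(ncol(dm$values))
  b_true[dm$interest] <- rnorm(sum(dm$interest))
  y <- dm$values %*% b_true
  fit <- fit_ols(y, dm)
  expect_equal(unname(drop(fit$betas)[dm$interest]),
               b_true[dm$interest], tolerance = 1e-6)
  # roi_fir_timecourse: voxel mean (here voxels carry y and 3y, so the
  # mean beta is 2 b) then task mean per bin, computed from the planted
  # values directly
  fit2 <- fit_ols(cbind(y, 3 * y), dm)
  tc <- roi_fir_timecourse(fit2)
  nm <- dm$names[dm$interest]
  bin <- as.integer(sub("^.*\\.bin", "", nm))
  expected_tc <- vapply(1:60, function(b)
    mean(2 * b_true[dm$interest][bin == b]), 0)
  expect_length(tc, 60L)
  expect_equal(tc, expected_tc, tolerance = 1e-6)
})

test_that("error-episode flagging uses a strict threshold", {
  beh <- expand.grid(search = 1:3, step = 1:4, episode = 1:3)
  beh$correct <- TRUE
  beh$correct[beh$episode == 2][1:3] <- FALSE          # 3/12 = 25%
  beh$correct[beh$episode == 3][1:4] <- FALSE          # 4/12 > 25%
  fl <- flag_error_episodes(beh)
  expect_equal(unname(fl[c("1", "2", "3")]), c(FALSE, FALSE, TRUE))
  # missing responses count as errors
  beh$correct[beh$episode == 2][4] <- NA               # now 4/12
  expect_true(flag_error_episodes(beh)[["2"]])
})

test_that("high-pass filtering attenuates only sub-cutoff frequencies", {
  TR <- 1.373
  n <- 1200L
  t <- seq(0, by = TR, length.out = n)
  # amplitude of a period-P component via quadrature demodulation
  amp_at <- function(x, P) {
    2 * sqrt(mean(x * sin(2 * pi * t / P))^2 +
               mean(x * cos(2 * pi * t / P))^2)
  }
  slow <- sin(2 * pi * t / 256)
  fast <- sin(2 * pi * t / 32)
  expect_lt(amp_at(highpass_filter(slow, 128, TR = TR), 256), 0.05)
  expect_gt(amp_at(highpass_filter(fast, 128, TR = TR), 32), 0.95)
  # idempotent projection
  x <- rnorm(n)
  f1 <- highpass_filter(x, 128, TR = TR)
  expect_equal(highpass_filter(f1, 128, TR = TR), f1, tolerance = 1e-10)
  expect_error(highpass_filter(x, 2, TR = TR), "exceed")
})

test_that("OLS matches the pseudoinverse oracle and its invariants", {
  set.seed(21)
  X <- matrix(rnorm(40 * 5), 40, 5)
  colnames(X) <- paste0("c", 1:5)
  B <- matrix(rnorm(5 * 3), 5, 3)
  y <- X %*% B
  fit <- fit_ols(y, X)
  expect_equal(unname(fit$betas), B, tolerance = 1e-10)
  # noisy instance vs explicit pseudoinverse
  y2 <- y + matrix(rnorm(length(y)), nrow(y))
  fit2 <- fit_ols(y2, X)
  expect_equal(unname(fit2$betas),
               unname(solve(t(X) %*% X) %*% t(X) %*% y2),
               tolerance = 1e-8)
  # residuals orthogonal to the design
  expect_lt(max(abs(t(X) %*% fit2$residuals)), 1e-8)
  expect_equal(fit2$df, 35L)
  # rank deficiency names the collinear column
  X2 <- cbind(X, c5b = X[, 5])
  expect_error(fit_ols(y2, X2), "c5b")
})

test_that("interest-regressor collinearity of a selected design stays
           near the published maximum", {
  # one efficiency-selected design; the acceptance suite covers 10 seeds
  sel <- select_efficient_order(fixture_structure(), n_candidates = 50,
                                seed = 61)
  dm <- build_event_design(sel, TR = 1.373)
  cc <- abs(stats::cor(dm$values[, dm$interest]))
  diag(cc) <- 0
  expect_lte(max(cc), 0.55)
})

test_that("FIR and event models agree on step-wise response shape", {
  # noiseless data generated from the event model with step-specific
  # amplitudes shared across combinations: per-step means of the fitted
  # FIR curve reproduce the onset+epoch reconstruction
  des <- fixture_design()
  dm_ev <- fixture_event_dm()
  b <- numeric(ncol(dm_ev$values))
  names(b) <- dm_ev$names
  amp_on <- c(1.2, 0.8, 1.0, 1.4)
  amp_ep <- c(0.5, 0.7, 0.9, 1.1)
  for (k in 1:4) {
    b[grepl(sprintf("\\.s%d\\.onset$", k), names(b))] <- amp_on[k]
    b[grepl(sprintf("\\.s%d\\.epoch$", k), names(b))] <- amp_ep[k]
  }
  b[grepl("\\.offset$", names(b))] <- 0.6
  y <- dm_ev$values %*% b
  dm_fir <- suppressWarnings(build_fir_design(des, TR = 1.373))
  fit <- fit_ols(y, dm_fir)
  fitted <- dm_fir$values %*% fit$betas
  scan_t <- seq(0, by = dm_fir$TR, length.out = nrow(fitted))
  ep <- des$episodes
  even <- ep[!ep$is_dummy & ep$index %% 2 == 0, ]
  scale <- stats::sd(y)
  for (tk in unique(even$cued_task)) {
    anchors <- even$step1_onset[even$cued_task == tk]
    for (k in 1:8) {  # eight 9 s steps across the episode pair
      sel <- Reduce(`|`, lapply(anchors, function(a)
        scan_t >= a + 9 * (k - 1) & scan_t < a + 9 * k))
      expect_lt(abs(mean(fitted[sel]) - mean(y[sel])) / scale, 1e-3)
    }
  }
})
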