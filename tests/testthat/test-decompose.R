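test_that("model RDM cells follow the coding rules", {
  ts <- fixture_structure()
  mod <- fixture_model_rdms()
  co <- mod$conditions
  # same task, same distractor, steps 1 vs 2: only step (and no visual)
  i <- which(co$label == "K1.B1.s1"); j <- which(co$label == "K1.B1.s2")
  expect_equal(mod$room[i, j], 0)
  expect_equal(mod$task[i, j], 0)
  expect_equal(mod$step[i, j], 1)
  expect_equal(mod$visual[i, j], 0)   # both display tasks shared
  expect_true(mod$include[i, j])
  # same task and step, different distractor: the matched-item cell
  k <- which(co$label == "K1.B2.s1")
  expect_false(mod$include[i, k])
  # kitchen vs bathroom cued tasks: room and task both differ
  l <- which(co$label == "B1.K1.s1")
  expect_equal(mod$room[i, l], 1)
  expect_equal(mod$task[i, l], 1)
  expect_equal(mod$visual[i, l], 0)   # {K1,B1} vs {B1,K1}: two shared
  m <- which(co$label == "B2.K2.s1")
  expect_equal(mod$visual[i, m], 1)   # no shared display tasks
  n <- which(co$label == "B1.K2.s1")
  expect_equal(mod$visual[i, n], 0.5) # one shared display task
  # room difference implies task difference everywhere
  expect_true(all(mod$task[mod$room == 1] == 1))
  # step difference is the absolute position difference
  expect_equal(mod$step[i, which(co$label == "K1.B1.s4")], 3)
})

test_that("the include mask matches exhaustive pair enumeration", {
  mod <- fixture_model_rdms()
  co <- mod$conditions
  excluded <- outer(seq_len(72), seq_len(72), Vectorize(function(i, j) {
    i == j || (co$task[i] == co$task[j] && co$step[i] == co$step[j])
  }))
  expect_equal(mod$include, !excluded, ignore_attr = TRUE)
  # 72 diagonal + 72 conditions x 2 other distractors matched-item cells
  expect_equal(sum(!mod$include), 72L + 72L * 2L)
  expect_equal(sum(mod$include & upper.tri(mod$include)), 2484L)
})

test_that("noiseless linear RDMs are recovered exactly", {
  mod <- fixture_model_rdms()
  b <- c(item = 0.7, room = 0.25, task = 0.4, step = 0.15, visual = 0.3)
  M <- b[["item"]] + b[["room"]] * mod$room + b[["task"]] * mod$task +
    b[["step"]] * mod$step + b[["visual"]] * mod$visual
  diag(M) <- 0
  rdm <- rdm_from_matrix(M, mod$conditions)
  fit <- fit_decomposition(rdm, mod)
  expect_equal(fit$coefficients, b, tolerance = 1e-10)
  # all-zero RDM gives all-zero coefficients
  fit0 <- fit_decomposition(rdm_from_matrix(M * 0, mod$conditions), mod)
  expect_true(all(abs(fit0$coefficients) < 1e-14))
})

test_that("the fit equals an independent normal-equations solve", {
  mod <- fixture_model_rdms()
  set.seed(41)
  M <- matrix(rnorm(72 * 72), 72, 72)
  M <- (M + t(M)) / 2; diag(M) <- 0
  rdm <- rdm_from_matrix(M, mod$conditions)
  fit <- fit_decomposition(rdm, mod)
  # oracle: lm on the extracted upper-triangle cell table
  ut <- upper.tri(M) & mod$include
  tab <- data.frame(y = M[ut], room = mod$room[ut], task = mod$task[ut],
                    step = mod$step[ut], visual = mod$visual[ut])
  ref <- stats::lm(y ~ room + task + step + visual, data = tab)
  expect_equal(unname(fit$coefficients),
               unname(stats::coef(ref)), tolerance = 1e-10)
  expect_equal(unname(fit$se),
               unname(summary(ref)$coefficients[, "Std. Error"]),
               tolerance = 1e-8)
  expect_equal(fit$n_cells, nrow(tab))
})

test_that("step-stratified fits use the right cells", {
  mod <- fixture_model_rdms()
  co <- mod$conditions
  # planted constant task effect: equal task coefficients in all strata
  M <- 0.5 + 0.3 * mod$task + 0.1 * mod$visual + 0.2 * mod$step
  diag(M) <- 0
  rdm <- rdm_from_matrix(M, co)
  coefs <- vapply(1:3, function(s)
    fit_step_stratified(rdm, mod, s)$coefficients[["task"]], 0)
  expect_equal(coefs, rep(0.3, 3), tolerance = 1e-10)
  # per-stratum cell counts match combinatorial enumeration:
  # pairs (i < j) at step difference s, excluding matched-item cells
  # (step difference > 0 never matches items, so none are excluded)
  for (s in 1:3) {
    fit <- fit_step_stratified(rdm, mod, s)
    n_steppairs <- 4 - s            # ordered step pairs (k, k+s)
    # unordered condition pairs: 18 x 18 combos, minus same-condition
    count <- n_steppairs * (18 * 18)
    expect_equal(fit$n_cells, count)
  }
  expect_error(fit_step_stratified(rdm, mod, 4), "step_apart")
})

test_that("the cross-validated RT RDM behaves like a null covariate", {
  # identical RTs: all zeros
  expect_true(all(build_rt_rdm(rep(1, 5), rep(1, 5)) == 0))
  # equal signed differences square
  rt <- c(0.1, 0.5, 0.2)
  M <- build_rt_rdm(rt, rt)
  expect_true(all(M >= 0))
  expect_equal(M[1, 2], (0.1 - 0.5)^2)
  expect_equal(M, t(M))
  expect_true(all(diag(M) == 0))
  expect_error(build_rt_rdm(c(1, NA), c(1, 2)), "missing")
  # independent RTs across runs: zero expectation
  set.seed(43)
  vals <- replicate(1200, {
    m <- build_rt_rdm(rnorm(6), rnorm(6))
    mean(m[upper.tri(m)])
  })
  expect_lt(abs(mean(vals)), 3 * stats::sd(vals) / sqrt(length(vals)))
})

test_that("condition mean RTs aggregate correct trials only", {
  des <- fixture_design()
  bm <- behavior_model(step_error_rates = c(0.3, 0.3, 0.3, 0.3),
                       high_error_rate = 0)
  beh <- simulate_behavior(des, bm, seed = 3)
  conds <- condition_table(fixture_structure())
  rt <- condition_mean_rt(beh, conds)
  # manual recomputation for one condition
  pick <- conds[7, ]
  sel <- beh$cued_task == pick$task &
    beh$distractor_task == pick$distractor & beh$step == pick$step &
    beh$correct & !is.na(beh$rt)
  expect_equal(unname(rt[7]), mean(beh$rt[sel]))
})

test_that("an orthogonal RT covariate leaves the fit unchanged", {
  mod <- fixture_model_rdms()
  b <- c(item = 0.6, room = 0.2, task = 0.35, step = 0.12, visual = 0.25)
  M <- b[["item"]] + b[["room"]] * mod$room + b[["task"]] * mod$task +
    b[["step"]] * mod$step + b[["visual"]] * mod$visual
  diag(M) <- 0
  rdm <- rdm_from_matrix(M, mod$conditions)
  set.seed(47)
  # RT structure independent of the pattern structure
  rt_rdm <- build_rt_rdm(rnorm(72, sd = 0.05), rnorm(72, sd = 0.05))
  fit0 <- fit_decomposition(rdm, mod)
  fit1 <- fit_decomposition(rdm, mod, extra_covariates = list(rt = rt_rdm))
  expect_equal(fit1$coefficients[names(fit0$coefficients)],
               fit0$coefficients, tolerance = 1e-6)
  expect_true("rt" %in% names(fit1$coefficients))
})
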