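## End-to-end pipeline over simulated subjects, NIfTI helpers, and the
## per-subject analysis path shared by tests and scripts.

#' Read / write NIfTI volumes
#'
#' Thin wrappers around RNifti keeping data and voxel-to-mm transform
#' together.
#'
#' @param path NIfTI file.
#' @return \code{read_volume}: list with \code{data} (array) and
#'   \code{affine} (4 x 4 matrix).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("volume not found: ", path)
  img <- RNifti::readNifti(path)
  list(data = as.array(img), affine = structure(RNifti::xform(img),
                                                dimnames = NULL))
}

#' @rdname read_volume
#' @param data Numeric array.
#' @param affine Optional 4 x 4 transform (pixdim is taken from its
#'   diagonal).
#' @export
write_volume <- function(data, path, affine = NULL) {
  img <- RNifti::asNifti(data)
  if (!is.null(affine))
    RNifti::pixdim(img) <- abs(diag(affine)[seq_len(min(3L,
                                                        length(dim(data))))])
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Analyze one simulated subject
#'
#' The per-subject analysis path: per run, build the event design with
#' error-episode handling, high-pass filter data and design, fit OLS,
#' average onset/epoch betas into 72 condition patterns, estimate the
#' shrinkage noise covariance from the residuals; then compute the
#' cross-validated LDC RDM between runs and fit the decomposition,
#' optionally with the cross-validated RT covariate.
#'
#' @param subject A [simulate_subject()] result.
#' @param rt_covariate Include the cross-validated RT RDM as a covariate.
#' @param cutoff_period High-pass cutoff in seconds (default 128).
#' @return List with \code{fit} (\code{rdm_decomp}), \code{rdm},
#'   \code{strata} (step-stratified task coefficients), per-run
#'   \code{patterns} and \code{noise}.
#' @export
analyze_subject <- function(subject, rt_covariate = FALSE,
                            cutoff_period = 128) {
  structure_ <- subject$structure
  runs <- lapply(subject$runs, function(run) {
    dm <- build_event_design(run$design, behavior = run$behavior,
                             TR = subject$TR, n_scans = run$n_scans)
    dm_f <- highpass_filter(dm, cutoff_period)
    y_f <- highpass_filter(run$bold, cutoff_period, TR = subject$TR)
    fit <- fit_ols(y_f, dm_f)
    # residual df accounts for the DCT functions removed by filtering
    k_dct <- floor(2 * (run$n_scans * subject$TR) / cutoff_period) + 1L
    list(patterns = average_condition_patterns(fit),
         noise = estimate_noise_covariance(fit$residuals,
                                           df = fit$df - k_dct),
         behavior = run$behavior)
  })
  rdm <- compute_rdm(runs[[1]]$patterns, runs[[2]]$patterns,
                     noise1 = runs[[1]]$noise, noise2 = runs[[2]]$noise,
                     normalize = TRUE)
  model <- build_model_rdms(structure_)
  extra <- NULL
  if (rt_covariate) {
    rt1 <- condition_mean_rt(runs[[1]]$behavior, model$conditions)
    rt2 <- condition_mean_rt(runs[[2]]$behavior, model$conditions)
    extra <- list(rt = build_rt_rdm(rt1, rt2))
  }
  fit <- fit_decomposition(rdm, model, extra_covariates = extra)
  strata <- vapply(1:3, function(s)
    fit_step_stratified(rdm, model, s)$coefficients[["task"]], 0)
  list(fit = fit, rdm = rdm, strata = strata,
       patterns = lapply(runs, `[[`, "patterns"),
       noise = lapply(runs, `[[`, "noise"))
}

# A subject is usable when every cued x distractor combination retains at
# least one non-error episode in both runs (otherwise some condition has
# no interest regressors, as in the excluded participants of the
# original cohort).
subject_usable <- function(subject) {
  for (run in subject$runs) {
    fl <- flag_error_episodes(run$behavior)
    bad <- as.integer(names(fl))[fl]
    ep <- run$design$episodes
    ep <- ep[!ep$is_dummy & !(ep$index %in% bad), ]
    if (nrow(unique(ep[c("cued_task", "distractor_task")])) < 18L)
      return(FALSE)
  }
  TRUE
}

#' Simulate and analyze a group of subjects
#'
#' Simulates subjects with a common planted geometry, analyzes each, and
#' runs the group-level tests: one-sample one-tailed t tests per
#' representation measure with BH-FDR across measures. Subjects in whom
#' an error episode eliminates all episodes of some cued x distractor
#' combination are replaced (next seed), mirroring cohort exclusion.
#'
#' @param n_subjects Number of subjects.
#' @param model A [pattern_model()].
#' @param seed Integer seed.
#' @param structure A [task_structure()].
#' @param n_candidates Candidate orders per run.
#' @param rt_covariate Include the RT covariate in the decomposition.
#' @param rt_model A [behavior_model()].
#' @param out_dir Optional directory for TSV/JSON outputs.
#' @return List with \code{coefficients} (subject x measure matrix),
#'   \code{strata} (subject x step-difference task coefficients),
#'   \code{group} (per-measure t table with FDR flags), \code{manifest}.
#' @export
run_pipeline <- function(n_subjects = 10, model = pattern_model(),
                         seed = 1, structure = task_structure(),
                         n_candidates = 10L, rt_covariate = FALSE,
                         rt_model = behavior_model(), out_dir = NULL) {
  stopifnot(n_subjects >= 2)
  coefs <- NULL; strata <- NULL
  used_seeds <- integer(0)
  s <- 0L
  while (length(used_seeds) < n_subjects) {
    s <- s + 1L
    subj <- simulate_subject(model, structure,
                             seed = derive_seed(seed, s),
                             n_candidates = n_candidates,
                             rt_model = rt_model)
    if (!subject_usable(subj)) next
    res <- analyze_subject(subj, rt_covariate = rt_covariate)
    cf <- res$fit$coefficients
    coefs <- rbind(coefs, cf[c("item", "room", "task", "step", "visual")])
    strata <- rbind(strata, res$strata)
    used_seeds <- c(used_seeds, derive_seed(seed, s))
  }
  measures <- c("item", "room", "task", "step", "visual")
  colnames(coefs) <- measures
  colnames(strata) <- paste0("apart", 1:3)

  tests <- do.call(rbind, lapply(measures[1:4], function(m)
    cbind(measure = m, group_ttest(coefs[, m], tail = "one"))))
  fdr <- fdr_bh(tests$p, q = 0.05)
  tests$p_adjusted <- fdr$adjusted
  tests$significant <- fdr$reject

  manifest <- NULL
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    cpath <- file.path(out_dir, "subject_coefficients.tsv")
    utils::write.table(cbind(subject = seq_len(nrow(coefs)), coefs),
                       cpath, sep = "\t", quote = FALSE, row.names = FALSE)
    gpath <- file.path(out_dir, "group_tests.tsv")
    utils::write.table(tests, gpath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    spath <- file.path(out_dir, "provenance.json")
    jsonlite::write_json(list(seed = seed, subject_seeds = used_seeds,
                              n_subjects = n_subjects,
                              model = unclass(model)),
                         spath, auto_unbox = TRUE, digits = NA)
    manifest <- c(coefficients = cpath, group = gpath, provenance = spath)
  }
  list(coefficients = coefs, strata = strata, group = tests,
       subject_seeds = used_seeds, manifest = manifest)
}
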