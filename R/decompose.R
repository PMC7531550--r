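## The core statistic: linear decomposition of RDM cells into room, task,
## step-difference and visual-difference components, with the item
## component as intercept, matched-item exclusion, step-stratified task
## fits, and the cross-validated reaction-time covariate.

#' Model RDMs and the include mask
#'
#' Builds, for every pair of the 72 conditions, the cell-wise regressors
#' of the decomposition model: \code{room} (0/1, different room),
#' \code{task} (0/1, different cued task), \code{step} (absolute step
#' difference, 0-3), \code{visual} (1, 0.5 or 0 for zero, one or two
#' display tasks shared between the two conditions), and the include mask
#' that drops the diagonal and the matched-item cells (same cued task and
#' same step with a different distractor — the only off-diagonal pairs
#' sharing the target item), so that the intercept of the fit measures
#' item representation.
#'
#' @param structure A [task_structure()].
#' @param conditions Optional condition table (defaults to
#'   [condition_table()] of \code{structure}).
#' @return Object of class \code{model_rdm_set}: matrices \code{room},
#'   \code{task}, \code{step}, \code{visual}, logical \code{include}, and
#'   the \code{conditions} table.
#' @export
build_model_rdms <- function(structure, conditions = NULL) {
  conds <- if (is.null(conditions)) condition_table(structure) else conditions
  need <- c("task", "distractor", "step", "room")
  if (!all(need %in% names(conds))) stop("malformed condition table")
  n <- nrow(conds)
  same_task <- outer(conds$task, conds$task, "==")
  same_room <- outer(conds$room, conds$room, "==")
  room <- 1 * !same_room
  task <- 1 * !same_task
  step <- abs(outer(conds$step, conds$step, "-"))
  shared <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j) {
    length(intersect(c(conds$task[i], conds$distractor[i]),
                     c(conds$task[j], conds$distractor[j])))
  }))
  visual <- 1 - shared / 2
  include <- same_task & outer(conds$step, conds$step, "==")
  include <- !include  # drops diagonal and matched-item cells
  structure(list(room = room, task = task, step = step, visual = visual,
                 include = include, conditions = conds),
            class = "model_rdm_set")
}

# cell table of unique included upper-triangle cells
decomposition_cells <- function(rdm, model, extra = NULL) {
  n <- nrow(model$include)
  if (!all(dim(rdm$mat) == n))
    stop("RDM and model RDMs differ in condition count")
  if (!is.null(rdm$conditions) &&
      !identical(rdm$conditions$label, model$conditions$label))
    stop("RDM and model RDMs differ in condition ordering")
  ut <- upper.tri(matrix(0, n, n)) & model$include
  cells <- data.frame(ldc = rdm$mat[ut], room = model$room[ut],
                      task = model$task[ut], step = model$step[ut],
                      visual = model$visual[ut])
  if (!is.null(extra)) {
    extra <- as.list(extra)
    for (nm in names(extra)) {
      em <- if (inherits(extra[[nm]], "rdm")) extra[[nm]]$mat
            else as.matrix(extra[[nm]])
      if (!all(dim(em) == n)) stop("covariate '", nm, "' has wrong size")
      cells[[nm]] <- em[ut]
    }
  }
  cells
}

#' Fit the RDM decomposition
#'
#' Ordinary least squares of the included upper-triangle RDM cells on the
#' model regressors. The coefficients are the representation measures:
#' \code{item} (intercept: estimated dissimilarity with no room, task or
#' step difference), \code{room} (different-room minus same-room
#' different-task), \code{task} (different-task minus same-task),
#' \code{step} (slope of dissimilarity against step difference), and
#' \code{visual} (display-item confound).
#'
#' @param rdm An \code{rdm} (72 conditions).
#' @param model A \code{model_rdm_set} from [build_model_rdms()].
#' @param extra_covariates Optional named list of additional cell-wise
#'   covariate matrices (or \code{rdm}s), e.g. the cross-validated RT RDM
#'   of [build_rt_rdm()].
#' @return Object of class \code{rdm_decomp} with \code{coefficients},
#'   \code{residual_variance}, \code{n_cells}, the cell table and the fit.
#' @seealso [fit_step_stratified()], [expected_decomposition()]
#' @export
fit_decomposition <- function(rdm, model, extra_covariates = NULL) {
  cells <- decomposition_cells(rdm, model, extra_covariates)
  X <- cbind(item = 1, as.matrix(cells[, -1L, drop = FALSE]))
  fit_decomposition_cells(cells$ldc, X, cells)
}

fit_decomposition_cells <- function(y, X, cells) {
  qrx <- qr(X)
  if (qrx$rank < ncol(X))
    stop("collinear model regressors on the included cells: ",
         paste(colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]],
               collapse = ", "))
  beta <- qr.coef(qrx, y)
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  rv <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qrx))
  se <- sqrt(rv * diag(XtXinv))
  names(se) <- names(beta)
  structure(list(coefficients = beta, se = se,
                 residual_variance = rv, df = df,
                 n_cells = length(y), cells = cells),
            class = "rdm_decomp")
}

#' @export
print.rdm_decomp <- function(x, digits = 4, ...) {
  cat("RDM decomposition (", x$n_cells, " cells):\n", sep = "")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
coef.rdm_decomp <- function(object, ...) object$coefficients

#' @export
summary.rdm_decomp <- function(object, ...) {
  tab <- data.frame(estimate = object$coefficients, se = object$se,
                    t = object$coefficients / object$se)
  out <- list(coefficients = tab,
              residual_variance = object$residual_variance,
              n_cells = object$n_cells, df = object$df)
  class(out) <- "summary.rdm_decomp"
  out
}

#' @export
print.summary.rdm_decomp <- function(x, digits = 4, ...) {
  cat("RDM decomposition:", x$n_cells, "included cells, residual variance",
      format(x$residual_variance, digits = digits), "\n")
  print(round(x$coefficients, digits))
  cat("(cell-level t values are descriptive; inference is across",
      "subjects)\n")
  invisible(x)
}

#' Step-stratified task representation
#'
#' Refits the decomposition using only cells at exactly the given step
#' difference (one, two or three steps apart), with room, task and visual
#' regressors plus the intercept. Used to test whether apparent task
#' representation depends on the temporal separation of the steps
#' compared.
#'
#' @param rdm An \code{rdm}.
#' @param model A \code{model_rdm_set}.
#' @param step_apart 1, 2 or 3.
#' @return An \code{rdm_decomp} (coefficients \code{item}, \code{room},
#'   \code{task}, \code{visual}).
#' @export
fit_step_stratified <- function(rdm, model, step_apart) {
  if (!step_apart %in% 1:3) stop("step_apart must be 1, 2 or 3")
  cells <- decomposition_cells(rdm, model)
  cells <- cells[cells$step == step_apart, , drop = FALSE]
  if (nrow(cells) == 0L) stop("empty stratum")
  X <- cbind(item = 1, room = cells$room, task = cells$task,
             visual = cells$visual)
  fit_decomposition_cells(cells$ldc, X, cells)
}

#' Cross-validated reaction-time RDM
#'
#' The matrix of signed condition-wise RT differences from one run,
#' multiplied element-wise by the signed differences from the other run:
#' \code{cell(i, j) = (rt1_i - rt1_j) * (rt2_i - rt2_j)}. Like the LDC,
#' this cross-validated measure has expected value zero when there is no
#' true RT difference.
#'
#' @param rt_run1,rt_run2 Per-condition mean RTs (aligned vectors; no
#'   missing values).
#' @return Symmetric zero-diagonal matrix.
#' @export
build_rt_rdm <- function(rt_run1, rt_run2) {
  if (length(rt_run1) != length(rt_run2))
    stop("RT vectors must cover the same conditions")
  if (anyNA(rt_run1) || anyNA(rt_run2))
    stop("missing condition in RT vector")
  d1 <- outer(rt_run1, rt_run1, "-")
  d2 <- outer(rt_run2, rt_run2, "-")
  d1 * d2
}

#' Per-condition mean reaction times
#'
#' Condition-level RT is the mean correct-trial RT over the responses of
#' that condition's episodes within a run (each cued task x distractor x
#' step condition has two episodes, hence up to six correct responses).
#'
#' @param behavior Trial table from [simulate_behavior()] (or with the
#'   same columns).
#' @param conditions Condition table defining the output order.
#' @return Numeric vector of mean RTs aligned with \code{conditions}
#'   (NA when a condition has no correct response).
#' @export
condition_mean_rt <- function(behavior, conditions) {
  key_b <- paste(behavior$cued_task, behavior$distractor_task,
                 behavior$step)
  key_c <- paste(conditions$task, conditions$distractor, conditions$step)
  ok <- behavior$correct & !is.na(behavior$rt)
  means <- tapply(behavior$rt[ok], key_b[ok], mean)
  out <- as.vector(means[key_c])
  names(out) <- conditions$label
  out
}

#' Export the included cells of a decomposition as a table
#'
#' @param decomp An \code{rdm_decomp}.
#' @param path Optional TSV path; when given the table is written there.
#' @return The cell table (invisibly when written).
#' @export
decomposition_cell_table <- function(decomp, path = NULL) {
  tab <- decomp$cells
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
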