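## Cross-validated linear discriminant contrast (LDC) dissimilarities:
## shrinkage noise covariance from GLM residuals, pairwise LDC, and the
## 72 x 72 representational dissimilarity matrix.

#' Shrinkage noise covariance
#'
#' Sample covariance of GLM residuals shrunk toward its diagonal,
#' \eqn{\hat\Sigma = (1-\lambda) S + \lambda \mathrm{diag}(S)}, with the
#' shrinkage intensity chosen by the analytic (Ledoit-Wolf style) formula
#' unless supplied. The result is the multivariate noise model used to
#' normalize pattern differences in the LDC.
#'
#' @param residuals Time x voxel matrix of GLM residuals.
#' @param shrinkage Optional fixed shrinkage intensity in [0, 1].
#' @param df Residual degrees of freedom used to scale the covariance
#'   (defaults to rows minus one; pass the GLM residual df so the noise
#'   variance is not underestimated after a large model fit).
#' @return Object of class \code{noise_model}: \code{sigma} (voxel x voxel,
#'   symmetric positive definite), \code{lambda}, \code{df}.
#' @export
estimate_noise_covariance <- function(residuals, shrinkage = NULL,
                                      df = NULL) {
  R <- as.matrix(residuals)
  n <- nrow(R)
  if (n < 2L) stop("need at least 2 time points")
  if (is.null(df)) df <- n - 1L
  Rc <- sweep(R, 2L, colMeans(R))
  S0 <- crossprod(Rc) / (n - 1L)   # sample scale, for the intensity
  if (any(diag(S0) <= 0))
    stop("zero-variance voxel in residuals; mask it upstream")
  if (is.null(shrinkage)) {
    # analytic intensity: sum of estimated variances of off-diagonal
    # covariances over the sum of their squares (Ledoit-Wolf style,
    # diagonal target)
    C1 <- crossprod(Rc)            # sum_k x_ki x_kj
    C2 <- crossprod(Rc^2)          # sum_k (x_ki x_kj)^2
    Vhat <- n / (n - 1)^3 * (C2 - C1^2 / n)
    off <- !diag(TRUE, ncol(S0))
    denom <- sum(S0[off]^2)
    lambda <- if (denom <= 0) 1 else sum(Vhat[off]) / denom
    lambda <- min(1, max(0, lambda))
  } else {
    if (shrinkage < 0 || shrinkage > 1) stop("shrinkage must be in [0, 1]")
    lambda <- shrinkage
  }
  S <- S0 * (n - 1L) / df          # df-aware scale
  sigma <- (1 - lambda) * S + lambda * diag(diag(S), ncol(S))
  # guarantee positive definiteness (can fail only at lambda ~ 0 with
  # fewer time points than voxels)
  while (inherits(tryCatch(chol(sigma), error = identity), "error") &&
         lambda < 1) {
    lambda <- min(1, lambda + 0.05)
    sigma <- (1 - lambda) * S + lambda * diag(diag(S), ncol(S))
  }
  structure(list(sigma = sigma, lambda = lambda, df = df),
            class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf("noise_model: %d voxels, shrinkage %.3f, df %d\n",
              ncol(x$sigma), x$lambda, x$df))
  invisible(x)
}

# Sigma^{-1} %*% t(P) for a noise model or "identity"
solve_noise <- function(noise, Pt) {
  if (identical(noise, "identity")) return(Pt)
  stopifnot(inherits(noise, "noise_model"))
  solve(noise$sigma, Pt)
}

#' Cross-validated LDC between two conditions
#'
#' The pattern difference of one run is projected onto the Fisher
#' discriminant fitted on the other run (using that run's noise
#' covariance), and the two directions are averaged:
#' \deqn{d = \tfrac12 [(u_{A1}-u_{B1})^\top \hat\Sigma_2^{-1}
#'   (u_{A2}-u_{B2}) + (u_{A2}-u_{B2})^\top \hat\Sigma_1^{-1}
#'   (u_{A1}-u_{B1})]}
#' a cross-validated estimate of squared Mahalanobis distance, distributed
#' around zero when the true distance is zero (no truncation).
#'
#' @param uA1,uB1 Condition patterns in run 1.
#' @param uA2,uB2 The same conditions in run 2.
#' @param noise1,noise2 Per-run \code{noise_model}s (or \code{"identity"}).
#' @return Signed scalar dissimilarity.
#' @export
crossvalidated_ldc <- function(uA1, uB1, uA2, uB2,
                               noise1 = "identity", noise2 = "identity") {
  if (length(unique(c(length(uA1), length(uB1), length(uA2),
                      length(uB2)))) != 1L)
    stop("patterns must share the same voxel set")
  d1 <- uA1 - uB1
  d2 <- uA2 - uB2
  0.5 * (sum(d1 * solve_noise(noise2, d2)) +
           sum(d2 * solve_noise(noise1, d1)))
}

#' Representational dissimilarity matrix of all condition pairs
#'
#' Computes the cross-validated LDC for every pair of conditions between
#' two runs (72 conditions give a 72 x 72 RDM with 2556 unique
#' off-diagonal values), optionally dividing all entries by the voxel
#' count so dissimilarities are comparable across ROIs of different size.
#'
#' @param patterns1,patterns2 \code{condition_patterns} objects (or plain
#'   condition x voxel matrices with identical row order).
#' @param noise1,noise2 Per-run \code{noise_model}s or \code{"identity"}.
#' @param normalize Divide entries by the voxel count (default TRUE).
#' @return Object of class \code{rdm}: \code{mat} (symmetric, zero
#'   diagonal), \code{conditions}, \code{n_voxels}, \code{normalized}.
#' @export
compute_rdm <- function(patterns1, patterns2, noise1 = "identity",
                        noise2 = "identity", normalize = TRUE) {
  conds <- NULL
  if (inherits(patterns1, "condition_patterns")) {
    conds <- patterns1$conditions
    if (inherits(patterns2, "condition_patterns") &&
        !identical(conds$label, patterns2$conditions$label))
      stop("condition sets differ between runs")
    P1 <- patterns1$patterns
    P2 <- if (inherits(patterns2, "condition_patterns"))
      patterns2$patterns else patterns2
  } else {
    P1 <- as.matrix(patterns1)
    P2 <- if (inherits(patterns2, "condition_patterns"))
      patterns2$patterns else as.matrix(patterns2)
  }
  if (!all(dim(P1) == dim(P2))) stop("pattern sets must match in shape")
  V <- ncol(P1)

  # d_ij per direction from the cross-run Gram matrix
  pair_dist <- function(Ga) {
    dg <- diag(Ga)
    outer(dg, dg, "+") - Ga - t(Ga)
  }
  Ga <- P1 %*% solve_noise(noise2, t(P2))
  Gb <- P2 %*% solve_noise(noise1, t(P1))
  D <- (pair_dist(Ga) + pair_dist(Gb)) / 2
  if (normalize) D <- D / V
  diag(D) <- 0
  D <- (D + t(D)) / 2
  dimnames(D) <- list(rownames(P1), rownames(P1))
  structure(list(mat = D, conditions = conds, n_voxels = V,
                 normalized = normalize),
            class = "rdm")
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("RDM: %d x %d, %d voxels%s\n", nrow(x$mat), ncol(x$mat),
              x$n_voxels,
              if (x$normalized) ", voxel-normalized" else ""))
  invisible(x)
}

#' Collapse an RDM across the distractor factor
#'
#' Averages the cells of the full 72 x 72 RDM over distractor pairs,
#' yielding the simplified 24 x 24 (task x step) RDM with a zero
#' diagonal.
#'
#' @param rdm An \code{rdm} with a 72-condition table.
#' @return An \code{rdm} over the 24 task x step conditions.
#' @export
collapse_rdm <- function(rdm) {
  conds <- rdm$conditions
  if (is.null(conds)) stop("RDM carries no condition table")
  grp <- if (!is.null(conds$label))
    vapply(strsplit(conds$label, ".", fixed = TRUE),
           function(p) paste(p[1L], p[3L], sep = "."), "")
  else paste(conds$task, conds$step, sep = ".s")
  levels <- unique(grp)
  n <- length(levels)
  M <- matrix(0, n, n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    M[a, b] <- mean(rdm$mat[grp == levels[a], grp == levels[b]])
  }
  first <- match(levels, grp)
  cond24 <- data.frame(task = conds$task[first], step = conds$step[first],
                       room = conds$room[first], label = levels,
                       stringsAsFactors = FALSE)
  dimnames(M) <- list(levels, levels)
  structure(list(mat = M, conditions = cond24, n_voxels = rdm$n_voxels,
                 normalized = rdm$normalized),
            class = "rdm")
}

#' Write / read an RDM as TSV with a JSON sidecar
#'
#' @param rdm An \code{rdm}.
#' @param path TSV path; the sidecar is written alongside with extension
#'   \code{.json}.
#' @return Invisibly, the paths written.
#' @export
write_rdm <- function(rdm, path) {
  utils::write.table(rdm$mat, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  side <- sub("\\.tsv$", ".json", path)
  if (identical(side, path)) side <- paste0(path, ".json")
  jsonlite::write_json(list(n_voxels = rdm$n_voxels,
                            normalized = rdm$normalized),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(c(path, side))
}

#' @rdname write_rdm
#' @export
read_rdm <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1L, check.names = FALSE))
  side <- sub("\\.tsv$", ".json", path)
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  structure(list(mat = m, conditions = NULL,
                 n_voxels = meta$n_voxels %||% NA_integer_,
                 normalized = meta$normalized %||% NA),
            class = "rdm")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
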