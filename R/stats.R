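## Group-level inferential layer: ROI FIR time courses, repeated-measures
## ANOVA with polynomial trends and Greenhouse-Geisser correction,
## one-sample/paired t tests with Cohen's d, and Benjamini-Hochberg FDR.

#' ROI FIR time course
#'
#' Extracts the 60 FIR bin estimates from a FIR-model fit: betas are
#' averaged over the voxels of the region and then across the per-task
#' regressor sets, one value per 1.5 s bin.
#'
#' @param fir_betas A \code{beta_set} from [build_fir_design()].
#' @param voxels Indices (or logical vector) of the voxels in the region;
#'   default all.
#' @return Numeric vector of length \code{n_bins} (bin means).
#' @export
roi_fir_timecourse <- function(fir_betas, voxels = NULL) {
  if (!identical(fir_betas$kind, "fir"))
    stop("roi_fir_timecourse requires a FIR-kind beta_set")
  B <- fir_betas$betas[fir_betas$interest, , drop = FALSE]
  if (!is.null(voxels)) B <- B[, voxels, drop = FALSE]
  if (ncol(B) == 0L) stop("empty ROI mask")
  vox_mean <- rowMeans(B)
  nm <- rownames(fir_betas$betas)[fir_betas$interest]
  bin <- sub("^.*\\.bin", "", nm)
  out <- tapply(vox_mean, bin, mean)
  as.vector(out[order(as.integer(names(out)))])
}

# Greenhouse-Geisser epsilon from the within-subject covariance of the
# k levels (double-centered covariance eigen formula).
gg_epsilon <- function(Y) {
  k <- ncol(Y)
  S <- stats::cov(Y)
  C <- diag(k) - matrix(1 / k, k, k)
  M <- C %*% S %*% C
  tr <- sum(diag(M))
  eps <- tr^2 / ((k - 1) * sum(M * M))
  min(1, max(1 / (k - 1), eps))
}

# standard trend weights: the stated integer contrasts for 4 levels,
# orthogonal polynomials otherwise
trend_weights <- function(k) {
  if (k == 4L)
    list(linear = c(-3, -1, 1, 3), quadratic = c(1, -1, -1, 1))
  else {
    cp <- stats::contr.poly(k)
    list(linear = cp[, 1L], quadratic = if (k > 2L) cp[, 2L])
  }
}

#' One-way repeated-measures ANOVA with trend contrasts
#'
#' Omnibus F with Greenhouse-Geisser corrected degrees of freedom and
#' partial eta-squared, plus linear and quadratic trend contrasts
#' (weights -3, -1, 1, 3 and 1, -1, -1, 1 for four equally spaced
#' levels), tested as one-df contrasts without sphericity correction.
#'
#' @param data Subject x level numeric matrix (fully crossed, one
#'   observation per cell).
#' @return Data frame with rows \code{omnibus}, \code{linear},
#'   \code{quadratic}: columns \code{effect}, \code{F}, \code{df1},
#'   \code{df2}, \code{epsilon}, \code{p}, \code{partial_eta_sq}.
#' @export
rm_anova_trends <- function(data) {
  Y <- as.matrix(data)
  if (anyNA(Y)) stop("missing cells; a fully crossed design is required")
  n <- nrow(Y); k <- ncol(Y)
  if (n < 3L || k < 2L) stop("need >= 3 subjects and >= 2 levels")
  gm <- mean(Y)
  m_lvl <- colMeans(Y); m_sub <- rowMeans(Y)
  ss_lvl <- n * sum((m_lvl - gm)^2)
  ss_err <- sum((Y - outer(m_sub, m_lvl, "+") + gm)^2)
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)
  Fo <- (ss_lvl / df1) / (ss_err / df2)
  eps <- gg_epsilon(Y)
  p_o <- stats::pf(Fo, eps * df1, eps * df2, lower.tail = FALSE)
  pes_o <- ss_lvl / (ss_lvl + ss_err)

  out <- data.frame(effect = "omnibus", F = Fo, df1 = eps * df1,
                    df2 = eps * df2, epsilon = eps, p = p_o,
                    partial_eta_sq = pes_o, stringsAsFactors = FALSE)
  tw <- trend_weights(k)
  for (nm in names(tw)) {
    w <- tw[[nm]]
    if (is.null(w)) next
    sc <- Y %*% w
    Ft <- (mean(sc) / (stats::sd(sc) / sqrt(n)))^2
    pt <- stats::pf(Ft, 1, n - 1, lower.tail = FALSE)
    out <- rbind(out, data.frame(effect = nm, F = Ft, df1 = 1,
                                 df2 = n - 1, epsilon = NA_real_, p = pt,
                                 partial_eta_sq = Ft / (Ft + n - 1),
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- out$effect
  out
}

#' Two-factor within-subject ANOVA
#'
#' Fully crossed two-way repeated-measures ANOVA (e.g. the 2 network x 4
#' information-type analysis): main effects and interaction, each tested
#' against its own subject-interaction error term, with
#' Greenhouse-Geisser epsilon and partial eta-squared per effect.
#'
#' @param data Subject x cell matrix, cells ordered so that factor B
#'   varies fastest within factor A.
#' @param ka,kb Number of levels of factors A and B
#'   (\code{ka * kb == ncol(data)}).
#' @return Data frame with rows \code{A}, \code{B}, \code{A:B}.
#' @export
rm_anova_2w <- function(data, ka, kb) {
  Y <- as.matrix(data)
  if (anyNA(Y)) stop("missing cells; a fully crossed design is required")
  stopifnot(ka * kb == ncol(Y))
  n <- nrow(Y)
  fA <- rep(seq_len(ka), each = kb)
  fB <- rep(seq_len(kb), times = ka)
  gm <- mean(Y)
  m_sub <- rowMeans(Y)
  m_A <- vapply(seq_len(ka), function(a) mean(Y[, fA == a]), 0)
  m_B <- vapply(seq_len(kb), function(b) mean(Y[, fB == b]), 0)
  m_AB <- matrix(0, ka, kb)
  for (a in seq_len(ka)) for (b in seq_len(kb))
    m_AB[a, b] <- mean(Y[, fA == a & fB == b])
  m_As <- vapply(seq_len(ka), function(a)
    rowMeans(Y[, fA == a, drop = FALSE]), numeric(n))
  m_Bs <- vapply(seq_len(kb), function(b)
    rowMeans(Y[, fB == b, drop = FALSE]), numeric(n))

  ss_A <- n * kb * sum((m_A - gm)^2)
  ss_B <- n * ka * sum((m_B - gm)^2)
  ss_AB <- n * sum((sweep(sweep(m_AB, 1L, m_A - gm), 2L, m_B - gm) - gm)^2)
  ss_As <- kb * sum((m_As - outer(m_sub, m_A, "+") + gm)^2)
  ss_Bs <- ka * sum((m_Bs - outer(m_sub, m_B, "+") + gm)^2)
  cell_ab <- matrix(m_AB[cbind(fA, fB)], n, ncol(Y), byrow = TRUE)
  cell_main <- matrix(m_A[fA] + m_B[fB] - gm, n, ncol(Y), byrow = TRUE)
  resid <- Y - m_As[, fA] - m_Bs[, fB] - cell_ab + m_sub + cell_main
  ss_ABs <- sum(resid^2)

  # orthonormal contrast bases per effect (b varies fastest)
  onb <- function(k) qr.Q(qr(cbind(1, diag(k))))[, 2:k, drop = FALSE]
  Ca <- onb(ka); Cb <- onb(kb)
  eps_of <- function(M) {
    d <- ncol(M)
    Sd <- stats::cov(Y %*% M)
    min(1, max(1 / d, sum(diag(Sd))^2 / (d * sum(Sd * Sd))))
  }
  eff <- function(name, ss, df1, ss_err, df_err, M) {
    eps <- if (df1 > 1) eps_of(M) else 1
    F <- (ss / df1) / (ss_err / df_err)
    data.frame(effect = name, F = F, df1 = eps * df1, df2 = eps * df_err,
               epsilon = eps,
               p = stats::pf(F, eps * df1, eps * df_err,
                             lower.tail = FALSE),
               partial_eta_sq = ss / (ss + ss_err),
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    eff("A", ss_A, ka - 1, ss_As, (n - 1) * (ka - 1),
        kronecker(Ca, matrix(1, kb, 1))),
    eff("B", ss_B, kb - 1, ss_Bs, (n - 1) * (kb - 1),
        kronecker(matrix(1, ka, 1), Cb)),
    eff("A:B", ss_AB, (ka - 1) * (kb - 1), ss_ABs,
        (n - 1) * (ka - 1) * (kb - 1), kronecker(Ca, Cb)))
  rownames(out) <- out$effect
  out
}

#' Group t test with Cohen's d
#'
#' One-sample or paired t test with the tail the analysis specifies
#' (one-tailed greater-than-zero for RSA representation measures,
#' two-tailed for network comparisons), plus Cohen's d (mean over SD of
#' the tested values or differences).
#'
#' @param values Per-subject scalars (one-sample), or the first member of
#'   a pair.
#' @param y Second member for \code{mode = "paired"}.
#' @param mode \code{"one-sample"} or \code{"paired"}.
#' @param tail \code{"one"} (greater) or \code{"two"}.
#' @param mu Null value (default 0).
#' @return Data frame with \code{t}, \code{df}, \code{p}, \code{d},
#'   \code{tail}, \code{mode}.
#' @export
group_ttest <- function(values, y = NULL, mode = c("one-sample", "paired"),
                        tail = c("one", "two"), mu = 0) {
  mode <- match.arg(mode); tail <- match.arg(tail)
  x <- if (identical(mode, "paired")) {
    if (is.null(y)) stop("paired mode needs y")
    values - y
  } else values
  if (length(x) < 2L) stop("need n >= 2")
  if (stats::sd(x) == 0) stop("zero variance; t test undefined")
  alt <- if (tail == "one") "greater" else "two.sided"
  tt <- stats::t.test(x, mu = mu, alternative = alt)
  data.frame(t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value, d = (mean(x) - mu) / stats::sd(x),
             tail = tail, mode = mode, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up procedure at level \code{q}: rejects the hypotheses with the
#' \code{k*} smallest p values where \code{k*} is the largest \code{k}
#' with \code{p_(k) <= k q / m}; adjusted p values are the standard
#' monotone BH values.
#'
#' @param p_values Vector of p values in [0, 1].
#' @param q FDR level (default 0.05).
#' @return List with \code{reject} (logical) and \code{adjusted}
#'   (numeric), both in input order.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  p <- as.numeric(p_values)
  if (length(p) == 0L) return(list(reject = logical(0),
                                   adjusted = numeric(0)))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  thresh <- which(p[o] <= q * seq_len(m) / m)
  reject <- rep(FALSE, m)
  if (length(thresh) > 0L) reject[o[seq_len(max(thresh))]] <- TRUE
  list(reject = reject, adjusted = stats::p.adjust(p, method = "BH"))
}
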