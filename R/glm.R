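## GLM layer: canonical HRF, event-based and FIR design matrices,
## discrete-cosine high-pass filtering, per-voxel OLS, and extraction of
## the 72 condition patterns entering RSA.

#' Canonical haemodynamic response function
#'
#' Double-gamma HRF (response peak 6 s, undershoot peak 16 s,
#' response/undershoot ratio 6, 32 s support), evaluated at the given
#' times and scaled to unit peak.
#'
#' @param t Times in seconds.
#' @return Numeric vector of HRF values; zero for \code{t < 0}.
#' @export
canonical_hrf <- function(t) {
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h[t < 0] <- 0
  h / max(h)
}

# Microtime stick function for a set of events. Zero-duration events are
# unit impulses at the nearest microtime bin.
stick_function <- function(onsets, durations, n_micro, dt) {
  s <- numeric(n_micro)
  for (i in seq_along(onsets)) {
    if (durations[i] <= 0) {
      j <- round(onsets[i] / dt) + 1L
      s[j] <- s[j] + 1
    } else {
      a <- floor(onsets[i] / dt) + 1L
      b <- min(floor((onsets[i] + durations[i]) / dt), n_micro)
      s[a:b] <- s[a:b] + 1
    }
  }
  s
}

# Convolve microtime stick columns with the canonical HRF and sample at
# scan onsets.
hrf_convolve_sample <- function(sticks, n_scans, TR, dt) {
  h <- canonical_hrf(seq(0, 32, by = dt))
  cv <- fft_conv_batch(sticks, h)
  cv[floor(seq(0, by = TR, length.out = n_scans) / dt) + 1L, ,
     drop = FALSE]
}

new_design_matrix <- function(values, interest, TR, kind, conditions = NULL) {
  structure(list(values = values, names = colnames(values),
                 interest = interest, TR = TR, kind = kind,
                 conditions = conditions),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("%s design matrix: %d scans x %d regressors (%d of interest)\n",
              x$kind, nrow(x$values), ncol(x$values), sum(x$interest)))
  invisible(x)
}

# short task codes K1..K3 / B1..B3 in structure order
task_codes <- function(structure) {
  codes <- unlist(lapply(structure$rooms, function(r) {
    paste0(toupper(substr(r, 1, 1)), seq_len(sum(structure$tasks$room == r)))
  }))
  stats::setNames(codes, structure$tasks$task)
}

#' Canonical ordering of the 72 conditions
#'
#' One condition per cued task x distractor task x step, ordered by cued
#' task (structure order), then distractor task, then step.
#'
#' @param structure A [task_structure()].
#' @return Data frame with columns \code{task}, \code{distractor},
#'   \code{step}, \code{room}, and short \code{label} codes.
#' @export
condition_table <- function(structure) {
  codes <- task_codes(structure)
  rows <- list()
  for (tk in structure$tasks$task) {
    other <- structure$tasks$task[structure$tasks$room !=
                                    structure_room(structure, tk)]
    for (d in other) for (k in 1:4)
      rows[[length(rows) + 1L]] <- data.frame(
        task = tk, distractor = d, step = k,
        room = structure_room(structure, tk),
        label = sprintf("%s.%s.s%d", codes[[tk]], codes[[d]], k),
        stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Flag error episodes
#'
#' An episode is an error episode when strictly more than
#' \code{threshold} of its 12 search responses are errors (incorrect or
#' missed). Missing responses count as errors.
#'
#' @param behavior Trial table with columns \code{episode} and
#'   \code{correct} (logical; \code{NA} = missed).
#' @param threshold Error fraction above which an episode is flagged
#'   (default 0.25).
#' @return Named logical vector, one entry per episode index.
#' @export
flag_error_episodes <- function(behavior, threshold = 0.25) {
  err <- !behavior$correct | is.na(behavior$correct)
  frac <- tapply(err, behavior$episode, mean)
  flags <- as.vector(frac) > threshold
  names(flags) <- names(frac)
  flags
}

#' Event-based design matrix
#'
#' Builds the onset/epoch/offset GLM: for each of the 18 cued task x
#' distractor task combinations, a 0 s onset regressor and a 9 s epoch
#' regressor per step plus a 0 s offset regressor at the episode end
#' (162 regressors of interest), all convolved with the canonical HRF.
#' The cue is modeled by separate onset and epoch (cue to first step)
#' regressors; the dummy episode, error episodes (> 25% errors) and
#' individual error searches (2 s events) are modeled by separate
#' non-interest regressor sets; a block-mean column and optional motion
#' columns complete the matrix.
#'
#' @param design A \code{run_design}.
#' @param behavior Optional trial table used to flag error episodes and
#'   error searches (columns \code{episode}, \code{step}, \code{search},
#'   \code{correct}).
#' @param TR Repetition time in seconds (default 1.373).
#' @param n_scans Number of volumes; default covers the full run.
#' @param motion Optional scans x 6 matrix of motion parameters.
#' @param microtime Microtime upsampling factor (default 16 bins per TR).
#' @return A \code{design_matrix} of kind \code{"event"} whose
#'   \code{conditions} element maps interest columns to conditions.
#' @export
build_event_design <- function(design, behavior = NULL, TR = 1.373,
                               n_scans = NULL, motion = NULL,
                               microtime = 16L) {
  ep <- design$episodes
  if (is.null(n_scans)) n_scans <- floor(design$total_duration / TR)
  dt <- TR / microtime
  flags <- rep(FALSE, nrow(ep))
  if (!is.null(behavior)) {
    fl <- flag_error_episodes(behavior)
    flags <- ep$index %in% as.integer(names(fl))[fl]
  }
  usable <- !ep$is_dummy & !flags

  conds <- condition_table(design$structure)
  combos <- unique(conds[c("task", "distractor")])
  n_micro <- ceiling((n_scans * TR + 33) / dt) + 1L
  cols <- list(); interest <- logical(0)
  add_col <- function(name, onsets, durations, is_interest) {
    if (length(onsets) == 0L) return(invisible(NULL))
    cols[[name]] <<- stick_function(onsets, durations, n_micro, dt)
    interest <<- c(interest, stats::setNames(is_interest, name))
    invisible(NULL)
  }

  codes <- task_codes(design$structure)
  for (i in seq_len(nrow(combos))) {
    tk <- combos$task[i]; d <- combos$distractor[i]
    rows <- which(usable & ep$cued_task == tk & ep$distractor_task == d)
    base <- sprintf("%s.%s", codes[[tk]], codes[[d]])
    for (k in 1:4) {
      on_k <- ep[[paste0("step", k, "_onset")]][rows]
      add_col(sprintf("%s.s%d.onset", base, k), on_k, rep(0, length(on_k)),
              TRUE)
      add_col(sprintf("%s.s%d.epoch", base, k), on_k,
              rep(.timing$step, length(on_k)), TRUE)
    }
    add_col(sprintf("%s.offset", base), ep$episode_offset[rows],
            rep(0, length(rows)), TRUE)
  }

  # cue regressors across all non-dummy episodes
  nd <- which(!ep$is_dummy)
  add_col("cue.onset", ep$cue_onset[nd], rep(0, length(nd)), FALSE)
  add_col("cue.epoch", ep$cue_onset[nd],
          ep$step1_onset[nd] - ep$cue_onset[nd], FALSE)

  # dummy episode: cue-to-offset epoch plus onset/offset impulses
  dmy <- which(ep$is_dummy)
  add_col("dummy.epoch", ep$cue_onset[dmy],
          ep$episode_offset[dmy] - ep$cue_onset[dmy], FALSE)
  add_col("dummy.onset", ep$step1_onset[dmy], rep(0, length(dmy)), FALSE)
  add_col("dummy.offset", ep$episode_offset[dmy], rep(0, length(dmy)), FALSE)

  # error episodes: separate per-step onset/epoch set plus offset
  fe <- which(flags & !ep$is_dummy)
  if (length(fe) > 0L) {
    for (k in 1:4) {
      ons <- ep[[paste0("step", k, "_onset")]][fe]
      add_col(sprintf("error.s%d.onset", k), ons, rep(0, length(ons)),
              FALSE)
      add_col(sprintf("error.s%d.epoch", k), ons,
              rep(.timing$step, length(ons)), FALSE)
    }
    add_col("error.offset", ep$episode_offset[fe], rep(0, length(fe)), FALSE)
  }

  # individual error searches (2 s events) in non-flagged episodes
  if (!is.null(behavior)) {
    b <- behavior[(!behavior$correct | is.na(behavior$correct)) &
                    !(behavior$episode %in% ep$index[flags]), ]
    if (nrow(b) > 0L) {
      ons <- vapply(seq_len(nrow(b)), function(j) {
        row <- ep[ep$index == b$episode[j], ]
        row[[paste0("step", b$step[j], "_onset")]] +
          .timing$search[b$search[j]]
      }, numeric(1))
      add_col("search.error", ons, rep(.timing$array, nrow(b)), FALSE)
    }
  }

  X <- hrf_convolve_sample(do.call(cbind, cols), n_scans, TR, dt)
  colnames(X) <- names(cols)
  if (!is.null(motion)) {
    stopifnot(nrow(motion) == n_scans)
    colnames(motion) <- paste0("motion", seq_len(ncol(motion)))
    X <- cbind(X, motion)
    interest <- c(interest, stats::setNames(rep(FALSE, ncol(motion)),
                                            colnames(motion)))
  }
  X <- cbind(X, mean = 1)
  interest <- c(interest, mean = FALSE)
  new_design_matrix(X, unname(interest), TR, "event", conditions = conds)
}

#' FIR design matrix
#'
#' Models consecutive pairs of episodes with a finite impulse response
#' basis: a 90 s window starting at the first-step onset of every
#' even-numbered episode is covered by 60 boxcar regressors of 1.5 s,
#' separately for each cued task of the anchoring episode (interest
#' columns). Windows containing an error episode use a separate shared
#' non-interest bin set; the dummy episode and episode 1 are covered by
#' their own non-interest set; a block-mean column and optional motion
#' columns are appended.
#'
#' @inheritParams build_event_design
#' @param bin_width FIR bin width in seconds (default 1.5).
#' @param n_bins Number of bins per window (default 60).
#' @return A \code{design_matrix} of kind \code{"fir"}.
#' @export
build_fir_design <- function(design, behavior = NULL, bin_width = 1.5,
                             n_bins = 60L, TR = 1.373, n_scans = NULL,
                             motion = NULL) {
  ep <- design$episodes
  if (sum(!ep$is_dummy) < 2L) stop("need at least 2 non-dummy episodes")
  if (is.null(n_scans)) n_scans <- floor(design$total_duration / TR)
  scan_t <- seq(0, by = TR, length.out = n_scans)
  flags <- rep(FALSE, nrow(ep))
  if (!is.null(behavior)) {
    fl <- flag_error_episodes(behavior)
    flags <- ep$index %in% as.integer(names(fl))[fl]
  }

  anchors <- which(!ep$is_dummy & ep$index %% 2L == 0L)
  window_len <- n_bins * bin_width
  run_end <- n_scans * TR
  codes <- task_codes(design$structure)

  # group windows: per-task interest sets; error-pair set; lead-in set
  sets <- list()
  add_window <- function(set, anchor_t) {
    if (anchor_t + window_len > run_end)
      warning("FIR window truncated at run end")
    sets[[set]] <<- c(sets[[set]], anchor_t)
  }
  for (a in anchors) {
    pair <- c(a, if (a + 1L <= nrow(ep)) a + 1L)
    set <- if (any(flags[pair])) "errorpair"
           else codes[[ep$cued_task[a]]]
    add_window(set, ep$step1_onset[a])
  }
  add_window("lead", ep$step1_onset[ep$is_dummy][1L])

  cols <- list(); interest <- logical(0)
  for (set in names(sets)) {
    is_int <- !(set %in% c("errorpair", "lead"))
    for (b in seq_len(n_bins)) {
      v <- numeric(n_scans)
      for (anchor in sets[[set]]) {
        lo <- anchor + bin_width * (b - 1L)
        v[scan_t >= lo & scan_t < lo + bin_width] <- 1
      }
      if (!is_int && all(v == 0)) next  # truncated nuisance bin
      nm <- sprintf("%s.bin%02d", set, b)
      cols[[nm]] <- v
      interest <- c(interest, stats::setNames(is_int, nm))
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  if (!is.null(motion)) {
    stopifnot(nrow(motion) == n_scans)
    colnames(motion) <- paste0("motion", seq_len(ncol(motion)))
    X <- cbind(X, motion)
    interest <- c(interest, stats::setNames(rep(FALSE, ncol(motion)),
                                            colnames(motion)))
  }
  X <- cbind(X, mean = 1)
  interest <- c(interest, mean = FALSE)
  new_design_matrix(X, unname(interest), TR, "fir")
}

#' Temporal high-pass filter
#'
#' Residualizes time series (and, identically, design-matrix columns)
#' against a discrete-cosine low-frequency basis with
#' \code{K = floor(2 * T / cutoff) + 1} non-constant functions, removing
#' fluctuations slower than the cutoff period. Filtering is an orthogonal
#' projection, hence idempotent. The constant component is left to the
#' block-mean regressor: a column named \code{"mean"} in a design matrix
#' is not filtered.
#'
#' @param x Numeric vector or matrix (scans in rows), or a
#'   \code{design_matrix}.
#' @param cutoff_period Cutoff period in seconds (default 128).
#' @param TR Repetition time in seconds; taken from the design matrix when
#'   filtering one.
#' @return The filtered object, same shape and class as the input.
#' @export
highpass_filter <- function(x, cutoff_period = 128, TR = NULL) {
  if (inherits(x, "design_matrix")) {
    keep <- x$names == "mean"
    v <- x$values
    v[, !keep] <- highpass_filter(v[, !keep, drop = FALSE], cutoff_period,
                                  TR = x$TR)
    x$values <- v
    return(x)
  }
  if (is.null(TR)) stop("TR required when filtering a plain matrix")
  v <- as.matrix(x)
  n <- nrow(v)
  if (cutoff_period <= 2 * TR) stop("cutoff_period must exceed 2 * TR")
  K <- floor(2 * (n * TR) / cutoff_period) + 1L
  B <- dct_basis(n, K)
  out <- v - B %*% crossprod(B, v)  # B has orthonormal columns
  if (is.vector(x)) out <- drop(out)
  out
}

# Orthonormal non-constant DCT-II basis, columns k = 1..K.
dct_basis <- function(n, K) {
  i <- seq_len(n)
  B <- vapply(seq_len(K), function(k)
    sqrt(2 / n) * cos(pi * (2 * i - 1) * k / (2 * n)), numeric(n))
  matrix(B, nrow = n)
}

#' Per-voxel ordinary least squares
#'
#' Fits every voxel's time series against a common design matrix by OLS.
#'
#' @param data Scans x voxels numeric matrix (a vector is treated as one
#'   voxel).
#' @param design A \code{design_matrix} or plain numeric matrix.
#' @return A \code{beta_set}: list with \code{betas} (regressor x voxel),
#'   \code{residuals} (scans x voxel), \code{df} (residual degrees of
#'   freedom), \code{names}, \code{interest}, \code{kind} and
#'   \code{conditions} carried over from the design.
#' @export
fit_ols <- function(data, design) {
  X <- if (inherits(design, "design_matrix")) design$values else design
  Y <- as.matrix(data)
  stopifnot(nrow(Y) == nrow(X))
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  betas <- qr.coef(qrx, Y)
  resid <- Y - X %*% betas
  structure(list(
    betas = betas, residuals = resid, df = nrow(Y) - qrx$rank,
    names = colnames(X),
    interest = if (inherits(design, "design_matrix")) design$interest,
    kind = if (inherits(design, "design_matrix")) design$kind else "matrix",
    conditions = if (inherits(design, "design_matrix")) design$conditions
  ), class = "beta_set")
}

#' @export
print.beta_set <- function(x, ...) {
  cat(sprintf("beta_set (%s): %d regressors x %d voxels, df = %d\n",
              x$kind, nrow(x$betas), ncol(x$betas), x$df))
  invisible(x)
}

#' Condition patterns from an event-model fit
#'
#' For every cued task x distractor x step condition, the activation
#' pattern is the average of that condition's onset and epoch betas,
#' giving 72 patterns per run.
#'
#' @param betas A \code{beta_set} from an event-kind design.
#' @return A \code{condition_patterns} object: list with \code{patterns}
#'   (72 x voxels matrix) and \code{conditions} (the condition table).
#' @export
average_condition_patterns <- function(betas) {
  if (!identical(betas$kind, "event"))
    stop("condition patterns require an event-kind beta_set")
  conds <- betas$conditions
  P <- matrix(NA_real_, nrow(conds), ncol(betas$betas))
  for (i in seq_len(nrow(conds))) {
    on <- paste0(conds$label[i], ".onset")
    epo <- paste0(conds$label[i], ".epoch")
    if (!(on %in% betas$names) || !(epo %in% betas$names))
      stop("missing regressor for condition ", conds$label[i])
    P[i, ] <- (betas$betas[on, ] + betas$betas[epo, ]) / 2
  }
  rownames(P) <- conds$label
  structure(list(patterns = P, conditions = conds),
            class = "condition_patterns")
}
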