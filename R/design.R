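## Run-design generation: transition-balanced episode orders, episode
## timings, search-array composition, and efficiency-based order selection.

# Fixed paradigm timing (seconds)
.timing <- list(
  episode   = 45,    # first-step-onset to first-step-onset
  cue       = 1,
  step      = 9,     # three searches: 2 s array + 1 s fixation, then
                     # 0.2 s "STEP COMPLETED" + 0.8 s fixation
  search    = c(0, 3, 6),
  array     = 2,
  n_steps   = 4,
  f_pre_min = 1.5,
  f_pre_max = 7.5,
  gap       = 9,     # last step offset to next first step onset
  rest      = 10     # initial rest before the dummy episode's cue
)

#' Transition-balanced task order
#'
#' Generates an episode order in which every ordered pair of tasks
#' (including task repeats) occurs exactly once among consecutive episodes.
#' This is an Eulerian path on the complete digraph with self-loops over the
#' tasks, built with Hierholzer's algorithm using seeded random edge
#' choices; the initial element serves as the dummy episode.
#'
#' @param n_tasks Number of tasks (vertices).
#' @param seed Integer seed for the random edge choices.
#' @return Integer vector of length \code{n_tasks^2 + 1}; consecutive pairs
#'   enumerate each ordered task pair exactly once.
#' @examples
#' ord <- transition_balanced_order(6, seed = 1)
#' table(head(ord, -1), ord[-1])  # all-ones 6 x 6 transition matrix
#' @export
transition_balanced_order <- function(n_tasks, seed) {
  stopifnot(n_tasks >= 1)
  rng <- local_rng(seed)
  # remaining out-edges per vertex (targets, shuffled once)
  edges <- lapply(seq_len(n_tasks), function(v) rng$shuffle(seq_len(n_tasks)))
  n_left <- rep(n_tasks, n_tasks)
  start <- rng$int(n_tasks)
  # Hierholzer: walk until stuck (Eulerian circuit exists: graph is
  # connected and every vertex has in-degree = out-degree = n_tasks),
  # then splice sub-circuits from vertices with unused edges.
  path <- integer(0)
  stack <- start
  while (length(stack) > 0) {
    v <- stack[length(stack)]
    if (n_left[v] > 0L) {
      w <- edges[[v]][n_left[v]]
      n_left[v] <- n_left[v] - 1L
      stack <- c(stack, w)
    } else {
      path <- c(path, v)
      stack <- stack[-length(stack)]
    }
  }
  rev(path)
}

#' Assign episode timings to a task order
#'
#' Turns a transition-balanced order into a fully timed run. Each 45 s
#' episode consists of a 1 s cue, a pre-step fixation drawn from
#' Uniform(1.5, 7.5) s, four 9 s steps, and a post-episode fixation.
#' The 9 s interval between the last step of one episode and the first step
#' of the next (fixation + cue + fixation) forces the post-episode fixation
#' of episode k to equal 8 s minus the pre-step fixation of episode k + 1,
#' so first-step onsets are spaced exactly 45 s apart. Distractor tasks are
#' drawn from the other room, balanced so that each cued x distractor
#' combination occurs exactly twice among the 36 non-dummy episodes.
#'
#' @param order Task index order from [transition_balanced_order()].
#' @param structure A [task_structure()].
#' @param seed Integer seed for fixation jitter and distractor assignment.
#' @return An object of class \code{run_design}; see Details.
#' @details The \code{episodes} element is a data frame with one row per
#'   episode: \code{index} (0 = dummy), \code{is_dummy}, \code{cued_task},
#'   \code{distractor_task}, \code{cue_onset}, \code{f_pre},
#'   \code{step1_onset} .. \code{step4_onset}, \code{episode_offset}.
#' @export
episode_timings <- function(order, structure, seed) {
  rng <- local_rng(seed)
  n_ep <- length(order)
  tasks <- structure$tasks$task
  cued <- tasks[order]
  rooms <- structure_room(structure, cued)

  # balanced distractors: each cued task occurs 6 times among non-dummy
  # episodes; give it each other-room task exactly twice, in random order
  distractor <- character(n_ep)
  for (tk in tasks) {
    other <- tasks[structure$tasks$room != structure_room(structure, tk)]
    idx <- which(cued == tk & seq_len(n_ep) > 1L)
    pool <- rep(other, length.out = length(idx))
    if (length(idx) == 6L) pool <- rep(other, each = 2L)
    distractor[idx] <- pool[rng$shuffle(seq_along(pool))]
  }
  # dummy episode: random other-room task
  other1 <- tasks[structure$tasks$room != rooms[1L]]
  distractor[1L] <- other1[rng$int(length(other1))]

  f_pre <- rng$unif(n_ep, .timing$f_pre_min, .timing$f_pre_max)
  step1 <- .timing$rest + .timing$cue + f_pre[1L] +
    .timing$episode * (seq_len(n_ep) - 1L)
  cue_onset <- step1 - f_pre - .timing$cue
  offset <- step1 + .timing$n_steps * .timing$step
  # trailing fixation after the final episode (would precede a next cue)
  f_tail <- rng$unif(1L, .timing$f_pre_min, .timing$f_pre_max)

  ep <- data.frame(
    index = seq_len(n_ep) - 1L,
    is_dummy = c(TRUE, rep(FALSE, n_ep - 1L)),
    cued_task = cued,
    distractor_task = distractor,
    cue_onset = cue_onset,
    f_pre = f_pre,
    stringsAsFactors = FALSE
  )
  for (k in seq_len(.timing$n_steps))
    ep[[paste0("step", k, "_onset")]] <- step1 + .timing$step * (k - 1L)
  ep$episode_offset <- offset

  structure(list(
    episodes = ep,
    structure = structure,
    seed = seed,
    total_duration = max(offset) + (8 - f_tail) + .timing$rest,
    efficiency = NA_real_
  ), class = "run_design")
}

#' @export
print.run_design <- function(x, ...) {
  cat("Run design:", sum(!x$episodes$is_dummy), "episodes (+ dummy),",
      sprintf("%.1f s total", x$total_duration), "\n")
  if (!is.na(x$efficiency))
    cat("  efficiency score:", format(x$efficiency, digits = 4), "\n")
  invisible(x)
}

#' Compose the visual-search arrays of an episode
#'
#' Each step has three search events; each event displays four images in a
#' random left-to-right order: the step's target item, a random wrong-step
#' item from the cued task, the same-step item from the distractor task,
#' and the matching wrong-step item from the distractor task. Every display
#' therefore contains two images from each room, and all three arrays of a
#' step share the same target.
#'
#' @param episode One row of \code{run_design$episodes} (a data frame row or
#'   a list with \code{cued_task} and \code{distractor_task}).
#' @param structure A [task_structure()].
#' @param seed Integer seed for the wrong-step choices and positions.
#' @return Data frame with one row per displayed image: \code{step},
#'   \code{search} (1-3), \code{position} (1-4), \code{item}, \code{role}
#'   (\code{target}, \code{wrong_step}, \code{wrong_task},
#'   \code{wrong_both}).
#' @export
build_search_arrays <- function(episode, structure, seed) {
  rng <- local_rng(seed)
  cued <- episode$cued_task
  dis <- episode$distractor_task
  if (structure_room(structure, cued) == structure_room(structure, dis))
    stop("distractor task must come from the other room")
  out <- vector("list", 12L)
  i <- 0L
  for (step in 1:4) {
    for (search in 1:3) {
      wrong <- rng$int_except(4L, step)  # random incorrect step
      items <- c(structure_item(structure, cued, step),
                 structure_item(structure, cued, wrong),
                 structure_item(structure, dis, step),
                 structure_item(structure, dis, wrong))
      roles <- c("target", "wrong_step", "wrong_task", "wrong_both")
      pos <- rng$shuffle(1:4)
      i <- i + 1L
      out[[i]] <- data.frame(step = step, search = search,
                             position = pos, item = items, role = roles,
                             stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$step, res$search, res$position), ]
}

#' Design efficiency of contrasts
#'
#' Dale-style estimation efficiency: for a contrast c over the columns of a
#' design matrix X, e(c) = 1 / (c' (X'X)^-1 c); the reported score is the
#' mean of e over the supplied contrasts. Higher is better.
#'
#' @param X Numeric design matrix (time by regressor).
#' @param contrasts Matrix of contrast vectors, one per row (or a single
#'   vector).
#' @return Mean efficiency (scalar).
#' @export
design_efficiency <- function(X, contrasts) {
  if (is.vector(contrasts)) contrasts <- matrix(contrasts, nrow = 1L)
  stopifnot(ncol(contrasts) == ncol(X))
  G <- crossprod(X)
  R <- tryCatch(chol(G), error = function(e)
    stop("design matrix is rank deficient for efficiency scoring"))
  # c' G^-1 c via triangular solves
  e <- apply(contrasts, 1L, function(cc) {
    z <- backsolve(R, cc, transpose = TRUE)
    1 / sum(z * z)
  })
  mean(e)
}

# 45 s per-task episode boxcar regressors convolved with the HRF, sampled
# at scan times; used only for candidate scoring.
task_boxcar_regressors <- function(design, TR = 1.373, dt = 0.5) {
  ep <- design$episodes[!design$episodes$is_dummy, ]
  tasks <- design$structure$tasks$task
  n_scan <- floor(design$total_duration / TR)
  tmax <- design$total_duration + 32
  n_micro <- ceiling(tmax / dt) + 1L
  h <- canonical_hrf(seq(0, 32, by = dt))
  scan_idx <- floor(seq(0, by = TR, length.out = n_scan) / dt) + 1L
  dur <- .timing$n_steps * .timing$step
  S <- vapply(tasks, function(tk) {
    s <- numeric(n_micro)
    for (on in ep$step1_onset[ep$cued_task == tk]) {
      a <- floor(on / dt) + 1L
      b <- min(floor((on + dur) / dt), n_micro)
      s[a:b] <- 1
    }
    s
  }, numeric(n_micro))
  X <- fft_conv_batch(S, h)[scan_idx, , drop = FALSE] * dt
  colnames(X) <- tasks
  X
}

pairwise_task_contrasts <- function(n_tasks) {
  pairs <- utils::combn(n_tasks, 2L)
  t(apply(pairs, 2L, function(p) {
    v <- numeric(n_tasks); v[p[1L]] <- 1; v[p[2L]] <- -1; v
  }))
}

# score one run design on all pairwise task contrasts
score_run_design <- function(design, TR = 1.373) {
  X <- task_boxcar_regressors(design, TR = TR)
  X <- cbind(X, 1)  # block mean
  cons <- cbind(pairwise_task_contrasts(ncol(X) - 1L), 0)
  design_efficiency(X, cons)
}

#' Generate and select an efficient run design
#'
#' Simulates \code{n_candidates} transition-balanced, fully timed candidate
#' orders and returns the one maximizing the mean design efficiency of all
#' pairwise between-task contrasts (HRF-convolved per-task episode
#' regressors). Ties are broken by the lowest candidate index.
#'
#' @param structure A [task_structure()].
#' @param n_candidates Number of candidate orders to simulate (default 1000).
#' @param seed Integer seed; candidate k uses a sub-seed derived from it.
#' @param TR Repetition time in seconds used for efficiency scoring.
#' @return A \code{run_design} with its \code{efficiency} field set.
#' @export
select_efficient_order <- function(structure, n_candidates = 1000, seed = 1,
                                   TR = 1.373) {
  stopifnot(n_candidates >= 1)
  n_tasks <- nrow(structure$tasks)
  best <- NULL
  for (k in seq_len(n_candidates)) {
    sk <- derive_seed(seed, k)
    ord <- transition_balanced_order(n_tasks, seed = sk)
    cand <- episode_timings(ord, structure, seed = derive_seed(sk, 1L))
    cand$efficiency <- score_run_design(cand, TR = TR)
    if (is.null(best) || cand$efficiency > best$efficiency) best <- cand
  }
  best
}

#' Export a run design as a BIDS-style events table
#'
#' One row per event: cue, step and search onsets, and the episode offset.
#' Columns: \code{onset}, \code{duration}, \code{trial_type},
#' \code{cued_task}, \code{distractor_task}, \code{step},
#' \code{search_index}, \code{is_dummy}.
#'
#' @param design A \code{run_design}.
#' @return Data frame of events ordered by onset.
#' @export
design_events <- function(design) {
  rows <- list()
  for (i in seq_len(nrow(design$episodes))) {
    ep <- design$episodes[i, ]
    add <- function(onset, duration, type, step = NA_integer_,
                    search = NA_integer_) {
      data.frame(onset = onset, duration = duration, trial_type = type,
                 cued_task = ep$cued_task,
                 distractor_task = ep$distractor_task,
                 step = step, search_index = search,
                 is_dummy = ep$is_dummy, stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- add(ep$cue_onset, .timing$cue, "cue")
    for (k in 1:4) {
      on_k <- ep[[paste0("step", k, "_onset")]]
      rows[[length(rows) + 1L]] <- add(on_k, .timing$step, "step", step = k)
      for (s in 1:3)
        rows[[length(rows) + 1L]] <-
          add(on_k + .timing$search[s], .timing$array, "search",
              step = k, search = s)
    }
    rows[[length(rows) + 1L]] <- add(ep$episode_offset, 0, "offset")
  }
  ev <- do.call(rbind, rows)
  ev[order(ev$onset), ]
}

#' Write a run design to disk
#'
#' Writes the events table as TSV plus a JSON sidecar holding the seed,
#' efficiency score and total duration.
#'
#' @param design A \code{run_design}.
#' @param path Path of the TSV file to write (sidecar gets extension
#'   \code{.json}).
#' @return Invisibly, the paths written.
#' @export
write_design <- function(design, path) {
  ev <- design_events(design)
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- sub("\\.tsv$", ".json", path)
  if (identical(side, path)) side <- paste0(path, ".json")
  jsonlite::write_json(list(seed = design$seed,
                            efficiency = design$efficiency,
                            total_duration = design$total_duration),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(c(path, side))
}

#' Read an events table
#'
#' @param path TSV events file written by [write_design()].
#' @return Data frame of events.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("events file not found: ", path)
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
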