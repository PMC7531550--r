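#' Construct the task hierarchy
#'
#' Builds the 2-room x 3-task x 4-step hierarchy used throughout the package:
#' two "rooms" (kitchen, bathroom), three everyday tasks per room, four
#' ordered steps per task, and a unique image ("item") attached to every
#' task-step. The item is the target of the visual searches of that step.
#'
#' @param labels Optional data frame with columns \code{room}, \code{task},
#'   \code{step} (integer 1-4) and \code{item}, one row per task-step. When
#'   omitted, the default six-task stimulus set is used.
#' @return An object of class \code{task_structure}: a list with elements
#'   \code{rooms} (character, length 2), \code{tasks} (data frame with
#'   columns \code{task}, \code{room}) and \code{items} (data frame with
#'   columns \code{room}, \code{task}, \code{step}, \code{item}).
#' @examples
#' ts <- task_structure()
#' subset(ts$items, task == "make a stew")
#' @export
task_structure <- function(labels = NULL) {
  if (is.null(labels)) labels <- default_task_labels()
  labels <- as.data.frame(labels, stringsAsFactors = FALSE)
  required <- c("room", "task", "step", "item")
  if (!all(required %in% names(labels)))
    stop("labels must have columns room, task, step, item")
  labels$step <- as.integer(labels$step)

  rooms <- unique(labels$room)
  if (length(rooms) != 2L)
    stop("invalid task structure: expected exactly 2 rooms, got ",
         length(rooms))
  tasks <- unique(labels[c("task", "room")])
  if (anyDuplicated(tasks$task))
    stop("invalid task structure: a task label appears in more than one room")
  for (r in rooms) {
    if (sum(tasks$room == r) != 3L)
      stop("invalid task structure: room '", r, "' must have exactly 3 tasks")
  }
  for (tk in tasks$task) {
    st <- sort(labels$step[labels$task == tk])
    if (!identical(st, 1:4))
      stop("invalid task structure: task '", tk,
           "' must have exactly steps 1..4")
  }
  if (anyDuplicated(labels$item))
    stop("invalid task structure: duplicate item label '",
         labels$item[duplicated(labels$item)][1L], "'")

  labels <- labels[order(match(labels$room, rooms),
                         match(labels$task, tasks$task), labels$step), ]
  rownames(labels) <- NULL
  structure(list(rooms = rooms,
                 tasks = tasks[order(match(tasks$room, rooms)), ,
                               drop = FALSE],
                 items = labels),
            class = "task_structure")
}

# Default stimulus set. The "make a stew" steps, "hand mix batter" and
# "use facial wash" follow the published stimulus material; the remaining
# items are stand-in labels with the same structure.
default_task_labels <- function() {
  rows <- list(
    c("kitchen", "make a stew", "take food from fridge"),
    c("kitchen", "make a stew", "wash vegetables"),
    c("kitchen", "make a stew", "chop vegetables"),
    c("kitchen", "make a stew", "cook on stove"),
    c("kitchen", "bake cupcakes", "weigh ingredients"),
    c("kitchen", "bake cupcakes", "hand mix batter"),
    c("kitchen", "bake cupcakes", "fill paper cases"),
    c("kitchen", "bake cupcakes", "bake in oven"),
    c("kitchen", "make tea", "boil the kettle"),
    c("kitchen", "make tea", "put teabag in pot"),
    c("kitchen", "make tea", "pour the water"),
    c("kitchen", "make tea", "add milk"),
    c("bathroom", "wash face", "tie hair back"),
    c("bathroom", "wash face", "use facial wash"),
    c("bathroom", "wash face", "rinse with water"),
    c("bathroom", "wash face", "pat dry with towel"),
    c("bathroom", "scrub toilet", "put on gloves"),
    c("bathroom", "scrub toilet", "squirt bleach"),
    c("bathroom", "scrub toilet", "scrub with brush"),
    c("bathroom", "scrub toilet", "flush the toilet"),
    c("bathroom", "clean teeth", "wet the toothbrush"),
    c("bathroom", "clean teeth", "apply toothpaste"),
    c("bathroom", "clean teeth", "brush the teeth"),
    c("bathroom", "clean teeth", "rinse the mouth")
  )
  out <- do.call(rbind.data.frame,
                 c(rows, list(stringsAsFactors = FALSE)))
  names(out) <- c("room", "task", "item")
  out$step <- rep(1:4, times = 6)
  out[c("room", "task", "step", "item")]
}

#' @export
print.task_structure <- function(x, ...) {
  cat("Task structure:", length(x$rooms), "rooms,",
      nrow(x$tasks), "tasks,", nrow(x$items), "items\n")
  for (r in x$rooms) {
    cat("  ", r, ": ",
        paste(x$tasks$task[x$tasks$room == r], collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' @export
as.data.frame.task_structure <- function(x, ...) x$items

# item label for (task, step)
structure_item <- function(structure, task, step) {
  it <- structure$items
  it$item[match(paste(task, step), paste(it$task, it$step))]
}

# room of a task
structure_room <- function(structure, task) {
  structure$tasks$room[match(task, structure$tasks$task)]
}
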