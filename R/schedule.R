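#' Trial schedule specification
#'
#' Describes the factorial design of one experiment: four intersections
#' (I1--I4) reachable from four approach directions (D1--D4), two target
#' landmarks (T1 = town hall, T2 = church), and a number of repetitions per
#' cell, partitioned into learning blocks of retrieval trials (plus, for the
#' scanner variant, colour-judgement control trials).
#'
#' Two presets are provided. `"behavioral"`: 8 blocks x 12 retrieval trials
#' (3 repetitions per cell) with the direction-split constraint, i.e. each
#' intersection/target combination is approached from two of the four
#' directions in the first experiment half and from the remaining two in the
#' second half. `"fmri"`: 8 blocks x 8 retrieval trials (2 repetitions) plus
#' 4 control trials per block, without the direction split.
#'
#' @param preset `"behavioral"` or `"fmri"`, or `NULL` to build a custom
#'   spec from the remaining arguments.
#' @param blocks number of learning blocks.
#' @param retrieval_per_block retrieval (pointing) trials per block.
#' @param control_per_block control trials per block (0 for behavioral).
#' @param repetitions repetitions of each intersection x direction x target
#'   cell across the experiment.
#' @param direction_split logical; enforce the two-directions-per-half
#'   constraint.
#' @param timeout response timeout in seconds.
#' @return An object of class `navlearn_schedule_spec`.
#' @export
schedule_spec <- function(preset = c("behavioral", "fmri"),
                          blocks = NULL, retrieval_per_block = NULL,
                          control_per_block = NULL, repetitions = NULL,
                          direction_split = NULL, timeout = 12) {
  if (!is.null(preset)) {
    preset <- match.arg(preset)
    defaults <- switch(preset,
      behavioral = list(blocks = 8L, retrieval_per_block = 12L,
                        control_per_block = 0L, repetitions = 3L,
                        direction_split = TRUE),
      fmri = list(blocks = 8L, retrieval_per_block = 8L,
                  control_per_block = 4L, repetitions = 2L,
                  direction_split = FALSE)
    )
  } else {
    preset <- "custom"
    defaults <- list()
  }
  spec <- list(
    preset = preset,
    n_intersections = 4L,
    n_directions = 4L,
    n_targets = 2L,
    blocks = as.integer(blocks %||% defaults$blocks),
    retrieval_per_block = as.integer(retrieval_per_block %||%
                                       defaults$retrieval_per_block),
    control_per_block = as.integer(control_per_block %||%
                                     defaults$control_per_block %||% 0L),
    repetitions = as.integer(repetitions %||% defaults$repetitions),
    direction_split = isTRUE(direction_split %||% defaults$direction_split),
    timeout = as.numeric(timeout)
  )
  class(spec) <- "navlearn_schedule_spec"
  validate_schedule_spec(spec)
  spec
}

validate_schedule_spec <- function(spec) {
  with(spec, {
    if (is.na(repetitions) || repetitions < 1L) {
      stopf("infeasible schedule: repetitions must be >= 1 (got %s)",
            repetitions)
    }
    total <- n_intersections * n_directions * n_targets * repetitions
    if (total != blocks * retrieval_per_block) {
      stopf(paste0("infeasible schedule: %d cells x %d repetitions = %d ",
                   "trials cannot fill %d blocks x %d retrieval trials"),
            n_intersections * n_directions * n_targets, repetitions, total,
            blocks, retrieval_per_block)
    }
    if (direction_split) {
      half_cells <- n_intersections * n_targets * (n_directions / 2L)
      if ((total / 2L) %% half_cells != 0L || blocks %% 2L != 0L) {
        stopf("infeasible schedule: direction split requires an even block count and half-balanced cells")
      }
    }
    if (timeout <= 0) stopf("timeout must be positive")
  })
  invisible(spec)
}

#' Build a pseudo-randomized trial plan
#'
#' Emits an ordered trial plan satisfying the factorial balance of the
#' design: every intersection x direction x target cell appears exactly
#' `repetitions` times, and, when the direction split is enabled, each
#' intersection/target combination is approached from two directions in the
#' first half and the other two in the second half. Within those
#' constraints the order is a seeded uniform shuffle.
#'
#' @param spec a [schedule_spec()].
#' @param seed integer seed; the plan is reproducible from it.
#' @return A data frame with columns `block`, `trial_in_block`,
#'   `intersection`, `direction`, `target`, `trial_kind`.
#' @export
build_schedule <- function(spec, seed = 1L) {
  validate_schedule_spec(spec)
  intersections <- paste0("I", seq_len(spec$n_intersections))
  directions <- paste0("D", seq_len(spec$n_directions))
  targets <- paste0("T", seq_len(spec$n_targets))

  with_local_seed(seed, {
    if (spec$direction_split) {
      half_blocks <- spec$blocks / 2L
      combos <- expand.grid(intersection = intersections, target = targets,
                            stringsAsFactors = FALSE)
      halves <- vector("list", 2L)
      # choose 2 of 4 directions per combo for half 1; complement for half 2
      first_dirs <- lapply(seq_len(nrow(combos)),
                           function(i) sample(directions, spec$n_directions / 2L))
      for (h in 1:2) {
        rows <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
          dirs <- if (h == 1L) first_dirs[[i]] else setdiff(directions, first_dirs[[i]])
          expand.grid(intersection = combos$intersection[i],
                      direction = dirs,
                      target = combos$target[i],
                      rep = seq_len(spec$repetitions),
                      stringsAsFactors = FALSE)
        }))
        rows <- rows[sample.int(nrow(rows)), c("intersection", "direction", "target")]
        rows$block <- rep(seq_len(half_blocks) + (h - 1L) * half_blocks,
                          each = spec$retrieval_per_block)
        halves[[h]] <- rows
      }
      plan <- rbind(halves[[1]], halves[[2]])
    } else {
      plan <- expand.grid(intersection = intersections, direction = directions,
                          target = targets, rep = seq_len(spec$repetitions),
                          stringsAsFactors = FALSE)
      plan <- plan[sample.int(nrow(plan)), c("intersection", "direction", "target")]
      plan$block <- rep(seq_len(spec$blocks), each = spec$retrieval_per_block)
    }
    plan$trial_kind <- "retrieval"

    if (spec$control_per_block > 0L) {
      n_ctrl <- spec$blocks * spec$control_per_block
      ctrl_reps <- n_ctrl / (spec$n_intersections * spec$n_directions)
      ctrl <- expand.grid(intersection = intersections, direction = directions,
                          rep = seq_len(ctrl_reps), stringsAsFactors = FALSE)
      ctrl <- ctrl[sample.int(nrow(ctrl)), c("intersection", "direction")]
      ctrl$target <- NA_character_
      ctrl$block <- rep(seq_len(spec$blocks), each = spec$control_per_block)
      ctrl$trial_kind <- "control"
      plan <- rbind(plan, ctrl[, names(plan)])
    }

    # retrieval trials first within each block, then controls
    plan <- plan[order(plan$block, plan$trial_kind == "control"), ]
    plan$trial_in_block <- stats::ave(seq_len(nrow(plan)), plan$block,
                                      FUN = seq_along)
    rownames(plan) <- NULL
    plan[, c("block", "trial_in_block", "intersection", "direction",
             "target", "trial_kind")]
  })
}

#' Exhaustively verify schedule balance
#'
#' Checks that every intersection x direction x target cell appears
#' exactly `repetitions` times among retrieval trials, that blocks have
#' the scheduled number of retrieval/control trials, and, when the
#' direction split is enabled, that each intersection/target pair uses
#' two disjoint direction pairs across the experiment halves.
#'
#' @param plan a trial plan from [build_schedule()].
#' @param spec the [schedule_spec()] it should satisfy.
#' @return `TRUE` if all constraints hold, else `FALSE`.
#' @export
check_schedule_balance <- function(plan, spec) {
  retr <- plan[plan$trial_kind == "retrieval", ]
  counts <- table(retr$intersection, retr$direction, retr$target)
  if (!all(counts == spec$repetitions)) return(FALSE)
  if (spec$direction_split) {
    half <- ifelse(retr$block <= spec$blocks / 2L, 1L, 2L)
    for (i in unique(retr$intersection)) {
      for (tg in unique(retr$target)) {
        d1 <- unique(retr$direction[retr$intersection == i & retr$target == tg & half == 1L])
        d2 <- unique(retr$direction[retr$intersection == i & retr$target == tg & half == 2L])
        if (length(d1) != 2L || length(d2) != 2L || length(intersect(d1, d2)) != 0L) {
          return(FALSE)
        }
      }
    }
  }
  tab <- table(plan$block, plan$trial_kind)
  all(tab[, "retrieval"] == spec$retrieval_per_block) &&
    (spec$control_per_block == 0L ||
       all(tab[, "control"] == spec$control_per_block))
}
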