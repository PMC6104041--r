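# Experimental task geometry and trial scheduling for the center-out
# visuomotor rotation paradigm.

#' Task geometry of the center-out reaching paradigm
#'
#' Encodes the screen geometry of the task: a central start circle, two reach
#' targets 8 cm away at +/-22.5 degrees from the midline, and a 45 degree
#' counterclockwise cursor rotation applied on rotated (STR / adaptation)
#' trials. Angles follow the mathematical convention: degrees counterclockwise
#' from the rightward horizontal, monitor "up" = 90 degrees, start circle at
#' the origin.
#'
#' @param start_radius Start circle radius (cm).
#' @param target_radius Target disc radius (cm).
#' @param cursor_radius Cursor disc radius (cm).
#' @param target_distance Start-to-target distance (cm).
#' @param target_angle_offset Angular offset of each target from the midline
#'   (degrees); the left target sits at `90 + offset`, the right at
#'   `90 - offset`.
#' @param rotation_angle Cursor rotation relative to the hand on rotated
#'   trials (degrees, counterclockwise positive).
#' @param feedback_cutoff_radius Radial distance beyond which cursor feedback
#'   is extinguished (cm).
#' @return An object of class `task_geometry`.
#' @examples
#' geo <- task_geometry()
#' target_angle(geo, "left")   # 112.5
#' @export
task_geometry <- function(start_radius = 0.5,
                          target_radius = 0.7,
                          cursor_radius = 0.3,
                          target_distance = 8,
                          target_angle_offset = 22.5,
                          rotation_angle = 45,
                          feedback_cutoff_radius = 8) {
  for (nm in c("start_radius", "target_radius", "cursor_radius",
               "target_distance", "feedback_cutoff_radius")) {
    stopifnot_scalar(get(nm), nm, lower = .Machine$double.eps)
  }
  stopifnot_scalar(target_angle_offset, "target_angle_offset", 0, 90)
  stopifnot_scalar(rotation_angle, "rotation_angle", -180, 180)
  geo <- list(
    start_radius = start_radius,
    target_radius = target_radius,
    cursor_radius = cursor_radius,
    target_distance = target_distance,
    target_angle_offset = target_angle_offset,
    rotation_angle = rotation_angle,
    feedback_cutoff_radius = feedback_cutoff_radius
  )
  class(geo) <- "task_geometry"
  geo
}

#' @export
print.task_geometry <- function(x, ...) {
  cat("Center-out task geometry\n")
  cat(sprintf("  targets: %g cm at %g / %g deg; rotation %+g deg (rotated trials)\n",
              x$target_distance, 90 + x$target_angle_offset,
              90 - x$target_angle_offset, x$rotation_angle))
  cat(sprintf("  radii (cm): start %g, target %g, cursor %g; feedback cutoff %g cm\n",
              x$start_radius, x$target_radius, x$cursor_radius,
              x$feedback_cutoff_radius))
  invisible(x)
}

#' Direction of a reach target
#'
#' @param geometry A [task_geometry()].
#' @param target `"left"` or `"right"` (vectorized).
#' @return Target direction(s) in degrees counterclockwise from rightward
#'   horizontal.
#' @export
target_angle <- function(geometry, target) {
  target <- match_target(target)
  ifelse(target == "left",
         90 + geometry$target_angle_offset,
         90 - geometry$target_angle_offset)
}

match_target <- function(target) {
  target <- as.character(target)
  bad <- !target %in% c("left", "right")
  if (any(bad)) stop("unknown target label: ", paste(unique(target[bad]), collapse = ", "),
                     call. = FALSE)
  target
}

#' Target position in task coordinates
#'
#' @inheritParams target_angle
#' @return A length-2 (or n x 2) matrix of x, y positions in cm.
#' @export
target_position <- function(geometry, target) {
  ang <- deg2rad(target_angle(geometry, target))
  cbind(x = geometry$target_distance * cos(ang),
        y = geometry$target_distance * sin(ang))
}

condition_levels <- c("NULL_R", "NULL_L", "STR", "ADAPT")

#' Ideal aim direction of the hand for a trial
#'
#' On NULL trials the hand aims straight at the cued target. On rotated trials
#' (STR and adaptation) the instructed / adapted aim is the cued target
#' direction rotated opposite to the cursor perturbation, so that the rotated
#' cursor lands on the cued target.
#'
#' @param condition Condition label(s): `"NULL_R"`, `"NULL_L"`, `"STR"`,
#'   `"ADAPT"` (or `"POST"`, treated as adaptation).
#' @param target Cued target, `"left"` or `"right"` (vectorized).
#' @param geometry A [task_geometry()].
#' @return Aim direction(s) in degrees.
#' @examples
#' geo <- task_geometry()
#' ideal_aim_direction("NULL_L", "left", geo)  # 112.5
#' ideal_aim_direction("STR", "left", geo)     # 67.5
#' @export
ideal_aim_direction <- function(condition, target, geometry) {
  condition <- as.character(condition)
  known <- c(condition_levels, "POST")
  bad <- !condition %in% known
  if (any(bad)) {
    stop("unknown condition label: ", paste(unique(condition[bad]), collapse = ", "),
         call. = FALSE)
  }
  rotated <- condition %in% c("STR", "ADAPT", "POST")
  target_angle(geometry, target) - ifelse(rotated, geometry$rotation_angle, 0)
}

#' Cursor position given a hand position
#'
#' The cursor reproduces the hand exactly on NULL trials and is rotated by the
#' geometry's rotation angle (an exact rotation, so `|cursor| = |hand|`) on
#' rotated trials.
#'
#' @param hand_xy n x 2 matrix of hand positions (cm).
#' @param condition Single condition label.
#' @param geometry A [task_geometry()].
#' @return n x 2 matrix of cursor positions.
#' @export
cursor_position <- function(hand_xy, condition, geometry) {
  hand_xy <- as.matrix(hand_xy)
  if (condition %in% c("STR", "ADAPT", "POST")) {
    rotate_xy(hand_xy, geometry$rotation_angle)
  } else {
    colnames(hand_xy) <- c("x", "y")
    hand_xy
  }
}

#' Generate the pseudorandomized trial schedule
#'
#' Builds the session schedule: an interleaved phase in which rotated
#' strategy (STR) reaches to the left target are embedded among unrotated
#' NULL reaches to the left and right targets, under the constraint that any
#' two STR trials are separated by at least `min_gap` NULL trials, followed by
#' an uninterrupted adaptation phase to the left target. The final
#' `n_post` adaptation trials constitute the post-adaptation (POST) bin. The
#' default counts reproduce the 596-trial session: 96 STR + 152 + 152 NULL in
#' the first 400 trials, then 196 adaptation trials of which the last 96 are
#' POST.
#'
#' Sampling is uniform over all interleavings satisfying the gap constraint:
#' STR positions are drawn by sampling ordered indices from a gap-reduced
#' index set and re-inflating, which is a bijection onto the valid position
#' sets; NULL left/right labels are then randomly interleaved.
#'
#' @param seed Integer seed; identical seeds give identical schedules.
#' @param n_str,n_null_right,n_null_left Counts in the interleaved phase.
#' @param n_adapt Number of adaptation trials appended at the end.
#' @param n_post Number of final adaptation trials labelled as POST.
#' @param min_gap Minimum number of NULL trials between consecutive STR trials.
#' @return A `data.frame` of class `reach_schedule` with columns `index`,
#'   `condition`, `target`, `block`, `post`, and attribute `post_indices`.
#' @examples
#' sched <- generate_schedule(seed = 1)
#' table(sched$condition[1:400])
#' @export
generate_schedule <- function(seed,
                              n_str = 96,
                              n_null_right = 152,
                              n_null_left = 152,
                              n_adapt = 196,
                              n_post = 96,
                              min_gap = 2) {
  n_null <- n_null_right + n_null_left
  n_pre <- n_str + n_null
  if (n_post > n_adapt) stop("`n_post` cannot exceed `n_adapt`", call. = FALSE)
  if (n_str > 1) {
    reduced <- n_pre - (n_str - 1L) * min_gap
    if (reduced < n_str) {
      stop("gap constraint infeasible: not enough NULL trials to separate STR trials",
           call. = FALSE)
    }
  }
  cond <- with_seed(seed, {
    cond <- rep(NA_character_, n_pre)
    if (n_str > 0) {
      reduced <- n_pre - (n_str - 1L) * min_gap
      q <- sort(sample.int(reduced, n_str))
      p <- q + (seq_len(n_str) - 1L) * min_gap
      cond[p] <- "STR"
    }
    cond[is.na(cond)] <- sample(c(rep("NULL_R", n_null_right),
                                  rep("NULL_L", n_null_left)))
    cond
  })
  condition <- factor(c(cond, rep("ADAPT", n_adapt)), levels = condition_levels)
  n_total <- n_pre + n_adapt
  target <- ifelse(condition == "NULL_R", "right", "left")
  post_indices <- if (n_post > 0) seq.int(n_total - n_post + 1L, n_total) else integer(0)
  sched <- data.frame(
    index = seq_len(n_total),
    condition = condition,
    target = target,
    block = pmin(ceiling(seq_len(n_total) / 100), 6L),
    post = seq_len(n_total) %in% post_indices
  )
  attr(sched, "post_indices") <- post_indices
  attr(sched, "n_pre") <- n_pre
  class(sched) <- c("reach_schedule", "data.frame")
  sched
}

#' Condition labels with the POST bin substituted
#'
#' Returns the schedule's condition labels as character, relabelling the final
#' post-adaptation trials `"POST"` so that downstream contrasts can address
#' them directly.
#'
#' @param schedule A [generate_schedule()] result.
#' @return Character vector of per-trial labels.
#' @export
schedule_conditions <- function(schedule) {
  lab <- as.character(schedule$condition)
  lab[schedule$post] <- "POST"
  lab
}

#' @export
print.reach_schedule <- function(x, ...) {
  n_pre <- attr(x, "n_pre")
  cat(sprintf("Reach schedule: %d trials (%d interleaved + %d adaptation, %d POST)\n",
              nrow(x), n_pre, nrow(x) - n_pre, sum(x$post)))
  print(table(condition = x$condition))
  invisible(x)
}

#' Minimum NULL gap between consecutive STR trials
#'
#' Linear scan over the schedule; returns `Inf` when fewer than two STR trials
#' are present.
#'
#' @param schedule A [generate_schedule()] result.
#' @return Smallest number of trials strictly between consecutive STR trials.
#' @export
min_str_gap <- function(schedule) {
  idx <- schedule$index[schedule$condition == "STR"]
  if (length(idx) < 2) return(Inf)
  min(diff(idx)) - 1
}
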