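# Per-trial movement variables and kinematic trial rejection.

#' Detect movement onset and termination in a stylus trajectory
#'
#' Onset is the first sample at which the stylus lies outside the start
#' circle. Termination is the first sample, at or after the first sample
#' whose radial distance from the start exceeds the feedback cutoff radius
#' (8 cm), at which stylus speed falls to or below the velocity threshold
#' (1.5 pixel/s, converted to cm/s via the configured pixel pitch). Speed is
#' computed by central finite differences of x and y, with one-sided
#' differences at the ends.
#'
#' @param trajectory `data.frame` with columns `t` (ms), `x`, `y` (cm),
#'   uniformly sampled; must begin inside the start circle.
#' @param geometry A [task_geometry()].
#' @param pixel_pitch Screen pixel pitch (cm per pixel) used to convert the
#'   pixel-based velocity threshold.
#' @param velocity_threshold Termination speed threshold in pixel/s.
#' @return List with `onset` and `termination` (sample indices) and `error`
#'   (`NULL`, or `"NO_ONSET"` / `"NO_TERMINATION"` with the indices `NA`).
#' @export
detect_bounds <- function(trajectory, geometry = task_geometry(),
                          pixel_pitch = 0.035, velocity_threshold = 1.5) {
  x <- trajectory$x; y <- trajectory$y
  r <- sqrt(x^2 + y^2)
  if (r[1] > geometry$start_radius) {
    stop("trajectory must begin inside the start circle", call. = FALSE)
  }
  onset <- which(r > geometry$start_radius)[1]
  if (is.na(onset)) {
    return(list(onset = NA_integer_, termination = NA_integer_, error = "NO_ONSET"))
  }
  speed <- trajectory_speed(trajectory)
  thr <- velocity_threshold * pixel_pitch    # cm/s
  past8 <- which(r > geometry$feedback_cutoff_radius)[1]
  if (is.na(past8)) {
    return(list(onset = onset, termination = NA_integer_, error = "NO_TERMINATION"))
  }
  term <- which(speed[past8:length(speed)] <= thr)[1]
  if (is.na(term)) {
    return(list(onset = onset, termination = NA_integer_, error = "NO_TERMINATION"))
  }
  list(onset = onset, termination = past8 + term - 1L, error = NULL)
}

# Resultant stylus speed (cm/s) by central differences, one-sided at the ends.
trajectory_speed <- function(trajectory) {
  t_s <- trajectory$t / 1000
  n <- length(t_s)
  if (n < 2) return(rep(0, n))
  d <- function(v) {
    c(v[2] - v[1],
      if (n > 2) (v[3:n] - v[1:(n - 2)]) / 2 else NULL,
      v[n] - v[n - 1]) /
      c(t_s[2] - t_s[1],
        if (n > 2) (t_s[3:n] - t_s[1:(n - 2)]) / 2 else NULL,
        t_s[n] - t_s[n - 1])
  }
  sqrt(d(trajectory$x)^2 + d(trajectory$y)^2)
}

#' Summarize one trial's kinematics
#'
#' Computes the per-trial movement variables: reaction time (go cue to
#' movement onset), movement time (onset to termination), peak resultant
#' velocity during the movement and its time from onset, the hand-vs-target
#' angle at peak velocity (target vector angle minus hand vector angle, so
#' positive values mean the hand is rotated clockwise of the target and
#' clockwise drift appears as an increase), the target-hit flag (the rotated
#' cursor disc overlaps the target disc at some sample during the movement),
#' and the absolute x and y offsets of the final hand position from the
#' aiming target (the cued target on NULL trials; its strategy-rotated
#' counterpart location on rotated trials).
#'
#' @param trajectory `data.frame` with columns `t` (ms), `x`, `y` (cm).
#' @param go_cue_time Go-cue time (ms) on the trajectory's time axis.
#' @param condition Condition label of the trial.
#' @param target Cued target, `"left"` or `"right"`.
#' @param geometry A [task_geometry()].
#' @param pixel_pitch,velocity_threshold Passed to [detect_bounds()].
#' @return One-row `data.frame` (class `kinematic_summary`): `rt`, `mt`,
#'   `peak_velocity`, `time_to_pv`, `angle_at_pv`, `final_err_x`,
#'   `final_err_y`, `hit`, `error`.
#' @export
summarize_trial <- function(trajectory, go_cue_time = 0, condition, target,
                            geometry = task_geometry(),
                            pixel_pitch = 0.035, velocity_threshold = 1.5) {
  b <- detect_bounds(trajectory, geometry, pixel_pitch, velocity_threshold)
  if (!is.null(b$error)) {
    out <- data.frame(trial = NA_integer_, condition = condition, target = target,
                      rt = NA_real_, mt = NA_real_, peak_velocity = NA_real_,
                      time_to_pv = NA_real_, angle_at_pv = NA_real_,
                      final_err_x = NA_real_, final_err_y = NA_real_,
                      hit = FALSE, error = b$error, stringsAsFactors = FALSE)
    class(out) <- c("kinematic_summary", "data.frame")
    return(out)
  }
  on <- b$onset; tm <- b$termination
  tt <- trajectory$t
  speed <- trajectory_speed(trajectory)
  mov <- on:tm
  pv_rel <- which.max(speed[mov])
  pv_idx <- mov[pv_rel]

  t_ang <- target_angle(geometry, target)
  hand_ang <- rad2deg(atan2(trajectory$y[pv_idx], trajectory$x[pv_idx]))
  angle_at_pv <- wrap_angle(t_ang - hand_ang)

  ## hit: rotated cursor disc overlaps the target disc at any movement sample
  cur <- cursor_position(cbind(trajectory$x[mov], trajectory$y[mov]), condition, geometry)
  tp <- target_position(geometry, target)
  dmin <- min(sqrt((cur[, 1] - tp[1])^2 + (cur[, 2] - tp[2])^2))
  hit <- dmin <= geometry$cursor_radius + geometry$target_radius

  ## final hand position error relative to the aiming target
  aim_ang <- deg2rad(ideal_aim_direction(condition, target, geometry))
  aim_tp <- geometry$target_distance * c(cos(aim_ang), sin(aim_ang))
  out <- data.frame(
    trial = NA_integer_, condition = condition, target = target,
    rt = tt[on] - go_cue_time,
    mt = tt[tm] - tt[on],
    peak_velocity = speed[pv_idx],
    time_to_pv = tt[pv_idx] - tt[on],
    angle_at_pv = angle_at_pv,
    final_err_x = abs(trajectory$x[tm] - aim_tp[1]),
    final_err_y = abs(trajectory$y[tm] - aim_tp[2]),
    hit = hit, error = NA_character_, stringsAsFactors = FALSE
  )
  class(out) <- c("kinematic_summary", "data.frame")
  out
}

#' Summarize all trials of a simulated or recorded session
#'
#' @param trials List of trial records (as produced by [simulate_reaches()]).
#' @param geometry A [task_geometry()].
#' @param ... Passed to [summarize_trial()].
#' @return A `data.frame` with one [summarize_trial()] row per trial.
#' @export
summarize_trials <- function(trials, geometry = task_geometry(), ...) {
  out <- do.call(rbind, lapply(trials, function(tr) {
    s <- summarize_trial(tr$trajectory, tr$go_cue_time, tr$condition, tr$target,
                         geometry, ...)
    s$trial <- tr$trial
    s
  }))
  rownames(out) <- NULL
  out
}

#' Kinematic trial rejection
#'
#' A trial is rejected when RT <= 150 ms, RT >= 600 ms, MT <= 150 ms,
#' MT >= 600 ms (boundaries inclusive), when the cursor never hit the target,
#' or when onset/termination detection failed.
#'
#' @param summaries `data.frame` from [summarize_trials()].
#' @param rt_bounds,mt_bounds Inclusive rejection boundaries (ms).
#' @return Logical retention mask with attribute `reasons`, a character
#'   vector (`""` for retained trials; otherwise comma-separated subset of
#'   `RT_RANGE`, `MT_RANGE`, `MISS`, `NO_BOUNDS`).
#' @export
reject_trials <- function(summaries, rt_bounds = c(150, 600),
                          mt_bounds = c(150, 600)) {
  bad_bounds <- !is.na(summaries$error)
  bad_rt <- !bad_bounds & (summaries$rt <= rt_bounds[1] | summaries$rt >= rt_bounds[2])
  bad_mt <- !bad_bounds & (summaries$mt <= mt_bounds[1] | summaries$mt >= mt_bounds[2])
  miss <- !bad_bounds & !summaries$hit
  reasons <- mapply(function(b, r, m, s) {
    paste(c(if (b) "NO_BOUNDS", if (r) "RT_RANGE", if (m) "MT_RANGE", if (s) "MISS"),
          collapse = ",")
  }, bad_bounds, bad_rt, bad_mt, miss)
  keep <- !(bad_bounds | bad_rt | bad_mt | miss)
  attr(keep, "reasons") <- unname(reasons)
  keep
}

#' Drift contrast: angles before vs after strategy trials
#'
#' Collects the hand-vs-target angle at peak velocity for NULL trials
#' immediately preceding (pre) and immediately following (post) each STR
#' trial, split by NULL target. Under implicit adaptation driven by the
#' counterclockwise rotation, post angles exceed pre angles (clockwise hand
#' drift) for reaches to the left target.
#'
#' @param summaries `data.frame` from [summarize_trials()] (rows in schedule
#'   order, with `trial` matching schedule indices).
#' @param schedule A [generate_schedule()] result.
#' @param retained Optional logical retention mask applied to neighbor trials.
#' @return List with elements `left` and `right`, each a `data.frame` with
#'   columns `str_index`, `pre`, `post` (angles, degrees; rows only for STR
#'   trials whose qualifying neighbor exists), plus `pre_mean`/`post_mean`
#'   attributes. Elements are empty `data.frame`s when no pairs qualify.
#' @export
drift_contrast <- function(summaries, schedule, retained = NULL) {
  if (is.null(retained)) retained <- rep(TRUE, nrow(schedule))
  cond <- as.character(schedule$condition)
  str_idx <- which(cond == "STR")
  ang <- summaries$angle_at_pv[match(schedule$index, summaries$trial)]
  one_side <- function(tgt) {
    null_lab <- if (tgt == "left") "NULL_L" else "NULL_R"
    rows <- lapply(str_idx, function(i) {
      pre_i <- i - 1L; post_i <- i + 1L
      pre <- if (pre_i >= 1 && cond[pre_i] == null_lab && retained[pre_i]) ang[pre_i] else NA_real_
      post <- if (post_i <= nrow(schedule) && cond[post_i] == null_lab && retained[post_i]) ang[post_i] else NA_real_
      c(i, pre, post)
    })
    tab <- if (length(rows)) as.data.frame(do.call(rbind, rows)) else
      data.frame(a = numeric(0), b = numeric(0), c = numeric(0))
    names(tab) <- c("str_index", "pre", "post")
    tab <- tab[!(is.na(tab$pre) & is.na(tab$post)), , drop = FALSE]
    attr(tab, "pre_mean") <- mean(tab$pre, na.rm = TRUE)
    attr(tab, "post_mean") <- mean(tab$post, na.rm = TRUE)
    tab
  }
  out <- list(left = one_side("left"), right = one_side("right"))
  if (length(str_idx) == 0) {
    attr(out, "empty") <- TRUE
  }
  out
}

#' Write a kinematic summary table
#'
#' @param summaries `data.frame` from [summarize_trials()].
#' @param path File path (CSV).
#' @return `path`, invisibly.
#' @export
write_kinematics <- function(summaries, path) {
  utils::write.csv(summaries, path, row.names = FALSE)
  invisible(path)
}
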