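# Synthetic stylus trajectories with a single-state implicit-adaptation model.

#' Simulate center-out reaches for a schedule
#'
#' Generates 100 Hz stylus trajectories for every trial of a schedule:
#' minimum-jerk reaches of roughly 300 ms aimed at the trial's ideal aim
#' direction plus the current implicit-adaptation state plus motor noise,
#' terminating 1-2 cm past the target ring and holding the final position.
#'
#' The implicit adaptation state `x` (degrees, counterclockwise positive)
#' follows the single-state update
#' `x[n+1] = retention * x[n] - learning_rate * e[n]`, where `e[n]` is the
#' sensory prediction error experienced on trial `n`: the imposed cursor
#' rotation on rotated trials (STR / adaptation) and 0 on NULL trials, on
#' which the state simply decays. With a counterclockwise (+45 degree)
#' rotation the state drifts clockwise (negative), producing the hallmark
#' drift of reaches on trials following strategy trials even though the
#' cursor lands on target.
#'
#' The state is expressed in the hand direction on NULL and STR trials
#' (aim = ideal + x + noise). On uninterrupted adaptation trials, explicit
#' and implicit compensation rebalance so that total compensation stays near
#' the full rotation: the expressed aiming residual starts at the state value
#' on entry into the adaptation phase and decays geometrically
#' (`task_correction` per trial), keeping adaptation/POST reaches
#' kinematically matched to STR reaches (both hit the target), while the
#' latent implicit state continues to evolve and is recorded as ground
#' truth.
#'
#' @param schedule A [generate_schedule()] result.
#' @param geometry A [task_geometry()].
#' @param retention State retention factor in `[0, 1]`.
#' @param learning_rate Learning rate in `[0, 1]`. The defaults
#'   (retention 0.98, learning rate 0.012) put the asymptotic implicit
#'   compensation near 25 degrees under a 45 degree rotation after ~100
#'   consecutive rotated trials.
#' @param motor_noise_sd SD of trial-to-trial aiming noise (degrees).
#' @param seed Integer seed; identical seeds give identical trials.
#' @param rate Trajectory sampling rate (Hz).
#' @param rt_mean,rt_sd Planned reaction-time distribution (ms) between go
#'   cue and movement start. Measured RT additionally includes the time the
#'   minimum-jerk profile needs to exit the start circle, so the defaults
#'   place measured RT / MT near the task's typical ~360 / ~300 ms.
#' @param mt_mean,mt_sd Planned movement-duration distribution (ms).
#' @param task_correction Per-trial retention of the expressed aiming
#'   residual during the uninterrupted adaptation phase (explicit
#'   re-aiming correcting residual task error).
#' @param overshoot Range (cm) of termination distance past the target ring.
#' @param hold_ms Post-movement hold duration sampled at the end of the trial.
#' @return A list with elements `trials` (a list of per-trial records: `trial`,
#'   `condition`, `target`, `go_cue_time`, and a `data.frame` `trajectory`
#'   with columns `t` (ms from go cue), `x`, `y` in cm) and `ground_truth`
#'   (list with `adaptation_state`, the state series in degrees, plus the
#'   drawn per-trial aim angles, reaction and movement times).
#' @examples
#' sched <- generate_schedule(seed = 1, n_str = 4, n_null_right = 8,
#'                            n_null_left = 8, n_adapt = 4, n_post = 2)
#' sim <- simulate_reaches(sched, seed = 1)
#' length(sim$trials)
#' @export
simulate_reaches <- function(schedule,
                             geometry = task_geometry(),
                             retention = 0.98,
                             learning_rate = 0.012,
                             motor_noise_sd = 2,
                             seed = 1,
                             rate = 100,
                             rt_mean = 310, rt_sd = 40,
                             mt_mean = 350, mt_sd = 20,
                             task_correction = 0.9,
                             overshoot = c(1, 2),
                             hold_ms = 500) {
  stopifnot_scalar(retention, "retention", 0, 1)
  stopifnot_scalar(learning_rate, "learning_rate", 0, 1)
  stopifnot_scalar(motor_noise_sd, "motor_noise_sd", 0)
  n <- nrow(schedule)
  cond <- as.character(schedule$condition)
  rotated <- cond %in% c("STR", "ADAPT")
  ideal <- ideal_aim_direction(cond, schedule$target, geometry)

  with_seed(seed, {
    state <- numeric(n)
    expressed <- numeric(n)
    x <- 0
    u <- NA_real_   # expressed residual during uninterrupted adaptation
    for (i in seq_len(n)) {
      state[i] <- x
      if (cond[i] == "ADAPT") {
        if (is.na(u)) u <- x
        expressed[i] <- u
        u <- task_correction * u
      } else {
        expressed[i] <- x
        u <- NA_real_
      }
      e <- if (rotated[i]) geometry$rotation_angle else 0
      x <- retention * x - learning_rate * e
    }
    noise <- rnorm(n, 0, motor_noise_sd)
    aim <- ideal + expressed + noise
    rt <- pmax(180, rnorm(n, rt_mean, rt_sd))
    mt <- pmax(180, rnorm(n, mt_mean, mt_sd))
    dist <- geometry$target_distance + runif(n, overshoot[1], overshoot[2])

    trials <- vector("list", n)
    dt <- 1000 / rate
    for (i in seq_len(n)) {
      t_end <- rt[i] + mt[i] + hold_ms
      tt <- seq(0, t_end, by = dt)
      tau <- pmin(pmax((tt - rt[i]) / mt[i], 0), 1)
      s <- dist[i] * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)  # minimum jerk
      a <- deg2rad(aim[i])
      trials[[i]] <- list(
        trial = i,
        condition = cond[i],
        target = schedule$target[i],
        go_cue_time = 0,
        trajectory = data.frame(t = tt, x = s * cos(a), y = s * sin(a))
      )
    }
    list(
      trials = trials,
      ground_truth = list(
        adaptation_state = state,
        expressed_offset = expressed,
        aim_angle = aim,
        reaction_time = rt,
        movement_time = mt,
        reach_distance = dist,
        seed = seed
      )
    )
  })
}

#' Write / read per-trial trajectory tables
#'
#' Long delimited table with columns `trial`, `t` (ms), `x`, `y` (cm).
#'
#' @param trials List of trial records from [simulate_reaches()].
#' @param path File path.
#' @return `read_trajectories` returns a list of `data.frame`s (one per
#'   trial, in trial order); `write_trajectories` returns `path` invisibly.
#' @export
write_trajectories <- function(trials, path) {
  tab <- do.call(rbind, lapply(trials, function(tr) {
    cbind(trial = tr$trial, tr$trajectory)
  }))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  tab <- utils::read.csv(path)
  lapply(split(tab[, c("t", "x", "y")], tab$trial), `rownames<-`, NULL)
}
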