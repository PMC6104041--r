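test_that("degenerate trajectories yield the documented error codes", {
  geo <- task_geometry()
  held <- data.frame(t = seq(0, 990, 10), x = rep(0.1, 100), y = 0)
  expect_equal(detect_bounds(held, geo)$error, "NO_ONSET")

  ## exits the start circle but stops at 7 cm: the 8 cm gate is never crossed
  tau <- pmin(seq(0, 2, length.out = 100), 1)
  s <- 7 * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
  short <- data.frame(t = seq(0, 990, 10), x = s, y = 0)
  expect_equal(detect_bounds(short, geo)$error, "NO_TERMINATION")

  ## starting outside the start circle violates the precondition
  expect_error(detect_bounds(data.frame(t = 0:9 * 10, x = 2, y = 0), geo),
               "start circle")
})

test_that("bounds and peak velocity agree with brute-force oracles", {
  set.seed(101)
  for (i in 1:150) {
    traj <- random_trajectory()
    got <- detect_bounds(traj)
    want <- oracle_bounds(traj)
    expect_identical(got$error, want$error)
    if (is.null(want$error)) {
      expect_equal(got$onset, want$onset)
      expect_equal(got$termination, want$termination)
      ## exhaustive-scan peak velocity oracle
      sm <- summarize_trial(traj, 0, "NULL_L", "left")
      speed <- reachpe:::trajectory_speed(traj)
      mov <- want$onset:want$termination
      expect_equal(sm$peak_velocity, max(speed[mov]))
      expect_equal(sm$time_to_pv,
                   traj$t[mov[which.max(speed[mov])]] - traj$t[want$onset])
    }
  }
})

test_that("a straight constant-speed reach along the target has zero angle", {
  geo <- task_geometry()
  ang <- 112.5 * pi / 180
  s <- c(seq(0, 9.5, length.out = 60), rep(9.5, 20))
  traj <- data.frame(t = seq(0, by = 10, length.out = 80),
                     x = s * cos(ang), y = s * sin(ang))
  sm <- summarize_trial(traj, 0, "NULL_L", "left", geo)
  expect_equal(sm$angle_at_pv, 0, tolerance = 1e-8)
  expect_true(sm$hit)
})

test_that("noise-free strategy reaches hit while aiming 45 deg clockwise", {
  geo <- task_geometry()
  aim <- 67.5 * pi / 180
  tau <- pmin(seq(0, 1.3, length.out = 90), 1)
  s <- 9.5 * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
  traj <- data.frame(t = seq(0, by = 10, length.out = 90),
                     x = s * cos(aim), y = s * sin(aim))
  sm <- summarize_trial(traj, 0, "STR", "left", geo)
  expect_true(sm$hit)
  expect_equal(sm$angle_at_pv, 45, tolerance = 1e-8)
})

test_that("rejection applies inclusive RT/MT boundaries and the hit rule", {
  base <- data.frame(trial = 1:5, condition = "STR", target = "left",
                     rt = c(150, 300, 600, 300, 300),
                     mt = c(300, 150, 300, 300, 300),
                     peak_velocity = 60, time_to_pv = 100, angle_at_pv = 0,
                     final_err_x = 0.5, final_err_y = 1,
                     hit = c(TRUE, TRUE, TRUE, FALSE, TRUE),
                     error = NA_character_, stringsAsFactors = FALSE)
  keep <- reject_trials(base)
  expect_equal(as.vector(keep), c(FALSE, FALSE, FALSE, FALSE, TRUE))
  reasons <- attr(keep, "reasons")
  expect_equal(reasons[1], "RT_RANGE")
  expect_equal(reasons[2], "MT_RANGE")
  expect_equal(reasons[3], "RT_RANGE")
  expect_equal(reasons[4], "MISS")
  expect_equal(reasons[5], "")
  ## idempotent and order-independent
  expect_equal(as.vector(reject_trials(base[keep, ])), TRUE)
  perm <- sample(5)
  expect_equal(as.vector(reject_trials(base[perm, ])), as.vector(keep)[perm])
})

test_that("drift contrast is empty without STR trials", {
  s <- generate_schedule(1, n_str = 0, n_null_right = 5, n_null_left = 5,
                         n_adapt = 0, n_post = 0, min_gap = 0)
  sim <- simulate_reaches(s, seed = 1)
  kin <- summarize_trials(sim$trials)
  d <- drift_contrast(kin, s)
  expect_equal(nrow(d$left), 0)
  expect_true(isTRUE(attr(d, "empty")))
})
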