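test_that("noise-free unadapted reaches aim exactly at the target", {
  s <- generate_schedule(1, n_str = 0, n_null_right = 6, n_null_left = 6,
                         n_adapt = 0, n_post = 0, min_gap = 0)
  sim <- simulate_reaches(s, learning_rate = 0, motor_noise_sd = 0, seed = 1)
  kin <- summarize_trials(sim$trials)
  expect_equal(kin$angle_at_pv, rep(0, nrow(kin)), tolerance = 1e-8)
  expect_true(all(kin$hit))
})

test_that("rotated noise-free strategy reaches close the geometry loop", {
  s <- generate_schedule(2, n_str = 4, n_null_right = 8, n_null_left = 8,
                         n_adapt = 0, n_post = 0)
  sim <- simulate_reaches(s, learning_rate = 0, motor_noise_sd = 0, seed = 1)
  geo <- task_geometry()
  tp <- target_position(geo, "left")
  for (tr in sim$trials[sapply(sim$trials, `[[`, "condition") == "STR"]) {
    end <- nrow(tr$trajectory)
    cur <- cursor_position(cbind(tr$trajectory$x[end], tr$trajectory$y[end]),
                           "STR", geo)
    ## reaches stop 1-2 cm past the ring, along the target line
    d <- sqrt(sum((cur - tp)^2))
    expect_lt(d, 2.05)
    expect_equal(atan2(cur[2], cur[1]) * 180 / pi, 112.5, tolerance = 1e-6)
  }
})

test_that("implicit adaptation produces clockwise drift on post-STR NULL trials", {
  s <- generate_schedule(5, n_str = 60, n_null_right = 120, n_null_left = 120,
                         n_adapt = 0, n_post = 0)
  sim <- simulate_reaches(s, learning_rate = 0.012, retention = 0.98,
                          motor_noise_sd = 0, seed = 2)
  kin <- summarize_trials(sim$trials)
  d <- drift_contrast(kin, s)
  ## clockwise hand drift = increase of the target-minus-hand angle
  expect_gt(attr(d$left, "post_mean"), attr(d$left, "pre_mean"))
  ## ground-truth state is clockwise (negative) and bounded by the rotation
  expect_true(all(sim$ground_truth$adaptation_state <= 0))
  expect_true(all(abs(sim$ground_truth$adaptation_state) <= 45))
})

test_that("zero learning gives a null drift contrast", {
  s <- generate_schedule(6, n_str = 40, n_null_right = 80, n_null_left = 80,
                         n_adapt = 0, n_post = 0)
  sim <- simulate_reaches(s, learning_rate = 0, motor_noise_sd = 1, seed = 3)
  kin <- summarize_trials(sim$trials)
  d <- drift_contrast(kin, s)
  diff <- attr(d$left, "post_mean") - attr(d$left, "pre_mean")
  expect_lt(abs(diff), 0.5)
})

test_that("reach simulation is deterministic and validates parameters", {
  s <- generate_schedule(7, n_str = 3, n_null_right = 6, n_null_left = 6,
                         n_adapt = 2, n_post = 1)
  a <- simulate_reaches(s, seed = 9)
  b <- simulate_reaches(s, seed = 9)
  expect_identical(a, b)
  expect_error(simulate_reaches(s, retention = 1.2), "retention")
  expect_error(simulate_reaches(s, learning_rate = -0.1), "learning_rate")
})

test_that("adaptation-phase reaches stay on target (explicit/implicit rebalance)", {
  s <- generate_schedule(8, n_str = 20, n_null_right = 40, n_null_left = 40,
                         n_adapt = 60, n_post = 30)
  sim <- simulate_reaches(s, seed = 4)
  kin <- summarize_trials(sim$trials)
  post <- schedule_conditions(s) == "POST"
  expect_gt(mean(kin$hit[post]), 0.9)
})
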