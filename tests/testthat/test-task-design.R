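test_that("generated schedules satisfy the design invariants across seeds", {
  for (seed in seq_len(100)) {
    s <- generate_schedule(seed)
    expect_equal(nrow(s), 596)
    tab <- table(s$condition[1:400])
    expect_equal(unname(tab[c("STR", "NULL_R", "NULL_L")]), c(96L, 152L, 152L),
                 ignore_attr = TRUE)
    expect_true(all(s$condition[401:596] == "ADAPT"))
    expect_gte(min_str_gap(s), 2)
    expect_equal(attr(s, "post_indices"), 501:596)
  }
})

test_that("schedules are deterministic in the seed and infeasible counts error", {
  expect_identical(generate_schedule(42), generate_schedule(42))
  expect_false(identical(generate_schedule(1)$condition,
                         generate_schedule(2)$condition))
  expect_error(generate_schedule(1, n_str = 10, n_null_right = 5,
                                 n_null_left = 4, n_adapt = 0, n_post = 0),
               "infeasible")
})

test_that("POST relabelling marks exactly the final adaptation trials", {
  s <- generate_schedule(3)
  lab <- schedule_conditions(s)
  expect_equal(sum(lab == "POST"), 96)
  expect_true(all(which(lab == "POST") == 501:596))
  expect_equal(sum(lab == "ADAPT"), 100)
})

test_that("ideal aim follows the target on NULL trials and counters the rotation", {
  geo <- task_geometry()
  expect_equal(ideal_aim_direction("NULL_L", "left", geo), 112.5)
  expect_equal(ideal_aim_direction("NULL_R", "right", geo), 67.5)
  expect_equal(ideal_aim_direction("STR", "left", geo), 67.5)
  ## applying the cursor rotation to the STR aim recovers the cued target
  aim <- ideal_aim_direction("STR", "left", geo)
  expect_equal(aim + geo$rotation_angle, 112.5)
  expect_error(ideal_aim_direction("WASHOUT", "left", geo), "unknown condition")
})

test_that("the cursor map is an exact rotation", {
  geo <- task_geometry()
  hand <- matrix(rnorm(40), ncol = 2)
  cur <- cursor_position(hand, "STR", geo)
  expect_equal(sqrt(rowSums(cur^2)), sqrt(rowSums(hand^2)))
  ## rotating the ideal STR hand direction lands on the left target
  aim <- ideal_aim_direction("STR", "left", geo)
  tip <- cursor_position(8 * cbind(cospi(aim / 180), sinpi(aim / 180)), "STR", geo)
  expect_equal(unname(tip), unname(target_position(geo, "left")), tolerance = 1e-9)
  ## NULL trials pass the hand through unchanged
  expect_equal(unname(cursor_position(hand, "NULL_L", geo)), unname(hand))
})

test_that("geometry rejects non-positive lengths", {
  expect_error(task_geometry(start_radius = 0), "start_radius")
  expect_error(task_geometry(target_distance = -1), "target_distance")
})
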