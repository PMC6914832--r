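test_that("posture-to-corner mapping is the expected bijection", {
  expect_equal(unname(posture_to_corner("FFS")), c(1, 1, 1))
  expect_equal(unname(posture_to_corner("EEP")), c(-1, -1, -1))
  corners <- t(vapply(all_postures(), posture_to_corner, numeric(3)))
  expect_equal(nrow(unique(corners)), 8L)
  expect_true(all(corners %in% c(-1, 1)))
  # axis sign flips give the other consistent conventions
  expect_equal(unname(posture_to_corner("FFS", axis_signs = c(-1, 1, 1))),
               c(-1, 1, 1))
  expect_error(posture_to_corner("QQS"), "invalid")
})

test_that("joint activation follows the intermittent switching rules", {
  # trial start: all three axes active
  a0 <- joint_activation(NULL, "FFS")
  expect_true(all(a0$mask))
  expect_false(a0$shoulder_lock)

  # FFS -> FEP: shoulder unchanged and inactivated, elbow+wrist active
  a1 <- joint_activation("FFS", "FEP")
  expect_equal(unname(a1$mask), c(FALSE, TRUE, TRUE))
  expect_false(a1$shoulder_lock)

  # EFS -> FEP: all three change; only the shoulder activates, lock set
  a2 <- joint_activation("EFS", "FEP")
  expect_equal(unname(a2$mask), c(TRUE, FALSE, FALSE))
  expect_true(a2$shoulder_lock)

  # while locked, a change involving the shoulder re-applies shoulder-only
  a3 <- joint_activation("FEP", "EES", shoulder_lock = TRUE)
  expect_equal(unname(a3$mask), c(TRUE, FALSE, FALSE))
  expect_true(a3$shoulder_lock)

  # the lock clears on a change not involving the shoulder
  a4 <- joint_activation("FEP", "FES", shoulder_lock = TRUE)
  expect_equal(unname(a4$mask), c(FALSE, FALSE, TRUE))
  expect_false(a4$shoulder_lock)

  # no joint changed: nothing activates, not a posture change
  a5 <- joint_activation("FFS", "FFS")
  expect_false(any(a5$mask))
})

test_that("RK4 reproduces the critically damped closed form and never overshoots", {
  params <- dynamics_params()  # omega 0.39, delta 1
  state <- list(position = c(0, 0, 0), velocity = c(0, 0, 0),
                reference = c(1, 0, 0), active = c(TRUE, FALSE, FALSE))
  dt <- 1 / 150
  n <- round(10 / dt)
  xs <- numeric(n)
  for (i in seq_len(n)) {
    state <- step_dynamics(state, params, dt)
    xs[i] <- state$position[1]
  }
  t <- seq_len(n) * dt
  closed <- 1 - (1 + 0.39 * t) * exp(-0.39 * t)
  expect_lt(max(abs(xs - closed)), 1e-6)
  # critical damping: monotone, no overshoot
  expect_true(all(diff(xs) >= -1e-12))
  expect_true(all(xs <= 1 + 1e-9))
  # equilibrium is a fixed point
  eq <- list(position = c(1, 0, 0), velocity = c(0, 0, 0),
             reference = c(1, 0, 0), active = c(TRUE, TRUE, TRUE))
  eq2 <- step_dynamics(eq, params, 0.5)
  expect_equal(eq2$position, eq$position, tolerance = 1e-12)
  expect_equal(eq2$velocity, eq$velocity, tolerance = 1e-12)
})

test_that("holding one posture converges to its corner", {
  tr <- run_trial(data.frame(time_s = 0, posture = "FEP"),
                  trial_config(c(0.99, 0.99, 0.99)),  # unreachable, full run
                  return_trajectory = TRUE)
  tj <- tr$trajectory
  at30 <- tj[which.min(abs(tj[, "time_s"] - 30)), 2:4]
  expect_lt(sqrt(sum((at30 - posture_to_corner("FEP"))^2)), 1e-3)
})

test_that("trials report the four performance measures correctly", {
  target <- c(0.4, -0.3, 0.2)
  cfg <- trial_config(target, time_limit_s = 30)
  # empty stream: no motion
  tr0 <- run_trial(NULL, cfg)
  expect_false(tr0$reached)
  expect_equal(tr0$trajectory_length, 0)
  expect_equal(tr0$final_distance, sqrt(sum(target^2)))
  expect_equal(tr0$n_posture_changes, 0L)

  # single posture toward the diagonal passes through a target on it
  diag_target <- 0.5 * posture_to_corner("FFS") / sqrt(3)
  tr1 <- run_trial(data.frame(time_s = 0, posture = "FFS"),
                   trial_config(diag_target))
  expect_true(tr1$reached)
  expect_equal(tr1$n_posture_changes, 1L)
  expect_gte(tr1$trajectory_length,
             sqrt(sum(tr1$final_position^2)) - 1e-9)  # polyline >= chord

  # repeated identical events are not posture changes
  tr2 <- run_trial(data.frame(time_s = c(0, 1, 2), posture = "FFS"),
                   trial_config(diag_target))
  expect_equal(tr2$n_posture_changes, 1L)

  # target at the center is captured immediately
  tr3 <- run_trial(NULL, trial_config(c(0, 0, 0)))
  expect_true(tr3$reached)
  expect_equal(tr3$time_s, 0)

  expect_error(run_trial(data.frame(time_s = c(2, 1), posture = c("FFS", "FFP")),
                         cfg), "non-decreasing")
  expect_error(run_trial(data.frame(time_s = 500, posture = "FFS"), cfg),
               "within")
})

test_that("inactive axes hold bit-identically while active axes move", {
  stream <- data.frame(time_s = c(0, 5), posture = c("FFS", "FFP"))
  tr <- run_trial(stream, trial_config(c(0.99, 0.99, -0.99), time_limit_s = 20),
                  return_trajectory = TRUE)
  tj <- tr$trajectory
  after <- tj[tj[, "time_s"] > 5 + 1e-9, ]
  # shoulder and elbow did not change after the wrist-only event
  expect_length(unique(after[, "x"]), 1L)
  expect_length(unique(after[, "y"]), 1L)
  expect_gt(abs(after[nrow(after), "z"] - after[1, "z"]), 0.1)
})

test_that("trajectory length converges with the integration step", {
  stream <- data.frame(time_s = c(0, 4, 9), posture = c("FFS", "FEP", "EFP"))
  cfg1 <- trial_config(c(0.95, 0.95, 0.95), time_limit_s = 30, substeps = 10L)
  cfg2 <- trial_config(c(0.95, 0.95, 0.95), time_limit_s = 30, substeps = 20L)
  l1 <- run_trial(stream, cfg1)$trajectory_length
  l2 <- run_trial(stream, cfg2)$trajectory_length
  expect_lt(abs(l1 - l2) / l2, 0.001)
})

test_that("shrinking the capture radius never turns a failure into a success", {
  stream <- data.frame(time_s = c(0, 6), posture = c("FFS", "FES"))
  target <- c(0.5, 0.1, 0.45)
  radii <- c(0.3, 0.2, 0.1, 0.05, 0.02)
  reached <- vapply(radii, function(r)
    run_trial(stream, trial_config(target, capture_radius = r,
                                   time_limit_s = 30))$reached, logical(1))
  # monotone: once a radius fails, all smaller radii fail
  expect_true(all(diff(as.integer(reached)) <= 0))
})

test_that("reachability handles the trivial minimal cases and validates witnesses", {
  # target at the center: zero commands
  r0 <- min_postures_to_reach(c(0, 0, 0), k_max = 1)
  expect_equal(r0$table$min_k, 0L)

  # target on a corner diagonal: one command suffices
  tg <- unname(0.5 * posture_to_corner("FFS") / sqrt(3))
  r1 <- min_postures_to_reach(tg, k_max = 2)
  expect_equal(r1$table$min_k, 1L)
  w <- r1$witnesses[[1]]
  expect_equal(nrow(w), 1L)
  # the witness replays successfully through the RK4 trial engine
  expect_true(run_trial(w, trial_config(tg))$reached)

  expect_error(min_postures_to_reach(c(1.5, 0, 0)), "inside")
})

test_that("the closed-form segment simulator agrees with the RK4 trial engine", {
  stream <- data.frame(time_s = c(0, 4.8, 12), posture = c("FFS", "FEP", "EEP"))
  tr <- run_trial(stream, trial_config(c(0.99, 0.99, 0.99), time_limit_s = 20),
                  return_trajectory = TRUE)
  sm <- synergycube:::sequence_masks(stream$posture)
  ts <- seq(0, 20, by = 1 / 15)
  traj <- synergycube:::simulate_segments(sm$masks, sm$refs, stream$time_s,
                                          ts, 0.39)
  # compare at matching times
  idx <- vapply(ts, function(t) which.min(abs(tr$trajectory[, "time_s"] - t)),
                integer(1))
  expect_lt(max(abs(tr$trajectory[idx, 2:4] - traj)), 1e-4)
})
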