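test_that("heading_error is the wrapped bearing minus heading", {
  expect_equal(heading_error(0, 0, 0, goal_spec(0, 1)), pi / 2)   # goal left
  expect_equal(heading_error(0, 0, pi / 2, goal_spec(0, 1)), 0)   # aligned
  expect_equal(heading_error(0, 0, 0, goal_spec(-1, 0)), pi)      # behind
  expect_equal(heading_error(3, -2, -pi / 4, goal_spec(3, -3)),
               wrap_angle(-pi / 2 + pi / 4))
  # at the goal center the error is 0 by definition
  expect_equal(heading_error(1, 1, 2.3, goal_spec(1, 1)), 0)
})

test_that("goal_spec validates radius and timeout", {
  expect_error(goal_spec(0, 0, radius = 0), "radius")
  expect_error(goal_spec(0, 0, timeout_s = -1), "timeout")
  g <- goal_spec(1, 2)
  expect_equal(g$timeout_s, 60)
})

test_that("pinwheel_command is bang-bang with deadband hysteresis", {
  expect_identical(pinwheel_command(0.5)$direction, "CCW")
  expect_identical(pinwheel_command(-0.5)$direction, "CW")
  # inside the deadband the previous direction is held
  expect_identical(pinwheel_command(0.1, previous = "CW")$direction, "CW")
  expect_identical(pinwheel_command(-0.1, previous = "CCW")$direction, "CCW")
  expect_identical(pinwheel_command(0, previous = NULL)$direction, "CCW")
  # exactly at the deadband edge counts as inside
  expect_identical(pinwheel_command(0.2, previous = "CW")$direction, "CW")
  expect_identical(pinwheel_command(0.5)$modality, "pinwheel")
  expect_equal(pinwheel_command(0.5)$intensity, 1)
})

test_that("led_command lateralizes and scales intensity with distance", {
  expect_identical(led_command(0.5, 5, 20)$direction, "blue")
  expect_identical(led_command(-0.5, 5, 20)$direction, "red")
  expect_identical(led_command(0, 5, 20)$direction, "both")   # aligned
  expect_equal(led_command(0.5, 5, 20)$intensity, 0.25)
  expect_equal(led_command(0.5, 1, 20)$intensity, 0.2)        # floor
  expect_equal(led_command(0.5, 50, 20)$intensity, 1)         # saturation
  expect_error(led_command(0.5, -1, 20), "distance_to_goal")
  expect_error(led_command(0.5, 5, 0), "d_max")
})

test_that("stimulus_command enforces the fixed-contrast pinwheel", {
  expect_error(stimulus_command("pinwheel", "CCW", intensity = 0.5),
               "intensity")
  expect_error(stimulus_command("pinwheel", "red"), "CW or CCW")
  expect_error(stimulus_command("led", "CCW"), "red, blue or both")
  expect_error(stimulus_command("led", "red", intensity = 1.5), "intensity")
})

test_that("the goal sequencer records successes, timeouts and cycles", {
  goals <- list(goal_spec(0, 0, 1, 60), goal_spec(10, 0, 1, 60))
  sq <- new_goal_sequencer(goals, wrap = TRUE)
  # start inside goal 1: immediate success, advance to goal 2
  g <- sq$update(0, 0.5, 0)
  expect_equal(c(g$x, g$y), c(10, 0))
  # sit still until the timeout: failure recorded at 60 s
  for (t in seq(1, 60)) g <- sq$update(t, 0.5, 0)
  tr <- sq$trials()
  expect_equal(nrow(tr), 2)
  expect_identical(tr$success, c(TRUE, FALSE))
  expect_equal(tr$end_s[2] - tr$start_s[2], 60)
  expect_equal(tr$goal_index, c(1L, 2L))
  # wrap: the active goal is goal 1 again
  expect_equal(sq$goal_index(), 1L)
  # path length accumulates between updates
  sq2 <- new_goal_sequencer(list(goal_spec(100, 0, 1, 60)))
  sq2$update(0, 0, 0)
  sq2$update(1, 3, 4)
  sq2$update(61, 3, 4)  # timeout
  expect_equal(sq2$trials()$path_length_cm, 5)
})

test_that("a 12-goal wrapping sequence visited twice yields 24 trials", {
  goals <- lapply(1:12, function(k) goal_spec(k, 0, 0.5, 60))
  sq <- new_goal_sequencer(goals, wrap = TRUE)
  t <- 0
  for (lap in 1:2) for (k in 1:12) { sq$update(t, k, 0); t <- t + 1 }
  tr <- sq$trials()
  expect_equal(nrow(tr), 24)
  expect_true(all(tr$success))
  expect_equal(tr$goal_index, rep(1:12, 2))
})

test_that("a non-wrapping sequence exhausts and returns NULL", {
  goals <- list(goal_spec(0, 0, 1, 60))
  sq <- new_goal_sequencer(goals, wrap = FALSE)
  expect_null(sq$update(0, 0, 0))
  expect_null(sq$update(1, 0, 0))
  expect_equal(nrow(sq$trials()), 1)
})

test_that("offline goal_sequencer matches the online closure", {
  goals <- list(goal_spec(0, 0, 1, 5), goal_spec(4, 0, 1, 5))
  traj <- data.frame(time_s = seq(0, 20, by = 0.5),
                     x = pmin(seq(0, 20, by = 0.5) * 0.5, 10), y = 0)
  off <- goal_sequencer(traj, goals, wrap = TRUE)
  expect_equal(length(off$goal_index), nrow(traj))
  expect_true(nrow(off$trials) >= 2)
  expect_error(goal_sequencer(traj[c(2, 1), ], goals), "time-ordered")
})

test_that("segment_windows matches hand-segmented examples", {
  dt <- 0.1
  cmd <- data.frame(
    time_s = seq(0, by = dt, length.out = 10), fly_id = 1L,
    modality = c(rep("pinwheel", 4), "none", rep("pinwheel", 3), "led", "led"),
    direction = c("CCW", "CCW", "CW", "CW", NA, "CW", "CW", "CCW", "red",
                  "both"),
    intensity = 1)
  w <- segment_windows(cmd, dt = dt)
  expect_equal(nrow(w), 5)
  expect_equal(w$commanded_sign, c(1, -1, -1, 1, -1))
  expect_equal(w$modality, c("pinwheel", "pinwheel", "pinwheel", "pinwheel",
                             "led"))
  expect_equal(w$start_s, c(0, 0.2, 0.5, 0.7, 0.8))
  expect_equal(w$end_s, c(0.2, 0.4, 0.7, 0.8, 0.9))
  # windows tile the signed stimulated time exactly
  signed_ticks <- sum(cmd$direction %in% c("CW", "CCW", "red", "blue"))
  expect_equal(sum(w$end_s - w$start_s), signed_ticks * dt)
})

test_that("segment_windows agrees with the brute-force oracle", {
  dt <- 1 / 30
  set.seed(77)
  for (rep in 1:5) {
    n <- 400
    modality <- sample(c("pinwheel", "led", "none"), n, replace = TRUE,
                       prob = c(0.45, 0.45, 0.1))
    direction <- ifelse(modality == "pinwheel",
                        sample(c("CW", "CCW"), n, replace = TRUE),
                        ifelse(modality == "led",
                               sample(c("red", "blue", "both"), n,
                                      replace = TRUE),
                               NA))
    cmd <- data.frame(time_s = rep(seq_len(n %/% 2) * dt, each = 2),
                      fly_id = rep(1:2, n %/% 2),
                      modality = modality, direction = direction,
                      intensity = 1)
    cmd <- cmd[order(cmd$fly_id, cmd$time_s), ]
    got <- segment_windows(cmd, dt = dt)
    want <- oracle_windows(cmd, dt)
    expect_equal(got, want)
  }
})

test_that("segment_windows breaks runs across time gaps", {
  dt <- 0.1
  cmd <- data.frame(time_s = c(0, 0.1, 0.5, 0.6), fly_id = 1L,
                    modality = "pinwheel", direction = "CCW", intensity = 1)
  w <- segment_windows(cmd, dt = dt)
  expect_equal(nrow(w), 2)
  expect_equal(w$start_s, c(0, 0.5))
  expect_error(segment_windows(cmd[c(2, 1, 3, 4), ]), "time-ordered")
  expect_equal(nrow(segment_windows(cmd[0, ])), 0)
})

test_that("assign_pens is greedy-nearest, tie-broken and injective", {
  # identity case
  pts <- cbind(c(0, 10, 20), c(0, 0, 0))
  expect_identical(assign_pens(pts, pts), 1:3)
  # swapped pens still pick their nearest detections
  expect_identical(assign_pens(pts, pts[c(2, 1, 3), ]), c(2L, 1L, 3L))
  # tie: two pens equidistant from one detection -> lower pen index wins
  det <- rbind(c(0, 0), c(5, 0))
  pens <- rbind(c(1, 0), c(-1, 0))
  a <- assign_pens(det, pens)
  expect_identical(a, c(1L, 2L))
  # degraded: fewer detections than pens -> NA for the leftover pen
  a2 <- assign_pens(rbind(c(0, 0)), pens)
  expect_identical(sort(is.na(a2)), c(FALSE, TRUE))
  expect_identical(assign_pens(det, det[0, , drop = FALSE]), integer(0))
})

test_that("assign_pens matches a brute-force greedy oracle and is injective", {
  set.seed(123)
  for (rep in 1:20) {
    n <- sample(1:8, 1)
    k <- sample(1:8, 1)
    det <- matrix(stats::runif(2 * n, -10, 10), n, 2)
    pens <- matrix(stats::runif(2 * k, -10, 10), k, 2)
    a <- assign_pens(det, pens)
    expect_length(a, k)
    got <- a[!is.na(a)]
    expect_identical(anyDuplicated(got), 0L)      # injective
    expect_equal(length(got), min(n, k))          # maximal matching
    # oracle: repeatedly take the globally smallest pen-detection distance
    d <- outer(seq_len(k), seq_len(n), function(i, j)
      sqrt((pens[i, 1] - det[j, 1])^2 + (pens[i, 2] - det[j, 2])^2))
    want <- rep(NA_integer_, k)
    for (s in seq_len(min(n, k))) {
      m <- which(d == min(d), arr.ind = TRUE)[1, ]  # row-major first = tie rule
      want[m[1]] <- m[2]
      d[m[1], ] <- Inf
      d[, m[2]] <- Inf
    }
    expect_identical(a, want)
  }
})

test_that("formation_spec validates patterns and goal overlap", {
  pats <- default_formation_patterns()
  f <- formation_spec(pats$pattern_a, pats$pattern_b)
  expect_identical(f$active, "A")
  expect_identical(f$switches, 0L)
  expect_error(formation_spec(pats$pattern_a[1:5], pats$pattern_b), "6 goals")
  bad <- pats$pattern_a
  bad[[2]] <- bad[[1]]
  expect_error(formation_spec(bad, pats$pattern_b), "overlap")
})

test_that("formation controller halts in-goal flies and toggles patterns", {
  pats <- default_formation_patterns()
  f <- formation_spec(pats$pattern_a, pats$pattern_b)
  at_goal <- function(g, mode) fly_state(x = g$x, y = g$y, mode = mode)
  # 5 in, 1 out: no toggle; the stray fly gets pinwheel guidance
  states <- lapply(pats$pattern_a, at_goal, mode = "halted")
  states[[6]] <- fly_state(x = 0, y = 0, heading = 0, mode = "walking")
  out <- formation_controller(states, f)
  expect_identical(out$formation$active, "A")
  expect_identical(out$formation$switches, 0L)
  mods <- vapply(out$commands, function(c) c$modality, character(1))
  expect_equal(sum(mods == "halt_laser"), 5)
  expect_equal(sum(mods == "pinwheel"), 1)
  # all 6 halted inside their goals: toggle to B, counter increments
  states6 <- lapply(pats$pattern_a, at_goal, mode = "halted")
  expect_true(formation_achieved(states6, pats$pattern_a))
  out2 <- formation_controller(states6, f)
  expect_identical(out2$formation$active, "B")
  expect_identical(out2$formation$switches, 1L)
  # after the toggle every fly is steered toward the new pattern
  mods2 <- vapply(out2$commands, function(c) c$modality, character(1))
  expect_true(all(mods2 == "pinwheel"))
  # all inside but still walking (not yet halted): no toggle
  walking <- lapply(pats$pattern_a, at_goal, mode = "walking")
  out3 <- formation_controller(walking, f)
  expect_identical(out3$formation$active, "A")
})
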