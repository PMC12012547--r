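# Stepwise closed-loop controllers: pinwheel direction selection,
# distance-scaled LED commands, goal sequencing under the 60-s rule,
# stimulation-window bookkeeping, pen assignment and formation control.

#' Construct a stimulus command
#'
#' The controller's output for one fly on one tick.
#'
#' @param modality `"pinwheel"`, `"led"`, `"halt_laser"` or `"none"`.
#' @param direction `"CW"`/`"CCW"` for the pinwheel, `"red"`/`"blue"`/`"both"`
#'   for the LEDs, `NA` otherwise.
#' @param intensity in `[0, 1]`; the pinwheel is always projected at full
#'   contrast (intensity 1), only the LEDs are modulated.
#' @param fly_id target fly.
#' @param time_s command timestamp (s).
#' @return an object of class `stimulus_command`.
#' @export
stimulus_command <- function(modality = c("pinwheel", "led", "halt_laser", "none"),
                             direction = NA_character_, intensity = 1,
                             fly_id = 1L, time_s = 0) {
  modality <- match.arg(modality)
  if (modality == "pinwheel") {
    if (!direction %in% c("CW", "CCW"))
      stop("pinwheel direction must be CW or CCW", call. = FALSE)
    if (intensity != 1)
      stop("pinwheel intensity is fixed at 1; only LEDs are modulated",
           call. = FALSE)
  } else if (modality == "led") {
    if (!direction %in% c("red", "blue", "both"))
      stop("led direction must be red, blue or both", call. = FALSE)
  }
  if (intensity < 0 || intensity > 1)
    stop("intensity must lie in [0, 1]", call. = FALSE)
  structure(list(modality = modality, direction = direction,
                 intensity = intensity, fly_id = as.integer(fly_id),
                 time_s = time_s),
            class = "stimulus_command")
}

#' Construct a spatial goal
#'
#' @param x,y goal center (cm).
#' @param radius capture radius (cm, > 0).
#' @param timeout_s per-trial time budget (s); a trial not reaching the goal
#'   within this time is a failure (default 60).
#' @return an object of class `goal_spec`.
#' @export
goal_spec <- function(x, y, radius = 1.5, timeout_s = 60) {
  if (radius <= 0) stop("goal radius must be > 0", call. = FALSE)
  if (timeout_s <= 0) stop("timeout_s must be > 0", call. = FALSE)
  structure(list(x = x, y = y, radius = radius, timeout_s = timeout_s),
            class = "goal_spec")
}

#' Signed heading error toward a goal
#'
#' The bearing to the goal minus the fly's heading, wrapped to (-pi, pi].
#' Positive error means the goal lies to the fly's left (a CCW/left turn
#' reduces it). A fly exactly at the goal center has error 0 by definition.
#'
#' @param x,y,heading fly pose (cm, cm, rad).
#' @param goal a [goal_spec()].
#' @return signed angle in (-pi, pi].
#' @export
#' @examples
#' heading_error(0, 0, 0, goal_spec(0, 1))  # +pi/2: goal due left
heading_error <- function(x, y, heading, goal) {
  dx <- goal$x - x
  dy <- goal$y - y
  if (dx == 0 && dy == 0) return(0)
  wrap_angle(atan2(dy, dx) - heading)
}

#' Pinwheel rotation command from the heading error
#'
#' Bang-bang rule with hysteresis: error above `+deadband` commands a CCW
#' pinwheel (left turn), below `-deadband` a CW pinwheel (right turn); inside
#' the deadband the previous direction is held so the command does not chatter
#' around alignment.
#'
#' @param error signed heading error (rad, in (-pi, pi]).
#' @param deadband half-width of the hysteresis band (rad).
#' @param previous the held direction (`"CW"`/`"CCW"`); used when
#'   `|error| <= deadband`. A `NULL` previous inside the deadband defaults to
#'   `"CCW"`.
#' @param fly_id,time_s passed through to the command.
#' @return a `stimulus_command` with modality `"pinwheel"`.
#' @export
pinwheel_command <- function(error, deadband = 0.2, previous = NULL,
                             fly_id = 1L, time_s = 0) {
  dir <- if (error > deadband) "CCW"
         else if (error < -deadband) "CW"
         else if (!is.null(previous)) previous
         else "CCW"
  stimulus_command("pinwheel", dir, 1, fly_id, time_s)
}

#' LED command from heading error and distance to goal
#'
#' Blue light (left turn) when the goal is to the left of the heading beyond
#' the deadband, red light (right turn) when to the right; both LEDs when the
#' fly is aligned (|error| <= deadband). Intensity scales linearly with the
#' distance to the goal, saturating at `d_max` and floored at `i_min`.
#'
#' @inheritParams pinwheel_command
#' @param distance_to_goal current distance to the goal (cm, >= 0).
#' @param d_max distance at which intensity saturates at 1 (cm, > 0).
#' @param i_min intensity floor.
#' @return a `stimulus_command` with modality `"led"`.
#' @export
led_command <- function(error, distance_to_goal, d_max, deadband = 0.2,
                        i_min = 0.2, fly_id = 1L, time_s = 0) {
  if (distance_to_goal < 0) stop("distance_to_goal must be >= 0", call. = FALSE)
  if (d_max <= 0) stop("d_max must be > 0", call. = FALSE)
  ch <- if (error > deadband) "blue"
        else if (error < -deadband) "red"
        else "both"
  stimulus_command("led", ch, clamp(distance_to_goal / d_max, i_min, 1),
                   fly_id, time_s)
}

#' Stateful goal sequencer
#'
#' Creates a sequencer over an ordered goal list implementing the trial rules:
#' a trial starts when its goal becomes active, succeeds when the fly enters
#' the goal radius within the timeout, fails at timeout, and either way the
#' sequencer advances to the next goal (wrapping to the first after the last
#' when `wrap = TRUE`).
#'
#' @param goals list of [goal_spec()] (>= 1).
#' @param wrap restart the sequence after completion?
#' @return a list of closures: `update(time_s, x, y)` returning the active
#'   goal (or `NULL` when a non-wrapping sequence is exhausted),
#'   `trials()` returning the accumulated trial `data.frame`, and
#'   `goal_index()`.
#' @seealso [goal_sequencer()] for the offline version over a logged
#'   trajectory.
#' @export
new_goal_sequencer <- function(goals, wrap = TRUE) {
  if (length(goals) < 1) stop("at least one goal is required", call. = FALSE)
  idx <- 1L
  trial_i <- 0L
  trial_t0 <- NA_real_
  path <- 0
  px <- NA_real_
  py <- NA_real_
  done <- FALSE
  rec <- list()

  close_trial <- function(time_s, success) {
    trial_i <<- trial_i + 1L
    g <- goals[[idx]]
    rec[[trial_i]] <<- data.frame(trial_index = trial_i, goal_index = idx,
                                  goal_x = g$x, goal_y = g$y,
                                  start_s = trial_t0, end_s = time_s,
                                  success = success, path_length_cm = path)
    if (idx == length(goals) && !wrap) done <<- TRUE
    idx <<- if (idx == length(goals)) 1L else idx + 1L
    trial_t0 <<- time_s
    path <<- 0
  }

  update <- function(time_s, x, y) {
    if (done) return(NULL)
    if (is.na(trial_t0)) trial_t0 <<- time_s
    if (!is.na(px)) path <<- path + sqrt((x - px)^2 + (y - py)^2)
    px <<- x
    py <<- y
    g <- goals[[idx]]
    if (sqrt((x - g$x)^2 + (y - g$y)^2) <= g$radius) {
      close_trial(time_s, TRUE)
    } else if (time_s - trial_t0 >= g$timeout_s) {
      close_trial(time_s, FALSE)
    }
    if (done) NULL else goals[[idx]]
  }

  trials <- function() {
    if (length(rec) == 0) {
      data.frame(trial_index = integer(), goal_index = integer(),
                 goal_x = numeric(), goal_y = numeric(), start_s = numeric(),
                 end_s = numeric(), success = logical(),
                 path_length_cm = numeric())
    } else do.call(rbind, rec)
  }

  list(update = update, trials = trials, goal_index = function() idx,
       n_trials = function() trial_i)
}

#' Sequence goals over a logged trajectory
#'
#' Offline application of the trial state machine to a recorded trajectory:
#' returns the active goal index at every sample and the trial records
#' (success under the per-goal timeout, path length per trial).
#'
#' @param traj data.frame with columns `time_s`, `x`, `y` (time-ordered).
#' @param goals list of [goal_spec()].
#' @param wrap restart the sequence after the last goal?
#' @return list with `goal_index` (integer per sample; `NA` once a
#'   non-wrapping sequence is exhausted) and `trials` (data.frame).
#' @export
goal_sequencer <- function(traj, goals, wrap = TRUE) {
  if (length(goals) < 1) stop("at least one goal is required", call. = FALSE)
  if (is.unsorted(traj$time_s)) stop("trajectory must be time-ordered", call. = FALSE)
  seq_ <- new_goal_sequencer(goals, wrap = wrap)
  gi <- integer(nrow(traj))
  for (k in seq_len(nrow(traj))) {
    g <- seq_$update(traj$time_s[k], traj$x[k], traj$y[k])
    gi[k] <- if (is.null(g)) NA_integer_ else seq_$goal_index()
  }
  list(goal_index = gi, trials = seq_$trials())
}

#' Segment a command log into stimulation windows
#'
#' A stimulation window is a maximal run of constant commanded turn sign
#' (+1 for left/CCW/blue, -1 for right/CW/red) for one fly. Unstimulated ticks
#' and neutral "both LEDs" ticks are gaps; windows tile the signed stimulated
#' time exactly. The window is the unit over which fidelity is scored.
#'
#' @param cmd_log data.frame with columns `time_s`, `fly_id`, `modality`,
#'   `direction`, `intensity`, time-ordered within each fly, sampled on a
#'   regular tick.
#' @param dt tick duration (s); window end = last tick time + `dt`. If `NULL`,
#'   inferred as the median time difference.
#' @return data.frame with columns `fly_id`, `start_s`, `end_s`,
#'   `commanded_sign`, `modality`.
#' @export
segment_windows <- function(cmd_log, dt = NULL) {
  out <- data.frame(fly_id = integer(), start_s = numeric(),
                    end_s = numeric(), commanded_sign = numeric(),
                    modality = character())
  if (nrow(cmd_log) == 0) return(out)
  for (fid in sort(unique(cmd_log$fly_id))) {
    cl <- cmd_log[cmd_log$fly_id == fid, ]
    if (is.unsorted(cl$time_s))
      stop("command log must be time-ordered within each fly", call. = FALSE)
    step <- dt
    if (is.null(step)) {
      dts <- diff(cl$time_s)
      step <- if (length(dts)) stats::median(dts) else 0
    }
    sgn <- ifelse(cl$direction %in% c("CCW", "blue"), 1,
                  ifelse(cl$direction %in% c("CW", "red"), -1, 0))
    sgn[!cl$modality %in% c("pinwheel", "led")] <- 0
    # break runs at sign changes, modality changes, or time gaps > 1.5 ticks
    gap <- c(FALSE, diff(cl$time_s) > 1.5 * step)
    key <- paste(sgn, cl$modality)
    newrun <- c(TRUE, key[-1] != key[-length(key)]) | gap
    first <- which(newrun)
    last <- c(first[-1] - 1L, length(key))
    keep <- sgn[first] != 0
    if (any(keep)) {
      out <- rbind(out, data.frame(
        fly_id = fid, start_s = cl$time_s[first[keep]],
        end_s = cl$time_s[last[keep]] + step,
        commanded_sign = sgn[first[keep]],
        modality = cl$modality[first[keep]]))
    }
  }
  rownames(out) <- NULL
  out
}

#' Assign writing pens to fly detections
#'
#' Identity-free multi-fly control: each "pen" (a goal-sequence cursor) is
#' re-attached every frame to the detection nearest its previously assigned
#' position, by globally greedy nearest-neighbor matching (smallest
#' pen-detection distance first; ties broken by lower pen index, then lower
#' detection index). The mapping is injective; pens may swap flies across
#' frames by design. With fewer detections than pens the unmatched pens are
#' returned as `NA` (degraded, to be paused by the caller).
#'
#' @param detections n x 2 matrix of detected positions (cm).
#' @param pen_positions k x 2 matrix of each pen's last assigned position.
#' @return integer vector of length k: detection index per pen (`NA` when
#'   degraded).
#' @export
assign_pens <- function(detections, pen_positions) {
  detections <- as.matrix(detections)
  pen_positions <- as.matrix(pen_positions)
  n <- nrow(detections)
  k <- nrow(pen_positions)
  if (k == 0) return(integer(0))
  d <- outer(seq_len(k), seq_len(n), function(i, j) {
    sqrt((pen_positions[i, 1] - detections[j, 1])^2 +
         (pen_positions[i, 2] - detections[j, 2])^2)
  })
  assign <- rep(NA_integer_, k)
  det_free <- rep(TRUE, n)
  pen_free <- rep(TRUE, k)
  for (step in seq_len(min(n, k))) {
    best <- Inf
    bi <- bj <- NA_integer_
    for (i in which(pen_free)) {
      for (j in which(det_free)) {
        if (d[i, j] < best - 1e-12) {
          best <- d[i, j]; bi <- i; bj <- j
        }
        # ties: lower pen index wins via loop order; lower detection index
        # wins because strictly-smaller is required to replace
      }
    }
    if (is.na(bi)) break
    assign[bi] <- bj
    pen_free[bi] <- FALSE
    det_free[bj] <- FALSE
  }
  assign
}

#' Construct a two-pattern formation specification
#'
#' @param pattern_a,pattern_b ordered lists of 6 [goal_spec()] each; goal
#'   regions within a pattern must not overlap.
#' @return an object of class `formation_spec` with `active = "A"` and a
#'   switch counter at 0.
#' @export
formation_spec <- function(pattern_a, pattern_b) {
  for (pat in list(pattern_a, pattern_b)) {
    if (length(pat) != 6) stop("each pattern needs 6 goals", call. = FALSE)
    for (i in 1:5) for (j in (i + 1):6) {
      gi <- pat[[i]]; gj <- pat[[j]]
      if (sqrt((gi$x - gj$x)^2 + (gi$y - gj$y)^2) <= gi$radius + gj$radius)
        stop("goal regions within a pattern must not overlap", call. = FALSE)
    }
  }
  structure(list(patterns = list(A = pattern_a, B = pattern_b),
                 active = "A", switches = 0L, assignment = NULL),
            class = "formation_spec")
}

#' Are all flies inside their formation goals?
#'
#' @param states list of [fly_state()].
#' @param goals list of [goal_spec()], one per fly (same order).
#' @return logical.
#' @export
formation_achieved <- function(states, goals) {
  all(vapply(seq_along(states), function(i) {
    s <- states[[i]]; g <- goals[[i]]
    sqrt((s$x - g$x)^2 + (s$y - g$y)^2) <= g$radius
  }, logical(1)))
}

#' One tick of the formation controller
#'
#' Each fly is matched to a goal of the active pattern (nearest-neighbor pen
#' assignment, recomputed on every pattern switch). Flies outside their goal
#' receive pinwheel guidance toward it; a fly inside its goal receives the
#' halt laser. When all six are simultaneously halted inside their goals the
#' formation is achieved: the active pattern toggles A/B, the switch counter
#' increments, halts are released (guidance to the new goals resumes next
#' tick) and pens are re-assigned.
#'
#' @param states list of 6 [fly_state()].
#' @param formation a [formation_spec()].
#' @param deadband pinwheel controller deadband (rad).
#' @param prev_dirs character vector of held pinwheel directions per fly.
#' @param time_s current time (s).
#' @return list with `commands` (list of `stimulus_command`), the updated
#'   `formation`, and updated `prev_dirs`.
#' @export
formation_controller <- function(states, formation, deadband = 0.2,
                                 prev_dirs = NULL, time_s = 0) {
  n <- length(states)
  goals_all <- formation$patterns[[formation$active]]
  if (is.null(prev_dirs)) prev_dirs <- rep(NA_character_, n)
  if (is.null(formation$assignment)) {
    pos <- t(vapply(states, function(s) c(s$x, s$y), numeric(2)))
    gpos <- t(vapply(goals_all, function(g) c(g$x, g$y), numeric(2)))
    # pens are the goals; each goal grabs its nearest fly
    formation$assignment <- assign_pens(pos, gpos)
  }
  # goal i of the active pattern belongs to fly formation$assignment[i]
  goal_of_fly <- integer(n)
  goal_of_fly[formation$assignment] <- seq_len(n)
  cmds <- vector("list", n)
  inside <- logical(n)
  for (f in seq_len(n)) {
    g <- goals_all[[goal_of_fly[f]]]
    s <- states[[f]]
    inside[f] <- sqrt((s$x - g$x)^2 + (s$y - g$y)^2) <= g$radius
    if (inside[f]) {
      cmds[[f]] <- stimulus_command("halt_laser", NA_character_, 1, s$id, time_s)
    } else {
      err <- heading_error(s$x, s$y, s$heading, g)
      prev <- if (is.na(prev_dirs[f])) NULL else prev_dirs[f]
      cmds[[f]] <- pinwheel_command(err, deadband, prev, s$id, time_s)
      prev_dirs[f] <- cmds[[f]]$direction
    }
  }
  halted <- vapply(states, function(s) s$mode == "halted", logical(1))
  if (all(inside) && all(halted)) {
    formation$active <- if (formation$active == "A") "B" else "A"
    formation$switches <- formation$switches + 1L
    formation$assignment <- NULL
    # release: guidance toward the new pattern from the next tick
    new_goals <- formation$patterns[[formation$active]]
    pos <- t(vapply(states, function(s) c(s$x, s$y), numeric(2)))
    gpos <- t(vapply(new_goals, function(g) c(g$x, g$y), numeric(2)))
    formation$assignment <- assign_pens(pos, gpos)
    goal_of_fly[formation$assignment] <- seq_len(n)
    for (f in seq_len(n)) {
      g <- new_goals[[goal_of_fly[f]]]
      s <- states[[f]]
      err <- heading_error(s$x, s$y, s$heading, g)
      cmds[[f]] <- pinwheel_command(err, deadband, NULL, s$id, time_s)
      prev_dirs[f] <- cmds[[f]]$direction
    }
  }
  list(commands = cmds, formation = formation, prev_dirs = prev_dirs)
}
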