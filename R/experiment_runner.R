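# Configuration, seeding, logging and orchestration: wires the fly agent,
# controllers and task environments into reproducible experiments and feeds
# the metrics.

#' Build a validated experiment configuration
#'
#' @param task one of `"line"`, `"letters"`, `"maze"`, `"ball"`,
#'   `"formation"`, `"multifly_letters"`.
#' @param modality `"visual"` (pinwheel), `"olfactory"` (lateralized LEDs) or
#'   `"none"` (unguided control).
#' @param n_flies number of flies (>= 1; the formation task requires 6).
#' @param duration_s simulated duration (s, > 0).
#' @param dt tick (s); default 1/30 (a typical tracking-camera frame period).
#' @param seed integer seed; identical seed + config give identical logs.
#' @param params [behavior_params()], shared by all flies.
#' @param arena arena override (`NULL` = task default: the 43-cm square, or a
#'   21.5-cm-radius circle for olfactory runs).
#' @param task_args list of task options: `separation`, `radius`, `timeout_s`
#'   (line); `text`, `scale`, `origin` (letters tasks); `ball_x`, `ball_y`,
#'   `push` (ball); `pattern_a`, `pattern_b` (formation).
#' @param deadband controller deadband (rad).
#' @param d_max,i_min LED intensity scaling: saturation distance (cm,
#'   `NULL` = arena half-extent) and intensity floor.
#' @param load_mg cargo per fly (mg).
#' @param max_trials stop early once this many trials are recorded
#'   (`Inf` = run the full duration).
#' @param use_imaging_path close the loop through rendered frames and the
#'   blob tracker instead of the true state.
#' @param px_per_cm,noise_sd imaging-path rendering options.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(task = c("line", "letters", "maze", "ball",
                                       "formation", "multifly_letters"),
                              modality = c("visual", "olfactory", "none"),
                              n_flies = 1, duration_s = 600, dt = 1 / 30,
                              seed = 1, params = behavior_params(),
                              arena = NULL, task_args = list(),
                              deadband = 0.2, d_max = NULL, i_min = 0.2,
                              load_mg = 0, max_trials = Inf,
                              use_imaging_path = FALSE, px_per_cm = 10,
                              noise_sd = 0) {
  task <- match.arg(task)
  modality <- match.arg(modality)
  chk <- function(ok, field, msg) {
    if (!ok) stop("invalid config field `", field, "`: ", msg, call. = FALSE)
  }
  chk(is.numeric(n_flies) && n_flies >= 1, "n_flies", "must be >= 1")
  chk(is.numeric(duration_s) && duration_s > 0, "duration_s", "must be > 0")
  chk(is.numeric(dt) && dt > 0, "dt", "must be > 0")
  chk(is.numeric(seed) && length(seed) == 1 && is.finite(seed), "seed",
      "must be a single integer")
  chk(inherits(params, "behavior_params"), "params",
      "must be a behavior_params object")
  chk(is.numeric(load_mg) && load_mg >= 0, "load_mg", "must be >= 0")
  if (task == "formation") chk(n_flies == 6, "n_flies",
                               "formation control uses 6 flies")
  if (task %in% c("letters", "multifly_letters")) {
    txt <- task_args$text
    chk(!is.null(txt) && nchar(txt) > 0, "task_args$text",
        "letters tasks need non-empty text")
  }
  structure(list(task = task, modality = modality,
                 n_flies = as.integer(n_flies), duration_s = duration_s,
                 dt = dt, seed = as.integer(seed), params = params,
                 arena = arena, task_args = task_args, deadband = deadband,
                 d_max = d_max, i_min = i_min, load_mg = load_mg,
                 max_trials = max_trials,
                 use_imaging_path = isTRUE(use_imaging_path),
                 px_per_cm = px_per_cm, noise_sd = noise_sd),
            class = "experiment_config")
}

default_formation_patterns <- function(radius = 2, timeout_s = 120) {
  hexa <- function(r, phase) lapply(0:5, function(k) {
    th <- phase + k * pi / 3
    goal_spec(r * cos(th), r * sin(th), radius, timeout_s)
  })
  list(pattern_a = hexa(12, 0), pattern_b = hexa(7, pi / 6))
}

# build arena + task fixtures from a config
setup_task <- function(config) {
  ta <- config$task_args
  maze <- NULL
  arena <- config$arena
  if (config$task == "maze") {
    maze <- make_maze(goal_radius = ta$radius %||% 1.2,
                      timeout_s = ta$timeout_s %||% 60)
    arena <- maze$arena
    goals <- maze$goals
  } else {
    if (is.null(arena)) {
      arena <- if (config$modality == "olfactory") arena_circle() else arena_square()
    }
    goals <- switch(config$task,
      line = make_line_task(ta$separation %||% 13, arena,
                            ta$radius %||% 1.5, ta$timeout_s %||% 60),
      letters = ,
      multifly_letters = make_letter_waypoints(
        ta$text, ta$scale %||% 8,
        ta$origin %||% c(-0.45 * (if (arena$shape == "square") arena$side else 2 * arena$radius), 0),
        ta$radius %||% 1.5, ta$timeout_s %||% 60),
      ball = NULL,
      formation = NULL)
  }
  formation <- NULL
  if (config$task == "formation") {
    pats <- default_formation_patterns()
    formation <- formation_spec(ta$pattern_a %||% pats$pattern_a,
                                ta$pattern_b %||% pats$pattern_b)
  }
  ball <- NULL
  if (config$task == "ball") {
    ball <- ball_state(ta$ball_x %||% 0, ta$ball_y %||% 0)
  }
  list(arena = arena, goals = goals, maze = maze, formation = formation,
       ball = ball, push = ta$push %||% push_params())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# initial fly states: spread on a small circle around the arena center;
# maze flies start in the loop corridor, the ball-task fly away from the ball
initial_states <- function(config, env) {
  n <- config$n_flies
  lapply(seq_len(n), function(i) {
    th <- 2 * pi * (i - 1) / max(n, 1)
    if (config$task == "maze") {
      g <- env$goals[[((i - 1) %% length(env$goals)) + 1]]
      x <- g$x; y <- g$y + 0  # on the corridor centerline
      th <- atan2(g$x, -g$y)  # tangent to the loop, CCW
    } else if (config$task == "ball") {
      b <- env$ball
      x <- b$x - 10; y <- b$y
      if (!all(in_arena(env$arena, x, y, margin = 1))) { x <- b$x + 10 }
      th <- 0
    } else {
      r <- if (n == 1) 0 else 5
      x <- r * cos(th); y <- r * sin(th)
    }
    fly_state(id = i, x = x, y = y, heading = th,
              speed = config$params$v_mean, load_mg = config$load_mg)
  })
}

#' Run a closed-loop experiment
#'
#' Orchestrates one simulated experiment: every tick the controller reads each
#' fly's pose (directly, or through the rendered-frame tracker when
#' `use_imaging_path` is on), emits a stimulus command, and the fly model is
#' stepped; goal sequencers record trials under the 60-s rule; the ball task
#' additionally advances the pushable ball. All logs share one clock, and an
#' identical seed + config reproduces them exactly. Each fly draws from its
#' own RNG stream, so adding a fly leaves existing flies' trajectories
#' unchanged.
#'
#' @param config an [experiment_config()].
#' @return list of class `experiment_result`: `traj`, `commands`, `windows`,
#'   `trials`, `ball_log` (ball task only), `metrics` (fidelity + success
#'   summary), `arena`, `maze`, `formation` (final state), and `config`.
#' @export
run_experiment <- function(config) {
  if (!inherits(config, "experiment_config"))
    stop("config must be an experiment_config", call. = FALSE)
  env <- setup_task(config)
  arena <- env$arena
  n <- config$n_flies
  dt <- config$dt
  nt <- ceiling(config$duration_s / dt)
  params <- config$params
  streams <- make_rng_streams(config$seed, n)
  states <- initial_states(config, env)
  d_max <- config$d_max %||%
    (if (arena$shape == "square") arena$side / 2 else arena$radius)

  per_fly_seq <- config$task %in% c("line", "letters", "maze", "multifly_letters")
  seqs <- if (per_fly_seq)
    lapply(seq_len(n), function(i) new_goal_sequencer(env$goals, wrap = TRUE))
  formation <- env$formation
  ball <- env$ball
  prev_dirs <- rep(NA_character_, n)

  # multifly pen bookkeeping: pen i's last assigned position
  pens <- if (config$task == "multifly_letters")
    t(vapply(states, function(s) c(s$x, s$y), numeric(2))) else NULL

  # imaging path state
  tracks <- NULL
  thr <- NULL
  est <- t(vapply(states, function(s) c(s$x, s$y, s$heading), numeric(3)))

  # preallocated logs
  N <- nt * n
  L <- list(time_s = numeric(N), fly_id = integer(N), x = numeric(N),
            y = numeric(N), heading = numeric(N), speed = numeric(N),
            omega = numeric(N), mode = character(N))
  C <- list(time_s = numeric(N), fly_id = integer(N), modality = character(N),
            direction = character(N), intensity = numeric(N))
  B <- if (!is.null(ball)) list(time_s = numeric(nt), x = numeric(nt),
                                y = numeric(nt), event_flag = logical(nt))
  row <- 0L
  used_ticks <- nt

  for (k in seq_len(nt)) {
    t <- (k - 1) * dt

    if (config$use_imaging_path) {
      frame <- with_stream(streams, 0,
                           render_frame(states, arena, config$px_per_cm,
                                        config$noise_sd, ball = ball))
      if (is.null(thr)) thr <- frame_threshold(frame)
      dets <- detect_blobs(frame, thr)
      tracks <- update_tracks(dets, tracks,
                              max_jump = 3 * config$px_per_cm * dt *
                                max(params$v_mean, 1) + 5)
      if (nrow(tracks) > 0) {
        cm <- tracks_to_cm(tracks, arena, config$px_per_cm)
        # attach estimates to flies by nearest neighbor to previous estimate
        am <- assign_pens(cbind(cm$x, cm$y), est[, 1:2, drop = FALSE])
        for (f in seq_len(n)) {
          if (!is.na(am[f]))
            est[f, ] <- c(cm$x[am[f]], cm$y[am[f]], cm$heading[am[f]])
        }
      }
    } else {
      est <- t(vapply(states, function(s) c(s$x, s$y, s$heading), numeric(3)))
    }

    # nearest-neighbor distances (pinwheel overlap penalty)
    cf <- rep(1, n)
    if (n > 1 && config$modality == "visual") {
      for (f in seq_len(n)) {
        dmin <- min(sqrt((est[-f, 1] - est[f, 1])^2 +
                         (est[-f, 2] - est[f, 2])^2))
        if (dmin < 2 * params$pinwheel_radius_cm)
          cf[f] <- params$overlap_compliance_factor
      }
    }

    # --- controller ---
    cmds <- vector("list", n)
    if (config$task == "formation") {
      fc <- formation_controller(states, formation, config$deadband,
                                 prev_dirs, t)
      cmds <- fc$commands
      formation <- fc$formation
      prev_dirs <- fc$prev_dirs
    } else if (config$task == "multifly_letters") {
      am <- assign_pens(est[, 1:2, drop = FALSE], pens)
      for (p in seq_len(n)) {
        f <- am[p]
        if (is.na(f)) next
        g <- seqs[[p]]$update(t, est[f, 1], est[f, 2])
        pens[p, ] <- est[f, 1:2]
        if (is.null(g) || config$modality == "none") next
        err <- heading_error(est[f, 1], est[f, 2], est[f, 3], g)
        cmds[[f]] <- make_guidance_command(config, err, est[f, ], g, d_max,
                                           prev_dirs[f], f, t)
        if (cmds[[f]]$modality == "pinwheel") prev_dirs[f] <- cmds[[f]]$direction
      }
    } else {
      for (f in seq_len(n)) {
        g <- if (per_fly_seq) {
          seqs[[f]]$update(t, est[f, 1], est[f, 2])
        } else if (config$task == "ball") {
          goal_spec(ball$x, ball$y,
                    radius = ball$radius + env$push$contact_cm,
                    timeout_s = config$task_args$timeout_s %||% 60)
        }
        if (is.null(g) || config$modality == "none") next
        err <- heading_error(est[f, 1], est[f, 2], est[f, 3], g)
        cmds[[f]] <- make_guidance_command(config, err, est[f, ], g, d_max,
                                           prev_dirs[f], f, t)
        if (cmds[[f]]$modality == "pinwheel") prev_dirs[f] <- cmds[[f]]$direction
      }
    }

    # --- log pose + command, then step ---
    for (f in seq_len(n)) {
      row <- row + 1L
      s <- states[[f]]
      cmd <- cmds[[f]]
      L$time_s[row] <- t; L$fly_id[row] <- f
      L$x[row] <- s$x; L$y[row] <- s$y; L$heading[row] <- s$heading
      L$speed[row] <- if (s$mode == "walking") s$speed else 0
      L$mode[row] <- s$mode
      C$time_s[row] <- t; C$fly_id[row] <- f
      C$modality[row] <- if (is.null(cmd)) "none" else cmd$modality
      C$direction[row] <- if (is.null(cmd)) NA_character_ else cmd$direction
      C$intensity[row] <- if (is.null(cmd)) 0 else cmd$intensity
      states[[f]] <- with_stream(streams, f,
                                 step_fly(s, cmd, params, dt, arena = arena,
                                          compliance_factor = cf[f]))
      L$omega[row] <- states[[f]]$omega  # response during [t, t + dt)
    }

    if (!is.null(ball)) {
      ball <- with_stream(streams, 0,
                          ball_update(ball, states, dt, arena, env$push, t))
      B$time_s[k] <- t; B$x[k] <- ball$x; B$y[k] <- ball$y
      B$event_flag[k] <- isTRUE(attr(ball, "moved"))
    }

    if (per_fly_seq && is.finite(config$max_trials)) {
      ntr <- sum(vapply(seqs, function(sq) sq$n_trials(), integer(1)))
      if (ntr >= config$max_trials) { used_ticks <- k; break }
    }
  }

  keep <- seq_len(row)
  traj <- data.frame(time_s = L$time_s[keep], fly_id = L$fly_id[keep],
                     x = L$x[keep], y = L$y[keep], heading = L$heading[keep],
                     speed = L$speed[keep], omega = L$omega[keep],
                     mode = L$mode[keep])
  commands <- data.frame(time_s = C$time_s[keep], fly_id = C$fly_id[keep],
                         modality = C$modality[keep],
                         direction = C$direction[keep],
                         intensity = C$intensity[keep])
  windows <- segment_windows(commands, dt = dt)
  trials <- if (per_fly_seq) {
    tl <- lapply(seq_len(n), function(f) {
      tr <- seqs[[f]]$trials()
      if (nrow(tr) > 0) cbind(fly_id = f, tr) else NULL
    })
    tl <- tl[!vapply(tl, is.null, logical(1))]
    if (length(tl)) do.call(rbind, tl) else NULL
  }
  ball_log <- if (!is.null(ball)) {
    kk <- seq_len(used_ticks)
    data.frame(time_s = B$time_s[kk], x = B$x[kk], y = B$y[kk],
               event_flag = B$event_flag[kk])
  }

  fid <- fidelity_score(windows, traj)
  total_dist <- sum(vapply(split(traj[, c("x", "y")], traj$fly_id),
                           function(d) sum(sqrt(diff(d$x)^2 + diff(d$y)^2)),
                           numeric(1)))
  metrics <- list(fidelity = fid$score, fidelity_per_sign = fid$per_sign,
                  n_windows = fid$n_windows,
                  total_distance_cm = total_dist,
                  mean_speed_cms = mean(traj$speed))
  if (!is.null(trials) && nrow(trials) > 0) {
    metrics <- c(metrics,
                 success_metrics(trials, duration_s = used_ticks * dt))
  }
  if (!is.null(ball_log)) {
    metrics$ball <- ball_metrics(ball_log,
                                 event_threshold = env$push$event_threshold,
                                 quiescence_s = env$push$quiescence_s)
  }

  structure(list(traj = traj, commands = commands, windows = windows,
                 trials = trials, ball_log = ball_log, metrics = metrics,
                 arena = arena, maze = env$maze, formation = formation,
                 config = config),
            class = "experiment_result")
}

make_guidance_command <- function(config, err, pose, goal, d_max, prev, f, t) {
  if (config$modality == "visual") {
    pinwheel_command(err, config$deadband,
                     if (is.na(prev)) NULL else prev, f, t)
  } else {
    dist <- sqrt((goal$x - pose[1])^2 + (goal$y - pose[2])^2)
    led_command(err, dist, d_max, config$deadband, config$i_min, f, t)
  }
}

#' @export
print.experiment_result <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<experiment_result> task=%s modality=%s flies=%d\n",
              x$config$task, x$config$modality, x$config$n_flies))
  cat(sprintf("  windows=%d fidelity=%s\n", m$n_windows,
              ifelse(is.na(m$fidelity), "NA", sprintf("%.3f", m$fidelity))))
  if (!is.null(m$success_ratio))
    cat(sprintf("  trials=%d success_ratio=%.3f\n", m$n_trials,
                m$success_ratio))
  if (!is.null(m$ball))
    cat(sprintf("  ball: distance=%.1fcm events=%d cleared=%s\n",
                m$ball$total_distance_cm, m$ball$n_movement_events,
                m$ball$cleared))
  invisible(x)
}

#' Impulse-response stimulation protocol
#'
#' Open-loop calibration protocol: a single fly walking in a large open arena
#' receives a fixed-duration stimulus in a randomly chosen direction, followed
#' by a gap, repeated `n_windows` times. Each stimulus is one stimulation
#' window, so the resulting fidelity score is a direct binomial estimate of
#' the compliance probability.
#'
#' @param n_windows number of stimulations.
#' @param p_comply compliance probability used for both directions (overrides
#'   the modality's default in `params`).
#' @param modality `"visual"` or `"olfactory"`.
#' @param seed integer seed.
#' @param stim_s,gap_s stimulus and gap durations (s); the classic impulse
#'   protocol uses 2-s stimuli.
#' @param dt tick (s).
#' @param params [behavior_params()] (compliance fields are overridden by
#'   `p_comply`).
#' @return list with `windows`, `traj`, `fidelity` (the [fidelity_score()]
#'   list) and `commands`.
#' @export
run_impulse_protocol <- function(n_windows, p_comply, modality = "visual",
                                 seed = 1, stim_s = 2, gap_s = 1, dt = 1 / 30,
                                 params = behavior_params()) {
  params$p_comply_vis <- p_comply
  params$p_comply_red <- p_comply
  params$p_comply_blue <- p_comply
  streams <- make_rng_streams(seed, 1)
  s <- fly_state(id = 1, speed = params$v_mean)
  # integer tick bookkeeping avoids float drift at window boundaries
  stim_ticks <- max(1L, round(stim_s / dt))
  gap_ticks <- max(1L, round(gap_s / dt))
  period_ticks <- stim_ticks + gap_ticks
  nt <- n_windows * period_ticks
  C <- list(time_s = numeric(nt), fly_id = rep(1L, nt),
            modality = character(nt), direction = character(nt),
            intensity = rep(1, nt))
  om <- numeric(nt)
  dir_now <- NA_character_
  for (k in seq_len(nt)) {
    t <- (k - 1) * dt
    phase <- (k - 1) %% period_ticks
    if (phase < stim_ticks) {
      if (phase == 0) {  # new window: pick a random direction (stream 0)
        dir_now <- with_stream(streams, 0, {
          if (modality == "visual") sample(c("CW", "CCW"), 1)
          else sample(c("red", "blue"), 1)
        })
      }
      cmd <- stimulus_command(if (modality == "visual") "pinwheel" else "led",
                              dir_now, 1, 1L, t)
    } else cmd <- NULL
    C$time_s[k] <- t
    C$modality[k] <- if (is.null(cmd)) "none" else cmd$modality
    C$direction[k] <- if (is.null(cmd)) NA_character_ else cmd$direction
    s <- with_stream(streams, 1, step_fly(s, cmd, params, dt))
    om[k] <- s$omega
  }
  commands <- data.frame(time_s = C$time_s, fly_id = C$fly_id,
                         modality = C$modality, direction = C$direction,
                         intensity = C$intensity)
  traj <- data.frame(time_s = commands$time_s, fly_id = 1L, omega = om)
  windows <- segment_windows(commands, dt = dt)
  list(windows = windows, traj = traj,
       fidelity = fidelity_score(windows, traj), commands = commands)
}

#' Write and read experiment logs
#'
#' Logs are written as plain-text tab-separated tables, one file per log, each
#' with a two-line header: `# flysteer-log v1` and `# meta: <JSON>` (schema
#' version, seed, row count). `read_logs(write_logs(x))` is the identity on
#' all records; version mismatches and truncated files raise errors.
#'
#' @param result an `experiment_result` (or any list of data.frames under the
#'   names `traj`, `commands`, `windows`, `trials`, `ball_log`).
#' @param dir directory to write into (created if needed).
#' @return `write_logs`: `dir`, invisibly. `read_logs`: list of data.frames
#'   plus `meta`.
#' @export
write_logs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (!is.null(result$config)) result$config$seed else NA
  for (nm in c("traj", "commands", "windows", "trials", "ball_log")) {
    tab <- result[[nm]]
    if (is.null(tab)) next
    meta <- list(schema = "flysteer-log", version = 1L, table = nm,
                 seed = seed, n_rows = nrow(tab))
    path <- file.path(dir, paste0(nm, ".tsv"))
    con <- file(path, "w")
    writeLines(c("# flysteer-log v1",
                 paste0("# meta: ", jsonlite::toJSON(meta, auto_unbox = TRUE))),
               con)
    utils::write.table(tab, con, sep = "\t", row.names = FALSE, quote = FALSE)
    close(con)
  }
  if (!is.null(result$metrics)) {
    jsonlite::write_json(result$metrics, file.path(dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  invisible(dir)
}

#' @rdname write_logs
#' @export
read_logs <- function(dir) {
  out <- list()
  for (nm in c("traj", "commands", "windows", "trials", "ball_log")) {
    path <- file.path(dir, paste0(nm, ".tsv"))
    if (!file.exists(path)) next
    hdr <- readLines(path, n = 2)
    if (length(hdr) < 2 || hdr[1] != "# flysteer-log v1")
      stop("schema mismatch in ", path, ": expected `# flysteer-log v1`, got `",
           if (length(hdr) >= 1) hdr[1] else "", "`", call. = FALSE)
    meta <- jsonlite::fromJSON(sub("^# meta: ", "", hdr[2]))
    tab <- utils::read.delim(path, comment.char = "#",
                             stringsAsFactors = FALSE)
    if (nrow(tab) != meta$n_rows)
      stop("truncated log ", path, ": header declares ", meta$n_rows,
           " rows, found ", nrow(tab), call. = FALSE)
    out[[nm]] <- tab
    out$meta <- meta[c("schema", "version", "seed")]
  }
  mpath <- file.path(dir, "metrics.json")
  if (file.exists(mpath)) out$metrics <- jsonlite::fromJSON(mpath)
  out
}
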