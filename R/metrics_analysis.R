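# Quantitative readouts: fidelity score, success metrics, occupancy
# heatmaps, grouped fidelity time courses, ball statistics and multi-fly
# proximity analyses.

#' Fidelity score over stimulation windows
#'
#' A window is scored correct when the sign of the fly's mean angular velocity
#' over the window equals the commanded sign; windows with exactly zero mean
#' are scored incorrect (conservative). The fidelity score is the fraction of
#' correct windows — the proportion of accurate turns relative to the total
#' stimulations.
#'
#' @param windows data.frame from [segment_windows()] (columns `fly_id`,
#'   `start_s`, `end_s`, `commanded_sign`, `modality`).
#' @param traj data.frame with columns `time_s`, `fly_id`, `omega`
#'   (the stimulus-evoked angular velocity trace).
#' @param by_fly if `TRUE`, also average per fly before pooling (per-fly mode);
#'   default pools all windows.
#' @return list with `score` (pooled fraction), `per_sign` (named vector:
#'   fraction for +1/left and -1/right windows), `verdicts` (logical per
#'   window), and `n_windows`. `score` is `NA` with zero windows.
#' @export
fidelity_score <- function(windows, traj, by_fly = FALSE) {
  if (nrow(windows) == 0) {
    return(list(score = NA_real_, per_sign = c(`+1` = NA_real_, `-1` = NA_real_),
                verdicts = logical(0), n_windows = 0L))
  }
  verdicts <- logical(nrow(windows))
  for (fid in unique(windows$fly_id)) {
    tr <- traj[traj$fly_id == fid, ]
    o <- order(tr$time_s)
    tt <- tr$time_s[o]
    cs <- c(0, cumsum(tr$omega[o]))
    wi <- which(windows$fly_id == fid)
    i0 <- findInterval(windows$start_s[wi] - 1e-9, tt) + 1L
    i1 <- findInterval(windows$end_s[wi] - 1e-9, tt)
    ok <- i1 >= i0
    m <- rep(0, length(wi))
    m[ok] <- (cs[i1[ok] + 1L] - cs[i0[ok]]) / (i1[ok] - i0[ok] + 1L)
    verdicts[wi] <- ok & m != 0 & sign(m) == windows$commanded_sign[wi]
  }
  per_sign <- c(`+1` = mean(verdicts[windows$commanded_sign == 1]),
                `-1` = mean(verdicts[windows$commanded_sign == -1]))
  score <- if (by_fly) {
    mean(tapply(verdicts, windows$fly_id, mean))
  } else mean(verdicts)
  list(score = score, per_sign = per_sign, verdicts = verdicts,
       n_windows = nrow(windows))
}

#' Success metrics over trial records
#'
#' success ratio = successful trials / total trials; the hourly rate is
#' successes per hour of experiment; time and distance per trial are means
#' over successful trials.
#'
#' @param trials data.frame of trial records (columns `start_s`, `end_s`,
#'   `success`, `path_length_cm`).
#' @param duration_s total experiment duration (s); defaults to the span of
#'   the trial records.
#' @return list with `success_ratio`, `n_success`, `n_trials`,
#'   `hourly_success_rate`, `time_per_trial_s`, `distance_per_trial_cm`.
#' @export
success_metrics <- function(trials, duration_s = NULL) {
  if (nrow(trials) == 0) stop("at least one trial is required", call. = FALSE)
  if (is.null(duration_s))
    duration_s <- max(trials$end_s) - min(trials$start_s)
  if (duration_s <= 0) stop("experiment duration must be > 0", call. = FALSE)
  n_success <- sum(trials$success)
  ok <- trials$success
  list(success_ratio = n_success / nrow(trials),
       n_success = n_success,
       n_trials = nrow(trials),
       hourly_success_rate = n_success / (duration_s / 3600),
       time_per_trial_s = if (n_success > 0)
         mean(trials$end_s[ok] - trials$start_s[ok]) else NA_real_,
       distance_per_trial_cm = if (n_success > 0)
         mean(trials$path_length_cm[ok]) else NA_real_)
}

#' Occupancy probability heatmap
#'
#' Bins trajectory samples on a regular grid over the arena's bounding box;
#' counts are normalized to a probability mass function (sums to 1).
#'
#' @param traj data.frame with columns `x`, `y` (cm).
#' @param arena the arena defining the extent.
#' @param bin_cm bin side (cm).
#' @return matrix of probabilities with `xbreaks`/`ybreaks` attributes; rows
#'   index x bins, columns y bins.
#' @export
occupancy_heatmap <- function(traj, arena, bin_cm = 1) {
  if (nrow(traj) == 0) stop("trajectory must be non-empty", call. = FALSE)
  h <- if (arena$shape == "square") arena$side / 2 else arena$radius
  br <- seq(-h, h, by = bin_cm)
  if (br[length(br)] < h) br <- c(br, h)
  ix <- pmin(pmax(findInterval(traj$x, br, all.inside = TRUE), 1), length(br) - 1)
  iy <- pmin(pmax(findInterval(traj$y, br, all.inside = TRUE), 1), length(br) - 1)
  m <- matrix(0, length(br) - 1, length(br) - 1)
  tab <- table(factor(ix, levels = seq_len(nrow(m))),
               factor(iy, levels = seq_len(ncol(m))))
  m[] <- as.numeric(tab) / nrow(traj)
  attr(m, "xbreaks") <- br
  attr(m, "ybreaks") <- br
  m
}

#' Fidelity time course over consecutive window groups
#'
#' Splits windows (time-ordered) into `n_groups` consecutive groups of
#' equal-as-possible size (earlier groups take the remainder) and scores each
#' group, exposing drift or fatigue in compliance over the experiment.
#'
#' @param verdicts logical vector of per-window verdicts (time-ordered), e.g.
#'   from [fidelity_score()].
#' @param n_groups number of groups (default 10).
#' @return data.frame with `group`, `n`, `score`.
#' @export
#' @examples
#' group_fidelity(rep(c(TRUE, FALSE), 75), n_groups = 10)  # groups of 15
group_fidelity <- function(verdicts, n_groups = 10) {
  n <- length(verdicts)
  if (n < n_groups)
    stop("fewer windows (", n, ") than groups (", n_groups, ")", call. = FALSE)
  base <- n %/% n_groups
  rem <- n %% n_groups
  sizes <- rep(base, n_groups) + c(rep(1, rem), rep(0, n_groups - rem))
  grp <- rep(seq_len(n_groups), times = sizes)
  data.frame(group = seq_len(n_groups), n = sizes,
             score = as.numeric(tapply(verdicts, grp, mean)))
}

#' Ball relocation metrics
#'
#' @param ball_log data.frame with columns `time_s`, `x`, `y` (time-ordered
#'   ball positions).
#' @param clearing_radius_cm radius of the clearing zone around the arena
#'   center (cm); the ball is cleared when its final position lies outside.
#' @param event_threshold,quiescence_s movement-event definition: a bout of
#'   motion (separated from the previous bout by at least `quiescence_s`
#'   without displacement) counts as an event once its path length exceeds
#'   `event_threshold` (cm).
#' @return list with `total_distance_cm`, `n_movement_events`, `cleared`
#'   (logical), and `final_displacement_cm` from the arena center.
#' @export
ball_metrics <- function(ball_log, clearing_radius_cm = 5,
                         event_threshold = 0.5, quiescence_s = 2) {
  if (is.unsorted(ball_log$time_s))
    stop("ball log must be time-ordered", call. = FALSE)
  n <- nrow(ball_log)
  if (n < 2) {
    return(list(total_distance_cm = 0, n_movement_events = 0L,
                cleared = FALSE, final_displacement_cm =
                  if (n == 1) sqrt(ball_log$x^2 + ball_log$y^2) else NA_real_))
  }
  steps <- sqrt(diff(ball_log$x)^2 + diff(ball_log$y)^2)
  total <- sum(steps)
  # movement events: bouts of motion separated by >= quiescence_s of rest
  events <- 0L
  bout <- 0
  counted <- FALSE
  last_move <- -Inf
  tmid <- ball_log$time_s[-1]
  for (i in seq_along(steps)) {
    if (steps[i] <= 0) next
    if (tmid[i] - last_move > quiescence_s) { bout <- 0; counted <- FALSE }
    bout <- bout + steps[i]
    if (!counted && bout > event_threshold) {
      events <- events + 1L
      counted <- TRUE
    }
    last_move <- tmid[i]
  }
  fin <- sqrt(ball_log$x[n]^2 + ball_log$y[n]^2)
  list(total_distance_cm = total, n_movement_events = events,
       cleared = fin > clearing_radius_cm, final_displacement_cm = fin)
}

#' Proximity analyses for multi-fly experiments
#'
#' Relates guidance performance to crowding: (i) the mean window fidelity as a
#' function of the binned distance to the nearest other fly (window midpoint
#' distance), and (ii) the fraction of time flies are actively moving
#' (speed above `moving_threshold`) per distance bin. Distances below twice
#' the pinwheel radius correspond to full pinwheel overlap.
#'
#' @param traj multi-fly trajectory data.frame (columns `time_s`, `fly_id`,
#'   `x`, `y`, `speed`).
#' @param windows window data.frame ([segment_windows()]).
#' @param verdicts logical per-window verdicts ([fidelity_score()]).
#' @param pinwheel_radius_cm pinwheel radius (cm); a bin edge is placed at
#'   twice this value.
#' @param bin_cm distance bin width (cm).
#' @param moving_threshold speed above which a fly counts as moving (cm/s).
#' @return list of two data.frames: `fidelity_by_distance` (`bin_lo`,
#'   `bin_hi`, `n`, `fidelity`, `overlap`) and `moving_by_distance` (`bin_lo`,
#'   `bin_hi`, `n`, `moving_fraction`, `overlap`).
#' @export
proximity_analyses <- function(traj, windows, verdicts,
                               pinwheel_radius_cm = 2.5, bin_cm = 2,
                               moving_threshold = 0.2) {
  ids <- sort(unique(traj$fly_id))
  if (length(ids) < 2) stop("at least two flies are required", call. = FALSE)
  times <- sort(unique(traj$time_s))
  # nearest-other-fly distance per (time, fly)
  wide_x <- matrix(NA_real_, length(times), length(ids))
  wide_y <- wide_x
  wide_v <- wide_x
  ti <- match(traj$time_s, times)
  fi <- match(traj$fly_id, ids)
  wide_x[cbind(ti, fi)] <- traj$x
  wide_y[cbind(ti, fi)] <- traj$y
  wide_v[cbind(ti, fi)] <- traj$speed
  nd <- matrix(Inf, length(times), length(ids))
  for (a in seq_along(ids)) for (b in seq_along(ids)) {
    if (a == b) next
    d <- sqrt((wide_x[, a] - wide_x[, b])^2 + (wide_y[, a] - wide_y[, b])^2)
    nd[, a] <- pmin(nd[, a], d, na.rm = TRUE)
  }
  dmax <- max(nd[is.finite(nd)])
  edges <- sort(unique(c(seq(0, dmax + bin_cm, by = bin_cm),
                         2 * pinwheel_radius_cm)))
  bin_of <- function(d) pmin(pmax(findInterval(d, edges, all.inside = TRUE), 1),
                             length(edges) - 1)
  # (i) fidelity vs nearest-fly distance at the window midpoint
  wbin <- integer(nrow(windows))
  for (i in seq_len(nrow(windows))) {
    mid <- (windows$start_s[i] + windows$end_s[i]) / 2
    k <- which.min(abs(times - mid))
    f <- match(windows$fly_id[i], ids)
    wbin[i] <- bin_of(nd[k, f])
  }
  nb <- length(edges) - 1
  fid <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                    n = tabulate(wbin, nb),
                    fidelity = vapply(seq_len(nb), function(b)
                      if (any(wbin == b)) mean(verdicts[wbin == b]) else NA_real_,
                      numeric(1)))
  fid$overlap <- fid$bin_hi <= 2 * pinwheel_radius_cm
  # (ii) moving-time fraction vs distance
  sbin <- bin_of(as.vector(nd))
  moving <- as.vector(wide_v) > moving_threshold
  keep <- is.finite(as.vector(nd)) & !is.na(moving)
  mv <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                   n = tabulate(sbin[keep], nb),
                   moving_fraction = vapply(seq_len(nb), function(b) {
                     s <- keep & sbin == b
                     if (any(s)) mean(moving[s]) else NA_real_
                   }, numeric(1)))
  mv$overlap <- mv$bin_hi <= 2 * pinwheel_radius_cm
  list(fidelity_by_distance = fid, moving_by_distance = mv)
}
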