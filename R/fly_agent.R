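# Stochastic 2D walking-fly agent: converts stimulus commands into turning,
# pausing and halting with tunable per-stimulation compliance.

#' Fly body dimensions
#'
#' The adult body is about 1.5 mm wide by 2.5 mm long; these dimensions set
#' the rendered ellipse in [render_frame()] and the body-length unit used to
#' express carried distances (e.g. 500 m of cargo transport is
#' `50000 / fly_body_cm()["length"]` = 200,000 body lengths).
#'
#' @return named numeric vector `c(length = 0.25, width = 0.15)` in cm.
#' @export
fly_body_cm <- function() c(length = 0.25, width = 0.15)

#' Behavioral parameters of the simulated fly
#'
#' Bundles every tunable of the walking-fly model. Defaults are plausible
#' walking-*Drosophila* magnitudes; the two compliance probabilities default to
#' the empirical anchors of the two guidance modalities (~0.94 visual, ~0.80
#' olfactory).
#'
#' @param v_mean,v_sd mean and stationary SD of forward walking speed (cm/s).
#'   Speed follows an Ornstein-Uhlenbeck relaxation (1 s time constant).
#' @param sigma_heading heading diffusion coefficient (rad/sqrt(s)); Brownian
#'   jitter added to the heading on top of the stimulus-evoked turning.
#' @param p_pause,p_resume per-second probabilities of walk->pause and
#'   pause->walk transitions.
#' @param p_comply_vis per-stimulation-window probability of following a
#'   pinwheel command.
#' @param p_comply_red,p_comply_blue per-window probabilities of following
#'   red- and blue-LED turn commands.
#' @param omega_gain saturated magnitude of the commanded turn (rad/s).
#' @param tau_on,tau_off first-order onset and decay time constants of the
#'   turn kernel (s).
#' @param counterturn_gain,counterturn_dur magnitude (rad/s) and duration (s)
#'   of the opposite-signed counterturn after an olfactory light offset.
#' @param halt_latency delay between a halt-laser command and full stop (s).
#' @param load_knee_mg load (mg) at which performance drops sharply.
#' @param load_slope post-knee decline of the speed/compliance multipliers
#'   (per mg).
#' @param wall_follow_prob probability of aligning to the wall tangent (rather
#'   than reflecting) on boundary contact.
#' @param pinwheel_radius_cm radius of the projected pinwheel; two flies closer
#'   than twice this radius have fully overlapping pinwheels.
#' @param overlap_compliance_factor multiplicative compliance penalty applied
#'   while pinwheels overlap.
#' @return an object of class `behavior_params` (a validated list).
#' @export
#' @examples
#' p <- behavior_params(p_comply_vis = 1, sigma_heading = 0)
#' p$omega_gain
behavior_params <- function(v_mean = 1.5, v_sd = 0.5, sigma_heading = 0.5,
                            p_pause = 0.05, p_resume = 0.5,
                            p_comply_vis = 0.94,
                            p_comply_red = 0.8, p_comply_blue = 0.8,
                            omega_gain = 2, tau_on = 0.3, tau_off = 0.5,
                            counterturn_gain = 1.5, counterturn_dur = 1.0,
                            halt_latency = 0.2,
                            load_knee_mg = 1.1, load_slope = 0.4,
                            wall_follow_prob = 0.8,
                            pinwheel_radius_cm = 2.5,
                            overlap_compliance_factor = 0.8) {
  p <- list(v_mean = v_mean, v_sd = v_sd, sigma_heading = sigma_heading,
            p_pause = p_pause, p_resume = p_resume,
            p_comply_vis = p_comply_vis, p_comply_red = p_comply_red,
            p_comply_blue = p_comply_blue, omega_gain = omega_gain,
            tau_on = tau_on, tau_off = tau_off,
            counterturn_gain = counterturn_gain,
            counterturn_dur = counterturn_dur, halt_latency = halt_latency,
            load_knee_mg = load_knee_mg, load_slope = load_slope,
            wall_follow_prob = wall_follow_prob,
            pinwheel_radius_cm = pinwheel_radius_cm,
            overlap_compliance_factor = overlap_compliance_factor)
  probs <- c(p_pause = p_pause, p_resume = p_resume,
             p_comply_vis = p_comply_vis, p_comply_red = p_comply_red,
             p_comply_blue = p_comply_blue,
             wall_follow_prob = wall_follow_prob,
             overlap_compliance_factor = overlap_compliance_factor)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "),
         call. = FALSE)
  if (tau_on <= 0 || tau_off <= 0 || counterturn_dur <= 0)
    stop("time constants must be > 0", call. = FALSE)
  if (omega_gain <= 0) stop("omega_gain must be > 0", call. = FALSE)
  if (v_mean < 0 || v_sd < 0 || sigma_heading < 0 || load_knee_mg < 0 ||
      load_slope < 0 || halt_latency < 0)
    stop("kinematic parameters must be non-negative", call. = FALSE)
  structure(p, class = "behavior_params")
}

#' Construct the state of one simulated fly
#'
#' @param id integer fly identifier (>= 1).
#' @param x,y position (cm), arena-centered coordinates.
#' @param heading heading angle (rad, CCW from +x); wrapped to (-pi, pi].
#' @param speed forward speed (cm/s, >= 0).
#' @param omega stimulus-evoked angular velocity (rad/s).
#' @param mode one of `"walking"`, `"paused"`, `"halted"`.
#' @param load_mg attached mass (mg, >= 0).
#' @param time_s simulation clock (s).
#' @return an object of class `fly_state`.
#' @export
fly_state <- function(id = 1L, x = 0, y = 0, heading = 0, speed = 1.5,
                      omega = 0, mode = c("walking", "paused", "halted"),
                      load_mg = 0, time_s = 0) {
  mode <- match.arg(mode)
  stopifnot_finite(c(x, y, heading, speed, omega, load_mg, time_s),
                   "fly state fields")
  if (speed < 0) stop("speed must be >= 0", call. = FALSE)
  if (load_mg < 0) stop("load_mg must be >= 0", call. = FALSE)
  if (mode == "halted") { speed <- 0; omega <- 0 }
  structure(list(id = as.integer(id), x = x, y = y,
                 heading = wrap_angle(heading), speed = speed, omega = omega,
                 mode = mode, load_mg = load_mg, time_s = time_s,
                 stim = NULL, offstim = NULL, halt_on = NULL),
            class = "fly_state")
}

#' @export
print.fly_state <- function(x, ...) {
  cat(sprintf("<fly_state> id=%d t=%.2fs pos=(%.2f, %.2f)cm heading=%.2frad speed=%.2fcm/s mode=%s load=%.2fmg\n",
              x$id, x$time_s, x$x, x$y, x$heading, x$speed, x$mode, x$load_mg))
  invisible(x)
}

#' Optomotor turn response to a rotating pinwheel
#'
#' A clockwise pinwheel drives a right turn (negative angular velocity under
#' the CCW-positive convention) and a counter-clockwise pinwheel a left turn.
#' The response is a first-order lag, `omega_gain * (1 - exp(-t / tau_on))`,
#' signed by the rotation direction; a failed compliance draw inverts the
#' sign. After the stimulus ends the response decays with `tau_off`.
#'
#' @param direction `"CW"` or `"CCW"` pinwheel rotation.
#' @param comply logical; the per-window compliance draw.
#' @param t_since_onset time since stimulus onset (s); when `t_since_offset`
#'   is given this is the total stimulus duration.
#' @param params [behavior_params()].
#' @param t_since_offset time since stimulus offset (s), or `NULL` while the
#'   stimulus is on.
#' @return angular velocity contribution (rad/s).
#' @export
#' @examples
#' p <- behavior_params()
#' optomotor_response("CCW", TRUE, 10, p)  # ~ +omega_gain
optomotor_response <- function(direction, comply, t_since_onset, params,
                               t_since_offset = NULL) {
  if (!direction %in% c("CW", "CCW"))
    stop("unknown pinwheel direction: ", direction, call. = FALSE)
  if (t_since_onset < 0) stop("t_since_onset must be >= 0", call. = FALSE)
  s <- if (direction == "CCW") 1 else -1
  if (!comply) s <- -s
  amp <- s * params$omega_gain * (1 - exp(-t_since_onset / params$tau_on))
  if (is.null(t_since_offset)) amp else amp * exp(-t_since_offset / params$tau_off)
}

#' Osmotropotaxis turn response to lateralized optogenetic light
#'
#' Red light triggers right turns (negative omega), blue light left turns
#' (positive omega), scaled by the commanded intensity; simultaneous red+blue
#' activation is bilaterally symmetric and contributes no net turn. After
#' light offset the on-response decays with `tau_off` and an opposite-signed
#' counterturn of magnitude `counterturn_gain` lasts `counterturn_dur`,
#' mimicking the local-search counterturn seen at light offset.
#'
#' @param channel `"red"`, `"blue"` or `"both"`.
#' @inheritParams optomotor_response
#' @param intensity commanded light intensity in `[0, 1]`.
#' @return angular velocity contribution (rad/s).
#' @export
osmotropotaxis_response <- function(channel, comply, t_since_onset, params,
                                    t_since_offset = NULL, intensity = 1) {
  if (!channel %in% c("red", "blue", "both"))
    stop("unknown LED channel: ", channel, call. = FALSE)
  if (t_since_onset < 0) stop("t_since_onset must be >= 0", call. = FALSE)
  s <- switch(channel, blue = 1, red = -1, both = 0)
  if (s == 0) return(0)
  if (!comply) s <- -s
  amp <- s * params$omega_gain * intensity *
    (1 - exp(-t_since_onset / params$tau_on))
  if (is.null(t_since_offset)) return(amp)
  out <- amp * exp(-t_since_offset / params$tau_off)
  if (t_since_offset < params$counterturn_dur)
    out <- out - s * params$counterturn_gain * intensity
  out
}

#' Load-dependent performance degradation
#'
#' Returns multiplicative penalties on walking speed and compliance for a fly
#' carrying `load_mg` of cargo: identity at zero load, a shallow decline
#' (0.05/mg) up to the knee, and a sharp decline (`load_slope`/mg) beyond it,
#' floored at 0.05 so multipliers stay in (0, 1].
#'
#' @param load_mg attached mass (mg, >= 0).
#' @param params [behavior_params()] (uses `load_knee_mg`, `load_slope`).
#' @return named numeric vector `c(speed = ..., compliance = ...)`.
#' @export
#' @examples
#' load_effect(0, behavior_params())    # c(1, 1)
#' load_effect(2.5, behavior_params())  # well below the 1.1 mg value
load_effect <- function(load_mg, params) {
  if (any(load_mg < 0)) stop("load_mg must be >= 0", call. = FALSE)
  knee <- params$load_knee_mg
  pre <- 0.05
  m <- ifelse(load_mg <= knee,
              1 - pre * load_mg,
              1 - pre * knee - params$load_slope * (load_mg - knee))
  m <- pmax(m, 0.05)
  c(speed = unname(m), compliance = unname(m))
}

# +1 for left/CCW/blue, -1 for right/CW/red, 0 for neutral (both LEDs)
command_sign <- function(command) {
  switch(command$direction, CCW = 1, blue = 1, CW = -1, red = -1, both = 0,
         stop("unknown command direction: ", command$direction, call. = FALSE))
}

# close the active stimulation window: freeze the response amplitude at
# offset so it can decay (and, for LEDs, counterturn) in subsequent ticks
end_stimulus <- function(state, t, params) {
  st <- state$stim
  dur <- t - st$t_on
  s_eff <- if (st$comply) st$sign else -st$sign
  scale <- if (st$modality == "led") st$intensity else 1
  amp <- s_eff * params$omega_gain * scale * (1 - exp(-dur / params$tau_on))
  state$offstim <- list(amp = amp, t0 = t, modality = st$modality,
                        intensity = st$intensity)
  state$stim <- NULL
  state
}

#' Advance one fly by one time step
#'
#' Integrates the fly model over `dt`: stimulation-window bookkeeping (one
#' compliance draw per maximal constant-command window; a failed draw inverts
#' the commanded turn), the turn kernel and post-offset dynamics, pause/resume
#' mode transitions, halting, Brownian heading jitter, forward displacement,
#' load effects and arena collision resolution with wall following.
#'
#' Order of kinematic updates: the heading is advanced first
#' (`heading + omega * dt` + jitter), then the position by
#' `speed * dt` along the new heading, then collisions are resolved.
#' Draws come from the calling RNG state; wrap calls in [with_stream()] to use
#' a dedicated per-fly stream.
#'
#' @param state a [fly_state()].
#' @param command a [stimulus_command()] or `NULL` (no stimulus).
#' @param params [behavior_params()].
#' @param dt time step (s, > 0).
#' @param arena optional arena (see [arena_square()]); when given, the
#'   proposed position is collision-resolved against walls and boundary.
#' @param compliance_factor extra multiplicative compliance penalty applied to
#'   windows opened this tick (e.g. pinwheel overlap with a neighbor).
#' @return the advanced `fly_state`.
#' @export
#' @examples
#' s <- fly_state(x = 0, y = 0, heading = 0, speed = 1)
#' p <- behavior_params(sigma_heading = 0, v_sd = 0, v_mean = 1, p_pause = 0)
#' step_fly(s, NULL, p, dt = 1)  # walks to (1, 0)
step_fly <- function(state, command = NULL, params = behavior_params(),
                     dt, arena = NULL, compliance_factor = 1) {
  if (!inherits(state, "fly_state")) stop("state must be a fly_state", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1 || !is.finite(dt) || dt <= 0)
    stop("dt must be a positive number", call. = FALSE)
  stopifnot_finite(c(state$x, state$y, state$heading, state$speed),
                   "fly state fields")
  t <- state$time_s
  lm <- load_effect(state$load_mg, params)

  modality <- if (is.null(command)) "none" else command$modality
  if (modality == "halt_laser") {
    if (is.null(state$halt_on)) state$halt_on <- t
    if (t - state$halt_on >= params$halt_latency) state$mode <- "halted"
    if (!is.null(state$stim)) state <- end_stimulus(state, t, params)
  } else {
    state$halt_on <- NULL
    if (modality %in% c("pinwheel", "led")) {
      # an incoming guidance command releases a halted fly; with no command
      # the halt persists
      if (state$mode == "halted") state$mode <- "walking"
      sgn <- command_sign(command)
      if (sgn == 0) {
        # both LEDs on: bilateral, no net drive; closes any signed window
        if (!is.null(state$stim)) state <- end_stimulus(state, t, params)
      } else {
        new_window <- is.null(state$stim) ||
          state$stim$modality != modality || state$stim$sign != sgn
        if (new_window) {
          # a direct command reversal replaces the reflexive response: the
          # response tracks the currently displayed stimulus, so no decaying
          # remnant of the old direction is carried into the new window
          state$stim <- NULL
          state$offstim <- NULL
          p <- switch(modality,
                      pinwheel = params$p_comply_vis,
                      led = if (command$direction == "red")
                        params$p_comply_red else params$p_comply_blue)
          p <- clamp(p * lm[["compliance"]] * compliance_factor, 0, 1)
          state$stim <- list(modality = modality, sign = sgn,
                             direction = command$direction,
                             intensity = command$intensity, t_on = t,
                             comply = (stats::runif(1) < p))
        } else {
          state$stim$intensity <- command$intensity
        }
      }
    } else if (!is.null(state$stim)) {
      state <- end_stimulus(state, t, params)
    }
  }

  if (state$mode == "walking") {
    if (params$p_pause > 0 && stats::runif(1) < params$p_pause * dt)
      state$mode <- "paused"
  } else if (state$mode == "paused") {
    if (stats::runif(1) < params$p_resume * dt) state$mode <- "walking"
  }

  # responses evaluated at the tick midpoint (midpoint rule; also gives a
  # nonzero, correctly-signed drive on the first tick of a window)
  omega <- 0
  if (!is.null(state$stim)) {
    tso <- t - state$stim$t_on + dt / 2
    omega <- omega + if (state$stim$modality == "pinwheel") {
      optomotor_response(state$stim$direction, state$stim$comply, tso, params)
    } else {
      osmotropotaxis_response(state$stim$direction, state$stim$comply, tso,
                              params, intensity = state$stim$intensity)
    }
  }
  if (!is.null(state$offstim)) {
    toff <- t - state$offstim$t0 + dt / 2
    tail_w <- state$offstim$amp * exp(-toff / params$tau_off)
    if (state$offstim$modality == "led" && state$offstim$amp != 0 &&
        toff < params$counterturn_dur) {
      tail_w <- tail_w - sign(state$offstim$amp) * params$counterturn_gain *
        state$offstim$intensity
    }
    omega <- omega + tail_w
    if (toff > 5 * params$tau_off && toff >= params$counterturn_dur)
      state$offstim <- NULL
  }

  if (state$mode == "halted") {
    state$omega <- 0
    state$speed <- 0
  } else {
    state$omega <- omega
    if (state$mode == "walking") {
      jitter <- if (params$sigma_heading > 0)
        stats::rnorm(1, 0, params$sigma_heading * sqrt(dt)) else 0
      state$heading <- wrap_angle(state$heading + omega * dt + jitter)
      v_eff <- state$speed * lm[["speed"]]
      prop <- c(state$x + v_eff * dt * cos(state$heading),
                state$y + v_eff * dt * sin(state$heading))
      if (!is.null(arena)) {
        res <- resolve_collision(c(state$x, state$y), prop, arena)
        if (res$contact) {
          tang <- atan2(res$tangent[2], res$tangent[1])
          if (stats::runif(1) < params$wall_follow_prob) {
            # align along the wall, choosing the tangent direction nearer the
            # current heading
            if (abs(wrap_angle(tang - state$heading)) > pi / 2)
              tang <- wrap_angle(tang + pi)
            state$heading <- tang
          } else {
            # specular reflection about the wall tangent
            state$heading <- wrap_angle(2 * tang - state$heading)
          }
        }
        state$x <- res$pos[1]
        state$y <- res$pos[2]
      } else {
        state$x <- prop[1]
        state$y <- prop[2]
      }
      # OU relaxation of speed toward v_mean (1 s time constant), applied
      # after the displacement so the step uses the pre-update speed
      if (params$v_sd > 0 || state$speed != params$v_mean) {
        ddt <- min(dt, 1)
        z <- if (params$v_sd > 0) stats::rnorm(1) else 0
        state$speed <- max(0, state$speed +
                             (params$v_mean - state$speed) * ddt +
                             params$v_sd * sqrt(2 * ddt) * z)
      }
    }
  }

  state$time_s <- t + dt
  state
}
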