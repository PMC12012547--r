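# Geometry and physics of the guidance tasks: arenas, the 13-cm A/B line
# task, stroke-font letter waypoints, the 12-goal looping maze, wall
# collision resolution, and the pushable 10 mg ball.

#' Square and circular arenas
#'
#' Arena-centered coordinates (origin at the arena center). The square arena
#' defaults to the 43-cm experimental arena; the circular arena to the
#' equivalent 21.5-cm radius. `walls` holds interior wall segments (one row
#' per segment, columns `x1, y1, x2, y2`), used by mazes.
#'
#' @param side square side length (cm).
#' @param radius circle radius (cm).
#' @param walls data.frame of interior wall segments, or `NULL`.
#' @return an object of class `arena`.
#' @export
arena_square <- function(side = 43, walls = NULL) {
  stopifnot(side > 0)
  a <- structure(list(shape = "square", side = side,
                      walls = validate_walls(walls, side / 2)),
                 class = "arena")
  a$wall_mat <- rbind(as.matrix(a$walls),
                      as.matrix(boundary_segments(a)))
  a
}

#' @rdname arena_square
#' @export
arena_circle <- function(radius = 21.5, walls = NULL) {
  stopifnot(radius > 0)
  a <- structure(list(shape = "circle", radius = radius,
                      walls = validate_walls(walls, radius)),
                 class = "arena")
  a$wall_mat <- as.matrix(a$walls)
  dimnames(a$wall_mat) <- NULL
  a
}

validate_walls <- function(walls, half_extent) {
  if (is.null(walls) || nrow(walls) == 0) {
    return(data.frame(x1 = numeric(), y1 = numeric(),
                      x2 = numeric(), y2 = numeric()))
  }
  walls <- as.data.frame(walls)[, c("x1", "y1", "x2", "y2")]
  if (any(walls$x1 == walls$x2 & walls$y1 == walls$y2))
    stop("degenerate wall segment", call. = FALSE)
  if (any(abs(as.matrix(walls)) > half_extent + 1e-9))
    stop("walls must lie inside the arena", call. = FALSE)
  walls
}

#' Is a point inside the arena?
#'
#' @param arena an [arena_square()] or [arena_circle()].
#' @param x,y coordinates (cm), vectorized.
#' @param margin shrink the boundary by this much (cm).
#' @return logical vector.
#' @export
in_arena <- function(arena, x, y, margin = 0) {
  if (arena$shape == "square") {
    h <- arena$side / 2 - margin
    abs(x) <= h & abs(y) <= h
  } else {
    sqrt(x^2 + y^2) <= arena$radius - margin
  }
}

# boundary of a square arena as four wall segments
boundary_segments <- function(arena) {
  if (arena$shape != "square") return(NULL)
  h <- arena$side / 2
  data.frame(x1 = c(-h, h, h, -h), y1 = c(-h, -h, h, h),
             x2 = c(h, h, -h, -h), y2 = c(-h, h, h, -h))
}

# first crossing of segment p->q with any wall (matrix rows x1,y1,x2,y2);
# returns NULL or list(t, wall = c(x1,y1,x2,y2))
first_wall_hit <- function(p, q, wm) {
  if (is.null(wm) || nrow(wm) == 0) return(NULL)
  dx <- q[1] - p[1]; dy <- q[2] - p[2]
  ex <- wm[, 3] - wm[, 1]; ey <- wm[, 4] - wm[, 2]
  denom <- dx * ey - dy * ex
  wx <- wm[, 1] - p[1]; wy <- wm[, 2] - p[2]
  t <- (wx * ey - wy * ex) / denom
  s <- (wx * dy - wy * dx) / denom
  ok <- is.finite(t) & is.finite(s) & t >= 0 & t <= 1 & s >= -1e-9 & s <= 1 + 1e-9
  if (!any(ok)) return(NULL)
  i <- which(ok)[which.min(t[ok])]
  list(t = t[i], wall = wm[i, ])
}

#' Resolve a proposed step against walls and the arena boundary
#'
#' If the segment from `current` to `proposed` crosses a wall (or the arena
#' boundary), the returned position is the sliding projection along the
#' obstacle: the fly stops just short of the wall and the remaining motion is
#' projected onto the wall tangent. The result is never on the far side of a
#' wall and always inside the arena.
#'
#' @param current free (non-violating) position, length-2 numeric (cm).
#' @param proposed proposed position (cm).
#' @param arena an arena; its `walls` plus the boundary are the obstacles.
#' @param eps standoff distance from obstacles (cm).
#' @return list with `pos` (resolved position), `contact` (logical) and
#'   `tangent` (unit vector along the contacted obstacle, or `NULL`).
#' @export
resolve_collision <- function(current, proposed, arena, eps = 1e-3) {
  walls <- arena$wall_mat
  if (is.null(walls)) {
    walls <- rbind(as.matrix(arena$walls),
                   if (arena$shape == "square")
                     as.matrix(boundary_segments(arena)))
    dimnames(walls) <- NULL
  }
  if (!all(in_arena(arena, current[1], current[2])))
    stop("current position already violates the arena", call. = FALSE)
  pos <- proposed
  contact <- FALSE
  tangent <- NULL
  start <- current
  for (iter in 1:3) {
    hit <- if (!is.null(walls) && nrow(walls) > 0)
      first_wall_hit(start, pos, walls) else NULL
    if (is.null(hit)) break
    contact <- TRUE
    w <- unname(hit$wall)
    u <- c(w[3] - w[1], w[4] - w[2])
    u <- u / sqrt(sum(u^2))
    hp <- start + hit$t * (pos - start)
    # pull back toward the start side of the wall
    nvec <- c(-u[2], u[1])
    side <- sign(sum((start - hp) * nvec))
    if (side == 0) side <- 1
    safe <- hp + side * eps * nvec
    rem <- pos - hp
    pos <- safe + sum(rem * u) * u
    tangent <- u
    start <- safe
  }
  # final guard: any residual crossing collapses to the last safe point
  if (!is.null(walls) && nrow(walls) > 0 &&
      !is.null(first_wall_hit(start, pos, walls))) {
    pos <- start
  }
  if (arena$shape == "circle") {
    r <- sqrt(sum(pos^2))
    if (r > arena$radius - eps) {
      contact <- TRUE
      if (r > 0) {
        pos <- pos * (arena$radius - eps) / r
        tangent <- c(-pos[2], pos[1]) / sqrt(sum(pos^2))
      }
    }
  } else {
    h <- arena$side / 2 - eps / 2
    pos <- clamp(pos, -h, h)
  }
  list(pos = pos, contact = contact, tangent = tangent)
}

#' The A/B shuttle line task
#'
#' Two goals symmetric about the arena center, 13 cm apart by default, between
#' which the fly is shuttled back and forth.
#'
#' @param separation distance between goal centers (cm).
#' @param arena the arena the goals must fit in.
#' @param radius goal capture radius (cm).
#' @param timeout_s per-trial timeout (s).
#' @return list of two [goal_spec()] (A then B) on the x axis.
#' @export
#' @examples
#' g <- make_line_task()
#' sqrt((g[[1]]$x - g[[2]]$x)^2 + (g[[1]]$y - g[[2]]$y)^2)  # 13
make_line_task <- function(separation = 13, arena = arena_square(),
                           radius = 1.5, timeout_s = 60) {
  if (separation <= 0) stop("separation must be > 0", call. = FALSE)
  half <- separation / 2
  if (!all(in_arena(arena, c(-half, half), c(0, 0), margin = radius)))
    stop("separation exceeds the arena", call. = FALSE)
  list(goal_spec(-half, 0, radius, timeout_s),
       goal_spec(half, 0, radius, timeout_s))
}

# Minimal stroke font on a 1 x 2 (width x height) em box, strokes as polylines.
# Covers the HELLO WORLD alphabet plus a few extras.
stroke_font <- function() {
  list(
    H = list(rbind(c(0, 0), c(0, 2)), rbind(c(1, 0), c(1, 2)),
             rbind(c(0, 1), c(1, 1))),
    E = list(rbind(c(1, 2), c(0, 2), c(0, 0), c(1, 0)),
             rbind(c(0, 1), c(0.8, 1))),
    L = list(rbind(c(0, 2), c(0, 0), c(1, 0))),
    O = list(rbind(c(0, 0), c(0, 2), c(1, 2), c(1, 0), c(0, 0))),
    W = list(rbind(c(0, 2), c(0.25, 0), c(0.5, 1.4), c(0.75, 0), c(1, 2))),
    R = list(rbind(c(0, 0), c(0, 2), c(1, 2), c(1, 1), c(0, 1)),
             rbind(c(0.3, 1), c(1, 0))),
    D = list(rbind(c(0, 0), c(0, 2), c(0.7, 2), c(1, 1.6), c(1, 0.4),
                   c(0.7, 0), c(0, 0))),
    I = list(rbind(c(0.5, 0), c(0.5, 2))),
    T = list(rbind(c(0, 2), c(1, 2)), rbind(c(0.5, 2), c(0.5, 0))),
    ` ` = list()
  )
}

# resample a polyline so consecutive vertices are at most max_step apart
densify <- function(poly, max_step) {
  out <- poly[1, , drop = FALSE]
  for (i in seq_len(nrow(poly) - 1)) {
    a <- poly[i, ]; b <- poly[i + 1, ]
    len <- sqrt(sum((b - a)^2))
    k <- max(1L, ceiling(len / max_step))
    for (j in seq_len(k)) out <- rbind(out, a + (b - a) * j / k)
  }
  out
}

#' Waypoints tracing text with a stroke font
#'
#' Converts text into an ordered list of goals tracing each glyph's strokes,
#' letters laid out left to right. Strokes are densified so consecutive
#' waypoints are at most `scale / 4` apart. The built-in font covers
#' `H E L O W R D I T` and space.
#'
#' @param text string to trace.
#' @param scale glyph height (cm).
#' @param origin length-2 numeric: position (cm) of the lower-left corner of
#'   the first glyph.
#' @param radius goal radius (cm).
#' @param timeout_s per-goal timeout (s).
#' @return ordered list of [goal_spec()]; empty list for empty text.
#' @export
#' @examples
#' length(make_letter_waypoints("H", scale = 8)) > 0
make_letter_waypoints <- function(text, scale = 8, origin = c(0, 0),
                                  radius = 1.5, timeout_s = 60) {
  if (nchar(text) == 0) return(list())
  font <- stroke_font()
  chars <- strsplit(toupper(text), "")[[1]]
  unknown <- setdiff(chars, names(font))
  if (length(unknown) > 0)
    stop("unsupported character(s): ", paste(unique(unknown), collapse = " "),
         call. = FALSE)
  em_w <- 1.4  # glyph advance in em units (1 em = glyph width)
  unit <- scale / 2  # font box is 1 x 2 em; scale = glyph height
  goals <- list()
  for (k in seq_along(chars)) {
    gx <- origin[1] + (k - 1) * em_w * unit
    for (stroke in font[[chars[k]]]) {
      pts <- densify(stroke, max_step = scale / 4 / unit)
      for (i in seq_len(nrow(pts))) {
        goals[[length(goals) + 1]] <- goal_spec(gx + pts[i, 1] * unit,
                                                origin[2] + pts[i, 2] * unit,
                                                radius, timeout_s)
      }
    }
  }
  goals
}

#' The looping maze with dead-end offshoots
#'
#' A square 43-cm arena containing a closed square corridor loop (between an
#' inner 16 x 16 cm block and an outer 24 x 24 cm wall, corridor width 4 cm)
#' with one dead-end stub opening from the middle of each side of the outer
#' wall (3 cm wide, extending 6 cm outward), and 12 goals evenly spaced along
#' the loop centerline.
#'
#' @param goal_radius capture radius of the loop goals (cm).
#' @param timeout_s per-goal timeout (s).
#' @return list with `arena` (walled [arena_square()]), `goals` (ordered list
#'   of 12 [goal_spec()]), and `dead_ends` (data.frame of bounding boxes
#'   `xmin, xmax, ymin, ymax`, one per stub).
#' @export
make_maze <- function(goal_radius = 1.2, timeout_s = 60) {
  inner <- 8; outer <- 12; stub_half <- 1.5; stub_end <- 18
  seg <- function(x1, y1, x2, y2) data.frame(x1 = x1, y1 = y1, x2 = x2, y2 = y2)
  walls <- rbind(
    # inner block
    seg(-inner, -inner, inner, -inner), seg(inner, -inner, inner, inner),
    seg(inner, inner, -inner, inner), seg(-inner, inner, -inner, -inner),
    # outer loop wall, with a gap in the middle of each side for the stubs
    seg(-outer, outer, -stub_half, outer), seg(stub_half, outer, outer, outer),
    seg(-outer, -outer, -stub_half, -outer), seg(stub_half, -outer, outer, -outer),
    seg(-outer, -outer, -outer, -stub_half), seg(-outer, stub_half, -outer, outer),
    seg(outer, -outer, outer, -stub_half), seg(outer, stub_half, outer, outer),
    # dead-end stubs (sides + end cap), one per side
    seg(-stub_half, outer, -stub_half, stub_end), seg(stub_half, outer, stub_half, stub_end),
    seg(-stub_half, stub_end, stub_half, stub_end),
    seg(-stub_half, -outer, -stub_half, -stub_end), seg(stub_half, -outer, stub_half, -stub_end),
    seg(-stub_half, -stub_end, stub_half, -stub_end),
    seg(-outer, -stub_half, -stub_end, -stub_half), seg(-outer, stub_half, -stub_end, stub_half),
    seg(-stub_end, -stub_half, -stub_end, stub_half),
    seg(outer, -stub_half, stub_end, -stub_half), seg(outer, stub_half, stub_end, stub_half),
    seg(stub_end, -stub_half, stub_end, stub_half)
  )
  arena <- arena_square(43, walls = walls)
  # 12 goals on the loop centerline (square of half-side 10), evenly spaced
  # by perimeter arc length, starting at (10, 0) and running CCW
  r <- (inner + outer) / 2
  perim <- 8 * r
  arc <- function(sdist) {
    sdist <- sdist %% perim
    side <- floor(sdist / (2 * r))
    u <- sdist - side * 2 * r
    switch(as.integer(side) + 1L,
           c(r, -r + u) ,      # right side, going up... starts at (r, 0)
           c(r - u, r),        # top, going left
           c(-r, r - u),       # left, going down
           c(-r + u, -r))      # bottom, going right
  }
  # offset so goal 1 sits at (r, 0): (r, 0) is at arc distance r on side 0
  goals <- lapply(seq_len(12) - 1, function(k) {
    p <- arc(r + k * perim / 12)
    goal_spec(p[1], p[2], goal_radius, timeout_s)
  })
  dead_ends <- data.frame(
    xmin = c(-stub_half, -stub_half, -stub_end, outer),
    xmax = c(stub_half, stub_half, -outer, stub_end),
    ymin = c(outer, -stub_end, -stub_half, -stub_half),
    ymax = c(stub_end, -outer, stub_half, stub_half))
  list(arena = arena, goals = goals, dead_ends = dead_ends)
}

#' Fraction of trajectory samples inside maze dead ends
#'
#' @param traj data.frame with columns `x`, `y` (cm).
#' @param maze a [make_maze()] fixture.
#' @return fraction in `[0, 1]`.
#' @export
dead_end_occupancy <- function(traj, maze) {
  de <- maze$dead_ends
  inside <- rep(FALSE, nrow(traj))
  for (i in seq_len(nrow(de))) {
    inside <- inside |
      (traj$x >= de$xmin[i] & traj$x <= de$xmax[i] &
       traj$y >= de$ymin[i] & traj$y <= de$ymax[i])
  }
  mean(inside)
}

#' Pushable-ball state and physics
#'
#' `ball_state()` constructs the 10-mg spherical object; `ball_update()`
#' advances it one tick: a walking fly within contact distance and moving
#' toward the ball displaces it by `step_size * dt` along the fly's heading
#' plus wide angular noise (the relocation direction is nearly isotropic —
#' flies show no directional preference when moving the ball). A movement
#' event is logged when the cumulative displacement of a contact bout exceeds
#' `event_threshold`; bouts are separated by at least `quiescence_s` without
#' motion. The ball respects the arena walls.
#'
#' @param x,y ball position (cm).
#' @param radius ball radius (cm).
#' @param mass_mg ball mass (mg).
#' @return `ball_state()`: an object of class `ball_state`.
#' @export
ball_state <- function(x = 0, y = 0, radius = 0.25, mass_mg = 10) {
  structure(list(x = x, y = y, radius = radius, mass_mg = mass_mg,
                 movement_events = 0L, bout_path = 0, bout_counted = FALSE,
                 last_move_s = -Inf),
            class = "ball_state")
}

#' @rdname ball_state
#' @param contact_cm extra contact reach beyond the ball radius (cm).
#' @param step_size push speed while in contact (cm/s).
#' @param dir_sd SD of the angular noise on the push direction (rad); large
#'   values make relocation nearly isotropic.
#' @param event_threshold bout path length that counts as a movement event
#'   (cm).
#' @param quiescence_s minimum motionless gap separating bouts (s).
#' @export
push_params <- function(contact_cm = 0.3, step_size = 0.5, dir_sd = 1.5,
                        event_threshold = 0.5, quiescence_s = 2) {
  list(contact_cm = contact_cm, step_size = step_size, dir_sd = dir_sd,
       event_threshold = event_threshold, quiescence_s = quiescence_s)
}

#' @rdname ball_state
#' @param ball a `ball_state`.
#' @param flies list of [fly_state()].
#' @param dt tick (s).
#' @param arena the arena (walls respected).
#' @param push [push_params()].
#' @param time_s current time (s).
#' @export
ball_update <- function(ball, flies, dt, arena, push = push_params(),
                        time_s = 0) {
  moved <- FALSE
  for (s in flies) {
    if (s$mode != "walking" || s$speed <= 0) next
    dx <- ball$x - s$x; dy <- ball$y - s$y
    dist <- sqrt(dx^2 + dy^2)
    if (dist > ball$radius + push$contact_cm) next
    # moving toward the ball?
    vx <- cos(s$heading); vy <- sin(s$heading)
    if (dist > 0 && (vx * dx + vy * dy) <= 0) next
    dir <- s$heading + stats::rnorm(1, 0, push$dir_sd)
    step <- push$step_size * dt
    prop <- c(ball$x + step * cos(dir), ball$y + step * sin(dir))
    res <- resolve_collision(c(ball$x, ball$y), prop, arena)
    d <- sqrt(sum((res$pos - c(ball$x, ball$y))^2))
    ball$x <- res$pos[1]; ball$y <- res$pos[2]
    if (d > 0) {
      if (time_s - ball$last_move_s > push$quiescence_s) {
        ball$bout_path <- 0
        ball$bout_counted <- FALSE
      }
      ball$bout_path <- ball$bout_path + d
      if (!ball$bout_counted && ball$bout_path > push$event_threshold) {
        ball$movement_events <- ball$movement_events + 1L
        ball$bout_counted <- TRUE
      }
      ball$last_move_s <- time_s
      moved <- TRUE
    }
  }
  attr(ball, "moved") <- moved
  ball
}
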