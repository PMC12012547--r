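test_that("arenas validate their geometry and membership", {
  a <- arena_square(43)
  expect_true(all(in_arena(a, c(0, 21.4, -21.4), c(0, 0, 21.4))))
  expect_false(in_arena(a, 21.6, 0))
  expect_false(in_arena(a, 20.5, 0, margin = 2))
  ci <- arena_circle(21.5)
  expect_true(in_arena(ci, 15, 15))
  expect_false(in_arena(ci, 16, 16))
  expect_error(arena_square(-1))
  expect_error(arena_square(43, walls = data.frame(x1 = 0, y1 = 0,
                                                   x2 = 0, y2 = 0)),
               "degenerate")
  expect_error(arena_square(43, walls = data.frame(x1 = 0, y1 = 0,
                                                   x2 = 30, y2 = 0)),
               "inside the arena")
})

test_that("the line task separates two goals by 13 cm about the center", {
  g <- make_line_task()
  expect_length(g, 2)
  expect_equal(sqrt((g[[1]]$x - g[[2]]$x)^2 + (g[[1]]$y - g[[2]]$y)^2), 13)
  expect_equal(g[[1]]$x, -g[[2]]$x)
  expect_equal(c(g[[1]]$y, g[[2]]$y), c(0, 0))
  g2 <- make_line_task(separation = 0.5)
  expect_equal(g2[[2]]$x, 0.25)
  expect_error(make_line_task(separation = 0), "separation")
  expect_error(make_line_task(separation = 60), "exceeds the arena")
})

test_that("letter waypoints trace the stroke font deterministically", {
  h <- make_letter_waypoints("H", scale = 8, origin = c(0, 0))
  expect_gt(length(h), 3)
  xs <- vapply(h, function(g) g$x, numeric(1))
  ys <- vapply(h, function(g) g$y, numeric(1))
  # the H glyph spans its 1 x 2 em box scaled to 4 x 8 cm
  expect_equal(range(xs), c(0, 4))
  expect_equal(range(ys), c(0, 8))
  # consecutive waypoints within a stroke are close (densified)
  expect_identical(make_letter_waypoints("HELLO", scale = 8),
                   make_letter_waypoints("HELLO", scale = 8))
  expect_identical(make_letter_waypoints(""), list())
  expect_error(make_letter_waypoints("HQ"), "Q")
  # spaces advance the cursor without adding goals
  hw <- make_letter_waypoints("H H", scale = 8)
  expect_equal(length(hw), 2 * length(h))
  expect_gt(max(vapply(hw, function(g) g$x, numeric(1))), 8)
})

test_that("the maze has 12 goals on the corridor centerline, clear of walls", {
  mz <- make_maze()
  expect_length(mz$goals, 12)
  expect_equal(nrow(mz$dead_ends), 4)
  wm <- mz$arena$wall_mat
  pt_seg_dist <- function(p, s) {
    a <- s[1:2]; b <- s[3:4]
    ab <- b - a
    t <- clamp_num(sum((p - a) * ab) / sum(ab^2), 0, 1)
    sqrt(sum((a + t * ab - p)^2))
  }
  clamp_num <- function(x, lo, hi) min(max(x, lo), hi)
  for (g in mz$goals) {
    d <- min(apply(wm, 1, function(s) pt_seg_dist(c(g$x, g$y), s)))
    expect_gt(d, g$radius)  # the capture disc never pokes through a wall
  }
  # goals are evenly spaced along the loop (equal arc length = equal chord
  # pattern on a square: distances repeat with the side symmetry)
  expect_equal(mz$goals[[1]]$x, 10)
  expect_equal(mz$goals[[1]]$y, 0)
})

test_that("maze free space is connected: every goal reaches every other", {
  mz <- make_maze()
  wm <- mz$arena$wall_mat
  # grid offset by 0.25 so no node or edge touches a wall coordinate
  step <- 1
  gx <- seq(-20.75, 20.75, by = step)
  nodes <- expand.grid(x = gx, y = gx)
  id_of <- function(x, y) {  # nearest grid node
    ix <- round((x - gx[1]) / step) + 1
    iy <- round((y - gx[1]) / step) + 1
    (iy - 1) * length(gx) + ix
  }
  # adjacency: 4-neighbors whose connecting segment crosses no wall
  n <- nrow(nodes)
  adj <- vector("list", n)
  for (k in seq_len(n)) {
    p <- c(nodes$x[k], nodes$y[k])
    for (d in list(c(step, 0), c(0, step))) {
      q <- p + d
      if (q[1] > max(gx) || q[2] > max(gx)) next
      j <- id_of(q[1], q[2])
      if (!crosses_any_wall(p, q, wm)) {
        adj[[k]] <- c(adj[[k]], j)
        adj[[j]] <- c(adj[[j]], k)
      }
    }
  }
  start <- id_of(10, 0)  # node nearest goal 1
  seen <- logical(n)
  seen[start] <- TRUE
  frontier <- start
  while (length(frontier) > 0) {
    nxt <- unique(unlist(adj[frontier]))
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  for (g in mz$goals) expect_true(seen[id_of(g$x, g$y)])
  # dead-end interiors are reachable too (unguided flies can wander in)
  de <- mz$dead_ends
  for (i in seq_len(nrow(de))) {
    expect_true(seen[id_of((de$xmin[i] + de$xmax[i]) / 2,
                           (de$ymin[i] + de$ymax[i]) / 2)])
  }
  # and the inner block is sealed: its center is unreachable
  expect_false(seen[id_of(0, 0)])
})

test_that("dead_end_occupancy counts samples inside the stub boxes", {
  mz <- make_maze()
  traj <- data.frame(x = c(0, 10, 0, 20, -15), y = c(16, 0, -15, 0, 0))
  # (0,16): north stub; (0,-15): south stub; (-15,0): west stub; others not
  expect_equal(dead_end_occupancy(traj, mz), 3 / 5)
  expect_equal(dead_end_occupancy(data.frame(x = 10, y = 0), mz), 0)
})

test_that("resolve_collision passes free moves through unchanged", {
  a <- arena_square(43)
  r <- resolve_collision(c(0, 0), c(1, 1), a)
  expect_equal(r$pos, c(1, 1))
  expect_false(r$contact)
  expect_null(r$tangent)
  expect_error(resolve_collision(c(100, 0), c(0, 0), a), "violates")
})

test_that("resolve_collision slides along walls and stays on the near side", {
  wall <- data.frame(x1 = 5, y1 = -5, x2 = 5, y2 = 5)
  a <- arena_square(43, walls = wall)
  # head-on: stops just short of x = 5, sliding keeps the y motion
  r <- resolve_collision(c(4, 0), c(6, 1), a)
  expect_true(r$contact)
  expect_lt(r$pos[1], 5)
  expect_gt(r$pos[2], 0.5)  # tangential component survives
  expect_equal(abs(r$tangent), c(0, 1))
  # boundary contact
  rb <- resolve_collision(c(21, 0), c(25, 0), a)
  expect_true(rb$pos[1] <= 21.5)
  # circular boundary
  ci <- arena_circle(10)
  rc <- resolve_collision(c(9, 0), c(12, 0), ci)
  expect_true(rc$contact)
  expect_lte(sqrt(sum(rc$pos^2)), 10)
})

test_that("random maze steps never cross a wall (seeded property)", {
  mz <- make_maze()
  a <- mz$arena
  wm <- a$wall_mat
  set.seed(2024)
  pos <- c(10, 0)
  bad <- 0L
  for (k in 1:4000) {
    ang <- stats::runif(1, -pi, pi)
    step <- stats::runif(1, 0, 0.5)
    prop <- pos + step * c(cos(ang), sin(ang))
    r <- resolve_collision(pos, prop, a)
    if (!all(in_arena(a, r$pos[1], r$pos[2]))) bad <- bad + 1L
    if (crosses_any_wall(pos, r$pos, wm)) bad <- bad + 1L
    pos <- r$pos
    # occasionally teleport to another corridor point to cover more geometry
    if (k %% 500 == 0) pos <- c(-10, 0)
  }
  expect_identical(bad, 0L)
})

test_that("the ball moves only under contact from an approaching fly", {
  a <- arena_square(43)
  b <- ball_state(0, 0)
  far <- fly_state(x = 5, y = 0, heading = pi)
  set.seed(3)
  b2 <- ball_update(b, list(far), dt = 1 / 30, arena = a)
  expect_equal(c(b2$x, b2$y), c(0, 0))
  expect_false(isTRUE(attr(b2, "moved")))
  # touching but walking away: no push
  away <- fly_state(x = 0.4, y = 0, heading = 0)
  b3 <- ball_update(b, list(away), dt = 1 / 30, arena = a)
  expect_equal(c(b3$x, b3$y), c(0, 0))
  # touching and approaching: the ball is displaced
  toward <- fly_state(x = 0.4, y = 0, heading = pi)
  b4 <- ball_update(b, list(toward), dt = 1 / 30, arena = a)
  expect_gt(sqrt(b4$x^2 + b4$y^2), 0)
  expect_true(isTRUE(attr(b4, "moved")))
  # halted flies never push
  halted <- fly_state(x = 0.4, y = 0, heading = pi, mode = "halted")
  b5 <- ball_update(b, list(halted), dt = 1 / 30, arena = a)
  expect_equal(c(b5$x, b5$y), c(0, 0))
})

test_that("ball_metrics: cleared iff final displacement exceeds the zone", {
  mk <- function(xend) data.frame(time_s = 0:10, x = seq(0, xend, length.out = 11),
                                  y = 0)
  expect_true(ball_metrics(mk(6))$cleared)
  expect_false(ball_metrics(mk(4))$cleared)
  expect_false(ball_metrics(mk(5))$cleared)  # boundary: strictly greater
  m <- ball_metrics(mk(6))
  expect_equal(m$total_distance_cm, 6)
  expect_equal(m$final_displacement_cm, 6)
})

test_that("ball_metrics counts movement bouts against the threshold", {
  # one slow 0.3-cm bout: below the 0.5-cm event threshold
  small <- data.frame(time_s = seq(0, 1, by = 0.25),
                      x = seq(0, 0.3, length.out = 5), y = 0)
  expect_identical(ball_metrics(small)$n_movement_events, 0L)
  # one 0.6-cm bout: a single event even though motion continues
  one <- data.frame(time_s = seq(0, 2, by = 0.25),
                    x = seq(0, 1.2, length.out = 9), y = 0)
  expect_identical(ball_metrics(one)$n_movement_events, 1L)
  # two bouts separated by 3 s of rest: two events
  two <- data.frame(
    time_s = c(seq(0, 1, by = 0.25), 4, seq(4.25, 5.25, by = 0.25)),
    x = c(seq(0, 0.6, length.out = 5), 0.6, seq(0.75, 1.35, length.out = 5)),
    y = 0)
  expect_identical(ball_metrics(two)$n_movement_events, 2L)
  expect_error(ball_metrics(data.frame(time_s = c(1, 0), x = 0:1, y = 0)),
               "time-ordered")
  expect_identical(ball_metrics(data.frame(time_s = 0, x = 1, y = 0))$cleared,
                   FALSE)
})
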