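# Shared test helpers: deterministic parameter sets, binomial confidence
# bounds and small brute-force oracles used by the property tests.

# fully deterministic fly: no noise, no pausing, perfect compliance
det_params <- function(...) {
  args <- list(sigma_heading = 0, v_sd = 0, p_pause = 0,
               p_comply_vis = 1, p_comply_red = 1, p_comply_blue = 1)
  over <- list(...)
  args[names(over)] <- over
  do.call(behavior_params, args)
}

# exact binomial 99% confidence bounds on an observed fraction of n draws
binom_bounds <- function(p, n, level = 0.99) {
  a <- (1 - level) / 2
  c(lo = stats::qbinom(a, n, p) / n, hi = stats::qbinom(1 - a, n, p) / n)
}

# brute-force stimulation-window oracle: walk the ticks one by one
oracle_windows <- function(cmd, dt) {
  rows <- list()
  for (fid in sort(unique(cmd$fly_id))) {
    cl <- cmd[cmd$fly_id == fid, ]
    cur <- NULL
    flush <- function() {
      if (!is.null(cur)) rows[[length(rows) + 1]] <<- cur
      cur <<- NULL
    }
    for (i in seq_len(nrow(cl))) {
      sgn <- 0
      if (cl$modality[i] %in% c("pinwheel", "led")) {
        if (isTRUE(cl$direction[i] %in% c("CCW", "blue"))) sgn <- 1
        if (isTRUE(cl$direction[i] %in% c("CW", "red"))) sgn <- -1
      }
      gap <- !is.null(cur) &&
        (cl$time_s[i] - (cur$end_s - dt)) > 1.5 * dt + 1e-12
      same <- !is.null(cur) && !gap && sgn == cur$commanded_sign &&
        cl$modality[i] == cur$modality
      if (same) {
        cur$end_s <- cl$time_s[i] + dt
      } else {
        flush()
        if (sgn != 0) {
          cur <- data.frame(fly_id = fid, start_s = cl$time_s[i],
                            end_s = cl$time_s[i] + dt, commanded_sign = sgn,
                            modality = cl$modality[i])
        }
      }
    }
    flush()
  }
  if (length(rows) == 0) {
    return(data.frame(fly_id = integer(), start_s = numeric(),
                      end_s = numeric(), commanded_sign = numeric(),
                      modality = character()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# proper segment intersection test (counter-clockwise orientation predicate);
# independent of the package's wall-crossing code
segments_cross <- function(p1, p2, q1, q2) {
  ccw <- function(a, b, c) {
    (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  }
  d1 <- ccw(q1, q2, p1); d2 <- ccw(q1, q2, p2)
  d3 <- ccw(p1, p2, q1); d4 <- ccw(p1, p2, q2)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

# does the segment a -> b cross any wall (matrix rows x1,y1,x2,y2)?
crosses_any_wall <- function(a, b, wm) {
  for (i in seq_len(nrow(wm))) {
    if (segments_cross(a, b, wm[i, 1:2], wm[i, 3:4])) return(TRUE)
  }
  FALSE
}
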