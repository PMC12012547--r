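# Synthetic imaging path: renders infrared-style frames (dark fly blobs on a
# bright background) and recovers poses with a blob detector and
# nearest-neighbor tracker, so the closed loop can be run through imaging.

#' Render a synthetic camera frame
#'
#' Draws each fly as a dark ellipse (2.5 mm long x 1.5 mm wide body) on a
#' bright background, anti-aliased by 4x4 subpixel coverage sampling, with
#' optional additive Gaussian noise. Pixel (i, j) covers
#' `[i-1, i) x [j-1, j)` in pixel units; a point at `(x, y)` cm maps to pixel
#' coordinate `((x + h) * px_per_cm, (y + h) * px_per_cm)` where `h` is the
#' arena half-extent.
#'
#' @param flies list of [fly_state()] (poses in cm).
#' @param arena the arena (sets the frame extent).
#' @param px_per_cm spatial scale (px/cm).
#' @param noise_sd additive Gaussian noise SD (8-bit gray levels).
#' @param ball optional [ball_state()], drawn as a dark disc.
#' @param bg,fg background and body gray levels (0-255).
#' @return numeric matrix (x-pixel by y-pixel, values clamped to 0-255) with
#'   attribute `px_per_cm`; attribute `clipped` lists ids of flies outside the
#'   frame.
#' @export
render_frame <- function(flies, arena, px_per_cm = 10, noise_sd = 0,
                         ball = NULL, bg = 230, fg = 30) {
  if (px_per_cm <= 0) stop("px_per_cm must be > 0", call. = FALSE)
  h <- if (arena$shape == "square") arena$side / 2 else arena$radius
  npx <- ceiling(2 * h * px_per_cm)
  img <- matrix(bg, npx, npx)
  a <- 0.125 * px_per_cm  # semi-major axis: 2.5 mm body length
  b <- 0.075 * px_per_cm  # semi-minor axis: 1.5 mm body width
  off <- seq(-0.375, 0.375, by = 0.25)  # 4x4 subpixel offsets
  clipped <- integer(0)
  draw <- function(img, cx, cy, theta, sa, sb) {
    r <- ceiling(max(sa, sb)) + 1L
    i0 <- floor(cx) - r; i1 <- floor(cx) + r
    j0 <- floor(cy) - r; j1 <- floor(cy) + r
    if (i0 > npx || i1 < 1 || j0 > npx || j1 < 1)
      return(list(img = img, drawn = FALSE))  # entirely outside the frame
    ii <- max(1, i0):min(npx, i1)
    jj <- max(1, j0):min(npx, j1)
    ct <- cos(theta); st <- sin(theta)
    cov <- matrix(0, length(ii), length(jj))
    for (ox in off) for (oy in off) {
      u <- outer(ii - 0.5 + ox - cx, rep(1, length(jj)))
      v <- outer(rep(1, length(ii)), jj - 0.5 + oy - cy)
      xr <- u * ct + v * st
      yr <- -u * st + v * ct
      cov <- cov + ((xr / sa)^2 + (yr / sb)^2 <= 1)
    }
    cov <- cov / length(off)^2
    img[ii, jj] <- img[ii, jj] - cov * (bg - fg)
    list(img = img, drawn = TRUE)
  }
  for (s in flies) {
    cx <- (s$x + h) * px_per_cm
    cy <- (s$y + h) * px_per_cm
    if (cx < 0 || cx > npx || cy < 0 || cy > npx) clipped <- c(clipped, s$id)
    res <- draw(img, cx, cy, s$heading, a, b)
    img <- res$img
  }
  if (!is.null(ball)) {
    rb <- ball$radius * px_per_cm
    img <- draw(img, (ball$x + h) * px_per_cm, (ball$y + h) * px_per_cm,
                0, rb, rb)$img
  }
  if (noise_sd > 0)
    img <- img + matrix(stats::rnorm(npx * npx, 0, noise_sd), npx, npx)
  img <- clamp(img, 0, 255)
  attr(img, "px_per_cm") <- px_per_cm
  attr(img, "clipped") <- clipped
  img
}

#' Background-statistics threshold for a frame
#'
#' Flies occupy a negligible pixel fraction, so the frame is essentially all
#' background; the threshold is set 6 robust SDs (MAD) below the median
#' background level (at least 1 gray level below it), which rejects Gaussian
#' pixel noise while keeping the dark fly bodies. Intended to be computed once
#' on the first frame and held fixed.
#'
#' @param img frame from [render_frame()].
#' @return scalar threshold in gray levels.
#' @export
frame_threshold <- function(img) {
  stats::median(img) - max(6 * stats::mad(img), 1)
}

#' Detect dark blobs in a frame
#'
#' Thresholds the frame (pixels darker than `threshold`), labels connected
#' components (EBImage), and for each component at least `min_area` pixels
#' large computes the intensity-weighted centroid (weights
#' `max(bg - pixel, 0)` inside the component, where `bg` is the median
#' background level) and the major-axis orientation from second central
#' moments. The axis angle is defined modulo pi; heading disambiguation is the
#' tracker's job ([update_tracks()]).
#'
#' @param img frame matrix (x-pixel by y-pixel).
#' @param threshold gray-level threshold; defaults to [frame_threshold()].
#' @param min_area minimum blob area (px).
#' @return data.frame with columns `cx`, `cy` (px), `area` (px^2),
#'   `axis_angle` (rad in (-pi/2, pi/2]).
#' @export
detect_blobs <- function(img, threshold = NULL, min_area = 2) {
  if (is.null(threshold)) threshold <- frame_threshold(img)
  mask <- img < threshold
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- EBImage::imageData(lab)
  nlab <- max(lab)
  out <- data.frame(cx = numeric(), cy = numeric(), area = numeric(),
                    axis_angle = numeric())
  if (nlab == 0) return(out)
  bg <- stats::median(img)
  w_all <- pmax(bg - img, 0)
  for (k in seq_len(nlab)) {
    idx <- which(lab == k, arr.ind = TRUE)
    if (nrow(idx) < min_area) next
    w <- w_all[idx]
    sw <- sum(w)
    px <- idx[, 1] - 0.5
    py <- idx[, 2] - 0.5
    cx <- sum(w * px) / sw
    cy <- sum(w * py) / sw
    mu20 <- sum(w * (px - cx)^2) / sw
    mu02 <- sum(w * (py - cy)^2) / sw
    mu11 <- sum(w * (px - cx) * (py - cy)) / sw
    ang <- 0.5 * atan2(2 * mu11, mu20 - mu02)
    out <- rbind(out, data.frame(cx = cx, cy = cy, area = nrow(idx),
                                 axis_angle = ang))
  }
  rownames(out) <- NULL
  out
}

#' Associate detections with tracks and disambiguate headings
#'
#' Greedy nearest-neighbor association gated at `max_jump`; unmatched
#' detections spawn new tracks. The body-axis orientation is only defined
#' modulo pi, so the heading is the axis angle flipped, if necessary, to lie
#' within pi/2 of the displacement direction; flies that moved less than
#' `min_disp` (px/frame) keep their previous heading (flip hysteresis).
#'
#' @param detections data.frame from [detect_blobs()].
#' @param tracks data.frame from a previous call (columns `track_id`, `cx`,
#'   `cy`, `heading`), or `NULL` to start.
#' @param max_jump association gate (px).
#' @param min_disp displacement below which the heading is held (px/frame).
#' @return data.frame with columns `track_id`, `cx`, `cy`, `area`,
#'   `axis_angle`, `heading`.
#' @export
update_tracks <- function(detections, tracks = NULL, max_jump = 10,
                          min_disp = 0.2) {
  n <- nrow(detections)
  if (is.null(tracks) || nrow(tracks) == 0) {
    if (n == 0) {
      return(data.frame(track_id = integer(), cx = numeric(), cy = numeric(),
                        area = numeric(), axis_angle = numeric(),
                        heading = numeric()))
    }
    return(data.frame(track_id = seq_len(n), cx = detections$cx,
                      cy = detections$cy, area = detections$area,
                      axis_angle = detections$axis_angle,
                      heading = detections$axis_angle))
  }
  k <- nrow(tracks)
  assoc <- rep(NA_integer_, k)  # detection index per track
  if (n > 0) {
    d <- outer(seq_len(k), seq_len(n), function(i, j)
      sqrt((tracks$cx[i] - detections$cx[j])^2 +
           (tracks$cy[i] - detections$cy[j])^2))
    det_free <- rep(TRUE, n)
    trk_free <- rep(TRUE, k)
    repeat {
      dm <- d
      dm[!trk_free, ] <- Inf
      dm[, !det_free] <- Inf
      m <- which.min(dm)
      if (length(m) == 0 || dm[m] > max_jump) break
      i <- (m - 1) %% k + 1
      j <- (m - 1) %/% k + 1
      assoc[i] <- j
      trk_free[i] <- FALSE
      det_free[j] <- FALSE
      if (!any(trk_free) || !any(det_free)) break
    }
  }
  out <- list()
  next_id <- max(tracks$track_id) + 1L
  for (i in seq_len(k)) {
    j <- assoc[i]
    if (is.na(j)) next  # track lost this frame
    dx <- detections$cx[j] - tracks$cx[i]
    dy <- detections$cy[j] - tracks$cy[i]
    ang <- detections$axis_angle[j]
    if (sqrt(dx^2 + dy^2) >= min_disp) {
      move <- atan2(dy, dx)
      hd <- if (abs(wrap_angle(ang - move)) <= pi / 2) ang
            else wrap_angle(ang + pi)
    } else {
      hd <- tracks$heading[i]
    }
    out[[length(out) + 1]] <- data.frame(track_id = tracks$track_id[i],
                                         cx = detections$cx[j],
                                         cy = detections$cy[j],
                                         area = detections$area[j],
                                         axis_angle = ang, heading = hd)
  }
  if (n > 0) {
    for (j in which(!seq_len(n) %in% assoc)) {
      out[[length(out) + 1]] <- data.frame(track_id = next_id,
                                           cx = detections$cx[j],
                                           cy = detections$cy[j],
                                           area = detections$area[j],
                                           axis_angle = detections$axis_angle[j],
                                           heading = detections$axis_angle[j])
      next_id <- next_id + 1L
    }
  }
  if (length(out) == 0) {
    data.frame(track_id = integer(), cx = numeric(), cy = numeric(),
               area = numeric(), axis_angle = numeric(), heading = numeric())
  } else do.call(rbind, out)
}

#' Convert tracked pixel poses back to arena coordinates
#'
#' @param tracks data.frame from [update_tracks()].
#' @param arena the arena used for rendering.
#' @param px_per_cm the rendering scale.
#' @return data.frame with `x`, `y` (cm), `heading` (rad) and `track_id`.
#' @export
tracks_to_cm <- function(tracks, arena, px_per_cm = 10) {
  h <- if (arena$shape == "square") arena$side / 2 else arena$radius
  data.frame(track_id = tracks$track_id,
             x = tracks$cx / px_per_cm - h,
             y = tracks$cy / px_per_cm - h,
             heading = tracks$heading)
}
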