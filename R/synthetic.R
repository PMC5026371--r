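# Run expr with a private RNG stream so generators are deterministic without
# disturbing the caller's RNG state.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Grooming motif: synchronous confined paw oscillation
#'
#' Ground-truth trajectories of a grooming bout: the body sits still while
#' both forepaws perform the same small Lissajous stroke pattern near the
#' snout, plus a little independent positional jitter. Left and right
#' displacement series are therefore highly correlated with zero phase lag
#' and the paws stay inside a confined region — the kinematic signature of
#' grooming.
#'
#' @param n Number of frames.
#' @param fps Frame rate (default 60).
#' @param center Body center \code{c(x, y)}, pixels.
#' @param base_sep_px Left-right paw base separation, pixels (default 7).
#' @param front_offset_px Distance from body center to the paw base along
#'   the body axis, pixels (default 32).
#' @param amp_px Stroke amplitudes \code{c(x, y)}, pixels (default
#'   \code{c(10, 6)}).
#' @param freq_hz Stroke frequency (default 3).
#' @param jitter_px SD-like amplitude of per-frame uniform jitter (default
#'   0.3).
#' @param seed RNG seed for the jitter.
#' @return List of tibbles \code{body} (frame, x, y, orientation) and
#'   \code{left}, \code{right} (frame, x, y); frames 0-based.
#' @export
grooming_motif <- function(n, fps = 60, center = c(120, 90), base_sep_px = 7,
                           front_offset_px = 32, amp_px = c(10, 6),
                           freq_hz = 3, jitter_px = 0.3, seed = 1) {
  .with_seed(seed, {
    t <- (seq_len(n) - 1) / fps
    osc_x <- amp_px[1] * sin(2 * pi * freq_hz * t)
    osc_y <- amp_px[2] * sin(2 * pi * 2 * freq_hz * t + pi / 3)
    base_y <- center[2] - front_offset_px
    jit <- function() cbind(stats::runif(n, -jitter_px, jitter_px),
                            stats::runif(n, -jitter_px, jitter_px))
    jl <- jit(); jr <- jit()
    frame <- seq_len(n) - 1L
    list(
      body = tibble::tibble(frame = frame, x = center[1], y = center[2],
                            orientation = 90),
      left = tibble::tibble(frame = frame,
                            x = center[1] - base_sep_px / 2 + osc_x + jl[, 1],
                            y = base_y + osc_y + jl[, 2]),
      right = tibble::tibble(frame = frame,
                             x = center[1] + base_sep_px / 2 + osc_x + jr[, 1],
                             y = base_y + osc_y + jr[, 2])
    )
  })
}

#' Walking motif: translating body with alternating paw strides
#'
#' Ground-truth trajectories of a walking bout: the body translates
#' horizontally (ping-pong within the given x range, with a slow lateral
#' sway), while the paws stride along the movement axis. The right paw's
#' stride is the left's delayed by \code{phase_lag_frames} — the left-right
#' gait alternation that produces walking's bilateral time lag — and the
#' traversal spreads the trajectory over a far larger area than grooming.
#'
#' @param n Number of frames.
#' @param fps Frame rate (default 60).
#' @param x_range Horizontal traversal interval of the body center, pixels.
#' @param y_center Vertical body position, pixels.
#' @param speed_px_s Body translation speed (default 40).
#' @param lateral_sep_px Left-right paw separation across the movement axis
#'   (default 16).
#' @param stride_amp_px Stride oscillation amplitude (default 10).
#' @param stride_freq_hz Stride frequency (default 1.25).
#' @param phase_lag_frames Right-paw delay in frames; default half a stride
#'   period.
#' @param sway_amp_px,sway_freq_hz Slow lateral body sway (defaults 12 px,
#'   0.3 Hz).
#' @param jitter_px Per-frame uniform jitter amplitude (default 0.3).
#' @param seed RNG seed for the jitter.
#' @return Same shape as [grooming_motif()].
#' @export
walking_motif <- function(n, fps = 60, x_range = c(50, 190), y_center = 90,
                          speed_px_s = 40, lateral_sep_px = 16,
                          stride_amp_px = 10, stride_freq_hz = 1.25,
                          phase_lag_frames = round(fps / (2 * stride_freq_hz)),
                          sway_amp_px = 12, sway_freq_hz = 0.3,
                          jitter_px = 0.3, seed = 1) {
  .with_seed(seed, {
    t <- (seq_len(n) - 1) / fps
    span <- x_range[2] - x_range[1]
    # triangle-wave (ping-pong) traversal of the x range
    phase <- (speed_px_s * t) %% (2 * span)
    bx <- x_range[1] + ifelse(phase <= span, phase, 2 * span - phase)
    by <- y_center + sway_amp_px * sin(2 * pi * sway_freq_hz * t)
    stride <- function(delay_frames) {
      td <- (seq_len(n) - 1 - delay_frames) / fps
      stride_amp_px * sin(2 * pi * stride_freq_hz * td)
    }
    jit <- function() cbind(stats::runif(n, -jitter_px, jitter_px),
                            stats::runif(n, -jitter_px, jitter_px))
    jl <- jit(); jr <- jit()
    frame <- seq_len(n) - 1L
    list(
      body = tibble::tibble(frame = frame, x = bx, y = by, orientation = 0),
      left = tibble::tibble(frame = frame,
                            x = bx + stride(0) + jl[, 1],
                            y = by - lateral_sep_px / 2 + jl[, 2]),
      right = tibble::tibble(frame = frame,
                             x = bx + stride(phase_lag_frames) + jr[, 1],
                             y = by + lateral_sep_px / 2 + jr[, 2])
    )
  })
}

#' Compose a synthetic scene
#'
#' Bundles ground-truth trajectories with rendering parameters for the
#' deterministic test renderer: an elliptical fur-colored body and two
#' neon-hued anti-aliased paw disks per mouse on a contrasting arena floor,
#' optional per-paw occlusion intervals (paws hidden behind the body) and a
#' per-frame brightness profile that modulates only the V channel.
#'
#' @param mice List of motif outputs (see [grooming_motif()]), one per mouse.
#' @param width,height Frame dimensions, pixels.
#' @param fps Frame rate.
#' @param pixel_size_mm Physical pixel size, mm.
#' @param fur \code{"dark"} (near-black body on white floor) or
#'   \code{"light"} (white body on dark floor).
#' @param body_axes Ellipse semi-axes \code{c(major, minor)}, pixels.
#' @param paw_radius Paw disk radius, pixels.
#' @param paw_hues Hues of the left and right paw, degrees (neon green 120
#'   and neon magenta 300).
#' @param occlusions Per-mouse list \code{list(left =, right =)} of
#'   inclusive 0-based frame intervals (2-column matrices) during which the
#'   paw is hidden.
#' @param v_profile Scalar or per-frame vector of V-channel multipliers in
#'   \code{(0, 1]}.
#' @param seed Scene seed (propagated to optional render noise).
#' @return A \code{synthetic_scene} list.
#' @export
synthetic_scene <- function(mice, width = 240, height = 160, fps = 60,
                            pixel_size_mm = 0.75, fur = c("dark", "light"),
                            body_axes = c(40, 20), paw_radius = 5,
                            paw_hues = c(120, 300), occlusions = NULL,
                            v_profile = 1, seed = 1) {
  fur <- match.arg(fur)
  if (!is.list(mice[[1]]$body %||% NULL) && !is.data.frame(mice[[1]]$body)) {
    stop("mice must be a list of motif outputs", call. = FALSE)
  }
  # fur and floor are achromatic (hue 0 by convention); paw hues must be
  # distinct from that and from each other for hue-based tracking to work
  circ <- function(a, b) { d <- abs(a - b) %% 360; pmin(d, 360 - d) }
  if (any(circ(paw_hues, 0) < 30)) {
    stop("scene error: paw hue collides with the body/background hue",
         call. = FALSE)
  }
  if (circ(paw_hues[1], paw_hues[2]) < 30) {
    stop("scene error: the two paw hues are too similar", call. = FALSE)
  }
  n <- nrow(mice[[1]]$body)
  if (length(v_profile) == 1) v_profile <- rep(v_profile, n)
  stopifnot(length(v_profile) == n, all(v_profile > 0), all(v_profile <= 1))
  if (is.null(occlusions)) {
    occlusions <- rep(list(list(left = NULL, right = NULL)), length(mice))
  }
  structure(
    list(mice = mice, width = width, height = height, fps = fps,
         pixel_size_mm = pixel_size_mm, fur = fur, body_axes = body_axes,
         paw_radius = paw_radius, paw_hues = paw_hues,
         occlusions = occlusions, v_profile = v_profile,
         n_frames = n, seed = seed),
    class = "synthetic_scene"
  )
}

.occluded_at <- function(intervals, frame0) {
  if (is.null(intervals)) return(FALSE)
  intervals <- matrix(intervals, ncol = 2)
  any(frame0 >= intervals[, 1] & frame0 <= intervals[, 2])
}

# hue (deg) at s = v = 1 -> RGB triple in [0,1]
.hue_rgb <- function(h) {
  grDevices::col2rgb(grDevices::hsv(h / 360, 1, 1))[, 1] / 255
}

#' Render a synthetic scene
#'
#' Deterministically renders every frame (anti-aliased ellipse body, paw
#' disks drawn on top unless occluded, whole-frame V-channel modulation with
#' hue untouched) and returns the frames with the ground truth, whose
#' visibility flags mirror the occlusion intervals exactly. Frames are
#' quantized to 8 bits per channel.
#'
#' @param scene A [synthetic_scene()].
#' @return List with \code{frames} (list of RGB arrays) and \code{truth}
#'   (tibble: frame, mouse, body_x, body_y, orientation, left_x, left_y,
#'   left_visible, right_x, right_y, right_visible), with
#'   \code{pixel_size_mm} and \code{fps} attributes.
#' @export
render_scene <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  w <- scene$width; h <- scene$height
  bg_v <- if (scene$fur == "dark") 1 else 0.05
  fur_v <- if (scene$fur == "dark") 0.15 else 0.9
  paw_cols <- lapply(scene$paw_hues, .hue_rgb)
  n <- scene$n_frames
  frames <- vector("list", n)
  truth_rows <- vector("list", n)
  for (f in seq_len(n)) {
    frame <- array(bg_v, dim = c(h, w, 3))
    rows <- vector("list", length(scene$mice))
    for (m in seq_along(scene$mice)) {
      tr <- scene$mice[[m]]
      b <- tr$body[f, ]
      frame <- .draw_ellipse(frame, b$x, b$y, scene$body_axes[1],
                             scene$body_axes[2], b$orientation, fur_v)
      occ <- scene$occlusions[[m]]
      lv <- !.occluded_at(occ$left, f - 1L)
      rv <- !.occluded_at(occ$right, f - 1L)
      if (lv) frame <- .draw_disk(frame, tr$left$x[f], tr$left$y[f],
                                  scene$paw_radius, paw_cols[[1]])
      if (rv) frame <- .draw_disk(frame, tr$right$x[f], tr$right$y[f],
                                  scene$paw_radius, paw_cols[[2]])
      rows[[m]] <- tibble::tibble(
        frame = f - 1L, mouse = m - 1L,
        body_x = b$x, body_y = b$y, orientation = b$orientation,
        left_x = tr$left$x[f], left_y = tr$left$y[f], left_visible = lv,
        right_x = tr$right$x[f], right_y = tr$right$y[f], right_visible = rv
      )
    }
    frame <- frame * scene$v_profile[f]
    frames[[f]] <- round(frame * 255) / 255
    truth_rows[[f]] <- dplyr::bind_rows(rows)
  }
  truth <- dplyr::bind_rows(truth_rows)
  attr(truth, "pixel_size_mm") <- scene$pixel_size_mm
  attr(truth, "fps") <- scene$fps
  list(frames = frames, truth = truth)
}

# Anti-aliased composite of a rotated ellipse (gray value `val`) onto frame.
# cx, cy are 0-based pixel-center coordinates; theta degrees, y-down.
.draw_ellipse <- function(frame, cx, cy, a, b, theta, val) {
  h <- dim(frame)[1]; w <- dim(frame)[2]
  r <- max(a, b) + 1
  cols <- max(1, floor(cx - r) + 1):min(w, ceiling(cx + r) + 1)
  rows <- max(1, floor(cy - r) + 1):min(h, ceiling(cy + r) + 1)
  dx <- outer(rep(1, length(rows)), cols - 1 - cx)
  dy <- outer(rows - 1 - cy, rep(1, length(cols)))
  th <- theta * pi / 180
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  d <- (sqrt((u / a)^2 + (v / b)^2) - 1) * min(a, b)
  alpha <- pmin(pmax(0.5 - d, 0), 1)
  for (ch in 1:3) {
    sub <- frame[rows, cols, ch]
    frame[rows, cols, ch] <- alpha * val + (1 - alpha) * sub
  }
  frame
}

.draw_disk <- function(frame, cx, cy, radius, col) {
  h <- dim(frame)[1]; w <- dim(frame)[2]
  r <- radius + 1
  cols <- max(1, floor(cx - r) + 1):min(w, ceiling(cx + r) + 1)
  rows <- max(1, floor(cy - r) + 1):min(h, ceiling(cy + r) + 1)
  dx <- outer(rep(1, length(rows)), cols - 1 - cx)
  dy <- outer(rows - 1 - cy, rep(1, length(cols)))
  d <- sqrt(dx^2 + dy^2) - radius
  alpha <- pmin(pmax(0.5 - d, 0), 1)
  for (ch in 1:3) {
    sub <- frame[rows, cols, ch]
    frame[rows, cols, ch] <- alpha * col[ch] + (1 - alpha) * sub
  }
  frame
}

#' Tracking configuration matched to a synthetic scene
#'
#' Builds a [tracker_config()] whose arena covers the full frame and whose
#' HSV mask limits select the scene's fur and the two neon paw hues. Paw
#' saturation limits do the selecting (saturation is unchanged by V-channel
#' modulation), so the configuration tracks identically across brightness
#' profiles. Reference paw ROIs are squares centered on the frame-0 ground
#' truth.
#'
#' @param scene A [synthetic_scene()].
#' @param truth The rendered ground truth (from [render_scene()]).
#' @param roi_half Reference ROI half-side, pixels (default 3).
#' @param ... Overrides passed on to [tracker_config()].
#' @return A \code{tracker_config}.
#' @export
scene_tracker_config <- function(scene, truth, roi_half = 3, ...) {
  stopifnot(inherits(scene, "synthetic_scene"))
  w <- scene$width; h <- scene$height
  body_hsv <- if (scene$fur == "dark") {
    hsv_range(0, 359.9, 0, 0.3, 0, 0.35)
  } else {
    hsv_range(0, 359.9, 0, 0.3, 0.45, 1)
  }
  paw_rng <- function(hue) {
    lo <- (hue - 20) %% 360; hi <- (hue + 20) %% 360
    hsv_range(lo, hi, 0.5, 1, 0.15, 1)
  }
  t0 <- truth[truth$frame == 0L, ]
  rois <- lapply(seq_len(nrow(t0)), function(i) {
    list(
      left = c(round(t0$left_x[i]) - roi_half, round(t0$left_y[i]) - roi_half,
               2 * roi_half, 2 * roi_half),
      right = c(round(t0$right_x[i]) - roi_half, round(t0$right_y[i]) - roi_half,
                2 * roi_half, 2 * roi_half)
    )
  })
  tracker_config(
    corners = rbind(c(0, 0), c(w - 1, 0), c(w - 1, h - 1)),
    n_mice = nrow(t0),
    dividers = if (nrow(t0) == 2) list(rbind(c((w - 1) / 2, 0), c((w - 1) / 2, h - 1))) else list(),
    body_hsv = body_hsv,
    left_hsv = paw_rng(scene$paw_hues[1]),
    right_hsv = paw_rng(scene$paw_hues[2]),
    paw_rois = rois,
    pixel_size_mm = scene$pixel_size_mm,
    fps = scene$fps,
    ...
  )
}
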