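#' Extract a single-target trajectory from tracking records
#'
#' Pulls one paw's (or the body's) per-frame positions for one mouse into a
#' trajectory tibble carrying the spatial calibration and frame rate needed
#' by all downstream kinematic analyses.
#'
#' @param records Records tibble from [track_video()] or [read_records()].
#' @param mouse Mouse / enclosure id (0-based).
#' @param target \code{"left"}, \code{"right"} or \code{"body"}.
#' @param pixel_size_mm mm per pixel; defaults to the records attribute.
#' @param fps Frames per second; defaults to the records attribute.
#' @return A \code{paw_trajectory} tibble: \code{frame}, \code{x}, \code{y},
#'   \code{tracked}, with \code{pixel_size_mm} and \code{fps} attributes.
#' @export
as_trajectory <- function(records, mouse = 0,
                          target = c("left", "right", "body"),
                          pixel_size_mm = NULL, fps = NULL) {
  target <- match.arg(target)
  pixel_size_mm <- pixel_size_mm %||% attr(records, "pixel_size_mm") %||% 1
  fps <- fps %||% attr(records, "fps") %||% 1
  r <- dplyr::filter(records, .data$mouse == !!mouse) |>
    dplyr::arrange(.data$frame)
  out <- switch(target,
    left = tibble::tibble(frame = r$frame, x = r$left_x, y = r$left_y,
                          tracked = r$left_tracked),
    right = tibble::tibble(frame = r$frame, x = r$right_x, y = r$right_y,
                           tracked = r$right_tracked),
    body = tibble::tibble(frame = r$frame, x = r$body_x, y = r$body_y,
                          tracked = !is.na(r$body_x))
  )
  new_trajectory(out, pixel_size_mm, fps)
}

#' Build a trajectory from raw frame/position samples
#'
#' @param data Data frame with columns \code{frame}, \code{x}, \code{y} and
#'   optionally \code{tracked}.
#' @param pixel_size_mm mm per pixel.
#' @param fps Frames per second.
#' @return A \code{paw_trajectory} tibble.
#' @export
new_trajectory <- function(data, pixel_size_mm = 1, fps = 1) {
  stopifnot(pixel_size_mm > 0, fps > 0,
            all(c("frame", "x", "y") %in% names(data)))
  out <- tibble::as_tibble(data)
  if (!"tracked" %in% names(out)) out$tracked <- !is.na(out$x)
  stopifnot(!is.unsorted(out$frame, strictly = TRUE))
  attr(out, "pixel_size_mm") <- pixel_size_mm
  attr(out, "fps") <- fps
  class(out) <- c("paw_trajectory", class(out))
  out
}

.traj_px <- function(t) attr(t, "pixel_size_mm")
.traj_fps <- function(t) attr(t, "fps")

#' Convert a pixel distance to millimetres
#'
#' @param d Distance(s) in pixels.
#' @param pixel_size_mm Physical pixel size, mm per pixel.
#' @return Distance(s) in mm.
#' @examples
#' px_to_mm(3, 0.21)  # 0.63 mm
#' @export
px_to_mm <- function(d, pixel_size_mm) {
  stopifnot(pixel_size_mm > 0)
  d * pixel_size_mm
}

#' Frame-to-frame displacement series
#'
#' Euclidean displacement per consecutive pair of tracked frames, in pixels.
#' Pairs spanning an untracked gap are excluded; the number of excluded
#' pairs is reported in the \code{"n_excluded"} attribute.
#'
#' @param t A \code{paw_trajectory}.
#' @return Tibble with \code{frame} (the leading frame of each pair),
#'   \code{dx}, \code{dy} and \code{step_px}.
#' @export
displacements <- function(t) {
  tr <- t[t$tracked, ]
  if (nrow(tr) < 2) {
    stop("insufficient data: need at least 2 tracked samples", call. = FALSE)
  }
  consecutive <- which(t$tracked[-nrow(t)] & t$tracked[-1])
  out <- tibble::tibble(
    frame = t$frame[consecutive],
    dx = t$x[consecutive + 1] - t$x[consecutive],
    dy = t$y[consecutive + 1] - t$y[consecutive]
  )
  out$step_px <- sqrt(out$dx^2 + out$dy^2)
  attr(out, "n_excluded") <- (nrow(t) - 1) - nrow(out)
  out
}

#' Total path length of a trajectory
#'
#' Sum of frame-to-frame displacements, converted to mm. This is the
#' quantity that grows sharply with stress-induced grooming.
#'
#' @param t A \code{paw_trajectory}.
#' @return Length in mm.
#' @export
path_length <- function(t) {
  px_to_mm(sum(displacements(t)$step_px), .traj_px(t))
}

#' Instantaneous speed series
#'
#' Frame-to-frame displacement scaled by pixel size and frame rate.
#'
#' @param t A \code{paw_trajectory}.
#' @return Tibble with \code{frame} and \code{speed_mm_s}; mean and SD are
#'   attached as attributes \code{"mean"} and \code{"sd"}.
#' @export
speed_series <- function(t) {
  d <- displacements(t)
  out <- tibble::tibble(
    frame = d$frame,
    speed_mm_s = px_to_mm(d$step_px, .traj_px(t)) * .traj_fps(t)
  )
  attr(out, "mean") <- mean(out$speed_mm_s)
  attr(out, "sd") <- stats::sd(out$speed_mm_s)
  out
}

# Shoelace area of the convex hull of a point set, in squared input units.
.hull_area <- function(x, y) {
  if (length(x) < 3) return(0)
  h <- grDevices::chull(x, y)
  if (length(h) < 3) return(0)
  hx <- x[h]; hy <- y[h]
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

#' Area covered by a trajectory
#'
#' Area of the convex hull of the tracked points, projected on the camera's
#' 2-D field of view, in cm squared. Grooming confines the paws to a few
#' cm squared while walking covers tens.
#'
#' @param t A \code{paw_trajectory}.
#' @return Area in cm^2 (0 for fewer than 3 non-collinear points).
#' @export
covered_area <- function(t) {
  tr <- t[t$tracked, ]
  .hull_area(tr$x, tr$y) * .traj_px(t)^2 / 100
}

#' Spatial occupancy map
#'
#' Visit counts of the trajectory over a square spatial binning of the
#' frame, the raster complement of the convex-hull area: how often the paw
#' moved over each location.
#'
#' @param t A \code{paw_trajectory}.
#' @param bin_px Bin side in pixels (default 1: per-pixel counts).
#' @return Tibble of visited bins: \code{bin_x}, \code{bin_y} (0-based bin
#'   indices), \code{n}. The sum of \code{n} equals the number of tracked
#'   samples.
#' @export
occupancy_map <- function(t, bin_px = 1) {
  stopifnot(bin_px > 0)
  tr <- t[t$tracked, ]
  dplyr::count(
    tibble::tibble(
      bin_x = floor(tr$x / bin_px),
      bin_y = floor(tr$y / bin_px)
    ),
    .data$bin_x, .data$bin_y, name = "n"
  )
}

#' Mean inter-paw distance
#'
#' Mean euclidean distance between the left and right paw over the frames
#' where both are tracked, in mm. Small during grooming (paws held near the
#' snout), larger during walking.
#'
#' @param left,right \code{paw_trajectory} objects of the two paws.
#' @return Mean distance in mm.
#' @export
interpaw_distance <- function(left, right) {
  j <- dplyr::inner_join(
    dplyr::filter(left, .data$tracked),
    dplyr::filter(right, .data$tracked),
    by = "frame", suffix = c("_l", "_r")
  )
  if (nrow(j) < 1) {
    stop("insufficient data: no mutually tracked frames", call. = FALSE)
  }
  px_to_mm(mean(sqrt((j$x_l - j$x_r)^2 + (j$y_l - j$y_r)^2)), .traj_px(left))
}

# Mean-subtracted displacement vectors on the common frame grid.
.paired_steps <- function(left, right) {
  dl <- displacements(left)
  dr <- displacements(right)
  j <- dplyr::inner_join(dl, dr, by = "frame", suffix = c("_l", "_r"))
  j
}

#' Bilateral movement time lag
#'
#' The lag maximizing the normalized cross-correlation between the
#' mean-subtracted left and right displacement vector series (dx and dy
#' components jointly), searched over a bounded window. Walking's left-right
#' paw alternation produces a noticeable lag; grooming's synchronous strokes
#' do not. The magnitude is returned; the signed lag and a degenerate flag
#' (zero-variance input) are attached as attributes.
#'
#' @param left,right \code{paw_trajectory} objects.
#' @param max_lag_s Search half-window in seconds (default 1).
#' @return Lag magnitude in seconds, with attributes \code{"signed_lag_s"}
#'   and \code{"degenerate"}.
#' @export
movement_lag <- function(left, right, max_lag_s = 1) {
  fps <- .traj_fps(left)
  j <- .paired_steps(left, right)
  max_lag <- round(max_lag_s * fps)
  if (nrow(j) < 2 * max_lag || max_lag < 1) {
    stop("insufficient data: displacement series too short for the lag window",
         call. = FALSE)
  }
  ux <- j$dx_l - mean(j$dx_l); uy <- j$dy_l - mean(j$dy_l)
  wx <- j$dx_r - mean(j$dx_r); wy <- j$dy_r - mean(j$dy_r)
  su <- sum(ux^2 + uy^2); sw <- sum(wx^2 + wy^2)
  if (su == 0 || sw == 0) {
    return(structure(0, signed_lag_s = 0, degenerate = TRUE))
  }
  n <- nrow(j)
  lags <- -max_lag:max_lag
  r <- vapply(lags, function(l) {
    if (l >= 0) {
      i <- seq_len(n - l)
      sum(ux[i] * wx[i + l] + uy[i] * wy[i + l])
    } else {
      i <- seq_len(n + l)
      sum(ux[i - l] * wx[i] + uy[i - l] * wy[i])
    }
  }, numeric(1)) / sqrt(su * sw)
  best <- lags[which.max(r)]
  structure(abs(best) / fps, signed_lag_s = best / fps, degenerate = FALSE)
}

#' Bilateral displacement correlation
#'
#' Pearson correlation between the paired frame-by-frame displacement
#' magnitudes of the two paws, the standard summary of bilateral
#' coordination of grooming strokes.
#'
#' @param left,right \code{paw_trajectory} objects.
#' @return Pearson r.
#' @export
displacement_correlation <- function(left, right) {
  j <- .paired_steps(left, right)
  if (nrow(j) < 3) {
    stop("insufficient data: need at least 3 paired displacement steps",
         call. = FALSE)
  }
  sl <- j$step_px_l; sr <- j$step_px_r
  if (stats::sd(sl) == 0 || stats::sd(sr) == 0) {
    stop("degenerate input: zero-variance displacement series", call. = FALSE)
  }
  stats::cor(sl, sr)
}

#' Summarize a bout of forepaw movement
#'
#' Computes the full metric set of one bout from its two paw trajectories:
#' covered area and path length (averaged over the two paws), mean speed,
#' mean inter-paw distance, bilateral lag and displacement correlation.
#'
#' @param left,right \code{paw_trajectory} objects.
#' @param max_lag_s Lag search window, seconds.
#' @return One-row \code{bout_metrics} tibble: \code{covered_area_cm2},
#'   \code{path_length_mm}, \code{mean_speed_mm_s}, \code{mean_interpaw_mm},
#'   \code{lag_s}, \code{displacement_r}.
#' @export
bout_metrics <- function(left, right, max_lag_s = 1) {
  out <- tibble::tibble(
    covered_area_cm2 = (covered_area(left) + covered_area(right)) / 2,
    path_length_mm = (path_length(left) + path_length(right)) / 2,
    mean_speed_mm_s = (attr(speed_series(left), "mean") +
                         attr(speed_series(right), "mean")) / 2,
    mean_interpaw_mm = interpaw_distance(left, right),
    lag_s = as.numeric(movement_lag(left, right, max_lag_s)),
    displacement_r = displacement_correlation(left, right)
  )
  class(out) <- c("bout_metrics", class(out))
  out
}

#' @exportS3Method generics::tidy
tidy.bout_metrics <- function(x, ...) {
  tibble::tibble(metric = names(x), value = as.numeric(x[1, ]))
}

#' @exportS3Method generics::glance
glance.bout_metrics <- function(x, ...) tibble::as_tibble(unclass(x))

#' Classify a bout as grooming or walking
#'
#' Three criteria vote independently: covered area, inter-paw distance and
#' bilateral lag, each voting grooming when strictly below its threshold and
#' walking when strictly above (a value exactly at threshold abstains). The
#' majority decides; without a majority the bout is unclassified. The
#' default thresholds sit midway between typical grooming and walking group
#' values (area 10 cm^2, distance 8 mm, lag 0.2 s) and are calibration
#' constants, not claims.
#'
#' @param m A \code{bout_metrics} row.
#' @param thr Named thresholds \code{c(area_cm2 =, dist_mm =, lag_s =)}.
#' @return \code{"GROOMING"}, \code{"WALKING"} or \code{"UNCLASSIFIED"}.
#' @export
classify_bout <- function(m, thr = c(area_cm2 = 10, dist_mm = 8, lag_s = 0.2)) {
  vals <- c(m$covered_area_cm2, m$mean_interpaw_mm, m$lag_s)
  lims <- c(thr[["area_cm2"]], thr[["dist_mm"]], thr[["lag_s"]])
  groom <- sum(vals < lims)
  walk <- sum(vals > lims)
  if (groom > walk && groom >= 2) "GROOMING"
  else if (walk > groom && walk >= 2) "WALKING"
  else "UNCLASSIFIED"
}

#' Detect grooming episodes from paw trajectories
#'
#' A sliding window computes the joint covered area of both paws around
#' every frame; frames where that area stays below the threshold and both
#' paws are tracked are grooming candidates. Candidate runs shorter than
#' \code{min_duration_s} are dropped and surviving runs separated by less
#' than \code{merge_gap_s} are merged.
#'
#' @param left,right \code{paw_trajectory} objects.
#' @param window_s Sliding window width, seconds (default 1).
#' @param area_thresh_cm2 Covered-area threshold at window scale, cm^2
#'   (default 2.5; note this is a per-window threshold, necessarily smaller
#'   than the whole-bout classification threshold).
#' @param min_duration_s Minimum episode duration, seconds (default 2).
#' @param merge_gap_s Maximum gap between merged runs, seconds (default 0.5).
#' @return Tibble of episodes: \code{start_frame}, \code{end_frame}
#'   (inclusive), \code{duration_min}.
#' @export
detect_episodes <- function(left, right, window_s = 1, area_thresh_cm2 = 2.5,
                            min_duration_s = 2, merge_gap_s = 0.5) {
  fps <- .traj_fps(left)
  px <- .traj_px(left)
  n <- nrow(left)
  stopifnot(nrow(right) == n, all(left$frame == right$frame))
  half <- max(1L, round(window_s * fps / 2))
  xs <- c(left$x, right$x); ys <- c(left$y, right$y)
  ok <- c(left$tracked, right$tracked)
  cand <- logical(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    sel <- c(lo:hi, n + (lo:hi))
    sel <- sel[ok[sel]]
    area <- .hull_area(xs[sel], ys[sel]) * px^2 / 100
    cand[i] <- left$tracked[i] && right$tracked[i] && area < area_thresh_cm2
  }
  runs <- .runs_from_logical(cand)
  if (nrow(runs) == 0) return(.empty_episodes())
  runs <- runs[(runs$end - runs$start + 1) / fps >= min_duration_s, ]
  if (nrow(runs) == 0) return(.empty_episodes())
  merged <- runs[1, ]
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      gap <- (runs$start[i] - merged$end[nrow(merged)] - 1) / fps
      if (gap < merge_gap_s) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
  }
  tibble::tibble(
    start_frame = left$frame[merged$start],
    end_frame = left$frame[merged$end],
    duration_min = (merged$end - merged$start + 1) / fps / 60
  )
}

.runs_from_logical <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(start = starts[r$values], end = ends[r$values])
}

.empty_episodes <- function() {
  tibble::tibble(start_frame = integer(), end_frame = integer(),
                 duration_min = numeric())
}
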