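#' Reference hue histogram of a paw ROI
#'
#' Frequency counts of pixel hues inside the reference rectangle drawn on the
#' first video frame, binned over \code{[0, 360)} and normalized so the
#' maximum bin equals 1. Only hue is histogrammed — not saturation or value —
#' which is what makes tracking insensitive to lighting and to paws lifting
#' off the arena floor.
#'
#' @param img An \code{hsv_image}.
#' @param roi Rectangle \code{c(x, y, w, h)}, 0-based half-open, inside the
#'   frame.
#' @param n_bins Number of hue bins (default 36, i.e. 10-degree bins).
#' @return A \code{hue_histogram}: list with \code{n_bins} and \code{weights}
#'   (max-normalized bin weights).
#' @export
reference_histogram <- function(img, roi, n_bins = 36) {
  stopifnot(inherits(img, "hsv_image"), length(roi) == 4, n_bins >= 1)
  d <- dim(img$h)
  roi <- round(roi)
  if (roi[3] < 1 || roi[4] < 1 ||
      roi[1] < 0 || roi[2] < 0 ||
      roi[1] + roi[3] > d[2] || roi[2] + roi[4] > d[1]) {
    stop("reference ROI is empty or outside the frame", call. = FALSE)
  }
  rows <- (roi[2] + 1):(roi[2] + roi[4])
  cols <- (roi[1] + 1):(roi[1] + roi[3])
  h <- img$h[rows, cols]
  bins <- .hue_bin(h, n_bins)
  counts <- tabulate(bins, nbins = n_bins)
  structure(list(n_bins = n_bins, weights = counts / max(counts)),
            class = "hue_histogram")
}

.hue_bin <- function(h, n_bins) {
  b <- floor(h / (360 / n_bins)) + 1L
  pmin(pmax(b, 1L), n_bins)
}

#' Back-project a hue histogram onto a frame
#'
#' Every pixel inside the paw color mask is replaced by the weight of its hue
#' bin in the reference histogram, yielding a probability map of how
#' reference-like each pixel is; pixels outside the mask are 0.
#'
#' @param img An \code{hsv_image}.
#' @param hist A \code{hue_histogram}.
#' @param paw_mask Logical matrix, frame-sized.
#' @return Numeric matrix in \code{[0, 1]}, frame-sized.
#' @export
back_project <- function(img, hist, paw_mask) {
  stopifnot(inherits(img, "hsv_image"), inherits(hist, "hue_histogram"),
            all(dim(img$h) == dim(paw_mask)))
  p <- matrix(0, nrow(paw_mask), ncol(paw_mask))
  idx <- which(paw_mask)
  if (length(idx)) {
    p[idx] <- hist$weights[.hue_bin(img$h[idx], hist$n_bins)]
  }
  p
}

# Probability-weighted centroid and mass inside an integer window
# (0-based half-open rect), in 0-based pixel coordinates.
.window_stats <- function(pmap, w) {
  d <- dim(pmap)
  x0 <- max(0, round(w[1])); y0 <- max(0, round(w[2]))
  x1 <- min(d[2], round(w[1] + w[3])); y1 <- min(d[1], round(w[2] + w[4]))
  if (x1 <= x0 || y1 <= y0) return(list(mass = 0, cx = NA_real_, cy = NA_real_))
  sub <- pmap[(y0 + 1):y1, (x0 + 1):x1, drop = FALSE]
  mass <- sum(sub)
  if (mass == 0) return(list(mass = 0, cx = NA_real_, cy = NA_real_))
  xs <- x0:(x1 - 1); ys <- y0:(y1 - 1)
  list(mass = mass,
       cx = sum(colSums(sub) * xs) / mass,
       cy = sum(rowSums(sub) * ys) / mass)
}

#' Mean-shift window tracking on a probability map
#'
#' The window is iteratively re-centered on the probability-weighted centroid
#' of its contents until the center shift drops below \code{eps} pixels or
#' \code{max_iter} iterations, converging onto the highest-density pixel
#' cluster near the start window.
#'
#' @param pmap Probability map (matrix).
#' @param w0 Start window \code{c(x, y, w, h)}.
#' @param max_iter Iteration cap (default 10).
#' @param eps Convergence threshold on the center shift, pixels (default 1).
#' @return List: \code{window} (same size, repositioned), \code{center}
#'   \code{c(x, y)} weighted centroid (NA if mass 0), \code{mass} summed
#'   probability in the final window, \code{converged} flag.
#' @export
mean_shift <- function(pmap, w0, max_iter = 10, eps = 1) {
  stopifnot(max_iter >= 1, eps > 0)
  w <- as.numeric(w0)
  d <- dim(pmap)
  converged <- FALSE
  st <- .window_stats(pmap, w)
  if (st$mass == 0) {
    return(list(window = w, center = c(NA_real_, NA_real_),
                mass = 0, converged = FALSE))
  }
  for (i in seq_len(max_iter)) {
    st <- .window_stats(pmap, w)
    if (st$mass == 0) break
    new_x <- st$cx - w[3] / 2 + 0.5
    new_y <- st$cy - w[4] / 2 + 0.5
    # keep the window inside the frame
    new_x <- min(max(new_x, 0), d[2] - w[3])
    new_y <- min(max(new_y, 0), d[1] - w[4])
    shift <- sqrt((new_x - w[1])^2 + (new_y - w[2])^2)
    w[1] <- new_x; w[2] <- new_y
    if (shift < eps) { converged <- TRUE; break }
  }
  st <- .window_stats(pmap, w)
  list(window = w,
       center = c(st$cx, st$cy),
       mass = st$mass,
       converged = converged)
}

#' Rescale the tracking window to the detected cluster size
#'
#' Continuously-adaptive (CAM-shift style) window scaling: the bigger the
#' pixel cluster, the bigger the window. Side lengths follow
#' \code{side = scale * sqrt(mass)} with the window's aspect ratio preserved,
#' clamped between \code{min_side} and the body box dimensions.
#'
#' @param w Window \code{c(x, y, w, h)}.
#' @param mass Summed probability of the detected cluster.
#' @param scale Proportionality constant (default 2).
#' @param min_side Lower clamp on each side, pixels.
#' @param max_dims Optional upper clamp \code{c(w, h)} (the body box).
#' @return Window of the new size, same center.
#' @export
adapt_window <- function(w, mass, scale = 2, min_side = 4, max_dims = NULL) {
  stopifnot(mass >= 0)
  if (mass == 0) return(as.numeric(w))
  side <- scale * sqrt(mass)
  aspect <- sqrt(w[3] / w[4])
  nw <- side * aspect
  nh <- side / aspect
  nw <- max(nw, min_side); nh <- max(nh, min_side)
  if (!is.null(max_dims)) {
    nw <- min(nw, max_dims[1]); nh <- min(nh, max_dims[2])
  }
  cx <- w[1] + w[3] / 2; cy <- w[2] + w[4] / 2
  c(cx - nw / 2, cy - nh / 2, nw, nh)
}

#' Grow the tracking window after a lost paw
#'
#' When a paw disappears (occluded behind the body or out of the field of
#' view) the window is progressively enlarged about its center until it
#' matches the body box, so the paw is re-acquired as soon as it reappears.
#'
#' @param w Window \code{c(x, y, w, h)}.
#' @param body_bbox Body box \code{c(x, y, w, h)} capping the growth.
#' @param rate Fractional growth per frame (default 0.10).
#' @param frame_dim Frame dimensions \code{c(height, width)} for clipping.
#' @return Grown window.
#' @export
grow_on_loss <- function(w, body_bbox, rate = 0.10, frame_dim = NULL) {
  stopifnot(rate > 0)
  cx <- w[1] + w[3] / 2; cy <- w[2] + w[4] / 2
  nw <- min(w[3] * (1 + rate), body_bbox[3])
  nh <- min(w[4] * (1 + rate), body_bbox[4])
  out <- c(cx - nw / 2, cy - nh / 2, nw, nh)
  if (!is.null(frame_dim)) {
    out[1] <- min(max(out[1], 0), frame_dim[2] - out[3])
    out[2] <- min(max(out[2], 0), frame_dim[1] - out[4])
  }
  out
}

# Highest-mass probability cluster inside an optional region; used to re-seed
# the window when it has drifted off all probability mass (e.g. after a long
# occlusion while the mouse moved). Ties broken by smaller y, then smaller x.
.best_cluster <- function(pmap, min_mass, region = NULL) {
  m <- pmap > 0
  if (!is.null(region)) {
    keep <- matrix(FALSE, nrow(m), ncol(m))
    x0 <- max(0, floor(region[1])); y0 <- max(0, floor(region[2]))
    x1 <- min(ncol(m), ceiling(region[1] + region[3]))
    y1 <- min(nrow(m), ceiling(region[2] + region[4]))
    if (x1 > x0 && y1 > y0) keep[(y0 + 1):y1, (x0 + 1):x1] <- TRUE
    m <- m & keep
  }
  if (!any(m)) return(NULL)
  comps <- find_components(m, min_area = 1)
  lab <- attr(comps, "labels")
  mass <- vapply(comps$label, function(l) sum(pmap[lab == l]), numeric(1))
  ok <- mass >= min_mass
  if (!any(ok)) return(NULL)
  cand <- comps[ok, ]
  cand$mass <- mass[ok]
  cand <- cand[order(-cand$mass, cand$y, cand$x), ]
  list(x = cand$x[1], y = cand$y[1], mass = cand$mass[1])
}

#' Track one paw through one frame
#'
#' One step of the tracking loop: back-project the reference hue histogram
#' through the paw color mask, restrict to the mouse's search region, run
#' mean shift from the previous window, and accept the detection only if the
#' cluster mass reaches \code{min_box_size} and the centroid lies inside the
#' search region. On success the window is rescaled to the cluster; on loss
#' the centroid is the LOST sentinel (NA) and the window grows toward the
#' body box. A window that has drifted off all probability mass is re-seeded
#' at the highest-mass cluster inside the search region.
#'
#' @param img An \code{hsv_image} of the current frame.
#' @param prev Previous paw state: list with \code{window} (and optionally
#'   \code{tracked}).
#' @param body One row of [body_state()] for this mouse's enclosure.
#' @param hist The paw's reference \code{hue_histogram} (from frame 0).
#' @param paw_mask Logical paw color mask of the current frame.
#' @param cfg A [tracker_config()] (uses \code{min_box_size}, mean-shift and
#'   window parameters).
#' @return Paw state: list with \code{window}, \code{x}, \code{y} (NA when
#'   lost), \code{mass}, \code{tracked}.
#' @export
track_paw_frame <- function(img, prev, body, hist, paw_mask, cfg) {
  d <- dim(img$h)
  pmap <- back_project(img, hist, paw_mask)
  region <- NULL
  if (isTRUE(body$present)) {
    region <- search_region(
      c(body$bbox_x, body$bbox_y, body$bbox_w, body$bbox_h),
      d, expansion = cfg$expansion
    )
    # detections outside the search region belong to another mouse
    mask_reg <- matrix(0, d[1], d[2])
    x0 <- max(0, floor(region[1])); y0 <- max(0, floor(region[2]))
    x1 <- min(d[2], ceiling(region[1] + region[3]))
    y1 <- min(d[1], ceiling(region[2] + region[4]))
    if (x1 > x0 && y1 > y0) mask_reg[(y0 + 1):y1, (x0 + 1):x1] <- 1
    pmap <- pmap * mask_reg
  }
  w <- as.numeric(prev$window)
  if (.window_stats(pmap, w)$mass == 0) {
    seed <- .best_cluster(pmap, cfg$min_box_size, region)
    if (!is.null(seed)) {
      w <- c(seed$x - w[3] / 2, seed$y - w[4] / 2, w[3], w[4])
    }
  }
  ms <- mean_shift(pmap, w, max_iter = cfg$max_iter, eps = cfg$eps)
  tracked <- is.finite(ms$mass) && ms$mass >= cfg$min_box_size &&
    !any(is.na(ms$center))
  if (tracked && !is.null(region)) {
    tracked <- ms$center[1] >= region[1] &&
      ms$center[1] <= region[1] + region[3] &&
      ms$center[2] >= region[2] &&
      ms$center[2] <= region[2] + region[4]
  }
  if (tracked) {
    max_dims <- if (isTRUE(body$present)) c(body$bbox_w, body$bbox_h) else NULL
    win <- adapt_window(ms$window, ms$mass, scale = cfg$window_scale,
                        min_side = cfg$min_window_side, max_dims = max_dims)
    list(window = win, x = ms$center[1], y = ms$center[2],
         mass = ms$mass, tracked = TRUE)
  } else {
    body_box <- if (isTRUE(body$present)) {
      c(body$bbox_x, body$bbox_y, body$bbox_w, body$bbox_h)
    } else {
      c(0, 0, d[2], d[1])
    }
    win <- grow_on_loss(as.numeric(prev$window), body_box,
                        rate = cfg$loss_growth_rate, frame_dim = d)
    list(window = win, x = NA_real_, y = NA_real_,
         mass = ms$mass, tracked = FALSE)
  }
}
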