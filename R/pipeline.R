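#' Read an ordered frame stream
#'
#' Ingests a video as an image-sequence directory of TIFF or PNG frames
#' (read in filename order) or passes through an in-memory list of frames.
#' Every frame is a \code{height x width x 3} RGB array in \code{[0, 1]};
#' grayscale frames are expanded to three channels, alpha channels dropped.
#'
#' @param source Directory path containing numbered \code{.tif/.tiff/.png}
#'   frames, or a list of frame arrays.
#' @return List with \code{frames} (list of arrays), \code{n_frames} and
#'   \code{dim} \code{c(height, width)}.
#' @export
read_frames <- function(source) {
  if (is.list(source) && !is.character(source)) {
    frames <- lapply(source, .as_rgb_frame)
  } else if (is.character(source) && dir.exists(source)) {
    files <- list.files(source, pattern = "\\.(tif|tiff|png)$",
                        ignore.case = TRUE, full.names = TRUE)
    files <- sort(files)
    if (length(files) == 0) {
      stop("I/O error: no TIFF/PNG frames found in directory ", source,
           call. = FALSE)
    }
    frames <- lapply(files, function(f) {
      img <- if (grepl("\\.png$", f, ignore.case = TRUE)) {
        png::readPNG(f)
      } else {
        tiff::readTIFF(f)
      }
      .as_rgb_frame(img)
    })
  } else if (is.character(source)) {
    ext <- tolower(tools::file_ext(source))
    stop(sprintf(
      "I/O error: cannot read '%s' (format '%s'); supported sources are image-sequence directories (TIFF/PNG) and in-memory frame lists",
      source, ext), call. = FALSE)
  } else {
    stop("I/O error: unsupported frame source", call. = FALSE)
  }
  dims <- dim(frames[[1]])[1:2]
  for (f in frames) {
    if (!all(dim(f)[1:2] == dims)) {
      stop("I/O error: frames have inconsistent dimensions", call. = FALSE)
    }
  }
  list(frames = frames, n_frames = length(frames), dim = dims)
}

.as_rgb_frame <- function(img) {
  if (length(dim(img)) == 2) {
    img <- array(rep(img, 3), dim = c(dim(img), 3))
  } else if (dim(img)[3] > 3) {
    img <- img[, , 1:3, drop = FALSE]
  }
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
  img
}

#' Write frames as a PNG image sequence
#'
#' @param frames List of RGB arrays in \code{[0, 1]}.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_frames <- function(frames, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_along(frames)) {
    png::writePNG(frames[[i]],
                  file.path(dir, sprintf("frame_%06d.png", i - 1)))
  }
  invisible(dir)
}

#' Track bodies and forepaws through a video
#'
#' The full tracking loop. Each frame is converted to HSV; body and paw
#' color masks are generated (and optionally dilated); the body of each
#' enclosure is detected by component merging; each paw is tracked by hue
#' back projection and mean shift seeded from its previous window, with
#' adaptive window resizing on success and progressive growth on loss.
#' Reference hue histograms come from the user-drawn ROIs on frame 0 only,
#' and the same HSV limits apply to every enclosure. The tracker is fully
#' deterministic: identical frames and configuration give identical records.
#'
#' @param frames Frame source accepted by [read_frames()].
#' @param cfg A [tracker_config()].
#' @param keep_windows If TRUE, append per-paw tracking-window sizes
#'   (\code{left_win_w}, \code{left_win_h}, \code{right_win_w},
#'   \code{right_win_h}) to the records, useful to inspect loss-recovery
#'   behavior.
#' @return A tibble of tracking records, one row per frame per mouse:
#'   \code{frame} (0-based), \code{mouse} (enclosure id), \code{body_x},
#'   \code{body_y}, \code{orientation}, \code{left_x}, \code{left_y},
#'   \code{left_tracked}, \code{right_x}, \code{right_y},
#'   \code{right_tracked}. Lost paws carry NA coordinates and a FALSE flag;
#'   no frame is ever dropped from the output.
#' @export
track_video <- function(frames, cfg, keep_windows = FALSE) {
  stopifnot(inherits(cfg, "tracker_config"))
  src <- read_frames(frames)
  layout <- build_layout(cfg$corners, cfg$n_mice, cfg$dividers)
  d <- src$dim
  img0 <- frame_to_hsv(src$frames[[1]])
  state <- vector("list", cfg$n_mice)
  for (m in seq_len(cfg$n_mice)) {
    rois <- cfg$paw_rois[[m]]
    for (side in c("left", "right")) {
      roi <- rois[[side]]
      if (roi[1] < 0 || roi[2] < 0 ||
          roi[1] + roi[3] > d[2] || roi[2] + roi[4] > d[1]) {
        stop(sprintf("config error: %s paw reference ROI of mouse %d is outside the frame",
                     side, m - 1), call. = FALSE)
      }
    }
    state[[m]] <- list(
      left = list(window = as.numeric(rois$left), tracked = TRUE,
                  hist = reference_histogram(img0, rois$left, cfg$n_bins)),
      right = list(window = as.numeric(rois$right), tracked = TRUE,
                   hist = reference_histogram(img0, rois$right, cfg$n_bins))
    )
  }
  n <- src$n_frames
  rows <- vector("list", n)
  for (f in seq_len(n)) {
    img <- if (f == 1) img0 else frame_to_hsv(src$frames[[f]])
    body_mask <- dilate_mask(make_mask(img, cfg$body_hsv), cfg$dilation)
    bodies <- body_state(body_mask, layout,
                         min_area = cfg$body_min_area,
                         merge_gap = cfg$merge_gap)
    left_mask <- dilate_mask(make_mask(img, cfg$left_hsv), cfg$dilation)
    right_mask <- dilate_mask(make_mask(img, cfg$right_hsv), cfg$dilation)
    rec <- vector("list", cfg$n_mice)
    for (m in seq_len(cfg$n_mice)) {
      body <- bodies[bodies$enclosure == m - 1L, ]
      st <- state[[m]]
      lp <- track_paw_frame(img, st$left, body, st$left$hist, left_mask, cfg)
      rp <- track_paw_frame(img, st$right, body, st$right$hist, right_mask, cfg)
      state[[m]]$left[c("window", "tracked")] <- lp[c("window", "tracked")]
      state[[m]]$right[c("window", "tracked")] <- rp[c("window", "tracked")]
      rec[[m]] <- tibble::tibble(
        frame = f - 1L, mouse = m - 1L,
        body_x = body$x, body_y = body$y, orientation = body$orientation,
        left_x = lp$x, left_y = lp$y, left_tracked = lp$tracked,
        right_x = rp$x, right_y = rp$y, right_tracked = rp$tracked
      )
      if (keep_windows) {
        rec[[m]]$left_win_w <- lp$window[3]
        rec[[m]]$left_win_h <- lp$window[4]
        rec[[m]]$right_win_w <- rp$window[3]
        rec[[m]]$right_win_h <- rp$window[4]
      }
    }
    rows[[f]] <- dplyr::bind_rows(rec)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "pixel_size_mm") <- cfg$pixel_size_mm
  attr(out, "fps") <- cfg$fps
  out
}
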