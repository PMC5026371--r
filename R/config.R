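#' Tracking configuration
#'
#' All user-set detection parameters, the headless equivalent of the GUI
#' controls: arena corners and dividers, number of mice, HSV mask limits for
#' the body and each paw, mask dilation, cluster-size threshold, search
#' region expansion, mean-shift parameters, pixel size and frame rate.
#'
#' @param corners 3x2 matrix of arena corner pixel coordinates.
#' @param n_mice 1, 2 or 4.
#' @param dividers List of divider segments (see [build_layout()]).
#' @param body_hsv,left_hsv,right_hsv [hsv_range()] mask limits; the same
#'   limits are applied to every enclosure.
#' @param paw_rois Per-mouse list of \code{list(left = c(x,y,w,h),
#'   right = ...)} reference rectangles drawn inside the colored paws on the
#'   first frame.
#' @param dilation Mask dilation radius, pixels.
#' @param body_min_area Minimum body component area, pixels.
#' @param merge_gap Body fragment collision gap, pixels.
#' @param min_box_size Lower threshold on paw cluster probability mass below
#'   which the detection is rejected as noise.
#' @param expansion Search-region linear enlargement (default 0.10: paws are
#'   tracked within a region 10\% larger than the body box).
#' @param n_bins Hue histogram bins (default 36).
#' @param max_iter,eps Mean-shift iteration cap and convergence threshold.
#' @param window_scale,min_window_side Adaptive window scaling constant and
#'   lower side clamp.
#' @param loss_growth_rate Window growth per frame while a paw is lost.
#' @param pixel_size_mm Physical size of one pixel, mm.
#' @param fps Frame rate, frames per second.
#' @return A \code{tracker_config} list.
#' @export
tracker_config <- function(corners, n_mice = 1, dividers = list(),
                           body_hsv, left_hsv, right_hsv, paw_rois,
                           dilation = 0, body_min_area = 50, merge_gap = 5,
                           min_box_size = 25, expansion = 0.10, n_bins = 36,
                           max_iter = 10, eps = 1, window_scale = 2,
                           min_window_side = 4, loss_growth_rate = 0.10,
                           pixel_size_mm = 0.21, fps = 60) {
  stopifnot(pixel_size_mm > 0, fps > 0, n_mice %in% c(1, 2, 4))
  cfg <- list(
    corners = as.matrix(corners), n_mice = as.integer(n_mice),
    dividers = dividers,
    body_hsv = body_hsv, left_hsv = left_hsv, right_hsv = right_hsv,
    paw_rois = paw_rois,
    dilation = dilation, body_min_area = body_min_area,
    merge_gap = merge_gap, min_box_size = min_box_size,
    expansion = expansion, n_bins = n_bins,
    max_iter = max_iter, eps = eps,
    window_scale = window_scale, min_window_side = min_window_side,
    loss_growth_rate = loss_growth_rate,
    pixel_size_mm = pixel_size_mm, fps = fps
  )
  class(cfg) <- "tracker_config"
  cfg
}

#' Read / write a tracking configuration file
#'
#' Flat \code{key = value} text dialect; vector values are space-separated.
#' HSV ranges are six numbers (h_lo h_hi s_lo s_hi v_lo v_hi) on the
#' degree/unit scales; rectangles are \code{x y w h}; corners are
#' \code{x1 y1 x2 y2 x3 y3}. Paw ROI keys are \code{left_roi_m<i>} /
#' \code{right_roi_m<i>} per mouse i (0-based).
#'
#' @param path File path.
#' @return \code{read_config}: a \code{tracker_config}.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[[`, "", 1))
  vals <- lapply(kv, function(x) {
    as.numeric(strsplit(trimws(paste(x[-1], collapse = "=")), "\\s+")[[1]])
  })
  names(vals) <- keys
  need <- function(k) {
    if (is.null(vals[[k]])) stop("config is missing key: ", k, call. = FALSE)
    vals[[k]]
  }
  opt <- function(k, default) if (is.null(vals[[k]])) default else vals[[k]]
  n_mice <- as.integer(need("n_mice"))
  dividers <- list()
  for (k in c("divider1", "divider2")) {
    if (!is.null(vals[[k]])) {
      dividers <- c(dividers, list(matrix(vals[[k]], 2, 2, byrow = TRUE)))
    }
  }
  rng <- function(k) do.call(hsv_range, as.list(need(k)))
  rois <- lapply(seq_len(n_mice) - 1L, function(i) {
    list(left = need(sprintf("left_roi_m%d", i)),
         right = need(sprintf("right_roi_m%d", i)))
  })
  tracker_config(
    corners = matrix(need("corners"), 3, 2, byrow = TRUE),
    n_mice = n_mice, dividers = dividers,
    body_hsv = rng("body_hsv"), left_hsv = rng("left_hsv"),
    right_hsv = rng("right_hsv"), paw_rois = rois,
    dilation = opt("dilation", 0),
    body_min_area = opt("body_min_area", 50),
    merge_gap = opt("merge_gap", 5),
    min_box_size = opt("min_box_size", 25),
    expansion = opt("expansion", 0.10),
    n_bins = opt("n_bins", 36),
    max_iter = opt("max_iter", 10), eps = opt("eps", 1),
    window_scale = opt("window_scale", 2),
    min_window_side = opt("min_window_side", 4),
    loss_growth_rate = opt("loss_growth_rate", 0.10),
    pixel_size_mm = opt("pixel_size_mm", 0.21),
    fps = opt("fps", 60)
  )
}

#' @rdname read_config
#' @param cfg A \code{tracker_config}.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "tracker_config"))
  num <- function(x) paste(format(x, trim = TRUE, scientific = FALSE),
                           collapse = " ")
  rng <- function(r) num(unlist(r[c("h_lo", "h_hi", "s_lo", "s_hi",
                                    "v_lo", "v_hi")]))
  lines <- c(
    paste("corners =", num(as.vector(t(cfg$corners)))),
    paste("n_mice =", cfg$n_mice)
  )
  for (i in seq_along(cfg$dividers)) {
    lines <- c(lines, paste0("divider", i, " = ",
                             num(as.vector(t(cfg$dividers[[i]])))))
  }
  lines <- c(
    lines,
    paste("body_hsv =", rng(cfg$body_hsv)),
    paste("left_hsv =", rng(cfg$left_hsv)),
    paste("right_hsv =", rng(cfg$right_hsv))
  )
  for (i in seq_along(cfg$paw_rois)) {
    lines <- c(
      lines,
      sprintf("left_roi_m%d = %s", i - 1, num(cfg$paw_rois[[i]]$left)),
      sprintf("right_roi_m%d = %s", i - 1, num(cfg$paw_rois[[i]]$right))
    )
  }
  for (k in c("dilation", "body_min_area", "merge_gap", "min_box_size",
              "expansion", "n_bins", "max_iter", "eps", "window_scale",
              "min_window_side", "loss_growth_rate", "pixel_size_mm", "fps")) {
    lines <- c(lines, paste(k, "=", num(cfg[[k]])))
  }
  writeLines(lines, path)
  invisible(path)
}
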