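#' Arena geometry
#'
#' The behavioral arena is a rectangle specified by three of its four corners
#' (the fourth is completed as a parallelogram). Because camera and arena are
#' rarely perfectly aligned, the layout carries a rotation correction that
#' maps raw pixel coordinates into a rectified frame where the arena is
#' axis-aligned. Arenas holding 2 or 4 mice are split by 1 or 2 divider lines
#' into enclosures numbered row-major from the top-left.
#'
#' Pixel coordinates are 0-based, origin top-left, x rightward, y downward.
#'
#' @param corners Numeric 3x2 matrix (or data frame with columns x, y) of
#'   three consecutive rectangle corners in pixel coordinates; the middle
#'   point is the shared vertex of the two edges.
#' @param n_enclosures 1, 2 or 4 mice/enclosures.
#' @param dividers List of divider segments, each a 2x2 matrix of endpoint
#'   coordinates; 0, 1 or 2 segments for 1, 2 or 4 enclosures.
#' @return An \code{arena_layout} object with elements \code{corners} (all
#'   four), \code{center}, \code{rotation} (degrees; the correction applied
#'   to rectify), \code{bounds} (xmin, ymin, w, h in rectified coordinates),
#'   \code{n_enclosures}, and divider positions in rectified coordinates.
#' @export
build_layout <- function(corners, n_enclosures = 1, dividers = list()) {
  corners <- as.matrix(corners)
  stopifnot(nrow(corners) == 3, ncol(corners) == 2)
  if (!n_enclosures %in% c(1L, 2L, 4L)) {
    stop("n_enclosures must be 1, 2 or 4", call. = FALSE)
  }
  n_div <- c(`1` = 0L, `2` = 1L, `4` = 2L)[as.character(n_enclosures)]
  if (length(dividers) != n_div) {
    stop(sprintf("%d enclosure(s) require %d divider line(s), got %d",
                 n_enclosures, n_div, length(dividers)), call. = FALSE)
  }
  p1 <- corners[1, ]; p2 <- corners[2, ]; p3 <- corners[3, ]
  cross <- (p1[1] - p2[1]) * (p3[2] - p2[2]) - (p1[2] - p2[2]) * (p3[1] - p2[1])
  scale <- max(1, max(abs(corners)))
  if (abs(cross) < 1e-9 * scale^2) {
    stop("arena corners are collinear", call. = FALSE)
  }
  p4 <- p1 + p3 - p2  # parallelogram completion
  all4 <- rbind(corners, p4)
  center <- colMeans(all4)
  # correction angle: rotate so the first edge (p1 -> p2) becomes horizontal
  edge <- p2 - p1
  rotation <- -atan2(edge[2], edge[1]) * 180 / pi

  layout <- structure(
    list(corners = all4, center = center, rotation = rotation,
         n_enclosures = as.integer(n_enclosures)),
    class = "arena_layout"
  )
  rect <- to_rectified(all4, layout)
  layout$bounds <- c(
    xmin = min(rect[, 1]), ymin = min(rect[, 2]),
    w = max(rect[, 1]) - min(rect[, 1]),
    h = max(rect[, 2]) - min(rect[, 2])
  )
  # classify dividers in rectified space: vertical splits left/right,
  # horizontal splits top/bottom
  layout$div_x <- NA_real_
  layout$div_y <- NA_real_
  for (seg in dividers) {
    seg <- to_rectified(as.matrix(seg), layout)
    dx <- abs(seg[2, 1] - seg[1, 1]); dy <- abs(seg[2, 2] - seg[1, 2])
    if (dy >= dx) layout$div_x <- mean(seg[, 1]) else layout$div_y <- mean(seg[, 2])
  }
  if (n_enclosures == 4 && (is.na(layout$div_x) || is.na(layout$div_y))) {
    stop("a 2x2 arena needs one vertical and one horizontal divider",
         call. = FALSE)
  }
  layout
}

#' Map points into/out of the rectified arena frame
#'
#' Rotation about the arena center by the layout's correction angle (and its
#' inverse). Both accept a single point \code{c(x, y)} or an n x 2 matrix.
#'
#' @param p Point(s), pixel coordinates.
#' @param layout An \code{arena_layout}.
#' @return Point(s) of the same shape.
#' @export
to_rectified <- function(p, layout) .rotate_about(p, layout$center, layout$rotation)

#' @rdname to_rectified
#' @export
from_rectified <- function(p, layout) .rotate_about(p, layout$center, -layout$rotation)

.rotate_about <- function(p, center, angle_deg) {
  vec <- is.null(dim(p))
  p <- matrix(p, ncol = 2)
  a <- angle_deg * pi / 180
  co <- cos(a); si <- sin(a)
  dx <- p[, 1] - center[1]; dy <- p[, 2] - center[2]
  out <- cbind(center[1] + co * dx - si * dy,
               center[2] + si * dx + co * dy)
  if (vec && nrow(out) == 1) c(out) else out
}

#' Assign a point to an enclosure
#'
#' The point is rectified, tested against the arena bounds and the divider
#' half-planes. Enclosure ids are 0-based, row-major from the top-left;
#' points exactly on a divider go to the lower id. Points outside the arena
#' return \code{NA} (outside).
#'
#' @param p Point \code{c(x, y)} or n x 2 matrix, raw pixel coordinates.
#' @param layout An \code{arena_layout}.
#' @return Integer enclosure id(s); \code{NA_integer_} when outside.
#' @export
assign_enclosure <- function(p, layout) {
  r <- to_rectified(p, layout)
  r <- matrix(r, ncol = 2)
  b <- layout$bounds
  inside <- r[, 1] >= b["xmin"] & r[, 1] <= b["xmin"] + b["w"] &
    r[, 2] >= b["ymin"] & r[, 2] <= b["ymin"] + b["h"]
  right <- if (!is.na(layout$div_x)) r[, 1] > layout$div_x else FALSE
  below <- if (!is.na(layout$div_y)) r[, 2] > layout$div_y else FALSE
  ncol_grid <- if (!is.na(layout$div_x)) 2L else 1L
  id <- as.integer(below) * ncol_grid + as.integer(right)
  id[!inside] <- NA_integer_
  id
}
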