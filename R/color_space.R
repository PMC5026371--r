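#' Convert 8-bit RGB colors to HSV
#'
#' Standard hexcone conversion. Hue is reported in degrees on \code{[0, 360)},
#' saturation and value as fractions in \code{[0, 1]}. Achromatic pixels
#' (black, white, any gray) have zero saturation and carry hue 0 by
#' convention, which is why tracking by hue works equally well for black- and
#' white-furred mice: fur and background never collide with a neon paw hue.
#'
#' @param r,g,b Numeric vectors of equal length, channels in \code{[0, 255]}.
#' @return A tibble with columns \code{h} (degrees), \code{s}, \code{v}.
#' @examples
#' rgb_to_hsv(0, 255, 0)    # neon green, h = 120
#' rgb_to_hsv(255, 0, 255)  # neon magenta, h = 300
#' @export
rgb_to_hsv <- function(r, g, b) {
  if (any(c(r, g, b) < 0) || any(c(r, g, b) > 255)) {
    stop("RGB channels must lie in [0, 255]", call. = FALSE)
  }
  m <- grDevices::rgb2hsv(rbind(r, g, b), maxColorValue = 255)
  tibble::tibble(h = unname(m["h", ]) * 360, s = unname(m["s", ]),
                 v = unname(m["v", ]))
}

#' Convert an RGB frame to an HSV raster
#'
#' @param frame Numeric array \code{height x width x 3}, RGB in \code{[0, 1]}.
#' @return An \code{hsv_image}: list of matrices \code{h} (degrees), \code{s},
#'   \code{v}, each \code{height x width}.
#' @export
frame_to_hsv <- function(frame) {
  stopifnot(length(dim(frame)) == 3, dim(frame)[3] >= 3)
  d <- dim(frame)[1:2]
  m <- grDevices::rgb2hsv(rbind(
    as.vector(frame[, , 1]),
    as.vector(frame[, , 2]),
    as.vector(frame[, , 3])
  ), maxColorValue = 1)
  out <- list(
    h = matrix(m["h", ] * 360, d[1], d[2]),
    s = matrix(m["s", ], d[1], d[2]),
    v = matrix(m["v", ], d[1], d[2])
  )
  class(out) <- "hsv_image"
  out
}

#' Define an HSV mask range
#'
#' Six numbers delimit the mask: hue bounds in degrees (the hue interval may
#' wrap around 0 degrees, e.g. \code{h_lo = 350, h_hi = 10} for reds),
#' saturation and value bounds as ordered fractions.
#'
#' @param h_lo,h_hi Hue bounds, degrees in \code{[0, 360)}.
#' @param s_lo,s_hi Saturation bounds in \code{[0, 1]}, \code{s_lo <= s_hi}.
#' @param v_lo,v_hi Value bounds in \code{[0, 1]}, \code{v_lo <= v_hi}.
#' @return An \code{hsv_range} object.
#' @export
hsv_range <- function(h_lo, h_hi, s_lo = 0, s_hi = 1, v_lo = 0, v_hi = 1) {
  stopifnot(
    h_lo >= 0, h_lo < 360, h_hi >= 0, h_hi < 360,
    s_lo >= 0, s_hi <= 1, s_lo <= s_hi,
    v_lo >= 0, v_hi <= 1, v_lo <= v_hi
  )
  structure(
    list(h_lo = h_lo, h_hi = h_hi, s_lo = s_lo, s_hi = s_hi,
         v_lo = v_lo, v_hi = v_hi),
    class = "hsv_range"
  )
}

#' Test hue membership with wrap-around
#'
#' A hue interval with \code{lo > hi} crosses the 0-degree seam (relevant for
#' magenta/red ranges); membership is then \code{h >= lo | h <= hi}.
#'
#' @param h Hue(s), degrees in \code{[0, 360)}. Vectorized.
#' @param lo,hi Interval bounds, degrees in \code{[0, 360)}.
#' @return Logical vector.
#' @export
hue_in_range <- function(h, lo, hi) {
  stopifnot(all(h >= 0 & h < 360), lo >= 0, lo < 360, hi >= 0, hi < 360)
  if (lo <= hi) h >= lo & h <= hi else h >= lo | h <= hi
}

#' Build a binary color mask from an HSV raster
#'
#' A pixel is in the mask iff its hue lies in the (possibly wrapping) hue
#' interval and its saturation and value lie within their bounds. This is the
#' background-subtraction step: one range isolates the fur, one each the two
#' neon paw colors, with no empty-arena reference frame needed.
#'
#' @param img An \code{hsv_image}.
#' @param rng An \code{hsv_range}.
#' @return Logical matrix of the image's dimensions.
#' @export
make_mask <- function(img, rng) {
  stopifnot(inherits(img, "hsv_image"), inherits(rng, "hsv_range"))
  h_ok <- if (rng$h_lo <= rng$h_hi) {
    img$h >= rng$h_lo & img$h <= rng$h_hi
  } else {
    img$h >= rng$h_lo | img$h <= rng$h_hi
  }
  h_ok &
    img$s >= rng$s_lo & img$s <= rng$s_hi &
    img$v >= rng$v_lo & img$v <= rng$v_hi
}

#' Dilate a binary mask
#'
#' Morphological dilation with a square structuring element of side
#' \code{2 * radius + 1}, mirroring the user-set mask enlargement of the
#' tracking configuration. Radius 0 is the identity.
#'
#' @param mask Logical matrix.
#' @param radius Non-negative integer, pixels.
#' @return Logical matrix, a superset of \code{mask}.
#' @export
dilate_mask <- function(mask, radius) {
  stopifnot(is.matrix(mask))
  if (length(radius) != 1 || radius < 0 || radius != round(radius)) {
    stop("dilation radius must be a non-negative integer", call. = FALSE)
  }
  if (radius == 0 || !any(mask)) return(mask & TRUE)
  out <- EBImage::dilate(mask * 1, EBImage::makeBrush(2 * radius + 1, "box"))
  matrix(out > 0, nrow(mask), ncol(mask))
}
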