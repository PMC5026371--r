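#' Find connected components of a binary mask
#'
#' 8-connected components with at least \code{min_area} pixels, each with its
#' tight bounding box and centroid. This is the substrate for body-contour
#' detection: a loosely masked mouse body often fragments into several blobs
#' that are merged downstream.
#'
#' @param mask Logical matrix.
#' @param min_area Minimum pixel count per component (>= 1).
#' @return Tibble with one row per component: \code{label}, \code{area},
#'   centroid \code{x}, \code{y} (0-based pixel coordinates) and bounding box
#'   \code{bbox_x}, \code{bbox_y}, \code{bbox_w}, \code{bbox_h} (half-open).
#'   The label matrix is attached as attribute \code{"labels"}.
#' @export
find_components <- function(mask, min_area = 1) {
  stopifnot(is.matrix(mask), min_area >= 1)
  empty <- tibble::tibble(
    label = integer(), area = integer(), x = numeric(), y = numeric(),
    bbox_x = numeric(), bbox_y = numeric(), bbox_w = numeric(), bbox_h = numeric()
  )
  if (!any(mask)) {
    attr(empty, "labels") <- matrix(0L, nrow(mask), ncol(mask))
    return(empty)
  }
  lab <- .label8(mask)
  idx <- which(lab > 0L)
  labs <- lab[idx]
  row <- (idx - 1L) %% nrow(mask) + 1L
  col <- (idx - 1L) %/% nrow(mask) + 1L
  x <- col - 1L  # 0-based pixel coordinates
  y <- row - 1L
  comp <- tibble::tibble(lab = labs, x = x, y = y) |>
    dplyr::group_by(.data$lab) |>
    dplyr::summarise(
      area = dplyr::n(),
      cx = mean(.data$x), cy = mean(.data$y),
      x0 = min(.data$x), y0 = min(.data$y),
      x1 = max(.data$x), y1 = max(.data$y),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$area >= min_area)
  if (nrow(comp) == 0) {
    attr(empty, "labels") <- lab
    return(empty)
  }
  out <- tibble::tibble(
    label = as.integer(comp$lab), area = as.integer(comp$area),
    x = comp$cx, y = comp$cy,
    bbox_x = comp$x0, bbox_y = comp$y0,
    bbox_w = comp$x1 - comp$x0 + 1, bbox_h = comp$y1 - comp$y0 + 1
  )
  attr(out, "labels") <- lab
  out
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so diagonal
# neighbour label pairs are merged with a union-find pass.
.label8 <- function(mask) {
  lab <- matrix(as.integer(EBImage::bwlabel(mask * 1)), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal pairs
  a2 <- lab[-1, -nc];  b2 <- lab[-nr, -1]   # up-right diagonal pairs
  pairs <- rbind(
    cbind(as.vector(a1), as.vector(b1)),
    cbind(as.vector(a2), as.vector(b2))
  )
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs) == 0) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(n), find, integer(1))
  lab[lab > 0L] <- root[lab[lab > 0L]]
  lab
}

#' Merge fragmented components by collision detection
#'
#' Components whose bounding boxes, each expanded by \code{gap} pixels,
#' intersect are transitively merged; the largest merged group (by total
#' area) is returned as a single component with the union bounding box and
#' the area-weighted centroid. This keeps body detection robust when a tight
#' color mask splits the mouse into fragments.
#'
#' @param components Tibble from [find_components()].
#' @param gap Expansion in pixels applied to every box before the
#'   intersection test.
#' @return One-row tibble (\code{area}, \code{x}, \code{y}, \code{bbox_*})
#'   with the member labels attached as attribute \code{"members"}.
#' @export
merge_fragments <- function(components, gap = 5) {
  if (nrow(components) == 0) {
    stop("no components to merge (no body detected)", call. = FALSE)
  }
  n <- nrow(components)
  x0 <- components$bbox_x - gap
  y0 <- components$bbox_y - gap
  x1 <- components$bbox_x + components$bbox_w + gap
  y1 <- components$bbox_y + components$bbox_h + gap
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    if (x0[i] < x1[j] && x0[j] < x1[i] && y0[i] < y1[j] && y0[j] < y1[i]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  grp <- vapply(seq_len(n), find, integer(1))
  tot <- tapply(components$area, grp, sum)
  win <- as.integer(names(tot)[which.max(tot)])
  m <- components[grp == win, ]
  out <- tibble::tibble(
    area = sum(m$area),
    x = sum(m$x * m$area) / sum(m$area),
    y = sum(m$y * m$area) / sum(m$area),
    bbox_x = min(m$bbox_x), bbox_y = min(m$bbox_y),
    bbox_w = max(m$bbox_x + m$bbox_w) - min(m$bbox_x),
    bbox_h = max(m$bbox_y + m$bbox_h) - min(m$bbox_y)
  )
  attr(out, "members") <- m$label
  out
}

#' Detect the mouse body in every enclosure
#'
#' Connected components of the body mask are attributed to enclosures by
#' their centroid, merged per enclosure by collision detection, and reduced
#' to a body state: the bounding box scaled to the mask extent, the mask
#' center of mass, and the principal-axis orientation from second-order
#' central moments (degrees in \code{[0, 180)}; head/tail ambiguity is not
#' resolvable from a silhouette).
#'
#' @param mask Logical body mask, frame-sized.
#' @param layout An \code{arena_layout}.
#' @param min_area Minimum component area in pixels.
#' @param merge_gap Collision-detection box expansion in pixels.
#' @return Tibble with one row per enclosure: \code{enclosure} (0-based id),
#'   \code{present}, centroid \code{x}, \code{y}, \code{orientation},
#'   \code{bbox_x}, \code{bbox_y}, \code{bbox_w}, \code{bbox_h}.
#' @export
body_state <- function(mask, layout, min_area = 50, merge_gap = 5) {
  comps <- find_components(mask, min_area = min_area)
  lab <- attr(comps, "labels")
  n_enc <- layout$n_enclosures
  out <- tibble::tibble(
    enclosure = seq_len(n_enc) - 1L, present = FALSE,
    x = NA_real_, y = NA_real_, orientation = NA_real_,
    bbox_x = NA_real_, bbox_y = NA_real_, bbox_w = NA_real_, bbox_h = NA_real_
  )
  if (nrow(comps) == 0) return(out)
  enc <- assign_enclosure(cbind(comps$x, comps$y), layout)
  for (e in unique(enc[!is.na(enc)])) {
    sub <- comps[!is.na(enc) & enc == e, ]
    merged <- merge_fragments(sub, gap = merge_gap)
    members <- attr(merged, "members")
    idx <- which(matrix(lab %in% members, nrow(lab), ncol(lab)))
    px <- (idx - 1L) %/% nrow(lab)      # 0-based x
    py <- (idx - 1L) %% nrow(lab)       # 0-based y
    cx <- mean(px); cy <- mean(py)
    mu20 <- mean((px - cx)^2); mu02 <- mean((py - cy)^2)
    mu11 <- mean((px - cx) * (py - cy))
    theta <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
    theta <- theta %% 180
    row <- which(out$enclosure == e)
    out$present[row] <- TRUE
    out$x[row] <- cx; out$y[row] <- cy
    out$orientation[row] <- theta
    out$bbox_x[row] <- merged$bbox_x; out$bbox_y[row] <- merged$bbox_y
    out$bbox_w[row] <- merged$bbox_w; out$bbox_h[row] <- merged$bbox_h
  }
  out
}

#' Paw search region around a body box
#'
#' The paw search region is the body bounding box with each linear dimension
#' scaled by \code{1 + expansion} about its center, clipped to the frame.
#' Paws are attributed to a mouse only inside this region, which keeps
#' tracking robust when a forelimb stretches away from the body and prevents
#' a neighbour's paw from being captured.
#'
#' @param body_bbox Numeric \code{c(x, y, w, h)}, pixels (half-open box).
#' @param frame_dim Frame dimensions \code{c(height, width)} (matrix `dim()`
#'   order).
#' @param expansion Fractional linear enlargement, default 0.10.
#' @return Numeric \code{c(x, y, w, h)} clipped to the frame.
#' @export
search_region <- function(body_bbox, frame_dim, expansion = 0.10) {
  stopifnot(expansion >= 0, length(body_bbox) == 4)
  cx <- body_bbox[1] + body_bbox[3] / 2
  cy <- body_bbox[2] + body_bbox[4] / 2
  w <- body_bbox[3] * (1 + expansion)
  h <- body_bbox[4] * (1 + expansion)
  x0 <- max(0, cx - w / 2); y0 <- max(0, cy - h / 2)
  x1 <- min(frame_dim[2], cx + w / 2); y1 <- min(frame_dim[1], cy + h / 2)
  c(x = x0, y = y0, w = x1 - x0, h = y1 - y0)
}
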