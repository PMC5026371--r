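test_that("reference histogram is a max-normalized hue frequency count", {
  # uniform hue 120 -> single unit bin
  img <- uniform_hsv(120, 1, 1, 10, 10)
  h1 <- reference_histogram(img, c(0, 0, 10, 10), n_bins = 36)
  expect_equal(h1$weights[13], 1)  # 120 deg falls in bin 13 of 36
  expect_equal(sum(h1$weights), 1)

  # half 120 / half 300: both bins reach weight 1
  img$h[, 6:10] <- 300
  h2 <- reference_histogram(img, c(0, 0, 10, 10), n_bins = 36)
  expect_equal(h2$weights[13], 1)
  expect_equal(h2$weights[31], 1)

  # 75% / 25% mix: weights 1 and 1/3 (direct count oracle)
  img2 <- uniform_hsv(120, 1, 1, 8, 8)
  img2$h[1:2, ] <- 300
  h3 <- reference_histogram(img2, c(0, 0, 8, 8), n_bins = 36)
  expect_equal(h3$weights[13], 1)
  expect_equal(h3$weights[31], 1 / 3)

  expect_error(reference_histogram(img, c(0, 0, 0, 4)), "ROI")
  expect_error(reference_histogram(img, c(8, 8, 10, 10)), "ROI")
})

test_that("back projection equals a per-pixel histogram lookup", {
  img <- uniform_hsv(120, 1, 1, 6, 6)
  hist <- reference_histogram(img, c(0, 0, 6, 6))
  all_true <- matrix(TRUE, 6, 6)
  expect_equal(back_project(img, hist, all_true), matrix(1, 6, 6))

  other <- uniform_hsv(300, 1, 1, 6, 6)
  expect_equal(back_project(other, hist, all_true), matrix(0, 6, 6))

  # random images vs the lookup oracle, including out-of-mask zeros
  set.seed(41)
  for (rep in 1:10) {
    rnd <- uniform_hsv(0, 1, 1, 50, 50)
    rnd$h[] <- runif(2500, 0, 360)
    hist <- reference_histogram(rnd, c(10, 10, 20, 20), n_bins = 36)
    mask <- matrix(runif(2500) > 0.4, 50, 50)
    pm <- back_project(rnd, hist, mask)
    oracle <- matrix(0, 50, 50)
    for (i in 1:50) for (j in 1:50) {
      if (mask[i, j]) {
        b <- min(floor(rnd$h[i, j] / 10) + 1, 36)
        oracle[i, j] <- hist$weights[b]
      }
    }
    expect_identical(pm, oracle)
  }
})

gaussian_map <- function(n, cx, cy, sd) {
  outer(0:(n - 1), 0:(n - 1), function(y, x) exp(-((x - cx)^2 + (y - cy)^2) / (2 * sd^2)))
}

test_that("mean shift converges onto a unimodal blob", {
  set.seed(42)
  for (rep in 1:20) {
    cx <- runif(1, 20, 60); cy <- runif(1, 20, 60)
    pm <- gaussian_map(80, cx, cy, runif(1, 2, 5))
    w0 <- c(cx + runif(1, -8, 8), cy + runif(1, -8, 8), 15, 15)
    ms <- mean_shift(pm, w0, max_iter = 50, eps = 0.1)
    oracle <- centroid_fixed_point(pm, w0)
    expect_lt(sqrt(sum((ms$center - oracle)^2)), 1)
    expect_lt(sqrt(sum((ms$center - c(cx, cy))^2)), 1.5)
  }

  # all-zero map: window unchanged, mass 0
  z <- matrix(0, 30, 30)
  ms0 <- mean_shift(z, c(5, 5, 10, 10))
  expect_equal(ms0$window, c(5, 5, 10, 10))
  expect_equal(ms0$mass, 0)

  # blob symmetric about the window center: converges immediately
  pm <- gaussian_map(41, 20, 20, 4)
  ms1 <- mean_shift(pm, c(20 - 7, 20 - 7, 15, 15), eps = 0.5)
  expect_true(ms1$converged)
  expect_equal(ms1$window[1:2], c(13, 13), tolerance = 1e-6)
})

test_that("mean shift does not move away from a unimodal mode", {
  set.seed(43)
  pm <- gaussian_map(60, 35, 25, 4)
  w <- c(20, 10, 13, 13)
  d_prev <- Inf
  for (k in 1:8) {
    ms <- mean_shift(pm, w, max_iter = 1, eps = 1e-6)
    d <- sqrt(sum((ms$center - c(35, 25))^2))
    expect_lte(d, d_prev + 1e-9)
    d_prev <- d
    w <- ms$window
  }
})

test_that("adaptive window follows the sqrt(mass) law with preserved aspect", {
  w <- c(10, 10, 12, 12)
  a1 <- adapt_window(w, mass = 25, scale = 2)
  expect_equal(a1[3:4], c(10, 10))
  a2 <- adapt_window(w, mass = 100, scale = 2)  # mass x4 -> sides x2
  expect_equal(a2[3:4], a1[3:4] * 2)
  # center preserved
  expect_equal(a2[1] + a2[3] / 2, 16)
  # aspect ratio preserved
  rect <- adapt_window(c(0, 0, 20, 5), mass = 64, scale = 2)
  expect_equal(rect[3] / rect[4], 4)
  # mass 0: unchanged
  expect_equal(adapt_window(w, 0), w)
  # clamped to body dims
  big <- adapt_window(w, mass = 1e4, scale = 2, max_dims = c(30, 25))
  expect_equal(big[3:4], c(30, 25))
})

test_that("lost-paw window grows toward the body box and is capped by it", {
  body <- c(0, 0, 50, 40)
  g1 <- grow_on_loss(c(20, 20, 10, 10), body, rate = 0.2)
  expect_equal(g1[3:4], c(12, 12))
  expect_equal(g1[1:2], c(19, 19))  # grown about the center
  # repeated growth converges exactly to the body size
  w <- c(20, 20, 10, 10)
  for (k in 1:40) w <- grow_on_loss(w, body, rate = 0.2)
  expect_equal(w[3:4], c(50, 40))
  expect_equal(grow_on_loss(w, body, rate = 0.2)[3:4], c(50, 40))
})

test_that("paw tracking on a rendered frame localizes the paw or reports loss", {
  # paws rendered disjoint so the localization bound is clean; overlapping
  # paws are exercised by the end-to-end RMS checks
  g <- grooming_motif(1, base_sep_px = 16, seed = 6)
  sc <- synthetic_scene(list(g), seed = 6)
  r <- render_scene(sc)
  cfg <- scene_tracker_config(sc, r$truth)
  img <- frame_to_hsv(r$frames[[1]])
  lay <- build_layout(cfg$corners)
  body <- body_state(make_mask(img, cfg$body_hsv), lay)
  hist <- reference_histogram(img, cfg$paw_rois[[1]]$left, cfg$n_bins)
  mask <- make_mask(img, cfg$left_hsv)
  prev <- list(window = cfg$paw_rois[[1]]$left, tracked = TRUE)

  st <- track_paw_frame(img, prev, body, hist, mask, cfg)
  expect_true(st$tracked)
  expect_lt(abs(st$x - r$truth$left_x[1]), 1)
  expect_lt(abs(st$y - r$truth$left_y[1]), 1)

  # raising the cluster threshold above the paw mass forces a loss
  cfg_hi <- cfg; cfg_hi$min_box_size <- 1e5
  st_lost <- track_paw_frame(img, prev, body, hist, mask, cfg_hi)
  expect_false(st_lost$tracked)
  expect_true(is.na(st_lost$x))
  # the lost window grew
  expect_gt(st_lost$window[3], prev$window[3])
})

test_that("a paw outside the mouse's search region is not claimed", {
  # two mice side by side; mouse 0's tracker must ignore mouse 1's paw
  g0 <- grooming_motif(1, center = c(60, 90), seed = 7)
  g1 <- grooming_motif(1, center = c(180, 90), seed = 8)
  # mouse 0's own left paw is hidden, so the only green blob in the frame
  # belongs to mouse 1 and lies outside mouse 0's search region
  sc <- synthetic_scene(list(g0, g1), seed = 7,
                        occlusions = list(list(left = c(0, 0), right = NULL),
                                          list(left = NULL, right = NULL)))
  r <- render_scene(sc)
  cfg <- scene_tracker_config(sc, r$truth)
  img <- frame_to_hsv(r$frames[[1]])
  lay <- build_layout(cfg$corners, cfg$n_mice, cfg$dividers)
  bodies <- body_state(make_mask(img, cfg$body_hsv), lay)
  # reference hue histogram from the visible green paw (same color for all
  # mice: the same HSV limits and reference hues apply to every enclosure)
  hist <- reference_histogram(img, cfg$paw_rois[[2]]$left, cfg$n_bins)
  mask <- make_mask(img, cfg$left_hsv)
  # seed the window on the *other* mouse's paw: outside mouse 0's region
  t1 <- r$truth[r$truth$mouse == 1, ]
  prev <- list(window = c(t1$left_x - 3, t1$left_y - 3, 6, 6), tracked = TRUE)
  st <- track_paw_frame(img, prev, bodies[bodies$enclosure == 0, ],
                        hist, mask, cfg)
  expect_false(st$tracked)
})

test_that("the tracked centroid is invariant to V-channel scaling", {
  g <- grooming_motif(1, seed = 9)
  sc1 <- synthetic_scene(list(g), v_profile = 1, seed = 9)
  sc2 <- synthetic_scene(list(g), v_profile = 0.6, seed = 9)
  r1 <- render_scene(sc1); r2 <- render_scene(sc2)
  cfg <- scene_tracker_config(sc1, r1$truth)
  find_paw <- function(frame) {
    img <- frame_to_hsv(frame)
    lay <- build_layout(cfg$corners)
    body <- body_state(make_mask(img, cfg$body_hsv), lay)
    hist <- reference_histogram(img, cfg$paw_rois[[1]]$left, cfg$n_bins)
    st <- track_paw_frame(img, list(window = cfg$paw_rois[[1]]$left),
                          body, hist, make_mask(img, cfg$left_hsv), cfg)
    c(st$x, st$y)
  }
  p1 <- find_paw(r1$frames[[1]])
  p2 <- find_paw(r2$frames[[1]])
  expect_lt(sqrt(sum((p1 - p2)^2)), 0.5)
})
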