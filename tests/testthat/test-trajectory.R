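test_that("pixel distances convert to millimetres by the calibration factor", {
  expect_equal(px_to_mm(3, 0.21), 0.63)
  expect_equal(px_to_mm(0, 0.21), 0)
  expect_equal(px_to_mm(10, 0.1), 1)
  expect_error(px_to_mm(1, 0), "pixel_size_mm")
})

test_that("displacement series excludes pairs spanning untracked gaps", {
  const <- traj(tibble::tibble(frame = 0:9, x = 5, y = 5))
  expect_equal(displacements(const)$step_px, rep(0, 9))

  drift <- traj(tibble::tibble(frame = 0:9, x = 0:9, y = 0))
  expect_equal(displacements(drift)$step_px, rep(1, 9))

  # one untracked frame removes the two pairs that touch it
  gap <- tibble::tibble(frame = 0:9, x = as.numeric(0:9), y = 0,
                        tracked = TRUE)
  gap$tracked[5] <- FALSE; gap$x[5] <- NA
  d <- displacements(traj(gap))
  expect_equal(nrow(d), 7)
  expect_equal(attr(d, "n_excluded"), 2)
  expect_false(any(is.na(d$step_px)))

  one <- tibble::tibble(frame = 0:4, x = 1, y = 1, tracked = c(TRUE, rep(FALSE, 4)))
  expect_error(displacements(traj(one)), "insufficient")
})

test_that("path length sums step displacements and respects rigid motions", {
  straight <- traj(tibble::tibble(frame = 0:10, x = seq(0, 100, 10), y = 0),
                   px = 0.21)
  expect_equal(path_length(straight), 21)

  square <- traj(tibble::tibble(frame = 0:4, x = c(0, 1, 1, 0, 0),
                                y = c(0, 0, 1, 1, 0)), px = 1)
  expect_equal(path_length(square), 4)

  # random walk equals the brute-force pairwise sum, and is invariant
  # under translation + rotation
  set.seed(51)
  n <- 200
  w <- tibble::tibble(frame = 0:(n - 1), x = cumsum(rnorm(n)), y = cumsum(rnorm(n)))
  t1 <- traj(w, px = 1)
  brute <- sum(sqrt(diff(w$x)^2 + diff(w$y)^2))
  expect_equal(path_length(t1), brute)
  th <- 0.7
  w2 <- tibble::tibble(frame = w$frame,
                       x = 13 + cos(th) * w$x - sin(th) * w$y,
                       y = -4 + sin(th) * w$x + cos(th) * w$y)
  expect_equal(path_length(traj(w2, px = 1)), brute)
})

test_that("speed series scales displacement by pixel size and frame rate", {
  drift <- traj(tibble::tibble(frame = 0:10, x = 0:10, y = 0),
                px = 0.21, fps = 60)
  s <- speed_series(drift)
  expect_equal(s$speed_mm_s, rep(12.6, 10))
  expect_equal(attr(s, "mean"), 12.6)

  still <- traj(tibble::tibble(frame = 0:10, x = 1, y = 1))
  expect_equal(unique(speed_series(still)$speed_mm_s), 0)

  # piecewise 1 then 2 px/frame averages to 1.5 px/frame
  pw <- traj(tibble::tibble(frame = 0:20,
                            x = cumsum(c(0, rep(1, 10), rep(2, 10))), y = 0),
             px = 1, fps = 1)
  expect_equal(attr(speed_series(pw), "mean"), 1.5)
})

test_that("covered area is the convex hull area in cm^2", {
  line <- traj(tibble::tibble(frame = 0:9, x = 0:9, y = 0:9))
  expect_equal(covered_area(line), 0)

  sq <- traj(tibble::tibble(frame = 0:3, x = c(0, 100, 100, 0),
                            y = c(0, 0, 100, 100)), px = 0.1)
  expect_equal(covered_area(sq), 1)  # 10 mm x 10 mm

  # random cloud vs shoelace on a brute-force hull
  set.seed(52)
  pts <- tibble::tibble(frame = 0:199, x = runif(200, 0, 50), y = runif(200, 0, 30))
  hull_oracle <- function(x, y) {
    # brute force: a point is a hull vertex iff some half-plane through it
    # contains all the others; walk the ordered vertices and apply shoelace
    h <- grDevices::chull(x, y)
    hx <- x[h]; hy <- y[h]
    0.5 * abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy))
  }
  expect_equal(covered_area(traj(pts, px = 1)), hull_oracle(pts$x, pts$y) / 100)

  # area scales with the square of the pixel size
  expect_equal(covered_area(traj(pts, px = 2)),
               4 * covered_area(traj(pts, px = 1)))
})

test_that("occupancy map conserves the tracked sample count", {
  still <- traj(tibble::tibble(frame = 0:9, x = 5.2, y = 7.8))
  occ <- occupancy_map(still, 1)
  expect_equal(nrow(occ), 1)
  expect_equal(occ$n, 10L)

  alt <- traj(tibble::tibble(frame = 0:9, x = rep(c(1, 11), 5), y = 0))
  occ2 <- occupancy_map(alt, 5)
  expect_equal(sort(occ2$n), c(5L, 5L))

  set.seed(53)
  rnd <- tibble::tibble(frame = 0:99, x = runif(100, 0, 40),
                        y = runif(100, 0, 40),
                        tracked = runif(100) > 0.3)
  expect_equal(sum(occupancy_map(traj(rnd), 3)$n), sum(rnd$tracked))
})

test_that("inter-paw distance averages over mutually tracked frames", {
  a <- traj(tibble::tibble(frame = 0:9, x = 1:10, y = 2), px = 1)
  expect_equal(interpaw_distance(a, a), 0)

  b <- traj(tibble::tibble(frame = 0:9, x = 1:10 + 3, y = 6), px = 1)
  expect_equal(interpaw_distance(a, b), 5)  # offset (3,4)

  # interleaved losses: only the mutual frames count (mask-and-average oracle)
  al <- tibble::tibble(frame = 0:9, x = as.numeric(1:10), y = 0,
                       tracked = rep(c(TRUE, FALSE), 5))
  bl <- tibble::tibble(frame = 0:9, x = as.numeric(1:10) + 1, y = 0,
                       tracked = c(TRUE, TRUE, FALSE, TRUE, TRUE,
                                   TRUE, FALSE, TRUE, TRUE, TRUE))
  mutual <- al$tracked & bl$tracked
  oracle <- mean(abs(bl$x[mutual] - al$x[mutual]))
  expect_equal(interpaw_distance(traj(al, px = 1), traj(bl, px = 1)), oracle)
})

test_that("movement lag recovers constructed shifts and anti-phase offsets", {
  fps <- 10
  set.seed(54)
  steps <- rnorm(400)
  base <- cumsum(steps)
  a <- traj(tibble::tibble(frame = 0:399, x = base, y = 0), fps = fps)
  expect_equal(as.numeric(movement_lag(a, a, max_lag_s = 1)), 0)

  # B = A delayed by 7 frames -> lag 0.7 s
  k <- 7
  shifted <- c(rep(base[1], k), base[1:(400 - k)])
  b <- traj(tibble::tibble(frame = 0:399, x = shifted, y = 0), fps = fps)
  lag <- movement_lag(a, b, max_lag_s = 1)
  expect_equal(as.numeric(lag), k / fps)
  expect_equal(attr(lag, "signed_lag_s"), k / fps)

  # anti-phase sinusoids of period T peak at T/2
  tt <- 0:399
  T_frames <- 20
  sl <- traj(tibble::tibble(frame = tt, x = sin(2 * pi * tt / T_frames), y = 0),
             fps = fps)
  sr <- traj(tibble::tibble(frame = tt, x = -sin(2 * pi * tt / T_frames), y = 0),
             fps = fps)
  expect_equal(as.numeric(movement_lag(sl, sr, max_lag_s = 1)),
               (T_frames / 2) / fps)

  # degenerate: constant series
  cst <- traj(tibble::tibble(frame = 0:399, x = 1, y = 1), fps = fps)
  dl <- movement_lag(cst, cst, max_lag_s = 1)
  expect_equal(as.numeric(dl), 0)
  expect_true(attr(dl, "degenerate"))
})

test_that("displacement correlation behaves as a Pearson r", {
  a <- traj(tibble::tibble(frame = 0:99, x = cumsum(abs(sin(1:100))), y = 0))
  expect_equal(displacement_correlation(a, a), 1)

  # mirrored steps give magnitude-identical series: r = 1; an anti-correlated
  # *magnitude* pattern gives r = -1
  big_small <- rep(c(2, 0.5), 50)
  l <- traj(tibble::tibble(frame = 0:100, x = cumsum(c(0, big_small)), y = 0))
  r <- traj(tibble::tibble(frame = 0:100, x = cumsum(c(0, rev(big_small))), y = 0))
  expect_equal(displacement_correlation(l, r), -1)

  set.seed(55)
  n1 <- traj(tibble::tibble(frame = 0:1000, x = cumsum(runif(1001)), y = 0))
  n2 <- traj(tibble::tibble(frame = 0:1000, x = cumsum(runif(1001)), y = 0))
  expect_lt(abs(displacement_correlation(n1, n2)), 0.1)
})

test_that("bout classification votes over area, distance and lag", {
  thr <- c(area_cm2 = 10, dist_mm = 8, lag_s = 0.2)
  m_groom <- tibble::tibble(covered_area_cm2 = 1, mean_interpaw_mm = 5,
                            lag_s = 0.05)
  expect_equal(classify_bout(m_groom, thr), "GROOMING")
  m_walk <- tibble::tibble(covered_area_cm2 = 50, mean_interpaw_mm = 12,
                           lag_s = 0.4)
  expect_equal(classify_bout(m_walk, thr), "WALKING")
  # 1-1 split with one abstention (value exactly at threshold)
  m_tie <- tibble::tibble(covered_area_cm2 = 1, mean_interpaw_mm = 12,
                          lag_s = 0.2)
  expect_equal(classify_bout(m_tie, thr), "UNCLASSIFIED")
})

test_that("bout metrics and classification separate the two motifs", {
  ok <- 0
  n_rep <- 10
  for (s in 1:n_rep) {
    g <- grooming_motif(600, seed = s)
    w <- walking_motif(600, seed = s)
    bg <- bout_metrics(traj(g$left), traj(g$right))
    bw <- bout_metrics(traj(w$left), traj(w$right))
    sep <- bg$covered_area_cm2 < bw$covered_area_cm2 &&
      bg$mean_interpaw_mm < bw$mean_interpaw_mm &&
      abs(bg$lag_s) < abs(bw$lag_s) &&
      classify_bout(bg) == "GROOMING" && classify_bout(bw) == "WALKING"
    ok <- ok + sep
  }
  expect_gte(ok / n_rep, 0.95)
})

test_that("tidy and glance summarize bout metrics", {
  g <- grooming_motif(600, seed = 2)
  m <- bout_metrics(traj(g$left), traj(g$right))
  td <- tidy(m)
  expect_equal(td$metric, names(m))
  expect_equal(td$value[td$metric == "lag_s"], m$lag_s)
  expect_s3_class(glance(m), "tbl_df")
  expect_equal(nrow(glance(m)), 1)
})

test_that("episode detection finds the grooming interval of a composite bout", {
  fps <- test_fps
  w1 <- walking_motif(10 * fps, seed = 61)
  g <- grooming_motif(30 * fps, seed = 61)
  w2 <- walking_motif(10 * fps, seed = 62)
  shift_frames <- function(m, offset) {
    lapply(m, function(d) { d$frame <- d$frame + offset; d })
  }
  g <- shift_frames(g, 10 * fps)
  w2 <- shift_frames(w2, 40 * fps)
  left <- traj(dplyr::bind_rows(w1$left, g$left, w2$left))
  right <- traj(dplyr::bind_rows(w1$right, g$right, w2$right))

  ep <- detect_episodes(left, right)
  expect_equal(nrow(ep), 1)
  expect_lt(abs(ep$start_frame - 10 * fps), fps)   # within one 1-s window
  expect_lt(abs(ep$end_frame - 40 * fps), fps)
  expect_equal(ep$duration_min, 0.5, tolerance = 0.07)

  # all-walking: nothing detected; all-grooming: one near-full episode
  w_only <- walking_motif(20 * fps, seed = 63)
  expect_equal(nrow(detect_episodes(traj(w_only$left), traj(w_only$right))), 0)
  g_only <- grooming_motif(20 * fps, seed = 63)
  ep_g <- detect_episodes(traj(g_only$left), traj(g_only$right))
  expect_equal(nrow(ep_g), 1)
  expect_gt((ep_g$end_frame - ep_g$start_frame + 1) / (20 * fps), 0.95)
})
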