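# Shared fixtures: study-condition scenes, built in code and cached per
# session so the heavier end-to-end runs happen once.

test_px <- 0.75   # mm per pixel of the synthetic camera
test_fps <- 60

traj <- function(samples, px = test_px, fps = test_fps) {
  new_trajectory(samples, pixel_size_mm = px, fps = fps)
}

# uniform hsv image helper
uniform_hsv <- function(h, s, v, nr = 4, nc = 4) {
  structure(list(h = matrix(h, nr, nc), s = matrix(s, nr, nc),
                 v = matrix(v, nr, nc)), class = "hsv_image")
}

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) {
    assign(key, force(expr), envir = .run_cache)
  }
  get(key, envir = .run_cache)
}

# 600-frame single-mouse grooming scene, no occlusion: the end-to-end
# tracking substrate.
baseline_scene <- function(v = 1) {
  g <- grooming_motif(600, fps = test_fps, seed = 42)
  synthetic_scene(list(g), fps = test_fps, pixel_size_mm = test_px,
                  v_profile = v, seed = 42)
}

baseline_run <- function() {
  cached("baseline", {
    r <- render_scene(baseline_scene())
    cfg <- scene_tracker_config(baseline_scene(), r$truth)
    list(truth = r$truth, records = track_video(r$frames, cfg), cfg = cfg)
  })
}

dimmed_run <- function() {
  cached("dimmed", {
    r <- render_scene(baseline_scene(v = 0.6))
    cfg <- scene_tracker_config(baseline_scene(v = 0.6), r$truth)
    list(truth = r$truth, records = track_video(r$frames, cfg))
  })
}

# same grooming scene with the left paw occluded for 30 frames
occlusion_run <- function(start = 200, len = 30) {
  cached("occlusion", {
    g <- grooming_motif(360, fps = test_fps, seed = 42)
    sc <- synthetic_scene(
      list(g), fps = test_fps, pixel_size_mm = test_px,
      occlusions = list(list(left = c(start, start + len - 1), right = NULL)),
      seed = 42
    )
    r <- render_scene(sc)
    cfg <- scene_tracker_config(sc, r$truth)
    list(truth = r$truth,
         records = track_video(r$frames, cfg, keep_windows = TRUE),
         start = start, len = len)
  })
}

rms <- function(x) sqrt(mean(x^2))

paw_rms_error <- function(records, truth, side) {
  tx <- truth[[paste0(side, "_x")]]
  ty <- truth[[paste0(side, "_y")]]
  px <- records[[paste0(side, "_x")]]
  py <- records[[paste0(side, "_y")]]
  ok <- records[[paste0(side, "_tracked")]]
  rms(sqrt((px[ok] - tx[ok])^2 + (py[ok] - ty[ok])^2))
}
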