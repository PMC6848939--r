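# Shared fixtures: a small synthetic rack reused across tests, cached
# per session. Reduced image/grid keep the suite fast; rig constants
# (30 mm pitch, 505 mm plane, 2 mm depth noise, 4 frames, 11x11/1.3
# smoothing) stay at the study values.

.scene_cache <- new.env(parent = emptyenv())

small_scene_config <- function(seed = 3, ...) {
  scene_config(density_class = "high", rows = 4, cols = 5,
               image_size = c(300, 380), focal_px = 700, seed = seed, ...)
}

cached_scene <- function(das, seed = 3) {
  key <- paste0("s", seed, "_d", das)
  if (is.null(.scene_cache[[key]])) {
    .scene_cache[[key]] <- generate_scene(small_scene_config(seed), das)
  }
  .scene_cache[[key]]
}

# grid detected from the early-day image of the cached rack
cached_grid <- function(seed = 3) {
  key <- paste0("g", seed)
  if (is.null(.scene_cache[[key]])) {
    .scene_cache[[key]] <-
      build_tray_grid(cached_scene(7, seed)$frames[[1]]$color)
  }
  .scene_cache[[key]]
}

# merged + line-masked + smoothed height surface for a cached scene
cached_height <- function(das, seed = 3) {
  key <- paste0("h", seed, "_d", das)
  if (is.null(.scene_cache[[key]])) {
    sc <- cached_scene(das, seed)
    g <- cached_grid(seed)
    merged <- merge_depth_frames(lapply(sc$frames, `[[`, "depth"))
    Ms <- smooth_depth(apply_line_mask(merged, g$line_mask))
    .scene_cache[[key]] <- suppressWarnings(
      compute_height_surface(Ms, sc$truth$config$plane_distance, das = das))
  }
  .scene_cache[[key]]
}

# identity-K intrinsics for pure-geometry tests
unit_intrinsics <- function() {
  camera_intrinsics(f = 1, mx = 1, my = 1, height = 100, width = 100)
}

# disk fixture: planar grid samples of a radius-10mm disk
disk_points <- function(h = 0.15, r = 10) {
  g <- as.matrix(expand.grid(X = seq(-r, r, h), Y = seq(-r, r, h)))
  P <- cbind(g[g[, 1]^2 + g[, 2]^2 <= r^2, ], Z = 0)
  colnames(P) <- c("X", "Y", "Z")
  P
}

rot_x <- function(a) {
  matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)), 3, 3,
         byrow = TRUE)
}
rot_z <- function(a) {
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}
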