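#' Scene configuration for the synthetic feeding-scene generator
#'
#' Describes the imaging geometry and photometry of a synthetic lateral view
#' of a chick head at the feeder: frame size, frame rate, pixel pitch, the
#' gray levels of the four scene classes (background, head/beak, eye, feed
#' particles), eye and beak geometry, feed-particle load, and imaging noise.
#'
#' Defaults emulate a 250 fps recording at 1/4 of a 1536x1024 sensor
#' (384x256 px) with a 0.1 mm pixel pitch. The eye must be darker than the
#' head, and at the default settings all four gray levels are pairwise
#' separated by at least 20 intensity units so that intensity-based
#' segmentation is well posed.
#'
#' @param image_width,image_height Frame size in pixels.
#' @param fps Acquisition rate, frames per second.
#' @param mm_per_px Pixel pitch, mm per pixel.
#' @param background_gray,head_gray,eye_gray,particle_gray Scene gray levels
#'   on a 0-255 scale.
#' @param eye_radius Eye radius in pixels.
#' @param beak_length Hinge-to-tip beak length in pixels.
#' @param beak_facing Direction the beak points, `"left"` or `"right"`.
#' @param noise_sd Standard deviation of additive Gaussian imaging noise, in
#'   intensity units (added after ground truth is recorded).
#' @param particle_count Number of feed particles rendered near the beak.
#' @param particle_radius_px Feed-particle radius in pixels.
#' @param seed Integer seed for the scene's random elements (particle
#'   placement, noise).
#'
#' @return An object of class `scene_config` (a validated list).
#' @examples
#' cfg <- scene_config(noise_sd = 0, particle_count = 0)
#' cfg$fps
#' @export
scene_config <- function(image_width = 384L, image_height = 256L,
                         fps = 250, mm_per_px = 0.1,
                         background_gray = 200, head_gray = 120,
                         eye_gray = 30, particle_gray = 70,
                         eye_radius = 9, beak_length = 60,
                         beak_facing = c("right", "left"),
                         noise_sd = 5, particle_count = 3,
                         particle_radius_px = 4, seed = 1L) {
  beak_facing <- match.arg(beak_facing)
  cfg <- list(
    image_width = as.integer(image_width),
    image_height = as.integer(image_height),
    fps = fps, mm_per_px = mm_per_px,
    background_gray = background_gray, head_gray = head_gray,
    eye_gray = eye_gray, particle_gray = particle_gray,
    eye_radius = eye_radius, beak_length = beak_length,
    beak_facing = beak_facing, noise_sd = noise_sd,
    particle_count = as.integer(particle_count),
    particle_radius_px = particle_radius_px,
    seed = as.integer(seed)
  )
  validate_scene_config(cfg)
  class(cfg) <- "scene_config"
  cfg
}

validate_scene_config <- function(cfg) {
  stopifnot(
    cfg$image_width > 0, cfg$image_height > 0,
    cfg$fps > 0, cfg$mm_per_px > 0,
    cfg$eye_radius > 0, cfg$beak_length > 0,
    cfg$noise_sd >= 0, cfg$particle_count >= 0,
    cfg$particle_radius_px > 0
  )
  if (cfg$eye_gray >= cfg$head_gray)
    stop("eye_gray must be darker (smaller) than head_gray")
  grays <- c(cfg$background_gray, cfg$head_gray, cfg$eye_gray, cfg$particle_gray)
  if (any(grays < 0 | grays > 255))
    stop("gray levels must lie in [0, 255]")
  if (min(dist(grays)) < 20)
    stop("gray levels must be pairwise separated by at least 20 intensity units")
  invisible(cfg)
}

#' Kinematic script for one synthetic feeding sequence
#'
#' A script fixes, frame by frame, what the rendered head does: an optional
#' withdrawal prefix (the approach-and-upward-withdrawal head motion that
#' precedes the first mandibulation), then a list of mandibulation cycles.
#' Each cycle spans `n_frames` frames in which the gape rises from a
#' baseline to `peak_gape_mm` and falls back; the beak is never fully closed
#' at a cycle boundary. Head motion is given as per-frame (dx, dy) steps in
#' mm (y pointing down, as in image coordinates).
#'
#' @param mandibulations A list of cycle specs, each a list with elements
#'   `order` (1-4), `n_frames` (>= 3), `peak_gape_mm`, `head_path` (an
#'   `n_frames` x 2 matrix of per-frame (dx, dy) displacements in mm) and
#'   `catch_and_throw` (logical).
#' @param withdrawal_path Matrix of per-frame (dx, dy) head steps (mm) for
#'   the prefix before the first mandibulation; may have zero rows.
#' @param withdrawal_gape_mm Gape during the prefix, either a scalar or one
#'   value per prefix frame; ramps down to `base_gape_mm` are typical.
#' @param tail_path,tail_gape_mm Like the withdrawal arguments, for the few
#'   frames appended after the last cycle (the series must end away from a
#'   cycle interior so the last cycle has a right boundary).
#' @param base_gape_mm Baseline (never-fully-closed) gape at cycle
#'   boundaries, mm; must be > 0.
#' @param start_xy_px Eye-center position (x, y) in pixels at the first
#'   frame, 0-based image coordinates.
#'
#' @return An object of class `kinematic_script`.
#' @seealso [make_feeding_script()] for a randomised generator,
#'   [render_sequence()] to rasterise a script.
#' @export
kinematic_script <- function(mandibulations,
                             withdrawal_path = matrix(0, 0, 2),
                             withdrawal_gape_mm = numeric(0),
                             tail_path = matrix(0, 0, 2),
                             tail_gape_mm = numeric(0),
                             base_gape_mm = 0.6,
                             start_xy_px = c(120, 150)) {
  stopifnot(is.list(mandibulations), base_gape_mm > 0)
  withdrawal_path <- as_path(withdrawal_path)
  tail_path <- as_path(tail_path)
  n_pre <- nrow(withdrawal_path)
  n_tail <- nrow(tail_path)
  withdrawal_gape_mm <- rep_len(withdrawal_gape_mm, n_pre)
  tail_gape_mm <- rep_len(tail_gape_mm, n_tail)
  for (i in seq_along(mandibulations)) {
    m <- mandibulations[[i]]
    stopifnot(
      m$order %in% 1:4,
      m$n_frames >= 3,
      m$peak_gape_mm > base_gape_mm,
      is.logical(m$catch_and_throw)
    )
    mandibulations[[i]]$head_path <- as_path(m$head_path, m$n_frames)
  }
  structure(
    list(mandibulations = mandibulations,
         withdrawal_path = withdrawal_path,
         withdrawal_gape_mm = withdrawal_gape_mm,
         tail_path = tail_path, tail_gape_mm = tail_gape_mm,
         base_gape_mm = base_gape_mm,
         start_xy_px = as.numeric(start_xy_px)),
    class = "kinematic_script"
  )
}

as_path <- function(p, n = NULL) {
  p <- matrix(as.numeric(p), ncol = 2)
  if (!is.null(n) && nrow(p) != n)
    stop("head_path must have one (dx, dy) row per frame")
  p
}

#' Per-frame gape trajectory of one scripted mandibulation cycle
#'
#' Frame 0 of the cycle sits exactly at the baseline gape (the unique local
#' minimum that marks the cycle boundary); frames 1..n-1 follow a unimodal
#' half-sine `base + amp * sin(pi * (t + 0.25) / n)`, with `amp` scaled so
#' the single largest frame equals `peak_gape_mm` exactly. The 0.25-frame
#' phase offset guarantees a unique maximum for both odd and even `n`.
#'
#' @param n_frames Cycle length in frames (>= 3).
#' @param peak_gape_mm Maximum gape reached, mm.
#' @param base_gape_mm Baseline gape at the cycle boundary, mm.
#' @return Numeric vector of length `n_frames`; attribute `peak_frame` gives
#'   the 0-based index of the maximum within the cycle.
#' @export
cycle_gape_trajectory <- function(n_frames, peak_gape_mm, base_gape_mm = 0.6) {
  stopifnot(n_frames >= 3, peak_gape_mm > base_gape_mm)
  t <- seq_len(n_frames - 1)             # frames 1 .. n-1
  s <- sin(pi * (t + 0.25) / n_frames)
  amp <- (peak_gape_mm - base_gape_mm) / max(s)
  g <- c(base_gape_mm, base_gape_mm + amp * s)
  attr(g, "peak_frame") <- which.max(g) - 1L
  g
}

# Expand a script into per-frame eye positions (px), gape (mm) and cycle
# bookkeeping. Internal; render_sequence() and the truth builder use it.
expand_script <- function(script, config) {
  steps_mm <- rbind(script$withdrawal_path,
                    do.call(rbind, lapply(script$mandibulations, `[[`, "head_path")),
                    script$tail_path)
  n_pre <- nrow(script$withdrawal_path)
  n_tail <- nrow(script$tail_path)
  gape <- c(script$withdrawal_gape_mm)
  starts <- integer(0); ends <- integer(0); peaks <- integer(0)
  cursor <- n_pre
  for (m in script$mandibulations) {
    g <- cycle_gape_trajectory(m$n_frames, m$peak_gape_mm, script$base_gape_mm)
    starts <- c(starts, cursor)
    ends <- c(ends, cursor + m$n_frames)
    peaks <- c(peaks, cursor + attr(g, "peak_frame"))
    gape <- c(gape, as.numeric(g))
    cursor <- cursor + m$n_frames
  }
  gape <- c(gape, script$tail_gape_mm)
  n <- length(gape)
  stopifnot(nrow(steps_mm) == n)
  # position at frame 0 is start_xy; step row f moves frame f-1 -> f, so the
  # last step row is unused
  steps_px <- steps_mm[seq_len(n - 1), , drop = FALSE] / config$mm_per_px
  eye_x <- script$start_xy_px[1] + c(0, cumsum(steps_px[, 1]))
  eye_y <- script$start_xy_px[2] + c(0, cumsum(steps_px[, 2]))
  list(n_frames = n, eye_x = eye_x, eye_y = eye_y, gape_mm = gape,
       cycle_start = starts, cycle_end = ends, cycle_peak = peaks,
       n_pre = n_pre, n_tail = n_tail)
}
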