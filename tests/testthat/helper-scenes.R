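# Shared fixtures, built in code at test time.

cal_of <- function(config) {
  structure(list(mm_per_px = config$mm_per_px), class = "calibration")
}

# clean scene: no noise, no particles
clean_config <- function(...) scene_config(noise_sd = 0, particle_count = 0, ...)

# a blank background-only frame matching a config
blank_frame <- function(config) {
  matrix(config$background_gray, config$image_height, config$image_width)
}

# one-cycle script with a deterministic head path (no randomness)
one_cycle_script <- function(n_frames = 20, peak_gape_mm = 4,
                             start_xy_px = c(110, 130)) {
  kinematic_script(
    list(list(order = 1L, n_frames = n_frames, peak_gape_mm = peak_gape_mm,
              head_path = matrix(0, n_frames, 2), catch_and_throw = FALSE)),
    tail_path = matrix(0, 4, 2),
    tail_gape_mm = 0.6 + c(-0.2, 0.2, 0.5, 0.8),
    start_xy_px = start_xy_px
  )
}

# script with explicit per-cycle frame counts / gapes, stationary head
multi_cycle_script <- function(n_frames, peak_gape_mm = rep(4, length(n_frames)),
                               start_xy_px = c(110, 130)) {
  mand <- lapply(seq_along(n_frames), function(j)
    list(order = min(j, 4L), n_frames = n_frames[j],
         peak_gape_mm = peak_gape_mm[j],
         head_path = matrix(0, n_frames[j], 2), catch_and_throw = FALSE))
  kinematic_script(mand,
                   tail_path = matrix(0, 4, 2),
                   tail_gape_mm = 0.6 + c(-0.2, 0.2, 0.5, 0.8),
                   start_xy_px = start_xy_px)
}

quiet <- function(expr) suppressWarnings(expr)
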