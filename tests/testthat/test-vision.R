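# Vision steps are validated against the generator's exact ground truth.

test_that("ruler calibration inverts the renderer", {
  cal <- calibrate_from_ruler(render_ruler(clean_config(), 1.0), 1.0)
  expect_equal(cal$mm_per_px, 0.1, tolerance = 0.005)
  cal2 <- calibrate_from_ruler(render_ruler(clean_config(mm_per_px = 0.05), 1.0), 1.0)
  expect_equal(cal2$mm_per_px, 0.05, tolerance = 0.0025)
  expect_error(calibrate_from_ruler(blank_frame(clean_config()), 1.0),
               "calibration failure")
})

test_that("eye detection recovers the scripted centre on clean frames", {
  cfg <- clean_config()
  fs <- render_sequence(cfg, one_cycle_script(start_xy_px = c(100, 80)))
  eye <- detect_eye(fs$frames[[1]])
  expect_lt(sqrt(sum((eye - c(100, 80))^2)), 0.5)
})

test_that("the eye beats an equal-area square particle on circularity", {
  cfg <- clean_config()
  img <- blank_frame(cfg)
  # disc r = 9 (area ~254) and a 16 x 16 square (area 256), same darkness
  yy <- 71:89; xx <- 91:109
  for (y in yy) for (x in xx)
    if ((x - 100)^2 + (y - 80)^2 <= 81) img[y + 1, x + 1] <- cfg$eye_gray
  img[(150:165) + 1, (200:215) + 1] <- cfg$eye_gray
  p <- vision_params(area_min = 200, area_max = 300)
  eye <- detect_eye(img, p)
  expect_lt(sqrt(sum((eye - c(100, 80))^2)), 1)
})

test_that("blank frames fail eye detection gracefully", {
  eye <- detect_eye(blank_frame(clean_config()))
  expect_true(all(is.na(eye)))
  expect_true(attr(eye, "failed"))
})

test_that("head ROI contains both tips and round-trips coordinates", {
  cfg <- clean_config()
  fs <- render_sequence(cfg, one_cycle_script())
  pf <- fs$truth$per_frame[10, ]
  hr <- extract_head_roi(fs$frames[[10]], c(pf$eye_x, pf$eye_y), "right")
  expect_true(pf$up_x - hr$offset[1] >= 0 &&
              pf$up_x - hr$offset[1] <= ncol(hr$roi) - 1)
  expect_true(pf$lo_y - hr$offset[2] >= 0 &&
              pf$lo_y - hr$offset[2] <= nrow(hr$roi) - 1)
  # identity round-trip: ROI pixel + offset reproduces the frame pixel
  expect_identical(hr$roi[5, 7], fs$frames[[10]][5 + hr$offset[2],
                                                 7 + hr$offset[1]])
  hr0 <- extract_head_roi(fs$frames[[10]], c(0, 0), "right")
  expect_identical(hr0$offset, c(0, 0))
})

test_that("particle removal is a no-op without particles and warns on empty ROI", {
  cfg <- clean_config()
  fs <- render_sequence(cfg, one_cycle_script())
  pf <- fs$truth$per_frame[10, ]
  hr <- extract_head_roi(fs$frames[[10]], c(pf$eye_x, pf$eye_y), "right")
  eye_roi <- c(pf$eye_x, pf$eye_y) - hr$offset
  m_on <- remove_particle_pixels(hr$roi, eye_roi, vision_params())
  m_off <- remove_particle_pixels(hr$roi, eye_roi,
                                  vision_params(removal_enabled = FALSE))
  expect_identical(unclass(m_on), unclass(m_off))
  m_bg <- remove_particle_pixels(blank_frame(cfg)[1:40, 1:40], c(5, 5))
  expect_false(any(m_bg))
  expect_match(attr(m_bg, "warning"), "no foreground")
})

test_that("particle removal rescues the occluded lower tip", {
  cfg <- scene_config(noise_sd = 0, particle_count = 1)
  fs <- render_sequence(cfg, one_cycle_script())
  f <- which.max(fs$truth$per_frame$gape_mm)
  pf <- fs$truth$per_frame[f, ]
  err_of <- function(p) {
    hr <- extract_head_roi(fs$frames[[f]], c(pf$eye_x, pf$eye_y), "right", p)
    mask <- remove_particle_pixels(hr$roi, c(pf$eye_x, pf$eye_y) - hr$offset, p)
    tips <- detect_beak_tips(mask, c(pf$eye_x, pf$eye_y) - hr$offset, "right", p)
    sqrt(sum((tips$lower + hr$offset - c(pf$lo_x, pf$lo_y))^2))
  }
  expect_lt(err_of(vision_params()), 2)
  expect_gt(err_of(vision_params(removal_enabled = FALSE)), 2)
})

test_that("beak tips are recovered within a pixel on clean frames", {
  cfg <- clean_config()
  fs <- render_sequence(cfg, one_cycle_script())
  f <- which.max(fs$truth$per_frame$gape_mm)
  pf <- fs$truth$per_frame[f, ]
  hr <- extract_head_roi(fs$frames[[f]], c(pf$eye_x, pf$eye_y), "right")
  mask <- remove_particle_pixels(hr$roi, c(pf$eye_x, pf$eye_y) - hr$offset)
  tips <- detect_beak_tips(mask, c(pf$eye_x, pf$eye_y) - hr$offset, "right")
  expect_lt(max(abs(tips$upper + hr$offset - c(pf$up_x, pf$up_y))), 1.1)
  expect_lt(max(abs(tips$lower + hr$offset - c(pf$lo_x, pf$lo_y))), 1.1)
})

test_that("a near-closed beak yields a near-zero gape", {
  cfg <- clean_config()
  sc <- kinematic_script(
    list(list(order = 1L, n_frames = 6, peak_gape_mm = 0.7,
              head_path = matrix(0, 6, 2), catch_and_throw = FALSE)),
    base_gape_mm = 0.1, start_xy_px = c(110, 130),
    tail_path = matrix(0, 2, 2), tail_gape_mm = c(0.1, 0.3)
  )
  fs <- render_sequence(cfg, sc)
  f <- which.min(fs$truth$per_frame$gape_mm)   # ~1 px gape
  pf <- fs$truth$per_frame[f, ]
  hr <- extract_head_roi(fs$frames[[f]], c(pf$eye_x, pf$eye_y), "right")
  mask <- remove_particle_pixels(hr$roi, c(pf$eye_x, pf$eye_y) - hr$offset)
  tips <- detect_beak_tips(mask, c(pf$eye_x, pf$eye_y) - hr$offset, "right")
  expect_lte(sqrt(sum((tips$upper - tips$lower)^2)), 2)
})

test_that("tracking a clean sequence is flag-free and sub-pixel accurate", {
  cfg <- clean_config()
  fs <- render_sequence(cfg, one_cycle_script(n_frames = 40))
  tr <- track_sequence(fs, cal_of(cfg), "right")
  tru <- fs$truth$per_frame
  expect_equal(sum(tr$flag), 0)
  expect_lt(sqrt(mean((tr$eye_x - tru$eye_x)^2 + (tr$eye_y - tru$eye_y)^2)), 0.5)
  expect_gte(suppressWarnings(cor(tr$gape_mm, tru$gape_mm, method = "spearman")),
             0.99)
  # invariant: gape_mm = gape_px * mm_per_px exactly, and nonnegative
  expect_identical(tr$gape_mm, tr$gape_px * cfg$mm_per_px)
  expect_true(all(tr$gape_mm >= 0))
})

test_that("blanked frames are flagged and interpolated from neighbours", {
  cfg <- clean_config()
  fs <- render_sequence(cfg, one_cycle_script(n_frames = 30))
  frames <- fs$frames
  for (f in c(10, 11, 18)) frames[[f]] <- blank_frame(cfg)
  tr <- track_sequence(frames, cal_of(cfg), "right")
  expect_identical(which(tr$flag), c(10L, 11L, 18L))
  expect_equal(tr$eye_x[18], (tr$eye_x[17] + tr$eye_x[19]) / 2)
  expect_equal(tr$eye_y[18], (tr$eye_y[17] + tr$eye_y[19]) / 2)
})

test_that("sequences with too many failures are rejected", {
  cfg <- clean_config()
  fs <- render_sequence(cfg, one_cycle_script(n_frames = 10))
  frames <- fs$frames
  for (f in 1:8) frames[[f]] <- blank_frame(cfg)
  expect_error(track_sequence(frames, cal_of(cfg), "right"), "rejected")
})

test_that("eye tracking is translation-equivariant", {
  cfg <- clean_config()
  fs <- render_sequence(cfg, one_cycle_script())
  img <- fs$frames[[5]]
  dx <- 7L; dy <- 4L
  shifted <- blank_frame(cfg)
  shifted[(dy + 1):nrow(img), (dx + 1):ncol(img)] <-
    img[1:(nrow(img) - dy), 1:(ncol(img) - dx)]
  e0 <- detect_eye(img)
  e1 <- detect_eye(shifted)
  expect_equal(e1, e0 + c(dx, dy), tolerance = 1e-12)
})
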