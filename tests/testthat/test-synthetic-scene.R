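# The scene generator is the oracle for everything downstream, so its own
# contracts are checked exactly.

test_that("scene configuration rejects inconsistent photometry", {
  expect_error(scene_config(eye_gray = 150, head_gray = 120), "darker")
  expect_error(scene_config(eye_gray = 110, head_gray = 120), "separated")
  expect_error(scene_config(mm_per_px = 0), "mm_per_px")
})

test_that("scripted max gape and peak frame are recorded exactly", {
  cfg <- clean_config()
  sc <- one_cycle_script(n_frames = 20, peak_gape_mm = 4)
  fs <- render_sequence(cfg, sc)
  rec <- fs$truth$records
  expect_equal(nrow(rec), 1)
  expect_equal(rec$max_gape_mm, 4, tolerance = 1e-9)
  g <- cycle_gape_trajectory(20, 4)
  expect_equal(rec$peak_frame, rec$start + attr(g, "peak_frame"))
  # the peak frame is unique
  pf <- fs$truth$per_frame
  expect_equal(sum(pf$gape_mm == max(pf$gape_mm)), 1)
})

test_that("ground-truth gape equals tip distance times pixel pitch exactly", {
  cfg <- clean_config()
  fs <- render_sequence(cfg, one_cycle_script())
  pf <- fs$truth$per_frame
  d <- sqrt((pf$up_x - pf$lo_x)^2 + (pf$up_y - pf$lo_y)^2)
  expect_identical(pf$gape_mm, d * cfg$mm_per_px)
})

test_that("rendering is bit-identical under a fixed seed", {
  cfg <- scene_config(seed = 42)     # default noise and particles
  sc <- make_feeding_script("F2", 2, cfg, seed = 9)
  a <- render_sequence(cfg, sc)
  b <- render_sequence(cfg, sc)
  expect_identical(a$frames, b$frames)
  expect_identical(a$truth, b$truth)
})

test_that("scripted frame counts give the per-order durations of a 250 fps recording", {
  cfg <- clean_config()
  fs <- render_sequence(cfg, multi_cycle_script(c(20, 24, 23, 26)))
  expect_identical(fs$truth$records$duration_ms, c(80, 96, 92, 104))
  expect_identical(fs$truth$records$order, c(1L, 2L, 3L, 4L))
})

test_that("cycle trajectories are unimodal with positive boundary gape", {
  for (n in c(8, 13, 20, 27)) {
    g <- cycle_gape_trajectory(n, 3.7, base_gape_mm = 0.6)
    expect_length(g, n)
    expect_true(all(g > 0))
    p <- which.max(g)
    expect_true(all(diff(g[1:p]) > 0))
    if (p < n) expect_true(all(diff(g[p:n]) < 0))
    expect_equal(max(g), 3.7)
    expect_equal(sum(g == max(g)), 1)
  }
})

test_that("out-of-bounds geometry is rejected naming the frame", {
  cfg <- clean_config()
  sc <- one_cycle_script(start_xy_px = c(cfg$image_width - 30, 130))
  expect_error(render_sequence(cfg, sc), "frame 0")
})

test_that("ruler ticks land at tick_spacing_mm / mm_per_px pixels", {
  cfg <- clean_config()
  img <- render_ruler(cfg, 1.0)        # 10 px spacing
  prof <- colMeans(img)
  ticks <- which(prof < (min(prof) + max(prof)) / 2)
  expect_true(all(diff(ticks) %in% c(10)))
  img2 <- render_ruler(clean_config(mm_per_px = 0.05), 1.0)  # 20 px
  prof2 <- colMeans(img2)
  ticks2 <- which(prof2 < (min(prof2) + max(prof2)) / 2)
  expect_true(all(diff(ticks2) %in% c(20)))
  expect_error(render_ruler(cfg, 0.15), "unresolvable")
})
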