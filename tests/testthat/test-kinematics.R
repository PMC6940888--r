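# Cycle segmentation, ordering and the four kinematic variables.

# brute-force peak/boundary oracle: scan every local maximum of the raw
# series, keep those with prominence >= p by direct min/max scans, then find
# boundary minima linearly with the stated tie rules (earliest on the right,
# latest on the left)
brute_segments <- function(x, p_min) {
  n <- length(x)
  peaks <- integer(0)
  for (i in 2:(n - 1)) {
    if (x[i] > x[i - 1] && x[i] > x[i + 1]) {
      lh <- which(x[1:(i - 1)] > x[i])
      lo <- if (length(lh)) max(lh) + 1 else 1
      rh <- which(x[(i + 1):n] > x[i]) + i
      hi <- if (length(rh)) min(rh) - 1 else n
      prom <- x[i] - max(min(x[lo:(i - 1)]), min(x[(i + 1):hi]))
      if (prom >= p_min) peaks <- c(peaks, i)
    }
  }
  t(vapply(seq_along(peaks), function(j) {
    lo <- if (j == 1) 1 else peaks[j - 1] + 1
    hi <- if (j == length(peaks)) n else peaks[j + 1] - 1
    lseg <- x[lo:(peaks[j] - 1)]
    left <- lo + max(which(lseg == min(lseg))) - 1
    rseg <- x[(peaks[j] + 1):hi]
    right <- peaks[j] + min(which(rseg == min(rseg)))
    as.integer(c(left - 1, right - 1))
  }, integer(2)))
}

test_that("segmentation recovers scripted cycles with exact boundaries", {
  cfg <- clean_config()
  fs <- render_sequence(cfg, multi_cycle_script(c(20, 24, 23, 26),
                                                c(4, 3.5, 3, 2.5)))
  iv <- segment_mandibulations(fs$truth$per_frame$gape_mm)
  tru <- fs$truth$records
  expect_equal(nrow(iv), 4)
  expect_identical(iv$start, tru$start)
  expect_identical(iv$end, tru$end)
  expect_true(all(abs(iv$peak_frame - tru$peak_frame) <= 1))
})

test_that("a monotone series contains no complete cycle", {
  iv <- segment_mandibulations(seq(0.5, 5, length.out = 30))
  expect_equal(nrow(iv), 0)
})

test_that("segmentation matches a brute-force oracle and skips flat plateaus", {
  x <- c(1, 3, 5, 3, 1, 1, 1, 3, 6, 3, 1, 2)
  p <- kin_params(smooth_w = 1, prominence_min_mm = 1, separation_min = 2)
  iv <- segment_mandibulations(x, p)
  bf <- brute_segments(x, 1)
  expect_equal(nrow(iv), 2)
  expect_identical(cbind(iv$start, iv$end), unname(bf))
  # the plateau interior (frames 4..5 here) belongs to neither cycle
  expect_lte(iv$end[1], 4)
  expect_gte(iv$start[2], 6)
  # random series agree with the oracle too
  set.seed(71)
  for (r in 1:20) {
    y <- cumsum(rnorm(60))
    ivr <- segment_mandibulations(y, kin_params(smooth_w = 1,
                                                prominence_min_mm = 1.5,
                                                separation_min = 1))
    bfr <- brute_segments(y, 1.5)
    expect_identical(cbind(ivr$start, ivr$end),
                     unname(bfr[seq_len(nrow(ivr)), , drop = FALSE]))
    expect_equal(nrow(ivr), nrow(bfr))
  }
})

test_that("orders run 1,2,3 then 4 within each episode", {
  iv <- data.frame(start = seq(0, 50, 10), end = seq(8, 58, 10),
                   peak_frame = seq(4, 54, 10))
  o <- assign_orders(iv)
  expect_identical(o$order, c(1L, 2L, 3L, 4L, 4L, 4L))
  o2 <- assign_orders(iv[1:4, ], boundaries = 20)
  expect_identical(o2$order, c(1L, 2L, 1L, 2L))
  expect_identical(o2$episode, c(1L, 1L, 2L, 2L))
  empty <- assign_orders(iv[0, ])
  expect_equal(nrow(empty), 0)
  expect_warning(assign_orders(iv, boundaries = 5), "straddle")
})

test_that("withdrawal detection finds scripted episode starts", {
  cfg <- clean_config()
  mkpath <- function(n_app, n_wd, rise) rbind(
    cbind(rep(0, n_app), rep(1.5 / n_app, n_app)),
    cbind(rep(0, n_wd), rep(-rise / n_wd, n_wd)))
  # one approach + 5 mm withdrawal, then quiet: boundary near frame 15
  y_steps <- rbind(mkpath(5, 10, 5), matrix(0, 60, 2))
  track <- data.frame(eye_y = 130 + cumsum(c(0, y_steps[-nrow(y_steps), 2])) / cfg$mm_per_px)
  b <- detect_withdrawals(track, cfg$mm_per_px)
  expect_length(b, 1)
  expect_lte(abs(b - 14), 2)
  # flat trajectory: no boundary
  flat <- data.frame(eye_y = rep(130, 80))
  expect_length(detect_withdrawals(flat, cfg$mm_per_px), 0)
  # two scripted episodes: two boundaries
  y2 <- rbind(mkpath(5, 10, 5), matrix(0, 40, 2), mkpath(8, 10, 6),
              matrix(0, 40, 2))
  tr2 <- data.frame(eye_y = 130 + cumsum(c(0, y2[-nrow(y2), 2])) / cfg$mm_per_px)
  b2 <- detect_withdrawals(tr2, cfg$mm_per_px)
  expect_length(b2, 2)
})

test_that("kinematic variables follow their definitions exactly", {
  fps <- 250; mm <- 0.1
  n <- 30
  track <- data.frame(eye_x = 0.5 * (seq_len(n) - 1), eye_y = rep(0, n),
                      gape_mm = rep(1, n))
  rec <- compute_kinematics(data.frame(start = 0, end = 20), track, mm, fps)
  expect_equal(rec$duration_ms, 80)
  expect_equal(rec$displacement_mm, 1.0)      # 20 steps of 0.05 mm
  expect_equal(rec$speed_mm_s, 12.5)
  # stationary head
  still <- data.frame(eye_x = rep(3, n), eye_y = rep(4, n), gape_mm = rep(1, n))
  rec2 <- compute_kinematics(data.frame(start = 2, end = 12), still, mm, fps)
  expect_equal(rec2$displacement_mm, 0)
  expect_equal(rec2$speed_mm_s, 0)
  expect_error(compute_kinematics(data.frame(start = 0, end = 1), track, mm, fps),
               "shorter")
})

test_that("catch-and-throw flags: annotations verbatim, heuristic by episode medians", {
  rec <- data.frame(episode = c(1, 1, 1, 2),
                    max_gape_mm = c(4, 2, 2.5, 3),
                    displacement_mm = c(3, 1, 1.5, 2))
  ann <- c(FALSE, TRUE, FALSE, TRUE)
  expect_identical(flag_catch_and_throw(rec, ann)$catch_and_throw, ann)
  expect_error(flag_catch_and_throw(rec, ann[1:2]), "length")
  h <- flag_catch_and_throw(rec)
  expect_identical(h$catch_and_throw, c(TRUE, FALSE, FALSE, FALSE))
  # single-record episode can never exceed its own median
  expect_false(flag_catch_and_throw(rec[4, ])$catch_and_throw)
})
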