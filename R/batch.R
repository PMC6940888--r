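# Randomised feeding-script generation under the study conditions (three
# feed types differing in granulometry), batch simulation (19 birds x 3
# feeds), end-to-end analysis, and recovery evaluation against ground truth.

# Per-feed script conditions: median cycle durations (frames at 250 fps),
# median peak gapes (mm), median per-cycle head displacement (mm) for
# mandibulation orders 1..4, and catch-and-throw rates. Fine mash chews
# slowly with wide gapes; coarse mash is narrower; crumble starts fast with
# the widest gapes and the highest catch-and-throw incidence.
feed_conditions <- function(feed) {
  switch(feed,
    F1 = list(frames = c(20, 24, 23, 26), gape = c(4.0, 4.0, 3.0, 2.0),
              disp = c(3.5, 2.0, 2.0, 2.0), ct_rate = 0.26),
    F2 = list(frames = c(17, 21, 21, 20), gape = c(3.0, 3.0, 2.0, 2.0),
              disp = c(3.0, 1.0, 2.0, 2.0), ct_rate = 0.20),
    F3 = list(frames = c(14, 20, 22, 23), gape = c(4.0, 4.0, 3.0, 3.0),
              disp = c(3.0, 2.0, 2.0, 2.0), ct_rate = 0.33),
    stop("unknown feed type: ", feed)
  )
}

# random head path of n steps with total path length ~ target_mm: isotropic
# small jitter with damped vertical component (the head jerks in place while
# stationing/transporting; sustained vertical drift would mimic a
# withdrawal)
wander_path <- function(n, target_mm) {
  step <- target_mm / n
  phi <- stats::runif(n, 0, 2 * pi)
  v <- cbind(cos(phi), 0.5 * sin(phi))
  v <- v / sqrt(rowSums(v^2))
  v * step
}

#' Generate a randomised feeding script under a feed type's conditions
#'
#' One grasp-to-swallow episode: an approach-plus-withdrawal prefix (head
#' moves down to the feed, then upward by `withdraw_mm`), then
#' `n_mandibulations` cycles whose frame counts, peak gapes and head-path
#' lengths are drawn around the per-order medians of the feed type, with
#' catch-and-throw cycles (drawn at the feed's rate) showing augmented gape
#' and head motion. The gape ramps down to the cycle baseline at the end of
#' the prefix and ramps back up in a short tail, so every cycle boundary is
#' a unique minimum of the gape series.
#'
#' @param feed `"F1"` (fine mash), `"F2"` (coarse mash) or `"F3"` (crumble).
#' @param n_mandibulations Number of cycles (orders 1, 2, 3, 4, 4, ...).
#' @param config A [scene_config()] (frame rate and pixel pitch).
#' @param seed Integer seed.
#' @param withdraw_mm Upward withdrawal amplitude, mm.
#' @param start_xy_px Eye position at the first frame.
#' @return A [kinematic_script()].
#' @export
make_feeding_script <- function(feed = "F1", n_mandibulations = 5,
                                config = scene_config(), seed = 1,
                                withdraw_mm = 5,
                                start_xy_px = c(110, 150)) {
  fc <- feed_conditions(feed)
  base <- 0.6
  with_seed(seed, {
    mand <- lapply(seq_len(n_mandibulations), function(j) {
      o <- min(j, 4L)
      nf <- max(8L, round(stats::rnorm(1, fc$frames[o], 1.5)))
      peak <- max(base + 1, stats::rnorm(1, fc$gape[o], 0.25))
      disp <- max(0.3, stats::rnorm(1, fc$disp[o], 0.3))
      ct <- stats::runif(1) < fc$ct_rate
      if (ct) { peak <- peak * 1.25; disp <- disp * 1.5 }
      list(order = o, n_frames = nf, peak_gape_mm = peak,
           head_path = wander_path(nf, disp), catch_and_throw = ct)
    })
    n_app <- 5L; n_wd <- 10L
    pre_path <- rbind(
      cbind(stats::rnorm(n_app, 0, 0.02), rep(1.5 / n_app, n_app)),   # approach down
      cbind(stats::rnorm(n_wd, 0, 0.02), rep(-withdraw_mm / n_wd, n_wd))  # withdrawal up
    )
    pre_gape <- c(rep(base + 0.8, n_app + n_wd - 4), base + c(0.8, 0.6, 0.4, 0.2))
    n_tail <- 5L
    tail_path <- cbind(stats::rnorm(n_tail, 0, 0.02),
                       stats::rnorm(n_tail, 0, 0.02))
    # first tail frame sits below the cycle baseline (beak still not fully
    # closed) so the last cycle's right boundary is a unique minimum even
    # for shallow final cycles
    tail_gape <- base + seq(-0.2, 0.8, length.out = n_tail)
    kinematic_script(mand, withdrawal_path = pre_path,
                     withdrawal_gape_mm = pre_gape,
                     tail_path = tail_path, tail_gape_mm = tail_gape,
                     base_gape_mm = base, start_xy_px = start_xy_px)
  })
}

#' Ground truth of a script without rasterising frames
#'
#' Expands a script into per-frame eye/tip geometry and the per-cycle true
#' records (the same quantities [render_sequence()] stores), skipping the
#' pixel rendering. Useful for script-level bookkeeping at scale.
#'
#' @param config A [scene_config()].
#' @param script A [kinematic_script()].
#' @return List with `per_frame` and `records` (see [render_sequence()]).
#' @export
truth_from_script <- function(config, script) {
  ex <- expand_script(script, config)
  n <- ex$n_frames
  up <- matrix(NA_real_, n, 2); lo <- matrix(NA_real_, n, 2)
  for (f in seq_len(n)) {
    geo <- beak_geometry(ex$eye_x[f], ex$eye_y[f],
                         ex$gape_mm[f] / config$mm_per_px, config)
    up[f, ] <- geo$upper_tip; lo[f, ] <- geo$lower_tip
  }
  gape_mm <- sqrt((up[, 1] - lo[, 1])^2 + (up[, 2] - lo[, 2])^2) * config$mm_per_px
  per_frame <- data.frame(frame = seq_len(n) - 1L, eye_x = ex$eye_x,
                          eye_y = ex$eye_y, up_x = up[, 1], up_y = up[, 2],
                          lo_x = lo[, 1], lo_y = lo[, 2], gape_mm = gape_mm)
  list(per_frame = per_frame,
       records = true_records(ex, per_frame, script, config))
}

#' Simulate a batch of feeding sequences
#'
#' Default design: 19 birds x 3 feed types = 57 sequences, 5 mandibulations
#' each. `mand_per_feed` instead fixes the *total* mandibulation count per
#' feed (spread as evenly as possible over the birds), which is the
#' script-level bookkeeping mode (`render = FALSE`) used to emulate a full
#' recording campaign.
#'
#' @param n_birds Number of birds.
#' @param feeds Character vector of feed types.
#' @param n_mandibulations Cycles per sequence (ignored when
#'   `mand_per_feed` is given).
#' @param mand_per_feed Optional named integer vector of per-feed total
#'   mandibulation counts, e.g. `c(F1 = 576, F2 = 602, F3 = 551)`.
#' @param config A [scene_config()].
#' @param seed Integer master seed; per-sequence seeds derive from it.
#' @param render Rasterise and keep frames in memory (`TRUE`; only sensible
#'   for small batches) or keep scripts + ground truth only (`FALSE`, the
#'   default — [analyze_batch()] rasterises such sequences one at a time).
#' @return List of class `sim_batch`: `sequences` (each with bird_id,
#'   feed_type, seed, script, truth, and frames when rendered) and `config`.
#' @export
simulate_batch <- function(n_birds = 19, feeds = c("F1", "F2", "F3"),
                           n_mandibulations = 5, mand_per_feed = NULL,
                           config = scene_config(), seed = 1,
                           render = FALSE) {
  design <- expand.grid(bird = seq_len(n_birds), feed = feeds,
                        stringsAsFactors = FALSE)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1,
                                      nrow(design) + 1))
  sequences <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    feed <- design$feed[i]
    n_mand <- if (is.null(mand_per_feed)) n_mandibulations else {
      total <- mand_per_feed[[feed]]
      base <- total %/% n_birds
      base + as.integer(design$bird[i] <= total %% n_birds)
    }
    cfg_i <- config
    cfg_i$seed <- seeds[i]
    script <- make_feeding_script(feed, n_mand, cfg_i, seed = seeds[i])
    sq <- if (render) render_sequence(cfg_i, script)
          else list(frames = NULL, truth = truth_from_script(cfg_i, script),
                    config = cfg_i, script = script)
    sq$bird_id <- design$bird[i]
    sq$feed_type <- feed
    sq$sequence_id <- sprintf("bird%02d_%s", design$bird[i], feed)
    sequences[[i]] <- sq
  }
  structure(list(sequences = sequences, config = config, seed = seed),
            class = "sim_batch")
}

#' @export
print.sim_batch <- function(x, ...) {
  feeds <- table(vapply(x$sequences, `[[`, "", "feed_type"))
  rendered <- sum(vapply(x$sequences, function(s) !is.null(s$frames),
                         logical(1)))
  cat(sprintf("simulated feeding campaign: %d sequences (%s), %d rendered\n",
              length(x$sequences),
              paste(names(feeds), feeds, sep = ":", collapse = ", "),
              rendered))
  invisible(x)
}

#' @export
print.feeding_sequence <- function(x, ...) {
  cat(sprintf(
    "synthetic feeding sequence: %d frames (%dx%d px, %g fps), %d mandibulations\n",
    length(x$frames), x$config$image_width, x$config$image_height,
    x$config$fps, nrow(x$truth$records)))
  invisible(x)
}

#' Aggregate per-sequence records into one tidy table
#'
#' Binds either the ground-truth records (`source = "truth"`) or previously
#' computed estimated records (`source = "estimated"`) of all sequences,
#' prefixing bird, feed and sequence identity columns.
#'
#' @param batch A `sim_batch` (or a list of sequence-like lists).
#' @param source `"truth"` or `"estimated"` (the latter requires an
#'   `est_records` element per sequence, see [analyze_batch()]).
#' @return data.frame of records; `attr(, "per_feed_n")` holds per-feed
#'   counts.
#' @export
aggregate_records <- function(batch, source = c("truth", "estimated")) {
  source <- match.arg(source)
  seqs <- if (inherits(batch, "sim_batch")) batch$sequences else batch
  rows <- lapply(seqs, function(sq) {
    rec <- if (source == "truth") sq$truth$records else sq$est_records
    if (is.null(rec) || nrow(rec) == 0) return(NULL)
    cbind(data.frame(bird_id = sq$bird_id, feed_type = sq$feed_type,
                     sequence_id = sq$sequence_id), rec)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  else attr(out, "per_feed_n") <- table(out$feed_type)
  out
}

#' Analyse one feeding sequence end to end
#'
#' Tracks eye and beak tips, detects the feeding-sequence boundary from the
#' withdrawal motion (unless boundaries are supplied), segments the gape
#' series into mandibulations, assigns temporal orders, computes the four
#' kinematic variables per cycle and flags catch-and-throw movements
#' (annotation-first, heuristic otherwise).
#'
#' @param frames List of frames or a `feeding_sequence`.
#' @param calibration A `calibration` (or anything with `mm_per_px`).
#' @param fps Frame rate.
#' @param beak_facing `"left"` or `"right"`.
#' @param vparams,kparams [vision_params()] / [kin_params()].
#' @param boundaries Optional annotated 0-based boundary frames (overrides
#'   withdrawal detection).
#' @param ct_annotations Optional catch-and-throw annotations (see
#'   [flag_catch_and_throw()]).
#' @return List: `track` (head_track), `boundaries`, `records` (one row per
#'   mandibulation: episode, order, start, end, kinematic variables,
#'   catch_and_throw).
#' @export
analyze_sequence <- function(frames, calibration, fps = 250,
                             beak_facing = "right",
                             vparams = vision_params(),
                             kparams = kin_params(),
                             boundaries = NULL, ct_annotations = NULL) {
  if (inherits(frames, "feeding_sequence")) {
    fps <- frames$config$fps
    beak_facing <- frames$config$beak_facing
    frames <- frames$frames
  }
  track <- track_sequence(frames, calibration, beak_facing, vparams)
  if (is.null(boundaries))
    boundaries <- detect_withdrawals(track, calibration$mm_per_px, kparams)
  iv <- segment_mandibulations(track$gape_mm, kparams)
  # the first mandibulation starts right at the withdrawal end, so snap a
  # detected boundary onto a nearby cycle start rather than into its interior
  if (length(boundaries) && nrow(iv)) {
    boundaries <- vapply(boundaries, function(b) {
      d <- abs(iv$start - b)
      if (min(d) <= 6) iv$start[which.min(d)] else b
    }, numeric(1))
    boundaries <- sort(unique(boundaries))
  }
  iv <- assign_orders(iv, boundaries)
  if (nrow(iv) == 0)
    return(list(track = track, boundaries = boundaries,
                records = cbind(iv[, c("episode", "order"), drop = FALSE],
                                empty_records()[, -(1:2)])))
  recs <- do.call(rbind, lapply(seq_len(nrow(iv)), function(i)
    compute_kinematics(iv[i, ], track, calibration$mm_per_px, fps)))
  recs$episode <- iv$episode
  recs$order <- iv$order
  recs <- flag_catch_and_throw(recs, ct_annotations)
  list(track = track, boundaries = boundaries, records = recs)
}

#' Analyse every sequence of a batch
#'
#' Sequences without rendered frames (the memory-friendly
#' `simulate_batch(render = FALSE)` form) are rasterised on the fly and
#' their frames discarded after tracking, so a study-scale batch streams
#' through a bounded footprint.
#'
#' @param batch A `sim_batch`.
#' @param vparams,kparams Pipeline parameters.
#' @return The batch with `est_records` and `track` attached to each
#'   sequence; failed sequences carry `error` instead.
#' @export
analyze_batch <- function(batch, vparams = vision_params(),
                          kparams = kin_params()) {
  stopifnot(inherits(batch, "sim_batch"))
  cal <- structure(list(mm_per_px = batch$config$mm_per_px),
                   class = "calibration")
  for (i in seq_along(batch$sequences)) {
    sq <- batch$sequences[[i]]
    frames <- sq$frames
    if (is.null(frames))
      frames <- render_sequence(sq$config, sq$script)$frames
    res <- tryCatch(
      analyze_sequence(frames, cal, fps = sq$config$fps,
                       beak_facing = sq$config$beak_facing,
                       vparams = vparams, kparams = kparams),
      error = function(e) e)
    rm(frames)
    if (inherits(res, "error")) {
      batch$sequences[[i]]$error <- conditionMessage(res)
    } else {
      batch$sequences[[i]]$est_records <- res$records
      batch$sequences[[i]]$track <- res$track
    }
  }
  batch
}

#' Compare estimated records with ground truth
#'
#' Matches estimated and true mandibulations by temporal ordinal within
#' each sequence (after checking the counts agree) and summarises the
#' absolute errors of the three recovered quantities against their
#' tolerances: max gape within `2 * mm_per_px`, duration exact, and
#' displacement within `3 * mm_per_px * n_frames`.
#'
#' @param batch An analysed `sim_batch` (see [analyze_batch()]).
#' @return List: `per_record` data.frame of matched errors,
#'   `count_match_fraction` (sequences whose cycle count equals the
#'   scripted count), `gape_within_tol`, `duration_exact`,
#'   `displacement_within_tol` (fractions over matched records).
#' @export
recovery_summary <- function(batch) {
  mm <- batch$config$mm_per_px
  rows <- list()
  n_seq <- 0; n_count_ok <- 0
  for (sq in batch$sequences) {
    if (!is.null(sq$error) || is.null(sq$est_records)) next
    n_seq <- n_seq + 1
    tru <- sq$truth$records; est <- sq$est_records
    if (nrow(tru) == nrow(est)) n_count_ok <- n_count_ok + 1
    k <- min(nrow(tru), nrow(est))
    if (k == 0) next
    tru <- tru[seq_len(k), ]; est <- est[seq_len(k), ]
    rows[[length(rows) + 1]] <- data.frame(
      sequence_id = sq$sequence_id,
      n_frames = tru$end - tru$start,
      gape_err = abs(est$max_gape_mm - tru$max_gape_mm),
      dur_err = abs(est$duration_ms - tru$duration_ms),
      disp_err = abs(est$displacement_mm - tru$displacement_mm)
    )
  }
  per <- do.call(rbind, rows)
  list(per_record = per,
       count_match_fraction = n_count_ok / max(n_seq, 1),
       gape_within_tol = mean(per$gape_err <= 2 * mm),
       duration_exact = mean(per$dur_err == 0),
       displacement_within_tol = mean(per$disp_err <= 3 * mm * per$n_frames))
}
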