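# Machine-vision steps for marker-free head tracking: eye detection (the
# reference point for the head), head-region extraction, feed-particle pixel
# removal, and beak-tip detection, plus pixel-to-mm ruler calibration.
#
# Frames are numeric intensity matrices (0-255), indexed [y+1, x+1] with
# 0-based pixel coordinates, x rightward, y downward. EBImage expects the
# transpose (its first dimension is x), handled at the call sites.

ebi <- function(m) EBImage::Image(t(m) / 255)

otsu255 <- function(values) {
  if (length(values) < 2 || diff(range(values)) < 1) return(NA_real_)
  EBImage::otsu(EBImage::Image(matrix(values / 255, ncol = 1))) * 255
}

#' Vision-pipeline parameters
#'
#' All tunables of the tracking pipeline, scaled off an expected eye radius
#' (px). Area limits bracket the eye blob; `circ_min` is the minimum
#' circularity 4*pi*A/P^2 an eye candidate must reach; the region of
#' interest extends `roi_forward` px from the eye toward the beak and
#' `roi_back`/`roi_up`/`roi_down` on the other sides; the particle band
#' `particle_gray +/- particle_band` is excised during particle removal and
#' the mask is then opened with a diamond kernel of size `particle_kernel`.
#'
#' @param eye_radius Expected eye radius, px.
#' @param area_min,area_max Eye candidate area limits, px^2.
#' @param circ_min Minimum circularity of an eye candidate.
#' @param roi_forward,roi_back,roi_up,roi_down ROI extents from the eye, px.
#' @param particle_gray Centre of the feed-particle intensity band (0-255).
#' @param particle_band Half-width of the particle intensity band.
#' @param particle_kernel Size (odd) of the diamond opening kernel, px.
#' @param removal_enabled Excise the particle band? (The ablation switch for
#'   the particle-removal step; thresholding, eye-component pruning and the
#'   opening run either way.)
#' @param min_offset Tip candidates must lie at least this far beyond the
#'   eye toward the beak, px.
#' @param tip_band Width (px) behind the most distal column searched for tip
#'   pixels.
#' @param cluster_gap Vertical gap (px) separating the upper and lower tip
#'   pixel clusters.
#' @param max_fail_fraction Reject a sequence when more than this fraction
#'   of frames fail detection.
#' @return A list of class `vision_params`.
#' @export
vision_params <- function(eye_radius = 9,
                          area_min = round(0.5 * pi * eye_radius^2),
                          area_max = round(2.5 * pi * eye_radius^2),
                          circ_min = 0.6,
                          roi_forward = 14 * eye_radius,
                          roi_back = 6 * eye_radius,
                          roi_up = 6 * eye_radius,
                          roi_down = 6 * eye_radius,
                          particle_gray = 70, particle_band = 25,
                          particle_kernel = 3, removal_enabled = TRUE,
                          min_offset = 2 * eye_radius,
                          tip_band = 1, cluster_gap = 2,
                          max_fail_fraction = 0.2) {
  p <- as.list(environment())
  stopifnot(p$particle_kernel %% 2 == 1, p$max_fail_fraction >= 0)
  class(p) <- "vision_params"
  p
}

#' Calibration from a ruler image
#'
#' Estimates the pixel pitch from an image of equally spaced dark ticks:
#' the mean-intensity profile along each axis is thresholded midway between
#' its extremes, runs of dark positions give tick centres, and the pixel
#' pitch is `tick_spacing_mm / median inter-tick spacing`. The axis with
#' more resolvable ticks is used; fewer than 3 ticks is a calibration
#' failure.
#'
#' @param image Intensity matrix (0-255).
#' @param tick_spacing_mm Physical tick spacing, mm.
#' @return A list of class `calibration` with element `mm_per_px`.
#' @examples
#' cfg <- scene_config(noise_sd = 0)
#' cal <- calibrate_from_ruler(render_ruler(cfg, 1), 1)
#' cal$mm_per_px
#' @export
calibrate_from_ruler <- function(image, tick_spacing_mm) {
  stopifnot(tick_spacing_mm > 0)
  ticks_along <- function(profile) {
    if (diff(range(profile)) < 10) return(numeric(0))
    dark <- profile < (min(profile) + max(profile)) / 2
    r <- rle(dark)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    centres <- (starts[r$values] + ends[r$values]) / 2
    centres
  }
  cx <- ticks_along(colMeans(image))
  cy <- ticks_along(rowMeans(image))
  centres <- if (length(cx) >= length(cy)) cx else cy
  if (length(centres) < 3)
    stop("calibration failure: fewer than 3 ruler ticks found")
  mm_per_px <- tick_spacing_mm / stats::median(diff(centres))
  structure(list(mm_per_px = mm_per_px, n_ticks = length(centres)),
            class = "calibration")
}

#' Detect the chick's eye in a frame
#'
#' The eye is the darkest compact blob in a lateral view. A first Otsu
#' threshold separates the animal from the background; a second Otsu pass
#' over the foreground intensities isolates the darkest pixels (eye, and
#' possibly feed particles). Connected components are filtered by area and
#' circularity (4*pi*A/P^2) and the winner is the most circular candidate;
#' ties break by larger area, then smaller y.
#'
#' @param frame Intensity matrix (0-255).
#' @param params A [vision_params()].
#' @return Numeric `c(x, y)` centroid in 0-based pixel coordinates, or
#'   `c(NA, NA)` with attribute `failed = TRUE` when no candidate passes.
#' @export
detect_eye <- function(frame, params = vision_params()) {
  fail <- structure(c(NA_real_, NA_real_), failed = TRUE)
  th1 <- otsu255(as.numeric(frame))
  if (is.na(th1)) return(fail)
  fg <- frame < th1
  if (!any(fg)) return(fail)
  th2 <- otsu255(frame[fg])
  # a single-valued foreground (no head/eye contrast) is itself the dark set
  dark <- if (is.na(th2)) fg else frame < th2
  if (!any(dark)) return(fail)
  lab <- EBImage::bwlabel(ebi(dark * 255))
  sh <- EBImage::computeFeatures.shape(lab)
  if (is.null(sh) || nrow(sh) == 0) return(fail)
  mo <- EBImage::computeFeatures.moment(lab)
  area <- sh[, "s.area"]; per <- pmax(sh[, "s.perimeter"], 1)
  circ <- 4 * pi * area / per^2
  ok <- area >= params$area_min & area <= params$area_max &
    circ >= params$circ_min
  if (!any(ok)) return(fail)
  idx <- which(ok)
  # EBImage centroids are in 1-based index units; convert to 0-based coords
  cx <- mo[idx, "m.cx"] - 1; cy <- mo[idx, "m.cy"] - 1
  ord <- order(-circ[idx], -area[idx], cy)
  c(cx[ord[1]], cy[ord[1]])
}

#' Extract the head region of interest around the eye
#'
#' Rectangular window anchored at the eye centre, extending `roi_forward`
#' px toward the beak and `roi_back`/`roi_up`/`roi_down` on the other
#' sides, clipped to the frame. The returned offset maps ROI pixel
#' coordinates back to frame coordinates (`frame_xy = roi_xy + offset`).
#'
#' @param frame Intensity matrix.
#' @param eye_center `c(x, y)`, 0-based.
#' @param beak_facing `"left"` or `"right"`.
#' @param params A [vision_params()].
#' @return List with `roi` (matrix) and `offset` (`c(x0, y0)`).
#' @export
extract_head_roi <- function(frame, eye_center, beak_facing = "right",
                             params = vision_params()) {
  W <- ncol(frame); H <- nrow(frame)
  ex <- eye_center[1]; ey <- eye_center[2]
  stopifnot(ex >= 0, ex <= W - 1, ey >= 0, ey <= H - 1)
  if (beak_facing == "right") {
    x0 <- floor(ex - params$roi_back); x1 <- ceiling(ex + params$roi_forward)
  } else {
    x0 <- floor(ex - params$roi_forward); x1 <- ceiling(ex + params$roi_back)
  }
  y0 <- floor(ey - params$roi_up); y1 <- ceiling(ey + params$roi_down)
  x0 <- max(0L, x0); y0 <- max(0L, y0)
  x1 <- min(W - 1L, x1); y1 <- min(H - 1L, y1)
  list(roi = frame[(y0:y1) + 1L, (x0:x1) + 1L, drop = FALSE],
       offset = c(x0, y0))
}

#' Foreground mask of the head with feed-particle pixels removed
#'
#' Otsu-thresholds the ROI, keeps only the 4-connected component containing
#' the eye, then (when removal is enabled) excises pixels inside the
#' configured particle intensity band, and finally opens the mask with a
#' small diamond kernel. Disabling removal skips only the band excision, so
#' the enabled/disabled comparison isolates the particle-removal step.
#'
#' @param roi Intensity matrix (ROI).
#' @param eye_in_roi Eye centre in ROI coordinates, `c(x, y)` 0-based.
#' @param params A [vision_params()].
#' @return Logical matrix (same shape as `roi`); attribute `warning` is set
#'   to a message when the eye component could not be found (pass-through
#'   mask) or the ROI is empty of foreground.
#' @export
remove_particle_pixels <- function(roi, eye_in_roi, params = vision_params()) {
  th <- otsu255(as.numeric(roi))
  if (is.na(th) || !any(roi < th)) {
    m <- matrix(FALSE, nrow(roi), ncol(roi))
    attr(m, "warning") <- "no foreground in ROI"
    return(m)
  }
  fg <- roi < th
  lab <- t(EBImage::imageData(EBImage::bwlabel(ebi(fg * 255))))
  ex <- round(eye_in_roi[1]) + 1L; ey <- round(eye_in_roi[2]) + 1L
  eye_lab <- if (ey >= 1 && ey <= nrow(lab) && ex >= 1 && ex <= ncol(lab))
    lab[ey, ex] else 0
  warn <- NULL
  if (eye_lab == 0) {
    warn <- "eye component not found in ROI; pass-through mask"
    mask <- fg
  } else {
    mask <- lab == eye_lab
  }
  if (params$removal_enabled) {
    band <- roi >= params$particle_gray - params$particle_band &
      roi <= params$particle_gray + params$particle_band
    mask <- mask & !band
  }
  if (params$particle_kernel > 1 && any(mask)) {
    kern <- EBImage::makeBrush(params$particle_kernel, shape = "diamond")
    mask <- t(EBImage::imageData(EBImage::opening(ebi(mask * 255) > 0.5,
                                                  kern))) > 0
  }
  attr(mask, "warning") <- warn
  mask
}

#' Detect the upper and lower beak tips in a head mask
#'
#' Considers foreground pixels on the beak side of the eye (at least
#' `min_offset` px beyond it in the facing direction). Because the two beak
#' lobes rotate symmetrically about the hinge, both tips share the most
#' distal column; pixels within `tip_band` px of that column are split into
#' an upper and a lower cluster by vertical gaps larger than `cluster_gap`.
#' Each cluster's most distal pixel (ties toward the extreme y) is its tip.
#' A single cluster means the beak is (near) closed and the same most
#' distal point is returned for both tips.
#'
#' @param mask Logical foreground matrix.
#' @param eye_center Eye position in the mask's coordinates, `c(x, y)`.
#' @param beak_facing `"left"` or `"right"`.
#' @param params A [vision_params()].
#' @return List with `upper` and `lower` (`c(x, y)` each, upper y <= lower
#'   y), or `NULL` with no candidates (tip failure).
#' @export
detect_beak_tips <- function(mask, eye_center, beak_facing = "right",
                             params = vision_params()) {
  if (!any(mask)) return(NULL)
  idx <- which(mask, arr.ind = TRUE)
  x <- idx[, 2] - 1; y <- idx[, 1] - 1
  s <- if (beak_facing == "right") 1 else -1
  d <- s * (x - eye_center[1])
  keep <- d >= params$min_offset
  if (!any(keep)) return(NULL)
  x <- x[keep]; y <- y[keep]; d <- d[keep]
  D <- max(d)
  band <- d >= D - params$tip_band
  xb <- x[band]; yb <- y[band]; db <- d[band]
  o <- order(yb)
  yb <- yb[o]; xb <- xb[o]; db <- db[o]
  cluster <- cumsum(c(1, diff(yb) > params$cluster_gap))
  # tip of a cluster: its most distal column, y at the column's pixel mean
  # (sub-pixel, robust to the one-pixel jitter of the rasterised lobe cap)
  pick <- function(i) {
    di <- db[i]; yi <- yb[i]; xi <- xb[i]
    best <- di == max(di)
    c(xi[best][1], mean(yi[best]))
  }
  if (max(cluster) >= 2) {
    upper <- pick(which(cluster == 1))
    lower <- pick(which(cluster == max(cluster)))
  } else {
    tip <- pick(seq_along(yb))
    upper <- tip; lower <- tip
  }
  if (upper[2] > lower[2]) { tmp <- upper; upper <- lower; lower <- tmp }
  list(upper = upper, lower = lower)
}

#' Track eye and beak tips through a frame sequence
#'
#' Runs eye detection, head-ROI extraction, particle removal and beak-tip
#' detection on every frame. Frames where any step fails are flagged and
#' filled by linear interpolation between neighbouring detections (constant
#' extrapolation at the ends); the gape is recomputed from the interpolated
#' tips so `gape_px = ||upper - lower||` holds on every row. Sequences with
#' more than `max_fail_fraction` failed frames are rejected.
#'
#' @param frames List of intensity matrices, or a `feeding_sequence`.
#' @param calibration A `calibration` (or a [scene_config()]; only
#'   `mm_per_px` is used).
#' @param beak_facing `"left"` or `"right"`.
#' @param params A [vision_params()].
#' @return A data.frame of class `head_track`: frame (0-based), eye_x,
#'   eye_y, up_x, up_y, lo_x, lo_y, gape_px, gape_mm, flag (TRUE where the
#'   frame was interpolated).
#' @export
track_sequence <- function(frames, calibration, beak_facing = "right",
                           params = vision_params()) {
  if (inherits(frames, "feeding_sequence")) frames <- frames$frames
  n <- length(frames)
  stopifnot(n >= 2)
  mm_per_px <- calibration$mm_per_px
  stopifnot(is.numeric(mm_per_px), mm_per_px > 0)
  out <- matrix(NA_real_, n, 6,
                dimnames = list(NULL, c("eye_x", "eye_y", "up_x", "up_y",
                                        "lo_x", "lo_y")))
  prev <- NULL
  w <- ceiling(5 * params$eye_radius)   # local search half-window
  for (f in seq_len(n)) {
    frame <- frames[[f]]
    eye <- c(NA_real_, NA_real_)
    if (!is.null(prev)) {
      # the head moves a few px per frame at most: search a window around
      # the previous eye first, falling back to the full frame
      x0 <- max(0L, round(prev[1]) - w); x1 <- min(ncol(frame) - 1L, round(prev[1]) + w)
      y0 <- max(0L, round(prev[2]) - w); y1 <- min(nrow(frame) - 1L, round(prev[2]) + w)
      el <- detect_eye(frame[(y0:y1) + 1L, (x0:x1) + 1L, drop = FALSE], params)
      if (!is.na(el[1])) eye <- el + c(x0, y0)
    }
    if (is.na(eye[1])) eye <- detect_eye(frame, params)
    if (is.na(eye[1])) { prev <- NULL; next }
    prev <- eye
    hr <- extract_head_roi(frame, eye, beak_facing, params)
    mask <- remove_particle_pixels(hr$roi, eye - hr$offset, params)
    tips <- detect_beak_tips(mask, eye - hr$offset, beak_facing, params)
    if (is.null(tips)) next
    out[f, ] <- c(eye, tips$upper + hr$offset, tips$lower + hr$offset)
  }
  failed <- is.na(out[, 1])
  if (mean(failed) > params$max_fail_fraction)
    stop(sprintf("sequence rejected: %d of %d frames failed detection",
                 sum(failed), n))
  if (all(failed)) stop("sequence rejected: no frame succeeded")
  if (any(failed)) {
    good <- which(!failed)
    for (j in seq_len(ncol(out)))
      out[failed, j] <- stats::approx(good, out[good, j], xout = which(failed),
                                      rule = 2)$y
  }
  gape_px <- sqrt((out[, "up_x"] - out[, "lo_x"])^2 +
                  (out[, "up_y"] - out[, "lo_y"])^2)
  res <- data.frame(frame = seq_len(n) - 1L, out, gape_px = gape_px,
                    gape_mm = gape_px * mm_per_px, flag = failed)
  class(res) <- c("head_track", "data.frame")
  res
}
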