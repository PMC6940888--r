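# --- low-level rasterisation helpers (pixel centres at integer 0-based
#     coordinates, x rightward, y downward) ---------------------------------

pixel_window <- function(lo, hi, n) {
  lo <- max(0L, floor(lo)); hi <- min(n - 1L, ceiling(hi))
  if (hi < lo) integer(0) else seq.int(lo, hi)
}

draw_ellipse <- function(img, cx, cy, rx, ry, value) {
  xs <- pixel_window(cx - rx, cx + rx, ncol(img))
  ys <- pixel_window(cy - ry, cy + ry, nrow(img))
  if (!length(xs) || !length(ys)) return(img)
  m <- outer((ys - cy)^2 / ry^2, (xs - cx)^2 / rx^2, `+`) <= 1
  sub <- img[ys + 1L, xs + 1L, drop = FALSE]
  sub[m] <- value
  img[ys + 1L, xs + 1L] <- sub
  img
}

draw_disc <- function(img, cx, cy, r, value) {
  draw_ellipse(img, cx, cy, r, r, value)
}

# thick segment with rounded ends: all pixels within r of the segment pq.
# Used for the beak-lobe spines so the lobes keep >= kernel width out to the
# very tip (a bare triangle thins below one pixel near its apex and breaks
# up under rasterisation and morphological opening).
draw_capsule <- function(img, p, q, r, value) {
  xs <- pixel_window(min(p[1], q[1]) - r, max(p[1], q[1]) + r, ncol(img))
  ys <- pixel_window(min(p[2], q[2]) - r, max(p[2], q[2]) + r, nrow(img))
  if (!length(xs) || !length(ys)) return(img)
  X <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  Y <- matrix(ys, nrow = length(ys), ncol = length(xs))
  v <- q - p
  len2 <- sum(v^2)
  t <- if (len2 == 0) 0 else pmin(1, pmax(0, ((X - p[1]) * v[1] + (Y - p[2]) * v[2]) / len2))
  d2 <- (X - (p[1] + t * v[1]))^2 + (Y - (p[2] + t * v[2]))^2
  m <- d2 <= r^2
  sub <- img[ys + 1L, xs + 1L, drop = FALSE]
  sub[m] <- value
  img[ys + 1L, xs + 1L] <- sub
  img
}

fill_triangle <- function(img, p1, p2, p3, value) {
  xs <- pixel_window(min(p1[1], p2[1], p3[1]), max(p1[1], p2[1], p3[1]), ncol(img))
  ys <- pixel_window(min(p1[2], p2[2], p3[2]), max(p1[2], p2[2], p3[2]), nrow(img))
  if (!length(xs) || !length(ys)) return(img)
  X <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  Y <- matrix(ys, nrow = length(ys), ncol = length(xs))
  edge <- function(p, q) (q[1] - p[1]) * (Y - p[2]) - (q[2] - p[2]) * (X - p[1])
  d1 <- edge(p1, p2); d2 <- edge(p2, p3); d3 <- edge(p3, p1)
  neg <- (d1 < 0) | (d2 < 0) | (d3 < 0)
  pos <- (d1 > 0) | (d2 > 0) | (d3 > 0)
  m <- !(neg & pos)
  sub <- img[ys + 1L, xs + 1L, drop = FALSE]
  sub[m] <- value
  img[ys + 1L, xs + 1L] <- sub
  img
}

# --- scene geometry --------------------------------------------------------

#' Beak geometry for a given eye position and gape
#'
#' The two beak wedges hinge at a vertex offset forward and slightly below
#' the eye; the gape is realised by rotating both wedges symmetrically about
#' the hinge, so a tip-to-tip separation `g` (px) corresponds to a half-angle
#' `asin(g / (2 * beak_length))`. Both tips then share the same distal x
#' coordinate.
#'
#' @param eye_x,eye_y Eye centre, 0-based px.
#' @param gape_px Tip-to-tip separation, px (must be < 2 * beak_length).
#' @param config A [scene_config()].
#' @return List with `hinge`, `upper_tip`, `lower_tip` (each length-2 (x, y)).
#' @export
beak_geometry <- function(eye_x, eye_y, gape_px, config) {
  s <- if (config$beak_facing == "right") 1 else -1
  r <- config$eye_radius
  L <- config$beak_length
  if (gape_px >= 1.98 * L)
    stop("gape exceeds the geometric range of the beak wedges")
  hinge <- c(eye_x + s * 2.6 * r, eye_y + 1.1 * r)
  theta <- asin(gape_px / (2 * L))
  dx <- s * L * cos(theta)
  dy <- L * sin(theta)
  list(hinge = hinge,
       upper_tip = c(hinge[1] + dx, hinge[2] - dy),
       lower_tip = c(hinge[1] + dx, hinge[2] + dy))
}

render_head_frame <- function(config, eye_x, eye_y, gape_px, particles,
                              template = NULL) {
  W <- config$image_width; H <- config$image_height
  s <- if (config$beak_facing == "right") 1 else -1
  r <- config$eye_radius
  geo <- beak_geometry(eye_x, eye_y, gape_px, config)
  img <- if (is.null(template)) matrix(config$background_gray, H, W)
         else template
  # head silhouette (scenery; only eye and tips are metrically exact)
  img <- draw_ellipse(img, eye_x - s * 2 * r, eye_y + 0.7 * r,
                      4.5 * r, 3.8 * r, config$head_gray)
  # beak wedges, base tucked inside the head so the beak stays 4-connected
  base_x <- geo$hinge[1] - s * 8
  img <- fill_triangle(img, c(base_x, geo$hinge[2] - 12),
                       c(base_x, geo$hinge[2] + 2), geo$upper_tip,
                       config$head_gray)
  img <- fill_triangle(img, c(base_x, geo$hinge[2] - 2),
                       c(base_x, geo$hinge[2] + 12), geo$lower_tip,
                       config$head_gray)
  img <- draw_capsule(img, geo$hinge, geo$upper_tip, 1.6, config$head_gray)
  img <- draw_capsule(img, geo$hinge, geo$lower_tip, 1.6, config$head_gray)
  img <- draw_disc(img, eye_x, eye_y, r, config$eye_gray)
  # particles are drawn last (they occlude the beak where they overlap)
  if (nrow(particles)) {
    for (i in seq_len(nrow(particles)))
      img <- draw_disc(img, particles[i, 1], particles[i, 2],
                       config$particle_radius_px, config$particle_gray)
  }
  img
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Render a synthetic feeding sequence with exact ground truth
#'
#' Rasterises a [kinematic_script()] under a [scene_config()]: per frame, a
#' head ellipse with a dark circular eye, two beak wedges hinged at a vertex
#' whose tip separation realises the scripted gape, feed particles near the
#' beak (one grasped particle rides with the lower tip and overlaps the
#' beak-tip region; the rest rest in the trough), and additive Gaussian
#' imaging noise. Ground truth (eye centre, both tips, gape) is recorded
#' before noise is added, and per-mandibulation true records are derived
#' from the scripted geometry with the same kinematic definitions the
#' analysis uses.
#'
#' @param config A [scene_config()].
#' @param script A [kinematic_script()].
#' @return A list of class `feeding_sequence`:
#' \describe{
#'   \item{frames}{list of H x W intensity matrices (0-255).}
#'   \item{truth}{list with `per_frame` (data.frame: frame, eye_x, eye_y,
#'     up_x, up_y, lo_x, lo_y, gape_mm) and `records` (one row per scripted
#'     mandibulation with the four kinematic variables and flags).}
#'   \item{config, script}{the inputs, for provenance.}
#' }
#' @examples
#' cfg <- scene_config(noise_sd = 0, particle_count = 0)
#' sc <- make_feeding_script(n_mandibulations = 1, config = cfg, seed = 1)
#' seq <- render_sequence(cfg, sc)
#' nrow(seq$truth$records)
#' @export
render_sequence <- function(config, script) {
  validate_scene_config(config)
  ex <- expand_script(script, config)
  n <- ex$n_frames
  W <- config$image_width; H <- config$image_height
  margin <- 2
  frames <- vector("list", n)
  template <- matrix(config$background_gray, H, W)
  up <- matrix(NA_real_, n, 2); lo <- matrix(NA_real_, n, 2)
  with_seed(config$seed, {
    # static trough particles near the beak's initial position
    geo0 <- beak_geometry(ex$eye_x[1], ex$eye_y[1],
                          ex$gape_mm[1] / config$mm_per_px, config)
    s <- if (config$beak_facing == "right") 1 else -1
    n_static <- max(0L, config$particle_count - 1L)
    static_p <- cbind(
      geo0$hinge[1] + s * stats::runif(n_static, 5, 0.7 * config$beak_length),
      geo0$hinge[2] + stats::runif(n_static, 8, 30)
    )
    for (f in seq_len(n)) {
      gape_px <- ex$gape_mm[f] / config$mm_per_px
      geo <- beak_geometry(ex$eye_x[f], ex$eye_y[f], gape_px, config)
      pts <- rbind(c(ex$eye_x[f], ex$eye_y[f]), geo$upper_tip, geo$lower_tip)
      if (any(pts[, 1] < margin | pts[, 1] > W - 1 - margin |
              pts[, 2] < margin | pts[, 2] > H - 1 - margin))
        stop(sprintf("scene geometry out of frame bounds at frame %d", f - 1L))
      particles <- static_p
      if (config$particle_count > 0) {
        # grasped particle: rides with the lower tip, rim touching the lobe
        # from below and poking past it distally, so it corrupts tip
        # detection unless its pixels are removed — while leaving the tip
        # cap itself unoccluded
        pr <- config$particle_radius_px
        particles <- rbind(particles,
                           geo$lower_tip + c(s * (pr - 1), pr + 0.5))
      }
      img <- render_head_frame(config, ex$eye_x[f], ex$eye_y[f], gape_px,
                               particles, template)
      up[f, ] <- geo$upper_tip; lo[f, ] <- geo$lower_tip
      if (config$noise_sd > 0) {
        img <- img + stats::rnorm(H * W, 0, config$noise_sd)
        img[img < 0] <- 0; img[img > 255] <- 255
      }
      frames[[f]] <- img
    }
  })
  # ground truth: gape is *defined* as tip distance times the pixel pitch,
  # so the invariant holds bit-exactly
  gape_mm <- sqrt((up[, 1] - lo[, 1])^2 + (up[, 2] - lo[, 2])^2) * config$mm_per_px
  per_frame <- data.frame(
    frame = seq_len(n) - 1L,
    eye_x = ex$eye_x, eye_y = ex$eye_y,
    up_x = up[, 1], up_y = up[, 2], lo_x = lo[, 1], lo_y = lo[, 2],
    gape_mm = gape_mm
  )
  records <- true_records(ex, per_frame, script, config)
  structure(list(frames = frames, truth = list(per_frame = per_frame,
                                               records = records),
                 config = config, script = script),
            class = "feeding_sequence")
}

# Per-mandibulation ground-truth records, using the same kinematic
# definitions as compute_kinematics() (path-length displacement over the
# half-open interval, duration from frame count).
true_records <- function(ex, per_frame, script, config) {
  k <- length(ex$cycle_start)
  if (k == 0) return(empty_records())
  n <- ex$n_frames
  rec <- lapply(seq_len(k), function(i) {
    s0 <- ex$cycle_start[i]; e0 <- ex$cycle_end[i]
    idx <- seq.int(s0, min(e0, n - 1L)) + 1L     # positions s..e inclusive
    dx <- diff(per_frame$eye_x[idx]); dy <- diff(per_frame$eye_y[idx])
    disp <- sum(sqrt(dx^2 + dy^2)) * config$mm_per_px
    net <- sqrt((per_frame$eye_x[idx[length(idx)]] - per_frame$eye_x[idx[1]])^2 +
                (per_frame$eye_y[idx[length(idx)]] - per_frame$eye_y[idx[1]])^2) *
      config$mm_per_px
    dur <- (e0 - s0) * 1000 / config$fps
    data.frame(
      cycle = i, order = as.integer(script$mandibulations[[i]]$order),
      start = as.integer(s0), end = as.integer(e0),
      peak_frame = as.integer(ex$cycle_peak[i]),
      max_gape_mm = max(per_frame$gape_mm[seq.int(s0, e0 - 1L) + 1L]),
      displacement_mm = disp, net_displacement_mm = net,
      duration_ms = dur, speed_mm_s = disp / (dur / 1000),
      catch_and_throw = script$mandibulations[[i]]$catch_and_throw
    )
  })
  do.call(rbind, rec)
}

empty_records <- function() {
  data.frame(cycle = integer(0), order = integer(0), start = integer(0),
             end = integer(0), peak_frame = integer(0),
             max_gape_mm = numeric(0), displacement_mm = numeric(0),
             net_displacement_mm = numeric(0), duration_ms = numeric(0),
             speed_mm_s = numeric(0), catch_and_throw = logical(0))
}

#' Render a synthetic calibration ruler
#'
#' Produces an image of equally spaced dark ticks on a light background; the
#' pixel spacing of the ticks is `tick_spacing_mm / mm_per_px`. Spacings that
#' would fall below 2 px are rejected as unresolvable.
#'
#' @param config A [scene_config()].
#' @param tick_spacing_mm Physical distance between adjacent ticks, mm.
#' @return An H x W intensity matrix.
#' @examples
#' r <- render_ruler(scene_config(), tick_spacing_mm = 1)
#' @export
render_ruler <- function(config, tick_spacing_mm) {
  stopifnot(tick_spacing_mm > 0)
  spacing_px <- tick_spacing_mm / config$mm_per_px
  if (spacing_px < 2)
    stop("tick spacing below 2 px is unresolvable")
  W <- config$image_width; H <- config$image_height
  img <- matrix(config$background_gray, H, W)
  xs <- seq(5, W - 6, by = spacing_px)
  y0 <- floor(H / 4); y1 <- floor(3 * H / 4)
  for (x in round(xs)) img[(y0:y1) + 1L, x + 1L] <- config$eye_gray
  if (config$noise_sd > 0) {
    img <- with_seed(config$seed,
                     img + matrix(stats::rnorm(H * W, 0, config$noise_sd), H, W))
    img[img < 0] <- 0; img[img > 255] <- 255
  }
  img
}
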