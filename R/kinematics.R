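# Segmentation of the beak-gape series into mandibulation cycles (one
# opening-closing cycle of the beak), temporal ordering within feeding
# sequences, the four kinematic variables, and catch-and-throw flagging.
#
# Frame indices are 0-based and intervals half-open [start, end), matching
# the image-coordinate convention used everywhere else.

#' Centred moving average
#'
#' Window `w` (odd) moving average; the window shrinks symmetrically at the
#' series ends so the output has the same length as the input.
#'
#' @param x Numeric vector.
#' @param w Window width, odd positive integer.
#' @return Numeric vector, same length as `x`.
#' @export
moving_average <- function(x, w = 3) {
  stopifnot(w >= 1, w %% 2 == 1)
  if (w == 1 || length(x) < 2) return(x)
  h <- (w - 1) / 2
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(1, seq_len(n) - h); hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Local maxima filtered by topographic prominence and separation
#'
#' A local maximum is the first index of a run of equal values higher than
#' both neighbouring runs. Its prominence is its height above the higher of
#' the two key saddles: the lowest point between the peak and the nearest
#' higher point on each side (series ends count as walls). Peaks are kept
#' when prominence >= `prominence_min`; of two kept peaks closer than
#' `separation_min`, the higher (ties: earlier) survives.
#'
#' @param x Numeric vector.
#' @param prominence_min Minimum prominence, same units as `x`.
#' @param separation_min Minimum index separation between kept peaks.
#' @return Integer vector of peak indices (1-based), sorted increasing,
#'   with attribute `prominence`.
#' @export
find_peaks <- function(x, prominence_min = 0, separation_min = 1) {
  n <- length(x)
  if (n < 3) return(integer(0))
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  k <- length(r$values)
  if (k < 3) return(integer(0))
  is_peak <- c(FALSE, r$values[2:(k - 1)] > r$values[1:(k - 2)] &
                 r$values[2:(k - 1)] > r$values[3:k], FALSE)
  cand <- starts[is_peak]
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(p) {
    hp <- x[p]
    left <- if (p > 1) {
      higher <- which(x[1:(p - 1)] > hp)
      lo <- if (length(higher)) max(higher) + 1 else 1
      min(x[lo:(p - 1)])
    } else hp
    right <- if (p < n) {
      higher <- which(x[(p + 1):n] > hp) + p
      hi <- if (length(higher)) min(higher) - 1 else n
      min(x[(p + 1):hi])
    } else hp
    hp - max(left, right)
  }, numeric(1))
  keep <- prom >= prominence_min
  cand <- cand[keep]; prom <- prom[keep]
  if (length(cand) > 1 && separation_min > 1) {
    ord <- order(-x[cand], cand)
    taken <- integer(0)
    for (i in ord) {
      if (!length(taken) || all(abs(cand[i] - cand[taken]) >= separation_min))
        taken <- c(taken, i)
    }
    keep2 <- sort(taken)
    cand <- cand[keep2]; prom <- prom[keep2]
  }
  structure(cand, prominence = prom)
}

#' Kinematics parameters
#'
#' @param smooth_w Moving-average window (frames) used before peak finding.
#' @param prominence_min_mm Minimum gape-peak prominence, mm.
#' @param separation_min Minimum peak separation, frames.
#' @param withdraw_min_mm Minimum upward head excursion opening a feeding
#'   sequence boundary, mm.
#' @param withdraw_max_frames Maximum duration of that excursion, frames.
#' @param approach_min_mm Minimum preceding downward (approach) excursion, mm.
#' @return List of class `kin_params`.
#' @export
kin_params <- function(smooth_w = 3, prominence_min_mm = 0.3,
                       separation_min = 4, withdraw_min_mm = 3,
                       withdraw_max_frames = 50, approach_min_mm = 0.3) {
  p <- as.list(environment())
  class(p) <- "kin_params"
  p
}

#' Segment a gape series into mandibulation cycles
#'
#' Peaks are found on a moving-average-smoothed copy of the series
#' (prominence and separation filtered); each cycle spans the local minimum
#' before its peak to the local minimum after it, located on the *raw*
#' series. Boundary minima are not zero-gape points — the beak is never
#' fully closed at a cycle boundary. Within the minimal region between two
#' peaks, the cycle to the left ends at the earliest minimal frame and the
#' cycle to the right starts at the latest minimal frame, so a flat
#' inter-cycle plateau belongs to neither cycle. The reported peak frame is
#' the argmax of the raw series inside the interval.
#'
#' @param gape_mm Numeric gape series, one value per frame (mm).
#' @param params A [kin_params()].
#' @return data.frame with 0-based `start`, `end` (half-open) and
#'   `peak_frame`; zero rows when no complete cycle is present.
#' @export
segment_mandibulations <- function(gape_mm, params = kin_params()) {
  n <- length(gape_mm)
  stopifnot(n >= 5)
  sm <- moving_average(gape_mm, params$smooth_w)
  pk <- find_peaks(sm, params$prominence_min_mm, params$separation_min)
  if (!length(pk))
    return(data.frame(start = integer(0), end = integer(0),
                      peak_frame = integer(0)))
  k <- length(pk)
  argmin_first <- function(i) i[which.min(gape_mm[i])]
  argmin_last <- function(i) rev(i)[which.min(rev(gape_mm[i]))]
  lefts <- integer(k); rights <- integer(k)
  for (j in seq_len(k)) {
    lo <- if (j == 1) 1L else pk[j - 1] + 1L
    hi <- if (j == k) n else pk[j + 1] - 1L
    lefts[j] <- argmin_last(lo:(pk[j] - 1L))
    rights[j] <- argmin_first((pk[j] + 1L):hi)
  }
  peaks <- vapply(seq_len(k), function(j) {
    i <- lefts[j]:(rights[j] - 1L)
    i[which.max(gape_mm[i])]
  }, integer(1))
  data.frame(start = lefts - 1L, end = rights - 1L, peak_frame = peaks - 1L)
}

#' Detect feeding-sequence boundaries from the eye track
#'
#' A feeding sequence opens with the withdrawal phase: an upward head
#' excursion (y decreasing, image coordinates) of at least
#' `withdraw_min_mm` completed within `withdraw_max_frames`, preceded by a
#' downward approach excursion. Boundaries are placed at the end of the
#' upward excursion. When sequence boundaries are annotated externally,
#' pass those to [assign_orders()] directly instead.
#'
#' @param eye_track A `head_track` (or any data.frame with `eye_y`).
#' @param mm_per_px Pixel pitch, mm.
#' @param params A [kin_params()].
#' @return Integer vector of 0-based boundary frames (possibly empty: the
#'   whole recording is then one episode).
#' @export
detect_withdrawals <- function(eye_track, mm_per_px, params = kin_params()) {
  y <- moving_average(eye_track$eye_y * mm_per_px, 3)
  n <- length(y)
  if (n < 5) return(integer(0))
  maxima <- find_peaks(y, params$approach_min_mm, 1)   # head at its lowest
  minima <- find_peaks(-y, params$approach_min_mm, 1)  # head at its highest
  bounds <- integer(0)
  last <- 0L
  for (m in maxima) {
    if (m <= last) next
    prev_min <- minima[minima < m]
    base <- if (length(prev_min)) y[max(prev_min)] else y[1]
    if (y[m] - base < params$approach_min_mm) next     # no approach before
    hi <- min(n, m + params$withdraw_max_frames)
    t <- m
    while (t < hi) {
      t <- t + 1L
      if (y[m] - y[t] >= params$withdraw_min_mm) {
        # ride the rest of the rise while it keeps at least the minimum
        # sustained withdrawal rate (slower declines are drift, not motion)
        rate <- params$withdraw_min_mm / params$withdraw_max_frames
        while (t < hi && y[t] - y[t + 1L] >= rate) t <- t + 1L
        bounds <- c(bounds, t - 1L)
        last <- t
        break
      }
    }
  }
  sort(unique(bounds))
}

#' Assign temporal orders to mandibulation intervals
#'
#' Within each boundary-delimited feeding sequence (episode), mandibulations
#' are numbered in temporal order 1, 2, 3; the fourth and all later ones
#' share order 4. An interval straddling a boundary is assigned to the
#' episode containing its peak frame (with a warning).
#'
#' @param intervals data.frame from [segment_mandibulations()].
#' @param boundaries Sorted integer vector of 0-based boundary frames (from
#'   [detect_withdrawals()] or an annotation file).
#' @return `intervals` with `episode` and `order` columns added, ordered by
#'   `start`.
#' @export
assign_orders <- function(intervals, boundaries = integer(0)) {
  if (nrow(intervals) == 0) {
    intervals$episode <- integer(0); intervals$order <- integer(0)
    return(intervals)
  }
  intervals <- intervals[order(intervals$start), , drop = FALSE]
  boundaries <- sort(boundaries)
  straddle <- vapply(seq_len(nrow(intervals)), function(i)
    any(boundaries > intervals$start[i] & boundaries < intervals$end[i]),
    logical(1))
  if (any(straddle))
    warning(sprintf("%d interval(s) straddle an episode boundary; %s",
                    sum(straddle), "assigned by peak frame"))
  ep <- findInterval(intervals$peak_frame, boundaries) + 1L
  intervals$episode <- ep
  intervals$order <- stats::ave(rep(1L, nrow(intervals)), ep,
                                FUN = function(v) pmin(seq_along(v), 4L))
  rownames(intervals) <- NULL
  intervals
}

#' Kinematic variables of one mandibulation
#'
#' For a half-open interval `[start, end)`: maximum beak gape is the raw
#' maximum of `gape_mm` inside the interval; head displacement is the total
#' path length of the eye centre over positions `start..end` (each of the
#' `end - start` per-frame time slices contributes its step; the path is
#' truncated when `end` is past the last frame); duration is
#' `(end - start) * 1000 / fps` ms; average speed is displacement over
#' duration, in mm/s. The straight-line (net) displacement is also emitted.
#'
#' @param interval One row of a segmentation data.frame (`start`, `end`,
#'   0-based half-open).
#' @param head_track A `head_track` data.frame (needs eye_x, eye_y, gape_mm).
#' @param mm_per_px Pixel pitch, mm.
#' @param fps Frame rate.
#' @return One-row data.frame: start, end, peak_frame, max_gape_mm,
#'   displacement_mm, net_displacement_mm, duration_ms, speed_mm_s.
#' @export
compute_kinematics <- function(interval, head_track, mm_per_px, fps) {
  stopifnot(fps > 0)
  s0 <- interval$start; e0 <- interval$end
  n <- nrow(head_track)
  if (e0 - s0 < 2) stop("interval shorter than 2 frames rejected")
  stopifnot(s0 >= 0, e0 <= n)
  within <- seq.int(s0, e0 - 1L) + 1L
  path_idx <- seq.int(s0, min(e0, n - 1L)) + 1L
  dx <- diff(head_track$eye_x[path_idx]); dy <- diff(head_track$eye_y[path_idx])
  disp <- sum(sqrt(dx^2 + dy^2)) * mm_per_px
  net <- sqrt(sum(dx)^2 + sum(dy)^2) * mm_per_px
  dur <- (e0 - s0) * 1000 / fps
  g <- head_track$gape_mm[within]
  pf <- if (!is.null(interval$peak_frame)) interval$peak_frame
        else within[which.max(g)] - 1L
  data.frame(start = s0, end = e0, peak_frame = pf,
             max_gape_mm = max(g), displacement_mm = disp,
             net_displacement_mm = net, duration_ms = dur,
             speed_mm_s = disp / (dur / 1000))
}

#' Flag catch-and-throw mandibulations
#'
#' Catch-and-throw movements (repositioning/transport of the particle within
#' the beak) show augmented head motion and beak aperture. When an
#' annotation vector/data.frame is supplied its flags are copied verbatim;
#' otherwise a labelled heuristic flags records whose maximum gape AND
#' displacement both strictly exceed their episode medians. A single-record
#' episode is never flagged.
#'
#' @param records data.frame with `max_gape_mm`, `displacement_mm` and an
#'   `episode` column (see [assign_orders()]).
#' @param annotations Optional logical vector of length `nrow(records)`, or
#'   a data.frame with columns `episode`, `cycle` (1-based ordinal within
#'   episode) and `catch_and_throw`. Ids that do not match the records are
#'   an error.
#' @return `records` with a logical `catch_and_throw` column.
#' @export
flag_catch_and_throw <- function(records, annotations = NULL) {
  if (nrow(records) == 0) {
    records$catch_and_throw <- logical(0)
    return(records)
  }
  if (is.null(records$episode)) records$episode <- 1L
  if (!is.null(annotations)) {
    if (is.logical(annotations)) {
      if (length(annotations) != nrow(records))
        stop("annotation length does not match the records")
      records$catch_and_throw <- annotations
      return(records)
    }
    key_rec <- paste(records$episode,
                     stats::ave(rep(1L, nrow(records)), records$episode,
                                FUN = seq_along))
    key_ann <- paste(annotations$episode, annotations$cycle)
    m <- match(key_rec, key_ann)
    if (anyNA(m)) stop("annotation ids do not cover all records")
    records$catch_and_throw <- annotations$catch_and_throw[m]
    return(records)
  }
  flag <- logical(nrow(records))
  for (e in unique(records$episode)) {
    i <- records$episode == e
    flag[i] <- records$max_gape_mm[i] > stats::median(records$max_gape_mm[i]) &
      records$displacement_mm[i] > stats::median(records$displacement_mm[i])
  }
  records$catch_and_throw <- flag
  records
}
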