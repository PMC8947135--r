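#' Tracker configuration
#'
#' Tuning of the constant-velocity Kalman tracker.  The filter is the
#' standard discrete white-noise-acceleration model on pixel position; the
#' two image axes share one covariance recursion because process and
#' measurement noise are isotropic.
#'
#' @param process_noise_accel Acceleration noise intensity (px / frame^2).
#' @param measurement_noise Detection noise std (px).
#' @param gate_radius Validation gate around the predicted position (px);
#'   detections outside it are never associated.
#' @param max_coast Maximum consecutive frames a track may survive without a
#'   measurement before it is terminated.
#' @param min_track_length Minimum frames for a track to be reported.
#' @return A \code{kalman_config} list.
#' @export
kalman_config <- function(process_noise_accel = 1.0, measurement_noise = 0.7,
                          gate_radius = 25, max_coast = 10,
                          min_track_length = 20) {
  cfg <- list(process_noise_accel = process_noise_accel,
              measurement_noise = measurement_noise,
              gate_radius = gate_radius, max_coast = max_coast,
              min_track_length = min_track_length)
  if (any(unlist(cfg) <= 0)) stop("all tracker parameters must be positive")
  structure(cfg, class = "kalman_config")
}

#' Estimate a static background from an image stack
#'
#' Per-pixel median over frames; robust to a moving target that occupies any
#' pixel in fewer than half of the frames.
#'
#' @param frames List of numeric matrices (grayscale images), identical size.
#' @return One matrix, the background.
#' @export
estimate_background <- function(frames) {
  if (length(frames) < 3) stop("need at least 3 frames to estimate a background")
  d <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), d), logical(1))))
    stop("frames differ in size")
  arr <- array(unlist(frames), dim = c(d, length(frames)))
  apply(arr, c(1, 2), stats::median)
}

# label 8-connected foreground components of a logical matrix; returns an
# integer matrix of labels (0 = background)
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask)
  nxt <- 0L
  for (s in fg) {
    if (lab[s] != 0L) next
    nxt <- nxt + 1L
    queue <- s
    lab[s] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      i <- (p - 1L) %% nr + 1L
      j <- (p - 1L) %/% nr + 1L
      for (dj in -1:1) for (di in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1L && ii <= nr && jj >= 1L && jj <= nc) {
          q <- (jj - 1L) * nr + ii
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- nxt
            queue <- c(queue, q)
          }
        }
      }
    }
  }
  lab
}

#' Detect candidate targets by background subtraction
#'
#' The absolute difference to the background is thresholded, 8-connected
#' components are extracted, and components of sufficient area are reported
#' with intensity-weighted (sub-pixel) centroids, largest first.  Image
#' convention: a matrix with rows indexed by \code{v} and columns by
#' \code{u}, so \code{frame[v, u]}.
#'
#' @param frame,background Numeric matrices of identical size.
#' @param threshold Intensity difference threshold.
#' @param min_blob_area Minimum component area (px^2).
#' @param frame_index Frame number recorded in the output.
#' @param camera_id Camera label recorded in the output.
#' @return Data frame with columns \code{camera_id}, \code{frame}, \code{u},
#'   \code{v}, \code{area}, sorted by decreasing area.
#' @export
detect_blobs <- function(frame, background, threshold = 0.1,
                         min_blob_area = 4, frame_index = 0L,
                         camera_id = "cam") {
  if (!identical(dim(frame), dim(background)))
    stop("frame and background differ in size")
  d <- abs(frame - background)
  lab <- label_components(d >= threshold)
  out <- list()
  if (max(lab) > 0) {
    for (k in seq_len(max(lab))) {
      idx <- which(lab == k)
      if (length(idx) < min_blob_area) next
      w <- d[idx]
      vv <- (idx - 1L) %% nrow(d) + 1L
      uu <- (idx - 1L) %/% nrow(d) + 1L
      out[[length(out) + 1L]] <- data.frame(
        camera_id = camera_id, frame = frame_index,
        u = sum(uu * w) / sum(w), v = sum(vv * w) / sum(w),
        area = length(idx))
    }
  }
  if (!length(out))
    return(data.frame(camera_id = character(0), frame = integer(0),
                      u = numeric(0), v = numeric(0), area = numeric(0)))
  res <- do.call(rbind, out)
  res[order(-res$area), , drop = FALSE]
}

#' Track a single target through per-frame detections
#'
#' A constant-velocity Kalman filter predicts the target pixel position each
#' frame; detections within the validation gate are costed by Euclidean
#' distance to the prediction and associated by the Munkres algorithm (which
#' matters when distractors are present).  Frames with no associated
#' detection are coasted on the prediction; a track ends after
#' \code{max_coast} consecutive coasts, and tracking restarts from the next
#' detection.  The longest track is returned.  The filter governs
#' association, gating and coasting; on measured frames the recorded
#' \code{(u, v)} is the detection's centroid itself (so clean measurements
#' pass through untouched), while \code{(du, dv)} and coasted positions come
#' from the filter state.
#'
#' @param detections Data frame with columns \code{frame}, \code{u},
#'   \code{v} (one row per detection; multiple rows per frame allowed).
#' @param config A \code{kalman_config}.
#' @param camera_id Label stored on the result.
#' @return A \code{track2d} object: data frame with columns \code{frame},
#'   \code{u}, \code{v}, \code{du}, \code{dv}, \code{status}
#'   (\code{"measured"} or \code{"coasted"}); trailing coasts are trimmed so
#'   the track ends on a measurement.
#' @export
track_single_target <- function(detections, config = kalman_config(),
                                camera_id = "cam") {
  if (nrow(detections) == 0) stop("no detections: no track")
  det_frames <- sort(unique(detections$frame))
  if (length(det_frames) < config$min_track_length)
    stop("no track: detections span fewer frames than min_track_length")
  frame_lo <- det_frames[1]; frame_hi <- det_frames[length(det_frames)]
  u_all <- detections$u; v_all <- detections$v

  q <- config$process_noise_accel^2
  r2 <- config$measurement_noise^2
  # shared 2x2 covariance blocks for (pos, vel) on each axis
  Qp <- q * matrix(c(0.25, 0.5, 0.5, 1), 2, 2)

  nspan <- frame_hi - frame_lo + 1L
  # preallocated buffers for the track under construction
  b_frame <- integer(nspan); b_u <- numeric(nspan); b_v <- numeric(nspan)
  b_du <- numeric(nspan); b_dv <- numeric(nspan); b_meas <- logical(nspan)
  k <- 0L                 # samples in the current track
  active <- FALSE
  # covariance recursion is shared by the two axes: track (p11, p12, p22)
  p11 <- p12 <- p22 <- 0
  n_coast <- 0L
  q11 <- 0.25 * q; q12 <- 0.5 * q; q22 <- q
  idx_by_frame <- split(seq_along(detections$frame),
                        factor(detections$frame - frame_lo + 1L,
                               levels = seq_len(nspan)))
  tracks <- list()
  finish <- function() {
    n <- k
    while (n > 0L && !b_meas[n]) n <- n - 1L
    if (n > 0L)
      tracks[[length(tracks) + 1L]] <<- data.frame(
        frame = b_frame[1:n], u = b_u[1:n], v = b_v[1:n],
        du = b_du[1:n], dv = b_dv[1:n],
        status = ifelse(b_meas[1:n], "measured", "coasted"))
  }
  for (f in frame_lo:frame_hi) {
    ids <- idx_by_frame[[f - frame_lo + 1L]]
    if (!active) {
      if (!length(ids)) next
      # initialise on the largest (first) detection of the frame
      k <- 1L
      b_frame[1] <- f; b_u[1] <- u_all[ids[1]]; b_v[1] <- v_all[ids[1]]
      b_du[1] <- 0; b_dv[1] <- 0; b_meas[1] <- TRUE
      fu <- b_u[1]; fv <- b_v[1]; fdu <- 0; fdv <- 0  # internal filter state
      p11 <- r2; p12 <- 0; p22 <- 400
      n_coast <- 0L
      active <- TRUE
      next
    }
    # predict
    up <- fu + fdu; vp <- fv + fdv
    a11 <- p11 + 2 * p12 + p22 + q11
    a12 <- p12 + p22 + q12
    a22 <- p22 + q22
    assigned <- 0L
    if (length(ids)) {
      dist <- sqrt((u_all[ids] - up)^2 + (v_all[ids] - vp)^2)
      cand <- which(dist <= config$gate_radius)
      if (length(cand) == 1L) {
        assigned <- ids[cand]
      } else if (length(cand) > 1L) {
        a <- munkres_assign(matrix(dist[cand], nrow = 1))
        assigned <- ids[cand[a$assignment[1]]]
      }
    }
    if (assigned > 0L) {
      S <- a11 + r2
      Kp <- a11 / S; Kv <- a12 / S
      ru <- u_all[assigned] - up; rv <- v_all[assigned] - vp
      fu <- up + Kp * ru; fv <- vp + Kp * rv
      fdu <- fdu + Kv * ru; fdv <- fdv + Kv * rv
      k <- k + 1L
      b_frame[k] <- f
      b_u[k] <- u_all[assigned]; b_v[k] <- v_all[assigned]
      b_du[k] <- fdu; b_dv[k] <- fdv
      b_meas[k] <- TRUE
      p11 <- a11 - Kp * a11; p12 <- a12 - Kp * a12; p22 <- a22 - Kv * a12
      n_coast <- 0L
    } else {
      n_coast <- n_coast + 1L
      if (n_coast > config$max_coast) {
        finish()
        active <- FALSE
        next
      }
      fu <- up; fv <- vp
      k <- k + 1L
      b_frame[k] <- f
      b_u[k] <- up; b_v[k] <- vp
      b_du[k] <- fdu; b_dv[k] <- fdv
      b_meas[k] <- FALSE
      p11 <- a11; p12 <- a12; p22 <- a22
    }
  }
  if (active) finish()
  len <- vapply(tracks, nrow, integer(1))
  if (!length(len) || max(len) < config$min_track_length)
    stop("no track: no association chain reached min_track_length")
  out <- tracks[[which.max(len)]]
  attr(out, "camera_id") <- camera_id
  class(out) <- c("track2d", "data.frame")
  out
}

#' Outlier rejection on a 2D track
#'
#' Stands in for the manual review step of a human digitising tool: frames
#' whose displacement from the previous state exceeds \code{nsigma} times
#' the median absolute deviation of all per-frame displacements are treated
#' as misses and replaced by linear interpolation from their neighbours.
#'
#' @param track A \code{track2d}.
#' @param nsigma MAD multiplier (default 5).
#' @return The cleaned \code{track2d}; repaired rows are flagged
#'   \code{"coasted"}.
#' @export
reject_track_outliers <- function(track, nsigma = 5) {
  n <- nrow(track)
  if (n < 3) return(track)
  disp <- sqrt(diff(track$u)^2 + diff(track$v)^2)
  m <- stats::median(disp)
  s <- stats::mad(disp)
  if (s <= 0) return(track)
  bad <- which(c(FALSE, disp > m + nsigma * s))
  bad <- bad[bad > 1 & bad < n]
  for (i in bad) {
    track$u[i] <- (track$u[i - 1] + track$u[i + 1]) / 2
    track$v[i] <- (track$v[i - 1] + track$v[i + 1]) / 2
    track$status[i] <- "coasted"
  }
  track
}
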