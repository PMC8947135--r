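#' 3D trajectory reconstruction and conditioning
#'
#' A \code{trajectory3d} is a data frame (\code{frame}, \code{t}, \code{x},
#' \code{y}, \code{z}, \code{reproj_err}, \code{flag}) of triangulated
#' positions in the tunnel frame at the camera frame rate.  \code{flag} is
#' \code{"ok"} where both views measured the bee and \code{"coasted_one"}
#' where one view coasted over a dropout (those frames are triangulated from
#' one measured and one predicted pixel position and are kept but marked).
#'
#' @name trajectory3d
NULL

new_trajectory3d <- function(df, frame_rate, flight_id = NA_character_) {
  attr(df, "frame_rate") <- frame_rate
  attr(df, "flight_id") <- flight_id
  class(df) <- c("trajectory3d", "data.frame")
  df
}

#' Fuse two per-camera tracks into a 3D trajectory
#'
#' Frames where both tracks carry a state are triangulated; frames coasted
#' in both views are dropped, frames coasted in one view are triangulated
#' and flagged.  A median reprojection error above
#' \code{calib_warn_threshold} marks the whole trajectory with a
#' \code{calibration_warning} attribute.
#'
#' @param track_a,track_b \code{track2d} objects from the two views.
#' @param cam_a,cam_b The matching \code{camera_params}.
#' @param frame_rate Frames per second (default 500).
#' @param min_overlap Minimum overlapping frames (default 20).
#' @param flight_id Identifier carried through to metrics.
#' @param calib_warn_threshold Median reprojection error (px) above which a
#'   calibration mismatch is flagged.
#' @return A \code{trajectory3d}.
#' @export
reconstruct <- function(track_a, track_b, cam_a, cam_b, frame_rate = 500,
                        min_overlap = 20, flight_id = NA_character_,
                        calib_warn_threshold = 5) {
  frames <- intersect(track_a$frame, track_b$frame)
  if (length(frames) < min_overlap)
    stop("track overlap too short to reconstruct")
  frames <- sort(frames)
  ia <- match(frames, track_a$frame)
  ib <- match(frames, track_b$frame)
  ma <- track_a$status[ia] == "measured"
  mb <- track_b$status[ib] == "measured"
  keep <- ma | mb
  frames <- frames[keep]; ia <- ia[keep]; ib <- ib[keep]
  tri <- triangulate(cam_a, cam_b,
                     data.frame(u = track_a$u[ia], v = track_a$v[ia]),
                     data.frame(u = track_b$u[ib], v = track_b$v[ib]))
  df <- data.frame(frame = frames, t = frames / frame_rate,
                   x = tri$x, y = tri$y, z = tri$z,
                   reproj_err = tri$reproj_err,
                   flag = ifelse(ma[keep] & mb[keep], "ok", "coasted_one"))
  out <- new_trajectory3d(df, frame_rate, flight_id)
  attr(out, "calibration_warning") <-
    stats::median(df$reproj_err) > calib_warn_threshold
  out
}

#' Clip a trajectory to the obstacle-field transit
#'
#' Keeps the samples with longitudinal position inside the field's extent,
#' closed interval: a sample exactly on the boundary belongs to the transit.
#' Entry and exit are the first and last retained samples.
#'
#' @param traj A \code{trajectory3d}.
#' @param scene A \code{scene_spec}.
#' @return The clipped \code{trajectory3d}.
#' @export
clip_to_field <- function(traj, scene) {
  keep <- traj$x >= scene$field_x_extent[1] & traj$x <= scene$field_x_extent[2]
  if (!any(keep)) stop("no transit: trajectory never enters the obstacle field")
  out <- traj[which(keep), , drop = FALSE]
  rownames(out) <- NULL
  new_trajectory3d(out, attr(traj, "frame_rate"), attr(traj, "flight_id"))
}

#' Excluded-zone filter
#'
#' Flights that cross into the band within \code{excluded_zone_depth} of the
#' ceiling are discarded, as in the filming protocol.  The rule is applied
#' to the observed (clipped, unsmoothed) positions; the boundary itself is
#' allowed (strict inequality).
#'
#' @param traj A clipped \code{trajectory3d}.
#' @param scene A \code{scene_spec}.
#' @return \code{TRUE} to keep the flight, \code{FALSE} to discard it.
#' @export
excluded_zone_filter <- function(traj, scene) {
  !any(traj$z > scene$tunnel_height - scene$excluded_zone_depth)
}

#' Smooth a 3D trajectory with quintic splines
#'
#' Each axis is fitted independently (\code{\link{fit_quintic_spline}});
#' velocities are the analytic first derivatives of the fitted splines.
#'
#' @param traj A \code{trajectory3d} with at least 12 samples.
#' @param smoothing \code{"auto"} for GCV selection per axis, or a fixed
#'   penalty weight.
#' @return A \code{smooth_trajectory}: list of per-axis \code{quintic_fit}s
#'   plus the sample times; use \code{\link{evaluate_trajectory}} to get
#'   positions and velocities.
#' @export
smooth_trajectory <- function(traj, smoothing = "auto") {
  if (nrow(traj) < 12) stop("too few samples to smooth (need >= 12)")
  fits <- lapply(c(x = "x", y = "y", z = "z"), function(ax)
    fit_quintic_spline(traj$t, traj[[ax]], smoothing = smoothing))
  structure(list(fits = fits, t = traj$t,
                 frame = traj$frame,
                 frame_rate = attr(traj, "frame_rate"),
                 flight_id = attr(traj, "flight_id"),
                 smoothing = smoothing),
            class = "smooth_trajectory")
}

#' Evaluate a smoothed trajectory
#'
#' @param st A \code{smooth_trajectory}.
#' @param t Times (defaults to the original sample times).
#' @return Data frame with \code{t}, positions \code{x}, \code{y}, \code{z}
#'   (mm) and velocities \code{vx}, \code{vy}, \code{vz} (mm/s).
#' @export
evaluate_trajectory <- function(st, t = st$t) {
  data.frame(t = t,
             x = predict(st$fits$x, t), y = predict(st$fits$y, t),
             z = predict(st$fits$z, t),
             vx = predict(st$fits$x, t, deriv = 1),
             vy = predict(st$fits$y, t, deriv = 1),
             vz = predict(st$fits$z, t, deriv = 1))
}

#' Write / read trajectory CSV
#'
#' Columns: \code{flight_id}, \code{frame}, \code{t}, \code{x}, \code{y},
#' \code{z}, \code{reproj_err}, \code{flag}; smoothed output appends
#' \code{vx}, \code{vy}, \code{vz}.
#' @param traj A \code{trajectory3d}.
#' @param path File path.
#' @param ... Passed to \code{\link{write_csv_provenance}}.
#' @export
write_trajectory_csv <- function(traj, path, ...) {
  df <- cbind(flight_id = attr(traj, "flight_id"), as.data.frame(traj))
  write_csv_provenance(df, path, ...)
}
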