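#' Run one flight through the measurement chain
#'
#' Detections to metrics: per-camera Kalman/Munkres tracking, outlier
#' repair, two-view triangulation, clipping to the obstacle-field transit,
#' the excluded-zone filter, quintic-spline smoothing, and the flight
#' metrics.
#'
#' @param detections List with per-camera detection data frames \code{a}
#'   and \code{b} (columns \code{frame}, \code{u}, \code{v}).
#' @param rig Stereo rig (\code{a}, \code{b}, \code{frame_rate}).
#' @param scene The flight's \code{scene_spec}.
#' @param cond The \code{trial_condition}.
#' @param config A \code{kalman_config}.
#' @param smoothing Spline smoothing parameter or \code{"auto"}.
#' @return List with \code{metrics} (one-row data frame, or \code{NULL} if
#'   rejected), \code{reason} (\code{"ok"} or the rejection reason), and
#'   \code{trajectory}, the clipped \code{trajectory3d}.
#' @export
process_flight <- function(detections, rig, scene, cond,
                           config = kalman_config(), smoothing = "auto") {
  res <- list(metrics = NULL, reason = "ok", trajectory = NULL)
  out <- tryCatch({
    ta <- reject_track_outliers(
      track_single_target(detections$a, config, camera_id = rig$a$camera_id))
    tb <- reject_track_outliers(
      track_single_target(detections$b, config, camera_id = rig$b$camera_id))
    flight_id <- paste0(cond$bee_id, "_f", cond$flight_number)
    traj <- reconstruct(ta, tb, rig$a, rig$b, frame_rate = rig$frame_rate,
                        flight_id = flight_id)
    traj <- clip_to_field(traj, scene)
    if (!excluded_zone_filter(traj, scene)) {
      res$reason <- "excluded_zone"
      res$trajectory <- traj
      return(res)
    }
    st <- smooth_trajectory(traj, smoothing = smoothing)
    res$metrics <- compute_metrics(st, scene, cond)
    res$trajectory <- traj
    res$smooth <- st
    res
  }, error = function(e) {
    res$reason <- conditionMessage(e)
    res
  })
  out
}

#' Run the full pipeline over a simulated experiment
#'
#' @param experiment A \code{flight_experiment} from
#'   \code{\link{simulate_experiment}} (with detections attached).
#' @param config A \code{kalman_config}.
#' @param smoothing Spline smoothing parameter or \code{"auto"}.
#' @param keep_trajectories Keep per-flight trajectories (memory heavy for
#'   full-size experiments).
#' @return List with \code{metrics}, the recovered per-flight metrics table
#'   (column \code{flight_id} matches \code{experiment$truth}),
#'   \code{rejects}, a table of discarded flights and reasons, and
#'   optionally \code{trajectories}.
#' @export
run_pipeline <- function(experiment, config = kalman_config(),
                         smoothing = "auto", keep_trajectories = FALSE) {
  metrics <- list(); rejects <- list(); trajs <- list()
  for (i in seq_along(experiment$flights)) {
    fl <- experiment$flights[[i]]
    if (is.null(fl$detections))
      stop("experiment was simulated without detections")
    cond <- fl$flight$cond
    scene <- experiment$scenes[[as.character(cond$field_height)]]
    r <- process_flight(fl$detections, experiment$rig, scene, cond,
                        config = config, smoothing = smoothing)
    fid <- paste0(cond$bee_id, "_f", cond$flight_number)
    if (!is.null(r$metrics)) {
      m <- r$metrics
      m$flight_id <- fid
      metrics[[length(metrics) + 1]] <- m
    } else {
      rejects[[length(rejects) + 1]] <-
        data.frame(flight_id = fid, reason = r$reason,
                   stringsAsFactors = FALSE)
    }
    if (keep_trajectories) trajs[[fid]] <- r$trajectory
  }
  out <- list(
    metrics = if (length(metrics)) do.call(rbind, metrics) else NULL,
    rejects = if (length(rejects)) do.call(rbind, rejects)
              else data.frame(flight_id = character(0), reason = character(0)))
  if (keep_trajectories) out$trajectories <- trajs
  out
}

#' Route-choice and effect-size summaries of a metrics table
#'
#' Percent differences between pooled group medians, the quantities the
#' experiment was designed around: above- vs within-route ground speed and
#' lateral excursion, windy vs still lateral excursion, tailwind vs
#' still-air down-tunnel ground speed, the still-air median ground speed,
#' and the median altitudinal range.
#'
#' @param metrics Metrics table from \code{\link{run_pipeline}} (or the
#'   ground-truth table).
#' @return Named list of summary values; speeds in m/s, percentages as
#'   percent.
#' @export
summarize_effects <- function(metrics) {
  med <- function(x) stats::median(x)
  pct <- function(a, b) 100 * (med(a) / med(b) - 1)
  above <- metrics$route == "above"
  windy <- metrics$wind_class %in% c("headwind", "tailwind")
  down <- metrics$direction == "down_tunnel"
  list(
    speed_above_vs_within_pct =
      pct(metrics$ground_speed[above], metrics$ground_speed[!above]),
    excursion_above_vs_within_pct =
      pct(metrics$lateral_excursion[above], metrics$lateral_excursion[!above]),
    excursion_wind_vs_still_pct =
      pct(metrics$lateral_excursion[windy], metrics$lateral_excursion[!windy]),
    speed_tailwind_vs_still_down_pct =
      pct(metrics$ground_speed[down & metrics$wind_class == "tailwind"],
          metrics$ground_speed[down & metrics$wind_class == "still_down"]),
    still_air_median_speed_m_s =
      med(metrics$ground_speed[!windy]) / 1000,
    median_altitudinal_range_mm = med(metrics$altitude_range),
    n_flights = nrow(metrics),
    n_within = sum(!above))
}
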