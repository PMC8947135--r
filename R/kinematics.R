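#' Trial condition of one flight
#'
#' @param bee_id Bee identifier.
#' @param flight_number Flight index within the bee's session.
#' @param wind \code{"still"} or \code{"wind"}.
#' @param direction \code{"up_tunnel"} or \code{"down_tunnel"}.  With the
#'   fans on, up-tunnel flights face a headwind and down-tunnel flights a
#'   tailwind.
#' @param field_height Obstacle field height (mm) for the bee's session.
#' @return A \code{trial_condition} list including the derived
#'   \code{wind_class} (\code{still_up}, \code{still_down}, \code{headwind},
#'   \code{tailwind}).
#' @export
trial_condition <- function(bee_id, flight_number, wind, direction,
                            field_height) {
  wind <- match.arg(wind, c("still", "wind"))
  direction <- match.arg(direction, c("up_tunnel", "down_tunnel"))
  wind_class <- if (wind == "wind") {
    if (direction == "up_tunnel") "headwind" else "tailwind"
  } else {
    if (direction == "up_tunnel") "still_up" else "still_down"
  }
  structure(list(bee_id = bee_id, flight_number = flight_number,
                 wind = wind, direction = direction,
                 wind_class = wind_class, field_height = field_height),
            class = "trial_condition")
}

#' Flight-performance metrics for one obstacle-field transit
#'
#' Computes the per-flight summary used in the analysis:
#' \itemize{
#'   \item \code{altitude_floor}: median altitude above the floor (mm);
#'   \item \code{altitude_range}: max minus min altitude over the transit (mm);
#'   \item \code{altitude_obstacle}: \code{altitude_floor - field_height} (mm);
#'   \item \code{route}: \code{"above"} if \code{altitude_obstacle > 0},
#'     else \code{"within"} (the boundary counts as within);
#'   \item \code{ground_speed}: median horizontal-plane speed
#'     \eqn{\sqrt{v_x^2 + v_y^2}} (mm/s) — speed over ground, the wind is
#'     not subtracted;
#'   \item \code{lateral_excursion}: interquartile range of lateral position
#'     (mm), type-7 quantiles;
#'   \item \code{speed_change_entry_exit}: mean horizontal speed over the
#'     last 10\% of samples minus the first 10\% (mm/s);
#'   \item \code{min_obstacle_clearance}: minimum horizontal clearance to
#'     any column reaching the bee's altitude (mm);
#'   \item \code{collision}: clearance ever at or below \code{body_radius}.
#' }
#'
#' @param st A \code{smooth_trajectory} of the clipped, kept transit.
#' @param scene The \code{scene_spec}.
#' @param cond The \code{trial_condition}.
#' @param body_radius Approximate bee body half-width (mm) for the collision
#'   flag.
#' @return One-row data frame (a \code{flight_metrics} row) combining the
#'   condition and the metrics.
#' @export
compute_metrics <- function(st, scene, cond, body_radius = 6) {
  ev <- evaluate_trajectory(st)
  n <- nrow(ev)
  if (n < 12) stop("too few samples for metrics")
  hspeed <- sqrt(ev$vx^2 + ev$vy^2)
  altitude_floor <- stats::median(ev$z)
  altitude_obstacle <- altitude_floor - cond$field_height
  route <- if (altitude_obstacle > 0) "above" else "within"
  nw <- max(1L, floor(0.1 * n))
  clear <- distance_to_nearest_column(scene, cbind(ev$x, ev$y, ev$z))
  min_clear <- suppressWarnings(min(clear))
  data.frame(
    bee_id = cond$bee_id, flight_number = cond$flight_number,
    wind = cond$wind, direction = cond$direction,
    wind_class = cond$wind_class, field_height = cond$field_height,
    altitude_floor = altitude_floor,
    altitude_range = max(ev$z) - min(ev$z),
    altitude_obstacle = altitude_obstacle,
    route = route,
    ground_speed = stats::median(hspeed),
    lateral_excursion = stats::IQR(ev$y, type = 7),
    speed_change = mean(hspeed[(n - nw + 1):n]) - mean(hspeed[1:nw]),
    min_clearance = min_clear,
    collision = is.finite(min_clear) && min_clear <= body_radius,
    stringsAsFactors = FALSE)
}

#' Airspeed needed to hold a ground speed in wind
#'
#' Signed along the flight direction: \code{wind_speed_signed} is positive
#' for a tailwind, negative for a headwind, zero in still air.  A negative
#' result means the bee must fly backwards relative to the air: e.g. holding
#' the preferred 0.32 m/s ground speed in a 0.54 m/s tailwind requires
#' flying backwards through the air at 0.22 m/s.
#'
#' @param ground_speed Ground speed (m/s).
#' @param wind_speed_signed Signed wind speed (m/s).
#' @return Required airspeed (m/s).
#' @examples
#' required_airspeed(0.32, 0.54)   # -0.22
#' required_airspeed(0.32, -0.54)  # 0.86 against a headwind
#' @export
required_airspeed <- function(ground_speed, wind_speed_signed) {
  ground_speed - wind_speed_signed
}
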