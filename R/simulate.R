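#' Behavioural configuration of the synthetic experiment
#'
#' Encodes the study conditions the generator emulates: 58 bees, 5 to 13
#' flights each (mean about 9), half in still air and half with a 0.54 m/s
#' wind, one obstacle-field height per bee drawn from \{11, 40, 69, 98,
#' 127\} mm.  Behavioural structure is injected multiplicatively on the
#' medians of lognormal distributions so that ratios of medians equal the
#' configured ratios exactly:
#' \itemize{
#'   \item above-route flights are \code{route_speed_ratio} (1.40) times
#'     faster and have \code{route_excursion_ratio} (1.36) times larger
#'     lateral excursions than within-route flights;
#'   \item windy flights (head- or tailwind) have
#'     \code{wind_excursion_ratio} (1.19) times larger excursions;
#'   \item tailwind flights are \code{tailwind_speed_ratio} (1.23) times
#'     faster than still air, headwinds match still air;
#'   \item the still-air median ground speed over all routes is
#'     \code{still_air_ground_speed_median} (0.32 m/s) — the above-route
#'     location parameter is derived from it by inverting the analytic
#'     lognormal-mixture CDF implied by the route-probability design;
#'   \item the per-flight altitudinal range (max minus min) has median
#'     \code{altitudinal_range_median} (20.9 mm);
#'   \item bees prefer an altitude near 100 mm (about the floor-to-ceiling
#'     midpoint) and shift upward by 22.2 / 26.6 mm for the 98- and 127-mm
#'     fields when flying above them.
#' }
#'
#' @param n_bees Number of bees.
#' @param flights_min,flights_max Flights per bee (uniform on the range).
#' @param still_air_ground_speed_median Median still-air ground speed (m/s).
#' @param route_speed_ratio Above/within median ground-speed ratio.
#' @param route_excursion_ratio Above/within lateral-excursion ratio.
#' @param wind_excursion_ratio Windy/still lateral-excursion ratio.
#' @param tailwind_speed_ratio Tailwind/still median ground-speed ratio.
#' @param headwind_speed_ratio Headwind/still ratio (1: headwind ground
#'   speeds match still air).
#' @param altitude_preference Preferred above-route altitude (mm).
#' @param altitude_shift_high Named upward shifts (mm) of the above-route
#'   altitude at the two tallest fields.
#' @param altitudinal_range_median Median per-flight altitude range (mm).
#' @param p_within Named probabilities of choosing the within route per
#'   field height; the 11-mm control field is too short to fly within.
#' @param base_excursion_iqr Above-route still-air lateral-excursion IQR (mm).
#' @param casting_freq Lateral casting frequency (Hz).
#' @param altitude_freq Vertical oscillation frequency (Hz).
#' @param bee_speed_sd,flight_speed_sd Per-bee / per-flight lognormal sigma
#'   of ground speed (natural-log scale).
#' @param bee_altitude_sd Per-bee altitude intercept SD (mm).
#' @param excursion_flight_sd Per-flight lognormal sigma of the excursion.
#' @param range_flight_sd Per-flight lognormal sigma of the altitude range.
#' @param lateral_jitter_sd,vertical_jitter_sd High-frequency positional
#'   jitter SD (mm), removed by smoothing.
#' @param wind_speed Fan-driven flow speed (m/s).
#' @param frame_rate Camera frame rate (Hz).
#' @param margin_x Simulated approach before/after the field extent (mm).
#' @param pixel_noise Detection noise SD (px) used by default observation.
#' @param dropout Per-detection dropout probability.
#' @param distractor_rate Expected spurious detections per frame.
#' @return A validated \code{behavior_config} list; the derived field
#'   \code{speed_base_above} (mm/s) is the above-route still-air lognormal
#'   median implied by the calibration.
#' @export
behavior_config <- function(n_bees = 58, flights_min = 5, flights_max = 13,
                            still_air_ground_speed_median = 0.32,
                            route_speed_ratio = 1.40,
                            route_excursion_ratio = 1.36,
                            wind_excursion_ratio = 1.19,
                            tailwind_speed_ratio = 1.23,
                            headwind_speed_ratio = 1.0,
                            altitude_preference = 100,
                            altitude_shift_high = c("98" = 22.2, "127" = 26.6),
                            altitudinal_range_median = 20.9,
                            p_within = c("11" = 0, "40" = 0.05, "69" = 0.10,
                                         "98" = 0.25, "127" = 0.55),
                            base_excursion_iqr = 15,
                            casting_freq = 1.4, altitude_freq = 1.7,
                            bee_speed_sd = 0.10, flight_speed_sd = 0.12,
                            bee_altitude_sd = 6,
                            excursion_flight_sd = 0.15,
                            range_flight_sd = 0.25,
                            lateral_jitter_sd = 0.8,
                            vertical_jitter_sd = 0.3,
                            wind_speed = 0.54, frame_rate = 500,
                            margin_x = 25,
                            pixel_noise = 0.5, dropout = 0.02,
                            distractor_rate = 0) {
  cfg <- as.list(environment())
  ratios <- c(route_speed_ratio, route_excursion_ratio, wind_excursion_ratio,
              tailwind_speed_ratio, headwind_speed_ratio)
  if (any(ratios <= 0)) stop("ratios must be positive")
  if (any(p_within < 0 | p_within > 1)) stop("p_within must be in [0, 1]")
  if (p_within[["11"]] != 0)
    stop("the 11-mm control field is too short to fly within (p_within must be 0)")
  if (flights_min < 1 || flights_max < flights_min)
    stop("invalid flights-per-bee range")
  cfg$speed_base_above <- calibrate_speed_base(cfg)
  class(cfg) <- "behavior_config"
  cfg
}

# still-air median ground speed is the median of the route mixture: find the
# above-route lognormal median whose mixture CDF crosses 1/2 at the target.
# Deterministic, analytic; done once at config build.
calibrate_speed_base <- function(cfg) {
  target <- cfg$still_air_ground_speed_median * 1000  # mm/s
  sigma <- sqrt(cfg$bee_speed_sd^2 + cfg$flight_speed_sd^2)
  p_w <- mean(cfg$p_within)
  mix_cdf <- function(base) {
    (1 - p_w) * stats::plnorm(target, log(base), sigma) +
      p_w * stats::plnorm(target, log(base / cfg$route_speed_ratio), sigma)
  }
  stats::uniroot(function(b) mix_cdf(b) - 0.5,
                 interval = target * c(0.8, 2), tol = 1e-10)$root
}

altitude_shift_for <- function(cfg, field_height) {
  key <- as.character(field_height)
  if (key %in% names(cfg$altitude_shift_high)) cfg$altitude_shift_high[[key]]
  else 0
}

corridor_centers <- function(scene) {
  row_y <- sort(unique(scene$column_positions[, "y"]))
  (row_y[-1] + row_y[-length(row_y)]) / 2
}

#' Simulate one ground-truth flight
#'
#' Draws a route by the field's within-route probability, then builds a
#' transit at the camera frame rate: constant forward speed solved so that
#' the median horizontal speed (including the casting velocity) equals the
#' flight's target ground speed; lateral position a bounded random-phase
#' casting sinusoid plus high-frequency jitter, centred on the tunnel axis
#' (above) or in a randomly chosen corridor (within); altitude a bounded
#' random-phase oscillation around the route-appropriate level, its
#' amplitude drawn so the per-transit max-minus-min has the configured
#' median.
#'
#' @param cond A \code{trial_condition}.
#' @param config A \code{behavior_config}.
#' @param scene The bee's \code{scene_spec}.
#' @param bee_effects Optional list with \code{speed_factor} and
#'   \code{altitude_shift}; drawn fresh when omitted.  Random draws use R's
#'   global RNG stream (seed upstream with \code{set.seed}).
#' @return A \code{ground_truth_flight}: condition, true route, positions
#'   and velocities at the frame rate, and \code{true_metrics}, the metric
#'   values computed directly from the generative process (its smooth
#'   component; jitter is motion the smoother is meant to remove).
#' @export
simulate_flight <- function(cond, config, scene, bee_effects = NULL) {
  if (is.null(bee_effects))
    bee_effects <- list(speed_factor = exp(stats::rnorm(1, 0, config$bee_speed_sd)),
                        altitude_shift = stats::rnorm(1, 0, config$bee_altitude_sd))
  h <- scene$field_height
  p_w <- config$p_within[[as.character(h)]]
  if (is.null(p_w)) p_w <- 0
  route <- if (stats::runif(1) < p_w) "within" else "above"

  # target median ground speed (mm/s)
  wind_mult <- switch(cond$wind_class,
                      tailwind = config$tailwind_speed_ratio,
                      headwind = config$headwind_speed_ratio, 1)
  route_mult <- if (route == "within") 1 / config$route_speed_ratio else 1
  target_speed <- config$speed_base_above * wind_mult * route_mult *
    bee_effects$speed_factor * exp(stats::rnorm(1, 0, config$flight_speed_sd))

  # lateral casting
  windy <- cond$wind_class %in% c("headwind", "tailwind")
  exc_target <- config$base_excursion_iqr *
    (if (route == "within") 1 / config$route_excursion_ratio else 1) *
    (if (windy) config$wind_excursion_ratio else 1) *
    exp(stats::rnorm(1, 0, config$excursion_flight_sd))
  half_w <- scene$tunnel_width / 2
  if (route == "within") {
    cc <- corridor_centers(scene)
    y0 <- cc[sample.int(length(cc), 1)]
    lat_space <- (scene$corridor_width + scene$column_diameter) / 2 -
      scene$column_diameter / 2
    A_y_max <- 0.8 * lat_space
  } else {
    y0 <- max(-40, min(40, stats::rnorm(1, 0, 15)))
    A_y_max <- half_w - 15 - abs(y0)
  }

  # altitude level and oscillation
  ez_top <- scene$tunnel_height - scene$excluded_zone_depth
  if (route == "above") {
    level <- max(config$altitude_preference + altitude_shift_for(config, h),
                 h + 14) + bee_effects$altitude_shift
    level <- max(h + 12, min(ez_top - 14, level))
  } else {
    level <- max(15, h / 2) + bee_effects$altitude_shift
    level <- max(10, min(h - 8, level))
  }
  A_z <- (config$altitudinal_range_median / 2) *
    exp(stats::rnorm(1, 0, config$range_flight_sd))
  A_z <- if (route == "above")
    min(A_z, 0.9 * min(level - h, ez_top - 3 - level))
  else
    min(A_z, 0.9 * min(level - 3, h - 3 - level))

  # Solve jointly for the casting amplitude and the forward speed: the
  # realized in-field IQR of the casting sinusoid must equal the excursion
  # target (the unit IQR depends on how many cycles the transit covers,
  # which depends on speed), and the realized in-field median horizontal
  # speed must equal the target ground speed (casting contributes to it).
  # Two fixed-point passes suffice.
  om_y <- 2 * pi * config$casting_freq
  ph_y <- stats::runif(1, 0, 2 * pi)
  dt <- 1 / config$frame_rate
  span <- diff(scene$field_x_extent) + 2 * config$margin_x
  s <- target_speed
  A_unit <- exc_target / sqrt(2)
  for (pass in 1:2) {
    dur_field <- diff(scene$field_x_extent) / s
    t_enter <- config$margin_x / s
    tf <- seq(t_enter, t_enter + dur_field, by = dt)
    u_iqr <- stats::IQR(sin(om_y * tf + ph_y), type = 7)
    A_unit <- exc_target / max(u_iqr, 0.7)
    vy2 <- (A_unit * om_y * cos(om_y * tf + ph_y))^2
    s <- sqrt(max(target_speed^2 - stats::median(vy2),
                  (0.3 * target_speed)^2))
  }
  A_y <- min(A_y_max, A_unit)

  nt <- max(ceiling(span / (s * dt)) + 1, 24)
  t <- seq_len(nt) * dt
  dir_sign <- if (cond$direction == "up_tunnel") 1 else -1
  x_from <- if (dir_sign > 0) scene$field_x_extent[1] - config$margin_x
            else scene$field_x_extent[2] + config$margin_x
  x <- x_from + dir_sign * s * (t - t[1])
  ph_z <- stats::runif(1, 0, 2 * pi)
  om_z <- 2 * pi * config$altitude_freq
  y_s <- y0 + A_y * sin(om_y * t + ph_y)
  z_s <- level + A_z * sin(om_z * t + ph_z)
  y <- y_s + stats::rnorm(nt, 0, config$lateral_jitter_sd)
  z <- z_s + stats::rnorm(nt, 0, config$vertical_jitter_sd)
  vx <- rep(dir_sign * s, nt)
  vy <- A_y * om_y * cos(om_y * t + ph_y)
  vz <- A_z * om_z * cos(om_z * t + ph_z)

  infield <- x >= scene$field_x_extent[1] & x <= scene$field_x_extent[2]
  hs <- sqrt(vx[infield]^2 + vy[infield]^2)
  n_in <- sum(infield)
  nw <- max(1L, floor(0.1 * n_in))
  hs_in <- hs
  true_metrics <- data.frame(
    bee_id = cond$bee_id, flight_number = cond$flight_number,
    wind = cond$wind, direction = cond$direction,
    wind_class = cond$wind_class, field_height = h,
    altitude_floor = stats::median(z_s[infield]),
    altitude_range = max(z_s[infield]) - min(z_s[infield]),
    altitude_obstacle = stats::median(z_s[infield]) - h,
    route = route,
    ground_speed = stats::median(hs_in),
    lateral_excursion = stats::IQR(y_s[infield], type = 7),
    speed_change = mean(hs_in[(n_in - nw + 1):n_in]) - mean(hs_in[1:nw]),
    stringsAsFactors = FALSE)

  structure(list(cond = cond, route = route, field_height = h,
                 frame_rate = config$frame_rate,
                 frame = seq_len(nt), t = t,
                 positions = cbind(x = x, y = y, z = z),
                 velocities = cbind(vx = vx, vy = vy, vz = vz),
                 true_metrics = true_metrics),
            class = "ground_truth_flight")
}

#' Observe a flight through a stereo rig
#'
#' Projects every sample into both cameras, keeps in-frame projections,
#' adds isotropic pixel noise, drops each detection independently with the
#' dropout probability, and optionally injects uniformly placed distractor
#' detections (flagged \code{is_target = FALSE} for scoring).
#'
#' @param flight A \code{ground_truth_flight}.
#' @param rig A stereo rig as from \code{\link{default_stereo_rig}}.
#' @param noise Pixel noise SD.
#' @param dropout Per-detection dropout probability.
#' @param distractor_rate Expected distractors per frame per camera.
#' @return List with data frames \code{a} and \code{b}; columns
#'   \code{camera_id}, \code{frame}, \code{u}, \code{v}, \code{area},
#'   \code{is_target}.
#' @export
observe_flight <- function(flight, rig, noise = 0.5, dropout = 0.02,
                           distractor_rate = 0) {
  one_cam <- function(cam) {
    pr <- project(cam, flight$positions)
    keep <- pr$in_frame & stats::runif(nrow(pr)) >= dropout
    df <- data.frame(camera_id = cam$camera_id,
                     frame = flight$frame[keep],
                     u = pr$u[keep] + stats::rnorm(sum(keep), 0, noise),
                     v = pr$v[keep] + stats::rnorm(sum(keep), 0, noise),
                     area = round(stats::rnorm(sum(keep), 25, 3)),
                     is_target = TRUE,
                     stringsAsFactors = FALSE)
    if (distractor_rate > 0) {
      nd <- stats::rpois(1, distractor_rate * length(flight$frame))
      if (nd > 0) {
        dd <- data.frame(camera_id = cam$camera_id,
                         frame = sample(flight$frame, nd, replace = TRUE),
                         u = stats::runif(nd, 0, cam$image_size[1]),
                         v = stats::runif(nd, 0, cam$image_size[2]),
                         area = round(stats::rnorm(nd, 12, 3)),
                         is_target = FALSE, stringsAsFactors = FALSE)
        df <- rbind(df, dd)
        df <- df[order(df$frame), , drop = FALSE]
      }
    }
    df
  }
  list(a = one_cam(rig$a), b = one_cam(rig$b))
}

#' Render synthetic frames for the blob detector
#'
#' Static speckled background (emulating the patterned tunnel walls) with a
#' moving Gaussian blob at the bee's projected position.  Intended at test
#' fixture scale: use a small-sensor rig.
#'
#' @param flight A \code{ground_truth_flight}.
#' @param camera A \code{camera_params} (one view).
#' @param frames Which flight frames to render (default: all).
#' @param texture_seed Seed for the background speckle.
#' @param blob_sigma,blob_amplitude Gaussian blob shape.
#' @return List with \code{background} (matrix) and \code{frames}, a list of
#'   matrices indexed like \code{frames}; pixels in [0, 1.5].
#' @export
render_frames <- function(flight, camera, frames = flight$frame,
                          texture_seed = 1, blob_sigma = 2,
                          blob_amplitude = 0.8) {
  w <- camera$image_size[1]; h <- camera$image_size[2]
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(texture_seed)
  bg <- matrix(stats::runif(w * h, 0, 0.45), nrow = h, ncol = w)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  pr <- project(camera, flight$positions[match(frames, flight$frame), , drop = FALSE])
  vg <- seq_len(h); ug <- seq_len(w)
  out <- lapply(seq_along(frames), function(i) {
    f <- bg
    if (pr$in_frame[i]) {
      bump_v <- exp(-(vg - pr$v[i])^2 / (2 * blob_sigma^2))
      bump_u <- exp(-(ug - pr$u[i])^2 / (2 * blob_sigma^2))
      f <- f + blob_amplitude * outer(bump_v, bump_u)
    }
    f
  })
  list(background = bg, frames = out, projections = pr)
}

#' Simulate the full experiment
#'
#' Assigns each bee one obstacle-field height at random, 5 to 13 flights
#' alternating direction, with one contiguous block of still-air flights
#' and one block of windy flights (random starting condition), then
#' simulates each transit and (optionally) its stereo observations.
#'
#' @param config A \code{behavior_config}.
#' @param seed Integer seed for the whole dataset.
#' @param observe Attach per-camera detections (default TRUE).
#' @param rig Stereo rig (default \code{\link{default_stereo_rig}}).
#' @return A \code{flight_experiment}: list with \code{config}, \code{rig},
#'   \code{scenes} (one \code{scene_spec} per height), \code{flights} (each
#'   a list with \code{flight} and \code{detections}), and \code{truth}, the
#'   ground-truth metrics table (one row per flight).
#' @export
simulate_experiment <- function(config = behavior_config(), seed = 1,
                                observe = TRUE, rig = default_stereo_rig()) {
  set.seed(seed)
  heights <- as.numeric(names(config$p_within))
  scenes <- lapply(heights, build_scene)
  names(scenes) <- as.character(heights)
  flights <- list()
  truth <- list()
  for (b in seq_len(config$n_bees)) {
    bee_id <- sprintf("bee%02d", b)
    h <- sample(heights, 1)
    scene <- scenes[[as.character(h)]]
    n_fl <- sample(seq(config$flights_min, config$flights_max), 1)
    first_block <- sample(c("still", "wind"), 1)
    first_dir <- sample(c("up_tunnel", "down_tunnel"), 1)
    bee_effects <- list(speed_factor = exp(stats::rnorm(1, 0, config$bee_speed_sd)),
                        altitude_shift = stats::rnorm(1, 0, config$bee_altitude_sd))
    for (fl in seq_len(n_fl)) {
      wind <- if (fl <= ceiling(n_fl / 2)) first_block
              else setdiff(c("still", "wind"), first_block)
      direction <- if (fl %% 2 == 1) first_dir
                   else setdiff(c("up_tunnel", "down_tunnel"), first_dir)
      cond <- trial_condition(bee_id, fl, wind, direction, h)
      gt <- simulate_flight(cond, config, scene, bee_effects)
      det <- if (observe)
        observe_flight(gt, rig, noise = config$pixel_noise,
                       dropout = config$dropout,
                       distractor_rate = config$distractor_rate)
      else NULL
      flights[[length(flights) + 1]] <- list(flight = gt, detections = det)
      truth[[length(truth) + 1]] <- gt$true_metrics
    }
  }
  truth <- do.call(rbind, truth)
  truth$flight_id <- paste0(truth$bee_id, "_f", truth$flight_number)
  structure(list(config = config, rig = rig, scenes = scenes,
                 flights = flights, truth = truth, seed = seed),
            class = "flight_experiment")
}

#' @export
print.flight_experiment <- function(x, ...) {
  cat(sprintf("<flight_experiment> %d bees, %d flights (seed %s)\n",
              x$config$n_bees, nrow(x$truth), format(x$seed)))
  print(table(route = x$truth$route, wind = x$truth$wind))
  invisible(x)
}
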