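# shared fixtures: scaled-down camera rig for rendering tests, quick
# simulated flights, and a metrics-table generator for the model layer

scale_camera <- function(cam, factor = 8) {
  camera_params(focal = cam$focal / factor,
                principal_point = cam$principal_point / factor,
                radial_distortion = cam$radial_distortion,
                rotation = cam$rotation, translation = cam$translation,
                image_size = round(cam$image_size / factor),
                camera_id = paste0(cam$camera_id, "_small"))
}

small_rig <- function() {
  rig <- default_stereo_rig()
  list(a = scale_camera(rig$a), b = scale_camera(rig$b),
       frame_rate = rig$frame_rate)
}

quick_flight <- function(seed = 1, field_height = 69, wind = "still",
                         direction = "up_tunnel", config = behavior_config()) {
  set.seed(seed)
  scene <- build_scene(field_height)
  cond <- trial_condition("bee01", 1, wind, direction, field_height)
  simulate_flight(cond, config, scene)
}

# straight-line pixel detections with optional per-frame distractor
straight_detections <- function(n = 60, u0 = 100, v0 = 80, du = 3, dv = 1,
                                distractor_offset = NULL) {
  frames <- seq_len(n)
  det <- data.frame(frame = frames, u = u0 + du * (frames - 1),
                    v = v0 + dv * (frames - 1))
  if (!is.null(distractor_offset)) {
    det <- rbind(det, data.frame(frame = frames,
                                 u = det$u + distractor_offset,
                                 v = det$v + distractor_offset))
    det <- det[order(det$frame), ]
  }
  det
}

# exhaustive minimum-cost assignment over all row-to-column injections
brute_force_assignment <- function(cost) {
  nr <- nrow(cost); nc <- ncol(cost)
  if (nr > nc) return(brute_force_assignment(t(cost)))
  best <- Inf
  rec <- function(i, used, acc) {
    if (acc >= best) return()
    if (i > nr) { best <<- acc; return() }
    for (j in seq_len(nc)[!used]) {
      used[j] <- TRUE
      rec(i + 1, used, acc + cost[i, j])
      used[j] <- FALSE
    }
  }
  rec(1, logical(nc), 0)
  best
}

# metrics-like table with known mixed-model structure, for the stats layer
simulate_metrics_table <- function(n_bees = 30, n_per_bee = 8, beta_wind = 0.5,
                                   sigma_b = 1, sigma = 1,
                                   sigma_by_height = NULL, seed = 1) {
  set.seed(seed)
  heights <- c(11, 40, 69, 98, 127)
  rows <- list()
  for (b in seq_len(n_bees)) {
    h <- heights[(b - 1) %% 5 + 1]
    u <- rnorm(1, 0, sigma_b)
    for (i in seq_len(n_per_bee)) {
      wind <- if (i %% 2 == 0) "wind" else "still"
      direction <- if (i %% 4 < 2) "up_tunnel" else "down_tunnel"
      sd_i <- if (is.null(sigma_by_height)) sigma
              else sigma * sigma_by_height[[as.character(h)]]
      y <- 10 + beta_wind * (wind == "wind") + u + rnorm(1, 0, sd_i)
      rows[[length(rows) + 1]] <- data.frame(
        bee_id = sprintf("bee%02d", b), flight_number = i, wind = wind,
        direction = direction,
        wind_class = if (wind == "still") {
          if (direction == "up_tunnel") "still_up" else "still_down"
        } else {
          if (direction == "up_tunnel") "headwind" else "tailwind"
        },
        field_height = h, response = y, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
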