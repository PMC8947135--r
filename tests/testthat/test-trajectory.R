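make_traj <- function(df, frame_rate = 500, id = "f1") {
  df$reproj_err <- df$reproj_err %||% 0
  df$flag <- df$flag %||% "ok"
  flighttunnel:::new_trajectory3d(df, frame_rate, id)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("reconstruction inverts a noiseless simulated flight", {
  fl <- quick_flight(seed = 21)
  rig <- default_stereo_rig()
  set.seed(21)
  det <- observe_flight(fl, rig, noise = 0, dropout = 0)
  ta <- track_single_target(det$a, kalman_config())
  tb <- track_single_target(det$b, kalman_config())
  traj <- reconstruct(ta, tb, rig$a, rig$b, flight_id = "f1")
  idx <- match(traj$frame, fl$frame)
  err <- sqrt(rowSums((as.matrix(traj[, c("x", "y", "z")]) -
                         fl$positions[idx, ])^2))
  # the Kalman filter needs a few frames to converge; steady state is exact
  expect_lt(median(err), 1e-3)
  expect_lt(median(tail(err, 200)), 1e-4)
  expect_false(attr(traj, "calibration_warning"))
})

test_that("reconstruction at default noise keeps RMS error small and flags dropouts", {
  fl <- quick_flight(seed = 22)
  rig <- default_stereo_rig()
  set.seed(22)
  det <- observe_flight(fl, rig, noise = 0.5, dropout = 0.02)
  ta <- track_single_target(det$a, kalman_config())
  tb <- track_single_target(det$b, kalman_config())
  traj <- reconstruct(ta, tb, rig$a, rig$b)
  idx <- match(traj$frame, fl$frame)
  err <- sqrt(rowSums((as.matrix(traj[, c("x", "y", "z")]) -
                         fl$positions[idx, ])^2))
  expect_lt(sqrt(mean(err^2)), 1.5)
  expect_true(any(traj$flag == "coasted_one"))
})

test_that("non-overlapping tracks cannot be reconstructed", {
  t1 <- data.frame(frame = 1:30, u = 1, v = 1, du = 0, dv = 0,
                   status = "measured")
  t2 <- t1; t2$frame <- 101:130
  rig <- default_stereo_rig()
  expect_error(reconstruct(t1, t2, rig$a, rig$b), "overlap")
})

test_that("clipping keeps the closed field interval and is idempotent", {
  sc <- build_scene(69)
  x <- seq(300, 900, by = 5)
  traj <- make_traj(data.frame(frame = seq_along(x), t = seq_along(x) / 500,
                               x = x, y = 0, z = 100))
  cl <- clip_to_field(traj, sc)
  expect_true(all(cl$x >= sc$field_x_extent[1] & cl$x <= sc$field_x_extent[2]))
  expect_equal(min(cl$x), 345)  # boundary sample retained (closed interval)
  expect_equal(max(cl$x), 805)
  expect_equal(as.data.frame(clip_to_field(cl, sc)), as.data.frame(cl))
  # a path that turns around before the field is "no transit"
  short <- make_traj(data.frame(frame = 1:50, t = (1:50) / 500,
                                x = seq(10, 300, length.out = 50), y = 0, z = 100))
  expect_error(clip_to_field(short, sc), "no transit")
})

test_that("excluded-zone filter discards ceiling approaches, boundary exclusive", {
  sc <- build_scene(69)
  base <- data.frame(frame = 1:20, t = (1:20) / 500,
                     x = seq(400, 700, length.out = 20), y = 0, z = 100)
  expect_true(excluded_zone_filter(make_traj(base), sc))
  high <- base; high$z[10] <- 180
  expect_false(excluded_zone_filter(make_traj(high), sc))
  at_boundary <- base; at_boundary$z[10] <- 176
  expect_true(excluded_zone_filter(make_traj(at_boundary), sc))
})

test_that("quintic splines reproduce quintic polynomials exactly", {
  t <- seq(0, 2, by = 0.005)
  y <- 1 - 2 * t + 0.3 * t^2 + t^3 - 0.4 * t^4 + 0.05 * t^5
  f <- fit_quintic_spline(t, y, smoothing = 0)
  expect_lt(max(abs(predict(f, t) - y)), 1e-8)
  # derivative is exact too
  dy <- -2 + 0.6 * t + 3 * t^2 - 1.6 * t^3 + 0.25 * t^4
  expect_lt(max(abs(predict(f, t, deriv = 1) - dy)), 1e-6)
})

test_that("a constant position smooths to zero velocity", {
  traj <- make_traj(data.frame(frame = 1:100, t = (1:100) / 500,
                               x = 500, y = 3, z = 100))
  st <- smooth_trajectory(traj)
  ev <- evaluate_trajectory(st)
  expect_lt(max(abs(ev$vx), abs(ev$vy), abs(ev$vz)), 1e-3)
  expect_equal(ev$y, rep(3, 100), tolerance = 1e-6)
})

test_that("GCV smoothing recovers a sinusoid's velocity from noisy samples", {
  set.seed(23)
  A <- 10; f <- 2
  t <- seq(0, 2, by = 1 / 500)
  z <- A * sin(2 * pi * f * t) + rnorm(length(t), 0, 0.5)
  fit <- fit_quintic_spline(t, z, smoothing = "auto")
  v <- predict(fit, t, deriv = 1)
  v_true <- A * 2 * pi * f * cos(2 * pi * f * t)
  expect_lt(sqrt(mean((v - v_true)^2)), 0.1 * A * 2 * pi * f)
})

test_that("smoothing shrinks high-frequency velocity noise without losing fit", {
  set.seed(24)
  t <- (1:400) / 500
  z_true <- 100 + 10 * sin(2 * pi * 1.7 * t)
  z <- z_true + rnorm(400, 0, 0.5)
  traj <- make_traj(data.frame(frame = 1:400, t = t, x = 320 * t, y = 0, z = z))
  st <- smooth_trajectory(traj)
  ev <- evaluate_trajectory(st)
  # residual to the observed data stays at the noise scale
  expect_lt(sqrt(mean((ev$z - z)^2)), 1)
  # spline velocity is far less variable than finite differences of raw data
  v_fd <- diff(z) / diff(t)
  expect_lt(stats::var(ev$vz), 0.25 * stats::var(v_fd))
  expect_error(smooth_trajectory(traj[1:8, ]), "few samples")
})

test_that("trajectory CSV writes provenance and round-trips", {
  traj <- make_traj(data.frame(frame = 1:20, t = (1:20) / 500,
                               x = seq(400, 500, length.out = 20),
                               y = 1, z = 100))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(traj, path, seed = 99)
  lines <- readLines(path)
  expect_match(lines[1], "flighttunnel")
  expect_match(lines[2], "seed: 99")
  back <- read_pipeline_csv(path, required = c("flight_id", "frame", "x"))
  expect_equal(nrow(back), 20)
  expect_error(read_pipeline_csv(path, required = "route"), "route")
})
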