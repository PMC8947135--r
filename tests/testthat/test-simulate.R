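test_that("the control field never yields within-route flights", {
  cfg <- behavior_config()
  sc <- build_scene(11)
  set.seed(61)
  routes <- replicate(50, {
    cond <- trial_condition("b", 1, "still", "up_tunnel", 11)
    simulate_flight(cond, cfg, sc)$route
  })
  expect_true(all(routes == "above"))
})

test_that("the within-route fraction at the tallest field matches its probability", {
  cfg <- behavior_config()
  sc <- build_scene(127)
  set.seed(62)
  n_within <- sum(replicate(1000, {
    cond <- trial_condition("b", 1, "still", "up_tunnel", 127)
    simulate_flight(cond, cfg, sc)$route == "within"
  }))
  expect_gte(n_within / 1000, 0.50)
  expect_lte(n_within / 1000, 0.60)
})

test_that("still-air true ground speeds have the configured median", {
  cfg <- behavior_config()
  heights <- c(11, 40, 69, 98, 127)
  scenes <- lapply(heights, build_scene)
  set.seed(63)
  speeds <- replicate(500, {
    i <- sample(5, 1)
    dir <- sample(c("up_tunnel", "down_tunnel"), 1)
    cond <- trial_condition("b", 1, "still", dir, heights[i])
    simulate_flight(cond, cfg, scenes[[i]])$true_metrics$ground_speed
  })
  expect_lt(abs(median(speeds) / 1000 - 0.32), 0.03 * 0.32)
})

test_that("noiseless observation reproduces exact projections", {
  fl <- quick_flight(seed = 64)
  rig <- default_stereo_rig()
  det <- observe_flight(fl, rig, noise = 0, dropout = 0)
  pr <- project(rig$a, fl$positions)
  expect_equal(nrow(det$a), sum(pr$in_frame))
  idx <- match(det$a$frame, fl$frame)
  expect_equal(det$a$u, pr$u[idx], tolerance = 1e-12)
  expect_equal(det$a$v, pr$v[idx], tolerance = 1e-12)
})

test_that("dropout removes detections at the configured binomial rate", {
  fl <- quick_flight(seed = 65)
  rig <- default_stereo_rig()
  set.seed(65)
  n_vis <- sum(project(rig$a, fl$positions)$in_frame)
  det <- observe_flight(fl, rig, noise = 0, dropout = 0.05)
  missing <- n_vis - nrow(det$a)
  band <- qbinom(c(0.005, 0.995), n_vis, 0.05)
  expect_gte(missing, band[1])
  expect_lte(missing, band[2])
})

test_that("distractor detections are flagged for scoring", {
  fl <- quick_flight(seed = 66)
  rig <- default_stereo_rig()
  set.seed(66)
  det <- observe_flight(fl, rig, noise = 0, dropout = 0,
                        distractor_rate = 0.1)
  expect_true(any(!det$a$is_target))
  expect_true(any(det$a$is_target))
})

test_that("the experiment design follows the protocol", {
  cfg <- behavior_config(n_bees = 12)
  ex <- simulate_experiment(cfg, seed = 67, observe = FALSE)
  tr <- ex$truth
  # each bee has exactly one field height
  per_bee <- tapply(tr$field_height, tr$bee_id, function(x) length(unique(x)))
  expect_true(all(per_bee == 1))
  # flights per bee within the configured range
  counts <- table(tr$bee_id)
  expect_true(all(counts >= 5 & counts <= 13))
  # both wind conditions and both directions appear for every bee
  expect_true(all(tapply(tr$wind, tr$bee_id,
                         function(x) length(unique(x))) == 2))
  expect_true(all(tapply(tr$direction, tr$bee_id,
                         function(x) length(unique(x))) == 2))
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- behavior_config(n_bees = 4)
  ex1 <- simulate_experiment(cfg, seed = 68)
  ex2 <- simulate_experiment(cfg, seed = 68)
  expect_identical(ex1$truth, ex2$truth)
  expect_identical(ex1$flights[[3]]$detections, ex2$flights[[3]]$detections)
  ex3 <- simulate_experiment(cfg, seed = 69)
  expect_false(identical(ex3$truth, ex1$truth))
})

test_that("generated flights respect tunnel bounds and route constraints", {
  cfg <- behavior_config(n_bees = 10)
  ex <- simulate_experiment(cfg, seed = 70, observe = FALSE)
  for (fl in ex$flights) {
    p <- fl$flight$positions
    sc <- ex$scenes[[as.character(fl$flight$field_height)]]
    expect_true(all(p[, "z"] > 0 & p[, "z"] < sc$tunnel_height))
    expect_true(all(abs(p[, "y"]) < sc$tunnel_width / 2))
    infield <- p[, "x"] >= sc$field_x_extent[1] &
      p[, "x"] <= sc$field_x_extent[2]
    h <- fl$flight$field_height
    if (fl$flight$route == "above") {
      expect_true(all(p[infield, "z"] > h))
    } else {
      # within-route flights stay inside one corridor
      y <- p[infield, "y"]
      centers <- flighttunnel:::corridor_centers(sc)
      center <- centers[which.min(abs(centers - mean(y)))]
      half <- (sc$corridor_width + sc$column_diameter) / 2 -
        sc$column_diameter / 2
      expect_true(all(abs(y - center) < half))
      expect_true(all(p[infield, "z"] < h))
    }
  }
})

test_that("rendered frames round-trip through detection and background estimation", {
  rig <- small_rig()
  fl <- quick_flight(seed = 71)
  frames <- fl$frame[seq(1, length(fl$frame), length.out = 30)]
  rend <- render_frames(fl, rig$a, frames = frames)
  bg <- estimate_background(rend$frames)
  expect_lt(max(abs(bg - rend$background)), 0.1)
  errs <- sapply(seq_along(frames), function(i) {
    det <- detect_blobs(rend$frames[[i]], rend$background, threshold = 0.1)
    if (nrow(det) == 0) return(NA_real_)
    sqrt((det$u[1] - rend$projections$u[i])^2 +
           (det$v[1] - rend$projections$v[i])^2)
  })
  expect_true(all(!is.na(errs)))
  expect_lt(sqrt(mean(errs^2)), 0.5)
  # a frame without the blob yields no detection
  expect_equal(nrow(detect_blobs(rend$background, rend$background)), 0)
})

test_that("behavior config validates its invariants", {
  expect_error(behavior_config(route_speed_ratio = -1), "positive")
  expect_error(behavior_config(p_within = c("11" = 0.2, "40" = 0.05,
                                            "69" = 0.1, "98" = 0.25,
                                            "127" = 0.55)), "control")
  expect_error(behavior_config(flights_min = 8, flights_max = 5), "range")
  cfg <- behavior_config()
  expect_gt(cfg$speed_base_above, 320)  # above-route median exceeds the mixture median
})

test_that("config files round-trip through YAML and JSON", {
  path_y <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_bees: 10", "wind_speed: 0.6"), path_y)
  cfg <- read_behavior_config(path_y)
  expect_equal(cfg$n_bees, 10)
  expect_equal(cfg$wind_speed, 0.6)
  path_j <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(n_bees = 7), path_j, auto_unbox = TRUE)
  expect_equal(read_behavior_config(path_j)$n_bees, 7)
  writeLines("not_a_key: 3", path_y)
  expect_error(read_behavior_config(path_y), "unknown config key")
})
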