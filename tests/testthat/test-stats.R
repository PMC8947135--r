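test_that("response transforms match the registered conventions", {
  expect_equal(transform_response(4, "altitude_floor"), 16)
  expect_equal(transform_response(100, "altitude_range"), 2)
  expect_equal(transform_response(27, "lateral_excursion"), 3)
  expect_equal(transform_response(c(1, 10), "ground_speed"), c(0, 1))
  expect_error(transform_response(c(5, 0), "ground_speed",
                                  flight_id = c("a", "b")), "b")
  expect_error(transform_response(1, "unknown_metric"), "no transform")
})

test_that("Levene's test holds its level and detects a variance ratio of 3", {
  set.seed(41)
  null_p <- replicate(100, {
    levene_test(c(rnorm(50), rnorm(50)), rep(c("a", "b"), each = 50))$p_value
  })
  expect_gte(mean(null_p > 0.05), 0.90)
  alt_p <- replicate(100, {
    levene_test(c(rnorm(50, sd = 1), rnorm(50, sd = 3)),
                rep(c("a", "b"), each = 50))$p_value
  })
  expect_gte(mean(alt_p < 0.05), 0.90)
  expect_error(levene_test(rnorm(10), rep("a", 10)), "2 groups")
})

test_that("the mixed model recovers known fixed effects and variances", {
  set.seed(42)
  est <- replicate(100, {
    d <- simulate_metrics_table(n_bees = 58, n_per_bee = 9, beta_wind = 0.5,
                                sigma_b = 1, sigma = 1,
                                seed = sample.int(1e6, 1))
    f <- fit_lmm(d, model_spec("response", ~ wind, transform = "identity"))
    c(f$coefficients[["windwind"]], f$sigma_b, f$sigma)
  })
  mc_se <- apply(est, 1, sd) / sqrt(ncol(est))
  expect_lt(abs(mean(est[1, ]) - 0.5), 3 * mc_se[1])
  expect_lt(abs(mean(est[2, ]) - 1), 3 * mc_se[2] + 0.02)
  expect_lt(abs(mean(est[3, ]) - 1), 3 * mc_se[3] + 0.02)
})

test_that("with no bee effect the fixed estimates match ordinary least squares", {
  set.seed(43)
  d <- simulate_metrics_table(n_bees = 40, n_per_bee = 8, beta_wind = 0.8,
                              sigma_b = 0, sigma = 1)
  f <- fit_lmm(d, model_spec("response", ~ wind * direction,
                             transform = "identity"))
  ols <- lm(response ~ wind * direction, data = f$data)
  expect_equal(unname(f$coefficients), unname(coef(ols)), tolerance = 1e-4)
})

test_that("stratum-specific residual scales recover a simulated ratio of 2", {
  set.seed(44)
  d <- simulate_metrics_table(n_bees = 60, n_per_bee = 9, sigma_b = 0.5,
                              sigma = 1,
                              sigma_by_height = list("11" = 1, "40" = 1,
                                                     "69" = 1, "98" = 1,
                                                     "127" = 1))
  # overwrite: double the residual scale for windy flights
  extra <- rnorm(nrow(d), 0, 1) * (d$wind == "wind") * sqrt(3)
  d$response <- d$response + extra  # total windy SD = sqrt(1 + 3) = 2
  f <- fit_lmm(d, model_spec("response", ~ wind, transform = "identity",
                             variance_strata = "wind"))
  ratio <- max(f$sigma_strata) / min(f$sigma_strata)
  expect_gt(ratio, 1.7)
  expect_lt(ratio, 2.3)
})

test_that("REML at the fitted optimum matches a brute-force criterion grid", {
  set.seed(45)
  n_g <- 6; n_per <- 5
  g <- rep(seq_len(n_g), each = n_per)
  x <- rnorm(30)
  y <- 2 + 0.5 * x + rnorm(n_g, 0, 0.8)[g] + rnorm(30, 0, 0.6)
  d <- data.frame(bee_id = sprintf("b%d", g), wind = "still",
                  direction = "up_tunnel", field_height = 69,
                  flight_number = 1, response = y, x = x)
  f <- fit_lmm(d, model_spec("response", ~ x, transform = "identity"))
  X <- cbind(1, x)
  reml_crit <- function(sb, s) {
    V <- diag(s^2, 30) + sb^2 * outer(g, g, "==")
    Vi <- solve(V)
    XtVX <- t(X) %*% Vi %*% X
    beta <- solve(XtVX, t(X) %*% Vi %*% y)
    r <- y - X %*% beta
    -0.5 * (determinant(V)$modulus + determinant(XtVX)$modulus +
              t(r) %*% Vi %*% r)[1]
  }
  grid <- expand.grid(sb = seq(0.05, 2, length.out = 40),
                      s = seq(0.2, 1.5, length.out = 40))
  grid_best <- max(mapply(reml_crit, grid$sb, grid$s))
  at_fit <- reml_crit(f$sigma_b, f$sigma)
  expect_gte(at_fit, grid_best - 1e-3)
})

test_that("variance-structure selection is parsimonious under homoskedasticity", {
  set.seed(46)
  wins <- replicate(30, {
    d <- simulate_metrics_table(n_bees = 25, n_per_bee = 8, sigma_b = 0.7,
                                sigma = 1, seed = sample.int(1e6, 1))
    sel <- candidate_variance_models(
      d, model_spec("response", ~ wind, transform = "identity"))
    base_aic <- sel$table$AIC[sel$table$variance_structure == "homoskedastic"]
    base_aic <= min(sel$table$AIC, na.rm = TRUE) + 2
  })
  expect_gte(mean(wins), 0.80)
})

test_that("variance-structure selection finds a field-height variance ratio of 3", {
  set.seed(47)
  wins <- replicate(30, {
    d <- simulate_metrics_table(
      n_bees = 25, n_per_bee = 8, sigma_b = 0.7, sigma = 1,
      sigma_by_height = list("11" = 1, "40" = 1, "69" = 1, "98" = 3,
                             "127" = 3),
      seed = sample.int(1e6, 1))
    sel <- candidate_variance_models(
      d, model_spec("response", ~ wind, transform = "identity"))
    best <- sel$table$variance_structure[which.min(sel$table$AIC)]
    grepl("field_height", best)
  })
  expect_gte(mean(wins), 0.90)
})

test_that("AIC ranking returns all eight variance structures ordered", {
  d <- simulate_metrics_table(n_bees = 20, n_per_bee = 8, seed = 5)
  sel <- candidate_variance_models(
    d, model_spec("response", ~ wind, transform = "identity"))
  expect_equal(nrow(sel$table), 8)
  ok <- sel$table[sel$table$converged, ]
  expect_true(!is.unsorted(ok$AIC))
  # nesting: the heteroskedastic winner cannot have lower REML loglik than
  # the homoskedastic base
  base_ll <- sel$table$logLik[sel$table$variance_structure == "homoskedastic"]
  expect_gte(sel$best$logLik, base_ll - 1e-6)
})

test_that("altitude-definition selection distinguishes threshold from linear effects", {
  # route-threshold generator: the categorical model must win
  cfg <- behavior_config()
  set.seed(48)
  ex <- simulate_experiment(cfg, seed = 481, observe = FALSE)
  sel <- candidate_altitude_models(ex$truth, "ground_speed")
  expect_equal(sel$best_definition, "route")
  expect_equal(nrow(sel$table), 3)
  expect_true(!is.unsorted(sel$table$AIC_ML[sel$table$converged]))
  # converse: speed linear in altitude with no route step
  set.seed(49)
  linear_wins <- replicate(10, {
    d <- ex$truth[sample(nrow(ex$truth), 400), ]
    u <- rnorm(length(unique(d$bee_id)), 0, 0.02)
    names(u) <- unique(d$bee_id)
    d$ground_speed <- 10^(2.3 + 0.002 * d$altitude_floor +
                            u[d$bee_id] + rnorm(400, 0, 0.05))
    sel2 <- candidate_altitude_models(d, "ground_speed")
    sel2$best_definition != "route"
  })
  expect_gte(mean(linear_wins), 0.7)
})

test_that("marginal contrasts reproduce a textbook Tukey HSD", {
  # balanced one-factor design; compare against TukeyHSD on aov
  set.seed(50)
  g <- rep(c("still_up", "still_down", "headwind"), each = 20)
  y <- rnorm(60) + c(still_up = 0, still_down = 0.8, headwind = 1.5)[g]
  d <- data.frame(bee_id = rep(sprintf("b%d", 1:20), 3), flight_number = 1,
                  wind = "still", direction = "up_tunnel", field_height = 69,
                  wind_class = g, response = y)
  f <- fit_lmm(d, model_spec("response", ~ wind_class, transform = "identity"))
  mc <- marginal_contrasts(f, "wind_class")
  hsd <- TukeyHSD(aov(y ~ g))$g
  # match contrasts by the pair of levels involved
  got <- mc$contrasts
  for (i in seq_len(nrow(got))) {
    lv <- strsplit(as.character(got$contrast[i]), " - ")[[1]]
    key1 <- paste(lv[2], lv[1], sep = "-")
    key2 <- paste(lv[1], lv[2], sep = "-")
    row <- if (key1 %in% rownames(hsd)) -hsd[key1, ] else hsd[key2, ]
    expect_equal(got$estimate[i], unname(row["diff"]), tolerance = 0.05)
  }
  expect_error(marginal_contrasts(f, "route"), "not a term")
})

test_that("identical group means give null contrasts with p near 1", {
  set.seed(51)
  d <- simulate_metrics_table(n_bees = 30, n_per_bee = 8, beta_wind = 0,
                              sigma_b = 0.5, sigma = 1)
  f <- fit_lmm(d, model_spec("response", ~ wind, transform = "identity"))
  mc <- marginal_contrasts(f, "wind")
  expect_lt(abs(mc$contrasts$estimate[1]), 0.2)
  expect_gt(mc$contrasts$p.value[1], 0.2)
})

test_that("a five-level factor yields ten pairwise contrasts", {
  d <- simulate_metrics_table(n_bees = 30, n_per_bee = 8, seed = 6)
  f <- fit_lmm(d, model_spec("response", ~ field_height,
                             transform = "identity"))
  mc <- marginal_contrasts(f, "field_height")
  expect_equal(nrow(mc$contrasts), 10)
})

test_that("paired first-vs-last tests match hand-computed values and skip tiny strata", {
  base <- data.frame(
    bee_id = rep(c("a", "b", "c"), each = 2),
    flight_number = rep(c(1, 5), 3), wind = "still",
    direction = "up_tunnel", wind_class = "still_up", field_height = 69)
  m <- base
  m$altitude_floor <- c(100, 101, 100, 102, 100, 103)  # diffs 1, 2, 3
  m$ground_speed <- 300
  m$lateral_excursion <- 12
  res <- first_last_paired_test(m)
  alt <- res[res$metric == "altitude_floor", ]
  expect_equal(alt$t, 2 * sqrt(3), tolerance = 1e-9)
  expect_equal(alt$df, 2)
  speed <- res[res$metric == "ground_speed", ]
  expect_true(is.na(speed$t) || speed$p_value > 0.99 || speed$t == 0)
  one_bee <- m[m$bee_id == "a", ]
  expect_warning(first_last_paired_test(one_bee), "skipped")
})

test_that("non-convergence is flagged, never silent", {
  d <- simulate_metrics_table(n_bees = 3, n_per_bee = 2, seed = 7)
  f <- suppressWarnings(
    fit_lmm(d, model_spec("response",
                          ~ wind * direction * field_height,
                          transform = "identity")))
  expect_false(is.null(f$converged))
  if (!f$converged) expect_true(nzchar(f$message))
})
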