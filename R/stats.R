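#' Response transforms used in the analysis
#'
#' Each flight metric is transformed toward normality before model fitting:
#' median altitude is squared, altitudinal range and ground speed are
#' log10-transformed, lateral excursion is cube-root-transformed.
#'
#' @param values Numeric vector.
#' @param metric_name One of \code{"altitude_floor"},
#'   \code{"altitude_range"}, \code{"ground_speed"},
#'   \code{"lateral_excursion"}; or a transform name (\code{"square"},
#'   \code{"log10"}, \code{"cbrt"}, \code{"identity"}).
#' @param flight_id Optional ids used to name offenders in error messages.
#' @return Transformed vector.
#' @export
transform_response <- function(values, metric_name, flight_id = NULL) {
  tr <- switch(metric_name,
               altitude_floor = "square", altitude_range = "log10",
               ground_speed = "log10", lateral_excursion = "cbrt",
               square = "square", log10 = "log10", cbrt = "cbrt",
               identity = "identity",
               stop("no transform registered for metric ", metric_name))
  if (tr == "log10" && any(values <= 0)) {
    bad <- which(values <= 0)
    lab <- if (!is.null(flight_id)) paste(flight_id[bad], collapse = ", ")
           else paste(bad, collapse = ", ")
    stop("log10 transform needs positive values; offending flight(s): ", lab)
  }
  switch(tr,
         square = values^2,
         log10 = log10(values),
         cbrt = sign(values) * abs(values)^(1 / 3),
         identity = values)
}

#' Levene's test for homogeneity of variances
#'
#' Classic Levene: an ANOVA on absolute deviations from the group centre
#' (mean by default, median optional), used to check the homoskedasticity
#' assumption of the mixed models.
#'
#' @param values Numeric response.
#' @param groups Grouping factor (or interaction of factors).
#' @param center \code{"mean"} (classic) or \code{"median"}
#'   (Brown-Forsythe).
#' @return List with \code{statistic} (F), \code{df}, and \code{p_value}.
#' @export
levene_test <- function(values, groups, center = c("mean", "median")) {
  center <- match.arg(center)
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) stop("need at least 2 groups for Levene's test")
  if (any(table(groups) < 2)) stop("every group needs >= 2 observations")
  fit <- car::leveneTest(values, groups,
                         center = if (center == "mean") mean else stats::median)
  list(statistic = fit[1, "F value"],
       df = c(fit[1, "Df"], fit[2, "Df"]),
       p_value = fit[1, "Pr(>F)"])
}

#' Model specification for the mixed analysis
#'
#' @param response Metric name (transformed per
#'   \code{\link{transform_response}}) or a list
#'   \code{list(metric =, transform =)}.
#' @param fixed One-sided formula of fixed effects, e.g.
#'   \code{~ wind * direction * field_height}.
#' @param variance_strata Character vector of grouping factors whose levels
#'   get their own residual variance (\code{NULL} = homoskedastic).
#' @param transform Overrides the metric's registered transform.
#' @return A \code{model_spec}.
#' @export
model_spec <- function(response, fixed, variance_strata = NULL,
                       transform = NULL) {
  structure(list(response = response, fixed = fixed,
                 variance_strata = variance_strata,
                 transform = transform %||% response),
            class = "model_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

prepare_flight_table <- function(metrics) {
  d <- as.data.frame(metrics)
  d$bee_id <- factor(d$bee_id)
  d$wind <- factor(d$wind, levels = c("still", "wind"))
  d$direction <- factor(d$direction, levels = c("up_tunnel", "down_tunnel"))
  d$field_height <- factor(d$field_height)
  if (!is.null(d$route)) d$route <- factor(d$route, levels = c("within", "above"))
  if (!is.null(d$wind_class))
    d$wind_class <- factor(d$wind_class,
                           levels = c("still_up", "still_down",
                                      "headwind", "tailwind"))
  d
}

#' Fit a random-intercept LMM with optional stratum variances
#'
#' REML fit of \eqn{y = X\beta + b_{bee} + \epsilon} with
#' \eqn{b \sim N(0, \sigma_b^2)} and residual variance allowed to differ by
#' the levels of the variance strata (an \code{nlme::varIdent} structure,
#' one scale per stratum).  The response is transformed per its registered
#' transform before fitting.
#'
#' @param data Flight metrics table (one row per kept flight).
#' @param spec A \code{model_spec}.
#' @param method \code{"REML"} (default) or \code{"ML"} (required when
#'   comparing models with different fixed effects by AIC).
#' @return An \code{lmm_fit}: coefficients and standard errors,
#'   \code{sigma_b} (random-intercept SD), \code{sigma_strata} (per-stratum
#'   residual SDs), log-likelihood, \code{AIC}, \code{n_obs},
#'   \code{n_groups}, \code{converged}, and the underlying \code{lme}
#'   object in \code{$model}.  Non-convergence yields a fit flagged
#'   \code{converged = FALSE} with the error message, never a silent
#'   failure.
#' @export
fit_lmm <- function(data, spec, method = c("REML", "ML")) {
  method <- match.arg(method)
  d <- prepare_flight_table(data)
  d$.resp <- transform_response(d[[spec$response]], spec$transform,
                                flight_id = d$flight_id)
  fixed <- stats::as.formula(paste(".resp ~",
                                   as.character(spec$fixed)[2]))
  weights <- NULL
  if (!is.null(spec$variance_strata) && length(spec$variance_strata)) {
    strat <- interaction(d[spec$variance_strata], drop = TRUE)
    if (any(table(strat) < 2))
      stop("each variance stratum needs >= 2 observations")
    d$.stratum <- strat
    weights <- nlme::varIdent(form = ~ 1 | .stratum)
  }
  fit <- tryCatch(
    nlme::lme(fixed, random = ~ 1 | bee_id, data = d, weights = weights,
              method = method,
              control = nlme::lmeControl(opt = "optim", maxIter = 100,
                                         msMaxIter = 100, returnObject = FALSE)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(converged = FALSE, message = conditionMessage(fit),
                          spec = spec, method = method, AIC = NA_real_,
                          logLik = NA_real_),
                     class = "lmm_fit"))
  }
  vc <- nlme::VarCorr(fit)
  sigma_b <- as.numeric(vc["(Intercept)", "StdDev"])
  sigma <- fit$sigma
  sigma_strata <- if (!is.null(weights)) {
    w <- stats::coef(fit$modelStruct$varStruct, unconstrained = FALSE,
                     allCoef = TRUE)
    stats::setNames(sigma * as.numeric(w), names(w))
  } else c(all = sigma)
  sm <- summary(fit)$tTable
  structure(list(
    converged = TRUE,
    coefficients = sm[, "Value"], std_errors = sm[, "Std.Error"],
    t_table = sm,
    sigma_b = sigma_b, sigma = sigma, sigma_strata = sigma_strata,
    logLik = as.numeric(stats::logLik(fit)),
    AIC = stats::AIC(fit),
    n_obs = fit$dims$N, n_groups = fit$dims$ngrps[["bee_id"]],
    method = method, spec = spec, model = fit, data = d),
    class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<lmm_fit> NOT CONVERGED:", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf("<lmm_fit> %s on %s (%s), AIC %.2f, logLik %.2f\n",
              deparse(x$spec$fixed), x$spec$response, x$method,
              x$AIC, x$logLik))
  cat(sprintf("  n = %d obs, %d bees; sigma_b = %.4g; residual SD%s\n",
              x$n_obs, x$n_groups, x$sigma_b,
              if (length(x$sigma_strata) > 1)
                paste0("s: ", paste(sprintf("%s=%.3g", names(x$sigma_strata),
                                            x$sigma_strata), collapse = ", "))
              else sprintf(" %.4g", x$sigma)))
  invisible(x)
}

#' Compare variance structures by AIC
#'
#' Refits the base model with every non-empty subset of
#' \code{\{wind, direction, field_height\}} as variance strata (seven
#' heteroskedastic structures) plus the homoskedastic base, all by REML
#' with identical fixed effects, and ranks by AIC; the lowest-AIC model is
#' the selection.
#'
#' @param data Flight metrics table.
#' @param base_spec The homoskedastic \code{model_spec}.
#' @param factors Stratification factors to combine.
#' @return List with \code{fits} (AIC-ascending), \code{table} (structure,
#'   AIC, logLik), and \code{best}.  Failed fits are recorded in the table
#'   and excluded from the ranking.
#' @export
candidate_variance_models <- function(data, base_spec,
                                      factors = c("wind", "direction",
                                                  "field_height")) {
  subsets <- list(NULL)
  for (k in seq_along(factors))
    subsets <- c(subsets, utils::combn(factors, k, simplify = FALSE))
  fits <- lapply(subsets, function(s)
    tryCatch(fit_lmm(data, model_spec(base_spec$response, base_spec$fixed,
                                      variance_strata = s,
                                      transform = base_spec$transform)),
             error = function(e)
               structure(list(converged = FALSE,
                              message = conditionMessage(e), AIC = NA_real_,
                              logLik = NA_real_),
                         class = "lmm_fit")))
  labels <- vapply(subsets, function(s)
    if (is.null(s)) "homoskedastic" else paste(s, collapse = "*"),
    character(1))
  tab <- data.frame(variance_structure = labels,
                    AIC = vapply(fits, function(f) f$AIC, numeric(1)),
                    logLik = vapply(fits, function(f) f$logLik, numeric(1)),
                    converged = vapply(fits, function(f) isTRUE(f$converged),
                                       logical(1)))
  ok <- which(tab$converged)
  if (!length(ok)) {
    warning("no variance-structure candidate converged")
    return(list(fits = list(), table = tab, best = NULL))
  }
  ord <- ok[order(tab$AIC[ok])]
  list(fits = fits[ord], table = tab[order(!tab$converged, tab$AIC), ],
       best = fits[[ord[1]]])
}

#' Compare the three altitude definitions by AIC
#'
#' Flight performance can be modelled against altitude defined (a) above
#' the floor together with the obstacle-field height, (b) relative to the
#' obstacle tops, or (c) categorically as the route (above vs within).
#' Fits the three candidate LMMs — each with wind and direction terms and
#' their interactions with the altitude term, bee as random intercept — and
#' ranks by AIC.  Because the candidates differ in fixed effects the
#' ranking uses maximum-likelihood fits; REML AICs are reported alongside.
#'
#' @param data Flight metrics table.
#' @param performance_metric \code{"ground_speed"} or
#'   \code{"lateral_excursion"}.
#' @return List with \code{fits} (ML, AIC-ascending), \code{table}
#'   (definition, AIC_ML, AIC_REML, logLik), and \code{best}.
#' @export
candidate_altitude_models <- function(data, performance_metric) {
  specs <- list(
    altitude_floor = model_spec(
      performance_metric,
      ~ wind * direction * altitude_floor + altitude_floor * field_height),
    altitude_obstacle = model_spec(
      performance_metric, ~ wind * direction * altitude_obstacle),
    route = model_spec(performance_metric, ~ wind * direction * route))
  fits_ml <- lapply(specs, function(s) fit_lmm(data, s, method = "ML"))
  fits_reml <- lapply(specs, function(s) fit_lmm(data, s, method = "REML"))
  tab <- data.frame(
    altitude_definition = names(specs),
    AIC_ML = vapply(fits_ml, function(f) f$AIC, numeric(1)),
    AIC_REML = vapply(fits_reml, function(f) f$AIC, numeric(1)),
    logLik_ML = vapply(fits_ml, function(f) f$logLik, numeric(1)),
    converged = vapply(fits_ml, function(f) isTRUE(f$converged), logical(1)))
  ok <- which(tab$converged)
  if (!length(ok)) {
    warning("no altitude-definition candidate converged")
    return(list(fits = list(), reml_fits = fits_reml, table = tab,
                best = NULL, best_definition = NA_character_))
  }
  ord <- ok[order(tab$AIC_ML[ok])]
  list(fits = fits_ml[ord], reml_fits = fits_reml,
       table = tab[order(!tab$converged, tab$AIC_ML), ],
       best = fits_ml[[ord[1]]],
       best_definition = tab$altitude_definition[ord[1]])
}

#' Tukey-adjusted marginal contrasts
#'
#' Estimated marginal means of a factor, averaged over the other terms'
#' levels, with all pairwise differences adjusted by the studentized-range
#' (Tukey HSD) method.  Degrees of freedom use the containment method.
#'
#' @param fit An \code{lmm_fit}.
#' @param factor Name of a factor in the fitted model.
#' @return List with \code{emmeans} and \code{contrasts} data frames
#'   (estimate, SE, df, t-ratio, adjusted p).
#' @export
marginal_contrasts <- function(fit, factor) {
  if (!isTRUE(fit$converged)) stop("cannot contrast a non-converged fit")
  if (!factor %in% all.vars(fit$spec$fixed))
    stop("factor '", factor, "' is not a term of the fitted model")
  em <- emmeans::emmeans(fit$model, stats::as.formula(paste("~", factor)),
                         data = fit$data, mode = "containment")
  ct <- emmeans::contrast(em, method = "pairwise", adjust = "tukey")
  list(emmeans = as.data.frame(em), contrasts = as.data.frame(ct))
}

#' Paired first-vs-last flight tests
#'
#' Checks for systematic change over a bee's session (e.g. learning):
#' paired t-tests of each bee's last recorded flight against its first,
#' separately for still-air and windy flights because wind covaries with
#' flight number, for median altitude, ground speed and lateral excursion.
#'
#' @param metrics Flight metrics table.
#' @param metrics_tested Metric columns to test.
#' @return Data frame with one row per metric and wind stratum: \code{n}
#'   (pairs), \code{t}, \code{df}, \code{p_value}.  Strata with fewer than
#'   2 complete pairs are skipped with a warning.
#' @export
first_last_paired_test <- function(metrics,
                                   metrics_tested = c("altitude_floor",
                                                      "ground_speed",
                                                      "lateral_excursion")) {
  out <- list()
  for (w in unique(metrics$wind)) {
    dw <- metrics[metrics$wind == w, ]
    firsts <- lasts <- list()
    for (b in unique(dw$bee_id)) {
      db <- dw[dw$bee_id == b, ]
      if (nrow(db) < 2) next
      firsts[[b]] <- db[which.min(db$flight_number), ]
      lasts[[b]] <- db[which.max(db$flight_number), ]
    }
    if (length(firsts) < 2) {
      warning("stratum '", w, "' skipped: fewer than 2 bees with paired flights")
      next
    }
    fd <- do.call(rbind, firsts); ld <- do.call(rbind, lasts)
    for (m in metrics_tested) {
      diffs <- ld[[m]] - fd[[m]]
      if (stats::sd(diffs) == 0) {
        # degenerate but well-defined: no change at all
        row <- data.frame(metric = m, wind = w, n = length(diffs),
                          t = if (mean(diffs) == 0) 0 else Inf,
                          df = length(diffs) - 1,
                          p_value = if (mean(diffs) == 0) 1 else 0)
      } else {
        tt <- stats::t.test(ld[[m]], fd[[m]], paired = TRUE)
        row <- data.frame(metric = m, wind = w, n = length(diffs),
                          t = unname(tt$statistic),
                          df = unname(tt$parameter), p_value = tt$p.value)
      }
      out[[length(out) + 1]] <- row
    }
  }
  do.call(rbind, out)
}

#' Full statistical analysis of a metrics table
#'
#' Runs the inference chain on recovered flight metrics: first-vs-last
#' paired checks, the altitude models (variance-structure selection on the
#' squared median altitude), and the performance models
#' (altitude-definition selection for ground speed and lateral excursion,
#' with Tukey contrasts of the selected route term).
#'
#' @param metrics Flight metrics table from \code{\link{run_pipeline}}.
#' @return List with \code{first_last}, \code{altitude} (variance-model
#'   selection), \code{ground_speed} and \code{lateral_excursion}
#'   (altitude-definition selections), and \code{effects}
#'   (\code{\link{summarize_effects}}).
#' @export
analyze_flights <- function(metrics) {
  alt <- candidate_variance_models(
    metrics, model_spec("altitude_floor",
                        ~ wind * direction * field_height))
  list(first_last = first_last_paired_test(metrics),
       altitude = alt,
       ground_speed = candidate_altitude_models(metrics, "ground_speed"),
       lateral_excursion = candidate_altitude_models(metrics,
                                                     "lateral_excursion"),
       effects = summarize_effects(metrics))
}
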