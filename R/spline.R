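#' Quintic smoothing splines for trajectory data
#'
#' Flight paths are smoothed per axis with penalized quintic (order-6)
#' B-splines: minimize \eqn{\sum_i (y_i - f(t_i))^2 + \lambda \int f'''(t)^2 dt}.
#' Penalizing the third derivative is the quintic analogue of the cubic
#' smoothing spline's curvature penalty and leaves velocity and acceleration
#' unpenalized up to quadratic trends.  Velocities come from the exact
#' analytic derivative of the fitted spline.  The smoothing parameter is
#' selected by generalized cross-validation (GCV) unless given.
#'
#' @name quintic_spline
NULL

quintic_knots <- function(t, nbasis) {
  ord <- 6L
  n_interior <- nbasis - ord
  t0 <- min(t); t1 <- max(t)
  interior <- if (n_interior > 0)
    seq(t0, t1, length.out = n_interior + 2)[-c(1, n_interior + 2)]
  else numeric(0)
  c(rep(t0, ord), interior, rep(t1, ord))
}

# integral of products of third-derivative basis functions, exact by 3-point
# Gauss-Legendre per inter-knot interval (integrand is piecewise quartic)
quintic_penalty <- function(knots) {
  ord <- 6L
  k <- length(knots) - ord
  breaks <- unique(knots)
  gx <- c(-sqrt(3 / 5), 0, sqrt(3 / 5))
  gw <- c(5 / 9, 8 / 9, 5 / 9)
  K <- matrix(0, k, k)
  for (i in seq_len(length(breaks) - 1)) {
    a <- breaks[i]; b <- breaks[i + 1]
    if (b <= a) next
    nodes <- (a + b) / 2 + (b - a) / 2 * gx
    G <- splines::splineDesign(knots, nodes, ord = ord, derivs = rep(3L, 3))
    K <- K + (b - a) / 2 * crossprod(G * sqrt(gw), G * sqrt(gw))
  }
  K
}

#' Fit a quintic smoothing spline to one coordinate
#'
#' @param t Sample times (strictly increasing).
#' @param y Values at \code{t}.
#' @param smoothing \code{"auto"} (GCV selection), or a non-negative number:
#'   the raw penalty weight \eqn{\lambda}; \code{0} gives the unpenalized
#'   least-squares quintic regression spline.
#' @param nbasis Number of B-spline basis functions (default scales with the
#'   series length, capped at 40).
#' @return A \code{quintic_fit}: list with \code{knots}, \code{coef},
#'   \code{lambda}, \code{edf} (effective degrees of freedom), \code{gcv}.
#' @export
fit_quintic_spline <- function(t, y, smoothing = "auto", nbasis = NULL) {
  n <- length(t)
  if (n < 12) stop("too few samples for quintic smoothing (need >= 12)")
  if (any(diff(t) <= 0)) stop("times must be strictly increasing")
  if (is.null(nbasis)) nbasis <- max(8L, min(40L, floor(n / 8) + 6L))
  nbasis <- min(nbasis, n)
  knots <- quintic_knots(t, nbasis)
  B <- splines::splineDesign(knots, t, ord = 6L)
  K <- quintic_penalty(knots)
  BtB <- crossprod(B)
  Bty <- drop(crossprod(B, y))
  yty <- sum(y^2)
  # Demmler-Reinsch: rotate so the penalized solve is diagonal in lambda
  R <- chol(BtB + diag(1e-10 * mean(diag(BtB)), nbasis))
  M <- backsolve(R, t(backsolve(R, t(K), transpose = TRUE)), transpose = TRUE)
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  z <- backsolve(R, Bty, transpose = TRUE)
  zt <- drop(crossprod(eg$vectors, z))
  solve_lambda <- function(lam) {
    shrink <- 1 / (1 + lam * d)
    w <- eg$vectors %*% (zt * shrink)
    coef <- backsolve(R, w)
    rss <- max(yty - 2 * sum(zt^2 * shrink) + sum(zt^2 * shrink^2), 0)
    edf <- sum(shrink)
    list(coef = drop(coef), rss = rss, edf = edf,
         gcv = n * rss / (n - edf)^2)
  }
  if (identical(smoothing, "auto")) {
    ref <- sum(diag(BtB)) / max(sum(diag(K)), .Machine$double.eps)
    grid <- ref * 10^seq(-8, 6, by = 0.5)
    gcvs <- vapply(grid, function(l) solve_lambda(l)$gcv, numeric(1))
    lambda <- grid[which.min(gcvs)]
  } else {
    lambda <- as.numeric(smoothing)
    if (!is.finite(lambda) || lambda < 0) stop("smoothing must be >= 0 or 'auto'")
  }
  fit <- solve_lambda(lambda)
  structure(list(knots = knots, coef = fit$coef, lambda = lambda,
                 edf = fit$edf, rss = fit$rss, gcv = fit$gcv,
                 range = range(t)),
            class = "quintic_fit")
}

#' Evaluate a quintic spline fit (or its derivatives)
#'
#' @param object A \code{quintic_fit}.
#' @param t Evaluation times inside the fitted range.
#' @param deriv Derivative order (0 = position, 1 = velocity, ...).
#' @param ... Unused.
#' @return Numeric vector.
#' @export
predict.quintic_fit <- function(object, t, deriv = 0L, ...) {
  t <- pmin(pmax(t, object$range[1]), object$range[2])
  B <- splines::splineDesign(object$knots, t, ord = 6L,
                             derivs = rep(as.integer(deriv), length(t)))
  drop(B %*% object$coef)
}
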