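#' Calibrated pinhole camera
#'
#' Cameras are modelled as pinholes with two radial distortion terms, the
#' model a standard checkerboard calibration yields.  World points are mapped
#' to pixels by a rigid transform (world to camera), perspective division,
#' the radial polynomial \eqn{1 + k_1 r^2 + k_2 r^4} applied to normalized
#' image coordinates, and finally the focal lengths and principal point.
#'
#' @param focal Numeric length-2, \code{(fx, fy)} in pixels.
#' @param principal_point Numeric length-2, \code{(cx, cy)} in pixels.
#' @param radial_distortion Numeric length-2, \code{(k1, k2)}.
#' @param rotation 3x3 orthonormal matrix, world-to-camera.
#' @param translation Length-3 vector (mm): \code{X_cam = R X_world + t}.
#' @param image_size Integer length-2, \code{(width, height)} pixels.
#' @param camera_id Label.
#' @return A \code{camera_params} object.
#' @export
camera_params <- function(focal, principal_point, radial_distortion = c(0, 0),
                          rotation = diag(3), translation = c(0, 0, 0),
                          image_size = c(1280, 800), camera_id = "cam") {
  R <- matrix(as.numeric(rotation), 3, 3)
  if (max(abs(crossprod(R) - diag(3))) > 1e-9 || abs(det(R) - 1) > 1e-9)
    stop("rotation must be orthonormal with determinant +1")
  if (any(focal <= 0)) stop("focal lengths must be positive")
  if (any(image_size <= 0)) stop("image_size must be positive")
  structure(list(focal = as.numeric(focal),
                 principal_point = as.numeric(principal_point),
                 radial_distortion = as.numeric(radial_distortion),
                 rotation = R, translation = as.numeric(translation),
                 image_size = as.numeric(image_size),
                 camera_id = as.character(camera_id)),
            class = "camera_params")
}

#' @export
print.camera_params <- function(x, ...) {
  cat(sprintf("<camera_params> %s: f = (%g, %g) px, c = (%g, %g), k = (%g, %g), image %g x %g\n",
              x$camera_id, x$focal[1], x$focal[2], x$principal_point[1],
              x$principal_point[2], x$radial_distortion[1],
              x$radial_distortion[2], x$image_size[1], x$image_size[2]))
  invisible(x)
}

#' Camera centre in world coordinates
#' @param camera A \code{camera_params}.
#' @return Length-3 vector (mm).
#' @export
camera_center <- function(camera) {
  drop(-crossprod(camera$rotation, camera$translation))
}

apply_distortion <- function(xn, yn, k) {
  r2 <- xn^2 + yn^2
  s <- 1 + k[1] * r2 + k[2] * r2^2
  cbind(xn * s, yn * s)
}

# invert the radial model by fixed-point iteration on the undistorted radius
remove_distortion <- function(xd, yd, k, max_iter = 20, tol = 1e-12) {
  xn <- xd; yn <- yd
  for (i in seq_len(max_iter)) {
    r2 <- xn^2 + yn^2
    s <- 1 + k[1] * r2 + k[2] * r2^2
    xn_new <- xd / s; yn_new <- yd / s
    if (max(abs(xn_new - xn), abs(yn_new - yn)) < tol) {
      xn <- xn_new; yn <- yn_new
      break
    }
    xn <- xn_new; yn <- yn_new
  }
  cbind(xn, yn)
}

#' Project world points into a camera
#'
#' @param camera A \code{camera_params}.
#' @param point_world Length-3 vector or \code{n x 3} matrix of world points (mm).
#' @return Data frame with columns \code{u}, \code{v} (pixels), \code{depth}
#'   (mm along the optical axis) and \code{in_frame}.
#' @export
project <- function(camera, point_world) {
  P <- if (is.matrix(point_world)) point_world else matrix(point_world, ncol = 3)
  Xc <- P %*% t(camera$rotation) +
    matrix(camera$translation, nrow(P), 3, byrow = TRUE)
  if (any(Xc[, 3] <= 0)) stop("point behind camera (non-positive depth)")
  xn <- Xc[, 1] / Xc[, 3]
  yn <- Xc[, 2] / Xc[, 3]
  d <- apply_distortion(xn, yn, camera$radial_distortion)
  u <- camera$principal_point[1] + camera$focal[1] * d[, 1]
  v <- camera$principal_point[2] + camera$focal[2] * d[, 2]
  data.frame(u = u, v = v, depth = Xc[, 3],
             in_frame = u >= 0 & u < camera$image_size[1] &
                        v >= 0 & v < camera$image_size[2])
}

# back-project pixels to unit ray directions in world coordinates
pixel_rays <- function(camera, u, v) {
  xd <- (u - camera$principal_point[1]) / camera$focal[1]
  yd <- (v - camera$principal_point[2]) / camera$focal[2]
  n <- remove_distortion(xd, yd, camera$radial_distortion)
  dirs_cam <- cbind(n[, 1], n[, 2], 1)
  dirs <- dirs_cam %*% camera$rotation  # = t(R) %*% dir, per row
  dirs / sqrt(rowSums(dirs^2))
}

#' Triangulate a point (or a track) from two camera views
#'
#' Pixels are undistorted numerically, back-projected to rays, and each 3D
#' point is taken as the midpoint of the common perpendicular of the two rays
#' (linear least squares on the two ray parameters).  The mean reprojection
#' error over both views is reported per point.
#'
#' @param cam_a,cam_b \code{camera_params} for the two views.
#' @param obs_a,obs_b Data frames with columns \code{u}, \code{v} and
#'   optionally \code{frame}; rows are matched pairwise.  If \code{frame} is
#'   present in both it must agree row-wise.
#' @param min_ray_angle Minimum angle (radians) between the two rays below
#'   which the geometry is declared degenerate.
#' @return Data frame with \code{x}, \code{y}, \code{z} (mm) and
#'   \code{reproj_err} (pixels).
#' @export
triangulate <- function(cam_a, cam_b, obs_a, obs_b, min_ray_angle = 1e-4) {
  if (nrow(obs_a) != nrow(obs_b)) stop("observation lists differ in length")
  if (!is.null(obs_a$frame) && !is.null(obs_b$frame) &&
      any(obs_a$frame != obs_b$frame))
    stop("mismatched frame_index between views")
  Ca <- camera_center(cam_a); Cb <- camera_center(cam_b)
  da <- pixel_rays(cam_a, obs_a$u, obs_a$v)
  db <- pixel_rays(cam_b, obs_b$u, obs_b$v)
  b <- Cb - Ca
  # solve [1 -d; -d 1] style 2x2 normal equations for ray parameters s, t
  dd <- rowSums(da * db)
  det <- 1 - dd^2                       # = sin^2(angle) for unit rays
  if (any(det < sin(min_ray_angle)^2))
    stop("degenerate geometry: near-parallel rays")
  ba <- drop(da %*% b)
  bb <- drop(db %*% b)
  s <- (ba - dd * bb) / det
  t <- (dd * ba - bb) / det
  Pa <- matrix(Ca, nrow(da), 3, byrow = TRUE) + da * s
  Pb <- matrix(Cb, nrow(db), 3, byrow = TRUE) + db * t
  X <- (Pa + Pb) / 2
  pa <- project(cam_a, X); pb <- project(cam_b, X)
  err <- (sqrt((pa$u - obs_a$u)^2 + (pa$v - obs_a$v)^2) +
          sqrt((pb$u - obs_b$u)^2 + (pb$v - obs_b$v)^2)) / 2
  data.frame(x = X[, 1], y = X[, 2], z = X[, 3], reproj_err = err)
}

look_at_rotation <- function(center, target, up = c(0, 0, 1)) {
  zc <- target - center; zc <- zc / sqrt(sum(zc^2))
  xc <- c(zc[2] * up[3] - zc[3] * up[2],
          zc[3] * up[1] - zc[1] * up[3],
          zc[1] * up[2] - zc[2] * up[1])
  xc <- xc / sqrt(sum(xc^2))
  yc <- c(zc[2] * xc[3] - zc[3] * xc[2],
          zc[3] * xc[1] - zc[1] * xc[3],
          zc[1] * xc[2] - zc[2] * xc[1])
  rbind(xc, yc, zc)
}

#' The default synthetic stereo rig
#'
#' Two cameras mounted high above the up-tunnel end on opposing sides,
#' looking down the length of the tunnel at the obstacle field, with their
#' optical axes about 30 degrees off vertical — the configuration used to
#' film the experiment.  Exact poses, focal lengths and distortion are fixed
#' package constants chosen so the working section fills the frames.
#'
#' @param scene Optional \code{scene_spec}; the cameras aim at the centre of
#'   its obstacle field (defaults to the standard tunnel).
#' @return List with elements \code{a} and \code{b} (\code{camera_params})
#'   and \code{frame_rate} (Hz, default 500).
#' @export
default_stereo_rig <- function(scene = build_scene(69)) {
  target <- c(mean(scene$field_x_extent), 0, scene$tunnel_height / 2)
  mk <- function(center, id) {
    R <- look_at_rotation(center, target, up = c(-1, 0, 0))
    camera_params(focal = c(3000, 3000), principal_point = c(640, 480),
                  radial_distortion = c(-0.08, 0.01),
                  rotation = R, translation = drop(-R %*% center),
                  image_size = c(1280, 960), camera_id = id)
  }
  list(a = mk(c(1250, -300, 1500), "cam_a"),
       b = mk(c(1250,  300, 1500), "cam_b"),
       frame_rate = 500)
}

#' Read / write camera parameters as JSON
#'
#' One file per camera; keys mirror the \code{camera_params} fields, the
#' rotation stored row-major.
#' @param camera A \code{camera_params}.
#' @param path File path.
#' @export
write_camera_json <- function(camera, path) {
  x <- unclass(camera)
  x$rotation <- as.vector(t(x$rotation))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_camera_json
#' @export
read_camera_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  camera_params(focal = x$focal, principal_point = x$principal_point,
                radial_distortion = x$radial_distortion,
                rotation = matrix(x$rotation, 3, 3, byrow = TRUE),
                translation = x$translation, image_size = x$image_size,
                camera_id = x$camera_id)
}
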