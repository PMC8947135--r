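#' Tunnel and obstacle-field geometry
#'
#' The experimental arena is a rectangular flight tunnel containing a field of
#' vertical columns arranged in three longitudinal rows of five columns each,
#' leaving two unobstructed flight corridors between the rows.  All stages of
#' the pipeline share one world coordinate frame:
#' \itemize{
#'   \item \code{x}: longitudinal position along the tunnel axis (mm),
#'     down-tunnel positive, \code{0} at the down-tunnel end;
#'   \item \code{y}: lateral position (mm), tunnel centreline at \code{0};
#'   \item \code{z}: altitude above the floor (mm).
#' }
#' The frame is right-handed.  A \code{scene_spec} object records the tunnel
#' dimensions, the obstacle layout, and the excluded zone below the ceiling
#' within which flights are discarded.
#'
#' @param field_height Height of every column in the obstacle field (mm).
#'   The heights used in the experiment were 11, 40, 69, 98 and 127 mm; any
#'   positive height below the excluded zone is accepted.
#' @param overrides Named list overriding individual geometry defaults
#'   (\code{tunnel_width}, \code{tunnel_height}, \code{tunnel_length},
#'   \code{excluded_zone_depth}, \code{column_diameter}, \code{n_rows},
#'   \code{n_cols_per_row}, \code{corridor_width}, \code{field_x_extent}).
#'
#' @return An object of class \code{scene_spec}: a list with the geometry
#'   fields plus \code{column_positions}, an \code{n_rows * n_cols_per_row} by
#'   2 matrix of column axis locations \code{(x, y)}, and \code{control}, a
#'   flag marking fields too short for a bee to fly within.
#'
#' @details The middle row of columns sits on the tunnel centreline
#'   (\code{y = 0}); adjacent rows are separated so that the edge-to-edge gap
#'   between columns of neighbouring rows equals \code{corridor_width}.  The
#'   field occupies the central 40\% of the tunnel length by default, with the
#'   five columns per row evenly spaced across that extent.  An 11-mm field is
#'   flagged \code{control = TRUE}: it is shorter than a flying bee's body
#'   clearance, so "within" routes do not exist there.
#'
#' @examples
#' sc <- build_scene(127)
#' nrow(sc$column_positions)  # 15 columns
#' ceiling_clearance(sc)      # 64 mm of obstruction-free space below the ceiling
#' @export
build_scene <- function(field_height, overrides = list()) {
  spec <- list(
    tunnel_width = 200, tunnel_height = 191, tunnel_length = 1150,
    excluded_zone_depth = 15, field_height = field_height,
    column_diameter = 7, n_rows = 3, n_cols_per_row = 5,
    corridor_width = 57, field_x_extent = NULL
  )
  for (nm in names(overrides)) {
    if (!nm %in% names(spec)) stop("unknown scene override: ", nm)
    spec[[nm]] <- overrides[[nm]]
  }
  if (is.null(spec$field_x_extent)) {
    half <- 0.2 * spec$tunnel_length
    mid <- spec$tunnel_length / 2
    spec$field_x_extent <- c(mid - half, mid + half)
  }
  dims <- c(spec$tunnel_width, spec$tunnel_height, spec$tunnel_length,
            spec$column_diameter, spec$corridor_width)
  if (any(!is.finite(dims)) || any(dims <= 0))
    stop("scene dimensions must be positive")
  if (!is.finite(field_height) || field_height <= 0)
    stop("field_height must be positive")
  if (field_height >= spec$tunnel_height - spec$excluded_zone_depth)
    stop("field_height must leave obstruction-free space below the excluded zone")

  # rows are centre-to-centre corridor_width + column_diameter apart so the
  # edge-to-edge corridor gap equals corridor_width exactly
  row_pitch <- spec$corridor_width + spec$column_diameter
  row_idx <- seq_len(spec$n_rows) - (spec$n_rows + 1) / 2
  row_y <- row_idx * row_pitch
  col_x <- seq(spec$field_x_extent[1], spec$field_x_extent[2],
               length.out = spec$n_cols_per_row)
  pos <- cbind(x = rep(col_x, times = spec$n_rows),
               y = rep(row_y, each = spec$n_cols_per_row))
  r <- spec$column_diameter / 2
  if (any(abs(pos[, "y"]) + r > spec$tunnel_width / 2) ||
      any(pos[, "x"] < 0 | pos[, "x"] > spec$tunnel_length))
    stop("obstacle layout does not fit inside the tunnel footprint")
  spec$column_positions <- pos
  spec$control <- field_height <= 15  # too short to fly within
  class(spec) <- "scene_spec"
  spec
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("<scene_spec> tunnel %g x %g x %g mm (w x h x l)\n",
              x$tunnel_width, x$tunnel_height, x$tunnel_length))
  cat(sprintf("  obstacle field: %d columns (d = %g mm), height %g mm%s\n",
              nrow(x$column_positions), x$column_diameter, x$field_height,
              if (x$control) " [control: too short to fly within]" else ""))
  cat(sprintf("  corridors: %g mm; field x-extent [%g, %g] mm; excluded zone above %g mm\n",
              x$corridor_width, x$field_x_extent[1], x$field_x_extent[2],
              x$tunnel_height - x$excluded_zone_depth))
  invisible(x)
}

#' Obstruction-free vertical space below the ceiling
#'
#' @param scene A \code{scene_spec}.
#' @return Distance (mm) between the top of the obstacle field and the
#'   ceiling, e.g. 64 mm for the tallest (127 mm) field in the 191-mm tunnel.
#' @export
ceiling_clearance <- function(scene) {
  stopifnot(inherits(scene, "scene_spec"))
  scene$tunnel_height - scene$field_height
}

#' Horizontal clearance from a point to the nearest obstacle column
#'
#' Only columns that reach the query altitude matter: for \code{z} above the
#' field height there is nothing to collide with and \code{Inf} is returned.
#' A negative value means the point lies inside a column's footprint.
#'
#' @param scene A \code{scene_spec}.
#' @param point Numeric \code{(x, y, z)} in mm, or an \code{n x 3} matrix of
#'   points.
#' @return Clearance in mm (horizontal distance to the nearest column axis
#'   minus the column radius); vectorised over rows of \code{point}.
#' @export
distance_to_nearest_column <- function(scene, point) {
  stopifnot(inherits(scene, "scene_spec"))
  p <- if (is.matrix(point)) point else matrix(point, ncol = 3)
  stopifnot(ncol(p) == 3)
  r <- scene$column_diameter / 2
  cp <- scene$column_positions
  out <- vapply(seq_len(nrow(p)), function(i) {
    if (p[i, 3] > scene$field_height) return(Inf)
    d2 <- (cp[, 1] - p[i, 1])^2 + (cp[, 2] - p[i, 2])^2
    sqrt(min(d2)) - r
  }, numeric(1))
  out
}

#' Serialize / read a scene to JSON
#'
#' @param scene A \code{scene_spec}.
#' @param path File path.
#' @return \code{read_scene_json} returns a \code{scene_spec}.
#' @export
write_scene_json <- function(scene, path) {
  stopifnot(inherits(scene, "scene_spec"))
  x <- unclass(scene)
  x$column_positions <- NULL  # derived
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scene_json
#' @export
read_scene_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fh <- x$field_height
  x$field_height <- NULL
  x$control <- NULL
  build_scene(fh, overrides = x)
}
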