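# Metric, gravity-aligned calibration from the in-scene references.
#
# The scale rectangle of known physical length gives cm per pixel; the
# plumb line gives the gravitational vertical, from which a rotation is
# derived so that world coordinates are gravity-aligned (y up) regardless
# of camera roll.  A single global scale per image; no perspective or
# parallax correction.

#' Compute the image scale from the rectangle observation
#'
#' @param rect A `rectangle_observation` (see [detect_scale_rectangle()]).
#' @param known_length_cm Physical length of the rectangle's longer side;
#'   default 20 cm.
#' @return Scale in cm per pixel.
#' @export
#' @examples
#' rect <- structure(list(pixel_length = 400), class = "rectangle_observation")
#' compute_scale(rect)   # 0.05
compute_scale <- function(rect, known_length_cm = 20) {
  stopifnot(known_length_cm > 0)
  if (is.null(rect$pixel_length) || rect$pixel_length <= 0) {
    stop_pk("rectangle observation has non-positive pixel length",
            "bad_observation")
  }
  known_length_cm / rect$pixel_length
}

#' Build a calibration frame from the rectangle and plumb observations
#'
#' The calibration carries cm-per-pixel scale, the rotation (in degrees)
#' that maps the observed plumb direction onto the world vertical, and a
#' pixel origin (the rectangle center).  Rotation is constrained to
#' (-45, 45] degrees; positive rotation corresponds to a clockwise camera
#' roll on screen.
#'
#' @param rect A `rectangle_observation`, or `NULL` if detection failed.
#' @param plumb A `plumb_line_observation`, or `NULL` if detection failed.
#' @param known_length_cm Rectangle physical length (cm).
#' @return A `posture_calibration` list: `cm_per_px`, `rotation_deg`,
#'   `origin_px`.
#' @export
build_frame <- function(rect, plumb, known_length_cm = 20) {
  missing <- c(if (is.null(rect)) "scale rectangle",
               if (is.null(plumb)) "plumb line")
  if (length(missing) > 0) {
    stop_pk(paste0("calibration incomplete: ",
                   paste(missing, collapse = " and "), " not found"),
            "calibration_incomplete")
  }
  cm_per_px <- compute_scale(rect, known_length_cm)
  d <- plumb$direction
  rotation <- deg(atan2(-d[["x"]], d[["y"]]))
  if (rotation <= -45 || rotation > 45) {
    stop_pk(sprintf("implausible plumb rotation %.1f deg (expected within 45 deg of vertical)",
                    rotation), "implausible_rotation")
  }
  structure(list(cm_per_px = cm_per_px, rotation_deg = rotation,
                 origin_px = c(x = unname(rect$center[["x"]]),
                               y = unname(rect$center[["y"]]))),
            class = "posture_calibration")
}

#' Identity-like calibration (for landmark tables already in pixels)
#'
#' @param cm_per_px Scale; default 1.
#' @param rotation_deg Roll correction; default 0.
#' @param origin_px Pixel origin; default (0, 0).
#' @return A `posture_calibration`.
#' @export
manual_calibration <- function(cm_per_px = 1, rotation_deg = 0,
                               origin_px = c(x = 0, y = 0)) {
  stopifnot(cm_per_px > 0, rotation_deg > -45, rotation_deg <= 45)
  structure(list(cm_per_px = cm_per_px, rotation_deg = rotation_deg,
                 origin_px = c(x = unname(origin_px[1]),
                               y = unname(origin_px[2]))),
            class = "posture_calibration")
}

#' Convert pixel coordinates to world coordinates
#'
#' Applies the rigid de-rotation about the calibration origin, flips the
#' vertical axis (image y grows downward, world y grows upward) and scales
#' to cm.  Vertex angles between points are invariant under this map;
#' alignment angles against the world horizontal are corrected for camera
#' roll.
#'
#' @param points Two-column matrix or data frame of pixel (x, y)
#'   coordinates.
#' @param cal A `posture_calibration`.
#' @return A tibble with columns `x_cm`, `y_cm`.
#' @export
to_world <- function(points, cal) {
  stopifnot(inherits(cal, "posture_calibration"))
  p <- as.matrix(as.data.frame(points)[, 1:2])
  th <- rad(cal$rotation_deg)
  dx <- p[, 1] - cal$origin_px[["x"]]
  dy <- p[, 2] - cal$origin_px[["y"]]
  # rotate by -rotation so the plumb direction becomes the image vertical
  rx <- cos(th) * dx + sin(th) * dy
  ry <- -sin(th) * dx + cos(th) * dy
  tibble::tibble(x_cm = unname(rx * cal$cm_per_px),
                 y_cm = unname(-ry * cal$cm_per_px))
}

#' Serialize a calibration to JSON
#'
#' @param cal A `posture_calibration`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
calibration_to_json <- function(cal, path = NULL) {
  stopifnot(inherits(cal, "posture_calibration"))
  x <- list(cm_per_px = cal$cm_per_px, rotation_deg = cal$rotation_deg,
            origin_px = as.list(cal$origin_px))
  if (is.null(path)) {
    jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
    invisible(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  }
}

#' Read a calibration from JSON
#'
#' @param json JSON string or file path.
#' @return A `posture_calibration`.
#' @export
calibration_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  manual_calibration(x$cm_per_px, x$rotation_deg,
                     c(x = x$origin_px$x, y = x$origin_px$y))
}
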