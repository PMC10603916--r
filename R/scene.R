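# Synthetic scene generation.
#
# Emulates the photographic acquisition setup: a subject with green
# spherical markers on the template's anatomical sites, a blue rectangle of
# known length on the left of the frame, and a red plumb line (weighted
# string) on the right.  Every rendered primitive's true geometry is
# returned as ground truth, so detection, calibration and landmark
# assignment can be tested end to end.
#
# Image convention: 8-bit-equivalent RGB stored as a numeric array
# [height, width, 3] in [0, 1]; origin top-left, x right, y down, pixel
# centers at integer coordinates (column index = x, row index = y).

SCENE_PALETTE <- list(
  green = c(0.13, 0.70, 0.20),
  blue  = c(0.10, 0.25, 0.85),
  red   = c(0.85, 0.12, 0.10),
  gray  = c(0.82, 0.82, 0.82),
  white = c(0.97, 0.97, 0.97),
  red_background = c(0.80, 0.15, 0.12)
)

scene_color <- function(name) {
  if (is.numeric(name) && length(name) == 3) return(name)
  col <- SCENE_PALETTE[[name]]
  if (is.null(col)) stop_pk(paste0("unknown scene color '", name, "'"),
                            "bad_color")
  col
}

#' Specify a synthetic marker scene
#'
#' Describes one photographic view of a marked-up subject: the posture
#' template, image geometry, marker/reference object sizes and colors,
#' camera roll (which tilts the plumb line in the image), additive sensor
#' noise and occlusions.  The seed fully determines the rendered image.
#'
#' @param view View name, or a `posture_template` (whose view is used).
#' @param template Optional `posture_template`; defaults to the neutral
#'   template of `view`.
#' @param image_width,image_height Image size in pixels.
#' @param subject_height_cm Subject stature; the subject spans 85% of the
#'   image height.
#' @param marker_diameter_mm Marker diameter (spherical markers render as
#'   disks); default 20 mm.
#' @param rectangle_length_cm,rectangle_width_cm Scale rectangle dimensions;
#'   the known length (default 20 cm) is the longer side.
#' @param marker_color,rectangle_color,string_color,background Palette names
#'   (`"green"`, `"blue"`, `"red"`, `"gray"`, `"white"`,
#'   `"red_background"`) or RGB triples in \[0, 1\].
#' @param plumb_tilt_deg Camera roll in degrees: the whole scene is rotated
#'   about the image center so the plumb line appears tilted from the image
#'   vertical by this angle (positive = clockwise on screen).
#' @param noise_sd Gaussian intensity noise standard deviation in 8-bit
#'   units (0-255 scale).
#' @param occluded_sites Tibble with columns `site`, `side` (or character
#'   vector of `"site:side"` keys) of markers to leave unrendered.
#' @param seed Integer RNG seed for the noise field.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(view = "anterior", template = NULL,
                       image_width = 800, image_height = 1200,
                       subject_height_cm = 166.4,
                       marker_diameter_mm = 20,
                       rectangle_length_cm = 20, rectangle_width_cm = 4,
                       marker_color = "green", rectangle_color = "blue",
                       string_color = "red", background = "gray",
                       plumb_tilt_deg = 0, noise_sd = 0,
                       occluded_sites = NULL, seed = 1L) {
  if (inherits(view, "posture_template")) {
    template <- view
    view <- attr(template, "view")
  }
  view <- match.arg(view, POSTURE_VIEWS)
  if (is.null(template)) template <- posture_template(view)
  stopifnot(marker_diameter_mm > 0, rectangle_length_cm > 0,
            subject_height_cm > 0, image_width >= 64, image_height >= 64)
  if (is.character(occluded_sites)) {
    parts <- strsplit(occluded_sites, ":", fixed = TRUE)
    occluded_sites <- tibble::tibble(site = vapply(parts, `[[`, "", 1),
                                     side = vapply(parts, `[[`, "", 2))
  }
  if (!is.null(occluded_sites)) {
    missing <- dplyr::anti_join(occluded_sites, template,
                                by = c("site", "side"))
    if (nrow(missing) > 0) {
      stop_pk("occluded sites must be a subset of the template's sites",
              "bad_occlusion")
    }
  }
  structure(list(
    view = view, template = template,
    image_width = as.integer(image_width),
    image_height = as.integer(image_height),
    subject_height_cm = subject_height_cm,
    marker_diameter_mm = marker_diameter_mm,
    rectangle_length_cm = rectangle_length_cm,
    rectangle_width_cm = rectangle_width_cm,
    marker_color = marker_color, rectangle_color = rectangle_color,
    string_color = string_color, background = background,
    plumb_tilt_deg = plumb_tilt_deg, noise_sd = noise_sd,
    occluded_sites = occluded_sites, seed = as.integer(seed)
  ), class = "scene_spec")
}

# Map body-frame template coordinates to unrotated image pixel coordinates.
# Mirrored views flip the subject's x axis (image-left = subject-right).
template_to_image <- function(template, view, image_width, image_height,
                              subject_height_cm) {
  h_px <- 0.85 * image_height
  cm_per_px <- subject_height_cm / h_px
  feet_y <- 0.925 * image_height
  center_x <- 0.52 * image_width
  sgn <- if (view %in% MIRRORED_VIEWS) -1 else 1
  tibble::tibble(
    site = template$site, side = template$side,
    x_px = center_x + sgn * (template$x - 0.5) * h_px,
    y_px = feet_y - template$y * h_px
  ) |>
    dplyr::mutate(cm_per_px = cm_per_px)
}

rotate_about <- function(x, y, cx, cy, theta_deg) {
  th <- rad(theta_deg)
  dx <- x - cx; dy <- y - cy
  list(x = cx + dx * cos(th) - dy * sin(th),
       y = cy + dx * sin(th) + dy * cos(th))
}

# Anti-aliased shape coverage, returned as linear pixel indices into an
# h x w matrix plus per-pixel coverage in [0, 1] (linear falloff across a
# 1-px edge).  Shapes are composited channel-wise by the renderer.
disk_coverage <- function(cx, cy, r, h, w) {
  x0 <- max(1L, floor(cx - r - 2)); x1 <- min(w, ceiling(cx + r + 2))
  y0 <- max(1L, floor(cy - r - 2)); y1 <- min(h, ceiling(cy + r + 2))
  if (x0 > x1 || y0 > y1) return(NULL)
  xs <- x0:x1; ys <- y0:y1
  d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, `+`))
  cov <- clamp01(r + 0.5 - d)
  keep <- cov > 0
  idx <- outer(ys, (xs - 1L) * h, `+`)
  list(idx = idx[keep], cov = cov[keep])
}

# Filled rotated rectangle centered at (cx, cy): `len` along the axis
# `angle_deg` from the image vertical, `wid` across it.
rect_coverage <- function(cx, cy, len, wid, angle_deg, h, w) {
  th <- rad(angle_deg)
  hx <- abs(sin(th)) * len / 2 + abs(cos(th)) * wid / 2 + 2
  hy <- abs(cos(th)) * len / 2 + abs(sin(th)) * wid / 2 + 2
  x0 <- max(1L, floor(cx - hx)); x1 <- min(w, ceiling(cx + hx))
  y0 <- max(1L, floor(cy - hy)); y1 <- min(h, ceiling(cy + hy))
  if (x0 > x1 || y0 > y1) return(NULL)
  xs <- x0:x1; ys <- y0:y1
  ux <- -sin(th); uy <- cos(th)       # unit vector along the length
  vx <- cos(th);  vy <- sin(th)       # across
  dx <- outer(rep(1, length(ys)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(xs)))
  du <- abs(dx * ux + dy * uy)
  dv <- abs(dx * vx + dy * vy)
  cov <- clamp01(len / 2 + 0.5 - du) * clamp01(wid / 2 + 0.5 - dv)
  keep <- cov > 0
  idx <- outer(ys, (xs - 1L) * h, `+`)
  list(idx = idx[keep], cov = cov[keep])
}

#' Render a synthetic scene
#'
#' Rasterizes the scene described by a [scene_spec()]: one anti-aliased
#' filled disk per non-occluded marker, the scale rectangle, the plumb
#' line, and optional Gaussian sensor noise.  Ground-truth centroids are
#' the continuous disk centers (not rasterized centroids).
#'
#' @param spec A `scene_spec`.
#' @return A `posture_scene` list with elements `image` (numeric array
#'   height x width x 3 in \[0, 1\]) and `ground_truth` (list with the
#'   marker centroid table, rectangle and plumb endpoints, `cm_per_px` and
#'   `rotation_deg`).
#' @export
#' @examples
#' sc <- render_view(scene_spec("anterior", image_width = 320,
#'                              image_height = 480))
#' dim(sc$image)
render_view <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  w <- spec$image_width; h <- spec$image_height
  pts <- template_to_image(spec$template, spec$view, w, h,
                           spec$subject_height_cm)
  cm_per_px <- pts$cm_per_px[1]
  r_px <- (spec$marker_diameter_mm / 10) / cm_per_px / 2
  if (2 * r_px < 3) {
    stop_pk(sprintf(
      "markers render %.1f px wide (< 3 px) at %.3f cm/px; undetectable",
      2 * r_px, cm_per_px), "marker_too_small")
  }

  if (!is.null(spec$occluded_sites)) {
    vis <- dplyr::anti_join(pts, spec$occluded_sites, by = c("site", "side"))
  } else {
    vis <- pts
  }

  # reference objects (unrotated positions)
  rect_c <- c(0.10 * w, 0.45 * h)
  rect_len <- spec$rectangle_length_cm / cm_per_px
  rect_wid <- spec$rectangle_width_cm / cm_per_px
  plumb_x <- 0.92 * w
  plumb_y <- c(0.06 * h, 0.94 * h)
  plumb_wid <- 3

  # camera roll: rotate all scene content about the image center
  t <- spec$plumb_tilt_deg
  ctr <- c((w + 1) / 2, (h + 1) / 2)
  rot <- function(x, y) rotate_about(x, y, ctr[1], ctr[2], t)
  mk <- rot(vis$x_px, vis$y_px)
  rc <- rot(rect_c[1], rect_c[2])
  re1 <- rot(rect_c[1], rect_c[2] - (rect_len - 1) / 2)
  re2 <- rot(rect_c[1], rect_c[2] + (rect_len - 1) / 2)
  pe1 <- rot(plumb_x, plumb_y[1])
  pe2 <- rot(plumb_x, plumb_y[2])

  plumb_len <- plumb_y[2] - plumb_y[1]
  pc <- rot(plumb_x, mean(plumb_y))
  shapes <- c(
    list(c(list(col = scene_color(spec$rectangle_color)),
           rect_coverage(rc$x, rc$y, rect_len, rect_wid, t, h, w)),
         c(list(col = scene_color(spec$string_color)),
           rect_coverage(pc$x, pc$y, plumb_len, plumb_wid, t, h, w))),
    purrr::map(seq_along(mk$x), function(i) {
      c(list(col = scene_color(spec$marker_color)),
        disk_coverage(mk$x[i], mk$y[i], r_px, h, w))
    })
  )
  bg <- scene_color(spec$background)
  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) {
    plane <- matrix(bg[ch], h, w)
    for (s in shapes) {
      if (!is.null(s$idx)) {
        plane[s$idx] <- plane[s$idx] * (1 - s$cov) + s$col[ch] * s$cov
      }
    }
    img[, , ch] <- plane
  }

  if (spec$noise_sd > 0) {
    img <- with_preserved_seed(spec$seed, {
      clamp01(img + stats::rnorm(length(img), 0, spec$noise_sd / 255))
    })
  }

  gt <- list(
    markers = tibble::tibble(site = vis$site, side = vis$side,
                             x_px = mk$x, y_px = mk$y),
    rectangle_endpoints = rbind(c(re1$x, re1$y), c(re2$x, re2$y)),
    plumb_endpoints = rbind(c(pe1$x, pe1$y), c(pe2$x, pe2$y)),
    cm_per_px = cm_per_px,
    rotation_deg = t
  )
  structure(list(image = img, ground_truth = gt, spec = spec),
            class = "posture_scene")
}

#' Write a scene image as PNG
#'
#' @param scene A `posture_scene` (or plain image array).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scene_png <- function(scene, path) {
  img <- if (inherits(scene, "posture_scene")) scene$image else scene
  png::writePNG(img, path)
  invisible(path)
}

#' Read an RGB image
#'
#' Reads a PNG image into the package's array convention
#' (height x width x 3 in \[0, 1\]); alpha channels are dropped and
#' grayscale images replicated across channels.
#'
#' @param path PNG file path.
#' @return Numeric array height x width x 3.
#' @export
read_view_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  img
}
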