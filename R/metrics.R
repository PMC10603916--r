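# Anatomical feature computation.
#
# Every feature is one of four primitives evaluated on gravity-aligned
# world coordinates (cm, y up):
#   * alignment angle of a left-to-right segment against the horizontal
#     (signed; positive when the subject's anatomical right end is higher),
#   * unsigned angle between two lines (acute convention by default),
#   * unsigned angle at the vertex of a point triple,
#   * Euclidean distance in cm.
# Mirrored views (anterior, lateral right) have their world x negated so
# that +x is always the subject's anatomical right before any signed angle
# is taken.

#' Signed angle of a segment against the horizontal
#'
#' Angle in (-90, 90] degrees between the line through `p1` (left end) and
#' `p2` (right end) and the world horizontal; positive when the right end
#' is higher.  Points must be in the subject-frame world (x toward the
#' subject's anatomical right, y up).
#'
#' @param p1,p2 Numeric length-2 points (left end, right end).
#' @return Signed degrees.
#' @export
#' @examples
#' angle_to_horizontal(c(0, 0), c(20, -1))   # right end 1 cm lower
angle_to_horizontal <- function(p1, p2) {
  d <- c(p2[1] - p1[1], p2[2] - p1[2])
  if (all(d == 0)) stop_pk("coincident points", "degenerate_geometry")
  a <- deg(atan2(d[2], d[1]))
  if (a > 90) a <- a - 180
  if (a <= -90) a <- a + 180
  unname(a)
}

#' Unsigned angle at a vertex
#'
#' Angle at `b` of the triple (`a`, `b`, `c`) in \[0, 180\] degrees;
#' collinear points give 180.
#'
#' @param a,b,c Numeric length-2 points; `b` is the vertex.
#' @return Degrees in \[0, 180\].
#' @export
#' @examples
#' angle_at_vertex(c(0, 1), c(0, 0), c(1, 0))   # 90
angle_at_vertex <- function(a, b, c) {
  u <- c(a[1] - b[1], a[2] - b[2])
  v <- c(c[1] - b[1], c[2] - b[2])
  if (all(u == 0) || all(v == 0)) {
    stop_pk("vertex coincides with an endpoint", "degenerate_geometry")
  }
  # atan2 of cross and dot: numerically stable near 0 and 180
  unname(deg(atan2(abs(u[1] * v[2] - u[2] * v[1]),
                   u[1] * v[1] + u[2] * v[2])))
}

#' Unsigned angle between two lines
#'
#' Angle between the undirected lines `p1`-`p2` and `q1`-`q2`.  By the
#' default acute convention the result is in \[0, 90\] degrees (so left and
#' right versions of the same bilateral feature are comparable); with
#' `obtuse = TRUE` the raw angle between the directed segments in
#' \[0, 180\] is returned instead.
#'
#' @param p1,p2,q1,q2 Numeric length-2 points.
#' @param obtuse Report the \[0, 180\] angle between the directed segments.
#' @return Degrees.
#' @export
angle_between_lines <- function(p1, p2, q1, q2, obtuse = FALSE) {
  u <- c(p2[1] - p1[1], p2[2] - p1[2])
  v <- c(q2[1] - q1[1], q2[2] - q1[2])
  if (all(u == 0) || all(v == 0)) {
    stop_pk("degenerate line (coincident endpoints)", "degenerate_geometry")
  }
  a <- deg(atan2(abs(u[1] * v[2] - u[2] * v[1]), u[1] * v[1] + u[2] * v[2]))
  if (!obtuse && a > 90) a <- 180 - a
  unname(a)
}

#' Euclidean distance
#'
#' @param p1,p2 Numeric length-2 world points (cm).
#' @return Distance in cm.
#' @export
distance_cm <- function(p1, p2) {
  unname(sqrt((p2[1] - p1[1])^2 + (p2[2] - p1[2])^2))
}

# Resolve a point key ("site:side" or "mid(a,b)") to subject-frame world
# coordinates from a named coordinate lookup; NULL when unavailable.
resolve_point <- function(key, coords) {
  if (startsWith(key, "mid(")) {
    parts <- strsplit(sub("^mid\\((.*)\\)$", "\\1", key), ",",
                      fixed = TRUE)[[1]]
    a <- resolve_point(parts[1], coords)
    b <- resolve_point(parts[2], coords)
    if (is.null(a) || is.null(b)) return(NULL)
    return((a + b) / 2)
  }
  p <- coords[[key]]
  if (is.null(p) || anyNA(p)) return(NULL)
  p
}

# Subject-frame world coordinates of one view's landmark set as a named
# list of length-2 vectors.  Mirrored views get x negated so +x is the
# subject's anatomical right.
view_world_coords <- function(ls, cal, view) {
  present <- !is.na(ls$x_px)
  w <- to_world(cbind(ls$x_px[present], ls$y_px[present]), cal)
  sgn <- if (view %in% MIRRORED_VIEWS) -1 else 1
  keys <- site_key(ls$site[present], ls$side[present])
  stats::setNames(
    purrr::map(seq_along(keys), function(i) c(sgn * w$x_cm[i], w$y_cm[i])),
    keys)
}

#' Compute the 38 anatomical features
#'
#' Evaluates every feature of [feature_definitions()] from calibrated
#' landmark sets.  Features whose landmarks are missing (occluded markers
#' or absent views) are returned as `NA`, never imputed.
#'
#' @param views Named list mapping view names to `landmark_set` objects
#'   (any subset of the four views).
#' @param calibrations Named list mapping the same view names to
#'   `posture_calibration` objects, or a single calibration recycled for
#'   all views.
#' @param obtuse_line_angles Report line-pair angles on the \[0, 180\]
#'   medial convention instead of the default acute \[0, 90\].
#' @return A one-row tibble with the 38 feature columns; attribute
#'   `missing_features` lists the `NA` features.
#' @export
compute_features <- function(views, calibrations,
                             obtuse_line_angles = FALSE) {
  stopifnot(is.list(views), length(views) > 0)
  bad <- setdiff(names(views), POSTURE_VIEWS)
  if (length(bad) > 0) {
    stop_pk(paste0("unknown view(s): ", paste(bad, collapse = ", ")),
            "bad_view")
  }
  if (inherits(calibrations, "posture_calibration")) {
    calibrations <- stats::setNames(
      rep(list(calibrations), length(views)), names(views))
  }

  coords <- purrr::imap(views, function(ls, v) {
    view_world_coords(ls, calibrations[[v]], v)
  })

  defs <- feature_definitions()
  absent_views <- setdiff(unique(defs$view), names(views))
  if (length(absent_views) > 0) {
    warn_pk(paste0("view(s) absent, their features set to NA: ",
                   paste(absent_views, collapse = ", ")),
            "missing_view")
  }

  vals <- purrr::pmap_dbl(defs, function(feature, view, kind, points, ...) {
    cv <- coords[[view]]
    if (is.null(cv)) return(NA_real_)
    pts <- purrr::map(points, resolve_point, coords = cv)
    if (any(purrr::map_lgl(pts, is.null))) return(NA_real_)
    switch(kind,
      horizontal = angle_to_horizontal(pts[[1]], pts[[2]]),
      vertex     = angle_at_vertex(pts[[1]], pts[[2]], pts[[3]]),
      lines      = angle_between_lines(pts[[1]], pts[[2]], pts[[3]], pts[[4]],
                                       obtuse = obtuse_line_angles),
      distance   = distance_cm(pts[[1]], pts[[2]])
    )
  })

  out <- tibble::as_tibble(stats::setNames(as.list(vals), defs$feature))
  attr(out, "missing_features") <- defs$feature[is.na(vals)]
  out
}
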