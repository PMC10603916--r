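# Color thresholding and shape-filtered blob detection.
#
# Pipeline: an RGB image is thresholded in HSV space to isolate a color of
# interest; 8-connected components of the mask are measured with four shape
# descriptors (area, circularity, convexity, inertia ratio); components are
# kept or rejected by min/max bounds on each descriptor.  The same
# machinery detects the spherical markers (high circularity), the scale
# rectangle (large, low circularity) and the plumb line (extreme
# elongation, i.e. inertia ratio near 0).
#
# Hue convention: half-degrees (0-180), the common machine-vision scale for
# 8-bit hue channels.  Red may wrap around 0 and therefore carries two hue
# intervals.

#' Specify an HSV color range
#'
#' @param name Color label (informational).
#' @param h_ranges List of one or two `c(lo, hi)` hue intervals on the
#'   half-degree scale (0-180); two intervals allow red's wraparound.
#' @param s_min,v_min Minimum saturation and value in \[0, 1\].
#' @return A `color_spec` list.
#' @export
color_spec <- function(name, h_ranges, s_min = 0.3, v_min = 0.3) {
  if (is.numeric(h_ranges)) h_ranges <- list(h_ranges)
  for (r in h_ranges) {
    stopifnot(length(r) == 2, r[1] <= r[2], r[1] >= 0, r[2] <= 180)
  }
  stopifnot(s_min >= 0, s_min <= 1, v_min >= 0, v_min <= 1)
  structure(list(name = name, h_ranges = h_ranges,
                 s_min = s_min, v_min = v_min),
            class = "color_spec")
}

#' Default color specifications
#'
#' Green markers, blue scale rectangle and red plumb line.
#'
#' @return Named list of [color_spec()] objects.
#' @export
default_color_specs <- function() {
  list(
    green = color_spec("green", list(c(40, 80))),
    blue  = color_spec("blue",  list(c(100, 130))),
    red   = color_spec("red",   list(c(0, 10), c(170, 180)))
  )
}

#' Threshold an RGB image by color
#'
#' A pixel is selected iff its hue falls in one of the spec's hue intervals
#' and its saturation and value meet the spec's minima.  An empty mask is a
#' valid result.
#'
#' @param image Numeric array height x width x 3 in \[0, 1\].
#' @param color A [color_spec()].
#' @return Logical matrix height x width.
#' @export
threshold_color <- function(image, color) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3,
            inherits(color, "color_spec"))
  h <- dim(image)[1]; w <- dim(image)[2]
  rgb <- rbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
               as.vector(image[, , 3]))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  hue <- hsv[1, ] * 180
  in_h <- Reduce(`|`, lapply(color$h_ranges,
                             function(r) hue >= r[1] & hue <= r[2]))
  mask <- in_h & hsv[2, ] >= color$s_min & hsv[3, ] >= color$v_min
  matrix(mask, nrow = h, ncol = w)
}

# 8-connected component labeling: EBImage's fast 4-connected labeling
# followed by a union-find merge of diagonally adjacent labels.
label_components <- function(mask) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow = nrow(mask)))
  lab <- matrix(as.integer(lab), nrow = nrow(mask))
  n <- max(lab)
  if (n <= 1) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  diag_pairs <- function(a, b) {
    sel <- which(a > 0L & b > 0L & a != b)
    cbind(a[sel], b[sel])
  }
  pairs <- rbind(
    diag_pairs(lab[-h, -w], lab[-1, -1]),   # down-right
    diag_pairs(lab[-h, -1], lab[-1, -w])    # down-left
  )
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(n), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

# --- contour tracing -------------------------------------------------------

# Moore-neighbor boundary tracing on a pixel set given as (x, y) integer
# coordinates.  Returns the closed boundary polygon (pixel centers) in
# order.  Single pixels and straight 1-px lines are handled.
trace_boundary <- function(px) {
  x <- px[, 1]; y <- px[, 2]
  x0 <- min(x) - 2L; y0 <- min(y) - 2L    # 1-px background pad all around
  h <- max(y) - y0 + 2L; w <- max(x) - x0 + 2L
  m <- matrix(FALSE, h, w)
  m[cbind(y - y0, x - x0)] <- TRUE

  # start pixel: topmost, then leftmost
  start_r <- min(which(rowSums(m) > 0))
  start_c <- min(which(m[start_r, ]))
  # clockwise Moore neighborhood starting at W
  dr <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  cur <- c(start_r, start_c)
  b_dir <- 1L   # backtrack direction index (came from the west)
  path_r <- integer(0); path_c <- integer(0)
  seen <- new.env(hash = TRUE)
  repeat {
    key <- paste(cur[1], cur[2], b_dir)   # tracing state
    if (!is.null(seen[[key]])) break      # closed: state repeats
    assign(key, TRUE, envir = seen)
    path_r <- c(path_r, cur[1]); path_c <- c(path_c, cur[2])
    found <- FALSE
    for (s in 0:7) {
      d <- ((b_dir - 1L + s) %% 8L) + 1L
      nr <- cur[1] + dr[d]; nc <- cur[2] + dc[d]
      if (m[nr, nc]) {
        # next backtrack: the neighbor examined just before this one
        prev <- ((d - 2L) %% 8L) + 1L
        # direction from new pixel back to the last background neighbor
        br <- cur[1] + dr[prev] - nr; bc <- cur[2] + dc[prev] - nc
        b_dir <- which(dr == br & dc == bc)
        cur <- c(nr, nc)
        found <- TRUE
        break
      }
    }
    if (!found) break                     # isolated pixel
  }
  cbind(x = path_c + x0, y = path_r + y0)
}

# Perimeter of a closed pixel contour.  The staircase polygon through the
# boundary pixel centers overestimates smooth perimeters by ~5%, so the
# contour is smoothed with a circular moving average (window 5) before the
# polygon length is measured; short contours use the raw chain with
# diagonal steps counted as sqrt(2).
contour_perimeter <- function(contour) {
  n <- nrow(contour)
  if (n < 2) return(4)                  # lone pixel: unit-square boundary
  if (n < 10) {
    d <- contour - contour[c(2:n, 1), ]
    return(sum(sqrt(d[, 1]^2 + d[, 2]^2)))
  }
  k <- 2L  # window half-width
  idx <- function(off) ((seq_len(n) - 1L + off) %% n) + 1L
  sx <- rowMeans(vapply(-k:k, function(o) contour[idx(o), 1],
                        numeric(n)))
  sy <- rowMeans(vapply(-k:k, function(o) contour[idx(o), 2],
                        numeric(n)))
  dx <- sx - sx[c(2:n, 1)]
  dy <- sy - sy[c(2:n, 1)]
  sum(sqrt(dx^2 + dy^2))
}

gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) {
    t <- a %% b; a <- b; b <- t
  }
  a
}

# Number of lattice points inside or on a lattice polygon (Pick's theorem).
hull_lattice_count <- function(hx, hy) {
  n <- length(hx)
  nxt <- c(2:n, 1)
  a2 <- abs(sum(hx * hy[nxt] - hx[nxt] * hy))      # twice the area
  bpts <- sum(mapply(gcd2, hx[nxt] - hx, hy[nxt] - hy))
  if (bpts == 0) bpts <- n                          # degenerate tiny hull
  a2 / 2 + bpts / 2 + 1
}

#' Shape descriptors of a pixel set
#'
#' Computes area (pixel count), perimeter (smoothed outer contour),
#' circularity `4*pi*area/perimeter^2`, convexity (area over convex-hull
#' area, hull area counted in lattice pixels via Pick's theorem) and
#' inertia ratio (square root of the ratio of the second-central-moment
#' eigenvalues: 1 for a circle, 0 for a line).  Circularity and convexity
#' are clamped to \[0, 1\]; a digitized circle can slightly exceed 1 before
#' clamping.
#'
#' @param pixels Two-column matrix of pixel (x, y) coordinates.
#' @return A one-row tibble with columns `x`, `y` (centroid), `area`,
#'   `perimeter`, `circularity`, `convexity`, `inertia_ratio`.
#' @export
#' @examples
#' g <- expand.grid(x = 1:40, y = 1:40)
#' disk <- as.matrix(g[(g$x - 20)^2 + (g$y - 20)^2 <= 15^2, ])
#' shape_descriptors(disk)
shape_descriptors <- function(pixels) {
  pixels <- as.matrix(pixels)
  stopifnot(ncol(pixels) == 2)
  n <- nrow(pixels)
  x <- pixels[, 1]; y <- pixels[, 2]
  cx <- mean(x); cy <- mean(y)

  contour <- trace_boundary(pixels)
  per <- contour_perimeter(contour)
  circ <- clamp01(4 * pi * n / per^2)

  if (n >= 3) {
    hull <- grDevices::chull(x, y)
    hull_area <- hull_lattice_count(x[hull], y[hull])
  } else {
    hull_area <- n
  }
  conv <- clamp01(n / hull_area)

  mxx <- mean((x - cx)^2)
  myy <- mean((y - cy)^2)
  mxy <- mean((x - cx) * (y - cy))
  tr <- mxx + myy
  disc <- sqrt(max(0, (mxx - myy)^2 + 4 * mxy^2))
  lmax <- (tr + disc) / 2
  lmin <- (tr - disc) / 2
  inertia <- if (lmax <= 0) 0 else clamp01(sqrt(max(0, lmin) / lmax))

  tibble::tibble(x = cx, y = cy, area = as.numeric(n), perimeter = per,
                 circularity = circ, convexity = conv,
                 inertia_ratio = inertia)
}

#' Shape descriptors of a polygon
#'
#' Continuous analogue of [shape_descriptors()] for a simple polygon given
#' by its vertices: exact area (Green's theorem), edge-length perimeter,
#' convexity against the convex hull and inertia ratio from the exact
#' polygon second central moments.
#'
#' @param vertices Two-column matrix of (x, y) vertices in order (closed
#'   implicitly).
#' @return A one-row tibble as in [shape_descriptors()].
#' @export
polygon_shape_descriptors <- function(vertices) {
  v <- as.matrix(vertices)
  stopifnot(ncol(v) == 2, nrow(v) >= 3)
  mom <- polygon_moments(v)
  per <- {
    d <- v - v[c(2:nrow(v), 1), , drop = FALSE]
    sum(sqrt(d[, 1]^2 + d[, 2]^2))
  }
  circ <- clamp01(4 * pi * mom$area / per^2)
  hull <- grDevices::chull(v[, 1], v[, 2])
  hull_mom <- polygon_moments(v[hull, , drop = FALSE])
  conv <- clamp01(mom$area / hull_mom$area)
  tr <- mom$sxx + mom$syy
  disc <- sqrt(max(0, (mom$sxx - mom$syy)^2 + 4 * mom$sxy^2))
  lmax <- (tr + disc) / 2
  lmin <- (tr - disc) / 2
  inertia <- if (lmax <= 0) 0 else clamp01(sqrt(max(0, lmin) / lmax))
  tibble::tibble(x = mom$cx, y = mom$cy, area = mom$area, perimeter = per,
                 circularity = circ, convexity = conv,
                 inertia_ratio = inertia)
}

# Area, centroid and normalized second central moments of a simple polygon
# via Green's-theorem edge accumulation.
polygon_moments <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  n <- length(x)
  nxt <- c(2:n, 1)
  cr <- x * y[nxt] - x[nxt] * y
  a <- sum(cr) / 2
  if (a < 0) {           # enforce counter-clockwise orientation
    v <- v[n:1, , drop = FALSE]
    return(polygon_moments(v))
  }
  if (a == 0) {
    return(list(area = 0, cx = mean(x), cy = mean(y),
                sxx = 0, syy = 0, sxy = 0))
  }
  cx <- sum((x + x[nxt]) * cr) / (6 * a)
  cy <- sum((y + y[nxt]) * cr) / (6 * a)
  ixx <- sum((y^2 + y * y[nxt] + y[nxt]^2) * cr) / 12
  iyy <- sum((x^2 + x * x[nxt] + x[nxt]^2) * cr) / 12
  ixy <- sum((x * y[nxt] + 2 * x * y + 2 * x[nxt] * y[nxt] + x[nxt] * y) *
               cr) / 24
  list(area = a, cx = cx, cy = cy,
       sxx = iyy / a - cx^2,            # variance along x
       syy = ixx / a - cy^2,
       sxy = ixy / a - cx * cy)
}

#' Blob filter parameters
#'
#' Min/max bounds on the four shape descriptors used to accept a connected
#' component as a marker blob.  Defaults accept a 20 mm spherical marker at
#' typical acquisition scales and reject the scale rectangle and the plumb
#' line.
#'
#' @param min_area,max_area Area bounds in px^2.
#' @param min_circularity,max_circularity Circularity bounds in \[0, 1\].
#' @param min_convexity,max_convexity Convexity bounds in \[0, 1\].
#' @param min_inertia_ratio,max_inertia_ratio Inertia-ratio bounds in
#'   \[0, 1\].
#' @return A `blob_filter_params` list.
#' @export
blob_filter_params <- function(min_area = 80, max_area = 8000,
                               min_circularity = 0.6, max_circularity = 1,
                               min_convexity = 0.85, max_convexity = 1,
                               min_inertia_ratio = 0.4,
                               max_inertia_ratio = 1) {
  p <- list(min_area = min_area, max_area = max_area,
            min_circularity = min_circularity,
            max_circularity = max_circularity,
            min_convexity = min_convexity, max_convexity = max_convexity,
            min_inertia_ratio = min_inertia_ratio,
            max_inertia_ratio = max_inertia_ratio)
  stopifnot(min_area <= max_area, min_circularity <= max_circularity,
            min_convexity <= max_convexity,
            min_inertia_ratio <= max_inertia_ratio,
            min_circularity >= 0, max_circularity <= 1,
            min_convexity >= 0, max_convexity <= 1,
            min_inertia_ratio >= 0, max_inertia_ratio <= 1)
  structure(p, class = "blob_filter_params")
}

# Shape descriptors of every connected component of a mask, ordered by
# centroid (y, then x).
component_descriptors <- function(mask) {
  lab <- label_components(mask)
  n <- max(lab)
  if (n == 0) {
    return(tibble::tibble(x = numeric(0), y = numeric(0), area = numeric(0),
                          perimeter = numeric(0), circularity = numeric(0),
                          convexity = numeric(0), inertia_ratio = numeric(0)))
  }
  idx <- which(lab > 0, arr.ind = TRUE)
  labs <- lab[lab > 0]
  comps <- split.data.frame(idx, labs)
  rows <- purrr::map(comps, function(rc) {
    shape_descriptors(cbind(x = rc[, 2], y = rc[, 1]))
  })
  dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$y, .data$x)
}

#' Detect marker blobs in a binary mask
#'
#' Labels 8-connected components, measures the four shape descriptors and
#' keeps components passing every filter bound.  Components touching the
#' image border are kept.  Output order is deterministic (centroid y, then
#' x).
#'
#' @param mask Logical matrix (e.g. from [threshold_color()]).
#' @param params A [blob_filter_params()].
#' @return A tibble of blobs with columns `x`, `y`, `area`, `perimeter`,
#'   `circularity`, `convexity`, `inertia_ratio`.
#' @export
detect_blobs <- function(mask, params = blob_filter_params()) {
  stopifnot(inherits(params, "blob_filter_params"))
  comps <- component_descriptors(mask)
  dplyr::filter(
    comps,
    .data$area >= params$min_area, .data$area <= params$max_area,
    .data$circularity >= params$min_circularity,
    .data$circularity <= params$max_circularity,
    .data$convexity >= params$min_convexity,
    .data$convexity <= params$max_convexity,
    .data$inertia_ratio >= params$min_inertia_ratio,
    .data$inertia_ratio <= params$max_inertia_ratio
  )
}

#' Detect the scale rectangle
#'
#' Finds the single largest low-circularity component of the rectangle
#' color.  Its pixel length is the extent along the principal axis (the
#' longer side of the minimum rotated bounding box for a rectangle).
#'
#' @param image RGB image array.
#' @param color A [color_spec()]; default blue.
#' @param min_area Minimum candidate area in px^2.
#' @param max_circularity Maximum candidate circularity (rectangles of the
#'   deployed aspect ratio are well below circles).
#' @param ambiguity_ratio A second candidate whose area exceeds this
#'   fraction of the best candidate's area triggers an ambiguity error.
#' @return A `rectangle_observation` list: `center`, `endpoints` (2 x 2
#'   matrix of major-axis endpoints), `pixel_length`.
#' @export
detect_scale_rectangle <- function(image,
                                   color = default_color_specs()$blue,
                                   min_area = 300, max_circularity = 0.75,
                                   ambiguity_ratio = 0.8) {
  mask <- threshold_color(image, color)
  lab <- label_components(mask)
  if (max(lab) == 0) {
    stop_pk("scale reference not found: no component of the rectangle color",
            "scale_not_found")
  }
  idx <- which(lab > 0, arr.ind = TRUE)
  comps <- split.data.frame(idx, lab[lab > 0])
  cand <- purrr::keep(comps, function(rc) {
    if (nrow(rc) < min_area) return(FALSE)
    d <- shape_descriptors(cbind(x = rc[, 2], y = rc[, 1]))
    d$circularity <= max_circularity
  })
  if (length(cand) == 0) {
    stop_pk("scale reference not found: no qualifying low-circularity component",
            "scale_not_found")
  }
  areas <- vapply(cand, nrow, integer(1))
  ord <- order(areas, decreasing = TRUE)
  if (length(cand) > 1 && areas[ord[2]] >= ambiguity_ratio * areas[ord[1]]) {
    centers <- vapply(cand[ord[1:2]], function(rc) {
      c(mean(rc[, 2]), mean(rc[, 1]))
    }, numeric(2))
    stop_pk(paste0("ambiguous scale reference: candidates at (",
                   paste(sprintf("%.0f,%.0f", centers[1, ], centers[2, ]),
                         collapse = ") and ("), ")"),
            "ambiguous_scale")
  }
  rc <- cand[[ord[1]]]
  axis_observation(cbind(x = rc[, 2], y = rc[, 1]), "rectangle_observation")
}

#' Detect the plumb line
#'
#' Finds the most elongated component of the string color (inertia ratio at
#' or below `max_inertia_ratio`).  When the background shares the string's
#' color the string merges into one compact blob and no qualifying
#' component exists: the red-on-red failure mode.
#'
#' @param image RGB image array.
#' @param color A [color_spec()]; default red (two hue intervals).
#' @param min_area Minimum candidate area in px^2.
#' @param max_inertia_ratio Elongation threshold; a component must be at
#'   least this line-like to qualify.
#' @return A `plumb_line_observation` list: `direction` (unit vector with
#'   positive y-descending component, image frame), `endpoints`,
#'   `inertia_ratio`.
#' @export
detect_plumb_line <- function(image, color = default_color_specs()$red,
                              min_area = 200, max_inertia_ratio = 0.1) {
  mask <- threshold_color(image, color)
  lab <- label_components(mask)
  best <- NULL; best_inertia <- Inf
  if (max(lab) > 0) {
    idx <- which(lab > 0, arr.ind = TRUE)
    comps <- split.data.frame(idx, lab[lab > 0])
    for (rc in comps) {
      if (nrow(rc) < min_area) next
      d <- shape_descriptors(cbind(x = rc[, 2], y = rc[, 1]))
      if (d$inertia_ratio <= max_inertia_ratio &&
            d$inertia_ratio < best_inertia) {
        best <- rc; best_inertia <- d$inertia_ratio
      }
    }
  }
  if (is.null(best)) {
    stop_pk(paste("plumb line not found: no sufficiently elongated component",
                  "of the string color (is the background the same color as",
                  "the string?)"),
            "plumb_not_found")
  }
  obs <- axis_observation(cbind(x = best[, 2], y = best[, 1]),
                          "plumb_line_observation")
  obs$inertia_ratio <- best_inertia
  obs
}

# Principal-axis observation of a pixel set: centroid, major-axis unit
# vector (oriented y-descending), extent endpoints and pixel length.
axis_observation <- function(px, class) {
  x <- px[, 1]; y <- px[, 2]
  cx <- mean(x); cy <- mean(y)
  mxx <- mean((x - cx)^2); myy <- mean((y - cy)^2)
  mxy <- mean((x - cx) * (y - cy))
  ev <- eigen(matrix(c(mxx, mxy, mxy, myy), 2), symmetric = TRUE)
  u <- ev$vectors[, 1]
  if (u[2] < 0) u <- -u                 # image frame: y grows downward
  # principal-axis span of the pixel centers; with anti-aliased edges the
  # thresholded set reaches the physical edge, so no half-pixel inflation
  proj <- (x - cx) * u[1] + (y - cy) * u[2]
  len <- max(proj) - min(proj)
  e1 <- c(cx, cy) + u * min(proj)
  e2 <- c(cx, cy) + u * max(proj)
  structure(list(center = c(x = cx, y = cy), direction = c(x = u[1], y = u[2]),
                 endpoints = rbind(e1, e2), pixel_length = len),
            class = class)
}
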