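green <- default_color_specs()$green
blue <- default_color_specs()$blue
red <- default_color_specs()$red

solid_image <- function(h, w, rgb) {
  array(rep(rgb, each = h * w), dim = c(h, w, 3))
}

test_that("color thresholding selects exactly the in-range pixels", {
  img <- solid_image(20, 30, c(0.13, 0.7, 0.2))
  expect_true(all(threshold_color(img, green)))
  expect_false(any(threshold_color(img, blue)))
  # white background is excluded by the saturation floor
  img2 <- solid_image(10, 10, c(0.97, 0.97, 0.97))
  expect_false(any(threshold_color(img2, green)))
})

test_that("a green disk on white yields a pixel count close to its area", {
  h <- 80; w <- 80; r <- 20
  img <- solid_image(h, w, c(1, 1, 1))
  cov <- posturekit:::disk_coverage(40, 40, r, h, w)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[cov$idx] <- plane[cov$idx] * (1 - cov$cov) +
      c(0.13, 0.7, 0.2)[ch] * cov$cov
    img[, , ch] <- plane
  }
  mask <- threshold_color(img, green)
  expect_equal(sum(mask), pi * r^2, tolerance = 0.03)
})

test_that("thresholding is idempotent on its own positive pixels", {
  sc <- render_view(scene_spec("anterior", noise_sd = 1.5, seed = 4))
  mask <- threshold_color(sc$image, green)
  img2 <- sc$image
  for (ch in 1:3) {
    plane <- img2[, , ch]
    plane[!mask] <- 0                      # black out everything else
    img2[, , ch] <- plane
  }
  expect_identical(threshold_color(img2, green), mask)
})

test_that("descriptors approach their circle limits on a digitized circle", {
  d <- shape_descriptors(raster_disk(60.3, 55.7, 50))
  expect_gte(d$circularity, 0.95)
  expect_gte(d$inertia_ratio, 0.95)
  expect_gte(d$convexity, 0.98)
  expect_equal(d$x, 60.3, tolerance = 0.05)
  expect_equal(d$y, 55.7, tolerance = 0.05)
})

test_that("square circularity is near pi/4 and bar inertia near its side ratio", {
  sq <- as.matrix(expand.grid(x = 1:100, y = 1:100))
  expect_equal(shape_descriptors(sq)$circularity, pi / 4, tolerance = 0.05)
  bar <- as.matrix(expand.grid(x = 1:100, y = 1:10))
  expect_equal(shape_descriptors(bar)$inertia_ratio, 0.1, tolerance = 0.005)
  # degenerate 1-px-wide component: inertia exactly 0, no error
  line <- cbind(x = 1:30, y = rep(4, 30))
  expect_equal(shape_descriptors(line)$inertia_ratio, 0)
})

test_that("polygon descriptors match independent brute-force oracles", {
  withr::local_seed(421)
  for (i in 1:200) {
    v <- random_convex_polygon(n = sample(6:20, 1))
    got <- polygon_shape_descriptors(v)
    a <- oracle_polygon_area(v)
    per <- oracle_polygon_perimeter(v)
    cov <- oracle_polygon_covariance(v)
    ev <- eigen(matrix(c(cov$sxx, cov$sxy, cov$sxy, cov$syy), 2),
                symmetric = TRUE, only.values = TRUE)$values
    expect_equal(got$area, a, tolerance = 1e-6)
    expect_equal(got$perimeter, per, tolerance = 1e-6)
    expect_equal(got$circularity, min(1, 4 * pi * a / per^2),
                 tolerance = 1e-6)
    expect_equal(got$convexity, 1, tolerance = 1e-6)  # convex input
    expect_equal(got$inertia_ratio, sqrt(max(0, ev[2]) / ev[1]),
                 tolerance = 1e-6)
    expect_equal(got$x, cov$cx, tolerance = 1e-6)
    expect_equal(got$y, cov$cy, tolerance = 1e-6)
  }
})

test_that("blob detection counts, locates and filters disks correctly", {
  mask <- matrix(FALSE, 120, 200)
  centers <- rbind(c(40, 30.2), c(100.5, 60), c(160, 90))
  for (i in 1:3) {
    px <- raster_disk(centers[i, 1], centers[i, 2], 10)
    mask[cbind(px[, 2], px[, 1])] <- TRUE
  }
  blobs <- detect_blobs(mask, blob_filter_params(min_area = 200,
                                                 max_area = 500))
  expect_equal(nrow(blobs), 3)
  ord <- order(centers[, 2], centers[, 1])
  expect_equal(blobs$x, centers[ord, 1], tolerance = 0.5)
  expect_equal(blobs$y, centers[ord, 2], tolerance = 0.5)
  # area filter rejection: min above the disk area
  expect_equal(nrow(detect_blobs(mask, blob_filter_params(min_area = 400))),
               0)
})

test_that("the inertia filter separates bars from disks", {
  mask <- matrix(FALSE, 60, 140)
  mask[20:29, 21:120] <- TRUE              # 100 x 10 bar
  p_strict <- blob_filter_params(min_area = 1, min_circularity = 0,
                                 min_convexity = 0, min_inertia_ratio = 0.4)
  p_loose <- blob_filter_params(min_area = 1, min_circularity = 0,
                                min_convexity = 0, min_inertia_ratio = 0.05)
  expect_equal(nrow(detect_blobs(mask, p_strict)), 0)
  expect_equal(nrow(detect_blobs(mask, p_loose)), 1)
})

test_that("loosening any single filter bound never decreases the blob count", {
  withr::local_seed(77)
  mask <- matrix(FALSE, 150, 150)
  for (i in 1:6) {
    r <- sample(3:12, 1)
    px <- raster_disk(runif(1, 20, 130), runif(1, 20, 130), r)
    mask[cbind(px[, 2], px[, 1])] <- TRUE
  }
  base <- blob_filter_params(min_area = 100, max_area = 300,
                             min_circularity = 0.7, max_circularity = 0.95,
                             min_convexity = 0.9, max_convexity = 0.99,
                             min_inertia_ratio = 0.5,
                             max_inertia_ratio = 0.95)
  n0 <- nrow(detect_blobs(mask, base))
  looser <- list(
    list(min_area = 1), list(max_area = 1e5),
    list(min_circularity = 0), list(max_circularity = 1),
    list(min_convexity = 0), list(max_convexity = 1),
    list(min_inertia_ratio = 0), list(max_inertia_ratio = 1))
  for (ch in looser) {
    p <- utils::modifyList(unclass(base), ch)
    p <- do.call(blob_filter_params, p)
    expect_gte(nrow(detect_blobs(mask, p)), n0)
  }
})

test_that("8-connectivity keeps anti-aliased diagonal pixels together", {
  m <- matrix(FALSE, 6, 6)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE; m[4, 4] <- TRUE
  lab <- posturekit:::label_components(m)
  expect_equal(max(lab), 1)
})

test_that("the scale rectangle is measured to within 1% of its length", {
  sc <- render_view(scene_spec("anterior", seed = 6))
  rect <- detect_scale_rectangle(sc$image)
  true_len <- 20 / sc$ground_truth$cm_per_px
  expect_equal(rect$pixel_length, true_len, tolerance = 0.01)
  # endpoint geometry consistent with the ground truth
  gt_ep <- sc$ground_truth$rectangle_endpoints
  d <- sqrt(rowSums((rect$endpoints - gt_ep)^2))
  expect_lt(max(d), 2)
})

test_that("missing or ambiguous rectangles raise distinct errors", {
  img <- solid_image(60, 60, c(0.82, 0.82, 0.82))
  expect_error(detect_scale_rectangle(img),
               class = "posturekit_error_scale_not_found")
  # two equal blue rectangles
  img2 <- img <- solid_image(200, 200, c(0.82, 0.82, 0.82))
  for (cx in c(50, 150)) {
    cov <- posturekit:::rect_coverage(cx, 100, 120, 24, 0, 200, 200)
    for (ch in 1:3) {
      plane <- img2[, , ch]
      plane[cov$idx] <- plane[cov$idx] * (1 - cov$cov) +
        c(0.10, 0.25, 0.85)[ch] * cov$cov
      img2[, , ch] <- plane
    }
  }
  expect_error(detect_scale_rectangle(img2),
               class = "posturekit_error_ambiguous_scale")
})

test_that("the plumb direction is recovered to 0.2 degrees", {
  sc <- render_view(scene_spec("anterior", plumb_tilt_deg = 2, seed = 7))
  plumb <- detect_plumb_line(sc$image)
  ang <- atan2(-plumb$direction[["x"]], plumb$direction[["y"]]) * 180 / pi
  expect_equal(ang, 2, tolerance = 0.1)
  expect_lte(plumb$inertia_ratio, 0.1)
  # perfectly vertical plumb
  sc0 <- render_view(scene_spec("anterior", seed = 8))
  p0 <- detect_plumb_line(sc0$image)
  expect_equal(unname(p0$direction), c(0, 1), tolerance = 2e-3)
})

test_that("a red background makes the plumb line undetectable", {
  sc <- render_view(scene_spec("anterior", background = "red_background",
                               seed = 9))
  expect_error(detect_plumb_line(sc$image),
               class = "posturekit_error_plumb_not_found")
  # markers and the rectangle are still detected on that background
  expect_equal(nrow(detect_blobs(threshold_color(sc$image, green))),
               nrow(required_sites("anterior")))
  expect_no_error(detect_scale_rectangle(sc$image))
})
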