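# Shared fixtures and independent oracles, built in code at test time.

all_view_names <- c("anterior", "posterior", "lateral_left", "lateral_right")

# Rasterize a disk: pixel centers within radius r of (cx, cy).
raster_disk <- function(cx, cy, r, pad = 3) {
  xs <- floor(cx - r - pad):ceiling(cx + r + pad)
  ys <- floor(cy - r - pad):ceiling(cy + r + pad)
  g <- expand.grid(x = xs, y = ys)
  as.matrix(g[(g$x - cx)^2 + (g$y - cy)^2 <= r^2, c("x", "y")])
}

# Random convex polygon: convex hull of points on a random ellipse.
random_convex_polygon <- function(n = 12, scale = 50) {
  th <- sort(stats::runif(n, 0, 2 * pi))
  a <- stats::runif(1, 0.3, 1) * scale
  b <- stats::runif(1, 0.3, 1) * scale
  rot <- stats::runif(1, 0, pi)
  x0 <- a * cos(th); y0 <- b * sin(th)
  x <- x0 * cos(rot) - y0 * sin(rot) + stats::runif(1, -10, 10)
  y <- x0 * sin(rot) + y0 * cos(rot) + stats::runif(1, -10, 10)
  h <- grDevices::chull(x, y)
  cbind(x = x[h], y = y[h])
}

# --- independent polygon oracles (triangle-fan decomposition) --------------

# Shoelace area via triangle fan from the first vertex.
oracle_polygon_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  n <- nrow(v)
  s <- 0
  for (i in 2:(n - 1)) {
    s <- s + ((x[i] - x[1]) * (y[i + 1] - y[1]) -
                (x[i + 1] - x[1]) * (y[i] - y[1])) / 2
  }
  abs(s)
}

# Exact second central moments by triangle-fan integration: each triangle's
# covariance about its own centroid is known in closed form.
oracle_polygon_covariance <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  n <- nrow(v)
  A_tot <- 0; cx_tot <- 0; cy_tot <- 0
  sxx <- 0; syy <- 0; sxy <- 0
  tris <- list()
  for (i in 2:(n - 1)) {
    p1 <- v[1, ]; p2 <- v[i, ]; p3 <- v[i + 1, ]
    a <- ((p2[1] - p1[1]) * (p3[2] - p1[2]) -
            (p3[1] - p1[1]) * (p2[2] - p1[2])) / 2
    cx <- (p1[1] + p2[1] + p3[1]) / 3
    cy <- (p1[2] + p2[2] + p3[2]) / 3
    tris[[i - 1]] <- list(a = a, cx = cx, cy = cy, p = rbind(p1, p2, p3))
    A_tot <- A_tot + a
    cx_tot <- cx_tot + a * cx
    cy_tot <- cy_tot + a * cy
  }
  cx_tot <- cx_tot / A_tot; cy_tot <- cy_tot / A_tot
  for (t in tris) {
    p <- t$p
    # second moment of a triangle about its centroid:
    # Ixx = A/36 * sum over vertex differences; use the direct formula
    # E[uu'] over the triangle = (1/12) * sum_i sum_j (vi - c)(vj - c)' for
    # i = j plus cross terms: cov = (1/12) * sum_i (vi - c)(vi - c)'  ...
    dx <- p[, 1] - t$cx; dy <- p[, 2] - t$cy
    ixx <- sum(dx^2) / 12
    iyy <- sum(dy^2) / 12
    ixy <- sum(dx * dy) / 12
    dcx <- t$cx - cx_tot; dcy <- t$cy - cy_tot
    sxx <- sxx + t$a * (ixx + dcx^2)
    syy <- syy + t$a * (iyy + dcy^2)
    sxy <- sxy + t$a * (ixy + dcx * dcy)
  }
  list(area = unname(A_tot), cx = unname(cx_tot), cy = unname(cy_tot),
       sxx = unname(sxx / A_tot), syy = unname(syy / A_tot),
       sxy = unname(sxy / A_tot))
}

oracle_polygon_perimeter <- function(v) {
  n <- nrow(v)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    s <- s + sqrt(sum((v[j, ] - v[i, ])^2))
  }
  s
}

# Brute-force optimal assignment over all permutations (n <= 8).
brute_force_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(n == ncol(cost), n <= 8)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  best <- NULL; best_cost <- Inf
  for (p in perms(seq_len(n))) {
    cc <- sum(cost[cbind(seq_len(n), p)])
    if (cc < best_cost) {
      best_cost <- cc; best <- p
    }
  }
  list(assignment = best, cost = best_cost)
}

# Simple Gaussian two/three-class datasets for classifier tests.
gaussian_classes <- function(n_per_class, means, sd = 1, p = 2,
                             labels = NULL) {
  if (is.null(labels)) labels <- paste0("c", seq_along(n_per_class))
  rows <- purrr::map2(n_per_class, seq_along(n_per_class), function(n, i) {
    m <- matrix(stats::rnorm(n * p, mean = means[i], sd = sd), n, p)
    df <- tibble::as_tibble(as.data.frame(m), .name_repair = "minimal")
    names(df) <- paste0("f", seq_len(p))
    df$label <- labels[i]
    df
  })
  df <- dplyr::bind_rows(rows)
  df$label <- factor(df$label, levels = labels)
  df
}
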