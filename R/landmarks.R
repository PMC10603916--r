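# Blob-to-anatomical-site labeling and manual overrides.
#
# Detected blob centroids carry no identity; they are matched one-to-one to
# the view's template sites by exact minimum-cost assignment on squared
# distances after robust normalization (translate to the coordinate-wise
# median, scale by the median radius) of both point sets.  Median
# normalization is exactly invariant to uniform scale and offset, and
# degrades gracefully when a marker is occluded or a spurious blob lies far
# from the body, unlike bounding-box or RMS normalization, which a single
# extremal point distorts.

# Normalize a point set: median center to origin, 70th-percentile radius
# to 1 (high enough to be stable when many sites cluster near the body
# center, low enough to ignore a few far-off spurious points).
moment_normalize <- function(x, y) {
  cx <- stats::median(x); cy <- stats::median(y)
  r <- stats::quantile(sqrt((x - cx)^2 + (y - cy)^2), 0.7,
                       names = FALSE, type = 7)
  if (r == 0) r <- 1
  list(x = (x - cx) / r, y = (y - cy) / r)
}

#' Assign detected blobs to anatomical sites
#'
#' One-to-one assignment between blob centroids and the view's template
#' sites minimizing the total squared distance after moment normalization
#' of both point sets (blob y is flipped to the template's feet-to-head
#' convention, and blob x is mirrored in mirrored views).  Sites left
#' without a blob are flagged `missing`; surplus blobs are reported via the
#' `surplus_blobs` attribute and a warning.
#'
#' @param blobs Tibble of blobs (needs columns `x`, `y`), e.g. from
#'   [detect_blobs()].
#' @param view View name.
#' @param template A `posture_template` for the view; default neutral.
#' @param reject_threshold Mean normalized squared distance of the matched
#'   pairs above which the whole configuration is rejected.
#' @param pair_threshold Normalized squared distance above which an
#'   individual pair is unmatched (site flagged missing, blob surplus)
#'   instead of silently mislabeled.
#' @return A `landmark_set`: tibble with columns `view`, `site`, `side`,
#'   `x_px`, `y_px`, `provenance` (`"detected"` or `"missing"`), attributes
#'   `view`, `assignment_cost`, `surplus_blobs`.
#' @export
assign_landmarks <- function(blobs, view, template = NULL,
                             reject_threshold = 0.04,
                             pair_threshold = 0.1) {
  view <- match.arg(view, POSTURE_VIEWS)
  if (is.null(template)) template <- posture_template(view)
  stopifnot(attr(template, "view") == view)
  if (nrow(blobs) < 3) {
    stop_pk(sprintf("insufficient markers: %d blob(s) detected, need >= 3",
                    nrow(blobs)), "insufficient_markers")
  }

  sgn <- if (view %in% MIRRORED_VIEWS) -1 else 1
  n_sites <- nrow(template)
  bx <- sgn * blobs$x; by <- -blobs$y       # template-frame blob coordinates
  tx <- template$x; ty <- template$y
  t_norm <- moment_normalize(tx, ty)
  # template reference radius, used to express refined residuals on the
  # same normalized scale as the bootstrap costs
  t_radius <- stats::quantile(
    sqrt((tx - stats::median(tx))^2 + (ty - stats::median(ty))^2),
    0.7, names = FALSE, type = 7)

  # Solve the (padded rectangular) matching for a given cost matrix over
  # sites x pool, discarding blobs that are far from EVERY site (truly
  # spurious) and re-solving; genuine blobs caught in a mismatch chain
  # stay.  Ambiguous far pairs are left unmatched rather than guessed.
  solve_pool <- function(pool, cost_fn) {
    repeat {
      if (length(pool) < 3) {
        stop_pk(
          "implausible marker configuration: fewer than 3 blobs lie near any template site",
          "implausible_configuration")
      }
      cost <- cost_fn(pool)
      m <- max(n_sites, length(pool))
      full <- matrix(0, m, m)
      full[seq_len(n_sites), seq_len(length(pool))] <- cost
      a <- solve_assignment(full)
      site_blob <- a[seq_len(n_sites)]
      site_blob[site_blob > length(pool)] <- NA_integer_   # dummy column
      matched <- !is.na(site_blob)
      pair_cost <- rep(NA_real_, n_sites)
      pair_cost[matched] <- cost[cbind(which(matched), site_blob[matched])]
      far <- matched & pair_cost > pair_threshold
      if (!any(far)) {
        return(list(pool = pool, site_blob = site_blob, matched = matched,
                    pair_cost = pair_cost))
      }
      spurious <- which(apply(cost, 2, min) > pair_threshold)
      if (length(spurious) == 0) {
        site_blob[far] <- NA_integer_
        matched <- !is.na(site_blob)
        pair_cost[far] <- NA_real_
        return(list(pool = pool, site_blob = site_blob, matched = matched,
                    pair_cost = pair_cost))
      }
      pool <- pool[-spurious]
    }
  }

  # Bootstrap pass: robust normalization of both point sets, one plain
  # matching, no exclusions.  An occluded extremal site or a spurious blob
  # distorts this frame, so it only establishes a provisional
  # correspondence for the similarity fit below.
  all_blobs <- seq_len(nrow(blobs))
  b0 <- moment_normalize(bx, by)
  cost0 <- outer(t_norm$x, b0$x, `-`)^2 + outer(t_norm$y, b0$y, `-`)^2
  m0 <- max(n_sites, nrow(blobs))
  full0 <- matrix(0, m0, m0)
  full0[seq_len(n_sites), all_blobs] <- cost0
  a0 <- solve_assignment(full0)
  sb0 <- a0[seq_len(n_sites)]
  sb0[sb0 > nrow(blobs)] <- NA_integer_
  res <- list(pool = all_blobs, site_blob = sb0, matched = !is.na(sb0),
              pair_cost = ifelse(is.na(sb0), NA_real_,
                                 cost0[cbind(seq_len(n_sites), sb0)]))

  # Refinement passes: fit the similarity transform (isotropic scale +
  # offset) by least squares over the trustworthy matched pairs (cost at
  # most pair_threshold; all matched pairs if too few) and re-solve the
  # matching on the aligned residuals.  The fit uses only matched pairs,
  # so missing sites cannot distort the frame, and trimming keeps far-off
  # spurious blobs from pulling it.
  for (iter in 1:2) {
    good <- res$matched & res$pair_cost <= pair_threshold
    if (sum(good, na.rm = TRUE) < 3) good <- res$matched
    ti <- which(good)
    if (length(ti) < 3) break
    bi <- res$pool[res$site_blob[ti]]
    tm <- cbind(tx[ti], ty[ti]); bm <- cbind(bx[bi], by[bi])
    tc <- colMeans(tm); bc <- colMeans(bm)
    denom <- sum(sweep(tm, 2, tc)^2)
    if (denom == 0) break
    s <- sum(sweep(tm, 2, tc) * sweep(bm, 2, bc)) / denom
    if (!is.finite(s) || s <= 0) break
    shift <- bc - s * tc
    px <- s * tx + shift[1]; py <- s * ty + shift[2]
    ref_cost <- function(pool) {
      (outer(px, bx[pool], `-`)^2 + outer(py, by[pool], `-`)^2) /
        (s * t_radius)^2
    }
    res <- solve_pool(all_blobs, ref_cost)
  }

  site_blob <- res$site_blob
  matched <- res$matched
  pair_cost <- res$pair_cost
  # the typical (median) pair cost judges the whole configuration, and a
  # configuration that leaves most sites without a plausible blob is not a
  # marker scene at all
  typical_cost <- stats::median(pair_cost[matched])
  if (!is.finite(typical_cost) || typical_cost > reject_threshold) {
    stop_pk(sprintf(
      "implausible marker configuration: median normalized squared distance %.3f exceeds %.3f",
      typical_cost, reject_threshold), "implausible_configuration")
  }
  if (sum(matched) < n_sites / 2) {
    stop_pk(sprintf(
      "implausible marker configuration: only %d of %d sites have a plausible blob",
      sum(matched), n_sites), "implausible_configuration")
  }

  site_blob[matched] <- res$pool[site_blob[matched]]  # back to blob rows
  mean_cost <- mean(pair_cost[matched])

  out <- tibble::tibble(
    view = view,
    site = template$site,
    side = template$side,
    x_px = ifelse(matched, blobs$x[site_blob], NA_real_),
    y_px = ifelse(matched, blobs$y[site_blob], NA_real_),
    provenance = ifelse(matched, "detected", "missing")
  )
  surplus <- setdiff(seq_len(nrow(blobs)), site_blob[matched])
  if (length(surplus) > 0) {
    warn_pk(sprintf("%d surplus blob(s) not assigned to any site",
                    length(surplus)), "surplus_blobs")
  }
  structure(out, view = view, assignment_cost = mean_cost,
            surplus_blobs = blobs[surplus, , drop = FALSE],
            class = c("landmark_set", class(out)))
}

#' Construct a landmark set from known coordinates
#'
#' Entry point for landmark tables that bypass image detection (e.g. CSV
#' exports from other software).
#'
#' @param df Data frame with columns `site`, `side`, `x_px`, `y_px` and
#'   optionally `provenance` (default `"manual"`).
#' @param view View name.
#' @return A `landmark_set`.
#' @export
landmark_set <- function(df, view) {
  view <- match.arg(view, POSTURE_VIEWS)
  req <- required_sites(view)
  df <- tibble::as_tibble(df)
  if (!"provenance" %in% names(df)) df$provenance <- "manual"
  out <- dplyr::left_join(req, df, by = c("site", "side")) |>
    dplyr::mutate(view = view,
                  provenance = ifelse(is.na(.data$x_px), "missing",
                                      .data$provenance)) |>
    dplyr::select("view", "site", "side", "x_px", "y_px", "provenance")
  structure(out, view = view,
            class = c("landmark_set", class(out)))
}

#' Apply manual landmark overrides
#'
#' Fills missing landmarks and replaces detected ones with operator-supplied
#' pixel coordinates; overridden landmarks get provenance `"manual"`.
#' Mirrors the manual completion step needed in practice when markers are
#' occluded by body parts or clothing.
#'
#' @param ls A `landmark_set`.
#' @param overrides Data frame with columns `site`, `side`, `x_px`, `y_px`.
#'   Zero rows return `ls` unchanged.
#' @return The updated `landmark_set`.
#' @export
apply_overrides <- function(ls, overrides) {
  stopifnot(inherits(ls, "landmark_set"))
  if (is.null(overrides) || nrow(overrides) == 0) return(ls)
  overrides <- tibble::as_tibble(overrides)
  bad <- dplyr::anti_join(overrides, ls, by = c("site", "side"))
  if (nrow(bad) > 0) {
    stop_pk(paste0("override site(s) not in view '", attr(ls, "view"), "': ",
                   paste(site_key(bad$site, bad$side), collapse = ", ")),
            "bad_override")
  }
  for (i in seq_len(nrow(overrides))) {
    j <- which(ls$site == overrides$site[i] & ls$side == overrides$side[i])
    ls$x_px[j] <- overrides$x_px[i]
    ls$y_px[j] <- overrides$y_px[i]
    ls$provenance[j] <- "manual"
  }
  ls
}
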