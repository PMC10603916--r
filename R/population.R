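# Labeled synthetic feature populations.
#
# Emulates a screening study population: each synthetic subject is a
# perturbed four-view posture template, its 38 features computed through
# the same geometry as the imaging pipeline, plus additive measurement
# noise.  Class-conditional perturbation distributions express ordered
# severity: zero deviations, small deviations, large deviations.

#' Compute features directly from four-view templates
#'
#' Bypasses rendering and detection: template coordinates are projected to
#' pixel coordinates with the standard scene geometry and fed through the
#' calibrated feature computation.
#'
#' @param templates Named list of `posture_template`s (one per view); a
#'   single template is accepted.
#' @param subject_height_cm Subject stature in cm.
#' @return One-row tibble of the 38 features (features of absent views are
#'   `NA`).
#' @export
features_from_templates <- function(templates,
                                    subject_height_cm = 166.4) {
  if (inherits(templates, "posture_template")) {
    templates <- stats::setNames(list(templates), attr(templates, "view"))
  }
  views <- list(); cals <- list()
  for (v in names(templates)) {
    pts <- template_to_image(templates[[v]], v, 800, 1200, subject_height_cm)
    views[[v]] <- landmark_set(
      tibble::tibble(site = pts$site, side = pts$side,
                     x_px = pts$x_px, y_px = pts$y_px,
                     provenance = "detected"), v)
    cals[[v]] <- manual_calibration(cm_per_px = pts$cm_per_px[1])
  }
  suppressWarnings(compute_features(views, cals))
}

#' Default class-conditional perturbation effects
#'
#' Mean and standard deviation of each perturbation parameter per class,
#' expressing ordered severity: the no-evidence class is unperturbed, mild
#' evidence carries small (2-4 degree) pelvic obliquity and shoulder drop,
#' moderate-to-severe evidence carries large (6-10 degree) deviations plus
#' increased kyphosis and a frontal-plane spine offset.
#'
#' @return Named list (per class) of named lists `c(mean, sd)` per
#'   perturbation parameter.
#' @export
default_class_effects <- function() {
  list(
    none = list(pelvic_obliquity_deg = c(0, 0), shoulder_drop_deg = c(0, 0),
                kyphosis_gain = c(0, 0), lordosis_gain = c(0, 0),
                scoliosis_offset = c(0, 0)),
    mild = list(pelvic_obliquity_deg = c(3, 0.5), shoulder_drop_deg = c(3, 0.5),
                kyphosis_gain = c(0.15, 0.05), lordosis_gain = c(0.1, 0.05),
                scoliosis_offset = c(0.005, 0.002)),
    moderate_severe = list(pelvic_obliquity_deg = c(8, 1),
                           shoulder_drop_deg = c(8, 1),
                           kyphosis_gain = c(0.5, 0.1),
                           lordosis_gain = c(0.35, 0.1),
                           scoliosis_offset = c(0.015, 0.004))
  )
}

#' Generate a labeled synthetic feature population
#'
#' Draws per-subject perturbations from the class-conditional effect
#' distributions, computes the 38 features from the perturbed four-view
#' templates and adds independent Gaussian measurement noise to every
#' feature.  Fully reproducible under `seed`.
#'
#' @param n_per_class Named counts per class label; the default mirrors a
#'   57-subject screening population split 16 / 25 / 16 across
#'   `none` / `mild` / `moderate_severe`.
#' @param effects Class effects as in [default_class_effects()].
#' @param noise_sd Measurement noise standard deviation added to every
#'   feature, in the feature's native unit (degrees or cm).
#' @param height_mean_cm,height_sd_cm Subject stature distribution.
#' @param seed Integer RNG seed.
#' @return A tibble: `subject_id`, `label` (factor) and the 38 feature
#'   columns.
#' @export
#' @examples
#' pop <- make_feature_population(c(none = 4, mild = 4, moderate_severe = 4),
#'                                seed = 7)
#' dplyr::count(pop, label)
make_feature_population <- function(n_per_class = c(none = 16, mild = 25,
                                                    moderate_severe = 16),
                                    effects = default_class_effects(),
                                    noise_sd = 0.5,
                                    height_mean_cm = 166.4,
                                    height_sd_cm = 9.3,
                                    seed = 1L) {
  stopifnot(all(n_per_class >= 0))
  if (sum(n_per_class) == 0) {
    stop_pk("all class counts are zero", "empty_population")
  }
  missing_fx <- setdiff(names(n_per_class), names(effects))
  if (length(missing_fx) > 0) {
    stop_pk(paste0("no effect definition for class(es): ",
                   paste(missing_fx, collapse = ", ")), "missing_effect")
  }

  with_preserved_seed(seed, {
    rows <- purrr::imap(as.list(n_per_class), function(n, label) {
      purrr::map(seq_len(n), function(i) {
        fx <- effects[[label]]
        pert <- purrr::map(fx, function(ms) stats::rnorm(1, ms[1], ms[2]))
        height <- stats::rnorm(1, height_mean_cm, height_sd_cm)
        tpls <- stats::setNames(
          purrr::map(POSTURE_VIEWS, posture_template, perturbations = pert),
          POSTURE_VIEWS)
        feats <- features_from_templates(tpls, subject_height_cm = height)
        dplyr::mutate(feats, label = label, .before = 1)
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()

    fcols <- feature_names()
    noise <- matrix(stats::rnorm(nrow(rows) * length(fcols), 0, noise_sd),
                    nrow = nrow(rows))
    rows[fcols] <- rows[fcols] + noise
    dplyr::mutate(rows,
                  subject_id = sprintf("S%03d", dplyr::row_number()),
                  label = factor(.data$label,
                                 levels = intersect(
                                   c("none", "mild", "moderate_severe"),
                                   unique(.data$label))),
                  .before = 1)
  })
}
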