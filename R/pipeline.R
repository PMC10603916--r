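# End-to-end pipeline: images -> detection -> calibration -> landmarks ->
# features, per subject and per study, with a YAML-configurable parameter
# set and per-view diagnostics.

#' Default pipeline configuration
#'
#' Collects every tunable parameter of the pipeline: color thresholds,
#' blob filters, the scale rectangle's known length, landmark-assignment
#' thresholds, the statistical protocol and the classifier defaults.
#' Serializes losslessly to YAML.
#'
#' @param scale_length_cm Known physical length of the scale rectangle.
#' @param seed Default RNG seed for stochastic stages.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(scale_length_cm = 20, seed = 1L) {
  structure(list(
    colors = list(
      marker = list(h = list(c(40, 80)), s_min = 0.3, v_min = 0.3),
      rectangle = list(h = list(c(100, 130)), s_min = 0.3, v_min = 0.3),
      string = list(h = list(c(0, 10), c(170, 180)), s_min = 0.3,
                    v_min = 0.3)
    ),
    blob_filters = list(min_area = 80, max_area = 8000,
                        min_circularity = 0.6, max_circularity = 1,
                        min_convexity = 0.85, max_convexity = 1,
                        min_inertia_ratio = 0.4, max_inertia_ratio = 1),
    scale_length_cm = scale_length_cm,
    assignment = list(reject_threshold = 0.04, pair_threshold = 0.1),
    stats = list(alphas = c(0.05, 0.1),
                 tost_ladder = list(c(-0.01, 0.01), c(-0.05, 0.05),
                                    c(-0.06, 0.06)),
                 outlier_k = 1.5, gate_on = "sources"),
    classify = list(model = "knn", k = 5, scheme = "split70_30",
                    feature_set = "multiclass"),
    obtuse_line_angles = FALSE,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Read / write a pipeline configuration
#'
#' @param path YAML file path.
#' @param config A `pipeline_config`.
#' @return `load_config` returns a `pipeline_config`; `save_config`
#'   returns `path` invisibly.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  cfg[] <- utils::modifyList(unclass(cfg), raw)
  # yaml flattens numeric pairs into lists; coerce ranges back
  cfg$colors <- purrr::map(cfg$colors, function(cs) {
    cs$h <- purrr::map(cs$h, as.numeric)
    cs
  })
  cfg$stats$tost_ladder <- purrr::map(cfg$stats$tost_ladder, as.numeric)
  cfg$stats$alphas <- as.numeric(cfg$stats$alphas)
  cfg
}

#' @rdname load_config
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_color_specs <- function(config) {
  list(
    marker = color_spec("marker", config$colors$marker$h,
                        config$colors$marker$s_min,
                        config$colors$marker$v_min),
    rectangle = color_spec("rectangle", config$colors$rectangle$h,
                           config$colors$rectangle$s_min,
                           config$colors$rectangle$v_min),
    string = color_spec("string", config$colors$string$h,
                        config$colors$string$s_min,
                        config$colors$string$v_min)
  )
}

config_blob_params <- function(config) {
  do.call(blob_filter_params, config$blob_filters)
}

# Run detection + calibration + assignment on one view image.
process_view <- function(image, view, config, overrides = NULL) {
  specs <- config_color_specs(config)
  rect <- detect_scale_rectangle(image, specs$rectangle)
  plumb <- detect_plumb_line(image, specs$string)
  cal <- build_frame(rect, plumb, config$scale_length_cm)
  mask <- threshold_color(image, specs$marker)
  blobs <- detect_blobs(mask, config_blob_params(config))
  ls <- assign_landmarks(blobs, view,
                         reject_threshold = config$assignment$reject_threshold,
                         pair_threshold = config$assignment$pair_threshold)
  if (!is.null(overrides)) ls <- apply_overrides(ls, overrides)
  list(landmarks = ls, calibration = cal,
       diagnostics = list(view = view, n_blobs = nrow(blobs),
                          cm_per_px = cal$cm_per_px,
                          rotation_deg = cal$rotation_deg,
                          missing_sites = site_key(
                            ls$site[ls$provenance == "missing"],
                            ls$side[ls$provenance == "missing"])))
}

#' Run the full pipeline on one subject
#'
#' For every supplied view: detect the references and the markers,
#' calibrate, assign landmarks and finally compute the 38 features across
#' views.  Stage errors abort with the failing view named; a red-on-red
#' scene, for instance, surfaces a calibration error advising a different
#' background or string color.
#'
#' @param images Named list/vector mapping view names to PNG paths, image
#'   arrays or `posture_scene` objects.
#' @param config A [pipeline_config()].
#' @param overrides Optional named list (per view) of manual landmark
#'   override tables.
#' @return List: `features` (one-row tibble of 38 features),
#'   `diagnostics` (per view), `landmarks`, `calibrations`.
#' @export
run_subject <- function(images, config = pipeline_config(),
                        overrides = NULL) {
  stopifnot(length(images) >= 1)
  views <- names(images)
  bad <- setdiff(views, POSTURE_VIEWS)
  if (length(bad) > 0) {
    stop_pk(paste0("unknown view(s): ", paste(bad, collapse = ", ")),
            "bad_view")
  }
  res <- list()
  for (v in views) {
    img <- images[[v]]
    if (inherits(img, "posture_scene")) img <- img$image
    if (is.character(img)) img <- read_view_image(img)
    res[[v]] <- withCallingHandlers(
      tryCatch(process_view(img, v, config, overrides[[v]]),
               posturekit_error = function(e) {
                 stop_pk(paste0("view '", v, "': ", conditionMessage(e),
                                if (inherits(e, "posturekit_error_plumb_not_found"))
                                  " (hint: use a background color distinct from the plumb string)"
                                else ""),
                         class = sub("posturekit_error_", "",
                                     class(e)[1]),
                         parent = e)
               }),
      posturekit_warning = function(w) invokeRestart("muffleWarning"))
  }
  features <- compute_features(
    purrr::map(res, "landmarks"),
    purrr::map(res, "calibration"),
    obtuse_line_angles = config$obtuse_line_angles)
  list(features = features,
       diagnostics = purrr::map(res, "diagnostics"),
       landmarks = purrr::map(res, "landmarks"),
       calibrations = purrr::map(res, "calibration"))
}

#' Run the pipeline over a study manifest
#'
#' Processes every subject of a manifest (columns `subject_id`, `view`,
#' `path`); per-subject failures are collected, the run continues, and the
#' failures are reported in the `failures` attribute.
#'
#' @param manifest Data frame with columns `subject_id`, `view`, `path`
#'   (PNG paths), or with a list column `image` of arrays.
#' @param config A [pipeline_config()].
#' @param output_dir Optional directory; when given, `features.csv` and a
#'   provenance record `run.json` are written there.
#' @return Feature table, one row per successful subject (`subject_id` +
#'   38 features), with attribute `failures` (tibble `subject_id`,
#'   `error`).
#' @export
run_study <- function(manifest, config = pipeline_config(),
                      output_dir = NULL) {
  manifest <- tibble::as_tibble(manifest)
  stopifnot(all(c("subject_id", "view") %in% names(manifest)))
  subjects <- unique(manifest$subject_id)
  rows <- list(); fails <- list()
  for (s in subjects) {
    mrows <- manifest[manifest$subject_id == s, ]
    imgs <- if ("image" %in% names(mrows)) {
      stats::setNames(mrows$image, mrows$view)
    } else {
      stats::setNames(as.list(mrows$path), mrows$view)
    }
    out <- tryCatch(
      suppressWarnings(run_subject(imgs, config)),
      error = function(e) e)
    if (inherits(out, "error")) {
      fails[[s]] <- tibble::tibble(subject_id = s,
                                   error = conditionMessage(out))
    } else {
      rows[[s]] <- dplyr::mutate(out$features, subject_id = s, .before = 1)
    }
  }
  features <- dplyr::bind_rows(rows)
  failures <- dplyr::bind_rows(fails)
  if (nrow(failures) > 0) {
    warn_pk(sprintf("%d subject(s) failed; see attr(, 'failures')",
                    nrow(failures)), "subject_failures")
  }
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(features, file.path(output_dir, "features.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(seed = config$seed,
           config_hash = rlang::hash(unclass(config)),
           package_version = as.character(utils::packageVersion("posturekit")),
           n_subjects = length(subjects), n_failed = nrow(failures)),
      file.path(output_dir, "run.json"), auto_unbox = TRUE)
  }
  structure(features, failures = failures)
}
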