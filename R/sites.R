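# Anatomical site catalog and the definitions of the 38 posture features.
#
# Seventeen anatomical site names are used, twelve of them bilateral, giving
# the 29 physical markers a fully instrumented subject wears.  Features are
# computed per view (anterior, posterior, lateral_left, lateral_right) from
# calibrated landmark coordinates; each feature is one of four geometric
# primitives: an alignment angle against the gravitational horizontal, an
# unsigned angle between two lines, an unsigned angle at a vertex, or a
# Euclidean distance in cm.

POSTURE_VIEWS <- c("anterior", "posterior", "lateral_left", "lateral_right")

# Views in which the photograph mirrors the subject (image-left is the
# subject's anatomical right).  Posterior photographs are unmirrored.
MIRRORED_VIEWS <- c("anterior", "lateral_right")

#' Anatomical site catalog
#'
#' The 17 anatomical sites used for marker placement.  Twelve are bilateral,
#' so a fully instrumented subject carries 29 physical markers.
#'
#' @return A tibble with columns `site` and `bilateral`.
#' @export
#' @examples
#' anatomical_sites()
anatomical_sites <- function() {
  tibble::tibble(
    site = c("jugular_notch", "xiphoid", "C7", "kyphosis_apex", "lordosis_apex",
             "acromion", "ASIS", "PSIS", "trochanter", "femur_lateral_condyle",
             "popliteal_fossa", "patella", "tibial_tuberosity",
             "lateral_malleolus", "posterior_intermalleolar_point",
             "calcaneus", "fifth_metatarsal"),
    bilateral = c(rep(FALSE, 5), rep(TRUE, 12))
  )
}

#' Physical markers of the full-body template
#'
#' Expands the site catalog into one row per physical marker (bilateral
#' sites appear once per side).
#'
#' @return A tibble with columns `site` and `side`
#'   (`"none"`, `"left"` or `"right"`); 29 rows.
#' @export
marker_catalog <- function() {
  sites <- anatomical_sites()
  dplyr::bind_rows(
    dplyr::mutate(dplyr::filter(sites, !.data$bilateral), side = "none"),
    tidyr::crossing(dplyr::filter(sites, .data$bilateral),
                    side = c("left", "right"))
  ) |>
    dplyr::select("site", "side") |>
    dplyr::arrange(.data$site, .data$side)
}

site_key <- function(site, side) paste(site, side, sep = ":")

# Point specifications used by the feature table.  A point is either a
# "site:side" key or "mid(site:side,site:side)" for a midpoint.
mid_spec <- function(a, b) paste0("mid(", a, ",", b, ")")

#' Definitions of the 38 anatomical features
#'
#' One row per feature: its view, geometric primitive (`kind`) and the
#' anatomical points it uses.  `kind` is one of `"horizontal"` (signed
#' alignment angle of a left-to-right segment against the gravitational
#' horizontal), `"lines"` (unsigned angle between two lines), `"vertex"`
#' (unsigned angle at the middle point of a triple) and `"distance"`
#' (Euclidean distance in cm).
#'
#' @return A tibble with columns `feature`, `view`, `kind`, `points`
#'   (list column of point keys) and `description`; 38 rows.
#' @export
#' @examples
#' feature_definitions()
feature_definitions <- function() {
  if (!is.null(.pk_cache$feature_definitions)) {
    return(.pk_cache$feature_definitions)
  }
  k <- site_key
  def <- function(feature, view, kind, points, description) {
    tibble::tibble(feature = feature, view = view, kind = kind,
                   points = list(points), description = description)
  }
  bilat <- function(f) {
    # expand a per-side definition generator over both sides
    dplyr::bind_rows(f("left", "L"), f("right", "R"))
  }

  out <- dplyr::bind_rows(
    ## Anterior view -------------------------------------------------------
    def("AHA_A", "anterior", "horizontal",
        c(k("acromion", "left"), k("acromion", "right")),
        "Acromions horizontal alignment (anterior)"),
    def("ASA", "anterior", "lines",
        c(k("jugular_notch", "none"), k("xiphoid", "none"),
          k("acromion", "left"), k("acromion", "right")),
        "Angle between the sternum line and the acromions' line"),
    def("ASISHA", "anterior", "horizontal",
        c(k("ASIS", "left"), k("ASIS", "right")),
        "ASISs horizontal alignment"),
    bilat(function(s, S) def(
      paste0("ASISLA_", S), "anterior", "lines",
      c(k("trochanter", s), k("patella", s), k("ASIS", "left"), k("ASIS", "right")),
      paste("Angle between the", s, "trochanter-patella line and the ASISs' line"))),
    bilat(function(s, S) def(
      paste0("AKLA_", S), "anterior", "lines",
      c(k("trochanter", s), k("patella", s),
        k("tibial_tuberosity", s), k("lateral_malleolus", s)),
      paste("Knee lateral angle,", s, "(anterior)"))),
    bilat(function(s, S) def(
      paste0("AJND_", S), "anterior", "distance",
      c(k("jugular_notch", "none"), k("acromion", s)),
      paste("Distance between the jugular notch and the", s, "acromion"))),
    bilat(function(s, S) def(
      paste0("AAD_", S), "anterior", "distance",
      c(k("acromion", s), k("ASIS", s)),
      paste("Distance between the", s, "acromion and ASIS"))),
    bilat(function(s, S) def(
      paste0("ALLL_", S), "anterior", "distance",
      c(k("trochanter", s), k("lateral_malleolus", s)),
      paste("Lower limb length,", s, "(anterior)"))),

    ## Posterior view ------------------------------------------------------
    def("AHA_P", "posterior", "horizontal",
        c(k("acromion", "left"), k("acromion", "right")),
        "Acromions horizontal alignment (posterior)"),
    def("AVA", "posterior", "lines",
        c(k("C7", "none"), k("kyphosis_apex", "none"),
          k("acromion", "left"), k("acromion", "right")),
        "Angle between the C7-kyphosis line and the acromions' line"),
    def("TKA", "posterior", "vertex",
        c(k("C7", "none"), k("kyphosis_apex", "none"), k("lordosis_apex", "none")),
        "Thoracic kyphosis lateral angle (posterior)"),
    def("LLA", "posterior", "vertex",
        c(k("kyphosis_apex", "none"), k("lordosis_apex", "none"),
          mid_spec(k("PSIS", "left"), k("PSIS", "right"))),
        "Lumbar lordosis lateral angle (posterior)"),
    def("PSISHA", "posterior", "horizontal",
        c(k("PSIS", "left"), k("PSIS", "right")),
        "PSISs horizontal alignment"),
    bilat(function(s, S) def(
      paste0("PSISLA_", S), "posterior", "lines",
      c(k("trochanter", s), k("popliteal_fossa", s),
        k("PSIS", "left"), k("PSIS", "right")),
      paste("Angle between the", s, "trochanter-popliteal line and the PSISs' line"))),
    bilat(function(s, S) def(
      paste0("PKLA_", S), "posterior", "vertex",
      c(k("trochanter", s), k("popliteal_fossa", s),
        k("posterior_intermalleolar_point", s)),
      paste("Knee lateral angle,", s, "(posterior); vertex at the popliteal fossa"))),
    bilat(function(s, S) def(
      paste0("ALA_", S), "posterior", "vertex",
      c(k("popliteal_fossa", s), k("posterior_intermalleolar_point", s),
        k("calcaneus", s)),
      paste("Ankle lateral angle,", s))),
    bilat(function(s, S) def(
      paste0("APD_", S), "posterior", "distance",
      c(k("acromion", s), k("PSIS", s)),
      paste("Distance between the", s, "acromion and PSIS"))),
    bilat(function(s, S) def(
      paste0("PLLL_", S), "posterior", "distance",
      c(k("trochanter", s), k("calcaneus", s)),
      paste("Lower limb length,", s, "(posterior)"))),

    ## Lateral views -------------------------------------------------------
    bilat(function(s, S) def(
      paste0("TKC_", S), paste0("lateral_", s), "vertex",
      c(k("C7", "none"), k("kyphosis_apex", "none"), k("lordosis_apex", "none")),
      paste("Thoracic kyphosis curvature,", s, "lateral view"))),
    bilat(function(s, S) def(
      paste0("LLC_", S), paste0("lateral_", s), "vertex",
      c(k("kyphosis_apex", "none"), k("lordosis_apex", "none"), k("PSIS", s)),
      paste("Lumbar lordosis curvature,", s, "lateral view"))),
    bilat(function(s, S) def(
      paste0("PLA_", S), paste0("lateral_", s), "lines",
      c(k("ASIS", s), k("PSIS", s),
        k("trochanter", s), k("femur_lateral_condyle", s)),
      paste("Pelvis-leg angle,", s))),
    bilat(function(s, S) def(
      paste0("KA_", S), paste0("lateral_", s), "vertex",
      c(k("trochanter", s), k("femur_lateral_condyle", s), k("lateral_malleolus", s)),
      paste("Knee angle,", s))),
    bilat(function(s, S) def(
      paste0("LFA_", S), paste0("lateral_", s), "lines",
      c(k("trochanter", s), k("femur_lateral_condyle", s),
        k("calcaneus", s), k("fifth_metatarsal", s)),
      paste("Leg-foot angle,", s)))
  )
  .pk_cache$feature_definitions <- out
  out
}

#' Names of the 38 anatomical features
#'
#' @return Character vector of length 38, in definition order.
#' @export
feature_names <- function() feature_definitions()$feature

#' Sites required by a view's feature subset
#'
#' @param view One of `"anterior"`, `"posterior"`, `"lateral_left"`,
#'   `"lateral_right"`.
#' @return A tibble with columns `site` and `side`.
#' @export
required_sites <- function(view) {
  view <- match.arg(view, POSTURE_VIEWS)
  key <- paste0("required_sites_", view)
  if (!is.null(.pk_cache[[key]])) return(.pk_cache[[key]])
  defs <- dplyr::filter(feature_definitions(), .data$view == !!view)
  keys <- unique(unlist(lapply(defs$points, expand_point_keys)))
  parts <- strsplit(keys, ":", fixed = TRUE)
  out <- tibble::tibble(site = vapply(parts, `[[`, "", 1),
                        side = vapply(parts, `[[`, "", 2)) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$site, .data$side)
  .pk_cache[[key]] <- out
  out
}

# Expand midpoint specs into their constituent site keys.
expand_point_keys <- function(points) {
  unlist(lapply(points, function(p) {
    if (startsWith(p, "mid(")) {
      strsplit(sub("^mid\\((.*)\\)$", "\\1", p), ",", fixed = TRUE)[[1]]
    } else {
      p
    }
  }))
}
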