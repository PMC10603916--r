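# Posture templates: normalized body-frame landmark coordinates per view,
# plus the affine perturbation model that generates postural deviations.
#
# Body frame: x in [0,1] runs from the subject's anatomical left (0) to
# right (1); y in [0,1] runs from the feet (0) to the head (1).  Both axes
# share the same physical scale (a unit step is one subject height), so the
# frame is isotropic and angles computed in it are physical angles.  In the
# sagittal (lateral) views x runs posterior (0) to anterior (1) instead.

# Base coordinates of a neutral standing adult.  Bilateral x offsets are
# half-widths about the midline x = 0.5, as fractions of subject height.
frontal_base <- function() {
  tibble::tribble(
    ~site,                              ~dx,   ~y,
    "jugular_notch",                    0,     0.810,
    "xiphoid",                          0,     0.720,
    "C7",                               0,     0.845,
    "kyphosis_apex",                    0,     0.745,
    "lordosis_apex",                    0,     0.610,
    "acromion",                         0.120, 0.820,
    "ASIS",                             0.080, 0.570,
    "PSIS",                             0.055, 0.585,
    "trochanter",                       0.118, 0.540,
    "patella",                          0.085, 0.300,
    "tibial_tuberosity",                0.082, 0.255,
    "popliteal_fossa",                  0.090, 0.290,
    "lateral_malleolus",                0.100, 0.048,
    "posterior_intermalleolar_point",   0.095, 0.042,
    "calcaneus",                        0.092, 0.020
  )
}

sagittal_base <- function() {
  tibble::tribble(
    ~site,                   ~x,    ~y,
    "C7",                    0.455, 0.845,
    "kyphosis_apex",         0.415, 0.745,
    "lordosis_apex",         0.465, 0.610,
    "ASIS",                  0.565, 0.570,
    "PSIS",                  0.425, 0.585,
    "trochanter",            0.500, 0.540,
    "femur_lateral_condyle", 0.495, 0.290,
    "lateral_malleolus",     0.480, 0.048,
    "calcaneus",             0.405, 0.020,
    "fifth_metatarsal",      0.600, 0.012
  )
}

#' Default perturbation parameters (all zero)
#'
#' The perturbation model applies named affine displacements to specific
#' landmarks: `pelvic_obliquity_deg` rotates the ASIS and PSIS pairs about
#' the pelvic midpoint (positive = subject's right side higher);
#' `shoulder_drop_deg` rotates the acromion pair (positive = right acromion
#' lower); `kyphosis_gain` and `lordosis_gain` scale the sagittal offset of
#' the corresponding spinal apex from its chord by `(1 + gain)`;
#' `scoliosis_offset` displaces the spinal apices laterally in the posterior
#' view (normalized body units, i.e. fractions of subject height).
#'
#' @return Named list of five zero parameters.
#' @export
zero_perturbations <- function() {
  list(pelvic_obliquity_deg = 0, shoulder_drop_deg = 0,
       kyphosis_gain = 0, lordosis_gain = 0, scoliosis_offset = 0)
}

#' Build a posture template for one view
#'
#' Returns the normalized body-frame coordinates of every marker visible in
#' the requested view, after applying the perturbation model.  A
#' zero-perturbation template is bilaterally symmetric about the midline
#' x = 0.5 in the anterior and posterior views.
#'
#' @param view One of `"anterior"`, `"posterior"`, `"lateral_left"`,
#'   `"lateral_right"`.
#' @param perturbations Named list; see [zero_perturbations()] for the
#'   parameter names and meanings.  Omitted entries default to zero.
#' @return A tibble with columns `site`, `side`, `x`, `y` and attributes
#'   `view` and `perturbations`; class `posture_template`.
#' @export
#' @examples
#' posture_template("anterior")
#' posture_template("posterior", list(pelvic_obliquity_deg = 5))
posture_template <- function(view, perturbations = list()) {
  view <- match.arg(view, POSTURE_VIEWS)
  p <- utils::modifyList(zero_perturbations(), perturbations)
  stopifnot(all(names(p) %in% names(zero_perturbations())))

  tpl <- if (view %in% c("anterior", "posterior")) {
    base <- frontal_base()
    req <- required_sites(view)
    dplyr::inner_join(req, base, by = "site") |>
      dplyr::mutate(x = 0.5 + dplyr::case_when(.data$side == "left"  ~ -.data$dx,
                                               .data$side == "right" ~ .data$dx,
                                               TRUE ~ 0)) |>
      dplyr::select("site", "side", "x", "y")
  } else {
    side <- sub("lateral_", "", view)
    base <- sagittal_base()
    req <- required_sites(view)
    dplyr::inner_join(req, base, by = "site") |>
      dplyr::select("site", "side", "x", "y")
  }

  tpl <- apply_perturbations(tpl, view, p)
  structure(dplyr::arrange(tpl, .data$site, .data$side),
            view = view, perturbations = p,
            class = c("posture_template", class(tpl)))
}

# Rotate the (left, right) pair of `site` about its midpoint by `theta_deg`;
# positive angles raise the subject's right side (body frame, y up).
rotate_pair <- function(tpl, site, theta_deg) {
  idx <- which(tpl$site == site)
  if (length(idx) != 2) return(tpl)
  th <- rad(theta_deg)
  cx <- mean(tpl$x[idx]); cy <- mean(tpl$y[idx])
  dx <- tpl$x[idx] - cx;  dy <- tpl$y[idx] - cy
  tpl$x[idx] <- cx + dx * cos(th) - dy * sin(th)
  tpl$y[idx] <- cy + dx * sin(th) + dy * cos(th)
  tpl
}

# Scale the offset of `apex` from the chord joining `top` and `bottom`
# by (1 + gain), displacing the apex along the chord normal.
scale_apex_offset <- function(tpl, apex, top, bottom, gain) {
  ia <- which(tpl$site == apex)
  it <- which(tpl$site == top)
  ib <- which(tpl$site == bottom)
  if (length(ia) != 1 || length(it) != 1 || length(ib) != 1 || gain == 0) {
    return(tpl)
  }
  a <- c(tpl$x[ia], tpl$y[ia])
  t <- c(tpl$x[it], tpl$y[it])
  b <- c(tpl$x[ib], tpl$y[ib])
  u <- (b - t) / sqrt(sum((b - t)^2))
  rel <- a - t
  off <- rel - sum(rel * u) * u          # component normal to the chord
  newp <- a + gain * off
  tpl$x[ia] <- newp[1]; tpl$y[ia] <- newp[2]
  tpl
}

apply_perturbations <- function(tpl, view, p) {
  if (view %in% c("anterior", "posterior")) {
    if (p$pelvic_obliquity_deg != 0) {
      tpl <- rotate_pair(tpl, "ASIS", p$pelvic_obliquity_deg)
      tpl <- rotate_pair(tpl, "PSIS", p$pelvic_obliquity_deg)
    }
    if (p$shoulder_drop_deg != 0) {
      tpl <- rotate_pair(tpl, "acromion", -p$shoulder_drop_deg)
    }
  }
  if (view == "posterior" && p$scoliosis_offset != 0) {
    tpl$x[tpl$site == "kyphosis_apex"] <-
      tpl$x[tpl$site == "kyphosis_apex"] + p$scoliosis_offset
    tpl$x[tpl$site == "lordosis_apex"] <-
      tpl$x[tpl$site == "lordosis_apex"] + p$scoliosis_offset / 2
  }
  if (startsWith(view, "lateral")) {
    tpl <- scale_apex_offset(tpl, "kyphosis_apex", "C7", "lordosis_apex",
                             p$kyphosis_gain)
    tpl <- scale_apex_offset(tpl, "lordosis_apex", "kyphosis_apex", "PSIS",
                             p$lordosis_gain)
  }
  tpl
}
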