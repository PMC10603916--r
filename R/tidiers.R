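# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a classifier evaluation
#'
#' One row per class with its one-vs-rest F1 and confusion-matrix margins.
#'
#' @param x A `posture_eval`.
#' @param ... Unused.
#' @return A tibble: `class`, `f1`, `n_true`, `n_predicted`.
#' @export
tidy.posture_eval <- function(x, ...) {
  tibble::tibble(class = names(x$f1), f1 = unname(x$f1),
                 n_true = rowSums(x$confusion),
                 n_predicted = colSums(x$confusion))
}

#' Glance at a classifier evaluation
#'
#' @param x A `posture_eval`.
#' @param ... Unused.
#' @return One-row tibble: `accuracy`, `macro_f1`, `n`, `model`, `scheme`.
#' @export
glance.posture_eval <- function(x, ...) {
  kind <- if (is.list(x$model) && !inherits(x$model, "model_spec")) {
    "cascade"
  } else {
    x$model$kind
  }
  tibble::tibble(accuracy = x$accuracy, macro_f1 = mean(x$f1),
                 n = sum(x$confusion), model = kind,
                 scheme = x$scheme$kind)
}

#' Tidy a validation report
#'
#' @param x A `posture_validation`.
#' @param ... Unused.
#' @return The per-feature report as a plain tibble (key columns first).
#' @export
tidy.posture_validation <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::select("feature", "n", "mean_diff", "sd_diff", "gate", "test",
                  "p", "tost_lower", "tost_upper", "tost_p",
                  dplyr::everything())
}

#' Glance at a validation report
#'
#' @param x A `posture_validation`.
#' @param ... Unused.
#' @return One-row tibble with feature counts by outcome.
#' @export
glance.posture_validation <- function(x, ...) {
  al <- attr(x, "config")$alphas
  eq_col <- paste0("equivalent_", al[1])
  tibble::tibble(
    n_features = nrow(x),
    n_significant_both = sum(x$significant_both, na.rm = TRUE),
    n_equivalent = sum(x[[eq_col]], na.rm = TRUE),
    n_exact = sum(x$exact_agreement))
}

#' Glance at a calibration
#'
#' @param x A `posture_calibration`.
#' @param ... Unused.
#' @return One-row tibble: `cm_per_px`, `rotation_deg`, `origin_x`,
#'   `origin_y`.
#' @export
glance.posture_calibration <- function(x, ...) {
  tibble::tibble(cm_per_px = x$cm_per_px, rotation_deg = x$rotation_deg,
                 origin_x = x$origin_px[["x"]], origin_y = x$origin_px[["y"]])
}
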