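# Agreement validation between two measurement sources.
#
# Protocol, per feature: test each source's sample for normality
# (Shapiro-Wilk); if both are normal use the paired t test on the
# differences, otherwise the Wilcoxon signed-rank test; when the
# difference is significant at both significance levels (0.05 and 0.1),
# remove outlier differences (Tukey 1.5 IQR) and repeat; independently,
# test equivalence with paired TOST over a widening boundary ladder
# (+/-0.01, +/-0.05, +/-0.06), stopping at the first rung that declares
# equivalence.

#' Shapiro-Wilk normality test
#'
#' @param x Numeric sample, 3 <= n <= 5000, non-constant.
#' @param alphas Significance levels for the normality decision
#'   (normal when p >= alpha).
#' @return One-row tibble: `test`, `statistic`, `p`, and one logical
#'   `normal_<alpha>` column per level.
#' @export
shapiro_wilk <- function(x, alphas = c(0.05, 0.1)) {
  x <- x[!is.na(x)]
  if (length(x) < 3 || length(x) > 5000) {
    stop_pk("Shapiro-Wilk requires 3 <= n <= 5000", "bad_sample")
  }
  if (stats::sd(x) == 0) {
    stop_pk("zero variance: constant sample has no defined normality test",
            "zero_variance")
  }
  sw <- stats::shapiro.test(x)
  out <- tibble::tibble(test = "shapiro_wilk",
                        statistic = unname(sw$statistic), p = sw$p.value)
  for (a in alphas) out[[paste0("normal_", a)]] <- sw$p.value >= a
  out
}

#' Normality-gated paired comparison
#'
#' Tests the location difference between paired samples `a` and `b`.  The
#' gate runs Shapiro-Wilk on each source's sample (or on the differences
#' with `gate_on = "differences"`): both normal at `alpha` selects the
#' paired t test, otherwise the Wilcoxon signed-rank test (zeros
#' discarded; exact null for n <= 25, normal approximation with continuity
#' correction above).
#'
#' @param a,b Paired numeric vectors (same subjects, same order).
#' @param alpha Significance level for both the gate and the decision.
#' @param gate_on Gate on each source's sample (default) or on the
#'   differences.
#' @return One-row tibble: `gate` (`"parametric"`/`"nonparametric"`),
#'   `test`, `statistic`, `p`, `significant`, `n`.
#' @export
paired_compare <- function(a, b, alpha = 0.05,
                           gate_on = c("sources", "differences")) {
  gate_on <- match.arg(gate_on)
  stopifnot(length(a) == length(b), length(a) >= 3, !anyNA(a), !anyNA(b))
  d <- a - b
  if (all(d == 0)) {
    stop_pk("no nonzero differences: the paired samples agree exactly",
            "degenerate_differences")
  }
  normal <- if (gate_on == "sources") {
    sa <- shapiro_wilk(a, alpha); sb <- shapiro_wilk(b, alpha)
    sa$p >= alpha && sb$p >= alpha
  } else {
    shapiro_wilk(d, alpha)$p >= alpha
  }
  if (normal) {
    if (stats::sd(d) == 0) {
      # constant nonzero difference: the t statistic degenerates to
      # +/- infinity; the shift is certain
      res <- tibble::tibble(gate = "parametric", test = "paired_t",
                            statistic = Inf * sign(mean(d)), p = 0)
    } else {
      tt <- stats::t.test(d)
      res <- tibble::tibble(gate = "parametric", test = "paired_t",
                            statistic = unname(tt$statistic), p = tt$p.value)
    }
  } else {
    dz <- d[d != 0]
    wt <- suppressWarnings(
      stats::wilcox.test(dz, exact = length(dz) <= 25, correct = TRUE))
    res <- tibble::tibble(gate = "nonparametric",
                          test = "wilcoxon_signed_rank",
                          statistic = unname(wt$statistic), p = wt$p.value)
  }
  dplyr::mutate(res, significant = .data$p < alpha, n = length(a))
}

#' Paired TOST equivalence test
#'
#' Two one-sided paired t tests of the mean difference against the lower
#' and upper equivalence bounds (t distribution, n - 1 degrees of
#' freedom); the TOST p-value is the larger of the two one-sided p-values
#' and equivalence is declared when it is below `alpha`.  Zero-variance
#' differences are handled exactly: equivalent iff the constant difference
#' lies strictly inside the bounds.
#'
#' @param a,b Paired numeric vectors, or `b = NULL` to treat `a` as the
#'   differences.
#' @param lower,upper Equivalence bounds on the mean difference
#'   (`lower < upper`), in the feature's native units.
#' @param alphas Significance levels for the equivalence decision.
#' @return One-row tibble: `test`, `lower`, `upper`, `mean_diff`, `p`, and
#'   one logical `equivalent_<alpha>` column per level.
#' @export
tost_equivalence <- function(a, b = NULL, lower = -0.01, upper = 0.01,
                             alphas = c(0.05, 0.1)) {
  stopifnot(lower < upper)
  d <- if (is.null(b)) a else a - b
  stopifnot(length(d) >= 2, !anyNA(d))
  n <- length(d)
  m <- mean(d); s <- stats::sd(d)
  if (s == 0) {
    p <- if (m > lower && m < upper) 0 else 1
  } else {
    se <- s / sqrt(n)
    p_lower <- stats::pt((m - lower) / se, df = n - 1, lower.tail = FALSE)
    p_upper <- stats::pt((m - upper) / se, df = n - 1, lower.tail = TRUE)
    p <- max(p_lower, p_upper)
  }
  out <- tibble::tibble(test = "tost", lower = lower, upper = upper,
                        mean_diff = m, p = p)
  for (al in alphas) out[[paste0("equivalent_", al)]] <- p < al
  out
}

#' Remove outlier pairs by the Tukey rule on the differences
#'
#' Pairs whose difference lies outside
#' `[Q1 - k IQR, Q3 + k IQR]` of the differences are removed from both
#' sources, so both keep the same subjects.
#'
#' @param a,b Paired numeric vectors, n >= 5.
#' @param k IQR multiplier (default 1.5).
#' @return List with `a`, `b`, `kept` (logical index), `n_removed`.
#' @export
remove_outlier_pairs <- function(a, b, k = 1.5) {
  stopifnot(length(a) == length(b), length(a) >= 5)
  d <- a - b
  q <- stats::quantile(d, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  kept <- d >= q[1] - k * iqr & d <= q[2] + k * iqr
  if (sum(kept) < 3) {
    stop_pk("outlier removal would leave fewer than 3 pairs",
            "too_few_pairs")
  }
  list(a = a[kept], b = b[kept], kept = kept, n_removed = sum(!kept))
}

#' Default validation protocol configuration
#'
#' @param alphas Significance levels.
#' @param tost_ladder List of widening `c(lower, upper)` equivalence
#'   bounds, tried in order.
#' @param outlier_k Tukey IQR multiplier for the outlier re-analysis.
#' @param gate_on Normality gate target (see [paired_compare()]).
#' @return A `validation_config` list.
#' @export
validation_config <- function(alphas = c(0.05, 0.1),
                              tost_ladder = list(c(-0.01, 0.01),
                                                 c(-0.05, 0.05),
                                                 c(-0.06, 0.06)),
                              outlier_k = 1.5,
                              gate_on = "sources") {
  structure(list(alphas = sort(alphas), tost_ladder = tost_ladder,
                 outlier_k = outlier_k, gate_on = gate_on),
            class = "validation_config")
}

# Run the full per-feature protocol on paired vectors; returns a one-row
# tibble of every intermediate number.
validate_feature_pair <- function(a, b, config) {
  al <- config$alphas
  d <- a - b
  exact <- all(d == 0)
  row <- tibble::tibble(n = length(a), mean_diff = mean(d),
                        sd_diff = stats::sd(d), exact_agreement = exact)

  if (exact) {
    row <- dplyr::mutate(row, normal_a = NA, normal_b = NA, gate = NA_character_,
                         test = "exact", statistic = NA_real_, p = NA_real_,
                         significant_both = FALSE, outliers_removed = 0L,
                         p_after_outliers = NA_real_)
  } else {
    sa <- try(shapiro_wilk(a, al), silent = TRUE)
    sb <- try(shapiro_wilk(b, al), silent = TRUE)
    cmp <- purrr::map(al, function(x) {
      paired_compare(a, b, alpha = x, gate_on = config$gate_on)
    })
    sig_both <- all(purrr::map_lgl(cmp, "significant"))
    main <- cmp[[1]]
    row <- dplyr::mutate(
      row,
      normal_a = if (inherits(sa, "try-error")) NA else sa$p >= al[1],
      normal_b = if (inherits(sb, "try-error")) NA else sb$p >= al[1],
      gate = main$gate, test = main$test, statistic = main$statistic,
      p = main$p, significant_both = sig_both,
      outliers_removed = 0L, p_after_outliers = NA_real_)
    if (sig_both) {
      trimmed <- remove_outlier_pairs(a, b, k = config$outlier_k)
      redo <- paired_compare(trimmed$a, trimmed$b, alpha = al[1],
                             gate_on = config$gate_on)
      row$outliers_removed <- trimmed$n_removed
      row$p_after_outliers <- redo$p
    }
  }

  # TOST ladder: stop at the first rung equivalent at the stricter level
  tost <- NULL
  for (bounds in config$tost_ladder) {
    tost <- tost_equivalence(d, lower = bounds[1], upper = bounds[2],
                             alphas = al)
    if (tost$p < al[1]) break
  }
  row$tost_lower <- tost$lower
  row$tost_upper <- tost$upper
  row$tost_p <- tost$p
  for (x in al) {
    row[[paste0("equivalent_", x)]] <- tost$p < x
  }
  row
}

#' Validate two feature tables against each other
#'
#' Runs the full agreement protocol feature by feature on two tables of
#' the same subjects measured by two sources (e.g. this package and a
#' reference software): normality-gated paired comparison at every
#' significance level, outlier re-analysis when the difference is
#' significant at all levels, and the TOST equivalence ladder.
#'
#' @param table_a,table_b Data frames with the same `subject_id` rows and
#'   the same numeric feature columns.
#' @param config A [validation_config()].
#' @return A `posture_validation` tibble, one row per feature, with all
#'   intermediate statistics; attribute `config`.
#' @export
validate_feature_tables <- function(table_a, table_b,
                                    config = validation_config()) {
  table_a <- tibble::as_tibble(table_a)
  table_b <- tibble::as_tibble(table_b)
  if ("subject_id" %in% names(table_a) && "subject_id" %in% names(table_b)) {
    if (!identical(table_a$subject_id, table_b$subject_id)) {
      diff <- c(setdiff(table_a$subject_id, table_b$subject_id),
                setdiff(table_b$subject_id, table_a$subject_id))
      stop_pk(paste0("subject mismatch between tables: ",
                     paste(utils::head(unique(diff), 10), collapse = ", ")),
              "subject_mismatch")
    }
  } else if (nrow(table_a) != nrow(table_b)) {
    stop_pk("tables have different numbers of rows and no subject_id column",
            "subject_mismatch")
  }
  feats_a <- names(table_a)[vapply(table_a, is.numeric, logical(1))]
  feats_b <- names(table_b)[vapply(table_b, is.numeric, logical(1))]
  if (!setequal(feats_a, feats_b)) {
    stop_pk(paste0("feature mismatch between tables: ",
                   paste(c(setdiff(feats_a, feats_b),
                           setdiff(feats_b, feats_a)), collapse = ", ")),
            "feature_mismatch")
  }

  rows <- purrr::map(feats_a, function(f) {
    keep <- !is.na(table_a[[f]]) & !is.na(table_b[[f]])
    dplyr::mutate(
      validate_feature_pair(table_a[[f]][keep], table_b[[f]][keep], config),
      feature = f, .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, config = config,
            class = c("posture_validation", class(out)))
}

#' Write a validation report
#'
#' @param report A `posture_validation`.
#' @param json_path,csv_path Optional output paths; each is written only
#'   when non-`NULL`.
#' @return The report, invisibly.
#' @export
write_validation_report <- function(report, json_path = NULL,
                                    csv_path = NULL) {
  stopifnot(inherits(report, "posture_validation"))
  if (!is.null(json_path)) {
    jsonlite::write_json(as.data.frame(report), json_path, auto_unbox = TRUE,
                         digits = NA, na = "null")
  }
  if (!is.null(csv_path)) {
    utils::write.csv(as.data.frame(report), csv_path, row.names = FALSE)
  }
  invisible(report)
}
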