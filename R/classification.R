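# Feature ranking and classifier evaluation.
#
# Three filter rankings (information gain and chi-squared on equal-frequency
# 4-bin discretizations, and ReliefF), two classifiers (LDA and kNN on
# z-scored features with deterministic tie-breaking), two validation
# schemes (stratified 10-fold cross-validation with pooled out-of-fold
# predictions, and a stratified 70/30 split), evaluated as a three-class
# multiclass problem or as a two-level binary cascade (evidence vs none,
# then mild vs moderate-to-severe).

# --- feature ranking -------------------------------------------------------

entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Equal-frequency binning into up to `bins` intervals; constant features
# collapse to a single bin.
equal_freq_bin <- function(x, bins = 4) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                               type = 7, names = FALSE))
  if (length(br) < 2) return(factor(rep(1L, length(x))))
  cut(x, breaks = br, include.lowest = TRUE)
}

info_gain_score <- function(x, y, bins = 4) {
  b <- equal_freq_bin(x, bins)
  hy <- entropy(table(y) / length(y))
  tab <- table(b, y)
  pj <- rowSums(tab) / length(y)
  hcond <- sum(pj * apply(tab, 1, function(r) {
    if (sum(r) == 0) 0 else entropy(r / sum(r))
  }))
  hy - hcond
}

chi2_score <- function(x, y, bins = 4) {
  b <- equal_freq_bin(x, bins)
  if (nlevels(b) < 2) return(NA_real_)
  unname(suppressWarnings(stats::chisq.test(table(b, y))$statistic))
}

# ReliefF weights: for every instance, contrast the k nearest hits with
# the k nearest misses of each other class (miss classes weighted by their
# prior), on min-max scaled features with per-feature absolute difference.
relief_scores <- function(x, y, k = 5) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  rng <- apply(x, 2, function(col) {
    r <- max(col) - min(col)
    if (r == 0) 1 else r
  })
  xs <- sweep(sweep(x, 2, apply(x, 2, min)), 2, rng, `/`)
  d2 <- as.matrix(stats::dist(xs, method = "manhattan"))
  priors <- table(y) / n
  w <- numeric(p)
  for (i in seq_len(n)) {
    same <- which(y == y[i]); same <- same[same != i]
    kh <- same[order(d2[i, same])][seq_len(min(k, length(same)))]
    if (length(kh) > 0) {
      w <- w - colSums(abs(xs[kh, , drop = FALSE] -
                             rep(xs[i, ], each = length(kh)))) /
        (length(kh) * n)
    }
    for (cl in names(priors)) {
      if (cl == as.character(y[i])) next
      miss <- which(y == cl)
      km <- miss[order(d2[i, miss])][seq_len(min(k, length(miss)))]
      if (length(km) == 0) next
      pc <- priors[[cl]] / (1 - priors[[as.character(y[i])]])
      w <- w + pc * colSums(abs(xs[km, , drop = FALSE] -
                                  rep(xs[i, ], each = length(km)))) /
        (length(km) * n)
    }
  }
  w
}

#' Rank features by a filter criterion
#'
#' Ranks every numeric feature column by information gain (class-entropy
#' reduction after equal-frequency 4-bin discretization), the chi-squared
#' statistic of the binned feature-by-class table, or ReliefF weights
#' (k = 5 nearest hits/misses over all instances, min-max scaled
#' features).  Ordering is deterministic; ties break by feature name.
#' Constant features score 0 under information gain and ReliefF and are
#' excluded from the chi-squared ranking with a warning.
#'
#' @param data Tibble with feature columns and a label column.
#' @param method `"info_gain"`, `"chi2"` or `"relief"`.
#' @param label_col Name of the label column.
#' @param bins Number of discretization bins (info gain, chi-squared).
#' @param relief_k Neighbors per class for ReliefF.
#' @return Tibble `feature`, `score`, `rank`, ordered best first.
#' @export
rank_features <- function(data, method = c("info_gain", "chi2", "relief"),
                          label_col = "label", bins = 4, relief_k = 5) {
  method <- match.arg(method)
  y <- factor(data[[label_col]])
  stopifnot(nlevels(droplevels(y)) >= 2)
  feats <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                   label_col)
  stopifnot(length(feats) >= 2)
  x <- data[feats]

  scores <- switch(method,
    info_gain = vapply(x, info_gain_score, numeric(1), y = y, bins = bins),
    chi2 = vapply(x, chi2_score, numeric(1), y = y, bins = bins),
    relief = stats::setNames(relief_scores(x, y, k = relief_k), feats)
  )
  if (method == "chi2" && anyNA(scores)) {
    warn_pk(paste0("constant feature(s) excluded from chi-squared ranking: ",
                   paste(names(scores)[is.na(scores)], collapse = ", ")),
            "constant_feature")
    scores <- scores[!is.na(scores)]
  }
  tibble::tibble(feature = names(scores), score = unname(scores)) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$feature) |>
    dplyr::mutate(rank = dplyr::row_number())
}

#' Fixed feature-set presets
#'
#' Named feature subsets for the three classification problems
#' (multiclass, cascade level 1, cascade level 2), as selected by filter
#' ranking on the original screening study; shipped so its classifier
#' configurations can be reproduced on new data.
#'
#' @param name `"multiclass"`, `"level1"` or `"level2"`.
#' @return Character vector of feature names.
#' @export
feature_set_preset <- function(name = c("multiclass", "level1", "level2")) {
  name <- match.arg(name)
  switch(name,
    multiclass = c("ASA", "AJND_L", "AAD_L", "AAD_R", "PSISHA", "PSISLA_R",
                   "APD_L", "APD_R", "LLC_L"),
    level1 = c("AHA_A", "ASA", "AAD_L", "TKA", "LLA", "PKLA_L", "PKLA_R",
               "APD_L", "APD_R", "PLLL_R", "TKC_L", "LLC_L"),
    level2 = c("ASISLA_R", "AKLA_R", "AAD_L", "AAD_R", "APD_L", "APD_R",
               "LLC_L")
  )
}

# --- model / scheme specs --------------------------------------------------

#' Specify a classifier
#'
#' @param kind `"lda"` or `"knn"`.
#' @param k Neighbor count (kNN only).
#' @param scale Z-score features with statistics fit on the training
#'   portion only.
#' @return A `model_spec` list.
#' @export
model_spec <- function(kind = c("lda", "knn"), k = 5, scale = TRUE) {
  kind <- match.arg(kind)
  if (kind == "knn") stopifnot(k >= 1)
  structure(list(kind = kind, k = if (kind == "knn") as.integer(k) else NULL,
                 scale = scale), class = "model_spec")
}

#' Specify an evaluation scheme
#'
#' @param kind `"cv10"` (stratified 10-fold cross-validation, metrics
#'   pooled over out-of-fold predictions) or `"split70_30"` (stratified
#'   70% train / 30% test split).
#' @param stratified Stratify folds/splits by class.
#' @param seed RNG seed for fold/split assignment.
#' @return An `eval_scheme` list.
#' @export
eval_scheme <- function(kind = c("cv10", "split70_30"), stratified = TRUE,
                        seed = 1L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, folds = if (kind == "cv10") 10L else NULL,
                 train_frac = if (kind == "split70_30") 0.7 else NULL,
                 stratified = stratified, seed = as.integer(seed)),
            class = "eval_scheme")
}

# Deterministic kNN prediction: Euclidean distances, majority vote among
# the k nearest; vote ties break by smaller mean neighbor distance, then
# smaller class index.  Distance ties rank by training-row order.
knn_predict <- function(train_x, train_y, test_x, k) {
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  stopifnot(k >= 1, k < nrow(train_x) + 1)
  lv <- levels(train_y)
  pred <- character(nrow(test_x))
  for (i in seq_len(nrow(test_x))) {
    d <- sqrt(colSums((t(train_x) - test_x[i, ])^2))
    nn <- order(d)[seq_len(min(k, length(d)))]
    votes <- table(factor(train_y[nn], levels = lv))
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1) {
      mean_d <- vapply(top, function(cl) {
        mean(d[nn][train_y[nn] == cl])
      }, numeric(1))
      top <- top[order(mean_d, match(top, lv))][1]
    }
    pred[i] <- top
  }
  factor(pred, levels = lv)
}

# Stratified fold assignment (1..folds) or train/test split flags.
make_partitions <- function(y, scheme) {
  n <- length(y)
  with_preserved_seed(scheme$seed, {
    if (scheme$kind == "cv10") {
      fold <- integer(n)
      if (scheme$stratified) {
        for (cl in levels(y)) {
          idx <- sample(which(y == cl))
          fold[idx] <- rep_len(seq_len(scheme$folds), length(idx))
        }
      } else {
        fold[sample(n)] <- rep_len(seq_len(scheme$folds), n)
      }
      fold
    } else {
      train <- logical(n)
      if (scheme$stratified) {
        for (cl in levels(y)) {
          idx <- sample(which(y == cl))
          n_tr <- max(1L, min(length(idx) - 1L,
                              round(scheme$train_frac * length(idx))))
          train[idx[seq_len(n_tr)]] <- TRUE
        }
      } else {
        train[sample(n, round(scheme$train_frac * n))] <- TRUE
      }
      train
    }
  })
}

fit_predict <- function(train_x, train_y, test_x, model) {
  if (model$scale) {
    mu <- colMeans(train_x)
    sg <- apply(train_x, 2, stats::sd)
    sg[sg == 0] <- 1
    train_x <- sweep(sweep(as.matrix(train_x), 2, mu), 2, sg, `/`)
    test_x <- sweep(sweep(as.matrix(test_x), 2, mu), 2, sg, `/`)
  }
  if (model$kind == "lda") {
    fit <- MASS::lda(as.matrix(train_x), grouping = train_y)
    factor(stats::predict(fit, as.matrix(test_x))$class,
           levels = levels(train_y))
  } else {
    k <- min(model$k, nrow(train_x) - 1L)
    knn_predict(train_x, train_y, test_x, k)
  }
}

metrics_from_confusion <- function(conf) {
  acc <- 100 * sum(diag(conf)) / sum(conf)
  f1 <- vapply(rownames(conf), function(cl) {
    tp <- conf[cl, cl]
    fp <- sum(conf[, cl]) - tp
    fn <- sum(conf[cl, ]) - tp
    if (2 * tp + fp + fn == 0) 0 else 100 * 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  list(accuracy = acc, f1 = f1)
}

#' Train and evaluate a classifier
#'
#' Evaluates `model` on `data` under `scheme`, reporting accuracy and
#' one-vs-rest F1 per class (percentages) from the pooled out-of-sample
#' confusion matrix.  Feature scaling statistics are always fit on the
#' training portion only.
#'
#' @param data Tibble with feature columns and a label column.
#' @param model A [model_spec()].
#' @param scheme An [eval_scheme()].
#' @param features Feature subset to use (default: every numeric column).
#' @param label_col Label column name.
#' @return A `posture_eval` object: `accuracy`, `f1` (named, per class),
#'   `confusion` (true x predicted), `predictions` tibble, `model`,
#'   `scheme`, `f1_zero_division` flag.
#' @export
train_eval <- function(data, model, scheme, features = NULL,
                       label_col = "label") {
  y <- droplevels(factor(data[[label_col]]))
  stopifnot(nlevels(y) >= 2)
  if (is.null(features)) {
    features <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                        label_col)
  }
  x <- as.matrix(data[features])
  stopifnot(!anyNA(x))

  idx_all <- integer(0); pred_all <- character(0)
  if (scheme$kind == "cv10") {
    fold <- make_partitions(y, scheme)
    for (f in sort(unique(fold))) {
      tr <- fold != f; te <- fold == f
      if (nlevels(droplevels(y[tr])) < nlevels(y)) {
        stop_pk("stratification violation: a fold's training part lacks a class",
                "stratification_violation")
      }
      pred <- fit_predict(x[tr, , drop = FALSE], y[tr],
                          x[te, , drop = FALSE], model)
      idx_all <- c(idx_all, which(te))
      pred_all <- c(pred_all, as.character(pred))
    }
  } else {
    tr <- make_partitions(y, scheme)
    if (nlevels(droplevels(y[tr])) < nlevels(y)) {
      stop_pk("stratification violation: the training split lacks a class",
              "stratification_violation")
    }
    pred <- fit_predict(x[tr, , drop = FALSE], y[tr],
                        x[!tr, , drop = FALSE], model)
    idx_all <- which(!tr)
    pred_all <- as.character(pred)
  }

  ord <- order(idx_all)
  predictions <- tibble::tibble(
    row = idx_all[ord],
    truth = y[idx_all[ord]],
    predicted = factor(pred_all[ord], levels = levels(y)))
  conf <- table(truth = predictions$truth, predicted = predictions$predicted)
  conf <- unclass(conf)
  m <- metrics_from_confusion(conf)
  structure(list(accuracy = m$accuracy, f1 = m$f1, confusion = conf,
                 predictions = predictions, model = model, scheme = scheme,
                 features = features,
                 f1_zero_division = any(rowSums(conf) + colSums(conf) == 0)),
            class = "posture_eval")
}

#' @export
print.posture_eval <- function(x, ...) {
  cat(sprintf("<posture_eval> %s, %s\n", x$model$kind, x$scheme$kind))
  cat(sprintf("  accuracy: %.2f%%\n", x$accuracy))
  for (cl in names(x$f1)) cat(sprintf("  F1 %s: %.2f%%\n", cl, x$f1[[cl]]))
  invisible(x)
}

#' Choose kNN neighbor counts by error rate
#'
#' Estimates the classification error under `scheme` for every k in
#' `k_grid` and returns the `n_best` values with the lowest error, ties
#' broken toward smaller k.
#'
#' @param data,scheme,features,label_col As in [train_eval()].
#' @param k_grid Candidate neighbor counts.
#' @param n_best Number of candidates to return.
#' @return Tibble `k`, `error_rate`, best first.
#' @export
knn_k_candidates <- function(data, scheme, k_grid = 1:21, n_best = 5,
                             features = NULL, label_col = "label") {
  n <- nrow(data)
  feasible <- k_grid[k_grid >= 1 & k_grid < n]
  if (length(feasible) < length(k_grid)) {
    warn_pk("some k values are infeasible for the dataset size and were dropped",
            "infeasible_k")
  }
  err <- vapply(feasible, function(k) {
    ev <- train_eval(data, model_spec("knn", k = k), scheme,
                     features = features, label_col = label_col)
    1 - ev$accuracy / 100
  }, numeric(1))
  res <- tibble::tibble(k = feasible, error_rate = err) |>
    dplyr::arrange(.data$error_rate, .data$k)
  if (nrow(res) < n_best) {
    warn_pk(sprintf("only %d feasible k value(s); returning all", nrow(res)),
            "few_k")
    res
  } else {
    res[seq_len(n_best), ]
  }
}

#' Evaluate the two-level binary cascade
#'
#' Level 1 separates evidence (mild and moderate-to-severe merged) from
#' none on all subjects; level 2 separates mild from moderate-to-severe on
#' the truly-with-evidence subjects only.  The combined three-class report
#' chains each subject's level-1 out-of-sample prediction through level 2:
#' subjects predicted `none` stay `none`; subjects predicted `evidence`
#' take their level-2 out-of-sample prediction when they have one,
#' otherwise the prediction of a level-2 model fit on the full evidence
#' subset.
#'
#' @param data Tibble with three-class labels
#'   (`none`/`mild`/`moderate_severe`).
#' @param level1_model,level2_model [model_spec()]s for the two levels.
#' @param scheme An [eval_scheme()] used at both levels.
#' @param level1_features,level2_features Feature subsets per level
#'   (default: all numeric columns).
#' @param label_col Label column name.
#' @param level1_predictor Optional function `(data) -> factor` replacing
#'   the level-1 out-of-sample predictions (diagnostic hook for testing
#'   the chaining logic).
#' @return List with `level1`, `level2` (both `posture_eval`) and
#'   `combined` (three-class `posture_eval`-like list).
#' @export
cascade_evaluate <- function(data, level1_model, level2_model, scheme,
                             level1_features = NULL, level2_features = NULL,
                             label_col = "label",
                             level1_predictor = NULL) {
  y3 <- droplevels(factor(data[[label_col]]))
  stopifnot(all(levels(y3) %in% c("none", "mild", "moderate_severe")),
            nlevels(y3) == 3)

  d1 <- data
  d1[[label_col]] <- factor(ifelse(y3 == "none", "none", "evidence"),
                            levels = c("none", "evidence"))
  ev1 <- train_eval(d1, level1_model, scheme, features = level1_features,
                    label_col = label_col)

  evidence_idx <- which(y3 != "none")
  if (scheme$kind == "cv10" && length(evidence_idx) < 2 * scheme$folds) {
    stop_pk("evidence subset too small for 10-fold cross-validation",
            "scheme_degradation")
  }
  d2 <- data[evidence_idx, ]
  d2[[label_col]] <- droplevels(factor(y3[evidence_idx],
                                       levels = c("mild", "moderate_severe")))
  ev2 <- train_eval(d2, level2_model, scheme, features = level2_features,
                    label_col = label_col)

  # chained three-class predictions
  n <- nrow(data)
  l1_pred <- rep(NA_character_, n)
  if (is.null(level1_predictor)) {
    l1_pred[ev1$predictions$row] <- as.character(ev1$predictions$predicted)
  } else {
    l1_pred <- as.character(level1_predictor(data))
  }
  scored <- which(!is.na(l1_pred))

  l2_oof <- rep(NA_character_, n)
  l2_oof[evidence_idx[ev2$predictions$row]] <-
    as.character(ev2$predictions$predicted)

  feats2 <- ev2$features
  full_l2 <- function(rows) {
    fit_predict(as.matrix(d2[feats2]), d2[[label_col]],
                as.matrix(data[rows, feats2]), level2_model)
  }
  combined <- rep(NA_character_, n)
  for (i in scored) {
    if (l1_pred[i] == "none") {
      combined[i] <- "none"
    } else if (!is.na(l2_oof[i])) {
      combined[i] <- l2_oof[i]
    } else {
      combined[i] <- as.character(full_l2(i))
    }
  }
  truth <- factor(y3[scored], levels = c("none", "mild", "moderate_severe"))
  pred <- factor(combined[scored],
                 levels = c("none", "mild", "moderate_severe"))
  conf <- unclass(table(truth = truth, predicted = pred))
  m <- metrics_from_confusion(conf)
  combined_report <- structure(
    list(accuracy = m$accuracy, f1 = m$f1, confusion = conf,
         predictions = tibble::tibble(row = scored, truth = truth,
                                      predicted = pred),
         model = list(level1 = level1_model, level2 = level2_model),
         scheme = scheme, features = union(ev1$features, ev2$features),
         f1_zero_division = any(rowSums(conf) + colSums(conf) == 0)),
    class = "posture_eval")

  list(level1 = ev1, level2 = ev2, combined = combined_report,
       level2_n = length(evidence_idx))
}
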