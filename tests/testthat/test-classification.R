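# Dataset where one feature carries all the signal (disjoint supports) and
# the rest are noise.
signal_dataset <- function(n = 200, p_noise = 4) {
  half <- n %/% 2
  tibble::tibble(
    signal = c(runif(half, 0, 1), runif(n - half, 2, 3)),
    !!!stats::setNames(
      purrr::map(seq_len(p_noise), ~ rnorm(n)),
      paste0("noise", seq_len(p_noise))),
    label = factor(rep(c("a", "b"), c(half, n - half))))
}

test_that("all three ranking methods put the signal feature first", {
  withr::local_seed(81)
  ds <- signal_dataset()
  for (m in c("info_gain", "chi2", "relief")) {
    r <- rank_features(ds, m)
    expect_equal(r$feature[1], "signal")
    expect_equal(r$rank, seq_len(nrow(r)))
  }
})

test_that("constant features score zero (info gain, relief) or are excluded (chi2)", {
  withr::local_seed(82)
  ds <- signal_dataset(100)
  ds$flat <- 1
  expect_equal(rank_features(ds, "info_gain") |>
                 dplyr::filter(.data$feature == "flat") |>
                 dplyr::pull("score"), 0)
  expect_equal(rank_features(ds, "relief") |>
                 dplyr::filter(.data$feature == "flat") |>
                 dplyr::pull("score"), 0)
  expect_warning(r <- rank_features(ds, "chi2"),
                 class = "posturekit_warning_constant_feature")
  expect_false("flat" %in% r$feature)
})

test_that("a label-independent feature earns near-zero scores on average", {
  withr::local_seed(83)
  ig <- replicate(40, {
    ds <- tibble::tibble(x = rnorm(120), y = rnorm(120),
                         label = factor(rep(c("a", "b"), 60)))
    rank_features(ds, "relief")$score[rank_features(ds, "relief")$feature == "x"]
  })
  expect_lt(abs(mean(ig)), 0.02)
  # chi-squared p-values are roughly uniform: mean near 0.5
  ps <- replicate(60, {
    ds <- tibble::tibble(x = rnorm(100),
                         label = factor(rep(c("a", "b"), 50)))
    ds$filler <- rnorm(100)
    stat <- rank_features(ds, "chi2")$score[1]
    NA
    suppressWarnings(stats::chisq.test(
      table(posturekit:::equal_freq_bin(ds$x, 4), ds$label))$p.value)
  })
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
})

test_that("perfectly separable classes score 100% with 1-NN on a split", {
  withr::local_seed(84)
  ds <- gaussian_classes(c(30, 30), means = c(0, 10), sd = 1)
  ev <- train_eval(ds, model_spec("knn", k = 1),
                   eval_scheme("split70_30", seed = 5))
  expect_equal(ev$accuracy, 100)
  expect_equal(unname(ev$f1), c(100, 100))
})

test_that("kNN predictions match class::knn where no vote ties arise", {
  withr::local_seed(85)
  tr <- gaussian_classes(c(40, 40), means = c(0, 3), sd = 1)
  te <- gaussian_classes(c(15, 15), means = c(0, 3), sd = 1)
  xtr <- as.matrix(tr[c("f1", "f2")]); xte <- as.matrix(te[c("f1", "f2")])
  for (k in c(1, 3, 5)) {     # odd k: no two-class vote ties
    mine <- posturekit:::knn_predict(xtr, tr$label, xte, k)
    ref <- class::knn(xtr, xte, tr$label, k = k)
    expect_equal(as.character(mine), as.character(ref))
  }
})

test_that("kNN with k = 1 reproduces its own training labels", {
  withr::local_seed(86)
  ds <- gaussian_classes(c(25, 25, 25), means = c(0, 2, 4), sd = 1, p = 3)
  x <- as.matrix(ds[paste0("f", 1:3)])
  pred <- posturekit:::knn_predict(x, ds$label, x, k = 1)
  expect_equal(as.character(pred), as.character(ds$label))
})

test_that("accuracy and F1 are exactly recomputable from the confusion matrix", {
  withr::local_seed(87)
  ds <- gaussian_classes(c(20, 25, 16), means = c(0, 1, 2), sd = 1.2, p = 3)
  for (scheme in list(eval_scheme("cv10", seed = 2),
                      eval_scheme("split70_30", seed = 2))) {
    ev <- train_eval(ds, model_spec("knn", k = 5), scheme)
    conf <- ev$confusion
    expect_equal(ev$accuracy, 100 * sum(diag(conf)) / sum(conf),
                 tolerance = 1e-12)
    for (cl in rownames(conf)) {
      tp <- conf[cl, cl]
      fp <- sum(conf[, cl]) - tp
      fn <- sum(conf[cl, ]) - tp
      f1 <- if (2 * tp + fp + fn == 0) 0 else 100 * 2 * tp / (2 * tp + fp + fn)
      expect_equal(unname(ev$f1[cl]), f1, tolerance = 1e-12)
    }
    # confusion rows cover the evaluated subjects
    expect_equal(sum(conf), nrow(ev$predictions))
  }
  # the textbook fixed example: TP 8, FP 2, FN 2 gives F1 = 80%
  expect_equal(100 * 2 * 8 / (2 * 8 + 2 + 2), 80)
})

test_that("cv10 pools out-of-fold predictions over every subject", {
  withr::local_seed(88)
  ds <- gaussian_classes(c(20, 20), means = c(0, 2))
  ev <- train_eval(ds, model_spec("lda"), eval_scheme("cv10", seed = 3))
  expect_equal(sort(ev$predictions$row), 1:40)
  expect_equal(sum(ev$confusion), 40)
})

test_that("evaluation is reproducible under the scheme seed", {
  withr::local_seed(89)
  ds <- gaussian_classes(c(25, 25), means = c(0, 1.5))
  e1 <- train_eval(ds, model_spec("knn", k = 3), eval_scheme("cv10", seed = 7))
  e2 <- train_eval(ds, model_spec("knn", k = 3), eval_scheme("cv10", seed = 7))
  e3 <- train_eval(ds, model_spec("knn", k = 3), eval_scheme("cv10", seed = 8))
  expect_identical(e1$confusion, e2$confusion)
  expect_identical(e1$predictions, e2$predictions)
  expect_false(identical(e1$predictions, e3$predictions))
})

test_that("permuted labels give chance-level three-class accuracy", {
  withr::local_seed(90)
  accs <- replicate(120, {
    ds <- gaussian_classes(c(19, 19, 19), means = c(0, 3, 6))
    ds$label <- sample(ds$label)
    train_eval(ds, model_spec("knn", k = 5),
               eval_scheme("split70_30", seed = sample.int(1e6, 1)))$accuracy
  })
  expect_gt(mean(accs), 25)
  expect_lt(mean(accs), 42)
})

test_that("k candidates come from the error curve with ties toward smaller k", {
  withr::local_seed(91)
  ds <- gaussian_classes(c(30, 30), means = c(0, 8), sd = 0.5)
  kc <- knn_k_candidates(ds, eval_scheme("split70_30", seed = 4),
                         k_grid = 1:15)
  expect_equal(nrow(kc), 5)
  expect_true(1 %in% kc$k)              # 1-NN is perfect here
  expect_equal(kc$error_rate, sort(kc$error_rate))
  # separable data: many ks tie at zero error; ties resolve to smallest
  expect_equal(kc$k[kc$error_rate == 0], sort(kc$k[kc$error_rate == 0]))
  # a 5-value grid comes back whole
  kc5 <- knn_k_candidates(ds, eval_scheme("split70_30", seed = 4),
                          k_grid = c(1, 3, 5, 7, 9))
  expect_setequal(kc5$k, c(1, 3, 5, 7, 9))
  # determinism
  kc2 <- knn_k_candidates(ds, eval_scheme("split70_30", seed = 4),
                          k_grid = 1:15)
  expect_identical(kc, kc2)
})

test_that("the cascade evaluates level 2 on exactly the with-evidence subset", {
  withr::local_seed(92)
  ds <- gaussian_classes(c(16, 25, 16), means = c(0, 4, 8), sd = 1, p = 3,
                         labels = c("none", "mild", "moderate_severe"))
  cas <- cascade_evaluate(ds, model_spec("knn", k = 3),
                          model_spec("knn", k = 3),
                          eval_scheme("split70_30", seed = 6))
  expect_equal(cas$level2_n, 41)
  # stratified split: round(0.3 * 25) + round(0.3 * 16) test subjects
  expect_equal(sum(cas$level2$confusion), 12)
  expect_setequal(rownames(cas$level1$confusion), c("none", "evidence"))
  expect_setequal(rownames(cas$level2$confusion),
                  c("mild", "moderate_severe"))
  expect_setequal(rownames(cas$combined$confusion),
                  c("none", "mild", "moderate_severe"))
})

test_that("a level-1 model that always answers none silences the cascade", {
  withr::local_seed(93)
  ds <- gaussian_classes(c(16, 25, 16), means = c(0, 3, 6), p = 2,
                         labels = c("none", "mild", "moderate_severe"))
  cas <- cascade_evaluate(
    ds, model_spec("knn", k = 3), model_spec("knn", k = 3),
    eval_scheme("split70_30", seed = 6),
    level1_predictor = function(data) {
      factor(rep("none", nrow(data)), levels = c("none", "evidence"))
    })
  expect_true(all(cas$combined$predictions$predicted == "none"))
})

test_that("well-separated classes give the cascade high combined accuracy", {
  withr::local_seed(94)
  ds <- gaussian_classes(c(16, 25, 16), means = c(0, 6, 12), sd = 1, p = 3,
                         labels = c("none", "mild", "moderate_severe"))
  cas <- cascade_evaluate(ds, model_spec("knn", k = 3),
                          model_spec("knn", k = 3),
                          eval_scheme("cv10", seed = 6))
  multi <- train_eval(ds, model_spec("knn", k = 3),
                      eval_scheme("cv10", seed = 6))
  expect_gte(cas$combined$accuracy, 95)
  expect_gte(multi$accuracy, 95)
})

test_that("feature-set presets carry the published configurations", {
  expect_length(feature_set_preset("multiclass"), 9)
  expect_length(feature_set_preset("level1"), 12)
  expect_length(feature_set_preset("level2"), 7)
  expect_true(all(unlist(purrr::map(c("multiclass", "level1", "level2"),
                                    feature_set_preset)) %in%
                    feature_names()))
})

test_that("tidy and glance summarize evaluations", {
  withr::local_seed(95)
  ds <- gaussian_classes(c(20, 20), means = c(0, 4))
  ev <- train_eval(ds, model_spec("lda"), eval_scheme("split70_30", seed = 1))
  td <- generics::tidy(ev)
  expect_equal(td$class, rownames(ev$confusion))
  gl <- generics::glance(ev)
  expect_equal(gl$accuracy, ev$accuracy)
  expect_equal(gl$model, "lda")
})
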