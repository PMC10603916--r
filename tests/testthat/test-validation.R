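test_that("Shapiro-Wilk wrapper decides by p >= alpha and rejects constants", {
  withr::local_seed(61)
  x <- rnorm(50)
  sw <- shapiro_wilk(x)
  ref <- stats::shapiro.test(x)
  expect_equal(sw$statistic, unname(ref$statistic))
  expect_equal(sw$p, ref$p.value)
  expect_equal(sw$normal_0.05, ref$p.value >= 0.05)
  expect_error(shapiro_wilk(rep(1, 20)),
               class = "posturekit_error_zero_variance")
  expect_error(shapiro_wilk(1:2), class = "posturekit_error_bad_sample")
})

test_that("the normality gate selects t for normal and Wilcoxon for uniform data", {
  withr::local_seed(62)
  a <- rnorm(57); b <- a + rnorm(57, 0, 0.5)
  expect_equal(paired_compare(a, b)$test, "paired_t")
  # uniform sources fail Shapiro-Wilk at n = 57 with high probability
  n_wilcox <- 0
  for (i in 1:20) {
    u1 <- runif(57); u2 <- runif(57)
    n_wilcox <- n_wilcox + (paired_compare(u1, u2)$test ==
                              "wilcoxon_signed_rank")
  }
  expect_gte(n_wilcox, 15)
})

test_that("paired tests agree with direct-formula oracles to 1e-9", {
  withr::local_seed(63)
  for (i in 1:100) {
    n <- sample(10:80, 1)
    a <- rnorm(n); b <- a + rnorm(n, 0.05, 0.3)
    d <- a - b
    # force each branch via gate_on = differences on constructed data
    res_t <- paired_compare(a, b, gate_on = "differences")
    if (res_t$test == "paired_t") {
      tstat <- mean(d) / (sd(d) / sqrt(n))
      pref <- 2 * stats::pt(-abs(tstat), n - 1)
      expect_equal(res_t$statistic, tstat, tolerance = 1e-9)
      expect_equal(res_t$p, pref, tolerance = 1e-9)
    } else {
      dz <- d[d != 0]
      r <- rank(abs(dz))
      v <- sum(r[dz > 0])
      expect_equal(res_t$statistic, v, tolerance = 1e-9)
      if (length(dz) > 25) {
        nn <- length(dz)
        mu <- nn * (nn + 1) / 4
        sig <- sqrt(nn * (nn + 1) * (2 * nn + 1) / 24)
        z <- v - mu
        pref <- 2 * min(stats::pnorm((z - 0.5 * sign(z)) / sig),
                        1 - stats::pnorm((z - 0.5 * sign(z)) / sig))
        expect_equal(res_t$p, min(1, pref), tolerance = 1e-9)
      }
    }
  }
})

test_that("the exact signed-rank null is used at small n", {
  withr::local_seed(64)
  d <- rnorm(12, 0.4, 1)
  a <- rnorm(12); b <- a - d
  res <- paired_compare(a, b, gate_on = "differences")
  if (res$test == "wilcoxon_signed_rank") {
    ref <- stats::wilcox.test(d, exact = TRUE)
    expect_equal(res$p, ref$p.value, tolerance = 1e-12)
  }
  # identical samples: degenerate, surfaced as an error
  expect_error(paired_compare(a, a),
               class = "posturekit_error_degenerate_differences")
})

test_that("type-I rate of the gated comparison is near nominal at n = 57", {
  withr::local_seed(65)
  hits <- 0; reps <- 400
  for (i in seq_len(reps)) {
    a <- rnorm(57); b <- a + rnorm(57, 0, 0.4)   # true shift zero
    hits <- hits + paired_compare(a, b, alpha = 0.05)$significant
  }
  expect_gt(hits / reps, 0.02)
  expect_lt(hits / reps, 0.09)
})

test_that("TOST declares equivalence for tight data and not at a boundary", {
  # identically zero differences: equivalent at both levels
  res0 <- tost_equivalence(rep(0, 30), lower = -0.05, upper = 0.05)
  expect_true(res0$equivalent_0.05 && res0$equivalent_0.1)
  # constant difference outside the bounds: not equivalent
  res1 <- tost_equivalence(rep(0.2, 30), lower = -0.05, upper = 0.05)
  expect_false(res1$equivalent_0.05)
  # mean exactly at the upper bound: one-sided p near 0.5
  withr::local_seed(66)
  d <- rnorm(500, 0, 1); d <- d - mean(d) + 0.05
  res2 <- tost_equivalence(d, lower = -0.05, upper = 0.05)
  expect_equal(res2$p, 0.5, tolerance = 0.01)
  expect_false(res2$equivalent_0.05)
})

test_that("TOST p never increases along the widening boundary ladder", {
  withr::local_seed(67)
  ladder <- list(c(-0.01, 0.01), c(-0.05, 0.05), c(-0.06, 0.06))
  for (i in 1:50) {
    d <- rnorm(sample(10:80, 1), rnorm(1, 0, 0.05), runif(1, 0.01, 0.3))
    ps <- vapply(ladder, function(b) {
      tost_equivalence(d, lower = b[1], upper = b[2])$p
    }, numeric(1))
    expect_true(all(diff(ps) <= 1e-12))
  }
})

test_that("outlier removal follows the Tukey fences on the differences", {
  a <- c(rep(0.01, 9), 5); b <- rep(0, 10)
  out <- remove_outlier_pairs(a, b)
  expect_equal(out$n_removed, 1)
  expect_equal(length(out$a), 9)
  expect_false(5 %in% out$a)
  # quartile oracle
  d <- a - b
  q <- stats::quantile(d, c(0.25, 0.75), names = FALSE)
  fence <- c(q[1] - 1.5 * (q[2] - q[1]), q[2] + 1.5 * (q[2] - q[1]))
  expect_equal(out$kept, d >= fence[1] & d <= fence[2])
  # all-equal differences: nothing removed
  expect_equal(remove_outlier_pairs(1:10, (1:10) - 2)$n_removed, 0)
  # permutation invariance of the surviving subjects
  withr::local_seed(68)
  a2 <- rnorm(30); b2 <- a2 + c(rnorm(28, 0, 0.01), 3, -4)
  perm <- sample(30)
  o1 <- remove_outlier_pairs(a2, b2)
  o2 <- remove_outlier_pairs(a2[perm], b2[perm])
  expect_equal(sort(o1$a), sort(o2$a))
  expect_error(remove_outlier_pairs(1:4, 2:5))   # needs n >= 5
})

test_that("near-identical tables validate as equivalent at +/-0.05", {
  withr::local_seed(69)
  n <- 30
  ta <- tibble::as_tibble(as.data.frame(matrix(rnorm(n * 6, 10, 3), n)))
  names(ta) <- paste0("f", 1:6)
  ta$subject_id <- sprintf("S%02d", 1:n)
  tb <- ta
  tb[paste0("f", 1:6)] <- tb[paste0("f", 1:6)] +
    matrix(rnorm(n * 6, 0, 0.002), n)
  rep <- validate_feature_tables(ta, tb)
  expect_s3_class(rep, "posture_validation")
  expect_true(all(rep$equivalent_0.05))
  expect_true(all(rep$tost_upper <= 0.05 + 1e-12))
})

test_that("a systematic 0.2 shift is significant and never equivalent at 0.06", {
  withr::local_seed(70)
  n <- 40
  ta <- tibble::as_tibble(as.data.frame(matrix(rnorm(n * 4, 50, 5), n)))
  names(ta) <- paste0("f", 1:4)
  tb <- ta
  tb[] <- tb[] + 0.2 + matrix(rnorm(n * 4, 0, 0.02), n)
  rep <- validate_feature_tables(ta, tb)
  expect_true(all(rep$significant_both))
  expect_true(all(!rep$equivalent_0.05))
  expect_true(all(rep$tost_upper == 0.06))     # ladder exhausted
  expect_true(all(rep$outliers_removed >= 0))
  expect_true(all(!is.na(rep$p_after_outliers)))
})

test_that("identical tables exercise the exact-agreement branch", {
  ta <- tibble::tibble(f1 = rnorm(20), f2 = runif(20))
  rep <- validate_feature_tables(ta, ta)
  expect_true(all(rep$exact_agreement))
  expect_true(all(rep$test == "exact"))
  expect_true(all(rep$equivalent_0.05))        # 0 inside (-0.01, 0.01)
})

test_that("mismatched tables are rejected with a diagnosis", {
  ta <- tibble::tibble(subject_id = c("a", "b", "c"), f1 = 1:3)
  tb <- tibble::tibble(subject_id = c("a", "b", "d"), f1 = 1:3)
  err <- tryCatch(validate_feature_tables(ta, tb), error = identity)
  expect_s3_class(err, "posturekit_error_subject_mismatch")
  expect_match(conditionMessage(err), "d")
  tc <- tibble::tibble(subject_id = c("a", "b", "c"), f2 = 1:3)
  expect_error(validate_feature_tables(ta, tc),
               class = "posturekit_error_feature_mismatch")
})

test_that("validation reports serialize to JSON and CSV", {
  ta <- tibble::tibble(f1 = rnorm(20), f2 = rnorm(20))
  tb <- ta + 0.001
  rep <- validate_feature_tables(ta, tb)
  jp <- withr::local_tempfile(fileext = ".json")
  cp <- withr::local_tempfile(fileext = ".csv")
  write_validation_report(rep, json_path = jp, csv_path = cp)
  expect_true(file.exists(jp) && file.exists(cp))
  back <- jsonlite::fromJSON(jp)
  expect_equal(back$feature, rep$feature)
  expect_equal(back$tost_p, rep$tost_p, tolerance = 1e-12)
})
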